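# Simulated radiographic projections.

#' Render a simulated radiograph of a tissue state
#'
#' Line-integrates a radiographic density proxy through the voxel grid:
#' per cell `rho = sum_t c_t * rho_t` (nail cells take `rho_nail`), summed
#' along the projection axis and linearly rescaled to 8 bits.  The `ap`
#' (anteroposterior) view projects along +x, the `ml` (mediolateral) view
#' along +y; image rows run from proximal (top) to distal (bottom).
#'
#' @param state A `tissue_state`.
#' @param model The `voxel_model`.
#' @param axis `"ap"` or `"ml"`.
#' @param densities Named density proxies for `lamellar`, `woven`,
#'   `cartilage`, `fibrous` and `nail`.
#' @return An integer matrix of gray levels in `[0, 255]` (class
#'   `sim_projection`), rows = axial position, columns = transverse
#'   position.
#' @export
render_projection <- function(state, model, axis = c("ap", "ml"),
                              densities = c(lamellar = 1.0, woven = 0.6,
                                            cartilage = 0.1, fibrous = 0.05,
                                            nail = 2.0)) {
  axis <- match.arg(axis)
  rho <- state$lamellar * densities[["lamellar"]] +
    state$woven * densities[["woven"]] +
    state$cartilage * densities[["cartilage"]] +
    state$fibrous * densities[["fibrous"]]
  rho[model$region == .REGION[["nail"]]] <- densities[["nail"]]
  a <- array(rho, model$dims)
  proj <- if (axis == "ap") apply(a, c(2, 3), sum) else apply(a, c(1, 3), sum)
  # rows: z from proximal (top) to distal; columns: y (ap) or x (ml)
  img <- t(proj)[rev(seq_len(model$dims[3])), , drop = FALSE]
  mx <- max(img)
  gray <- if (mx > 0) round(img / mx * 255) else img * 0
  structure(matrix(as.integer(gray), nrow(img), ncol(img)),
            class = "sim_projection", axis = axis)
}

#' Write a projection image as PNG
#'
#' @param img A `sim_projection` (or any integer matrix of gray levels).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_projection_png <- function(img, path) {
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}
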