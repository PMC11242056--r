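# Cortical bridging detection and outcome classification.

#' Is a quadrant bridged by lamellar bone?
#'
#' Runs a path search over the cell lattice: the quadrant is bridged when a
#' connected path of cells with lamellar fraction >= `c_min` joins any
#' fragment-0 cortical cell to any fragment-1 cortical cell, restricted to
#' the quadrant's bone and healing-domain cells (periosteal callus beyond
#' the original cortex counts).  Face (6) connectivity is the conservative
#' default - a shared face is a load path; full 26-connectivity is
#' available as a flag.
#'
#' @param state A `tissue_state`.
#' @param model A `voxel_model` with quadrants assigned.
#' @param quadrant `"anterior"`, `"posterior"`, `"medial"` or `"lateral"`.
#' @param c_min Lamellar-fraction threshold in `(0, 1]` (default 0.5).
#' @param connectivity 6 (faces) or 26 (faces, edges and corners).
#' @return `TRUE` if the quadrant is bridged.
#' @export
is_bridged <- function(state, model, quadrant, c_min = 0.5,
                       connectivity = 6) {
  stopifnot(c_min > 0, c_min <= 1)
  qc <- quadrant_code(quadrant)
  searchable <- model$region %in% .REGION[c("cortical", "cancellous",
                                            "healing_domain")] &
    model$quadrant == qc
  pass <- searchable & state$lamellar >= c_min
  cortical <- model$region == .REGION[["cortical"]] |
    model$region == .REGION[["cancellous"]]
  seeds <- which(pass & cortical & model$fragment == 0L)
  targets <- which(pass & cortical & model$fragment == 1L)
  if (length(seeds) == 0 || length(targets) == 0) return(FALSE)
  cpp_path_connected(model$dims, pass, seeds, targets, connectivity == 26)
}

#' Bridged status of all four quadrants
#'
#' @inheritParams is_bridged
#' @return Named logical vector over anterior, posterior, medial, lateral.
#' @export
bridged_quadrants <- function(state, model, c_min = 0.5, connectivity = 6) {
  qs <- c("anterior", "posterior", "medial", "lateral")
  vapply(qs, function(q) is_bridged(state, model, q, c_min, connectivity),
         logical(1))
}

#' Classify union versus non-union from a bridging timeline
#'
#' A case is a union when on some day within the horizon at least three of
#' the four quadrants are simultaneously bridged; the consolidation day is
#' the first such day.  Otherwise the case is a non-union.
#'
#' @param timeline A logical matrix or data frame with one row per day and
#'   one column per quadrant (a `healing_run` timeline's `bridged_*`
#'   columns are accepted directly).
#' @param horizon Number of simulated days the verdict refers to; rows
#'   beyond it are ignored.  Defaults to the number of rows.
#' @param min_quadrants Quadrants that must be bridged simultaneously
#'   (default 3).
#' @return A list with `outcome` (`"union"` or `"non_union"`),
#'   `consolidation_day` (integer or `NA`), and `max_bridged` (the largest
#'   simultaneous bridged count observed).
#' @export
classify_outcome <- function(timeline, horizon = NULL, min_quadrants = 3L) {
  if (is.data.frame(timeline)) {
    cols <- grep("^bridged_", names(timeline), value = TRUE)
    if (length(cols) > 0) {
      days <- if ("day" %in% names(timeline)) timeline$day else seq_len(nrow(timeline))
      m <- as.matrix(timeline[cols])
    } else {
      m <- as.matrix(timeline)
      days <- seq_len(nrow(m))
    }
  } else {
    m <- as.matrix(timeline)
    days <- seq_len(nrow(m))
  }
  if (nrow(m) == 0) stop("empty bridging timeline")
  if (is.null(horizon)) horizon <- max(days)
  keep <- days <= horizon
  m <- m[keep, , drop = FALSE]
  days <- days[keep]
  if (nrow(m) == 0) stop("bridging timeline has no days within the horizon")
  nb <- rowSums(m)
  hit <- which(nb >= min_quadrants)
  list(outcome = if (length(hit) > 0) "union" else "non_union",
       consolidation_day = if (length(hit) > 0) as.integer(days[hit[1]]) else
         NA_integer_,
       max_bridged = as.integer(max(nb)))
}

#' Interfragmentary mechanics metrics
#'
#' From a displacement solution: the maximum distortional strain over the
#' interfragmentary gap cells, the mean relative displacement between the
#' gap faces of fragment 1 and fragment 0 (mm), and the angulation between
#' the least-squares longitudinal axes of the two displaced fragments
#' (degrees).  Fragment geometry is never updated; the angulation is a
#' reported indicator of axial deviation under load.
#'
#' @param model A `voxel_model`.
#' @param u Nodal displacements from [solve_displacements()].
#' @param strains Optional precomputed [compute_strains()] result.
#' @return A list with `gap_strain_max`, `rel_disp_mm`, `angulation_deg`.
#' @export
interfragmentary_metrics <- function(model, u, strains = NULL) {
  if (is.null(strains)) strains <- compute_strains(model, u)
  gap_strain_max <- if (any(model$gap_cell))
    max(strains$distortional[model$gap_cell]) else 0

  ucell <- cell_mean_displacement(model, u)
  face0 <- gap_face_cells(model, 0L)
  face1 <- gap_face_cells(model, 1L)
  rel <- if (length(face0) > 0 && length(face1) > 0) {
    d <- colMeans(ucell[face1, , drop = FALSE]) -
      colMeans(ucell[face0, , drop = FALSE])
    sqrt(sum(d^2))
  } else 0

  ang <- fragment_angulation(model, ucell)
  list(gap_strain_max = gap_strain_max, rel_disp_mm = rel,
       angulation_deg = ang)
}

# mean of the eight nodal displacements per cell, for active cells only;
# rows for inactive cells are zero
cell_mean_displacement <- function(model, u) {
  fem <- fem_setup(model)
  ncell <- prod(model$dims)
  out <- matrix(0, ncell, 3)
  for (c in 1:3) {
    s <- numeric(nrow(fem$conn))
    for (a in 1:8) s <- s + u[fem$conn[, a], c]
    out[fem$active_cells, c] <- s / 8
  }
  out
}

# bone cells of a fragment that share a face with an interfragmentary cell
gap_face_cells <- function(model, fragment) {
  dims <- model$dims
  gap <- array(model$gap_cell, dims)
  nb <- array(FALSE, dims)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  nb[-nx, , ] <- nb[-nx, , ] | gap[-1, , ]
  nb[-1, , ] <- nb[-1, , ] | gap[-nx, , ]
  nb[, -ny, ] <- nb[, -ny, ] | gap[, -1, ]
  nb[, -1, ] <- nb[, -1, ] | gap[, -ny, ]
  nb[, , -nz] <- nb[, , -nz] | gap[, , -1]
  nb[, , -1] <- nb[, , -1] | gap[, , -nz]
  which(as.vector(nb) & model$fragment == fragment &
          model$region %in% .REGION[c("cortical", "cancellous")])
}

# angle (degrees) between the least-squares longitudinal axes of the two
# displaced main fragments.  Each axis is fit through the displaced
# per-slice centroids of the fragment's bone cells, so the tubular
# cross-section does not dominate the fit.
fragment_angulation <- function(model, ucell) {
  ctr <- cell_centers(model)
  nxy <- prod(model$dims[1:2])
  iz <- rep(seq_len(model$dims[3]), each = nxy)
  axis_of <- function(fragment) {
    cells <- which(model$fragment == fragment &
                     model$region %in% .REGION[c("cortical", "cancellous")])
    if (length(cells) < 3) return(NULL)
    pts <- ctr[cells, , drop = FALSE] + ucell[cells, , drop = FALSE]
    layer <- iz[cells]
    cent <- do.call(rbind, lapply(split(seq_along(layer), layer),
                                  function(i) colMeans(pts[i, , drop = FALSE])))
    if (nrow(cent) < 2) return(NULL)
    sv <- svd(sweep(cent, 2, colMeans(cent)), nu = 0, nv = 1)
    sv$v[, 1]
  }
  a0 <- axis_of(0L); a1 <- axis_of(1L)
  if (is.null(a0) || is.null(a1)) return(0)
  cosang <- abs(sum(a0 * a1))
  acos(pmin(1, cosang)) * 180 / pi
}
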