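#' Material table for tissues and implant
#'
#' Young's moduli (MPa) and Poisson ratios per tissue, the nail material,
#' and the exponent of the tissue-mixture rule.  Defaults are in line with
#' the tissue-differentiation modeling literature: lamellar bone 10000 MPa,
#' woven bone 4000 MPa, cartilage 10 MPa, fibrous connective tissue 3 MPa,
#' all with Poisson ratio 0.3, and a titanium nail at 110000 MPa.
#'
#' @param E_lamellar,E_woven,E_cartilage,E_fibrous Tissue moduli (MPa).
#' @param nu_lamellar,nu_woven,nu_cartilage,nu_fibrous Tissue Poisson ratios.
#' @param E_nail,nu_nail Nail material constants.
#' @param E_locking,nu_locking Effective constants of the interlocking
#'   interface ring (screws plus peri-implant bone).  The default is in the
#'   cancellous-bone range and sets the axial stiffness of the locked
#'   construct to the order measured for intramedullary nail fixations,
#'   which rigid bonding would overestimate by orders of magnitude.
#' @param mixture_exponent Exponent `p` of the mixture rule
#'   `E = (sum_t c_t * E_t^(1/p))^p`; `p = 1` is the linear rule of mixtures.
#' @return An object of class `material_table`.
#' @export
material_table <- function(E_lamellar = 10000, E_woven = 4000,
                           E_cartilage = 10, E_fibrous = 3,
                           nu_lamellar = 0.3, nu_woven = 0.3,
                           nu_cartilage = 0.3, nu_fibrous = 0.3,
                           E_nail = 110000, nu_nail = 0.3,
                           E_locking = 1000, nu_locking = 0.3,
                           mixture_exponent = 1) {
  tab <- structure(list(
    E_lamellar = E_lamellar, E_woven = E_woven, E_cartilage = E_cartilage,
    E_fibrous = E_fibrous, nu_lamellar = nu_lamellar, nu_woven = nu_woven,
    nu_cartilage = nu_cartilage, nu_fibrous = nu_fibrous,
    E_nail = E_nail, nu_nail = nu_nail,
    E_locking = E_locking, nu_locking = nu_locking,
    mixture_exponent = mixture_exponent
  ), class = "material_table")
  E <- tissue_E(tab)
  nu <- c(tissue_nu(tab), nail = nu_nail, locking = nu_locking)
  if (any(c(E, E_nail, E_locking) <= 0)) stop("all moduli must be > 0")
  if (any(nu <= 0 | nu >= 0.5)) stop("Poisson ratios must lie in (0, 0.5)")
  tab
}

tissue_E <- function(table) {
  c(lamellar = table$E_lamellar, woven = table$E_woven,
    cartilage = table$E_cartilage, fibrous = table$E_fibrous)
}

tissue_nu <- function(table) {
  c(lamellar = table$nu_lamellar, woven = table$nu_woven,
    cartilage = table$nu_cartilage, fibrous = table$nu_fibrous)
}

#' Per-cell elastic properties from the tissue composition
#'
#' Young's modulus follows the mixture rule
#' `E = (sum_t c_t * E_t^(1/p))^p` with `p = mixture_exponent` (the linear
#' rule of mixtures for `p = 1`); the Poisson ratio is the fraction-weighted
#' average.  Nail cells take the nail constants.  Cells without tissue
#' (outside) get `NA`; they carry no elements.
#'
#' @param state A `tissue_state`.
#' @param table A [material_table()].
#' @param model The `voxel_model` the state lives on.
#' @return A list with per-cell numeric vectors `E` (MPa) and `nu`.
#' @export
mixture_properties <- function(state, table, model) {
  Et <- tissue_E(table); nut <- tissue_nu(table)
  p <- table$mixture_exponent
  comp <- cbind(state$lamellar, state$woven, state$cartilage, state$fibrous)
  tot <- rowSums(comp)
  E <- nu <- rep(NA_real_, length(tot))
  has <- tot > 0
  if (p == 1) {
    E[has] <- comp[has, , drop = FALSE] %*% Et
  } else {
    E[has] <- (comp[has, , drop = FALSE] %*% (Et^(1 / p)))^p
  }
  nu[has] <- (comp[has, , drop = FALSE] %*% nut) / tot[has]
  nail <- model$region == .REGION[["nail"]]
  E[nail] <- table$E_nail
  nu[nail] <- table$nu_nail
  if (!is.null(model$lock_cell) && any(model$lock_cell)) {
    E[model$lock_cell] <- table$E_locking
    nu[model$lock_cell] <- table$nu_locking
  }
  list(E = E, nu = nu)
}

#' Physiological load case for a bone type
#'
#' Tibia: peak gait-cycle load of 2.2 x body weight, split 55% / 45% over
#' the medial and lateral plateau patches, applied axially in compression.
#' Femur: a single resultant of `peak_multiplier` x body weight on the
#' proximal patch (default 2.38, standing in for the instrumented-hip
#' muscle/joint load sets).  The load is scaled by the weight-bearing
#' fraction and applied as the static daily peak.
#'
#' @param bone_type `"tibia"` or `"femur"`.
#' @param body_weight Body weight (N), > 0.
#' @param weight_bearing Weight-bearing fraction in `[0, 1]`.
#' @param peak_multiplier Femoral peak-load multiple of body weight.
#' @return An object of class `load_case` with `total_peak_force` (N),
#'   `patch_split` (fractions summing to 1), a unit `direction`, and the
#'   `weight_bearing` fraction.
#' @examples
#' lc <- build_load_case("tibia", body_weight = 800, weight_bearing = 1)
#' lc$total_peak_force                      # 1760 N
#' lc$total_peak_force * lc$patch_split     # medial 968 N, lateral 792 N
#' @export
build_load_case <- function(bone_type, body_weight, weight_bearing,
                            peak_multiplier = 2.38) {
  if (!(body_weight > 0)) stop("body_weight must be > 0")
  if (weight_bearing < 0 || weight_bearing > 1)
    stop("weight_bearing must lie in [0, 1]")
  if (bone_type == "tibia") {
    total <- 2.2 * body_weight * weight_bearing
    split <- c(medial = 0.55, lateral = 0.45)
  } else if (bone_type == "femur") {
    total <- peak_multiplier * body_weight * weight_bearing
    split <- c(axial = 1)
  } else {
    stop("unknown bone_type: ", bone_type)
  }
  load_case(total, split, c(0, 0, -1), weight_bearing)
}

#' Construct a load case directly
#'
#' @param total_peak_force Total peak force (N).
#' @param patch_split Named fractions per load patch, summing to 1.
#' @param direction Load direction (unit vector; normalized if not).
#' @param weight_bearing Weight-bearing fraction recorded on the case.
#' @return A `load_case`.
#' @export
load_case <- function(total_peak_force, patch_split = c(axial = 1),
                      direction = c(0, 0, -1), weight_bearing = 1) {
  if (abs(sum(patch_split) - 1) > 1e-12)
    stop("patch_split fractions must sum to 1")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be non-zero")
  structure(list(total_peak_force = total_peak_force,
                 patch_split = patch_split,
                 direction = direction / nrm,
                 weight_bearing = weight_bearing),
            class = "load_case")
}

#' @export
print.load_case <- function(x, ...) {
  cat(sprintf("<load_case> total %g N, weight-bearing %.0f%%\n",
              x$total_peak_force, 100 * x$weight_bearing))
  cat("  patches:", paste(sprintf("%s=%.0f%%", names(x$patch_split),
                                  100 * x$patch_split), collapse = " "), "\n")
  invisible(x)
}
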