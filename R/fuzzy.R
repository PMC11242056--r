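# Fuzzy mechano-regulation of tissue differentiation.
#
# The distortional (octahedral shear) strain is the primary stimulus,
# partitioned into five categories by trapezoidal memberships; a signed
# dilatational (volumetric) category gates chondrogenesis on compression.
# The strain windows follow the Claes-Heigele tissue-differentiation
# hypothesis; rule activations use Mamdani min-AND and additive
# aggregation, defuzzified as rate-scaled daily tissue transfers.

#' Fuzzy rule set: strain windows, rates and vascular parameters
#'
#' All strain breakpoints are dimensionless; transitions between adjacent
#' distortional categories are linear crossfades over a shoulder of width
#' `shoulder` x breakpoint, centered on the breakpoint (so at a breakpoint
#' both neighboring memberships equal 0.5, and the memberships always sum
#' to 1).  Rates are per day.
#'
#' Category boundaries on the distortional strain:
#' understimulated < `eta_min` < low < `low_hi` < moderate < `mid_hi`
#' < high < `destroy_hi` < excessive.  Dilatational categories are
#' compressive (below `compress_thresh`), neutral, and tensile (mirrored).
#'
#' @param low_hi Upper edge of the low-strain (intramembranous) window.
#' @param mid_hi Upper edge of the moderate (chondrogenic) window.
#' @param destroy_hi Lower edge of the excessive (destructive) window.
#' @param compress_thresh Dilatational compression threshold (signed).
#' @param shoulder Relative shoulder width of the membership crossfades.
#' @param k_woven Intramembranous woven-bone formation rate (1/day).
#' @param k_chondro Chondrogenesis rate (1/day).
#' @param k_endo Endochondral ossification rate (1/day).
#' @param k_remodel Woven-to-lamellar remodeling rate (1/day).
#' @param k_resorb Atrophic resorption rate under understimulation (1/day).
#' @param k_destroy Tissue destruction rate under excessive strain (1/day).
#' @param v_rate Vascular front speed (mm/day).
#' @param gamma_angio Distortional strain above which angiogenesis stalls.
#' @param v_min Minimum vascularity required for ossification.
#' @param eta_min Understimulation floor on the distortional strain.
#' @return An object of class `fuzzy_ruleset`.
#' @export
fuzzy_rules <- function(low_hi = 0.05, mid_hi = 0.15, destroy_hi = 0.30,
                        compress_thresh = -0.002, shoulder = 0.2,
                        k_woven = 0.03, k_chondro = 0.05, k_endo = 0.04,
                        k_remodel = 0.02, k_resorb = 0.01, k_destroy = 0.10,
                        v_rate = 0.3, gamma_angio = 0.06, v_min = 0.5,
                        eta_min = 5e-4) {
  rules <- structure(list(
    low_hi = low_hi, mid_hi = mid_hi, destroy_hi = destroy_hi,
    compress_thresh = compress_thresh, shoulder = shoulder,
    k_woven = k_woven, k_chondro = k_chondro, k_endo = k_endo,
    k_remodel = k_remodel, k_resorb = k_resorb, k_destroy = k_destroy,
    v_rate = v_rate, gamma_angio = gamma_angio, v_min = v_min,
    eta_min = eta_min
  ), class = "fuzzy_ruleset")
  if (!(0 < eta_min && eta_min < low_hi && low_hi < mid_hi &&
        mid_hi < destroy_hi))
    stop("strain breakpoints must satisfy 0 < eta_min < low_hi < mid_hi < destroy_hi")
  rates <- unlist(rules[c("k_woven", "k_chondro", "k_endo", "k_remodel",
                          "k_resorb", "k_destroy", "v_rate")])
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (compress_thresh >= 0) stop("compress_thresh must be negative")
  rules
}

# fraction of the crossfade completed at x for a boundary at b with
# relative shoulder width s: 0 below 0.9 b, 1 above 1.1 b (for s = 0.2)
.ramp_up <- function(x, b, s) {
  w <- s * abs(b)
  if (w == 0) return(as.numeric(x >= b))
  pmin(1, pmax(0, (x - (b - w / 2)) / w))
}

#' Fuzzify a strain field into stimulus memberships
#'
#' Evaluates the per-cell membership degrees of the distortional strain
#' categories (understimulated, low, moderate, high, excessive; a partition
#' of unity) and the dilatational categories (compressive, neutral,
#' tensile).
#'
#' @param strains A `strain_field`.
#' @param rules A [fuzzy_rules()] set.
#' @return An object of class `stimulus_summary`: list of per-cell
#'   membership vectors.
#' @export
fuzzify <- function(strains, rules) {
  d <- strains$distortional
  r1 <- .ramp_up(d, rules$eta_min, rules$shoulder)
  r2 <- .ramp_up(d, rules$low_hi, rules$shoulder)
  r3 <- .ramp_up(d, rules$mid_hi, rules$shoulder)
  r4 <- .ramp_up(d, rules$destroy_hi, rules$shoulder)
  v <- strains$dilatational
  comp <- 1 - .ramp_up(v, rules$compress_thresh, rules$shoulder)
  tens <- .ramp_up(v, -rules$compress_thresh, rules$shoulder)
  structure(list(
    understimulated = 1 - r1,
    low = r1 - r2,
    moderate = r2 - r3,
    high = r3 - r4,
    excessive = r4,
    compressive = comp,
    neutral = 1 - comp - tens,
    tensile = tens
  ), class = "stimulus_summary")
}

#' Daily vascularity update
#'
#' Vascularity spreads from vascularized face-neighbors as an advancing
#' front: each evolving cell gains `v_rate / voxel_size` times the largest
#' neighboring vascularity, damped by `(1 - excessive membership)` and
#' suppressed entirely where the distortional strain exceeds `gamma_angio`.
#' Vascularity is clamped to `[0, 1]` and never decreases.
#'
#' @param state A `tissue_state`.
#' @param strains A `strain_field`.
#' @param rules A [fuzzy_rules()] set.
#' @param model The `voxel_model`.
#' @param stimuli Optional precomputed [fuzzify()] result.
#' @return The updated per-cell vascularity vector.
#' @export
update_vascularity <- function(state, strains, rules, model,
                               stimuli = fuzzify(strains, rules)) {
  v <- state$vascularity
  nb <- neighbor_max(v, model$dims)
  gain <- (rules$v_rate / model$spacing) * nb * (1 - stimuli$excessive)
  gain[strains$distortional > rules$gamma_angio] <- 0
  idx <- model$evolving
  v[idx] <- pmin(1, v[idx] + pmax(0, gain[idx]))
  v
}

# per-cell maximum over the six face neighbors (zero outside the grid)
neighbor_max <- function(v, dims) {
  a <- array(v, dims)
  n <- array(0, dims)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  n[-nx, , ] <- pmax(n[-nx, , ], a[-1, , ])
  n[-1, , ] <- pmax(n[-1, , ], a[-nx, , ])
  n[, -ny, ] <- pmax(n[, -ny, ], a[, -1, ])
  n[, -1, ] <- pmax(n[, -1, ], a[, -ny, ])
  n[, , -nz] <- pmax(n[, , -nz], a[, , -1])
  n[, , -1] <- pmax(n[, , -1], a[, , -nz])
  as.vector(n)
}

#' Daily tissue-composition update
#'
#' Applies the mechano-regulation rule base as simultaneous rate-scaled
#' transfers between tissue fractions on every evolving cell (Mamdani
#' min-AND activations, additive aggregation, outflows capped so fractions
#' stay in `[0, 1]` and sum to 1):
#'
#' * R1 intramembranous ossification: low strain and vascularity >= `v_min`
#'   moves fibrous -> woven at `k_woven`.
#' * R2 chondrogenesis: moderate strain and compression moves
#'   fibrous -> cartilage at `k_chondro`.
#' * R3 endochondral ossification: low-or-moderate strain and vascularity
#'   of at least `v_min` moves cartilage -> woven at `k_endo`.
#' * R4 remodeling: low-or-understimulated strain moves woven -> lamellar
#'   at `k_remodel`.
#' * R5 atrophy: understimulation moves woven -> fibrous and
#'   lamellar -> fibrous at `k_resorb` (evolving cells only, so the
#'   far-field cortex never resorbs).
#' * R6 destruction: excessive strain moves woven, cartilage and lamellar
#'   back to fibrous at `k_destroy`.
#'
#' @param state A `tissue_state`.
#' @param stimuli A [fuzzify()] result.
#' @param rules A [fuzzy_rules()] set.
#' @param model The `voxel_model`.
#' @return A new `tissue_state` (same day; [step_day()] advances the day).
#' @export
update_tissues <- function(state, stimuli, rules, model) {
  idx <- which(model$evolving)
  lam <- state$lamellar[idx]; wov <- state$woven[idx]
  car <- state$cartilage[idx]; fib <- state$fibrous[idx]
  v <- state$vascularity[idx]
  m_un <- stimuli$understimulated[idx]; m_lo <- stimuli$low[idx]
  m_mo <- stimuli$moderate[idx]; m_ex <- stimuli$excessive[idx]
  m_co <- stimuli$compressive[idx]
  gate <- as.numeric(v >= rules$v_min)

  a1 <- pmin(m_lo, gate)               # intramembranous
  a2 <- pmin(m_mo, m_co)               # chondrogenesis
  a3 <- pmin(pmax(m_lo, m_mo), gate)   # endochondral
  a4 <- pmax(m_lo, m_un)               # remodeling
  a5 <- m_un                           # atrophy
  a6 <- m_ex                           # destruction

  cap <- function(coef) ifelse(coef > 1, 1 / coef, 1)
  c_f <- rules$k_woven * a1 + rules$k_chondro * a2
  s_f <- cap(c_f)
  t_fw <- rules$k_woven * a1 * s_f * fib
  t_fc <- rules$k_chondro * a2 * s_f * fib
  c_c <- rules$k_endo * a3 + rules$k_destroy * a6
  s_c <- cap(c_c)
  t_cw <- rules$k_endo * a3 * s_c * car
  t_cf <- rules$k_destroy * a6 * s_c * car
  c_w <- rules$k_remodel * a4 + rules$k_resorb * a5 + rules$k_destroy * a6
  s_w <- cap(c_w)
  t_wl <- rules$k_remodel * a4 * s_w * wov
  t_wf <- (rules$k_resorb * a5 + rules$k_destroy * a6) * s_w * wov
  c_l <- rules$k_resorb * a5 + rules$k_destroy * a6
  s_l <- cap(c_l)
  t_lf <- c_l * s_l * lam

  state$fibrous[idx] <- fib - t_fw - t_fc + t_cf + t_wf + t_lf
  state$woven[idx] <- wov + t_fw + t_cw - t_wl - t_wf
  state$cartilage[idx] <- car + t_fc - t_cw - t_cf
  state$lamellar[idx] <- lam + t_wl - t_lf
  state
}
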