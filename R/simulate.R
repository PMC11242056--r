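# Daily stepping and full healing simulations.

#' Advance the healing state by one day
#'
#' Composes the daily pipeline: mixture properties -> elasticity solve ->
#' strain stimuli -> fuzzification -> vascularity update -> tissue update,
#' then increments the day.  Per-cell fraction sums are conserved exactly.
#'
#' @param model A `voxel_model`.
#' @param state The current `tissue_state`.
#' @param table A [material_table()].
#' @param rules A [fuzzy_rules()] set.
#' @param loadcase A [load_case()].
#' @param context Optional solver context environment (see
#'   [solve_displacements()]); [simulate_healing()] supplies one so the
#'   factorization is reused across days.
#' @return A list with the advanced `state`, the day's `strains`,
#'   `stimuli`, the displacement solution `sol`, and `metrics` from
#'   [interfragmentary_metrics()].
#' @export
step_day <- function(model, state, table, rules, loadcase, context = NULL) {
  props <- mixture_properties(state, table, model)
  sol <- tryCatch(
    solve_displacements(model, props, loadcase, context = context),
    error = function(e) stop("day ", state$day + 1L, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  strains <- compute_strains(model, sol$u)
  stimuli <- fuzzify(strains, rules)
  state$vascularity <- update_vascularity(state, strains, rules, model,
                                          stimuli)
  state <- update_tissues(state, stimuli, rules, model)
  state$day <- state$day + 1L
  metrics <- interfragmentary_metrics(model, sol$u, strains)
  list(state = state, strains = strains, stimuli = stimuli, sol = sol,
       metrics = metrics)
}

#' Run a full healing simulation
#'
#' Builds the scenario (unless a prebuilt model is supplied), initializes
#' the tissue state, advances the mechano-regulated dynamics one day at a
#' time over the configured horizon, tracks per-quadrant bridging, and
#' classifies the outcome.  The dynamics are deterministic: two runs from
#' the same configuration produce identical results.
#'
#' @param config A [scenario_config()]; ignored when `model` is given.
#' @param table A [material_table()].
#' @param rules A [fuzzy_rules()] set.
#' @param model Optional prebuilt `voxel_model`.
#' @param state Optional initial `tissue_state`.
#' @param days Horizon override (defaults to `config$days`).
#' @param c_min Lamellar threshold for bridging detection.
#' @param stop_at_union Stop stepping once three quadrants are bridged
#'   (the consolidation day and verdict are unaffected; later rows are
#'   simply not simulated).
#' @param snapshot_days Integer vector of days at which to retain full
#'   tissue states (e.g. for rendering); `integer(0)` keeps none.
#' @param check_invariants Track conservation/bounds/monotonicity
#'   diagnostics every day (cheap; on by default).
#' @param progress Print a line every `progress` days (0 = silent).
#' @return An object of class `healing_run`: list with `timeline` (one row
#'   per simulated day), `report` from [classify_outcome()], `final_state`,
#'   `snapshots`, `diagnostics`, `model`, and the inputs.
#' @export
simulate_healing <- function(config = NULL, table = material_table(),
                             rules = fuzzy_rules(), model = NULL,
                             state = NULL, days = NULL, c_min = 0.5,
                             stop_at_union = FALSE,
                             snapshot_days = integer(0),
                             check_invariants = TRUE, progress = 0) {
  if (is.null(model)) {
    if (is.null(config)) stop("either config or model is required")
    model <- build_scenario(config)
  }
  if (is.null(config)) config <- model$config
  if (is.null(state)) state <- initial_state(model)
  if (is.null(days)) days <- config$days
  loadcase <- build_load_case(config$bone_type, config$body_weight,
                              config$weight_bearing,
                              config$peak_multiplier)
  context <- new.env(parent = emptyenv())
  qs <- c("anterior", "posterior", "medial", "lateral")

  rows <- vector("list", days)
  snapshots <- list()
  diag <- list(max_fraction_dev = 0, min_field = 0, max_field = 1,
               vasc_monotone = TRUE, refactor_days = 0L)
  prev_vasc <- state$vascularity
  stopped_day <- days

  for (d in seq_len(days)) {
    stp <- step_day(model, state, table, rules, loadcase, context)
    state <- stp$state
    if (stp$sol$refactored) diag$refactor_days <- diag$refactor_days + 1L

    br <- bridged_quadrants(state, model, c_min)
    frag_bone <- fragment_bone_fractions(state, model)
    rows[[d]] <- data.frame(
      day = d,
      bridged_anterior = br[["anterior"]], bridged_posterior = br[["posterior"]],
      bridged_medial = br[["medial"]], bridged_lateral = br[["lateral"]],
      n_bridged = sum(br),
      gap_strain_max = stp$metrics$gap_strain_max,
      rel_disp_mm = stp$metrics$rel_disp_mm,
      angulation_deg = stp$metrics$angulation_deg,
      frag0_bone = frag_bone[1], frag1_bone = frag_bone[2],
      frag2_bone = frag_bone[3],
      mean_vascularity = mean(state$vascularity[model$evolving]),
      solver_residual = stp$sol$residual
    )

    if (check_invariants && any(model$evolving)) {
      ev <- model$evolving
      s <- state$lamellar[ev] + state$woven[ev] + state$cartilage[ev] +
        state$fibrous[ev]
      diag$max_fraction_dev <- max(diag$max_fraction_dev, max(abs(s - 1)))
      fields <- c(state$lamellar[ev], state$woven[ev], state$cartilage[ev],
                  state$fibrous[ev], state$vascularity[ev])
      diag$min_field <- min(diag$min_field, min(fields))
      diag$max_field <- max(diag$max_field, max(fields))
      if (any(state$vascularity < prev_vasc - 1e-15))
        diag$vasc_monotone <- FALSE
      prev_vasc <- state$vascularity
    }
    if (d %in% snapshot_days) snapshots[[as.character(d)]] <- state
    if (progress > 0 && d %% progress == 0)
      message(sprintf("day %3d: %d quadrant(s) bridged, gap strain %.2e",
                      d, sum(br), stp$metrics$gap_strain_max))
    if (stop_at_union && sum(br) >= 3) { stopped_day <- d; break }
  }

  timeline <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  report <- classify_outcome(timeline, horizon = days)
  structure(list(
    timeline = timeline, report = report, final_state = state,
    snapshots = snapshots, diagnostics = diag, model = model,
    config = config, table = table, rules = rules, c_min = c_min,
    days_requested = days, days_simulated = stopped_day
  ), class = "healing_run")
}

# mean mineralized (lamellar + woven) fraction per fragment id 0, 1, 2
fragment_bone_fractions <- function(state, model) {
  vapply(0:2, function(f) {
    cells <- model$fragment == f
    if (!any(cells)) return(NA_real_)
    mean(state$lamellar[cells] + state$woven[cells])
  }, numeric(1))
}

#' @export
print.healing_run <- function(x, ...) {
  cat(sprintf("<healing_run> %s %s, %d day(s) simulated\n",
              x$config$bone_type, x$config$fracture_kind,
              nrow(x$timeline)))
  cd <- x$report$consolidation_day
  cat(sprintf("  outcome: %s%s; max simultaneous bridged quadrants: %d\n",
              x$report$outcome,
              if (!is.na(cd)) sprintf(" (consolidation day %d)", cd) else "",
              x$report$max_bridged))
  invisible(x)
}

#' Weight-bearing sweep
#'
#' Re-runs a scenario at several weight-bearing levels (default: full
#' weight-bearing plus the 10% and 5% partial-weight-bearing levels) and
#' tabulates outcome, consolidation day, and the final mean mineralized
#' fraction of each fragment, which tracks the dissipation of a
#' devascularized interposed fragment under low loading.
#'
#' @param config A [scenario_config()].
#' @param levels Weight-bearing fractions, each in `[0, 1]`.
#' @param ... Passed on to [simulate_healing()].
#' @return An object of class `wb_sweep`: list with `table` (one row per
#'   level) and `runs` (the underlying `healing_run` objects).  Failures at
#'   individual levels are recorded in the table and do not stop the sweep.
#' @export
weight_bearing_sweep <- function(config, levels = c(1.0, 0.10, 0.05), ...) {
  stopifnot(length(levels) > 0, all(levels >= 0 & levels <= 1))
  runs <- list()
  rows <- lapply(seq_along(levels), function(i) {
    cfg <- config
    cfg$weight_bearing <- levels[i]
    run <- tryCatch(simulate_healing(cfg, ...), error = function(e) e)
    runs[[i]] <<- run
    if (inherits(run, "error")) {
      return(data.frame(weight_bearing = levels[i], outcome = "error",
                        consolidation_day = NA_integer_,
                        frag0_bone = NA_real_, frag1_bone = NA_real_,
                        frag2_bone = NA_real_,
                        error = conditionMessage(run)))
    }
    fin <- run$timeline[nrow(run$timeline), ]
    data.frame(weight_bearing = levels[i], outcome = run$report$outcome,
               consolidation_day = run$report$consolidation_day,
               frag0_bone = fin$frag0_bone, frag1_bone = fin$frag1_bone,
               frag2_bone = fin$frag2_bone, error = NA_character_)
  })
  structure(list(table = do.call(rbind, rows), runs = runs,
                 config = config, levels = levels),
            class = "wb_sweep")
}

#' @export
print.wb_sweep <- function(x, ...) {
  cat("<wb_sweep>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
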