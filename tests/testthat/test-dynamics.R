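make_strains <- function(n, distortional = 0, dilatational = 0) {
  structure(list(eps = matrix(0, n, 6),
                 distortional = rep_len(distortional, n),
                 dilatational = rep_len(dilatational, n)),
            class = "strain_field")
}

test_that("distortional memberships partition unity and hit the shoulder midpoints", {
  rules <- fuzzy_rules()
  s <- make_strains(3, distortional = c(0, rules$low_hi, rules$mid_hi))
  st <- fuzzify(s, rules)
  expect_equal(st$understimulated[1], 1)  # 0 lies below the eta_min shoulder
  expect_equal(st$low[2], 0.5)
  expect_equal(st$moderate[2], 0.5)
  expect_equal(st$moderate[3], 0.5)
  expect_equal(st$high[3], 0.5)

  set.seed(42)
  d <- c(runif(5000, 0, 0.5), runif(5000, 0, 0.002))
  st <- fuzzify(make_strains(10000, distortional = d), rules)
  total <- st$understimulated + st$low + st$moderate + st$high + st$excessive
  expect_true(all(abs(total - 1) < 1e-12))
  expect_true(all(vapply(st, function(m) all(m >= 0 & m <= 1), logical(1))))
})

test_that("dilatational categories gate on signed compression", {
  rules <- fuzzy_rules()
  s <- make_strains(4, dilatational = c(-0.01, -0.002, 0, 0.01))
  st <- fuzzify(s, rules)
  expect_equal(st$compressive, c(1, 0.5, 0, 0))
  expect_equal(st$tensile, c(0, 0, 0, 1))
  expect_equal(st$compressive + st$neutral + st$tensile, rep(1, 4))
})

test_that("vascularity advances as a damped front and never decreases", {
  m <- callusim:::make_block_model(4, 1, 1, h = 1, mid_layers = 0L)
  m$evolving <- rep(TRUE, 4)
  st <- initial_state(m)
  st$vascularity <- c(1, 0, 0, 0)
  rules <- fuzzy_rules()

  # quiescent strain: first neighbor gains v_rate * 1 / voxel = 0.3
  v1 <- update_vascularity(st, make_strains(4), rules, m)
  expect_equal(v1, c(1, 0.3, 0, 0))

  # no vascular source anywhere: nothing changes
  st0 <- st; st0$vascularity <- rep(0, 4)
  expect_equal(update_vascularity(st0, make_strains(4), rules, m), rep(0, 4))

  # angiogenesis stalls above gamma_angio
  vhi <- update_vascularity(st, make_strains(4, distortional = 0.1), rules, m)
  expect_equal(vhi, st$vascularity)

  # monotone under repeated updates, capped at 1
  v <- st$vascularity
  for (i in 1:20) {
    st$vascularity <- v
    vn <- update_vascularity(st, make_strains(4), rules, m)
    expect_true(all(vn >= v))
    v <- vn
  }
  expect_equal(v, rep(1, 4))
})

test_that("single-rule transfers match the rate arithmetic", {
  m <- callusim:::make_block_model(1, 1, 3, mid_layers = 1)
  rules <- fuzzy_rules()
  st <- initial_state(m)
  mid <- which(m$evolving)

  # R1 at full low membership and full vascularity: fibrous -> woven at 0.03
  st$vascularity[mid] <- 1
  stim <- fuzzify(make_strains(3, distortional = 0.01,
                               dilatational = 0), rules)
  out <- update_tissues(st, stim, rules, m)
  expect_equal(out$woven[mid], 0.03)
  expect_equal(out$fibrous[mid], 0.97)

  # same stimulus, avascular cell: R1 gated off
  st2 <- initial_state(m)
  out2 <- update_tissues(st2, stim, rules, m)
  expect_equal(out2$woven[mid], 0)
  expect_equal(out2$fibrous[mid], 1)

  # R6: excessive membership 1 destroys woven at k_destroy
  st3 <- initial_state(m)
  st3$woven[mid] <- 0.5
  st3$fibrous[mid] <- 0.5
  stim3 <- fuzzify(make_strains(3, distortional = 0.5), rules)
  out3 <- update_tissues(st3, stim3, rules, m)
  expect_equal(out3$woven[mid], 0.45)
  expect_equal(out3$fibrous[mid], 0.55)

  # R2: moderate + compressive forms cartilage at k_chondro
  st4 <- initial_state(m)
  stim4 <- fuzzify(make_strains(3, distortional = 0.1,
                                dilatational = -0.01), rules)
  out4 <- update_tissues(st4, stim4, rules, m)
  expect_equal(out4$cartilage[mid], 0.05)

  # conservation in every case
  for (o in list(out, out2, out3, out4)) {
    s <- o$lamellar + o$woven + o$cartilage + o$fibrous
    expect_true(all(abs(s[mid] - 1) < 1e-12))
  }
})

test_that("with all rates zero the state is a fixed point of step_day", {
  m <- callusim:::make_block_model(3, 3, 5, mid_layers = 1)
  rules <- fuzzy_rules(k_woven = 0, k_chondro = 0, k_endo = 0,
                       k_remodel = 0, k_resorb = 0, k_destroy = 0,
                       v_rate = 0)
  st <- initial_state(m)
  stp <- step_day(m, st, material_table(), rules, load_case(50, c(axial = 1)))
  for (f in c("lamellar", "woven", "cartilage", "fibrous", "vascularity"))
    expect_identical(stp$state[[f]], st[[f]])
  expect_equal(stp$state$day, 1L)
})

test_that("one step_day matches the dense per-cell reference on a toy grid", {
  m <- callusim:::make_block_model(3, 3, 3, mid_layers = 1)
  st <- initial_state(m)
  st$vascularity[m$evolving][1:3] <- c(1, 0.6, 0.2)
  tab <- material_table()
  rules <- fuzzy_rules()
  lc <- load_case(40, c(axial = 1))

  pr <- mixture_properties(st, tab, m)
  sol <- solve_displacements(m, pr, lc)
  strains <- compute_strains(m, sol$u)
  ref <- reference_day_update(m, st, strains, rules)

  stp <- step_day(m, st, tab, rules, lc)
  for (f in c("lamellar", "woven", "cartilage", "fibrous", "vascularity")) {
    expect_lt(max(abs(stp$state[[f]] - ref[[f]])), 1e-10)
  }
  expect_equal(stp$state$day, ref$day)
})

test_that("without load no cartilage forms and dynamics stay deterministic", {
  cfg <- coarse_tibia_config(weight_bearing = 0)
  r1 <- simulate_healing(cfg, days = 30)
  expect_true(all(r1$final_state$cartilage == 0))
  r2 <- simulate_healing(cfg, days = 30)
  expect_identical(r1$final_state, r2$final_state)
  expect_identical(r1$timeline, r2$timeline)
})

test_that("scaling the load down reduces every excessive membership", {
  cfg <- coarse_tibia_config()
  m <- build_scenario(cfg)
  st <- initial_state(m)
  tab <- material_table(E_nail = 1100, E_locking = 10)  # destabilized
  pr <- mixture_properties(st, tab, m)
  hi <- solve_displacements(m, pr, build_load_case("tibia", 800, 1))
  lo <- solve_displacements(m, pr, build_load_case("tibia", 800, 0.25))
  rules <- fuzzy_rules()
  mhi <- fuzzify(compute_strains(m, hi$u), rules)$excessive
  mlo <- fuzzify(compute_strains(m, lo$u), rules)$excessive
  expect_gt(max(mhi), 0)        # the destabilized case is actually excessive
  expect_true(all(mlo <= mhi))
  expect_lt(max(mlo[mhi > 0]), max(mhi))
})
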