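test_that("load cases follow the bone-specific loading conventions", {
  lc <- build_load_case("tibia", body_weight = 800, weight_bearing = 1)
  expect_equal(lc$total_peak_force, 1760)
  expect_equal(unname(lc$total_peak_force * lc$patch_split["medial"]), 968)
  expect_equal(unname(lc$total_peak_force * lc$patch_split["lateral"]), 792)
  expect_equal(sum(lc$patch_split), 1)
  expect_equal(sqrt(sum(lc$direction^2)), 1)

  expect_equal(build_load_case("tibia", 800, 0)$total_peak_force, 0)
  lf <- build_load_case("femur", 800, 0.05)
  expect_equal(lf$total_peak_force, 0.05 * 2.38 * 800)
  expect_error(build_load_case("humerus", 800, 1), "unknown bone_type")
})

test_that("mixture rule reproduces single- and two-component properties", {
  m <- callusim:::make_block_model(2, 2, 2)
  st <- initial_state(m)
  tab <- material_table()
  pr <- mixture_properties(st, tab, m)
  expect_true(all(pr$E == 10000))  # pure lamellar
  expect_true(all(pr$nu == 0.3))

  st$lamellar[] <- 0.5
  st$fibrous[] <- 0.5
  pr <- mixture_properties(st, tab, m)
  expect_equal(unique(pr$E), 5001.5)
  expect_equal(unique(pr$nu), 0.3)

  # non-linear mixture exponent
  tab2 <- material_table(mixture_exponent = 2)
  pr2 <- mixture_properties(st, tab2, m)
  expect_equal(unique(pr2$E), (0.5 * sqrt(10000) + 0.5 * sqrt(3))^2)
})

test_that("axial compression of a homogeneous cylinder matches the bar solution", {
  # solid cylinder via a degenerate scenario: no canal, no nail, no gap
  cfg <- scenario_config(bone_type = "femur", outer_diameter = 24,
                         cortical_thickness = 11.9, canal_diameter = 0,
                         nail_diameter = 0, segment_length = 96,
                         gap_width = 0, callus_diameter = 24,
                         voxel_size = 2)
  m <- build_scenario(cfg)
  expect_setequal(unique(m$region[m$region != 0L]), 1L)
  st <- initial_state(m)
  pr <- mixture_properties(st, material_table(), m)
  lc <- load_case(1760, c(axial = 1))
  sol <- solve_displacements(m, pr, lc)
  expect_lt(sol$residual, 1e-8)

  h <- m$spacing
  A <- sum(m$region[seq_len(prod(m$dims[1:2]))] != 0L) * h^2
  L <- m$dims[3] * h
  expected <- -1760 * L / (10000 * A)
  patch <- m$load_patches$axial
  tip <- sum(sol$u[patch$nodes, 3] * patch$weights)
  expect_lt(abs(tip - expected) / abs(expected), 0.05)
})

test_that("patch test: uniform traction produces uniform strain", {
  m <- callusim:::make_block_model(4, 4, 6, h = 1, base_mode = "axial")
  st <- initial_state(m)
  pr <- mixture_properties(st, material_table(), m)
  lc <- load_case(16, c(axial = 1))  # traction 1 MPa over 16 mm^2
  sol <- solve_displacements(m, pr, lc)
  strains <- compute_strains(m, sol$u)
  act <- m$region != 0L
  ezz_exp <- -1 / 10000
  expect_true(all(abs(strains$eps[act, "ezz"] - ezz_exp) < 1e-6))
  expect_true(all(abs(strains$eps[act, "exx"] - 0.3 / 10000) < 1e-6))
  expect_true(all(abs(strains$eps[act, "gxy"]) < 1e-6))
  expect_true(all(abs(strains$dilatational[act] -
                        (-1 + 2 * 0.3) / 10000) < 1e-6))
})

test_that("zero load gives zero displacement and doubling the load doubles it", {
  m <- callusim:::make_block_model(4, 4, 6)
  st <- initial_state(m)
  pr <- mixture_properties(st, material_table(), m)
  sol0 <- solve_displacements(m, pr, load_case(0, c(axial = 1)))
  expect_true(all(sol0$u == 0))
  sol1 <- solve_displacements(m, pr, load_case(100, c(axial = 1)))
  sol2 <- solve_displacements(m, pr, load_case(200, c(axial = 1)))
  expect_lt(max(abs(sol2$u - 2 * sol1$u)), 1e-8 * max(abs(sol1$u)))
  s1 <- compute_strains(m, sol1$u)
  s2 <- compute_strains(m, sol2$u)
  expect_lt(max(abs(s2$distortional - 2 * s1$distortional)),
            1e-8 * max(s1$distortional))
})

test_that("strain invariants follow from imposed displacement fields", {
  m <- callusim:::make_block_model(3, 3, 3, h = 1)
  fem <- callusim:::fem_setup(m)
  nodes <- expand.grid(x = 0:3, y = 0:3, z = 0:3)

  # uniaxial compression with lateral expansion: ezz -0.01, exx = eyy +0.003
  u <- cbind(0.003 * nodes$x, 0.003 * nodes$y, -0.01 * nodes$z)
  s <- compute_strains(m, u)
  act <- m$region != 0L
  expect_true(all(abs(s$dilatational[act] - (-0.004)) < 1e-12))

  # pure hydrostatic: distortional vanishes, dilatational is the trace
  # (the invariant square root amplifies rounding, hence 1e-8)
  u <- cbind(-0.01 * nodes$x, -0.01 * nodes$y, -0.01 * nodes$z)
  s <- compute_strains(m, u)
  expect_true(all(abs(s$distortional[act]) < 1e-8))
  expect_true(all(abs(s$dilatational[act] + 0.03) < 1e-12))

  # rigid translation: no strain at all
  u <- cbind(rep(0.5, nrow(nodes)), rep(-0.2, nrow(nodes)), rep(1, nrow(nodes)))
  s <- compute_strains(m, u)
  expect_true(all(abs(s$eps) < 1e-12))
})

test_that("mirrored loading of a symmetric model yields the mirrored displacements", {
  cfg <- coarse_tibia_config()
  m <- build_scenario(cfg)
  pr <- mixture_properties(initial_state(m), material_table(), m)
  u1 <- solve_displacements(m, pr,
                            load_case(1760, c(medial = 0.55, lateral = 0.45)))$u
  u2 <- solve_displacements(m, pr,
                            load_case(1760, c(medial = 0.45, lateral = 0.55)))$u
  d <- m$dims
  nn1 <- d[1] + 1L; nn2 <- d[2] + 1L; nn3 <- d[3] + 1L
  idx <- expand.grid(i = 0:(nn1 - 1L), j = 0:(nn2 - 1L), k = 0:(nn3 - 1L))
  mir <- 1L + idx$i + nn1 * ((d[2] - idx$j) + nn2 * idx$k)
  tol <- 1e-8 * max(abs(u1))
  expect_lt(max(abs(u2[mir, 1] - u1[, 1])), tol)
  expect_lt(max(abs(u2[mir, 2] + u1[, 2])), tol)
  expect_lt(max(abs(u2[mir, 3] - u1[, 3])), tol)
})

test_that("stiffer gap tissue never raises the peak gap distortional strain", {
  cfg <- coarse_tibia_config()
  m <- build_scenario(cfg)
  st <- initial_state(m)
  tab <- material_table()
  lc <- build_load_case("tibia", cfg$body_weight, 1)
  peaks <- vapply(c(0, 0.5, 1), function(w) {
    s <- st
    s$fibrous[m$gap_cell] <- 1 - w
    s$woven[m$gap_cell] <- w
    pr <- mixture_properties(s, tab, m)
    sol <- solve_displacements(m, pr, lc)
    max(compute_strains(m, sol$u)$distortional[m$gap_cell])
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("a floating fragment yields a diagnostic error", {
  m <- callusim:::make_block_model(3, 3, 6, mid_layers = 2)
  # carve the soft mid layers out entirely: top fragment floats
  m$region[m$region == 5L] <- 0L
  m$cache <- new.env(parent = emptyenv())
  st <- initial_state(m)
  pr <- mixture_properties(st, material_table(), m)
  expect_error(
    solve_displacements(m, pr, load_case(10, c(axial = 1))),
    "not connected to the fixed base.*fragment id\\(s\\): 0")
})
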