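test_that("configuration invariants are enforced with named inequalities", {
  expect_error(tibia_shaft_config(nail_diameter = 12, canal_diameter = 11),
               "nail_diameter <= canal_diameter")
  expect_error(tibia_shaft_config(canal_diameter = 15),
               "canal_diameter < outer_diameter - 2 \\* cortical_thickness")
  expect_error(tibia_shaft_config(callus_diameter = 20),
               "callus_diameter >= outer_diameter")
  expect_error(tibia_shaft_config(gap_width = -1), "gap_width >= 0")
  expect_error(tibia_shaft_config(voxel_size = 0), "voxel_size > 0")
  expect_error(tibia_shaft_config(days = 0), "days >= 1")
  expect_error(tibia_shaft_config(weight_bearing = 1.5),
               "weight_bearing in \\[0, 1\\]")
})

test_that("transverse gap occupies round(gap/spacing) cell layers", {
  cfg <- tibia_shaft_config(gap_width = 3, voxel_size = 1)
  m <- build_scenario(cfg)
  gap <- array(m$gap_cell, m$dims)
  layers <- which(apply(gap, 3, any))
  expect_length(layers, 3)
  expect_true(all(diff(layers) == 1))
})

test_that("zero-gap fragments are face-connected through bone", {
  m <- build_scenario(coarse_tibia_config(gap_width = 0))
  bone <- m$region %in% c(1L, 2L)
  lab <- callusim:::cpp_components(m$dims, bone)
  shared <- intersect(unique(lab[bone & m$fragment == 0L]),
                      unique(lab[bone & m$fragment == 1L]))
  expect_gt(length(shared), 0)

  # and a gapped model keeps them in disjoint bone components
  mg <- build_scenario(coarse_tibia_config(gap_width = 3))
  labg <- callusim:::cpp_components(mg$dims, mg$region %in% c(1L, 2L))
  expect_length(intersect(unique(labg[mg$fragment == 0L]),
                          unique(labg[mg$fragment == 1L])), 0)
})

test_that("oblique fractures tilt the fragment boundary along the cut axis", {
  m <- build_scenario(tibia_shaft_config(fracture_kind = "oblique",
                                         oblique_angle = 30, voxel_size = 2,
                                         segment_length = 48))
  expect_setequal(unique(m$fragment[m$fragment >= 0]), c(0L, 1L))
  expect_gt(sum(m$gap_cell), 0)
  ctr <- cell_centers(m)
  bone <- m$region %in% c(1L, 2L)
  xs <- sort(unique(ctr[bone, 1]))
  top1 <- vapply(xs, function(xx)
    max(ctr[bone & ctr[, 1] == xx & m$fragment == 1L, 3]), numeric(1))
  # distal fragment reaches higher on the +x side: monotone trend, total
  # rise consistent with tan(30 deg) over the diameter
  expect_true(all(diff(top1) >= 0))
  expect_gt(top1[length(top1)] - top1[1], 0.5 * tan(pi / 6) * (max(xs) - min(xs)))
})

test_that("wedge scenarios carry exactly three fragments", {
  m <- build_scenario(femur_wedge_config())
  expect_setequal(unique(m$fragment[m$fragment >= 0]), c(0L, 1L, 2L))
  expect_gt(sum(m$fragment == 2L), 0)
})

test_that("every bone cell has a fragment id and a quadrant", {
  for (cfg in list(tibia_shaft_config(), femur_wedge_config())) {
    m <- build_scenario(cfg)
    bone <- m$region %in% c(1L, 2L)
    expect_true(all(m$fragment[bone] >= 0))
    expect_true(all(m$quadrant[bone] != 0L))
    labeled <- m$region %in% c(1L, 2L, 5L)
    expect_true(all(m$quadrant[labeled] != 0L))
    # nail cells lie within the former canal: never beyond the endosteum
    ctr <- cell_centers(m)
    r <- sqrt(ctr[, 1]^2 + ctr[, 2]^2)
    r_endo <- cfg$outer_diameter / 2 - cfg$cortical_thickness
    expect_true(all(r[m$region == 4L] <= r_endo + 1e-9))
  }
})

test_that("geometry generation is deterministic", {
  m1 <- build_scenario(tibia_shaft_config(seed = 1))
  m2 <- build_scenario(tibia_shaft_config(seed = 99))
  expect_identical(m1$region, m2$region)
  expect_identical(m1$fragment, m2$fragment)
  expect_identical(m1$quadrant, m2$quadrant)
})

test_that("quadrants are balanced on a symmetric cylinder and ties go anterior", {
  m <- build_scenario(tibia_shaft_config())
  cortical <- m$region == 1L
  dims <- m$dims
  iz <- rep(seq_len(dims[3]), each = dims[1] * dims[2])
  for (k in unique(iz[cortical])) {
    counts <- table(factor(m$quadrant[cortical & iz == k], levels = 1:4))
    n <- sum(counts)
    # each sector within one boundary layer of a perfect quarter
    expect_true(all(abs(counts - n / 4) <= max(4, 0.15 * n)))
  }
  # a cell exactly on the +x axis is anterior, on +y medial
  ctr <- cell_centers(m)
  on_x <- cortical & abs(ctr[, 2]) < 1e-9 & ctr[, 1] > 0
  if (any(on_x)) expect_true(all(m$quadrant[on_x] == 1L))
})

test_that("mirroring about the x-z plane swaps medial and lateral exactly", {
  m <- build_scenario(tibia_shaft_config())
  dims <- m$dims
  q <- array(m$quadrant, dims)
  qm <- q[, rev(seq_len(dims[2])), ]  # mirror y
  swap <- qm
  swap[qm == 2L] <- 4L
  swap[qm == 4L] <- 2L
  expect_identical(as.vector(swap), as.vector(q))
  r <- array(m$region, dims)
  expect_identical(r[, rev(seq_len(dims[2])), ], r)
})

test_that("initial state is normalized, vascularized bone, avascular callus", {
  m <- build_scenario(femur_wedge_config())
  st <- initial_state(m)
  ev <- m$evolving
  s <- st$lamellar + st$woven + st$cartilage + st$fibrous
  expect_true(all(abs(s[ev] - 1) < 1e-9))
  expect_equal(mean(st$vascularity[m$region == 1L & m$fragment != 2L]), 1.0)
  expect_true(all(st$lamellar[m$region %in% c(1L, 2L)] == 1))
  expect_true(all(st$fibrous[m$region == 5L] == 1))
  expect_true(all(st$vascularity[m$region == 5L] == 0))
  # devascularized interposed fragment: avascular but still lamellar
  expect_true(all(st$vascularity[m$fragment == 2L] == 0))
  expect_true(all(st$lamellar[m$fragment == 2L] == 1))
  # nothing on nail or outside cells
  off <- m$region %in% c(0L, 4L)
  expect_true(all(s[off] == 0) && all(st$vascularity[off] == 0))
})

test_that("healing domain forms one face-connected component spanning the gap", {
  m <- build_scenario(tibia_shaft_config())
  heal <- m$region == 5L
  lab <- callusim:::cpp_components(m$dims, heal)
  expect_equal(length(unique(lab[heal])), 1)
  expect_true(all(m$gap_cell[m$gap_cell] & heal[m$gap_cell]))
})

test_that("YAML configuration round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- femur_wedge_config(weight_bearing = 0.1)
  write_sim_config(cfg, path, material_table(E_nail = 1100), fuzzy_rules())
  back <- read_sim_config(path)
  expect_equal(unclass(back$scenario), unclass(cfg))
  expect_equal(back$materials$E_nail, 1100)
  expect_equal(back$rules$k_woven, 0.03)
  shipped <- system.file("extdata", "tibia_shaft.yaml", package = "callusim")
  ref <- read_sim_config(shipped)
  expect_equal(unclass(ref$scenario), unclass(tibia_shaft_config()))
  expect_equal(unclass(ref$rules), unclass(fuzzy_rules()))
  expect_equal(unclass(ref$materials), unclass(material_table()))
})
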