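test_that("material assignment: homogeneous body and threshold segmentation", {
  set <- prostate_like_structures()
  g <- tiny_grid(c(30, 30, 12), c(0.6, 0.6, 0.7), c(-9, -9, -4.2))
  # uniform intensity, single body rule -> homogeneous phantom inside body
  intens <- synthetic_intensity(g, set)
  ph <- assign_materials(intens, set,
                         list(list(structure = "body", material = "water")),
                         g, outside = "air")
  body <- structure_mask(set, "body", g)
  mats <- array(ph$material, g$dim)
  expect_true(all(mats[body] == "water"))
  expect_true(all(mats[!body] == "air"))

  # high-intensity ellipsoid + threshold rule -> exactly those voxels bone
  bc <- c(5.5, 0, 0)
  intens2 <- synthetic_intensity(g, set, bone_center = bc)
  ph2 <- assign_materials(intens2, set, list(
    list(structure = "body", material = "bone", range = c(300, 2000)),
    list(structure = "body", material = "water")), g, outside = "air")
  mats2 <- array(ph2$material, g$dim)
  oracle_bone <- body & intens2 >= 300
  expect_identical(unname(mats2 == "bone"), unname(oracle_bone))

  # bone-as-water toggle: same rules without the threshold rule
  ph3 <- assign_materials(intens2, set, list(
    list(structure = "body", material = "water")), g, outside = "air")
  expect_false(any(array(ph3$material, g$dim) == "bone"))

  # unclaimed voxels raise with a count
  expect_error(assign_materials(intens, set,
                                list(list(structure = "prostate",
                                          material = "water")), g),
               "[0-9]+ voxels matched no")
})

test_that("rule order gives structure precedence", {
  set <- prostate_like_structures()
  g <- tiny_grid(c(20, 20, 8), c(0.9, 0.9, 1.0), c(-9, -9, -4))
  intens <- synthetic_intensity(g, set)
  ph <- assign_materials(intens, set, list(
    list(structure = "rectum", material = "air"),
    list(structure = "body", material = "water")), g, outside = "air")
  rec <- structure_mask(set, "rectum", g)
  mats <- array(ph$material, g$dim)
  expect_true(all(mats[rec] == "air"))
})

test_that("scatter shell pads the grid without touching the interior", {
  ph <- cube_phantom(4, 0.5, "water")
  expect_identical(add_scatter_shell(ph, 0), ph)
  big <- add_scatter_shell(ph, 2, "water")
  expect_equal(big$dim * big$spacing, ph$dim * ph$spacing + 4)
  expect_true(all(big$material == "water"))
  # a 20 cm shell on a case-like grid grows the extent by 40 cm per axis
  pat <- voxel_phantom(c(19L, 19L, 21L), c(1, 1, 1), c(-9.5, -9.5, -10.5),
                       "bone")
  shl <- add_scatter_shell(pat, 20, "water")
  expect_equal(shl$dim * shl$spacing - pat$dim * pat$spacing, rep(40, 3))
  mats <- array(shl$material, shl$dim)
  expect_true(all(mats[1:20, , ] == "water"))
  expect_equal(mats[21, 30, 31], "bone")
})

test_that("cumulative DVH: steps, counting, and the threshold-count oracle", {
  vv <- 0.125
  # uniform dose: 100% up to D0, 0 after
  d <- array(10, c(4, 4, 4)); m <- array(TRUE, c(4, 4, 4))
  cv <- cumulative_dvh(d, m, vv)
  expect_equal(cv$volume[1], 100)
  expect_true(all(cv$volume[cv$dose <= 10] == 100))
  expect_true(all(cv$volume[cv$dose > 10] == 0))
  expect_true(all(diff(cv$volume) <= 0))
  # three voxels at 10/20/30: V(15) = 66.67%
  d3 <- array(c(10, 20, 30), c(3, 1, 1)); m3 <- array(TRUE, c(3, 1, 1))
  cv3 <- cumulative_dvh(d3, m3, vv)
  expect_equal(cv3$volume[which.min(abs(cv3$dose - 15))], 200 / 3,
               tolerance = 1e-9)
  # random grid vs brute-force threshold counting, exact at grid levels
  set.seed(6)
  dr <- array(runif(200, 0, 25), c(10, 10, 2))
  mr <- array(runif(200) < 0.6, c(10, 10, 2))
  cvr <- cumulative_dvh(dr, mr, vv)
  for (lev in c(0, 5.01, 12.5, 24.99))
    expect_equal(cvr$volume[which.min(abs(cvr$dose - lev))],
                 100 * sum(dr[mr] >= cvr$dose[which.min(abs(cvr$dose - lev))]) /
                   sum(mr))
  expect_error(cumulative_dvh(dr, array(FALSE, dim(dr)), vv, "empty one"),
               "empty structure: empty one")
})

test_that("DVH metrics: closed forms and the sort-based oracle", {
  vv <- 1
  d <- array(15, c(3, 3, 3)); m <- array(TRUE, c(3, 3, 3))
  cv <- cumulative_dvh(d, m, vv)
  met <- dvh_metrics(cv, 15)
  expect_equal(met$V100, 100)
  expect_equal(met$D90, 15, tolerance = 0.02)
  expect_equal(met$D50, 15, tolerance = 0.02)

  d3 <- array(c(10, 20, 30), c(3, 1, 1)); m3 <- array(TRUE, c(3, 1, 1))
  met3 <- dvh_metrics(cumulative_dvh(d3, m3, vv), 15)
  expect_equal(met3$V100, 200 / 3, tolerance = 0.1)
  expect_equal(met3$D50, 20, tolerance = 0.02)

  # random dose: Dy from the curve vs direct voxel-sort quantile oracle
  set.seed(7)
  dr <- array(runif(400, 0, 30), c(20, 20, 1))
  mr <- array(TRUE, dim(dr))
  cvr <- cumulative_dvh(dr, mr, 0.1, resolution = 0.005)
  metr <- dvh_metrics(cvr, 15)
  v <- sort(dr[mr], decreasing = TRUE)
  oracle_d90 <- v[ceiling(0.9 * length(v))]
  oracle_d50 <- v[ceiling(0.5 * length(v))]
  expect_equal(metr$D90, oracle_d90, tolerance = 0.01)
  expect_equal(metr$D50, oracle_d50, tolerance = 0.01)
  oracle_v100 <- 100 * mean(dr[mr] >= 15)
  expect_equal(metr$V100, oracle_v100, tolerance = 0.1)
  # Vx decreasing in x, Dy decreasing in y
  expect_true(metr$V100 >= metr$V150 && metr$V150 >= metr$V200)
  expect_true(metr$D50 >= metr$D90)
  # volume ordering invariance
  perm <- sample(length(dr))
  cvp <- cumulative_dvh(array(dr[perm], dim(dr)), mr, 0.1,
                        resolution = 0.005)
  expect_equal(cvp$volume, cvr$volume)

  # structures below 2 cm^3 flag D2cc as undefined
  small <- cumulative_dvh(array(5, c(2, 1, 1)), array(TRUE, c(2, 1, 1)), 0.5)
  expect_true(is.na(dvh_metrics(small, 15)$D2cc))
  expect_false(dvh_metrics(small, 15)$d2cc_defined)
})

test_that("plan normalization reproduces the prescription exactly", {
  fin <- list(mean = array(runif(27, 1, 2), c(3, 3, 3)))
  g <- tiny_grid(c(3, 3, 3), rep(1, 3), rep(-1.5, 3))
  plan <- treatment_plan(list(dwell_position(c(0, 0, 0), 1)), 15,
                         c(0.9, 0, 0))
  nd <- normalize_plan_dose(fin, g, plan)
  expect_equal(nd$dose[matrix(nd$prescription_voxel, ncol = 3)], 15)
})

test_that("structure JSON dialect round trips", {
  set <- lung_like_structures(nz = 5)
  f <- tempfile(fileext = ".json")
  write_structures(set, f)
  back <- read_structures(f)
  expect_equal(back$names, set$names)
  expect_equal(back$structures[[1]]$contours[[2]]$points,
               set$structures[[1]]$contours[[2]]$points, tolerance = 1e-12)
  expect_equal(back$structures[[3]]$contours[[1]]$z,
               set$structures[[3]]$contours[[1]]$z)
})
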