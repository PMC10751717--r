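test_that("local difference ratio: identity, closed form, naive-loop oracle", {
  d <- array(1.01, c(3, 3, 3)); r <- array(1.00, c(3, 3, 3))
  expect_equal(unique(as.numeric(delta_local(d, r))), 1)
  expect_true(all(delta_local(r, r) == 0))
  set.seed(1)
  D <- array(runif(60, 0.5, 2), c(5, 4, 3))
  R <- array(runif(60, 0.5, 2), c(5, 4, 3))
  got <- delta_local(D, R)
  oracle <- array(NA_real_, dim(D))
  for (i in 1:5) for (j in 1:4) for (k in 1:3)
    oracle[i, j, k] <- 100 * (D[i, j, k] - R[i, j, k]) / R[i, j, k]
  expect_equal(as.numeric(got), as.numeric(oracle), tolerance = 1e-12)
  # zero-reference voxels are auto-masked and counted
  R2 <- R; R2[2, 2, 2] <- 0
  g2 <- delta_local(D, R2)
  expect_true(is.na(g2[2, 2, 2]))
  expect_equal(attr(g2, "auto_masked"), 1)
})

test_that("global difference ratio normalizes by the reference voxel", {
  set.seed(2)
  D <- array(runif(60, 0.5, 2), c(5, 4, 3))
  R <- array(runif(60, 0.5, 2), c(5, 4, 3))
  rv <- c(3, 2, 2)
  got <- delta_global(D, R, rv)
  oracle <- array(NA_real_, dim(D))
  for (i in 1:5) for (j in 1:4) for (k in 1:3)
    oracle[i, j, k] <- 100 * (D[i, j, k] - R[i, j, k]) / R[3, 2, 2]
  expect_equal(as.numeric(got), as.numeric(oracle), tolerance = 1e-12)
  # at the reference voxel with D = Dref the value is 0
  D2 <- R; expect_equal(delta_global(D2, R, rv)[3, 2, 2], 0)
  # uniform offset of 0.001 * Dref(ref) -> +0.1% everywhere
  D3 <- R + 0.001 * R[3, 2, 2]
  expect_equal(unique(round(as.numeric(delta_global(D3, R, rv)), 9)), 0.1)
  R0 <- R; R0[3, 2, 2] <- 0
  expect_error(delta_global(D, R0, rv), "reference voxel")
})

test_that("relative dose map self-normalizes and flattens inverse-square", {
  g <- tiny_grid(c(9, 9, 9), rep(0.5, 3), rep(-2.25, 3))
  rs <- c(0, 0, 0)
  r <- voxel_radii(g, rs)
  D <- 1 / r^2
  rv <- c(8, 5, 5)
  m <- relative_dose_map(D, g, rs, rv)
  expect_equal(m[8, 5, 5], 1)
  expect_equal(as.numeric(m[is.finite(m)]), rep(1, sum(is.finite(m))),
               tolerance = 1e-12)
  # random field vs naive loop
  set.seed(3)
  D2 <- array(runif(9^3, 0.1, 1), dim(D))
  m2 <- relative_dose_map(D2, g, rs, rv)
  ctr <- voxel_centers(g)
  for (idx in list(c(1, 1, 1), c(9, 3, 7), c(4, 8, 2))) {
    rr <- sqrt(sum((c(ctr$x[idx[1]], ctr$y[idx[2]], ctr$z[idx[3]]) - rs)^2))
    rref <- sqrt(sum((c(ctr$x[8], ctr$y[5], ctr$z[5]) - rs)^2))
    expect_equal(m2[idx[1], idx[2], idx[3]],
                 D2[idx[1], idx[2], idx[3]] * rr^2 /
                   (D2[8, 5, 5] * rref^2), tolerance = 1e-12)
  }
})

test_that("fraction_within counts unmasked voxels exactly", {
  expect_equal(fraction_within(array(0, c(2, 2, 2)), 1), 100)
  m <- array(c(-2, 0, 2), c(3, 1, 1))
  expect_equal(fraction_within(m, 1), 100 / 3, tolerance = 1e-9)
  set.seed(4)
  v <- array(rnorm(1000), c(10, 10, 10))
  v[1, 1, 1] <- NA
  expect_equal(fraction_within(v, 0.8),
               100 * sum(abs(v) <= 0.8, na.rm = TRUE) / 999)
})

test_that("difference histogram recovers mode and sigma of a Gaussian", {
  set.seed(5)
  v <- array(rnorm(2e5, mean = -0.2, sd = 0.16), c(200, 100, 10))
  h <- difference_histogram(v, binwidth = 0.05)
  expect_lt(abs(h$mode - (-0.2)), 0.03)
  expect_lt(abs(h$sigma - 0.16), 0.03)
})

test_that("benchmark scenes follow the published geometry", {
  sc1 <- build_test_case(1)
  expect_equal(sc1$phantom$dim * sc1$phantom$spacing, rep(51.1, 3))
  expect_true(all(sc1$phantom$material == "water"))
  expect_equal(sc1$capsule$origin, c(0, 0, 0))
  expect_equal(sc1$mesh$dim * sc1$mesh$spacing, rep(20.1, 3))
  expect_equal(sc1$mesh$spacing, rep(0.1, 3))   # 1 mm^3 voxels

  sc2 <- build_test_case(2)
  ctr <- voxel_centers(sc2$phantom)
  mats <- array(sc2$phantom$material, sc2$phantom$dim)
  ix <- which.min(abs(ctr$x)); ox <- which.min(abs(ctr$x - 20))
  expect_equal(mats[ix, ix, ix], "water")   # inside the 20.1 cm cube
  expect_equal(mats[ox, ix, ix], "air")     # outside it

  sc3 <- build_test_case(3)
  expect_equal(sc3$capsule$origin, c(7, 0, 0))
  expect_equal(sc3$source_position, c(7, 0, 0))
  # the reference voxel lies 1 cm from the source along -x
  cm <- voxel_centers(sc3$mesh)
  expect_equal(cm$x[sc3$reference_voxel[1]], 6, tolerance = 0.05)
  expect_error(build_test_case(4), "not implemented|shield")
})

test_that("capsule mask removes the source voxels and metrics respect it", {
  sc <- build_test_case(1, phantom_side = 10.1, phantom_voxel = 0.5,
                        mesh_side = 2.1, mesh_voxel = 0.1)
  mask <- mask_capsule(sc$mesh, sc$capsule)
  expect_gt(sum(mask), 0)
  ctrv <- (sc$mesh$dim + 1) / 2
  expect_true(mask[ctrv[1], ctrv[2], ctrv[3]])
  D <- array(1, sc$mesh$dim)
  dl <- delta_local(D, D, mask = mask)
  expect_true(all(is.na(dl[mask])))
  expect_equal(fraction_within(dl, 0.1), 100)
})

test_that("missing backscatter lowers kerma near the water-air boundary", {
  # the same water cube, with vs without surrounding water (matched seeds)
  n <- 1.5e5
  scA <- build_test_case(1, phantom_side = 20.1, inner_side = 12.1,
                         phantom_voxel = 0.3, mesh_side = 11.5,
                         mesh_voxel = 0.5)
  scB <- build_test_case(2, phantom_side = 20.1, inner_side = 12.1,
                         phantom_voxel = 0.3, mesh_side = 11.5,
                         mesh_voxel = 0.5)
  rA <- run_test_case(scA, n, seed = 13)
  rB <- run_test_case(scB, n, seed = 13)
  fA <- finalize_uncertainty(rA$result$grids[[1]]$tlke)
  fB <- finalize_uncertainty(rB$result$grids[[1]]$tlke)
  r <- voxel_radii(scA$mesh, c(0, 0, 0))
  shell <- r > 5.05 & r < 5.75      # outer 1 cm of the reduced water cube
  lower <- fB$mean[shell] < fA$mean[shell]
  # sign test: far more than half the shell voxels lose backscatter
  expect_gt(mean(lower), 0.75)
})
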