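test_that("uncollided transmission through a water slab follows exp(-mu t)", {
  ph <- cube_phantom(5, 0.5, "water")
  n <- 1e5
  res <- mc_run(ph, src_pencil(c(-5, 0, 0), c(1, 0, 0), 350), n, seed = 71)
  mu <- lookup_mu(load_material("water"), 350, "total") * 0.998
  p <- exp(-mu * 5)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(res$n_uncollided / n - p), 3 * se)
})

test_that("first-interaction depths in a layered phantom match the 1-D oracle", {
  # water | bone | water slabs along x; analogue deposits of primaries give
  # the interaction-depth distribution
  nvx <- 30L
  mats <- rep(c("water", "bone", "water"), each = 10)
  ph <- voxel_phantom(c(nvx, 1L, 1L), c(0.5, 30, 30), c(0, -15, -15), mats)
  mesh <- score_grid(c(nvx, 1L, 1L), c(0.5, 30, 30), c(0, -15, -15),
                     materials = mats, tlke = FALSE, analog = TRUE)
  E <- 100
  n <- 2e5
  res <- mc_run(ph, src_pencil(c(-1, 0.01, 0.01), c(1, 0, 0), E), n,
                seed = 5, grids = list(mesh), primaries_only = TRUE)
  fin <- finalize_uncertainty(res$grids[[1]]$analog)
  # counts per voxel from deposits (each event deposits E/(rho V))
  rho <- mesh$density
  vv <- voxel_volume(mesh)
  counts <- fin$mean * rho * vv / (E * 1000) * n
  # analytic per-voxel first-interaction probabilities
  mu <- vapply(seq_len(nvx), function(i)
    lookup_mu(load_material(mats[i]), E, "total") *
      load_material(mats[i])$density, 0)
  edges <- cumsum(c(0, mu * 0.5))
  pvox <- exp(-edges[-length(edges)]) - exp(-edges[-1])
  expect_gt(sum(pvox), 0.95)  # nearly everything interacts in 15 cm
  z <- (counts - n * pvox) / sqrt(n * pvox * (1 - pvox))
  expect_true(all(abs(z) < 4))
  expect_lt(mean(abs(z)), 1.5)
})

test_that("Compton sampling obeys the kinematic relation and the KN mean", {
  E <- 300
  s <- hdrkerma:::cpp_sample_compton(E, 2e4, seed = 9)
  Ep <- s[, 1]; cost <- s[, 2]
  # kinematic relation holds exactly for every sample
  expect_equal(Ep, E / (1 + E / 510.99895 * (1 - cost)), tolerance = 1e-12)
  # backscatter bound: never below the Compton edge
  expect_true(all(Ep >= E / (1 + 2 * E / 510.99895) - 1e-9))
  # Thomson limit: E' -> E as E -> 0
  s0 <- hdrkerma:::cpp_sample_compton(1, 2000, seed = 10)
  expect_true(all(abs(s0[, 1] / 1 - 1) < 0.01))
  # mean scattered fraction vs quadrature of the KN cross section
  s2 <- hdrkerma:::cpp_sample_compton(350, 1e6, seed = 11)
  frac <- s2[, 1] / 350
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - kn_mean_fraction(350)), 3 * se)
})

test_that("Rayleigh sampling matches quadrature over the form factor", {
  ffd <- read.table(system.file("extdata", "ff", "water.txt",
                                package = "hdrkerma"),
                    comment.char = "#", col.names = c("x", "f2"))
  E <- 350
  cost <- hdrkerma:::cpp_sample_rayleigh(E, 2e5, 13, ffd$x, ffd$f2)
  # oracle: <cos> over (1 + cos^2) F^2 by quadrature in the x^2 domain
  # (where the tabulated F^2 is piecewise linear), with each table bin
  # subdivided to resolve the forward peak
  k2 <- (E / 12.39842)^2
  x2n <- c(ffd$x[ffd$x^2 <= k2]^2, k2)
  grid <- unlist(lapply(seq_len(length(x2n) - 1), function(i)
    seq(x2n[i], x2n[i + 1], length.out = 201)[-201]))
  grid <- c(grid, k2)
  f2 <- approx(ffd$x^2, ffd$f2, xout = grid, rule = 2)$y
  cth2 <- 1 - 2 * grid / k2
  w <- (1 + cth2^2) * f2
  dg <- diff(grid)
  tr <- function(y) sum((y[-1] + y[-length(y)]) / 2 * dg)
  oracle <- tr(w * cth2) / tr(w)
  se <- sd(cost) / sqrt(length(cost))
  expect_lt(abs(mean(cost) - oracle), 3 * se)
})

test_that("runs are bit-reproducible for a fixed seed and energy is conserved", {
  ph <- cube_phantom(6, 0.6, "water")
  mesh <- score_mesh_cube(3, 0.3, analog = TRUE)
  r1 <- mc_run(ph, src_point(c(0, 0, 0), energy = 350), 2e4, seed = 17,
               grids = list(mesh))
  r2 <- mc_run(ph, src_point(c(0, 0, 0), energy = 350), 2e4, seed = 17,
               grids = list(mesh))
  expect_identical(r1$grids[[1]]$tlke$sum, r2$grids[[1]]$tlke$sum)
  expect_identical(r1$escaped, r2$escaped)
  r3 <- mc_run(ph, src_point(c(0, 0, 0), energy = 350), 2e4, seed = 18,
               grids = list(mesh))
  expect_false(identical(r1$grids[[1]]$tlke$sum, r3$grids[[1]]$tlke$sum))
  # per-history energy bookkeeping closes to 1e-9 relative
  expect_lt(r1$conservation_residual, 1e-9)
  expect_equal(r1$emitted, r1$escaped + r1$deposited,
               tolerance = 1e-9)
})

test_that("a photon aimed away from a finite phantom leaves no tally", {
  ph <- cube_phantom(4, 0.5, "water")
  mesh <- score_mesh_cube(4, 0.5)
  res <- mc_run(ph, src_pencil(c(0, 0, 3), c(0, 0, 1), 350), 100, seed = 2,
                grids = list(mesh))
  expect_equal(res$n_uncollided, 100)
  expect_true(all(res$grids[[1]]$tlke$sum == 0))
  expect_equal(res$escaped, res$emitted)
})

test_that("Type A uncertainty scales as 1/sqrt(N)", {
  cap <- generic_hdr_source()
  spec <- ir192_spectrum()
  cell <- cylinder_cell(4.95, 5.05, 0.05, "water")
  r1 <- mc_run(world_sphere(10, "water"), src_capsule(spec), 2e4, seed = 31,
               capsule = cap, cells = list(cell))
  r2 <- mc_run(world_sphere(10, "water"), src_capsule(spec), 8e4, seed = 32,
               capsule = cap, cells = list(cell))
  ratio <- r1$cells[[1]]$rel_se / r2$cells[[1]]$rel_se
  expect_gt(ratio, 2 * 0.8); expect_lt(ratio, 2 * 1.2)
})
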