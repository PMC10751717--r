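test_that("siddon traversal: axis-aligned, oblique, and miss cases", {
  g <- tiny_grid(c(10, 10, 10), rep(0.1, 3), c(0, 0, 0))  # 1 mm voxels, cm
  # axis-aligned 2 mm ray centered on a face between two voxels
  tr <- siddon_traverse(c(0.4, 0.55, 0.55), c(0.6, 0.55, 0.55), g)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$length, c(0.1, 0.1))
  expect_equal(tr$i, c(5, 6))
  # oblique ray against the marching oracle
  p0 <- c(0.02, 0.05, 0.05); p1 <- c(0.18, 0.13, 0.05) + c(0.6, 0.5, 0.3)
  tr <- siddon_traverse(p0, p1, g)
  expect_equal(sum(tr$length), sqrt(sum((p1 - p0)^2)), tolerance = 1e-9)
  oracle <- march_traverse(p0, p1, g, step = 1e-5)
  key <- paste(tr$i, tr$j, tr$k)
  expect_setequal(key, names(oracle))
  expect_equal(tr$length[order(key)],
               as.numeric(oracle[order(names(oracle))]),
               tolerance = 1e-3)
  # ray entirely outside
  expect_equal(nrow(siddon_traverse(c(5, 5, 5), c(6, 6, 6), g)), 0)
  # zero-length ray
  expect_equal(nrow(siddon_traverse(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5), g)), 0)
})

test_that("TLKE contribution is exactly l E muen / V for a single crossing", {
  # vacuum world: a pencil photon crosses the mesh without interacting,
  # so every history scores the same deterministic track-length kerma
  mesh <- score_grid(c(1L, 1L, 1L), c(0.2, 0.2, 0.2), c(-0.1, -0.1, -0.1),
                     materials = "water")
  E <- 350
  res <- mc_run(world_vacuum(), src_pencil(c(-1, 0, 0), c(1, 0, 0), E),
                10, seed = 1, grids = list(mesh))
  g <- res$grids[[1]]$tlke
  muen <- lookup_mu(load_material("water"), E, "muen")
  expected <- 0.2 * E * 1000 * muen / (0.2^3)   # eV/g per history
  expect_equal(g$sum / 10, expected, tolerance = 1e-6)
  # identical histories -> zero variance
  fin <- finalize_uncertainty(g)
  expect_equal(as.numeric(fin$se), 0, tolerance = expected * 1e-9)
})

test_that("history-by-history uncertainty has the textbook closed forms", {
  mk <- function(sum, sumsq, n)
    structure(list(dim = c(1L, 1L, 1L), spacing = rep(1, 3),
                   origin = rep(0, 3), sum = sum, sumsq = sumsq, n = n,
                   estimator = "tlke", units = "eV/g per history"),
              class = "dose_grid")
  # two histories scoring 0 and 2: mean 1, se 1, relative 100%
  fin <- finalize_uncertainty(mk(2, 4, 2))
  expect_equal(as.numeric(fin$mean), 1)
  expect_equal(as.numeric(fin$se), 1)
  expect_equal(as.numeric(fin$rel_se), 1)
  # identical histories: zero uncertainty
  fin2 <- finalize_uncertainty(mk(30, 90, 10))
  expect_equal(as.numeric(fin2$se), 0, tolerance = 1e-12)
  expect_error(finalize_uncertainty(mk(1, 1, 1)), "fewer than 2")
  # k = 2 doubles the standard error
  expect_equal(finalize_uncertainty(mk(2, 4, 2), k = 2)$se[1], 2)
})

test_that("cylindrical cell chords: axis, tangent, and random-ray oracle", {
  cell <- cylinder_cell(0, 0.5, 0.3, "air")
  # along the axis through both caps
  expect_equal(cell_chord(cell, c(0, 0, -2), c(0, 0, 2)), 0.6)
  # tangent ray misses
  expect_equal(cell_chord(cell, c(-2, 0.5000001, 0), c(2, 0.5000001, 0)), 0)
  # annular cell: diameter ray crosses the annulus twice
  ann <- cylinder_cell(0.975, 1.025, 0.05, "air")
  expect_equal(cell_chord(ann, c(-2, 0, 0), c(2, 0, 0)), 0.1)
  # random rays against the marching oracle
  set.seed(99)
  for (i in 1:20) {
    p0 <- runif(3, -2, 2); p1 <- runif(3, -2, 2)
    got <- cell_chord(ann, p0, p1)
    ora <- march_chord(p0, p1, ann$origin, ann$rotation, ann$r_in,
                       ann$r_out, ann$half_h, step = 2e-5)
    expect_lt(abs(got - ora), 2e-4)
  }
  expect_error(cylinder_cell(0.5, 0.4, 0.1), "degenerate")
})

test_that("analogue scorer deposits transferred energy in the event voxel", {
  # a fully absorbing scene: grid total must equal the deposited-energy
  # bookkeeping of the engine (conservation across scorers)
  ph <- cube_phantom(30, 1, "water")
  mesh <- score_grid(ph$dim, ph$spacing, ph$origin, materials = "water",
                     tlke = FALSE, analog = TRUE)
  res <- mc_run(ph, src_point(c(0, 0, 0), energy = 80), 2e3, seed = 4,
                grids = list(mesh))
  g <- res$grids[[1]]$analog
  vv <- voxel_volume(mesh)
  total_keV <- sum(g$sum) * 0.998 * vv / 1000
  expect_equal(total_keV, res$deposited, tolerance = 1e-6)
})

test_that("TLKE and analogue scorers agree within combined uncertainties", {
  scene <- build_test_case(1, phantom_side = 16.1, phantom_voxel = 0.3,
                           mesh_side = 4.4, mesh_voxel = 0.4, analog = TRUE)
  run <- run_test_case(scene, histories = 2e5, seed = 12)
  ft <- finalize_uncertainty(run$result$grids[[1]]$tlke)
  fa <- finalize_uncertainty(run$result$grids[[1]]$analog)
  r <- voxel_radii(scene$mesh, scene$source_position)
  sel <- r >= 0.8 & r <= 2 & !run$mask
  z <- (ft$mean[sel] - fa$mean[sel]) / sqrt(ft$se[sel]^2 + fa$se[sel]^2)
  expect_gt(mean(abs(z) < 3), 0.95)
})

test_that("primary-only TLKE kerma matches the point-source closed form", {
  spec_E <- 350
  cells <- lapply(c(2, 5, 10), function(r)
    cylinder_cell(r - 0.025, r + 0.025, 0.05, "water"))
  res <- mc_run(world_sphere(15, "water"), src_point(energy = spec_E),
                3e5, seed = 21, cells = cells, primaries_only = TRUE)
  w <- load_material("water")
  mu <- lookup_mu(w, spec_E, "total") * 0.998
  muen <- lookup_mu(w, spec_E, "muen")
  for (i in seq_along(cells)) {
    r <- c(2, 5, 10)[i]
    expected <- spec_E * 1000 * muen * exp(-mu * r) / (4 * pi * r^2)
    got <- res$cells[[i]]$mean
    se <- res$cells[[i]]$se
    expect_lt(abs(got - expected), 3 * se + 1e-3 * expected)
  }
})
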