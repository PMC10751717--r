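test_that("capsule-core emission is uniform, isotropic and contained", {
  spec <- ir192_spectrum()
  em <- hdrkerma:::cpp_emit(0.03, 0.175, cbind(spec$energy, spec$intensity),
                            1e5, seed = 8)
  # containment in the core cylinder
  r <- sqrt(em[, 2]^2 + em[, 3]^2)
  expect_true(all(r <= 0.03))
  expect_true(all(abs(em[, 4]) <= 0.175))
  # mean position at the core center within 3 standard errors
  for (j in 2:4) {
    se <- sd(em[, j]) / sqrt(nrow(em))
    expect_lt(abs(mean(em[, j])), 3 * se)
  }
  # direction cosines uniform on [-1, 1] (Kolmogorov-Smirnov, alpha 0.01)
  ks <- suppressWarnings(ks.test(em[, 7], "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
  expect_equal(sqrt(em[, 5]^2 + em[, 6]^2 + em[, 7]^2), rep(1, nrow(em)),
               tolerance = 1e-9)
})

test_that("phase-space files round trip losslessly and validate headers", {
  set.seed(1)
  rec <- cbind(runif(1000, 60, 612), matrix(rnorm(3000, 0, 0.03), 1000),
               matrix(rnorm(3000), 1000), runif(1000))
  # normalize directions
  nn <- sqrt(rowSums(rec[, 5:7]^2))
  rec[, 5:7] <- rec[, 5:7] / nn
  f <- tempfile(fileext = ".psf")
  psf_write(rec, f, capsule_id = "generic", seed = 123)
  back <- psf_read(f)
  expect_equal(unname(back$records), unname(rec), tolerance = 0) # bit-exact
  expect_equal(back$header$capsule_id, "generic")
  expect_equal(back$header$n_records, 1000)
  # empty file: valid header, zero records
  f2 <- tempfile(fileext = ".psf")
  psf_write(rec[0, , drop = FALSE], f2)
  expect_equal(nrow(psf_read(f2)$records), 0)
  # truncation is detected with an offset
  raw <- readBin(f, "raw", file.size(f))
  writeBin(raw[1:(length(raw) - 16)], f)
  expect_error(psf_read(f), "truncated.*offset")
  # bad magic
  f3 <- tempfile()
  writeBin(charToRaw("NOTPSF"), f3)
  expect_error(psf_read(f3), "bad magic")
})

test_that("dwell weights are proportional to dwell times", {
  mk <- function(times) {
    dwells <- lapply(seq_along(times), function(i)
      dwell_position(c(i, 0, 0), times[i]))
    treatment_plan(dwells, 10, c(0, 0, 0))
  }
  expect_equal(dwell_weights(mk(c(1, 1))), c(0.5, 0.5))
  expect_equal(dwell_weights(mk(c(3, 1))), c(0.75, 0.25))
  expect_equal(dwell_weights(mk(c(0, 2, 2)))[1], 0)
  expect_error(mk(c(0, 0)), "positive time")
})

test_that("dwell sampling frequencies follow the time weights (chi-square)", {
  plan <- lung_like_plan(seed = 3)
  w <- dwell_weights(plan)
  expect_equal(sum(w), 1)
  set.seed(10)
  rec <- c(350, 0, 0, 0, 0, 0, 1, 1)
  counts <- integer(length(w))
  for (i in 1:2e4) {
    cl <- plan_source_batch(plan, rec, split = 5)
    for (c_ in cl) {
      # recover the dwell from the clone position (unique z offsets)
      d <- which.min(vapply(plan$dwells, function(dw)
        sum((c_$position - dw$position)^2), 0))
      counts[d] <- counts[d] + 1
    }
  }
  expect_gt(chisq.test(counts, p = w)$p.value, 0.01)
})

test_that("plan-source transform: identity, weight conservation, rotation", {
  rec <- c(316.5, 0.01, -0.02, 0.1, 0, 0, 1, 1)
  # identity dwell at the origin reproduces the record
  d0 <- dwell_position(c(0, 0, 0), 1)
  cl <- transform_record(rec, d0)
  expect_equal(cl$position, rec[2:4])
  expect_equal(cl$direction, rec[5:7])
  expect_equal(cl$energy, rec[1])
  # split clones carry total weight 1
  plan <- treatment_plan(list(d0), 10, c(1, 0, 0))
  set.seed(2)
  clones <- plan_source_batch(plan, rec, split = 10)
  expect_equal(sum(vapply(clones, `[[`, 0, "weight")), 1)
  # rotation taking the capsule axis z onto x
  dz2x <- dwell_position(c(0, 0, 0), 1, rotation_between(c(0, 0, 1), c(1, 0, 0)))
  cl2 <- transform_record(c(316.5, 0, 0, 0, 0, 0, 1, 1), dz2x)
  expect_equal(cl2$direction, c(1, 0, 0), tolerance = 1e-12)
})

test_that("catheter orientations follow the path tangents", {
  # straight line: all tangents equal the line direction
  pos <- cbind(1:5 * 0.3, 1:5 * 0.4, 0)
  rots <- catheter_orientation(pos)
  for (R in rots)
    expect_equal(as.numeric(R %*% c(0, 0, 1)), c(0.6, 0.8, 0),
                 tolerance = 1e-9)
  # planar circular arc: interior tangents perpendicular to the radius
  th <- seq(0, pi / 2, length.out = 9)
  arc <- cbind(2 * cos(th), 2 * sin(th), 0)
  rots <- catheter_orientation(arc)
  for (i in 2:8) {
    tg <- as.numeric(rots[[i]] %*% c(0, 0, 1))
    radial <- c(arc[i, 1], arc[i, 2], 0) / 2
    # central differences are chords: |sin| bounded by the chord error
    expect_lt(abs(sum(tg * radial)), sin(diff(th)[1]))
  }
  # two-dwell catheter: both orientations along the segment
  two <- rbind(c(0, 0, 0), c(0, 1, 0))
  rots <- catheter_orientation(two)
  expect_equal(as.numeric(rots[[1]] %*% c(0, 0, 1)), c(0, 1, 0),
               tolerance = 1e-12)
  expect_equal(as.numeric(rots[[2]] %*% c(0, 0, 1)), c(0, 1, 0),
               tolerance = 1e-12)
  expect_error(catheter_orientation(rbind(c(0, 0, 0), c(0, 0, 0))),
               "coincident.*dwell")
})

test_that("splitting leaves tally expectations unchanged", {
  spec <- ir192_spectrum()
  cap <- microselectron_v2_source()
  psf <- generate_psf(cap, spec, 2e4, seed = 44)
  plan <- treatment_plan(list(
    dwell_position(c(-0.8, 0, 0), 2), dwell_position(c(0.8, 0, 0), 1)),
    10, c(0, 0, 1))
  ph <- cube_phantom(10, 0.5, "water")
  cell <- cylinder_cell(1.95, 2.05, 0.2, "water")
  r1 <- mc_run(ph, src_plan(psf, plan, split = 1), 4e4, seed = 5,
               cells = list(cell))
  r10 <- mc_run(ph, src_plan(psf, plan, split = 10), 4e4, seed = 6,
                cells = list(cell))
  z <- (r1$cells[[1]]$mean - r10$cells[[1]]$mean) /
    sqrt(r1$cells[[1]]$se^2 + r10$cells[[1]]$se^2)
  expect_lt(abs(z), 3)
  # split run emits total weight-energy equal to the record energies
  expect_equal(r10$emitted,
               sum(psf[(seq_len(4e4) - 1) %% nrow(psf) + 1, 1] *
                     psf[(seq_len(4e4) - 1) %% nrow(psf) + 1, 8]),
               tolerance = 1e-9)
})

test_that("plan JSON dialect round trips through mm coordinates", {
  plan <- lung_like_plan(seed = 9)
  f <- tempfile(fileext = ".json")
  write_plan(plan, f)
  back <- read_plan(f)
  expect_equal(length(back$dwells), 19)
  expect_equal(back$prescription_dose, 5)
  for (i in c(1, 10, 19)) {
    expect_equal(back$dwells[[i]]$position, plan$dwells[[i]]$position)
    expect_equal(back$dwells[[i]]$time, plan$dwells[[i]]$time)
    expect_equal(back$dwells[[i]]$rotation, plan$dwells[[i]]$rotation,
                 tolerance = 1e-9)
  }
})
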