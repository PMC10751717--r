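test_that("quadrature budget arithmetic", {
  # single component passes through
  b1 <- data.frame(type = "B", value = 0.3)
  expect_equal(quadrature_budget(b1)$total_k1, 0.3)
  # Pythagorean pair
  b2 <- data.frame(type = c("A", "B"), value = c(3, 4))
  q <- quadrature_budget(b2)
  expect_equal(q$total_k1, 5)
  expect_equal(q$total_k2, 10)
  expect_error(quadrature_budget(data.frame(type = "A", value = -1)),
               "negative")
  expect_error(quadrature_budget(data.frame(type = character(0),
                                            value = numeric(0))), "empty")
})

test_that("shipped budget combines to the standard totals", {
  b <- hdr_uncertainty_budget()
  qd <- quadrature_budget(b[b$quantity == "dose_rate_1cm" & b$type == "B", ])
  expect_equal(round(qd$type_b, 2), 0.22)
  qs <- quadrature_budget(b[b$quantity == "sk" & b$type == "B", ])
  expect_equal(round(qs$type_b, 2), 0.09)
})

test_that("Sk of a bare point source has the closed form, independent of d", {
  E <- 350
  air <- load_material("air")
  muen <- lookup_mu(air, E, "muen")
  for (d in c(5, 10)) {
    cell <- cylinder_cell(d - 0.05, d + 0.05, 0.05, "air")
    res <- mc_run(world_vacuum(horizon = d + 2), src_point(energy = E),
                  5e4, seed = 3, cells = list(cell))
    got <- res$cells[[1]]$mean * d^2          # eV cm^2 / g per history
    expected <- E * 1000 * muen / (4 * pi)
    expect_lt(abs(got / expected - 1), 3 * res$cells[[1]]$rel_se + 0.002)
  }
})

test_that("capsule attenuation lowers Sk below the bare spectrum value", {
  spec <- ir192_spectrum()
  sk_caps <- compute_sk(generic_hdr_source(), spec, 1e5, seed = 5)
  # bare-spectrum point source with the same scoring geometry
  cell <- cylinder_cell(9.95, 10.05, 0.05, "air")
  bare <- mc_run(world_vacuum(horizon = 15), src_point(spectrum = spec),
                 1e5, seed = 5, cells = list(cell))
  sk_bare <- bare$cells[[1]]$mean * 1.602176634e-16 * spec$total_yield *
    100 * 3600 / 1e-2
  expect_lt(sk_caps$sk, sk_bare)
  expect_gt(sk_caps$sk, 0.75 * sk_bare)   # attenuation is moderate
})

test_that("Lambda is the ratio of dose rate to Sk and scatter increases it", {
  spec <- ir192_spectrum()
  cap <- generic_hdr_source()
  sk <- compute_sk(cap, spec, 2e5, seed = 7)
  lam <- compute_lambda(cap, spec, 1e5, seed = 8, sk = sk)
  expect_equal(lam$lambda * sk$sk, lam$dose_rate_1cm, tolerance = 1e-12)
  expect_gt(lam$lambda, 0.5); expect_lt(lam$lambda, 1.5)
  lam0 <- compute_lambda(cap, spec, 1e5, seed = 8, sk = sk, scatter = FALSE)
  expect_lt(lam0$lambda, lam$lambda)   # missing scatter at 1 cm
})

test_that("Sk is invariant under rigid rotation of the whole scene", {
  spec <- ir192_spectrum()
  n <- 2e5
  sk1 <- compute_sk(generic_hdr_source(), spec, n, seed = 9)
  # rotate capsule and scoring ring together: axis z -> x
  R <- rotation_between(c(0, 0, 1), c(1, 0, 0))
  cap_r <- generic_hdr_source(rotation = R)
  cell_r <- cylinder_cell(9.95, 10.05, 0.05, "air", rotation = R)
  res <- mc_run(world_vacuum(horizon = 15), src_capsule(spec), n, seed = 10,
                capsule = cap_r, cells = list(cell_r))
  sk2 <- res$cells[[1]]$mean * 1.602176634e-16 * spec$total_yield *
    100 * 3600 / 1e-2
  z <- (sk1$sk - sk2) / (sk1$sk * sqrt(sk1$type_a^2 +
                                         res$cells[[1]]$rel_se^2))
  expect_lt(abs(z), 3)
})

test_that("characterization report file carries the headline numbers", {
  spec <- ir192_spectrum()
  res <- tg43_characterize(generic_hdr_source(), spec, 5e4, seed = 11)
  f <- tempfile(fileext = ".txt")
  write_tg43_report(res, f)
  txt <- readLines(f)
  expect_true(any(grepl("sk_U_per_Bq", txt)))
  expect_true(any(grepl("lambda_cGy_per_hU", txt)))
  expect_true(any(grepl("seed: 11", txt)))
})
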