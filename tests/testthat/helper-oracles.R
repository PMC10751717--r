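# independent oracles used across the suite

# fine-step marching chord of segment p0->p1 through an annular cylinder
march_chord <- function(p0, p1, origin, rotation, r_in, r_out, half_h,
                        step = 1e-4) {
  d <- p1 - p0
  L <- sqrt(sum(d^2))
  n <- max(2L, ceiling(L / step))
  t <- (seq_len(n) - 0.5) / n * L
  u <- d / L
  pts <- t(p0 + outer(u, t))            # n x 3
  loc <- t(t(rotation) %*% (t(pts) - origin))
  r2 <- loc[, 1]^2 + loc[, 2]^2
  inside <- r2 >= r_in^2 & r2 <= r_out^2 & abs(loc[, 3]) <= half_h
  sum(inside) * L / n
}

# fine-step marching voxel traversal oracle
march_traverse <- function(p0, p1, grid, step = 1e-4) {
  d <- p1 - p0
  L <- sqrt(sum(d^2))
  n <- max(2L, ceiling(L / step))
  t <- (seq_len(n) - 0.5) / n * L
  u <- d / L
  pts <- t(p0 + outer(u, t))
  idx <- floor(sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/")) + 1
  ok <- idx[, 1] >= 1 & idx[, 2] >= 1 & idx[, 3] >= 1 &
    idx[, 1] <= grid$dim[1] & idx[, 2] <= grid$dim[2] & idx[, 3] <= grid$dim[3]
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  tab <- tapply(rep(L / n, sum(ok)), key[ok], sum)
  tab
}

# Klein-Nishina differential cross section (unnormalized), cost = cos(theta)
kn_dcs <- function(E, cost) {
  a <- E / 510.99895
  r <- 1 / (1 + a * (1 - cost))
  0.5 * r^2 * (r + 1 / r - (1 - cost^2))
}

# quadrature mean of E'/E over the KN distribution
kn_mean_fraction <- function(E, n = 20001) {
  cost <- seq(-1, 1, length.out = n)
  w <- kn_dcs(E, cost)
  r <- 1 / (1 + E / 510.99895 * (1 - cost))
  sum(w * r) / sum(w)
}

tiny_grid <- function(dim, spacing, origin)
  list(dim = as.integer(dim), spacing = spacing, origin = origin)
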