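#' World definitions for a transport run
#'
#' Three world types surround the (optional) analytic capsule:
#' * `world_vacuum()`: no interactions outside the capsule; tallies are
#'   scored out to a configurable horizon radius,
#' * `world_sphere()`: a homogeneous sphere of one material centred at the
#'   origin (the TG-43 full-scatter water sphere), vacuum outside,
#' * a [voxel_phantom()] transported by Woodcock delta tracking.
#'
#' @param horizon scoring horizon radius in vacuum, cm
#' @param radius sphere radius, cm
#' @param material sphere material name
#' @export
world_vacuum <- function(horizon = 150) {
  structure(list(type = "vacuum", horizon = horizon), class = "mc_world")
}

#' @rdname world_vacuum
#' @export
world_sphere <- function(radius, material = "water") {
  structure(list(type = "sphere", radius = radius, material = material),
            class = "mc_world")
}

#' Monte Carlo sources
#'
#' * `src_capsule()`: primaries born uniformly in the capsule core with
#'   isotropic directions and energies sampled from the line spectrum,
#' * `src_point()` / `src_pencil()`: bare test sources,
#' * `src_plan()`: phase-space replay through a dwell plan — each record is
#'   split into `split` clones of weight `1/split`, each independently
#'   assigned a dwell position (probability proportional to dwell time) and
#'   rigidly transformed by that dwell's frame.
#'
#' @param spectrum an `emission_spectrum`
#' @param position,direction source position / beam direction, cm
#' @param energy monoenergetic line, keV (ignored when `spectrum` given)
#' @param psf phase-space record matrix (columns E, x, y, z, u, v, w, weight,
#'   capsule frame), e.g. from [psf_read()] or a PSF-collection run
#' @param plan a [treatment_plan()]
#' @param split splitting factor (>= 1)
#' @export
src_capsule <- function(spectrum) {
  structure(list(type = "capsule", spectrum = spectrum), class = "mc_source")
}

#' @rdname src_capsule
#' @export
src_point <- function(position = c(0, 0, 0), energy = NULL, spectrum = NULL) {
  structure(list(type = "point", position = position, energy = energy,
                 spectrum = spectrum), class = "mc_source")
}

#' @rdname src_capsule
#' @export
src_pencil <- function(position, direction, energy) {
  structure(list(type = "pencil", position = position,
                 direction = direction / sqrt(sum(direction^2)),
                 energy = energy), class = "mc_source")
}

#' @rdname src_capsule
#' @export
src_plan <- function(psf, plan, split = 10L) {
  stopifnot(split >= 1)
  structure(list(type = "plan", psf = psf, plan = plan,
                 split = as.integer(split)), class = "mc_source")
}

#' Scoring grid attached to a run
#'
#' A voxel mesh (independent of the phantom grid) on which collisional
#' kerma is accumulated by the track-length kerma estimator (TLKE) and/or
#' the analogue event-by-event scorer, with history-by-history variance.
#'
#' @param dim,spacing,origin mesh geometry (as in [voxel_phantom()])
#' @param materials scoring material per voxel (for the muen lookup);
#'   single name recycled
#' @param densities g/cm^3 per voxel (analogue scorer); defaults to nominal
#' @param tlke,analog which estimators to accumulate
#' @export
score_grid <- function(dim, spacing, origin, materials = "water",
                       densities = NULL, tlke = TRUE, analog = FALSE) {
  ph <- voxel_phantom(dim, spacing, origin, materials, densities)
  ph$tlke <- tlke; ph$analog <- analog
  class(ph) <- c("score_grid", "voxel_phantom")
  ph
}

#' Centered cubic scoring mesh
#' @param side mesh side, cm
#' @param voxel voxel size, cm
#' @param center mesh center
#' @param ... passed to [score_grid()]
#' @export
score_mesh_cube <- function(side, voxel, center = c(0, 0, 0), ...) {
  n <- max(1L, as.integer(round(side / voxel)))
  score_grid(c(n, n, n), rep(voxel, 3), center - n * voxel / 2, ...)
}

# assemble the material registry for a run: names -> 0-based ids,
# tables + form factors in id order
material_registry <- function(names) {
  names <- unique(names)
  tabs <- lapply(names, load_material)
  ffdir <- system.file("extdata", "ff", package = "hdrkerma")
  ffs <- lapply(names, function(n) {
    f <- file.path(ffdir, paste0(n, ".txt"))
    if (!file.exists(f)) stop("no form-factor table for material ", n)
    d <- read.table(f, comment.char = "#", col.names = c("x", "f2"))
    list(x = d$x, f2 = d$f2)
  })
  list(names = names,
       id = setNames(seq_along(names) - 1L, names),
       tables = lapply(tabs, function(t)
         list(energy = t$energy, pe = t$pe, compton = t$compton,
              rayleigh = t$rayleigh, total = t$total, muen = t$muen,
              density = t$density)),
       ff = ffs)
}

#' Run the Monte Carlo engine
#'
#' Transports `histories` primary photons (or phase-space records) through
#' the scene and returns the attached tallies with history-by-history
#' Type A statistics. With identical `seed` and configuration a run is
#' bit-reproducible; random streams are derived per history (PCG32 stream
#' = history index), so results are independent of batching.
#'
#' @param world a [world_vacuum()], [world_sphere()] or [voxel_phantom()]
#' @param source an `mc_source`
#' @param histories number of primary histories
#' @param seed integer seed
#' @param capsule optional [source_capsule()] overriding the world locally
#' @param grids list of [score_grid()]s
#' @param cells list of [cylinder_cell()]s scored by the TLKE
#' @param cutoff photon cut-off energy, keV
#' @param majorant_margin safety factor (>= 1) on the Woodcock majorant
#' @param primaries_only if `TRUE`, histories terminate at their first
#'   interaction (closed-form primary kerma checks)
#' @param collect_psf if `TRUE`, record photons leaving the capsule as
#'   phase-space rows (capsule frame); at most `psf_max` rows
#' @param psf_max cap on collected phase-space rows
#' @return an `mc_result`: `grids` (list of [dose_grid] pairs), `cells`
#'   (per-cell mean/se in eV/g/history), counters and run metadata
#' @export
mc_run <- function(world, source, histories, seed, capsule = NULL,
                   grids = list(), cells = list(), cutoff = 1,
                   majorant_margin = 1.01, primaries_only = FALSE,
                   collect_psf = FALSE, psf_max = 1e6) {
  stopifnot(histories >= 1)
  mat_names <- character(0)
  if (inherits(world, "voxel_phantom")) mat_names <- c(mat_names, world$material)
  if (identical(world$type, "sphere")) mat_names <- c(mat_names, world$material)
  if (!is.null(capsule))
    mat_names <- c(mat_names, capsule$core_mat, capsule$cap_mat,
                   capsule$cable_mat)
  for (g in grids) mat_names <- c(mat_names, g$material)
  for (cl in cells) mat_names <- c(mat_names, cl$material)
  if (!length(mat_names)) mat_names <- "water"
  reg <- material_registry(mat_names)

  wcfg <- if (inherits(world, "voxel_phantom")) {
    list(type = "voxel", dim = world$dim, spacing = world$spacing,
         origin = world$origin,
         mat = unname(reg$id[world$material]), rho = world$density)
  } else if (world$type == "sphere") {
    list(type = "sphere", radius = world$radius,
         material = unname(reg$id[world$material]))
  } else list(type = "vacuum", horizon = world$horizon)

  ccfg <- NULL
  if (!is.null(capsule))
    ccfg <- list(origin = capsule$origin, rotation = capsule$rotation,
                 core_r = capsule$core_r, core_hl = capsule$core_hl,
                 core_mat = unname(reg$id[capsule$core_mat]),
                 cap_r = capsule$cap_r, cap_hl = capsule$cap_hl,
                 cap_mat = unname(reg$id[capsule$cap_mat]),
                 cable_r = capsule$cable_r, cable_len = capsule$cable_len,
                 cable_mat = unname(reg$id[capsule$cable_mat]))

  gcfg <- lapply(grids, function(g)
    list(dim = g$dim, spacing = g$spacing, origin = g$origin,
         mat = unname(reg$id[g$material]), rho = g$density,
         tlke = isTRUE(g$tlke), analog = isTRUE(g$analog)))
  rcfg <- lapply(cells, function(cl)
    list(origin = cl$origin, rotation = cl$rotation, r_in = cl$r_in,
         r_out = cl$r_out, half_h = cl$half_h,
         material = unname(reg$id[cl$material])))

  scfg <- switch(source$type,
    capsule = {
      if (is.null(capsule)) stop("src_capsule() requires a capsule")
      list(type = "capsule",
           spectrum = cbind(source$spectrum$energy, source$spectrum$intensity))
    },
    point = list(type = "point", position = source$position,
                 energy = source$energy,
                 spectrum = if (!is.null(source$spectrum))
                   cbind(source$spectrum$energy, source$spectrum$intensity)),
    pencil = list(type = "pencil", position = source$position,
                  direction = source$direction, energy = source$energy),
    plan = {
      pl <- source$plan
      w <- dwell_weights(pl)
      rots <- t(vapply(pl$dwells, function(d) as.numeric(t(d$rotation)),
                       numeric(9)))
      pos <- t(vapply(pl$dwells, function(d) d$position, numeric(3)))
      list(type = "plan", psf = source$psf, dwell_pos = pos,
           dwell_rot = rots, dwell_weights = w, split = source$split)
    })

  cfg <- list(materials = reg$tables, formfactors = reg$ff, world = wcfg,
              capsule = ccfg, grids = gcfg, rings = rcfg, source = scfg,
              histories = as.numeric(histories), seed = as.numeric(seed),
              cutoff = cutoff, majorant_margin = majorant_margin,
              primaries_only = primaries_only, collect_psf = collect_psf,
              psf_max = as.numeric(psf_max))
  raw <- cpp_mc_run(cfg)

  n <- raw$n_histories
  gout <- vector("list", length(grids))
  for (i in seq_along(grids)) {
    g <- grids[[i]]; rg <- raw$grids[[i]]
    gout[[i]] <- list(
      tlke = if (isTRUE(g$tlke))
        new_dose_grid(g, rg$tlke_sum, rg$tlke_sumsq, n, "tlke"),
      analog = if (isTRUE(g$analog))
        new_dose_grid(g, rg$analog_sum, rg$analog_sumsq, n, "analogue"))
  }
  cout <- lapply(raw$rings, function(r) {
    m <- r$sum / n
    va <- (r$sumsq - r$sum^2 / n) / (n - 1)
    se <- sqrt(pmax(va, 0) / n)
    list(mean = m, se = se, rel_se = ifelse(m > 0, se / m, NA_real_))
  })
  structure(list(grids = gout, cells = cout, n_histories = n,
                 emitted = raw$emitted, escaped = raw$escaped,
                 deposited = raw$deposited,
                 conservation_residual = raw$max_conservation_residual,
                 n_uncollided = raw$n_uncollided,
                 psf = raw$psf, seed = seed),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat("<mc_result>", format(x$n_histories, big.mark = ","), "histories\n")
  cat(sprintf("  energy bookkeeping: emitted %.6g, escaped %.6g, deposited %.6g keV\n",
              x$emitted, x$escaped, x$deposited))
  cat(sprintf("  max per-history conservation residual: %.2e (relative)\n",
              x$conservation_residual))
  invisible(x)
}

new_dose_grid <- function(geom, sum, sumsq, n, estimator) {
  structure(list(dim = geom$dim, spacing = geom$spacing,
                 origin = geom$origin, material = geom$material,
                 density = geom$density,
                 sum = sum, sumsq = sumsq, n = n, estimator = estimator,
                 units = "eV/g per history"),
            class = "dose_grid")
}

#' Dose grid accessors and Type A uncertainty
#'
#' `finalize_uncertainty()` turns the per-voxel history accumulators of a
#' `dose_grid` into the per-history mean, its standard error
#' `s/sqrt(N)` (history-by-history estimate, coverage factor k = 1), and
#' the relative Type A uncertainty, defined only where the mean is
#' positive.
#'
#' @param grid a `dose_grid` from [mc_run()]
#' @param k coverage factor annotation (1 or 2)
#' @return list with 3D arrays `mean`, `se`, `rel_se`, plus `n` and `k`
#' @export
finalize_uncertainty <- function(grid, k = 1) {
  n <- grid$n
  if (n < 2) stop("Type A uncertainty undefined for fewer than 2 histories")
  m <- grid$sum / n
  va <- (grid$sumsq - grid$sum^2 / n) / (n - 1)
  se <- k * sqrt(pmax(va, 0) / n)
  rel <- ifelse(m > 0, se / m, NA_real_)
  list(mean = array(m, grid$dim), se = array(se, grid$dim),
       rel_se = array(rel, grid$dim), n = n, k = k,
       estimator = grid$estimator)
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid>", x$estimator, "estimator,",
      paste(x$dim, collapse = " x "), "voxels,",
      format(x$n, big.mark = ","), "histories\n")
  fin <- finalize_uncertainty(x)
  pos <- fin$mean > 0
  if (any(pos))
    cat(sprintf("  mean kerma (positive voxels): %.4g %s; median rel. unc. %.3g\n",
                mean(fin$mean[pos]), x$units, median(fin$rel_se[pos], na.rm = TRUE)))
  invisible(x)
}

#' Voxel center coordinates of a grid
#' @param grid a `dose_grid`, `voxel_phantom` or `score_grid`
#' @return list of vectors `x`, `y`, `z` (cm)
#' @export
voxel_centers <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$dim[1]) - 0.5) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$dim[2]) - 0.5) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(grid$dim[3]) - 0.5) * grid$spacing[3])
}

#' Distance of each voxel center from a point
#' @param grid a grid-like object
#' @param point 3-vector, cm
#' @return 3D array of distances, cm
#' @export
voxel_radii <- function(grid, point = c(0, 0, 0)) {
  ctr <- voxel_centers(grid)
  dx2 <- (ctr$x - point[1])^2
  dy2 <- (ctr$y - point[2])^2
  dz2 <- (ctr$z - point[3])^2
  sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
}

#' Exact voxel traversal of a segment (Siddon walk)
#'
#' Returns the ordered voxels crossed by the segment `p0 -> p1` and the
#' chord length in each; voxels outside the grid are skipped. Boundary
#' crossings follow the half-open voxel convention; zero-length corner
#' grazes are dropped.
#'
#' @param p0,p1 endpoints, cm
#' @param grid any grid-like object (`dim`, `spacing`, `origin`)
#' @return data.frame with 1-based `i`, `j`, `k` and `length` (cm)
#' @export
siddon_traverse <- function(p0, p1, grid) {
  r <- cpp_siddon(as.numeric(p0), as.numeric(p1), grid$dim, grid$spacing,
                  grid$origin)
  data.frame(i = r$i, j = r$j, k = r$k, length = r$length)
}
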