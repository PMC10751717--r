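# Synthetic fixtures: deterministic scene/plan/structure generators that
# emulate the benchmark and clinical scenarios without any external data.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    else rm(".Random.seed", envir = .GlobalEnv)
  })
  force(code)
}

ellipse_poly <- function(cx, cy, a, b, n = 24) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + a * cos(th), cy + b * sin(th))
}

#' Synthetic prostate-like treatment plan
#'
#' Seventeen parallel catheters along z in a hexagonal-ish grid covering
#' an ellipsoidal target, carrying 111 active dwell positions in total
#' (0.5 cm steps), with seeded dwell times and a 15 Gy single-fraction
#' prescription — the scale of a typical HDR prostate implant.
#'
#' @param seed RNG seed for the dwell times
#' @return a [treatment_plan()]
#' @export
prostate_like_plan <- function(seed = 1) {
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  xy <- rbind(c(0, 0),
              cbind(1.1 * cos(ang), 1.1 * sin(ang)),
              cbind(2.0 * cos(ang + pi / 8), 2.0 * sin(ang + pi / 8)))
  # 17 catheters: 9 inner (7 dwells) + 8 outer (6 dwells) = 111 dwells
  ndw <- c(rep(7, 9), rep(6, 8))
  with_seed(seed, {
    dwells <- list()
    for (ci in seq_len(17)) {
      n <- ndw[ci]
      z <- (seq_len(n) - (n + 1) / 2) * 0.5
      pos <- cbind(xy[ci, 1], xy[ci, 2], z)
      rots <- catheter_orientation(pos)
      times <- round(runif(n, 5, 25), 1)
      for (i in seq_len(n))
        dwells[[length(dwells) + 1]] <-
          dwell_position(pos[i, ], times[i], rots[[i]],
                         sprintf("cat%02d", ci))
    }
    treatment_plan(dwells, prescription_dose = 15,
                   prescription_point = c(2.0, 0, 0))
  })
}

#' Synthetic palliative lung-like plan
#'
#' A single catheter with 19 active dwell positions (0.5 cm steps)
#' following a gently curved endobronchial path, 5 Gy prescribed at 1 cm
#' from the catheter.
#'
#' @param seed RNG seed for the dwell times
#' @export
lung_like_plan <- function(seed = 1) {
  s <- (seq_len(19) - 10) * 0.5
  pos <- cbind(-2 + 0.08 * s^2, 0.05 * s, s)   # curved path, cm
  rots <- catheter_orientation(pos)
  with_seed(seed, {
    times <- round(runif(19, 8, 20), 1)
    dwells <- lapply(seq_len(19), function(i)
      dwell_position(pos[i, ], times[i], rots[[i]], "bronchial"))
    treatment_plan(dwells, prescription_dose = 5,
                   prescription_point = pos[10, ] + c(1, 0, 0))
  })
}

#' Synthetic patient structure sets
#'
#' Programmatic bodies emulating the clinical scenarios: an
#' elliptic-cylinder body with an ellipsoidal target, tubular urethra and
#' rectum and an ellipsoidal bladder (prostate-like); or a body with two
#' lung ellipsoids and a tubular bronchus (lung-like). All purely
#' synthetic; coordinates in cm.
#'
#' @param nz number of contoured slices
#' @param dz slice spacing, cm
#' @return a [structure_set()]
#' @export
prostate_like_structures <- function(nz = 21, dz = 0.4) {
  zs <- (seq_len(nz) - (nz + 1) / 2) * dz
  tgt <- list(); ure <- list(); rec <- list(); bla <- list(); bod <- list()
  for (z in zs) {
    bod[[length(bod) + 1]] <- list(z = z, points = ellipse_poly(0, 0, 8, 8))
    f <- 1 - (z / 2.2)^2               # target semi-axis profile
    if (f > 0.05) {
      tgt[[length(tgt) + 1]] <-
        list(z = z, points = ellipse_poly(0, 0, 2.6 * sqrt(f), 2.3 * sqrt(f)))
      ure[[length(ure) + 1]] <-
        list(z = z, points = ellipse_poly(0, 0, 0.3, 0.3, n = 12))
    }
    rec[[length(rec) + 1]] <-
      list(z = z, points = ellipse_poly(0, -3.4, 1.2, 1.0))
    fb <- 1 - ((z - 1) / 2.5)^2
    if (fb > 0.05)
      bla[[length(bla) + 1]] <-
        list(z = z, points = ellipse_poly(0, 3.4, 2.2 * sqrt(fb),
                                          1.8 * sqrt(fb)))
  }
  structure_set(list(
    structure_def("prostate", "target", tgt),
    structure_def("urethra", "oar", ure),
    structure_def("rectum", "oar", rec),
    structure_def("bladder", "oar", bla),
    structure_def("body", "body", bod)))
}

#' @rdname prostate_like_structures
#' @export
lung_like_structures <- function(nz = 21, dz = 0.5) {
  zs <- (seq_len(nz) - (nz + 1) / 2) * dz
  ll <- list(); rl <- list(); br <- list(); bod <- list()
  zmax <- max(abs(zs))
  for (z in zs) {
    bod[[length(bod) + 1]] <- list(z = z, points = ellipse_poly(0, 0, 12, 9))
    f <- 1 - (z / (zmax + 0.5))^2
    if (f > 0.05) {
      ll[[length(ll) + 1]] <-
        list(z = z, points = ellipse_poly(-4.5, 0, 3.5 * sqrt(f),
                                          5.5 * sqrt(f)))
      rl[[length(rl) + 1]] <-
        list(z = z, points = ellipse_poly(4.5, 0, 3.5 * sqrt(f),
                                          5.5 * sqrt(f)))
    }
    br[[length(br) + 1]] <-
      list(z = z, points = ellipse_poly(-2 + 0.08 * z^2, 0.05 * z,
                                        0.6, 0.6, n = 12))
  }
  structure_set(list(
    structure_def("lung_left", "oar", ll),
    structure_def("lung_right", "oar", rl),
    structure_def("bronchus", "oar", br),
    structure_def("body", "body", bod)))
}

#' Synthetic CT-like intensity grid
#'
#' A simple intensity model for segmentation tests: body tissue at ~0,
#' air at -1000, an optional high-intensity bone ellipsoid (~1200)
#' enabling intensity-range thresholding inside the body contour.
#'
#' @param grid grid geometry
#' @param set a [structure_set()] (used for the body outline)
#'   disables it
#' @param bone_center,bone_semiaxes optional bone ellipsoid (cm)
#' @return 3D intensity array
#' @export
synthetic_intensity <- function(grid, set, bone_center = NULL,
                                bone_semiaxes = c(1.5, 1, 1.5)) {
  body <- structure_mask(set, "body", grid)
  intens <- array(-1000, grid$dim)
  intens[body] <- 0
  if (!is.null(bone_center)) {
    ctr <- voxel_centers(grid)
    for (k in seq_len(grid$dim[3])) {
      dz <- (ctr$z[k] - bone_center[3]) / bone_semiaxes[3]
      if (abs(dz) > 1) next
      dx <- (ctr$x - bone_center[1]) / bone_semiaxes[1]
      dy <- (ctr$y - bone_center[2]) / bone_semiaxes[2]
      sl <- outer(dx^2, dy^2, `+`) + dz^2 <= 1
      intens[, , k][sl] <- 1200
    }
  }
  intens
}

#' Write a deterministic fixture to disk
#'
#' Produces the scene/plan/structure files for one of the named
#' scenarios: the water/air cube benchmark scenes (`testcase1` to
#' `testcase3`) or the synthetic clinical scenarios (`prostate_like`:
#' 17 catheters / 111 dwells / 15 Gy; `lung_like`: 1 catheter / 19
#' dwells / 5 Gy at 1 cm). Output is byte-deterministic for a given seed.
#'
#' @param kind scenario name
#' @param scale `"reduced"` (desk-size grids) or `"full"` (benchmark
#'   dimensions)
#' @param seed integer seed
#' @param dir output directory (created if needed)
#' @return invisibly, the written file paths
#' @export
generate_fixture <- function(kind = c("testcase1", "testcase2", "testcase3",
                                      "prostate_like", "lung_like"),
                             scale = c("reduced", "full"), seed, dir) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  red <- scale == "reduced"
  if (startsWith(kind, "testcase")) {
    case <- as.integer(substr(kind, 9, 9))
    cfg <- list(
      format = "hdrkerma-scene", version = 1L, kind = kind, seed = seed,
      case = case,
      phantom_side_cm = if (red) 20.1 else 51.1,
      inner_side_cm = if (case == 1) NULL else if (red) 12.1 else 20.1,
      phantom_voxel_cm = if (red) 0.3 else 0.7,
      mesh_side_cm = if (red) 4.1 else 20.1,
      mesh_voxel_cm = 0.1,
      source = "generic_hdr",
      transport = list(photon_cutoff_keV = 1, electron_transport = FALSE))
    p <- file.path(dir, paste0(kind, "_scene.yaml"))
    yaml::write_yaml(cfg, p)
    paths <- c(paths, p)
  } else {
    plan <- if (kind == "prostate_like") prostate_like_plan(seed)
            else lung_like_plan(seed)
    set <- if (kind == "prostate_like") prostate_like_structures()
           else lung_like_structures()
    pp <- file.path(dir, paste0(kind, "_plan.json"))
    ps <- file.path(dir, paste0(kind, "_structures.json"))
    write_plan(plan, pp)
    write_structures(set, ps)
    cfg <- list(format = "hdrkerma-scene", version = 1L, kind = kind,
                seed = seed, plan = basename(pp), structures = basename(ps),
                grid_voxel_cm = if (red) 0.4 else 0.2,
                scatter_shell_cm = 20,
                source = "microselectron_v2",
                transport = list(photon_cutoff_keV = 1,
                                 electron_transport = FALSE,
                                 psf_split = 10))
    pc <- file.path(dir, paste0(kind, "_scene.yaml"))
    yaml::write_yaml(cfg, pc)
    paths <- c(paths, pp, ps, pc)
  }
  invisible(paths)
}
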