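#' Structure sets
#'
#' Contoured structures as stacks of closed planar polygons in patient
#' coordinates (the JSON dialect stores mm, DICOM convention; converted
#' to cm at this boundary).
#'
#' @param name structure name
#' @param role one of `"target"`, `"oar"`, `"body"`, `"bone"`
#' @param contours list of `list(z, points)` with `z` in cm and `points`
#'   an n x 2 matrix (cm)
#' @export
structure_def <- function(name, role, contours) {
  for (ct in contours) {
    p <- ct$points
    if (nrow(p) < 3) stop("contour with fewer than 3 points in ", name)
  }
  list(name = name, role = role, contours = contours)
}

#' @rdname structure_def
#' @param structures list of [structure_def()]s
#' @export
structure_set <- function(structures) {
  structure(list(structures = structures,
                 names = vapply(structures, `[[`, "", "name")),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set>", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write the JSON structure dialect
#' @param path file path
#' @export
read_structures <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(j$format, "hdrkerma-structs"))
    stop("not an hdrkerma structure file: ", path)
  if (j$version > 1) stop("unsupported structure format version ", j$version)
  structure_set(lapply(j$structures, function(s) {
    structure_def(s$name, s$role, lapply(s$contours, function(ct) {
      pts <- do.call(rbind, lapply(ct$points_mm, unlist)) / 10
      list(z = ct$z_mm / 10, points = pts)
    }))
  }))
}

#' @rdname read_structures
#' @param set a [structure_set()]
#' @export
write_structures <- function(set, path) {
  j <- list(format = "hdrkerma-structs", version = 1L,
            generator = paste0("hdrkerma ",
                               as.character(packageVersion("hdrkerma"))),
            structures = lapply(set$structures, function(s) {
              list(name = s$name, role = s$role,
                   contours = lapply(s$contours, function(ct) {
                     list(z_mm = ct$z * 10,
                          points_mm = apply(ct$points * 10, 1, as.list,
                                            simplify = FALSE))
                   }))
            }))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Voxel membership mask of a structure
#'
#' Point-in-polygon membership of voxel centers, slice by slice: each
#' contour is applied to the grid slice whose plane is nearest to the
#' contour's z (within half a slice spacing); multiple contours on a
#' slice are united. No partial-volume weighting.
#'
#' @param set a [structure_set()]
#' @param name structure name
#' @param grid grid geometry (`dim`, `spacing`, `origin`)
#' @return logical 3D array
#' @export
structure_mask <- function(set, name, grid) {
  idx <- match(name, set$names)
  if (is.na(idx)) stop("unknown structure: ", name)
  s <- set$structures[[idx]]
  ctr <- voxel_centers(grid)
  mask <- array(FALSE, grid$dim)
  pts2 <- as.matrix(expand.grid(x = ctr$x, y = ctr$y))
  for (ct in s$contours) {
    k <- which.min(abs(ctr$z - ct$z))
    if (abs(ctr$z[k] - ct$z) > grid$spacing[3] / 2 + 1e-9) next
    poly <- ct$points
    if (any(poly[1, ] != poly[nrow(poly), ]))
      poly <- rbind(poly, poly[1, ])
    inside <- mgcv::in.out(poly, pts2)
    mask[, , k] <- mask[, , k] | matrix(inside, grid$dim[1], grid$dim[2])
  }
  mask
}

#' Material assignment from contours and intensity ranges
#'
#' Builds a phantom by applying rules in order: a voxel is claimed by the
#' first rule whose structure contains its center and (optionally) whose
#' intensity range contains the voxel intensity. Rules with
#' `structure = "body"`-role structures typically come last as the
#' default. Unclaimed voxels raise an error reporting their count.
#'
#' @param intensity 3D array of voxel intensities (CT-like numbers)
#' @param set a [structure_set()]
#' @param rules list of `list(structure =, material =, range = c(lo, hi))`
#'   (`range` optional)
#' @param grid grid geometry the intensity array lives on
#' @param outside material for voxels outside every structure (default
#'   `NULL`: such voxels are an error)
#' @return a [voxel_phantom()]
#' @export
assign_materials <- function(intensity, set, rules, grid, outside = NULL) {
  mat <- array(NA_character_, grid$dim)
  for (rule in rules) {
    m <- structure_mask(set, rule$structure, grid)
    claim <- m & is.na(mat)
    if (!is.null(rule$range))
      claim <- claim & intensity >= rule$range[1] & intensity <= rule$range[2]
    mat[claim] <- rule$material
  }
  un <- is.na(mat)
  if (any(un)) {
    if (is.null(outside))
      stop(sum(un), " voxels matched no assignment rule and no 'outside' ",
           "material was given")
    mat[un] <- outside
  }
  voxel_phantom(grid$dim, grid$spacing, grid$origin, as.character(mat))
}

#' Pad a phantom with a full-scatter shell
#'
#' Pads the grid on all faces by `thickness` of `material` (e.g. the
#' 20 cm water shell ensuring full scatter around a patient volume). The
#' original voxels, and any scoring region defined on them, are unchanged.
#'
#' @param phantom a [voxel_phantom()]
#' @param thickness shell thickness, cm
#' @param material shell material
#' @export
add_scatter_shell <- function(phantom, thickness, material = "water") {
  stopifnot(thickness >= 0)
  if (thickness == 0) return(phantom)
  npad <- ceiling(thickness / phantom$spacing)
  nd <- phantom$dim + 2L * as.integer(npad)
  m <- array(material, nd)
  d <- array(load_material(material)$density, nd)
  i1 <- npad[1] + seq_len(phantom$dim[1])
  i2 <- npad[2] + seq_len(phantom$dim[2])
  i3 <- npad[3] + seq_len(phantom$dim[3])
  m[i1, i2, i3] <- array(phantom$material, phantom$dim)
  d[i1, i2, i3] <- array(phantom$density, phantom$dim)
  voxel_phantom(nd, phantom$spacing, phantom$origin - npad * phantom$spacing,
                as.character(m), as.numeric(d))
}

#' Absolute plan dose normalization
#'
#' Scales a per-history kerma grid so that the prescription point receives
#' the prescribed dose (an exact arithmetic identity at that voxel).
#'
#' @param fin finalized grid (from [finalize_uncertainty()])
#' @param grid the scoring-grid geometry
#' @param plan a [treatment_plan()]
#' @return list: `dose` (Gy array), `scale`, `prescription_voxel`
#' @export
normalize_plan_dose <- function(fin, grid, plan) {
  ctr <- voxel_centers(grid)
  pv <- c(which.min(abs(ctr$x - plan$prescription_point[1])),
          which.min(abs(ctr$y - plan$prescription_point[2])),
          which.min(abs(ctr$z - plan$prescription_point[3])))
  ref <- fin$mean[matrix(pv, ncol = 3)]
  if (!is.finite(ref) || ref <= 0)
    stop("no dose scored at the prescription point")
  scale <- plan$prescription_dose / ref
  list(dose = fin$mean * scale, scale = scale, prescription_voxel = pv)
}

#' Cumulative dose-volume histogram
#'
#' For each dose level `d` (at `resolution` spacing), the volume fraction
#' of the structure receiving at least `d`. Starts at 100% at 0 Gy and is
#' non-increasing.
#'
#' @param dose 3D dose array, Gy
#' @param mask logical 3D array selecting the structure's voxels
#' @param voxel_volume voxel volume, cm^3
#' @param name structure name carried in the curve
#' @param resolution dose-axis resolution, Gy
#' @return a `dvh_curve`: `dose` (Gy), `volume` (%), `voxel_volume`,
#'   `total_volume` (cm^3), `structure`
#' @export
cumulative_dvh <- function(dose, mask, voxel_volume, name = "structure",
                           resolution = 0.01) {
  v <- dose[mask]
  if (!length(v)) stop("empty structure: ", name)
  levels <- seq(0, max(v) + resolution, by = resolution)
  vol <- vapply(levels, function(d) 100 * mean(v >= d), 0)
  structure(list(dose = levels, volume = vol, voxel_volume = voxel_volume,
                 total_volume = length(v) * voxel_volume,
                 structure = name),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat("<dvh_curve>", x$structure, sprintf("(%.2f cm^3),", x$total_volume),
      length(x$dose), "levels up to", max(x$dose), "Gy\n")
  invisible(x)
}

#' @export
plot.dvh_curve <- function(x, ...) {
  graphics::plot(x$dose, x$volume, type = "l", xlab = "dose (Gy)",
                 ylab = "volume (%)", main = x$structure, ...)
  invisible(x)
}

#' DVH metrics
#'
#' `Vx`: volume percentage receiving at least `x`% of the prescription;
#' `Dy`: greatest dose received by at least `y`% of the volume (inverse
#' curve lookup with linear interpolation); `D2cc`: greatest dose received
#' by at least 2 cm^3 (`NA` with a flag when the structure is smaller).
#'
#' @param curve a [cumulative_dvh()] result
#' @param prescription prescription dose, Gy
#' @return list: `V100`, `V150`, `V200` (%), `D90`, `D50`, `D2cc` (Gy),
#'   `d2cc_defined`
#' @export
dvh_metrics <- function(curve, prescription) {
  v_at <- function(d) {
    if (d <= 0) return(100)
    if (d > max(curve$dose)) return(0)
    approx(curve$dose, curve$volume, xout = d, ties = "ordered")$y
  }
  d_at <- function(vol_pct) {
    # greatest dose with volume >= vol_pct; curve is non-increasing
    if (vol_pct > curve$volume[1]) return(0)
    idx <- which(curve$volume >= vol_pct)
    i <- max(idx)
    if (i == length(curve$dose)) return(curve$dose[i])
    v1 <- curve$volume[i]; v2 <- curve$volume[i + 1]
    if (v2 == v1) return(curve$dose[i])
    curve$dose[i] + (curve$dose[i + 1] - curve$dose[i]) *
      (v1 - vol_pct) / (v1 - v2)
  }
  d2cc_ok <- curve$total_volume >= 2
  list(V100 = v_at(prescription), V150 = v_at(1.5 * prescription),
       V200 = v_at(2 * prescription),
       D90 = d_at(90), D50 = d_at(50),
       D2cc = if (d2cc_ok) d_at(100 * 2 / curve$total_volume) else NA_real_,
       d2cc_defined = d2cc_ok)
}

#' Two-column text export of a DVH curve
#' @param curve a `dvh_curve`
#' @param path output path
#' @export
write_dvh <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# hdrkerma DVH: ", curve$structure),
               sprintf("# total_volume_cm3: %.4f", curve$total_volume),
               "# columns: dose_Gy volume_pct"), con)
  write.table(data.frame(curve$dose, curve$volume), con,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
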