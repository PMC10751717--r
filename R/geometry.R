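#' Voxelized phantom
#'
#' Right-handed coordinates in cm; voxel `(i,j,k)` (1-based in R) occupies
#' the half-open box `[origin + (i-1)*spacing, origin + i*spacing)`.
#'
#' @param dim integer vector `(nx, ny, nz)`
#' @param spacing voxel spacing per axis, cm (length 1 or 3)
#' @param origin corner of voxel (1,1,1), cm
#' @param materials character: material name per voxel (single value is
#'   recycled), or an integer/character array of length `prod(dim)`
#' @param densities g/cm^3 per voxel; defaults to each material's nominal
#'   density
#' @return a `voxel_phantom`: fields `dim`, `spacing`, `origin`,
#'   `material` (character vector, voxel-major x fastest), `density`
#' @export
voxel_phantom <- function(dim, spacing, origin, materials, densities = NULL) {
  dim <- as.integer(dim)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(dim) == 3, all(dim > 0), all(spacing > 0),
            length(origin) == 3)
  nv <- prod(dim)
  materials <- rep_len(as.character(materials), nv)
  if (is.null(densities)) {
    dens_of <- vapply(unique(materials),
                      function(m) load_material(m)$density, 0)
    densities <- unname(dens_of[materials])
  } else densities <- rep_len(densities, nv)
  if (any(densities <= 0)) stop("densities must be positive")
  structure(list(dim = dim, spacing = spacing, origin = as.numeric(origin),
                 material = materials, density = densities),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat("<voxel_phantom>", paste(x$dim, collapse = " x "), "voxels,",
      paste(signif(x$spacing, 4), collapse = " x "), "cm spacing\n")
  cat("  extent:", paste(signif(x$dim * x$spacing, 4), collapse = " x "),
      "cm; materials:", paste(unique(x$material), collapse = ", "), "\n")
  invisible(x)
}

#' Voxel volume of a phantom or dose grid, cm^3
#' @param x a `voxel_phantom` or `dose_grid`
#' @export
voxel_volume <- function(x) prod(x$spacing)

#' Homogeneous cube phantom
#'
#' @param side cube side, cm
#' @param voxel voxel size, cm
#' @param material material name
#' @param center cube center, cm
#' @export
cube_phantom <- function(side, voxel, material = "water",
                         center = c(0, 0, 0)) {
  n <- max(1L, as.integer(round(side / voxel)))
  voxel_phantom(c(n, n, n), voxel, center - n * voxel / 2, material)
}

#' Analytic source capsule
#'
#' The radioactive core is a cylinder inside a coaxial steel capsule, with
#' an optional drive-cable stub attached at the proximal (-z) end. Wherever
#' the capsule overlaps a voxel grid the analytic solids take priority.
#' Dimensions are configuration; the two shipped configurations
#' ([generic_hdr_source()], [microselectron_v2_source()]) are simplified
#' models built from published source descriptions.
#'
#' @param core_radius,core_half_length core cylinder, cm
#' @param capsule_radius,capsule_half_length outer capsule cylinder, cm
#' @param cable_radius,cable_length cable stub, cm (`cable_length = 0`
#'   disables it)
#' @param core_material,capsule_material,cable_material material names
#' @param origin capsule center, cm (world frame)
#' @param rotation 3x3 rotation matrix, capsule local frame to world
#' @return a `source_capsule`
#' @export
source_capsule <- function(core_radius, core_half_length,
                           capsule_radius, capsule_half_length,
                           cable_radius = 0, cable_length = 0,
                           core_material = "iridium",
                           capsule_material = "steel316",
                           cable_material = "steel316",
                           origin = c(0, 0, 0), rotation = diag(3)) {
  stopifnot(core_radius > 0, core_half_length > 0,
            capsule_radius > core_radius,
            capsule_half_length > core_half_length)
  structure(list(core_r = core_radius, core_hl = core_half_length,
                 cap_r = capsule_radius, cap_hl = capsule_half_length,
                 cable_r = cable_radius, cable_len = cable_length,
                 core_mat = core_material, cap_mat = capsule_material,
                 cable_mat = cable_material,
                 origin = as.numeric(origin), rotation = rotation),
            class = "source_capsule")
}

#' @export
print.source_capsule <- function(x, ...) {
  cat(sprintf("<source_capsule> core %s r=%.3g hl=%.3g cm; capsule %s r=%.3g hl=%.3g cm\n",
              x$core_mat, x$core_r, x$core_hl, x$cap_mat, x$cap_r, x$cap_hl))
  invisible(x)
}

#' @rdname source_capsule
#' @details
#' `generic_hdr_source()` follows the generic HDR Ir-192 source used in the
#' joint working-group benchmark test cases: a pure-iridium cylindrical core
#' (diameter 0.6 mm, length 3.5 mm) inside an AISI 316 stainless-steel
#' capsule (outer diameter 1.0 mm) with a short steel cable stub. End-weld
#' and tip details are simplified to right cylinders.
#' @export
generic_hdr_source <- function(origin = c(0, 0, 0), rotation = diag(3)) {
  source_capsule(core_radius = 0.030, core_half_length = 0.175,
                 capsule_radius = 0.050, capsule_half_length = 0.210,
                 cable_radius = 0.050, cable_length = 0.200,
                 origin = origin, rotation = rotation)
}

#' @rdname source_capsule
#' @details
#' `microselectron_v2_source()` approximates the microSelectron HDR v2
#' source: iridium core diameter 0.65 mm, length 3.6 mm, steel capsule
#' outer diameter 0.9 mm, steel cable.
#' @export
microselectron_v2_source <- function(origin = c(0, 0, 0), rotation = diag(3)) {
  source_capsule(core_radius = 0.0325, core_half_length = 0.180,
                 capsule_radius = 0.045, capsule_half_length = 0.225,
                 cable_radius = 0.035, cable_length = 0.200,
                 origin = origin, rotation = rotation)
}

#' Minimal rotation taking one unit vector onto another
#'
#' Rotation about the axis normal to both vectors (no roll component);
#' used to orient the capsule axis along catheter tangents.
#'
#' @param from,to 3-vectors (normalized internally)
#' @return 3x3 rotation matrix with `R %*% from = to`
#' @export
rotation_between <- function(from, to) {
  a <- from / sqrt(sum(from^2)); b <- to / sqrt(sum(to^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # pick any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Cylindrical (annular) scoring cell
#'
#' @param r_in,r_out inner/outer radius, cm (`r_out > r_in >= 0`)
#' @param half_height half of the cell height, cm
#' @param material material used for the muen lookup
#' @param origin,rotation cell frame (axis = local z)
#' @export
cylinder_cell <- function(r_in, r_out, half_height, material = "air",
                          origin = c(0, 0, 0), rotation = diag(3)) {
  if (!(r_out > r_in && r_in >= 0) || half_height <= 0)
    stop("degenerate cylinder cell: need r_out > r_in >= 0, height > 0")
  structure(list(r_in = r_in, r_out = r_out, half_h = half_height,
                 material = material, origin = as.numeric(origin),
                 rotation = rotation,
                 volume = pi * (r_out^2 - r_in^2) * 2 * half_height),
            class = "cylinder_cell")
}

#' Chord length of a segment through a cylindrical cell
#'
#' Analytic intersection of the segment `p0 -> p1` with the annular
#' cylinder; zero if they do not intersect.
#'
#' @param cell a [cylinder_cell()]
#' @param p0,p1 segment endpoints, cm
#' @return chord length, cm
#' @export
cell_chord <- function(cell, p0, p1) {
  cpp_cyl_chord(as.numeric(p0), as.numeric(p1), cell$origin,
                cell$rotation, cell$r_in, cell$r_out, cell$half_h)
}
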