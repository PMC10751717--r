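#' Phase-space files
#'
#' Fixed-width little-endian binary records (8 doubles: energy keV,
#' position cm and direction in the capsule frame, statistical weight)
#' behind a versioned header carrying the capsule id, spectrum id, number
#' of primaries and seed. Round trips are bit-exact.
#'
#' @param records numeric matrix with 8 columns
#'   (`E`, `x`, `y`, `z`, `u`, `v`, `w`, `weight`)
#' @param path file path
#' @param capsule_id,spectrum_id free-text identifiers stored in the header
#' @param n_primaries number of primary histories used to generate the file
#' @param seed generator seed recorded in the header
#' @export
psf_write <- function(records, path, capsule_id = "unknown",
                      spectrum_id = "ir192", n_primaries = nrow(records),
                      seed = NA_real_) {
  records <- as.matrix(records)
  if (ncol(records) != 8) stop("phase-space records must have 8 columns")
  if (any(records[, 1] < 1)) stop("record energy below 1 keV cut-off")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("HKPSF"), con)
  writeBin(1L, con, size = 4, endian = "little")
  for (s in c(capsule_id, spectrum_id)) {
    r <- charToRaw(s)
    writeBin(length(r), con, size = 4, endian = "little")
    writeBin(r, con)
  }
  writeBin(as.numeric(n_primaries), con, size = 8, endian = "little")
  writeBin(as.numeric(seed), con, size = 8, endian = "little")
  writeBin(nrow(records), con, size = 4, endian = "little")
  writeBin(as.numeric(t(records)), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname psf_write
#' @return `psf_read()`: list with `records` (matrix) and `header`
#' @export
psf_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 5))
  if (!identical(magic, "HKPSF"))
    stop("not a phase-space file (bad magic at offset 0): ", path)
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(version) == 0 || version > 1)
    stop("unsupported phase-space format version: ", version)
  rd_str <- function() {
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(n) == 0 || n < 0 || n > 1e6) stop("corrupt header string")
    rawToChar(readBin(con, "raw", n))
  }
  capsule_id <- rd_str(); spectrum_id <- rd_str()
  n_primaries <- readBin(con, "numeric", 1, size = 8, endian = "little")
  seed <- readBin(con, "numeric", 1, size = 8, endian = "little")
  nrec <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(nrec) == 0) stop("truncated header")
  vals <- readBin(con, "numeric", 8 * nrec, size = 8, endian = "little")
  if (length(vals) != 8 * nrec)
    stop("truncated phase-space file: expected ", nrec, " records, got ",
         length(vals) %/% 8, " (offset ", 29 + 8 * length(vals), ")")
  records <- matrix(vals, ncol = 8, byrow = TRUE,
                    dimnames = list(NULL, c("E", "x", "y", "z",
                                            "u", "v", "w", "weight")))
  list(records = records,
       header = list(version = version, capsule_id = capsule_id,
                     spectrum_id = spectrum_id, n_primaries = n_primaries,
                     seed = seed, n_records = nrec))
}

#' Generate a phase-space file for a source model
#'
#' Runs the capsule in vacuum and records every photon crossing the
#' capsule surface outward (capsule frame).
#'
#' @param capsule a [source_capsule()]
#' @param spectrum an `emission_spectrum`
#' @param histories primary photons
#' @param seed engine seed
#' @return matrix of phase-space records
#' @export
generate_psf <- function(capsule, spectrum, histories, seed) {
  res <- mc_run(world_vacuum(), src_capsule(spectrum), histories, seed,
                capsule = capsule, collect_psf = TRUE, psf_max = histories)
  colnames(res$psf) <- c("E", "x", "y", "z", "u", "v", "w", "weight")
  res$psf
}

#' Dwell positions and treatment plans
#'
#' A dwell position couples a location (cm, phantom frame), an orientation
#' (rotation taking the capsule +z axis onto the local catheter tangent),
#' a dwell time (s) and a catheter id.
#'
#' @param position 3-vector, cm
#' @param time dwell time, s
#' @param rotation 3x3 orientation matrix
#' @param catheter catheter label
#' @export
dwell_position <- function(position, time, rotation = diag(3),
                           catheter = "c1") {
  stopifnot(time >= 0)
  list(position = as.numeric(position), time = time, rotation = rotation,
       catheter = catheter)
}

#' @rdname dwell_position
#' @param dwells list of [dwell_position()]s
#' @param prescription_dose Gy
#' @param prescription_point 3-vector, cm
#' @export
treatment_plan <- function(dwells, prescription_dose, prescription_point) {
  if (!length(dwells) || all(vapply(dwells, `[[`, 0, "time") <= 0))
    stop("plan needs at least one dwell with positive time")
  structure(list(dwells = dwells, prescription_dose = prescription_dose,
                 prescription_point = as.numeric(prescription_point)),
            class = "treatment_plan")
}

#' @export
print.treatment_plan <- function(x, ...) {
  cats <- vapply(x$dwells, `[[`, "", "catheter")
  cat("<treatment_plan>", length(x$dwells), "dwells in",
      length(unique(cats)), "catheters;",
      x$prescription_dose, "Gy prescribed\n")
  invisible(x)
}

#' Dwell sampling probabilities
#'
#' Probability of emitting from each dwell, proportional to its dwell
#' time: `w_d = t_d / sum(t)`.
#'
#' @param plan a [treatment_plan()]
#' @return numeric vector summing to 1
#' @export
dwell_weights <- function(plan) {
  t <- vapply(plan$dwells, `[[`, 0, "time")
  if (sum(t) <= 0) stop("all dwell times are zero")
  t / sum(t)
}

#' Catheter tangent orientations
#'
#' Tangents from central differences of neighbouring dwell positions
#' (one-sided at the catheter ends), each mapped from the capsule +z axis
#' by the minimal rotation convention of [rotation_between()].
#'
#' @param positions n x 3 matrix of dwell positions along one catheter,
#'   in catheter order
#' @return list of 3x3 rotation matrices
#' @export
catheter_orientation <- function(positions) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) stop("need at least 2 dwells to orient a catheter")
  lapply(seq_len(n), function(i) {
    a <- max(1, i - 1); b <- min(n, i + 1)
    tg <- positions[b, ] - positions[a, ]
    nt <- sqrt(sum(tg^2))
    if (nt < 1e-12)
      stop("coincident neighbouring dwells at index ", i,
           "; tangent undefined")
    rotation_between(c(0, 0, 1), tg / nt)
  })
}

#' Transform one phase-space record through a dwell frame
#'
#' Reference implementation of the plan-source transform (the engine
#' applies the same operation in compiled code): the record's capsule-frame
#' position/direction are rotated by the dwell orientation and translated
#' to the dwell position.
#'
#' @param record numeric vector of 8 (E, x, y, z, u, v, w, weight)
#' @param dwell a [dwell_position()]
#' @return list with `energy`, `position`, `direction`, `weight`
#' @export
transform_record <- function(record, dwell) {
  p <- dwell$position + as.numeric(dwell$rotation %*% record[2:4])
  d <- as.numeric(dwell$rotation %*% record[5:7])
  list(energy = record[[1]], position = p, direction = d,
       weight = record[[8]])
}

#' Plan-source batch (reference implementation)
#'
#' Reads one phase-space record and emits `split` clones of weight
#' `1/split`, each independently assigned a dwell sampled with
#' probability proportional to dwell time and transformed by that dwell's
#' frame. Uses R's RNG.
#'
#' @param plan a [treatment_plan()]
#' @param record one phase-space record (vector of 8)
#' @param split splitting factor
#' @return list of clones (as in [transform_record()])
#' @export
plan_source_batch <- function(plan, record, split = 10L) {
  stopifnot(split >= 1)
  w <- dwell_weights(plan)
  idx <- sample.int(length(w), split, replace = TRUE, prob = w)
  lapply(idx, function(i) {
    cl <- transform_record(record, plan$dwells[[i]])
    cl$weight <- cl$weight / split
    cl
  })
}

#' Read / write the JSON plan dialect
#'
#' Documented JSON dialect mirroring DICOM RTPLAN structure: catheters
#' hold ordered control points with positions in mm (DICOM convention;
#' converted to cm at this boundary) and dwell times in seconds, plus a
#' prescription block. Dwell orientations are reconstructed from the
#' catheter geometry via [catheter_orientation()] (single-dwell catheters
#' keep the identity orientation).
#'
#' @param path file path
#' @export
read_plan <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(j$format, "hdrkerma-plan"))
    stop("not an hdrkerma plan file: ", path)
  if (j$version > 1) stop("unsupported plan format version ", j$version)
  dwells <- list()
  for (cat_ in j$catheters) {
    pos <- t(vapply(cat_$control_points,
                    function(cp) unlist(cp$position_mm) / 10, numeric(3)))
    times <- vapply(cat_$control_points, function(cp) cp$time_s, 0)
    rots <- if (nrow(pos) >= 2) catheter_orientation(pos)
            else list(diag(3))
    for (i in seq_len(nrow(pos)))
      dwells[[length(dwells) + 1]] <-
        dwell_position(pos[i, ], times[i], rots[[i]], cat_$id)
  }
  treatment_plan(dwells, j$prescription$dose_gy,
                 unlist(j$prescription$point_mm) / 10)
}

#' @rdname read_plan
#' @param plan a [treatment_plan()]
#' @export
write_plan <- function(plan, path) {
  cats <- split(seq_along(plan$dwells),
                vapply(plan$dwells, `[[`, "", "catheter"))
  j <- list(
    format = "hdrkerma-plan", version = 1L,
    generator = paste0("hdrkerma ", as.character(packageVersion("hdrkerma"))),
    prescription = list(dose_gy = plan$prescription_dose,
                        point_mm = plan$prescription_point * 10),
    catheters = lapply(names(cats), function(cid) {
      list(id = cid, control_points = lapply(cats[[cid]], function(i) {
        d <- plan$dwells[[i]]
        list(position_mm = d$position * 10, time_s = d$time)
      }))
    }))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
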