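#' Validate a run configuration file
#'
#' YAML run configurations reference a scene file and set the transport
#' parameters. Unknown keys, a missing scene file or non-positive history
#' counts raise an itemized validation error; defaulted fields are
#' reported in the `"defaulted"` attribute.
#'
#' @param path YAML file
#' @return a validated `run_config` list
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("scene", "histories", "seed", "tallies", "output",
             "photon_cutoff_keV", "split", "majorant_margin",
             "compton_model", "fluorescence")
  defaults <- list(seed = 1L, tallies = "tlke", output = "run_out",
                   photon_cutoff_keV = 1, split = 10L,
                   majorant_margin = 1.01,
                   compton_model = "klein-nishina-free",
                   fluorescence = FALSE)
  problems <- character(0)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  if (is.null(cfg$scene)) {
    problems <- c(problems, "missing required key: scene")
  } else {
    scene_path <- if (file.exists(cfg$scene)) cfg$scene
                  else file.path(dirname(path), cfg$scene)
    if (!file.exists(scene_path))
      problems <- c(problems, paste0("scene file not found: ", cfg$scene))
    else cfg$scene <- scene_path
  }
  if (is.null(cfg$histories) || !is.numeric(cfg$histories) ||
      cfg$histories < 1)
    problems <- c(problems, "histories must be a positive integer")
  if (length(problems))
    stop("invalid run configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  defaulted <- setdiff(names(defaults), names(cfg))
  for (k in defaulted) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = "run_config", defaulted = defaulted)
}

#' Dose-grid text container
#'
#' Serializes a finalized dose grid (geometry metadata, units, seed, N,
#' per-voxel mean and relative Type A uncertainty) as a versioned
#' plain-text container; `write_dose_slice()` exports one z-slice as a
#' matrix table.
#'
#' @param grid a `dose_grid` from [mc_run()]
#' @param path output path
#' @param seed seed recorded in the header
#' @param units unit string recorded in the header
#' @export
write_dose_grid <- function(grid, path, seed = NA, units = grid$units) {
  fin <- finalize_uncertainty(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# hdrkerma-dosegrid",
               "# format_version: 1",
               paste0("# generator: hdrkerma ",
                      as.character(packageVersion("hdrkerma"))),
               paste0("# dim: ", paste(grid$dim, collapse = " ")),
               paste0("# spacing_cm: ", paste(grid$spacing, collapse = " ")),
               paste0("# origin_cm: ", paste(grid$origin, collapse = " ")),
               paste0("# units: ", units),
               paste0("# estimator: ", grid$estimator),
               paste0("# n_histories: ", format(grid$n, scientific = FALSE)),
               paste0("# seed: ", seed),
               "# kerma_caveat: collisional kerma approximates absorbed dose",
               "#   only beyond ~2 mm of the source (charged-particle equilibrium)",
               "# columns: mean rel_se_k1"), con)
  write.table(data.frame(as.numeric(fin$mean), as.numeric(fin$rel_se)),
              con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  hdr <- readLines(path, n = 20)
  hdr <- hdr[startsWith(hdr, "#")]
  if (!any(grepl("hdrkerma-dosegrid", hdr)))
    stop("not an hdrkerma dose-grid file: ", path)
  ver <- as.integer(sub(".*format_version:\\s*", "",
                        grep("format_version", hdr, value = TRUE)[1]))
  if (ver > 1) stop("unsupported dose-grid format version ", ver)
  getv <- function(key) {
    ln <- grep(paste0("# ", key, ":"), hdr, value = TRUE)[1]
    strsplit(trimws(sub(paste0(".*", key, ":"), "", ln)), "\\s+")[[1]]
  }
  dm <- as.integer(getv("dim"))
  d <- read.table(path, comment.char = "#",
                  col.names = c("mean", "rel_se"))
  list(dim = dm, spacing = as.numeric(getv("spacing_cm")),
       origin = as.numeric(getv("origin_cm")),
       units = paste(getv("units"), collapse = " "),
       n = as.numeric(getv("n_histories")),
       mean = array(d$mean, dm), rel_se = array(d$rel_se, dm))
}

#' @rdname write_dose_grid
#' @param k z-slice index
#' @export
write_dose_slice <- function(grid, k, path) {
  fin <- finalize_uncertainty(grid)
  write.table(fin$mean[, , k], path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Structured run log
#'
#' Records seed, history count, physics options and the engine's
#' interpretation flags (free-electron Compton model, no fluorescence
#' re-emission, azimuthally symmetrized ring cells) together with
#' wall-clock time, as YAML.
#'
#' @param path output path
#' @param histories,seed run parameters
#' @param wall_s wall time in seconds
#' @param status `"completed"` or `"interrupted"`
#' @param extra named list merged into the log
#' @export
write_run_log <- function(path, histories, seed, wall_s, status = "completed",
                          extra = list()) {
  log <- c(list(
    generator = paste0("hdrkerma ",
                       as.character(packageVersion("hdrkerma"))),
    r_version = as.character(getRversion()),
    status = status,
    seed = seed, histories = histories,
    wall_seconds = wall_s,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    physics = list(
      transport = "photon only, no electron transport",
      photon_cutoff_keV = 1,
      compton_model = "free-electron Klein-Nishina",
      fluorescence = "not re-emitted (absorbed locally)",
      ring_cells = "azimuthally symmetrized (exact by symmetry)")),
    extra)
  yaml::write_yaml(log, path)
  invisible(path)
}
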