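#' Photon interaction coefficient tables
#'
#' The package ships plain-text coefficient files (photoelectric, Compton,
#' Rayleigh, total attenuation and mass energy-absorption coefficients,
#' cm^2/g versus keV) for the materials of the HDR brachytherapy benchmark
#' scenes: water, dry air, cortical bone, AISI 316 stainless steel, iridium,
#' and elemental hydrogen/oxygen. Data-file headers record provenance.
#'
#' @param name material name; see [material_names()]
#' @return an object of class `xs_table` with fields `material`, `energy`
#'   (keV), `pe`, `compton`, `rayleigh`, `total`, `muen` (cm^2/g) and
#'   `density` (g/cm^3)
#' @examples
#' w <- load_material("water")
#' lookup_mu(w, 350, "total")
#' @export
load_material <- function(name) {
  path <- system.file("extdata", "xs", paste0(name, ".txt"),
                      package = "hdrkerma")
  if (path == "")
    stop("no interaction table shipped for material '", name, "'")
  load_xs_table(path, material = name)
}

#' @rdname load_material
#' @export
material_names <- function() {
  files <- list.files(system.file("extdata", "xs", package = "hdrkerma"),
                      pattern = "\\.txt$")
  sub("\\.txt$", "", files)
}

#' Read a photon coefficient file
#'
#' Plain-text format: comment header (`#` lines, carrying density,
#' composition and provenance), then columns
#' `E_keV mu_pe mu_co mu_ra mu_tot muen`. The loader validates the module
#' invariants: strictly increasing grid, positive coefficients, partials
#' summing to the total within 0.5%, and `muen <= mu_tot` everywhere.
#'
#' @param path file path
#' @param material label stored in the returned table
#' @return an `xs_table`
#' @export
load_xs_table <- function(path, material = basename(path)) {
  hdr <- readLines(path, n = 50L)
  hdr <- hdr[startsWith(hdr, "#")]
  dens <- grep("density_g_cm3", hdr, value = TRUE)
  density <- if (length(dens)) as.numeric(sub(".*density_g_cm3:", "", dens[1]))
             else NA_real_
  comp <- grep("# composition:", hdr, value = TRUE)
  composition <- NULL
  if (length(comp)) {
    toks <- strsplit(trimws(sub("# composition:", "", comp[1])), "\\s+")[[1]]
    kv <- strsplit(toks, ":")
    composition <- data.frame(
      element = vapply(kv, `[`, "", 1),
      fraction = as.numeric(vapply(kv, `[`, "", 2)))
  }
  d <- read.table(path, comment.char = "#",
                  col.names = c("energy", "pe", "compton", "rayleigh",
                                "total", "muen"))
  tab <- structure(
    list(material = material, energy = d$energy, pe = d$pe,
         compton = d$compton, rayleigh = d$rayleigh, total = d$total,
         muen = d$muen, density = density, composition = composition),
    class = "xs_table")
  validate_xs_table(tab)
  tab
}

validate_xs_table <- function(tab) {
  e <- tab$energy
  if (any(diff(e) <= 0)) stop("energy grid must be strictly increasing")
  if (e[1] > 1 || e[length(e)] < 1400)
    stop("energy grid must span [1, 1400] keV")
  for (f in c("pe", "compton", "rayleigh", "total", "muen"))
    if (any(tab[[f]] <= 0)) stop("coefficient '", f, "' must be positive")
  s <- tab$pe + tab$compton + tab$rayleigh
  if (any(abs(s / tab$total - 1) > 0.005))
    stop("partial coefficients do not sum to the total within 0.5%")
  if (any(tab$muen > tab$total))
    stop("muen exceeds mu_tot")
  invisible(tab)
}

#' @export
print.xs_table <- function(x, ...) {
  cat("<xs_table>", x$material, "\n")
  cat("  energy grid:", length(x$energy), "points,",
      x$energy[1], "-", x$energy[length(x$energy)], "keV\n")
  cat("  density:", x$density, "g/cm^3\n")
  invisible(x)
}

#' Interpolate an interaction coefficient
#'
#' Log-log linear interpolation on the energy grid; exact at grid nodes.
#'
#' @param table an [`xs_table`][load_xs_table]
#' @param energy photon energy, keV (vectorized)
#' @param channel one of `"total"`, `"photoelectric"`, `"compton"`,
#'   `"rayleigh"`, `"muen"`
#' @return coefficient(s) in cm^2/g
#' @export
lookup_mu <- function(table, energy,
                      channel = c("total", "photoelectric", "compton",
                                  "rayleigh", "muen")) {
  channel <- match.arg(channel)
  col <- switch(channel, total = "total", photoelectric = "pe",
                compton = "compton", rayleigh = "rayleigh", muen = "muen")
  e <- table$energy
  if (any(energy < e[1] | energy > e[length(e)]))
    stop("energy out of range for material '", table$material, "': ",
         paste(energy[energy < e[1] | energy > e[length(e)]], collapse = ", "),
         " keV (table spans ", e[1], "-", e[length(e)], " keV)")
  y <- log(table[[col]])
  exp(approx(log(e), y, xout = log(energy), method = "linear")$y)
}

#' Mass-fraction mixture of coefficient tables
#'
#' Builds a compound table by the mixture additivity rule: each coefficient
#' is the mass-fraction weighted sum of the component coefficients,
#' resampled by log-log interpolation onto the union energy grid.
#'
#' @param components list of `xs_table` objects
#' @param fractions mass fractions, summing to 1 within 1e-6
#' @param material label for the mixture
#' @param density nominal density of the mixture, g/cm^3
#' @return an `xs_table`
#' @export
mixture_table <- function(components, fractions, material = "mixture",
                          density = NA_real_) {
  if (length(components) != length(fractions))
    stop("components and fractions differ in length")
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("mass fractions must sum to 1 (got ", sum(fractions), ")")
  grid <- sort(unique(unlist(lapply(components, `[[`, "energy"))))
  lo <- max(vapply(components, function(t) t$energy[1], 0))
  hi <- min(vapply(components, function(t) max(t$energy), 0))
  grid <- grid[grid >= lo & grid <= hi]
  out <- list(material = material, energy = grid, density = density,
              composition = NULL)
  for (f in c("pe", "compton", "rayleigh", "total", "muen")) {
    acc <- 0
    for (i in seq_along(components)) {
      t <- components[[i]]
      v <- exp(approx(log(t$energy), log(t[[f]]), xout = log(grid))$y)
      acc <- acc + fractions[i] * v
    }
    out[[f]] <- acc
  }
  structure(out, class = "xs_table")
}

#' Interaction channel probabilities and sampling
#'
#' Probabilities of photoelectric absorption, Compton (incoherent) and
#' Rayleigh (coherent) scattering at a given energy, proportional to the
#' partial coefficients; `select_interaction()` samples channels with
#' those probabilities using R's RNG (reference implementation of the
#' engine's channel selection, which is driven by the same tables).
#'
#' @param table an `xs_table`
#' @param energy photon energy, keV
#' @return named probability vector summing to 1
#' @export
interaction_probabilities <- function(table, energy) {
  p <- c(photoelectric = lookup_mu(table, energy, "photoelectric"),
         compton = lookup_mu(table, energy, "compton"),
         rayleigh = lookup_mu(table, energy, "rayleigh"))
  p / sum(p)
}

#' @rdname interaction_probabilities
#' @param n number of draws
#' @export
select_interaction <- function(table, energy, n = 1L) {
  p <- interaction_probabilities(table, energy)
  sample(names(p), n, replace = TRUE, prob = p)
}
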