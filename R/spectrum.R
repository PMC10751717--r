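#' Photon emission spectra
#'
#' Line spectra are plain-text two-column files (energy keV, photons per
#' decay) with a comment header. The shipped `ir192` spectrum transcribes
#' the gamma and K X-ray lines of Ir-192 (intensity >= 0.05%).
#'
#' @param path path to a spectrum file
#' @return an `emission_spectrum`: fields `energy` (keV), `intensity`
#'   (photons/decay), `total_yield`
#' @export
read_spectrum <- function(path) {
  d <- read.table(path, comment.char = "#",
                  col.names = c("energy", "intensity"))
  if (nrow(d) == 0) stop("empty spectrum file: ", path)
  if (any(d$intensity <= 0)) stop("spectrum intensities must be positive")
  if (any(d$energy <= 1 | d$energy >= 1400))
    stop("spectrum line energies must lie within (1, 1400) keV")
  structure(list(energy = d$energy, intensity = d$intensity,
                 total_yield = sum(d$intensity)),
            class = "emission_spectrum")
}

#' @rdname read_spectrum
#' @export
ir192_spectrum <- function() {
  read_spectrum(system.file("extdata", "spectrum", "ir192.txt",
                            package = "hdrkerma"))
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat("<emission_spectrum>", length(x$energy), "lines,",
      sprintf("%.4f photons/decay, mean %.1f keV\n",
              x$total_yield, spectrum_mean_energy(x)))
  invisible(x)
}

#' Intensity-weighted mean line energy (keV)
#' @param spectrum an `emission_spectrum`
#' @export
spectrum_mean_energy <- function(spectrum) {
  sum(spectrum$energy * spectrum$intensity) / sum(spectrum$intensity)
}

#' Sample line energies from an emission spectrum
#'
#' Draws line energies with probability proportional to line intensity,
#' using R's RNG (`set.seed()` controls reproducibility).
#'
#' @param spectrum an `emission_spectrum`
#' @param n number of draws
#' @return numeric vector of energies, keV
#' @export
sample_emission <- function(spectrum, n = 1L) {
  if (length(spectrum$energy) == 0) stop("empty spectrum")
  spectrum$energy[sample.int(length(spectrum$energy), n, replace = TRUE,
                             prob = spectrum$intensity)]
}
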