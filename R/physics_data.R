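# Embedded physical data: Ir-192 emission spectrum, photon mass attenuation /
# energy-absorption tables for water, air and stainless steel, and the
# Klein-Nishina sampler used by the transport engine.

#' Ir-192 photon emission spectrum
#'
#' Returns the discrete gamma-ray and K x-ray line spectrum of \eqn{^{192}}Ir
#' used for source-energy sampling, as transcribed from standard radioactive
#' decay tables. Intensities are photons per decay; the `p` column is the
#' normalized sampling probability mass function.
#'
#' @return A tibble with class `energy_spectrum`: columns `energy_MeV`,
#'   `intensity` (photons/decay) and `p` (normalized pmf, sums to 1).
#' @examples
#' sp <- ir192_spectrum()
#' weighted.mean(sp$energy_MeV, sp$intensity)
#' @export
ir192_spectrum <- function() {
  if (is.null(the$spectrum)) {
    path <- system.file("extdata", "ir192_spectrum.tsv", package = "balloonbrachy")
    raw <- read.delim(path, comment.char = "#")
    sp <- as_tibble(raw) |>
      mutate(p = .data$intensity / sum(.data$intensity))
    class(sp) <- c("energy_spectrum", class(sp))
    the$spectrum <- sp
  }
  the$spectrum
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf("<energy_spectrum> %d lines, %.3f photons/decay, mean %.4f MeV\n",
              nrow(x), sum(x$intensity),
              weighted.mean(x$energy_MeV, x$intensity)))
  NextMethod()
}

xs_materials <- c("water", "air", "steel", "iridium")

#' Photon attenuation table for a material
#'
#' Loads the embedded mass attenuation (\eqn{\mu/\rho}) and mass
#' energy-absorption (\eqn{\mu_{en}/\rho}) table for one of the supported
#' materials. Two total-attenuation columns are stored: with and without
#' coherent (Rayleigh) scattering.
#'
#' @param material One of `"water"`, `"air"`, `"steel"`, `"iridium"`.
#' @return A tibble with columns `energy_MeV`, `mu_rho_total`,
#'   `mu_rho_no_coherent`, `muen_rho` (all cm\eqn{^2}/g) and attributes
#'   `density` (g/cm\eqn{^3}) and `electrons_per_gram`.
#' @export
attenuation_table <- function(material = c("water", "air", "steel", "iridium")) {
  material <- match.arg(material)
  key <- paste0("xs_", material)
  if (is.null(the[[key]])) {
    path <- system.file("extdata", paste0("xs_", material, ".tsv"),
                        package = "balloonbrachy")
    hdr <- readLines(path, n = 10)
    dens <- as.numeric(sub(".*: ", "", grep("density_g_cm3", hdr, value = TRUE)))
    ne <- as.numeric(sub(".*: ", "", grep("electrons_per_gram", hdr, value = TRUE)))
    tab <- as_tibble(read.delim(path, comment.char = "#"))
    attr(tab, "material") <- material
    attr(tab, "density") <- dens
    attr(tab, "electrons_per_gram") <- ne
    the[[key]] <- tab
  }
  the[[key]]
}

# cross-section bundle handed to the C++ engine
xs_bundle <- function() {
  if (is.null(the$xs_bundle)) {
    the$xs_bundle <- lapply(setNames(nm = xs_materials), function(m) {
      tab <- attenuation_table(m)
      list(table = as.matrix(tab[, c("energy_MeV", "mu_rho_total",
                                     "mu_rho_no_coherent", "muen_rho")]),
           ne = attr(tab, "electrons_per_gram"),
           rho = attr(tab, "density"))
    })
  }
  the$xs_bundle
}

#' Interpolated mass attenuation coefficient
#'
#' Log-log interpolation of the embedded attenuation tables; exact at grid
#' nodes. Between nodes the interpolant is monotone along each segment, so it
#' always lies between the neighbouring node values.
#'
#' @param material One of `"water"`, `"air"`, `"steel"`, `"iridium"`.
#' @param energy Photon energy in MeV (vectorized). Must lie within the table
#'   range.
#' @param kind Coefficient requested: `"total"` (with coherent),
#'   `"total_no_coherent"`, or `"energy_absorption"`.
#' @return Coefficient(s) in cm\eqn{^2}/g.
#' @examples
#' mu_over_rho("water", 0.3)          # about 0.118 cm^2/g
#' @export
mu_over_rho <- function(material, energy,
                        kind = c("total", "total_no_coherent", "energy_absorption")) {
  kind <- match.arg(kind)
  tab <- attenuation_table(material)
  rng <- range(tab$energy_MeV)
  if (any(energy < rng[1] | energy > rng[2])) {
    abort(sprintf("energy out of range for material '%s': table covers [%g, %g] MeV",
                  material, rng[1], rng[2]))
  }
  col <- switch(kind,
                total = tab$mu_rho_total,
                total_no_coherent = tab$mu_rho_no_coherent,
                energy_absorption = tab$muen_rho)
  exp(stats::approx(log(tab$energy_MeV), log(col), xout = log(energy),
                    rule = 1)$y)
}

#' Sample Compton scattering from the Klein-Nishina distribution
#'
#' Draws scattered photon energies and polar scattering angles for Compton
#' scattering on free electrons at the given incident energy, using Kahn's
#' composition-rejection method. The azimuthal angle is uniform and not
#' returned.
#'
#' @param energy Incident photon energy in MeV (single value, > 0).
#' @param n Number of samples.
#' @param seed Integer seed for the sampler's private random stream.
#' @return A tibble with columns `energy` (scattered energy, MeV) and
#'   `cos_theta`.
#' @examples
#' draws <- sample_compton(0.3, n = 1000, seed = 1)
#' range(draws$energy)   # within the Compton kinematic limits
#' @export
sample_compton <- function(energy, n = 1L, seed = 1L) {
  if (length(energy) != 1 || !is.finite(energy) || energy <= 0) {
    abort("`energy` must be a single positive number (MeV)")
  }
  m <- kn_sample_cpp(as.integer(n), energy, as.double(seed))
  as_tibble(as.data.frame(m))
}

#' Total Klein-Nishina cross section
#'
#' Closed-form total cross section for Compton scattering on a free electron.
#'
#' @param energy Photon energy in MeV (vectorized).
#' @return Cross section per electron in cm\eqn{^2}.
#' @export
kn_cross_section <- function(energy) {
  kn_sigma_cpp(as.numeric(energy))
}
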