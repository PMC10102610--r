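#' Physics sampling primitives
#'
#' Thin R interfaces to the transport kernel's samplers, exposed so that the
#' kernels used inside photon histories can be exercised directly.
#'
#' * `sample_free_path()` draws exponential free paths `-log(u)/mu`.
#' * `sample_compton()` draws Klein--Nishina (free-electron) polar angles by
#'   Kahn rejection; the scattered energy follows the Compton relation
#'   `E' = E / (1 + (E/511)(1 - cos(theta)))` with E in keV.
#' * `sample_coherent()` draws Thomson angles (density proportional to
#'   `1 + cos^2(theta)`); the photon energy is unchanged.
#' * `sample_interaction()` picks the interaction channel with probability
#'   proportional to the material's partial mass-attenuation components at
#'   the given energy.
#'
#' @param n Number of draws.
#' @param mu Linear attenuation coefficient (cm^-1, > 0).
#' @param energy_keV Photon energy in keV.
#' @param material Material (object or library name).
#' @param coherent_enabled When `FALSE` the coherent channel is excluded and
#'   the remaining partials renormalized.
#' @param lib Material library.
#' @param seed Integer seed; `NULL` draws one from R's RNG.
#' @return `sample_free_path()`: numeric vector of distances (cm).
#'   `sample_compton()`: tibble `energy_keV`, `theta`, `phi`.
#'   `sample_coherent()`: tibble `energy_keV`, `theta`, `phi`.
#'   `sample_interaction()`: factor with levels
#'   `photoelectric`, `incoherent`, `coherent`.
#' @examples
#' set.seed(1)
#' mean(sample_free_path(1e4, mu = 2))       # ~ 0.5 cm
#' sample_compton(5, 30)
#' table(sample_interaction(1e3, "water", 30))
#' @name sampling
NULL

#' @rdname sampling
#' @export
sample_free_path <- function(n, mu, seed = NULL) {
  if (!is.numeric(mu) || mu <= 0) {
    abort("mu must be positive; vacuum is handled by streaming, not sampling")
  }
  cpp_sample_free_path(as.double(n), mu, .default_seed(seed))
}

#' @rdname sampling
#' @export
sample_compton <- function(n, energy_keV, seed = NULL) {
  stopifnot(energy_keV > 0)
  m <- cpp_sample_compton(as.double(n), energy_keV, .default_seed(seed))
  tibble(energy_keV = m[, 1], theta = m[, 2], phi = m[, 3])
}

#' @rdname sampling
#' @export
sample_coherent <- function(n, energy_keV, seed = NULL) {
  stopifnot(energy_keV > 0)
  m <- cpp_sample_coherent(as.double(n), .default_seed(seed))
  tibble(energy_keV = energy_keV, theta = m[, 1], phi = m[, 2])
}

#' @rdname sampling
#' @export
sample_interaction <- function(n, material, energy_keV,
                               coherent_enabled = TRUE,
                               lib = material_library(), seed = NULL) {
  partials <- c(mu_rho(material, energy_keV, "photoelectric", lib),
                mu_rho(material, energy_keV, "incoherent", lib),
                if (coherent_enabled) mu_rho(material, energy_keV, "coherent", lib)
                else 0)
  if (sum(partials) <= 0) abort("all partial coefficients are zero")
  ch <- cpp_sample_channel(as.double(n), partials, .default_seed(seed))
  factor(c("photoelectric", "incoherent", "coherent")[ch],
         levels = c("photoelectric", "incoherent", "coherent"))
}
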