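#' Photon source specification
#'
#' Two emission models: an isotropic point source (used by the
#' transmission-factor pilot) and a collimated pyramidal beam whose
#' directions are uniform over the solid angle subtended by a rectangular
#' footprint (the mammography exposure aimed at the top face of the exposed
#' breast).
#'
#' @param kind `"collimated_pyramid"` or `"isotropic_point"`.
#' @param position Length-3 source position (cm).
#' @param energy_keV Monoenergetic photon energy in keV.
#' @param footprint For the collimated kind: `c(xmin, xmax, ymin, ymax, z)`,
#'   a horizontal target rectangle that must not sit at the source height.
#' @param n_histories Default number of histories for runs using this spec.
#' @return An object of class `source_spec`.
#' @examples
#' source_spec("isotropic_point", c(0, 0, 0), 30)
#' @export
source_spec <- function(kind = c("collimated_pyramid", "isotropic_point"),
                        position, energy_keV, footprint = NULL,
                        n_histories = 1e5) {
  kind <- match.arg(kind)
  stopifnot(length(position) == 3, is.numeric(energy_keV), energy_keV > 0,
            n_histories >= 1)
  if (kind == "collimated_pyramid") {
    if (is.null(footprint) || length(footprint) != 5) {
      abort("collimated source needs footprint = c(xmin, xmax, ymin, ymax, z)")
    }
    if (footprint[2] <= footprint[1] || footprint[4] <= footprint[3]) {
      abort("degenerate footprint: zero area")
    }
    if (footprint[5] == position[3]) {
      abort("footprint plane must not contain the source")
    }
  }
  structure(list(kind = kind, position = as.numeric(position),
                 energy_keV = as.numeric(energy_keV),
                 footprint = if (is.null(footprint)) NULL else as.numeric(footprint),
                 n_histories = n_histories),
            class = "source_spec")
}

source_to_cpp <- function(spec) {
  list(kind = if (spec$kind == "isotropic_point") 0L else 1L,
       position = spec$position,
       energy = spec$energy_keV,
       footprint = spec$footprint %||% numeric(5))
}

#' Sample emissions from a source
#'
#' Draws photon starting states. Isotropic directions are uniform on the
#' sphere; collimated directions are uniform over the solid angle subtended
#' by the footprint (cone sampling with rejection against the rectangle).
#' Every photon carries the configured energy and weight 1.
#'
#' @param spec A [source_spec()].
#' @param n Number of photons (default: the spec's `n_histories`).
#' @param seed Integer seed; when `NULL` one is drawn from R's RNG so that
#'   `set.seed()` makes the draw reproducible.
#' @return A tibble with columns `x, y, z, ux, uy, uz, energy_keV, weight`.
#' @examples
#' sp <- source_spec("isotropic_point", c(0, 0, 0), 30, n_histories = 10)
#' emit_photons(sp, seed = 1)
#' @export
emit_photons <- function(spec, n = spec$n_histories, seed = NULL) {
  m <- cpp_emit(source_to_cpp(spec), as.double(n), .default_seed(seed))
  tibble(x = m[, 1], y = m[, 2], z = m[, 3],
         ux = m[, 4], uy = m[, 5], uz = m[, 6],
         energy_keV = m[, 7], weight = 1)
}
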