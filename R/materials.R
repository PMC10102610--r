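#' Normalize a raw elemental composition
#'
#' Published tissue tables usually list weight percentages truncated to one
#' decimal, so rows sum to slightly less than 100%. This rescales the raw
#' percentages to weight fractions summing exactly to 1 while preserving the
#' published ratios.
#'
#' @param raw A data frame with columns `symbol` and `percent`, or a named
#'   numeric vector of percentages.
#' @return A tibble with columns `symbol` and `fraction` (fractions sum to 1).
#' @examples
#' # skin: printed row sums to 99.3
#' normalize_composition(c(H = 9.8, C = 17.8, N = 5, O = 66.7))
#' @export
normalize_composition <- function(raw) {
  if (is.numeric(raw) && !is.null(names(raw))) {
    raw <- tibble(symbol = names(raw), percent = unname(raw))
  }
  if (!is.data.frame(raw) || nrow(raw) == 0) {
    abort("composition must be a non-empty data frame or named vector")
  }
  if (!all(c("symbol", "percent") %in% names(raw))) {
    abort("composition needs columns 'symbol' and 'percent'")
  }
  if (any(!is.finite(raw$percent)) || any(raw$percent <= 0)) {
    abort("all composition percentages must be positive and finite")
  }
  tibble(symbol = as.character(raw$symbol),
         fraction = raw$percent / sum(raw$percent))
}

#' Define a material
#'
#' A material is a named elemental mixture with a bulk density. Compositions
#' are normalized to weight fractions summing to 1; every element must be
#' present in the embedded attenuation table.
#'
#' @param name Identifier.
#' @param density Bulk density in g/cm^3 (> 0).
#' @param composition Raw composition accepted by [normalize_composition()].
#' @param provenance Optional free-text note on where the composition comes
#'   from.
#' @return An object of class `mc_material`.
#' @examples
#' water <- material("water", 1.0, c(H = 11.19, O = 88.81))
#' mu_rho(water, 30)
#' @export
material <- function(name, density, composition, provenance = NULL) {
  if (!is.numeric(density) || length(density) != 1 || density <= 0) {
    abort("density must be a single positive number (g/cm^3)")
  }
  comp <- normalize_composition(composition)
  unknown <- setdiff(comp$symbol, element_symbols())
  if (length(unknown) > 0) {
    abort(paste0("element(s) not in the embedded table: ",
                 paste(unknown, collapse = ", ")))
  }
  structure(list(name = name, density = density, composition = comp,
                 provenance = provenance, vacuum = FALSE),
            class = "mc_material")
}

#' @rdname material
#' @export
material_vacuum <- function() {
  structure(list(name = "vacuum", density = 0,
                 composition = tibble(symbol = character(), fraction = numeric()),
                 provenance = "void region; photons stream without interacting",
                 vacuum = TRUE),
            class = "mc_material")
}

#' @export
print.mc_material <- function(x, ...) {
  cat("<mc_material>", x$name, "density", x$density, "g/cm^3\n")
  if (nrow(x$composition)) {
    cat(paste0("  ", x$composition$symbol, " ",
               signif(100 * x$composition$fraction, 4), "%", collapse = "\n"),
        "\n")
  }
  invisible(x)
}

#' Default material library
#'
#' Builds the registry of materials used by the phantom and screen models:
#' the three glandular-fraction breast layers and skin (printed tissue rows,
#' renormalized), ICRU-style four-component soft tissue for the body block,
#' air, vacuum, water and PMMA for checks, pure lead, the lead-acrylic
#' screen (PMMA loaded with 30 wt% Pb at 1.6 g/cm^3, chosen so that 12 mm
#' matches ~0.5 mm of lead in narrow-beam attenuation at 30 keV), and the
#' CdO-rich quaternary tellurite glass screen `c40`.
#'
#' The `c40` composition is not part of this package's own measurements: the
#' shipped default is a synthetic stand-in for the characterized glass
#' (40CdO-40TeO2-10ZnO-10Nb2O5 by mole, 5.7 g/cm^3) and is intended to be
#' overridden via [library_with()] or the config file when the measured
#' oxide fractions are available.
#'
#' @param overrides Optional named list of `mc_material` objects replacing or
#'   extending the defaults.
#' @return Named list of `mc_material` objects (class `material_library`).
#' @examples
#' lib <- material_library()
#' names(lib)
#' materials_table(lib)
#' @export
material_library <- function(overrides = NULL) {
  lib <- list(
    gf25 = material("gf25", 0.955, c(H = 11, C = 51, N = 2.1, O = 35.7),
                    "glandular-fraction 25% breast layer; printed row sums to 99.8, renormalized"),
    gf50 = material("gf50", 0.982, c(H = 10.7, C = 40.1, N = 2.5, O = 46.4),
                    "glandular-fraction 50% breast layer; printed row sums to 99.7, renormalized"),
    gf75 = material("gf75", 1.010, c(H = 10.5, C = 29.3, N = 2.9, O = 57),
                    "glandular-fraction 75% breast layer; printed row sums to 99.7, renormalized"),
    skin = material("skin", 1.090, c(H = 9.8, C = 17.8, N = 5, O = 66.7),
                    "skin layer; printed row sums to 99.3, renormalized"),
    soft_tissue = material("soft_tissue", 1.0,
                           c(H = 10.1, C = 11.1, N = 2.6, O = 76.2),
                           "ICRU four-component soft tissue for the body block"),
    air = material("air", 0.0012041, c(N = 75.5, O = 23.2, Ar = 1.3),
                   "dry air near sea level"),
    vacuum = material_vacuum(),
    water = material("water", 1.0, c(H = 11.19, O = 88.81), "liquid water"),
    pmma = material("pmma", 1.19, c(H = 8.05, C = 59.98, O = 31.96),
                    "polymethyl methacrylate"),
    lead = material("lead", 11.35, c(Pb = 100), "elemental lead"),
    lead_acrylic = material("lead_acrylic", 1.6,
                            c(H = 5.635, C = 41.986, O = 22.372, Pb = 30.0),
                            paste("PMMA loaded with 30 wt% Pb; 12 mm matches",
                                  "~0.5 mm Pb narrow-beam at 30 keV")),
    c40 = material("c40", 5.7,
                   c(Cd = 29.99, Te = 34.04, Zn = 4.361, Nb = 12.39, O = 19.21),
                   paste("CdO-rich quaternary tellurite glass; synthetic",
                         "stand-in composition 40CdO-40TeO2-10ZnO-10Nb2O5",
                         "(mol%), 5.7 g/cm^3 - override with the measured",
                         "glass when available"))
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) lib[[nm]] <- overrides[[nm]]
  }
  structure(lib, class = c("material_library", "list"))
}

#' @rdname material_library
#' @param lib A `material_library`.
#' @param ... Named `mc_material` objects to add or replace.
#' @export
library_with <- function(lib, ...) {
  overrides <- list(...)
  for (nm in names(overrides)) lib[[nm]] <- overrides[[nm]]
  lib
}

#' @rdname material_library
#' @export
materials_table <- function(lib = material_library()) {
  purrr::map_dfr(lib, function(m) {
    tibble(name = m$name, density = m$density,
           composition = paste0(m$composition$symbol, ":",
                                signif(100 * m$composition$fraction, 4),
                                "%", collapse = " "),
           provenance = m$provenance %||% NA_character_)
  })
}

resolve_material <- function(x, lib = material_library()) {
  if (inherits(x, "mc_material")) return(x)
  if (is.character(x) && length(x) == 1) {
    if (!x %in% names(lib)) abort(paste0("unknown material '", x, "'"))
    return(lib[[x]])
  }
  abort("material must be an mc_material or a library name")
}

#' Mass and linear attenuation coefficients of a material
#'
#' `mu_rho()` applies the mixture rule: the weight-fraction-weighted sum of
#' the elements' interpolated mass-attenuation components.
#' `linear_mu()` multiplies by the bulk density. Both are vectorised over
#' energy and refuse energies outside the embedded grid.
#'
#' @param material An `mc_material` or a library name.
#' @param energy_keV Photon energies in keV.
#' @param component `"total"` (default) or one of the partial components.
#' @param lib Material library used to resolve names.
#' @return Numeric vector, cm^2/g for `mu_rho()` and cm^-1 for `linear_mu()`.
#' @examples
#' mu_rho("water", 30)
#' linear_mu("skin", c(20, 30, 40))
#' @export
mu_rho <- function(material, energy_keV,
                   component = c("total", "photoelectric", "incoherent",
                                 "coherent"),
                   lib = material_library()) {
  component <- match.arg(component)
  m <- resolve_material(material, lib)
  if (m$vacuum) return(rep(0, length(energy_keV)))
  out <- rep(0, length(energy_keV))
  for (i in seq_len(nrow(m$composition))) {
    out <- out + m$composition$fraction[i] *
      element_xs(m$composition$symbol[i], energy_keV, component)
  }
  out
}

#' @rdname mu_rho
#' @export
linear_mu <- function(material, energy_keV,
                      component = c("total", "photoelectric", "incoherent",
                                    "coherent"),
                      lib = material_library()) {
  m <- resolve_material(material, lib)
  if (m$vacuum) return(rep(0, length(energy_keV)))
  m$density * mu_rho(m, energy_keV, component)
}

# pack the element tables + a vector of materials for the C++ kernel;
# vacuum is encoded as material index -1 (0-based: NA handled by caller)
materials_to_cpp <- function(mats) {
  lt <- element_log_tables()
  syms <- names(lt$log_components)
  n <- length(mats)
  wfrac <- matrix(0, nrow = max(n, 1), ncol = length(syms))
  dens <- numeric(max(n, 1))
  for (i in seq_len(n)) {
    m <- mats[[i]]
    dens[i] <- m$density
    if (!m$vacuum) {
      idx <- match(m$composition$symbol, syms)
      wfrac[i, idx] <- m$composition$fraction
    }
  }
  list(log_energy = lt$log_energy,
       log_components = unname(lt$log_components),
       wfrac = wfrac, density = dens)
}
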