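#' Embedded per-element attenuation components
#'
#' The package ships a static table of mass-attenuation components
#' (photoelectric, incoherent, coherent, in cm^2/g) for the elements used by
#' the material library, on a shared logarithmic energy grid covering
#' 1--150 keV with extra points bracketing the K and L edges of the high-Z
#' screen constituents (Zn, Nb, Cd, Te, Pb). The photoelectric component was
#' computed from the Cromer--Liberman photoabsorption compilation; coherent
#' and incoherent components were integrated from International Tables
#' atomic form factors with a Klein--Nishina kernel and the standard
#' incoherent-function approximation. The total mass attenuation coefficient
#' is the sum of the three components at every grid point.
#'
#' @return A tibble with columns `element`, `Z`, `A`, `energy_keV`,
#'   `photoelectric`, `incoherent`, `coherent` and `total` (all coefficients
#'   in cm^2/g).
#' @examples
#' et <- element_table()
#' dplyr::filter(et, element == "O", energy_keV > 29, energy_keV < 32)
#' @export
element_table <- function() {
  if (is.null(.ms_env$elements)) {
    path <- system.file("extdata", "element_xs.tsv", package = "mammoshield")
    raw <- utils::read.delim(path, stringsAsFactors = FALSE)
    tb <- as_tibble(raw)
    tb$total <- tb$photoelectric + tb$incoherent + tb$coherent
    .ms_env$elements <- tb
  }
  .ms_env$elements
}

element_symbols <- function() unique(element_table()$element)

# per-element list of log-component matrices (rows pe/inc/coh), plus the
# shared log-energy grid; cached because the transport kernel reuses it
element_log_tables <- function() {
  if (is.null(.ms_env$logtab)) {
    tb <- element_table()
    syms <- element_symbols()
    grid <- sort(unique(tb$energy_keV))
    mats <- lapply(syms, function(s) {
      d <- tb[tb$element == s, ]
      d <- d[order(d$energy_keV), ]
      stopifnot(nrow(d) == length(grid))
      rbind(log(pmax(d$photoelectric, 1e-300)),
            log(pmax(d$incoherent, 1e-300)),
            log(pmax(d$coherent, 1e-300)))
    })
    names(mats) <- syms
    .ms_env$logtab <- list(log_energy = log(grid), energy = grid,
                           log_components = mats)
  }
  .ms_env$logtab
}

#' Interpolated element mass-attenuation component
#'
#' Log-log interpolation of the embedded table for a single element. The
#' energy must lie inside the tabulated grid; no extrapolation is performed.
#'
#' @param symbol Chemical symbol (e.g. `"O"`, `"Pb"`).
#' @param energy_keV Photon energies in keV (vectorised).
#' @param component One of `"total"`, `"photoelectric"`, `"incoherent"`,
#'   `"coherent"`. The total is the sum of the three interpolated components.
#' @return Numeric vector of mass attenuation coefficients (cm^2/g).
#' @examples
#' element_xs("Pb", 30)
#' element_xs("O", c(20, 30, 40), component = "incoherent")
#' @export
element_xs <- function(symbol, energy_keV,
                       component = c("total", "photoelectric", "incoherent",
                                     "coherent")) {
  component <- match.arg(component)
  lt <- element_log_tables()
  if (!symbol %in% names(lt$log_components)) {
    abort(paste0("element '", symbol, "' is not in the embedded table"))
  }
  rng <- range(lt$energy)
  if (any(energy_keV < rng[1] | energy_keV > rng[2])) {
    abort(sprintf("energy outside the tabulated range [%g, %g] keV",
                  rng[1], rng[2]))
  }
  m <- lt$log_components[[symbol]]
  le <- log(energy_keV)
  interp <- function(row) exp(stats::approx(lt$log_energy, row, xout = le,
                                            rule = 1)$y)
  pe <- interp(m[1, ]); inc <- interp(m[2, ]); coh <- interp(m[3, ])
  switch(component,
         total = pe + inc + coh,
         photoelectric = pe,
         incoherent = inc,
         coherent = coh)
}
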