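#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a scenario result
#'
#' Returns the per-region dose table: one row per
#' (screen, energy, region) with the mean deposited energy per source
#' photon, the mass-normalized dose and the Monte Carlo relative error.
#'
#' @param x An `mc_scenario` from [run_scenario()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mc_scenario
#' @export
tidy.mc_scenario <- function(x, ...) x$doses

#' Glance at a scenario result
#'
#' One row per (screen, energy) run with the headline aggregates: total
#' right- and left-breast doses, total skin doses and their standard errors.
#'
#' @param x An `mc_scenario`.
#' @param ... Unused.
#' @return A tibble.
#' @method glance mc_scenario
#' @export
glance.mc_scenario <- function(x, ...) x$summary

#' @rdname tidy.mc_scenario
#' @method tidy mc_tf
#' @export
tidy.mc_tf <- function(x, ...) as_tibble(x)

#' @rdname tidy.mc_scenario
#' @method tidy mc_run
#' @export
tidy.mc_run <- function(x, ...) tally_report(x)

#' @rdname glance.mc_scenario
#' @method glance mc_run
#' @export
glance.mc_run <- function(x, ...) {
  tibble(n_histories = x$n_histories, energy_keV = x$energy_keV,
         emitted_keV = x$emitted_keV, deposited_keV = x$deposited_keV,
         escaped_keV = x$escaped_keV,
         max_conservation_err_keV = x$max_conservation_err_keV,
         n_aborted = x$n_aborted, seed = x$seed)
}
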