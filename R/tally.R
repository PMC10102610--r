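#' Monte Carlo relative error
#'
#' Sample standard error of the per-history mean divided by the mean, the
#' standard history-statistics estimator. A tally with zero mean has no
#' defined relative error and is reported as 1 with attribute
#' `degenerate = TRUE`.
#'
#' @param dep_sum Sum of per-history scores.
#' @param dep_sumsq Sum of squared per-history scores.
#' @param n Number of histories (>= 2).
#' @return Relative error in `[0, 1]` (vectorised).
#' @export
mc_relative_error <- function(dep_sum, dep_sumsq, n) {
  if (any(n < 2)) abort("relative error needs at least 2 histories")
  mean_ <- dep_sum / n
  var_ <- pmax(0, dep_sumsq / n - mean_^2) / (n - 1)
  out <- ifelse(mean_ > 0, pmin(1, sqrt(var_) / mean_), 1)
  attr(out, "degenerate") <- mean_ <= 0
  out
}

#' Per-region dose report
#'
#' Converts an [run_transport()] result into a tidy dose table: mean
#' deposited energy per source photon (eV/photon), the mass-normalized dose
#' (eV/g/photon) using the region's resolved volume and material density,
#' and the Monte Carlo relative error per region.
#'
#' @param run An `mc_run`.
#' @return A tibble with one row per tally cell (the world cell has id 0 and
#'   no mass normalization).
#' @export
tally_report <- function(run) {
  stopifnot(inherits(run, "mc_run"))
  tb <- run$cells
  n <- run$n_histories
  relerr <- mc_relative_error(tb$dep_sum_keV, tb$dep_sumsq_keV2, n)
  mass <- tb$volume_cm3 * tb$density
  tibble(region_id = tb$region_id, label = tb$label, material = tb$material,
         n_histories = n,
         mean_eV = 1000 * tb$dep_sum_keV / n,
         rel_error = as.numeric(relerr),
         volume_cm3 = tb$volume_cm3, mass_g = mass,
         mean_eV_per_g = 1000 * tb$dep_sum_keV / n / mass)
}

#' Transmission factor
#'
#' Ratio of the photon intensity recorded behind an absorber to the
#' intensity incident on it: `TF = secondary / primary`, with 1 meaning
#' fully transparent and 0 opaque. Intensities are weighted crossing counts
#' of the two detection rectangles. The standard error treats the secondary
#' count as binomial out of the primary count, which is exact when every
#' secondary crossing stems from a distinct primary photon.
#'
#' @param primary_count Weighted count on the source side (> 0).
#' @param secondary_count Weighted count behind the absorber.
#' @return A list with `tf` and `se`.
#' @examples
#' transmission_factor(1000, 368)
#' @export
transmission_factor <- function(primary_count, secondary_count) {
  if (any(primary_count <= 0)) {
    abort("undefined transmission factor: primary count is zero")
  }
  tf <- secondary_count / primary_count
  se <- sqrt(pmax(tf * (1 - tf), 0) / primary_count)
  list(tf = tf, se = se)
}

#' @rdname transmission_factor
#' @param run An `mc_run` with two plane tallies.
#' @param front,back Names of the front (primary) and rear (secondary)
#'   plane tallies.
#' @export
tf_from_run <- function(run, front = "front", back = "back") {
  pl <- run$planes
  miss <- setdiff(c(front, back), pl$name)
  if (length(miss)) abort(paste("missing plane tally:", paste(miss, collapse = ", ")))
  transmission_factor(pl$count[pl$name == front], pl$count[pl$name == back])
}

#' Total skin dose
#'
#' Sums the mean deposited energy over the listed skin cells (the way the
#' three independently modeled skin cells of the unexposed breast are summed
#' into one skin dose), combining their Monte Carlo uncertainties in
#' quadrature.
#'
#' @param report A [tally_report()] tibble.
#' @param skin_ids Integer region ids to sum (may be empty).
#' @return A list with `mean_eV` and `se_eV`.
#' @export
total_skin_dose <- function(report, skin_ids) {
  if (length(skin_ids) == 0) return(list(mean_eV = 0, se_eV = 0))
  idx <- match(skin_ids, report$region_id)
  if (anyNA(idx)) {
    abort(paste("region id(s) missing from report:",
                paste(skin_ids[is.na(idx)], collapse = ", ")))
  }
  m <- report$mean_eV[idx]
  se <- report$mean_eV[idx] * report$rel_error[idx]
  list(mean_eV = sum(m), se_eV = sqrt(sum(se^2)))
}
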