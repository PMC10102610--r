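#' Transport configuration
#'
#' @param cutoff_keV Photons falling below this energy deposit the remainder
#'   locally and terminate. Must be >= 1 keV (the lower edge of the embedded
#'   attenuation grid).
#' @param coherent_enabled Include Thomson coherent scattering (default TRUE).
#' @param max_interactions Hard cap per history; on reaching it the photon's
#'   remaining energy is deposited locally and the history is counted as
#'   aborted.
#' @return A list of class `transport_config`.
#' @export
transport_config <- function(cutoff_keV = 1, coherent_enabled = TRUE,
                             max_interactions = 1000L) {
  if (cutoff_keV < 1) abort("cutoff_keV must be >= 1 keV (table range)")
  if (max_interactions < 1) abort("max_interactions must be >= 1")
  structure(list(cutoff_keV = cutoff_keV,
                 coherent_enabled = isTRUE(coherent_enabled),
                 max_interactions = as.integer(max_interactions)),
            class = "transport_config")
}

#' Planar crossing tally
#'
#' A bounded rectangle on an axis-orthogonal plane; every photon track
#' segment strictly crossing the plane inside the rectangle adds its weight
#' to the count. With `primaries_only = TRUE` only photons that have not yet
#' interacted are counted (narrow-beam / primary-intensity mode).
#'
#' @param name Identifier used to look the count up in run results.
#' @param axis `"x"`, `"y"` or `"z"` (the plane is orthogonal to this axis).
#' @param coord Plane coordinate on `axis` (cm).
#' @param lo1,hi1,lo2,hi2 Rectangle bounds on the other two axes, taken in
#'   increasing axis order (x before y before z).
#' @param primaries_only Count only photons with zero prior interactions.
#' @return A one-row tibble.
#' @export
plane_tally <- function(name, axis = c("z", "x", "y"), coord,
                        lo1, hi1, lo2, hi2, primaries_only = FALSE) {
  axis <- match.arg(axis)
  tibble(name = name, axis = axis, coord = coord,
         lo1 = lo1, hi1 = hi1, lo2 = lo2, hi2 = hi2,
         primaries_only = isTRUE(primaries_only))
}

planes_to_cpp <- function(planes) {
  if (is.null(planes) || nrow(planes) == 0) return(list())
  ax <- match(planes$axis, c("x", "y", "z")) - 1L
  list(def = cbind(ax, planes$coord, planes$lo1, planes$hi1,
                   planes$lo2, planes$hi2, as.numeric(planes$primaries_only)))
}

#' Run a photon-transport batch
#'
#' Tracks `n_histories` analog photon histories through the scene:
#' exponential free paths, channel selection proportional to the partial
#' attenuation components, Klein--Nishina incoherent scattering with local
#' deposition of the energy transfer (kerma approximation), Thomson coherent
#' deflection, and photoelectric absorption depositing the full remaining
#' energy. Each history runs on its own deterministically seeded RNG stream,
#' so a given `(seed, configuration)` pair reproduces tallies bit for bit
#' and results do not depend on R's RNG state.
#'
#' @param scene An [mc_scene()].
#' @param source A [source_spec()].
#' @param planes Optional tibble of [plane_tally()] rows.
#' @param config A [transport_config()].
#' @param n_histories Number of histories (default: the source spec's).
#' @param seed Master seed (non-negative integer).
#' @param lib Material library resolving the scene's material names.
#' @return An `mc_run` object: list with `cells` (per-region tibble of
#'   deposition sums), `planes` (crossing counts), energy bookkeeping totals
#'   and run metadata. Use [tally_report()] to convert to doses.
#' @examples
#' sc <- mc_scene(box_region(1, "slab", -10, 10, -10, 10, 0, 1, "water"),
#'                world_bounds = c(-50, 50, -50, 50, -5, 70))
#' src <- source_spec("collimated_pyramid", c(0, 0, 10), 30,
#'                    footprint = c(-.1, .1, -.1, .1, 1))
#' run <- run_transport(sc, src, n_histories = 1000, seed = 1)
#' tally_report(run)
#' @export
run_transport <- function(scene, source, planes = NULL,
                          config = transport_config(),
                          n_histories = source$n_histories, seed = 1,
                          lib = material_library()) {
  stopifnot(inherits(scene, "mc_scene"), inherits(source, "source_spec"))
  packed <- scene_to_cpp(scene, lib)
  res <- cpp_run_batch(packed$cpp, packed$xs, source_to_cpp(source),
                       planes_to_cpp(planes),
                       config$cutoff_keV, config$coherent_enabled,
                       config$max_interactions,
                       as.double(n_histories), as.double(seed))
  cells <- packed$cells
  labels <- vapply(cells, function(id) {
    if (id == 0) return("world")
    paste(unique(scene$label[scene$region_id == id]), collapse = "+")
  }, character(1))
  mats <- vapply(cells, function(id) {
    if (id == 0) return(attr(scene, "world_material"))
    paste(unique(scene$material[scene$region_id == id]), collapse = "+")
  }, character(1))
  vols <- vapply(cells, function(id) {
    if (id == 0) return(NA_real_)
    sum(scene$volume_cm3[scene$region_id == id])
  }, numeric(1))
  dens <- vapply(cells, function(id) {
    if (id == 0) return(NA_real_)
    resolve_material(unique(scene$material[scene$region_id == id])[1],
                     lib)$density
  }, numeric(1))
  cell_tb <- tibble(region_id = cells, label = labels, material = mats,
                    volume_cm3 = vols, density = dens,
                    dep_sum_keV = res$dep_sum, dep_sumsq_keV2 = res$dep_sumsq)
  plane_tb <- if (is.null(planes) || nrow(planes) == 0) {
    tibble(name = character(), count = numeric())
  } else {
    tibble(name = planes$name, count = res$plane_counts,
           primaries_only = planes$primaries_only)
  }
  structure(list(cells = cell_tb, planes = plane_tb,
                 n_histories = res$n_histories,
                 emitted_keV = res$emitted_keV,
                 deposited_keV = res$deposited_keV,
                 escaped_keV = res$escaped_keV,
                 max_conservation_err_keV = res$max_conservation_err_keV,
                 n_aborted = res$n_aborted,
                 n_zero_interaction_escapes = res$n_zero_interaction_escapes,
                 energy_keV = source$energy_keV, seed = seed,
                 config = config),
            class = "mc_run")
}

#' @export
print.mc_run <- function(x, ...) {
  cat("<mc_run>", format(x$n_histories, big.mark = ","), "histories at",
      x$energy_keV, "keV, seed", x$seed, "\n")
  cat("  emitted", signif(x$emitted_keV, 6), "keV | deposited",
      signif(x$deposited_keV, 6), "| escaped", signif(x$escaped_keV, 6),
      "| max per-history closure error",
      format(x$max_conservation_err_keV, digits = 3), "keV\n")
  invisible(x)
}
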