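#' Phantom and screen specifications
#'
#' `phantom_spec()` parameterizes the two-breast phantom: per-breast block
#' dimensions, the three glandular-fraction layers ordered top (nearest the
#' source) to bottom, a skin shell on five faces, the inter-breast gap, a
#' soft-tissue body block behind both breasts, and the source-to-image
#' distance. The published model states the 2-mm skin, the 65-cm
#' source-image distance and the layer ordering; the lateral dimensions are
#' shown only as sketches, so the block sizes here are documented defaults.
#'
#' `screen_spec()` parameterizes the protective screen standing in the gap:
#' a 20 x 20 cm^2 face, 12 mm thick, centered on the geometric center of the
#' two breasts.
#'
#' @param breast_dim `c(width_x, depth_y, height_z)` of each breast block in
#'   cm (the three layers split the height equally).
#' @param layer_materials Materials of layers 1..3 from the top down.
#' @param skin_thickness Skin shell thickness in cm.
#' @param gap Distance between the medial faces of the two breasts (cm).
#' @param body_dim `c(x, y, z)` of the body block (cm).
#' @param body_material Material of the body block.
#' @param source_distance Source height above the image plane (cm).
#' @param world_material Material filling the rest of the world box.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(breast_dim = c(10, 10, 6),
                         layer_materials = c("gf25", "gf50", "gf75"),
                         skin_thickness = 0.2,
                         gap = 4,
                         body_dim = c(30, 20, 15),
                         body_material = "soft_tissue",
                         source_distance = 65,
                         world_material = "air") {
  stopifnot(length(breast_dim) == 3, all(breast_dim > 0),
            length(layer_materials) == 3, skin_thickness > 0, gap > 0,
            length(body_dim) == 3, source_distance > 0)
  structure(list(breast_dim = breast_dim, layer_materials = layer_materials,
                 skin_thickness = skin_thickness, gap = gap,
                 body_dim = body_dim, body_material = body_material,
                 source_distance = source_distance,
                 world_material = world_material),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param material Screen material name (`"lead_acrylic"`, `"c40"`, ...).
#' @param face `c(width, height)` of the screen face in cm.
#' @param thickness Screen thickness in cm.
#' @export
screen_spec <- function(material = "c40", face = c(20, 20), thickness = 1.2) {
  stopifnot(length(face) == 2, all(face > 0), thickness > 0)
  structure(list(material = material, face = face, thickness = thickness),
            class = "screen_spec")
}

# deterministic tally-cell numbering of the phantom
phantom_cell_ids <- function() {
  list(right_layers = 1:3, left_layers = 4:6, body = 7L, screen = 8L,
       left_skin = 9:11, right_skin = 12:14)
}

#' Build the two-breast phantom scene
#'
#' Constructs the right (exposed) and left (unexposed) breast blocks, three
#' layers each, skin shells on five faces (top, bottom, medial, lateral and
#' front; the chest-wall face abuts the body block), the body block and
#' optionally the protective screen centered between the breasts. Region
#' ids are deterministic: right layers 1-3 (top down), left layers 4-6,
#' body 7, screen 8, left-breast skin cells 9 (top+bottom), 10 (medial,
#' facing the screen) and 11 (remaining faces), right-breast skin 12-14 in
#' the same order. The world cell is 0.
#'
#' Boxes are laid out without overlaps except where the screen slab runs
#' into the body block; the screen takes priority there and the body's
#' resolved volume is corrected for the displaced overlap.
#'
#' @param spec A [phantom_spec()].
#' @param screen A [screen_spec()] or `NULL` for the unshielded phantom.
#' @return An [mc_scene()].
#' @examples
#' sc <- build_breast_phantom(phantom_spec(), screen_spec("c40"))
#' dplyr::count(sc, region_id)
#' @export
build_breast_phantom <- function(spec = phantom_spec(), screen = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  bw <- spec$breast_dim[1]; bd <- spec$breast_dim[2]; bh <- spec$breast_dim[3]
  sk <- spec$skin_thickness
  ids <- phantom_cell_ids()
  # breast core sits on a bottom skin slab: core z in [sk, sk + bh]
  z0 <- sk; z1 <- sk + bh; ztop <- z1 + sk
  lay <- bh / 3
  y0 <- -bd / 2; y1 <- bd / 2            # +y is the chest wall side
  half_gap <- spec$gap / 2

  one_breast <- function(x_in, x_out, layer_ids, skin_ids, side_label) {
    xlo <- min(x_in, x_out); xhi <- max(x_in, x_out)
    medial <- if (x_in < x_out) c(xlo - sk, xlo) else c(xhi, xhi + sk)
    lateral <- if (x_in < x_out) c(xhi, xhi + sk) else c(xlo - sk, xlo)
    layers <- purrr::map_dfr(1:3, function(i) {
      box_region(layer_ids[i], paste0(side_label, "_layer", i),
                 xlo, xhi, y0, y1, z1 - i * lay, z1 - (i - 1) * lay,
                 spec$layer_materials[i])
    })
    skin <- dplyr::bind_rows(
      box_region(skin_ids[1], paste0(side_label, "_skin_top"),
                 xlo, xhi, y0, y1, z1, ztop, "skin"),
      box_region(skin_ids[1], paste0(side_label, "_skin_bottom"),
                 xlo, xhi, y0, y1, z0 - sk, z0, "skin"),
      box_region(skin_ids[2], paste0(side_label, "_skin_medial"),
                 medial[1], medial[2], y0, y1, z0, z1, "skin"),
      box_region(skin_ids[3], paste0(side_label, "_skin_lateral"),
                 lateral[1], lateral[2], y0, y1, z0, z1, "skin"),
      box_region(skin_ids[3], paste0(side_label, "_skin_front"),
                 xlo, xhi, y0 - sk, y0, z0, z1, "skin"))
    dplyr::bind_rows(layers, skin)
  }

  right <- one_breast(half_gap, half_gap + bw, ids$right_layers,
                      ids$right_skin, "right")
  left <- one_breast(-half_gap, -half_gap - bw, ids$left_layers,
                     ids$left_skin, "left")

  body <- box_region(ids$body, "body", -spec$body_dim[1] / 2,
                     spec$body_dim[1] / 2, y1, y1 + spec$body_dim[2],
                     0, spec$body_dim[3], spec$body_material)

  regions <- dplyr::bind_rows(right, left, body)

  if (!is.null(screen)) {
    stopifnot(inherits(screen, "screen_spec"))
    if (screen$thickness >= spec$gap - 2 * sk) {
      abort("screen thicker than the inter-breast gap: volumes would overlap")
    }
    zc <- (0 + ztop) / 2                  # geometric center of the breasts
    sb <- box_region(ids$screen, "screen",
                     -screen$thickness / 2, screen$thickness / 2,
                     -screen$face[1] / 2, screen$face[1] / 2,
                     zc - screen$face[2] / 2, zc + screen$face[2] / 2,
                     screen$material, priority = 1L)
    # screen displaces body tissue where the slab runs into the body block
    ov <- box_overlap_volume(sb, body)
    if (ov > 0) {
      body$volume_cm3 <- body$volume_cm3 - ov
      regions$volume_cm3[regions$region_id == ids$body] <- body$volume_cm3
    }
    regions <- dplyr::bind_rows(regions, sb)
  }

  span_x <- max(abs(c(regions$xmin, regions$xmax))) + 25
  world <- c(-span_x, span_x, y0 - 25, y1 + spec$body_dim[2] + 10,
             -25, spec$source_distance + 5)
  mc_scene(regions, world_bounds = world,
           world_material = spec$world_material)
}

box_overlap_volume <- function(a, b) {
  dx <- min(a$xmax, b$xmax) - max(a$xmin, b$xmin)
  dy <- min(a$ymax, b$ymax) - max(a$ymin, b$ymin)
  dz <- min(a$zmax, b$zmax) - max(a$zmin, b$zmin)
  if (dx <= 0 || dy <= 0 || dz <= 0) return(0)
  dx * dy * dz
}

# collimated mammography source over the right breast top face
phantom_source <- function(spec, energy_keV, n_histories) {
  bw <- spec$breast_dim[1]; bd <- spec$breast_dim[2]
  sk <- spec$skin_thickness
  half_gap <- spec$gap / 2
  ztop <- 2 * sk + spec$breast_dim[3]
  source_spec("collimated_pyramid",
              position = c(half_gap + bw / 2, 0, spec$source_distance),
              energy_keV = energy_keV,
              footprint = c(half_gap, half_gap + bw, -bd / 2, bd / 2, ztop),
              n_histories = n_histories)
}

#' Run the shielding scenario matrix
#'
#' For every screen option and photon energy, builds the phantom, runs the
#' collimated exposure of the right breast and collects per-region doses
#' plus the headline aggregates: total right- and left-breast dose (sum of
#' the three layers), total skin dose per breast (sum of the three skin
#' cells) and their Monte Carlo uncertainties.
#'
#' @param spec A [phantom_spec()].
#' @param screens Character vector of screen options; `"none"` or material
#'   names present in the library.
#' @param energies Photon energies in keV.
#' @param n_histories Histories per (screen, energy) run.
#' @param seed Master seed; each (screen, energy) run derives its own
#'   deterministic sub-seed, so the whole table is reproducible.
#' @param lib Material library.
#' @param config A [transport_config()].
#' @param screen_template A [screen_spec()] supplying face size and
#'   thickness for the non-`"none"` options.
#' @param rel_error_warn Headline aggregates with a larger relative error
#'   are flagged unreliable.
#' @return An object of class `mc_scenario`: list with `doses` (per-region
#'   tibble), `summary` (per screen x energy aggregates) and `meta`.
#' @export
run_scenario <- function(spec = phantom_spec(),
                         screens = c("none", "lead_acrylic", "c40"),
                         energies = c(20, 25, 30, 35, 40),
                         n_histories = 1e6, seed = 1,
                         lib = material_library(),
                         config = transport_config(),
                         screen_template = screen_spec(),
                         rel_error_warn = 0.10) {
  ids <- phantom_cell_ids()
  grid <- tidyr::expand_grid(screen = screens, energy_keV = energies)
  grid$run_seed <- seed * 1e6 + seq_len(nrow(grid))

  res <- purrr::pmap(grid, function(screen, energy_keV, run_seed) {
    scr <- if (screen == "none") NULL else {
      s <- screen_template; s$material <- screen; s
    }
    scene <- build_breast_phantom(spec, scr)
    src <- phantom_source(spec, energy_keV, n_histories)
    run <- run_transport(scene, src, config = config,
                         n_histories = n_histories, seed = run_seed,
                         lib = lib)
    rep <- tally_report(run)
    agg <- function(cell_ids) total_skin_dose(rep, cell_ids)
    right <- agg(ids$right_layers); left <- agg(ids$left_layers)
    rskin <- agg(ids$right_skin); lskin <- agg(ids$left_skin)
    summary <- tibble(
      screen = screen, energy_keV = energy_keV,
      right_total_eV = right$mean_eV, right_se_eV = right$se_eV,
      left_total_eV = left$mean_eV, left_se_eV = left$se_eV,
      right_skin_eV = rskin$mean_eV, right_skin_se_eV = rskin$se_eV,
      left_skin_eV = lskin$mean_eV, left_skin_se_eV = lskin$se_eV,
      unreliable = left$mean_eV <= 0 ||
        left$se_eV / left$mean_eV > rel_error_warn,
      seed = run_seed)
    doses <- dplyr::mutate(rep, screen = screen, energy_keV = energy_keV,
                           .before = 1)
    list(summary = summary, doses = doses,
         conservation_err_keV = run$max_conservation_err_keV)
  })

  structure(list(
    doses = purrr::map_dfr(res, "doses"),
    summary = purrr::map_dfr(res, "summary"),
    meta = list(seed = seed, n_histories = n_histories,
                energies = energies, screens = screens,
                max_conservation_err_keV =
                  max(purrr::map_dbl(res, "conservation_err_keV")),
                spec = spec, config = config)),
    class = "mc_scenario")
}

#' @export
print.mc_scenario <- function(x, ...) {
  cat("<mc_scenario>", format(x$meta$n_histories, big.mark = ","),
      "histories per run, seed", x$meta$seed, "\n")
  print(x$summary)
  invisible(x)
}

#' Percent dose reduction
#'
#' `100 * (reference - candidate) / reference`, with first-order propagation
#' of the two Monte Carlo standard errors. Invariant to any common
#' normalization of both inputs (per photon vs per gram), since the
#' normalization cancels in the ratio.
#'
#' @param dose_reference Reference dose (> 0), e.g. behind the lead-acrylic
#'   screen.
#' @param dose_candidate Candidate dose, e.g. behind the glass screen.
#' @param se_reference,se_candidate Standard errors (default 0).
#' @return A tibble with `reduction_pct` and `se_pct`.
#' @examples
#' dose_reduction(10, 6.4)
#' @export
dose_reduction <- function(dose_reference, dose_candidate,
                           se_reference = 0, se_candidate = 0) {
  if (any(dose_reference <= 0)) {
    abort("undefined reduction: reference dose must be positive")
  }
  red <- 100 * (dose_reference - dose_candidate) / dose_reference
  se <- 100 * sqrt((se_candidate / dose_reference)^2 +
                   (dose_candidate * se_reference / dose_reference^2)^2)
  tibble(reduction_pct = red, se_pct = se)
}

#' @rdname dose_reduction
#' @param scenario An `mc_scenario` containing both screen options.
#' @param reference,candidate Screen option names to compare.
#' @return For `scenario_reduction()`: a tibble with one row per energy.
#' @export
scenario_reduction <- function(scenario, reference = "lead_acrylic",
                               candidate = "c40") {
  s <- scenario$summary
  r <- s[s$screen == reference, ]
  c_ <- s[s$screen == candidate, ]
  if (nrow(r) == 0 || nrow(c_) == 0) {
    abort("scenario lacks one of the requested screen options")
  }
  c_ <- c_[match(r$energy_keV, c_$energy_keV), ]
  dplyr::bind_cols(tibble(energy_keV = r$energy_keV),
                   dose_reduction(r$left_total_eV, c_$left_total_eV,
                                  r$left_se_eV, c_$left_se_eV))
}

#' Narrow-beam lead equivalence
#'
#' Thickness of pure lead with the same narrow-beam attenuation as
#' `thickness_cm` of the material at the given energy:
#' `t_Pb = mu_material * t / mu_Pb`, reported in mm.
#'
#' @param material Material (object or library name).
#' @param thickness_cm Material thickness in cm.
#' @param energy_keV Photon energy in keV.
#' @param lib Material library (supplies the `lead` entry).
#' @return Equivalent lead thickness in mm (vectorised over energy).
#' @examples
#' lead_equivalence("lead_acrylic", 1.2, 30)
#' @export
lead_equivalence <- function(material, thickness_cm, energy_keV,
                             lib = material_library()) {
  mu_m <- linear_mu(material, energy_keV, lib = lib)
  mu_pb <- linear_mu("lead", energy_keV, lib = lib)
  if (any(mu_pb <= 0)) abort("lead attenuation is zero at this energy")
  10 * mu_m * thickness_cm / mu_pb
}

#' Transmission-factor pilot
#'
#' The two-detection-zone setup: an isotropic point source in vacuum, a
#' screen slab of the given thickness, a bounded detection rectangle in
#' front of the slab counting primary photons and one behind it counting
#' every emerging photon (broad-beam by default). The transmission factor is
#' the ratio of the two counts. Because each history runs on its own seeded
#' RNG stream and the front zone only counts photons that have not yet
#' interacted, the primary count at a fixed seed and energy is identical
#' for every screen material.
#'
#' @param screen_materials Materials to compare.
#' @param energies Photon energies in keV.
#' @param n_histories Histories per (material, energy).
#' @param seed Master seed.
#' @param thickness_cm Slab thickness (cm).
#' @param face_cm Slab face side length (cm).
#' @param source_distance_cm Source-to-slab distance (cm).
#' @param broad_beam Count scattered photons behind the slab (default TRUE);
#'   `FALSE` counts only never-interacted photons (narrow-beam mode, the
#'   analytic-attenuation configuration).
#' @param lib Material library.
#' @param config A [transport_config()].
#' @return An object of class `mc_tf`: tibble with per (material, energy)
#'   primary and secondary counts, `tf` and its standard error.
#' @export
tf_pilot <- function(screen_materials = c("lead_acrylic", "c40"),
                     energies = c(20, 25, 30, 35, 40),
                     n_histories = 1e5, seed = 1,
                     thickness_cm = 1.2, face_cm = 20,
                     source_distance_cm = 5, broad_beam = TRUE,
                     lib = material_library(),
                     config = transport_config()) {
  half <- face_cm / 2
  z0 <- source_distance_cm
  # both detection rectangles cut the cone the slab's exit face subtends
  # from the point source, so in vacuum every counted primary reaches the
  # rear zone and TF = 1 up to edge effects
  cone <- half / (z0 + thickness_cm)
  zf <- z0 - 0.1; zb <- z0 + thickness_cm + 0.1
  fhw <- zf * cone; bhw <- zb * cone
  grid <- tidyr::expand_grid(material = screen_materials,
                             energy_keV = energies)
  grid$run_seed <- seed * 1e6 + match(grid$energy_keV, energies)
  # same sub-seed across materials at fixed energy: identical emissions
  rows <- purrr::pmap_dfr(grid, function(material, energy_keV, run_seed) {
    slab <- box_region(1, "slab", -half, half, -half, half, z0, z0 + thickness_cm,
                       material)
    scene <- mc_scene(slab, world_bounds = c(-60, 60, -60, 60, -60, 60),
                      world_material = "vacuum")
    src <- source_spec("isotropic_point", c(0, 0, 0), energy_keV,
                       n_histories = n_histories)
    planes <- dplyr::bind_rows(
      plane_tally("front", "z", zf, -fhw, fhw, -fhw, fhw,
                  primaries_only = TRUE),
      plane_tally("back", "z", zb, -bhw, bhw, -bhw, bhw,
                  primaries_only = !broad_beam))
    run <- run_transport(scene, src, planes = planes, config = config,
                         n_histories = n_histories, seed = run_seed,
                         lib = lib)
    tfv <- tf_from_run(run)
    tibble(material = material, energy_keV = energy_keV,
           primary = run$planes$count[run$planes$name == "front"],
           secondary = run$planes$count[run$planes$name == "back"],
           tf = tfv$tf, se = tfv$se, seed = run_seed)
  })
  structure(rows, class = c("mc_tf", class(rows)))
}

#' Validation run against the external mammography reference phantom
#'
#' Mammography transport models are conventionally validated against the
#' AAPM TG-195 reference dataset: a breast phantom with an 80/20
#' adipose-to-glandular tissue mixture and a reference deposited energy per
#' photon. The reference geometry and spectra are defined in the external
#' report and are not shipped here; this runner therefore requires the
#' caller to supply them and degrades gracefully otherwise.
#'
#' @param config `NULL`, or a list with elements `phantom_dim` (cm, length
#'   3), `source_distance` (cm), `energy_keV`, `n_histories`, `seed`, and
#'   optionally `glandular_fraction` (default 0.2).
#' @param lib Material library.
#' @return A list with `mean_eV_per_photon` and `rel_error`.
#' @export
tg195_validation <- function(config = NULL, lib = material_library()) {
  if (is.null(config)) {
    abort(paste("TG-195 validation is not configured: supply the reference",
                "phantom dimensions, spectrum and histories from the",
                "external report (list(phantom_dim=, source_distance=,",
                "energy_keV=, n_histories=, seed=))"))
  }
  needed <- c("phantom_dim", "source_distance", "energy_keV", "n_histories",
              "seed")
  miss <- setdiff(needed, names(config))
  if (length(miss)) {
    abort(paste("TG-195 config is missing:", paste(miss, collapse = ", ")))
  }
  gf <- config$glandular_fraction %||% 0.2
  mat <- tg195_breast_material(gf)
  d <- config$phantom_dim
  scene <- mc_scene(
    box_region(1, "tg195_breast", -d[1] / 2, d[1] / 2, -d[2] / 2, d[2] / 2,
               0, d[3], "tg195_breast"),
    world_bounds = c(-60, 60, -60, 60, -10, config$source_distance + 10),
    world_material = "vacuum")
  src <- source_spec("collimated_pyramid",
                     c(0, 0, config$source_distance), config$energy_keV,
                     footprint = c(-d[1] / 2, d[1] / 2, -d[2] / 2, d[2] / 2,
                                   d[3]),
                     n_histories = config$n_histories)
  run <- run_transport(scene, src, n_histories = config$n_histories,
                       seed = config$seed,
                       lib = library_with(lib, tg195_breast = mat))
  rep <- tally_report(run)
  list(mean_eV_per_photon = rep$mean_eV[rep$region_id == 1],
       rel_error = rep$rel_error[rep$region_id == 1])
}

#' @rdname tg195_validation
#' @param glandular_fraction Glandular weight fraction of the mixture
#'   (0.2 for the 80/20 adipose-to-glandular phantom).
#' @export
tg195_breast_material <- function(glandular_fraction = 0.2) {
  stopifnot(glandular_fraction > 0, glandular_fraction < 1)
  adipose <- c(H = 11.4, C = 59.8, N = 0.7, O = 27.8)    # ICRU adipose
  glandular <- c(H = 10.6, C = 33.2, N = 3.0, O = 52.7)  # ICRU glandular
  mixed <- (1 - glandular_fraction) * adipose + glandular_fraction * glandular
  density <- 1 / ((1 - glandular_fraction) / 0.95 + glandular_fraction / 1.02)
  material("tg195_breast", density, mixed,
           provenance = sprintf(
             "adipose/glandular mixture, glandular weight fraction %.2f",
             glandular_fraction))
}
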