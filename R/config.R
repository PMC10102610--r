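#' Study configuration
#'
#' `default_config()` returns the fully worked default configuration as a
#' nested list (materials, phantom, screens, source, transport blocks);
#' `read_config()` loads a YAML document and merges it over the defaults;
#' `library_from_config()` builds the material library with any material
#' overrides from a config.
#'
#' @return `default_config()` / `read_config()`: a nested list.
#' @examples
#' cfg <- default_config()
#' names(cfg)
#' @export
default_config <- function() {
  list(
    materials = list(),   # name -> list(density =, composition = list(sym = pct))
    phantom = list(breast_dim = c(10, 10, 6),
                   layer_materials = c("gf25", "gf50", "gf75"),
                   skin_thickness = 0.2, gap = 4,
                   body_dim = c(30, 20, 15), body_material = "soft_tissue",
                   source_distance = 65, world_material = "air"),
    screens = list(options = c("none", "lead_acrylic", "c40"),
                   face = c(20, 20), thickness = 1.2),
    source = list(energies_keV = c(20, 25, 30, 35, 40),
                  n_histories = 1e6, seed = 1),
    transport = list(cutoff_keV = 1, coherent_enabled = TRUE,
                     max_interactions = 1000))
}

#' @rdname default_config
#' @param path Path to a YAML config file.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user, keep.null = TRUE)
}

#' @rdname default_config
#' @param config A config list.
#' @export
library_from_config <- function(config = default_config()) {
  overrides <- lapply(names(config$materials), function(nm) {
    m <- config$materials[[nm]]
    material(nm, m$density, unlist(m$composition),
             provenance = m$provenance %||% "config override")
  })
  names(overrides) <- names(config$materials)
  material_library(overrides = overrides)
}

#' @rdname default_config
#' @export
run_study_from_config <- function(config = default_config()) {
  ph <- config$phantom
  run_scenario(
    spec = phantom_spec(breast_dim = ph$breast_dim,
                        layer_materials = ph$layer_materials,
                        skin_thickness = ph$skin_thickness, gap = ph$gap,
                        body_dim = ph$body_dim,
                        body_material = ph$body_material,
                        source_distance = ph$source_distance,
                        world_material = ph$world_material),
    screens = config$screens$options,
    energies = config$source$energies_keV,
    n_histories = config$source$n_histories,
    seed = config$source$seed,
    lib = library_from_config(config),
    config = transport_config(config$transport$cutoff_keV,
                              config$transport$coherent_enabled,
                              config$transport$max_interactions),
    screen_template = screen_spec(face = config$screens$face,
                                  thickness = config$screens$thickness))
}
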