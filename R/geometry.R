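#' Axis-aligned box region
#'
#' One constructive-geometry cell: an axis-aligned box with a material
#' assignment, a tally cell id and an overlap priority. Several boxes may
#' share one `region_id`; they are then tallied together as a single cell
#' (the way a skin shell built from several slabs is scored as one cell).
#'
#' @param region_id Integer tally-cell id (> 0; 0 is reserved for the world).
#' @param label Human-readable label.
#' @param xmin,xmax,ymin,ymax,zmin,zmax Bounds in cm (`min < max` per axis).
#' @param material Material name (resolved against the library at run time).
#' @param priority Integer; where boxes overlap the highest priority wins.
#' @param volume_cm3 Resolved volume of the box; defaults to the raw box
#'   volume, and builders that create known overlaps pass the corrected value.
#' @return A one-row tibble.
#' @export
box_region <- function(region_id, label, xmin, xmax, ymin, ymax, zmin, zmax,
                       material, priority = 0L, volume_cm3 = NULL) {
  if (any(c(xmax - xmin, ymax - ymin, zmax - zmin) <= 0)) {
    abort(paste0("degenerate box '", label, "': need min < max on every axis"))
  }
  if (region_id <= 0) abort("region_id must be a positive integer")
  vol <- volume_cm3 %||% ((xmax - xmin) * (ymax - ymin) * (zmax - zmin))
  tibble(region_id = as.integer(region_id), label = label,
         xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
         zmin = zmin, zmax = zmax, material = material,
         priority = as.integer(priority), volume_cm3 = vol)
}

#' Assemble a scene from box regions
#'
#' A scene is a tibble of [box_region()] rows plus an enclosing world box.
#' Point containment is half-open (`min <= x < max`); a point on a shared
#' face resolves to the region on the far side of the travel direction,
#' which the transport implements by nudging past each crossed surface.
#'
#' @param regions Tibble of box regions (rows from [box_region()]).
#' @param world_bounds Numeric `c(xmin, xmax, ymin, ymax, zmin, zmax)` in cm.
#' @param world_material Material filling space between regions
#'   (default `"vacuum"`).
#' @return The region tibble with class `mc_scene` and attributes
#'   `world_bounds` / `world_material`. The world tally cell has id 0.
#' @examples
#' sc <- mc_scene(box_region(1, "cube", -.5, .5, -.5, .5, -.5, .5, "water"),
#'                world_bounds = c(-5, 5, -5, 5, -5, 5))
#' scene_locate(sc, c(0, 0, 0))
#' @export
mc_scene <- function(regions, world_bounds, world_material = "vacuum") {
  regions <- as_tibble(regions)
  stopifnot(length(world_bounds) == 6)
  wb <- matrix(world_bounds, ncol = 2, byrow = TRUE)
  if (any(wb[, 1] >= wb[, 2])) abort("world bounds need min < max per axis")
  inside <- regions$xmin >= world_bounds[1] & regions$xmax <= world_bounds[2] &
    regions$ymin >= world_bounds[3] & regions$ymax <= world_bounds[4] &
    regions$zmin >= world_bounds[5] & regions$zmax <= world_bounds[6]
  if (!all(inside)) {
    abort(paste0("region(s) outside the world box: ",
                 paste(regions$label[!inside], collapse = ", ")))
  }
  structure(regions,
            world_bounds = as.numeric(world_bounds),
            world_material = world_material,
            class = c("mc_scene", class(regions)))
}

# pack a scene for the C++ kernel; returns the cpp list plus the cell-id map
scene_to_cpp <- function(scene, lib = material_library()) {
  wb <- attr(scene, "world_bounds")
  wm <- attr(scene, "world_material")
  cell_ids <- sort(unique(scene$region_id))
  if (0 %in% cell_ids) abort("region_id 0 is reserved for the world")
  cells <- c(cell_ids, 0L)                       # world cell is last
  mat_names <- unique(c(scene$material, wm))
  mats <- lapply(mat_names, resolve_material, lib = lib)
  list(cpp = list(
         bounds = as.matrix(scene[, c("xmin", "xmax", "ymin", "ymax",
                                      "zmin", "zmax")]),
         cell = match(scene$region_id, cells) - 1L,
         mat = match(scene$material, mat_names) - 1L,
         priority = as.integer(scene$priority),
         world_bounds = wb,
         world_cell = length(cells) - 1L,
         world_mat = match(wm, mat_names) - 1L),
       cells = cells,
       materials = mats,
       xs = materials_to_cpp(mats))
}

#' Locate points in a scene
#'
#' Returns the tally-cell id of the highest-priority region containing each
#' point, 0 for points in the world region, and `NA` for points outside the
#' world (escaped).
#'
#' @param scene An [mc_scene()].
#' @param points A length-3 vector or an `n x 3` matrix of coordinates (cm).
#' @return Integer vector of region ids.
#' @export
scene_locate <- function(scene, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  packed <- scene_to_cpp(scene)
  rows <- cpp_locate(packed$cpp, points)
  ifelse(is.na(rows), NA_integer_,
         ifelse(rows == 0L, 0L, scene$region_id[rows]))
}

#' Ray distance to the next region change
#'
#' Walks a ray from `point` along `direction` and returns the distance to
#' the nearest surface crossing at which the resolved region changes,
#' together with the id of the region beyond it. A ray that leaves the scene
#' reports the distance to the world boundary with `escaped = TRUE`.
#'
#' @param scene An [mc_scene()].
#' @param point Length-3 position (cm), inside the world.
#' @param direction Length-3 direction; normalized internally (must be within
#'   1e-9 of unit length).
#' @return A list with `distance` (cm), `next_region_id` and `escaped`.
#' @export
scene_distance <- function(scene, point, direction) {
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-9) {
    if (nrm == 0) abort("direction must be non-zero")
    direction <- direction / nrm
  }
  packed <- scene_to_cpp(scene)
  res <- cpp_distance_to_boundary(packed$cpp, as.numeric(point),
                                  as.numeric(direction))
  nid <- if (res$escaped || is.na(res$next_row)) NA_integer_
         else if (res$next_row == 0L) 0L
         else scene$region_id[res$next_row]
  list(distance = res$distance, next_region_id = nid, escaped = res$escaped)
}
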