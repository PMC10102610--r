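# Independent oracles and small scene builders shared across tests.

# numeric CDF of the free-electron Klein-Nishina angular distribution,
# integrated on a fine cos(theta) grid (independent of the sampler)
kn_angle_cdf <- function(energy_keV, grid = seq(-1, 1, length.out = 20001)) {
  k <- energy_keV / 510.99895
  r <- 1 / (1 + k * (1 - grid))
  f <- r^2 * (r + 1 / r - (1 - grid^2))
  cdf <- cumsum(f)
  list(x = grid, cdf = (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1]))
}

# pure-R point location (containment + priority), independent of the kernel
r_locate <- function(scene, p) {
  hit <- which(p[1] >= scene$xmin & p[1] < scene$xmax &
               p[2] >= scene$ymin & p[2] < scene$ymax &
               p[3] >= scene$zmin & p[3] < scene$zmax)
  if (length(hit) == 0) return(0L)
  hit <- hit[which.max(scene$priority[hit])]
  scene$region_id[hit]
}

# fine-step ray marching with the pure-R locator
r_ray_march <- function(scene, p, u, step = 1e-4, max_dist = 20) {
  wb <- attr(scene, "world_bounds")
  start <- r_locate(scene, p)
  d <- 0
  while (d < max_dist) {
    d <- d + step
    q <- p + d * u
    if (any(q < wb[c(1, 3, 5)]) || any(q > wb[c(2, 4, 6)])) {
      return(list(distance = d, next_region_id = NA_integer_, escaped = TRUE))
    }
    id <- r_locate(scene, q)
    if (id != start) {
      return(list(distance = d, next_region_id = id, escaped = FALSE))
    }
  }
  stop("ray-march oracle ran out of distance")
}

# single-slab scene in vacuum with a normally incident pencil beam
slab_case <- function(material, thickness, energy_keV, n_histories, seed,
                      primaries_only = TRUE) {
  half <- 30
  ztop <- thickness + 1
  scene <- mc_scene(
    box_region(1, "slab", -half, half, -half, half, 0, thickness, material),
    world_bounds = c(-half - 1, half + 1, -half - 1, half + 1,
                     -1, ztop + 1),
    world_material = "vacuum")
  src <- source_spec("collimated_pyramid", c(0, 0, ztop), energy_keV,
                     footprint = c(-1e-4, 1e-4, -1e-4, 1e-4, thickness))
  planes <- plane_tally("back", "z", -0.5, -half, half, -half, half,
                        primaries_only = primaries_only)
  run_transport(scene, src, planes = planes, n_histories = n_histories,
                seed = seed)
}

# transmitted-primary fraction through a slab and its binomial SE
slab_primary_fraction <- function(material, thickness, energy_keV,
                                  n_histories, seed) {
  run <- slab_case(material, thickness, energy_keV, n_histories, seed)
  p <- run$planes$count[run$planes$name == "back"] / n_histories
  list(p = p, se = sqrt(max(p * (1 - p), 1 / n_histories) / n_histories),
       run = run)
}
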