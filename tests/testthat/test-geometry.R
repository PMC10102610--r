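make_two_box_scene <- function() {
  mc_scene(dplyr::bind_rows(
    box_region(1, "outer", -1, 1, -1, 1, -1, 1, "water", priority = 0L),
    box_region(2, "inner", -0.3, 0.3, -0.3, 0.3, -0.3, 0.3, "skin",
               priority = 1L)),
    world_bounds = c(-5, 5, -5, 5, -5, 5), world_material = "vacuum")
}

test_that("locate resolves containment, fallback and priority", {
  lone <- mc_scene(box_region(7, "cube", -.5, .5, -.5, .5, -.5, .5, "water"),
                   world_bounds = c(-5, 5, -5, 5, -5, 5))
  expect_identical(scene_locate(lone, c(0, 0, 0)), 7L)
  expect_identical(scene_locate(lone, c(2, 2, 2)), 0L)      # world fallback
  expect_true(is.na(scene_locate(lone, c(10, 0, 0))))       # escaped

  sc <- make_two_box_scene()
  expect_identical(scene_locate(sc, c(0, 0, 0)), 2L)        # priority wins
  expect_identical(scene_locate(sc, c(0.5, 0.5, 0.5)), 1L)
  # several points at once
  expect_identical(scene_locate(sc, rbind(c(0, 0, 0), c(0.5, 0, 0), c(3, 0, 0))),
                   c(2L, 1L, 0L))
})

test_that("boundary distance handles axis rays and grazing directions", {
  lone <- mc_scene(box_region(1, "cube", -.5, .5, -.5, .5, -.5, .5, "water"),
                   world_bounds = c(-5, 5, -5, 5, -5, 5))
  d <- scene_distance(lone, c(0, 0, 0), c(1, 0, 0))
  expect_equal(d$distance, 0.5, tolerance = 1e-7)
  expect_identical(d$next_region_id, 0L)

  # ray started just outside a face, travelling parallel to it: the
  # parallel face is ignored and the ray exits through the world top
  g <- scene_distance(lone, c(0.6, 0, 0), c(0, 0, 1))
  expect_equal(g$distance, 5, tolerance = 1e-6)
  expect_true(g$escaped)

  expect_error(scene_distance(lone, c(20, 0, 0), c(1, 0, 0)), "outside")
})

test_that("boundary distances agree with a fine-step ray-marching oracle", {
  set.seed(421)
  sc <- make_two_box_scene()
  for (i in 1:25) {
    p <- runif(3, -0.9, 0.9)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    got <- scene_distance(sc, p, u)
    want <- r_ray_march(sc, p, u, step = 1e-4)
    expect_lt(abs(got$distance - want$distance), 2e-4)  # oracle step size
    expect_identical(got$escaped, want$escaped)
    if (!want$escaped) {
      expect_identical(got$next_region_id, want$next_region_id)
    }
  }
})

test_that("stepping just past the boundary lands in the reported region", {
  set.seed(99)
  sc <- make_two_box_scene()
  for (i in 1:20) {
    p <- runif(3, -0.9, 0.9)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    d <- scene_distance(sc, p, u)
    if (!d$escaped) {
      q <- p + (d$distance * (1 + 1e-9) + 1e-9) * u
      expect_identical(scene_locate(sc, q), d$next_region_id)
    }
  }
})

test_that("segment lengths along a ray sum to the world chord", {
  sc <- make_two_box_scene()
  set.seed(5)
  for (i in 1:10) {
    p <- runif(3, -0.2, 0.2)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    # walk surface to surface until escape, summing segments
    total <- 0; q <- p
    repeat {
      d <- scene_distance(sc, q, u)
      total <- total + d$distance
      if (d$escaped) break
      q <- q + (d$distance + 1e-9) * u
      total <- total + 1e-9
    }
    # chord through the world box from p
    wb <- attr(sc, "world_bounds")
    tmax <- min(pmax((wb[c(1, 3, 5)] - p) / u, (wb[c(2, 4, 6)] - p) / u))
    expect_equal(total, tmax, tolerance = 1e-5)
  }
})

test_that("scene construction enforces the world contract", {
  expect_error(box_region(1, "bad", 1, 0, 0, 1, 0, 1, "water"), "degenerate")
  expect_error(mc_scene(box_region(1, "big", -10, 10, -1, 1, -1, 1, "water"),
                        world_bounds = c(-5, 5, -5, 5, -5, 5)),
               "outside the world")
  sc0 <- mc_scene(box_region(1, "a", -1, 1, -1, 1, -1, 1, "water"),
                  world_bounds = c(-5, 5, -5, 5, -5, 5))
  sc0$region_id <- 0L
  expect_error(scene_to_cpp(sc0), "reserved")
})
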