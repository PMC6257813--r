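test_that("relative_azimuth handles the axis cases and wraparound", {
  p <- pose(position = c(0, 0, 0), yaw = 0)
  expect_equal(relative_azimuth(p, c(1, 0, 0)), 0)
  expect_equal(relative_azimuth(p, c(0, -1, 0)), 90)   # right-positive
  expect_equal(relative_azimuth(p, c(0, 1, 0)), -90)
  expect_equal(relative_azimuth(p, c(-1, 0, 0)), 180)
  # wraparound: facing 170, target at absolute azimuth -170 is 20 right
  p2 <- pose(yaw = 170)
  target <- c(cos(-170 * pi / 180), -sin(-170 * pi / 180), 0)
  expect_equal(relative_azimuth(p2, target), 20)
  expect_error(relative_azimuth(p, c(0, 0, 2)), "undefined")
})

test_that("relative_azimuth agrees with the unit-circle wrap oracle", {
  set.seed(42)
  for (i in 1:200) {
    p <- pose(position = runif(3, -5, 5), yaw = runif(1, -720, 720))
    q <- p$position + c(runif(2, -5, 5), runif(1, -1, 1))
    if (all(q[1:2] == p$position[1:2])) next
    abs_az <- -atan2(q[2] - p$position[2], q[1] - p$position[1]) * 180 / pi
    expect_equal(relative_azimuth(p, q), wrap_oracle(abs_az - p$yaw),
                 tolerance = 1e-12)
  }
})

test_that("a 180-degree turn flips the relative azimuth by 180 (mod 360)", {
  set.seed(7)
  for (i in 1:100) {
    p1 <- pose(position = c(runif(2, -3, 3), 0), yaw = runif(1, -180, 180))
    p2 <- pose(position = p1$position, yaw = p1$yaw + 180)
    q <- c(runif(2, -9, 9), 0)
    if (all(q[1:2] == p1$position[1:2])) next
    a1 <- relative_azimuth(p1, q)
    a2 <- relative_azimuth(p2, q)
    expect_equal(abs(wrap_angle(a1 - a2)), 180, tolerance = 1e-9)
  }
})

test_that("spotlight boundary is inclusive at half-aperture", {
  p <- pose()
  at_az <- function(az) c(cos(-az * pi / 180), -sin(-az * pi / 180), 0)
  expect_true(in_spotlight(p, at_az(0), 30))
  expect_true(in_spotlight(p, at_az(15), 30))
  expect_false(in_spotlight(p, at_az(16), 30))
  expect_false(in_spotlight(p, at_az(-15.01), 30))
  expect_error(in_spotlight(p, at_az(0), 360))
})

test_that("scan_order sorts left to right with id tie-break", {
  sc <- scene_at_azimuths(c(60, -60, 0), ids = c("c", "a", "b"))
  ord <- scan_order(sc, pose())
  expect_equal(vapply(ord, `[[`, "", "id"), c("a", "b", "c"))

  # single object
  expect_length(scan_order(scene_at_azimuths(10), pose()), 1)
  expect_length(scan_order(scene(), pose()), 0)

  # identical azimuth: lexicographic by id
  sc2 <- scene(list(scene_object("zeta", position = c(1, 0, 0)),
                    scene_object("alpha", position = c(2, 0, 0))))
  expect_equal(vapply(scan_order(sc2, pose()), `[[`, "", "id"),
               c("alpha", "zeta"))
})

test_that("scan_order is a permutation, invariant under global rotation", {
  set.seed(11)
  for (i in 1:25) {
    az <- runif(6, -179, 179)
    sc <- scene_at_azimuths(az)
    ids0 <- vapply(scan_order(sc, pose()), `[[`, "", "id")
    expect_setequal(ids0, sprintf("obj%02d", 1:6))
    delta <- runif(1, -180, 180)
    sc_rot <- scene_at_azimuths(az + delta)   # rotate scene ...
    ids1 <- vapply(scan_order(sc_rot, pose(yaw = delta)), `[[`, "", "id")
    expect_equal(ids1, ids0)                  # ... and the pose with it
  }
})

test_that("distance_to_nearest_obstacle matches the geometry", {
  g <- occupancy_grid(rows = 40, cols = 40, cell_size = 0.1)
  sc_empty <- scene(grid = g)
  expect_equal(distance_to_nearest_obstacle(sc_empty, c(2, 2, 0)), Inf)
  expect_equal(distance_to_nearest_obstacle(scene(), c(2, 2, 0)), Inf)

  # one blocked cell: cell (20, 30) covers x in (2.9, 3.0), y in (1.9, 2.0)
  g2 <- occupancy_grid(rows = 40, cols = 40, cell_size = 0.1,
                       blocked = cbind(20, 30))
  sc <- scene(grid = g2)
  expect_equal(distance_to_nearest_obstacle(sc, c(1.9, 1.95, 0)), 1.0)
  expect_equal(distance_to_nearest_obstacle(sc, c(2.95, 1.95, 0)), 0)
  expect_error(distance_to_nearest_obstacle(sc, c(50, 50, 0)), "bounds")

  near <- nearest_obstacle(sc, c(1.9, 1.95, 0))
  expect_equal(near$point, c(2.9, 1.95))
})

test_that("obstacle distance agrees with an independent per-cell formula", {
  set.seed(3)
  for (i in 1:20) {
    nr <- sample(5:20, 1); nc <- sample(5:20, 1)
    blk <- matrix(runif(nr * nc) < 0.15, nr, nc)
    if (!any(blk)) blk[1, 1] <- TRUE
    g <- occupancy_grid(rows = nr, cols = nc, cell_size = 0.25,
                        blocked = blk)
    sc <- scene(grid = g)
    p <- c(runif(1, 0, nc * 0.25), runif(1, 0, nr * 0.25), 0)
    idx <- which(blk, arr.ind = TRUE)
    h <- 0.25 / 2
    cx <- (idx[, 2] - 0.5) * 0.25
    cy <- (idx[, 1] - 0.5) * 0.25
    d_oracle <- min(sqrt(pmax(abs(p[1] - cx) - h, 0)^2 +
                           pmax(abs(p[2] - cy) - h, 0)^2))
    expect_equal(distance_to_nearest_obstacle(sc, p), d_oracle,
                 tolerance = 1e-12)
  }
})

test_that("scene validation catches bad fields", {
  expect_error(scene_object("x", position = c(1, 2, 0), radius = -1),
               "radius")
  expect_error(scene_object("", position = c(1, 2, 0)), "id")
  expect_error(scene_object("x", label = "", position = c(1, 2, 0)),
               "label")
  expect_error(occupancy_grid(10, 10, cell_size = 0), "cell_size")
  expect_error(
    scene(list(scene_object("a", position = c(1, 1, 0)),
               scene_object("a", position = c(2, 2, 0)))),
    "duplicate")
  g <- occupancy_grid(rows = 10, cols = 10, cell_size = 0.1)
  expect_error(scene(list(scene_object("far", position = c(9, 9, 0))),
                     grid = g), "outside")
})

test_that("scene config save/load is a round trip with field validation", {
  fx <- fixture_living_room()
  f <- withr::local_tempfile(fileext = ".json")
  save_scene(fx$scene, file = f)
  back <- load_scene(f)
  expect_length(back$scene$objects, 16)
  expect_equal(vapply(back$scene$objects, `[[`, "", "id"),
               vapply(fx$scene$objects, `[[`, "", "id"))
  expect_equal(t(vapply(back$scene$objects, `[[`, numeric(3), "position")),
               t(vapply(fx$scene$objects, `[[`, numeric(3), "position")))
  expect_equal(back$scene$grid$blocked, fx$scene$grid$blocked)

  # scene + path round trip
  path <- fixture_building_path()
  f2 <- withr::local_tempfile(fileext = ".json")
  save_scene(scene(), path = path, file = f2)
  back2 <- load_scene(f2)
  expect_equal(back2$path$waypoints, path$waypoints)
  expect_equal(back2$path$turn, path$turn)
  expect_equal(back2$path$stairs, path$stairs)
  expect_equal(back2$path$segment_labels, path$segment_labels)
  expect_equal(path_total_length(back2$path), 36.4)

  # empty objects is a valid scene
  expect_length(load_scene(list())$scene$objects, 0)

  # invalid fields are reported by name
  expect_error(load_scene(list(objects = list(list(id = "a",
                                                   position = c(0, 0, 0),
                                                   radius = -2)))),
               "radius")
  expect_error(load_scene(list(objects = list(list(position = c(0, 0, 0))))),
               "id")
  expect_error(load_scene(list(grid = list(rows = 5, cols = 5))),
               "cell_size")
})
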