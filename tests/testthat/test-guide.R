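straight_path <- function(len = 10, arrival_radius = 1.2) {
  guide_path(rbind(c(0, 0, 0), c(len, 0, 0)),
             arrival_radius = arrival_radius)
}

test_that("the guide waits for a user who falls behind", {
  path <- straight_path()
  gs <- guide_state(path)
  # let the guide get ahead first
  for (i in 1:50) gs <- update_guide(gs, path, c(0, 0, 0), 0.02)$state
  expect_equal(gs$s, 1)  # capped at 1 m lead
  s_before <- gs$s
  # user stationary 3 m behind the guide: guide must not move
  for (i in 1:100) {
    gs <- update_guide(gs, path, c(-2, 0, 0), 0.02)$state
    expect_equal(gs$status, "waiting")
  }
  expect_equal(gs$s, s_before)
  expect_error(update_guide(gs, path, c(0, 0, 0), 0), "dt")
})

test_that("a glued user is led down the whole path with 2 s calls", {
  path <- fixture_building_path()
  gs <- guide_state(path)
  dt <- 0.02
  t <- 0
  n_fm <- 0
  instr <- character(0)
  user <- path$waypoints[1, ]
  for (k in 1:10000) {
    t <- k * dt
    upd <- update_guide(gs, path, user, dt)
    gs <- upd$state
    for (e in upd$events) {
      if (e$kind == "follow_me") n_fm <- n_fm + 1
      if (e$kind == "instruction") instr <- c(instr, e$label)
    }
    user <- gs$guide_position  # glued to the guide
    if (gs$status == "arrived") break
  }
  expect_equal(gs$status, "arrived")
  expect_equal(n_fm, floor(t / 2), tolerance = 1)
  expect_length(instr, 7)  # waypoints 2..8, exactly once each
  # traversal covered every leg
  expect_gte(gs$s, path_total_length(path) - path$arrival_radius)
})

test_that("arrival triggers exactly at the 1.2 m radius, inclusive", {
  path <- straight_path(2.4)   # 2.4 - 1.2 is exact in binary
  near <- function(x) {
    gs <- guide_state(path)
    update_guide(gs, path, c(x, 0, 0), 0.02)$state$status
  }
  expect_equal(near(1.2), "arrived")    # exactly 1.2 m out: inclusive
  expect_false(near(1.19) == "arrived")
  path <- straight_path(10)
  # the arrival feedback message is emitted once
  gs <- guide_state(path)
  upd <- update_guide(gs, path, c(9, 0, 0), 0.02)
  labs <- vapply(upd$events, `[[`, "", "label")
  expect_true("You have arrived" %in% labs)
  upd2 <- update_guide(upd$state, path, c(9, 0, 0), 0.02)
  expect_length(upd2$events, 0)  # arrived state is absorbing
})

test_that("turn-by-turn text reports distance and signed turn", {
  # user 3 m before a waypoint with a 90 degree left turn
  path <- guide_path(rbind(c(0, 0, 0), c(5, 0, 0), c(5, 3, 0)),
                     turn = c("none", "left", "none"))
  p <- pose(position = c(2, 0, 0), yaw = 0)
  expect_equal(turn_by_turn(path, p), "3.0 m, then turn left 90 deg")
  # on the final leg: distance only
  p2 <- pose(position = c(5, 0.5, 0), yaw = -90)
  expect_equal(turn_by_turn(path, p2), "2.5 m to destination")
  # zero turn reads continue straight
  path3 <- guide_path(rbind(c(0, 0, 0), c(5, 0, 0), c(9, 0.1, 0)))
  expect_match(turn_by_turn(path3, pose(position = c(1, 0, 0), yaw = 0)),
               "continue straight")
  # past the final waypoint
  expect_equal(turn_by_turn(path, pose(position = c(5, 2.5, 0), yaw = 0)),
               "You have arrived")
})

test_that("wayfinding in an empty room is a straight two-point path", {
  g <- occupancy_grid(rows = 30, cols = 30, cell_size = 0.1)
  p <- compute_path(g, c(0.5, 0.5), c(2.5, 2.5))
  expect_equal(nrow(p$waypoints), 2)
  expect_equal(p$waypoints[1, 1:2], c(0.5, 0.5))
  expect_equal(p$waypoints[2, 1:2], c(2.5, 2.5))
})

test_that("wayfinding goes through a wall gap at optimal cost", {
  g <- matrix(FALSE, 21, 21)
  g[, 11] <- TRUE
  g[10, 11] <- FALSE  # one-cell doorway
  grid <- occupancy_grid(rows = 21, cols = 21, cell_size = 0.1,
                         blocked = g)
  p <- compute_path(grid, c(0.25, 0.55), c(1.85, 0.55))
  expect_gt(nrow(p$waypoints), 2)  # must detour via the gap
  oracle <- grid_cost_oracle(g, c(6, 3), c(6, 19))
  expect_equal(attr(p, "grid_cost"), oracle, tolerance = 1e-9)
  # all waypoints lie in free cells
  for (i in seq_len(nrow(p$waypoints))) {
    rc <- c(floor(p$waypoints[i, 2] / 0.1) + 1,
            floor(p$waypoints[i, 1] / 0.1) + 1)
    expect_false(g[min(rc[1], 21), min(rc[2], 21)])
  }
})

test_that("unreachable or blocked goals raise explicit errors", {
  g <- matrix(FALSE, 11, 11)
  g[, 6] <- TRUE  # solid wall, no gap
  grid <- occupancy_grid(rows = 11, cols = 11, cell_size = 0.1,
                         blocked = g)
  expect_error(compute_path(grid, c(0.25, 0.55), c(0.95, 0.55)),
               "no navigable path")
  expect_error(compute_path(grid, c(0.25, 0.55), c(0.55, 0.55)),
               "blocked cell")
  expect_error(compute_path(grid, c(-1, 0), c(0.95, 0.55)),
               "outside")
})

test_that("compute_path matches the value-iteration oracle on random grids", {
  set.seed(99)
  n_checked <- 0
  while (n_checked < 20) {
    nr <- sample(6:18, 1); nc <- sample(6:18, 1)
    blk <- matrix(runif(nr * nc) < 0.25, nr, nc)
    free <- which(!blk, arr.ind = TRUE)
    if (nrow(free) < 2) next
    se <- free[sample(nrow(free), 2), ]
    grid <- occupancy_grid(rows = nr, cols = nc, cell_size = 0.1,
                           blocked = blk)
    start <- c((se[1, 2] - 0.5) * 0.1, (se[1, 1] - 0.5) * 0.1)
    goal <- c((se[2, 2] - 0.5) * 0.1, (se[2, 1] - 0.5) * 0.1)
    oracle <- grid_cost_oracle(blk, se[1, ], se[2, ])
    if (is.infinite(oracle)) {
      expect_error(compute_path(grid, start, goal), "no navigable path")
    } else {
      p <- compute_path(grid, start, goal)
      expect_equal(attr(p, "grid_cost"), oracle, tolerance = 1e-9)
    }
    n_checked <- n_checked + 1
  }
})

test_that("guide paths validate their invariants", {
  expect_error(guide_path(rbind(c(0, 0, 0))), "at least 2")
  expect_error(guide_path(rbind(c(0, 0, 0), c(0, 0, 0))), "distinct")
  p <- fixture_building_path()
  expect_equal(nrow(p$waypoints), 9)
  expect_equal(path_total_length(p), 36.4)
  expect_equal(p$arrival_radius, 1.2)
})

test_that("arc-length projection is exact on segments and respects windows", {
  path <- guide_path(rbind(c(0, 0, 0), c(4, 0, 0), c(4, 4, 0)))
  expect_equal(project_arclength(path, c(2, 1, 0)), 2)
  expect_equal(project_arclength(path, c(5, 3, 0)), 7)
  expect_equal(point_at_arclength(path, 6), c(4, 2, 0))
  expect_equal(point_at_arclength(path, 100), c(4, 4, 0))  # clamped
  # windowed projection stays near the tracked station
  sq <- guide_path(rbind(c(0, 0, 0), c(6, 0, 0), c(6, 2, 0), c(0, 2, 0)))
  pt <- c(3, 1, 0)  # equidistant from first and last leg
  expect_equal(project_arclength(sq, pt, near = 1, window = 3), 3)
  expect_equal(project_arclength(sq, pt, near = 12, window = 3), 11)
})
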