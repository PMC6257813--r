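#' Point on a guide path at a given arc length
#'
#' @param path a [guide_path()].
#' @param s arc length from the first waypoint, meters (clamped to the
#'   path's extent).
#' @return xyz 3-vector.
#' @export
point_at_arclength <- function(path, s) {
  cl <- path$cumlen
  s <- min(max(s, 0), cl[length(cl)])
  i <- findInterval(s, cl, rightmost.closed = TRUE)
  i <- min(i, length(cl) - 1)
  f <- (s - cl[i]) / (cl[i + 1] - cl[i])
  path$waypoints[i, ] + f * (path$waypoints[i + 1, ] - path$waypoints[i, ])
}

#' Arc-length of the closest point on a guide path
#'
#' Orthogonal projection of a 3D point onto the polyline; the global
#' minimum over segments is returned, so the caller is responsible for paths
#' that do not self-overlap in space (the bundled building path does not).
#'
#' @param path a [guide_path()].
#' @param point xyz 3-vector.
#' @param near optional arc length around which to project; with `window`,
#'   restricts candidate segments to those within `near +/- window` meters
#'   of path. Continuous tracking of a moving user needs this, since a
#'   global projection can jump between path legs that pass close to each
#'   other in space.
#' @param window locality window in meters (default `Inf` = global).
#' @return arc length in meters of the nearest path point.
#' @export
project_arclength <- function(path, point, near = NULL, window = Inf) {
  a <- path$seg_a
  v <- path$seg_v
  nseg <- nrow(a)
  keep <- seq_len(nseg)
  if (!is.null(near) && is.finite(window)) {
    cl <- path$cumlen
    keep <- which(cl[-length(cl)] <= near + window & cl[-1] >= near - window)
    if (length(keep) == 0) keep <- seq_len(nseg)
  }
  dx <- point[1] - a[keep, 1]
  dy <- point[2] - a[keep, 2]
  dz <- point[3] - a[keep, 3]
  tt <- pmin(pmax((dx * v[keep, 1] + dy * v[keep, 2] + dz * v[keep, 3]) /
                    path$seg_len2[keep], 0), 1)
  d2 <- (dx - tt * v[keep, 1])^2 + (dy - tt * v[keep, 2])^2 +
    (dz - tt * v[keep, 3])^2
  i <- which.min(d2)
  k <- keep[i]
  path$cumlen[k] + tt[i] * sqrt(path$seg_len2[k])
}

#' Height of the horizontally nearest path point
#'
#' Projects a point onto the path in the xy plane only and returns the
#' path's interpolated z there. Used to carry a simulated walker up and
#' down stairs without modelling stair geometry.
#'
#' @param path a [guide_path()].
#' @param point xyz (z ignored).
#' @return z in meters.
#' @export
nearest_path_z <- function(path, point) {
  a <- path$seg_a
  v <- path$seg_v
  len2 <- v[, 1]^2 + v[, 2]^2
  len2[len2 == 0] <- 1e-12  # vertical segment: project onto its base
  dx <- point[1] - a[, 1]; dy <- point[2] - a[, 2]
  tt <- pmin(pmax((dx * v[, 1] + dy * v[, 2]) / len2, 0), 1)
  d2 <- (dx - tt * v[, 1])^2 + (dy - tt * v[, 2])^2
  k <- which.min(d2)
  a[k, 3] + tt[k] * v[k, 3]
}

#' Virtual-guide state
#'
#' The guide is a moving sound source that walks a waypoint path ahead of
#' the user, calling "follow me" every `follow_interval` seconds. It stays
#' at most 1 m ahead of the user (measured along the path) and only
#' advances while the user is less than 1 m away, waiting otherwise; just
#' before each intermediate waypoint it announces the turn and any stairs,
#' exactly once; arrival triggers when the user comes within the path's
#' arrival radius (1.2 m, inclusive) of the final waypoint.
#'
#' @param path a [guide_path()].
#' @return object of class `nav_guidestate` with fields `s` (guide arc
#'   length), `guide_position`, `segment_index`, `time_since_call`,
#'   `status` (`"leading"`, `"waiting"` or `"arrived"`) and
#'   `instructions_issued` (waypoint indices).
#' @export
guide_state <- function(path) {
  structure(list(s = 0, s_user = 0, guide_position = path$waypoints[1, ],
                 segment_index = 1L, time_since_call = 0,
                 status = "leading", instructions_issued = integer(0)),
            class = "nav_guidestate")
}

instruction_text <- function(path, i) {
  parts <- character(0)
  if (path$turn[i] != "none") parts <- paste("turn", path$turn[i])
  if (path$stairs[i]) parts <- c(parts, "stairs ahead")
  if (length(parts) == 0) parts <- "continue"
  paste(parts, collapse = ", ")
}

#' Advance the virtual guide by one time step
#'
#' @param state a [guide_state()].
#' @param path the [guide_path()] being led.
#' @param user_position the user's current xyz position.
#' @param dt time step in seconds (> 0).
#' @param guide_speed guide walking speed cap, m/s (default 1.2; the
#'   effective speed is limited by the 1 m lead rule).
#' @param lead maximum lead distance, meters (default 1; both the
#'   Euclidean advance condition and the along-path cap).
#' @param follow_interval seconds between "follow me" calls (default 2).
#' @param instruction_lead path-distance before an intermediate waypoint at
#'   which its instruction is spoken, meters (default 2; subjects report
#'   that earlier timing can help, so this is a knob).
#' @return list with `state` (updated) and `events` (list of
#'   [audio_event()]s emitted during this step).
#' @export
update_guide <- function(state, path, user_position, dt,
                         guide_speed = 1.2, lead = 1,
                         follow_interval = 2, instruction_lead = 2) {
  if (dt <= 0) stop("'dt' must be > 0")
  events <- list()
  if (state$status == "arrived") return(list(state = state, events = events))

  total <- path_total_length(path)
  # monotone progress ("station") tracking: the raw nearest-point
  # projection is discontinuous at corner interiors, so the user's
  # along-path progress estimate never decreases
  s_user <- max(state$s_user,
                project_arclength(path, user_position, near = state$s_user,
                                  window = 1.5))
  state$s_user <- s_user
  d_eucl <- sqrt(sum((state$guide_position - user_position)^2))

  # advance only while the user keeps up; never more than `lead` m of path
  # ahead of the user's projection (falling back if the user retreats)
  if (d_eucl < lead) {
    state$s <- min(state$s + guide_speed * dt, s_user + lead, total)
    state$status <- "leading"
  } else {
    state$status <- "waiting"
  }
  state$s <- min(state$s, s_user + lead)
  state$guide_position <- point_at_arclength(path, state$s)
  state$segment_index <- min(findInterval(state$s, path$cumlen,
                                          rightmost.closed = TRUE),
                             nrow(path$waypoints) - 1L)

  # periodic follow-me call from the guide's position
  state$time_since_call <- state$time_since_call + dt
  if (state$time_since_call >= follow_interval) {
    state$time_since_call <- state$time_since_call - follow_interval
    events[[length(events) + 1]] <-
      audio_event(NA_real_, "follow_me", state$guide_position,
                  label = "follow me",
                  pitch_factor = pitch_for_distance(d_eucl))
  }

  # one-shot turn/stairs instructions just before waypoints 2..(n-1)
  n <- nrow(path$waypoints)
  if (n > 2) {
    for (i in setdiff(2:(n - 1), state$instructions_issued)) {
      if (path$cumlen[i] - s_user <= instruction_lead) {
        events[[length(events) + 1]] <-
          audio_event(NA_real_, "instruction", path$waypoints[i, ],
                      label = instruction_text(path, i))
        state$instructions_issued <- c(state$instructions_issued, i)
      }
    }
  }

  # arrival: within the arrival radius (inclusive) of the final waypoint
  d_goal <- sqrt(sum((user_position - path$waypoints[n, ])^2))
  if (d_goal <= path$arrival_radius) {
    state$status <- "arrived"
    events[[length(events) + 1]] <-
      audio_event(NA_real_, "feedback", path$waypoints[n, ],
                  label = "You have arrived")
  }

  list(state = state, events = events)
}

#' Turn-by-turn instruction text
#'
#' On-demand verbal instruction: the distance to the current target waypoint
#' (rounded to 0.1 m) and the turn needed to orient onto the next leg.
#' Turns below 5 degrees read "continue straight"; past the final waypoint
#' the arrival text is returned.
#'
#' @param path a [guide_path()].
#' @param user_pose the user's [pose()].
#' @return a single instruction string, e.g. `"3.0 m, then turn left 90
#'   deg"`.
#' @export
turn_by_turn <- function(path, user_pose) {
  n <- nrow(path$waypoints)
  d_goal <- sqrt(sum((user_pose$position - path$waypoints[n, ])^2))
  if (d_goal <= path$arrival_radius) return("You have arrived")
  s_user <- project_arclength(path, user_pose$position)
  # current target waypoint: first one still ahead along the path
  i <- findInterval(s_user, path$cumlen, rightmost.closed = TRUE) + 1L
  i <- min(i, n)
  d <- sqrt(sum((user_pose$position - path$waypoints[i, ])^2))
  dist_txt <- sprintf("%.1f m", round(d, 1))
  if (i == n) return(paste(dist_txt, "to destination"))
  # signed turn from the current heading onto the next leg
  leg_az <- absolute_azimuth(path$waypoints[i, ], path$waypoints[i + 1, ])
  turn <- wrap_angle(leg_az - user_pose$yaw)
  if (abs(turn) < 5) return(paste0(dist_txt, ", then continue straight"))
  sprintf("%s, then turn %s %.0f deg", dist_txt,
          if (turn > 0) "right" else "left", abs(turn))
}

#' Automated wayfinding on an occupancy grid
#'
#' Computes the shortest 8-connected path between two free positions with
#' A* (octile heuristic; straight steps cost one cell, diagonal steps
#' sqrt(2) cells; diagonal moves are disallowed when either adjacent
#' orthogonal cell is blocked, so paths never clip corners), then
#' simplifies the cell chain to waypoints at direction changes and
#' annotates turns.
#'
#' @param grid an [occupancy_grid()].
#' @param start,goal xy positions in meters; both must lie in free cells
#'   inside the grid.
#' @param arrival_radius arrival radius for the resulting path, meters.
#' @return a [guide_path()] (z = 0) with attribute `grid_cost`, the optimal
#'   grid path cost in cell units (for cross-checking against brute-force
#'   search). Signals an error when the goal is unreachable or either
#'   endpoint is blocked/outside the grid.
#' @export
compute_path <- function(grid, start, goal, arrival_radius = 1.2) {
  stopifnot(inherits(grid, "nav_grid"))
  for (nm in c("start", "goal")) {
    p <- get(nm)
    if (!in_grid_bounds(grid, p)) stop("'", nm, "' is outside the grid")
    rc <- grid_cell_of(grid, p)
    if (grid$blocked[rc[1], rc[2]]) stop("'", nm, "' lies in a blocked cell")
  }
  s <- grid_cell_of(grid, start)
  g <- grid_cell_of(grid, goal)
  cells <- astar_grid(grid$blocked, s, g)
  if (is.null(cells))
    stop("no navigable path from start to goal")
  grid_cost <- attr(cells, "cost")
  xy <- t(apply(cells, 1, function(rc) grid_cell_center(grid, rc[1], rc[2])))
  xy[1, ] <- start[1:2]
  xy[nrow(xy), ] <- goal[1:2]
  xy <- simplify_polyline(xy)
  n <- nrow(xy)
  turn <- rep("none", n)
  if (n > 2) {
    for (i in 2:(n - 1)) {
      a <- xy[i, ] - xy[i - 1, ]
      b <- xy[i + 1, ] - xy[i, ]
      cross <- a[1] * b[2] - a[2] * b[1]
      if (abs(cross) > 1e-9)
        turn[i] <- if (cross > 0) "left" else "right"
    }
  }
  out <- guide_path(cbind(xy, 0), turn = turn,
                    arrival_radius = arrival_radius)
  attr(out, "grid_cost") <- grid_cost
  out
}

# drop interior points that are collinear with their neighbours
simplify_polyline <- function(xy) {
  n <- nrow(xy)
  if (n <= 2) return(xy)
  keep <- c(TRUE, vapply(2:(n - 1), function(i) {
    a <- xy[i, ] - xy[i - 1, ]
    b <- xy[i + 1, ] - xy[i, ]
    abs(a[1] * b[2] - a[2] * b[1]) > 1e-9
  }, logical(1)), TRUE)
  xy[keep, , drop = FALSE]
}

# A* over a logical blocked matrix; returns the cell chain (row, col) or
# NULL when the goal is unreachable. Octile distance heuristic (admissible
# for the 1 / sqrt(2) step costs used here).
astar_grid <- function(blocked, start_rc, goal_rc) {
  nr <- nrow(blocked); nc <- ncol(blocked)
  idx <- function(r, c) (c - 1L) * nr + r
  sr <- as.integer(start_rc[1]); sc <- as.integer(start_rc[2])
  gr <- as.integer(goal_rc[1]); gc <- as.integer(goal_rc[2])
  if (sr == gr && sc == gc)
    return(structure(matrix(c(sr, sc), ncol = 2), cost = 0))

  ncell <- nr * nc
  gscore <- rep(Inf, ncell)
  fscore <- rep(Inf, ncell)
  came <- integer(ncell)
  inopen <- rep(FALSE, ncell)
  closed <- rep(FALSE, ncell)
  h <- function(r, c) {
    dr <- abs(r - gr); dc <- abs(c - gc)
    (sqrt(2) - 1) * pmin(dr, dc) + pmax(dr, dc)
  }
  dirs <- cbind(dr = c(-1, 1, 0, 0, -1, -1, 1, 1),
                dc = c(0, 0, -1, 1, -1, 1, -1, 1),
                cost = c(1, 1, 1, 1, sqrt(2), sqrt(2), sqrt(2), sqrt(2)))
  s0 <- idx(sr, sc)
  gscore[s0] <- 0
  fscore[s0] <- h(sr, sc)
  inopen[s0] <- TRUE
  open <- s0

  while (length(open)) {
    k <- open[which.min(fscore[open])]
    if (k == idx(gr, gc)) {
      cost <- gscore[k]
      chain <- k
      while (came[k] != 0L) {
        k <- came[k]
        chain <- c(k, chain)
      }
      return(structure(cbind(((chain - 1L) %% nr) + 1L,
                             ((chain - 1L) %/% nr) + 1L),
                       cost = cost))
    }
    open <- open[open != k]
    inopen[k] <- FALSE
    closed[k] <- TRUE
    r <- ((k - 1L) %% nr) + 1L
    c <- ((k - 1L) %/% nr) + 1L
    for (d in seq_len(8)) {
      r2 <- r + dirs[d, 1]; c2 <- c + dirs[d, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (blocked[r2, c2]) next
      if (d > 4 && (blocked[r, c2] || blocked[r2, c])) next  # no corner clip
      k2 <- idx(r2, c2)
      if (closed[k2]) next
      tentative <- gscore[k] + dirs[d, 3]
      if (tentative < gscore[k2]) {
        gscore[k2] <- tentative
        fscore[k2] <- tentative + h(r2, c2)
        came[k2] <- k
        if (!inopen[k2]) {
          open <- c(open, k2)
          inopen[k2] <- TRUE
        }
      }
    }
  }
  NULL
}
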