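# Independent oracles used by the unit and acceptance tests. These are
# deliberately implemented by different routes than the package code.

# angle wrapping via the unit circle
wrap_oracle <- function(x) {
  r <- x * pi / 180
  atan2(sin(r), cos(r)) * 180 / pi -> w
  ifelse(abs(w + 180) < 1e-9, 180, w)  # map -180 to +180
}

# brute-force shortest grid path cost (cell units) by value iteration:
# relax all 8 neighbour moves simultaneously until a fixpoint. Same move
# rules as the package A* (diagonals blocked when either orthogonal
# neighbour is blocked), but no search heuristic and no priority queue.
grid_cost_oracle <- function(blocked, start_rc, goal_rc) {
  nr <- nrow(blocked); nc <- ncol(blocked)
  d <- matrix(Inf, nr, nc)
  d[start_rc[1], start_rc[2]] <- 0
  shift <- function(m, dr, dc, fill = Inf) {
    out <- matrix(fill, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    out
  }
  blk <- matrix(FALSE, nr, nc); blk[blocked] <- TRUE
  repeat {
    old <- d
    for (mv in list(c(-1, 0, 1), c(1, 0, 1), c(0, -1, 1), c(0, 1, 1),
                    c(-1, -1, sqrt(2)), c(-1, 1, sqrt(2)),
                    c(1, -1, sqrt(2)), c(1, 1, sqrt(2)))) {
      cand <- shift(d, mv[1], mv[2]) + mv[3]
      if (mv[1] != 0 && mv[2] != 0) {
        # corner-clip rule: both orthogonal neighbours of the *destination*
        # along the move must be free
        ok <- !(shift(blk, mv[1], 0, fill = TRUE) |
                  shift(blk, 0, mv[2], fill = TRUE))
        cand[!ok] <- Inf
      }
      cand[blk] <- Inf  # cannot step onto a blocked cell
      d <- pmin(d, cand)
    }
    if (identical(d, old)) break
  }
  d[goal_rc[1], goal_rc[2]]
}

# ordinary least squares by the normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  list(intercept = beta[1], slope = beta[2], r = r)
}

# pairwise-sum trajectory length
path_length_oracle <- function(df, dims = 2) {
  n <- nrow(df)
  if (n < 2) return(0)
  tot <- 0
  for (i in 2:n) {
    d2 <- (df$x[i] - df$x[i - 1])^2 + (df$y[i] - df$y[i - 1])^2
    if (dims == 3) d2 <- d2 + (df$z[i] - df$z[i - 1])^2
    tot <- tot + sqrt(d2)
  }
  tot
}

# a scene of objects placed at given azimuths on a circle around a pose
scene_at_azimuths <- function(az, distance = 2, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("obj%02d", seq_along(az))
  r <- az * pi / 180
  scene(lapply(seq_along(az), function(i)
    scene_object(ids[i], position = c(distance * cos(r[i]),
                                      -distance * sin(r[i]), 0))))
}
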