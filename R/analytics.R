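#' Moving-average trajectory smoothing
#'
#' Head tracking includes lateral sway perpendicular to the walking
#' direction; a centered moving average with a 2 s sliding window (10
#' samples at 5 Hz) estimates the center-of-mass trajectory. Edges use the
#' available shrinking window so the series length is preserved.
#'
#' @param series pose data frame with columns `t, x, y, z` (uniformly
#'   sampled); extra columns are passed through untouched.
#' @param window window length in seconds (default 2).
#' @return the series with smoothed `x, y, z`.
#' @export
smooth_series <- function(series, window = 2) {
  if (is.null(nrow(series)) || nrow(series) == 0)
    stop("cannot smooth an empty series")
  n <- nrow(series)
  if (n == 1) return(series)
  rate <- 1 / stats::median(diff(series$t))
  w <- max(1L, round(window * rate))
  half <- w %/% 2
  for (col in c("x", "y", "z")) {
    v <- series[[col]]
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    series[[col]] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  series
}

#' Trajectory path length
#'
#' Sum of successive displacement norms. 2D (xy) by default, matching the
#' planar tasks; use `dims = 3` for trajectories with vertical movement
#' (guided navigation through a stairwell).
#'
#' @param series pose data frame with `x, y` (and `z`).
#' @param dims 2 or 3.
#' @return length in meters (0 for fewer than 2 samples).
#' @export
path_length <- function(series, dims = 2) {
  n <- nrow(series)
  if (n < 2) return(0)
  d2 <- diff(series$x)^2 + diff(series$y)^2
  if (dims == 3) d2 <- d2 + diff(series$z)^2
  sum(sqrt(d2))
}

#' Deviation index
#'
#' The fractional excess of the walked trajectory length over a reference
#' length: `DI = (L_exp - L_ref) / L_ref`. A value near 0 means the
#' reference was followed closely; negative values arise when the user cuts
#' corners of the reference path.
#'
#' @param L_exp experimental (walked) trajectory length, meters.
#' @param L_ref reference length, meters (> 0).
#' @return dimensionless DI.
#' @examples
#' deviation_index(36, 36.4)   # about -1%: slight corner cutting
#' @export
deviation_index <- function(L_exp, L_ref) {
  if (any(L_ref <= 0)) stop("'L_ref' must be > 0")
  (L_exp - L_ref) / L_ref
}

#' Onset of the navigation phase
#'
#' A trial splits into an orientation phase (turning in place) and a
#' navigation phase. The onset is the first sample at which the distance to
#' the target has changed by at least `threshold` (default 0.3 m) from its
#' initial value -- an absolute change, so a wrong-direction start also
#' triggers the onset.
#'
#' @param series pose data frame.
#' @param target_position xyz (xy used).
#' @param threshold meters.
#' @return the onset sample index, or NA if the distance never changes
#'   enough (whole series is orientation).
#' @export
segment_phases <- function(series, target_position, threshold = 0.3) {
  d <- sqrt((series$x - target_position[1])^2 +
              (series$y - target_position[2])^2)
  hit <- which(abs(d - d[1]) >= threshold)
  if (length(hit) == 0) return(NA_integer_)
  hit[1]
}

#' Robust walking speed
#'
#' Frame-wise displacement over the (smoothed) series; walking speed is
#' estimated by the 90th percentile of the speed distribution, which
#' rejects phases where the user stands and orients. Speeds are 2D for
#' planar tasks and 3D for guided navigation (`dims = 3`).
#'
#' @param series smoothed pose data frame.
#' @param free_walk_speed unobstructed straight-line walking speed, m/s
#'   (> 0), used for normalization; NULL skips normalization.
#' @param dims 2 or 3.
#' @return list with `speed_p90` (m/s) and `normalized` (dimensionless or
#'   NA).
#' @export
walking_speed <- function(series, free_walk_speed = NULL, dims = 2) {
  if (!is.null(free_walk_speed) && free_walk_speed <= 0)
    stop("'free_walk_speed' must be > 0")
  n <- nrow(series)
  if (n < 2) stop("need at least 2 samples")
  d2 <- diff(series$x)^2 + diff(series$y)^2
  if (dims == 3) d2 <- d2 + diff(series$z)^2
  v <- sqrt(d2) / diff(series$t)
  p90 <- unname(stats::quantile(v, 0.9, type = 7))
  list(speed_p90 = p90,
       normalized = if (is.null(free_walk_speed)) NA_real_
       else p90 / free_walk_speed)
}

#' Aiming statistics over trials
#'
#' The signed aiming error of a trial is the difference between the
#' subject's facing azimuth and the target azimuth (positive = aimed to
#' the right of the target), measured `offset_before_end` seconds before
#' the end of the trial (1 s for the memory task, correcting for the voice
#' command registration delay; 0 otherwise). Bias is the circular mean of
#' the errors and accuracy their circular standard deviation; at the error
#' magnitudes involved these agree with the linear statistics to a
#' fraction of a degree.
#'
#' @param trials list of trial logs whose meta carries `target_az`.
#' @param offset_before_end seconds before trial end at which the error is
#'   read (default 0).
#' @return object of class `nav_aiming`: `errors` (degrees, wrapped),
#'   `bias`, `accuracy`.
#' @export
aiming_stats <- function(trials, offset_before_end = 0) {
  errors <- vapply(trials, function(tr) {
    tt <- tr$poses$t
    t_read <- max(tt) - offset_before_end
    i <- which.min(abs(tt - t_read))
    wrap_angle(tr$poses$yaw[i] - tr$meta$target_az)
  }, numeric(1))
  structure(list(errors = errors, bias = circ_mean(errors),
                 accuracy = circ_sd(errors)),
            class = "nav_aiming")
}

#' @export
print.nav_aiming <- function(x, ...) {
  cat(sprintf("<aiming: n=%d bias=%.2f deg accuracy=%.2f deg>\n",
              length(x$errors), x$bias, x$accuracy))
  invisible(x)
}

#' Recall regression
#'
#' Ordinary least squares of recalled azimuths on true azimuths, the
#' standard readout of the spatial memory task: a slope of 1 with r = 1 is
#' perfect recall of the scene's layout and scale.
#'
#' @param true_angles,recalled_angles degrees.
#' @return list with `slope`, `intercept`, `r` (Pearson correlation).
#' @export
recall_regression <- function(true_angles, recalled_angles) {
  stopifnot(length(true_angles) == length(recalled_angles),
            length(true_angles) >= 2)
  fit <- stats::lm(recalled_angles ~ true_angles)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(true_angles, recalled_angles))
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether angles are consistent with a uniform circular
#' distribution. With mean resultant length \eqn{\bar R} and sample size n,
#' \eqn{z = n \bar R^2} and the p-value uses the standard series
#' approximation
#' \eqn{p \approx e^{-z} [1 + (2z - z^2)/(4n) - (24z - 132z^2 + 76z^3 -
#' 9z^4)/(288 n^2)]}, clamped to `[0, 1]`.
#'
#' @param angles degrees (n >= 2).
#' @return list with `z`, `p`, `r_bar`, `n`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 2) stop("Rayleigh test needs at least 2 angles")
  rbar <- mean_resultant_length(angles)
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(z = z, p = min(max(p, 0), 1), r_bar = rbar, n = n)
}

# --- per-trial metric extraction -----------------------------------------

#' Trajectory metrics of a single navigation trial
#'
#' Runs the full measurement pipeline on one trial log: 2 s moving-average
#' smoothing, navigation-phase onset, experimental path length from onset
#' to completion, reference length, deviation index, and percentile
#' walking speed. For direct navigation, L_ref is the straight line from
#' the position at navigation onset to the nearest point of the target
#' trigger zone; for guided navigation, L_ref is the guide path length and
#' lengths are 3D.
#'
#' @param log a trial log from [run_direct_nav_task()] or
#'   [run_guided_nav_task()].
#' @param free_walk_speed optional normalization speed, m/s.
#' @param window smoothing window, seconds.
#' @return list with `L_exp`, `L_ref`, `DI`, `speed_p90`,
#'   `normalized_speed`, `duration`, `onset_index`.
#' @export
trial_metrics <- function(log, free_walk_speed = NULL, window = 2) {
  sm <- smooth_series(log$poses, window = window)
  if (log$task == "guided_nav") {
    L_ref <- log$meta$L_ref
    L_exp <- path_length(sm, dims = 3)
    onset <- 1L
    sp <- walking_speed(sm, free_walk_speed, dims = 3)
  } else {
    target <- log$meta$target_position
    onset <- segment_phases(sm, target)
    if (is.na(onset)) onset <- nrow(sm)
    nav <- sm[onset:nrow(sm), , drop = FALSE]
    L_exp <- path_length(nav, dims = 2)
    d0 <- sqrt(sum((c(nav$x[1], nav$y[1]) - target[1:2])^2))
    r <- if (!is.null(log$meta$completion_radius))
      log$meta$completion_radius else 0
    L_ref <- max(d0 - r, 1e-9)
    sp <- walking_speed(sm, free_walk_speed, dims = 2)
  }
  list(L_exp = L_exp, L_ref = L_ref,
       DI = deviation_index(L_exp, L_ref),
       speed_p90 = sp$speed_p90, normalized_speed = sp$normalized,
       duration = max(log$poses$t), onset_index = onset)
}

# split a guided trial into the path's named segments by the arc-length
# projection of each pose sample
guided_segments <- function(log) {
  path <- log$meta$path
  if (is.null(path$segment_breaks))
    return(list(all = log$poses))
  s <- apply(as.matrix(log$poses[, c("x", "y", "z")]), 1,
             function(p) project_arclength(path, p))
  bounds <- path$cumlen[path$segment_breaks]
  out <- list()
  for (i in seq_along(path$segment_labels)) {
    lo <- bounds[i]; hi <- bounds[i + 1]
    sel <- if (i == length(path$segment_labels))
      s >= lo else s >= lo & s < hi
    out[[path$segment_labels[i]]] <- log$poses[sel, , drop = FALSE]
  }
  out
}

#' Tidy summary table of trial logs
#'
#' One row per trial (and, for guided navigation, per path segment):
#' task, profile, trial, segment, outcome, duration, trajectory metrics and
#' the aiming error where defined.
#'
#' @param logs list of trial logs (possibly mixed tasks).
#' @param free_walk_speed optional normalization speed, m/s.
#' @return data frame.
#' @export
summarize_trials <- function(logs, free_walk_speed = NULL) {
  empty <- data.frame(task = character(0), profile = character(0),
                      trial = integer(0), segment = character(0),
                      outcome = character(0), duration = numeric(0),
                      L_exp = numeric(0), L_ref = numeric(0),
                      DI = numeric(0), speed_p90 = numeric(0),
                      normalized_speed = numeric(0),
                      aiming_error = numeric(0))
  if (length(logs) == 0) return(empty)
  rows <- list()
  for (log in logs) {
    base <- list(task = log$task, profile = log$profile_name,
                 trial = log$trial, segment = "all", outcome = log$outcome,
                 duration = max(log$poses$t),
                 L_exp = NA_real_, L_ref = NA_real_, DI = NA_real_,
                 speed_p90 = NA_real_, normalized_speed = NA_real_,
                 aiming_error = if (is.null(log$meta$aiming_error))
                   NA_real_ else log$meta$aiming_error)
    if (log$task %in% c("direct_nav", "direct_nav_baseline",
                        "benchmark_chair", "benchmark_key")) {
      m <- trial_metrics(log, free_walk_speed)
      base[c("L_exp", "L_ref", "DI", "speed_p90", "normalized_speed")] <-
        m[c("L_exp", "L_ref", "DI", "speed_p90", "normalized_speed")]
      rows[[length(rows) + 1]] <- base
    } else if (log$task == "guided_nav") {
      path <- log$meta$path
      m <- trial_metrics(log, free_walk_speed)
      base[c("L_exp", "L_ref", "DI", "speed_p90", "normalized_speed")] <-
        m[c("L_exp", "L_ref", "DI", "speed_p90", "normalized_speed")]
      rows[[length(rows) + 1]] <- base
      segs <- guided_segments(log)
      if (!identical(names(segs), "all")) {
        for (i in seq_along(segs)) {
          poses <- segs[[i]]
          b <- base
          b$segment <- names(segs)[i]
          b[c("L_exp", "L_ref", "DI", "speed_p90", "normalized_speed")] <-
            NA_real_
          if (nrow(poses) >= 2) {
            sm <- smooth_series(poses)
            L_exp <- path_length(sm, dims = 3)
            L_ref <- diff(path$cumlen[path$segment_breaks[c(i, i + 1)]])
            b$L_exp <- L_exp; b$L_ref <- L_ref
            b$DI <- deviation_index(L_exp, L_ref)
            b$duration <- max(poses$t) - min(poses$t)
            sp <- walking_speed(sm, free_walk_speed, dims = 3)
            b$speed_p90 <- sp$speed_p90
            b$normalized_speed <- sp$normalized
          }
          rows[[length(rows) + 1]] <- b
        }
      }
    } else {
      rows[[length(rows) + 1]] <- base
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}
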