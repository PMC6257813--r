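#' Default task configuration
#'
#' All geometry, trial counts and limits default to the published task
#' battery: 21 localization trials with the target 1 m away at a uniform
#' random azimuth; five memory objects 2 m away at -60..+60 degrees with a
#' 60 s spotlight exploration and two recall blocks; 20 direct-navigation
#' trials to a chair 2 m away at one of four azimuths, completed within
#' 0.5 m; guided navigation started within 1.2 m of the first waypoint;
#' benchmark tasks with 20 trials, a 60 s limit and termination after five
#' consecutive failures. Poses are logged at 5 Hz; the simulation substep
#' is finer and decimated for the log. The per-trial time limit of the
#' non-benchmark tasks is not part of the published protocol; 120 s bounds
#' the simulations.
#'
#' @param ... named overrides merged over the defaults (top level only).
#' @return nested list of class `nav_config`.
#' @export
task_config <- function(...) {
  cfg <- list(
    dt = 0.02, log_rate = 5,
    localization = list(n_trials = 21, target_distance = 1,
                        time_limit = 120, dt = 0.1),
    memory = list(object_distance = 2,
                  azimuths = c(-60, -30, 0, 30, 60),
                  block_labels = list(
                    c("piano", "table", "chair", "lamp", "trash bin"),
                    c("trash bin", "piano", "table", "chair", "lamp")),
                  explore_duration = 60, n_recall = 4,
                  spotlight_aperture = 30, reference_sector = c(-7.5, 7.5),
                  hold_duration = 1, time_limit = 120, dt = 0.1),
    direct_nav = list(n_trials = 20, target_distance = 2,
                      target_azimuths = c(0, 90, 180, 270),
                      start_radius = 0.5, completion_radius = 0.5,
                      time_limit = 120, arrival_hold = 2),
    guided = list(time_limit = 120, guide_speed = 1.2, lead = 1,
                  follow_interval = 2, instruction_lead = 2,
                  arrival_hold = 2),
    benchmark = list(n_trials = 20, time_limit = 60,
                     max_consecutive_failures = 5,
                     chair_radius = 0.5, key_radius = 1, key_face_deg = 30,
                     arrival_hold = 2),
    free_walk = list(distance = 20)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "nav_config")
}

# --- trial log ------------------------------------------------------------

new_trial_log <- function(task, trial, poses, events, outcome, meta = list(),
                          profile = NULL) {
  structure(list(task = task, trial = trial, poses = poses, events = events,
                 outcome = outcome, meta = meta,
                 profile_name = if (is.null(profile)) NA_character_ else profile$name),
            class = "nav_trial")
}

#' @export
print.nav_trial <- function(x, ...) {
  cat(sprintf("<trial %s #%d: %s, %.1f s, %d poses, %d events>\n",
              x$task, x$trial, x$outcome,
              if (nrow(x$poses)) max(x$poses$t) else 0,
              nrow(x$poses), nrow(x$events)))
  invisible(x)
}

# pose recorder: preallocated matrix, grown on demand
make_recorder <- function(n0 = 1024L) {
  env <- new.env(parent = emptyenv())
  env$m <- matrix(NA_real_, n0, 7)
  env$i <- 0L
  env
}

rec_pose <- function(env, t, position, yaw) {
  i <- env$i + 1L
  if (i > nrow(env$m))
    env$m <- rbind(env$m, matrix(NA_real_, nrow(env$m), 7))
  env$m[i, ] <- c(t, position, yaw, 0, 0)
  env$i <- i
}

rec_poses_df <- function(env) {
  m <- env$m[seq_len(env$i), , drop = FALSE]
  data.frame(t = m[, 1], x = m[, 2], y = m[, 3], z = m[, 4],
             yaw = m[, 5], pitch = m[, 6], roll = m[, 7])
}

events_df <- function(events) {
  if (length(events) == 0)
    return(data.frame(t = numeric(0), kind = character(0),
                      label = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), pitch_factor = numeric(0)))
  data.frame(
    t = vapply(events, function(e) e$t, numeric(1)),
    kind = vapply(events, function(e) e$kind, character(1)),
    label = vapply(events, function(e) e$label, character(1)),
    x = vapply(events, function(e) e$source_position[1], numeric(1)),
    y = vapply(events, function(e) e$source_position[2], numeric(1)),
    z = vapply(events, function(e) e$source_position[3], numeric(1)),
    pitch_factor = vapply(events, function(e) e$pitch_factor, numeric(1)))
}

# stationary tail while the arrival feedback plays: the subject stands at
# the target, so the moving-average endpoint of the smoothed trajectory
# coincides with the true stopping point
rec_hold <- function(env, t, position, yaw, hold, log_dt) {
  if (hold <= 0) return(invisible())
  for (tt in seq(t + log_dt, t + hold, by = log_dt))
    rec_pose(env, tt, position, yaw)
}

# position of a point `distance` meters from `origin` at absolute azimuth
# `az` (degrees, 0 = +x, positive clockwise from above)
point_at_azimuth <- function(origin, az, distance, z = 0) {
  r <- deg2rad(az)
  c(origin[1] + distance * cos(r), origin[2] - distance * sin(r), z)
}

# --- task 1: object localization -----------------------------------------

#' Object localization task
#'
#' Per trial a single target is placed `target_distance` (default 1 m) from
#' the stationary agent at an azimuth drawn uniformly from 0-360 degrees.
#' The agent clicks, hears the spatialized call, turns toward the perceived
#' direction, and confirms once a post-turn perception falls inside its aim
#' tolerance. The signed aiming error (facing azimuth minus target azimuth;
#' positive = aimed right of the target) is stored in each trial's meta.
#'
#' @param profile an [agent_profile()].
#' @param config a [task_config()].
#' @param seed integer seed; the whole task replays identically for a
#'   given seed.
#' @return list of trial logs (class `nav_trial`), one per trial.
#' @export
run_localization_task <- function(profile, config = task_config(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tc <- config$localization
  dt <- tc$dt
  log_every <- max(1L, round(1 / (config$log_rate * dt)))
  max_steps <- ceiling(tc$time_limit / dt)
  lapply(seq_len(tc$n_trials), function(trial) {
    target_az <- stats::runif(1, 0, 360)
    target_pos <- point_at_azimuth(c(0, 0, 0), target_az, tc$target_distance)
    yaw <- 0
    desired <- 0
    tsc <- profile$click_interval  # first click immediately
    n_heard <- 0L
    events <- list()
    rec <- make_recorder(256L)
    rec_pose(rec, 0, c(0, 0, 0), yaw)
    confirmed <- FALSE
    t <- 0
    for (k in seq_len(max_steps)) {
      t <- k * dt
      tsc <- tsc + dt
      if (!confirmed && tsc >= profile$click_interval) {
        tsc <- 0
        true_rel <- wrap_angle(target_az - yaw)
        per <- perceive_azimuth(true_rel, profile)
        events[[length(events) + 1]] <-
          audio_event(t, "name_call", target_pos, label = "box",
                      pitch_factor = pitch_for_distance(tc$target_distance))
        if (n_heard >= 1L && abs(per) < profile$aim_tolerance_deg) {
          # the voice command takes a moment to register; the subject
          # fine-tunes the aim on one final call while speaking, so the
          # recorded error is a fresh, unselected draw of bias + noise.
          # By this point the accumulated head movements have resolved any
          # front-back ambiguity, so the final percept is never mirrored.
          confirmed <- TRUE
          fine <- profile
          fine$fb_confusion_prob <- 0
          per2 <- perceive_azimuth(wrap_angle(target_az - yaw), fine)
          desired <- wrap_angle(yaw + per2)
        } else {
          desired <- wrap_angle(yaw + per)
        }
        n_heard <- n_heard + 1L
      }
      dyaw <- wrap_angle(desired - yaw)
      yaw <- wrap_angle(yaw + sign(dyaw) * min(abs(dyaw),
                                               profile$turn_speed * dt))
      if (k %% log_every == 0L) {
        rec_pose(rec, t, c(0, 0, 0), yaw)
        if (confirmed && abs(wrap_angle(desired - yaw)) < 1e-9) break
      }
    }
    err <- wrap_angle(yaw - target_az)
    new_trial_log("localization", trial, rec_poses_df(rec),
                  events_df(events),
                  outcome = if (confirmed) "completed" else "timeout",
                  meta = list(target_az = target_az,
                              target_position = target_pos,
                              aiming_error = err),
                  profile = profile)
  })
}

# --- task 2: spatial memory ----------------------------------------------

memory_scene <- function(tc, block) {
  labels <- tc$block_labels[[block]]
  objs <- lapply(seq_along(tc$azimuths), function(i)
    scene_object(id = labels[i], label = labels[i],
                 position = point_at_azimuth(c(0, 0, 0), tc$azimuths[i],
                                             tc$object_distance)))
  scene(objs)
}

#' Spatial memory task
#'
#' Two blocks. In each block five objects sit 2 m away at azimuths -60,
#' -30, 0, +30, +60 degrees (left-to-right label orders
#' piano/table/chair/lamp/trash bin, then trash bin/piano/table/chair/lamp).
#' The agent explores the scene for 60 s in spotlight mode by sweeping its
#' head, encoding each heard object's azimuth into memory, then performs
#' four recall trials per block: it turns to the recalled direction and
#' holds for 1 s while the voice command registers. The center object
#' (azimuth 0) is never queried because a sonar-beep reference sector marks
#' straight ahead.
#'
#' @inheritParams run_localization_task
#' @return list with `exploration` (one trial log per block) and `recall`
#'   (one trial log per query; meta carries `true_az`, `recalled_az`,
#'   `block` and the signed `aiming_error`).
#' @export
run_memory_task <- function(profile, config = task_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tc <- config$memory
  dt <- tc$dt
  log_every <- max(1L, round(1 / (config$log_rate * dt)))
  exploration <- list()
  recall_logs <- list()
  trial_no <- 0L

  for (block in seq_along(tc$block_labels)) {
    sc <- memory_scene(tc, block)
    # exploration: triangular head sweep across the object fan
    sweep_max <- max(abs(tc$azimuths)) + tc$spotlight_aperture / 2
    events <- list()
    rec <- make_recorder(512L)
    yaw <- 0
    direction <- 1
    last_call <- list()
    n_steps <- ceiling(tc$explore_duration / dt)
    for (k in seq_len(n_steps)) {
      t <- k * dt
      yaw <- yaw + direction * profile$turn_speed * dt
      if (yaw >= sweep_max) { yaw <- sweep_max; direction <- -1 }
      if (yaw <= -sweep_max) { yaw <- -sweep_max; direction <- 1 }
      p <- pose(t = t, position = c(0, 0, 0), yaw = yaw)
      for (ev in spotlight_mode_events(sc, p, t = t,
                                       aperture_deg = tc$spotlight_aperture)) {
        lc <- last_call[[ev$label]]
        if (is.null(lc) || t - lc >= 1) {  # re-call at most once per second
          events[[length(events) + 1]] <- ev
          last_call[[ev$label]] <- t
        }
      }
      if (k %% log_every == 0L) rec_pose(rec, t, c(0, 0, 0), yaw)
    }
    trace <- explore_and_store(sc, events, profile)
    exploration[[block]] <-
      new_trial_log("memory_exploration", block, rec_poses_df(rec),
                    events_df(events), "completed",
                    meta = list(block = block,
                                labels = tc$block_labels[[block]],
                                azimuths = tc$azimuths),
                    profile = profile)

    # recall: query the four off-center objects in random order
    queryable <- tc$block_labels[[block]][tc$azimuths != 0]
    queries <- sample(queryable, tc$n_recall)
    for (q in queries) {
      trial_no <- trial_no + 1L
      true_az <- absolute_azimuth(
        c(0, 0), scene_get_object(sc, q)$position)
      recalled <- recall(trace, q)
      yaw <- 0
      rec <- make_recorder(128L)
      rec_pose(rec, 0, c(0, 0, 0), yaw)
      t <- 0
      k <- 0L
      while (abs(wrap_angle(recalled - yaw)) > 1e-9 && t < tc$time_limit) {
        k <- k + 1L
        t <- k * dt
        dyaw <- wrap_angle(recalled - yaw)
        yaw <- wrap_angle(yaw + sign(dyaw) * min(abs(dyaw),
                                                 profile$turn_speed * dt))
        if (k %% log_every == 0L) rec_pose(rec, t, c(0, 0, 0), yaw)
      }
      for (j in seq_len(ceiling(tc$hold_duration / dt))) {  # command delay
        k <- k + 1L
        t <- k * dt
        if (k %% log_every == 0L) rec_pose(rec, t, c(0, 0, 0), yaw)
      }
      recall_logs[[trial_no]] <-
        new_trial_log("memory_recall", trial_no, rec_poses_df(rec),
                      events_df(list()), "completed",
                      meta = list(block = block, queried = q,
                                  true_az = true_az, recalled_az = recalled,
                                  target_az = true_az,
                                  aiming_error = wrap_angle(yaw - true_az)),
                      profile = profile)
    }
  }
  list(exploration = exploration, recall = recall_logs)
}

# --- task 3: direct navigation -------------------------------------------

#' Direct navigation task
#'
#' Per trial a chair is placed 2 m from the arena center at an azimuth
#' drawn from \{0, 90, 180, 270\} degrees. The agent starts at the center
#' (inside the 1 m diameter start zone) with a random initial heading,
#' localizes the chair's voice in target mode, and walks to it; the trial
#' completes when the agent is within 0.5 m of the chair center (boundary
#' inclusive). With `baseline = TRUE` the audio is off and the agent runs
#' the uninformed cane-search policy instead.
#'
#' @inheritParams run_localization_task
#' @param baseline run the cane-only random-search baseline.
#' @return list of trial logs.
#' @export
run_direct_nav_task <- function(profile, config = task_config(),
                                seed = NULL, baseline = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  tc <- config$direct_nav
  dt <- config$dt
  log_every <- max(1L, round(1 / (config$log_rate * dt)))
  max_steps <- ceiling(tc$time_limit / dt)
  lapply(seq_len(tc$n_trials), function(trial) {
    target_az <- sample(tc$target_azimuths, 1)
    target_pos <- point_at_azimuth(c(0, 0, 0), target_az, tc$target_distance)
    sc <- scene(list(scene_object("chair", position = target_pos,
                                  radius = tc$completion_radius)),
                start_zone = list(center = c(0, 0, 0),
                                  radius = tc$start_radius))
    st <- agent_state(c(0, 0, 0), yaw = stats::runif(1, -180, 180))
    st$time_since_click <- profile$click_interval  # click at once
    events <- list()
    rec <- make_recorder(1024L)
    rec_pose(rec, 0, st$position, st$yaw)
    completed <- FALSE
    t <- 0
    for (k in seq_len(max_steps)) {
      t <- k * dt
      if (baseline) {
        res <- cane_search_policy(st, profile, dt,
                                  bounds = c(-3, 3, -3, 3))
        st <- res$state
      } else {
        ev <- NULL
        if (st$time_since_click + dt >= profile$click_interval) {
          ev <- target_mode_event(sc, pose(t = t, position = st$position,
                                           yaw = st$yaw), "chair", t = t)
          events[[length(events) + 1]] <- ev
        }
        res <- direct_nav_policy(st, ev, profile, dt)
        st <- res$state
      }
      if (k %% log_every == 0L) rec_pose(rec, t, st$position, st$yaw)
      if (sqrt(sum((st$position[1:2] - target_pos[1:2])^2)) <=
          tc$completion_radius) {
        completed <- TRUE
        rec_hold(rec, (k %/% log_every) * log_every * dt, st$position,
                 st$yaw, tc$arrival_hold, 1 / config$log_rate)
        break
      }
    }
    new_trial_log(if (baseline) "direct_nav_baseline" else "direct_nav",
                  trial, rec_poses_df(rec), events_df(events),
                  outcome = if (completed) "completed" else "timeout",
                  meta = list(target_az = target_az,
                              target_position = target_pos,
                              completion_radius = tc$completion_radius),
                  profile = profile)
  })
}

# --- task 4: long-range guided navigation --------------------------------

#' Long-range guided navigation task
#'
#' The agent starts within 1.2 m of the first waypoint and follows the
#' virtual guide's "follow me" calls along the path until arrival (within
#' the path's 1.2 m arrival radius of the final waypoint) or timeout. The
#' agent's height tracks the path (stairs are annotations on the projected
#' path, not geometry). The trial meta records the maximum along-path lead
#' of the guide over the user, the instruction events, and the path.
#'
#' @inheritParams run_localization_task
#' @param path a [guide_path()], e.g. the bundled nine-waypoint building
#'   path from [fixture_building_path()].
#' @return a single trial log.
#' @export
run_guided_nav_task <- function(profile, path, config = task_config(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tc <- config$guided
  dt <- config$dt
  log_every <- max(1L, round(1 / (config$log_rate * dt)))
  max_steps <- ceiling(tc$time_limit / dt)

  start <- path$waypoints[1, ]
  yaw0 <- absolute_azimuth(path$waypoints[1, ], path$waypoints[2, ]) +
    stats::runif(1, -30, 30)
  st <- agent_state(start, yaw = yaw0)
  gs <- guide_state(path)
  events <- list()
  rec <- make_recorder(2048L)
  rec_pose(rec, 0, st$position, st$yaw)
  max_lead <- -Inf
  t <- 0
  arrived <- FALSE
  for (k in seq_len(max_steps)) {
    t <- k * dt
    upd <- update_guide(gs, path, st$position, dt,
                        guide_speed = tc$guide_speed, lead = tc$lead,
                        follow_interval = tc$follow_interval,
                        instruction_lead = tc$instruction_lead)
    gs <- upd$state
    step_events <- lapply(upd$events, function(e) { e$t <- t; e })
    events <- c(events, step_events)
    max_lead <- max(max_lead, gs$s - gs$s_user)
    res <- guide_follow_policy(st, step_events, profile, dt,
                               follow_interval = tc$follow_interval)
    st <- res$state
    # height follows the horizontally nearest path point: stairs are
    # annotations on the projected path, not geometry the agent climbs
    st$position[3] <- nearest_path_z(path, st$position)
    if (k %% log_every == 0L) rec_pose(rec, t, st$position, st$yaw)
    if (gs$status == "arrived") {
      arrived <- TRUE
      rec_hold(rec, (k %/% log_every) * log_every * dt, st$position,
               st$yaw, tc$arrival_hold, 1 / config$log_rate)
      break
    }
  }
  new_trial_log("guided_nav", 1L, rec_poses_df(rec), events_df(events),
                outcome = if (arrived) "completed" else "timeout",
                meta = list(path = path, max_lead = max_lead,
                            L_ref = path_total_length(path)),
                profile = profile)
}

# --- free walking ---------------------------------------------------------

#' Free walking measurement
#'
#' A straight unobstructed walk of `distance` meters at the profile's
#' walking speed, used to normalize task speeds.
#'
#' @inheritParams run_localization_task
#' @return a single trial log.
#' @export
run_free_walk <- function(profile, config = task_config(), seed = NULL) {
  tc <- config$free_walk
  dt <- config$dt
  log_every <- max(1L, round(1 / (config$log_rate * dt)))
  rec <- make_recorder(512L)
  rec_pose(rec, 0, c(0, 0, 0), 0)
  x <- 0
  t <- 0
  k <- 0L
  while (x < tc$distance) {
    k <- k + 1L
    t <- k * dt
    x <- min(x + profile$walk_speed * dt, tc$distance)
    if (k %% log_every == 0L) rec_pose(rec, t, c(x, 0, 0), 0)
  }
  new_trial_log("free_walk", 1L, rec_poses_df(rec), events_df(list()),
                "completed", meta = list(distance = tc$distance),
                profile = profile)
}

# --- benchmark tasks ------------------------------------------------------

#' Virtual-reality benchmark tasks
#'
#' Three tasks in the 10 x 10 m virtual living room: (1) aim the head at a
#' randomly chosen object; (2) walk to a randomly placed chair; (3) find a
#' key on the floor (complete only when the head is within 1 m of the key
#' AND faces within 30 degrees of it). Each task runs up to 20 trials with
#' a 60 s limit per trial and is terminated early after five consecutive
#' failures.
#'
#' With the `"assistant"` sonifier the agent hears talking objects (target
#' mode). With the `"voice"` raw image-sonification baseline the policy
#' only receives spectrogram summaries that carry no object identity or
#' range, a deliberately reduced observation: the agent aims at a random
#' azimuth in task 1 and falls back to an uninformed search in tasks 2-3,
#' which yields the near-chance performance observed for untrained users
#' of raw sensory substitution.
#'
#' @inheritParams run_localization_task
#' @param living_room a [scene()] with the 16 benchmark objects; default
#'   the bundled fixture.
#' @param sonifier `"assistant"` (talking objects) or `"voice"` (raw
#'   image-to-spectrogram baseline).
#' @param tasks subset of `c("aim", "chair", "key")`.
#' @return list of trial logs across the selected tasks.
#' @export
run_benchmark_tasks <- function(profile,
                                living_room = fixture_living_room()$scene,
                                sonifier = c("assistant", "voice"),
                                config = task_config(), seed = NULL,
                                tasks = c("aim", "chair", "key")) {
  sonifier <- match.arg(sonifier)
  if (!is.null(seed)) set.seed(seed)
  tc <- config$benchmark
  dt <- config$dt
  log_every <- max(1L, round(1 / (config$log_rate * dt)))
  max_steps <- ceiling(tc$time_limit / dt)
  center <- c(5, 5, 0)
  bounds <- c(1, 9, 1, 9)
  logs <- list()

  run_one <- function(task, trial) {
    if (task == "aim") {
      obj <- living_room$objects[[sample(length(living_room$objects), 1)]]
      target_pos <- obj$position
      target_az <- absolute_azimuth(center, target_pos)
      yaw <- stats::runif(1, -180, 180)
      rec <- make_recorder(256L)
      rec_pose(rec, 0, center, yaw)
      t <- 0
      completed <- FALSE
      if (sonifier == "assistant") {
        desired <- yaw; tsc <- profile$click_interval; n_heard <- 0L
        for (k in seq_len(ceiling(tc$time_limit / 0.1))) {
          t <- k * 0.1
          tsc <- tsc + 0.1
          if (!completed && tsc >= profile$click_interval) {
            tsc <- 0
            per <- perceive_azimuth(wrap_angle(target_az - yaw), profile)
            if (n_heard >= 1L && abs(per) < profile$aim_tolerance_deg) {
              completed <- TRUE  # final fine-tune as in the localization task
              fine <- profile
              fine$fb_confusion_prob <- 0
              per2 <- perceive_azimuth(wrap_angle(target_az - yaw), fine)
              desired <- wrap_angle(yaw + per2)
            } else desired <- wrap_angle(yaw + per)
            n_heard <- n_heard + 1L
          }
          dyaw <- wrap_angle(desired - yaw)
          yaw <- wrap_angle(yaw + sign(dyaw) * min(abs(dyaw),
                                                   profile$turn_speed * 0.1))
          if (k %% 2L == 0L) {
            rec_pose(rec, t, center, yaw)
            if (completed && abs(wrap_angle(desired - yaw)) < 1e-9) break
          }
        }
      } else {
        # raw sonification: scans convey no object identity; the aim is a
        # uniform random guess after a listening period
        aim <- stats::runif(1, -180, 180)
        for (k in seq_len(ceiling(10 / 0.1))) {
          t <- k * 0.1
          dyaw <- wrap_angle(aim - yaw)
          yaw <- wrap_angle(yaw + sign(dyaw) * min(abs(dyaw),
                                                   profile$turn_speed * 0.1))
          if (k %% 2L == 0L) rec_pose(rec, t, center, yaw)
        }
        completed <- TRUE
      }
      return(new_trial_log("benchmark_aim", trial, rec_poses_df(rec),
                           events_df(list()),
                           if (completed) "completed" else "failed",
                           meta = list(target_az = target_az,
                                       queried = obj$id,
                                       target_position = target_pos,
                                       aiming_error = wrap_angle(yaw - target_az),
                                       sonifier = sonifier),
                           profile = profile))
    }

    is_key <- task == "key"
    target_pos <- if (is_key)
      c(stats::runif(1, 3, 7), stats::runif(1, 3, 7), 0)
    else
      point_at_azimuth(center, sample(c(0, 90, 180, 270), 1), 2)
    target_id <- if (is_key) "key" else "chair"
    sc <- scene(list(scene_object(target_id, position = target_pos,
                                  radius = if (is_key) tc$key_radius else
                                    tc$chair_radius)))
    st <- agent_state(center, yaw = stats::runif(1, -180, 180))
    st$time_since_click <- profile$click_interval
    rec <- make_recorder(1024L)
    rec_pose(rec, 0, st$position, st$yaw)
    completed <- FALSE
    t <- 0
    done_pred <- function(st) {
      d <- sqrt(sum((st$position[1:2] - target_pos[1:2])^2))
      if (!is_key) return(d <= tc$chair_radius)
      if (d > tc$key_radius) return(FALSE)
      p <- pose(t = 0, position = st$position, yaw = st$yaw)
      abs(relative_azimuth(p, target_pos)) <= tc$key_face_deg
    }
    for (k in seq_len(max_steps)) {
      t <- k * dt
      if (sonifier == "assistant") {
        ev <- NULL
        if (st$time_since_click + dt >= profile$click_interval) {
          ev <- target_mode_event(sc, pose(t = t, position = st$position,
                                           yaw = st$yaw), target_id, t = t)
        }
        # near the key, stop walking and aim (the dual completion rule)
        if (is_key &&
            sqrt(sum((st$position[1:2] - target_pos[1:2])^2)) <=
            0.8 * tc$key_radius)
          st$phase <- "orient"
        res <- direct_nav_policy(st, ev, profile, dt)
        st <- res$state
      } else {
        # reduced observation: the raw spectrogram scans carry no object
        # identity or range, so the agent can only search blindly, at the
        # hesitant pace of an untrained user
        res <- cane_search_policy(st, profile, dt, bounds = bounds,
                                  pace = 0.3)
        st <- res$state
      }
      if (k %% log_every == 0L) rec_pose(rec, t, st$position, st$yaw)
      if (done_pred(st)) {
        completed <- TRUE
        rec_hold(rec, (k %/% log_every) * log_every * dt, st$position,
                 st$yaw, tc$arrival_hold, 1 / config$log_rate)
        break
      }
    }
    new_trial_log(paste0("benchmark_", task), trial, rec_poses_df(rec),
                  events_df(list()),
                  if (completed) "completed" else "failed",
                  meta = list(target_position = target_pos,
                              sonifier = sonifier),
                  profile = profile)
  }

  for (task in tasks) {
    consecutive_failures <- 0L
    for (trial in seq_len(tc$n_trials)) {
      log <- run_one(task, trial)
      logs[[length(logs) + 1]] <- log
      if (log$outcome == "completed") {
        consecutive_failures <- 0L
      } else {
        consecutive_failures <- consecutive_failures + 1L
        if (consecutive_failures >= tc$max_consecutive_failures) {
          logs[[length(logs)]]$meta$terminated_task <- TRUE
          break
        }
      }
    }
  }
  logs
}
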