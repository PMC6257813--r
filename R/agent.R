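#' Agent profile: stochastic perceptual and motor parameters
#'
#' A simulated user is described by an auditory localization model (a
#' systematic azimuth bias, Gaussian azimuth noise, and a front-back
#' confusion probability), motor parameters, and task-policy thresholds.
#' The defaults are calibrated to measured human performance with
#' spatialized audio: per-subject localization noise of 3-12 degrees s.d.
#' and biases between -9 and +13 degrees; front-back reversals on roughly
#' 5 of 139 direct-navigation trials (probability ~0.036); and a recalled
#' scene accurate to ~15 degrees rms.
#'
#' @param name profile label used in summaries.
#' @param bias_deg systematic azimuth offset, degrees (positive = perceives
#'   sources further to the right than they are).
#' @param noise_sd_deg s.d. of Gaussian azimuth noise per perception,
#'   degrees (>= 0).
#' @param fb_confusion_prob probability that a perception is mirrored about
#'   the interaural axis before noise is added (default 0.036).
#' @param walk_speed walking speed, m/s (default 1.2).
#' @param turn_speed turning rate, deg/s (default 90).
#' @param aim_tolerance_deg perceived azimuth below which the agent
#'   considers itself aimed, degrees (default 10).
#' @param click_interval seconds between clicker presses (default 0.5).
#' @param recovery_threshold_deg perceived azimuth above which a walking
#'   agent stops and re-orients, degrees (default 90; models the recovery
#'   after a wrong-direction start).
#' @param recall_noise_sd_deg s.d. of recall noise added on top of the
#'   encoded scene memory, degrees (default 15, the rms recall calibration).
#' @param seed optional integer stored for bookkeeping; tasks seed the RNG
#'   themselves.
#' @return object of class `nav_profile`.
#' @export
agent_profile <- function(name = "default", bias_deg = 0, noise_sd_deg = 0,
                          fb_confusion_prob = 0.036, walk_speed = 1.2,
                          turn_speed = 90, aim_tolerance_deg = 10,
                          click_interval = 0.5, recovery_threshold_deg = 90,
                          recall_noise_sd_deg = 15, seed = NULL) {
  stopifnot(noise_sd_deg >= 0,
            fb_confusion_prob >= 0, fb_confusion_prob <= 1,
            walk_speed > 0, turn_speed > 0, aim_tolerance_deg > 0,
            click_interval > 0, recall_noise_sd_deg >= 0)
  structure(list(name = name, bias_deg = bias_deg,
                 noise_sd_deg = noise_sd_deg,
                 fb_confusion_prob = fb_confusion_prob,
                 walk_speed = walk_speed, turn_speed = turn_speed,
                 aim_tolerance_deg = aim_tolerance_deg,
                 click_interval = click_interval,
                 recovery_threshold_deg = recovery_threshold_deg,
                 recall_noise_sd_deg = recall_noise_sd_deg,
                 seed = seed),
            class = "nav_profile")
}

#' Named preset profiles
#'
#' `"noiseless"` is the deterministic limit (no bias, no noise, no
#' reversals), `"typical"` a mid-range subject, `"noisy"` the
#' worst-calibrated subject in the measured ranges.
#'
#' @param name preset name.
#' @return an [agent_profile()].
#' @export
preset_profile <- function(name = c("noiseless", "typical", "noisy")) {
  name <- match.arg(name)
  switch(name,
    noiseless = agent_profile("noiseless", bias_deg = 0, noise_sd_deg = 0,
                              fb_confusion_prob = 0),
    typical   = agent_profile("typical", bias_deg = 2, noise_sd_deg = 7.5),
    noisy     = agent_profile("noisy", bias_deg = 13, noise_sd_deg = 12))
}

#' Read/write agent profiles as JSON
#' @param file JSON file path.
#' @return `load_profile()`: an [agent_profile()].
#' @export
load_profile <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(agent_profile, cfg)
}

#' @rdname load_profile
#' @param profile an [agent_profile()].
#' @export
save_profile <- function(profile, file) {
  jsonlite::write_json(unclass(profile), file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(file)
}

#' Perceived azimuth of a sound source
#'
#' Applies the localization model: with probability `fb_confusion_prob` the
#' true azimuth is first mirrored about the interaural (left-right) axis
#' (`az -> 180 - az`, sign preserved), then the systematic bias and
#' Gaussian noise are added and the result is wrapped to (-180, 180].
#' Draws from the session RNG; seed upstream for replay.
#'
#' @param true_az true relative azimuth(s), degrees.
#' @param profile an [agent_profile()].
#' @return perceived azimuth(s) in (-180, 180].
#' @export
perceive_azimuth <- function(true_az, profile) {
  n <- length(true_az)
  az <- true_az
  if (profile$fb_confusion_prob > 0) {
    conf <- stats::runif(n) < profile$fb_confusion_prob
    if (any(conf)) {
      s <- ifelse(az >= 0, 1, -1)
      az[conf] <- (s * (180 - abs(az)))[conf]
    }
  }
  noise <- if (profile$noise_sd_deg > 0)
    stats::rnorm(n, 0, profile$noise_sd_deg) else 0
  wrap_angle(az + profile$bias_deg + noise)
}

#' Initial agent state for the navigation policies
#'
#' @param position xyz start position.
#' @param yaw initial yaw, degrees.
#' @return list holding the policy's mutable state.
#' @export
agent_state <- function(position = c(0, 0, 0), yaw = 0) {
  list(position = as.numeric(position), yaw = wrap_angle(yaw),
       phase = "orient", desired_yaw = wrap_angle(yaw),
       time_since_click = 0, time_since_event = 0,
       n_heard = 0L, last_perceived = NA_real_, est_dist = Inf,
       confirmed = FALSE)
}

heading_vector <- function(yaw) {
  r <- deg2rad(yaw)
  c(cos(r), -sin(r))  # yaw positive clockwise from +x, z up
}

#' Two-phase direct navigation policy
#'
#' Models the strategy observed in humans: first localize the voice by
#' turning in place (ORIENT), then walk swiftly toward it (WALK),
#' re-clicking on the way and correcting the heading. The agent confirms
#' its aim (and, when navigating, starts walking) once a perception after
#' at least one orienting turn falls below `aim_tolerance_deg`; a walking
#' agent whose perceived azimuth exceeds `recovery_threshold_deg` drops
#' back to ORIENT, reproducing the recovery after occasional
#' front-back-confused wrong-direction starts.
#'
#' @param state an [agent_state()].
#' @param last_event the [audio_event()] heard this step, or NULL.
#' @param profile an [agent_profile()].
#' @param dt time step, seconds.
#' @return list with the updated `state` and the action taken: `turn`
#'   (signed degrees), `step` (meters), `click` (a clicker press is due),
#'   `confirm` (the agent just confirmed its aim).
#' @export
direct_nav_policy <- function(state, last_event = NULL, profile, dt) {
  confirm <- FALSE
  state$time_since_click <- state$time_since_click + dt
  if (!is.null(last_event)) {
    true_rel <- relative_azimuth(
      pose(t = 0, position = state$position, yaw = state$yaw),
      last_event$source_position)
    per <- perceive_azimuth(true_rel, profile)
    state$time_since_click <- 0
    state$last_perceived <- per
    state$desired_yaw <- wrap_angle(state$yaw + per)
    if (state$phase == "orient") {
      if (state$n_heard >= 1L && abs(per) < profile$aim_tolerance_deg) {
        confirm <- TRUE
        state$confirmed <- TRUE
        state$phase <- "walk"
      }
    } else if (abs(per) > profile$recovery_threshold_deg) {
      state$phase <- "orient"
      state$n_heard <- -1L  # force a fresh orienting turn before re-confirm
    }
    state$n_heard <- state$n_heard + 1L
  }
  dyaw <- wrap_angle(state$desired_yaw - state$yaw)
  turn <- sign(dyaw) * min(abs(dyaw), profile$turn_speed * dt)
  state$yaw <- wrap_angle(state$yaw + turn)
  step <- 0
  if (state$phase == "walk") {
    step <- profile$walk_speed * dt
    state$position[1:2] <- state$position[1:2] + step * heading_vector(state$yaw)
  }
  list(state = state,
       turn = turn, step = step,
       click = state$time_since_click >= profile$click_interval,
       confirm = confirm)
}

#' Guide-following policy
#'
#' Steers toward the perceived azimuth of the latest "follow me" call at
#' walking speed, estimating the caller's distance from the call's pitch.
#' The agent pauses when it has heard nothing for more than twice the call
#' interval, when it believes it has reached the caller, or while its
#' heading is more than 60 degrees off (turn in place first).
#'
#' @param state an [agent_state()].
#' @param events list of [audio_event()]s heard this step (may be empty).
#' @param profile an [agent_profile()].
#' @param dt time step, seconds.
#' @param follow_interval the guide's call interval, seconds (default 2).
#' @return list with updated `state`, `turn` (degrees) and `step` (meters).
#' @export
guide_follow_policy <- function(state, events, profile, dt,
                                follow_interval = 2) {
  state$time_since_event <- state$time_since_event + dt
  for (ev in events) {
    if (ev$kind != "follow_me") next
    true_rel <- relative_azimuth(
      pose(t = 0, position = state$position, yaw = state$yaw),
      ev$source_position)
    per <- perceive_azimuth(true_rel, profile)
    state$desired_yaw <- wrap_angle(state$yaw + per)
    state$est_dist <- pitch_map()$d_ref / max(ev$pitch_factor, 1e-9)
    state$time_since_event <- 0
    state$n_heard <- state$n_heard + 1L
  }
  dyaw <- wrap_angle(state$desired_yaw - state$yaw)
  turn <- sign(dyaw) * min(abs(dyaw), profile$turn_speed * dt)
  state$yaw <- wrap_angle(state$yaw + turn)
  paused <- state$n_heard == 0L ||
    state$time_since_event > 2 * follow_interval ||
    state$est_dist < 0.1 || abs(dyaw) > 60
  step <- 0
  if (!paused) {
    step <- profile$walk_speed * dt
    state$position[1:2] <- state$position[1:2] + step * heading_vector(state$yaw)
    state$est_dist <- state$est_dist - step
  }
  list(state = state, turn = turn, step = step)
}

#' Uninformed search policy (cane-only baseline)
#'
#' A correlated random walk inside rectangular bounds: the heading diffuses
#' and reflects off the walls. Models a search without any audio
#' information; never consumes audio events.
#'
#' @param state an [agent_state()].
#' @param profile an [agent_profile()].
#' @param dt time step, seconds.
#' @param bounds c(xmin, xmax, ymin, ymax) of the walkable area.
#' @param heading_sd heading diffusion, degrees per sqrt(second).
#' @param pace fraction of the profile's walking speed (default 0.5, a
#'   cautious cane pace).
#' @return list with updated `state` and `step`.
#' @export
cane_search_policy <- function(state, profile, dt, bounds = c(-3, 3, -3, 3),
                               heading_sd = 40, pace = 0.5) {
  state$yaw <- wrap_angle(state$yaw + stats::rnorm(1, 0, heading_sd * sqrt(dt)))
  sp <- pace * profile$walk_speed
  newp <- state$position[1:2] + sp * dt * heading_vector(state$yaw)
  if (newp[1] < bounds[1] || newp[1] > bounds[2] ||
      newp[2] < bounds[3] || newp[2] > bounds[4]) {
    state$yaw <- wrap_angle(state$yaw + 180 + stats::rnorm(1, 0, 30))
    newp <- state$position[1:2]
  }
  state$position[1:2] <- newp
  list(state = state, step = sp * dt)
}

#' Spatial memory: encode an explored scene and recall object directions
#'
#' During exploration the agent stores one azimuth per object it heard,
#' corrupted by encoding noise (the profile's localization noise); recall
#' adds an independent Gaussian draw with the profile's recall noise.
#' Both model layers are this package's construct: only recall outcomes
#' (~15 deg rms) are empirically calibrated.
#'
#' @param scene the explored [scene()].
#' @param events name-call events heard during the exploration window.
#' @param profile an [agent_profile()].
#' @param origin the agent's (stationary) position during exploration.
#' @return object of class `nav_memory`: stored absolute azimuths by object
#'   id, plus the recall noise s.d.
#' @export
explore_and_store <- function(scene, events, profile, origin = c(0, 0, 0)) {
  stored <- list()
  for (ev in events) {
    if (ev$kind != "name_call") next
    true_az <- absolute_azimuth(origin, ev$source_position)
    noise <- if (profile$noise_sd_deg > 0)
      stats::rnorm(1, 0, profile$noise_sd_deg) else 0
    stored[[ev$label]] <- wrap_angle(true_az + noise)
  }
  structure(list(stored = stored,
                 recall_noise_sd_deg = profile$recall_noise_sd_deg),
            class = "nav_memory")
}

#' @rdname explore_and_store
#' @param trace a `nav_memory`.
#' @param object_id id/label of the queried object; must have been heard
#'   during exploration.
#' @return `recall()`: recalled absolute azimuth in (-180, 180].
#' @export
recall <- function(trace, object_id) {
  stopifnot(inherits(trace, "nav_memory"))
  if (is.null(trace$stored[[object_id]]))
    stop("object '", object_id, "' was never heard during exploration")
  noise <- if (trace$recall_noise_sd_deg > 0)
    stats::rnorm(1, 0, trace$recall_noise_sd_deg) else 0
  wrap_angle(trace$stored[[object_id]] + noise)
}
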