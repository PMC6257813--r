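#' Audio events
#'
#' One sonification emission: an object voice calling its name, the guide's
#' "follow me", a collision hiss, a turn/stairs instruction, or spoken
#' feedback. Events carry the 3D source location (the basis of spatialized
#' rendering, here consumed by the agent's perception model) and a
#' dimensionless pitch multiplier encoding source distance.
#'
#' @param t emission time, seconds.
#' @param kind one of `"name_call"`, `"follow_me"`, `"hiss"`,
#'   `"instruction"`, `"feedback"`.
#' @param source_position numeric 3-vector, meters.
#' @param label spoken text (object name, instruction, ...).
#' @param pitch_factor finite multiplier >= 0, 1 = reference pitch.
#' @return object of class `nav_event`.
#' @export
audio_event <- function(t, kind, source_position, label = "",
                        pitch_factor = 1) {
  kinds <- c("name_call", "follow_me", "hiss", "instruction", "feedback")
  if (!kind %in% kinds)
    stop("event 'kind' must be one of: ", paste(kinds, collapse = ", "))
  if (!is.finite(pitch_factor) || pitch_factor < 0)
    stop("'pitch_factor' must be finite and >= 0")
  stopifnot(length(source_position) == 3)
  structure(list(t = t, kind = kind,
                 source_position = as.numeric(source_position),
                 label = label, pitch_factor = pitch_factor),
            class = "nav_event")
}

#' Distance-to-pitch mapping
#'
#' Object voices rise in pitch as the object gets closer. The map is
#' `factor = min(c, d_ref / d)`: factor 1 at the reference distance,
#' inversely proportional to distance below it, clamped at `max_factor` so
#' a touching object does not diverge.
#'
#' @param d_ref reference distance in meters (> 0) at which the factor is 1;
#'   default 2 m, the canonical task distance.
#' @param max_factor clamp `c >= 1`; default 4.
#' @return object of class `nav_pitchmap`.
#' @export
pitch_map <- function(d_ref = 2, max_factor = 4) {
  stopifnot(d_ref > 0, max_factor >= 1)
  structure(list(d_ref = d_ref, max_factor = max_factor),
            class = "nav_pitchmap")
}

#' @rdname pitch_map
#' @param d distance(s) in meters, >= 0 (d = 0 is clamped).
#' @param map a [pitch_map()].
#' @return `pitch_for_distance()`: pitch factor(s), monotone non-increasing
#'   in `d`.
#' @examples
#' pitch_for_distance(2)            # 1 at the reference distance
#' pitch_for_distance(c(1, 0.5, 0)) # rising, then clamped
#' @export
pitch_for_distance <- function(d, map = pitch_map()) {
  stopifnot(all(d >= 0))
  pmin(map$max_factor, map$d_ref / pmax(d, 1e-9))
}

#' Target mode: the selected object calls once per clicker press
#'
#' @param scene a [scene()].
#' @param pose the user's current [pose()].
#' @param target_id id of the selected object (must exist in the scene).
#' @param t time of the clicker press, seconds.
#' @param map a [pitch_map()].
#' @return a single name-call [audio_event()] at the object's position.
#' @export
target_mode_event <- function(scene, pose, target_id, t = pose$t,
                              map = pitch_map()) {
  obj <- scene_get_object(scene, target_id)
  d <- sqrt(sum((obj$position - pose$position)^2))
  audio_event(t, "name_call", obj$position, label = obj$label,
              pitch_factor = pitch_for_distance(d, map))
}

#' Spotlight mode: objects inside the facing cone speak, nearest first
#'
#' @inheritParams target_mode_event
#' @param aperture_deg full cone aperture, degrees (default 30).
#' @return list of name-call events (possibly empty), nearest object first.
#' @export
spotlight_mode_events <- function(scene, pose, t = pose$t, aperture_deg = 30,
                                  map = pitch_map()) {
  hit <- Filter(function(o) in_spotlight(pose, o$position, aperture_deg),
                scene$objects)
  if (length(hit) == 0) return(list())
  d <- vapply(hit, function(o) sqrt(sum((o$position - pose$position)^2)),
              numeric(1))
  hit <- hit[order(d)]
  lapply(hit, function(o)
    audio_event(t, "name_call", o$position, label = o$label,
                pitch_factor = pitch_for_distance(
                  sqrt(sum((o$position - pose$position)^2)), map)))
}

#' Scan mode: all objects call in sequence from left to right
#'
#' Events are scheduled at `t, t + gap, t + 2 gap, ...` in [scan_order()].
#'
#' @inheritParams target_mode_event
#' @param inter_call_gap seconds between successive calls (default 1).
#' @return list of name-call events, one per object.
#' @export
scan_mode_events <- function(scene, pose, t = pose$t, inter_call_gap = 1,
                             map = pitch_map()) {
  ord <- scan_order(scene, pose)
  lapply(seq_along(ord), function(i) {
    o <- ord[[i]]
    audio_event(t + (i - 1) * inter_call_gap, "name_call", o$position,
                label = o$label,
                pitch_factor = pitch_for_distance(
                  sqrt(sum((o$position - pose$position)^2)), map))
  })
}

#' Collision warning hiss
#'
#' Any obstacle surface hisses when the user gets too close. The warning
#' fires strictly below `warn_dist` (an obstacle at exactly the threshold is
#' silent) and is emitted from the nearest obstacle point.
#'
#' @inheritParams target_mode_event
#' @param warn_dist warning distance in meters; default 0.7 (about arm's
#'   length plus one step; the threshold is a configuration knob).
#' @return a hiss [audio_event()] or NULL.
#' @export
collision_warning <- function(scene, pose, warn_dist = 0.7, t = pose$t) {
  near <- nearest_obstacle(scene, pose$position)
  if (near$distance >= warn_dist) return(NULL)
  audio_event(t, "hiss", c(near$point, pose$position[3]), label = "hiss",
              pitch_factor = 1)
}

#' Raw image-to-spectrogram sonification (vOICe-style baseline)
#'
#' The low-level sensory-substitution baseline treats a grayscale image as a
#' spectrogram and plays it as a left-to-right scan: image column j maps to
#' time `j / (cols - 1) * scan_duration`, image row i to a frequency
#' (top row = highest), and brightness to amplitude. Frequencies are
#' log-spaced across `freq_range`, following the usual convention
#' (brightness to loudness, height to pitch).
#'
#' @param image numeric matrix with values in `[0, 1]`; row 1 is the top of
#'   the image.
#' @param scan_duration scan length in seconds (default 1).
#' @param freq_range c(low, high) Hz (default 500-5000).
#' @return object of class `nav_specscan`: fields `matrix` (rows =
#'   frequency bins, top = highest), `freqs` (Hz per row, decreasing),
#'   `times` (seconds per column), `scan_duration`, `freq_range`.
#' @export
voice_encode <- function(image, scan_duration = 1, freq_range = c(500, 5000)) {
  image <- as.matrix(image)
  if (length(image) == 0) stop("image must be non-empty")
  if (anyNA(image) || min(image) < 0 || max(image) > 1)
    stop("image values must lie in [0, 1]")
  stopifnot(scan_duration > 0, length(freq_range) == 2,
            freq_range[1] > 0, freq_range[2] > freq_range[1])
  nr <- nrow(image); nc <- ncol(image)
  freqs <- exp(seq(log(freq_range[2]), log(freq_range[1]), length.out = max(nr, 2)))[seq_len(nr)]
  times <- if (nc == 1) 0 else (seq_len(nc) - 1) / (nc - 1) * scan_duration
  structure(list(matrix = unname(image), freqs = freqs, times = times,
                 scan_duration = scan_duration, freq_range = freq_range),
            class = "nav_specscan")
}

#' @rdname voice_encode
#' @param scan a `nav_specscan`.
#' @param sample_rate waveform sample rate, Hz.
#' @return `voice_waveform()`: numeric vector in `[-1, 1]`, the scan
#'   rendered as a sum of amplitude-weighted sinusoids per column.
#' @export
voice_waveform <- function(scan, sample_rate = 8000) {
  stopifnot(inherits(scan, "nav_specscan"))
  nc <- ncol(scan$matrix)
  col_dur <- scan$scan_duration / nc
  n_per <- max(1L, round(col_dur * sample_rate))
  out <- numeric(n_per * nc)
  tt <- (seq_len(n_per) - 1) / sample_rate
  for (j in seq_len(nc)) {
    amps <- scan$matrix[, j]
    active <- which(amps > 0)
    seg <- numeric(n_per)
    t0 <- (j - 1) * col_dur
    for (i in active)
      seg <- seg + amps[i] * sin(2 * pi * scan$freqs[i] * (t0 + tt))
    out[(j - 1) * n_per + seq_len(n_per)] <- seg
  }
  peak <- max(1, max(abs(out)))
  out / peak
}
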