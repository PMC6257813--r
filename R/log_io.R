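#' Write and read trial logs
#'
#' Each trial is stored as three plain-text files sharing a stem
#' `<task>_<trial>`: a pose CSV (`t, x, y, z, yaw, pitch, roll` at 5 Hz),
#' a JSON-lines event sidecar, and a JSON metadata file (task, outcome,
#' target information, and the guide path for guided trials).
#'
#' @param logs list of trial logs.
#' @param dir output directory (created if needed).
#' @return `write_trial_logs()`: the file stems written, invisibly;
#'   `read_trial_logs()`: the reconstructed list of trial logs.
#' @export
write_trial_logs <- function(logs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stems <- character(0)
  for (log in logs) {
    stem <- file.path(dir, sprintf("%s_%03d", log$task, log$trial))
    utils::write.csv(log$poses, paste0(stem, ".csv"), row.names = FALSE)
    con <- file(paste0(stem, ".events.jsonl"), "w")
    if (nrow(log$events))
      for (i in seq_len(nrow(log$events)))
        writeLines(jsonlite::toJSON(as.list(log$events[i, ]),
                                    auto_unbox = TRUE, digits = NA), con)
    close(con)
    meta <- log$meta
    if (!is.null(meta$path)) {
      p <- meta$path
      meta$path <- list(waypoints = apply(p$waypoints, 1, identity,
                                          simplify = FALSE),
                        turn = p$turn, stairs = p$stairs,
                        arrival_radius = p$arrival_radius,
                        segment_breaks = p$segment_breaks,
                        segment_labels = p$segment_labels)
    }
    jsonlite::write_json(
      list(task = log$task, trial = log$trial, outcome = log$outcome,
           profile_name = log$profile_name, meta = meta),
      paste0(stem, ".meta.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
    stems <- c(stems, stem)
  }
  invisible(stems)
}

#' @rdname write_trial_logs
#' @export
read_trial_logs <- function(dir) {
  metas <- sort(list.files(dir, pattern = "\\.meta\\.json$",
                           full.names = TRUE))
  lapply(metas, function(mf) {
    stem <- sub("\\.meta\\.json$", "", mf)
    info <- jsonlite::read_json(mf, simplifyVector = TRUE)
    meta <- as.list(info$meta)
    if (!is.null(meta$path)) {
      p <- meta$path
      wp <- if (is.list(p$waypoints))
        do.call(rbind, lapply(p$waypoints, unlist)) else as.matrix(p$waypoints)
      meta$path <- guide_path(
        wp, turn = p$turn, stairs = p$stairs,
        arrival_radius = p$arrival_radius,
        segment_breaks = if (length(p$segment_breaks)) p$segment_breaks else NULL,
        segment_labels = if (length(p$segment_labels)) p$segment_labels else NULL)
    }
    poses <- utils::read.csv(paste0(stem, ".csv"))
    ev_file <- paste0(stem, ".events.jsonl")
    ev_lines <- if (file.exists(ev_file)) readLines(ev_file) else character(0)
    events <- if (length(ev_lines)) {
      do.call(rbind, lapply(ev_lines, function(l)
        as.data.frame(jsonlite::fromJSON(l))))
    } else events_df(list())
    log <- new_trial_log(info$task, info$trial, poses, events,
                         info$outcome, meta = meta)
    log$profile_name <- info$profile_name
    log
  })
}
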