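test_that("localization runs 21 five-hertz trials with bounded errors", {
  prof <- preset_profile("noiseless")
  logs <- run_localization_task(prof, seed = 1)
  expect_length(logs, 21)
  for (log in logs) {
    expect_equal(log$outcome, "completed")
    expect_equal(diff(log$poses$t), rep(0.2, nrow(log$poses) - 1),
                 tolerance = 1e-9)
    expect_lte(abs(log$meta$aiming_error), prof$aim_tolerance_deg)
  }
})

test_that("a deterministic bias shows up as the mean aiming error", {
  prof <- agent_profile(bias_deg = 7, noise_sd_deg = 0,
                        fb_confusion_prob = 0)
  logs <- run_localization_task(prof, seed = 2)
  stats <- aiming_stats(logs)
  expect_equal(stats$bias, 7, tolerance = 2)
  expect_lt(stats$accuracy, 4)
})

test_that("task runs replay identically under a fixed seed", {
  prof <- preset_profile("typical")
  a <- run_localization_task(prof, seed = 77)
  b <- run_localization_task(prof, seed = 77)
  expect_identical(a, b)
  cfg <- task_config(direct_nav = list(n_trials = 4))
  expect_identical(run_direct_nav_task(prof, cfg, seed = 78),
                   run_direct_nav_task(prof, cfg, seed = 78))
})

test_that("the memory task uses the printed layouts and query rules", {
  prof <- agent_profile(noise_sd_deg = 0, recall_noise_sd_deg = 0,
                        fb_confusion_prob = 0)
  res <- run_memory_task(prof, seed = 3)
  expect_length(res$exploration, 2)
  expect_length(res$recall, 8)
  expect_equal(res$exploration[[1]]$meta$labels,
               c("piano", "table", "chair", "lamp", "trash bin"))
  expect_equal(res$exploration[[2]]$meta$labels,
               c("trash bin", "piano", "table", "chair", "lamp"))
  expect_equal(res$exploration[[1]]$meta$azimuths,
               c(-60, -30, 0, 30, 60))
  # the center object (azimuth 0) is never queried
  center_labels <- c("chair", "table")  # center of block 1, 2
  for (i in seq_along(res$recall)) {
    log <- res$recall[[i]]
    expect_false(log$meta$queried ==
                   center_labels[log$meta$block])
    expect_lt(min(abs(abs(log$meta$true_az) - c(30, 60))), 1e-6)
  }
  # perfect memory: recall reproduces the layout exactly
  rr <- recall_regression(
    vapply(res$recall, function(l) l$meta$true_az, 0),
    vapply(res$recall, function(l) l$meta$recalled_az, 0))
  expect_equal(rr$slope, 1, tolerance = 1e-6)
  expect_equal(rr$r, 1, tolerance = 1e-6)
  # each block queries 4 distinct objects
  for (b in 1:2) {
    q <- vapply(Filter(function(l) l$meta$block == b, res$recall),
                function(l) l$meta$queried, "")
    expect_length(unique(q), 4)
  }
})

test_that("exploration stores every off-center object it hears", {
  prof <- preset_profile("typical")
  res <- run_memory_task(prof, seed = 9)
  ev <- res$exploration[[1]]$events
  expect_setequal(unique(ev$label[ev$kind == "name_call"]),
                  c("piano", "table", "chair", "lamp", "trash bin"))
})

test_that("direct navigation respects the start zone and trigger zone", {
  prof <- preset_profile("typical")
  cfg <- task_config(direct_nav = list(n_trials = 6))
  logs <- run_direct_nav_task(prof, cfg, seed = 11)
  expect_length(logs, 6)
  for (log in logs) {
    first <- log$poses[1, ]
    expect_lte(sqrt(first$x^2 + first$y^2), 0.5)  # starts in the zone
    expect_equal(log$outcome, "completed")
    # completion flag agrees with re-checking the geometric predicate
    d <- sqrt((log$poses$x - log$meta$target_position[1])^2 +
                (log$poses$y - log$meta$target_position[2])^2)
    expect_lte(min(d), log$meta$completion_radius + 1e-9)
    expect_true(log$meta$target_az %in% c(0, 90, 180, 270))
    # pose series is 5 Hz throughout
    expect_equal(diff(log$poses$t), rep(0.2, nrow(log$poses) - 1),
                 tolerance = 1e-9)
  }
  # target mode events were heard
  expect_gt(nrow(logs[[1]]$events), 0)
  expect_true(all(logs[[1]]$events$kind == "name_call"))
})

test_that("the cane baseline searches without any audio events", {
  prof <- preset_profile("typical")
  cfg <- task_config(direct_nav = list(n_trials = 2, time_limit = 30))
  logs <- run_direct_nav_task(prof, cfg, seed = 12, baseline = TRUE)
  for (log in logs) {
    expect_equal(nrow(log$events), 0)
    expect_equal(log$task, "direct_nav_baseline")
  }
})

test_that("guided navigation arrives, honors the lead rule and segments", {
  prof <- preset_profile("noiseless")
  path <- fixture_building_path()
  log <- run_guided_nav_task(prof, path, seed = 14)
  expect_equal(log$outcome, "completed")
  expect_lte(log$meta$max_lead, 1 + 1.2 * 0.02 + 1e-9)
  # arrival really is within 1.2 m of the final waypoint
  last <- log$poses[nrow(log$poses), ]
  expect_lte(sqrt(sum((c(last$x, last$y, last$z) -
                         path$waypoints[9, ])^2)), 1.2 + 1e-9)
  # intermediate instructions fire exactly once each
  instr <- log$events[log$events$kind == "instruction", ]
  expect_equal(nrow(instr), 7)
  # follow-me cadence is the 2 s call interval
  fm <- log$events$t[log$events$kind == "follow_me"]
  expect_equal(diff(fm), rep(2, length(fm) - 1), tolerance = 1e-9)
  # the poses partition into the three building segments
  segs <- guided_segments(log)
  expect_equal(sum(vapply(segs, nrow, 0L)), nrow(log$poses))
})

test_that("free walking yields the profile's walking speed", {
  log <- run_free_walk(preset_profile("typical"))
  sp <- walking_speed(smooth_series(log$poses))
  expect_equal(sp$speed_p90, 1.2, tolerance = 0.05)
})

test_that("benchmark chair trials with talking objects finish quickly", {
  prof <- preset_profile("typical")
  cfg <- task_config(benchmark = list(n_trials = 5))
  logs <- run_benchmark_tasks(prof, sonifier = "assistant", config = cfg,
                              seed = 21, tasks = "chair")
  expect_length(logs, 5)
  for (log in logs) {
    expect_equal(log$outcome, "completed")
    expect_lt(max(log$poses$t), 30)  # well inside the 60 s limit
  }
})

test_that("key trials enforce the dual distance-and-facing condition", {
  prof <- preset_profile("typical")
  cfg <- task_config(benchmark = list(n_trials = 4))
  logs <- run_benchmark_tasks(prof, sonifier = "assistant", config = cfg,
                              seed = 22, tasks = "key")
  for (log in Filter(function(l) l$outcome == "completed", logs)) {
    last <- log$poses[nrow(log$poses), ]
    tp <- log$meta$target_position
    expect_lte(sqrt((last$x - tp[1])^2 + (last$y - tp[2])^2), 1 + 1e-9)
    p <- pose(position = c(last$x, last$y, last$z), yaw = last$yaw)
    expect_lte(abs(relative_azimuth(p, tp)), 30 + 1e-9)
  }
  expect_gt(sum(vapply(logs, function(l) l$outcome, "") == "completed"), 0)
})

test_that("a benchmark task terminates after five consecutive failures", {
  prof <- preset_profile("typical")
  cfg <- task_config(benchmark = list(n_trials = 20, time_limit = 1))
  logs <- run_benchmark_tasks(prof, sonifier = "voice", config = cfg,
                              seed = 23, tasks = "chair")
  expect_length(logs, 5)   # terminated early
  expect_true(all(vapply(logs, function(l) l$outcome, "") == "failed"))
  expect_true(isTRUE(logs[[5]]$meta$terminated_task))
})
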