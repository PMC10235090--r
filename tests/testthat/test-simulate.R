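arena <- default_arena()

test_that("identical seeds give identical records and tables", {
  p <- simulation_params(cutoff = 400)
  t1 <- simulate_trial(p, "bionoise", arena, seed = 5)
  t2 <- simulate_trial(p, "bionoise", arena, seed = 5)
  expect_identical(t1, t2)
  c1 <- simulate_cohort(simulation_params(cutoff = 200, trials_per_male = 2),
                        c("control_plus", "duet"), 2, arena, seed = 9)
  c2 <- simulate_cohort(simulation_params(cutoff = 200, trials_per_male = 2),
                        c("control_plus", "duet"), 2, arena, seed = 9)
  expect_identical(c1$metrics, c2$metrics)
})

test_that("complete gap avoidance keeps every signal onset out of noise", {
  p <- simulation_params(gamma = 0, cutoff = 900)
  for (seed in 1:10) {
    tr <- simulate_trial(p, "bionoise", arena, seed = seed)
    g <- group_signals(tr$sections)
    onsets <- vapply(c(g$signals, g$fragments), `[[`, numeric(1), "begin")
    if (length(onsets))
      expect_equal(onset_in_noise_fraction(onsets, tr$schedules$noise), 0)
  }
})

test_that("an immobile male yields an empty, excluded trajectory", {
  p <- simulation_params(move_hazard = 0, search_trigger_prob = 0,
                         cutoff = 300)
  tr <- simulate_trial(p, "control_plus", arena, seed = 3)
  expect_equal(nrow(tr$trajectory), 0L)
  row <- compute_trial_metrics(tr, arena)
  expect_true(row$excluded)
})

test_that("every reply is anchored to a preceding Me3 end", {
  for (trt in c("control_plus", "rival", "bionoise")) {
    spec <- treatment_spec(trt)
    tr <- simulate_trial(simulation_params(cutoff = 900), trt, arena,
                         seed = 13)
    reply <- tr$schedules$reply$intervals
    me3 <- tr$ground_truth$me3_ends
    if (!nrow(reply)) next
    for (k in seq_len(nrow(reply))) {
      # reply begins manual_offset before an Me3 end (modulo end-clipping)
      expect_true(any(abs(me3 - spec$manual_offset_s - reply[k, 1]) < 1e-9))
    }
  }
})

test_that("search movement only happens after the first reply", {
  for (seed in 1:5) {
    tr <- simulate_trial(simulation_params(cutoff = 600), "control_plus",
                         arena, seed = seed)
    st <- tr$trajectory$time[tr$trajectory$class == "search"]
    if (length(st) && nrow(tr$schedules$reply$intervals))
      expect_gte(min(st), min(tr$schedules$reply$intervals[, 1]))
  }
  # negative control: no playback, so walking only
  tr0 <- simulate_trial(simulation_params(cutoff = 600), "control_minus",
                        arena, seed = 2)
  expect_false(any(tr0$trajectory$class == "search"))
  expect_equal(nrow(tr0$schedules$reply$intervals), 0L)
})

test_that("perfect junction choice with eager search finds the target", {
  p <- simulation_params(p_correct = 1, search_trigger_prob = 1,
                         search_bout_len = 60, search_rate = 2,
                         isi_meanlog = log(20), cutoff = 900)
  found <- vapply(1:15, function(s) {
    m <- compute_trial_metrics(simulate_trial(p, "control_plus", arena,
                                              seed = s), arena)
    isTRUE(m$found_target)
  }, logical(1))
  expect_gte(mean(found), 0.9)
})

test_that("searching junction choices hit the target branch at p_correct", {
  p <- simulation_params(p_correct = 0.5, search_trigger_prob = 1,
                         search_bout_len = 40, search_rate = 2,
                         stop_on_target = FALSE, cutoff = 400)
  correct <- logical(0)
  for (s in 1:80) {
    tr <- simulate_trial(p, "control_plus", arena, seed = s)
    traj <- tr$trajectory
    if (nrow(traj) < 2) next
    # a crossing step lands on subsection 1 of a new chain, coming from
    # subsection 1 of another chain
    prev_sec <- traj$section[-nrow(traj)]
    prev_sub <- traj$subsection[-nrow(traj)]
    cur <- traj[-1, ]
    crossing <- prev_sub == 1 & cur$subsection == 1 & prev_sec != cur$section &
      !startsWith(prev_sec, "leaf") & !startsWith(cur$section, "leaf")
    k <- which(crossing & cur$class == "search")
    correct <- c(correct, cur$section[k] == "stalk_ipsi")
  }
  expect_gt(length(correct), 100)
  expect_gt(mean(correct), 0.4)
  expect_lt(mean(correct), 0.6)
})

test_that("metrics invariants hold across simulated trials", {
  p <- simulation_params(cutoff = 500)
  trts <- c("control_plus", "rival", "duet", "bionoise", "anthronoise",
            "control_minus")
  for (s in 1:30) {
    tr <- simulate_trial(p, trts[1 + s %% 6], arena, seed = 1000 + s)
    m <- compute_trial_metrics(tr, arena)
    expect_gte(m$duty_cycle, 0); expect_lte(m$duty_cycle, 1)
    if (!m$excluded) {
      expect_gte(m$approach, 0); expect_lte(m$approach, 1)
      expect_gte(m$search_ratio, 0); expect_lte(m$search_ratio, 1)
      expect_gt(m$path_efficiency, 0)
      # a male that reached the target walked at least the starting distance
      if (isTRUE(m$found_target && m$d_min == 0))
        expect_lte(m$path_efficiency, 1)
      expect_lte(m$search_distance, m$total_distance)
      expect_lte(m$d_min, m$d_start)
      if (isTRUE(m$found_target && m$d_min == 0)) expect_equal(m$approach, 1)
    }
  }
})

test_that("cohorts carry ids and injected effects shift the metrics", {
  p0 <- simulation_params(cutoff = 400, trials_per_male = 2,
                          sd_male = 0, sd_plant = 0, sd_operator = 0)
  coh <- simulate_cohort(p0, c("control_plus", "duet"), 3, arena, seed = 17)
  expect_equal(nrow(coh$metrics), 2 * 3 * 2)
  expect_setequal(unique(coh$metrics$treatment), c("control_plus", "duet"))
  expect_equal(length(unique(coh$metrics$male_id)), 6)

  p1 <- simulation_params(cutoff = 400, trials_per_male = 3,
                          sd_male = 0, sd_plant = 0, sd_operator = 0,
                          treatment_effects = list(
                            bionoise = list(isi_mult = 4)))
  coh1 <- simulate_cohort(p1, c("control_plus", "bionoise"), 8, arena,
                          seed = 23)
  agg <- tapply(coh1$metrics$duty_cycle, coh1$metrics$treatment, mean,
                na.rm = TRUE)
  expect_lt(agg[["bionoise"]], agg[["control_plus"]])
})
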