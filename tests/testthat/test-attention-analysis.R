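# Analysis surfaces: epoch classification, peri-microsaccadic before/after
# structure, the motor and null controls, behavior splits, and
# modulation-by-outcome, each checked against its generative ground truth.

test_that("epoch classification is an exact partition with interval semantics", {
  # a trial with one toward onset at 520 ms is toward in the 500-600 epoch
  # and no-microsaccade in the other four
  spec <- epoch_spec()
  cls <- sapply(seq_len(nrow(spec$epochs)), function(e) {
    saccmod:::epoch_class(onsets = 520, labels = "toward", spec$epochs[e, ])
  })
  expect_equal(cls, c("none", "none", "toward", "none", "none"))
  # no events anywhere: none in all epochs
  expect_true(all(sapply(seq_len(5), function(e) {
    saccmod:::epoch_class(numeric(0), character(0), spec$epochs[e, ])
  }) == "none"))
  # both directions inside one epoch: mixed
  expect_equal(saccmod:::epoch_class(c(510, 580), c("toward", "away"),
                                     c(500, 600)), "mixed")
  # randomized partition property against an interval-membership oracle
  withr::with_seed(41, {
    for (i in 1:200) {
      n <- sample(0:4, 1)
      on <- runif(n, 150, 950)
      lb <- sample(c("toward", "away"), n, replace = TRUE)
      ep <- spec$epochs[sample(5, 1), ]
      got <- saccmod:::epoch_class(on, lb, ep)
      inside <- on >= ep[1] & on < ep[2]
      want <- if (!any(inside)) "none"
      else if (all(lb[inside] == "toward")) "toward"
      else if (all(lb[inside] == "away")) "away"
      else "mixed"
      expect_identical(got, want)
    }
  })
})

test_that("epoch analysis recovers a flat attention profile and its ANOVA structure", {
  fx <- shared_study()
  ea <- epoch_analysis(fx$study, fx$events, fx$norms)
  n_units <- nrow(ea$cells) / 30
  expect_equal(ea$anova$total_df, n_units * 30 - 1)
  expect_equal(ea$anova$error_df, n_units * 30 - 1 - 29)
  # attention contrasts exist for every epoch x microsaccade class
  expect_equal(nrow(ea$posthoc), 15)
  # generator has a constant (non-ramping) attention delta: the attention
  # modulation in no-microsaccade cells is positive and flat across epochs
  cm <- ea$anova$cell_means
  none <- cm[cm$microsaccade == "none", ]
  d_by_epoch <- sapply(levels(ea$cells$epoch), function(e) {
    mean(none$mean[none$epoch == e & none$attention == "cue_in_rf"]) -
      mean(none$mean[none$epoch == e & none$attention == "cue_out_rf"])
  })
  expect_true(all(d_by_epoch > 0))
  expect_lt(diff(range(d_by_epoch)), 0.35)
})

test_that("perisaccadic analysis requires matching provenance and shows suppression", {
  fx <- shared_study()
  expect_error(perisaccadic_analysis(fx$study, list(a = data.frame()), fx$norms),
               "matched_set")
  seeds <- seq_along(fx$study$sessions)
  matched <- lapply(seq_along(fx$study$sessions), function(i) {
    sid <- names(fx$study$sessions)[i]
    timing_match(fx$study$sessions[[sid]],
                 fx$events[fx$events$session_id == sid, ], seed = seeds[i])
  })
  names(matched) <- names(fx$study$sessions)
  pa <- perisaccadic_analysis(fx$study, matched, fx$norms)
  n_units <- length(unique(pa$cells$unit_id))
  expect_equal(pa$anova_rates$total_df, n_units * 12 - 1)
  expect_equal(pa$anova_delta_attention$total_df, n_units * 6 - 1)
  expect_equal(pa$anova_delta_suppression$total_df, n_units * 6 - 1)
  # multiplicative suppression: after < before for microsaccade conditions,
  # no suppression in the timing-matched no-microsaccade rows
  ds <- pa$delta_suppression
  supp_ms <- mean(ds$value[ds$microsaccade != "none"])
  supp_none <- mean(ds$value[ds$microsaccade == "none"])
  expect_lt(supp_ms, -0.05)
  expect_lt(abs(supp_none), 0.1)
  # eye-speed companion peaks after the aligned onsets
  es <- pa$eye_speed
  expect_gt(max(es$mean_dps[es$t_ms >= 0 & es$t_ms < 40]),
            2 * mean(es$mean_dps[es$t_ms < -100]))
})

test_that("suppression deltas vanish when the generator has no suppression", {
  task <- task_config(n_sessions_per_monkey = 1, n_blocks = 2,
                      trials_per_block = 40,
                      single_patch_trials_per_transition = 6)
  nm <- neuron_model(suppression_depth = 0, attention_delta = 4)
  study <- simulate_study(task, eye_model(), nm, seed = 404,
                          n_units_per_monkey = 3)
  events <- study_events(study)
  norms <- study_norms(study)
  matched <- lapply(names(study$sessions), function(sid) {
    timing_match(study$sessions[[sid]],
                 events[events$session_id == sid, ], seed = 77)
  })
  names(matched) <- names(study$sessions)
  pa <- perisaccadic_analysis(study, matched, norms)
  # no generative suppression: each class mean is zero up to Monte-Carlo
  # error across units
  ds <- pa$delta_suppression
  for (m in unique(ds$microsaccade)) {
    v <- ds$value[ds$microsaccade == m]
    expect_lt(abs(mean(v)), max(3.5 * sd(v) / sqrt(length(v)), 0.06))
  }
})

test_that("motor control sees no before/after change without a motor term", {
  fx <- shared_study()
  mc <- motor_control_analysis(fx$study, fx$events, fx$norms, seed = 31)
  n_units <- length(unique(mc$cells$unit_id))
  expect_equal(mc$anova$total_df, n_units * 6 - 1)
  # no stimulus in the RF and no premicrosaccade bias: time main effect small
  tab <- mc$anova$table
  # baseline-only activity: suppression still acts (it is saccade-locked),
  # so before/after differs for microsaccade rows but none-rows stay flat
  cm <- mc$anova$cell_means
  none_diff <- cm$mean[cm$microsaccade == "none" & cm$window == "after"] -
    cm$mean[cm$microsaccade == "none" & cm$window == "before"]
  expect_lt(abs(none_diff), 0.15)
})

test_that("a premicrosaccade motor burst is detected by the motor control", {
  task <- task_config(n_sessions_per_monkey = 1, n_blocks = 2,
                      trials_per_block = 30,
                      single_patch_trials_per_transition = 24)
  nm <- neuron_model(baseline_rate = 20, transient_amp = 30,
                     suppression_depth = 0, attention_delta = 0,
                     premicrosaccade_bias = 25)
  study <- simulate_study(task, eye_model(), nm, seed = 12, n_units_per_monkey = 3)
  events <- study_events(study)
  norms <- study_norms(study)
  mc <- motor_control_analysis(study, events, norms, seed = 8)
  cm <- mc$anova$cell_means
  # the bias loads the 100 ms before toward-RF microsaccades
  bias_effect <- cm$mean[cm$microsaccade == "toward_rf" & cm$window == "before"] -
    cm$mean[cm$microsaccade == "away_rf" & cm$window == "before"]
  expect_gt(bias_effect, 0.15)
})

test_that("position matching yields a balanced two-level microsaccade design", {
  fx <- shared_study()
  pm <- position_matched_analysis(fx$study, fx$events, fx$norms, seed = 5)
  n_units <- length(unique(pm$cells$unit_id))
  expect_equal(pm$anova$total_df, n_units * 8 - 1)
  expect_setequal(unique(as.character(pm$cells$microsaccade)),
                  c("toward", "away"))
  for (m in pm$matched_sets) {
    expect_true(all(apply(m$post_counts, 1,
                          function(r) length(unique(r)) == 1)))
  }
})

test_that("behavioral split recovers the injected away-microsaccade RT penalty", {
  task <- task_config(n_sessions_per_monkey = 1, n_blocks = 4,
                      trials_per_block = 60,
                      single_patch_trials_per_transition = 0,
                      rt_shift_away_ms = 60, rt_sd_ms = 40)
  em <- eye_model(microsaccade_rate_hz = 2.5, dip_factor = 1, rebound_factor = 1)
  study <- simulate_study(task, em, neuron_model(), seed = 90,
                          n_units_per_monkey = 1)
  events <- study_events(study)
  bh <- behavior_by_microsaccade(study, events)
  expect_true(bh$rates$none$present)
  expect_gt(bh$rt_tests$none_vs_away$mean_rt_2,
            bh$rt_tests$none_vs_away$mean_rt_1)
  expect_lt(bh$rt_tests$none_vs_away$p_value, 0.05)
  # hit-rate CI is the Clopper-Pearson interval of the class counts
  r <- bh$rates$none
  expect_equal(unname(binomial_ci(r$k, r$n)["lower"]), r$ci_lower)
})

test_that("modulation by outcome recovers a reduced miss-trial delta", {
  task <- task_config(n_sessions_per_monkey = 1, n_blocks = 4,
                      trials_per_block = 60,
                      single_patch_trials_per_transition = 0,
                      hit_rate = 0.6)
  nm <- neuron_model(baseline_rate = 20, attention_delta = 8,
                     miss_delta_scale = 0)
  study <- simulate_study(task, eye_model(), nm, seed = 55,
                          n_units_per_monkey = 6)
  norms <- study_norms(study)
  mo <- modulation_by_outcome(study, norms)
  expect_gt(mean(mo$deltas$delta_hit), mean(mo$deltas$delta_miss))
  expect_lt(mo$test$p_value, 0.05)
  # identical hit/miss generative parameters: no systematic difference
  fx <- shared_study()
  mo0 <- modulation_by_outcome(fx$study, fx$norms)
  expect_gt(mo0$test$p_value, 0.001)
})
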