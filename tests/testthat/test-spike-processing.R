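# Binning, z-normalization, event alignment, window means, and the unit
# screen.

test_that("binning counts spikes into half-open bins and conserves totals", {
  expect_equal(bin_spikes(numeric(0), c(0, 20, 40)), c(0L, 0L))
  expect_equal(bin_spikes(c(5, 15, 25), c(0, 20, 40)), c(2L, 1L))
  # boundary spike belongs to the right-hand bin
  expect_equal(bin_spikes(c(20), c(0, 20, 40)), c(0L, 1L))
  expect_error(bin_spikes(1, c(0, 0, 10)), "strictly increasing")
  expect_error(bin_spikes(c(1, NA), c(0, 10)), "non-finite")
  # random spike sets vs exhaustive per-spike assignment
  withr::with_seed(5, {
    for (i in 1:20) {
      tms <- runif(200, -50, 250)
      edges <- sort(sample(seq(-40, 240, by = 20), 8))
      got <- bin_spikes(tms, edges)
      want <- integer(length(edges) - 1)
      for (s in tms) {
        for (b in seq_len(length(edges) - 1)) {
          if (s >= edges[b] && s < edges[b + 1]) want[b] <- want[b] + 1L
        }
      }
      expect_equal(got, want)
      expect_equal(sum(got), sum(tms >= edges[1] & tms < edges[length(edges)]))
    }
  })
})

test_that("z-scoring uses the population SD over the normalization sample", {
  # counts [0, 2, 0, 2]: mean 1, population SD 1, z = (-1, 1, -1, 1)
  v <- c(0, 2, 0, 2)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  expect_equal(s, 1)
  expect_equal((v - m) / s, c(-1, 1, -1, 1))
})

sd_pop_test <- function(x) sqrt(mean((x - mean(x))^2))

test_that("session z-normalization satisfies its contract", {
  task <- tiny_task()
  s <- simulate_session(task, eye_model(), list(neuron_model(), neuron_model()),
                        seed = 17)
  norm <- zscore_normalize(s)
  n_bins <- length(norm$edges) - 1
  expect_equal(dim(norm$z), c(2, nrow(s$trials), n_bins))
  for (u in 1:2) {
    vals <- as.numeric(norm$z[u, , ])
    expect_lt(abs(mean(vals)), 1e-6)
    expect_lt(abs(sqrt(mean((vals - mean(vals))^2)) - 1), 1e-6)
    # z-scoring is order-preserving and recoverable
    cts <- as.numeric(norm$counts[u, , ])
    expect_true(all(diff(vals[order(cts)]) >= -1e-12))
    expect_equal(vals * norm$unit_sd[u] + norm$unit_mean[u], cts)
  }
  # affine invariance of the z transform itself
  z1 <- (c(1, 5, 3) - mean(c(1, 5, 3))) / sd_pop_test(c(1, 5, 3))
  z2 <- (c(1, 5, 3) * 7 + 2 - mean(c(1, 5, 3) * 7 + 2)) / sd_pop_test(c(1, 5, 3) * 7 + 2)
  expect_equal(z1, z2)
})

test_that("a unit with constant counts is excluded from normalization", {
  task <- tiny_task()
  silent <- neuron_model(baseline_rate = 0, transient_amp = 0,
                         attention_delta = 0, suppression_depth = 0)
  s <- simulate_session(task, quiet_eye(), list(silent, neuron_model()), seed = 3)
  norm <- zscore_normalize(s)
  expect_equal(norm$excluded_units, s$units$unit_id[1])
  expect_true(all(is.na(norm$z[1, , ])))
})

test_that("event alignment is translation invariant and drops uncovered windows", {
  task <- tiny_task()
  s <- simulate_session(task, quiet_eye(), list(neuron_model()), seed = 9)
  norm <- zscore_normalize(s)
  ev <- data.frame(trial_id = s$trials$trial_id[1:3], t0_ms = c(300, 500, 700))
  al <- align_to_events(s, ev, norm, window = c(-200, 200))
  expect_equal(dim(al$z), c(1, 3, 20))
  # shifting spikes and the event time by the same amount leaves rows equal
  s2 <- s
  sel <- s2$spikes$trial_id == ev$trial_id[1]
  s2$spikes$t_ms[sel] <- s2$spikes$t_ms[sel] + 40
  al2 <- align_to_events(s2, data.frame(trial_id = ev$trial_id[1],
                                        t0_ms = ev$t0_ms[1] + 40),
                         norm, window = c(-200, 200))
  expect_equal(al2$z[1, 1, ], al$z[1, 1, ])
  # events whose window leaves the recorded span are dropped and counted
  al3 <- align_to_events(s, data.frame(trial_id = s$trials$trial_id[1],
                                       t0_ms = s$trials$t_end_ms[1]),
                         norm, window = c(-200, 200))
  expect_equal(nrow(al3$events), 0)
  expect_equal(al3$n_dropped, 1)
})

test_that("aligned averages show the injected suppression dip", {
  # strong multiplicative suppression; aligned mean in the suppressed span
  # must drop by about depth x baseline, per the generative rate
  task <- tiny_task(n_blocks = 2, trials_per_block = 40,
                    single_patch_trials_per_transition = 0)
  nm <- neuron_model(baseline_rate = 40, transient_amp = 0, attention_delta = 0,
                     suppression_depth = 0.5, suppression_latency_ms = 20,
                     suppression_duration_ms = 60)
  em <- eye_model(tremor_sd = 0.003)
  s <- simulate_session(task, em, list(nm), seed = 33)
  norm <- zscore_normalize(s)
  gt <- s$ground_truth$events
  gt <- gt[gt$onset_ms >= 200 & gt$onset_ms < 800, ]
  al <- align_to_events(s, data.frame(trial_id = gt$trial_id, t0_ms = gt$onset_ms),
                        norm, window = c(-200, 200))
  before <- mean(window_mean(al, c(-60, 0)))
  during <- mean(window_mean(al, c(40, 100)))
  # expected z drop: rate falls from ~40 to ~20 sp/s over the 2/3 of the
  # window covered by the suppressed span. The prediction is a lower bound:
  # follow-on microsaccades add suppression inside the after window, and the
  # generator's refractory gap keeps the before window suppression-free, so
  # the measured drop can exceed it by a moderate factor.
  drop_z <- (0.5 * 40 * (2 / 3)) * 0.020 / norm$unit_sd[1]
  expect_lt(during, before)
  expect_gt(before - during, 0.7 * drop_z)
  expect_lt(before - during, 2 * drop_z)
})

test_that("window_mean averages exactly the fully covered bins", {
  x <- list(z = array(1, dim = c(2, 3, 10)), edges = seq(0, 200, by = 20))
  expect_equal(window_mean(x, c(0, 200)), matrix(1, 2, 3))
  x$z[1, 1, ] <- 1:10
  expect_equal(window_mean(x, c(20, 40))[1, 1], 2)   # single bin
  expect_equal(window_mean(x, c(30, 70))[1, 1], 3)   # only bin [40,60) fits
  expect_error(window_mean(x, c(30, 40)), "no complete bin")
  # arbitrary window vs direct mean over selected bins
  withr::with_seed(2, {
    x$z <- array(rnorm(60), dim = c(2, 3, 10))
    got <- window_mean(x, c(40, 120))
    want <- apply(x$z[, , 3:6], c(1, 2), mean)
    expect_equal(got, want)
  })
})

test_that("the unit screen accepts responsive modulated units and rejects silent ones", {
  task <- tiny_task(n_blocks = 2, trials_per_block = 50,
                    single_patch_trials_per_transition = 14)
  good <- neuron_model(baseline_rate = 10, transient_amp = 30,
                       attention_delta = 6, rf_side = "right")
  silent <- neuron_model(baseline_rate = 0, transient_amp = 0,
                         attention_delta = 0, suppression_depth = 0)
  s <- simulate_session(task, eye_model(), list(good, silent), seed = 55)
  scr <- screen_units(s)
  expect_true(scr$included[1])
  expect_false(scr$included[2])
  expect_false(scr$visually_responsive[2])
})

test_that("the attention screen holds its nominal level under the null", {
  # null units: visual transient present, no attention delta; the screen's
  # attention component (two-sided alpha with a sign requirement) should
  # pass at about alpha/2
  task <- tiny_task(n_blocks = 2, trials_per_block = 30,
                    single_patch_trials_per_transition = 4)
  nulls <- replicate(150, neuron_model(attention_delta = 0), simplify = FALSE)
  s <- simulate_session(task, eye_model(), nulls, seed = 71)
  scr <- screen_units(s)
  alpha <- 0.01
  p0 <- alpha / 2
  se <- sqrt(p0 * (1 - p0) / nrow(scr))
  expect_lt(abs(mean(scr$attention_modulated) - p0), 3 * se + 1e-9)
})
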