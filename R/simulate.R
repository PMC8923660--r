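# Synthetic-session generator: eye traces with injected microsaccades,
# inhomogeneous-Poisson spike trains, and behavioral outcomes, all with
# recorded ground truth. Times are in ms relative to color-patch onset.

# Minimum-jerk position profile from 0 to 1 over n samples (tau in (0, 1]).
min_jerk_profile <- function(n) {
  tau <- seq_len(n) / n
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# Piecewise-constant microsaccade hazard (events/s) at times t (ms relative
# to patch onset): baseline rate scaled inside the post-onset dip and the
# rebound window.
ms_hazard <- function(t, eye) {
  f <- rep(1, length(t))
  f[t >= eye$dip_window_ms[1] & t < eye$dip_window_ms[2]] <- eye$dip_factor
  f[t >= eye$rebound_window_ms[1] & t < eye$rebound_window_ms[2]] <- eye$rebound_factor
  eye$microsaccade_rate_hz * f
}

# Draw microsaccade onset times on [t0, t1) ms by thinning the hazard, then
# enforce a minimum gap between events (duration + min_gap_ms).
draw_ms_onsets <- function(t0, t1, eye, duration_ms) {
  lam_max <- eye$microsaccade_rate_hz * max(1, eye$dip_factor, eye$rebound_factor)
  if (lam_max <= 0) return(numeric(0))
  span_s <- (t1 - t0) / 1000
  n_cand <- stats::rpois(1, lam_max * span_s)
  if (n_cand == 0) return(numeric(0))
  cand <- sort(stats::runif(n_cand, t0, t1))
  keep <- stats::runif(n_cand) < ms_hazard(cand, eye) / lam_max
  onsets <- cand[keep]
  if (length(onsets) < 2) return(onsets)
  out <- onsets[1]
  for (s in onsets[-1]) {
    if (s - out[length(out)] >= duration_ms + eye$min_gap_ms) out <- c(out, s)
  }
  out
}

# Draw cue-relative microsaccade directions from the toward/away/uniform
# mixture (wrapped-normal lobes at 0 and 180 degrees).
draw_ms_directions <- function(n, eye) {
  if (n == 0) return(numeric(0))
  comp <- sample(c("toward", "away", "uniform"), n, replace = TRUE,
                 prob = eye$direction_weights[c("toward", "away", "uniform")])
  rel <- numeric(n)
  rel[comp == "toward"] <- stats::rnorm(sum(comp == "toward"), 0, eye$direction_sd_deg)
  rel[comp == "away"] <- stats::rnorm(sum(comp == "away"), 180, eye$direction_sd_deg)
  rel[comp == "uniform"] <- stats::runif(sum(comp == "uniform"), -180, 180)
  wrap_angle(rel)
}

#' Simulate one fixational eye trace with known microsaccades
#'
#' The trace is the sum of a mean-reverting drift process, white tremor, and
#' injected microsaccades with minimum-jerk displacement profiles whose peak
#' speed follows the main sequence. Every injected event is returned as
#' ground truth.
#'
#' @param span_ms Two-vector `c(t_start, t_end)` in ms relative to patch
#'   onset (`t_start` may be negative).
#' @param eye An [eye_model()].
#' @param cue_direction_deg Azimuth of the cued location in degrees; event
#'   directions are drawn relative to it.
#' @param sample_rate_hz Sampling rate (default 1000).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A list of class `eye_trace` with elements `t0` (time of the first
#'   sample, ms), `dt` (sample interval, ms), `x`, `y` (positions, degrees),
#'   and `events`, a data frame of true events with columns `onset_ms`,
#'   `offset_ms`, `dx_deg`, `dy_deg`, `amplitude_deg`, `peak_speed_dps`,
#'   `direction_deg`, `rel_direction_deg`.
#' @export
simulate_eye_trace <- function(span_ms, eye, cue_direction_deg = 0,
                               sample_rate_hz = 1000, seed = NULL) {
  check_that(length(span_ms) == 2 && span_ms[2] > span_ms[1],
             "span_ms", "must be an increasing interval")
  with_seed_or_current(seed, {
    dt <- 1000 / sample_rate_hz
    n <- floor((span_ms[2] - span_ms[1]) / dt)
    t <- span_ms[1] + (seq_len(n) - 1) * dt

    # Microsaccade kinematics: minimum-jerk peak speed is 1.875 * A / D, so a
    # linear main sequence (peak speed = slope * A) fixes the duration.
    dur_ms <- 1875 / eye$main_sequence_slope
    dur_n <- max(2L, round(dur_ms / dt))
    onsets <- draw_ms_onsets(span_ms[1], span_ms[2] - dur_ms - dt, eye, dur_ms)
    n_ev <- length(onsets)
    amp <- numeric(0)
    if (n_ev > 0) {
      amp <- stats::rlnorm(n_ev, eye$amplitude_meanlog, eye$amplitude_sdlog)
      while (any(amp > eye$amplitude_max_deg)) {
        bad <- amp > eye$amplitude_max_deg
        amp[bad] <- stats::rlnorm(sum(bad), eye$amplitude_meanlog, eye$amplitude_sdlog)
      }
    }
    rel_dir <- draw_ms_directions(n_ev, eye)
    abs_dir <- wrap_angle(cue_direction_deg + rel_dir)

    # Drift: Ornstein-Uhlenbeck via a recursive filter; tremor: white noise.
    step_sd <- sqrt(eye$drift_diffusion * dt / 1000)
    k <- dt / eye$centering_tau_ms
    x <- as.numeric(stats::filter(stats::rnorm(n, 0, step_sd), 1 - k, "recursive"))
    y <- as.numeric(stats::filter(stats::rnorm(n, 0, step_sd), 1 - k, "recursive"))

    prof <- min_jerk_profile(dur_n)
    for (i in seq_len(n_ev)) {
      i0 <- floor((onsets[i] - span_ms[1]) / dt) + 1L
      idx <- i0:(i0 + dur_n - 1L)
      th <- abs_dir[i] * pi / 180
      x[idx] <- x[idx] + amp[i] * cos(th) * prof
      y[idx] <- y[idx] + amp[i] * sin(th) * prof
      if (i0 + dur_n <= n) {
        x[(i0 + dur_n):n] <- x[(i0 + dur_n):n] + amp[i] * cos(th)
        y[(i0 + dur_n):n] <- y[(i0 + dur_n):n] + amp[i] * sin(th)
      }
    }
    if (eye$tremor_sd > 0) {
      x <- x + stats::rnorm(n, 0, eye$tremor_sd)
      y <- y + stats::rnorm(n, 0, eye$tremor_sd)
    }

    events <- data.frame(
      onset_ms = t[floor((onsets - span_ms[1]) / dt) + 1L][seq_len(n_ev)],
      offset_ms = numeric(n_ev),
      dx_deg = amp * cos(abs_dir * pi / 180),
      dy_deg = amp * sin(abs_dir * pi / 180),
      amplitude_deg = amp,
      peak_speed_dps = 1.875 * amp / (dur_n * dt / 1000),
      direction_deg = abs_dir,
      rel_direction_deg = rel_dir
    )
    if (n_ev > 0) events$offset_ms <- events$onset_ms + dur_n * dt
    structure(list(t0 = span_ms[1], dt = dt, x = x, y = y, events = events),
              class = "eye_trace")
  })
}

# Sample times of an eye trace.
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$x) - 1) * trace$dt
}

# Evaluate a unit's generative firing rate (spikes/s) at times t (ms) for one
# trial. `ms_events` is the trial's true event data frame; `patch_in_rf` and
# `cue_in_rf` are trial-level flags; `t_end` bounds the attention increment.
unit_rate <- function(t, nm, patch_in_rf, cue_in_rf, ms_events, rf_direction_deg,
                      delta_scale = 1) {
  r <- rep(nm$baseline_rate, length(t))
  if (patch_in_rf && nm$transient_amp > 0) {
    post <- t >= nm$transient_latency_ms
    r[post] <- r[post] + nm$transient_amp *
      exp(-(t[post] - nm$transient_latency_ms) / nm$transient_decay_ms)
  }
  if (cue_in_rf && nm$attention_delta > 0) {
    d <- nm$attention_delta * delta_scale
    r[t >= nm$attention_onset_ms] <- r[t >= nm$attention_onset_ms] + d
  }
  if (nm$premicrosaccade_bias > 0 && nrow(ms_events) > 0) {
    rel_rf <- wrap_angle(ms_events$direction_deg - rf_direction_deg)
    for (i in which(abs(rel_rf) < 90)) {
      s <- ms_events$onset_ms[i]
      idx <- t >= s - 100 & t < s
      r[idx] <- r[idx] + nm$premicrosaccade_bias
    }
  }
  if (nm$suppression_depth > 0 && nrow(ms_events) > 0) {
    for (s in ms_events$onset_ms) {
      idx <- t >= s + nm$suppression_latency_ms &
        t < s + nm$suppression_latency_ms + nm$suppression_duration_ms
      if (nm$suppression_mode == "multiplicative") {
        r[idx] <- r[idx] * (1 - nm$suppression_depth)
      } else {
        r[idx] <- r[idx] - nm$suppression_depth * nm$baseline_rate
      }
    }
  }
  pmax(r, 0)
}

# Inhomogeneous-Poisson spike times on [t0, t1) by thinning.
draw_spikes <- function(t0, t1, nm, patch_in_rf, cue_in_rf, ms_events, rf_dir,
                        delta_scale = 1) {
  lam_max <- nm$baseline_rate + nm$transient_amp +
    nm$attention_delta * max(1, delta_scale) + nm$premicrosaccade_bias
  if (lam_max <= 0) return(numeric(0))
  n_cand <- stats::rpois(1, lam_max * (t1 - t0) / 1000)
  if (n_cand == 0) return(numeric(0))
  cand <- sort(stats::runif(n_cand, t0, t1))
  r <- unit_rate(cand, nm, patch_in_rf, cue_in_rf, ms_events, rf_dir, delta_scale)
  cand[stats::runif(n_cand) < r / lam_max]
}

# Truncated-normal reaction time within the response window (ms after change).
draw_rt <- function(task, shift_ms) {
  lo <- task$response_window_ms[1]
  hi <- task$response_window_ms[2]
  for (i in 1:50) {
    rt <- stats::rnorm(1, task$rt_mean_ms + shift_ms, task$rt_sd_ms)
    if (rt >= lo && rt <= hi) return(rt)
  }
  (lo + hi) / 2
}

# Classify a trial's true microsaccades within +/-50 ms of the change onset
# for the behavioral coupling: "none", "toward", "away" (mixed -> "none").
change_ms_class <- function(ms_events, change_ms) {
  if (nrow(ms_events) == 0) return("none")
  near <- abs(ms_events$onset_ms - change_ms) <= 50
  if (!any(near)) return("none")
  toward <- abs(ms_events$rel_direction_deg[near]) < 90 |
    ms_events$rel_direction_deg[near] == -90
  if (all(toward)) "toward" else if (!any(toward)) "away" else "none"
}

#' Simulate one complete session of the covert attention task
#'
#' Builds the trial sequence (single-patch transition trials announcing each
#' block's cued location, followed by two-patch cued-block trials with the
#' cue side alternating between blocks), simulates a fixational eye trace
#' per trial, draws each unit's spike train from its inhomogeneous-Poisson
#' rate function (thinning algorithm), and generates behavioral outcomes.
#' Identical arguments and seed reproduce the session byte for byte.
#'
#' @param task A [task_config()].
#' @param eye An [eye_model()].
#' @param neurons A list of [neuron_model()] objects (one per unit).
#' @param seed Integer seed.
#' @param session_id,monkey Identifiers stamped into all tables.
#' @return A list of class `sc_session` with elements `trials` (data frame),
#'   `units` (data frame with generative parameters), `spikes` (long data
#'   frame `unit_id`, `trial_id`, `t_ms`), `eye_traces` (list of
#'   [simulate_eye_trace()] outputs named by trial id), and `ground_truth`
#'   (true events per trial plus the seed).
#' @export
simulate_session <- function(task, eye, neurons, seed,
                             session_id = "s1", monkey = "m1") {
  stopifnot(inherits(task, "task_config"), inherits(eye, "eye_model"))
  if (inherits(neurons, "neuron_model")) neurons <- list(neurons)
  lapply(neurons, function(nm) stopifnot(inherits(nm, "neuron_model")))
  withr::with_seed(seed, {
    sides <- rep(c("left", "right"), length.out = task$n_blocks)
    n_single <- task$single_patch_trials_per_transition
    trial_rows <- list()
    tid <- 0L
    for (b in seq_len(task$n_blocks)) {
      side <- sides[b]
      if (n_single > 0) {
        for (i in seq_len(n_single)) {
          tid <- tid + 1L
          trial_rows[[tid]] <- data.frame(trial_id = tid, block = b,
                                          trial_type = "single_patch",
                                          cue_side = side, change_site = "cue")
        }
      }
      n_cue <- round(task$trials_per_block * task$cue_foil_ratio[1] /
                       sum(task$cue_foil_ratio))
      site <- sample(c(rep("cue", n_cue), rep("foil", task$trials_per_block - n_cue)))
      for (i in seq_len(task$trials_per_block)) {
        tid <- tid + 1L
        trial_rows[[tid]] <- data.frame(trial_id = tid, block = b,
                                        trial_type = "two_patch",
                                        cue_side = side, change_site = site[i])
      }
    }
    trials <- do.call(rbind, trial_rows)
    n_trials <- nrow(trials)
    trials$change_ms <- round(stats::runif(n_trials, task$change_window_ms[1],
                                           task$change_window_ms[2]))
    trials$t_start_ms <- -task$pre_patch_ms
    trials$t_end_ms <- trials$change_ms + task$post_change_ms
    trials$outcome <- NA_character_
    trials$rt_ms <- NA_real_

    unit_ids <- sprintf("%s_u%02d", session_id, seq_along(neurons))
    units <- data.frame(
      unit_id = unit_ids,
      session_id = session_id,
      monkey = monkey,
      rf_side = vapply(neurons, function(nm) nm$rf_side, character(1)),
      baseline_rate = vapply(neurons, function(nm) nm$baseline_rate, numeric(1)),
      attention_delta = vapply(neurons, function(nm) nm$attention_delta, numeric(1)),
      suppression_depth = vapply(neurons, function(nm) nm$suppression_depth, numeric(1)),
      suppression_mode = vapply(neurons, function(nm) nm$suppression_mode, character(1))
    )

    eye_traces <- vector("list", n_trials)
    gt_events <- vector("list", n_trials)
    spike_list <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      tr <- trials[i, ]
      cue_dir <- side_angle(tr$cue_side)
      trace <- simulate_eye_trace(c(tr$t_start_ms, tr$t_end_ms), eye,
                                  cue_direction_deg = cue_dir,
                                  sample_rate_hz = task$sample_rate_hz)
      eye_traces[[i]] <- trace
      ev <- trace$events
      gt_events[[i]] <- if (nrow(ev) > 0) cbind(trial_id = tr$trial_id, ev) else NULL

      # Behavior from the true events near the change.
      cls <- change_ms_class(ev, tr$change_ms)
      p_hit <- task$hit_rate +
        switch(cls, toward = task$hit_shift_toward, away = task$hit_shift_away, 0)
      p_hit <- min(max(p_hit, 0), 1)
      rt_shift <- switch(cls, toward = task$rt_shift_toward_ms,
                         away = task$rt_shift_away_ms, 0)
      if (tr$change_site == "cue") {
        if (stats::runif(1) < p_hit) {
          trials$outcome[i] <- "hit"
          trials$rt_ms[i] <- draw_rt(task, rt_shift)
        } else {
          trials$outcome[i] <- "miss"
        }
      } else {
        if (stats::runif(1) < task$false_alarm_rate) {
          trials$outcome[i] <- "false_alarm"
          trials$rt_ms[i] <- draw_rt(task, rt_shift)
        } else {
          trials$outcome[i] <- "correct_reject"
        }
      }

      # Spikes for every unit on this trial.
      per_unit <- vector("list", length(neurons))
      for (u in seq_along(neurons)) {
        nm <- neurons[[u]]
        patch_in_rf <- if (tr$trial_type == "two_patch") TRUE else tr$cue_side == nm$rf_side
        cue_in_rf <- tr$trial_type == "two_patch" && tr$cue_side == nm$rf_side
        dscale <- if (identical(trials$outcome[i], "miss")) nm$miss_delta_scale else 1
        st <- draw_spikes(tr$t_start_ms, tr$t_end_ms, nm, patch_in_rf, cue_in_rf,
                          ev, side_angle(nm$rf_side), dscale)
        if (length(st) > 0) {
          per_unit[[u]] <- data.frame(unit_id = unit_ids[u],
                                      trial_id = tr$trial_id, t_ms = st)
        }
      }
      spike_list[[i]] <- do.call(rbind, per_unit)
    }
    spikes <- do.call(rbind, spike_list)
    if (is.null(spikes)) {
      spikes <- data.frame(unit_id = character(0), trial_id = integer(0),
                           t_ms = numeric(0))
    }
    rownames(spikes) <- NULL
    names(eye_traces) <- as.character(trials$trial_id)
    gt <- do.call(rbind, gt_events)
    if (is.null(gt)) gt <- data.frame()
    structure(list(
      session_id = session_id,
      monkey = monkey,
      task = task,
      eye_model = eye,
      neurons = neurons,
      trials = trials,
      units = units,
      spikes = spikes,
      eye_traces = eye_traces,
      ground_truth = list(events = gt, seed = seed)
    ), class = "sc_session")
  })
}

#' Simulate a multi-session, two-subject study
#'
#' Distributes `n_units_per_monkey` units over `task$n_sessions_per_monkey`
#' sessions per subject, alternating the response-field side across units
#' within each session, and simulates each session independently with a seed
#' derived reproducibly from `seed`.
#'
#' @param task A [task_config()].
#' @param eye An [eye_model()].
#' @param neuron A template [neuron_model()]; per-unit baselines are drawn
#'   uniformly from `baseline_range` around it, other parameters are shared.
#' @param seed Integer master seed.
#' @param n_units_per_monkey Units per subject (default 34).
#' @param baseline_range Two-vector of baseline rates (spikes/s) across
#'   units.
#' @return A list of class `sc_study` with elements `sessions` (list of
#'   `sc_session`) and the generating configuration.
#' @export
simulate_study <- function(task = task_config(), eye = eye_model(),
                           neuron = neuron_model(), seed = 1,
                           n_units_per_monkey = 34,
                           baseline_range = c(10, 25)) {
  n_sess <- task$n_sessions_per_monkey
  per_sess <- diff(c(0, round(seq_len(n_sess) * n_units_per_monkey / n_sess)))
  seeds <- derive_seeds(seed, 2 * n_sess + 1)
  base_draw <- withr::with_seed(seeds[2 * n_sess + 1],
                                stats::runif(2 * n_units_per_monkey,
                                             baseline_range[1], baseline_range[2]))
  sessions <- list()
  k <- 0L
  b <- 0L
  for (m in 1:2) {
    for (s in seq_len(n_sess)) {
      k <- k + 1L
      nunits <- per_sess[s]
      neurons <- lapply(seq_len(nunits), function(u) {
        b <<- b + 1L
        nm <- neuron
        nm$baseline_rate <- base_draw[b]
        nm$rf_side <- if (u %% 2 == 1) "right" else "left"
        nm
      })
      sid <- sprintf("m%d_s%02d", m, s)
      sessions[[sid]] <- simulate_session(task, eye, neurons, seed = seeds[k],
                                          session_id = sid,
                                          monkey = sprintf("m%d", m))
    }
  }
  structure(list(sessions = sessions, task = task, eye_model = eye,
                 neuron = neuron, seed = seed),
            class = "sc_study")
}

#' @export
print.sc_session <- function(x, ...) {
  cat(sprintf("Session %s (%s): %d trials, %d units, %d spikes, %d true microsaccades\n",
              x$session_id, x$monkey, nrow(x$trials), nrow(x$units),
              nrow(x$spikes), nrow(x$ground_truth$events)))
  invisible(x)
}

#' @export
print.sc_study <- function(x, ...) {
  cat(sprintf("Simulated study: %d sessions, %d units total\n",
              length(x$sessions),
              sum(vapply(x$sessions, function(s) nrow(s$units), numeric(1)))))
  invisible(x)
}
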