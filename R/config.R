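# Configuration objects for the task simulator, the eye/neuron generative
# models, and the analysis stages. Each constructor validates its invariants
# and returns a classed list so downstream code can dispatch and print.

#' Task configuration for a covert spatial-attention session
#'
#' Describes the structure of one behavioral session: cued blocks with the
#' cue side alternating from block to block, single-patch transition trials
#' announcing each block's cued location, a peripheral cue ring flashed
#' briefly before two color patches appear, and a saturation change at the
#' cued or foil patch that the subject reports by releasing a joystick.
#'
#' Times are in milliseconds relative to color-patch onset (t = 0) unless
#' noted. The behavioral fields (`hit_rate`, `rt_mean_ms`, ...) parameterize
#' the generative model of outcomes; the `rt_shift_*` and `hit_shift_*`
#' fields optionally couple behavior to microsaccades occurring within
#' +/-50 ms of the change, so microsaccade-conditioned behavioral analyses
#' have a testable ground truth.
#'
#' @param n_sessions_per_monkey Sessions simulated per subject.
#' @param n_blocks Cued blocks per session; the cue side alternates
#'   left/right starting on the left.
#' @param trials_per_block Two-patch trials per cued block (default 70).
#' @param single_patch_trials_per_transition Single-patch trials announcing
#'   each block's cued location (default 18), presented before every block.
#' @param cue_flash_ms Duration of the peripheral cue ring flash (default 133).
#' @param cue_to_patch_ms Interval from cue-ring onset to patch onset
#'   (default 500; the cue therefore appears at t = -500).
#' @param change_window_ms Two-vector; the saturation change occurs uniformly
#'   within this window after patch onset (default `c(1000, 4000)`).
#' @param response_window_ms Two-vector; joystick releases are scored as
#'   responses when they fall in this window after the change
#'   (default `c(150, 750)`).
#' @param cue_foil_ratio Two-vector of positive integers; ratio of cue-change
#'   to foil-change trials within a block (default `c(3, 1)`).
#' @param sample_rate_hz Eye-position sample rate (default 1000; must be
#'   at least 500).
#' @param cue_ecc_deg Cue/patch eccentricity in degrees of visual angle.
#' @param pre_patch_ms Recorded time before patch onset (default 700, which
#'   covers the cue flash and the -100 to 0 ms baseline window).
#' @param post_change_ms Recorded time after the change (default 750, the
#'   end of the response window).
#' @param hit_rate Baseline probability of a hit on cue-change trials.
#' @param false_alarm_rate Probability of a joystick release on foil-change
#'   trials.
#' @param rt_mean_ms,rt_sd_ms Mean and SD of the (truncated normal) reaction
#'   time distribution, within `response_window_ms`.
#' @param rt_shift_toward_ms,rt_shift_away_ms Additive RT shifts when a true
#'   microsaccade toward/away from the cue occurs within +/-50 ms of the
#'   change onset.
#' @param hit_shift_toward,hit_shift_away Additive shifts of the hit
#'   probability under the same conditioning.
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_sessions_per_monkey = 5,
                        n_blocks = 4,
                        trials_per_block = 70,
                        single_patch_trials_per_transition = 18,
                        cue_flash_ms = 133,
                        cue_to_patch_ms = 500,
                        change_window_ms = c(1000, 4000),
                        response_window_ms = c(150, 750),
                        cue_foil_ratio = c(3, 1),
                        sample_rate_hz = 1000,
                        cue_ecc_deg = 8,
                        pre_patch_ms = 700,
                        post_change_ms = 750,
                        hit_rate = 0.83,
                        false_alarm_rate = 0.05,
                        rt_mean_ms = 400,
                        rt_sd_ms = 80,
                        rt_shift_toward_ms = 0,
                        rt_shift_away_ms = 30,
                        hit_shift_toward = 0,
                        hit_shift_away = 0) {
  check_that(n_sessions_per_monkey >= 1, "n_sessions_per_monkey", "must be >= 1")
  check_that(n_blocks >= 1, "n_blocks", "must be >= 1")
  check_that(trials_per_block >= 1, "trials_per_block", "must be >= 1")
  check_that(single_patch_trials_per_transition >= 0,
             "single_patch_trials_per_transition", "must be >= 0")
  check_that(cue_flash_ms > 0, "cue_flash_ms", "must be positive")
  check_that(cue_to_patch_ms > 0, "cue_to_patch_ms", "must be positive")
  check_that(length(change_window_ms) == 2 && change_window_ms[1] > 0 &&
               change_window_ms[2] > change_window_ms[1],
             "change_window_ms", "must be an increasing positive interval")
  check_that(length(response_window_ms) == 2 && response_window_ms[1] > 0 &&
               response_window_ms[2] > response_window_ms[1],
             "response_window_ms", "must be an increasing positive interval")
  check_that(length(cue_foil_ratio) == 2 && all(cue_foil_ratio >= 1) &&
               all(cue_foil_ratio == round(cue_foil_ratio)),
             "cue_foil_ratio", "must be two positive integers")
  check_that(sample_rate_hz >= 500, "sample_rate_hz", "must be >= 500 Hz")
  check_that(cue_ecc_deg > 0, "cue_ecc_deg", "must be positive")
  check_that(pre_patch_ms >= cue_to_patch_ms + 100,
             "pre_patch_ms", "must cover the cue flash and baseline window")
  check_that(hit_rate >= 0 && hit_rate <= 1, "hit_rate", "must be in [0, 1]")
  check_that(false_alarm_rate >= 0 && false_alarm_rate <= 1,
             "false_alarm_rate", "must be in [0, 1]")
  check_that(rt_sd_ms >= 0, "rt_sd_ms", "must be nonnegative")
  structure(list(
    n_sessions_per_monkey = n_sessions_per_monkey,
    n_blocks = n_blocks,
    trials_per_block = trials_per_block,
    single_patch_trials_per_transition = single_patch_trials_per_transition,
    cue_flash_ms = cue_flash_ms,
    cue_to_patch_ms = cue_to_patch_ms,
    change_window_ms = change_window_ms,
    response_window_ms = response_window_ms,
    cue_foil_ratio = cue_foil_ratio,
    sample_rate_hz = sample_rate_hz,
    cue_ecc_deg = cue_ecc_deg,
    pre_patch_ms = pre_patch_ms,
    post_change_ms = post_change_ms,
    hit_rate = hit_rate,
    false_alarm_rate = false_alarm_rate,
    rt_mean_ms = rt_mean_ms,
    rt_sd_ms = rt_sd_ms,
    rt_shift_toward_ms = rt_shift_toward_ms,
    rt_shift_away_ms = rt_shift_away_ms,
    hit_shift_toward = hit_shift_toward,
    hit_shift_away = hit_shift_away
  ), class = "task_config")
}

#' Generative model of fixational eye movements
#'
#' Fixational traces are the sum of (i) a slow drift component, modeled as an
#' Ornstein-Uhlenbeck process (random walk with diffusion `drift_diffusion`
#' pulled back to fixation with time constant `centering_tau_ms`), (ii) white
#' tremor of SD `tremor_sd`, and (iii) injected microsaccades with smooth
#' minimum-jerk displacement profiles. Microsaccade onsets follow an
#' inhomogeneous Poisson process whose hazard dips sharply after patch onset
#' and then rebounds, as is typical after a salient visual transient.
#'
#' Microsaccade amplitudes are log-normal truncated at `amplitude_max_deg`
#' (support below one degree, as expected for fixational saccades), and
#' directions relative to the cue are a mixture of a toward component, an
#' away component (wrapped normals of SD `direction_sd_deg` centered at 0 and
#' 180 degrees), and a uniform component. Peak speed follows the main
#' sequence: `peak speed = main_sequence_slope * amplitude`, which for a
#' minimum-jerk profile fixes the movement duration at
#' `1875 / main_sequence_slope` milliseconds.
#'
#' @param drift_diffusion Drift diffusion constant, deg^2/s.
#' @param centering_tau_ms Time constant of the drift's pull back to the
#'   fixation point, ms.
#' @param tremor_sd Per-sample tremor SD, degrees.
#' @param microsaccade_rate_hz Baseline microsaccade rate, events/s.
#' @param dip_window_ms Two-vector: window after patch onset in which the
#'   rate is scaled by `dip_factor` (near-zero dip).
#' @param dip_factor Multiplier on the rate inside `dip_window_ms`.
#' @param rebound_window_ms Two-vector: rebound window after the dip.
#' @param rebound_factor Multiplier on the rate inside `rebound_window_ms`.
#' @param amplitude_meanlog,amplitude_sdlog Log-normal amplitude parameters.
#' @param amplitude_max_deg Upper truncation of the amplitude distribution.
#' @param direction_weights Named numeric vector with components `toward`,
#'   `away`, `uniform`; must be nonnegative and sum to 1.
#' @param direction_sd_deg SD of the wrapped-normal toward/away components.
#' @param main_sequence_slope Peak speed per amplitude, 1/s.
#' @param min_gap_ms Minimum interval between a microsaccade offset and the
#'   next onset; later candidate onsets violating it are discarded.
#' @return An object of class `eye_model`.
#' @export
eye_model <- function(drift_diffusion = 0.001,
                      centering_tau_ms = 2000,
                      tremor_sd = 0.005,
                      microsaccade_rate_hz = 1.5,
                      dip_window_ms = c(0, 150),
                      dip_factor = 0.05,
                      rebound_window_ms = c(150, 600),
                      rebound_factor = 1.3,
                      amplitude_meanlog = log(0.3),
                      amplitude_sdlog = 0.4,
                      amplitude_max_deg = 1,
                      direction_weights = c(toward = 0.25, away = 0.25, uniform = 0.5),
                      direction_sd_deg = 30,
                      main_sequence_slope = 100,
                      min_gap_ms = 80) {
  check_that(drift_diffusion >= 0, "drift_diffusion", "must be nonnegative")
  check_that(centering_tau_ms > 0, "centering_tau_ms", "must be positive")
  check_that(tremor_sd >= 0, "tremor_sd", "must be nonnegative")
  check_that(microsaccade_rate_hz >= 0, "microsaccade_rate_hz", "must be nonnegative")
  check_that(dip_factor >= 0 && rebound_factor >= 0,
             "dip_factor/rebound_factor", "must be nonnegative")
  check_that(amplitude_max_deg > 0, "amplitude_max_deg", "must be positive")
  check_that(all(direction_weights >= 0) &&
               abs(sum(direction_weights) - 1) < 1e-8 &&
               setequal(names(direction_weights), c("toward", "away", "uniform")),
             "direction_weights",
             "must be nonnegative, named toward/away/uniform, and sum to 1")
  check_that(main_sequence_slope > 0, "main_sequence_slope", "must be positive")
  check_that(min_gap_ms >= 0, "min_gap_ms", "must be nonnegative")
  structure(list(
    drift_diffusion = drift_diffusion,
    centering_tau_ms = centering_tau_ms,
    tremor_sd = tremor_sd,
    microsaccade_rate_hz = microsaccade_rate_hz,
    dip_window_ms = dip_window_ms,
    dip_factor = dip_factor,
    rebound_window_ms = rebound_window_ms,
    rebound_factor = rebound_factor,
    amplitude_meanlog = amplitude_meanlog,
    amplitude_sdlog = amplitude_sdlog,
    amplitude_max_deg = amplitude_max_deg,
    direction_weights = direction_weights,
    direction_sd_deg = direction_sd_deg,
    main_sequence_slope = main_sequence_slope,
    min_gap_ms = min_gap_ms
  ), class = "eye_model")
}

#' Generative model of one recorded unit
#'
#' Firing rate is baseline plus a phasic visual transient after stimulus
#' onset in the unit's response field (RF), plus a sustained attention
#' increment when the cued patch is inside the RF, modulated by a
#' suppressive episode after every microsaccade. Suppression is
#' multiplicative by default (`rate * (1 - depth)` during the suppressed
#' span); an additive variant (`rate - depth * baseline`, floored at zero)
#' is available so that analyses can be validated against a generative
#' regime in which attention-related modulation passes through suppression
#' unchanged.
#'
#' @param baseline_rate Baseline rate, spikes/s (nonnegative).
#' @param transient_amp Peak visual transient above baseline, spikes/s.
#' @param transient_latency_ms Latency of the transient after stimulus onset.
#' @param transient_decay_ms Exponential decay constant of the transient.
#' @param attention_delta Sustained rate increment when the cue is in the RF,
#'   spikes/s, applied from `attention_onset_ms` to the end of the trial.
#' @param attention_onset_ms Onset of the attention increment, ms after
#'   patch onset.
#' @param miss_delta_scale Multiplier on `attention_delta` in trials ending
#'   as misses (default 1 = no coupling between modulation and outcome);
#'   values below 1 give behavioral analyses a recoverable
#'   modulation-by-outcome effect.
#' @param suppression_depth Fraction in `[0, 1]`; depth of the
#'   post-microsaccadic suppression.
#' @param suppression_latency_ms Latency of suppression after microsaccade
#'   onset.
#' @param suppression_duration_ms Duration of the suppressed span.
#' @param suppression_mode `"multiplicative"` or `"additive"` (see above).
#' @param premicrosaccade_bias Optional rate increment, spikes/s, during the
#'   100 ms preceding microsaccades directed toward the RF side.
#' @param rf_side `"left"` or `"right"`; which hemifield drives the unit.
#' @return An object of class `neuron_model`.
#' @export
neuron_model <- function(baseline_rate = 15,
                         transient_amp = 50,
                         transient_latency_ms = 45,
                         transient_decay_ms = 80,
                         attention_delta = 4,
                         attention_onset_ms = 200,
                         miss_delta_scale = 1,
                         suppression_depth = 0.5,
                         suppression_latency_ms = 20,
                         suppression_duration_ms = 60,
                         suppression_mode = c("multiplicative", "additive"),
                         premicrosaccade_bias = 0,
                         rf_side = "right") {
  suppression_mode <- match.arg(suppression_mode)
  check_that(baseline_rate >= 0, "baseline_rate", "must be nonnegative")
  check_that(transient_amp >= 0, "transient_amp", "must be nonnegative")
  check_that(transient_latency_ms >= 0, "transient_latency_ms", "must be nonnegative")
  check_that(transient_decay_ms > 0, "transient_decay_ms", "must be positive")
  check_that(attention_delta >= 0, "attention_delta", "must be nonnegative")
  check_that(miss_delta_scale >= 0, "miss_delta_scale", "must be nonnegative")
  check_that(suppression_depth >= 0 && suppression_depth <= 1,
             "suppression_depth", "must be in [0, 1]")
  check_that(suppression_latency_ms >= 0, "suppression_latency_ms", "must be nonnegative")
  check_that(suppression_duration_ms >= 0, "suppression_duration_ms", "must be nonnegative")
  check_that(premicrosaccade_bias >= 0, "premicrosaccade_bias", "must be nonnegative")
  check_that(rf_side %in% c("left", "right"), "rf_side", "must be 'left' or 'right'")
  structure(list(
    baseline_rate = baseline_rate,
    transient_amp = transient_amp,
    transient_latency_ms = transient_latency_ms,
    transient_decay_ms = transient_decay_ms,
    attention_delta = attention_delta,
    attention_onset_ms = attention_onset_ms,
    miss_delta_scale = miss_delta_scale,
    suppression_depth = suppression_depth,
    suppression_latency_ms = suppression_latency_ms,
    suppression_duration_ms = suppression_duration_ms,
    suppression_mode = suppression_mode,
    premicrosaccade_bias = premicrosaccade_bias,
    rf_side = rf_side
  ), class = "neuron_model")
}

#' Microsaccade detection parameters
#'
#' Parameters of the two-dimensional velocity-threshold detector: a relative
#' threshold of `lambda_rel` robust SDs of the velocity noise on each axis
#' (elliptical criterion), a minimum event duration, a merge rule for
#' suprathreshold runs separated by brief gaps (suppressing double detection
#' of dynamic overshoots), and an amplitude ceiling that stands in for the
#' manual screening of implausibly large events.
#'
#' @param lambda_rel Relative velocity threshold (default 4).
#' @param min_duration_ms Minimum event duration in ms (default 6).
#' @param merge_gap_ms Runs separated by less than this are merged
#'   (default 20).
#' @param velocity_window_samples Width of the moving-window velocity filter
#'   (odd, default 5).
#' @param max_amplitude_deg Detected events larger than this are discarded
#'   (default 2).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(lambda_rel = 4,
                             min_duration_ms = 6,
                             merge_gap_ms = 20,
                             velocity_window_samples = 5,
                             max_amplitude_deg = 2) {
  check_that(lambda_rel > 0, "lambda_rel", "must be positive")
  check_that(min_duration_ms > 0, "min_duration_ms", "must be positive")
  check_that(merge_gap_ms >= 0, "merge_gap_ms", "must be nonnegative")
  check_that(velocity_window_samples >= 3 && velocity_window_samples %% 2 == 1,
             "velocity_window_samples", "must be an odd integer >= 3")
  check_that(max_amplitude_deg > 0, "max_amplitude_deg", "must be positive")
  structure(list(
    lambda_rel = lambda_rel,
    min_duration_ms = min_duration_ms,
    merge_gap_ms = merge_gap_ms,
    velocity_window_samples = velocity_window_samples,
    max_amplitude_deg = max_amplitude_deg
  ), class = "detection_params")
}

#' Specification of the timing-matching control
#'
#' The analysis window (200-1000 ms after patch onset by default) is tiled
#' with `n_bins` non-overlapping bins. Microsaccade-aligned conditions are
#' counted per bin; the no-microsaccade condition counts trials with no
#' detected microsaccade within `exclusion_halfwidth_ms` of the bin center,
#' with the bin center standing in as the alignment time. All conditions are
#' then subsampled, without replacement, to the per-bin minimum.
#'
#' @param window_ms Two-vector analysis window, ms after patch onset.
#' @param n_bins Number of bins tiling the window (default 8, i.e. 100 ms
#'   bins for the default window).
#' @param exclusion_halfwidth_ms Half-width of the event-free window around
#'   each bin center for the no-microsaccade condition (default 200).
#' @param mode `"event"`: every microsaccade in a bin is a separate
#'   subsampling candidate; `"trial"`: one candidate per trial per bin (the
#'   trial's first qualifying event provides the alignment time).
#' @return An object of class `timing_match_spec`.
#' @export
timing_match_spec <- function(window_ms = c(200, 1000),
                              n_bins = 8,
                              exclusion_halfwidth_ms = 200,
                              mode = c("event", "trial")) {
  mode <- match.arg(mode)
  check_that(length(window_ms) == 2 && window_ms[2] > window_ms[1],
             "window_ms", "must be an increasing interval")
  check_that(n_bins >= 1, "n_bins", "must be >= 1")
  bin_width <- diff(window_ms) / n_bins
  check_that(exclusion_halfwidth_ms >= bin_width / 2,
             "exclusion_halfwidth_ms", "must be at least half a bin width")
  structure(list(
    window_ms = window_ms,
    n_bins = n_bins,
    bin_width_ms = bin_width,
    exclusion_halfwidth_ms = exclusion_halfwidth_ms,
    mode = mode
  ), class = "timing_match_spec")
}

#' Specification of the eye-position matching control
#'
#' Average eye position in the pre-microsaccadic window is histogrammed on a
#' square spatial grid; per spatial bin, all conditions are subsampled
#' without replacement to the joint minimum so that the matched sets share
#' identical pre-event eye-position distributions.
#'
#' @param bin_deg Spatial bin size in degrees (default 0.25).
#' @param before_window_ms Window used to average eye position, ms relative
#'   to microsaccade onset (default `c(-60, 0)`).
#' @return An object of class `position_match_spec`.
#' @export
position_match_spec <- function(bin_deg = 0.25,
                                before_window_ms = c(-60, 0)) {
  check_that(bin_deg > 0, "bin_deg", "must be positive")
  check_that(length(before_window_ms) == 2 &&
               before_window_ms[2] > before_window_ms[1],
             "before_window_ms", "must be an increasing interval")
  structure(list(
    bin_deg = bin_deg,
    before_window_ms = before_window_ms
  ), class = "position_match_spec")
}

#' Epoch specification for the time-course analysis
#'
#' Five 100-ms epochs spanning the delay period; trials are classified by the
#' microsaccades they contain within each epoch, and normalized firing rate
#' is measured in a window of `measure_ms` immediately following the epoch.
#'
#' @param epochs Two-column matrix of epoch start/end times (ms after patch
#'   onset). Defaults to 200-300, 350-450, 500-600, 650-750, 800-900.
#' @param measure_ms Length of the measurement window abutting each epoch's
#'   end (default 100).
#' @return An object of class `epoch_spec`.
#' @export
epoch_spec <- function(epochs = cbind(c(200, 350, 500, 650, 800),
                                      c(300, 450, 600, 750, 900)),
                       measure_ms = 100) {
  epochs <- as.matrix(epochs)
  check_that(ncol(epochs) == 2 && all(epochs[, 2] > epochs[, 1]),
             "epochs", "must be a two-column matrix of increasing intervals")
  if (nrow(epochs) > 1) {
    ord <- order(epochs[, 1])
    epochs <- epochs[ord, , drop = FALSE]
    check_that(all(epochs[-1, 1] >= epochs[-nrow(epochs), 2]),
               "epochs", "must be non-overlapping")
  }
  check_that(measure_ms > 0, "measure_ms", "must be positive")
  structure(list(epochs = epochs, measure_ms = measure_ms), class = "epoch_spec")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Covert attention task configuration\n")
  cat(sprintf("  %d blocks x %d trials, %d single-patch trials per transition\n",
              x$n_blocks, x$trials_per_block, x$single_patch_trials_per_transition))
  cat(sprintf("  cue flash %d ms at t = -%d ms; change in [%d, %d] ms; %d Hz sampling\n",
              x$cue_flash_ms, x$cue_to_patch_ms,
              x$change_window_ms[1], x$change_window_ms[2], x$sample_rate_hz))
  invisible(x)
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf(
    "Velocity-threshold detection: lambda = %g, min duration %g ms, merge gap %g ms\n",
    x$lambda_rel, x$min_duration_ms, x$merge_gap_ms))
  invisible(x)
}
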