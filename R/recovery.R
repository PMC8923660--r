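# Parameter recovery from simulated sessions: estimates of the generative
# attention increment and suppression depth computed from the spike data and
# the ground-truth event times, for validating the pipeline end to end.

#' Recover generative parameters from a simulated study
#'
#' Two estimators, both computed from raw spike counts and the ground-truth
#' microsaccade times (never from the stored parameter values):
#'
#' * `delta_recovered`: per unit, the delay-period firing-rate difference in
#'   spikes/s between cue-in-RF and cue-out-of-RF two-patch trials — the
#'   quantity the attention increment controls.
#' * `depth_recovered`: per unit, one minus the ratio of spike counts in the
#'   suppressed span after isolated true microsaccades
#'   (`supp_window`, default 20-80 ms after onset) to counts in a
#'   pre-microsaccadic reference span (`ref_window`, default -80 to -20 ms).
#'   Only events with no neighboring event within `isolation_ms` and onset
#'   at or after `min_onset_ms` (clear of the visual transient) are used.
#'
#' @param study An `sc_study` from [simulate_study()].
#' @param delay_window Delay period for the rate difference (ms).
#' @param supp_window,ref_window Windows relative to event onset (ms).
#' @param isolation_ms Minimum separation from neighboring events.
#' @param min_onset_ms Earliest usable event onset (ms after patch onset).
#' @return Data frame with one row per unit: `unit_id`, `delta_recovered`,
#'   `depth_recovered` (NA when a unit has no usable isolated events), and
#'   `n_isolated_events`.
#' @export
recover_generative_parameters <- function(study,
                                          delay_window = c(200, 1000),
                                          supp_window = c(20, 80),
                                          ref_window = c(-80, -20),
                                          isolation_ms = 200,
                                          min_onset_ms = 400) {
  span_s <- diff(delay_window) / 1000
  rows <- list()
  for (sid in names(study$sessions)) {
    s <- study$sessions[[sid]]
    tr <- s$trials
    two <- tr[tr$trial_type == "two_patch", ]
    gt <- s$ground_truth$events
    # isolated ground-truth events in the usable span
    iso <- do.call(rbind, lapply(split(gt, gt$trial_id), function(g) {
      if (nrow(g) == 0) return(NULL)
      sep <- vapply(seq_len(nrow(g)), function(i) {
        others <- g$onset_ms[-i]
        length(others) == 0 || min(abs(others - g$onset_ms[i])) >= isolation_ms
      }, logical(1))
      g[sep & g$onset_ms >= min_onset_ms &
          g$onset_ms < delay_window[2], , drop = FALSE]
    }))
    sp_by_unit <- split(s$spikes, s$spikes$unit_id)
    for (u in seq_len(nrow(s$units))) {
      uid <- s$units$unit_id[u]
      rf <- s$units$rf_side[u]
      sp <- sp_by_unit[[uid]]
      if (is.null(sp)) sp <- data.frame(trial_id = integer(0), t_ms = numeric(0))
      in_delay <- sp$t_ms >= delay_window[1] & sp$t_ms < delay_window[2]
      cnt <- table(factor(sp$trial_id[in_delay], levels = two$trial_id))
      rate <- as.numeric(cnt) / span_s
      delta <- mean(rate[two$cue_side == rf]) - mean(rate[two$cue_side != rf])
      c_supp <- 0
      c_ref <- 0
      if (!is.null(iso) && nrow(iso) > 0) {
        sp_t <- split(sp$t_ms, factor(sp$trial_id, levels = unique(iso$trial_id)))
        for (e in seq_len(nrow(iso))) {
          st <- sp_t[[as.character(iso$trial_id[e])]]
          if (is.null(st)) next
          rel <- st - iso$onset_ms[e]
          c_supp <- c_supp + sum(rel >= supp_window[1] & rel < supp_window[2])
          c_ref <- c_ref + sum(rel >= ref_window[1] & rel < ref_window[2])
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = uid,
        delta_recovered = delta,
        depth_recovered = if (c_ref > 0) 1 - c_supp / c_ref else NA_real_,
        n_isolated_events = if (is.null(iso)) 0L else nrow(iso))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Redraw every unit's spike train of a session from the current RNG stream,
# holding trials, eye traces, and true events fixed. Used for null
# calibration at fixed task structure.
redraw_spikes <- function(session) {
  rows <- list()
  for (i in seq_len(nrow(session$trials))) {
    tr <- session$trials[i, ]
    ev <- session$eye_traces[[as.character(tr$trial_id)]]$events
    for (u in seq_along(session$neurons)) {
      nm <- session$neurons[[u]]
      patch_in_rf <- if (tr$trial_type == "two_patch") TRUE else tr$cue_side == nm$rf_side
      cue_in_rf <- tr$trial_type == "two_patch" && tr$cue_side == nm$rf_side
      dscale <- if (identical(tr$outcome, "miss")) nm$miss_delta_scale else 1
      st <- draw_spikes(tr$t_start_ms, tr$t_end_ms, nm, patch_in_rf, cue_in_rf,
                        ev, side_angle(nm$rf_side), dscale)
      if (length(st) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = session$units$unit_id[u], trial_id = tr$trial_id, t_ms = st)
      }
    }
  }
  session$spikes <- do.call(rbind, rows)
  rownames(session$spikes) <- NULL
  session
}
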