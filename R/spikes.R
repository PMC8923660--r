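# Spike processing: binned counts, per-unit z-normalization, event-aligned
# rate matrices, and the responsiveness/modulation screen for unit inclusion.

#' Bin spike times into half-open bins
#'
#' @param times Numeric vector of spike times (ms).
#' @param edges Strictly increasing bin edges (ms); bins are `[a, b)`.
#' @return Integer vector of counts, length `length(edges) - 1`. Spikes
#'   outside `[edges[1], edges[n])` are not counted.
#' @export
bin_spikes <- function(times, edges) {
  if (any(!is.finite(times))) stop("non-finite spike times", call. = FALSE)
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  idx <- findInterval(times, edges, rightmost.closed = FALSE)
  idx <- idx[idx >= 1 & times < edges[length(edges)]]
  tabulate(idx, nbins = length(edges) - 1L)
}

# Bin a whole session's spikes on a common patch-onset-aligned grid.
# Returns an integer array unit x trial x bin.
bin_session <- function(session, edges) {
  units <- session$units$unit_id
  trials <- session$trials$trial_id
  nb <- length(edges) - 1L
  counts <- array(0L, dim = c(length(units), length(trials), nb),
                  dimnames = list(units, as.character(trials), NULL))
  sp <- session$spikes
  bin <- findInterval(sp$t_ms, edges, rightmost.closed = FALSE)
  keep <- bin >= 1 & sp$t_ms < edges[length(edges)]
  if (any(keep)) {
    ui <- match(sp$unit_id[keep], units)
    ti <- match(sp$trial_id[keep], trials)
    flat <- ui + (ti - 1L) * length(units) + (bin[keep] - 1L) * length(units) * length(trials)
    tab <- tabulate(flat, nbins = length(units) * length(trials) * nb)
    counts[] <- counts[] + tab
  }
  counts
}

#' Bin and z-normalize a session's spike counts around patch onset
#'
#' Spike counts are binned in non-overlapping windows (20 ms by default)
#' aligned on color-patch onset, and each unit's counts are z-scored: mean
#' subtracted and divided by the population SD, both computed from that
#' unit's binned counts pooled across all trials, conditions, and bins of
#' the normalization span. Units with zero SD are excluded and reported.
#'
#' @param session An `sc_session`.
#' @param span_ms Two-vector normalization/analysis span, ms relative to
#'   patch onset (default `c(-100, 1000)`).
#' @param bin_ms Bin width (default 20).
#' @return A list of class `norm_rates` with `z` (numeric array unit x trial
#'   x bin), `counts` (the raw counts), `edges`, `unit_mean`, `unit_sd`
#'   (the stored normalization constants), `alignment = "patch_onset"`,
#'   `norm_span`, `excluded_units`, and the trial/unit tables for
#'   convenience.
#' @export
zscore_normalize <- function(session, span_ms = c(-100, 1000), bin_ms = 20) {
  edges <- seq(span_ms[1], span_ms[2], by = bin_ms)
  if (length(edges) < 3) stop("normalization span must contain >= 2 bins", call. = FALSE)
  counts <- bin_session(session, edges)
  nu <- dim(counts)[1]
  unit_mean <- numeric(nu)
  unit_sd <- numeric(nu)
  excluded <- character(0)
  z <- array(NA_real_, dim = dim(counts), dimnames = dimnames(counts))
  for (u in seq_len(nu)) {
    v <- as.numeric(counts[u, , ])
    unit_mean[u] <- mean(v)
    unit_sd[u] <- sd_pop(v)
    if (unit_sd[u] <= 0) {
      excluded <- c(excluded, dimnames(counts)[[1]][u])
    } else {
      z[u, , ] <- (counts[u, , ] - unit_mean[u]) / unit_sd[u]
    }
  }
  names(unit_mean) <- names(unit_sd) <- dimnames(counts)[[1]]
  structure(list(z = z, counts = counts, edges = edges,
                 unit_mean = unit_mean, unit_sd = unit_sd,
                 alignment = "patch_onset", norm_span = span_ms,
                 bin_ms = bin_ms,
                 excluded_units = excluded,
                 session_id = session$session_id,
                 trials = session$trials, units = session$units),
            class = "norm_rates")
}

#' Align spike counts to a set of events
#'
#' Re-bins each unit's spikes in half-open bins relative to each event's
#' alignment time and z-scores the counts with the unit's stored
#' normalization constants, so that event-aligned rates are on the same
#' normalized scale as the patch-aligned matrix. A companion average
#' eye-speed trace over the same events is returned for verification of the
#' event timing. Events whose window is not fully covered by the trial's
#' recorded span are dropped and counted.
#'
#' @param session An `sc_session`.
#' @param events Data frame with columns `trial_id` and `t0_ms` (alignment
#'   times, ms relative to patch onset).
#' @param norm A `norm_rates` for the same session (normalization source).
#' @param window Two-vector window relative to the alignment time
#'   (default `c(-200, 200)`).
#' @param bin_ms Bin width (default `norm$bin_ms`).
#' @return A list of class `aligned_rates` with `z` (unit x event x bin),
#'   `edges` (bin edges relative to the event), `events` (the retained
#'   rows), `n_dropped`, `eye_speed` (list with `t_ms`, `mean_dps`), and
#'   normalization provenance.
#' @export
align_to_events <- function(session, events, norm, window = c(-200, 200),
                            bin_ms = NULL) {
  stopifnot(inherits(norm, "norm_rates"))
  if (is.null(bin_ms)) bin_ms <- norm$bin_ms
  rel_edges <- seq(window[1], window[2], by = bin_ms)
  nb <- length(rel_edges) - 1L
  tr <- session$trials
  span_lo <- tr$t_start_ms[match(events$trial_id, tr$trial_id)]
  span_hi <- tr$t_end_ms[match(events$trial_id, tr$trial_id)]
  ok <- events$t0_ms + window[1] >= span_lo & events$t0_ms + window[2] <= span_hi
  n_dropped <- sum(!ok)
  events <- events[ok, , drop = FALSE]
  units <- session$units$unit_id
  z <- array(NA_real_, dim = c(length(units), nrow(events), nb),
             dimnames = list(units, NULL, NULL))
  sp <- split(session$spikes[, c("trial_id", "t_ms")], session$spikes$unit_id)
  for (u in seq_along(units)) {
    su <- sp[[units[u]]]
    if (is.null(su)) su <- data.frame(trial_id = integer(0), t_ms = numeric(0))
    by_trial <- split(su$t_ms, su$trial_id)
    for (e in seq_len(nrow(events))) {
      st <- by_trial[[as.character(events$trial_id[e])]]
      if (is.null(st)) st <- numeric(0)
      cts <- bin_spikes(st - events$t0_ms[e], rel_edges)
      z[u, e, ] <- (cts - norm$unit_mean[units[u]]) / norm$unit_sd[units[u]]
    }
  }
  # Companion eye-speed average at the native sampling resolution.
  eye_speed <- NULL
  if (nrow(events) > 0) {
    dt <- session$eye_traces[[1]]$dt
    rel_t <- seq(window[1], window[2] - dt, by = dt)
    acc <- matrix(0, nrow = nrow(events), ncol = length(rel_t))
    for (e in seq_len(nrow(events))) {
      trace <- session$eye_traces[[as.character(events$trial_id[e])]]
      vel <- compute_velocity(trace)
      sp_tr <- sqrt(vel$vx^2 + vel$vy^2)
      idx <- round((events$t0_ms[e] + rel_t - trace$t0) / dt) + 1L
      acc[e, ] <- sp_tr[idx]
    }
    eye_speed <- list(t_ms = rel_t, mean_dps = colMeans(acc, na.rm = TRUE))
  }
  structure(list(z = z, edges = rel_edges, events = events,
                 n_dropped = n_dropped, eye_speed = eye_speed,
                 alignment = "event_onset", bin_ms = bin_ms,
                 norm_provenance = list(span = norm$norm_span,
                                        session_id = norm$session_id)),
            class = "aligned_rates")
}

#' Mean normalized rate over a time window
#'
#' Averages z-scored counts over the bins lying fully inside the half-open
#' window `[w1, w2)`; partially covered bins are excluded.
#'
#' @param x A `norm_rates` or `aligned_rates`.
#' @param window Two-vector window in the object's time reference.
#' @return Numeric matrix, unit x trial (or unit x event).
#' @export
window_mean <- function(x, window) {
  edges <- x$edges
  sel <- which(edges[-length(edges)] >= window[1] & edges[-1] <= window[2])
  if (length(sel) == 0) stop("window covers no complete bin", call. = FALSE)
  apply(x$z[, , sel, drop = FALSE], c(1, 2), mean)
}

#' Screen units for visual responsiveness and attention modulation
#'
#' A unit is visually responsive if its per-trial spike counts 50-150 ms
#' after patch onset exceed the -100 to 0 ms baseline (two-sided Wilcoxon
#' rank-sum test, p < 0.01) on both two-patch trials and single-patch trials
#' with the patch in the unit's response field. It is attention-modulated if
#' its mean delay-period rate (200-1000 ms, two-patch trials) is higher with
#' the cue in the RF than out of the RF (two-sided rank-sum test p < 0.01
#' together with the required sign). Included units satisfy both.
#'
#' @param session An `sc_session`.
#' @param alpha Significance level of each screen (default 0.01).
#' @param visual_window,baseline_window,delay_window Analysis windows (ms).
#' @return Data frame with one row per unit: p-values, flags
#'   `visually_responsive`, `attention_modulated`, `included`, and an
#'   `unscreenable` flag when a trial class is missing.
#' @export
screen_units <- function(session, alpha = 0.01,
                         visual_window = c(50, 150),
                         baseline_window = c(-100, 0),
                         delay_window = c(200, 1000)) {
  tr <- session$trials
  counts_in <- function(unit_id, trial_ids, window) {
    sp <- session$spikes
    sel <- sp$unit_id == unit_id & sp$trial_id %in% trial_ids &
      sp$t_ms >= window[1] & sp$t_ms < window[2]
    tab <- table(factor(sp$trial_id[sel], levels = trial_ids))
    as.numeric(tab)
  }
  two_patch <- tr$trial_id[tr$trial_type == "two_patch"]
  res <- lapply(seq_len(nrow(session$units)), function(u) {
    uid <- session$units$unit_id[u]
    rf <- session$units$rf_side[u]
    single_rf <- tr$trial_id[tr$trial_type == "single_patch" & tr$cue_side == rf]
    cue_in <- tr$trial_id[tr$trial_type == "two_patch" & tr$cue_side == rf]
    cue_out <- setdiff(two_patch, cue_in)
    if (length(two_patch) == 0 || length(single_rf) == 0 ||
        length(cue_in) == 0 || length(cue_out) == 0) {
      return(data.frame(unit_id = uid, p_visual_two_patch = NA_real_,
                        p_visual_single_patch = NA_real_, p_attention = NA_real_,
                        visually_responsive = NA, attention_modulated = NA,
                        included = NA, unscreenable = TRUE))
    }
    p_two <- safe_rank_p(counts_in(uid, two_patch, visual_window),
                         counts_in(uid, two_patch, baseline_window))
    p_single <- safe_rank_p(counts_in(uid, single_rf, visual_window),
                            counts_in(uid, single_rf, baseline_window))
    rate_in <- counts_in(uid, cue_in, delay_window)
    rate_out <- counts_in(uid, cue_out, delay_window)
    p_attn <- safe_rank_p(rate_in, rate_out)
    vis <- p_two < alpha && p_single < alpha
    attn <- p_attn < alpha && mean(rate_in) > mean(rate_out)
    data.frame(unit_id = uid, p_visual_two_patch = p_two,
               p_visual_single_patch = p_single, p_attention = p_attn,
               visually_responsive = vis, attention_modulated = attn,
               included = vis && attn, unscreenable = FALSE)
  })
  do.call(rbind, res)
}

# Two-sided rank-sum p-value that degrades gracefully on all-tied data.
safe_rank_p <- function(x, y) {
  if (length(unique(c(x, y))) == 1) return(1)
  suppressWarnings(stats::wilcox.test(x, y)$p.value)
}
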