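# Microsaccade detection: moving-window velocity estimation, robust
# (median-based) noise thresholds, the elliptical suprathreshold criterion,
# and cue-relative classification of the detected events.

#' Compute eye velocity with a moving-window derivative
#'
#' Applies the classic window differentiation filter; for the default
#' five-sample window at sampling interval `dt`,
#' `v_n = (x[n+2] + x[n+1] - x[n-1] - x[n-2]) / (6 dt)`. The
#' `(w - 1) / 2` boundary samples at each end are marked invalid (`NA`).
#'
#' @param trace An `eye_trace` (see [simulate_eye_trace()]), or any list with
#'   fields `x`, `y`, `dt` (ms) and `t0`. If a `t` field of explicit
#'   timestamps is present it must be uniform.
#' @param params A [detection_params()]; `velocity_window_samples` sets the
#'   window width.
#' @return A list of class `velocity_trace` with `vx`, `vy` (deg/s, `NA` at
#'   invalid boundary samples), `valid` (logical), and the source `t0`, `dt`.
#' @export
compute_velocity <- function(trace, params = detection_params()) {
  x <- trace$x
  y <- trace$y
  n <- length(x)
  w <- params$velocity_window_samples
  if (n < w) stop("trace shorter than the velocity window", call. = FALSE)
  if (!is.null(trace$t)) {
    dts <- diff(trace$t)
    if (any(abs(dts - dts[1]) > 1e-9)) {
      stop("non-uniform timestamps in eye trace", call. = FALSE)
    }
  }
  dt_s <- trace$dt / 1000
  m <- (w - 1L) %/% 2L
  denom <- 2 * sum(seq_len(m)) * dt_s
  vx <- rep(NA_real_, n)
  vy <- rep(NA_real_, n)
  core <- (m + 1L):(n - m)
  sx <- numeric(length(core))
  sy <- numeric(length(core))
  for (k in seq_len(m)) {
    sx <- sx + x[core + k] - x[core - k]
    sy <- sy + y[core + k] - y[core - k]
  }
  vx[core] <- sx / denom
  vy[core] <- sy / denom
  valid <- !is.na(vx)
  structure(list(vx = vx, vy = vy, valid = valid, t0 = trace$t0, dt = trace$dt),
            class = "velocity_trace")
}

#' Estimate per-axis velocity thresholds
#'
#' The noise scale on each axis is the median-based robust SD
#' `sigma = sqrt(median(v^2) - median(v)^2)` over valid samples; the
#' detection threshold is `eta = lambda_rel * sigma`.
#'
#' @param vel A `velocity_trace` from [compute_velocity()].
#' @param params A [detection_params()].
#' @param context Optional label (e.g. a trial id) used in error messages.
#' @return Named numeric vector `c(eta_x, eta_y)` in deg/s.
#' @export
estimate_thresholds <- function(vel, params = detection_params(), context = NULL) {
  vx <- vel$vx[vel$valid]
  vy <- vel$vy[vel$valid]
  if (length(vx) < 10) stop("fewer than 10 valid velocity samples", call. = FALSE)
  sx <- sqrt(stats::median(vx^2) - stats::median(vx)^2)
  sy <- sqrt(stats::median(vy^2) - stats::median(vy)^2)
  if (!is.finite(sx) || !is.finite(sy) || sx <= 0 || sy <= 0) {
    where <- if (is.null(context)) "" else sprintf(" (%s)", context)
    stop(sprintf("degenerate velocity trace%s: zero robust SD", where),
         call. = FALSE)
  }
  c(eta_x = params$lambda_rel * sx, eta_y = params$lambda_rel * sy)
}

#' Classify a cue-relative direction as toward or away
#'
#' Directions within a 180-degree window centered on the cue are "toward".
#' The boundary is split deterministically so each label covers exactly half
#' the circle: -90 is toward, +90 is away.
#'
#' @param rel_direction_deg Numeric vector of cue-relative directions in
#'   `(-180, 180]` degrees.
#' @return Character vector of `"toward"` / `"away"`.
#' @export
classify_direction <- function(rel_direction_deg) {
  stopifnot(all(rel_direction_deg > -180 - 1e-9 & rel_direction_deg <= 180 + 1e-9))
  ifelse(abs(rel_direction_deg) < 90 | rel_direction_deg == -90, "toward", "away")
}

# Merge suprathreshold runs separated by fewer than gap_samples subthreshold
# samples. `runs` is a two-column matrix of (start, end) sample indices.
merge_runs <- function(runs, gap_samples) {
  if (nrow(runs) < 2) return(runs)
  out <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    if (runs[i, 1] - out[nrow(out), 2] - 1 < gap_samples) {
      out[nrow(out), 2] <- runs[i, 2]
    } else {
      out <- rbind(out, runs[i, , drop = FALSE])
    }
  }
  out
}

#' Detect microsaccades in one eye trace
#'
#' Samples satisfying the elliptical criterion
#' `(vx / eta_x)^2 + (vy / eta_y)^2 > 1` are grouped into maximal runs; runs
#' shorter than `min_duration_ms` are rejected, then qualifying runs
#' separated by less than `merge_gap_ms` are merged (suppressing double
#' detection of dynamic overshoots; the duration filter is applied first so
#' that scattered brief noise crossings cannot accumulate into events), and
#' events larger than `max_amplitude_deg` are discarded. Onset
#' is the time of the first suprathreshold sample; offset is one sample past
#' the last, so `offset - onset` is the event duration.
#'
#' @param trace An `eye_trace`.
#' @param params A [detection_params()].
#' @param cue_direction_deg Azimuth of the cued location (degrees); if `NA`,
#'   cue-relative fields are left `NA`.
#' @param trial_id Optional id copied into the output.
#' @return Data frame with one row per detected microsaccade: `trial_id`,
#'   `onset_ms`, `offset_ms`, `dx_deg`, `dy_deg`, `amplitude_deg`,
#'   `peak_speed_dps`, `direction_deg`, `rel_direction_deg`, `label`.
#' @export
detect_microsaccades <- function(trace, params = detection_params(),
                                 cue_direction_deg = NA, trial_id = NA) {
  vel <- compute_velocity(trace, params)
  eta <- estimate_thresholds(vel, params, context = trial_id)
  crit <- (vel$vx / eta[1])^2 + (vel$vy / eta[2])^2 > 1
  crit[is.na(crit)] <- FALSE
  empty <- data.frame(
    trial_id = if (is.na(trial_id)) integer(0) else integer(0),
    onset_ms = numeric(0), offset_ms = numeric(0), dx_deg = numeric(0),
    dy_deg = numeric(0), amplitude_deg = numeric(0), peak_speed_dps = numeric(0),
    direction_deg = numeric(0), rel_direction_deg = numeric(0),
    label = character(0))
  if (!any(crit)) return(empty)
  r <- rle(crit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  dur <- (runs[, 2] - runs[, 1] + 1) * trace$dt
  runs <- runs[dur >= params$min_duration_ms, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)
  runs <- merge_runs(runs, gap_samples = round(params$merge_gap_ms / trace$dt))
  t <- trace$t0 + (seq_along(trace$x) - 1) * trace$dt
  speed <- sqrt(vel$vx^2 + vel$vy^2)
  rows <- lapply(seq_len(nrow(runs)), function(i) {
    a <- runs[i, 1]; b <- runs[i, 2]
    dx <- trace$x[b] - trace$x[a]
    dy <- trace$y[b] - trace$y[a]
    data.frame(trial_id = trial_id,
               onset_ms = t[a],
               offset_ms = t[b] + trace$dt,
               dx_deg = dx, dy_deg = dy,
               amplitude_deg = sqrt(dx^2 + dy^2),
               peak_speed_dps = max(speed[a:b], na.rm = TRUE),
               direction_deg = atan2(dy, dx) * 180 / pi,
               rel_direction_deg = NA_real_, label = NA_character_)
  })
  out <- do.call(rbind, rows)
  out <- out[out$amplitude_deg <= params$max_amplitude_deg, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  out$direction_deg <- wrap_angle(out$direction_deg)
  if (!is.na(cue_direction_deg)) {
    out$rel_direction_deg <- wrap_angle(out$direction_deg - cue_direction_deg)
    out$label <- classify_direction(out$rel_direction_deg)
  }
  out[order(out$onset_ms), , drop = FALSE]
}

#' Detect microsaccades in every trial of a session
#'
#' Runs [detect_microsaccades()] on each trial's eye trace with the trial's
#' cue direction (for single-patch trials, the patch location).
#'
#' @param session An `sc_session`.
#' @param params A [detection_params()].
#' @return Data frame of detected events across trials with a `session_id`
#'   column prepended.
#' @export
detect_session <- function(session, params = detection_params()) {
  out <- lapply(seq_len(nrow(session$trials)), function(i) {
    tr <- session$trials[i, ]
    detect_microsaccades(session$eye_traces[[as.character(tr$trial_id)]], params,
                         cue_direction_deg = side_angle(tr$cue_side),
                         trial_id = tr$trial_id)
  })
  out <- do.call(rbind, out)
  if (nrow(out) > 0) out <- cbind(session_id = session$session_id, out)
  rownames(out) <- NULL
  out
}

#' Time course of microsaccade probability by direction label
#'
#' For each time bin and label, the fraction of trials containing at least
#' one microsaccade onset of that label in the bin, averaged within each
#' session and then across sessions (error bars are the SEM across
#' sessions).
#'
#' @param sessions A list of `sc_session` objects (or an `sc_study`).
#' @param events Detected events for those sessions, as returned by
#'   [detect_session()] (row-bound), with `session_id`, `trial_id`,
#'   `onset_ms` and `label`.
#' @param bin_ms Bin width in ms (default 20).
#' @param window Two-vector analysis window, ms relative to patch onset.
#' @param trial_type Which trials enter the denominator (default two-patch).
#' @return Data frame with columns `t_mid_ms`, `label`, `p`, `sem`.
#' @export
microsaccade_probability <- function(sessions, events, bin_ms = 20,
                                     window = c(-500, 1000),
                                     trial_type = "two_patch") {
  if (inherits(sessions, "sc_study")) sessions <- sessions$sessions
  if (inherits(sessions, "sc_session")) sessions <- list(sessions)
  if (length(sessions) == 0) stop("no sessions supplied", call. = FALSE)
  edges <- seq(window[1], window[2], by = bin_ms)
  mids <- edges[-length(edges)] + bin_ms / 2
  labels <- c("toward", "away")
  per_session <- lapply(sessions, function(s) {
    tr <- s$trials[s$trials$trial_type == trial_type, ]
    ev <- events[events$session_id == s$session_id &
                   events$trial_id %in% tr$trial_id &
                   !is.na(events$label), , drop = FALSE]
    sapply(labels, function(lb) {
      e <- ev[ev$label == lb, , drop = FALSE]
      bin <- findInterval(e$onset_ms, edges, rightmost.closed = FALSE)
      ok <- bin >= 1 & bin < length(edges)
      # fraction of trials with >= 1 onset in each bin
      counts <- table(factor(bin[ok], levels = seq_along(mids)),
                      factor(e$trial_id[ok], levels = tr$trial_id))
      rowMeans(counts > 0)
    })
  })
  arr <- simplify2array(per_session)  # bin x label x session
  if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1))
  out <- expand.grid(t_mid_ms = mids, label = labels, stringsAsFactors = FALSE)
  out$p <- as.vector(apply(arr, c(1, 2), mean))
  out$sem <- as.vector(apply(arr, c(1, 2), function(v) {
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  }))
  out
}

#' Directional histogram of microsaccades in a window
#'
#' Counts events by cue-relative direction bin for onsets inside the window
#' (a polar histogram when plotted), together with the overall proportions
#' of toward and away events.
#'
#' @param events Detected events with `onset_ms`, `rel_direction_deg`,
#'   `label`.
#' @param window Two-vector window, ms after patch onset (default the
#'   delay period, 200-1000).
#' @param n_bins Number of direction bins tiling `(-180, 180]` (default 12).
#' @return A list with `breaks`, `counts`, `proportion_toward`,
#'   `proportion_away`, and `n`. With no events in the window the counts are
#'   zero and proportions `NA` (flagged by `empty = TRUE`).
#' @export
direction_histogram <- function(events, window = c(200, 1000), n_bins = 12) {
  ev <- events[!is.na(events$rel_direction_deg) &
                 events$onset_ms >= window[1] & events$onset_ms < window[2], ,
               drop = FALSE]
  breaks <- seq(-180, 180, length.out = n_bins + 1)
  if (nrow(ev) == 0) {
    return(list(breaks = breaks, counts = rep(0L, n_bins),
                proportion_toward = NA_real_, proportion_away = NA_real_,
                n = 0L, empty = TRUE))
  }
  # (-180, 180] binning: map -180-boundary values onto the first bin edge.
  idx <- findInterval(ev$rel_direction_deg, breaks, left.open = TRUE,
                      rightmost.closed = FALSE)
  idx[idx == 0] <- 1L
  counts <- tabulate(idx, nbins = n_bins)
  list(breaks = breaks, counts = counts,
       proportion_toward = mean(ev$label == "toward"),
       proportion_away = mean(ev$label == "away"),
       n = nrow(ev), empty = FALSE)
}
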