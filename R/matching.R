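# Resampling controls: timing-matched subsampling of microsaccade-aligned
# data (with a timing-matched no-microsaccade condition) and 2D eye-position
# distribution matching. Both subsample, without replacement, every
# condition down to the per-bin minimum so that the matched sets share the
# bin-count distribution exactly.

# Core subsampler: `candidates` is a named list (one element per condition)
# of data frames with at least a `bin` column; every condition is subsampled
# to the per-bin minimum count, without replacement, with a single seeded
# RNG consumed in condition-then-bin order.
match_by_bins <- function(candidates, n_bins, seed) {
  conds <- names(candidates)
  pre <- sapply(candidates, function(df) {
    tabulate(df$bin, nbins = n_bins)
  })
  pre <- matrix(pre, nrow = n_bins, dimnames = list(NULL, conds))
  target <- apply(pre, 1, min)
  selected <- withr::with_seed(seed, {
    lapply(conds, function(cn) {
      df <- candidates[[cn]]
      keep <- integer(0)
      for (b in seq_len(n_bins)) {
        idx <- which(df$bin == b)
        if (target[b] > 0) {
          keep <- c(keep, idx[sample.int(length(idx), target[b])])
        }
      }
      df[sort(keep), , drop = FALSE]
    })
  })
  names(selected) <- conds
  post <- sapply(selected, function(df) tabulate(df$bin, nbins = n_bins))
  post <- matrix(post, nrow = n_bins, dimnames = list(NULL, conds))
  structure(list(conditions = selected, pre_counts = pre, post_counts = post,
                 seed = seed, n_bins = n_bins),
            class = "matched_set")
}

# Temporal bin index of event onsets for a timing-match spec (0 = outside).
timing_bin <- function(onset_ms, spec) {
  edges <- seq(spec$window_ms[1], spec$window_ms[2], length.out = spec$n_bins + 1)
  idx <- findInterval(onset_ms, edges, rightmost.closed = FALSE)
  idx[onset_ms >= spec$window_ms[2]] <- 0L
  idx
}

# Bin centers of a timing-match spec.
timing_bin_centers <- function(spec) {
  spec$window_ms[1] + (seq_len(spec$n_bins) - 0.5) * spec$bin_width_ms
}

#' Timing-matched subsampling of microsaccade-aligned conditions
#'
#' Tiles the analysis window with temporal bins and counts, for every
#' condition, the alignment candidates per bin: microsaccades toward/away
#' from the cue (per cue side) assigned to the bin containing their onset,
#' and, for the no-microsaccade condition, trials with no detected
#' microsaccade within `spec$exclusion_halfwidth_ms` of the bin center (the
#' bin center stands in as the alignment time). Every condition is then
#' subsampled without replacement to the per-bin minimum, so the temporal
#' distributions of analyzed events are identical across conditions. A bin
#' whose minimum is zero contributes no selections.
#'
#' @param session An `sc_session`.
#' @param events Detected microsaccades for the session
#'   ([detect_session()] output).
#' @param spec A [timing_match_spec()].
#' @param seed Integer seed for the subsampling RNG.
#' @param scheme `"cue"`: conditions are microsaccade class x cue side on
#'   two-patch trials (the main peri-microsaccadic analysis); `"rf"`:
#'   conditions are microsaccade class relative to a response field on
#'   single-patch trials with the patch opposite that RF (the motor
#'   control).
#' @param rf_side Required for `scheme = "rf"`.
#' @return A `matched_set`: per-condition data frames (`trial_id`, `t0_ms`,
#'   `bin`, `label`, `cue_side`), pre/post per-bin counts, and the seed.
#'   Condition names are `label.side` for the cue scheme and plain labels
#'   for the RF scheme.
#' @export
timing_match <- function(session, events, spec = timing_match_spec(), seed = 1,
                         scheme = c("cue", "rf"), rf_side = NULL) {
  scheme <- match.arg(scheme)
  tr <- session$trials
  centers <- timing_bin_centers(spec)
  all_onsets <- split(events$onset_ms, events$trial_id)

  no_ms_candidates <- function(trial_ids) {
    rows <- list()
    for (b in seq_len(spec$n_bins)) {
      lo <- centers[b] - spec$exclusion_halfwidth_ms
      hi <- centers[b] + spec$exclusion_halfwidth_ms
      free <- vapply(trial_ids, function(id) {
        on <- all_onsets[[as.character(id)]]
        is.null(on) || !any(on >= lo & on < hi)
      }, logical(1))
      if (any(free)) {
        rows[[b]] <- data.frame(trial_id = trial_ids[free], t0_ms = centers[b],
                                bin = b)
      }
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- data.frame(trial_id = integer(0), t0_ms = numeric(0),
                                        bin = integer(0))
    out
  }

  ms_candidates <- function(ev) {
    bin <- timing_bin(ev$onset_ms, spec)
    ev <- ev[bin >= 1, , drop = FALSE]
    bin <- bin[bin >= 1]
    out <- data.frame(trial_id = ev$trial_id, t0_ms = ev$onset_ms, bin = bin)
    if (spec$mode == "trial" && nrow(out) > 0) {
      out <- out[order(out$trial_id, out$bin, out$t0_ms), , drop = FALSE]
      out <- out[!duplicated(out[, c("trial_id", "bin")]), , drop = FALSE]
    }
    out
  }

  candidates <- list()
  if (scheme == "cue") {
    for (side in c("left", "right")) {
      ids <- tr$trial_id[tr$trial_type == "two_patch" & tr$cue_side == side]
      for (lb in c("toward", "away")) {
        ev <- events[events$trial_id %in% ids & events$label == lb, , drop = FALSE]
        cand <- ms_candidates(ev)
        cand$label <- if (nrow(cand)) lb else character(0)
        cand$cue_side <- if (nrow(cand)) side else character(0)
        candidates[[paste(lb, side, sep = ".")]] <- cand
      }
      cand <- no_ms_candidates(ids)
      cand$label <- if (nrow(cand)) "none" else character(0)
      cand$cue_side <- if (nrow(cand)) side else character(0)
      candidates[[paste("none", side, sep = ".")]] <- cand
    }
  } else {
    if (is.null(rf_side)) stop("rf_side is required for scheme = 'rf'", call. = FALSE)
    rf_dir <- side_angle(rf_side)
    ids <- tr$trial_id[tr$trial_type == "single_patch" & tr$cue_side != rf_side]
    if (length(ids) == 0) stop("no single-patch trials opposite the RF", call. = FALSE)
    ev <- events[events$trial_id %in% ids, , drop = FALSE]
    rel_rf <- wrap_angle(ev$direction_deg - rf_dir)
    lab_rf <- classify_direction(rel_rf)
    for (lb in c("toward", "away")) {
      cand <- ms_candidates(ev[lab_rf == lb, , drop = FALSE])
      cand$label <- if (nrow(cand)) paste0(lb, "_rf") else character(0)
      cand$cue_side <- NA_character_
      candidates[[paste0(lb, "_rf")]] <- cand
    }
    cand <- no_ms_candidates(ids)
    cand$label <- if (nrow(cand)) "none" else character(0)
    cand$cue_side <- NA_character_
    candidates[["none"]] <- cand
  }
  out <- match_by_bins(candidates, spec$n_bins, seed)
  out$spec <- spec
  out$scheme <- scheme
  out
}

# Mean eye position over the pre-event window, per event row.
event_positions <- function(session, events, window) {
  xs <- numeric(nrow(events))
  ys <- numeric(nrow(events))
  for (e in seq_len(nrow(events))) {
    trace <- session$eye_traces[[as.character(events$trial_id[e])]]
    t <- trace_times(trace)
    idx <- t >= events$t0_ms[e] + window[1] & t < events$t0_ms[e] + window[2]
    xs[e] <- mean(trace$x[idx])
    ys[e] <- mean(trace$y[idx])
  }
  cbind(x = xs, y = ys)
}

#' Match 2D eye-position distributions across conditions
#'
#' Computes, per condition, the 2D histogram of average eye position in the
#' pre-event window on a square spatial grid, then subsamples every
#' condition without replacement to the per-spatial-bin minimum, so the
#' matched sets share the same pre-event eye-position distribution exactly.
#'
#' @param session An `sc_session`.
#' @param events_by_condition Named list of data frames with `trial_id` and
#'   `t0_ms` (e.g. microsaccade onsets split by direction and cue side).
#' @param spec A [position_match_spec()].
#' @param seed Integer seed.
#' @return A `matched_set` whose `bin` column indexes occupied spatial
#'   cells; `bin_key` carries the `x,y` cell labels and `positions` the
#'   per-event average positions.
#' @export
eye_position_match <- function(session, events_by_condition,
                               spec = position_match_spec(), seed = 1) {
  conds <- names(events_by_condition)
  keyed <- lapply(conds, function(cn) {
    ev <- events_by_condition[[cn]]
    pos <- event_positions(session, ev, spec$before_window_ms)
    key <- paste(floor(pos[, "x"] / spec$bin_deg),
                 floor(pos[, "y"] / spec$bin_deg), sep = ",")
    cbind(ev, data.frame(pos_x = pos[, "x"], pos_y = pos[, "y"], bin_key = key))
  })
  names(keyed) <- conds
  keys <- sort(unique(unlist(lapply(keyed, function(df) df$bin_key))))
  candidates <- lapply(keyed, function(df) {
    df$bin <- match(df$bin_key, keys)
    df
  })
  out <- match_by_bins(candidates, n_bins = length(keys), seed = seed)
  out$spec <- spec
  out$bin_key <- keys
  out$scheme <- "eye_position"
  out
}

#' @export
print.matched_set <- function(x, ...) {
  cat(sprintf("Matched set (%s): %d conditions, %d bins, %d selected per condition\n",
              if (is.null(x$scheme)) "generic" else x$scheme,
              length(x$conditions), x$n_bins, sum(x$post_counts[, 1])))
  invisible(x)
}
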