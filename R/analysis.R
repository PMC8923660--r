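# Analysis surfaces: delay-period modulation by behavioral outcome,
# microsaccade-conditioned behavior, the epoch time-course analysis, the
# peri-microsaccadic before/after analysis on timing-matched data, the
# single-patch motor control, and the eye-position-matched control.

#' Z-normalize every session of a study
#'
#' @param study An `sc_study`.
#' @param ... Passed to [zscore_normalize()].
#' @return Named list of `norm_rates`, one per session.
#' @export
study_norms <- function(study, ...) {
  lapply(study$sessions, zscore_normalize, ...)
}

#' Detect microsaccades in every session of a study
#'
#' @param study An `sc_study`.
#' @param params A [detection_params()].
#' @return Row-bound data frame of detected events across sessions.
#' @export
study_events <- function(study, params = detection_params()) {
  do.call(rbind, c(lapply(study$sessions, detect_session, params = params),
                   make.row.names = FALSE))
}

# Keep only units that contribute every cell of a design, so the factorial
# fit stays balanced; report how many were dropped.
complete_units_only <- function(cells, factors) {
  cell <- interaction(cells[factors], drop = FALSE)
  n_cells <- nlevels(cell)
  per_unit <- table(cells$unit_id)
  keep <- names(per_unit)[per_unit == n_cells]
  out <- cells[cells$unit_id %in% keep, , drop = FALSE]
  attr(out, "n_dropped_units") <- length(per_unit) - length(keep)
  out
}

#' Delay-period attention modulation split by behavioral outcome
#'
#' For each unit, the attention-related modulation (mean normalized
#' delay-period rate with cue in the RF minus cue out of the RF) is computed
#' separately on hit and on miss trials; the two are compared across units
#' with a paired two-sided Wilcoxon signed-rank test. Units lacking an
#' outcome class in either cue condition are excluded and counted.
#'
#' @param study An `sc_study`.
#' @param norms Output of [study_norms()].
#' @param delay_window Delay period, ms after patch onset (default 200-1000).
#' @return List with `deltas` (per-unit `delta_hit`, `delta_miss`), `test`
#'   (the signed-rank result), and `n_excluded_units`.
#' @export
modulation_by_outcome <- function(study, norms, delay_window = c(200, 1000)) {
  rows <- list()
  for (sid in names(study$sessions)) {
    s <- study$sessions[[sid]]
    dm <- window_mean(norms[[sid]], delay_window)  # unit x trial
    tr <- s$trials
    for (u in seq_len(nrow(s$units))) {
      rf <- s$units$rf_side[u]
      vals <- sapply(c("hit", "miss"), function(oc) {
        sel_in <- tr$trial_type == "two_patch" & tr$cue_side == rf &
          tr$outcome == oc & tr$change_site == "cue"
        sel_out <- tr$trial_type == "two_patch" & tr$cue_side != rf &
          tr$outcome == oc & tr$change_site == "cue"
        if (!any(sel_in) || !any(sel_out)) return(NA_real_)
        mean(dm[u, sel_in]) - mean(dm[u, sel_out])
      })
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = s$units$unit_id[u], monkey = s$monkey,
        delta_hit = vals["hit"], delta_miss = vals["miss"])
    }
  }
  deltas <- do.call(rbind, rows)
  rownames(deltas) <- NULL
  ok <- stats::complete.cases(deltas[, c("delta_hit", "delta_miss")])
  test <- rank_tests(deltas$delta_hit[ok], deltas$delta_miss[ok], paired = TRUE)
  list(deltas = deltas[ok, , drop = FALSE], test = test,
       n_excluded_units = sum(!ok))
}

#' Behavioral performance conditioned on peri-change microsaccades
#'
#' Cue-change trials are split into three classes by the detected
#' microsaccades in a window around the change onset (default +/-50 ms):
#' none, toward the cue, away from the cue (trials with both directions are
#' excluded and counted). Each class gets a hit rate with a 95%
#' Clopper-Pearson interval; classes are compared pairwise with chi-square
#' proportion tests on hit rates and two-sided rank-sum tests on the
#' reaction times of hits.
#'
#' @param study An `sc_study`.
#' @param events Detected events ([study_events()] output).
#' @param halfwidth_ms Half-width of the peri-change window (default 50).
#' @return List with `rates` (per class: k, n, rate, CI), `hit_rate_tests`,
#'   `rt_tests` (pairwise), and `n_mixed_excluded`.
#' @export
behavior_by_microsaccade <- function(study, events, halfwidth_ms = 50) {
  cls_rows <- list()
  for (sid in names(study$sessions)) {
    s <- study$sessions[[sid]]
    tr <- s$trials[s$trials$trial_type == "two_patch" &
                     s$trials$change_site == "cue", ]
    ev <- events[events$session_id == s$session_id, ]
    for (i in seq_len(nrow(tr))) {
      e <- ev[ev$trial_id == tr$trial_id[i] &
                abs(ev$onset_ms - tr$change_ms[i]) <= halfwidth_ms, ]
      cls <- if (nrow(e) == 0) "none"
      else if (all(e$label == "toward")) "toward"
      else if (all(e$label == "away")) "away"
      else "mixed"
      cls_rows[[length(cls_rows) + 1L]] <- data.frame(
        class = cls, hit = tr$outcome[i] == "hit", rt_ms = tr$rt_ms[i])
    }
  }
  d <- do.call(rbind, cls_rows)
  n_mixed <- sum(d$class == "mixed")
  d <- d[d$class != "mixed", , drop = FALSE]
  classes <- c("none", "toward", "away")
  rates <- lapply(classes, function(cl) {
    dd <- d[d$class == cl, ]
    if (nrow(dd) == 0) return(list(present = FALSE, k = 0, n = 0))
    ci <- binomial_ci(sum(dd$hit), nrow(dd))
    list(present = TRUE, k = sum(dd$hit), n = nrow(dd),
         rate = mean(dd$hit), ci_lower = ci[["lower"]], ci_upper = ci[["upper"]])
  })
  names(rates) <- classes
  pairs <- utils::combn(classes, 2)
  hit_tests <- list()
  rt_tests <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    nm <- paste(a, b, sep = "_vs_")
    if (!rates[[a]]$present || !rates[[b]]$present) next
    hit_tests[[nm]] <- proportion_test(rates[[a]]$k, rates[[a]]$n,
                                       rates[[b]]$k, rates[[b]]$n)
    rt_a <- d$rt_ms[d$class == a & d$hit]
    rt_b <- d$rt_ms[d$class == b & d$hit]
    if (length(rt_a) > 0 && length(rt_b) > 0) {
      rt_tests[[nm]] <- c(rank_tests(rt_a, rt_b),
                          list(mean_rt_1 = mean(rt_a), mean_rt_2 = mean(rt_b)))
    }
  }
  list(rates = rates, hit_rate_tests = hit_tests, rt_tests = rt_tests,
       n_mixed_excluded = n_mixed)
}

# Classify one trial for one epoch from its detected events:
# none / toward / away / mixed.
epoch_class <- function(onsets, labels, epoch) {
  inside <- onsets >= epoch[1] & onsets < epoch[2]
  if (!any(inside)) return("none")
  lb <- labels[inside]
  if (all(lb == "toward")) "toward" else if (all(lb == "away")) "away" else "mixed"
}

#' Epoch time-course analysis of attention-related modulation
#'
#' For each epoch, every two-patch trial is classified by the microsaccades
#' it contains within the epoch (none / toward the cue / away from the cue;
#' trials with both directions are excluded and counted). Normalized firing
#' rate is measured in the window of `spec$measure_ms` immediately after the
#' epoch, averaged per unit within each (epoch, attention, microsaccade
#' class) cell, and the unit-level cell means are fed to a three-factor
#' full-factorial ANOVA with Tukey-Kramer post hoc attention contrasts
#' within every epoch x microsaccade-class combination.
#'
#' @param study An `sc_study`.
#' @param events Detected events ([study_events()]).
#' @param norms Output of [study_norms()].
#' @param spec An [epoch_spec()].
#' @param measure_window_offset_ms Optional shift of the measurement window
#'   relative to the epoch end (robustness sweeps use nonzero offsets).
#' @param equalize_trials If `TRUE`, the trial sets feeding every
#'   (epoch, cue side, microsaccade class) cell of a session are subsampled
#'   without replacement to the session-wide minimum cell count, so all cell
#'   means share one trial count. This makes the cell means homoskedastic —
#'   the assumption behind pooled-MSE studentized-range comparisons — at the
#'   price of discarding data; used by the null-calibration checks.
#' @param seed Seed for the equalizing subsampler (ignored otherwise).
#' @return List with `cells` (unit-level cell means), `anova`, `posthoc`
#'   (attention contrasts), `n_mixed_excluded`, `n_dropped_units`.
#' @export
epoch_analysis <- function(study, events, norms, spec = epoch_spec(),
                           measure_window_offset_ms = 0,
                           equalize_trials = FALSE, seed = 1) {
  n_epochs <- nrow(spec$epochs)
  rows <- list()
  n_mixed <- 0L
  eq_seeds <- derive_seeds(seed, length(study$sessions))
  for (si in seq_along(study$sessions)) {
    sid <- names(study$sessions)[si]
    s <- study$sessions[[sid]]
    norm <- norms[[sid]]
    tr <- s$trials
    two <- which(tr$trial_type == "two_patch")
    ev <- events[events$session_id == s$session_id, ]
    ev_by_trial <- split(ev[, c("onset_ms", "label")], ev$trial_id)
    # session-level trial sets per (epoch, cue side, class), shared by units
    sets <- list()
    for (e in seq_len(n_epochs)) {
      ep <- spec$epochs[e, ]
      cls <- vapply(two, function(i) {
        evt <- ev_by_trial[[as.character(tr$trial_id[i])]]
        if (is.null(evt)) "none" else epoch_class(evt$onset_ms, evt$label, ep)
      }, character(1))
      n_mixed <- n_mixed + sum(cls == "mixed")
      for (side in c("left", "right")) {
        for (m in c("none", "toward", "away")) {
          sets[[paste(e, side, m)]] <-
            two[tr$cue_side[two] == side & cls == m]
        }
      }
    }
    if (equalize_trials) {
      n_min <- min(lengths(sets))
      sets <- withr::with_seed(eq_seeds[si], lapply(sets, function(ix) {
        if (n_min > 0) ix[sample.int(length(ix), n_min)] else integer(0)
      }))
    }
    for (e in seq_len(n_epochs)) {
      ep <- spec$epochs[e, ]
      meas <- ep[2] + measure_window_offset_ms + c(0, spec$measure_ms)
      mm <- window_mean(norm, meas)  # unit x trial
      for (u in seq_len(nrow(s$units))) {
        rf <- s$units$rf_side[u]
        for (side in c("left", "right")) {
          a <- if (side == rf) "cue_in_rf" else "cue_out_rf"
          for (m in c("none", "toward", "away")) {
            sel <- sets[[paste(e, side, m)]]
            if (length(sel) == 0) next
            rows[[length(rows) + 1L]] <- data.frame(
              unit_id = s$units$unit_id[u], epoch = e, attention = a,
              microsaccade = m, value = mean(mm[u, sel]), n_trials = length(sel))
          }
        }
      }
    }
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  cells$epoch <- factor(cells$epoch, levels = seq_len(n_epochs))
  cells <- complete_units_only(cells, c("epoch", "attention", "microsaccade"))
  fit <- fit_factorial_anova(cells, "value",
                             c("epoch", "attention", "microsaccade"))
  ph <- tukey_kramer(fit, contrast_pairs(fit, "attention"))
  list(cells = cells, anova = fit, posthoc = ph,
       n_mixed_excluded = n_mixed,
       n_dropped_units = attr(cells, "n_dropped_units"))
}

# Per-session peri-event cell means from a matched set: one row per
# (unit, condition, window) with the mean z over the condition's events.
peri_cells_session <- function(session, matched, norm, before, after,
                               align_window) {
  rows <- list()
  speed <- list()
  for (cn in names(matched$conditions)) {
    sel <- matched$conditions[[cn]]
    if (nrow(sel) == 0) next
    al <- align_to_events(session, sel, norm, window = align_window)
    if (nrow(al$events) == 0) next
    mb <- window_mean(al, before)
    ma <- window_mean(al, after)
    speed[[cn]] <- c(al$eye_speed, list(n = nrow(al$events)))
    for (u in seq_len(nrow(session$units))) {
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = session$units$unit_id[u], rf_side = session$units$rf_side[u],
        condition = cn, label = sel$label[1],
        cue_side = if (is.na(sel$cue_side[1])) NA_character_ else sel$cue_side[1],
        window = c("before", "after"),
        value = c(mean(mb[u, ]), mean(ma[u, ])),
        n_events = nrow(al$events))
    }
  }
  list(cells = do.call(rbind, rows), eye_speed = speed)
}

# Pool per-condition eye-speed traces (weighted by event count).
pool_eye_speed <- function(speed_lists) {
  all <- unlist(speed_lists, recursive = FALSE)
  all <- all[!vapply(all, is.null, logical(1))]
  if (length(all) == 0) return(NULL)
  t_ms <- all[[1]]$t_ms
  w <- vapply(all, function(s) s$n, numeric(1))
  m <- sapply(all, function(s) s$mean_dps)
  list(t_ms = t_ms, mean_dps = as.numeric(m %*% w / sum(w)))
}

#' Peri-microsaccadic attention modulation on timing-matched data
#'
#' Aligns normalized firing rates to the onset of individual microsaccades
#' toward and away from the cue, and to the timing-matched no-microsaccade
#' bin centers, using the matched sets produced by [timing_match()] (the
#' matching provenance is mandatory: raw event lists are refused). Average
#' normalized rates are computed per unit in the before (-60 to 0 ms) and
#' after (40 to 100 ms) windows, yielding: a three-factor ANOVA (window x
#' attention x microsaccade class) with Tukey-Kramer attention and
#' suppression contrasts; the attention-related modulation
#' `delta_attention = cue-in-RF - cue-out-of-RF` per window (with a
#' window x microsaccade ANOVA); and the suppression
#' `delta_suppression = after - before` per cue condition (with an
#' attention x microsaccade ANOVA); plus the companion average eye-speed
#' trace.
#'
#' @param study An `sc_study`.
#' @param matched_sets Named list (by session id) of `matched_set` objects
#'   from [timing_match()] with `scheme = "cue"`.
#' @param norms Output of [study_norms()].
#' @param before,after Measurement windows, ms relative to event onset.
#' @param align_window Alignment window for the rate matrix.
#' @return List with `cells`, `anova_rates`, `posthoc_attention`,
#'   `posthoc_suppression`, `delta_attention` (+ `anova_delta_attention`),
#'   `delta_suppression` (+ `anova_delta_suppression`), `eye_speed`, and
#'   bookkeeping counts.
#' @export
perisaccadic_analysis <- function(study, matched_sets, norms,
                                  before = c(-60, 0), after = c(40, 100),
                                  align_window = c(-200, 200)) {
  if (!all(vapply(matched_sets, inherits, logical(1), "matched_set"))) {
    stop("perisaccadic analysis requires timing-matched sets (matched_set objects)",
         call. = FALSE)
  }
  per <- lapply(names(study$sessions), function(sid) {
    peri_cells_session(study$sessions[[sid]], matched_sets[[sid]], norms[[sid]],
                       before, after, align_window)
  })
  cells <- do.call(rbind, lapply(per, `[[`, "cells"))
  cells$attention <- ifelse(cells$cue_side == cells$rf_side,
                            "cue_in_rf", "cue_out_rf")
  cells$microsaccade <- cells$label
  # Average the two cue-side conditions mapping onto the same
  # (attention, microsaccade) cell for a unit (event-count weighted).
  agg <- stats::aggregate(
    cbind(value = cells$value * cells$n_events, w = cells$n_events),
    by = list(unit_id = cells$unit_id, window = cells$window,
              attention = cells$attention, microsaccade = cells$microsaccade),
    FUN = sum)
  agg$value <- agg$value / agg$w
  agg$n_events <- agg$w
  agg$w <- NULL
  agg <- complete_units_only(agg, c("window", "attention", "microsaccade"))
  agg$window <- factor(agg$window, levels = c("before", "after"))
  fit <- fit_factorial_anova(agg, "value", c("window", "attention", "microsaccade"))
  ph_attn <- tukey_kramer(fit, contrast_pairs(fit, "attention"))
  ph_supp <- tukey_kramer(fit, contrast_pairs(fit, "window"))

  # delta_attention per (unit, window, microsaccade)
  wide <- stats::reshape(agg[, c("unit_id", "window", "attention",
                                 "microsaccade", "value")],
                         idvar = c("unit_id", "window", "microsaccade"),
                         timevar = "attention", direction = "wide")
  wide$value <- wide$value.cue_in_rf - wide$value.cue_out_rf
  d_attn <- wide[, c("unit_id", "window", "microsaccade", "value")]
  fit_da <- fit_factorial_anova(d_attn, "value", c("window", "microsaccade"))

  # delta_suppression per (unit, attention, microsaccade)
  wide2 <- stats::reshape(agg[, c("unit_id", "window", "attention",
                                  "microsaccade", "value")],
                          idvar = c("unit_id", "attention", "microsaccade"),
                          timevar = "window", direction = "wide")
  wide2$value <- wide2$value.after - wide2$value.before
  d_supp <- wide2[, c("unit_id", "attention", "microsaccade", "value")]
  fit_ds <- fit_factorial_anova(d_supp, "value", c("attention", "microsaccade"))

  list(cells = agg, anova_rates = fit,
       posthoc_attention = ph_attn, posthoc_suppression = ph_supp,
       delta_attention = d_attn, anova_delta_attention = fit_da,
       delta_suppression = d_supp, anova_delta_suppression = fit_ds,
       eye_speed = pool_eye_speed(lapply(per, `[[`, "eye_speed")),
       n_dropped_units = attr(agg, "n_dropped_units"))
}

#' Single-patch motor control analysis
#'
#' Uses only single-patch trials in which the patch is opposite a unit's
#' response field (no stimulus inside the RF), with microsaccades labeled
#' relative to the RF rather than the cue, timing-matched against a
#' no-microsaccade condition. Before/after window means feed a two-factor
#' (window x microsaccade class) ANOVA with Tukey-Kramer contrasts; any
#' before/after change here would indicate a motor, not visual-attentional,
#' component.
#'
#' @param study An `sc_study`.
#' @param events Detected events ([study_events()]).
#' @param norms Output of [study_norms()].
#' @param spec A [timing_match_spec()].
#' @param seed Integer seed for the matching subsampler.
#' @param before,after,align_window As in [perisaccadic_analysis()].
#' @return List with `cells`, `anova`, `posthoc` (before/after contrasts),
#'   `matched_sets`, `n_dropped_units`.
#' @export
motor_control_analysis <- function(study, events, norms,
                                   spec = timing_match_spec(), seed = 1,
                                   before = c(-60, 0), after = c(40, 100),
                                   align_window = c(-200, 200)) {
  rows <- list()
  matched_all <- list()
  seeds <- derive_seeds(seed, 2 * length(study$sessions))
  k <- 0L
  for (sid in names(study$sessions)) {
    s <- study$sessions[[sid]]
    ev <- events[events$session_id == s$session_id, ]
    for (rf in unique(s$units$rf_side)) {
      k <- k + 1L
      matched <- timing_match(s, ev, spec, seed = seeds[k],
                              scheme = "rf", rf_side = rf)
      matched_all[[paste(sid, rf, sep = ".")]] <- matched
      sub <- s
      sub$units <- s$units[s$units$rf_side == rf, , drop = FALSE]
      pc <- peri_cells_session(sub, matched, norms[[sid]], before, after,
                               align_window)
      if (!is.null(pc$cells)) rows[[length(rows) + 1L]] <- pc$cells
    }
  }
  cells <- do.call(rbind, rows)
  cells$microsaccade <- cells$label
  cells$value <- cells$value
  cells <- complete_units_only(cells, c("window", "microsaccade"))
  cells$window <- factor(cells$window, levels = c("before", "after"))
  fit <- fit_factorial_anova(cells[, c("unit_id", "window", "microsaccade",
                                       "value")],
                             "value", c("window", "microsaccade"))
  ph <- tukey_kramer(fit, contrast_pairs(fit, "window"))
  list(cells = cells, anova = fit, posthoc = ph, matched_sets = matched_all,
       n_dropped_units = attr(cells, "n_dropped_units"))
}

#' Eye-position-matched peri-microsaccadic analysis
#'
#' Re-runs the peri-microsaccadic before/after analysis after matching the
#' 2D distribution of average eye position in the before window across the
#' four microsaccade x cue conditions (toward/away x cue side), on a
#' 0.25-degree grid by default. The resulting unit-level window means feed a
#' three-factor ANOVA: window x attention x microsaccade direction (two
#' levels here, since a no-microsaccade condition has no alignment events to
#' position-match).
#'
#' @param study An `sc_study`.
#' @param events Detected events ([study_events()]).
#' @param norms Output of [study_norms()].
#' @param tspec A [timing_match_spec()]; its window bounds the candidate
#'   microsaccades.
#' @param pspec A [position_match_spec()].
#' @param seed Integer seed.
#' @param before,after,align_window As in [perisaccadic_analysis()].
#' @return List with `cells`, `anova`, `posthoc_attention`, `matched_sets`,
#'   `n_dropped_units`.
#' @export
position_matched_analysis <- function(study, events, norms,
                                      tspec = timing_match_spec(),
                                      pspec = position_match_spec(), seed = 1,
                                      before = c(-60, 0), after = c(40, 100),
                                      align_window = c(-200, 200)) {
  rows <- list()
  matched_all <- list()
  seeds <- derive_seeds(seed, length(study$sessions))
  k <- 0L
  for (sid in names(study$sessions)) {
    k <- k + 1L
    s <- study$sessions[[sid]]
    ev <- events[events$session_id == s$session_id &
                   events$onset_ms >= tspec$window_ms[1] &
                   events$onset_ms < tspec$window_ms[2], ]
    tr <- s$trials
    by_cond <- list()
    for (side in c("left", "right")) {
      ids <- tr$trial_id[tr$trial_type == "two_patch" & tr$cue_side == side]
      for (lb in c("toward", "away")) {
        e <- ev[ev$trial_id %in% ids & ev$label == lb, , drop = FALSE]
        df <- data.frame(trial_id = e$trial_id, t0_ms = e$onset_ms)
        df$label <- if (nrow(df)) lb else character(0)
        df$cue_side <- if (nrow(df)) side else character(0)
        by_cond[[paste(lb, side, sep = ".")]] <- df
      }
    }
    matched <- eye_position_match(s, by_cond, pspec, seed = seeds[k])
    matched_all[[sid]] <- matched
    pc <- peri_cells_session(s, matched, norms[[sid]], before, after,
                             align_window)
    if (!is.null(pc$cells)) rows[[length(rows) + 1L]] <- pc$cells
  }
  cells <- do.call(rbind, rows)
  cells$attention <- ifelse(cells$cue_side == cells$rf_side,
                            "cue_in_rf", "cue_out_rf")
  cells$microsaccade <- cells$label
  agg <- stats::aggregate(
    cbind(value = cells$value * cells$n_events, w = cells$n_events),
    by = list(unit_id = cells$unit_id, window = cells$window,
              attention = cells$attention, microsaccade = cells$microsaccade),
    FUN = sum)
  agg$value <- agg$value / agg$w
  agg$n_events <- agg$w
  agg$w <- NULL
  agg <- complete_units_only(agg, c("window", "attention", "microsaccade"))
  agg$window <- factor(agg$window, levels = c("before", "after"))
  fit <- fit_factorial_anova(agg, "value", c("window", "attention", "microsaccade"))
  ph <- tukey_kramer(fit, contrast_pairs(fit, "attention"))
  list(cells = agg, anova = fit, posthoc_attention = ph,
       matched_sets = matched_all,
       n_dropped_units = attr(agg, "n_dropped_units"))
}
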