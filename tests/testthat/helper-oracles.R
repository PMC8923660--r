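# Shared fixtures and independent oracles used across the test files.
# Oracles deliberately use naive, direct implementations (per-sample loops,
# closed forms, enumeration) so they share no code path with the package.

# --- small configurations ---------------------------------------------------

tiny_task <- function(...) {
  args <- list(n_sessions_per_monkey = 1, n_blocks = 2, trials_per_block = 16,
               single_patch_trials_per_transition = 6)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(task_config, args)
}

quiet_eye <- function(...) {
  args <- list(drift_diffusion = 0, tremor_sd = 0, microsaccade_rate_hz = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(eye_model, args)
}

# --- detection oracles ------------------------------------------------------

# Exhaustive per-sample scan of the elliptical criterion with a naive
# run-finding loop; mirrors the published detection contract directly.
oracle_detect <- function(trace, params = detection_params()) {
  vel <- compute_velocity(trace, params)
  eta <- estimate_thresholds(vel, params)
  n <- length(trace$x)
  above <- logical(n)
  for (i in seq_len(n)) {
    if (!is.na(vel$vx[i]) && !is.na(vel$vy[i])) {
      above[i] <- (vel$vx[i] / eta[1])^2 + (vel$vy[i] / eta[2])^2 > 1
    }
  }
  runs <- list()
  i <- 1
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  # duration filter first, then gap merge, as documented
  runs <- Filter(function(r) (r[2] - r[1] + 1) * trace$dt >= params$min_duration_ms,
                 runs)
  merged <- list()
  for (r in runs) {
    if (length(merged) > 0 &&
        (r[1] - merged[[length(merged)]][2] - 1) <
          round(params$merge_gap_ms / trace$dt)) {
      merged[[length(merged)]][2] <- r[2]
    } else {
      merged[[length(merged) + 1]] <- r
    }
  }
  out <- do.call(rbind, lapply(merged, function(r) {
    dx <- trace$x[r[2]] - trace$x[r[1]]
    dy <- trace$y[r[2]] - trace$y[r[1]]
    data.frame(onset_ms = trace$t0 + (r[1] - 1) * trace$dt,
               offset_ms = trace$t0 + r[2] * trace$dt,
               amplitude_deg = sqrt(dx^2 + dy^2))
  }))
  if (is.null(out)) {
    out <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      amplitude_deg = numeric(0))
  }
  out[out$amplitude_deg <= params$max_amplitude_deg, , drop = FALSE]
}

# --- ANOVA sums-of-squares oracle ------------------------------------------

# Direct SS decomposition for a balanced full-factorial design from cell and
# marginal means, independent of lm/aov.
oracle_anova_ss <- function(data, response, factors) {
  y <- data[[response]]
  grand <- mean(y)
  ss <- list(total = sum((y - grand)^2))
  # effects built recursively: each term's effect is its cell-mean deviation
  # minus all contained lower-order effects
  terms <- unlist(lapply(seq_along(factors),
                         function(k) utils::combn(factors, k, simplify = FALSE)),
                  recursive = FALSE)
  eff_store <- list()
  for (cmb in terms) {
    cell <- interaction(data[cmb], drop = FALSE)
    eff <- ave(y, cell) - grand
    for (other in names(eff_store)) {
      sub <- strsplit(other, ":", fixed = TRUE)[[1]]
      if (all(sub %in% cmb)) eff <- eff - eff_store[[other]]
    }
    eff_store[[paste(cmb, collapse = ":")]] <- eff
  }
  for (nm in names(eff_store)) ss[[nm]] <- sum(eff_store[[nm]]^2)
  ss$error <- ss$total - sum(unlist(ss[names(eff_store)]))
  ss
}

# --- rank-test enumeration oracles ------------------------------------------

# Exact two-sided rank-sum p by full enumeration of group assignments.
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Exact two-sided signed-rank p by enumerating all sign assignments.
oracle_signedrank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
}

# --- generative-rate oracle -------------------------------------------------

# Time-averaged generative firing rate (spikes/s) of one unit over a window
# for one trial, integrating the piecewise rate analytically per 1-ms step.
# Uses only ground-truth events and the stated model parameters.
oracle_mean_rate <- function(nm, window, patch_in_rf, cue_in_rf, gt_events,
                             rf_dir = 0) {
  t <- seq(window[1], window[2] - 1) + 0.5
  r <- rep(nm$baseline_rate, length(t))
  if (patch_in_rf && nm$transient_amp > 0) {
    post <- t >= nm$transient_latency_ms
    r[post] <- r[post] + nm$transient_amp *
      exp(-(t[post] - nm$transient_latency_ms) / nm$transient_decay_ms)
  }
  if (cue_in_rf) r[t >= nm$attention_onset_ms] <- r[t >= nm$attention_onset_ms] + nm$attention_delta
  if (nrow(gt_events) > 0 && nm$suppression_depth > 0) {
    for (s in gt_events$onset_ms) {
      idx <- t >= s + nm$suppression_latency_ms &
        t < s + nm$suppression_latency_ms + nm$suppression_duration_ms
      if (nm$suppression_mode == "multiplicative") {
        r[idx] <- r[idx] * (1 - nm$suppression_depth)
      } else {
        r[idx] <- r[idx] - nm$suppression_depth * nm$baseline_rate
      }
    }
  }
  mean(pmax(r, 0))
}

# --- cached moderate-size fixture ------------------------------------------

# One small two-session study reused across analysis tests (built lazily).
.fixture_env <- new.env(parent = emptyenv())

shared_study <- function() {
  if (is.null(.fixture_env$study)) {
    task <- task_config(n_sessions_per_monkey = 1, n_blocks = 4,
                        trials_per_block = 40,
                        single_patch_trials_per_transition = 10)
    .fixture_env$study <- simulate_study(task, eye_model(), neuron_model(),
                                         seed = 2718, n_units_per_monkey = 4)
    .fixture_env$events <- study_events(.fixture_env$study)
    .fixture_env$norms <- study_norms(.fixture_env$study)
  }
  list(study = .fixture_env$study, events = .fixture_env$events,
       norms = .fixture_env$norms)
}

# Brute-force delay-period rate difference (cue-in minus cue-out, spikes/s)
# per unit, evaluated from each unit's generative rate function and the
# ground-truth events of every trial.
oracle_study_delta <- function(study, delay_window = c(200, 1000)) {
  out <- numeric(0)
  for (s in study$sessions) {
    two <- s$trials[s$trials$trial_type == "two_patch", ]
    gt_by_trial <- split(s$ground_truth$events, s$ground_truth$events$trial_id)
    empty <- data.frame(onset_ms = numeric(0))
    for (u in seq_along(s$neurons)) {
      nm <- s$neurons[[u]]
      rates <- vapply(seq_len(nrow(two)), function(i) {
        g <- gt_by_trial[[as.character(two$trial_id[i])]]
        if (is.null(g)) g <- empty
        oracle_mean_rate(nm, delay_window, TRUE, two$cue_side[i] == nm$rf_side, g)
      }, numeric(1))
      out <- c(out, mean(rates[two$cue_side == nm$rf_side]) -
                 mean(rates[two$cue_side != nm$rf_side]))
    }
  }
  out
}
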