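# End-to-end orchestration (simulate -> detect -> screen -> match -> analyze
# -> report) and the canonical plain-text table formats. Conventions, fixed
# package-wide: times in ms relative to color-patch onset; bins half-open
# [a, b); angles in degrees, cue-relative angles wrapped to (-180, 180];
# positions in degrees of visual angle.

#' Assemble a full pipeline configuration
#'
#' Bundles every stage's configuration with the master seed. The
#' configuration is fully serializable ([write_run_config()] /
#' [read_run_config()] round-trip losslessly) and its hash is stamped into
#' every analysis artifact.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param task,eye,neuron,detection,timing,position,epochs Stage
#'   configurations (see the respective constructors).
#' @param n_units_per_monkey Units per subject (default 34).
#' @param apply_screen If `TRUE`, analyses use only units passing
#'   [screen_units()]; otherwise all simulated units (which the generator
#'   already endows with attention modulation) are analyzed and the screen
#'   is merely reported.
#' @param write_eye If `TRUE`, per-sample eye traces are exported (large).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       task = task_config(),
                       eye = eye_model(),
                       neuron = neuron_model(),
                       detection = detection_params(),
                       timing = timing_match_spec(),
                       position = position_match_spec(),
                       epochs = epoch_spec(),
                       n_units_per_monkey = 34,
                       apply_screen = TRUE,
                       write_eye = FALSE) {
  structure(list(seed = seed, task = task, eye = eye, neuron = neuron,
                 detection = detection, timing = timing, position = position,
                 epochs = epochs, n_units_per_monkey = n_units_per_monkey,
                 apply_screen = apply_screen, write_eye = write_eye),
            class = "run_config")
}

#' Run the complete analysis pipeline
#'
#' Simulates the study, detects microsaccades, screens units, builds the
#' timing-matched sets, and runs every analysis surface: the epoch
#' time-course ANOVA, the peri-microsaccadic before/after analysis, the
#' single-patch motor control, the eye-position-matched control, the
#' modulation-by-outcome comparison, and the microsaccade-conditioned
#' behavioral summary. Deterministic given the configuration seed. If
#' `out_dir` is given, all canonical tables and a JSON summary are written
#' there.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `pipeline_result` with all stage outputs, the
#'   per-stage counts log, and the configuration hash.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  seeds <- derive_seeds(config$seed, 4)

  study <- stage("simulate", simulate_study(
    task = config$task, eye = config$eye, neuron = config$neuron,
    seed = seeds[1], n_units_per_monkey = config$n_units_per_monkey))
  log$n_sessions <- length(study$sessions)
  log$n_trials <- sum(vapply(study$sessions, function(s) nrow(s$trials), numeric(1)))

  events <- stage("detect", study_events(study, config$detection))
  log$n_events_detected <- nrow(events)

  screen <- stage("screen", do.call(rbind, c(
    lapply(study$sessions, screen_units), make.row.names = FALSE)))
  log$n_units_total <- nrow(screen)
  log$n_units_included <- sum(screen$included, na.rm = TRUE)
  if (config$apply_screen) {
    keep <- screen$unit_id[which(screen$included)]
    for (sid in names(study$sessions)) {
      s <- study$sessions[[sid]]
      s$units <- s$units[s$units$unit_id %in% keep, , drop = FALSE]
      s$spikes <- s$spikes[s$spikes$unit_id %in% keep, , drop = FALSE]
      study$sessions[[sid]] <- s
    }
  }

  norms <- stage("normalize", study_norms(study))

  match_seeds <- derive_seeds(seeds[2], length(study$sessions))
  matched <- stage("timing_match", {
    out <- list()
    for (i in seq_along(study$sessions)) {
      sid <- names(study$sessions)[i]
      ev <- events[events$session_id == sid, ]
      out[[sid]] <- timing_match(study$sessions[[sid]], ev, config$timing,
                                 seed = match_seeds[i])
    }
    out
  })

  epoch <- stage("epoch_analysis",
                 epoch_analysis(study, events, norms, config$epochs))
  peri <- stage("perisaccadic_analysis",
                perisaccadic_analysis(study, matched, norms))
  motor <- stage("motor_control",
                 motor_control_analysis(study, events, norms, config$timing,
                                        seed = seeds[3]))
  posmatch <- stage("position_matched",
                    position_matched_analysis(study, events, norms,
                                              config$timing, config$position,
                                              seed = seeds[4]))
  outcome <- stage("modulation_by_outcome",
                   modulation_by_outcome(study, norms))
  behavior <- stage("behavior", behavior_by_microsaccade(study, events))

  log$n_mixed_epoch_trials <- epoch$n_mixed_excluded
  hash <- config_hash(unclass(config))
  result <- structure(list(
    config = config, config_hash = hash, study = study, events = events,
    screen = screen, norms = norms, matched_sets = matched,
    epoch = epoch, perisaccadic = peri, motor_control = motor,
    position_matched = posmatch, modulation_by_outcome = outcome,
    behavior = behavior, log = log), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  cat(sprintf("  %d sessions, %d trials, %d detected microsaccades\n",
              x$log$n_sessions, x$log$n_trials, x$log$n_events_detected))
  cat(sprintf("  units included by screen: %d / %d\n",
              x$log$n_units_included, x$log$n_units_total))
  cat(sprintf("  epoch ANOVA d.o.f.: total %d, error %d\n",
              x$epoch$anova$total_df, x$epoch$anova$error_df))
  cat(sprintf("  config hash: %s\n", x$config_hash))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Canonical tables

ms_schema <- c("session_id", "trial_id", "onset_ms", "offset_ms", "dx_deg",
               "dy_deg", "amplitude_deg", "peak_speed_dps", "direction_deg",
               "rel_direction_deg", "label")

trial_schema <- c("trial_id", "block", "trial_type", "cue_side", "change_site",
                  "change_ms", "t_start_ms", "t_end_ms", "outcome", "rt_ms")

check_columns <- function(df, schema, what) {
  missing <- setdiff(schema, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing columns: %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Write / read the microsaccade table
#'
#' Plain CSV with one row per detected event. On read, the schema is
#' validated strictly: required columns must be present, onsets must
#' precede offsets, and cue-relative directions must lie in `(-180, 180]`
#' (violations are reported with their row indices).
#'
#' @param events Data frame in the [detect_session()] layout.
#' @param path CSV path.
#' @return `read_microsaccades()` returns the validated data frame.
#' @export
write_microsaccades <- function(events, path) {
  check_columns(events, ms_schema, "microsaccades table")
  utils::write.csv(events[, ms_schema], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_microsaccades
#' @export
read_microsaccades <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, ms_schema, "microsaccades table")
  bad <- which(!(df$offset_ms > df$onset_ms))
  if (length(bad) > 0) {
    stop(sprintf("microsaccades table: offset <= onset at rows %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  rel <- df$rel_direction_deg
  bad <- which(!is.na(rel) & !(rel > -180 & rel <= 180))
  if (length(bad) > 0) {
    stop(sprintf("microsaccades table: rel_direction_deg outside (-180, 180] at rows %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Write / read the trial table
#'
#' @param trials Trial data frame of an `sc_session` (a `session_id` column
#'   is added on write if absent).
#' @param path CSV path.
#' @return `read_trials()` returns the validated data frame.
#' @export
write_trials <- function(trials, path) {
  check_columns(trials, trial_schema, "trials table")
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, trial_schema, "trials table")
  bad <- which(df$t_end_ms <= df$t_start_ms)
  if (length(bad) > 0) {
    stop(sprintf("trials table: t_end_ms <= t_start_ms at rows %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Serialize / restore a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML path.
#' @return `read_run_config()` returns the reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  ser <- lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
  # named numeric vectors must round-trip as maps, not sequences
  ser$eye$direction_weights <- as.list(config$eye$direction_weights)
  # matrices (epoch windows) are stored row-wise with their dimensions
  ser$epochs$epochs <- list(dim = dim(config$epochs$epochs),
                            data = as.numeric(t(config$epochs$epochs)))
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ep <- matrix(unlist(raw$epochs$epochs$data), ncol = 2, byrow = TRUE)
  run_config(
    seed = raw$seed,
    task = do.call(task_config, raw$task[names(formals(task_config))]),
    eye = do.call(eye_model, {
      a <- raw$eye[names(formals(eye_model))]
      a$direction_weights <- unlist(a$direction_weights)
      a
    }),
    neuron = do.call(neuron_model, raw$neuron[names(formals(neuron_model))]),
    detection = do.call(detection_params, raw$detection[names(formals(detection_params))]),
    timing = do.call(timing_match_spec,
                     raw$timing[setdiff(names(formals(timing_match_spec)), "")]),
    position = do.call(position_match_spec,
                       raw$position[names(formals(position_match_spec))]),
    epochs = epoch_spec(ep, raw$epochs$measure_ms),
    n_units_per_monkey = raw$n_units_per_monkey,
    apply_screen = raw$apply_screen,
    write_eye = raw$write_eye
  )
}

# Flatten an anova_fit for JSON export.
anova_json <- function(fit) {
  list(total_df = fit$total_df, error_df = fit$error_df, mse = fit$mse,
       table = fit$table)
}

# Serialize a matched set's bookkeeping (not the raw trace data).
matched_json <- function(ms) {
  list(seed = ms$seed, scheme = ms$scheme,
       pre_counts = as.data.frame(ms$pre_counts),
       post_counts = as.data.frame(ms$post_counts),
       selected = lapply(ms$conditions, function(df) {
         df[, intersect(c("trial_id", "t0_ms", "bin"), names(df))]
       }))
}

#' Write all pipeline outputs to a directory
#'
#' Emits the canonical CSV tables (trials, microsaccades, unit screen,
#' analysis cells, deltas), the ANOVA tables and matched-set provenance as
#' JSON, the YAML configuration, and a JSON run log; every file set is
#' stamped with the configuration hash.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  trials <- do.call(rbind, lapply(result$study$sessions, function(s) {
    cbind(session_id = s$session_id, s$trials)
  }))
  rownames(trials) <- NULL
  write_trials(trials, p("trials.csv"))
  write_microsaccades(result$events, p("microsaccades.csv"))
  utils::write.csv(result$screen, p("unit_screen.csv"), row.names = FALSE)
  cells <- rbind(
    cbind(analysis = "epoch", result$epoch$cells[
      , c("unit_id", "attention", "microsaccade", "value")],
      window = as.character(result$epoch$cells$epoch)),
    cbind(analysis = "perisaccadic", result$perisaccadic$cells[
      , c("unit_id", "attention", "microsaccade", "value")],
      window = as.character(result$perisaccadic$cells$window)))
  utils::write.csv(cells, p("analysis_cells.csv"), row.names = FALSE)
  deltas <- rbind(
    cbind(kind = "attention", result$perisaccadic$delta_attention[
      , c("unit_id", "microsaccade", "value")],
      split_by = as.character(result$perisaccadic$delta_attention$window)),
    cbind(kind = "suppression", result$perisaccadic$delta_suppression[
      , c("unit_id", "microsaccade", "value")],
      split_by = result$perisaccadic$delta_suppression$attention))
  utils::write.csv(deltas, p("deltas.csv"), row.names = FALSE)
  anovas <- list(
    config_hash = result$config_hash,
    epoch = anova_json(result$epoch$anova),
    perisaccadic_rates = anova_json(result$perisaccadic$anova_rates),
    delta_attention = anova_json(result$perisaccadic$anova_delta_attention),
    delta_suppression = anova_json(result$perisaccadic$anova_delta_suppression),
    motor_control = anova_json(result$motor_control$anova),
    position_matched = anova_json(result$position_matched$anova))
  jsonlite::write_json(anovas, p("anova_tables.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  jsonlite::write_json(
    list(config_hash = result$config_hash,
         timing = lapply(result$matched_sets, matched_json)),
    p("matched_sets.json"), auto_unbox = TRUE, digits = NA)
  write_run_config(result$config, p("config.yaml"))
  jsonlite::write_json(c(list(config_hash = result$config_hash), result$log),
                       p("run_log.json"), auto_unbox = TRUE)
  if (isTRUE(result$config$write_eye)) {
    eye <- do.call(rbind, lapply(result$study$sessions, function(s) {
      do.call(rbind, lapply(names(s$eye_traces), function(tid) {
        tr <- s$eye_traces[[tid]]
        data.frame(session_id = s$session_id, trial_id = as.integer(tid),
                   t_ms = trace_times(tr), x_deg = tr$x, y_deg = tr$y)
      }))
    }))
    utils::write.csv(eye, p("eye.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}
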