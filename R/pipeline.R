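#' Normalized ankle cycles of one walking trial under one foot model
#'
#' The standard processing chain for a single trial: low-pass filter the
#' raw marker coordinates, detect gait events from the vertical GRF channel
#' (unless events are supplied), compute the model's sagittal ankle trace
#' with the subject's static calibration, and time-normalize each
#' contact-to-contact span to 101 samples.
#'
#' @param trial a walking [trial_recording()] with an analog `Fz` channel
#'   (or supply `events`).
#' @param model `"OFM"`, `"PiG"` or `"DAV"`.
#' @param offsets the subject's [static_calibration()] for this model.
#' @param events optional [gait_events()]; detected from `Fz` when `NULL`.
#' @param fspec a [filter_spec()] applied to the marker coordinates.
#' @param threshold_n,debounce_ms event-detection settings.
#' @return list of [normalized_cycle()] objects.
#' @export
trial_cycles <- function(trial, model, offsets, events = NULL,
                         fspec = filter_spec(), threshold_n = 20,
                         debounce_ms = 10) {
  stopifnot(inherits(trial, "TrialRecording"))
  filtered <- filter_trial(trial, fspec)
  if (is.null(events)) {
    if (is.null(trial$analog$Fz))
      stop("trial has no Fz channel; supply `events`", call. = FALSE)
    events <- detect_gait_events(
      trial$analog$Fz, trial$analog_rate, trial$marker_rate,
      threshold = threshold_n,
      debounce = round(debounce_ms / 1000 * trial$analog_rate))
  }
  trace <- compute_ankle_trace(filtered, model, offsets)
  time_normalize(trace$values, events, model = model,
                 condition = trial$condition, subject_id = trial$subject_id)
}

#' Analyze a synthetic cohort into parameter tables and rocker flags
#'
#' Runs the full chain on every subject of a [generate_cohort()] result:
#' static calibration per model, filtering, event detection, ankle traces
#' under all three foot models, time normalization, representative-cycle
#' selection per subject x model x condition, clinical parameter
#' extraction, and rocker classification of every cycle.
#'
#' @param cohort a [generate_cohort()] result.
#' @param models foot models to evaluate.
#' @param fspec a [filter_spec()].
#' @param criteria a [rocker_criteria()].
#' @return list with
#'   `tables`: named list of six [cohort_table()]s (`rom`, `angle_at_fc`,
#'     `peak_df`, `t_peak_df`, `peak_pf`, `t_peak_pf`);
#'   `rockers`: data.frame of per-cycle rocker flags;
#'   `representative`: list of representative cycles per
#'     subject/model/condition;
#'   `lfm`: per model x condition [lfm()] results over representative
#'     cycles.
#' @export
analyze_cohort <- function(cohort, models = c("OFM", "PiG", "DAV"),
                           fspec = filter_spec(),
                           criteria = rocker_criteria()) {
  param_names <- c("angle_at_fc", "peak_df", "t_peak_df", "peak_pf",
                   "t_peak_pf", "rom")
  rows <- list(); rocker_rows <- list(); reps <- list()
  for (sub in cohort) {
    cals <- lapply(stats::setNames(models, models), function(m)
      static_calibration(filter_trial(sub$static, fspec), m))
    for (cond in c("BF", "FO")) {
      entry <- sub[[cond]]
      if (is.null(entry)) next
      for (m in models) {
        cycles <- trial_cycles(entry$trial, m, cals[[m]], fspec = fspec)
        if (length(cycles) < 2L)
          stop("subject ", sub$subject_id, " has too few valid cycles",
               call. = FALSE)
        sel <- select_representative(cycles)
        rep_cycle <- cycles[[sel$chosen_index]]
        reps[[paste(sub$subject_id, m, cond, sep = ".")]] <- rep_cycle
        pars <- extract_parameters(rep_cycle)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sub$subject_id, model = m, condition = cond,
          angle_at_fc = pars$angle_at_fc, peak_df = pars$peak_df,
          t_peak_df = pars$t_peak_df, peak_pf = pars$peak_pf,
          t_peak_pf = pars$t_peak_pf, rom = pars$rom)
        for (k in seq_along(cycles)) {
          fl <- classify_rockers(cycles[[k]], criteria = criteria)
          rocker_rows[[length(rocker_rows) + 1L]] <- data.frame(
            subject = sub$subject_id, model = m, condition = cond,
            cycle = k, heel_rocker = fl$heel_rocker,
            premature_ff = fl$premature_forefoot_rocker)
        }
      }
    }
  }
  wide <- do.call(rbind, rows)
  tables <- lapply(stats::setNames(param_names, param_names), function(p)
    cohort_table(data.frame(subject = wide$subject, model = wide$model,
                            condition = wide$condition, value = wide[[p]]),
                 parameter = p))
  lfm_res <- list()
  for (m in unique(wide$model)) for (cond in unique(wide$condition)) {
    keys <- paste(unique(wide$subject), m, cond, sep = ".")
    cyc <- reps[keys]
    if (length(cyc) >= 2L && !any(vapply(cyc, is.null, logical(1))))
      lfm_res[[paste(m, cond, sep = "_")]] <- lfm(cyc)
  }
  list(tables = tables, rockers = do.call(rbind, rocker_rows),
       representative = reps, lfm = lfm_res)
}

#' Export a parameter table of cycles as CSV
#'
#' Writes the per-cycle clinical parameters and rocker flags in the long
#' layout `subject,model,condition,angle_at_fc,peak_df,t_peak_df,peak_pf,
#' t_peak_pf,rom,heel_rocker,premature_ff`.
#'
#' @param cycles list of [normalized_cycle()] objects.
#' @param path output CSV path.
#' @param criteria a [rocker_criteria()].
#' @return `path`, invisibly.
#' @export
write_parameters_csv <- function(cycles, path, criteria = rocker_criteria()) {
  rows <- lapply(cycles, function(cy) {
    p <- extract_parameters(cy)
    fl <- classify_rockers(cy, p, criteria)
    data.frame(subject = cy$subject_id, model = cy$model,
               condition = cy$condition, angle_at_fc = p$angle_at_fc,
               peak_df = p$peak_df, t_peak_df = p$t_peak_df,
               peak_pf = p$peak_pf, t_peak_pf = p$t_peak_pf, rom = p$rom,
               heel_rocker = fl$heel_rocker,
               premature_ff = fl$premature_forefoot_rocker)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export normalized cycles as a 101-row CSV
#'
#' One column per cycle (named by subject/cycle id), 101 rows at
#' 0..100 % GC.
#'
#' @param cycles list of [normalized_cycle()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cycles_csv <- function(cycles, path) {
  m <- cycles_matrix(cycles)
  colnames(m) <- vapply(cycles, function(c)
    paste(c$subject_id, c$cycle_id, sep = "_"), character(1))
  df <- data.frame(pct = 0:100, m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
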