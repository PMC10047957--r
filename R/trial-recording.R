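#' Trial recording: marker trajectories plus analog channels for one trial
#'
#' A `TrialRecording` bundles everything captured during one walking or
#' static standing trial: labelled 3D marker trajectories in the laboratory
#' frame, optional analog channels (vertical ground reaction force), the two
#' sampling rates, and trial metadata.  Marker positions are stored in mm;
#' frames where a marker was not visible are `NA` rows (never zero-filled).
#'
#' The laboratory frame convention used throughout the package is
#' right-handed with X the direction of progression, Z vertical up, and
#' Y = Z x X (pointing to the subject's left when walking along +X).
#'
#' @param trial_id character scalar identifying the trial.
#' @param condition one of `"BF"` (barefoot), `"FO"` (foot orthosis) or
#'   `"STATIC"` (standing calibration).
#' @param side `"left"` or `"right"`: the instrumented limb.
#' @param markers named list of numeric matrices, one per marker label, each
#'   with 3 columns (x, y, z in mm) and one row per marker frame.  All
#'   matrices must share the same number of rows.
#' @param marker_rate marker sampling rate in samples/s (nominal 250).
#' @param analog named list of numeric vectors (e.g. `Fz` in N), may be empty.
#' @param analog_rate analog sampling rate in samples/s (nominal 1000); must
#'   be an integer multiple of `marker_rate` when analog channels are present.
#' @param subject_id character scalar.
#'
#' @return An object of class `TrialRecording`.
#' @export
trial_recording <- function(trial_id, condition, side, markers, marker_rate,
                            analog = list(), analog_rate = NA_real_,
                            subject_id = "S01") {
  condition <- match.arg(condition, c("BF", "FO", "STATIC"))
  side <- match.arg(side, c("left", "right"))
  if (!is.list(markers) || length(markers) == 0L || is.null(names(markers)))
    stop("`markers` must be a non-empty named list of n x 3 matrices", call. = FALSE)
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) stop("marker matrices must have 3 columns", call. = FALSE)
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y", "z")
    m
  })
  n <- unique(vapply(markers, nrow, integer(1)))
  if (length(n) != 1L)
    stop("all marker series must share one length", call. = FALSE)
  if (!is.numeric(marker_rate) || marker_rate <= 0)
    stop("`marker_rate` must be > 0", call. = FALSE)
  if (length(analog) > 0L) {
    if (!is.finite(analog_rate) || analog_rate <= 0)
      stop("`analog_rate` required when analog channels are present", call. = FALSE)
    ratio <- analog_rate / marker_rate
    if (abs(ratio - round(ratio)) > 1e-9)
      stop("`analog_rate` must be an integer multiple of `marker_rate`", call. = FALSE)
  }
  structure(
    list(trial_id = as.character(trial_id), condition = condition, side = side,
         markers = markers, marker_rate = as.numeric(marker_rate),
         analog = analog, analog_rate = as.numeric(analog_rate),
         subject_id = as.character(subject_id)),
    class = "TrialRecording")
}

#' @export
print.TrialRecording <- function(x, ...) {
  nf <- if (length(x$markers)) nrow(x$markers[[1]]) else 0L
  cat(sprintf("TrialRecording '%s' (%s, %s side, subject %s)\n",
              x$trial_id, x$condition, x$side, x$subject_id))
  cat(sprintf("  %d markers x %d frames @ %g/s; %d analog channel(s)",
              length(x$markers), nf, x$marker_rate, length(x$analog)))
  if (length(x$analog)) cat(sprintf(" @ %g/s", x$analog_rate))
  cat("\n  markers:", paste(names(x$markers), collapse = ", "), "\n")
  invisible(x)
}

#' Number of marker frames in a trial
#' @param trial a [trial_recording()].
#' @return integer frame count.
#' @export
n_frames <- function(trial) {
  stopifnot(inherits(trial, "TrialRecording"))
  if (length(trial$markers)) nrow(trial$markers[[1]]) else 0L
}

#' Marker-set requirements of the three foot models
#'
#' All three models anchor the rear of the foot on the posterior calcaneus
#' marker `CA`.  The mono-segment models (PiG, DAV) define the foot axis with
#' a single forefoot marker (`MTH` for PiG, the distal `TOE` marker for DAV),
#' whereas the multi-segment OFM hindfoot needs the full calcaneal triad
#' (`CA`, medial `MCA`, lateral `LCA`) and never uses forefoot markers.
#' Every model needs the tibia set: lateral femoral epicondyle `KNE`, tibial
#' shaft `TIB`, and both malleoli `MMA`/`LMA`.
#'
#' @param model `"OFM"`, `"PiG"` or `"DAV"`.
#' @return A `MarkerSetSpec` list with `model`, `required_labels`,
#'   `optional_labels`.
#' @export
marker_set_spec <- function(model = c("OFM", "PiG", "DAV")) {
  model <- match.arg(model)
  tibia <- c("KNE", "TIB", "MMA", "LMA")
  req <- switch(model,
    OFM = c(tibia, "CA", "MCA", "LCA"),
    PiG = c(tibia, "CA", "MTH"),
    DAV = c(tibia, "CA", "TOE"))
  opt <- switch(model,
    OFM = c("MTH", "TOE", "HLX"),
    PiG = c("TOE", "MCA", "LCA"),
    DAV = c("MTH", "MCA", "LCA"))
  structure(list(model = model, required_labels = req, optional_labels = opt),
            class = "MarkerSetSpec")
}

#' Check a trial against a model's marker-set requirements
#'
#' Reports which required labels are unusable: absent from the trial, or
#' present but with too large a fraction of missing (occluded) samples.
#' Validation never throws.
#'
#' @param trial a [trial_recording()].
#' @param spec a [marker_set_spec()].
#' @param max_missing_frac maximum tolerated fraction of missing samples per
#'   required marker (default 0.1).
#' @return Character vector of missing/unusable labels (empty when valid).
#' @export
validate_marker_set <- function(trial, spec, max_missing_frac = 0.1) {
  stopifnot(inherits(trial, "TrialRecording"), inherits(spec, "MarkerSetSpec"))
  missing <- character(0)
  for (lab in spec$required_labels) {
    m <- trial$markers[[lab]]
    if (is.null(m)) { missing <- c(missing, lab); next }
    frac <- mean(!stats::complete.cases(m))
    if (frac > max_missing_frac) missing <- c(missing, lab)
  }
  missing
}

#' Gait events on the marker timeline
#'
#' Foot contacts and foot offs as marker-frame indices.  A gait cycle runs
#' from one foot contact to the next contact of the same side and must
#' enclose exactly one foot off.
#'
#' @param foot_contact_frames strictly increasing integer frame indices.
#' @param foot_off_frames strictly increasing integer frame indices.
#' @param source `"force_plate"` or `"provided"`.
#' @return A `GaitEvents` object.
#' @export
gait_events <- function(foot_contact_frames, foot_off_frames,
                        source = c("force_plate", "provided")) {
  source <- match.arg(source)
  fc <- as.numeric(foot_contact_frames); fo <- as.numeric(foot_off_frames)
  if (is.unsorted(fc, strictly = TRUE) || is.unsorted(fo, strictly = TRUE))
    stop("event frames must be strictly increasing", call. = FALSE)
  structure(list(foot_contact_frames = fc, foot_off_frames = fo,
                 source = source), class = "GaitEvents")
}

#' @export
print.GaitEvents <- function(x, ...) {
  cat(sprintf("GaitEvents (%s): %d contact(s), %d foot-off(s)\n", x$source,
              length(x$foot_contact_frames), length(x$foot_off_frames)))
  invisible(x)
}
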