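#' Read and write the plain-text trial fixture format
#'
#' The fixture format is a long CSV with header `frame,label,x,y,z` (one row
#' per visible marker per frame, positions in mm) plus a JSON sidecar holding
#' everything the CSV cannot: rates, condition, side, ids and analog
#' channels.  The sidecar lives next to the CSV with the `.csv` extension
#' replaced by `.json`.  Frames where a marker row is absent are read back
#' as missing (`NA`) samples, so a frame gap in the file round-trips to a
#' flagged-missing span, never to zeros.
#'
#' @param path path to the fixture CSV.
#' @return [read_fixture_csv()] returns a [trial_recording()];
#'   [write_fixture_csv()] returns `path` invisibly.
#' @seealso [read_c3d()] for the binary capture format.
#' @export
read_fixture_csv <- function(path) {
  sidecar <- fixture_sidecar_path(path)
  if (!file.exists(path)) stop("fixture CSV not found: ", path, call. = FALSE)
  if (!file.exists(sidecar))
    stop("missing sidecar JSON for fixture: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "label", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("fixture CSV must have columns frame,label,x,y,z", call. = FALSE)
  if (nrow(df) == 0L) stop("fixture CSV contains no marker samples", call. = FALSE)
  nf <- as.integer(meta$n_frames %||% max(df$frame))
  labels <- unique(df$label)
  markers <- vector("list", length(labels)); names(markers) <- labels
  for (lab in labels) {
    rows <- df[df$label == lab, , drop = FALSE]
    if (is.unsorted(rows$frame, strictly = TRUE))
      stop("non-monotone frames for marker ", lab, call. = FALSE)
    m <- matrix(NA_real_, nf, 3, dimnames = list(NULL, c("x", "y", "z")))
    m[rows$frame, ] <- as.matrix(rows[, c("x", "y", "z")])
    markers[[lab]] <- m
  }
  analog <- list()
  if (!is.null(meta$analog)) analog <- lapply(meta$analog, as.numeric)
  trial_recording(
    trial_id = meta$trial_id %||% basename(path),
    condition = meta$condition %||% "BF",
    side = meta$side %||% "right",
    markers = markers,
    marker_rate = as.numeric(meta$marker_rate %||% 250),
    analog = analog,
    analog_rate = as.numeric(meta$analog_rate %||% NA_real_),
    subject_id = meta$subject_id %||% "S01")
}

#' @rdname read_fixture_csv
#' @param trial a [trial_recording()] to serialize.
#' @export
write_fixture_csv <- function(trial, path) {
  stopifnot(inherits(trial, "TrialRecording"))
  nf <- n_frames(trial)
  pieces <- lapply(names(trial$markers), function(lab) {
    m <- trial$markers[[lab]]
    keep <- stats::complete.cases(m)
    if (!any(keep)) return(NULL)
    data.frame(frame = which(keep), label = lab,
               x = m[keep, 1], y = m[keep, 2], z = m[keep, 3])
  })
  df <- do.call(rbind, pieces)
  df <- df[order(df$label, df$frame), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(trial_id = trial$trial_id, condition = trial$condition,
               side = trial$side, subject_id = trial$subject_id,
               marker_rate = trial$marker_rate, n_frames = nf)
  if (length(trial$analog)) {
    meta$analog <- trial$analog
    meta$analog_rate <- trial$analog_rate
  }
  jsonlite::write_json(meta, fixture_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

fixture_sidecar_path <- function(path) sub("\\.csv$", ".json", path)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write gait events as JSON
#'
#' Events JSON holds two arrays of marker-frame indices:
#' `{"foot_contact_frames": [...], "foot_off_frames": [...]}`.
#'
#' @param path path to the JSON file.
#' @return [read_events_json()] returns a [gait_events()] with source
#'   `"provided"`.
#' @export
read_events_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gait_events(x$foot_contact_frames, x$foot_off_frames, source = "provided")
}

#' @rdname read_events_json
#' @param events a [gait_events()] object.
#' @export
write_events_json <- function(events, path) {
  stopifnot(inherits(events, "GaitEvents"))
  jsonlite::write_json(
    list(foot_contact_frames = events$foot_contact_frames,
         foot_off_frames = events$foot_off_frames),
    path, digits = NA)
  invisible(path)
}

#' Marker label aliasing
#'
#' Capture systems label markers in vendor dialects (e.g. Vicon `RHEE` for
#' the posterior calcaneus).  An alias map is a named character vector
#' `c(alias = canonical)`; [apply_alias_map()] renames a trial's markers to
#' the canonical vocabulary used by [marker_set_spec()].  Labels without an
#' alias entry pass through unchanged, so applying a map twice is a no-op.
#' The default map ships as editable JSON in
#' `system.file("extdata", "marker_aliases.json", package = "itwgait")`.
#'
#' @param path optional path to an alias JSON file (an object mapping alias
#'   to canonical label); the packaged default is used when omitted.
#' @return named character vector mapping alias to canonical label.
#' @export
read_alias_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "marker_aliases.json", package = "itwgait")
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_alias_map
#' @param trial a [trial_recording()].
#' @param alias_map named character vector `c(alias = canonical)`.
#' @export
apply_alias_map <- function(trial, alias_map) {
  stopifnot(inherits(trial, "TrialRecording"))
  labs <- names(trial$markers)
  hit <- labs %in% names(alias_map)
  labs[hit] <- unname(alias_map[labs[hit]])
  if (anyDuplicated(labs))
    stop("alias map produces duplicate marker labels", call. = FALSE)
  names(trial$markers) <- labs
  trial
}
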