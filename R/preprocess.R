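#' Low-pass filter specification
#'
#' Marker trajectories are low-pass filtered before any angle computation.
#' The default is the conventional gait-analysis choice: a fourth-order
#' Butterworth with a 12 Hz cutoff, applied with zero phase lag.  Zero phase
#' is realized as a forward-backward pass of a half-order (2nd-order) design,
#' giving the net fourth-order attenuation without shifting the timing of
#' kinematic features - essential here because peak timings expressed in
#' % gait cycle are clinical outcomes.
#'
#' @param cutoff_hz cutoff frequency in Hz (default 12).
#' @param order net filter order (default 4); must be even when `zero_phase`.
#' @param zero_phase logical; forward-backward filtering (default `TRUE`).
#' @return a `FilterSpec` object.
#' @export
filter_spec <- function(cutoff_hz = 12, order = 4, zero_phase = TRUE) {
  stopifnot(cutoff_hz > 0, order >= 1)
  if (zero_phase && order %% 2 != 0)
    stop("`order` must be even for zero-phase filtering", call. = FALSE)
  structure(list(cutoff_hz = cutoff_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)), class = "FilterSpec")
}

#' Zero-phase Butterworth low-pass filtering
#'
#' Filters a uniformly sampled series.  With `zero_phase = TRUE` (default) a
#' Butterworth design of half the requested order is run forward then
#' backward, so the magnitude response is that of the full requested order
#' and the phase response is identically zero.  Edge transients are
#' suppressed by odd-symmetric end padding plus steady-state initial
#' conditions, which makes the DC gain exactly 1 (a constant series passes
#' through unchanged).
#'
#' @param series numeric vector (or matrix, filtered column-wise).
#' @param rate sampling rate in samples/s.
#' @param spec a [filter_spec()].
#' @return filtered series, same shape as the input.
#' @export
butterworth_lowpass <- function(series, rate, spec = filter_spec()) {
  stopifnot(inherits(spec, "FilterSpec"), rate > 0)
  if (spec$cutoff_hz >= rate / 2)
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  if (is.matrix(series))
    return(apply(series, 2, butterworth_lowpass, rate = rate, spec = spec))
  n <- length(series)
  pass_order <- if (spec$zero_phase) spec$order %/% 2L else spec$order
  if (n <= 3L * spec$order)
    stop("series too short for the requested filter order", call. = FALSE)
  ba <- signal::butter(pass_order, spec$cutoff_hz / (rate / 2), type = "low")
  y <- filt_pass(series, ba$b, ba$a)
  if (spec$zero_phase) y <- rev(filt_pass(rev(y), ba$b, ba$a))
  y
}

# One causal pass with odd-reflection padding and steady-state initial
# conditions (init.x/init.y at the first padded value), so DC gain is exact.
filt_pass <- function(x, b, a) {
  n <- length(x)
  ord <- length(a) - 1L
  np <- min(n - 1L, max(12L, 3L * ord))
  pad <- 2 * x[1] - x[seq(np + 1L, 2L, by = -1L)]
  xp <- c(pad, x)
  y <- signal::filter(b, a, xp, init.x = rep(xp[1], ord),
                      init.y = rep(xp[1], ord))
  as.numeric(y)[np + seq_len(n)]
}

#' Filter every marker trajectory of a trial
#'
#' Applies [butterworth_lowpass()] to each coordinate of each marker.  The
#' pipeline filters raw marker coordinates, never computed joint angles;
#' angle computation happens downstream of this step.  Markers with missing
#' spans are filtered per contiguous visible segment when the segment is
#' long enough, otherwise left untouched.
#'
#' @param trial a [trial_recording()].
#' @param spec a [filter_spec()].
#' @return the trial with filtered marker coordinates.
#' @export
filter_trial <- function(trial, spec = filter_spec()) {
  stopifnot(inherits(trial, "TrialRecording"))
  min_len <- 3L * spec$order + 1L
  trial$markers <- lapply(trial$markers, function(m) {
    ok <- stats::complete.cases(m)
    if (all(ok)) return(butterworth_lowpass(m, trial$marker_rate, spec))
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len)) {
      i <- starts[k]:ends[k]
      m[i, ] <- butterworth_lowpass(m[i, , drop = FALSE], trial$marker_rate, spec)
    }
    m
  })
  trial
}

#' Detect gait events from a vertical ground-reaction-force channel
#'
#' Foot contact is the first analog sample where the vertical GRF rises
#' above `threshold` and stays above it for at least `debounce` samples;
#' foot off is the first subsequent sample where it falls below and stays
#' below for the same hold time.  Short spikes and dropouts are thereby
#' ignored.  Event indices are converted from the analog to the marker
#' timeline by the rate ratio.
#'
#' @param vertical_grf numeric vector of vertical force in N, on the analog
#'   timeline.
#' @param analog_rate,marker_rate sampling rates in samples/s.
#' @param threshold force threshold in N (default 20).
#' @param debounce hold time in analog samples (default 10 ms worth).
#' @return a [gait_events()] with source `"force_plate"`; empty (with a
#'   warning) when the GRF never crosses the threshold.
#' @export
detect_gait_events <- function(vertical_grf, analog_rate, marker_rate,
                               threshold = 20,
                               debounce = round(0.010 * analog_rate)) {
  stopifnot(threshold > 0, analog_rate > 0, marker_rate > 0)
  debounce <- max(1L, as.integer(debounce))
  above <- vertical_grf > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$lengths >= debounce
  # runs shorter than the hold time are merged into their neighbours
  state <- NA; contacts <- integer(0); offs <- integer(0)
  for (k in seq_along(r$values)) {
    if (!keep[k]) next
    if (r$values[k] && !isTRUE(state)) { contacts <- c(contacts, starts[k]); state <- TRUE }
    if (!r$values[k] && isTRUE(state)) { offs <- c(offs, starts[k]); state <- FALSE }
  }
  if (length(contacts) == 0L) {
    warning("vertical GRF never crosses the threshold; no events detected")
    return(gait_events(numeric(0), numeric(0), source = "force_plate"))
  }
  ratio <- analog_rate / marker_rate
  to_marker <- function(i) round((i - 1L) / ratio) + 1L
  gait_events(to_marker(contacts), to_marker(offs), source = "force_plate")
}

#' A time-normalized gait cycle of the sagittal ankle angle
#'
#' @param samples numeric vector of exactly 101 finite angle values (deg,
#'   dorsiflexion positive) at 0, 1, ..., 100 % of the gait cycle.
#' @param stance_end_pct foot-off instant in % gait cycle, in (0, 100).
#' @param model,condition,subject_id,cycle_id metadata carried along.
#' @return a `NormalizedCycle` object.
#' @export
normalized_cycle <- function(samples, stance_end_pct, model = "OFM",
                             condition = "BF", subject_id = "S01",
                             cycle_id = "c1") {
  samples <- as.numeric(samples)
  if (length(samples) != 101L) stop("a cycle has exactly 101 samples", call. = FALSE)
  if (!all(is.finite(samples))) stop("cycle samples must be finite", call. = FALSE)
  if (!(stance_end_pct > 0 && stance_end_pct < 100))
    stop("stance_end_pct must lie in (0, 100)", call. = FALSE)
  structure(list(samples = samples, stance_end_pct = as.numeric(stance_end_pct),
                 model = model, condition = condition,
                 subject_id = subject_id, cycle_id = cycle_id),
            class = "NormalizedCycle")
}

#' @export
print.NormalizedCycle <- function(x, ...) {
  cat(sprintf(
    "NormalizedCycle %s/%s (%s, %s): range [%.1f, %.1f] deg, foot off %.1f%% GC\n",
    x$subject_id, x$cycle_id, x$model, x$condition,
    min(x$samples), max(x$samples), x$stance_end_pct))
  invisible(x)
}

#' Time-normalize an angle trace into 101-sample gait cycles
#'
#' Each span from one foot contact to the next is linearly resampled to 101
#' points (0-100 % gait cycle, both contacts included).  The foot-off
#' enclosed by the span sets `stance_end_pct`.  Cycles without exactly one
#' enclosed foot off, or overlapping non-finite angle samples, are skipped
#' with a warning.
#'
#' @param angle_series numeric vector of angles (deg) on the marker timeline.
#' @param events a [gait_events()] with at least two foot contacts.
#' @param model,condition,subject_id metadata stamped on each cycle.
#' @return list of [normalized_cycle()] objects.
#' @export
time_normalize <- function(angle_series, events, model = "OFM",
                           condition = "BF", subject_id = "S01") {
  stopifnot(inherits(events, "GaitEvents"))
  fc <- events$foot_contact_frames
  if (length(fc) < 2L) stop("need at least two foot contacts", call. = FALSE)
  out <- list()
  for (k in seq_len(length(fc) - 1L)) {
    i0 <- fc[k]; i1 <- fc[k + 1L]
    fo <- events$foot_off_frames[events$foot_off_frames > i0 &
                                 events$foot_off_frames < i1]
    if (length(fo) != 1L) {
      warning(sprintf("cycle %d has %d enclosed foot-off(s); skipped",
                      k, length(fo)))
      next
    }
    seg <- angle_series[i0:i1]
    if (!all(is.finite(seg))) {
      warning(sprintf("cycle %d overlaps missing angle samples; skipped", k))
      next
    }
    pct_in <- seq(0, 100, length.out = length(seg))
    samples <- stats::approx(pct_in, seg, xout = 0:100)$y
    out[[length(out) + 1L]] <- normalized_cycle(
      samples, stance_end_pct = 100 * (fo - i0) / (i1 - i0),
      model = model, condition = condition, subject_id = subject_id,
      cycle_id = sprintf("c%d", k))
  }
  out
}
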