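#' Foot-model conventions
#'
#' Per-model construction choices: which forefoot marker defines the
#' mono-segment foot axis (the metatarsal marker `MTH` for PiG, the distal
#' `TOE` marker for DAV), whether the static-trial sagittal offset is
#' subtracted (PiG and OFM: yes; DAV reports the raw anatomical angle), and
#' whether the model is multi-segment.  All three models share the
#' posterior-calcaneus marker `CA` as the rear anchor of the foot (or
#' hindfoot) longitudinal axis; they differ in the anterior anchor, which is
#' exactly what makes mono-segment models fold midfoot motion into the
#' ankle angle.
#'
#' @param model `"OFM"`, `"PiG"` or `"DAV"`.
#' @param forefoot_label override the forefoot marker label.
#' @param apply_static_offset override the static-offset convention.
#' @return a `FootModelConfig` list.
#' @export
foot_model_config <- function(model = c("OFM", "PiG", "DAV"),
                              forefoot_label = NULL,
                              apply_static_offset = NULL) {
  model <- match.arg(model)
  cfg <- switch(model,
    OFM = list(multi_segment = TRUE, forefoot_label = NA_character_,
               apply_static_offset = TRUE),
    PiG = list(multi_segment = FALSE, forefoot_label = "MTH",
               apply_static_offset = TRUE),
    DAV = list(multi_segment = FALSE, forefoot_label = "TOE",
               apply_static_offset = FALSE))
  if (!is.null(forefoot_label)) cfg$forefoot_label <- forefoot_label
  if (!is.null(apply_static_offset)) cfg$apply_static_offset <- apply_static_offset
  structure(c(list(model = model), cfg), class = "FootModelConfig")
}

LAB_UP <- c(0, 0, 1)

# ---- tibia ------------------------------------------------------------------

tibia_frames <- function(mma, lma, kne, side, knee_width = 80) {
  mma <- as_mat3(mma); lma <- as_mat3(lma); kne <- as_mat3(kne)
  ajc <- (mma + lma) / 2
  medial <- vnormalize(mma - lma, "malleolar line")
  knee_center <- kne + (knee_width / 2) * medial
  z <- vnormalize(knee_center - ajc, "tibia longitudinal axis")
  yraw <- if (side == "right") mma - lma else lma - mma
  yproj <- vreject(yraw, z)
  if (any(vnorm(yproj) < 1e-6 * vnorm(yraw), na.rm = TRUE))
    stop("degenerate geometry: malleoli collinear with the knee center",
         call. = FALSE)
  y <- vnormalize(yproj, "tibia flexion axis")
  x <- vcross(y, z)
  frame_series(ajc, x, y, z)
}

#' Build the tibia anatomical frame
#'
#' The tibia longitudinal axis runs from the ankle joint center (the
#' inter-malleolar midpoint) to the knee joint center, approximated from the
#' lateral femoral epicondyle marker `KNE` shifted half a knee width along
#' the malleolar (medial) direction.  The flexion axis is the malleolar line
#' projected orthogonal to the longitudinal axis, oriented to the subject's
#' left; the anterior axis completes the right-handed triad.  Origin: ankle
#' joint center.
#'
#' @param markers named list of 3-vectors (mm): `MMA`, `LMA`, `KNE`
#'   required (`TIB` is used only for marker-set validation).
#' @param side `"left"` or `"right"`.
#' @param knee_width knee width in mm used to reach the knee center from the
#'   lateral epicondyle (default 80).
#' @return a [segment_frame()].
#' @export
build_tibia_frame <- function(markers, side = c("right", "left"),
                              knee_width = 80) {
  side <- match.arg(side)
  req_markers(markers, c("MMA", "LMA", "KNE"))
  single_frame(tibia_frames(markers$MMA, markers$LMA, markers$KNE, side,
                            knee_width))
}

# ---- mono-segment foot (PiG / DAV) -----------------------------------------

mono_foot_frames <- function(ca, ff) {
  ca <- as_mat3(ca); ff <- as_mat3(ff)
  if (any(vnorm(ff - ca) < 1e-6, na.rm = TRUE))
    stop("degenerate geometry: CA coincides with the forefoot marker",
         call. = FALSE)
  x <- vnormalize(ff - ca, "foot longitudinal axis")
  up <- matrix(LAB_UP, nrow(x), 3, byrow = TRUE)
  y0 <- vcross(up, x)
  if (any(vnorm(y0) < 1e-6, na.rm = TRUE))
    stop("degenerate geometry: foot axis is vertical", call. = FALSE)
  y <- vnormalize(y0, "foot flexion axis")
  z <- vcross(x, y)
  frame_series(ca, x, y, z)
}

#' Build the mono-segment foot frame (PiG / DAV)
#'
#' The foot longitudinal axis runs from the posterior calcaneus marker `CA`
#' to the forefoot marker (`MTH` for PiG, `TOE` for DAV); the sagittal plane
#' contains that axis and the laboratory vertical.  Because the axis spans
#' two bones that are not rigidly linked, any midfoot (intrinsic foot)
#' motion changes its pitch and is read as ankle motion - the defining
#' limitation of mono-segment foot models.  Origin: `CA`.
#'
#' @param markers named list of 3-vectors (mm) containing `CA` and the
#'   variant's forefoot marker.
#' @param variant `"PiG"` or `"DAV"`.
#' @param side `"left"` or `"right"` (the frame is side-independent; kept
#'   for interface symmetry).
#' @return a [segment_frame()].
#' @export
build_foot_frame_mono <- function(markers, variant = c("PiG", "DAV"),
                                  side = c("right", "left")) {
  variant <- match.arg(variant); side <- match.arg(side)
  ff_lab <- foot_model_config(variant)$forefoot_label
  req_markers(markers, c("CA", ff_lab))
  single_frame(mono_foot_frames(markers$CA, markers[[ff_lab]]))
}

# ---- OFM hindfoot -----------------------------------------------------------

# Calcaneus-local orthonormal triad frame (origin CA), used to pin the
# virtual anterior point rigidly to the calcaneus.
calcaneus_triad <- function(ca, mca, lca) {
  t1 <- mca - ca; t2 <- lca - ca
  nrm <- vcross(t1, t2)
  if (any(vnorm(nrm) < 1e-6 * pmax(vnorm(t1) * vnorm(t2), 1e-12), na.rm = TRUE))
    stop("degenerate geometry: calcaneus markers are collinear", call. = FALSE)
  e1 <- vnormalize(t1, "calcaneus triad")
  e3 <- vnormalize(nrm, "calcaneus triad normal")
  e2 <- vcross(e3, e1)
  list(origin = ca, e1 = e1, e2 = e2, e3 = e3)
}

hindfoot_frames <- function(ca, mca, lca, side, v_local = NULL,
                            virtual_length = 60) {
  ca <- as_mat3(ca); mca <- as_mat3(mca); lca <- as_mat3(lca)
  n <- nrow(ca)
  tri <- calcaneus_triad(ca, mca, lca)
  nsag <- vnormalize(if (side == "right") mca - lca else lca - mca,
                     "hindfoot sagittal normal")
  if (is.null(v_local)) {
    # calibration construction: virtual anterior point along the
    # intersection of the calcaneal sagittal plane with the horizontal plane
    up <- matrix(LAB_UP, n, 3, byrow = TRUE)
    d <- vcross(nsag, up)
    if (any(vnorm(d) < 1e-6, na.rm = TRUE))
      stop("degenerate geometry: calcaneal sagittal plane is horizontal",
           call. = FALSE)
    d <- vnormalize(d, "virtual-point direction")
    fwd <- (mca + lca) / 2 - ca
    flip <- vdot(d, fwd) < 0
    d[flip, ] <- -d[flip, , drop = FALSE]
    v_lab <- ca + virtual_length * d
  } else {
    v_lab <- tri$origin + v_local[1] * tri$e1 + v_local[2] * tri$e2 +
      v_local[3] * tri$e3
  }
  x <- vnormalize(v_lab - ca, "hindfoot longitudinal axis")
  y <- vnormalize(vreject(nsag, x), "hindfoot flexion axis")
  z <- vcross(x, y)
  fs <- frame_series(ca, x, y, z)
  fs$virtual_local <- cbind(vdot(v_lab - tri$origin, tri$e1),
                            vdot(v_lab - tri$origin, tri$e2),
                            vdot(v_lab - tri$origin, tri$e3))
  fs
}

#' Build the OFM hindfoot frame
#'
#' The hindfoot frame depends only on the three calcaneus markers (`CA`
#' posterior, `MCA` medial/sustentaculum tali, `LCA` lateral) - never on
#' forefoot markers.  The hindfoot sagittal plane is normal to the
#' medial-lateral calcaneal line; the longitudinal axis runs from `CA`
#' toward a virtual anterior calcaneal point.  At calibration the virtual
#' point is placed `virtual_length` mm from `CA` along the intersection of
#' the calcaneal sagittal plane with the horizontal plane, then pinned in
#' calcaneus-local coordinates so it moves rigidly with the calcaneus in
#' every subsequent frame (pass `v_local` from [static_calibration()]).
#' Origin: `CA`.
#'
#' @param markers named list of 3-vectors (mm): `CA`, `MCA`, `LCA`.
#' @param side `"left"` or `"right"`.
#' @param v_local optional length-3 numeric: virtual point in
#'   calcaneus-local coordinates from a static calibration.  When `NULL`
#'   the calibration construction is used on this frame itself.
#' @param virtual_length distance mm of the virtual point from `CA`
#'   (default 60; used only when `v_local` is `NULL`).
#' @return a [segment_frame()]; the calcaneus-local virtual point is
#'   attached as attribute `"virtual_local"`.
#' @export
build_hindfoot_frame_ofm <- function(markers, side = c("right", "left"),
                                     v_local = NULL, virtual_length = 60) {
  side <- match.arg(side)
  req_markers(markers, c("CA", "MCA", "LCA"))
  fs <- hindfoot_frames(markers$CA, markers$MCA, markers$LCA, side,
                        v_local = v_local, virtual_length = virtual_length)
  out <- single_frame(fs)
  attr(out, "virtual_local") <- as.numeric(fs$virtual_local[1, ])
  out
}

req_markers <- function(markers, labels) {
  miss <- setdiff(labels, names(markers))
  if (length(miss))
    stop("missing required marker(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

# ---- sagittal angle ---------------------------------------------------------

# Decompose the tibia-to-foot rotation with the flexion (y) axis first:
# R_rel = Ry(alpha) Rx(beta) Rz(gamma).  Dorsiflexion (toe-up) is -alpha.
# Vectorized over frames; returns list(angle, beta) in degrees.
sagittal_decompose <- function(tib, foot) {
  # R_rel[i] = t(Rt) %*% Rf with columns (x, y, z); we need entries
  # M13 = tib_x . foot_z ; M33 = tib_z . foot_z ; M23 = tib_y . foot_z
  m13 <- vdot(tib$x, foot$z)
  m23 <- vdot(tib$y, foot$z)
  m33 <- vdot(tib$z, foot$z)
  alpha <- atan2(m13, m33)
  beta <- -asin(pmin(1, pmax(-1, m23)))
  list(angle = -alpha * 180 / pi, beta = beta * 180 / pi)
}

#' Sagittal ankle angle between tibia and foot frames
#'
#' The rotation from the tibia frame to the foot (or hindfoot) frame is
#' decomposed with the flexion (mediolateral) axis first; the leading
#' rotation angle, minus the static neutral offset, is returned with
#' dorsiflexion positive and wrapped to (-180, 180].  Samples where the
#' second (inversion) rotation comes within 1 degree of +/-90 degrees are
#' gimbal-flagged and returned as `NA`.
#'
#' @param tibia,foot [segment_frame()] objects.
#' @param offsets a [static_calibration()] result, or `NULL` for the raw
#'   anatomical angle.
#' @return angle in degrees (scalar).
#' @export
sagittal_angle <- function(tibia, foot, offsets = NULL) {
  stopifnot(inherits(tibia, "SegmentFrame"), inherits(foot, "SegmentFrame"))
  tf <- list(x = rbind(tibia$x_axis), y = rbind(tibia$y_axis),
             z = rbind(tibia$z_axis))
  ff <- list(x = rbind(foot$x_axis), y = rbind(foot$y_axis),
             z = rbind(foot$z_axis))
  d <- sagittal_decompose(tf, ff)
  ang <- d$angle - if (is.null(offsets)) 0 else offsets$neutral_angle_deg
  ang <- wrap_deg(ang)
  if (abs(abs(d$beta) - 90) < 1) {
    warning("gimbal proximity: inversion angle within 1 deg of +/-90")
    ang <- NA_real_
  }
  ang
}

wrap_deg <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[!is.na(a) & a == -180] <- 180
  a
}

# ---- calibration + traces ---------------------------------------------------

marker_mat <- function(trial, lab) {
  m <- trial$markers[[lab]]
  if (is.null(m)) stop("missing required marker(s): ", lab, call. = FALSE)
  m
}

# frame series for one trial/model; offsets may carry the OFM virtual point
model_frame_series <- function(trial, model, v_local = NULL,
                               knee_width = 80, virtual_length = 60) {
  cfg <- foot_model_config(model)
  tib <- tibia_frames(marker_mat(trial, "MMA"), marker_mat(trial, "LMA"),
                      marker_mat(trial, "KNE"), trial$side, knee_width)
  foot <- if (cfg$multi_segment) {
    hindfoot_frames(marker_mat(trial, "CA"), marker_mat(trial, "MCA"),
                    marker_mat(trial, "LCA"), trial$side, v_local = v_local,
                    virtual_length = virtual_length)
  } else {
    mono_foot_frames(marker_mat(trial, "CA"),
                     marker_mat(trial, cfg$forefoot_label))
  }
  list(tibia = tib, foot = foot)
}

#' Static calibration of a foot model
#'
#' Computes the subject's neutral sagittal offset from a static standing
#' trial: the time-average raw sagittal angle, subtracted from dynamic
#' trials so the static pose reads `reference_deg` (default 0).  For OFM the
#' calibration also fixes the virtual anterior calcaneal point in
#' calcaneus-local coordinates (averaged over the static trial), making the
#' hindfoot axis rigid with the calcaneus thereafter.  Models whose
#' convention does not zero the static pose (DAV) record the measured
#' neutral angle but report `neutral_angle_deg = reference` behaviour via
#' `apply_static_offset = FALSE` in [foot_model_config()].
#'
#' @param static_trial a STATIC [trial_recording()] with all required
#'   markers visible for at least 1 s.
#' @param model `"OFM"`, `"PiG"` or `"DAV"`.
#' @param side `"left"` or `"right"`; defaults to the trial's side.
#' @param reference_deg angle the static pose should read after offsetting.
#' @param knee_width,virtual_length geometry constants, see
#'   [build_tibia_frame()] and [build_hindfoot_frame_ofm()].
#' @return a `CalibrationOffsets` object with `neutral_angle_deg` and, for
#'   OFM, the calcaneus-local virtual point `v_local`.
#' @export
static_calibration <- function(static_trial, model, side = static_trial$side,
                               reference_deg = 0, knee_width = 80,
                               virtual_length = 60) {
  stopifnot(inherits(static_trial, "TrialRecording"))
  cfg <- foot_model_config(model)
  spec <- marker_set_spec(model)
  miss <- validate_marker_set(static_trial, spec)
  if (length(miss))
    stop("static trial unusable; missing marker(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  visible <- Reduce(`&`, lapply(static_trial$markers[spec$required_labels],
                                stats::complete.cases))
  if (sum(visible) < static_trial$marker_rate)
    stop("insufficient static data: need >= 1 s with all markers visible",
         call. = FALSE)
  st <- static_trial
  st$side <- side
  fr <- model_frame_series(st, model, knee_width = knee_width,
                           virtual_length = virtual_length)
  d <- sagittal_decompose(fr$tibia, fr$foot)
  raw_mean <- mean(d$angle[visible])
  v_local <- if (cfg$multi_segment)
    colMeans(fr$foot$virtual_local[visible, , drop = FALSE]) else NULL
  structure(list(
    model = model, side = side,
    neutral_angle_deg = if (cfg$apply_static_offset)
      raw_mean - reference_deg else 0,
    measured_static_deg = raw_mean,
    v_local = v_local, knee_width = knee_width,
    virtual_length = virtual_length), class = "CalibrationOffsets")
}

#' @export
print.CalibrationOffsets <- function(x, ...) {
  cat(sprintf("CalibrationOffsets %s (%s): neutral %.2f deg (static %.2f deg)\n",
              x$model, x$side, x$neutral_angle_deg, x$measured_static_deg))
  invisible(x)
}

#' Compute the sagittal ankle angle trace of a trial under a foot model
#'
#' Builds the tibia and foot/hindfoot frames at every marker frame and
#' extracts the sagittal angle (dorsiflexion positive), minus the static
#' neutral offset.  OFM uses the calcaneus-only hindfoot frame (with the
#' calibrated virtual point); PiG and DAV use the CA-to-forefoot
#' mono-segment frame.  Frames with missing markers yield `NA` samples;
#' gimbal-flagged samples are also `NA` and counted in `n_flagged`.
#'
#' @param trial a [trial_recording()].
#' @param model `"OFM"`, `"PiG"` or `"DAV"`.
#' @param offsets the model's [static_calibration()] for this subject/side;
#'   `NULL` gives the raw (uncalibrated) angle.
#' @return an `AnkleAngleTrace`: list with `values` (deg per marker frame),
#'   `model`, `trial_id`, `n_flagged`.
#' @export
compute_ankle_trace <- function(trial, model, offsets = NULL) {
  stopifnot(inherits(trial, "TrialRecording"))
  spec <- marker_set_spec(model)
  for (lab in spec$required_labels) marker_mat(trial, lab)
  cfg <- foot_model_config(model)
  if (cfg$multi_segment && is.null(offsets$v_local) && !is.null(offsets))
    stop("OFM offsets must carry the calibrated virtual point", call. = FALSE)
  fr <- model_frame_series(
    trial, model, v_local = offsets$v_local,
    knee_width = offsets$knee_width %||% 80,
    virtual_length = offsets$virtual_length %||% 60)
  d <- sagittal_decompose(fr$tibia, fr$foot)
  vals <- wrap_deg(d$angle - (offsets$neutral_angle_deg %||% 0))
  gimbal <- !is.na(d$beta) & abs(abs(d$beta) - 90) < 1
  vals[gimbal] <- NA_real_
  structure(list(values = vals, model = model, trial_id = trial$trial_id,
                 n_flagged = sum(gimbal)), class = "AnkleAngleTrace")
}

#' @export
print.AnkleAngleTrace <- function(x, ...) {
  ok <- is.finite(x$values)
  cat(sprintf("AnkleAngleTrace %s (%s): %d frames, range [%.1f, %.1f] deg, %d flagged\n",
              x$trial_id, x$model, length(x$values),
              min(x$values[ok]), max(x$values[ok]), x$n_flagged))
  invisible(x)
}
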