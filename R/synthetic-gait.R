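#' Ankle waveform shape parameters
#'
#' Describes one 101-sample sagittal ankle waveform by its clinically
#' relevant landmarks.  Two named profiles set the defaults: `heel_toe`
#' emulates orthosis-corrected gait (foot contact near neutral, an early
#' plantarflexion dip - the heel rocker - and peak dorsiflexion in late
#' stance), while `toe_walking` emulates barefoot idiopathic toe walking
#' (plantarflexed contact below -5 deg, no heel rocker, peak dorsiflexion
#' before 30 % of the cycle).  The two profiles therefore fall on opposite
#' sides of both rocker-classification thresholds by construction.
#'
#' @param profile `"heel_toe"` or `"toe_walking"`.
#' @param angle_at_fc angle at foot contact, deg.
#' @param peak_df global stance maximum, deg, at `t_peak_df` % GC.
#' @param peak_pf global minimum, deg, at `t_peak_pf` % GC.
#' @param t_peak_df,t_peak_pf timings in % GC, `t_peak_df < t_peak_pf`.
#' @param stance_end_pct foot off, % GC.
#' @param early_dip_deg,early_dip_pct optional loading-response dip (the
#'   heel-rocker excursion); `early_dip_deg = 0` disables it.
#' @param harmonics number of Fourier harmonics kept when smoothing the
#'   knot-interpolated curve; 0 gives a constant waveform at `angle_at_fc`.
#' @return a `WaveformParams` object.
#' @export
waveform_params <- function(profile = c("heel_toe", "toe_walking"),
                            angle_at_fc = NULL, peak_df = NULL,
                            t_peak_df = NULL, peak_pf = NULL,
                            t_peak_pf = NULL, stance_end_pct = NULL,
                            early_dip_deg = NULL, early_dip_pct = 8,
                            harmonics = 12) {
  profile <- match.arg(profile)
  def <- if (profile == "heel_toe") {
    list(angle_at_fc = 0, peak_df = 10, t_peak_df = 45, peak_pf = -15,
         t_peak_pf = 65, stance_end_pct = 60, early_dip_deg = -4)
  } else {
    list(angle_at_fc = -10, peak_df = -2, t_peak_df = 20, peak_pf = -18,
         t_peak_pf = 62, stance_end_pct = 62, early_dip_deg = 0)
  }
  p <- list(profile = profile,
            angle_at_fc = angle_at_fc %||% def$angle_at_fc,
            peak_df = peak_df %||% def$peak_df,
            t_peak_df = t_peak_df %||% def$t_peak_df,
            peak_pf = peak_pf %||% def$peak_pf,
            t_peak_pf = t_peak_pf %||% def$t_peak_pf,
            stance_end_pct = stance_end_pct %||% def$stance_end_pct,
            early_dip_deg = early_dip_deg %||% def$early_dip_deg,
            early_dip_pct = early_dip_pct, harmonics = harmonics)
  if (p$peak_df < p$angle_at_fc && p$t_peak_df > 0)
    stop("infeasible waveform: peak_df below angle_at_fc", call. = FALSE)
  if (p$peak_pf > min(p$angle_at_fc, p$peak_df))
    stop("infeasible waveform: peak_pf is not the global minimum", call. = FALSE)
  if (!(p$t_peak_df < p$t_peak_pf))
    stop("infeasible waveform: need t_peak_df < t_peak_pf", call. = FALSE)
  if (p$early_dip_deg != 0 && !(p$early_dip_pct < p$t_peak_df))
    stop("infeasible waveform: early dip must precede peak dorsiflexion",
         call. = FALSE)
  structure(p, class = "WaveformParams")
}

#' Generate a smooth periodic ankle waveform from its landmarks
#'
#' Builds a C1 periodic curve through the landmark knots (foot contact,
#' optional early dip, peak dorsiflexion, peak plantarflexion, return to the
#' contact angle at 100 %) using half-cosine easing between knots - every
#' knot has zero slope, so the requested peaks are exact local extrema with
#' no overshoot - then smooths by truncating the Fourier series to
#' `harmonics` harmonics.  Running [extract_parameters()] on the result
#' recovers the requested landmarks within 0.5 deg / 1 % GC.
#'
#' @param params a [waveform_params()].
#' @return numeric vector of 101 samples (deg) at 0..100 % GC.
#' @export
generate_ankle_waveform <- function(params) {
  stopifnot(inherits(params, "WaveformParams"))
  if (params$harmonics == 0) return(rep(params$angle_at_fc, 101))
  kt <- c(0, params$t_peak_df, params$t_peak_pf, 100)
  kv <- c(params$angle_at_fc, params$peak_df, params$peak_pf,
          params$angle_at_fc)
  if (params$early_dip_deg != 0) {
    kt <- c(kt[1], params$early_dip_pct, kt[-1])
    kv <- c(kv[1], params$angle_at_fc + params$early_dip_deg, kv[-1])
  }
  fourier_truncate(cosine_knot_curve(kt, kv), params$harmonics)
}

# keep harmonics 0..k of a periodic 101-sample waveform (s[1] == s[101])
fourier_truncate <- function(y, k) {
  x <- y[1:100]
  co <- stats::fft(x)
  n <- length(x)
  keep <- c(seq_len(k + 1L), seq(n - k + 1L, n))
  co[setdiff(seq_len(n), keep)] <- 0
  x2 <- Re(stats::fft(co, inverse = TRUE)) / n
  c(x2, x2[1])
}

#' Synthetic subject configuration
#'
#' Geometry and motion parameters of one simulated subject.  Waveforms give
#' the hindfoot-tibia (true ankle) angle per walking condition; the midfoot
#' amplitudes drive a sagittal hinge between hindfoot and forefoot whose
#' motion a mono-segment foot model folds into the ankle.
#'
#' @param subject_id character id.
#' @param tibia_length,foot_length segment lengths, mm.
#' @param bf_waveform,fo_waveform [waveform_params()] per condition.
#' @param midfoot_amplitude_bf,midfoot_amplitude_fo peak midfoot
#'   plantarflexion, deg, per condition.
#' @param noise_sd isotropic Gaussian marker noise SD, mm.
#' @param mass_kg body mass, scales the synthetic GRF.
#' @param cycle_duration_s gait cycle duration, s.
#' @param seed integer RNG seed; a fixed seed makes the subject's trials
#'   bit-reproducible.
#' @return a `SyntheticSubjectConfig` object.
#' @export
synthetic_subject_config <- function(subject_id = "S01", tibia_length = 400,
                                     foot_length = 170,
                                     bf_waveform = waveform_params("toe_walking"),
                                     fo_waveform = waveform_params("heel_toe"),
                                     midfoot_amplitude_bf = 15,
                                     midfoot_amplitude_fo = 0,
                                     noise_sd = 0.5, mass_kg = 37,
                                     cycle_duration_s = 1.04, seed = 1L) {
  stopifnot(tibia_length > 0, foot_length > 0, noise_sd >= 0, mass_kg > 0)
  structure(list(subject_id = subject_id, tibia_length = tibia_length,
                 foot_length = foot_length, bf_waveform = bf_waveform,
                 fo_waveform = fo_waveform,
                 midfoot_amplitude_bf = midfoot_amplitude_bf,
                 midfoot_amplitude_fo = midfoot_amplitude_fo,
                 noise_sd = noise_sd, mass_kg = mass_kg,
                 cycle_duration_s = cycle_duration_s,
                 seed = as.integer(seed)),
            class = "SyntheticSubjectConfig")
}

# neutral-pose marker templates for the right side (mm); ankle joint center
# at (0, 0, 80). Hindfoot/forefoot templates are in segment-local coords.
subject_geometry <- function(config) {
  ajc <- c(0, 0, 80)
  fl <- config$foot_length / 170   # scale forefoot reach
  list(
    ajc = ajc,
    tibia = list(MMA = c(0, 35, 80), LMA = c(0, -35, 80),
                 KNE = c(0, -40, 80 + config$tibia_length),
                 TIB = c(0, -45, 80 + 0.5 * config$tibia_length)),
    # hindfoot-local (origin at the ankle joint center)
    hindfoot = list(CA = c(-65, 0, -35), MCA = c(-35, 25, -50),
                    LCA = c(-35, -25, -50)),
    # midtarsal (Chopart) hinge, ~1/3 of the heel-toe span from the heel
    midfoot_joint = c(15, 0, -45),
    # forefoot-local (origin at the midfoot hinge)
    forefoot = list(MTH = c(75 * fl, 0, -5), TOE = c(125 * fl, 5, -10),
                    HLX = c(145 * fl, 10, -13)))
}

#' Synthesize marker trajectories for one walking trial
#'
#' Drives a lab -> tibia -> hindfoot -> forefoot kinematic chain: the tibia
#' stands in the lab, the hindfoot rotates under it about the mediolateral
#' ankle axis following the condition's ankle waveform, and the forefoot
#' rotates about a midfoot hinge by the condition's midfoot waveform (a
#' stance-gated plantarflexion bump of the configured amplitude).  All
#' marker sets of the three foot models ride rigidly on their segments;
#' isotropic Gaussian noise is added per marker per frame.  A vertical GRF
#' channel (clipped double bump, 1.2 x body weight scale, active exactly
#' during stance) is synthesized at 4 x the marker rate so force-plate
#' event detection recovers the true gait events.
#'
#' @param config a [synthetic_subject_config()].
#' @param condition `"BF"` or `"FO"`.
#' @param n_cycles number of gait cycles (>= 1).
#' @param marker_rate,analog_rate sampling rates (default 250 and 1000).
#' @return list with `trial` (a [trial_recording()]) and `truth` (a
#'   `GroundTruth`: `hindfoot_tibia_angle` and `midfoot_angle` 101-sample
#'   waveforms, true `events`, and the per-frame driving angles).
#' @export
synthesize_trial <- function(config, condition = c("BF", "FO"), n_cycles = 6,
                             marker_rate = 250, analog_rate = 1000) {
  stopifnot(inherits(config, "SyntheticSubjectConfig"), n_cycles >= 1)
  condition <- match.arg(condition)
  wf_par <- if (condition == "BF") config$bf_waveform else config$fo_waveform
  mf_amp <- if (condition == "BF") config$midfoot_amplitude_bf
            else config$midfoot_amplitude_fo
  wf <- generate_ankle_waveform(wf_par)
  se <- wf_par$stance_end_pct
  mf <- midfoot_waveform(mf_amp, se)

  set.seed(config$seed * 4L + if (condition == "BF") 1L else 2L)
  cyc_frames <- round(marker_rate * config$cycle_duration_s)
  pad <- 25L
  nf <- as.integer(pad + n_cycles * cyc_frames + pad)
  frame_pct <- rep(NA_real_, nf)
  in_cycle <- logical(nf)
  contacts <- pad + 1L + cyc_frames * (0:(n_cycles))  # incl. final contact
  for (k in seq_len(n_cycles)) {
    i <- contacts[k]:(contacts[k + 1L])
    frame_pct[i] <- 100 * (i - contacts[k]) / cyc_frames
    in_cycle[i] <- TRUE
  }
  theta <- numeric(nf); phi <- numeric(nf)
  theta[!in_cycle] <- wf[1]; phi[!in_cycle] <- mf[1]
  theta[in_cycle] <- stats::approx(0:100, wf, xout = frame_pct[in_cycle])$y
  phi[in_cycle] <- stats::approx(0:100, mf, xout = frame_pct[in_cycle])$y

  geo <- subject_geometry(config)
  markers <- pose_markers(geo, theta, phi)
  if (config$noise_sd > 0)
    markers <- lapply(markers, function(m)
      m + matrix(stats::rnorm(length(m), 0, config$noise_sd), nrow(m), 3))

  # vertical GRF on the analog timeline, active exactly during stance
  ratio <- as.integer(round(analog_rate / marker_rate))
  na <- nf * ratio
  grf <- numeric(na)
  bw <- config$mass_kg * 9.81
  stance_frames <- round(cyc_frames * se / 100)
  for (k in seq_len(n_cycles + 1L)) {
    a0 <- (contacts[k] - 1L) * ratio + 1L
    a1 <- min((contacts[k] + stance_frames - 1L) * ratio, na)
    s <- seq(0, 1, length.out = stance_frames * ratio)[seq_len(a1 - a0 + 1L)]
    grf[a0:a1] <- 1.2 * bw *
      pmax(0, 0.45 + 0.75 * sin(pi * s) + 0.3 * sin(pi * s) * cos(2 * pi * s))
  }

  trial <- trial_recording(
    trial_id = sprintf("%s_%s", config$subject_id, condition),
    condition = condition, side = "right", markers = markers,
    marker_rate = marker_rate, analog = list(Fz = grf),
    analog_rate = analog_rate, subject_id = config$subject_id)
  truth <- structure(list(
    hindfoot_tibia_angle = wf, midfoot_angle = mf,
    events = gait_events(contacts,
                         contacts[seq_len(n_cycles)] + stance_frames,
                         source = "provided"),
    theta = theta, phi = phi, stance_end_pct = se), class = "GroundTruth")
  list(trial = trial, truth = truth)
}

# Midfoot (intrinsic foot) sagittal waveform, deg, plantarflexion positive:
# rises through stance to peak at foot off (push-off plantarflexion of the
# arch), decays to neutral in early swing.  C1 periodic.
midfoot_waveform <- function(amplitude, stance_end_pct) {
  se <- stance_end_pct
  cosine_knot_curve(c(0, se, min(se + 15, 95), 100),
                    amplitude * c(0, 1, 0, 0))
}

# C1 periodic curve through knots (kt in % GC, kv in deg) with half-cosine
# easing: zero slope at every knot, so knots are exact local extrema.
cosine_knot_curve <- function(kt, kv) {
  pct <- 0:100
  y <- numeric(101)
  for (k in seq_len(length(kt) - 1L)) {
    i <- pct >= kt[k] & pct <= kt[k + 1L]
    s <- (pct[i] - kt[k]) / (kt[k + 1L] - kt[k])
    y[i] <- kv[k] + (kv[k + 1L] - kv[k]) * (1 - cos(pi * s)) / 2
  }
  y
}

# forward kinematics: marker positions for per-frame ankle (theta, deg,
# dorsiflexion positive) and midfoot (phi, deg, plantarflexion positive)
pose_markers <- function(geo, theta, phi) {
  nf <- length(theta)
  out <- list()
  for (lab in names(geo$tibia))
    out[[lab]] <- matrix(geo$tibia[[lab]], nf, 3, byrow = TRUE)
  # dorsiflexion positive = toe-up = negative rotation about the +Y axis
  ct <- cos(-theta * pi / 180); st <- sin(-theta * pi / 180)
  rot_about_ajc <- function(p_local) {
    cbind(ct * p_local[1] + st * p_local[3],
          rep(p_local[2], nf),
          -st * p_local[1] + ct * p_local[3]) +
      matrix(geo$ajc, nf, 3, byrow = TRUE)
  }
  for (lab in names(geo$hindfoot))
    out[[lab]] <- rot_about_ajc(geo$hindfoot[[lab]])
  cp <- cos(phi * pi / 180); sp <- sin(phi * pi / 180)
  for (lab in names(geo$forefoot)) {
    p <- geo$forefoot[[lab]]
    # midfoot plantarflexion: positive rotation about +Y at the hinge
    p_hf <- cbind(cp * p[1] + sp * p[3] + geo$midfoot_joint[1],
                  rep(p[2], nf) + geo$midfoot_joint[2],
                  -sp * p[1] + cp * p[3] + geo$midfoot_joint[3])
    out[[lab]] <- cbind(ct * p_hf[, 1] + st * p_hf[, 3], p_hf[, 2],
                        -st * p_hf[, 1] + ct * p_hf[, 3]) +
      matrix(geo$ajc, nf, 3, byrow = TRUE)
  }
  out
}

#' Synthesize a static calibration trial
#'
#' The subject stands in the neutral template pose for `duration_s` seconds;
#' marker noise as configured.
#'
#' @param config a [synthetic_subject_config()].
#' @param duration_s standing time (default 1.5 s).
#' @param marker_rate samples/s.
#' @return a STATIC [trial_recording()].
#' @export
synthesize_static_trial <- function(config, duration_s = 1.5,
                                    marker_rate = 250) {
  set.seed(config$seed * 4L)
  nf <- round(duration_s * marker_rate)
  geo <- subject_geometry(config)
  markers <- pose_markers(geo, rep(0, nf), rep(0, nf))
  if (config$noise_sd > 0)
    markers <- lapply(markers, function(m)
      m + matrix(stats::rnorm(length(m), 0, config$noise_sd), nrow(m), 3))
  trial_recording(
    trial_id = sprintf("%s_STATIC", config$subject_id), condition = "STATIC",
    side = "right", markers = markers, marker_rate = marker_rate,
    subject_id = config$subject_id)
}

#' Default cohort effect configuration
#'
#' Distributions from which per-subject waveform landmarks are drawn, one
#' block per walking condition, plus the midfoot amplitudes and marker
#' noise.  Defaults emulate the study conditions: barefoot toe walking
#' (plantarflexed contact, early peak dorsiflexion, 15 deg midfoot
#' compliance) versus orthosis-corrected heel-toe gait (neutral contact,
#' late peak dorsiflexion, rigid midfoot).
#'
#' @param midfoot_amplitude_bf,midfoot_amplitude_fo deg.
#' @param noise_sd mm.
#' @param bf,fo lists of landmark means/SDs overriding the defaults.
#' @return an `EffectConfig` list.
#' @export
effect_config <- function(midfoot_amplitude_bf = 15,
                          midfoot_amplitude_fo = 0, noise_sd = 0.5,
                          bf = list(), fo = list()) {
  bf_def <- list(profile = "toe_walking",
                 angle_at_fc = c(-10, 2.5), peak_df = c(-2, 2),
                 t_peak_df = c(20, 3), peak_pf = c(-18, 2.5),
                 t_peak_pf = c(62, 3), stance_end_pct = c(62, 2),
                 early_dip_deg = c(0, 0))
  fo_def <- list(profile = "heel_toe",
                 angle_at_fc = c(0, 2), peak_df = c(10, 2.5),
                 t_peak_df = c(45, 3), peak_pf = c(-15, 2.5),
                 t_peak_pf = c(65, 3), stance_end_pct = c(60, 2),
                 early_dip_deg = c(-4, 1))
  structure(list(midfoot_amplitude_bf = midfoot_amplitude_bf,
                 midfoot_amplitude_fo = midfoot_amplitude_fo,
                 noise_sd = noise_sd,
                 bf = utils::modifyList(bf_def, bf),
                 fo = utils::modifyList(fo_def, fo)),
            class = "EffectConfig")
}

draw_waveform <- function(cfg) {
  g <- function(nm) stats::rnorm(1, cfg[[nm]][1], cfg[[nm]][2])
  fc <- g("angle_at_fc")
  pdf_ <- max(g("peak_df"), fc + 0.5)
  tdf <- g("t_peak_df")
  ppf <- min(g("peak_pf"), min(fc, pdf_) - 3)
  tpf <- max(g("t_peak_pf"), tdf + 10)
  se <- min(max(g("stance_end_pct"), tdf + 2), 75)
  dip <- if (cfg$early_dip_deg[1] == 0) 0 else min(g("early_dip_deg"), -0.5)
  waveform_params(cfg$profile, angle_at_fc = fc, peak_df = pdf_,
                  t_peak_df = max(8.5, min(tdf, 55)),
                  peak_pf = ppf, t_peak_pf = min(tpf, 90),
                  stance_end_pct = se, early_dip_deg = dip)
}

#' Generate a synthetic cohort of toe-walking subjects
#'
#' Draws per-subject waveform landmarks from the configured distributions
#' and synthesizes, for each subject, a static calibration trial and one
#' walking trial per condition (BF toe walking with midfoot compliance, FO
#' corrected gait), with per-subject cycle counts between 4 and 10 (mean
#' about 6).  Deterministic under `master_seed`.
#'
#' @param n_subjects number of subjects (default 14).
#' @param master_seed integer seed controlling every draw.
#' @param config an [effect_config()].
#' @return list of per-subject lists: `config`, `static`, `BF`, `FO` (each
#'   walking entry a `list(trial, truth)`).
#' @export
generate_cohort <- function(n_subjects = 14, master_seed = 1L,
                            config = effect_config()) {
  stopifnot(n_subjects >= 2)
  set.seed(master_seed)
  # draw every config (and per-subject trial seed) from the master stream
  # first; trial synthesis then runs under its own seed (bit-reproducible
  # per subject) without disturbing the cohort-level draws
  configs <- lapply(seq_len(n_subjects), function(i) {
    sub_cfg <- synthetic_subject_config(
      subject_id = sprintf("S%02d", i),
      tibia_length = stats::rnorm(1, 400, 30),
      foot_length = stats::rnorm(1, 170, 12),
      bf_waveform = draw_waveform(config$bf),
      fo_waveform = draw_waveform(config$fo),
      midfoot_amplitude_bf = config$midfoot_amplitude_bf,
      midfoot_amplitude_fo = config$midfoot_amplitude_fo,
      noise_sd = config$noise_sd,
      mass_kg = max(15, stats::rnorm(1, 37, 8)),
      seed = sample.int(2^28, 1))
    list(cfg = sub_cfg,
         n_cyc = sample(4:10, 1,
                        prob = c(0.10, 0.20, 0.30, 0.20, 0.10, 0.05, 0.05)))
  })
  lapply(configs, function(x) {
    list(subject_id = x$cfg$subject_id, config = x$cfg,
         static = synthesize_static_trial(x$cfg),
         BF = synthesize_trial(x$cfg, "BF", n_cycles = x$n_cyc),
         FO = synthesize_trial(x$cfg, "FO", n_cycles = x$n_cyc))
  })
}
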