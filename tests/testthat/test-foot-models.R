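test_that("the tibia frame matches the axis-aligned construction", {
  mk <- list(MMA = c(0, 40, 100), LMA = c(0, -40, 100), KNE = c(0, -40, 500))
  fr <- build_tibia_frame(mk, side = "right")
  expect_equal(fr$origin, c(0, 0, 100))
  expect_equal(fr$z_axis, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fr$y_axis, c(0, 1, 0), tolerance = 1e-9)
  expect_equal(fr$x_axis, c(1, 0, 0), tolerance = 1e-9)
})

test_that("frame builders are equivariant under rigid rotation", {
  mk <- list(MMA = c(0, 40, 100), LMA = c(0, -40, 100), KNE = c(0, -40, 500))
  R <- rot_z(30)
  fr0 <- build_tibia_frame(mk, "right")
  fr1 <- build_tibia_frame(apply_rot(mk, R), "right")
  expect_equal(frame_matrix(fr1), R %*% frame_matrix(fr0), tolerance = 1e-9)

  mono <- list(CA = c(0, 0, 50), TOE = c(150, 0, 20))
  f0 <- build_foot_frame_mono(mono, "DAV")
  f1 <- build_foot_frame_mono(apply_rot(mono, rot_y(10)), "DAV")
  expect_equal(f1$x_axis, as.numeric(rot_y(10) %*% f0$x_axis),
               tolerance = 1e-9)

  # hindfoot: pin the virtual point at calibration, then rotate the triad
  tri <- list(CA = c(0, 0, 40), MCA = c(30, 25, 25), LCA = c(30, -25, 25))
  h0 <- build_hindfoot_frame_ofm(tri, "right")
  v <- attr(h0, "virtual_local")
  h1 <- build_hindfoot_frame_ofm(apply_rot(tri, rot_y(15)), "right",
                                 v_local = v)
  expect_equal(h1$x_axis, as.numeric(rot_y(15) %*% h0$x_axis),
               tolerance = 1e-9)
  expect_equal(frame_matrix(h1), rot_y(15) %*% frame_matrix(h0),
               tolerance = 1e-9)
})

test_that("degenerate marker geometry is rejected with a clear error", {
  expect_error(build_tibia_frame(
    list(MMA = c(0, 40, 100), LMA = c(0, -40, 100), KNE = c(0, 120, 100)),
    "right"), "collinear|degenerate")
  expect_error(build_foot_frame_mono(
    list(CA = c(1, 2, 3), TOE = c(1, 2, 3)), "DAV"), "degenerate")
  expect_error(build_hindfoot_frame_ofm(
    list(CA = c(0, 0, 0), MCA = c(10, 0, 0), LCA = c(20, 0, 0)), "right"),
    "collinear")
  expect_error(build_tibia_frame(list(MMA = c(0, 40, 100)), "right"), "LMA")
})

test_that("the mono-segment foot axis runs from CA to the forefoot marker", {
  mk <- list(CA = c(0, 0, 50), TOE = c(150, 0, 20), MTH = c(110, 0, 28),
             MCA = c(25, 20, 35))
  fr <- build_foot_frame_mono(mk, "DAV")
  expect_equal(fr$origin, c(0, 0, 50))
  expect_equal(fr$x_axis, c(150, 0, -30) / sqrt(150^2 + 30^2),
               tolerance = 1e-9)
  # pitching the whole foot nose-down pitches the axis identically
  fr10 <- build_foot_frame_mono(
    apply_rot(mk, rot_y(10), center = mk$CA), "DAV")
  expect_equal(fr10$x_axis, as.numeric(rot_y(10) %*% fr$x_axis),
               tolerance = 1e-9)
  # only CA and the forefoot marker enter the construction
  mk2 <- mk; mk2$MCA <- mk$MCA + c(5, -3, 8)
  expect_identical(build_foot_frame_mono(mk2, "DAV"), fr)
  mk3 <- mk; mk3$CA <- mk$CA + c(0, 0, 10)
  expect_gt(sum(abs(build_foot_frame_mono(mk3, "DAV")$x_axis - fr$x_axis)), 0)
  # PiG uses the metatarsal marker instead
  frp <- build_foot_frame_mono(mk, "PiG")
  expect_equal(frp$x_axis, (mk$MTH - mk$CA) / sqrt(sum((mk$MTH - mk$CA)^2)),
               tolerance = 1e-9)
})

test_that("the OFM hindfoot frame is calcaneus-only and symmetric", {
  tri <- list(CA = c(0, 0, 40), MCA = c(30, 25, 25), LCA = c(30, -25, 25))
  fr <- build_hindfoot_frame_ofm(tri, "right")
  expect_equal(fr$y_axis, c(0, 1, 0), tolerance = 1e-9)  # sagittal normal +Y
  expect_equal(fr$x_axis[2], 0, tolerance = 1e-9)        # axis in XZ plane
  expect_equal(fr$origin, tri$CA)
  # forefoot markers play no role
  with_ff <- c(tri, list(TOE = c(170, 5, 25), MTH = c(120, 0, 30)))
  fr2 <- build_hindfoot_frame_ofm(with_ff, "right")
  expect_identical(frame_matrix(fr2), frame_matrix(fr))
})

test_that("static calibration averages the raw static angle", {
  cfg <- synthetic_subject_config(noise_sd = 0)
  st <- synthesize_static_trial(cfg)
  cal <- static_calibration(st, "PiG")
  # neutral pose: raw PiG angle is the CA->MTH pitch, reproduced exactly by
  # direct construction at one frame
  mk <- lapply(st$markers, function(m) m[1, ])
  tib <- build_tibia_frame(mk, "right")
  foot <- build_foot_frame_mono(mk, "PiG")
  raw <- sagittal_angle(tib, foot)
  expect_equal(cal$neutral_angle_deg, raw, tolerance = 1e-6)
  # applying the offset to the static trial itself reads ~0
  tr0 <- compute_ankle_trace(st, "PiG", cal)
  expect_lt(max(abs(tr0$values)), 1e-6)
  # alternating raw angles average to their midpoint: shrink then check mean
  expect_equal(cal$measured_static_deg, mean(raw), tolerance = 1e-6)
  # too-short static data is refused
  short <- st
  short$markers <- lapply(short$markers, function(m) m[1:100, , drop = FALSE])
  expect_error(static_calibration(short, "PiG"), "1 s")
})

test_that("DAV applies no static offset while PiG does", {
  cfg <- synthetic_subject_config(noise_sd = 0)
  st <- synthesize_static_trial(cfg)
  cal_d <- static_calibration(st, "DAV")
  expect_identical(cal_d$neutral_angle_deg, 0)
  expect_lt(cal_d$measured_static_deg, 0)  # toe marker below CA: raw pitch
  cal_p <- static_calibration(st, "PiG")
  expect_equal(cal_p$neutral_angle_deg, cal_p$measured_static_deg)
})

test_that("sagittal angle recovers the leading flexion rotation exactly", {
  mk <- neutral_markers()
  tib <- build_tibia_frame(mk, "right")
  expect_equal(sagittal_angle(tib, tib), 0)

  Rt <- frame_matrix(tib)
  pre <- function(R) {
    M <- Rt %*% R
    segment_frame(tib$origin, M[, 1], M[, 2], M[, 3])
  }
  # +20 deg dorsiflexion = -20 deg rotation about the flexion (y) axis
  expect_equal(sagittal_angle(tib, pre(rot_y(-20))), 20, tolerance = 1e-9)

  set.seed(11)
  for (k in 1:25) {
    a <- runif(1, -60, 60); b <- runif(1, -30, 30); g <- runif(1, -30, 30)
    fr <- pre(rot_y(a) %*% rot_x(b) %*% rot_z(g))
    expect_equal(sagittal_angle(tib, fr), -a, tolerance = 1e-6)
  }
})

test_that("gimbal-adjacent samples are flagged", {
  mk <- neutral_markers()
  tib <- build_tibia_frame(mk, "right")
  Rt <- frame_matrix(tib)
  M <- Rt %*% (rot_y(10) %*% rot_x(89.5) %*% rot_z(5))
  fr <- segment_frame(tib$origin, M[, 1], M[, 2], M[, 3])
  expect_warning(v <- sagittal_angle(tib, fr), "gimbal")
  expect_true(is.na(v))
})

test_that("ankle traces reproduce a constant plantarflexion exactly", {
  wp <- waveform_params("toe_walking", angle_at_fc = -10, peak_df = -10,
                        t_peak_df = 20, peak_pf = -10.0001, t_peak_pf = 62,
                        harmonics = 12)
  cfg <- synthetic_subject_config(noise_sd = 0, bf_waveform = wp,
                                  midfoot_amplitude_bf = 0)
  st <- synthesize_static_trial(cfg)
  cal <- static_calibration(st, "OFM")
  tr <- synthesize_trial(cfg, "BF", 2)$trial
  trace <- compute_ankle_trace(tr, "OFM", cal)
  expect_lt(max(abs(trace$values - (-10))), 0.1)

  broken <- tr; broken$markers$CA <- NULL
  expect_error(compute_ankle_trace(broken, "OFM", cal), "CA")
})

test_that("all sagittal angles are invariant under a common rigid transform", {
  cfg <- synthetic_subject_config(noise_sd = 0, seed = 3)
  st <- synthesize_static_trial(cfg)
  tr <- synthesize_trial(cfg, "BF", 1)$trial
  set.seed(21)
  for (k in 1:4) {
    R <- rot_z(runif(1, -180, 180))   # lab-vertical-preserving rigid motion
    tvec <- runif(3, -500, 500)
    move <- function(t) {
      t$markers <- lapply(t$markers, function(m)
        t(R %*% t(m)) + matrix(tvec, nrow(m), 3, byrow = TRUE))
      t
    }
    for (mod in c("OFM", "PiG", "DAV")) {
      cal0 <- static_calibration(st, mod)
      cal1 <- static_calibration(move(st), mod)
      a0 <- compute_ankle_trace(tr, mod, cal0)$values
      a1 <- compute_ankle_trace(move(tr), mod, cal1)$values
      expect_lt(max(abs(a0 - a1)), 1e-6)
    }
  }
})

test_that("the OFM trace is bitwise invariant to forefoot marker motion", {
  cfg <- synthetic_subject_config(noise_sd = 0)
  st <- synthesize_static_trial(cfg)
  cal <- static_calibration(st, "OFM")
  tr <- synthesize_trial(cfg, "BF", 2)$trial
  ref <- compute_ankle_trace(tr, "OFM", cal)$values
  set.seed(5)
  tr$markers$TOE <- tr$markers$TOE + matrix(rnorm(3 * n_frames(tr), 0, 30),
                                            ncol = 3)
  tr$markers$MTH <- tr$markers$MTH + 50
  tr$markers$HLX <- tr$markers$HLX * 0.5
  expect_identical(compute_ankle_trace(tr, "OFM", cal)$values, ref)
})

test_that("mono-segment deviation from OFM grows with midfoot amplitude", {
  st <- synthesize_static_trial(synthetic_subject_config(noise_sd = 0))
  cal_o <- static_calibration(st, "OFM")
  cal_p <- static_calibration(st, "PiG")
  devs <- sapply(c(0, 5, 10, 15), function(a) {
    cfg <- synthetic_subject_config(noise_sd = 0, midfoot_amplitude_bf = a)
    tr <- synthesize_trial(cfg, "BF", 1)$trial
    o <- compute_ankle_trace(tr, "OFM", cal_o)$values
    p <- compute_ankle_trace(tr, "PiG", cal_p)$values
    mean(abs(p - o))
  })
  expect_true(all(diff(devs) > 0))
  expect_lt(devs[1], 1e-6)
})

test_that("mirroring a right-side trial to the left reproduces the trace", {
  mirror <- function(t) {
    t$markers <- lapply(t$markers, function(m) { m[, 2] <- -m[, 2]; m })
    t$side <- "left"
    t
  }
  cfg <- synthetic_subject_config(noise_sd = 0)
  st <- synthesize_static_trial(cfg)
  tr <- synthesize_trial(cfg, "BF", 1)$trial
  for (mod in c("OFM", "PiG", "DAV")) {
    aR <- compute_ankle_trace(tr, mod, static_calibration(st, mod))$values
    aL <- compute_ankle_trace(mirror(tr), mod,
                              static_calibration(mirror(st), mod))$values
    expect_lt(max(abs(aR - aL)), 1e-6)
  }
})
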