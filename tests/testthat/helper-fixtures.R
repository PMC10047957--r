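# Shared fixtures and independent oracles, built in code at test time.

# a tiny trial with a few fixed markers (no physiology implied)
toy_trial <- function(n = 100, labels = c("CA", "TOE", "MTH"),
                      analog = list(), analog_rate = NA_real_) {
  markers <- lapply(seq_along(labels), function(k) {
    cbind(seq_len(n) + 10 * k, rep(5 * k, n), rep(40 + k, n))
  })
  names(markers) <- labels
  trial_recording("toy", "BF", "right", markers, 250,
                  analog = analog, analog_rate = analog_rate)
}

# full marker set in the neutral template pose, as single-frame 3-vectors
neutral_markers <- function() {
  list(MMA = c(0, 35, 80), LMA = c(0, -35, 80), KNE = c(0, -40, 480),
       TIB = c(0, -45, 280), CA = c(-65, 0, 45), MCA = c(-35, 25, 30),
       LCA = c(-35, -25, 30), MTH = c(120, 0, 30), TOE = c(170, 5, 25))
}

# rotation matrices, independent of any package geometry code
rot_x <- function(deg) {
  r <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(r), sin(r), 0, -sin(r), cos(r)), 3, 3)
}
rot_y <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), 0, -sin(r), 0, 1, 0, sin(r), 0, cos(r)), 3, 3)
}
rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}

apply_rot <- function(markers, R, center = c(0, 0, 0)) {
  lapply(markers, function(p) as.numeric(R %*% (p - center)) + center)
}

frame_matrix <- function(fr) cbind(fr$x_axis, fr$y_axis, fr$z_axis)

# constant-valued normalized cycle
const_cycle <- function(v, stance = 60, ...) {
  normalized_cycle(rep(v, 101), stance_end_pct = stance, ...)
}

# cycle passing through given (pct, value) anchor points, linear in between
anchor_cycle <- function(pcts, values, stance = 60, ...) {
  normalized_cycle(approx(pcts, values, xout = 0:100, rule = 2)$y,
                   stance_end_pct = stance, ...)
}

# a smooth random cycle under a fixed seed
random_cycle <- function(seed, stance = 60) {
  set.seed(seed)
  a <- rnorm(4, 0, 5)
  s <- a[1] * sin(2 * pi * (0:100) / 100 + a[2]) +
    a[3] * cos(4 * pi * (0:100) / 100) + a[4]
  normalized_cycle(s, stance_end_pct = stance)
}

# seeded random complete-case 3x2 cohort table
random_table <- function(seed, n = 14, means = rep(0, 6), sd = 1,
                         subject_sd = 1) {
  set.seed(seed)
  grid <- expand.grid(model = c("OFM", "PiG", "DAV"),
                      condition = c("BF", "FO"))
  rows <- do.call(rbind, lapply(seq_len(n), function(s) {
    off <- rnorm(1, 0, subject_sd)
    data.frame(subject = sprintf("S%02d", s), model = grid$model,
               condition = grid$condition,
               value = means + off + rnorm(6, 0, sd))
  }))
  cohort_table(rows)
}

# hand-derived rocker labels on constructed cycles spanning the boundary
# cases of both rules (threshold at exactly -5 deg, peak at exactly 30 %GC,
# up-going/flat/dipping first-12% patterns)
rocker_boundary_cases <- function() {
  mk <- function(fc, v12, peak, t_df) {
    anchor_cycle(c(0, 12, t_df, 80, 100), c(fc, v12, peak, peak - 20, fc),
                 stance = max(t_df + 5, 60))
  }
  list(
    list(cy = mk(0, -8, 12, 45),     heel = TRUE,  ff = FALSE),
    list(cy = mk(-5, -8, 12, 45),    heel = FALSE, ff = FALSE),
    list(cy = mk(-4.99, -8, 12, 45), heel = TRUE,  ff = FALSE),
    list(cy = mk(-5.01, -8, 12, 45), heel = FALSE, ff = FALSE),
    list(cy = mk(-10, -14, 12, 45),  heel = FALSE, ff = FALSE),
    list(cy = mk(0, 4, 12, 45),      heel = FALSE, ff = FALSE),
    list(cy = mk(0, 0, 12, 45),      heel = FALSE, ff = FALSE),
    list(cy = mk(2, 1.2, 12, 45),    heel = TRUE,  ff = FALSE),
    list(cy = mk(0, -6, 12, 30),     heel = TRUE,  ff = FALSE),
    list(cy = mk(0, -6, 12, 29),     heel = TRUE,  ff = TRUE),
    list(cy = mk(0, -6, 12, 31),     heel = TRUE,  ff = FALSE),
    list(cy = mk(-9, -12, 3, 20),    heel = FALSE, ff = TRUE),
    list(cy = mk(-6, -9, 0, 29),     heel = FALSE, ff = TRUE),
    list(cy = mk(-4, -7, 1, 29),     heel = TRUE,  ff = TRUE),
    list(cy = mk(-4, -7, 1, 30),     heel = TRUE,  ff = FALSE),
    list(cy = anchor_cycle(c(0, 20, 62, 100), c(-10, -2, -18, -10), 62),
         heel = FALSE, ff = TRUE),
    list(cy = anchor_cycle(c(0, 8, 45, 65, 100), c(0, -4, 10, -15, 0), 60),
         heel = TRUE, ff = FALSE),
    list(cy = anchor_cycle(c(0, 5, 12, 40, 70, 100), c(0, -3, 1, 10, -12, 0),
                           60), heel = FALSE, ff = FALSE),
    list(cy = anchor_cycle(c(0, 12, 40, 70, 100), c(0, -2, 12, -14, 0), 60),
         heel = TRUE, ff = FALSE),
    list(cy = const_cycle(-2), heel = FALSE, ff = TRUE),
    list(cy = anchor_cycle(c(0, 50, 100), c(5, -18, 5), 60),
         heel = TRUE, ff = TRUE))
}

# brute-force repeated-measures two-way ANOVA from the textbook SS
# definitions (cell/marginal/subject means), independent of aov()
rm_anova_oracle <- function(table) {
  v <- table$value
  s <- table$subject; m <- table$model; cnd <- table$condition
  n <- nlevels(s); I <- nlevels(m); J <- nlevels(cnd)
  mu <- mean(v)
  m_i <- tapply(v, m, mean); c_j <- tapply(v, cnd, mean)
  p_s <- tapply(v, s, mean)
  mc_ij <- tapply(v, list(m, cnd), mean)
  sm_is <- tapply(v, list(m, s), mean)
  sc_js <- tapply(v, list(cnd, s), mean)
  ss_model <- n * J * sum((m_i - mu)^2)
  ss_cond <- n * I * sum((c_j - mu)^2)
  ss_int <- n * sum((mc_ij - outer(m_i, c_j, `+`) + mu)^2)
  ss_ms <- J * sum((sm_is - outer(m_i, p_s, `+`) + mu)^2)
  ss_cs <- I * sum((sc_js - outer(c_j, p_s, `+`) + mu)^2)
  cell_msc <- tapply(v, list(m, cnd, s), mean)
  ss_total <- sum((v - mu)^2)
  ss_subj <- I * J * sum((p_s - mu)^2)
  ss_mcs <- ss_total - ss_subj - ss_model - ss_cond - ss_int - ss_ms - ss_cs
  list(
    model = list(F = (ss_model / (I - 1)) / (ss_ms / ((I - 1) * (n - 1))),
                 df = c(I - 1, (I - 1) * (n - 1)),
                 eta2 = ss_model / (ss_model + ss_ms)),
    condition = list(F = (ss_cond / (J - 1)) / (ss_cs / ((J - 1) * (n - 1))),
                     df = c(J - 1, (J - 1) * (n - 1)),
                     eta2 = ss_cond / (ss_cond + ss_cs)),
    interaction = list(
      F = (ss_int / ((I - 1) * (J - 1))) /
        (ss_mcs / ((I - 1) * (J - 1) * (n - 1))),
      df = c((I - 1) * (J - 1), (I - 1) * (J - 1) * (n - 1)),
      eta2 = ss_int / (ss_int + ss_mcs)))
}
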