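test_that("the median waveform is the pointwise median with midpoint ties", {
  expect_equal(median_waveform(list(const_cycle(0), const_cycle(1),
                                    const_cycle(4))), rep(1, 101))
  c1 <- random_cycle(1)
  expect_equal(median_waveform(list(c1, c1, c1)), c1$samples)
  expect_equal(median_waveform(list(const_cycle(0), const_cycle(4))),
               rep(2, 101))
  expect_error(median_waveform(list()), "empty")
})

test_that("representative selection minimizes the area to the median", {
  sel <- select_representative(list(const_cycle(0), const_cycle(1),
                                    const_cycle(4)))
  # hand integration of |c - 1| over 0..100 %GC
  expect_equal(sel$areas, c(100, 0, 300))
  expect_equal(sel$chosen_index, 2L)

  c1 <- random_cycle(2)
  tie <- select_representative(list(c1, c1, c1))
  expect_equal(tie$areas, rep(0, 3))
  expect_equal(tie$chosen_index, 1L)   # ties break to the lowest index
})

test_that("selection agrees with an independent trapezoid argmin oracle", {
  trapz_oracle <- function(mat) {
    med <- apply(mat, 1, median)
    apply(mat, 2, function(v) {
      d <- abs(v - med)
      sum((d[-1] + d[-101]) / 2)   # unit spacing trapezoid
    })
  }
  for (seed in 1:20) {
    set.seed(seed)
    cycles <- lapply(sample.int(1e6, sample(3:8, 1)), random_cycle)
    sel <- select_representative(cycles)
    areas <- trapz_oracle(sapply(cycles, `[[`, "samples"))
    expect_equal(sel$areas, areas, tolerance = 1e-10)
    expect_equal(sel$chosen_index, which.min(areas))
    expect_equal(min(sel$areas), areas[sel$chosen_index])
  }
})

test_that("selection is order-invariant up to tie-breaking", {
  cycles <- lapply(11:16, random_cycle)
  sel <- select_representative(cycles)
  for (seed in 1:5) {
    set.seed(seed)
    perm <- sample(length(cycles))
    sel_p <- select_representative(cycles[perm])
    expect_equal(sel_p$areas, sel$areas[perm])
    expect_equal(perm[sel_p$chosen_index], sel$chosen_index)
  }
})

test_that("the linear fit method recovers affine relations exactly", {
  ref <- random_cycle(31)
  same <- lfm(list(ref, ref, ref))
  expect_equal(unname(same$a1), rep(1, 3))
  expect_equal(unname(same$a0), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(same$r2), rep(1, 3))
  expect_true(same$consistent)

  aff <- normalized_cycle(2 * median_waveform(list(ref, ref)) + 3, 60)
  res <- lfm(list(ref, ref, aff))
  expect_equal(unname(res$a1[3]), 2, tolerance = 1e-9)
  expect_equal(unname(res$a0[3]), 3, tolerance = 1e-9)
  expect_equal(unname(res$r2[3]), 1, tolerance = 1e-12)

  set.seed(99)
  noise <- normalized_cycle(rnorm(101), 60)
  indep <- lfm(list(ref, ref, ref, noise))
  expect_lt(unname(indep$r2[4]), 0.1)

  expect_error(lfm(list(const_cycle(2), const_cycle(2))), "zero-variance")
})

test_that("parameter extraction reads the constructed landmarks", {
  cy <- anchor_cycle(c(0, 40, 80, 100), c(2, 12, -15, 2), stance = 60)
  p <- extract_parameters(cy)
  expect_equal(p$angle_at_fc, 2)
  expect_equal(p$peak_df, 12);  expect_equal(p$t_peak_df, 40)
  expect_equal(p$peak_pf, -15); expect_equal(p$t_peak_pf, 80)
  expect_equal(p$rom, 27)

  pc <- extract_parameters(const_cycle(-3))
  expect_equal(unclass(pc)[c("angle_at_fc", "peak_df", "t_peak_df",
                             "peak_pf", "t_peak_pf", "rom")],
               list(angle_at_fc = -3, peak_df = -3, t_peak_df = 0,
                    peak_pf = -3, t_peak_pf = 0, rom = 0))
})

test_that("parameter extraction equals an exhaustive scan on random cycles", {
  for (seed in 1:20) {
    cy <- random_cycle(seed, stance = sample(45:70, 1))
    p <- extract_parameters(cy)
    s <- cy$samples; pct <- 0:100
    stance_idx <- which(pct <= cy$stance_end_pct)
    i_df <- stance_idx[which(s[stance_idx] == max(s[stance_idx]))[1]]
    i_pf <- which(s == min(s))[1]
    expect_equal(p$peak_df, s[i_df]);  expect_equal(p$t_peak_df, pct[i_df])
    expect_equal(p$peak_pf, s[i_pf]);  expect_equal(p$t_peak_pf, pct[i_pf])
    expect_equal(p$rom, s[i_df] - s[i_pf])
    expect_gte(p$rom, 0)
    expect_gte(p$peak_df, p$angle_at_fc - 1e-12)
  }
})

test_that("adding a constant shifts angles but not timings or ROM", {
  cy <- random_cycle(77)
  p0 <- extract_parameters(cy)
  cy2 <- normalized_cycle(cy$samples + 6.5, cy$stance_end_pct)
  p1 <- extract_parameters(cy2)
  expect_equal(p1$angle_at_fc, p0$angle_at_fc + 6.5)
  expect_equal(p1$peak_df, p0$peak_df + 6.5)
  expect_equal(p1$peak_pf, p0$peak_pf + 6.5)
  expect_equal(p1$rom, p0$rom)
  expect_equal(p1$t_peak_df, p0$t_peak_df)
  expect_equal(p1$t_peak_pf, p0$t_peak_pf)
  expect_equal(classify_rockers(cy2)$premature_forefoot_rocker,
               classify_rockers(cy)$premature_forefoot_rocker)
})

test_that("rocker rules reproduce hand-derived labels on boundary cases", {
  cases <- rocker_boundary_cases()
  expect_gte(length(cases), 20)
  for (k in seq_along(cases)) {
    fl <- classify_rockers(cases[[k]]$cy)
    expect_identical(fl$heel_rocker, cases[[k]]$heel, label = paste("case", k))
    expect_identical(fl$premature_forefoot_rocker, cases[[k]]$ff,
                     label = paste("case", k))
  }
})

test_that("relaxing the contact threshold only turns heel flags on", {
  for (seed in 1:30) {
    cy <- random_cycle(seed + 400)
    strict <- classify_rockers(cy, criteria = rocker_criteria(-2))
    lax <- classify_rockers(cy, criteria = rocker_criteria(-8))
    expect_true(!strict$heel_rocker || lax$heel_rocker)
  }
})

test_that("rocker prevalence is the percentage of flagged cycles", {
  fl <- function(h) list(heel_rocker = h, premature_forefoot_rocker = !h)
  flags <- c(replicate(4, fl(TRUE), simplify = FALSE),
             replicate(6, fl(FALSE), simplify = FALSE))
  out <- rocker_prevalence(flags)
  expect_equal(out$heel_rocker_pct, 40)
  expect_equal(out$premature_ff_pct, 60)
  expect_equal(rocker_prevalence(replicate(3, fl(TRUE), simplify = FALSE))$heel_rocker_pct, 100)
  expect_equal(rocker_prevalence(replicate(3, fl(FALSE), simplify = FALSE))$heel_rocker_pct, 0)
  expect_error(rocker_prevalence(list()), "no rocker")
})
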