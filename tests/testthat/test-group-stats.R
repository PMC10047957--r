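test_that("the normality screen routes by per-cell Shapiro-Wilk", {
  hits_normal <- 0; hits_bimodal <- 0
  for (seed in 1:100) {
    set.seed(seed)
    if (stats::shapiro.test(rnorm(14))$p.value > 0.05)
      hits_normal <- hits_normal + 1
    bim <- c(rnorm(7, -8, 0.3), rnorm(7, 8, 0.3))
    if (stats::shapiro.test(bim)$p.value < 0.05) hits_bimodal <- hits_bimodal + 1
  }
  expect_gte(hits_normal, 90)
  expect_gte(hits_bimodal, 90)

  tab <- random_table(1)
  expect_identical(shapiro_normality(tab)$route, "parametric")
  # a constant cell is flagged non-normal and routes to ART
  tab2 <- tab
  tab2$value[tab2$model == "OFM" & tab2$condition == "BF"] <- 3
  expect_identical(shapiro_normality(tab2)$route, "art")
  # a heavy-tailed/bimodal cell routes to ART
  tab3 <- tab
  i <- tab3$model == "DAV" & tab3$condition == "FO"
  set.seed(4); tab3$value[i] <- c(rnorm(7, -8, 0.3), rnorm(7, 8, 0.3))
  expect_identical(shapiro_normality(tab3)$route, "art")
})

test_that("rm ANOVA matches the direct sums-of-squares oracle", {
  for (seed in 1:25) {
    tab <- random_table(seed, means = rnorm(6, 0, 2))
    got <- rm_anova_3x2(tab)
    want <- rm_anova_oracle(tab)
    for (eff in c("model", "condition", "interaction")) {
      g <- got[got$effect == eff, ]
      expect_equal(g$F, want[[eff]]$F, tolerance = 1e-8)
      expect_equal(c(g$df1, g$df2), want[[eff]]$df)
      expect_equal(g$eta2, want[[eff]]$eta2, tolerance = 1e-8)
    }
  }
  # df layout for n = 14 as reported in repeated-measures practice
  g <- rm_anova_3x2(random_table(7))
  expect_equal(g$df1[g$effect == "model"], 2)
  expect_equal(g$df2[g$effect == "model"], 26)
  expect_equal(g$df1[g$effect == "condition"], 1)
  expect_equal(g$df2[g$effect == "condition"], 13)
})

test_that("degenerate and constructed effect patterns behave analytically", {
  # identical conditions per subject: condition F = 0
  tab <- random_table(3)
  bf <- tab$condition == "BF"
  key <- paste(tab$subject, tab$model)
  tab$value[!bf] <- tab$value[bf][match(key[!bf], key[bf])]
  tab <- cohort_table(as.data.frame(tab))
  g <- rm_anova_3x2(tab)
  expect_equal(g$F[g$effect == "condition"], 0, tolerance = 1e-12)

  # pure additive model effect (+0/+5/+10) with subject offsets only:
  # interaction and its error are exactly zero; model effect is certain
  set.seed(8)
  grid <- expand.grid(model = c("OFM", "PiG", "DAV"), condition = c("BF", "FO"))
  rows <- do.call(rbind, lapply(1:14, function(s) {
    data.frame(subject = sprintf("S%02d", s), model = grid$model,
               condition = grid$condition,
               value = rnorm(1, 0, 3) +
                 c(OFM = 0, PiG = 5, DAV = 10)[as.character(grid$model)])
  }))
  add <- cohort_table(rows)
  ga <- rm_anova_3x2(add)
  expect_lt(ga$p[ga$effect == "model"], 0.05)
  expect_true(is.na(ga$F[ga$effect == "interaction"]) ||
                ga$F[ga$effect == "interaction"] < 1e-6)
})

test_that("rm ANOVA is invariant to subject offsets and level relabeling", {
  tab <- random_table(12, means = rnorm(6))
  f0 <- rm_anova_3x2(tab)$F
  tab2 <- tab
  tab2$value <- tab2$value + 100 * as.integer(tab2$subject)
  expect_equal(rm_anova_3x2(cohort_table(as.data.frame(tab2)))$F, f0,
               tolerance = 1e-8)
  # swapping model labels permutes cells but not the F statistics
  tab3 <- as.data.frame(tab)
  tab3$model <- c(OFM = "PiG", PiG = "OFM", DAV = "DAV")[as.character(tab3$model)]
  expect_equal(rm_anova_3x2(cohort_table(tab3))$F, f0, tolerance = 1e-8)
})

test_that("ART alignment zeroes the other effects' marginal means", {
  tab <- random_table(21, means = rnorm(6, 0, 3))
  aligned_means <- function(eff) {
    a <- itwgait:::align_effect(tab, eff)
    list(model = tapply(a, tab$model, mean),
         condition = tapply(a, tab$condition, mean),
         cell = tapply(a, list(tab$model, tab$condition), mean))
  }
  am <- aligned_means("model")
  expect_lt(max(abs(am$condition)), 1e-9)
  ia <- am$cell - outer(rowMeans(am$cell), rep(1, 2)) -
    outer(rep(1, 3), colMeans(am$cell)) + mean(am$cell)
  expect_lt(max(abs(ia)), 1e-9)
  ac <- aligned_means("condition")
  expect_lt(max(abs(ac$model)), 1e-9)
  ai <- aligned_means("interaction")
  expect_lt(max(abs(ai$model)), 1e-9)
  expect_lt(max(abs(ai$condition)), 1e-9)
})

test_that("ART agrees with the parametric ANOVA on normal data", {
  # no systematic effects beyond subject offsets: all F ~ 0 after alignment
  set.seed(30)
  grid <- expand.grid(model = c("OFM", "PiG", "DAV"), condition = c("BF", "FO"))
  rows <- do.call(rbind, lapply(1:14, function(s)
    data.frame(subject = sprintf("S%02d", s), model = grid$model,
               condition = grid$condition, value = rnorm(1, 0, 5))))
  flat <- cohort_table(rows)
  ga <- art_anova_3x2(flat)
  expect_true(all(is.na(ga$F) | ga$F < 1e-6))

  agree <- 0
  for (seed in 1:100) {
    tab <- random_table(seed + 500, means = c(0, 2, 4, 0, 2, 4), sd = 1.5)
    p_par <- rm_anova_3x2(tab)
    p_art <- art_anova_3x2(tab)
    dec <- function(r) r$p[r$effect == "model"] < 0.05
    if (identical(dec(p_par), dec(p_art))) agree <- agree + 1
  }
  expect_gte(agree, 95)
})

test_that("Bonferroni post-hocs match a paired sign-flip oracle", {
  tab <- random_table(41)
  same <- tab
  fo <- same$condition == "FO"
  key <- paste(same$subject, same$model)
  same$value[fo] <- same$value[!fo][match(key[fo], key[!fo])]
  res <- bonferroni_posthoc(cohort_table(as.data.frame(same)),
                            "conditions_within_model")
  expect_true(all(res$mean_diff == 0))
  expect_true(all(res$p_adjusted == 1))
  expect_false(any(res$significant))

  shift <- same
  shift$value[fo] <- shift$value[fo] + 5    # constant offset, zero noise in d
  res2 <- bonferroni_posthoc(cohort_table(as.data.frame(shift)),
                             "conditions_within_model")
  expect_true(all(res2$significant))

  # adjusted p = 3 x paired-t p for the 3-model family; the raw paired-t p
  # agrees with exact sign-flip enumeration (2^14 flips)
  set.seed(55)
  a <- rnorm(14, 0.6, 1); b <- rnorm(14, 0, 1)
  rows <- do.call(rbind, lapply(1:14, function(s)
    data.frame(subject = sprintf("S%02d", s),
               model = c("OFM", "PiG", "DAV"), condition = "BF",
               value = c(a[s], b[s], rnorm(1)))))
  tab3 <- cohort_table(rows)
  res3 <- bonferroni_posthoc(tab3, "models_within_condition")
  praw <- stats::t.test(a, b, paired = TRUE)$p.value
  i <- res3$comparison == "OFM_BF vs PiG_BF"
  expect_equal(res3$p_adjusted[i], min(1, 3 * praw), tolerance = 1e-12)
  d <- a - b
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 14)))
  tstat <- function(x) mean(x) / (sd(x) / sqrt(length(x)))
  t_obs <- abs(tstat(d))
  t_all <- abs(apply(signs * rep(d, each = nrow(signs)), 1, tstat))
  p_perm <- mean(t_all >= t_obs - 1e-12)
  expect_equal(praw, p_perm, tolerance = 0.02)
})

test_that("the factorial pipeline emits the expected report structure", {
  # built-in interaction: model spread present only in BF
  set.seed(61)
  grid <- expand.grid(model = c("OFM", "PiG", "DAV"), condition = c("BF", "FO"))
  mk_tab <- function(gap) cohort_table(do.call(rbind, lapply(1:14, function(s)
    data.frame(subject = sprintf("S%02d", s), model = grid$model,
               condition = grid$condition,
               value = rnorm(1, 0, 2) + rnorm(6, 0, 1) +
                 gap * (grid$condition == "BF") *
                 c(OFM = 0, PiG = 6, DAV = 10)[as.character(grid$model)]))))
  rep1 <- run_factorial_pipeline(list(rom = mk_tab(1)))
  expect_length(rep1$blocks, 1L)
  b <- rep1$blocks$rom
  expect_lt(b$effects$p[b$effects$effect == "interaction"], 0.05)
  expect_setequal(names(b$posthocs),
                  c("models_within_condition", "conditions_within_model"))
  expect_equal(nrow(b$posthocs$models_within_condition), 6)
  expect_equal(nrow(b$posthocs$conditions_within_model), 3)
  expect_output(print(rep1), "interaction")

  # null tables rarely trigger any post-hoc block
  with_ph <- 0
  for (seed in 1:40) {
    repn <- run_factorial_pipeline(list(p = random_table(seed + 900)))
    if (length(repn$blocks$p$posthocs) > 0) with_ph <- with_ph + 1
  }
  expect_lte(with_ph / 40, 0.25)   # ~3 effects at alpha 0.05 each
})

test_that("cohort tables enforce completeness and round-trip as CSV", {
  df <- data.frame(subject = rep(c("A", "B"), each = 6),
                   model = rep(c("OFM", "PiG", "DAV"), 4),
                   condition = rep(rep(c("BF", "FO"), each = 3), 2),
                   value = 1:12)
  tab <- cohort_table(df, "rom")
  p <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(tab, p)
  tab2 <- read_cohort_csv(p, "rom")
  expect_equal(tab2$value, tab$value)
  expect_error(cohort_table(df[-1, ]), "complete")
  expect_error(cohort_table(df[df$subject == "A", ]), "2 subjects")
})
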