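#' Cohort table for one clinical parameter
#'
#' Long-format complete-case table feeding the 3 (foot model) x 2 (walking
#' condition) within-subject factorial analysis: one row per subject x
#' model x condition cell.
#'
#' @param df data.frame with columns `subject`, `model`, `condition`,
#'   `value`; every subject must have all 6 cells (complete cases only).
#' @param parameter name of the clinical parameter (metadata).
#' @return a `CohortTable` (a data.frame subclass).
#' @export
cohort_table <- function(df, parameter = "value") {
  need <- c("subject", "model", "condition", "value")
  if (!all(need %in% names(df)))
    stop("cohort table needs columns subject, model, condition, value",
         call. = FALSE)
  df <- df[need]
  df$subject <- factor(df$subject)
  df$model <- factor(df$model, levels = intersect(c("OFM", "PiG", "DAV"),
                                                  unique(df$model)))
  df$condition <- factor(df$condition,
                         levels = intersect(c("BF", "FO"), unique(df$condition)))
  nlev <- nlevels(df$model) * nlevels(df$condition)
  counts <- table(df$subject)
  if (any(counts != nlev) || anyNA(df$value))
    stop("complete cases only: every subject needs all model x condition cells",
         call. = FALSE)
  if (nlevels(df$subject) < 2L) stop("need at least 2 subjects", call. = FALSE)
  df <- df[order(df$subject, df$model, df$condition), ]
  rownames(df) <- NULL
  structure(df, parameter = parameter,
            class = c("CohortTable", "data.frame"))
}

#' @rdname cohort_table
#' @param path CSV with columns `subject,model,condition,value`.
#' @export
read_cohort_csv <- function(path, parameter = "value") {
  cohort_table(utils::read.csv(path, stringsAsFactors = FALSE), parameter)
}

#' @rdname cohort_table
#' @param table a `CohortTable` to write.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-cell normality screen
#'
#' Shapiro-Wilk p-values of the within-cell residuals (value minus cell
#' mean, per model x condition cell).  The factorial pipeline routes to the
#' aligned-rank-transform analysis when any cell rejects normality at
#' `alpha`.  Degenerate (near-zero-variance) cells cannot support the
#' parametric route and are flagged non-normal (p = 0).
#'
#' @param table a [cohort_table()].
#' @param alpha routing significance level (default 0.05).
#' @return list with `p_values` (named per cell), `normal` (logical: all
#'   cells pass), `route` (`"parametric"` or `"art"`).
#' @export
shapiro_normality <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "CohortTable"))
  cells <- split(table$value, interaction(table$model, table$condition,
                                          drop = TRUE))
  p <- vapply(cells, function(v) {
    if (length(v) < 3L) return(NA_real_)
    if (stats::sd(v) < 1e-12) return(0)
    stats::shapiro.test(v - mean(v))$p.value
  }, numeric(1))
  normal <- all(p >= alpha, na.rm = TRUE)
  list(p_values = p, normal = normal,
       route = if (normal) "parametric" else "art")
}

#' 3 x 2 repeated-measures factorial ANOVA
#'
#' Classical fully-within-subject two-way ANOVA: total variation is
#' partitioned into subject, model, condition and interaction sums of
#' squares, each within-subject effect tested against its own
#' effect-by-subject error term (F = MS_effect / MS_effect:subject).  With
#' n = 14 subjects the degrees of freedom are (2, 26) for model and
#' interaction and (1, 13) for condition.  Effect size is partial
#' eta-squared, SS_effect / (SS_effect + SS_error), matching the default of
#' mainstream statistics software; set `eta2 = "classical"` for
#' SS_effect / SS_total.  Sphericity is not corrected by default (3-level
#' factor); `gg_correction = TRUE` applies Greenhouse-Geisser epsilon to the
#' df and p of the model and interaction terms.
#'
#' @param table a [cohort_table()].
#' @param eta2 `"partial"` (default) or `"classical"`.
#' @param gg_correction logical, default `FALSE`.
#' @return data.frame of class `EffectResults`: one row per effect
#'   (`model`, `condition`, `interaction`) with `F`, `df1`, `df2`, `p`,
#'   `eta2`.
#' @export
rm_anova_3x2 <- function(table, eta2 = c("partial", "classical"),
                         gg_correction = FALSE) {
  stopifnot(inherits(table, "CohortTable"))
  eta2 <- match.arg(eta2)
  fit <- stats::aov(value ~ model * condition +
                      Error(subject / (model * condition)), data = table)
  sm <- summary(fit)
  pick <- function(term) {
    for (stratum in sm) {
      tab <- stratum[[1]]
      rn <- trimws(rownames(tab))
      i <- match(term, rn)
      if (!is.na(i)) {
        j <- match("Residuals", rn)
        return(c(ss = tab[i, "Sum Sq"], df = tab[i, "Df"],
                 ss_err = tab[j, "Sum Sq"], df_err = tab[j, "Df"]))
      }
    }
    stop("term not found in ANOVA strata: ", term, call. = FALSE)
  }
  ss_total <- sum((table$value - mean(table$value))^2)
  terms <- list(model = "model", condition = "condition",
                interaction = "model:condition")
  tiny <- 1e-12 * max(ss_total, 1e-12)   # roundoff-level sums of squares
  rows <- lapply(names(terms), function(nm) {
    v <- pick(terms[[nm]])
    if (v["ss_err"] <= tiny) {
      # zero error SS: a null effect is exactly F = 0; a non-null effect
      # against a zero error term is degenerate (flagged, p pinned at 0)
      null_eff <- v["ss"] <= tiny
      return(data.frame(effect = nm, F = if (null_eff) 0 else Inf,
                        df1 = unname(v["df"]), df2 = unname(v["df_err"]),
                        p = if (null_eff) 1 else 0,
                        eta2 = if (null_eff) 0 else 1,
                        note = "zero error SS"))
    }
    ms_e <- v["ss_err"] / v["df_err"]
    f <- if (v["ss"] <= tiny) 0 else (v["ss"] / v["df"]) / ms_e
    eps <- 1
    if (gg_correction && v["df"] > 1)
      eps <- gg_epsilon(table, nm)
    p <- stats::pf(f, eps * v["df"], eps * v["df_err"], lower.tail = FALSE)
    e2 <- if (eta2 == "partial") v["ss"] / (v["ss"] + v["ss_err"])
          else v["ss"] / ss_total
    data.frame(effect = nm, F = unname(f), df1 = unname(eps * v["df"]),
               df2 = unname(eps * v["df_err"]), p = unname(p),
               eta2 = unname(e2), note = "")
  })
  out <- do.call(rbind, rows)
  attr(out, "parameter") <- attr(table, "parameter")
  attr(out, "method") <- "rm_anova"
  class(out) <- c("EffectResults", "data.frame")
  out
}

# Greenhouse-Geisser epsilon from the subject x cell wide matrix of the
# effect's contrasts; used only when requested.
gg_epsilon <- function(table, effect) {
  wide <- effect_cell_means(table, effect)
  S <- stats::cov(wide)
  k <- ncol(S)
  # standard formula on the double-centered covariance
  Sc <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  (sum(diag(Sc))^2) / ((k - 1) * sum(Sc^2))
}

# subject x level matrix of per-level means for one effect
effect_cell_means <- function(table, effect) {
  f <- switch(effect,
    model = table$model,
    condition = table$condition,
    interaction = interaction(table$model, table$condition, drop = TRUE))
  ag <- stats::aggregate(table$value, list(subject = table$subject, level = f),
                         mean)
  stats::xtabs(x ~ subject + level, ag)
}

#' Aligned-rank-transform 3 x 2 factorial analysis
#'
#' Non-parametric counterpart of [rm_anova_3x2()] for when the per-cell
#' normality screen fails.  For each effect in turn, responses are aligned
#' by stripping the estimated contributions of all other effects (computed
#' from cell and marginal means), leaving the residual plus that effect's
#' own estimate; the aligned values are ranked (midranks for ties) and the
#' parametric repeated-measures ANOVA is run on the ranks, keeping only the
#' effect's own line.
#'
#' @param table a [cohort_table()].
#' @return an `EffectResults` data.frame as in [rm_anova_3x2()], with
#'   method attribute `"art_anova"`.
#' @export
art_anova_3x2 <- function(table) {
  stopifnot(inherits(table, "CohortTable"))
  rows <- lapply(c("model", "condition", "interaction"), function(eff) {
    tab2 <- table
    tab2$value <- rank(align_effect(table, eff))
    res <- rm_anova_3x2(cohort_table(as.data.frame(tab2),
                                     attr(table, "parameter")))
    res[res$effect == eff, ]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "parameter") <- attr(table, "parameter")
  attr(out, "method") <- "art_anova"
  class(out) <- c("EffectResults", "data.frame")
  out
}

# aligned response for one effect: residual from cell means plus the
# effect's own estimated contribution
align_effect <- function(table, effect) {
  v <- table$value
  mu <- mean(v)
  cell <- stats::ave(v, table$model, table$condition)
  m_mar <- stats::ave(v, table$model)
  c_mar <- stats::ave(v, table$condition)
  est <- switch(effect,
    model = m_mar - mu,
    condition = c_mar - mu,
    interaction = cell - m_mar - c_mar + mu)
  (v - cell) + est
}

#' Bonferroni-corrected post-hoc pairwise comparisons
#'
#' Paired two-sided t-tests between cells, with p-values multiplied by the
#' family size (capped at 1).  Two families mirror the factorial structure:
#' `models_within_condition` compares the 3 model pairs inside one walking
#' condition (family size 3, adjusted threshold 0.05/3 ~ 0.017), and
#' `conditions_within_model` compares BF vs FO inside one model (family
#' size 1).
#'
#' @param table a [cohort_table()].
#' @param family which family of comparisons to run.
#' @param alpha familywise significance level (default 0.05).
#' @return data.frame of class `PosthocResults`: `comparison`, `mean_diff`,
#'   `p_adjusted`, `significant`.
#' @export
bonferroni_posthoc <- function(table,
                               family = c("models_within_condition",
                                          "conditions_within_model"),
                               alpha = 0.05) {
  stopifnot(inherits(table, "CohortTable"))
  family <- match.arg(family)
  cell_vec <- function(model, condition) {
    i <- table$model == model & table$condition == condition
    v <- table$value[i][order(table$subject[i])]
    v
  }
  pairs <- list()
  if (family == "models_within_condition") {
    mods <- levels(table$model)
    cmb <- utils::combn(mods, 2)
    for (cond in levels(table$condition))
      for (k in seq_len(ncol(cmb)))
        pairs[[length(pairs) + 1L]] <- list(
          label = sprintf("%s_%s vs %s_%s", cmb[1, k], cond, cmb[2, k], cond),
          a = cell_vec(cmb[1, k], cond), b = cell_vec(cmb[2, k], cond),
          m = ncol(cmb))
  } else {
    conds <- levels(table$condition)
    if (length(conds) != 2L)
      stop("conditions_within_model needs both conditions", call. = FALSE)
    for (mod in levels(table$model))
      pairs[[length(pairs) + 1L]] <- list(
        label = sprintf("%s_%s vs %s_%s", mod, conds[1], mod, conds[2]),
        a = cell_vec(mod, conds[1]), b = cell_vec(mod, conds[2]), m = 1L)
  }
  rows <- lapply(pairs, function(p) {
    d <- p$a - p$b
    if (stats::sd(d) < 1e-12) {
      praw <- if (all(abs(d) < 1e-12)) 1 else 0   # exact tie vs pure shift
    } else {
      praw <- stats::t.test(p$a, p$b, paired = TRUE)$p.value
    }
    padj <- min(1, praw * p$m)
    data.frame(comparison = p$label, mean_diff = mean(d), p_adjusted = padj,
               significant = padj < alpha)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("PosthocResults", "data.frame")
  out
}

#' Run the full factorial analysis over the clinical parameters
#'
#' For each parameter table: per-cell normality screen routes to the
#' parametric repeated-measures ANOVA or its aligned-rank-transform
#' fallback; post-hoc comparisons are emitted for significant effects.  A
#' significant model x condition interaction triggers simple-effect
#' post-hocs (model pairs within each condition at 0.05/3, condition pair
#' within each model at 0.05); otherwise only significant main effects get
#' their post-hocs.
#'
#' @param tables named list of [cohort_table()] objects, one per clinical
#'   parameter.
#' @param alpha significance level (default 0.05).
#' @return a `FactorialReport`: per-parameter list with `route`,
#'   `normality`, `effects`, and `posthocs`.
#' @export
run_factorial_pipeline <- function(tables, alpha = 0.05) {
  stopifnot(length(tables) >= 1L)
  if (is.null(names(tables)))
    names(tables) <- paste0("parameter", seq_along(tables))
  blocks <- lapply(names(tables), function(nm) {
    tab <- tables[[nm]]
    norm <- shapiro_normality(tab, alpha)
    eff <- if (norm$route == "parametric") rm_anova_3x2(tab)
           else art_anova_3x2(tab)
    sig <- function(e) isTRUE(eff$p[eff$effect == e] < alpha)
    ph <- list()
    if (sig("interaction")) {
      ph$models_within_condition <-
        bonferroni_posthoc(tab, "models_within_condition", alpha)
      ph$conditions_within_model <-
        bonferroni_posthoc(tab, "conditions_within_model", alpha)
    } else {
      if (sig("model"))
        ph$models_within_condition <-
          bonferroni_posthoc(tab, "models_within_condition", alpha)
      if (sig("condition"))
        ph$conditions_within_model <-
          bonferroni_posthoc(tab, "conditions_within_model", alpha)
    }
    list(parameter = nm, route = norm$route, normality = norm$p_values,
         effects = eff, posthocs = ph)
  })
  names(blocks) <- names(tables)
  structure(list(blocks = blocks, alpha = alpha), class = "FactorialReport")
}

#' @export
print.FactorialReport <- function(x, ...) {
  for (b in x$blocks) {
    cat(sprintf("== %s  [%s route] ==\n", b$parameter,
                if (b$route == "art") "aligned-rank" else "parametric"))
    e <- b$effects
    for (i in seq_len(nrow(e)))
      cat(sprintf("  %-12s F(%g,%g) = %.3f, p = %.4g, eta2 = %.3f\n",
                  e$effect[i], e$df1[i], e$df2[i], e$F[i], e$p[i], e$eta2[i]))
    for (fam in names(b$posthocs)) {
      cat(sprintf("  post-hoc (%s):\n", fam))
      ph <- b$posthocs[[fam]]
      for (i in seq_len(nrow(ph)))
        cat(sprintf("    %-22s diff %+7.2f  p_adj %.4g%s\n", ph$comparison[i],
                    ph$mean_diff[i], ph$p_adjusted[i],
                    if (ph$significant[i]) " *" else ""))
    }
  }
  invisible(x)
}

#' Serialize a factorial report to JSON
#' @param report a [run_factorial_pipeline()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "FactorialReport"))
  jsonlite::write_json(
    lapply(report$blocks, function(b) list(
      parameter = b$parameter, route = b$route,
      effects = b$effects, posthocs = b$posthocs)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
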