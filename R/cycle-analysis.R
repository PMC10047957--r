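#' Pointwise median waveform of a set of cycles
#'
#' The median value of the set at each of the 101 time instants; even counts
#' use the midpoint of the two central values.
#'
#' @param cycles non-empty list of [normalized_cycle()] objects (or a
#'   101-row numeric matrix with one column per cycle).
#' @return numeric vector of 101 samples.
#' @export
median_waveform <- function(cycles) {
  m <- cycles_matrix(cycles)
  if (ncol(m) == 0L) stop("empty cycle set", call. = FALSE)
  apply(m, 1, stats::median)
}

cycles_matrix <- function(cycles) {
  if (is.matrix(cycles)) {
    if (nrow(cycles) != 101L) stop("cycles must have 101 samples", call. = FALSE)
    return(cycles)
  }
  if (length(cycles) == 0L) stop("empty cycle set", call. = FALSE)
  vapply(cycles, function(c) {
    s <- if (inherits(c, "NormalizedCycle")) c$samples else as.numeric(c)
    if (length(s) != 101L) stop("cycles must have 101 samples", call. = FALSE)
    s
  }, numeric(101))
}

#' Select the representative gait cycle of a set
#'
#' For each cycle, the area (deg * %GC) between it and the set's pointwise
#' median waveform is computed by trapezoidal integration of the absolute
#' difference over 0-100 % gait cycle; the representative cycle is the one
#' with the smallest area.  Ties are broken toward the lowest index.
#' Selection looks only at the sagittal dorsi-plantarflexion trace.
#'
#' @param cycles list of at least two [normalized_cycle()] objects.
#' @return a `RepresentativeSelection`: list with `areas` (one per cycle)
#'   and `chosen_index`.
#' @export
select_representative <- function(cycles) {
  m <- cycles_matrix(cycles)
  if (ncol(m) < 2L) stop("need at least two cycles", call. = FALSE)
  med <- apply(m, 1, stats::median)
  areas <- apply(abs(m - med), 2, function(d) pracma::trapz(0:100, d))
  structure(list(areas = areas, chosen_index = which.min(areas)),
            class = "RepresentativeSelection")
}

#' Inter-subject waveform consistency by the linear fit method (LFM)
#'
#' Each subject's representative cycle is regressed onto a cohort reference
#' curve (the pointwise median of the set by default): subject = a1 *
#' reference + a0, by least squares over the 101 samples.  R-squared is the
#' squared Pearson correlation between subject and reference; the cohort is
#' considered consistent when the mean R-squared exceeds 0.5.
#'
#' @param subject_cycles list of at least two cycles, one representative
#'   cycle per subject.
#' @param reference `"median"` (default) or `"mean"` cohort reference curve.
#' @return an `LFMResult`: per-subject `a1`, `a0`, `r2`, plus `r2_mean` and
#'   the logical `consistent` flag.
#' @export
lfm <- function(subject_cycles, reference = c("median", "mean")) {
  reference <- match.arg(reference)
  m <- cycles_matrix(subject_cycles)
  if (ncol(m) < 2L) stop("need at least two subjects", call. = FALSE)
  ref <- if (reference == "median") apply(m, 1, stats::median) else rowMeans(m)
  if (stats::sd(ref) < 1e-12)
    stop("zero-variance reference curve: R2 undefined", call. = FALSE)
  fits <- apply(m, 2, function(y) {
    a1 <- stats::cov(y, ref) / stats::var(ref)
    a0 <- mean(y) - a1 * mean(ref)
    r2 <- if (stats::sd(y) < 1e-12) 0 else stats::cor(y, ref)^2
    c(a1 = a1, a0 = a0, r2 = r2)
  })
  structure(list(a1 = fits["a1", ], a0 = fits["a0", ], r2 = fits["r2", ],
                 r2_mean = mean(fits["r2", ]),
                 consistent = mean(fits["r2", ]) > 0.5),
            class = "LFMResult")
}

#' @export
print.LFMResult <- function(x, ...) {
  cat(sprintf("LFM: mean R2 = %.3f over %d subjects (%s)\n", x$r2_mean,
              length(x$r2), if (x$consistent) "consistent" else "inconsistent"))
  invisible(x)
}

#' Extract the clinical ankle parameters of one gait cycle
#'
#' The six scalar outcomes used for the factorial comparison: ankle angle at
#' foot contact (sample at 0 % GC); peak dorsiflexion over the stance phase
#' (0 % to foot off) with its timing; peak plantarflexion over the full
#' cycle with its timing; and sagittal range of motion (peak dorsiflexion
#' minus peak plantarflexion).  Ties take the earliest instant.
#'
#' @param cycle a [normalized_cycle()].
#' @return an `AnkleParameters` list: `angle_at_fc`, `peak_df`, `t_peak_df`,
#'   `peak_pf`, `t_peak_pf`, `rom` (deg and % GC).
#' @export
extract_parameters <- function(cycle) {
  stopifnot(inherits(cycle, "NormalizedCycle"))
  s <- cycle$samples
  pct <- 0:100
  stance <- pct <= cycle$stance_end_pct
  i_df <- which.max(s[stance])          # earliest tie by which.max
  peak_df <- s[stance][i_df]
  t_peak_df <- pct[stance][i_df]
  i_pf <- which.min(s)
  out <- list(angle_at_fc = s[1], peak_df = peak_df, t_peak_df = t_peak_df,
              peak_pf = s[i_pf], t_peak_pf = pct[i_pf],
              rom = peak_df - s[i_pf])
  structure(out, class = "AnkleParameters")
}

#' @export
print.AnkleParameters <- function(x, ...) {
  cat(sprintf(paste0(
    "AnkleParameters: FC %.1f deg | peak DF %.1f deg @ %g%% | ",
    "peak PF %.1f deg @ %g%% | ROM %.1f deg\n"),
    x$angle_at_fc, x$peak_df, x$t_peak_df, x$peak_pf, x$t_peak_pf, x$rom))
  invisible(x)
}

#' Rocker classification criteria
#'
#' Thresholds of the rule-based toe-walking severity screen: a heel (first)
#' rocker requires an ankle angle at foot contact above `fc_angle_threshold`
#' together with a down-going angular excursion within the first
#' `downgoing_window` % of the gait cycle; a premature forefoot (third)
#' rocker is a peak dorsiflexion occurring strictly before
#' `premature_ff_threshold` % of the gait cycle.
#'
#' @param fc_angle_threshold deg (default -5).
#' @param downgoing_window % GC (default 12).
#' @param premature_ff_threshold % GC (default 30).
#' @return a `RockerCriteria` object.
#' @export
rocker_criteria <- function(fc_angle_threshold = -5, downgoing_window = 12,
                            premature_ff_threshold = 30) {
  stopifnot(is.finite(fc_angle_threshold),
            downgoing_window > 0, downgoing_window < 100,
            premature_ff_threshold > 0, premature_ff_threshold < 100)
  structure(list(fc_angle_threshold = fc_angle_threshold,
                 downgoing_window = downgoing_window,
                 premature_ff_threshold = premature_ff_threshold),
            class = "RockerCriteria")
}

#' @rdname rocker_criteria
#' @param path JSON file with the three threshold fields.
#' @export
read_rocker_criteria <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rocker_criteria(x$fc_angle_threshold %||% -5, x$downgoing_window %||% 12,
                  x$premature_ff_threshold %||% 30)
}

#' Classify the foot rockers of one gait cycle
#'
#' `heel_rocker` is true when the angle at foot contact exceeds the
#' threshold AND the first-window pattern is down-going: the net excursion
#' from 0 % to the window end is negative and the running minimum over the
#' window falls strictly below the 0 % value after 0 %.
#' `premature_forefoot_rocker` is true when peak dorsiflexion occurs
#' strictly before the timing threshold.
#'
#' @param cycle a [normalized_cycle()].
#' @param params its [extract_parameters()] result (recomputed when omitted).
#' @param criteria a [rocker_criteria()].
#' @return a `RockerFlags` list: `heel_rocker`,
#'   `premature_forefoot_rocker`.
#' @export
classify_rockers <- function(cycle, params = extract_parameters(cycle),
                             criteria = rocker_criteria()) {
  stopifnot(inherits(cycle, "NormalizedCycle"),
            inherits(criteria, "RockerCriteria"))
  s <- cycle$samples
  w <- 0:100 <= criteria$downgoing_window
  net_down <- (s[w][sum(w)] - s[1]) < 0
  dips <- any(s[w][-1] < s[1])
  heel <- (params$angle_at_fc > criteria$fc_angle_threshold) &&
    net_down && dips
  structure(list(
    heel_rocker = heel,
    premature_forefoot_rocker =
      params$t_peak_df < criteria$premature_ff_threshold),
    class = "RockerFlags")
}

#' Rocker prevalence across gait cycles
#'
#' Percentage of cycles in which each rocker was detected, optionally per
#' grouping (e.g. foot model or subject).
#'
#' @param flags non-empty list of [classify_rockers()] results.
#' @param by optional factor/character vector (same length) to group by.
#' @return data.frame with columns `group` (when `by` given),
#'   `heel_rocker_pct`, `premature_ff_pct`, `n`.
#' @export
rocker_prevalence <- function(flags, by = NULL) {
  if (length(flags) == 0L) stop("no rocker flags supplied", call. = FALSE)
  heel <- vapply(flags, `[[`, logical(1), "heel_rocker")
  ff <- vapply(flags, `[[`, logical(1), "premature_forefoot_rocker")
  if (is.null(by))
    return(data.frame(heel_rocker_pct = 100 * mean(heel),
                      premature_ff_pct = 100 * mean(ff), n = length(flags)))
  sp <- split(seq_along(flags), by)
  do.call(rbind, lapply(names(sp), function(g) {
    i <- sp[[g]]
    data.frame(group = g, heel_rocker_pct = 100 * mean(heel[i]),
               premature_ff_pct = 100 * mean(ff[i]), n = length(i))
  }))
}
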