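# Longitudinal cohort summaries: per-visit means/SDs, the |z| > 3
# standardized-residual outlier rule, and paired within-participant visit
# contrasts. Deliberately *not* a mixed-model layer: the paired contrasts
# are labelled as such and no multiple-testing correction is applied.

#' Per-visit mean and SD for each clinical variable
#'
#' Summarizes a long visit table (one value per participant, visit and
#' variable) into arithmetic means and sample standard deviations (n - 1
#' denominator) per variable and visit. Missing values are excluded pairwise
#' and counted.
#'
#' @param table Data frame with columns `participant_id`, `visit`,
#'   `variable`, `value`.
#' @param visits Visit ordering; defaults to the three study visits.
#' @return Data frame with one row per (variable, visit): `variable`,
#'   `visit`, `n`, `n_missing`, `mean`, `sd` (`sd` is `NA` when fewer than
#'   two observations are available).
#' @export
summarize_visits <- function(table, visits = VISIT_LEVELS) {
  stopifnot(is.data.frame(table),
            all(c("participant_id", "visit", "variable", "value") %in% names(table)))
  if (anyDuplicated(table[c("participant_id", "visit", "variable")]))
    stop("at most one value per participant, visit and variable")
  vs <- factor(as.character(table$visit), levels = visits)
  if (anyNA(vs)) stop("unknown visit value(s)")
  vars <- unique(as.character(table$variable))
  grid <- expand.grid(visit = visits, variable = vars,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    v <- table$value[as.character(table$variable) == grid$variable[i] &
                       as.character(table$visit) == grid$visit[i]]
    ok <- v[!is.na(v)]
    data.frame(variable = grid$variable[i], visit = grid$visit[i],
               n = length(ok), n_missing = sum(is.na(v)),
               mean = if (length(ok)) mean(ok) else NA_real_,
               sd = if (length(ok) >= 2L) stats::sd(ok) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Standardized-residual outlier mask
#'
#' Pure threshold rule on standardized residuals: an observation is excluded
#' exactly when its residual lies more than three standard deviations from
#' zero (`|z| > 3`, strict, so `z = 3` is kept).
#'
#' @param residuals Numeric vector of standardized residuals; must be
#'   finite.
#' @return Logical vector, `TRUE` for kept observations.
#' @examples
#' flag_outliers(c(-3.1, -1, 0, 3)) # FALSE TRUE TRUE TRUE
#' @export
flag_outliers <- function(residuals) {
  residuals <- as.numeric(residuals)
  if (length(residuals) && !all(is.finite(residuals)))
    stop("standardized residuals must be finite")
  abs(residuals) <= 3
}

#' Paired within-participant change between two visits
#'
#' Computes the mean and SD of within-participant differences for one
#' variable between two visits, with a two-sided paired t-test p-value.
#' Optionally log10-transforms the values first (for variables whose
#' residuals are right-skewed on the raw scale). When all differences are
#' zero the change is reported as exactly zero with p = 1 ("no change"); the
#' paired t statistic is undefined in that degenerate case.
#'
#' @param table Long visit table as in [summarize_visits()].
#' @param variable Variable name to contrast.
#' @param visit_pair Character vector of two visits, `c(from, to)`; the
#'   change is `to - from`.
#' @param log10_transform Logical; transform values with `log10()` before
#'   differencing (all values must then be positive).
#' @return A one-row data frame: `variable`, `from`, `to`, `n_pairs`,
#'   `mean_change`, `sd_change`, `statistic`, `p_value`, `log10`.
#' @export
paired_change <- function(table, variable, visit_pair = c("baseline", "month3"),
                          log10_transform = FALSE) {
  stopifnot(is.data.frame(table),
            all(c("participant_id", "visit", "variable", "value") %in% names(table)),
            length(visit_pair) == 2L)
  sub <- table[as.character(table$variable) == variable &
                 as.character(table$visit) %in% visit_pair, ]
  if (anyDuplicated(sub[c("participant_id", "visit")]))
    stop("at most one value per participant and visit for '", variable, "'")
  w1 <- sub[as.character(sub$visit) == visit_pair[1L], ]
  w2 <- sub[as.character(sub$visit) == visit_pair[2L], ]
  ids <- intersect(w1$participant_id, w2$participant_id)
  v1 <- w1$value[match(ids, w1$participant_id)]
  v2 <- w2$value[match(ids, w2$participant_id)]
  ok <- !is.na(v1) & !is.na(v2)
  v1 <- v1[ok]; v2 <- v2[ok]
  if (length(v1) < 3L)
    stop("at least 3 complete pairs are required for '", variable, "'")
  if (log10_transform) {
    if (any(v1 <= 0) || any(v2 <= 0))
      stop("log10 transform requires positive values")
    v1 <- log10(v1); v2 <- log10(v2)
  }
  d <- v2 - v1
  if (stats::sd(d) == 0) {
    stat <- NA_real_
    p <- if (all(d == 0)) 1 else 0  # constant nonzero shift: certain change
  } else {
    tt <- stats::t.test(d, mu = 0, alternative = "two.sided")
    stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  data.frame(variable = variable, from = visit_pair[1L], to = visit_pair[2L],
             n_pairs = length(d), mean_change = mean(d),
             sd_change = stats::sd(d), statistic = stat, p_value = p,
             log10 = log10_transform, stringsAsFactors = FALSE)
}
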