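# Growth / non-growth labelling.
#
# Growth is defined as an increase in nodule mass of at least 25% within one
# year. The relative mass increase is annualised linearly (not compounded):
# y = ((M_t - M_{t-1}) / M_{t-1}) * 365 / dt. The boundary y == 0.25 is
# labelled growth (the criterion is inclusive); both the annualisation and
# the threshold are configurable.

#' Annualised relative mass increase rate
#'
#' @param prev_mass,curr_mass masses in mg (`prev_mass > 0`).
#' @param dt_days interval in days (> 0).
#' @return Per-year relative rate `((curr - prev)/prev) * 365 / dt_days`.
#' @examples
#' annualized_mass_rate(100, 130, 365)  # 0.30
#' @export
annualized_mass_rate <- function(prev_mass, curr_mass, dt_days) {
  if (!all(is.finite(prev_mass)) || any(prev_mass <= 0))
    stop("prev_mass must be > 0", call. = FALSE)
  if (!all(is.finite(dt_days)) || any(dt_days <= 0))
    stop("dt_days must be > 0", call. = FALSE)
  ((curr_mass - prev_mass) / prev_mass) * (365 / dt_days)
}

#' Binary growth label from the annualised mass rate
#'
#' @param y per-year relative mass rate.
#' @param threshold growth threshold; default 0.25 (a 25% mass increase per
#'   year). `y >= threshold` is labelled growth.
#' @return logical.
#' @export
growth_label <- function(y, threshold = 0.25) {
  if (any(!is.finite(y))) stop("y must be finite", call. = FALSE)
  y >= threshold
}

#' Univariate comparison of cohort characteristics between label groups
#'
#' For each requested variable: continuous variables are summarised as
#' median (Q1, Q3) per group and compared with a two-sided Welch t-test;
#' categorical variables as counts and compared with a chi-squared test
#' (without continuity correction by default).
#'
#' @param cohort data.frame of per-nodule characteristics.
#' @param by name of the logical/two-level column defining the groups.
#' @param vars variables to compare; default all columns except `by`.
#' @param correct logical, Yates continuity correction for the chi-squared
#'   test (default FALSE).
#' @return data.frame: variable, type, per-group summary, statistic, p_value.
#' @export
compare_groups <- function(cohort, by = "growth_label", vars = NULL,
                           correct = FALSE) {
  g <- cohort[[by]]
  if (is.null(g)) stop("column '", by, "' not found", call. = FALSE)
  g <- as.factor(g)
  if (nlevels(droplevels(g)) != 2L)
    stop("'", by, "' must define exactly two nonempty groups", call. = FALSE)
  g <- droplevels(g)
  if (is.null(vars)) vars <- setdiff(names(cohort), by)
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]]
    if (is.numeric(x)) {
      s <- vapply(levels(g), function(l) {
        q <- stats::quantile(x[g == l], c(0.25, 0.5, 0.75), names = FALSE)
        sprintf("%.4g (%.4g, %.4g)", q[2], q[1], q[3])
      }, character(1))
      st <- if (stats::sd(x[g == levels(g)[1]]) == 0 &&
                stats::sd(x[g == levels(g)[2]]) == 0) {
        eq <- isTRUE(all.equal(mean(x[g == levels(g)[1]]),
                               mean(x[g == levels(g)[2]])))
        list(statistic = 0, p.value = if (eq) 1 else 0)
      } else stats::t.test(x ~ g)
      data.frame(variable = v, type = "continuous",
                 group1 = s[1], group2 = s[2],
                 statistic = unname(st$statistic), p_value = st$p.value)
    } else {
      tab <- table(x, g)
      s <- vapply(seq_len(ncol(tab)), function(j)
        paste(sprintf("%s=%d", rownames(tab), tab[, j]), collapse = "/"),
        character(1))
      if (nrow(tab) < 2L) {
        # single observed level: no association to test
        data.frame(variable = v, type = "categorical",
                   group1 = s[1], group2 = s[2],
                   statistic = 0, p_value = 1)
      } else {
        st <- suppressWarnings(stats::chisq.test(tab, correct = correct))
        data.frame(variable = v, type = "categorical",
                   group1 = s[1], group2 = s[2],
                   statistic = unname(st$statistic), p_value = st$p.value)
      }
    }
  })
  do.call(rbind, rows)
}
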