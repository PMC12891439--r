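# Variance-heterogeneity tests used to contrast environmental variability
# between the two upwelling regimes, and the austral-season summary of
# low-pH days.

#' Brown-Forsythe (median-centered Levene) test
#'
#' One-way ANOVA on absolute deviations from the group medians — the robust
#' default of modern software when "Levene's test" is requested. The
#' classical mean-centered variant is available via `center = "mean"`.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups with
#'   >= 2 values each).
#' @param center `"median"` (Brown-Forsythe, default) or `"mean"` (Levene's
#'   original).
#' @return List: `statistic` (F), `df` (df1, df2), `p.value`, `method`.
#' @examples
#' brown_forsythe(list(c(1, 2, 3), c(2, 4, 6)))$statistic  # 0.8
#' @export
brown_forsythe <- function(groups, center = c("median", "mean")) {
  center <- match.arg(center)
  check_groups(groups)
  centerfun <- if (center == "median") stats::median else mean
  z <- unlist(lapply(groups, function(x) abs(x - centerfun(x))))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  a <- stats::anova(stats::lm(z ~ g))
  list(statistic = a$`F value`[1], df = a$Df, p.value = a$`Pr(>F)`[1],
       method = paste0("Levene-type test (", center, "-centered)"))
}

#' Fligner-Killeen test of variance homogeneity
#'
#' Rank-based test on absolute deviations from group medians, transformed by
#' normal quantiles; the statistic is chi-squared with k-1 degrees of
#' freedom. Thin wrapper over [stats::fligner.test()] with the package's
#' group-list interface.
#'
#' @param groups List of numeric vectors, one per group.
#' @return List: `statistic` (chi-squared), `df`, `p.value`, `method`.
#' @export
fligner_killeen <- function(groups) {
  check_groups(groups)
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ft <- stats::fligner.test(x, g)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p.value = ft$p.value, method = ft$method)
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(lengths(groups) < 2L))
    stop("every group needs at least two values", call. = FALSE)
  invisible(groups)
}

#' Austral season of a date
#'
#' Southern-hemisphere convention: spring Sep-Nov, summer Dec-Feb, autumn
#' Mar-May, winter Jun-Aug.
#'
#' @param dates Vector coercible with `as.Date`.
#' @return Factor with levels spring, summer, autumn, winter.
#' @export
austral_season <- function(dates) {
  m <- as.POSIXlt(as.Date(dates))$mon + 1L
  s <- ifelse(m %in% c(9L, 10L, 11L), "spring",
       ifelse(m %in% c(12L, 1L, 2L), "summer",
       ifelse(m %in% c(3L, 4L, 5L), "autumn", "winter")))
  factor(s, levels = c("spring", "summer", "autumn", "winter"))
}

#' Seasonal summary of low-pH days
#'
#' Counts the days on which pH fell below a threshold (a day counts once,
#' via its daily minimum) and distributes them over austral seasons, with
#' percentages reported to one decimal.
#'
#' @param dates Dates of the pH readings.
#' @param ph pH values aligned with `dates`.
#' @param threshold Low-pH threshold (default 7.3, the corrosive-event
#'   level used for the seasonal upwelling site).
#' @return Data frame with `season`, `n_days`, `percent`, plus attribute
#'   `total_days` (total low-pH days).
#' @export
low_ph_season_summary <- function(dates, ph, threshold = 7.3) {
  if (length(dates) != length(ph))
    stop("dates and ph must be aligned", call. = FALSE)
  if (anyNA(dates)) stop("undated pH values", call. = FALSE)
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable dates in pH series", call. = FALSE)
  daily_min <- tapply(ph, dates, min)
  low_days <- as.Date(names(daily_min)[daily_min < threshold])
  seas <- austral_season(low_days)
  n <- table(seas)
  total <- sum(n)
  out <- data.frame(season = names(n), n_days = as.integer(n),
                    percent = if (total > 0)
                      round(100 * as.integer(n) / total, 1) else rep(0, 4))
  attr(out, "total_days") <- total
  out
}
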