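#' A timed cell-count series for one culture
#'
#' One liquid culture of CD34+ cells under one condition: counts (cells/mL)
#' at ascending timepoints (hours) starting at seeding (time 0).
#'
#' @param sample_id sample label.
#' @param group `"healthy"` or `"cmml"`.
#' @param condition `"control"` (no CXCL8) or `"cxcl8"`.
#' @param timepoints hours, ascending, first = 0.
#' @param counts cells/mL aligned to `timepoints`; non-negative, positive at
#'   time 0.
#' @return A `count_series` object.
#' @export
count_series <- function(sample_id, group = c("healthy", "cmml"),
                         condition = c("control", "cxcl8"),
                         timepoints, counts) {
  group <- match.arg(group)
  condition <- match.arg(condition)
  check_timepoints(timepoints)
  if (length(counts) != length(timepoints))
    stop_invalid("`counts` and `timepoints` must have equal length (%s)",
                 sample_id)
  if (any(counts < 0))
    stop_invalid("negative count in sample '%s'", sample_id)
  if (counts[1L] <= 0)
    stop_invalid("count at time 0 must be > 0 (sample '%s')", sample_id)
  structure(
    list(sample_id = as.character(sample_id), group = group,
         condition = condition, seed_density = counts[1L],
         timepoints = as.numeric(timepoints), counts = as.numeric(counts)),
    class = "count_series"
  )
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series> %s (%s, %s): %d timepoints over %g h\n",
              x$sample_id, x$group, x$condition, length(x$timepoints),
              max(x$timepoints)))
  invisible(x)
}

#' Estimate the exponential growth rate of a culture
#'
#' Under the exponential growth model the count at day `t` is
#' `C(t) = C(0) * g^t`, so the daily fold-change is
#' `g = (C_t / C_0)^(1 / t_days)` (default, `convention = "daily_fold"`); a
#' culture that exactly doubles every day has `g = 2` and a static culture
#' `g = 1`. The alternative `convention = "rate_constant"` returns the
#' continuous rate `ln(C_t / C_0) / t_days`. By default the rate uses the
#' time-0 and final counts (the day-0/day-3 design of a 72-hour culture);
#' with more than two timepoints `method = "loglinear"` fits
#' `log(count) ~ time` by least squares instead and transforms the slope to
#' the requested convention.
#'
#' @param series a [count_series()].
#' @param method `"two_point"` (default) or `"loglinear"`.
#' @param convention `"daily_fold"` (default) or `"rate_constant"`.
#' @return A `growth_rate` object: `sample_id`, `group`, `condition`,
#'   `rate`, `convention`, `method`.
#' @examples
#' s <- count_series("hd1", "healthy", "control", c(0, 72), c(0.75e5, 6e5))
#' estimate_growth_rate(s)$rate # 2: eight-fold over three days
#' @export
estimate_growth_rate <- function(series,
                                 method = c("two_point", "loglinear"),
                                 convention = c("daily_fold", "rate_constant")) {
  stopifnot(inherits(series, "count_series"))
  method <- match.arg(method)
  convention <- match.arg(convention)
  t_days <- series$timepoints / 24
  n <- length(series$counts)
  if (method == "two_point" || n == 2L) {
    c0 <- series$counts[1L]; ct <- series$counts[n]
    if (ct <= 0)
      stop_invalid("growth rate undefined: non-positive final count in '%s'",
                   series$sample_id)
    slope <- log(ct / c0) / (t_days[n] - t_days[1L])
  } else {
    if (any(series$counts <= 0))
      stop_invalid("growth rate undefined: non-positive count in '%s'",
                   series$sample_id)
    slope <- unname(coef(lm(log(series$counts) ~ t_days))[2L])
  }
  rate <- if (convention == "daily_fold") exp(slope) else slope
  structure(
    list(sample_id = series$sample_id, group = series$group,
         condition = series$condition, rate = rate,
         convention = convention, method = method),
    class = "growth_rate"
  )
}

#' @export
print.growth_rate <- function(x, ...) {
  cat(sprintf("<growth_rate> %s (%s, %s): %.4g per day [%s, %s]\n",
              x$sample_id, x$group, x$condition, x$rate, x$convention,
              x$method))
  invisible(x)
}

#' Summarise healthy growth rates for one condition
#'
#' Arithmetic mean (the denominator of relative fitness), sample SD, minimum
#' and maximum of the healthy samples' growth rates under one condition.
#'
#' @param rates list of `growth_rate` objects (healthy samples; other groups
#'   are ignored with a message if present).
#' @param condition `"control"` or `"cxcl8"`; rates are filtered to it.
#' @return A `healthy_summary` object: `condition`, `n`, `mean_rate`,
#'   `sd_rate` (`NA` for n = 1), `min_rate`, `max_rate`.
#' @export
summarize_healthy <- function(rates, condition = c("control", "cxcl8")) {
  condition <- match.arg(condition)
  if (inherits(rates, "growth_rate")) rates <- list(rates)
  stopifnot(all(vapply(rates, inherits, logical(1), "growth_rate")))
  keep <- vapply(rates, function(g)
    g$group == "healthy" && g$condition == condition, logical(1))
  rates <- rates[keep]
  if (length(rates) == 0)
    stop_invalid("no healthy growth rates for condition '%s'", condition)
  x <- vapply(rates, `[[`, numeric(1), "rate")
  structure(
    list(condition = condition, n = length(x), mean_rate = mean(x),
         sd_rate = if (length(x) > 1) sd(x) else NA_real_,
         min_rate = min(x), max_rate = max(x)),
    class = "healthy_summary"
  )
}

#' @export
print.healthy_summary <- function(x, ...) {
  cat(sprintf(
    "<healthy_summary> %s: n = %d, mean %.3g +/- %.3g (range %.3g-%.3g)\n",
    x$condition, x$n, x$mean_rate, x$sd_rate, x$min_rate, x$max_rate))
  invisible(x)
}

#' Relative fitness of one sample
#'
#' The relative fitness `r` of a sample is the ratio of its growth rate to
#' the mean growth rate of healthy cells measured under the same condition.
#' Fitness is only meaningful condition-matched: a rate measured with CXCL8
#' must be divided by the healthy mean with CXCL8.
#'
#' @param rate a `growth_rate`.
#' @param summary a `healthy_summary` for the same condition.
#' @return A `fitness_estimate`: `sample_id`, `group`, `condition`, `r`.
#' @export
compute_fitness <- function(rate, summary) {
  stopifnot(inherits(rate, "growth_rate"), inherits(summary, "healthy_summary"))
  if (rate$condition != summary$condition)
    stop_invalid("condition mismatch: rate is '%s' but summary is '%s'",
                 rate$condition, summary$condition)
  if (summary$mean_rate <= 0)
    stop_invalid("healthy mean rate must be > 0")
  structure(
    list(sample_id = rate$sample_id, group = rate$group,
         condition = rate$condition, r = rate$rate / summary$mean_rate),
    class = "fitness_estimate"
  )
}

#' Cohort fitness table and advantageous-subset report
#'
#' Computes condition-matched relative fitness for every sample and reports
#' the CMML samples with \eqn{r > 1} (strictly: only a fitness above the healthy
#' mean predicts takeover, so \eqn{r = 1} is excluded). The minimum fitness is
#' reported under both conventions — over all CMML samples and over the
#' advantageous subset only — since the two differ whenever some samples sit
#' at or below the healthy mean.
#'
#' @param rates list of `growth_rate` objects (healthy and CMML, any
#'   conditions).
#' @param summaries named list of `healthy_summary` objects keyed by
#'   condition (as from [summarize_healthy()]); every condition present in
#'   `rates` must have a summary.
#' @return A data frame (class `fitness_table`) with columns `sample_id`,
#'   `group`, `condition`, `rate`, `r`, `advantageous`; attributes
#'   `advantageous_n`, `advantageous_ids`, `r_min_all`, `r_min_advantageous`,
#'   `r_max` summarise the CMML subset.
#' @export
fitness_table <- function(rates, summaries) {
  stopifnot(all(vapply(rates, inherits, logical(1), "growth_rate")))
  conds <- unique(vapply(rates, `[[`, character(1), "condition"))
  missing_cond <- setdiff(conds, names(summaries))
  if (length(missing_cond))
    stop_invalid("no healthy summary for condition(s): %s",
                 paste(missing_cond, collapse = ", "))
  rows <- lapply(rates, function(g) {
    f <- compute_fitness(g, summaries[[g$condition]])
    data.frame(sample_id = g$sample_id, group = g$group,
               condition = g$condition, rate = g$rate, r = f$r,
               advantageous = g$group == "cmml" & f$r > 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  cm <- out[out$group == "cmml", ]
  adv_ids <- unique(cm$sample_id[cm$advantageous])
  attr(out, "advantageous_n") <- length(adv_ids)
  attr(out, "advantageous_ids") <- adv_ids
  attr(out, "r_min_all") <- if (nrow(cm)) min(cm$r) else NA_real_
  attr(out, "r_min_advantageous") <-
    if (any(cm$advantageous)) min(cm$r[cm$advantageous]) else NA_real_
  attr(out, "r_max") <- if (nrow(cm)) max(cm$r) else NA_real_
  class(out) <- c("fitness_table", class(out))
  out
}
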