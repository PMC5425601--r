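# order-statistic index rule for empirical quantiles of B draws: the lower
# endpoint takes the floor((B+1)p)-th and the upper the ceiling((B+1)p)-th
# ordered value, clamped to [1, B]. The outward rounding keeps a symmetric
# pair of endpoints for symmetric draws (indices sum to B + 1).
.ci_index <- function(B, p, side) {
  i <- if (side == "lower") floor((B + 1) * p) else ceiling((B + 1) * p)
  min(max(i, 1L), B)
}

.ci_tag <- function(kind, draws) {
  suffix <- if (identical(draws$estimand, "difference")) "diff" else "ind"
  appr <- if (identical(draws$approach, "single")) "S" else "M"
  paste0(kind, suffix, appr)
}

.med_ci <- function(method, draws, lower, upper, level, extra = list()) {
  structure(c(list(method = method, target = draws$estimand,
                   lower = unname(lower), upper = unname(upper),
                   level = level, n_draws = draws$n_draws,
                   point_estimate = draws$point_estimate,
                   provenance = draws$provenance, seed = draws$seed,
                   n_dropped = draws$n_dropped,
                   excludes_zero = lower > 0 || upper < 0),
              extra),
            class = "med_ci")
}

#' @export
print.med_ci <- function(x, digits = 3, ...) {
  cat(x$method, ": ", format(100 * x$level), "% CI for ", x$target, " = (",
      format(round(x$lower, digits), nsmall = digits), ", ",
      format(round(x$upper, digits), nsmall = digits), ")",
      if (x$excludes_zero) "  [excludes 0]" else "", "\n", sep = "")
  invisible(x)
}

#' Percentile confidence interval from replicate draws
#'
#' The interval endpoints are the empirical alpha/2 and 1 - alpha/2
#' quantiles of the draws, using the order-statistic rule
#' `lower = floor((B+1)*alpha/2)`-th, `upper = ceiling((B+1)*(1-alpha/2))`-th
#' ordered value (clamped to the available range).
#'
#' @param draws A `draw_set` from [bootstrap_draws()] or
#'   [monte_carlo_draws()] with at least 100 draws.
#' @param level Nominal coverage, default 0.95.
#' @return A `med_ci` with method tag `PC...` (bootstrap) or `MC...`
#'   (Monte Carlo provenance).
#' @export
percentile_ci <- function(draws, level = 0.95) {
  if (!inherits(draws, "draw_set")) stop("draws must be a draw_set object")
  B <- draws$n_draws
  if (B < 100) stop("at least 100 draws are required for interval estimation")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  s <- sort(draws$draws)
  alpha <- 1 - level
  lower <- s[.ci_index(B, alpha / 2, "lower")]
  upper <- s[.ci_index(B, 1 - alpha / 2, "upper")]
  kind <- if (identical(draws$provenance, "monte_carlo")) "MC" else "PC"
  .med_ci(.ci_tag(kind, draws), draws, lower, upper, level)
}

#' Bias-corrected bootstrap confidence interval
#'
#' Shifts the percentile levels by the median-bias correction
#' `z0 = qnorm(prop)` where `prop` is the proportion of draws below the
#' original-sample point estimate (draws exactly equal to it count half).
#' The adjusted levels are `pnorm(2*z0 + qnorm(alpha/2))` and
#' `pnorm(2*z0 + qnorm(1 - alpha/2))`, and the endpoints use the same
#' order-statistic rule as [percentile_ci()]. A proportion of 0 or 1 is
#' clamped to `1/(2B)` or `1 - 1/(2B)` and flagged in the result.
#'
#' @inheritParams percentile_ci
#' @return A `med_ci` with method tag `BC...`, carrying `z0` and the
#'   adjusted quantile levels.
#' @export
bc_ci <- function(draws, level = 0.95) {
  if (!inherits(draws, "draw_set")) stop("draws must be a draw_set object")
  B <- draws$n_draws
  if (B < 100) stop("at least 100 draws are required for interval estimation")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  d <- draws$draws
  pe <- draws$point_estimate
  prop <- (sum(d < pe) + 0.5 * sum(d == pe)) / B
  clamped <- prop <= 0 || prop >= 1
  prop <- min(max(prop, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- qnorm(prop)
  alpha <- 1 - level
  p_lo <- pnorm(2 * z0 + qnorm(alpha / 2))
  p_hi <- pnorm(2 * z0 + qnorm(1 - alpha / 2))
  s <- sort(d)
  lower <- s[.ci_index(B, p_lo, "lower")]
  upper <- s[.ci_index(B, p_hi, "upper")]
  .med_ci(.ci_tag("BC", draws), draws, lower, upper, level,
          extra = list(z0 = z0, adjusted_levels = c(p_lo, p_hi),
                       proportion_clamped = clamped))
}

#' Does a confidence interval exclude zero?
#'
#' Uses the closed-interval convention: an endpoint exactly at zero counts
#' as covering zero, so the interval does not exclude it.
#'
#' @param interval A `med_ci` object.
#' @return `TRUE` iff `lower > 0` or `upper < 0`.
#' @export
ci_excludes_zero <- function(interval) {
  if (!inherits(interval, "med_ci")) stop("interval must be a med_ci object")
  if (interval$lower > interval$upper) stop("malformed interval: lower > upper")
  interval$lower > 0 || interval$upper < 0
}
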