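# ---- vectorized closed-form refits for bootstrap resamples ----
#
# Within a resample, the per-group path estimates have closed forms from the
# sample moments: a = S_xm/S_xx in the M equation, and (b, c') solve the
# 2x2 normal equations of the Y regression on (m, x). Columns of the index
# matrix are independent resamples; degenerate columns (zero x variance or
# singular Y design) are flagged.

.boot_calc_group <- function(x, m, y, k) {
  n <- length(x)
  idx <- sample.int(n, n * k, replace = TRUE)
  xb <- matrix(x[idx], n, k); mb <- matrix(m[idx], n, k); yb <- matrix(y[idx], n, k)
  mx <- colMeans(xb); mm <- colMeans(mb); my <- colMeans(yb)
  Sxx <- colMeans(xb * xb) - mx * mx
  Sxm <- colMeans(xb * mb) - mx * mm
  Smm <- colMeans(mb * mb) - mm * mm
  Smy <- colMeans(mb * yb) - mm * my
  Sxy <- colMeans(xb * yb) - mx * my
  a <- Sxm / Sxx
  det <- Smm * Sxx - Sxm * Sxm
  b <- (Smy * Sxx - Sxy * Sxm) / det
  bad <- !is.finite(a) | !is.finite(b) | Sxx <= 0 |
    det <= 1e-12 * pmax(Smm * Sxx, .Machine$double.eps)
  list(a = a, b = b, bad = bad)
}

.boot_redraw <- function(calc, B, max_redraw = 10L) {
  out <- calc(B)
  for (r in seq_len(max_redraw)) {
    bad_idx <- which(out$bad)
    if (!length(bad_idx)) break
    repl <- calc(length(bad_idx))
    for (f in setdiff(names(out), "bad")) out[[f]][bad_idx] <- repl[[f]]
    out$bad[bad_idx] <- repl$bad
  }
  out
}

# multi-group approach: independent stratified resamples per group
.boot_mg_draws <- function(x1, m1, y1, x2, m2, y2, B) {
  g1 <- .boot_redraw(function(k) .boot_calc_group(x1, m1, y1, k), B)
  g2 <- .boot_redraw(function(k) .boot_calc_group(x2, m2, y2, k), B)
  keep <- !(g1$bad | g2$bad)
  ind1 <- (g1$a * g1$b)[keep]
  ind2 <- (g2$a * g2$b)[keep]
  list(ind1 = ind1, ind2 = ind2, diff = ind1 - ind2, n_dropped = sum(!keep))
}

# single-group approach, stratified: per-group resampling with pooled
# Y-equation moments. Pooled OLS of M on (x, dummy, x*dummy) has per-group
# slopes as its exact coefficient solution, so only the group slopes and
# the pooled (m, x) regression are needed.
.boot_sg_strat_draws <- function(xr, mr, yr, xf, mf, yf, B) {
  n1 <- length(xr); n2 <- length(xf); N <- n1 + n2
  w1 <- n1 / N; w2 <- n2 / N
  calc <- function(k) {
    i1 <- sample.int(n1, n1 * k, replace = TRUE)
    i2 <- sample.int(n2, n2 * k, replace = TRUE)
    x1 <- matrix(xr[i1], n1, k); m1 <- matrix(mr[i1], n1, k); y1 <- matrix(yr[i1], n1, k)
    x2 <- matrix(xf[i2], n2, k); m2 <- matrix(mf[i2], n2, k); y2 <- matrix(yf[i2], n2, k)
    e1x <- colMeans(x1); e1m <- colMeans(m1); e1y <- colMeans(y1)
    e2x <- colMeans(x2); e2m <- colMeans(m2); e2y <- colMeans(y2)
    e1xx <- colMeans(x1 * x1); e2xx <- colMeans(x2 * x2)
    e1xm <- colMeans(x1 * m1); e2xm <- colMeans(x2 * m2)
    e1mm <- colMeans(m1 * m1); e2mm <- colMeans(m2 * m2)
    e1my <- colMeans(m1 * y1); e2my <- colMeans(m2 * y2)
    e1xy <- colMeans(x1 * y1); e2xy <- colMeans(x2 * y2)
    d1 <- e1xx - e1x * e1x; d2 <- e2xx - e2x * e2x
    a_ref <- (e1xm - e1x * e1m) / d1
    a_foc <- (e2xm - e2x * e2m) / d2
    ex <- w1 * e1x + w2 * e2x; em <- w1 * e1m + w2 * e2m; ey <- w1 * e1y + w2 * e2y
    Sxx <- w1 * e1xx + w2 * e2xx - ex * ex
    Sxm <- w1 * e1xm + w2 * e2xm - ex * em
    Smm <- w1 * e1mm + w2 * e2mm - em * em
    Smy <- w1 * e1my + w2 * e2my - em * ey
    Sxy <- w1 * e1xy + w2 * e2xy - ex * ey
    det <- Smm * Sxx - Sxm * Sxm
    b <- (Smy * Sxx - Sxy * Sxm) / det
    bad <- !is.finite(a_ref) | !is.finite(a_foc) | !is.finite(b) |
      d1 <= 0 | d2 <= 0 | det <= 1e-12 * pmax(Smm * Sxx, .Machine$double.eps)
    list(a1 = a_ref, a3 = a_foc - a_ref, b = b, bad = bad)
  }
  out <- .boot_redraw(calc, B)
  keep <- !out$bad
  a1 <- out$a1[keep]; a3 <- out$a3[keep]; b <- out$b[keep]
  list(ind_ref = a1 * b, ind_foc = (a1 + a3) * b, diff = a3 * b,
       n_dropped = sum(!keep))
}

# single-group approach, pooled resampling: rows drawn from the combined
# sample, so per-resample group sizes vary; group moments via indicator
# weights
.boot_sg_pooled_draws <- function(x, m, y, g, B) {
  N <- length(x)
  calc <- function(k) {
    idx <- sample.int(N, N * k, replace = TRUE)
    xb <- matrix(x[idx], N, k); mb <- matrix(m[idx], N, k); yb <- matrix(y[idx], N, k)
    gb <- matrix(g[idx], N, k)   # focal indicator 0/1
    nf <- colSums(gb); nr <- N - nf
    sum_r <- function(v) colSums(v * (1 - gb))
    sum_f <- function(v) colSums(v * gb)
    arx <- sum_r(xb) / nr; arm <- sum_r(mb) / nr
    afx <- sum_f(xb) / nf; afm <- sum_f(mb) / nf
    drx <- sum_r(xb * xb) / nr - arx * arx
    dfx <- sum_f(xb * xb) / nf - afx * afx
    a_ref <- (sum_r(xb * mb) / nr - arx * arm) / drx
    a_foc <- (sum_f(xb * mb) / nf - afx * afm) / dfx
    ex <- colMeans(xb); em <- colMeans(mb); ey <- colMeans(yb)
    Sxx <- colMeans(xb * xb) - ex * ex
    Sxm <- colMeans(xb * mb) - ex * em
    Smm <- colMeans(mb * mb) - em * em
    Smy <- colMeans(mb * yb) - em * ey
    Sxy <- colMeans(xb * yb) - ex * ey
    det <- Smm * Sxx - Sxm * Sxm
    b <- (Smy * Sxx - Sxy * Sxm) / det
    bad <- nf < 2 | nr < 2 | !is.finite(a_ref) | !is.finite(a_foc) |
      !is.finite(b) | drx <= 0 | dfx <= 0 |
      det <= 1e-12 * pmax(Smm * Sxx, .Machine$double.eps)
    list(a1 = a_ref, a3 = a_foc - a_ref, b = b, bad = bad)
  }
  out <- .boot_redraw(calc, B)
  keep <- !out$bad
  a1 <- out$a1[keep]; a3 <- out$a3[keep]; b <- out$b[keep]
  list(ind_ref = a1 * b, ind_foc = (a1 + a3) * b, diff = a3 * b,
       n_dropped = sum(!keep))
}

.draw_set <- function(draws, estimand, provenance, point_estimate, seed,
                      approach, n_requested, n_dropped = 0L,
                      resampling = NA_character_) {
  structure(list(draws = as.numeric(draws), n_draws = length(draws),
                 estimand = estimand, provenance = provenance,
                 point_estimate = unname(point_estimate), seed = seed,
                 approach = approach, n_requested = n_requested,
                 n_dropped = n_dropped, resampling = resampling),
            class = "draw_set")
}

#' @export
print.draw_set <- function(x, ...) {
  cat(x$provenance, "draws (", x$approach, "approach ) for", x$estimand,
      ":", x$n_draws, "replicates")
  if (x$n_dropped > 0L) cat(" (", x$n_dropped, "dropped )")
  cat("\n  point estimate =", format(x$point_estimate, digits = 5), "\n")
  invisible(x)
}

.check_dropped <- function(n_dropped, B) {
  if (n_dropped > 0.10 * B)
    stop("more than 10% of bootstrap replicates had degenerate designs (",
         n_dropped, " of ", B, ")")
  if (n_dropped > 0.01 * B)
    warning("more than 1% of bootstrap replicates dropped (", n_dropped,
            " of ", B, ")")
  invisible(NULL)
}

#' Bootstrap replicate estimates of an indirect-effect estimand
#'
#' Draws `B` bootstrap resamples of the data (with replacement), refits the
#' mediation model under the requested approach in each resample, and
#' returns the replicate estimates of one estimand: the simple indirect
#' effect in a group, or the group difference in the indirect effect
#' (focal minus reference for the single-group approach, Group 1 minus
#' Group 2 for the multi-group approach). The default resampling is
#' stratified by group, which keeps the group sizes fixed; pooled resampling
#' of the combined sample is available for the single-group approach.
#' Resamples with a degenerate design are redrawn up to 10 times and then
#' dropped (warning above 1% dropped, error above 10%). Results are
#' deterministic given `seed`.
#'
#' @param data A [mediation_data] object.
#' @param estimand One of the group labels, or `"difference"`.
#' @param approach `"multi"` or `"single"`.
#' @param B Number of bootstrap resamples (at least 100).
#' @param seed Integer seed; required for reproducible draws.
#' @param resampling `"stratified"` (default) or `"pooled"` (single-group
#'   approach only).
#' @param coding Optional [group_coding] for the single-group approach.
#' @param constraints Optional constraint set refitted in every resample
#'   (multi-group approach only; disables the fast closed-form refit).
#' @return A `draw_set` with the replicate estimates, the point estimate
#'   from the original sample, and the drop count.
#' @export
bootstrap_draws <- function(data, estimand, approach = c("multi", "single"),
                            B = 1000, seed = NULL,
                            resampling = c("stratified", "pooled"),
                            coding = NULL, constraints = character()) {
  approach <- match.arg(approach)
  resampling <- match.arg(resampling)
  if (!inherits(data, "mediation_data")) stop("data must be a mediation_data object")
  if (B < 100) stop("B must be at least 100")
  lev <- levels(data$group)
  if (!estimand %in% c(lev, "difference"))
    stop("estimand must be one of: ", paste(c(lev, "difference"), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  if (approach == "multi") {
    if (resampling == "pooled")
      stop("the multi-group approach resamples within groups; pooled resampling applies to the single-group approach")
    fit <- fit_multi_group(data, constraints = constraints, compute_vcov = FALSE)
    ind <- simple_indirect_effects(fit)
    pe <- if (estimand == "difference") ind$difference else ind$effects[[estimand]]
    i1 <- data$group == lev[1L]
    if (length(constraints) == 0L) {
      bd <- .boot_mg_draws(data$x[i1], data$m[i1], data$y[i1],
                           data$x[!i1], data$m[!i1], data$y[!i1], B)
      draws <- switch(estimand, difference = bd$diff,
                      if (estimand == lev[1L]) bd$ind1 else bd$ind2)
      n_dropped <- bd$n_dropped
    } else {
      # constrained refits have no closed form: loop over resamples
      n1 <- sum(i1); n2 <- data$n_total - n1
      draws <- rep(NA_real_, B)
      for (bi in seq_len(B)) {
        for (att in 1:11) {
          j1 <- sample.int(n1, n1, replace = TRUE)
          j2 <- sample.int(n2, n2, replace = TRUE)
          db <- mediation_data(c(data$x[i1][j1], data$x[!i1][j2]),
                               c(data$m[i1][j1], data$m[!i1][j2]),
                               c(data$y[i1][j1], data$y[!i1][j2]),
                               rep(lev, c(n1, n2)), levels = lev)
          fb <- tryCatch(fit_multi_group(db, constraints = constraints,
                                         compute_vcov = FALSE),
                         error = function(e) NULL)
          if (!is.null(fb)) break
        }
        if (is.null(fb)) next
        ib <- simple_indirect_effects(fb)
        draws[bi] <- if (estimand == "difference") ib$difference else ib$effects[[estimand]]
      }
      n_dropped <- sum(is.na(draws))
      draws <- draws[!is.na(draws)]
    }
  } else {
    if (is.null(coding)) coding <- group_coding(lev[1L], lev[2L])
    fit <- fit_single_group(data, coding = coding)
    ind <- simple_indirect_effects(fit)
    pe <- if (estimand == "difference") ind$difference else ind$effects[[estimand]]
    ir <- data$group == coding$reference
    if (resampling == "stratified") {
      bd <- .boot_sg_strat_draws(data$x[ir], data$m[ir], data$y[ir],
                                 data$x[!ir], data$m[!ir], data$y[!ir], B)
    } else {
      bd <- .boot_sg_pooled_draws(data$x, data$m, data$y,
                                  as.numeric(data$group == coding$focal), B)
    }
    draws <- switch(estimand, difference = bd$diff,
                    if (estimand == coding$reference) bd$ind_ref else bd$ind_foc)
    n_dropped <- bd$n_dropped
  }
  .check_dropped(n_dropped, B)
  .draw_set(draws, estimand, "bootstrap", pe, seed, approach,
            n_requested = B, n_dropped = n_dropped, resampling = resampling)
}

# parameter draws from the diagonal-covariance MVN of the four path
# estimates; one shared draw order so all estimands reuse the same draws
.mc_param_draws <- function(fit, R) {
  cf1 <- fit$coefficients[[1L]]; cf2 <- fit$coefficients[[2L]]
  se <- fit$se
  a1 <- rnorm(R, cf1[["a"]], se$se_a[1])
  b1 <- rnorm(R, cf1[["b"]], se$se_b[1])
  a2 <- rnorm(R, cf2[["a"]], se$se_a[2])
  b2 <- rnorm(R, cf2[["b"]], se$se_b[2])
  list(ind1 = a1 * b1, ind2 = a2 * b2, diff = a1 * b1 - a2 * b2)
}

#' Monte Carlo draws of indirect-effect estimands
#'
#' Draws `R` parameter vectors (a_G1, b_G1, a_G2, b_G2) from the
#' multivariate normal distribution centred at the unconstrained multi-group
#' estimates with diagonal covariance given by the squared standard errors:
#' groups are independent samples and the within-group covariance between
#' the a and b estimates is set to zero (they come from different equations
#' of the recursive model). Each draw yields replicate values of the simple
#' indirect effects a*b and of their Group 1 minus Group 2 difference.
#' Deterministic given `seed`.
#'
#' @param fit An unconstrained `mg_fit` with covariances computed.
#' @param estimand One of the group labels, or `"difference"`.
#' @param R Number of draws.
#' @param seed Integer seed.
#' @return A `draw_set` with provenance `"monte_carlo"`.
#' @export
monte_carlo_draws <- function(fit, estimand, R = 1000, seed = NULL) {
  if (!inherits(fit, "mg_fit")) stop("fit must be an mg_fit object")
  if (length(fit$constraints))
    stop("monte_carlo_draws requires the unconstrained multi-group fit")
  if (is.null(fit$se)) stop("fit was computed with compute_vcov = FALSE")
  ses <- c(fit$se$se_a, fit$se$se_b)
  if (any(!is.finite(ses)) || any(ses < 0))
    stop("standard errors of the path estimates are negative or undefined")
  lev <- fit$groups
  if (!estimand %in% c(lev, "difference"))
    stop("estimand must be one of: ", paste(c(lev, "difference"), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  d <- .mc_param_draws(fit, R)
  ind <- simple_indirect_effects(fit)
  pe <- if (estimand == "difference") ind$difference else ind$effects[[estimand]]
  draws <- switch(estimand, difference = d$diff,
                  if (estimand == lev[1L]) d$ind1 else d$ind2)
  .draw_set(draws, estimand, "monte_carlo", pe, seed, "multi",
            n_requested = R)
}
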