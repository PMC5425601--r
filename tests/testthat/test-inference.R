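test_that("z test of the interaction path matches the printed-coefficient
           arithmetic and the generic Wald machinery", {
  # z from rounded published inputs: -0.058/0.020 = -2.90, p about 0.004
  z <- -0.058 / 0.020
  expect_equal(round(z, 2), -2.90)
  expect_lt(abs(2 * pnorm(-abs(z)) - 0.004), 5e-4)

  d <- random_dat(50, 45, seed = 5)
  fit <- fit_single_group(d)
  zt <- z_test_a3(fit)
  # z^2 equals the 1-df Wald statistic for the linear constraint a3 = 0
  W_a3 <- coef(fit)[["a3"]]^2 / fit$vcov["a3", "a3"]
  expect_equal(zt$statistic^2, W_a3, tolerance = 1e-8)
  expect_equal(zt$p_value, 2 * pnorm(-abs(zt$statistic)), tolerance = 1e-12)
})

test_that("Wald product test agrees with a finite-difference delta-method
           oracle and is invariant to the coding", {
  d <- random_dat(45, 40, seed = 9)
  fit <- fit_single_group(d)
  wt <- wald_product_test(fit)
  # oracle: numerically differentiated gradient of theta = a3*b over the
  # model's joint coefficient covariance
  theta_fun <- function(p) p[4] * p[6]   # a3 and b positions in coef vector
  gr <- oracle_gradient(theta_fun, unname(coef(fit)))
  avar <- drop(t(gr) %*% fit$vcov %*% gr)
  W_oracle <- (coef(fit)[["a3"]] * coef(fit)[["b"]])^2 / avar
  expect_equal(wt$statistic, W_oracle, tolerance = 1e-8)
  # coding swap flips the sign of theta but not the statistic
  lev <- levels(d$group)
  wt2 <- wald_product_test(fit_single_group(d, group_coding(lev[2], lev[1])))
  expect_equal(wt$statistic, wt2$statistic, tolerance = 1e-10)
  expect_equal(wt$p_value, wt2$p_value, tolerance = 1e-10)
})

test_that("Wald difference test: zero for duplicated groups, oracle match,
           label-swap invariance", {
  base <- random_dat(30, 30, seed = 77)
  # identical observations relabelled as two groups: difference exactly zero
  i1 <- base$group == levels(base$group)[1]
  x <- base$x[i1]; m <- base$m[i1]; y <- base$y[i1]
  dd <- mediation_data(c(x, x), c(m, m), c(y, y),
                       rep(c("G1", "G2"), each = sum(i1)))
  wd0 <- wald_diff_test(fit_multi_group(dd))
  expect_equal(wd0$statistic, 0, tolerance = 1e-12)

  d <- random_dat(40, 50, seed = 78)
  fm <- fit_multi_group(d)
  wd <- wald_diff_test(fm)
  cf1 <- fm$coefficients[[1]]; cf2 <- fm$coefficients[[2]]
  th <- function(p) p[1] * p[2] - p[3] * p[4]
  est <- c(cf1[["a"]], cf1[["b"]], cf2[["a"]], cf2[["b"]])
  gr <- oracle_gradient(th, est)
  avar <- drop(t(gr) %*% asymptotic_cov_products(fm) %*% gr)
  expect_equal(wd$statistic, th(est)^2 / avar, tolerance = 1e-8)

  dswap <- mediation_data(d$x, d$m, d$y, d$group,
                          levels = rev(levels(d$group)))
  wd_s <- wald_diff_test(fit_multi_group(dswap))
  expect_equal(wd$statistic, wd_s$statistic, tolerance = 1e-9)
})

test_that("LR test: nesting checks, stacked-ML oracle, and the shared-b
           identity between the product and a-path constraints", {
  d <- random_dat(60, 55, seed = 21)
  f0 <- fit_multi_group(d)
  fa <- fit_multi_group(d, "a_equal")
  lt <- lr_test(f0, fa)
  expect_equal(lt$method, "LRaM")
  expect_equal(lt$df, 1)
  expect_gte(lt$statistic, 0)
  expect_equal(lt$p_value, pchisq(lt$statistic, 1, lower.tail = FALSE))
  # non-nested sets rejected; identical sets give a degenerate 0-df test
  fb <- fit_multi_group(d, "b_equal")
  expect_error(lr_test(fa, fb), "nested")
  same <- lr_test(f0, f0)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # deviance-difference oracle for a_equal via direct optimization
  i1 <- d$group == levels(d$group)[1]
  n1 <- sum(i1); n2 <- sum(!i1)
  f <- function(p) {
    r1 <- d$m[i1] - p[1] - p[3] * d$x[i1]
    r2 <- d$m[!i1] - p[2] - p[3] * d$x[!i1]
    n1 * (log(2 * pi * sum(r1^2) / n1) + 1) +
      n2 * (log(2 * pi * sum(r2^2) / n2) + 1)
  }
  o <- optim(c(0, 0, 0.3), f, method = "BFGS", control = list(reltol = 1e-14))
  m1 <- lm(d$m[i1] ~ d$x[i1]); m2 <- lm(d$m[!i1] ~ d$x[!i1])
  un_m <- n1 * (log(2 * pi * sum(residuals(m1)^2) / n1) + 1) +
    n2 * (log(2 * pi * sum(residuals(m2)^2) / n2) + 1)
  expect_equal(lt$statistic, o$value - un_m, tolerance = 1e-6)

  # with b_equal held in both fits, the product constraint reduces to the
  # a-path constraint: identical LR statistics
  fb0 <- fit_multi_group(d, "b_equal")
  fba <- fit_multi_group(d, c("b_equal", "a_equal"))
  fbp <- fit_multi_group(d, c("b_equal", "ab_product_equal"))
  lr_a <- lr_test(fb0, fba)
  lr_p <- lr_test(fb0, fbp)
  expect_equal(lr_p$statistic, lr_a$statistic, tolerance = 1e-4)
  expect_equal(lr_p$method, "LRdiffM")
  expect_equal(lr_a$method, "LRaM")
})

test_that("percentile interval follows the order-statistic rule", {
  mk <- function(v) medgroup:::.draw_set(v, "difference", "bootstrap",
                                         mean(v), 1L, "multi", length(v))
  # enumeration case: draws 1..1000 at level .95 -> 25th and 976th values
  ci <- percentile_ci(mk(1:1000), level = 0.95)
  expect_equal(ci$lower, 25)
  expect_equal(ci$upper, 976)
  # constant draws give a degenerate interval
  cc <- percentile_ci(mk(rep(3.5, 200)))
  expect_equal(cc$lower, 3.5)
  expect_equal(cc$upper, 3.5)
  # symmetric draws give symmetric endpoints
  v <- c(-(1:500), 1:500) / 83
  cs <- percentile_ci(mk(v))
  expect_equal(cs$lower, -cs$upper, tolerance = 1e-12)
  # widening the level never narrows the interval
  lv <- c(0.90, 0.95, 0.99)
  cis <- lapply(lv, function(l) percentile_ci(mk(rnorm(500)), level = l))
  for (i in 2:3) {
    expect_lte(cis[[i]]$lower, cis[[i - 1]]$lower)
    expect_gte(cis[[i]]$upper, cis[[i - 1]]$upper)
  }
  expect_error(percentile_ci(mk(1:50)), "at least 100")
})

test_that("bias-corrected interval: closed-form adjusted levels, ties, and
           reduction to the percentile interval at zero median bias", {
  mk <- function(v, pe) medgroup:::.draw_set(v, "difference", "bootstrap",
                                             pe, 1L, "multi", length(v))
  # draws 1..1000, point estimate 600.5: z0 = qnorm(0.6); endpoints by the
  # same order-statistic rule at the shifted levels
  ci <- bc_ci(mk(1:1000, 600.5), level = 0.95)
  z0 <- qnorm(0.6)
  p_lo <- pnorm(2 * z0 + qnorm(0.025))
  p_hi <- pnorm(2 * z0 + qnorm(0.975))
  expect_equal(ci$z0, z0, tolerance = 1e-12)
  expect_equal(ci$lower, sort(1:1000)[max(1, floor(1001 * p_lo))])
  expect_equal(ci$upper, sort(1:1000)[min(1000, ceiling(1001 * p_hi))])
  # exactly half the draws below the point estimate: BC == percentile
  v <- rnorm(400)
  pe <- median(v)  # even length: exactly 200 draws below
  bc <- bc_ci(mk(v, pe)); pc <- percentile_ci(mk(v, pe))
  expect_equal(bc$lower, pc$lower)
  expect_equal(bc$upper, pc$upper)
  # constant draws
  k <- bc_ci(mk(rep(2, 150), 2))
  expect_equal(c(k$lower, k$upper), c(2, 2))
  # all draws below the point estimate: proportion clamped and flagged
  cl <- bc_ci(mk(1:200, 500))
  expect_true(cl$proportion_clamped)
})

test_that("BC equals percentile whenever the draw median equals the point
           estimate, within one order statistic", {
  set.seed(81)
  for (i in 1:10) {
    v <- rnorm(501)
    mk <- medgroup:::.draw_set(v, "G1", "bootstrap", median(v), 1L, "multi",
                               length(v))
    bc <- bc_ci(mk); pc <- percentile_ci(mk)
    s <- sort(v)
    ilo_b <- which(s == bc$lower)[1]; ilo_p <- which(s == pc$lower)[1]
    ihi_b <- which(s == bc$upper)[1]; ihi_p <- which(s == pc$upper)[1]
    expect_lte(abs(ilo_b - ilo_p), 1)
    expect_lte(abs(ihi_b - ihi_p), 1)
  }
})

test_that("bootstrap draws: determinism, noiseless degeneracy, and agreement
           with an independently coded resampler", {
  d <- random_dat(30, 30, seed = 42)
  b1 <- bootstrap_draws(d, "difference", "multi", B = 300, seed = 99)
  b2 <- bootstrap_draws(d, "difference", "multi", B = 300, seed = 99)
  expect_identical(b1$draws, b2$draws)

  # noiseless single-group data: every replicate equals the point estimate
  x <- c(seq(-2, 2, length.out = 25), seq(-1, 3, length.out = 25))
  g <- rep(c("G1", "G2"), each = 25)
  m <- 0.5 * x + (g == "G2")
  y <- 0.4 * m
  dn <- mediation_data(x, m, y, g)
  bn <- bootstrap_draws(dn, "G1", "single", B = 200, seed = 4)
  expect_equal(unique(round(bn$draws, 12)), bn$point_estimate,
               tolerance = 1e-10)

  # independent resampler oracle (plain loop with lm refits)
  d2 <- generate_dataset(population_catalog()[["I-0"]], 60, 60, seed = 7)
  bd <- bootstrap_draws(d2, "difference", "multi", B = 800, seed = 123)
  set.seed(321)
  lev <- levels(d2$group)
  i1 <- d2$group == lev[1]
  oracle <- replicate(400, {
    j1 <- sample(which(i1), sum(i1), replace = TRUE)
    j2 <- sample(which(!i1), sum(!i1), replace = TRUE)
    est <- function(j) {
      a <- coef(lm(d2$m[j] ~ d2$x[j]))[2]
      b <- coef(lm(d2$y[j] ~ d2$m[j] + d2$x[j]))[2]
      a * b
    }
    est(j1) - est(j2)
  })
  se_comb <- sqrt(var(bd$draws) / length(bd$draws) + var(oracle) / length(oracle))
  expect_lt(abs(mean(bd$draws) - mean(oracle)), 3 * se_comb)
})

test_that("bootstrap preconditions and estimand naming", {
  d <- random_dat(30, 30, seed = 2)
  expect_error(bootstrap_draws(d, "difference", "multi", B = 50, seed = 1),
               "at least 100")
  expect_error(bootstrap_draws(d, "nope", "multi", B = 200, seed = 1),
               "estimand")
  expect_error(bootstrap_draws(d, "difference", "multi", B = 200, seed = 1,
                               resampling = "pooled"), "pooled")
  # group-label estimand selects that group's indirect effect draws
  lev <- levels(d$group)
  bg <- bootstrap_draws(d, lev[1], "multi", B = 200, seed = 11)
  expect_equal(bg$point_estimate,
               simple_indirect_effects(fit_multi_group(d))$effects[[lev[1]]])
})

test_that("Monte Carlo draws: determinism, degenerate-se limit, and the
           product-normal law", {
  d <- random_dat(80, 70, seed = 15)
  fm <- fit_multi_group(d)
  m1 <- monte_carlo_draws(fm, "difference", R = 500, seed = 77)
  m2 <- monte_carlo_draws(fm, "difference", R = 500, seed = 77)
  expect_identical(m1$draws, m2$draws)

  # zero standard errors: every draw equals the point estimate
  fz <- fm
  fz$se$se_a <- c(0, 0); fz$se$se_b <- c(0, 0)
  mz <- monte_carlo_draws(fz, "difference", R = 200, seed = 1)
  expect_true(all(mz$draws == mz$point_estimate))
  ciz <- percentile_ci(mz)
  expect_equal(ciz$lower, ciz$upper)

  # a_hat = b_hat = 0 with unit ses: draws follow the product-normal law;
  # compare the 0.975 quantile with numerical integration of its CDF
  f0 <- fm
  f0$coefficients[[1]][["a"]] <- 0; f0$coefficients[[1]][["b"]] <- 0
  f0$se$se_a <- c(1, 1); f0$se$se_b <- c(1, 1)
  lev <- f0$groups
  md <- monte_carlo_draws(f0, lev[1], R = 200000, seed = 5)
  q_emp <- unname(quantile(md$draws, 0.975))
  q_true <- uniroot(function(z) product_normal_cdf(z) - 0.975, c(0.5, 10))$root
  # sampling error of an empirical quantile: sqrt(p(1-p)/R) / f(q), with the
  # product-normal density f(z) = K_0(|z|)/pi
  se_q <- sqrt(0.975 * 0.025 / length(md$draws)) / (besselK(q_true, 0) / pi)
  expect_lt(abs(q_emp - q_true), 3.5 * se_q)

  # negative / undefined ses are rejected
  fneg <- fm; fneg$se$se_a <- c(-1, 1)
  expect_error(monte_carlo_draws(fneg, "difference", R = 200, seed = 1),
               "negative|undefined")
})

test_that("ci_excludes_zero uses the closed-interval convention", {
  mk <- function(lo, hi) structure(list(method = "PCdiffM", target = "difference",
                                        lower = lo, upper = hi, level = 0.95,
                                        n_draws = 1000), class = "med_ci")
  expect_true(ci_excludes_zero(mk(-0.057, -0.001)))
  expect_false(ci_excludes_zero(mk(-0.01, 0.02)))
  expect_false(ci_excludes_zero(mk(0, 0.3)))
  expect_true(ci_excludes_zero(mk(0.001, 0.3)))
  expect_error(ci_excludes_zero(mk(1, -1)), "malformed")
})

test_that("W reduces to z^2 when b is forced to one by a synthetic Y = M
           outcome", {
  d <- random_dat(40, 40, seed = 33)
  d2 <- mediation_data(d$x, d$m, d$m, d$group)  # y identical to m: b = 1 exactly
  fit <- suppressWarnings(fit_single_group(d2))
  zt <- z_test_a3(fit)
  wt <- wald_product_test(fit)
  # var(b) = 0 here, so avar(a3*b) = b^2 var(a3) = var(a3)
  expect_equal(wt$statistic, zt$statistic^2, tolerance = 1e-8)
})
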