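test_that("noiseless data are recovered exactly", {
  x <- c(seq(-2, 2, length.out = 12), seq(-1.5, 2.5, length.out = 10))
  g <- rep(c("G1", "G2"), c(12, 10))
  m <- 0.5 * x + 1 * (g == "G2")        # group shift keeps the Y design full rank
  y <- 0.4 * m
  d <- mediation_data(x, m, y, g)
  fit <- fit_single_group(d)
  cf <- coef(fit)
  expect_equal(cf[["a1"]], 0.5, tolerance = 1e-10)
  expect_equal(cf[["a3"]], 0, tolerance = 1e-10)
  expect_equal(cf[["a2"]], 1, tolerance = 1e-10)
  expect_equal(cf[["b"]], 0.4, tolerance = 1e-10)
  expect_equal(fit$psi_m, 0, tolerance = 1e-12)
  expect_equal(fit$psi_y, 0, tolerance = 1e-12)
})

test_that("single-group estimates match the least-squares oracle", {
  d <- random_dat(30, 30, seed = 7)
  fit <- fit_single_group(d)
  g <- as.numeric(d$group == levels(d$group)[2])
  om <- lm(d$m ~ d$x + g + I(d$x * g))
  oy <- lm(d$y ~ d$m + d$x)
  expect_equal(unname(coef(fit)[c("int_m", "a1", "a2", "a3")]),
               unname(coef(om)), tolerance = 1e-8)
  expect_equal(unname(coef(fit)[c("int_y", "b", "c_prime")]),
               unname(coef(oy)), tolerance = 1e-8)
  # ML residual variance = OLS RSS / n, and vcov is the n/(n-p)-rescaled
  # OLS covariance
  n <- d$n_total
  expect_equal(fit$psi_m, sum(residuals(om)^2) / n, tolerance = 1e-10)
  expect_equal(fit$vcov["a3", "a3"],
               vcov(om)[4, 4] * (n - 4) / n, tolerance = 1e-10)
})

test_that("large samples recover the population paths", {
  d <- generate_dataset(population_catalog()[["I-0"]], 1e5, 1e5, seed = 31)
  fit <- fit_single_group(d)
  expect_lt(abs(coef(fit)[["a1"]] - 0.424), 0.02)
  expect_lt(abs(coef(fit)[["b"]] - 0.390), 0.02)
})

test_that("rank-deficient designs raise an error naming the collinear column", {
  x <- rnorm(40)
  g <- rep(c("G1", "G2"), each = 20)
  d <- mediation_data(x, 2 * x, rnorm(40), g)  # m collinear with x in Y equation
  expect_error(fit_single_group(d), "collinear|rank")
  d1 <- mediation_data(rep(1, 40), rnorm(40), rnorm(40), g)  # constant x
  expect_error(fit_single_group(d1), "M equation")
})

test_that("single-group fit requires both group levels and valid coding", {
  x <- rnorm(20)
  expect_error(mediation_data(x, x + rnorm(20), rnorm(20), rep("G1", 20)),
               "two distinct")
  d <- random_dat(20, 20, seed = 2)
  expect_error(fit_single_group(d, coding = group_coding("A", "Z")),
               "do not match")
})

test_that("unconstrained multi-group fit equals per-group regressions", {
  d <- random_dat(35, 45, seed = 11)
  fit <- fit_multi_group(d)
  for (g in 1:2) {
    i <- d$group == levels(d$group)[g]
    om <- lm(d$m[i] ~ d$x[i])
    oy <- lm(d$y[i] ~ d$m[i] + d$x[i])
    expect_equal(unname(fit$coefficients[[g]][c("int_m", "a")]),
                 unname(coef(om)), tolerance = 1e-8)
    expect_equal(unname(fit$coefficients[[g]][c("int_y", "b", "c_prime")]),
                 unname(coef(oy)), tolerance = 1e-8)
  }
  # -2 loglik agrees with the direct formula at the estimates
  pars <- lapply(fit$coefficients, as.list)
  expect_equal(fit$neg2loglik, oracle_neg2ll(d, fit$coefficients),
               tolerance = 1e-8)
})

test_that("adding constraints never decreases -2 loglik, and shared-a fits
           beat any other feasible point", {
  for (s in 1:5) {
    d <- random_dat(30, 40, seed = 100 + s)
    f0 <- fit_multi_group(d)
    fa <- fit_multi_group(d, "a_equal")
    fb <- fit_multi_group(d, c("a_equal", "b_equal"))
    fc <- fit_multi_group(d, c("a_equal", "b_equal", "cprime_equal"))
    fab <- fit_multi_group(d, "ab_product_equal")
    expect_gte(fa$neg2loglik, f0$neg2loglik - 1e-6)
    expect_gte(fb$neg2loglik, fa$neg2loglik - 1e-6)
    expect_gte(fc$neg2loglik, fb$neg2loglik - 1e-6)
    expect_gte(fab$neg2loglik, f0$neg2loglik - 1e-6)
    # a_equal AND b_equal is a subset of the product-constraint manifold
    expect_lte(fab$neg2loglik, fb$neg2loglik + 1e-6)
  }
})

test_that("constrained shared-a fit matches a direct optimizer oracle", {
  d <- random_dat(25, 30, seed = 55)
  fa <- fit_multi_group(d, "a_equal")
  lev <- levels(d$group)
  i1 <- d$group == lev[1]
  # independent route: optimize the exact -2ll over (int1, int2, a) with
  # variances profiled out per group
  f <- function(p) {
    r1 <- d$m[i1] - p[1] - p[3] * d$x[i1]
    r2 <- d$m[!i1] - p[2] - p[3] * d$x[!i1]
    n1 <- sum(i1); n2 <- sum(!i1)
    n1 * (log(2 * pi * sum(r1^2) / n1) + 1) + n2 * (log(2 * pi * sum(r2^2) / n2) + 1)
  }
  o <- optim(c(0, 0, 0.3), f, method = "BFGS", control = list(reltol = 1e-14))
  # compare the M-equation deviance part
  ym <- fa$neg2loglik
  fy1 <- lm(d$y[i1] ~ d$m[i1] + d$x[i1]); fy2 <- lm(d$y[!i1] ~ d$m[!i1] + d$x[!i1])
  n1 <- sum(i1); n2 <- sum(!i1)
  y_part <- n1 * (log(2 * pi * sum(residuals(fy1)^2) / n1) + 1) +
    n2 * (log(2 * pi * sum(residuals(fy2)^2) / n2) + 1)
  expect_equal(ym - y_part, o$value, tolerance = 1e-6)
  expect_equal(fa$coefficients[[1]][["a"]], o$par[3], tolerance = 1e-5)
})

test_that("product-constrained fit matches a profile-likelihood grid oracle", {
  d <- random_dat(30, 25, seed = 99)
  fab <- fit_multi_group(d, "ab_product_equal")
  lev <- levels(d$group)
  # oracle: coarse grid over the common product tau; per group, inner
  # 1-parameter Brent solve over b with lm for the nuisance coefficients
  gfun <- function(tau, x, m, y) {
    f <- function(b) {
      n <- length(x)
      rm <- residuals(lm(I(m - (tau / b) * x) ~ 1))
      ry <- residuals(lm(I(y - b * m) ~ x))
      n * (log(2 * pi * sum(rm^2) / n) + 1) + n * (log(2 * pi * sum(ry^2) / n) + 1)
    }
    optim(0.4, f, method = "Brent", lower = 0.01, upper = 2)$value
  }
  i1 <- d$group == lev[1]
  taus <- seq(-0.2, 0.45, length.out = 600)
  vals <- vapply(taus, function(t)
    gfun(t, d$x[i1], d$m[i1], d$y[i1]) + gfun(t, d$x[!i1], d$m[!i1], d$y[!i1]), 0)
  expect_equal(fab$neg2loglik, min(vals), tolerance = 1e-4)
  # the constraint holds exactly at the solution
  p1 <- fab$coefficients[[1]][["a"]] * fab$coefficients[[1]][["b"]]
  p2 <- fab$coefficients[[2]][["a"]] * fab$coefficients[[2]][["b"]]
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("constraint-set preconditions are enforced", {
  d <- random_dat(20, 20, seed = 3)
  expect_error(fit_multi_group(d, c("ab_product_equal", "a_equal")),
               "may not be combined")
  expect_error(fit_multi_group(d, "nonsense"), "unknown constraint")
  small <- mediation_data(rnorm(8), rnorm(8), rnorm(8),
                          rep(c("G1", "G2"), c(5, 3)))
  expect_error(fit_multi_group(small), "at least 4")
})

test_that("vcov of the fit matches the inverted numerical Hessian of the
           log-likelihood", {
  d <- random_dat(30, 28, seed = 13)
  fit <- fit_single_group(d)
  g <- as.numeric(d$group == levels(d$group)[2])
  # -2 loglik as a function of all 7 coefficients, ML variances profiled;
  # at the MLE the profile Hessian equals the coefficient information
  f <- function(p) {
    n <- d$n_total
    rm <- d$m - p[1] - p[2] * d$x - p[3] * g - p[4] * d$x * g
    ry <- d$y - p[5] - p[6] * d$m - p[7] * d$x
    n * (log(2 * pi * sum(rm^2) / n) + 1) + n * (log(2 * pi * sum(ry^2) / n) + 1)
  }
  H <- oracle_hessian(f, unname(coef(fit)))
  V <- 2 * solve(H)
  expect_equal(unname(fit$vcov), V, tolerance = 1e-6 * max(abs(V)) / min(abs(diag(V))))
  # relative agreement on the diagonal
  expect_equal(diag(fit$vcov), diag(V), tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("asymptotic_cov_products: zero cross-group block, OLS-variance link", {
  d <- random_dat(40, 50, seed = 17)
  fm <- fit_multi_group(d)
  V <- asymptotic_cov_products(fm)
  expect_identical(unname(V[1:2, 3:4]), matrix(0, 2, 2))
  # a3 variance equals the OLS squared standard error up to the ML rescaling
  fs <- fit_single_group(d)
  g <- as.numeric(d$group == levels(d$group)[2])
  om <- summary(lm(d$m ~ d$x + g + I(d$x * g)))
  n <- d$n_total
  expect_equal(fs$vcov["a3", "a3"],
               om$coefficients[4, 2]^2 * (n - 4) / n, tolerance = 1e-8)
  # constrained fits are rejected
  expect_error(asymptotic_cov_products(fit_multi_group(d, "a_equal")),
               "unconstrained")
})

test_that("coding swap leaves group effects invariant and flips the difference", {
  d <- random_dat(35, 30, seed = 23)
  lev <- levels(d$group)
  f1 <- fit_single_group(d, group_coding(lev[1], lev[2]))
  f2 <- fit_single_group(d, group_coding(lev[2], lev[1]))
  i1 <- simple_indirect_effects(f1)
  i2 <- simple_indirect_effects(f2)
  expect_equal(i1$effects[lev], i2$effects[lev], tolerance = 1e-10)
  expect_equal(i1$difference, -i2$difference, tolerance = 1e-10)
})

test_that("multi-group fit with b and c' equal tracks the single-group fit", {
  # pooled-coefficient estimates agree with the single-group model when the
  # residual variances are homogeneous; agreement is approximate because the
  # multi-group model keeps per-group variances and Y intercepts
  d <- generate_dataset(population_catalog()[["I-0"]], 400, 400, seed = 77)
  fs <- fit_single_group(d)
  fm <- fit_multi_group(d, c("b_equal", "cprime_equal"))
  # per-group a estimates are identical by construction in both models
  expect_equal(fm$coefficients[[1]][["a"]], coef(fs)[["a1"]], tolerance = 1e-8)
  expect_equal(fm$coefficients[[2]][["a"]],
               coef(fs)[["a1"]] + coef(fs)[["a3"]], tolerance = 1e-8)
  expect_equal(fm$coefficients[[1]][["b"]], coef(fs)[["b"]], tolerance = 0.02)
  expect_equal(fm$coefficients[[1]][["c_prime"]], coef(fs)[["c_prime"]],
               tolerance = 0.02)
})

test_that("path coefficients are unbiased across repeated sampling", {
  pop <- population_catalog()[["I-M2"]]
  cond <- sim_condition(pop, 150, 150, n_reps = 500, seed = 424,
                        methods = c("za3S", "WdiffM"))
  sm <- run_condition(cond)
  paths <- sm$bias[sm$bias$parameter %in%
                     c("sg_a1", "sg_a3", "sg_b", "mg_a_G1", "mg_b_G1",
                       "mg_a_G2", "mg_b_G2"), ]
  expect_true(all(abs(paths$bias) <= 3 * paths$mc_se))
})
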