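# Independent oracles used across the test files. These deliberately take
# different computational routes than the package (lm/QR, finite
# differences, direct enumeration) so that agreement is informative.

# exact Gaussian -2 loglik of the full two-group path model at given
# parameters (ML variances profiled out per equation and group)
oracle_neg2ll <- function(dat, pars) {
  # pars: list per group with int_m, a, int_y, b, c_prime
  lev <- levels(dat$group)
  out <- 0
  for (g in 1:2) {
    i <- dat$group == lev[g]
    x <- dat$x[i]; m <- dat$m[i]; y <- dat$y[i]
    n <- length(x)
    p <- pars[[g]]
    rm <- m - p[["int_m"]] - p[["a"]] * x
    ry <- y - p[["int_y"]] - p[["b"]] * m - p[["c_prime"]] * x
    out <- out + n * (log(2 * pi * sum(rm^2) / n) + 1) +
      n * (log(2 * pi * sum(ry^2) / n) + 1)
  }
  out
}

# numerical Hessian of a scalar function (central differences)
oracle_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  hh <- h * pmax(1, abs(x))
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- numeric(p); ei[i] <- hh[i]
      ej <- numeric(p); ej[j] <- hh[j]
      if (i == j) H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / hh[i]^2
      else H[i, j] <- H[j, i] <- (f(x + ei + ej) - f(x + ei - ej) -
                                    f(x - ei + ej) + f(x - ei - ej)) /
          (4 * hh[i] * hh[j])
    }
  }
  H
}

# central-difference gradient
oracle_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h * max(1, abs(x[i]))
    (f(x + e) - f(x - e)) / (2 * e[i])
  }, 0)
}

# small helper: build a mediation_data with labelled groups
make_dat <- function(x, m, y, g, levels = NULL)
  mediation_data(x, m, y, g, levels = levels)

# a quick random two-group dataset not drawn from the catalog populations
random_dat <- function(n1 = 40, n2 = 35, seed = 1) {
  set.seed(seed)
  x <- c(rnorm(n1, 0.3, 1.2), rnorm(n2, -0.1, 0.8))
  g <- rep(c("A", "B"), c(n1, n2))
  m <- ifelse(g == "A", 0.5, 0.2) * x + rnorm(n1 + n2, 0, 1)
  y <- 0.4 * m + 0.1 * x + rnorm(n1 + n2, 0, 1.1)
  mediation_data(x, m, y, g)
}

# product-normal distribution function P(Z1 * Z2 <= z) for independent
# standard normals, by numerical integration over the first factor
product_normal_cdf <- function(z) {
  f <- function(x) {
    px <- dnorm(x)
    ifelse(x > 0, px * pnorm(z / x), px * pnorm(z / x, lower.tail = FALSE))
  }
  integrate(f, -Inf, 0)$value + integrate(f, 0, Inf)$value
}
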