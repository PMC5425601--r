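# Iterated weighted least squares for one equation with coefficients shared
# across groups and free per-group residual variances. This is coordinate
# ascent on the Gaussian likelihood (WLS step for the coefficients, closed
# form for the variances) and converges to the constrained ML solution.
.irls_shared <- function(X, y, gidx, n1, n2, tol = 1e-10, maxit = 500L) {
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient design in constrained fit; offending column(s): ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]], collapse = ", "))
  beta <- qr.coef(qx, y)
  res <- drop(y - X %*% beta)
  psi <- c(sum(res[gidx == 1L]^2) / n1, sum(res[gidx == 2L]^2) / n2)
  if (any(psi <= 0)) stop("degenerate zero residual variance in constrained fit")
  ll <- n1 * (log(2 * pi * psi[1]) + 1) + n2 * (log(2 * pi * psi[2]) + 1)
  done <- FALSE
  for (it in seq_len(maxit)) {
    sw <- sqrt(ifelse(gidx == 1L, 1 / psi[1], 1 / psi[2]))
    Xw <- X * sw
    R <- chol(crossprod(Xw))
    beta <- drop(backsolve(R, forwardsolve(t(R), crossprod(Xw, y * sw))))
    res <- drop(y - X %*% beta)
    psi_new <- c(sum(res[gidx == 1L]^2) / n1, sum(res[gidx == 2L]^2) / n2)
    ll_new <- n1 * (log(2 * pi * psi_new[1]) + 1) + n2 * (log(2 * pi * psi_new[2]) + 1)
    done <- abs(ll - ll_new) < tol * (abs(ll_new) + 1)
    psi <- psi_new; ll <- ll_new
    if (done) break
  }
  if (!done)
    stop("shared-coefficient ML did not converge in ", maxit,
         " iterations; last -2logLik = ", format(ll, digits = 12))
  sw <- sqrt(ifelse(gidx == 1L, 1 / psi[1], 1 / psi[2]))
  vc <- chol2inv(chol(crossprod(X * sw)))
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(beta = setNames(beta, colnames(X)), psi = psi, neg2loglik = ll,
       vcov = vc, iterations = it)
}

.mg_valid_constraints <- c("a_equal", "b_equal", "cprime_equal", "ab_product_equal")

# b_equal turns the product constraint a_G1*b_G1 = a_G2*b_G2 into a_G1 = a_G2
.mg_effective_constraints <- function(constraints) {
  if ("ab_product_equal" %in% constraints && "b_equal" %in% constraints)
    constraints <- union(setdiff(constraints, "ab_product_equal"), "a_equal")
  sort(unique(constraints))
}

#' Fit the multi-group mediation model, optionally with equality constraints
#'
#' Fits one path model per group (M regressed on X; Y regressed on M and X)
#' by Gaussian maximum likelihood with free per-group residual variances.
#' Without constraints the fit factorizes into independent per-group
#' least-squares fits. Cross-group equality constraints on single
#' coefficients (`a_equal`, `b_equal`, `cprime_equal`) are fitted by
#' shared-coefficient stacked estimation with per-group variance weights
#' (iterated WLS, the exact constrained ML). The nonlinear constraint
#' `ab_product_equal` (equal indirect effects a*b across groups) is fitted
#' by profiling the likelihood over the common product value with a
#' quasi-Newton polish; combined with `b_equal` it reduces algebraically to
#' `a_equal`.
#'
#' @param data A [mediation_data] object; both groups need at least 4
#'   observations.
#' @param constraints Character vector, subset of `a_equal`, `b_equal`,
#'   `cprime_equal`, `ab_product_equal`. `ab_product_equal` may not be
#'   combined with `a_equal` (it would doubly constrain the a paths).
#' @param compute_vcov Compute asymptotic covariance matrices (set `FALSE`
#'   to save time in large simulations; only `neg2loglik` and coefficients
#'   are then available).
#' @param solve_for Which parameter the product-constraint reparameterization
#'   solves for: `"a_G2" = a_G1*b_G1/b_G2` (default) or the symmetric
#'   `"b_G2" = a_G1*b_G1/a_G2`, used when `b_G2` is near zero.
#' @return An object of class `mg_fit` with per-group coefficients
#'   (int_m, a, int_y, b, c_prime), per-group ML residual variances `psi`,
#'   per-group asymptotic covariances `vcov` (unconstrained and linear
#'   constraints), per-group standard errors `se` for the a and b paths,
#'   `neg2loglik` (summed over groups), the imposed `constraints`, and the
#'   free-parameter count `n_free`.
#' @examples
#' d <- generate_dataset(population_catalog()[["I-0"]], 80, 80, seed = 2)
#' f0 <- fit_multi_group(d)
#' f1 <- fit_multi_group(d, constraints = "a_equal")
#' f1$neg2loglik - f0$neg2loglik
#' @export
fit_multi_group <- function(data, constraints = character(),
                            compute_vcov = TRUE,
                            solve_for = c("a_G2", "b_G2"),
                            control = list()) {
  if (!inherits(data, "mediation_data")) stop("data must be a mediation_data object")
  solve_for <- match.arg(solve_for)
  constraints <- unique(as.character(constraints))
  unknown <- setdiff(constraints, .mg_valid_constraints)
  if (length(unknown))
    stop("unknown constraint(s): ", paste(unknown, collapse = ", "))
  if (all(c("ab_product_equal", "a_equal") %in% constraints))
    stop("ab_product_equal may not be combined with a_equal")
  lev <- levels(data$group)
  if (any(data$n_per_group < 4L))
    stop("each group needs at least 4 observations for the multi-group fit")
  eff <- .mg_effective_constraints(constraints)
  i1 <- data$group == lev[1L]
  x1 <- data$x[i1]; m1 <- data$m[i1]; y1 <- data$y[i1]
  x2 <- data$x[!i1]; m2 <- data$m[!i1]; y2 <- data$y[!i1]
  n1 <- length(x1); n2 <- length(x2)

  if ("ab_product_equal" %in% eff) {
    fit <- .fit_mg_abprod(x1, m1, y1, x2, m2, y2,
                          c_shared = "cprime_equal" %in% eff,
                          solve_for = solve_for,
                          compute_vcov = compute_vcov, control = control)
  } else {
    fit <- .fit_mg_linear(x1, m1, y1, x2, m2, y2, eff,
                          compute_vcov = compute_vcov)
  }

  names(fit$coefficients) <- lev
  names(fit$psi) <- lev
  if (!is.null(fit$vcov)) names(fit$vcov) <- lev
  if (!is.null(fit$se)) fit$se$group <- lev

  structure(c(fit,
              list(groups = lev,
                   constraints = sort(constraints),
                   constraints_effective = eff,
                   n_free = 14L - length(eff),
                   n = data$n_total,
                   n_per_group = data$n_per_group)),
            class = "mg_fit")
}

# Unconstrained and linear-equality-constrained fits. Returns per-group
# coefficient vectors, per-group (marginal) vcov views, and standard errors.
.fit_mg_linear <- function(x1, m1, y1, x2, m2, y2, eff, compute_vcov = TRUE) {
  n1 <- length(x1); n2 <- length(x2)
  gidx <- rep(1:2, c(n1, n2))
  d1 <- as.numeric(gidx == 1L); d2 <- 1 - d1
  conv <- list()

  # --- M equation ---
  if ("a_equal" %in% eff) {
    Xm <- cbind(int_m_1 = d1, int_m_2 = d2, a = c(x1, x2))
    fm <- .irls_shared(Xm, c(m1, m2), gidx, n1, n2)
    conv$m_iterations <- fm$iterations
    m_beta <- list(c(int_m = fm$beta[["int_m_1"]], a = fm$beta[["a"]]),
                   c(int_m = fm$beta[["int_m_2"]], a = fm$beta[["a"]]))
    m_psi <- fm$psi
    m_n2ll <- fm$neg2loglik
    m_map <- list(c("int_m_1", "a"), c("int_m_2", "a"))
    m_vcov <- fm$vcov
  } else {
    f1 <- .ols_ml(cbind(int_m = 1, a = x1), m1, eq = "M equation (group 1)")
    f2 <- .ols_ml(cbind(int_m = 1, a = x2), m2, eq = "M equation (group 2)")
    m_beta <- list(f1$beta, f2$beta)
    m_psi <- c(f1$psi, f2$psi)
    m_n2ll <- f1$neg2loglik + f2$neg2loglik
    m_map <- NULL
    m_vcov <- list(f1$vcov, f2$vcov)
  }

  # --- Y equation ---
  b_eq <- "b_equal" %in% eff; c_eq <- "cprime_equal" %in% eff
  if (b_eq || c_eq) {
    cols <- list(int_y_1 = d1, int_y_2 = d2)
    mm <- c(m1, m2); xx <- c(x1, x2)
    if (b_eq) cols$b <- mm else { cols$b_1 <- mm * d1; cols$b_2 <- mm * d2 }
    if (c_eq) cols$c_prime <- xx else { cols$c_prime_1 <- xx * d1; cols$c_prime_2 <- xx * d2 }
    Xy <- do.call(cbind, cols)
    fy <- .irls_shared(Xy, c(y1, y2), gidx, n1, n2)
    conv$y_iterations <- fy$iterations
    bname <- function(g) if (b_eq) "b" else paste0("b_", g)
    cname <- function(g) if (c_eq) "c_prime" else paste0("c_prime_", g)
    y_beta <- lapply(1:2, function(g)
      c(int_y = fy$beta[[paste0("int_y_", g)]],
        b = fy$beta[[bname(g)]], c_prime = fy$beta[[cname(g)]]))
    y_psi <- fy$psi
    y_n2ll <- fy$neg2loglik
    y_map <- lapply(1:2, function(g) c(paste0("int_y_", g), bname(g), cname(g)))
    y_vcov <- fy$vcov
  } else {
    f1 <- .ols_ml(cbind(int_y = 1, b = m1, c_prime = x1), y1, eq = "Y equation (group 1)")
    f2 <- .ols_ml(cbind(int_y = 1, b = m2, c_prime = x2), y2, eq = "Y equation (group 2)")
    y_beta <- list(f1$beta, f2$beta)
    y_psi <- c(f1$psi, f2$psi)
    y_n2ll <- f1$neg2loglik + f2$neg2loglik
    y_map <- NULL
    y_vcov <- list(f1$vcov, f2$vcov)
  }

  coefs <- lapply(1:2, function(g)
    c(int_m = unname(m_beta[[g]][["int_m"]]), a = unname(m_beta[[g]][["a"]]),
      int_y = unname(y_beta[[g]][["int_y"]]), b = unname(y_beta[[g]][["b"]]),
      c_prime = unname(y_beta[[g]][["c_prime"]])))
  psi <- lapply(1:2, function(g) c(m = unname(m_psi[g]), y = unname(y_psi[g])))

  vcov <- NULL; se <- NULL
  if (compute_vcov) {
    nm <- c("int_m", "a", "int_y", "b", "c_prime")
    vcov <- lapply(1:2, function(g) {
      vm <- if (is.null(m_map)) m_vcov[[g]] else m_vcov[m_map[[g]], m_map[[g]]]
      vy <- if (is.null(y_map)) y_vcov[[g]] else y_vcov[y_map[[g]], y_map[[g]]]
      v <- matrix(0, 5, 5, dimnames = list(nm, nm))
      v[1:2, 1:2] <- vm
      v[3:5, 3:5] <- vy
      v
    })
    se <- data.frame(group = c("1", "2"),
                     se_a = sqrt(vapply(vcov, function(v) v["a", "a"], 0)),
                     se_b = sqrt(vapply(vcov, function(v) v["b", "b"], 0)),
                     stringsAsFactors = FALSE)
  }
  list(coefficients = coefs, psi = psi, vcov = vcov, se = se,
       neg2loglik = m_n2ll + y_n2ll, convergence = conv)
}
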