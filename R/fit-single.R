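# Gaussian ML for one linear equation. Coefficient estimates coincide with
# OLS (recursive path model); residual variance uses the ML 1/n denominator
# so that -2*loglik differences are exact deviances. vcov is the inverse
# ML information for the coefficients, psi * (X'X)^{-1}.
.ols_ml <- function(X, y, eq = "equation") {
  n <- nrow(X); p <- ncol(X)
  cols <- colnames(X)
  # collinearity guard on the standardized design (condition number 1e10)
  Xs <- X
  for (j in seq_len(p)) {
    s <- sd(X[, j])
    if (is.finite(s) && s > 0) Xs[, j] <- X[, j] / s
  }
  d <- svd(Xs, nu = 0, nv = 0)$d
  if (d[p] <= 0 || d[1] / d[p] > 1e10) {
    qx <- qr(X)
    bad <- if (qx$rank < p) cols[qx$pivot[(qx$rank + 1L):p]] else cols[p]
    stop("rank-deficient or near-collinear design in ", eq,
         "; offending column(s): ", paste(bad, collapse = ", "))
  }
  R <- chol(crossprod(X))
  beta <- drop(backsolve(R, forwardsolve(t(R), crossprod(X, y))))
  names(beta) <- cols
  res <- drop(y - X %*% beta)
  rss <- sum(res * res)
  psi <- rss / n
  XtXinv <- chol2inv(R)
  vcov <- psi * XtXinv
  dimnames(vcov) <- list(cols, cols)
  neg2ll <- if (psi <= 0) -Inf else n * (log(2 * pi * psi) + 1)
  list(beta = beta, psi = psi, vcov = vcov, neg2loglik = neg2ll,
       residuals = res, n = n)
}

#' Fit the single-group moderated mediation model
#'
#' Fits, by Gaussian maximum likelihood, the single-group parameterization
#' of the two-group mediation model: the M equation regresses M on X, the
#' group dummy, and the X-by-group product term (coefficients a1, a2, a3);
#' the Y equation regresses Y on M and X only (coefficients b and c',
#' pooled across groups). Residual variances are pooled across groups and
#' use the ML (1/n) denominator. Because the model is recursive, the
#' coefficient estimates equal the per-equation least-squares solutions.
#'
#' Under the coding in `coding`, a1 is the simple X-to-M effect in the
#' reference group (coded 0), a1 + a3 the simple effect in the focal group
#' (coded 1), and a3 their difference.
#'
#' @param data A [mediation_data] object with both group levels present.
#' @param coding A [group_coding] object; defaults to reference = first
#'   group level, focal = second.
#' @return An object of class `sg_fit`: coefficients (int_m, a1, a2, a3,
#'   int_y, b, c_prime), ML residual variances `psi_m` and `psi_y`, the
#'   block-diagonal asymptotic covariance `vcov` of all coefficients,
#'   `neg2loglik`, sample sizes and the coding used.
#' @examples
#' d <- generate_dataset(population_catalog()[["I-0"]], 100, 100, seed = 1)
#' fit <- fit_single_group(d)
#' coef(fit)
#' @export
fit_single_group <- function(data, coding = NULL) {
  if (!inherits(data, "mediation_data")) stop("data must be a mediation_data object")
  lev <- levels(data$group)
  if (length(lev) != 2L || any(data$n_per_group == 0L))
    stop("single-group fit requires exactly two group levels present")
  if (is.null(coding)) coding <- group_coding(lev[1L], lev[2L])
  if (!inherits(coding, "group_coding")) stop("coding must be a group_coding object")
  if (!all(c(coding$reference, coding$focal) %in% lev))
    stop("coding labels (", coding$reference, ", ", coding$focal,
         ") do not match group levels (", paste(lev, collapse = ", "), ")")
  g <- as.numeric(data$group == coding$focal)
  Xm <- cbind(int_m = 1, x = data$x, group = g, x_group = data$x * g)
  Xy <- cbind(int_y = 1, m = data$m, x = data$x)
  fm <- .ols_ml(Xm, data$m, eq = "M equation")
  fy <- .ols_ml(Xy, data$y, eq = "Y equation")
  coefs <- c(int_m = unname(fm$beta[1]), a1 = unname(fm$beta[2]),
             a2 = unname(fm$beta[3]), a3 = unname(fm$beta[4]),
             int_y = unname(fy$beta[1]), b = unname(fy$beta[2]),
             c_prime = unname(fy$beta[3]))
  nm <- names(coefs)
  vc <- matrix(0, 7, 7, dimnames = list(nm, nm))
  vc[1:4, 1:4] <- fm$vcov
  vc[5:7, 5:7] <- fy$vcov
  structure(list(coefficients = coefs,
                 psi_m = fm$psi, psi_y = fy$psi,
                 vcov = vc,
                 neg2loglik = fm$neg2loglik + fy$neg2loglik,
                 n = data$n_total, n_per_group = data$n_per_group,
                 coding = coding),
            class = "sg_fit")
}

#' @export
coef.sg_fit <- function(object, ...) object$coefficients

#' @export
vcov.sg_fit <- function(object, ...) object$vcov

#' @export
logLik.sg_fit <- function(object, ...) {
  structure(-object$neg2loglik / 2, df = 9, class = "logLik")
}

#' @export
print.sg_fit <- function(x, digits = 4, ...) {
  cat("Single-group moderated mediation fit (ML), n =", x$n, "\n")
  cat("Coding: 0 =", x$coding$reference, ", 1 =", x$coding$focal, "\n")
  print(round(x$coefficients, digits))
  cat("psi_M =", format(x$psi_m, digits = digits),
      " psi_Y =", format(x$psi_y, digits = digits),
      " -2logLik =", format(x$neg2loglik, digits = digits + 3), "\n")
  invisible(x)
}
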