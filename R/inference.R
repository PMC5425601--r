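.med_test <- function(method, statistic, df, p_value) {
  structure(list(method = method, statistic = unname(statistic),
                 df = df, p_value = unname(p_value)),
            class = "med_test")
}

#' @export
print.med_test <- function(x, digits = 4, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = digits), sep = "")
  if (!is.na(x$df)) cat(", df =", x$df)
  cat(", p =", format.pval(x$p_value, digits = digits), "\n")
  invisible(x)
}

#' z test for the group difference in the a path (single-group model)
#'
#' Tests a3 = 0 (no group difference in the X to M path) with
#' z = a3_hat / se(a3_hat) and a two-sided standard-normal p value. The
#' standard error is ML-based (residual variance with denominator n). This
#' test pools the M-equation residual variance across groups, so it relies
#' on the homogeneity-of-variance assumption.
#'
#' @param fit An `sg_fit` object.
#' @return A `med_test` with method tag `"za3S"`.
#' @export
z_test_a3 <- function(fit) {
  if (!inherits(fit, "sg_fit")) stop("fit must be an sg_fit object")
  se <- sqrt(fit$vcov["a3", "a3"])
  if (!is.finite(se) || se <= 0) stop("standard error of a3 is zero or undefined")
  z <- fit$coefficients[["a3"]] / se
  .med_test("za3S", z, NA_integer_, 2 * pnorm(-abs(z)))
}

# scalar delta-method Wald statistic: theta^2 / (grad' V grad)
.wald_scalar <- function(theta, grad, V, method) {
  avar <- drop(crossprod(grad, V %*% grad))
  if (!is.finite(avar) || avar <= 0)
    stop("asymptotic variance of the estimand is zero or negative")
  W <- theta^2 / avar
  .med_test(method, W, 1L, pchisq(W, df = 1, lower.tail = FALSE))
}

#' Wald test for the group difference in the indirect effect (single-group)
#'
#' Tests a3*b = 0 by the delta method: the estimand theta = a3_hat*b_hat has
#' gradient (b_hat, a3_hat) with respect to (a3, b), and
#' W = theta^2 / avar(theta) is referred to chi-square with 1 df.
#'
#' @param fit An `sg_fit` object.
#' @return A `med_test` with method tag `"WdiffS"`.
#' @export
wald_product_test <- function(fit) {
  if (!inherits(fit, "sg_fit")) stop("fit must be an sg_fit object")
  cf <- fit$coefficients
  V <- asymptotic_cov_products(fit)[c("a3", "b"), c("a3", "b")]
  .wald_scalar(cf[["a3"]] * cf[["b"]], c(cf[["b"]], cf[["a3"]]), V, "WdiffS")
}

#' Wald test for the group difference in the indirect effect (multi-group)
#'
#' Tests a_G1*b_G1 = a_G2*b_G2 in the unconstrained multi-group model by the
#' delta method on theta = a_G1*b_G1 - a_G2*b_G2, with gradient
#' (b_G1, a_G1, -b_G2, -a_G2) over the joint asymptotic covariance of the
#' four path estimates (cross-group and cross-equation covariances from the
#' ML information matrix).
#'
#' @param fit An unconstrained `mg_fit` object.
#' @return A `med_test` with method tag `"WdiffM"`.
#' @export
wald_diff_test <- function(fit) {
  if (!inherits(fit, "mg_fit")) stop("fit must be an mg_fit object")
  if (length(fit$constraints))
    stop("wald_diff_test requires the unconstrained multi-group fit")
  cf1 <- fit$coefficients[[1L]]; cf2 <- fit$coefficients[[2L]]
  theta <- cf1[["a"]] * cf1[["b"]] - cf2[["a"]] * cf2[["b"]]
  grad <- c(cf1[["b"]], cf1[["a"]], -cf2[["b"]], -cf2[["a"]])
  .wald_scalar(theta, grad, asymptotic_cov_products(fit), "WdiffM")
}

#' Likelihood ratio test between nested multi-group fits
#'
#' Computes the deviance difference
#' `statistic = neg2loglik(constrained) - neg2loglik(unconstrained)` for two
#' nested multi-group fits of the same data and refers it to chi-square with
#' df equal to the difference in free-parameter counts. Adding the
#' constraint `a_equal` gives the test of equal a paths (tag `LRaM`);
#' adding `ab_product_equal` gives the test of equal indirect effects (tag
#' `LRdiffM`). A statistic marginally below zero (within optimizer
#' tolerance) is clamped to zero.
#'
#' @param unconstrained,constrained `mg_fit` objects for the same data; the
#'   constraint set of `constrained` must strictly contain the one of
#'   `unconstrained`.
#' @return A `med_test` with method tag `"LRaM"`, `"LRdiffM"` or `"LR"`.
#' @export
lr_test <- function(unconstrained, constrained) {
  if (!inherits(unconstrained, "mg_fit") || !inherits(constrained, "mg_fit"))
    stop("both arguments must be mg_fit objects")
  if (!identical(unconstrained$n_per_group, constrained$n_per_group))
    stop("fits are not from the same data")
  eff_u <- unconstrained$constraints_effective
  eff_c <- constrained$constraints_effective
  if (!all(eff_u %in% eff_c))
    stop("constraint sets are not nested: {",
         paste(eff_u, collapse = ", "), "} vs {",
         paste(eff_c, collapse = ", "), "}")
  df <- unconstrained$n_free - constrained$n_free
  stat <- constrained$neg2loglik - unconstrained$neg2loglik
  if (stat < 0) {
    if (stat < -1e-4)
      warning("LR statistic ", format(stat), " below zero beyond optimizer ",
              "tolerance; clamped to 0 - check convergence of the fits")
    stat <- 0
  }
  if (df == 0L) {
    # identical constraint sets: degenerate comparison
    return(.med_test("LR", stat, 0L, if (stat <= 1e-8) 1 else 0))
  }
  added_given <- setdiff(constrained$constraints, unconstrained$constraints)
  method <- if (identical(added_given, "a_equal")) "LRaM"
  else if ("ab_product_equal" %in% added_given) "LRdiffM"
  else "LR"
  .med_test(method, stat, df, pchisq(stat, df = df, lower.tail = FALSE))
}
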