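#' Simple indirect effects from single-group coefficients
#'
#' Given the single-group coefficients a1 (X to M in the reference group),
#' a3 (focal-minus-reference difference in the X to M path) and b (M to Y,
#' pooled), returns the two simple (conditional) indirect effects and their
#' difference: reference = a1*b, focal = (a1 + a3)*b, difference
#' (focal minus reference) = a3*b.
#'
#' @param a1,a3,b Numeric scalars.
#' @return Named numeric vector `c(reference, focal, difference)`.
#' @examples
#' conditional_indirect(0.292, -0.058, 0.496)
#' @export
conditional_indirect <- function(a1, a3, b) {
  c(reference = a1 * b, focal = (a1 + a3) * b, difference = a3 * b)
}

#' Simple indirect effects and their group difference from a fitted model
#'
#' For a single-group fit the simple indirect effect is a1*b in the
#' reference group and (a1 + a3)*b in the focal group, and the difference is
#' focal minus reference, a3*b. For a multi-group fit it is a*b within each
#' group and the difference is the first group level minus the second
#' (Group 1 minus Group 2). Effects are always reported per group label.
#'
#' @param fit An `sg_fit` or `mg_fit` object.
#' @return An object of class `indirect_effects`: a list with `effects`
#'   (named by group label), `difference`, `convention` (which group is
#'   subtracted from which), and `source` (`"single_group"` or
#'   `"multi_group"`).
#' @export
simple_indirect_effects <- function(fit) {
  if (inherits(fit, "sg_fit")) {
    cf <- fit$coefficients
    ind <- conditional_indirect(cf[["a1"]], cf[["a3"]], cf[["b"]])
    eff <- setNames(ind[c("reference", "focal")],
                    c(fit$coding$reference, fit$coding$focal))
    out <- list(effects = eff,
                difference = unname(ind[["difference"]]),
                convention = paste0(fit$coding$focal, " - ", fit$coding$reference),
                source = "single_group")
  } else if (inherits(fit, "mg_fit")) {
    eff <- vapply(fit$coefficients, function(cf) cf[["a"]] * cf[["b"]], 0)
    names(eff) <- fit$groups
    out <- list(effects = eff,
                difference = unname(eff[1L] - eff[2L]),
                convention = paste0(fit$groups[1L], " - ", fit$groups[2L]),
                source = "multi_group")
  } else stop("fit must be an sg_fit or mg_fit object")
  structure(out, class = "indirect_effects")
}

#' @export
print.indirect_effects <- function(x, digits = 4, ...) {
  cat("Simple indirect effects (", x$source, "):\n", sep = "")
  print(round(x$effects, digits))
  cat("Difference (", x$convention, "): ", round(x$difference, digits), "\n", sep = "")
  invisible(x)
}

#' Asymptotic covariance of the a- and b-path estimates
#'
#' Extracts the joint asymptotic covariance of the path estimates that enter
#' indirect-effect products, as needed by the delta-method Wald tests. For a
#' single-group fit this is the 3x3 covariance of (a1, a3, b); for an
#' unconstrained multi-group fit the 4x4 covariance of
#' (a_G1, b_G1, a_G2, b_G2). Blocks between the M and Y equations and
#' between groups come from the ML information matrix, which is exactly
#' block-diagonal for this recursive Gaussian model with independent
#' samples, so those covariances are zero.
#'
#' @param fit An `sg_fit`, or an unconstrained `mg_fit` with covariances
#'   computed.
#' @return A labelled covariance matrix.
#' @export
asymptotic_cov_products <- function(fit) {
  if (inherits(fit, "sg_fit")) {
    v <- fit$vcov[c("a1", "a3", "b"), c("a1", "a3", "b")]
    if (any(!is.finite(v))) stop("singular or degenerate information matrix")
    return(v)
  }
  if (!inherits(fit, "mg_fit")) stop("fit must be an sg_fit or mg_fit object")
  if (length(fit$constraints))
    stop("asymptotic_cov_products requires an unconstrained multi-group fit")
  if (is.null(fit$vcov))
    stop("fit was computed with compute_vcov = FALSE")
  nm <- c(paste0(c("a_", "b_"), fit$groups[1L]), paste0(c("a_", "b_"), fit$groups[2L]))
  v <- matrix(0, 4, 4, dimnames = list(nm, nm))
  v[1:2, 1:2] <- fit$vcov[[1L]][c("a", "b"), c("a", "b")]
  v[3:4, 3:4] <- fit$vcov[[2L]][c("a", "b"), c("a", "b")]
  if (any(!is.finite(v))) stop("singular or degenerate information matrix")
  v
}
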