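# Constrained ML under a_G1*b_G1 = a_G2*b_G2 (equal indirect effects).
#
# Strategy: profile the joint Gaussian likelihood over the common product
# value tau. At fixed tau the problem separates by group; within a group,
# fixing b determines a = tau/b, and the intercepts and c' then have closed
# forms, leaving a one-dimensional minimization in b per group. The outer
# problem is one-dimensional in tau. The nested-profile solution is then
# polished with BFGS over the full free-parameter vector under the
# reparameterization a_G2 = a_G1*b_G1/b_G2 (or its symmetric counterpart).

# profile -2ll contribution (up to the additive Gaussian constant) of one
# group at common product tau: n*log(RSS_M/n) + n*log(RSS_Y/n)
.abprod_prof_group <- function(tau, x, m, y, b_hat, se_b) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc * xc)
  f <- function(b) {
    a <- tau / b
    rm <- m - a * x
    rmc <- rm - mean(rm)
    rss_m <- sum(rmc * rmc)
    ry <- y - b * m
    ryc <- ry - mean(ry)
    beta <- sum(xc * ryc) / sxx
    rss_y <- sum((ryc - beta * xc)^2)
    if (rss_m <= 0 || rss_y <= 0) return(.Machine$double.xmax)
    n * log(rss_m / n) + n * log(rss_y / n)
  }
  half <- max(0.5, 8 * se_b)
  lo <- b_hat - half; hi <- b_hat + half
  opt <- if (tau != 0 && lo < 0 && hi > 0) {
    # a = tau/b is singular at b = 0: search each sign region separately
    cands <- list()
    if (lo < -1e-8) cands <- c(cands, list(optimize(f, c(lo, -1e-8), tol = 1e-6)))
    if (hi > 1e-8) cands <- c(cands, list(optimize(f, c(1e-8, hi), tol = 1e-6)))
    cands[[which.min(vapply(cands, `[[`, 0, "objective"))]]
  } else {
    optimize(f, c(lo, hi), tol = 1e-6)
  }
  list(value = opt$objective, b = opt$minimum)
}

# full profile objective over the free structural parameters; psi profiled out
.abprod_objective <- function(x1, m1, y1, x2, m2, y2, c_shared, solve_for) {
  n1 <- length(x1); n2 <- length(x2)
  big <- .Machine$double.xmax
  function(par) {
    if (c_shared) {
      im1 <- par[1]; a1 <- par[2]; iy1 <- par[3]; b1 <- par[4]
      im2 <- par[5]; iy2 <- par[6]; p7 <- par[7]; cc <- par[8]
      c1 <- cc; c2 <- cc
    } else {
      im1 <- par[1]; a1 <- par[2]; iy1 <- par[3]; b1 <- par[4]; c1 <- par[5]
      im2 <- par[6]; iy2 <- par[7]; p7 <- par[8]; c2 <- par[9]
    }
    if (solve_for == "a_G2") {
      b2 <- p7
      if (abs(b2) < 1e-12) return(big)
      a2 <- a1 * b1 / b2
    } else {
      a2 <- p7
      if (abs(a2) < 1e-12) return(big)
      b2 <- a1 * b1 / a2
    }
    r <- m1 - im1 - a1 * x1; rss_m1 <- sum(r * r)
    r <- y1 - iy1 - b1 * m1 - c1 * x1; rss_y1 <- sum(r * r)
    r <- m2 - im2 - a2 * x2; rss_m2 <- sum(r * r)
    r <- y2 - iy2 - b2 * m2 - c2 * x2; rss_y2 <- sum(r * r)
    if (rss_m1 <= 0 || rss_y1 <= 0 || rss_m2 <= 0 || rss_y2 <= 0) return(big)
    n1 * (log(rss_m1 / n1) + log(rss_y1 / n1)) +
      n2 * (log(rss_m2 / n2) + log(rss_y2 / n2))
  }
}

# analytic gradient of the profile objective (chain rule through the
# reparameterization); layout must mirror .abprod_objective
.abprod_gradient <- function(x1, m1, y1, x2, m2, y2, c_shared, solve_for) {
  n1 <- length(x1); n2 <- length(x2)
  function(par) {
    if (c_shared) {
      im1 <- par[1]; a1 <- par[2]; iy1 <- par[3]; b1 <- par[4]
      im2 <- par[5]; iy2 <- par[6]; p7 <- par[7]; c1 <- par[8]; c2 <- par[8]
    } else {
      im1 <- par[1]; a1 <- par[2]; iy1 <- par[3]; b1 <- par[4]; c1 <- par[5]
      im2 <- par[6]; iy2 <- par[7]; p7 <- par[8]; c2 <- par[9]
    }
    if (solve_for == "a_G2") { b2 <- p7; a2 <- a1 * b1 / b2 }
    else { a2 <- p7; b2 <- a1 * b1 / a2 }
    rm1 <- m1 - im1 - a1 * x1
    ry1 <- y1 - iy1 - b1 * m1 - c1 * x1
    rm2 <- m2 - im2 - a2 * x2
    ry2 <- y2 - iy2 - b2 * m2 - c2 * x2
    gm1 <- n1 / sum(rm1 * rm1); gy1 <- n1 / sum(ry1 * ry1)
    gm2 <- n2 / sum(rm2 * rm2); gy2 <- n2 / sum(ry2 * ry2)
    D_im1 <- -2 * gm1 * sum(rm1)
    D_a1d <- -2 * gm1 * sum(rm1 * x1)
    D_iy1 <- -2 * gy1 * sum(ry1)
    D_b1d <- -2 * gy1 * sum(ry1 * m1)
    D_c1 <- -2 * gy1 * sum(ry1 * x1)
    D_im2 <- -2 * gm2 * sum(rm2)
    D_a2d <- -2 * gm2 * sum(rm2 * x2)
    D_iy2 <- -2 * gy2 * sum(ry2)
    D_b2d <- -2 * gy2 * sum(ry2 * m2)
    D_c2 <- -2 * gy2 * sum(ry2 * x2)
    if (solve_for == "a_G2") {
      D_a1 <- D_a1d + D_a2d * (b1 / b2)
      D_b1 <- D_b1d + D_a2d * (a1 / b2)
      D_p7 <- D_b2d + D_a2d * (-a1 * b1 / b2^2)
    } else {
      D_a1 <- D_a1d + D_b2d * (b1 / a2)
      D_b1 <- D_b1d + D_b2d * (a1 / a2)
      D_p7 <- D_a2d + D_b2d * (-a1 * b1 / a2^2)
    }
    if (c_shared)
      c(D_im1, D_a1, D_iy1, D_b1, D_im2, D_iy2, D_p7, D_c1 + D_c2)
    else
      c(D_im1, D_a1, D_iy1, D_b1, D_c1, D_im2, D_iy2, D_p7, D_c2)
  }
}

# closed-form intercepts / c' for fixed slopes within one group
.abprod_group_pars <- function(a, b, x, m, y, c_fixed = NULL) {
  im <- mean(m) - a * mean(x)
  ry <- y - b * m
  if (is.null(c_fixed)) {
    xc <- x - mean(x)
    cc <- sum(xc * (ry - mean(ry))) / sum(xc * xc)
  } else cc <- c_fixed
  iy <- mean(ry) - cc * mean(x)
  c(int_m = im, a = a, int_y = iy, b = b, c_prime = cc)
}

.fd_gradient <- function(f, par, h = 1e-6) {
  vapply(seq_along(par), function(i) {
    e <- numeric(length(par)); e[i] <- h * max(1, abs(par[i]))
    (f(par + e) - f(par - e)) / (2 * e[i])
  }, 0)
}

.fd_hessian <- function(f, par, h = 1e-5) {
  p <- length(par)
  H <- matrix(0, p, p)
  hh <- h * pmax(1, abs(par))
  f0 <- f(par)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- numeric(p); ei[i] <- hh[i]
      ej <- numeric(p); ej[j] <- hh[j]
      if (i == j) {
        H[i, i] <- (f(par + ei) - 2 * f0 + f(par - ei)) / hh[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(par + ei + ej) - f(par + ei - ej) -
             f(par - ei + ej) + f(par - ei - ej)) / (4 * hh[i] * hh[j])
      }
    }
  }
  H
}

.fit_mg_abprod <- function(x1, m1, y1, x2, m2, y2, c_shared = FALSE,
                           solve_for = "a_G2", compute_vcov = TRUE,
                           control = list()) {
  n1 <- length(x1); n2 <- length(x2)
  u <- .fit_mg_linear(x1, m1, y1, x2, m2, y2, character(), compute_vcov = TRUE)
  cf1 <- u$coefficients[[1]]; cf2 <- u$coefficients[[2]]
  se <- u$se
  p1 <- cf1[["a"]] * cf1[["b"]]; p2 <- cf2[["a"]] * cf2[["b"]]

  if (solve_for == "a_G2" && abs(cf2[["b"]]) < 1e-6)
    stop("b in group 2 is numerically zero; the a_G2 = a_G1*b_G1/b_G2 ",
         "reparameterization is ill-conditioned: refit with solve_for = \"b_G2\"")
  if (solve_for == "b_G2" && abs(cf2[["a"]]) < 1e-6)
    stop("a in group 2 is numerically zero; refit with solve_for = \"a_G2\"")

  obj <- .abprod_objective(x1, m1, y1, x2, m2, y2, c_shared, solve_for)
  grd <- .abprod_gradient(x1, m1, y1, x2, m2, y2, c_shared, solve_for)
  pack <- function(g1, g2) {
    p7 <- if (solve_for == "a_G2") g2[["b"]] else g2[["a"]]
    if (c_shared) {
      cc <- (n1 * g1[["c_prime"]] + n2 * g2[["c_prime"]]) / (n1 + n2)
      c(g1[["int_m"]], g1[["a"]], g1[["int_y"]], g1[["b"]],
        g2[["int_m"]], g2[["int_y"]], p7, cc)
    } else {
      c(g1[["int_m"]], g1[["a"]], g1[["int_y"]], g1[["b"]], g1[["c_prime"]],
        g2[["int_m"]], g2[["int_y"]], p7, g2[["c_prime"]])
    }
  }

  starts <- list()
  if (!c_shared) {
    # nested profile over the common product value tau
    se_p1 <- abs(cf1[["b"]]) * se$se_a[1] + abs(cf1[["a"]]) * se$se_b[1]
    se_p2 <- abs(cf2[["b"]]) * se$se_a[2] + abs(cf2[["a"]]) * se$se_b[2]
    spread <- max(0.02, abs(p1 - p2), 2 * (se_p1 + se_p2))
    lo <- min(p1, p2) - spread; hi <- max(p1, p2) + spread
    g_tau <- function(tau)
      .abprod_prof_group(tau, x1, m1, y1, cf1[["b"]], se$se_b[1])$value +
      .abprod_prof_group(tau, x2, m2, y2, cf2[["b"]], se$se_b[2])$value
    for (tries in 1:6) {
      op <- optimize(g_tau, c(lo, hi), tol = 1e-7)
      width <- hi - lo
      at_edge <- op$minimum < lo + 0.01 * width || op$minimum > hi - 0.01 * width
      if (!at_edge) break
      lo <- lo - width; hi <- hi + width
    }
    tau <- op$minimum
    pb1 <- .abprod_prof_group(tau, x1, m1, y1, cf1[["b"]], se$se_b[1])
    pb2 <- .abprod_prof_group(tau, x2, m2, y2, cf2[["b"]], se$se_b[2])
    g1 <- .abprod_group_pars(tau / pb1$b, pb1$b, x1, m1, y1)
    g2 <- .abprod_group_pars(tau / pb2$b, pb2$b, x2, m2, y2)
    starts <- list(pack(g1, g2))
  } else {
    # shared c': no separable profile; quasi-Newton from projected starts
    proj1 <- cf2; proj1[["a"]] <- p1 / cf2[["b"]]     # keep group 1, adjust a_G2
    proj2 <- cf1; proj2[["a"]] <- p2 / cf1[["b"]]     # keep group 2, adjust a_G1
    eqf <- .fit_mg_linear(x1, m1, y1, x2, m2, y2,
                          c("a_equal", "b_equal", "cprime_equal"),
                          compute_vcov = FALSE)
    starts <- list(pack(cf1, proj1), pack(proj2, cf2),
                   pack(eqf$coefficients[[1]], eqf$coefficients[[2]]))
  }

  best <- NULL
  for (s in starts) {
    o <- optim(s, obj, gr = grd, method = "BFGS",
               control = c(list(maxit = 300, reltol = 1e-13),
                           control[names(control) %in% c("maxit", "reltol")]))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # keep the profile solution if BFGS somehow moved uphill
  if (length(starts) == 1L && obj(starts[[1]]) < best$value)
    best <- list(par = starts[[1]], value = obj(starts[[1]]), convergence = 0L)
  gr <- .fd_gradient(obj, best$par)
  if (!is.null(best$convergence) && best$convergence != 0 &&
      max(abs(gr)) > 1e-2 * (1 + abs(best$value)))
    stop("product-constraint optimizer did not converge; last iterate = (",
         paste(format(best$par, digits = 6), collapse = ", "),
         "), gradient max-norm = ", format(max(abs(gr)), digits = 4))

  par <- best$par
  if (c_shared) {
    g1 <- c(int_m = par[1], a = par[2], int_y = par[3], b = par[4], c_prime = par[8])
    g2 <- c(int_m = par[5], a = NA, int_y = par[6], b = NA, c_prime = par[8])
    p7 <- par[7]
  } else {
    g1 <- c(int_m = par[1], a = par[2], int_y = par[3], b = par[4], c_prime = par[5])
    g2 <- c(int_m = par[6], a = NA, int_y = par[7], b = NA, c_prime = par[9])
    p7 <- par[8]
  }
  if (solve_for == "a_G2") {
    g2[["b"]] <- p7; g2[["a"]] <- g1[["a"]] * g1[["b"]] / p7
  } else {
    g2[["a"]] <- p7; g2[["b"]] <- g1[["a"]] * g1[["b"]] / p7
  }

  rss <- c(m1 = sum((m1 - g1[["int_m"]] - g1[["a"]] * x1)^2),
           y1 = sum((y1 - g1[["int_y"]] - g1[["b"]] * m1 - g1[["c_prime"]] * x1)^2),
           m2 = sum((m2 - g2[["int_m"]] - g2[["a"]] * x2)^2),
           y2 = sum((y2 - g2[["int_y"]] - g2[["b"]] * m2 - g2[["c_prime"]] * x2)^2))
  psi <- list(c(m = rss[["m1"]] / n1, y = rss[["y1"]] / n1),
              c(m = rss[["m2"]] / n2, y = rss[["y2"]] / n2))
  neg2ll <- best$value + (log(2 * pi) + 1) * 2 * (n1 + n2)

  vcov_free <- NULL
  if (compute_vcov) {
    H <- .fd_hessian(obj, par)
    vcov_free <- tryCatch(2 * solve(H), error = function(e) NULL)
  }

  list(coefficients = list(g1[c("int_m", "a", "int_y", "b", "c_prime")],
                           g2[c("int_m", "a", "int_y", "b", "c_prime")]),
       psi = psi, vcov = NULL, se = NULL,
       vcov_free = vcov_free,
       neg2loglik = neg2ll,
       convergence = list(optim_code = best$convergence,
                          gradient_max = max(abs(gr)),
                          value = best$value))
}

#' @export
coef.mg_fit <- function(object, ...) {
  do.call(rbind, object$coefficients)
}

#' @export
logLik.mg_fit <- function(object, ...) {
  structure(-object$neg2loglik / 2, df = object$n_free, class = "logLik")
}

#' @export
print.mg_fit <- function(x, digits = 4, ...) {
  cat("Multi-group mediation fit (ML), n =", x$n, "(",
      paste(x$groups, "=", x$n_per_group, collapse = ", "), ")\n")
  if (length(x$constraints))
    cat("Constraints:", paste(x$constraints, collapse = ", "), "\n")
  tab <- do.call(rbind, x$coefficients)
  tab <- cbind(tab, psi_m = vapply(x$psi, `[[`, 0, "m"),
               psi_y = vapply(x$psi, `[[`, 0, "y"))
  print(round(tab, digits))
  cat("-2logLik =", format(x$neg2loglik, digits = digits + 3),
      " free parameters =", x$n_free, "\n")
  invisible(x)
}
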