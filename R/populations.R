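#' Define a two-group mediation population
#'
#' A population is a pair of linear-normal structural models, one per group:
#' X ~ Normal(0, var_x); M = a*X + e_M with e_M ~ Normal(0, psi_m);
#' Y = b*M + c'*X + e_Y with e_Y ~ Normal(0, psi_y). Intercepts are zero.
#'
#' @param name Tag for the population (e.g. `"I-M3"`).
#' @param a,b,cprime Length-2 numeric vectors of structural paths (Group 1,
#'   Group 2).
#' @param psi_m,psi_y Length-2 positive residual variances of M and Y.
#' @param var_x Length-2 variances of X (default 1 in both groups).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(name, a, b, cprime = c(0, 0),
                            psi_m = c(1, 1), psi_y = c(1, 1),
                            var_x = c(1, 1)) {
  as2 <- function(v) if (length(v) == 1L) rep(as.numeric(v), 2L) else as.numeric(v)
  a <- as2(a); b <- as2(b); cprime <- as2(cprime)
  psi_m <- as2(psi_m); psi_y <- as2(psi_y); var_x <- as2(var_x)
  lens <- lengths(list(a, b, cprime, psi_m, psi_y, var_x))
  if (any(lens != 2L)) stop("all parameter vectors must have length 2 (one value per group)")
  if (any(psi_m <= 0) || any(psi_y <= 0) || any(var_x <= 0))
    stop("variances must be strictly positive")
  structure(list(name = as.character(name), a = a, b = b, cprime = cprime,
                 psi_m = psi_m, psi_y = psi_y, var_x = var_x),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat("Population", x$name, "\n")
  tab <- rbind(a = x$a, b = x$b, c_prime = x$cprime,
               psi_m = x$psi_m, psi_y = x$psi_y, var_x = x$var_x)
  colnames(tab) <- c("G1", "G2")
  print(tab)
  invisible(x)
}

#' Catalog of the 21 standard two-group simulation populations
#'
#' The grid crosses three structural-path sets with seven residual-variance
#' patterns; the direct effect c' is zero everywhere and var(X) = 1:
#'
#' * structural set I: a = 0.424 and b = 0.390 in both groups (equal
#'   indirect effects of 0.165);
#' * set II: a_G1 = 0, a_G2 = 0.141, b = 0.390 in both (difference -0.055);
#' * set III: a_G1 = 0, a_G2 = 0.424 (difference -0.165);
#' * variance pattern 0: all residual variances 1; patterns M1-M3 shrink
#'   psi_M in Group 1 to 0.5 and set psi_M in Group 2 to 1, 1.5, 2;
#'   patterns Y1-Y3 do the same to psi_Y.
#'
#' @return A named list of 21 [population_spec] objects, named like
#'   `"I-0"`, `"II-M3"`, `"III-Y1"`.
#' @examples
#' population_catalog()[["III-0"]]
#' @export
population_catalog <- function() {
  structural <- list(I = list(a = c(0.424, 0.424), b = c(0.390, 0.390)),
                     II = list(a = c(0.000, 0.141), b = c(0.390, 0.390)),
                     III = list(a = c(0.000, 0.424), b = c(0.390, 0.390)))
  variance <- list(`0` = list(psi_m = c(1, 1), psi_y = c(1, 1)),
                   M1 = list(psi_m = c(0.5, 1.0), psi_y = c(1, 1)),
                   M2 = list(psi_m = c(0.5, 1.5), psi_y = c(1, 1)),
                   M3 = list(psi_m = c(0.5, 2.0), psi_y = c(1, 1)),
                   Y1 = list(psi_m = c(1, 1), psi_y = c(0.5, 1.0)),
                   Y2 = list(psi_m = c(1, 1), psi_y = c(0.5, 1.5)),
                   Y3 = list(psi_m = c(1, 1), psi_y = c(0.5, 2.0)))
  out <- list()
  for (s in names(structural)) {
    for (v in names(variance)) {
      nm <- paste0(s, "-", v)
      out[[nm]] <- population_spec(nm,
                                   a = structural[[s]]$a, b = structural[[s]]$b,
                                   psi_m = variance[[v]]$psi_m,
                                   psi_y = variance[[v]]$psi_y)
    }
  }
  out
}

#' Population proportions of explained variance in M and Y
#'
#' Closed-form R-squared values implied by a [population_spec], per group:
#' `R2_M = a^2 var_x / (a^2 var_x + psi_M)` and
#' `R2_Y = (b^2 var_M + c'^2 var_x + 2 a b c' var_x) / (... + psi_Y)` with
#' `var_M = a^2 var_x + psi_M`.
#'
#' @param population A [population_spec].
#' @return A data frame with one row per group and columns `group`, `r2_m`,
#'   `r2_y`.
#' @export
explained_variance <- function(population) {
  p <- population
  if (!inherits(p, "population_spec")) stop("population must be a population_spec")
  var_m <- p$a^2 * p$var_x + p$psi_m
  r2_m <- p$a^2 * p$var_x / var_m
  expl_y <- p$b^2 * var_m + p$cprime^2 * p$var_x + 2 * p$a * p$b * p$cprime * p$var_x
  r2_y <- expl_y / (expl_y + p$psi_y)
  data.frame(group = c("G1", "G2"), r2_m = r2_m, r2_y = r2_y)
}

#' Population values of the simple indirect effects and their difference
#'
#' @param population A [population_spec].
#' @return Named vector with the per-group indirect effects `a*b` and the
#'   Group 1 minus Group 2 `difference`.
#' @export
population_indirect <- function(population) {
  p <- population
  if (!inherits(p, "population_spec")) stop("population must be a population_spec")
  ind <- p$a * p$b
  c(G1 = ind[1], G2 = ind[2], difference = ind[1] - ind[2])
}

#' Generate a dataset from a two-group mediation population
#'
#' Per group: X ~ Normal(0, var_x); M = a*X + e_M; Y = b*M + c'*X + e_Y,
#' with independent normal residuals and zero intercepts. X is drawn fresh
#' per call (random-X design). Deterministic given `seed`; Group 1 is
#' generated first.
#'
#' @param population A [population_spec].
#' @param n_g1,n_g2 Group sample sizes (at least 1).
#' @param seed Optional integer seed.
#' @param labels Group labels, default `c("G1", "G2")`.
#' @return A [mediation_data] object with Group 1 as the first level.
#' @export
generate_dataset <- function(population, n_g1, n_g2, seed = NULL,
                             labels = c("G1", "G2")) {
  p <- population
  if (!inherits(p, "population_spec")) stop("population must be a population_spec")
  if (n_g1 < 1L || n_g2 < 1L) stop("group sizes must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  gen <- function(g, n) {
    x <- rnorm(n, 0, sqrt(p$var_x[g]))
    m <- p$a[g] * x + rnorm(n, 0, sqrt(p$psi_m[g]))
    y <- p$b[g] * m + p$cprime[g] * x + rnorm(n, 0, sqrt(p$psi_y[g]))
    list(x = x, m = m, y = y)
  }
  g1 <- gen(1L, n_g1); g2 <- gen(2L, n_g2)
  mediation_data(c(g1$x, g2$x), c(g1$m, g2$m), c(g1$y, g2$y),
                 rep(labels, c(n_g1, n_g2)), levels = labels)
}
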