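# deterministic per-replication seed stream derived from the master seed by
# a counter; keeps every replication independently reproducible
.rep_seed <- function(master, k) {
  s <- as.double(master) %% 2147483647
  as.integer((s + as.double(k) * 48611) %% 2147483647)
}

.sim_methods <- data.frame(
  method   = c("za3S", "WdiffS", "PCindS", "BCindS",
               "LRaM", "LRdiffM", "WdiffM",
               "PCindM", "BCindM", "MCindM", "PCdiffM", "BCdiffM", "MCdiffM"),
  approach = c("single", "single", "single", "single",
               "multi", "multi", "multi",
               "multi", "multi", "multi", "multi", "multi", "multi"),
  target   = c("a_path", "difference", "ind", "ind",
               "a_path", "difference", "difference",
               "ind", "ind", "ind", "difference", "difference", "difference"),
  type     = c("test", "test", "ci", "ci",
               "test", "test", "test",
               "ci", "ci", "ci", "ci", "ci", "ci"),
  stringsAsFactors = FALSE
)

#' Specify one cell of the simulation design
#'
#' Bundles a population, the two group sample sizes, the replication count,
#' the master seed, the list of methods to evaluate, and the resampling
#' sizes B (bootstrap) and R (Monte Carlo).
#'
#' @param population A [population_spec].
#' @param n_g1,n_g2 Group sample sizes.
#' @param n_reps Number of replications.
#' @param seed Master seed; per-replication seeds are derived from it by a
#'   counter scheme, so the condition is reproducible bit-for-bit.
#' @param methods Character vector of method tags (see [run_condition()]).
#' @param B,R Bootstrap resamples and Monte Carlo draws per replication.
#' @param level Nominal confidence level (tests use alpha = 1 - level).
#' @param resampling Bootstrap scheme for the single-group approach.
#' @return An object of class `sim_condition`.
#' @export
sim_condition <- function(population, n_g1, n_g2, n_reps = 1000, seed = 1,
                          methods = c("za3S", "LRaM"), B = 1000, R = 1000,
                          level = 0.95, resampling = "stratified") {
  if (!inherits(population, "population_spec"))
    stop("population must be a population_spec")
  bad <- setdiff(methods, .sim_methods$method)
  if (length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(.sim_methods$method, collapse = ", "))
  if (n_reps < 1) stop("n_reps must be at least 1")
  structure(list(population = population, n_g1 = as.integer(n_g1),
                 n_g2 = as.integer(n_g2), n_reps = as.integer(n_reps),
                 seed = as.integer(seed), methods = unique(methods),
                 B = as.integer(B), R = as.integer(R), level = level,
                 resampling = resampling),
            class = "sim_condition")
}

#' Tally interval misses by side
#'
#' An interval misses on the left when it lies entirely below the true value
#' (upper endpoint under the truth), on the right when it lies entirely
#' above it (lower endpoint over the truth), and covers otherwise
#' (closed-interval convention). The ratio of left to right misses is
#' flagged undefined when there are no right-side misses.
#'
#' @param lower,upper Numeric vectors of interval endpoints.
#' @param true_value The population value of the estimand.
#' @return A list with counts `left`, `right`, `cover`, the `ratio`
#'   left/right (NA when undefined) and `ratio_defined`.
#' @export
miss_side_tally <- function(lower, upper, true_value) {
  if (length(lower) != length(upper)) stop("lower and upper must have equal length")
  if (any(lower > upper)) stop("malformed interval(s): lower > upper")
  left <- sum(true_value > upper)
  right <- sum(true_value < lower)
  cover <- length(lower) - left - right
  list(left = left, right = right, cover = cover,
       ratio = if (right > 0) left / right else NA_real_,
       ratio_defined = right > 0)
}

#' Run one simulation condition
#'
#' For each replication: generate a dataset from the population, fit the
#' single-group and/or multi-group models as required by the requested
#' methods, apply every method, and record rejection (test p < alpha, or
#' interval excluding zero), and for interval methods coverage of the true
#' value, interval width and miss side. Per-parameter estimates are
#' accumulated for bias summaries. Replications whose fit fails are
#' recorded and excluded from the rates; more than 2% failures is an error.
#'
#' Method tags: single-group `za3S` (z test of the interaction path),
#' `WdiffS` (Wald test of a3*b = 0), `PCindS`/`BCindS` (bootstrap CIs for
#' the simple indirect effect in each group); multi-group `LRaM` (LR test of
#' equal a paths), `LRdiffM` (LR test of equal indirect effects), `WdiffM`
#' (Wald test of the difference), `PCindM`/`BCindM`/`MCindM` (CIs for the
#' simple indirect effects), `PCdiffM`/`BCdiffM`/`MCdiffM` (CIs for the
#' Group 1 minus Group 2 difference).
#'
#' @param condition A [sim_condition].
#' @param verbose Print a progress line every 100 replications.
#' @return An object of class `sim_summary`: the condition echo, a
#'   `methods` data frame (per method and estimand: rejection rate,
#'   coverage, mean width, left/right miss counts and ratio, Monte Carlo
#'   standard errors), a `bias` data frame per parameter, and the failure
#'   count.
#' @export
run_condition <- function(condition, verbose = FALSE) {
  stopifnot(inherits(condition, "sim_condition"))
  pop <- condition$population
  n1 <- condition$n_g1; n2 <- condition$n_g2
  n_reps <- condition$n_reps
  level <- condition$level
  alpha <- 1 - level
  lev <- c("G1", "G2")
  info <- .sim_methods[match(condition$methods, .sim_methods$method), ]

  need_sg <- any(info$approach == "single")
  need_mg <- any(info$approach == "multi")
  need_sg_boot <- any(info$method %in% c("PCindS", "BCindS"))
  need_mg_boot <- any(info$method %in% c("PCindM", "BCindM", "PCdiffM", "BCdiffM"))
  need_mc <- any(info$method %in% c("MCindM", "MCdiffM"))
  need_lr_a <- "LRaM" %in% info$method
  need_lr_ab <- "LRdiffM" %in% info$method
  need_mg_vcov <- any(info$method %in% c("WdiffM", "MCindM", "MCdiffM"))

  # one slot per method x estimand
  slots <- do.call(rbind, lapply(seq_len(nrow(info)), function(i) {
    if (info$target[i] == "ind")
      data.frame(method = info$method[i], estimand = lev, stringsAsFactors = FALSE)
    else
      data.frame(method = info$method[i],
                 estimand = if (info$target[i] == "a_path") "a_path" else "difference",
                 stringsAsFactors = FALSE)
  }))
  ns <- nrow(slots)
  slot_id <- function(method, estimand)
    which(slots$method == method & slots$estimand == estimand)

  # population truths (Group 1 first level; single-group coding 0 = G1)
  t_ind <- pop$a * pop$b
  truth <- c(G1 = t_ind[1], G2 = t_ind[2], difference = t_ind[1] - t_ind[2])

  reject <- matrix(NA, n_reps, ns)
  width <- matrix(NA_real_, n_reps, ns)
  side <- matrix(NA_integer_, n_reps, ns)   # 0 cover, 1 left miss, 2 right miss
  par_names <- c("sg_a1", "sg_a3", "sg_b", "mg_a_G1", "mg_b_G1",
                 "mg_a_G2", "mg_b_G2", "ind_G1", "ind_G2", "difference")
  est <- matrix(NA_real_, n_reps, length(par_names),
                dimnames = list(NULL, par_names))
  failed <- logical(n_reps)

  for (r in seq_len(n_reps)) {
    s_data <- .rep_seed(condition$seed, 4L * (r - 1L) + 1L)
    s_boot_s <- .rep_seed(condition$seed, 4L * (r - 1L) + 2L)
    s_boot_m <- .rep_seed(condition$seed, 4L * (r - 1L) + 3L)
    s_mc <- .rep_seed(condition$seed, 4L * (r - 1L) + 4L)
    ok <- tryCatch({
      dat <- generate_dataset(pop, n1, n2, seed = s_data, labels = lev)
      rec_ci <- function(sl, ci, true) {
        reject[r, sl] <<- ci$lower > 0 || ci$upper < 0
        width[r, sl] <<- ci$upper - ci$lower
        # left-side miss: interval entirely below the truth
        side[r, sl] <<- if (true > ci$upper) 1L else if (true < ci$lower) 2L else 0L
      }
      both_ci <- function(meths, draws_list, pes, truths) {
        # draws_list: named list per estimand of raw draws
        for (i in seq_along(draws_list)) {
          en <- names(draws_list)[i]
          ds <- .draw_set(draws_list[[i]], en, "bootstrap", pes[[en]],
                          NA_integer_, "x", length(draws_list[[i]]))
          if (meths[1] %in% info$method)
            rec_ci(slot_id(meths[1], en), percentile_ci(ds, level), truths[[en]])
          if (length(meths) > 1 && meths[2] %in% info$method)
            rec_ci(slot_id(meths[2], en), bc_ci(ds, level), truths[[en]])
        }
      }

      if (need_sg) {
        fs <- fit_single_group(dat)
        cf <- fs$coefficients
        est[r, "sg_a1"] <- cf[["a1"]]; est[r, "sg_a3"] <- cf[["a3"]]
        est[r, "sg_b"] <- cf[["b"]]
        if ("za3S" %in% info$method)
          reject[r, slot_id("za3S", "a_path")] <- z_test_a3(fs)$p_value < alpha
        if ("WdiffS" %in% info$method)
          reject[r, slot_id("WdiffS", "difference")] <- wald_product_test(fs)$p_value < alpha
        if (need_sg_boot) {
          ind_s <- simple_indirect_effects(fs)
          set.seed(s_boot_s)
          ir <- dat$group == lev[1L]
          bd <- if (identical(condition$resampling, "pooled"))
            .boot_sg_pooled_draws(dat$x, dat$m, dat$y,
                                  as.numeric(dat$group == lev[2L]), condition$B)
          else
            .boot_sg_strat_draws(dat$x[ir], dat$m[ir], dat$y[ir],
                                 dat$x[!ir], dat$m[!ir], dat$y[!ir], condition$B)
          .check_dropped(bd$n_dropped, condition$B)
          both_ci(c("PCindS", "BCindS"),
                  list(G1 = bd$ind_ref, G2 = bd$ind_foc),
                  as.list(ind_s$effects), as.list(truth))
        }
      }

      if (need_mg) {
        fm <- fit_multi_group(dat, compute_vcov = need_mg_vcov || need_lr_a || need_lr_ab)
        cf1 <- fm$coefficients[[1L]]; cf2 <- fm$coefficients[[2L]]
        est[r, "mg_a_G1"] <- cf1[["a"]]; est[r, "mg_b_G1"] <- cf1[["b"]]
        est[r, "mg_a_G2"] <- cf2[["a"]]; est[r, "mg_b_G2"] <- cf2[["b"]]
        ind_m <- simple_indirect_effects(fm)
        est[r, "ind_G1"] <- ind_m$effects[["G1"]]
        est[r, "ind_G2"] <- ind_m$effects[["G2"]]
        est[r, "difference"] <- ind_m$difference
        if (need_lr_a) {
          fa <- fit_multi_group(dat, "a_equal", compute_vcov = FALSE)
          reject[r, slot_id("LRaM", "a_path")] <- lr_test(fm, fa)$p_value < alpha
        }
        if (need_lr_ab) {
          fab <- fit_multi_group(dat, "ab_product_equal", compute_vcov = FALSE)
          reject[r, slot_id("LRdiffM", "difference")] <- lr_test(fm, fab)$p_value < alpha
        }
        if ("WdiffM" %in% info$method)
          reject[r, slot_id("WdiffM", "difference")] <- wald_diff_test(fm)$p_value < alpha
        if (need_mg_boot) {
          set.seed(s_boot_m)
          i1 <- dat$group == lev[1L]
          bd <- .boot_mg_draws(dat$x[i1], dat$m[i1], dat$y[i1],
                               dat$x[!i1], dat$m[!i1], dat$y[!i1], condition$B)
          .check_dropped(bd$n_dropped, condition$B)
          both_ci(c("PCindM", "BCindM"),
                  list(G1 = bd$ind1, G2 = bd$ind2),
                  as.list(ind_m$effects), as.list(truth))
          both_ci(c("PCdiffM", "BCdiffM"),
                  list(difference = bd$diff),
                  list(difference = ind_m$difference), as.list(truth))
        }
        if (need_mc) {
          set.seed(s_mc)
          md <- .mc_param_draws(fm, condition$R)
          mk <- function(d, en, pe) .draw_set(d, en, "monte_carlo", pe,
                                              NA_integer_, "multi", length(d))
          if ("MCindM" %in% info$method) {
            rec_ci(slot_id("MCindM", "G1"),
                   percentile_ci(mk(md$ind1, "G1", ind_m$effects[["G1"]]), level),
                   truth[["G1"]])
            rec_ci(slot_id("MCindM", "G2"),
                   percentile_ci(mk(md$ind2, "G2", ind_m$effects[["G2"]]), level),
                   truth[["G2"]])
          }
          if ("MCdiffM" %in% info$method)
            rec_ci(slot_id("MCdiffM", "difference"),
                   percentile_ci(mk(md$diff, "difference", ind_m$difference), level),
                   truth[["difference"]])
        }
      }
      TRUE
    }, error = function(e) FALSE)
    failed[r] <- !ok
    if (verbose && r %% 100L == 0L)
      cat("  replication ", r, "/", n_reps, " (failures: ", sum(failed[1:r]),
          ")\n", sep = "")
  }

  if (sum(failed) > 0.02 * n_reps)
    stop("more than 2% of replications failed (", sum(failed), " of ",
         n_reps, ")")

  rate <- function(v) mean(v, na.rm = TRUE)
  mcse <- function(p, n) sqrt(p * (1 - p) / n)
  mdf <- do.call(rbind, lapply(seq_len(ns), function(j) {
    rj <- reject[, j]
    n_used <- sum(!is.na(rj))
    p <- rate(rj)
    is_ci <- !all(is.na(side[, j]))
    if (is_ci) {
      sd_j <- side[!is.na(side[, j]), j]
      cov_rate <- mean(sd_j == 0L)
      data.frame(method = slots$method[j], estimand = slots$estimand[j],
                 n_used = n_used, rejection_rate = p,
                 mcse_rejection = mcse(p, n_used),
                 coverage = cov_rate, mcse_coverage = mcse(cov_rate, n_used),
                 mean_width = mean(width[, j], na.rm = TRUE),
                 left_miss = sum(sd_j == 1L), right_miss = sum(sd_j == 2L),
                 lr_ratio = if (sum(sd_j == 2L) > 0)
                   sum(sd_j == 1L) / sum(sd_j == 2L) else NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(method = slots$method[j], estimand = slots$estimand[j],
                 n_used = n_used, rejection_rate = p,
                 mcse_rejection = mcse(p, n_used),
                 coverage = NA_real_, mcse_coverage = NA_real_,
                 mean_width = NA_real_, left_miss = NA_integer_,
                 right_miss = NA_integer_, lr_ratio = NA_real_,
                 stringsAsFactors = FALSE)
    }
  }))

  true_par <- c(sg_a1 = pop$a[1], sg_a3 = pop$a[2] - pop$a[1],
                sg_b = if (pop$b[1] == pop$b[2]) pop$b[1] else NA_real_,
                mg_a_G1 = pop$a[1], mg_b_G1 = pop$b[1],
                mg_a_G2 = pop$a[2], mg_b_G2 = pop$b[2],
                ind_G1 = truth[["G1"]], ind_G2 = truth[["G2"]],
                difference = truth[["difference"]])
  keep <- colSums(!is.na(est)) > 0L
  bias <- do.call(rbind, lapply(par_names[keep], function(pn) {
    v <- est[, pn]; v <- v[!is.na(v)]
    tv <- true_par[[pn]]
    b <- mean(v) - tv
    data.frame(parameter = pn, true = tv, mean_estimate = mean(v), bias = b,
               rel_bias = if (!is.na(tv) && tv != 0) b / tv else NA_real_,
               mc_se = sd(v) / sqrt(length(v)), stringsAsFactors = FALSE)
  }))

  structure(list(condition = condition, methods = mdf, bias = bias,
                 truth = truth, n_failed = sum(failed)),
            class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, digits = 3, ...) {
  cn <- x$condition
  cat("Simulation: population ", cn$population$name, ", n = (", cn$n_g1, ", ",
      cn$n_g2, "), ", cn$n_reps, " replications (", x$n_failed,
      " failed)\n", sep = "")
  df <- x$methods
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
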