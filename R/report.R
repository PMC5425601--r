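.cfg_methods_single <- c("za3S", "WdiffS", "PCindS", "BCindS",
                         "PCdiffS", "BCdiffS")
.cfg_methods_multi <- c("LRaM", "LRdiffM", "WdiffM",
                        "PCindM", "BCindM", "MCindM",
                        "PCdiffM", "BCdiffM", "MCdiffM")

#' Configuration for a complete two-group mediation analysis
#'
#' Validates a method menu against the chosen approach before any
#' computation: single-group methods (tags ending in `S`) require
#' `approach = "single"`, multi-group methods (tags ending in `M`) require
#' `approach = "multi"`.
#'
#' @param approach `"single"` or `"multi"`.
#' @param methods Character vector of method tags; may be empty (estimates
#'   only).
#' @param constraints Equality constraints for the multi-group fit reported
#'   in the bundle (tests and Monte Carlo draws that require the
#'   unconstrained fit always use one internally).
#' @param reference,focal Optional group labels fixing the single-group
#'   dummy coding.
#' @param level Confidence level for intervals.
#' @param B,R Bootstrap resamples and Monte Carlo draws.
#' @param seed Integer seed used for all resampling.
#' @param resampling Bootstrap scheme for the single-group approach.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(approach = c("multi", "single"),
                            methods = character(), constraints = character(),
                            reference = NULL, focal = NULL,
                            level = 0.95, B = 1000, R = 1000, seed = 1,
                            resampling = "stratified") {
  approach <- match.arg(approach)
  valid <- c(.cfg_methods_single, .cfg_methods_multi)
  bad <- setdiff(methods, valid)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  wrong <- if (approach == "single") intersect(methods, .cfg_methods_multi)
  else intersect(methods, .cfg_methods_single)
  if (length(wrong))
    stop("method(s) ", paste(wrong, collapse = ", "),
         " are incompatible with approach = \"", approach, "\"")
  if (approach == "single" && length(constraints))
    stop("constraints apply to the multi-group approach only")
  structure(list(approach = approach, methods = unique(methods),
                 constraints = sort(unique(constraints)),
                 reference = reference, focal = focal, level = level,
                 B = as.integer(B), R = as.integer(R), seed = as.integer(seed),
                 resampling = resampling),
            class = "analysis_config")
}

#' Run a configured analysis on a dataset
#'
#' Fits the model(s) for the configured approach and applies every
#' requested method. The returned bundle always contains the point
#' estimates of both simple indirect effects and of their group difference;
#' tests and interval estimates are added per method. The configuration is
#' echoed in the bundle so the analysis can be re-executed exactly.
#'
#' @param data A [mediation_data] object.
#' @param config An [analysis_config].
#' @return An object of class `report_bundle` with elements `estimates`,
#'   `fit`, `results` (one entry per method), `config` and `provenance`.
#' @export
run_analysis <- function(data, config) {
  if (!inherits(data, "mediation_data")) stop("data must be a mediation_data object")
  if (!inherits(config, "analysis_config")) stop("config must be an analysis_config")
  lev <- levels(data$group)
  results <- list()

  if (config$approach == "single") {
    coding <- if (is.null(config$reference)) group_coding(lev[1L], lev[2L])
    else group_coding(config$reference,
                      if (is.null(config$focal))
                        setdiff(lev, config$reference) else config$focal)
    fit <- fit_single_group(data, coding = coding)
    ind <- simple_indirect_effects(fit)
    fit_sum <- list(approach = "single",
                    coefficients = as.list(fit$coefficients),
                    psi_m = fit$psi_m, psi_y = fit$psi_y,
                    vcov = fit$vcov,
                    neg2loglik = fit$neg2loglik,
                    coding = list(reference = coding$reference,
                                  focal = coding$focal))
    for (m in config$methods) {
      results[[m]] <- switch(
        m,
        za3S = z_test_a3(fit),
        WdiffS = wald_product_test(fit),
        PCindS = , BCindS = , PCdiffS = , BCdiffS = {
          kind <- substr(m, 1, 2)
          targets <- if (grepl("ind", m)) lev else "difference"
          sub <- lapply(targets, function(tg) {
            ds <- bootstrap_draws(data, tg, approach = "single", B = config$B,
                                  seed = config$seed, coding = coding,
                                  resampling = config$resampling)
            if (kind == "PC") percentile_ci(ds, config$level)
            else bc_ci(ds, config$level)
          })
          names(sub) <- targets
          if (length(sub) == 1L) sub[[1L]] else sub
        })
    }
  } else {
    fit <- fit_multi_group(data, constraints = config$constraints)
    fit0 <- if (length(config$constraints) ||
                any(c("WdiffM", "MCindM", "MCdiffM") %in% config$methods))
      fit_multi_group(data) else fit
    if (length(config$constraints) == 0L) fit0 <- fit
    ind <- simple_indirect_effects(fit)
    fit_sum <- list(approach = "multi",
                    coefficients = lapply(fit$coefficients, as.list),
                    psi = lapply(fit$psi, as.list),
                    vcov = fit$vcov,
                    neg2loglik = fit$neg2loglik,
                    constraints = fit$constraints)
    base_fit_for_lr <- if (length(config$constraints)) fit else fit0
    for (m in config$methods) {
      results[[m]] <- switch(
        m,
        LRaM = lr_test(base_fit_for_lr,
                       fit_multi_group(data, union(config$constraints, "a_equal"),
                                       compute_vcov = FALSE)),
        LRdiffM = lr_test(base_fit_for_lr,
                          fit_multi_group(data,
                                          union(config$constraints, "ab_product_equal"),
                                          compute_vcov = FALSE)),
        WdiffM = wald_diff_test(fit0),
        MCindM = , MCdiffM = {
          targets <- if (m == "MCindM") lev else "difference"
          sub <- lapply(targets, function(tg)
            percentile_ci(monte_carlo_draws(fit0, tg, R = config$R,
                                            seed = config$seed), config$level))
          names(sub) <- targets
          if (length(sub) == 1L) sub[[1L]] else sub
        },
        PCindM = , BCindM = , PCdiffM = , BCdiffM = {
          kind <- substr(m, 1, 2)
          targets <- if (grepl("ind", m)) lev else "difference"
          sub <- lapply(targets, function(tg) {
            ds <- bootstrap_draws(data, tg, approach = "multi", B = config$B,
                                  seed = config$seed,
                                  constraints = config$constraints)
            if (kind == "PC") percentile_ci(ds, config$level)
            else bc_ci(ds, config$level)
          })
          names(sub) <- targets
          if (length(sub) == 1L) sub[[1L]] else sub
        })
    }
  }

  structure(list(estimates = list(simple_indirect = as.list(ind$effects),
                                  difference = ind$difference,
                                  convention = ind$convention),
                 fit = fit_sum,
                 results = results,
                 config = unclass(config),
                 provenance = list(package = "medgroup",
                                   version = as.character(packageVersion("medgroup")),
                                   seed = config$seed)),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, digits = 3, ...) {
  cat("Two-group mediation analysis (", x$config$approach, "-group approach)\n",
      sep = "")
  cat("Simple indirect effects:\n")
  for (nm in names(x$estimates$simple_indirect))
    cat("  ", nm, ": ", round(x$estimates$simple_indirect[[nm]], digits),
        "\n", sep = "")
  cat("Difference (", x$estimates$convention, "): ",
      round(x$estimates$difference, digits), "\n", sep = "")
  for (m in names(x$results)) {
    r <- x$results[[m]]
    if (inherits(r, "med_test") || inherits(r, "med_ci")) print(r, digits = digits)
    else for (rr in r) print(rr, digits = digits)
  }
  invisible(x)
}

.flatten_results <- function(bundle) {
  rows <- list()
  for (m in names(bundle$results)) {
    r <- bundle$results[[m]]
    items <- if (inherits(r, "med_test") || inherits(r, "med_ci")) list(r) else r
    for (it in items) {
      rows[[length(rows) + 1L]] <- if (inherits(it, "med_test"))
        data.frame(method = it$method, target = NA_character_,
                   statistic = it$statistic, df = ifelse(is.na(it$df), NA, it$df),
                   p_value = it$p_value, lower = NA_real_, upper = NA_real_,
                   level = NA_real_, excludes_zero = NA, stringsAsFactors = FALSE)
      else
        data.frame(method = it$method, target = it$target,
                   statistic = NA_real_, df = NA, p_value = NA_real_,
                   lower = it$lower, upper = it$upper, level = it$level,
                   excludes_zero = it$excludes_zero, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(method = character(), target = character(),
                      statistic = numeric(), df = numeric(),
                      p_value = numeric(), lower = numeric(), upper = numeric(),
                      level = numeric(), excludes_zero = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write an analysis report
#'
#' Formats a [run_analysis()] bundle as plain text (intervals printed as
#' `(lower, upper)` at 3 decimal places), as TSV (one row per method
#' result), or as JSON at full precision. The JSON form round-trips through
#' [read_report()].
#'
#' @param bundle A `report_bundle`.
#' @param path Output file path.
#' @param format `"text"`, `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(bundle, path, format = c("text", "json", "tsv")) {
  format <- match.arg(format)
  if (!inherits(bundle, "report_bundle")) stop("bundle must be a report_bundle")
  ok <- tryCatch({
    if (format == "text") {
      f3 <- function(v) formatC(round(v, 3), format = "f", digits = 3)
      lines <- c(paste0("medgroup analysis report (",
                        bundle$config$approach, "-group approach)"),
                 paste0("seed: ", bundle$provenance$seed),
                 "", "Simple indirect effects:")
      for (nm in names(bundle$estimates$simple_indirect))
        lines <- c(lines, paste0("  ", nm, ": ",
                                 f3(bundle$estimates$simple_indirect[[nm]])))
      lines <- c(lines, paste0("  difference (", bundle$estimates$convention,
                               "): ", f3(bundle$estimates$difference)), "")
      df <- .flatten_results(bundle)
      for (i in seq_len(nrow(df))) {
        if (!is.na(df$statistic[i])) {
          lines <- c(lines, paste0(df$method[i], ": statistic = ",
                                   f3(df$statistic[i]),
                                   if (!is.na(df$df[i]))
                                     paste0(", df = ", df$df[i]) else "",
                                   ", p = ", format.pval(df$p_value[i], digits = 4)))
        } else {
          lines <- c(lines, paste0(df$method[i],
                                   if (!is.na(df$target[i]))
                                     paste0(" [", df$target[i], "]") else "",
                                   ": ", format(100 * df$level[i]), "% CI = (",
                                   f3(df$lower[i]), ", ", f3(df$upper[i]), ")"))
        }
      }
      writeLines(lines, path)
    } else if (format == "tsv") {
      write.table(.flatten_results(bundle), path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    } else {
      strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
      jsonlite::write_json(strip(bundle), path, auto_unbox = TRUE,
                           digits = NA, null = "null", na = "null")
    }
    TRUE
  }, error = function(e)
    stop("failed to write report to '", path, "': ", conditionMessage(e)))
  invisible(path)
}

#' Read back a JSON analysis report
#'
#' Reconstructs a `report_bundle` written by [write_report()] with
#' `format = "json"`, restoring the result classes.
#'
#' @param path Path to a JSON report.
#' @return A `report_bundle`.
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  fix_item <- function(it) {
    it[vapply(it, is.null, TRUE)] <- NA
    cls <- if (!is.null(it$statistic)) "med_test" else "med_ci"
    if (cls == "med_test" && is.null(it$df)) it$df <- NA_integer_
    structure(it, class = cls)
  }
  raw$results <- lapply(raw$results, function(r) {
    if (!is.null(r$method)) fix_item(r) else lapply(r, fix_item)
  })
  class(raw$config) <- NULL
  structure(raw, class = "report_bundle")
}
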