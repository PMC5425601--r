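.size_patterns <- list(c(150L, 150L), c(200L, 100L), c(100L, 200L))

# run a grid of conditions and return one row per condition x method slot
.run_grid <- function(populations, sizes, methods, n_reps, seed, B, R,
                      level = 0.95, verbose = FALSE) {
  if (length(populations) == 0L || length(sizes) == 0L) {
    return(data.frame(population = character(), n_g1 = integer(),
                      n_g2 = integer(), method = character(),
                      estimand = character(), n_used = integer(),
                      rejection_rate = numeric(), mcse_rejection = numeric(),
                      coverage = numeric(), mcse_coverage = numeric(),
                      mean_width = numeric(), left_miss = integer(),
                      right_miss = integer(), lr_ratio = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  k <- 0L
  for (pop in populations) {
    for (sz in sizes) {
      k <- k + 1L
      cond <- sim_condition(pop, sz[1L], sz[2L], n_reps = n_reps,
                            seed = .rep_seed(seed, 1000003L * k),
                            methods = methods, B = B, R = R, level = level)
      if (verbose)
        cat("condition ", k, ": ", pop$name, " n = (", sz[1L], ", ", sz[2L],
            ")\n", sep = "")
      sm <- run_condition(cond, verbose = verbose)
      df <- sm$methods
      df <- cbind(data.frame(population = pop$name, n_g1 = sz[1L],
                             n_g2 = sz[2L], stringsAsFactors = FALSE), df)
      out[[k]] <- df
    }
  }
  do.call(rbind, out)
}

#' Reproduce the simulation report tables
#'
#' Runs the simulation grid underlying the standard report tables and
#' returns them in the familiar layouts, with Monte Carlo standard errors
#' appended so that reduced-replication runs carry explicit uncertainty:
#'
#' * `type1_a_path`: Type I error rates of `za3S` and `LRaM` for the group
#'   difference in the a path (structural set I populations, 3 size
#'   patterns).
#' * `type1_diff`: Type I error rates of the six methods for the group
#'   difference in the indirect effect (set I).
#' * `type1_ind`: Type I error rates for the Group 1 simple indirect effect
#'   (set II populations, where it is zero).
#' * `miss_ratio`: average left/right miss ratio of the interval methods for
#'   the simple indirect effects, by structural set and group.
#'
#' @param tables Which tables to produce (subset of the four names above).
#' @param populations Named list of [population_spec]s to use; defaults to
#'   the full [population_catalog()]. An empty list yields header-only
#'   tables.
#' @param sizes List of `c(n_g1, n_g2)` size patterns; defaults to the
#'   standard three: (150,150), (200,100), (100,200).
#' @param n_reps Replications per condition.
#' @param seed Master seed.
#' @param B,R Bootstrap resamples / Monte Carlo draws per replication.
#' @param out_dir Optional directory; each table is also written as a TSV.
#' @param verbose Progress output.
#' @return A named list of data frames.
#' @export
replicate_tables <- function(tables = c("type1_a_path", "type1_diff",
                                        "type1_ind", "miss_ratio"),
                             populations = population_catalog(),
                             sizes = .size_patterns,
                             n_reps = 1000, seed = 1, B = 1000, R = 1000,
                             out_dir = NULL, verbose = FALSE) {
  tables <- match.arg(tables, several.ok = TRUE)
  pops_of <- function(set) {
    sel <- populations[grepl(paste0("^", set, "-"), names(populations))]
    sel
  }
  res <- list()

  reshape_rates <- function(df, methods, estimand) {
    if (nrow(df) == 0L) {
      cols <- c("population", "n_g1", "n_g2",
                as.vector(rbind(methods, paste0("mcse_", methods))))
      out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
      out$population <- character(0)
      return(out)
    }
    df <- df[df$estimand == estimand & df$method %in% methods, ]
    keys <- unique(df[c("population", "n_g1", "n_g2")])
    for (m in methods) {
      i <- match(paste(keys$population, keys$n_g1, keys$n_g2),
                 paste(df$population[df$method == m], df$n_g1[df$method == m],
                       df$n_g2[df$method == m]))
      keys[[m]] <- df$rejection_rate[df$method == m][i]
      keys[[paste0("mcse_", m)]] <- df$mcse_rejection[df$method == m][i]
    }
    rownames(keys) <- NULL
    keys
  }

  if ("type1_a_path" %in% tables) {
    g <- .run_grid(pops_of("I"), sizes, c("za3S", "LRaM"), n_reps, seed, B, R,
                   verbose = verbose)
    res$type1_a_path <- reshape_rates(g, c("za3S", "LRaM"), "a_path")
  }
  if ("type1_diff" %in% tables) {
    meths <- c("WdiffS", "LRdiffM", "WdiffM", "PCdiffM", "BCdiffM", "MCdiffM")
    g <- .run_grid(pops_of("I"), sizes, meths, n_reps, seed + 1L, B, R,
                   verbose = verbose)
    res$type1_diff <- reshape_rates(g, meths, "difference")
  }
  if ("type1_ind" %in% tables) {
    meths <- c("PCindS", "BCindS", "PCindM", "BCindM", "MCindM")
    g <- .run_grid(pops_of("II"), sizes, meths, n_reps, seed + 2L, B, R,
                   verbose = verbose)
    g <- g[g$estimand == "G1", ]
    res$type1_ind <- reshape_rates(g, meths, "G1")
  }
  if ("miss_ratio" %in% tables) {
    meths <- c("PCindS", "BCindS", "PCindM", "BCindM", "MCindM")
    sets <- intersect(c("I", "II", "III"),
                      unique(sub("-.*$", "", names(populations))))
    rows <- list()
    for (set in sets) {
      g <- .run_grid(pops_of(set), sizes, meths, n_reps, seed + 3L, B, R,
                     verbose = verbose)
      if (nrow(g) == 0L) next
      for (grp in c("G1", "G2")) {
        sub <- g[g$estimand == grp, ]
        agg <- tapply(sub$lr_ratio, sub$method, mean, na.rm = TRUE)
        rows[[paste(set, grp)]] <-
          data.frame(set = set, group = grp, method = names(agg),
                     mean_lr_ratio = as.numeric(agg), stringsAsFactors = FALSE)
      }
    }
    res$miss_ratio <- if (length(rows)) do.call(rbind, rows) else
      data.frame(set = character(), group = character(), method = character(),
                 mean_lr_ratio = numeric(), stringsAsFactors = FALSE)
    rownames(res$miss_ratio) <- NULL
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(res))
      write.table(res[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
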