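#' Construct a two-group mediation dataset
#'
#' Bundles per-observation values of the independent variable, mediator and
#' outcome together with a two-level group label. All model fitting and
#' resampling in the package operates on this container.
#'
#' @param x,m,y Numeric vectors of equal length: independent variable,
#'   mediator and outcome.
#' @param group Vector of the same length with exactly two distinct values
#'   (character, factor or numeric) identifying group membership.
#' @param levels Optional length-2 vector fixing the group order; the first
#'   level plays the role of "Group 1" in multi-group output. Defaults to
#'   `sort(unique(group))`.
#' @return An object of class `mediation_data`: a list with elements `x`,
#'   `m`, `y`, `group` (a two-level factor), `n_total` and `n_per_group`.
#' @examples
#' d <- mediation_data(x = rnorm(20), m = rnorm(20), y = rnorm(20),
#'                     group = rep(c("G1", "G2"), each = 10))
#' d$n_per_group
#' @export
mediation_data <- function(x, m, y, group, levels = NULL) {
  x <- as.numeric(x); m <- as.numeric(m); y <- as.numeric(y)
  n <- length(x)
  if (n < 1L || length(m) != n || length(y) != n || length(group) != n)
    stop("x, m, y and group must have equal length >= 1")
  if (anyNA(x) || anyNA(m) || anyNA(y) || anyNA(group))
    stop("missing values are not allowed; remove or reject incomplete rows first")
  lev <- if (is.null(levels)) sort(unique(as.character(group))) else as.character(levels)
  if (length(lev) != 2L || anyDuplicated(lev))
    stop("exactly two distinct group labels are required, got: ",
         paste(unique(as.character(group)), collapse = ", "))
  g <- factor(as.character(group), levels = lev)
  if (anyNA(g)) stop("group contains labels not in 'levels'")
  npg <- table(g)
  if (any(npg == 0L)) stop("both group levels must be present in the data")
  structure(list(x = x, m = m, y = y, group = g,
                 n_total = n,
                 n_per_group = setNames(as.integer(npg), lev)),
            class = "mediation_data")
}

#' @export
print.mediation_data <- function(x, ...) {
  cat("Two-group mediation dataset: n =", x$n_total, "(",
      paste(names(x$n_per_group), "=", x$n_per_group, collapse = ", "), ")\n")
  invisible(x)
}

#' Group coding for the single-group parameterization
#'
#' Fixes which group label is coded 0 (reference) and which is coded 1
#' (focal) in the single-group dummy/interaction model. The interaction
#' coefficient a3 is then the focal-minus-reference difference in the X to M
#' path, and results are always reported per group label, never per numeric
#' code.
#'
#' @param reference Label coded 0.
#' @param focal Label coded 1.
#' @return An object of class `group_coding`.
#' @export
group_coding <- function(reference, focal) {
  reference <- as.character(reference); focal <- as.character(focal)
  if (identical(reference, focal)) stop("reference and focal labels must differ")
  structure(list(reference = reference, focal = focal), class = "group_coding")
}

#' @export
print.group_coding <- function(x, ...) {
  cat("Group coding: 0 =", x$reference, ", 1 =", x$focal, "\n")
  invisible(x)
}

#' Read a mediation dataset from a delimited text file
#'
#' Reads a CSV or TSV file with a header row, maps the named columns onto
#' the (x, m, y, group) roles, rejects rows with missing values in the
#' mapped columns (with a warning reporting the count), and validates the
#' result.
#'
#' @param path Path to a delimited text file with a header row. Files ending
#'   in `.tsv` or `.txt` are read as tab-separated, anything else as
#'   comma-separated; override with `sep`.
#' @param mapping Named character vector giving the file's column names for
#'   the roles `x`, `m`, `y` and `group`.
#' @param sep Optional field separator overriding the extension heuristic.
#' @param levels Optional group level order passed to [mediation_data()].
#' @return A [mediation_data] object. The number of dropped incomplete rows
#'   is attached as attribute `"n_dropped"`.
#' @export
load_dataset <- function(path,
                         mapping = c(x = "x", m = "m", y = "y", group = "group"),
                         sep = NULL, levels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  roles <- c("x", "m", "y", "group")
  if (!all(roles %in% names(mapping)))
    stop("mapping must name columns for: ", paste(roles, collapse = ", "))
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(mapping[roles]), names(df))
  if (length(missing_cols))
    stop("column(s) not found in ", path, ": ", paste(missing_cols, collapse = ", "))
  sub <- df[, unname(mapping[roles])]
  names(sub) <- roles
  for (v in c("x", "m", "y")) {
    raw <- sub[[v]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & trimws(as.character(raw)) != "")
    if (length(bad))
      stop("non-numeric value in column '", mapping[[v]], "' (", v,
           ") at data row ", bad[1L], ": '", raw[bad[1L]], "'")
    sub[[v]] <- num
  }
  sub$group[!is.na(sub$group) & trimws(as.character(sub$group)) == ""] <- NA
  keep <- complete.cases(sub)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    warning("dropped ", n_dropped, " row(s) with missing values in mapped columns")
  sub <- sub[keep, ]
  if (nrow(sub) == 0L) stop("no complete rows left after rejecting missing values")
  if (length(unique(as.character(sub$group))) < 2L)
    stop("group column '", mapping[["group"]], "' has fewer than two levels")
  out <- mediation_data(sub$x, sub$m, sub$y, sub$group, levels = levels)
  attr(out, "n_dropped") <- n_dropped
  out
}
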