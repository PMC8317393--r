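# Regression of per-gene retention counts on gene properties (length, GC,
# GRAVY, dN, dS).

#' Per-gene retention counts from a state matrix
#'
#' Number of species in which each gene is still mitochondrion-encoded
#' (state M).
#'
#' @param states Species-by-gene state matrix.
#' @return Named integer vector over genes, values in `[0, n_species]`.
#' @export
retention_counts <- function(states) {
  validate_state_matrix(states)
  counts <- colSums(states == "M")
  storage.mode(counts) <- "integer"
  counts
}

#' Regress retention counts on a gene property
#'
#' Simple ordinary least squares of per-gene retention counts on one
#' predictor, reporting Pearson's r, the coefficient of determination
#' (`r_squared = r^2` for the simple fit), slope, intercept and n.  No
#' multiple-testing adjustment is applied (each predictor is reported on
#' its own); use [fit_retention_all()] to fit several predictors and get a
#' collinearity caveat.
#'
#' @param counts Named integer vector from [retention_counts()], or a data
#'   frame with `gene_id` and `count`.
#' @param properties Data frame with `gene_id` plus predictor columns.
#' @param predictor Name of the predictor column.
#' @return Object of class `retention_fit`: `predictor`, `pearson_r`,
#'   `r_squared`, `slope`, `intercept`, `n`.
#' @export
fit_retention <- function(counts, properties, predictor) {
  if (is.data.frame(counts))
    counts <- stats::setNames(counts$count, counts$gene_id)
  stopifnot("gene_id" %in% names(properties),
            predictor %in% names(properties))
  x <- properties[[predictor]]
  y <- counts[properties$gene_id]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L)
    stop("need at least 3 genes with both retention count and '",
         predictor, "' (got ", n, ")")
  if (stats::var(x) == 0)
    stop("predictor '", predictor, "' has zero variance")
  fit <- stats::lm(y ~ x)
  r <- if (stats::var(y) == 0) 0 else stats::cor(x, y)
  structure(list(predictor = predictor, pearson_r = r,
                 r_squared = r^2, slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]), n = n),
            class = "retention_fit")
}

#' @export
print.retention_fit <- function(x, ...) {
  cat(sprintf(
    "retention ~ %s: r = %.4f, R^2 = %.4f, slope = %.4g, n = %d\n",
    x$predictor, x$pearson_r, x$r_squared, x$slope, x$n))
  invisible(x)
}

#' Fit retention against several predictors
#'
#' Runs [fit_retention()] per predictor (predictors failing their
#' preconditions are skipped with a note) and messages a caveat when
#' predictors are mutually correlated (|r| > 0.7), since simple per-
#' predictor OLS cannot separate their contributions.
#'
#' @param counts See [fit_retention()].
#' @param properties Data frame with `gene_id` plus predictor columns.
#' @param predictors Predictor column names (default: all numeric
#'   columns).
#' @return Data frame with one row per fitted predictor.
#' @export
fit_retention_all <- function(counts, properties, predictors = NULL) {
  if (is.null(predictors))
    predictors <- setdiff(names(properties)[vapply(properties, is.numeric,
                                                   logical(1L))],
                          "gene_id")
  fits <- list()
  for (p in predictors) {
    f <- tryCatch(fit_retention(counts, properties, p),
                  error = function(e) {
                    message("skipping predictor '", p, "': ",
                            conditionMessage(e))
                    NULL
                  })
    if (!is.null(f))
      fits[[p]] <- data.frame(predictor = f$predictor,
                              pearson_r = f$pearson_r,
                              r_squared = f$r_squared, slope = f$slope,
                              intercept = f$intercept, n = f$n,
                              stringsAsFactors = FALSE)
  }
  fitted <- names(fits)
  if (length(fitted) > 1L) {
    pm <- as.matrix(properties[, fitted, drop = FALSE])
    cc <- suppressWarnings(stats::cor(pm, use = "pairwise.complete.obs"))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 0
    if (any(abs(cc) > 0.7))
      message("note: predictors are mutually correlated (|r| > 0.7); ",
              "per-predictor fits overlap")
  }
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  out
}
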