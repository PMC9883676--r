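# Accuracy metrics for simulation studies: absolute proportion error and
# parameter-recovery summaries.

#' Absolute proportion error
#'
#' `ape(E, T) = |E - T| / (T + 1)`: the absolute error of an expression
#' estimate relative to the truth, damped by +1 so that lowly expressed
#' transcripts do not dominate.
#'
#' @param E estimated expression (vector or matrix).
#' @param truth true expression, non-negative, same shape (or recyclable).
#' @return elementwise APE, zero iff `E == truth`.
#' @export
ape <- function(E, truth) {
  if (any(truth < 0)) stop_config("true expression must be non-negative")
  abs(E - truth) / (truth + 1)
}

#' Per-isoform median APE across samples
#'
#' @param estimates matrix isoforms x samples of estimated expression.
#' @param truths matrix of the same shape (or a per-isoform vector recycled
#'   across samples) of true expression.  For merged paralog groups the truth
#'   row must already be the sum of the member truths (see
#'   [aggregate_truth()]).
#' @return named numeric vector: median over samples of the APE, per isoform.
#' @export
median_ape <- function(estimates, truths) {
  estimates <- as.matrix(estimates)
  if (ncol(estimates) == 0L) stop_config("no samples to take the median over")
  if (is.vector(truths)) {
    truths <- matrix(truths, nrow(estimates), ncol(estimates))
  }
  stopifnot(all(dim(estimates) == dim(truths)))
  e <- ape(estimates, truths)
  stats::setNames(apply(e, 1L, stats::median), rownames(estimates))
}

#' Aggregate true abundances onto merged paralog groups
#'
#' Rows of the truth matrix are summed over the member transcripts of each
#' (possibly merged, `"a+b"`-named) output unit.
#'
#' @param beta_true matrix transcripts x samples with row names.
#' @param units character vector of output unit names, members joined by
#'   `"+"` (e.g. `colnames` of a merged design matrix or `rownames` of an
#'   estimate matrix).
#' @return matrix `length(units)` x samples.
#' @export
aggregate_truth <- function(beta_true, units) {
  beta_true <- as.matrix(beta_true)
  out <- t(vapply(strsplit(units, "+", fixed = TRUE), function(members) {
    miss <- setdiff(members, rownames(beta_true))
    if (length(miss)) stop_config("truth has no row(s) %s",
                                  paste(miss, collapse = ","))
    colSums(beta_true[members, , drop = FALSE])
  }, numeric(ncol(beta_true))))
  dimnames(out) <- list(units, colnames(beta_true))
  out
}

#' Categorize output units of a set of design matrices
#'
#' Mirrors the standard three-way grouping of isoforms: `singleton` (alone in
#' its transcription cluster), `paralog` (a merged group), and `multi`
#' (member of a multi-transcript cluster, not merged).
#'
#' @param designs list of `design_matrix` objects (one per cluster).
#' @return named character vector, unit name -> category.
#' @export
design_categories <- function(designs) {
  out <- character(0)
  for (X in designs) {
    cats <- if (ncol(X) == 1L && length(attr(X, "pattern_transcripts")) == 1L) {
      "singleton"
    } else {
      ifelse(grepl("+", colnames(X), fixed = TRUE), "paralog", "multi")
    }
    out <- c(out, stats::setNames(rep(cats, length.out = ncol(X)),
                                  colnames(X)))
  }
  out
}

#' Parameter-recovery summary
#'
#' Per category of output unit, reports the median of the per-unit median
#' APEs, and Pearson/Spearman correlations between all estimated and true
#' values; optionally the Frobenius error of the recovered design matrix.
#'
#' @param beta_hat estimated expression matrix (units x samples).
#' @param beta_true true expression with original transcript row names;
#'   merged-group truths are aggregated automatically.
#' @param X_hat,X_true optional recovered and true design matrices of equal
#'   shape.
#' @param categories optional named vector from [design_categories()]; units
#'   without a category are reported as `"all"`.
#' @return `data.frame` with columns `category`, `n`, `median_ape`,
#'   `pearson`, `spearman`; if `X_hat`/`X_true` are given, an attribute
#'   `x_frobenius` holds `sqrt(sum((X_hat - X_true)^2))`.
#' @export
recovery_report <- function(beta_hat, beta_true, X_hat = NULL, X_true = NULL,
                            categories = NULL) {
  beta_hat <- as.matrix(beta_hat)
  truth <- aggregate_truth(beta_true, rownames(beta_hat))
  cat_of <- if (is.null(categories)) {
    stats::setNames(rep("all", nrow(beta_hat)), rownames(beta_hat))
  } else {
    categories
  }
  m_ape <- median_ape(beta_hat, truth)
  rows <- lapply(unique(cat_of[rownames(beta_hat)]), function(cc) {
    ids <- rownames(beta_hat)[cat_of[rownames(beta_hat)] == cc]
    if (!length(ids)) return(NULL)
    e <- as.numeric(beta_hat[ids, , drop = FALSE])
    t_ <- as.numeric(truth[ids, , drop = FALSE])
    data.frame(category = cc, n = length(ids),
               median_ape = stats::median(m_ape[ids]),
               pearson = if (stats::sd(e) > 0 && stats::sd(t_) > 0)
                 stats::cor(e, t_) else NA_real_,
               spearman = if (stats::sd(e) > 0 && stats::sd(t_) > 0)
                 stats::cor(e, t_, method = "spearman") else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (!is.null(X_hat) && !is.null(X_true)) {
    attr(out, "x_frobenius") <- sqrt(sum((unclass(X_hat) - unclass(X_true))^2))
  }
  out
}
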