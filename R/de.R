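# Two-group differential expression and rediscovery-rate validation.

#' CPM / log2 / median normalization of a count matrix
#'
#' Counts are standardized to counts-per-million within each sample,
#' transformed as `log2(CPM + 1)`, and (by default) centered by subtracting
#' each sample's median over the isoforms with nonzero counts.
#'
#' @param counts isoform x sample matrix of non-negative counts.
#' @param center subtract the per-sample median of nonzero log-CPM values.
#' @return normalized matrix; samples with a zero library size are dropped
#'   with a warning.
#' @export
cpm_log_mediannorm <- function(counts, center = TRUE) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    warning(sprintf("dropping sample(s) with zero library size: %s",
                    paste(colnames(counts)[lib == 0], collapse = ",")))
    counts <- counts[, lib > 0, drop = FALSE]
    lib <- lib[lib > 0]
  }
  cpm <- sweep(counts, 2L, lib, "/") * 1e6
  v <- log2(cpm + 1)
  if (center) {
    med <- vapply(seq_len(ncol(v)), function(n) {
      nz <- counts[, n] > 0
      if (any(nz)) stats::median(v[nz, n]) else 0
    }, 0)
    v <- sweep(v, 2L, med, "-")
  }
  v
}

#' Row-wise two-group Welch t-tests
#'
#' Two-sided Welch (unequal-variance) t-test per isoform between the two
#' groups.  Isoforms with zero variance in both groups get `p = 1` and a
#' t statistic of 0.
#'
#' @param normalized matrix isoforms x samples (e.g. from
#'   [cpm_log_mediannorm()]).
#' @param groups factor (or coercible) of length `ncol(normalized)` with
#'   exactly two levels, each with at least two samples.
#' @return object of class `de_result`: a `data.frame` with columns `id`,
#'   `pvalue`, `direction` (sign of mean of level 2 minus level 1) and
#'   `mean_diff`.
#' @export
ttest_pvalues <- function(normalized, groups) {
  normalized <- as.matrix(normalized)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop_config("groups must have exactly 2 levels")
  n1 <- sum(groups == levels(groups)[1L])
  n2 <- sum(groups == levels(groups)[2L])
  if (n1 < 2L || n2 < 2L) {
    stop_config("each group needs >= 2 samples (got %d and %d)", n1, n2)
  }
  x1 <- normalized[, groups == levels(groups)[1L], drop = FALSE]
  x2 <- normalized[, groups == levels(groups)[2L], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  flat <- se2 == 0
  tstat <- ifelse(flat, 0, (m2 - m1) / sqrt(ifelse(flat, 1, se2)))
  df <- ifelse(flat, 1,
               se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L)))
  p <- ifelse(flat, 1, 2 * stats::pt(-abs(tstat), df))
  ids <- rownames(normalized) %||% as.character(seq_len(nrow(normalized)))
  structure(data.frame(id = ids, pvalue = p, direction = sign(m2 - m1),
                       mean_diff = m2 - m1, stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("de_result", "data.frame"))
}

#' Rediscovery rate of top differentially expressed isoforms
#'
#' Takes the top `M` training-set isoforms that are significant at `alpha`
#' (ascending p-value, ties broken by id) and reports the fraction that are
#' also significant at `alpha` in the validation set (optionally requiring
#' the same direction of change).
#'
#' @param train,valid `de_result` objects over a shared isoform universe.
#' @param M number of top training isoforms; truncated (with a message) if
#'   fewer are significant.
#' @param alpha significance threshold on the raw p-value.
#' @param require_direction additionally require matching sign of change.
#' @param exclude optional ids to drop (e.g. merged paralog groups).
#' @return object of class `rdr_result`: list with `M`, `rediscovered`,
#'   `rdr` and the vector of top training ids.
#' @export
rdr <- function(train, valid, M = 100L, alpha = 0.05,
                require_direction = FALSE, exclude = NULL) {
  if (!is.null(exclude)) {
    train <- train[!train$id %in% exclude, ]
    valid <- valid[!valid$id %in% exclude, ]
  }
  shared <- intersect(train$id, valid$id)
  if (length(shared) == 0L) stop_config("train and valid share no isoforms")
  train <- train[train$id %in% shared, ]
  sig <- train[train$pvalue < alpha, ]
  sig <- sig[order(sig$pvalue, sig$id), ]
  if (nrow(sig) < M) {
    message(sprintf("rdr: only %d significant training isoforms; M truncated from %d",
                    nrow(sig), M))
    M <- nrow(sig)
  }
  top <- utils::head(sig, M)
  vi <- match(top$id, valid$id)
  hit <- valid$pvalue[vi] < alpha
  if (require_direction) {
    hit <- hit & valid$direction[vi] == top$direction
  }
  structure(list(M = M, rediscovered = sum(hit),
                 rdr = if (M > 0) sum(hit) / M else NA_real_,
                 top_ids = top$id),
            class = "rdr_result")
}

#' @export
print.rdr_result <- function(x, ...) {
  cat(sprintf("RDR: %d / %d top training isoforms rediscovered (%.3f)\n",
              x$rediscovered, x$M, x$rdr))
  invisible(x)
}
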