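# Alternating EM estimation of the bilinear model mu = X beta: a variational
# Bayes EM update of beta (digamma-weighted read allocation) alternating with
# an empirical re-estimation of X pooled across samples.

#' Initialize the abundance matrix
#'
#' The prior offset `beta0` is the mean read count per transcript per sample,
#' `sum(Y) / (T * N)`; every `beta[t, n]` starts at `beta0`, independent of
#' the pattern structure.
#'
#' @param Y count matrix (patterns x samples) matched to `X`'s rows.
#' @param X design matrix (patterns x transcripts).
#' @return list with `beta` (transcripts x samples) and scalar `beta0`.
#' @export
init_beta <- function(Y, X) {
  Y <- as.matrix(Y)
  beta0 <- sum(Y) / (ncol(X) * ncol(Y))
  if (beta0 == 0) {
    warning("all-zero count matrix; beta0 set to 1")
    beta0 <- 1
  }
  beta <- matrix(beta0, ncol(X), ncol(Y),
                 dimnames = list(colnames(X),
                                 colnames(Y) %||% paste0("s", seq_len(ncol(Y)))))
  list(beta = beta, beta0 = beta0)
}

#' One variational-Bayes EM update of the abundances
#'
#' Per sample, each pattern's reads are allocated to its member transcripts
#' with weights `w[j, t] = x[j, t] * exp(l[j, t])` where
#' `l[j, t] = digamma(beta0 + beta[t]) - digamma(sum_{t' in j}(beta0 +
#' beta[t']))`, and the updated abundance is
#' `beta[t] <- beta0 + sum_j y[j] * w[j, t] / sum_{t' in j} w[j, t']`.
#' With `literal_eq7 = TRUE` the design-matrix factor `x[j, t]` is dropped
#' from the weight and only pattern membership is used, reproducing the bare
#' digamma allocation; the default keeps the factor, as required for the
#' allocation to honour the model `mu = X beta`.
#'
#' @param Y count matrix (patterns x samples).
#' @param X design matrix (patterns x transcripts).
#' @param beta abundance matrix from the previous iterate (transcripts x
#'   samples), non-negative.
#' @param beta0 scalar prior offset.
#' @param literal_eq7 drop the `x[j, t]` factor from the allocation weight.
#' @return updated abundance matrix; patterns whose weights are all zero
#'   leave their reads unallocated (a message is emitted once).  The
#'   allocated read counts (`beta - beta0`, computed without round-off) are
#'   attached as attribute `"allocated"`.
#' @export
beta_update <- function(Y, X, beta, beta0, literal_eq7 = FALSE) {
  Y <- as.matrix(Y)
  Xm <- unclass(X)
  J <- nrow(Xm)
  stopifnot(nrow(Y) == J, nrow(beta) == ncol(Xm), all(beta >= 0))
  Wbase <- if (literal_eq7) (Xm > 0) * 1 else Xm
  out <- beta
  allocated <- beta * 0
  dropped <- 0
  for (n in seq_len(ncol(Y))) {
    g <- exp(digamma(beta0 + beta[, n]) -
               max(digamma(beta0 + beta[, n])))  # rescaled for stability
    W <- Wbase * rep(g, each = J)
    S <- rowSums(W)
    ok <- S > 0
    dropped <- dropped + sum(Y[!ok, n])
    alloc <- (ifelse(ok, Y[, n] / ifelse(ok, S, 1), 0)) * W
    allocated[, n] <- colSums(alloc)
    out[, n] <- beta0 + allocated[, n]
  }
  if (dropped > 0) {
    message(sprintf("beta_update: %g reads in zero-weight patterns left unallocated",
                    dropped))
  }
  attr(out, "allocated") <- allocated
  out
}

#' Re-estimate the design matrix from allocated read proportions
#'
#' Allocates each observed count to transcripts in proportion to
#' `x[j, t] * beta[t, n]`, pools the allocations over all samples, and
#' renormalizes each transcript's column to sum to 1.  Structural zeros of
#' `X_prev` are preserved; a transcript receiving no reads at all keeps its
#' previous column (a message is emitted).
#'
#' @param Y count matrix (patterns x samples).
#' @param X_prev current design matrix.
#' @param beta non-negative per-sample allocation weights (transcripts x
#'   samples); [aem_fit()] passes the fitted read counts of the preceding
#'   [beta_update()], so that the prior offset does not enter the
#'   allocation a second time.
#' @return updated `design_matrix` with unit column sums.
#' @export
x_update <- function(Y, X_prev, beta) {
  Y <- as.matrix(Y)
  Xm <- unclass(X_prev)
  J <- nrow(Xm)
  if (nrow(Y) != J || nrow(beta) != ncol(Xm) || ncol(Y) != ncol(beta)) {
    stop_config("dimension mismatch between Y (%dx%d), X (%dx%d) and beta (%dx%d)",
                nrow(Y), ncol(Y), J, ncol(Xm), nrow(beta), ncol(beta))
  }
  A <- matrix(0, J, ncol(Xm), dimnames = dimnames(Xm))
  for (n in seq_len(ncol(Y))) {
    M <- Xm * rep(beta[, n], each = J)
    mu <- rowSums(M)
    w <- ifelse(mu > 0, Y[, n] / ifelse(mu > 0, mu, 1), 0)
    A <- A + M * w
  }
  tot <- colSums(A)
  empty <- tot == 0
  if (any(empty)) {
    message(sprintf("x_update: column(s) %s received no reads; kept previous values",
                    paste(colnames(Xm)[empty], collapse = ",")))
    A[, empty] <- Xm[, empty]
    tot[empty] <- colSums(Xm)[empty]
  }
  keep_design_attrs(sweep(A, 2L, tot, "/"), X_prev)
}

#' Elementwise convergence test on successive iterates
#'
#' An element has converged when its relative change is below `rel_tol`,
#' except that elements smaller in magnitude than `abs_floor_value` use the
#' absolute threshold `abs_floor_tol` instead (1% of the floor by default).
#'
#' @param prev,next_ numeric vectors/matrices (or lists of them) holding the
#'   previous and next iterates of all monitored quantities.
#' @param rel_tol relative tolerance (default 1% change).
#' @param abs_floor_value magnitude below which the absolute rule applies.
#' @param abs_floor_tol absolute tolerance for small elements.
#' @return `TRUE` iff every element satisfies its criterion.
#' @export
converged <- function(prev, next_, rel_tol = 0.01, abs_floor_value = 0.01,
                      abs_floor_tol = 1e-4) {
  p <- unlist(lapply(if (is.list(prev)) prev else list(prev), as.numeric))
  q <- unlist(lapply(if (is.list(next_)) next_ else list(next_), as.numeric))
  stopifnot(length(p) == length(q))
  big <- abs(p) >= abs_floor_value
  d <- abs(q - p)
  all(ifelse(big, d / abs(p) < rel_tol, d < abs_floor_tol))
}

poisson_deviance <- function(y, mu) {
  term <- ifelse(y > 0, y * log(y / pmax(mu, .Machine$double.xmin)), 0)
  2 * sum(term - (y - mu))
}

#' Fit the bilinear model by alternating EM
#'
#' Alternates the variational-Bayes abundance update ([beta_update()]) with
#' the empirical design-matrix update ([x_update()]) until every element of
#' both X and beta changes by less than the convergence criterion, or
#' `max_iter` is reached.  With `update_X = FALSE` the design matrix is held
#' fixed, reproducing the conventional fixed-X estimator (no empirical bias
#' correction).
#'
#' @param Y count matrix (patterns x samples) matched to the rows of `X0`.
#' @param X0 starting design matrix (paralog-merged).
#' @param max_iter maximum number of outer iterations.
#' @param rel_tol,abs_floor_value,abs_floor_tol convergence parameters, see
#'   [converged()].
#' @param update_X update X at each iteration (the full AEM), or keep it
#'   fixed.
#' @param literal_eq7 passed to [beta_update()].
#' @param beta0 optional prior offset; defaults to the [init_beta()] value.
#' @return object of class `aem_fit`: list with the final `X`, `beta`
#'   (raw, including the `beta0` offset), `counts = beta - beta0` (estimated
#'   read counts, the reported expression), `beta0`, and `diagnostics`
#'   (iterations, convergence flag, per-iteration max deltas and Poisson
#'   deviance trace).
#' @export
aem_fit <- function(Y, X0, max_iter = 100L, rel_tol = 0.01,
                    abs_floor_value = 0.01, abs_floor_tol = 1e-4,
                    update_X = TRUE, literal_eq7 = FALSE, beta0 = NULL) {
  Y <- as.matrix(Y)
  init <- init_beta(Y, X0)
  if (is.null(beta0)) beta0 <- init$beta0
  beta <- matrix(beta0, nrow(init$beta), ncol(init$beta),
                 dimnames = dimnames(init$beta))
  X <- X0
  counts <- beta * 0
  delta_beta <- delta_x <- deviance <- numeric(0)
  conv <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    beta_new <- beta_update(Y, X, beta, beta0, literal_eq7 = literal_eq7)
    counts <- attr(beta_new, "allocated")
    attr(beta_new, "allocated") <- NULL
    # X is re-estimated from the allocated read counts (beta - beta0): the
    # observed reads are what the proportions in step B standardize, and the
    # prior offset must not enter the allocation a second time
    X_new <- if (update_X) x_update(Y, X, counts) else X
    delta_beta <- c(delta_beta, max(abs(beta_new - beta)))
    delta_x <- c(delta_x, max(abs(unclass(X_new) - unclass(X))))
    deviance <- c(deviance, poisson_deviance(Y, unclass(X_new) %*% counts))
    done <- converged(list(unclass(X), beta), list(unclass(X_new), beta_new),
                      rel_tol, abs_floor_value, abs_floor_tol)
    beta <- beta_new
    X <- X_new
    if (done) { conv <- TRUE; break }
  }
  if (!conv) {
    warning(sprintf("AEM did not converge within %d iterations", max_iter))
  }
  structure(list(X = X, beta = beta, counts = counts, beta0 = beta0,
                 diagnostics = list(iterations = iter, converged = conv,
                                    max_delta_beta = delta_beta,
                                    max_delta_x = delta_x,
                                    deviance = deviance,
                                    update_X = update_X,
                                    literal_eq7 = literal_eq7)),
            class = "aem_fit")
}

#' @export
print.aem_fit <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("AEM fit: %d transcripts x %d samples, %d iterations (%s), beta0 = %.3f\n",
              nrow(x$beta), ncol(x$beta), d$iterations,
              if (d$converged) "converged" else "not converged", x$beta0))
  invisible(x)
}

#' Match per-sample equivalence-class counts to a design matrix
#'
#' Builds the Y matrix whose rows are the patterns of `X` (matched by
#' transcript-set identity, not by row order or pattern string) and whose
#' columns are the samples.  Observed classes involving none of `X`'s
#' transcripts are silently ignored (they belong to other clusters); classes
#' that touch the cluster but match no pattern are dropped with a message.
#' Patterns of `X` never observed get zero counts.
#'
#' @param X a `design_matrix`.
#' @param samples list of [eqclass_counts()], one per sample (names used as
#'   column names).
#' @return integer-valued matrix (patterns x samples).
#' @export
match_counts <- function(X, samples) {
  keys <- vapply(design_row_sets(X), ec_key, "")
  universe <- attr(X, "pattern_transcripts") %||% colnames(X)
  Y <- matrix(0, nrow(X), length(samples),
              dimnames = list(rownames(X),
                              names(samples) %||%
                                paste0("s", seq_along(samples))))
  unmatched <- character(0)
  for (n in seq_along(samples)) {
    ec <- samples[[n]]
    hit <- match(ec$keys, keys)
    relevant <- vapply(ec$classes, function(m) any(m %in% universe), NA)
    if (any(is.na(hit) & relevant)) {
      unmatched <- union(unmatched, ec$keys[is.na(hit) & relevant])
    }
    ok <- !is.na(hit)
    Y[hit[ok], n] <- Y[hit[ok], n] + ec$counts[ok]
  }
  if (length(unmatched)) {
    message(sprintf("match_counts: %d observed class(es) not in the design matrix dropped",
                    length(unmatched)))
  }
  Y
}
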