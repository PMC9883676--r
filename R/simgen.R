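# Toy transcriptome simulation, read generation and the exact-substring
# mapper used both to build transcript response profiles and to create
# multi-sample synthetic experiments.

#' Read-simulation configuration
#'
#' Bundles the parameters of the uniform read generator.  The number of reads
#' simulated from a transcript of length `len` is
#' `max(reads_factor * len, min_reads)` unless overridden per call.
#'
#' @param read_length read length in bases.
#' @param base_error_rate per-base probability of a substitution error; each
#'   erroneous base is replaced by one of the other three nucleotides chosen
#'   uniformly.
#' @param fragment_mean,fragment_sd mean and standard deviation (bases) of the
#'   fragment-length distribution used when `paired = TRUE`.
#' @param paired if `TRUE`, read start positions are obtained by sampling a
#'   fragment first; reads themselves are always single-end sequences for
#'   mapping purposes.
#' @param reads_factor,min_reads the per-transcript read-count rule
#'   `max(reads_factor * length, min_reads)`.
#' @return an object of class `sim_config` (a list).
#' @export
sim_config <- function(read_length = 100L, base_error_rate = 0.005,
                       fragment_mean = 250, fragment_sd = 25,
                       paired = FALSE, reads_factor = 2, min_reads = 1000L) {
  if (base_error_rate < 0 || base_error_rate >= 1) {
    stop_config("base_error_rate must lie in [0, 1), got %g", base_error_rate)
  }
  if (read_length < 1) stop_config("read_length must be positive")
  structure(list(read_length = as.integer(read_length),
                 base_error_rate = base_error_rate,
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 paired = isTRUE(paired), reads_factor = reads_factor,
                 min_reads = as.integer(min_reads)),
            class = "sim_config")
}

#' Number of reads simulated for a transcript
#'
#' @param len transcript length in bases.
#' @param config a [sim_config()].
#' @return integer read count, `max(reads_factor * len, min_reads)`.
#' @export
n_reads_rule <- function(len, config = sim_config()) {
  as.integer(pmax(config$reads_factor * len, config$min_reads))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a toy transcriptome with exon-sharing structure
#'
#' Each gene owns one shared sequence block common to all of its isoforms and
#' one unique block per isoform; an isoform's sequence is the shared block
#' followed by its unique block.  Reads falling entirely inside the shared
#' block therefore map to every isoform of the gene (a shared equivalence
#' class) while reads touching a unique block map to a single isoform.
#' Distinct genes receive independently generated blocks and share no
#' sequence.  With `unique_block_len = 0` the isoforms of a gene are exact
#' paralogs (identical sequences).
#'
#' @param n_genes number of genes.
#' @param isoforms_per_gene isoforms per gene.
#' @param shared_block_len length of the per-gene shared block (bases); must
#'   be at least `read_length`.
#' @param unique_block_len length of the per-isoform unique block; either 0
#'   (exact paralogs) or at least `read_length`.
#' @param seed integer seed; generation is deterministic under it.
#' @param read_length read length the transcriptome must support.
#' @return a `data.frame` with columns `id`, `gene_id`, `sequence`.
#' @export
make_toy_transcriptome <- function(n_genes, isoforms_per_gene = 1L,
                                   shared_block_len = 200L,
                                   unique_block_len = 200L,
                                   seed = 1L, read_length = 100L) {
  if (shared_block_len < read_length) {
    stop_config("shared_block_len (%d) < read_length (%d)",
                shared_block_len, read_length)
  }
  if (unique_block_len != 0 && unique_block_len < read_length) {
    stop_config("unique_block_len (%d) must be 0 or >= read_length (%d)",
                unique_block_len, read_length)
  }
  gw <- nchar(as.character(n_genes))
  iw <- nchar(as.character(isoforms_per_gene))
  with_seed(seed, {
    n_blocks <- n_genes * (1L + (unique_block_len > 0) * isoforms_per_gene)
    # draw all blocks, redrawing any exact duplicates so genes never share one
    draw <- function(k, len) vapply(seq_len(k), function(i) random_dna(len), "")
    shared <- draw(n_genes, shared_block_len)
    for (r in 1:100) {
      dup <- duplicated(shared)
      if (!any(dup)) break
      shared[dup] <- draw(sum(dup), shared_block_len)
    }
    uniq <- if (unique_block_len > 0) {
      u <- draw(n_genes * isoforms_per_gene, unique_block_len)
      for (r in 1:100) {
        dup <- duplicated(u)
        if (!any(dup)) break
        u[dup] <- draw(sum(dup), unique_block_len)
      }
      matrix(u, nrow = n_genes, byrow = TRUE)
    }
    rows <- vector("list", n_genes * isoforms_per_gene)
    k <- 0L
    for (g in seq_len(n_genes)) {
      gene_id <- sprintf("g%0*d", gw, g)
      for (j in seq_len(isoforms_per_gene)) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          id = sprintf("%st%0*d", gene_id, iw, j),
          gene_id = gene_id,
          sequence = paste0(shared[g],
                            if (unique_block_len > 0) uniq[g, j] else ""),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate uniform reads from a transcript
#'
#' Start positions are uniform over the valid positions of the transcript
#' (or over valid fragment placements when `config$paired` is set, in which
#' case the read is the 5' `read_length` bases of the fragment).  Each base is
#' substituted with probability `config$base_error_rate` by one of the other
#' three nucleotides, uniformly.
#'
#' @param transcript a transcriptome row (list with `$sequence`) or a plain
#'   nucleotide string.
#' @param config a [sim_config()].
#' @param n_reads number of reads; defaults to the [n_reads_rule()] value.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return character vector of read sequences (length 0, with a warning, if
#'   the transcript is shorter than the read length).
#' @export
simulate_reads <- function(transcript, config = sim_config(), n_reads = NULL,
                           seed = NULL) {
  seq <- if (is.character(transcript)) transcript else transcript$sequence
  stopifnot(is.character(seq), length(seq) == 1L)
  len <- nchar(seq)
  rl <- config$read_length
  if (len < rl) {
    warning(sprintf("transcript of length %d shorter than read length %d; skipped",
                    len, rl))
    return(character(0))
  }
  if (is.null(n_reads)) n_reads <- n_reads_rule(len, config)
  n_reads <- as.integer(round(n_reads))
  stopifnot(length(n_reads) == 1L, !is.na(n_reads), n_reads >= 0L)
  if (n_reads == 0L) return(character(0))
  with_seed(seed, {
    if (config$paired) {
      frag <- round(stats::rnorm(n_reads, config$fragment_mean,
                                 config$fragment_sd))
      frag <- pmin(pmax(frag, rl), len)
      start <- 1L + floor(stats::runif(n_reads) * (len - frag + 1))
    } else {
      start <- 1L + floor(stats::runif(n_reads) * (len - rl + 1))
    }
    reads <- substring(seq, start, start + rl - 1L)
    if (config$base_error_rate > 0) {
      n_err <- stats::rbinom(n_reads, rl, config$base_error_rate)
      hit <- which(n_err > 0)
      bases <- c("A", "C", "G", "T")
      for (i in hit) {
        chars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
        pos <- sample.int(rl, n_err[i])
        for (p in pos) {
          chars[p] <- sample(setdiff(bases, chars[p]), 1L)
        }
        reads[i] <- paste(chars, collapse = "")
      }
    }
    reads
  })
}

#' Equivalence-class counts
#'
#' Container mapping transcript-id sets (equivalence classes) to read counts.
#'
#' @param classes list of character vectors, each the member transcripts of a
#'   class (stored sorted ascending).
#' @param counts numeric vector of non-negative read counts, one per class.
#' @return object of class `eqclass_counts`: a list with `classes`, `counts`,
#'   canonical `keys` (comma-joined sorted members) and `total_mapped`.
#' @export
eqclass_counts <- function(classes = list(), counts = numeric(0)) {
  stopifnot(length(classes) == length(counts), all(counts >= 0))
  classes <- lapply(classes, function(m) sort(as.character(m)))
  keys <- vapply(classes, paste, "", collapse = ",")
  if (anyDuplicated(keys)) stop("duplicate equivalence classes")
  structure(list(classes = classes, counts = as.numeric(counts), keys = keys,
                 total_mapped = sum(counts)),
            class = "eqclass_counts")
}

#' @export
print.eqclass_counts <- function(x, ...) {
  cat(sprintf("eqclass_counts: %d classes, %g mapped reads\n",
              length(x$counts), x$total_mapped))
  if (length(x$counts)) {
    print(utils::head(data.frame(class = x$keys, count = x$counts), 10))
  }
  invisible(x)
}

# Substring index: maps every length-k substring of the transcriptome to the
# sorted set of transcripts containing it.
kmer_index <- function(transcriptome, k) {
  kmers <- vector("list", nrow(transcriptome))
  txs <- vector("list", nrow(transcriptome))
  for (i in seq_len(nrow(transcriptome))) {
    s <- transcriptome$sequence[i]
    n <- nchar(s)
    if (n < k) next
    st <- seq_len(n - k + 1L)
    kmers[[i]] <- substring(s, st, st + k - 1L)
    txs[[i]] <- rep(transcriptome$id[i], length(st))
  }
  lst <- split(unlist(txs), unlist(kmers))
  lapply(lst, function(v) sort(unique(v)))
}

#' Map reads to equivalence classes by exact substring matching
#'
#' Deterministic stand-in for quasi-mapping: a read is assigned to the set of
#' transcripts that contain it as an exact substring.  Reads matching no
#' transcript are unmapped and excluded from the counts.
#'
#' @param reads character vector of read sequences.
#' @param transcriptome data.frame with `id` and `sequence` columns.
#' @return an [eqclass_counts()] object.
#' @export
quasi_map <- function(reads, transcriptome) {
  if (length(reads) == 0L) return(eqclass_counts())
  keys <- character(length(reads))
  for (k in unique(nchar(reads))) {
    sel <- which(nchar(reads) == k)
    idx <- kmer_index(transcriptome, k)
    hit <- match(reads[sel], names(idx))
    kk <- rep(NA_character_, length(sel))
    ok <- !is.na(hit)
    kk[ok] <- vapply(idx[hit[ok]], paste, "", collapse = ",")
    keys[sel] <- kk
  }
  keys <- keys[!is.na(keys)]
  if (length(keys) == 0L) return(eqclass_counts())
  tab <- table(keys)
  eqclass_counts(strsplit(names(tab), ",", fixed = TRUE), as.numeric(tab))
}

#' Sample expression values from a beta-Poisson model
#'
#' For each sample draws `p ~ Beta(alpha, beta)` and returns
#' `lambda2 * Poisson(lambda1 * p)`, a four-parameter family capturing the
#' overdispersed, occasionally bimodal expression seen across single cells.
#'
#' @param alpha,beta shape parameters of the Beta distribution (must be > 0).
#' @param lambda1 rate scale of the Poisson component (>= 0).
#' @param lambda2 multiplicative amplitude (>= 0).
#' @param n_samples number of samples to draw.
#' @param seed integer seed or `NULL`.
#' @return numeric vector of `n_samples` non-negative expression values.
#' @export
sample_beta_poisson <- function(alpha, beta, lambda1, lambda2 = 1,
                                n_samples = 1L, seed = NULL) {
  if (alpha <= 0 || beta <= 0) stop_config("alpha and beta must be > 0")
  if (lambda1 < 0 || lambda2 < 0) stop_config("lambda1/lambda2 must be >= 0")
  with_seed(seed, {
    p <- stats::rbeta(n_samples, alpha, beta)
    lambda2 * stats::rpois(n_samples, lambda1 * p)
  })
}

#' Simulate multi-sample equivalence-class counts from a known model
#'
#' Draws `y[j, n] ~ Poisson(sum_t x[j, t] * beta[t, n])`, the observation
#' model under which the estimator operates.
#'
#' @param X design matrix (patterns x transcripts) with unit column sums.
#' @param beta_true non-negative abundance matrix (transcripts x samples); a
#'   vector is treated as a single-sample column.
#' @param seed integer seed or `NULL`.
#' @return count matrix with the patterns of `X` as row names.
#' @export
simulate_multisample_counts <- function(X, beta_true, seed = NULL) {
  if (is.vector(beta_true)) beta_true <- matrix(beta_true, ncol = 1L)
  if (ncol(X) != nrow(beta_true)) {
    stop_config("ncol(X) = %d but nrow(beta_true) = %d", ncol(X), nrow(beta_true))
  }
  if (any(beta_true < 0)) stop_config("beta_true must be non-negative")
  cs <- colSums(X)
  if (any(abs(cs - 1) > 1e-6)) {
    stop_config("columns of X must sum to 1 (max deviation %.3g)",
                max(abs(cs - 1)))
  }
  mu <- unclass(X) %*% beta_true
  with_seed(seed, {
    y <- matrix(stats::rpois(length(mu), mu), nrow = nrow(mu))
    dimnames(y) <- list(rownames(X),
                        colnames(beta_true) %||%
                          paste0("s", seq_len(ncol(beta_true))))
    y
  })
}

#' Distort a design matrix to emulate non-uniform read distribution
#'
#' Multiplies each entry by an independent log-normal perturbation with
#' log-scale standard deviation `bias_strength` and renormalizes every column
#' to sum to 1.  Structural zeros are preserved; `bias_strength = 0` returns
#' `X` unchanged.
#'
#' @param X design matrix with unit column sums.
#' @param bias_strength non-negative log-scale perturbation SD.
#' @param seed integer seed or `NULL`.
#' @return design matrix of the same shape with unit column sums.
#' @export
apply_bias <- function(X, bias_strength, seed = NULL) {
  if (bias_strength < 0) stop_config("bias_strength must be >= 0")
  if (bias_strength == 0) return(X)
  with_seed(seed, {
    pert <- matrix(exp(stats::rnorm(length(X), 0, bias_strength)),
                   nrow = nrow(X))
    xb <- unclass(X) * pert
    xb <- sweep(xb, 2L, colSums(xb), "/")
    keep_design_attrs(xb, X)
  })
}
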