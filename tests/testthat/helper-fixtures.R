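# Shared fixtures and independent oracles used across test files.

# Brute-force mapping oracle: assigns each read to the set of transcripts
# containing it by direct substring search, independent of the k-mer index.
brute_force_map <- function(reads, transcriptome) {
  keys <- vapply(reads, function(r) {
    hit <- transcriptome$id[vapply(transcriptome$sequence,
                                   function(s) grepl(r, s, fixed = TRUE), NA)]
    if (length(hit)) paste(sort(hit), collapse = ",") else NA_character_
  }, "", USE.NAMES = FALSE)
  keys[!is.na(keys)]
}

# A three-isoform gene whose design matrix is full rank: one shared block
# plus one unique block per isoform.
three_isoform_cluster <- function(seed = 3L) {
  tr <- make_toy_transcriptome(1, 3, 200, 200, seed = seed)
  ds <- build_design_set(tr, seed = seed)
  list(transcriptome = tr, design = ds$designs[[1L]], design_set = ds)
}

# Simple diagonal design over two transcripts (exclusive patterns).
diag_design <- function() {
  x <- diag(2)
  dimnames(x) <- list(c("10", "01"), c("a", "b"))
  xaemlite:::new_design_matrix(x)
}

# Beta-Poisson null counts for DE simulations: per-isoform parameters drawn
# once, identical across groups (no true differential expression).
null_counts <- function(n_isoforms, n_samples, seed) {
  xaemlite:::with_seed(seed, {
    lam <- stats::runif(n_isoforms, 50, 500)
    a <- stats::runif(n_isoforms, 0.5, 2)
    b <- stats::runif(n_isoforms, 0.5, 2)
    counts <- matrix(0, n_isoforms, n_samples)
    for (g in seq_len(n_isoforms)) {
      counts[g, ] <- stats::rpois(n_samples, lam[g] * stats::rbeta(n_samples,
                                                                   a[g], b[g]))
    }
    rownames(counts) <- sprintf("iso%05d", seq_len(n_isoforms))
    counts
  })
}
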