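# End-to-end orchestration: TRPs -> neighbor filter -> clusters -> design
# matrices -> multi-sample quantification, plus the file-driven `run`
# pipeline behind the command-line wrapper.

#' Build the starting design matrices for a transcriptome
#'
#' Runs the full empirical construction: a transcript response profile per
#' transcript (uniform reads from that transcript alone, mapped back to the
#' whole transcriptome), neighbor filtering at `H`, transcription clusters
#' from the neighbor graph, pattern collapsing, column normalization, and
#' paralog merging.
#'
#' @param transcriptome data.frame with `id`, `sequence` (e.g. from
#'   [make_toy_transcriptome()] or [read_transcriptome_fasta()]).
#' @param config a [sim_config()] for the TRP simulations.
#' @param H neighbor threshold fraction.
#' @param sv_threshold singular-value cutoff for [merge_paralogs()].
#' @param seed master seed; each transcript's TRP simulation uses a derived
#'   sub-seed.
#' @param trps optional precomputed list of [trp()] objects (one per
#'   transcript), bypassing simulation.
#' @param merge apply [merge_paralogs()] to every cluster matrix.  Disable
#'   to inspect the raw column-normalized matrices; note that a cluster with
#'   fewer patterns than transcripts is always rank-deficient and will be
#'   collapsed by the SVD rule when merging is on.
#' @return object of class `design_set`: list with `designs` (list of
#'   `design_matrix`), `clusters`, `neighbor_sets`, and the parameters used.
#' @export
build_design_set <- function(transcriptome = NULL, config = sim_config(),
                             H = 0.025, sv_threshold = 0.02, seed = 1L,
                             trps = NULL, merge = TRUE) {
  if (is.null(trps)) {
    stopifnot(!is.null(transcriptome))
    trps <- lapply(seq_len(nrow(transcriptome)), function(i) {
      build_trp(transcriptome$id[i], transcriptome, config,
                seed = split_seed(seed, i))
    })
  }
  trps <- trps[order(vapply(trps, `[[`, "", "source"))]
  names(trps) <- vapply(trps, `[[`, "", "source")
  neighbor_sets <- lapply(trps, filter_neighbors, H = H)
  pruned <- lapply(names(trps), function(s) {
    prune_trp(trps[[s]], c(s, neighbor_sets[[s]]$neighbors))
  })
  names(pruned) <- names(trps)
  clusters <- build_clusters(neighbor_sets)
  designs <- lapply(clusters, function(cl) {
    pc <- collapse_patterns(cl, pruned[cl$transcripts])
    X <- normalize_design(pc)
    if (merge) X <- merge_paralogs(X, sv_threshold = sv_threshold,
                                   seed = seed)
    X
  })
  structure(list(designs = designs, clusters = clusters,
                 neighbor_sets = neighbor_sets, trps = pruned,
                 H = H, sv_threshold = sv_threshold, seed = seed),
            class = "design_set")
}

#' @export
print.design_set <- function(x, ...) {
  sizes <- vapply(x$designs, ncol, 0L)
  cat(sprintf("design set: %d cluster(s) (%d singleton, %d multi), H = %g\n",
              length(x$designs), sum(sizes == 1), sum(sizes > 1), x$H))
  invisible(x)
}

#' Quantify isoform expression across samples
#'
#' Matches each sample's equivalence-class counts to every cluster design
#' matrix and fits the bilinear model cluster by cluster with [aem_fit()].
#'
#' @param design_set a [build_design_set()] result (or plain list of
#'   `design_matrix`).
#' @param samples list of [eqclass_counts()], one per sample.
#' @param ... passed to [aem_fit()] (e.g. `update_X`, `max_iter`).
#' @return list with `counts` (estimated read counts, units x samples),
#'   `beta` (raw abundances including the prior offset), `fits` (per-cluster
#'   `aem_fit` objects) and `designs` (the updated design matrices).
#' @export
quantify_samples <- function(design_set, samples, ...) {
  designs <- if (inherits(design_set, "design_set")) design_set$designs
             else design_set
  fits <- lapply(designs, function(X) {
    aem_fit(match_counts(X, samples), X, ...)
  })
  counts <- do.call(rbind, lapply(fits, `[[`, "counts"))
  beta <- do.call(rbind, lapply(fits, `[[`, "beta"))
  list(counts = counts, beta = beta, fits = fits,
       designs = lapply(fits, `[[`, "X"))
}

#' Run the full pipeline from a configuration list
#'
#' Stages: `simulate` a toy transcriptome (or read one from FASTA), build
#' the design matrices, simulate or ingest per-sample equivalence-class
#' counts, quantify with the AEM estimator, and write all outputs as
#' plain-text files together with the resolved configuration and a
#' diagnostics JSON.
#'
#' @param config named list; recognised entries (with defaults):
#'   `out` (output directory, required), `seed` (1), `H` (0.025),
#'   `sv_threshold` (0.02), `max_iter` (100), `update_X` (TRUE),
#'   `literal_eq7` (FALSE), `fasta` (path of an existing transcriptome,
#'   otherwise one is simulated using `n_genes`, `isoforms_per_gene`,
#'   `shared_block_len`, `unique_block_len`), `counts_dir` (directory of
#'   per-sample eqclass files, `dialect` `"salmon"` or `"tsv"`), and for
#'   simulated experiments `n_samples` (10) plus beta-Poisson parameters
#'   `alpha`, `beta`, `lambda1`, `lambda2`.
#' @return invisibly, a list with the design set, quantification results and
#'   output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(list(seed = 1L, H = 0.025, sv_threshold = 0.02,
                                max_iter = 100L, update_X = TRUE,
                                literal_eq7 = FALSE, dialect = "tsv",
                                n_genes = 5L, isoforms_per_gene = 2L,
                                shared_block_len = 200L,
                                unique_block_len = 150L, n_samples = 10L,
                                alpha = 1, beta = 1, lambda1 = 500,
                                lambda2 = 1),
                           config)
  if (is.null(cfg$out)) stop_config("config$out (output directory) is required")
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(fmt, ...) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }

  transcriptome <- if (!is.null(cfg$fasta)) {
    if (!file.exists(cfg$fasta)) stop_config("no such file: %s", cfg$fasta)
    log_stage("reading transcriptome from %s", cfg$fasta)
    read_transcriptome_fasta(cfg$fasta)
  } else {
    log_stage("simulating toy transcriptome (%d genes x %d isoforms)",
              cfg$n_genes, cfg$isoforms_per_gene)
    tr <- make_toy_transcriptome(cfg$n_genes, cfg$isoforms_per_gene,
                                 cfg$shared_block_len, cfg$unique_block_len,
                                 seed = cfg$seed)
    write_transcriptome_fasta(tr, file.path(cfg$out, "transcriptome.fa"))
    tr
  }

  log_stage("building design matrices (H = %g, sv_threshold = %g)",
            cfg$H, cfg$sv_threshold)
  ds <- build_design_set(transcriptome, sim_config(), H = cfg$H,
                         sv_threshold = cfg$sv_threshold, seed = cfg$seed)
  for (i in seq_along(ds$designs)) {
    write_design(ds$designs[[i]], file.path(cfg$out, sprintf("X_%03d.tsv", i)))
  }

  samples <- if (!is.null(cfg$counts_dir)) {
    files <- sort(list.files(cfg$counts_dir, full.names = TRUE))
    if (!length(files)) stop_config("no count files in %s", cfg$counts_dir)
    log_stage("reading %d sample(s) from %s", length(files), cfg$counts_dir)
    stats::setNames(lapply(files, read_eqclass, dialect = cfg$dialect),
                    sub("\\.[^.]*$", "", basename(files)))
  } else {
    log_stage("simulating %d sample(s) of eqclass counts", cfg$n_samples)
    truth <- t(vapply(seq_len(nrow(transcriptome)), function(i) {
      sample_beta_poisson(cfg$alpha, cfg$beta, cfg$lambda1, cfg$lambda2,
                          cfg$n_samples, seed = split_seed(cfg$seed, 10000 + i))
    }, numeric(cfg$n_samples)))
    rownames(truth) <- transcriptome$id
    utils::write.table(data.frame(id = rownames(truth), truth,
                                  check.names = FALSE),
                       file.path(cfg$out, "true_counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sm <- lapply(seq_len(cfg$n_samples), function(n) {
      reads <- unlist(lapply(seq_len(nrow(transcriptome)), function(i) {
        simulate_reads(transcriptome[i, ], sim_config(),
                       n_reads = truth[i, n],
                       seed = split_seed(cfg$seed, 20000 + 1000 * n + i))
      }))
      quasi_map(reads, transcriptome)
    })
    names(sm) <- paste0("s", seq_len(cfg$n_samples))
    for (n in seq_along(sm)) {
      write_eqclass(sm[[n]], file.path(cfg$out, sprintf("eqclass_%s.tsv",
                                                        names(sm)[n])),
                    dialect = "tsv")
    }
    sm
  }

  log_stage("quantifying with AEM (update_X = %s)", cfg$update_X)
  q <- quantify_samples(ds, samples, max_iter = cfg$max_iter,
                        update_X = cfg$update_X,
                        literal_eq7 = cfg$literal_eq7)
  utils::write.table(data.frame(id = rownames(q$counts), q$counts,
                                check.names = FALSE),
                     file.path(cfg$out, "isoform_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (i in seq_along(q$designs)) {
    write_design(q$designs[[i]],
                 file.path(cfg$out, sprintf("X_updated_%03d.tsv", i)))
  }
  diag <- lapply(q$fits, function(f) {
    c(f$diagnostics[c("iterations", "converged")], list(beta0 = f$beta0))
  })
  jsonlite::write_json(list(seed = cfg$seed, clusters = diag),
                       file.path(cfg$out, "diagnostics.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(cfg[order(names(cfg))],
                       file.path(cfg$out, "config_resolved.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("done; outputs in %s", cfg$out)
  invisible(list(design_set = ds, quant = q, out = cfg$out))
}
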