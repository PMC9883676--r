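# Construction of the starting design matrix X per transcription cluster:
# transcript response profiles, neighbor filtering, transcription clusters,
# binary occupancy patterns, count transfer, column normalization, and
# paralog collapsing by SVD + k-means.

#' Transcript response profile (TRP)
#'
#' The equivalence-class count table observed when a single source transcript
#' is expressed in isolation.  Each class count is attributed in full to
#' every member transcript, so a transcript's total is the sum of the counts
#' of all classes containing it.
#'
#' @param source id of the source transcript.
#' @param classes list of character vectors (class member sets).
#' @param counts numeric read counts, one per class.
#' @return object of class `trp`: list with `source`, `classes`, `counts`,
#'   `keys` and the per-transcript `totals` (named, source first).
#' @export
trp <- function(source, classes, counts) {
  ec <- eqclass_counts(classes, counts)
  members <- sort(unique(unlist(ec$classes)))
  totals <- vapply(members, function(t) {
    sum(ec$counts[vapply(ec$classes, function(m) t %in% m, NA)])
  }, 0)
  if (length(totals) && source %in% names(totals) &&
      totals[source] < max(totals)) {
    warning(sprintf("TRP source %s does not have the maximal total", source))
  }
  ord <- c(source, setdiff(names(totals), source))
  structure(list(source = source, classes = ec$classes, counts = ec$counts,
                 keys = ec$keys, totals = totals[intersect(ord, names(totals))]),
            class = "trp")
}

#' @export
print.trp <- function(x, ...) {
  cat(sprintf("TRP of %s: %d eqclasses, totals:\n", x$source,
              length(x$counts)))
  print(x$totals)
  invisible(x)
}

#' Build the transcript response profile of one transcript
#'
#' Simulates uniform reads from the source transcript alone, maps them back
#' to the whole transcriptome with [quasi_map()], and tabulates the resulting
#' equivalence-class counts.
#'
#' @param source transcript id (present in `transcriptome`).
#' @param transcriptome data.frame with `id`, `sequence`.
#' @param config a [sim_config()].
#' @param seed integer seed or `NULL`.
#' @return a [trp()] object (empty, with a warning, if no read maps).
#' @export
build_trp <- function(source, transcriptome, config = sim_config(),
                      seed = NULL) {
  i <- match(source, transcriptome$id)
  if (is.na(i)) stop_config("transcript %s not in transcriptome", source)
  reads <- simulate_reads(transcriptome[i, ], config, seed = seed)
  ec <- quasi_map(reads, transcriptome)
  if (ec$total_mapped == 0) {
    warning(sprintf("no reads of %s mapped; empty TRP", source))
    return(structure(list(source = source, classes = list(),
                          counts = numeric(0), keys = character(0),
                          totals = numeric(0)), class = "trp"))
  }
  trp(source, ec$classes, ec$counts)
}

#' Filter false-positive neighbors of a TRP
#'
#' A transcript other than the source is kept as a neighbor only if its total
#' attributed reads reach a fraction `H` of the source transcript's total.
#'
#' @param x a [trp()].
#' @param H threshold fraction in `[0, 1)`; `H = 0` keeps every neighbor.
#' @return object of class `neighbor_set`: list with `source`, `neighbors`
#'   (sorted ids) and `H`.
#' @export
filter_neighbors <- function(x, H = 0.025) {
  stopifnot(inherits(x, "trp"))
  if (H < 0 || H >= 1) stop_config("H must lie in [0, 1), got %g", H)
  others <- setdiff(names(x$totals), x$source)
  keep <- others[x$totals[others] >= H * x$totals[[x$source]]]
  structure(list(source = x$source, neighbors = sort(keep), H = H),
            class = "neighbor_set")
}

#' Restrict a TRP to a set of retained transcripts
#'
#' Removes discarded transcripts from every equivalence class and recomputes
#' the patterns: classes that become identical after the removal are pooled,
#' classes that become empty are dropped.
#'
#' @param x a [trp()].
#' @param keep character vector of transcript ids to retain (must include the
#'   source).
#' @return a [trp()] over the retained transcripts.
#' @export
prune_trp <- function(x, keep) {
  stopifnot(inherits(x, "trp"), x$source %in% keep)
  classes <- lapply(x$classes, intersect, keep)
  nonempty <- lengths(classes) > 0
  classes <- classes[nonempty]
  counts <- x$counts[nonempty]
  keys <- vapply(classes, ec_key, "")
  agg <- rowsum(counts, keys)
  first <- !duplicated(keys)
  trp(x$source, classes[first], as.numeric(agg[match(keys[first],
                                                     rownames(agg)), 1L]))
}

#' Group transcripts into transcription clusters
#'
#' Builds the undirected transcript graph with an edge for every
#' (source, neighbor) pair and returns its connected components.
#'
#' @param neighbor_sets list of [filter_neighbors()] results, one per
#'   transcript.
#' @return list of `transcription_cluster` objects, each a list with
#'   `transcripts` (ids, ascending) and `edges` (two-column character
#'   matrix).  Clusters are ordered by their smallest transcript id.
#' @export
build_clusters <- function(neighbor_sets) {
  sources <- vapply(neighbor_sets, `[[`, "", "source")
  edges <- do.call(rbind, lapply(neighbor_sets, function(s) {
    if (length(s$neighbors)) cbind(s$source, s$neighbors)
  }))
  verts <- sort(unique(c(sources, as.character(edges))))
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(verts)
  if (!is.null(edges)) g <- g + igraph::edges(t(edges))
  comp <- igraph::components(g)
  clusters <- lapply(seq_len(comp$no), function(ci) {
    tx <- sort(names(comp$membership)[comp$membership == ci])
    ed <- matrix(character(0), 0L, 2L)
    if (!is.null(edges)) {
      e <- edges[edges[, 1L] %in% tx, , drop = FALSE]
      if (nrow(e) > 0L) {
        e <- unique(cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
        ed <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
      }
    }
    structure(list(transcripts = tx, edges = ed),
              class = "transcription_cluster")
  })
  clusters[order(vapply(clusters, function(cl) cl$transcripts[1L], ""))]
}

#' Collapse TRP equivalence classes into a pattern-count table
#'
#' Converts every equivalence class of every member TRP into a binary
#' occupancy pattern over the cluster's ordered transcripts, unifies
#' duplicate patterns, and fills cell (pattern, transcript) with the read
#' count of that pattern in the TRP whose source is the transcript.  Rows are
#' ordered by first occurrence, scanning TRPs in cluster transcript order.
#'
#' @param cluster a `transcription_cluster`.
#' @param trps list of neighbor-filtered [trp()] objects covering the
#'   cluster's transcripts (named by source or not).
#' @return numeric matrix patterns x transcripts; row names are the pattern
#'   bit strings (e.g. `"1101"`), column names the cluster transcripts.
#' @export
collapse_patterns <- function(cluster, trps) {
  tx <- cluster$transcripts
  srcs <- vapply(trps, `[[`, "", "source")
  patterns <- character(0)
  counts <- NULL
  for (t in tx) {
    i <- match(t, srcs)
    if (is.na(i)) stop_config("no TRP provided for cluster transcript %s", t)
    tr <- trps[[i]]
    for (ci in seq_along(tr$classes)) {
      members <- tr$classes[[ci]]
      if (!all(members %in% tx)) {
        stop_config("TRP of %s references transcript(s) outside the cluster: %s",
                    t, paste(setdiff(members, tx), collapse = ","))
      }
      pat <- paste(as.integer(tx %in% members), collapse = "")
      r <- match(pat, patterns)
      if (is.na(r)) {
        patterns <- c(patterns, pat)
        counts <- rbind(counts, matrix(0, 1L, length(tx),
                                       dimnames = list(pat, tx)))
        r <- length(patterns)
      }
      counts[r, t] <- counts[r, t] + tr$counts[ci]
    }
  }
  counts
}

new_design_matrix <- function(x, pattern_transcripts = colnames(x),
                              merged_groups = list()) {
  structure(x, pattern_transcripts = pattern_transcripts,
            merged_groups = merged_groups,
            class = c("design_matrix", class(matrix())))
}

# copy design-matrix attributes from `from` onto plain matrix `x`
keep_design_attrs <- function(x, from) {
  if (inherits(from, "design_matrix")) {
    new_design_matrix(x,
                      pattern_transcripts = attr(from, "pattern_transcripts"),
                      merged_groups = attr(from, "merged_groups") %||% list())
  } else {
    x
  }
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design matrix: %d patterns x %d transcripts\n",
              nrow(x), ncol(x)))
  print(round(unclass(x), 4))
  mg <- attr(x, "merged_groups")
  if (length(mg)) {
    cat("merged paralog groups:\n")
    for (g in mg) cat("  ", paste(g$members, collapse = " + "), "\n")
  }
  invisible(x)
}

#' Column-normalize a pattern-count table into a design matrix
#'
#' Standardizes the total reads of each transcript to sum to 1, giving the
#' starting design matrix X whose entry `x[j, t]` is the proportion of
#' transcript `t`'s reads that fall in pattern `j`.
#'
#' @param pattern_counts matrix from [collapse_patterns()].
#' @return a `design_matrix` with unit column sums; transcripts with a zero
#'   column total are dropped with a warning.
#' @export
normalize_design <- function(pattern_counts) {
  totals <- colSums(pattern_counts)
  if (any(totals == 0)) {
    warning(sprintf("dropping transcript(s) with no reads: %s",
                    paste(colnames(pattern_counts)[totals == 0],
                          collapse = ",")))
    pattern_counts <- pattern_counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  new_design_matrix(sweep(pattern_counts, 2L, totals, "/"))
}

#' Merge paralog transcripts in a design matrix
#'
#' Near-identical transcripts yield (nearly) collinear columns of X, making
#' their abundances non-identifiable.  The number of estimable units `k` is
#' taken as the number of singular values of X above `sv_threshold`; when
#' `k` is smaller than the number of columns, k-means clustering of the
#' columns (with `nstart` restarts under a fixed seed) groups the paralogs,
#' and each group is replaced by the arithmetic mean of its member columns,
#' renormalized to unit sum.  Merged column names join the member ids with
#' `"+"`.
#'
#' @param X a column-normalized `design_matrix`.
#' @param sv_threshold singular-value cutoff.
#' @param seed seed for the k-means restarts.
#' @param nstart number of k-means restarts.
#' @return a `design_matrix`; unchanged (apart from a recorded
#'   `singular_values` attribute) when `k` equals the number of columns.  The
#'   `merged_groups` attribute lists each group's `members` and the singular
#'   value spectrum that triggered the merge.
#' @export
merge_paralogs <- function(X, sv_threshold = 0.02, seed = 1L, nstart = 10L) {
  d <- svd(unclass(X))$d
  k <- sum(d > sv_threshold)
  if (k == 0) stop_config("degenerate design matrix: no singular value > %g",
                          sv_threshold)
  attr(X, "singular_values") <- d
  if (k >= ncol(X)) return(X)
  pts <- t(unclass(X))
  k <- min(k, nrow(unique(pts)))
  cl <- with_seed(seed, stats::kmeans(pts, centers = k, nstart = nstart))
  assign <- cl$cluster
  # deterministic group order: by the lowest member id of each cluster
  groups <- split(colnames(X), assign)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, "", 1L))]
  ord <- order(vapply(groups, function(g) match(g[1L], colnames(X)), 0L))
  groups <- groups[ord]
  cols <- lapply(groups, function(g) {
    v <- rowMeans(unclass(X)[, g, drop = FALSE])
    v / sum(v)
  })
  xm <- do.call(cbind, unname(cols))
  colnames(xm) <- unname(vapply(groups, paste, "", collapse = "+"))
  rownames(xm) <- rownames(X)
  mg <- c(attr(X, "merged_groups") %||% list(),
          lapply(Filter(function(g) length(g) > 1, groups), function(g) {
            list(members = g, singular_values = d,
                 sv_threshold = sv_threshold)
          }))
  out <- new_design_matrix(xm,
                           pattern_transcripts = attr(X, "pattern_transcripts") %||%
                             colnames(X),
                           merged_groups = unname(mg))
  attr(out, "singular_values") <- d
  out
}

#' Transcript sets of a design matrix's rows
#'
#' Decodes each row's bit pattern back into the member transcripts, using the
#' pre-merge transcript order stored on the matrix.
#'
#' @param X a `design_matrix`.
#' @return list of character vectors, one per row.
#' @export
design_row_sets <- function(X) {
  tx <- attr(X, "pattern_transcripts") %||% colnames(X)
  lapply(rownames(X), function(p) {
    bits <- as.integer(strsplit(p, "", fixed = TRUE)[[1L]])
    if (length(bits) != length(tx)) {
      stop_config("pattern %s does not match %d transcripts", p, length(tx))
    }
    tx[bits == 1L]
  })
}
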