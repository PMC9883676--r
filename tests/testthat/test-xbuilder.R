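test_that("worked-example TRP totals attribute class counts to every member", {
  t1 <- fig_trps()$tx1
  expect_equal(t1$totals,
               c(tx1 = 1000, tx2 = 870, tx3 = 850, tx4 = 150, tx5 = 20))
  expect_equal(sum(t1$counts), 1000)
})

test_that("a TRP built from simulated reads matches its class table", {
  tr <- make_toy_transcriptome(1, 3, 150, 150, seed = 2)
  x <- build_trp(tr$id[1], tr, sim_config(base_error_rate = 0), seed = 4)
  expect_identical(x$source, tr$id[1])
  # totals equal the column sums of the class-count table
  for (t in names(x$totals)) {
    expect_equal(x$totals[[t]],
                 sum(x$counts[vapply(x$classes, function(m) t %in% m, NA)]))
  }
  expect_equal(max(x$totals), x$totals[[x$source]])
  # two identical transcripts: each TRP lists both with equal totals
  tp <- make_toy_transcriptome(1, 2, 200, 0, seed = 2)
  xp <- build_trp(tp$id[1], tp, sim_config(base_error_rate = 0), seed = 4)
  expect_equal(unname(xp$totals[tp$id[1]]), unname(xp$totals[tp$id[2]]))
})

test_that("neighbor filtering applies the H threshold", {
  t1 <- fig_trps()$tx1
  ns <- filter_neighbors(t1, H = 0.025)
  expect_identical(ns$neighbors, c("tx2", "tx3", "tx4"))  # tx5 at 2% dropped
  expect_identical(filter_neighbors(t1, H = 0)$neighbors,
                   c("tx2", "tx3", "tx4", "tx5"))
  expect_error(filter_neighbors(t1, H = 1), "H must lie")
  solo <- trp("a", list("a"), 10)
  expect_length(filter_neighbors(solo)$neighbors, 0L)
})

test_that("pruning recomputes patterns after dropping transcripts", {
  t1 <- fig_trps()$tx1
  pr <- prune_trp(t1, c("tx1", "tx2", "tx3", "tx4"))
  expect_identical(pr$keys, c("tx1,tx2,tx4", "tx1,tx2,tx3", "tx1,tx4"))
  # classes colliding after removal are pooled
  t5 <- fig_trps()$tx5
  pr5 <- prune_trp(t5, "tx5")
  expect_identical(pr5$keys, "tx5")
  expect_equal(pr5$counts, 1000)
})

test_that("transcription clusters are the connected components", {
  trps <- fig_trps()
  ns <- lapply(trps, filter_neighbors, H = 0.025)
  cl <- build_clusters(ns)
  expect_length(cl, 2L)
  expect_identical(cl[[1]]$transcripts, c("tx1", "tx2", "tx3", "tx4"))
  expect_identical(cl[[2]]$transcripts, "tx5")
  # transitive chain a-b, b-c forms one cluster
  chain <- list(structure(list(source = "a", neighbors = "b", H = 0),
                          class = "neighbor_set"),
                structure(list(source = "b", neighbors = c("a", "c"), H = 0),
                          class = "neighbor_set"),
                structure(list(source = "c", neighbors = "b", H = 0),
                          class = "neighbor_set"))
  expect_identical(build_clusters(chain)[[1]]$transcripts, c("a", "b", "c"))
  # no neighbors anywhere: every transcript its own cluster
  iso <- lapply(c("x", "y"), function(s) {
    structure(list(source = s, neighbors = character(0), H = 0),
              class = "neighbor_set")
  })
  expect_length(build_clusters(iso), 2L)
})

test_that("pattern collapsing unifies duplicates and transfers counts", {
  trps <- fig_trps()
  ns <- lapply(trps, filter_neighbors, H = 0.025)
  pruned <- lapply(names(trps), function(s) {
    prune_trp(trps[[s]], c(s, ns[[s]]$neighbors))
  })
  names(pruned) <- names(trps)
  cl <- build_clusters(ns)[[1]]
  pc <- collapse_patterns(cl, pruned[cl$transcripts])
  expect_identical(rownames(pc), c("1101", "1110", "1001"))
  expect_equal(pc["1101", ], c(tx1 = 20, tx2 = 120, tx3 = 0, tx4 = 150))
  # single-transcript cluster gives the single pattern "1"
  cl5 <- build_clusters(ns)[[2]]
  pc5 <- collapse_patterns(cl5, pruned["tx5"])
  expect_identical(rownames(pc5), "1")
  # a class referencing a transcript outside the cluster is an error
  bad <- list(trp("tx5", list(c("tx5", "zz")), 10))
  expect_error(collapse_patterns(cl5, bad), "outside the cluster")
})

test_that("column normalization reproduces the worked-example matrix", {
  ds <- build_design_set(trps = fig_trps(), H = 0.025, merge = FALSE)
  X <- ds$designs[[1]]
  expect_equal(unclass(X), unclass(fig_design()), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(colSums(X)), rep(1, 4))
  # zero-pattern consistency: x is zero exactly where the bit is zero
  sets <- design_row_sets(X)
  for (j in seq_len(nrow(X))) {
    expect_true(all((unclass(X)[j, ] > 0) == (colnames(X) %in% sets[[j]])))
  }
  # degenerate single-cell table normalizes to 1
  one <- matrix(37, 1, 1, dimnames = list("1", "t"))
  expect_equal(unclass(normalize_design(one))[1, 1], 1)
  # zero column is dropped with a warning
  z <- matrix(c(5, 0), 1, 2, dimnames = list("11", c("a", "b")))
  expect_warning(nz <- normalize_design(z), "no reads")
  expect_identical(colnames(nz), "a")
})

test_that("transcript input order does not change the design matrix", {
  base <- build_design_set(trps = fig_trps(), merge = FALSE)$designs[[1]]
  shuf <- build_design_set(trps = fig_trps()[c(3, 5, 1, 4, 2)],
                           merge = FALSE)$designs[[1]]
  expect_equal(unclass(base), unclass(shuf))
})

test_that("paralog merging follows the singular-value rule", {
  # orthogonal (diagonal-like) columns: k = T, unchanged
  Xo <- xaemlite:::new_design_matrix(
    diag(3), pattern_transcripts = c("a", "b", "c"))
  dimnames(Xo) <- list(c("100", "010", "001"), c("a", "b", "c"))
  expect_equal(unclass(merge_paralogs(Xo)), unclass(Xo), ignore_attr = TRUE)
  # two identical columns plus one orthogonal: k = 2, the pair merges
  x <- cbind(a = c(0.5, 0.5, 0), b = c(0.5, 0.5, 0), c = c(0, 0, 1))
  rownames(x) <- c("110", "110b", "001")
  Xm <- merge_paralogs(xaemlite:::new_design_matrix(x))
  expect_identical(colnames(Xm), c("a+b", "c"))
  expect_equal(unname(unclass(Xm)[, "a+b"]), c(0.5, 0.5, 0))
  expect_equal(unname(colSums(Xm)), c(1, 1))
  mg <- attr(Xm, "merged_groups")
  expect_length(mg, 1L)
  expect_identical(mg[[1]]$members, c("a", "b"))
  expect_length(mg[[1]]$singular_values, 3L)
  # idempotence: merging a merged matrix changes nothing
  Xm2 <- merge_paralogs(Xm)
  expect_equal(unclass(Xm2), unclass(Xm), ignore_attr = TRUE)
  expect_identical(colnames(Xm2), colnames(Xm))
  # the pattern interpretation survives the merge
  expect_identical(attr(Xm, "pattern_transcripts"), c("a", "b", "c"))
  # absurd threshold drives k to zero: degenerate error
  expect_error(merge_paralogs(Xo, sv_threshold = 10), "degenerate")
})

test_that("exact paralogs from the generator end up merged", {
  tr <- make_toy_transcriptome(1, 2, 200, 0, seed = 6)
  ds <- build_design_set(tr, sim_config(base_error_rate = 0), seed = 6)
  X <- ds$designs[[1]]
  expect_identical(ncol(X), 1L)
  expect_identical(colnames(X), paste(sort(tr$id), collapse = "+"))
})

test_that("design TSV and TRP TSV round-trip through files", {
  X <- build_design_set(trps = fig_trps(), merge = FALSE)$designs[[1]]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_design(X, f)
  X2 <- read_design(f)
  expect_equal(unclass(X2), unclass(X), ignore_attr = TRUE)
  expect_identical(attr(X2, "pattern_transcripts"),
                   attr(X, "pattern_transcripts"))
  ftrp <- withr::local_tempfile(fileext = ".tsv")
  write_trp(fig_trps()$tx1, ftrp)
  tab <- read.delim(ftrp)
  expect_identical(tab$eqclass[nrow(tab)], "Sum")
  expect_equal(tab$tx1[nrow(tab)], 1000)
})
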