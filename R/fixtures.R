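# The five-transcript worked example: one fully specified transcript
# response profile plus four partially specified ones, completed so that
# every source generates 1000 reads.  Used throughout the documentation and
# tests as the reference for the X-construction pipeline.

#' Worked-example transcript response profiles
#'
#' Five TRPs over transcripts tx1..tx5 sharing exons.  The profile of tx1
#' has three equivalence classes — \{tx1,tx2,tx4,tx5\} = 20,
#' \{tx1,tx2,tx3\} = 850 and \{tx1,tx4\} = 130 — giving per-transcript totals
#' 1000/870/850/150/20, so that at the default neighbor threshold
#' `H = 0.025` transcript tx5 (2% of tx1's total) is filtered out.  The
#' remaining profiles are fixed such that each source also totals 1000 reads
#' and tx5 retains no neighbors, ending up in a singleton cluster.
#'
#' @return named list of five [trp()] objects.
#' @seealso [fig_design()] for the design matrix this fixture produces.
#' @export
fig_trps <- function() {
  list(
    tx1 = trp("tx1",
              list(c("tx1", "tx2", "tx4", "tx5"),
                   c("tx1", "tx2", "tx3"),
                   c("tx1", "tx4")),
              c(20, 850, 130)),
    tx2 = trp("tx2",
              list(c("tx1", "tx2", "tx4"),
                   c("tx1", "tx2", "tx3")),
              c(120, 880)),
    tx3 = trp("tx3",
              list(c("tx1", "tx2", "tx3")),
              1000),
    tx4 = trp("tx4",
              list(c("tx1", "tx2", "tx4"),
                   c("tx1", "tx4")),
              c(150, 850)),
    tx5 = trp("tx5",
              list(c("tx1", "tx2", "tx4", "tx5"),
                   "tx5"),
              c(20, 980)))
}

#' Worked-example design matrix
#'
#' The starting design matrix that [build_design_set()] produces from
#' [fig_trps()] at `H = 0.025`: three occupancy patterns (1101, 1110, 1001)
#' over tx1..tx4, columns summing to 1.
#'
#' @return a `design_matrix`.
#' @export
fig_design <- function() {
  x <- matrix(c(0.02, 0.85, 0.13,
                0.12, 0.88, 0,
                0, 1, 0,
                0.15, 0, 0.85),
              nrow = 3L,
              dimnames = list(c("1101", "1110", "1001"),
                              c("tx1", "tx2", "tx3", "tx4")))
  new_design_matrix(x)
}
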