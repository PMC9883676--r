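# Plain-text readers and writers: FASTA transcriptomes, equivalence-class
# count files (two dialects), design matrices and TRP tables.

#' Write a toy transcriptome as FASTA
#'
#' Header lines are `>txID gene=geneID`; sequences are wrapped at 80 columns.
#'
#' @param transcriptome data.frame with `id`, `gene_id`, `sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(transcriptome, path) {
  x <- Biostrings::DNAStringSet(transcriptome$sequence)
  names(x) <- paste0(transcriptome$id, " gene=", transcriptome$gene_id)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a toy transcriptome from FASTA
#'
#' @param path FASTA file with `>txID gene=geneID` headers (a missing
#'   `gene=` field falls back to the transcript id).
#' @return data.frame with `id`, `gene_id`, `sequence`.
#' @export
read_transcriptome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  gene <- ifelse(grepl("gene=", hdr),
                 sub("^.*gene=(\\S+).*$", "\\1", hdr), id)
  data.frame(id = id, gene_id = gene, sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write equivalence-class counts
#'
#' Two dialects: `"salmon"` writes the `eq_classes.txt` layout (number of
#' transcripts, number of classes, one transcript name per line, then per
#' class `k idx1 ... idxk count` with 0-based transcript indices);
#' `"tsv"` writes `comma-joined-ids<TAB>count` lines.
#'
#' @param ec an [eqclass_counts()].
#' @param path output file.
#' @param dialect `"salmon"` or `"tsv"`.
#' @param transcripts transcript name universe for the salmon dialect;
#'   defaults to the sorted union of class members.
#' @return `path`, invisibly.
#' @export
write_eqclass <- function(ec, path, dialect = c("salmon", "tsv"),
                          transcripts = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    writeLines(sprintf("%s\t%s", ec$keys, format(ec$counts, trim = TRUE,
                                                 scientific = FALSE)), path)
    return(invisible(path))
  }
  transcripts <- transcripts %||% sort(unique(unlist(ec$classes)))
  miss <- setdiff(unlist(ec$classes), transcripts)
  if (length(miss)) stop_config("transcript(s) %s absent from the name list",
                                paste(miss, collapse = ","))
  lines <- c(length(transcripts), length(ec$counts), transcripts,
             vapply(seq_along(ec$counts), function(i) {
               idx <- match(ec$classes[[i]], transcripts) - 1L
               paste(c(length(idx), idx,
                       format(ec$counts[i], trim = TRUE, scientific = FALSE)),
                     collapse = " ")
             }, ""))
  writeLines(as.character(lines), path)
  invisible(path)
}

#' Read equivalence-class counts
#'
#' @param path input file.
#' @param dialect `"salmon"` or `"tsv"` (see [write_eqclass()]).
#' @return an [eqclass_counts()].
#' @export
read_eqclass <- function(path, dialect = c("salmon", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_config("no such file: %s", path)
  lines <- readLines(path)
  if (dialect == "tsv") {
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(eqclass_counts())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad)) stop_config("%s: malformed line %d", path, bad[1L])
    counts <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
    if (anyNA(counts)) {
      stop_config("%s: non-numeric count at line %d", path, which(is.na(counts))[1L])
    }
    return(eqclass_counts(strsplit(vapply(parts, `[`, "", 1L), ",",
                                   fixed = TRUE), counts))
  }
  if (length(lines) < 2L) stop_config("%s: truncated header", path)
  n_tx <- suppressWarnings(as.integer(lines[1L]))
  n_cl <- suppressWarnings(as.integer(lines[2L]))
  if (is.na(n_tx) || is.na(n_cl)) stop_config("%s: malformed header", path)
  if (length(lines) < 2L + n_tx + n_cl) {
    stop_config("%s: expected %d transcript and %d class lines, found %d",
                path, n_tx, n_cl, length(lines) - 2L)
  }
  tx <- lines[2L + seq_len(n_tx)]
  classes <- vector("list", n_cl)
  counts <- numeric(n_cl)
  for (i in seq_len(n_cl)) {
    ln <- 2L + n_tx + i
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    k <- suppressWarnings(as.integer(f[1L]))
    if (is.na(k) || length(f) != k + 2L) {
      stop_config("%s: malformed class at line %d", path, ln)
    }
    idx <- suppressWarnings(as.integer(f[1L + seq_len(k)]))
    if (anyNA(idx) || any(idx < 0L | idx >= n_tx)) {
      stop_config("%s: transcript index out of range at line %d", path, ln)
    }
    classes[[i]] <- tx[idx + 1L]
    counts[i] <- as.numeric(f[k + 2L])
  }
  eqclass_counts(classes, counts)
}

#' Write a design matrix as TSV
#'
#' First column `pattern` holds the bit strings; the header carries the
#' transcript ids (merged groups joined by `+`).  A leading comment line
#' records the pre-merge transcript order the patterns refer to.
#'
#' @param X a `design_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_design <- function(X, path) {
  tx <- attr(X, "pattern_transcripts") %||% colnames(X)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# pattern_transcripts: ", paste(tx, collapse = ",")), con)
  writeLines(paste(c("pattern", colnames(X)), collapse = "\t"), con)
  for (j in seq_len(nrow(X))) {
    writeLines(paste(c(rownames(X)[j],
                       format(unclass(X)[j, ], digits = 17, trim = TRUE,
                              scientific = FALSE)), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a design matrix written by [write_design()]
#'
#' @param path input TSV.
#' @return a `design_matrix`.
#' @export
read_design <- function(path) {
  lines <- readLines(path)
  tx <- NULL
  if (startsWith(lines[1L], "# pattern_transcripts:")) {
    tx <- strsplit(trimws(sub("^# pattern_transcripts:", "", lines[1L])),
                   ",", fixed = TRUE)[[1L]]
    lines <- lines[-1L]
  }
  tab <- utils::read.delim(text = lines, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character"))
  x <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- tab[[1L]]
  new_design_matrix(x, pattern_transcripts = tx %||% colnames(x))
}

#' Write a TRP as a Table-style TSV
#'
#' Rows are equivalence classes (count repeated under every member
#' transcript, zero otherwise) with a final `Sum` row of per-transcript
#' totals.
#'
#' @param x a [trp()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trp <- function(x, path) {
  tx <- names(x$totals)
  m <- t(vapply(seq_along(x$classes), function(i) {
    ifelse(tx %in% x$classes[[i]], x$counts[i], 0)
  }, numeric(length(tx))))
  rn <- paste0("eqclass", seq_len(nrow(m)))
  tab <- rbind(m, Sum = x$totals)
  utils::write.table(data.frame(eqclass = c(rn, "Sum"), tab,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
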