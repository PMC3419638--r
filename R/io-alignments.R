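# Alignment tables hold one placement of a read on a reference sequence per
# row. Internal convention: 0-based half-open coordinates, ref_start <
# ref_end always, strand explicit in {+,-}. The outfmt6 dialect (BLAST
# tabular) uses 1-based inclusive coordinates with the reverse strand
# encoded as sstart > send; it is normalised on import so no downstream
# operation ever sees inverted coordinates.

alignment_cols <- c("query_id", "query_start", "query_end", "chrom",
                    "ref_start", "ref_end", "strand", "score", "evalue",
                    "pident", "mismatches")

#' Empty alignment table
#'
#' @return zero-row data.frame with the alignment-table schema.
#' @export
empty_alignments <- function() {
  data.frame(query_id = character(0), query_start = integer(0),
             query_end = integer(0), chrom = character(0),
             ref_start = integer(0), ref_end = integer(0),
             strand = character(0), score = numeric(0), evalue = numeric(0),
             pident = numeric(0), mismatches = integer(0),
             stringsAsFactors = FALSE)
}

validate_alignments <- function(hits) {
  if (nrow(hits) == 0L) return(invisible(hits))
  if (any(hits$ref_start >= hits$ref_end)) {
    stopf("alignment with ref_start >= ref_end (query %s)",
          hits$query_id[hits$ref_start >= hits$ref_end][1])
  }
  if (any(hits$query_start >= hits$query_end)) {
    stopf("alignment with query_start >= query_end (query %s)",
          hits$query_id[hits$query_start >= hits$query_end][1])
  }
  if (!all(hits$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  if (any(!is.finite(hits$score))) stopf("non-finite alignment score")
  invisible(hits)
}

#' Read a tabular alignment file
#'
#' Two dialects are supported. `outfmt6` is the 12-column BLAST tabular
#' format (qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore), 1-based inclusive, reverse strand encoded as
#' sstart > send; the bitscore column maps to `score`. `native` is the
#' package's own TSV with explicit 0-based half-open coordinates and a
#' strand column, which round-trips losslessly.
#'
#' @param path input file.
#' @param dialect `"outfmt6"` or `"native"`.
#' @return alignment table (see [empty_alignments()] for the schema).
#' @export
read_alignment_table <- function(path, dialect = c("native", "outfmt6")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("alignment file not found: %s", path)
  if (dialect == "native") {
    df <- read_tsv(path)
    missing <- setdiff(alignment_cols, names(df))
    if (length(missing)) stopf("native alignment table %s lacks columns: %s",
                               path, paste(missing, collapse = ", "))
    hits <- df[, alignment_cols]
    return(validate_alignments(hits))
  }
  raw <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(raw) == 0L) return(empty_alignments())
  if (ncol(raw) != 12L) {
    stopf("outfmt6 file %s has %d columns, expected 12", path, ncol(raw))
  }
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v)) {
      stopf("outfmt6 file %s: non-numeric %s at line %d",
            path, what, which(is.na(v))[1])
    }
    v
  }
  qstart <- num(7, "qstart"); qend <- num(8, "qend")
  sstart <- num(9, "sstart"); send <- num(10, "send")
  if (any(sstart == send)) {
    stopf("outfmt6 file %s: zero-extent subject coordinates at line %d",
          path, which(sstart == send)[1])
  }
  rev <- sstart > send
  hits <- data.frame(
    query_id = raw[[1]],
    query_start = as.integer(qstart - 1), query_end = as.integer(qend),
    chrom = raw[[2]],
    ref_start = as.integer(ifelse(rev, send, sstart) - 1),
    ref_end = as.integer(ifelse(rev, sstart, send)),
    strand = ifelse(rev, "-", "+"),
    score = num(12, "bitscore"), evalue = num(11, "evalue"),
    pident = num(3, "pident"), mismatches = as.integer(num(5, "mismatch")),
    stringsAsFactors = FALSE)
  validate_alignments(hits)
}

#' Write a tabular alignment file
#'
#' @param hits alignment table.
#' @param path output file.
#' @param dialect `"native"` (lossless) or `"outfmt6"` (1-based inclusive,
#'   reverse strand by coordinate inversion).
#' @return the path, invisibly.
#' @export
write_alignment_table <- function(hits, path, dialect = c("native", "outfmt6")) {
  dialect <- match.arg(dialect)
  validate_alignments(hits)
  if (dialect == "native") {
    out <- hits[, alignment_cols]
    out$score <- sprintf("%.17g", out$score)
    out$evalue <- sprintf("%.17g", out$evalue)
    out$pident <- sprintf("%.17g", out$pident)
    write_tsv(out, path)
    return(invisible(path))
  }
  rev <- hits$strand == "-"
  out <- data.frame(
    qseqid = hits$query_id, sseqid = hits$chrom,
    pident = sprintf("%.2f", hits$pident),
    length = hits$query_end - hits$query_start,
    mismatch = hits$mismatches, gapopen = 0L,
    qstart = hits$query_start + 1L, qend = hits$query_end,
    sstart = ifelse(rev, hits$ref_end, hits$ref_start + 1L),
    send = ifelse(rev, hits$ref_start + 1L, hits$ref_end),
    evalue = sprintf("%.2e", hits$evalue),
    bitscore = sprintf("%.1f", hits$score))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED-like repeat annotations
#'
#' Expected columns: read_id, start, end (0-based half-open on the read),
#' family. An optional score column is preserved.
#'
#' @param path input TSV.
#' @return data.frame with columns read_id, start, end, family, score.
#' @export
read_repeat_annotations <- function(path) {
  df <- read_tsv(path)
  need <- c("read_id", "start", "end", "family")
  missing <- setdiff(need, names(df))
  if (length(missing)) stopf("repeat annotation file %s lacks columns: %s",
                             path, paste(missing, collapse = ", "))
  if (!"score" %in% names(df)) df$score <- NA_real_
  if (any(df$start >= df$end)) {
    stopf("repeat annotation with start >= end in %s", path)
  }
  df[, c("read_id", "start", "end", "family", "score")]
}

#' Write BED-like repeat annotations
#'
#' @param annotations data.frame as from [annotate_repeats()].
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
write_repeat_annotations <- function(annotations, path) {
  keep <- intersect(c("read_id", "start", "end", "family", "score"),
                    names(annotations))
  write_tsv(annotations[, keep], path)
  invisible(path)
}
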