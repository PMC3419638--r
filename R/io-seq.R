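#' Read a FASTA file
#'
#' Returns one row per record with the sequence uppercased and record order
#' preserved. Identifiers are the header token up to the first whitespace;
#' the remainder is kept as the description.
#'
#' @param path path to an existing FASTA file.
#' @return data.frame with columns `id`, `description`, `sequence`.
#'   FASTA carries no quality channel; downstream operations assume an
#'   implicit uniform phred quality of 40 (see [get_quality()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  validate_fasta(path)
  set <- Biostrings::readDNAStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stopf("duplicate sequence id in %s: %s", path, ids[duplicated(ids)][1])
  }
  data.frame(id = ids, description = desc,
             sequence = toupper(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Structural validation so format errors can name the offending line;
# Biostrings does the actual parsing.
validate_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(invisible(TRUE))
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) return(invisible(TRUE))
  if (!startsWith(lines[nonempty[1]], ">")) {
    stopf("malformed FASTA %s: line %d does not start a record", path, nonempty[1])
  }
  hdr <- which(startsWith(lines, ">"))
  bad <- hdr[trimws(sub("^>", "", lines[hdr])) == ""]
  if (length(bad)) stopf("malformed FASTA %s: empty header at line %d", path, bad[1])
  # a header immediately followed by another header (or EOF) has no sequence
  nxt <- c(hdr[-1], length(lines) + 1L)
  for (i in seq_along(hdr)) {
    body <- lines[setdiff(seq(hdr[i] + 1L, length.out = nxt[i] - hdr[i] - 1L), hdr)]
    if (sum(nchar(trimws(body))) == 0L) {
      stopf("malformed FASTA %s: record at line %d has empty sequence", path, hdr[i])
    }
  }
  invisible(TRUE)
}

#' Write sequences to FASTA
#'
#' @param records data.frame with columns `id`, `sequence` and optionally
#'   `description`, or a named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width in bases.
#' @return the path, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), description = "",
                          sequence = unname(records), stringsAsFactors = FALSE)
  }
  set <- Biostrings::DNAStringSet(records$sequence)
  desc <- if ("description" %in% names(records)) records$description else ""
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (phred+33)
#'
#' @param path path to an existing FASTQ file.
#' @return data.frame with columns `id`, `description`, `sequence` and a
#'   list-column `quality` of per-base integer phred scores.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stopf("FASTQ file not found: %s", path)
  # QualityScaledDNAStringSet coercions emit a spurious metadata-column
  # warning; the metadata is empty here
  set <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(
    path, quality.scoring = "phred"))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  qual <- suppressWarnings(as(Biostrings::quality(set), "IntegerList"))
  out <- data.frame(id = ids, description = desc,
                    sequence = suppressWarnings(toupper(as.character(set))),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$quality <- as.list(qual)
  out
}

#' Write reads to FASTQ (phred+33)
#'
#' @param reads data.frame with `id`, `sequence` and optionally a `quality`
#'   list-column; missing qualities are written as uniform phred 40.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  n <- nrow(reads)
  con <- file(path, "w")
  on.exit(close(con))
  if (n == 0L) return(invisible(path))
  qs <- vapply(seq_len(n), function(i) {
    q <- get_quality(reads, i)
    intToUtf8(pmin(q, 60L) + 33L)
  }, character(1))
  desc <- if ("description" %in% names(reads)) reads$description else rep("", n)
  hdr <- ifelse(nzchar(desc), paste(reads$id, desc), reads$id)
  writeLines(paste0("@", hdr, "\n", reads$sequence, "\n+\n", qs), con)
  invisible(path)
}

#' Per-base quality of one read
#'
#' FASTA-derived records carry no quality channel; they are treated as
#' uniform phred 40 so that the trimming operators behave sensibly on them.
#'
#' @param reads a reads data.frame.
#' @param i row index.
#' @return integer vector of phred scores, one per base.
#' @export
get_quality <- function(reads, i) {
  q <- if ("quality" %in% names(reads)) reads$quality[[i]] else NULL
  len <- nchar(reads$sequence[i])
  if (is.null(q)) return(rep(40L, len))
  q <- as.integer(q)
  if (length(q) != len) {
    stopf("quality length %d != sequence length %d for read %s",
          length(q), len, reads$id[i])
  }
  q
}

#' Convert a records data.frame to a named sequence vector
#'
#' @param records data.frame from [read_fasta()].
#' @return named character vector (one element per chromosome/sequence).
#' @export
as_genome <- function(records) {
  setNames(records$sequence, records$id)
}
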