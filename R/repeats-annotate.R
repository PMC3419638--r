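# Repeat annotation of reads against a consensus library: read k-mers
# (both orientations, short seeds to tolerate copy divergence) are
# matched exactly against the library consensuses, grouped per (library
# sequence, orientation, diagonal) and extended ungapped exactly as in
# the genome mapper. The resulting read intervals are merged per family
# and resolved across families by score.

#' Build a repeat-library index
#'
#' @param repeat_library data.frame with `family` and `sequence` columns
#'   (e.g. from [simulate_repeat_library()] or a FASTA read with
#'   [read_fasta()] where ids are family names).
#' @param k seed length for read-vs-library matching (shorter than the
#'   genome-mapping seed, to tolerate copy divergence).
#' @return a `repeat_index` list wrapping a [build_seed_index()] of the
#'   consensus set.
#' @export
build_repeat_index <- function(repeat_library, k = 12L) {
  if (!all(c("family", "sequence") %in% names(repeat_library))) {
    if (all(c("id", "sequence") %in% names(repeat_library))) {
      repeat_library$family <- repeat_library$id
    } else stopf("repeat library needs family and sequence columns")
  }
  seqs <- setNames(toupper(repeat_library$sequence), repeat_library$family)
  structure(list(k = as.integer(k), index = build_seed_index(seqs, k)),
            class = "repeat_index")
}

#' Annotate repeat intervals on a set of reads
#'
#' Reports read intervals similar to a library consensus with ungapped
#' alignment score (+1/-3) at least `min_score`. Overlapping intervals
#' from the same family are merged (the best score is kept); overlaps
#' across families are resolved in favour of the higher score (ties:
#' longer interval, then lexicographic family name), the losing interval
#' being trimmed to its non-overlapping remainder (fragments shorter than
#' the seed length are dropped).
#'
#' @param reads data.frame with `id` and `sequence`.
#' @param index a [build_repeat_index()].
#' @param min_score minimum alignment score.
#' @return data.frame read_id, start, end, family, score (0-based
#'   half-open intervals, pairwise non-overlapping per read).
#' @export
annotate_reads <- function(reads, index, min_score = 30) {
  empty <- data.frame(read_id = character(0), start = integer(0),
                      end = integer(0), family = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)
  stride <- max(1L, index$k %/% 3)
  cfg <- bes_config()
  hits <- seed_extend_hits(reads, index$index, stride, cfg)
  hits <- hits[hits$score >= min_score, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  out <- lapply(split(hits, hits$query_id), function(h) {
    resolve_annotations(data.frame(start = h$query_start, end = h$query_end,
                                   family = h$chrom, score = h$score,
                                   stringsAsFactors = FALSE),
                        h$query_id[1], index$k)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Same-family merging and cross-family overlap resolution of candidate
# intervals on one read.
resolve_annotations <- function(segs, read_id, min_len) {
  merged <- list()
  for (fam in unique(segs$family)) {
    f <- segs[segs$family == fam, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(f$start + 1L, f$end))
    ov <- IRanges::findOverlaps(IRanges::IRanges(f$start + 1L, f$end), ir)
    sc <- tapply(f$score[S4Vectors::queryHits(ov)],
                 S4Vectors::subjectHits(ov), max)
    merged[[fam]] <- data.frame(
      start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir),
      family = fam, score = as.numeric(sc), stringsAsFactors = FALSE)
  }
  segs <- do.call(rbind, merged)
  segs <- segs[order(-segs$score, -(segs$end - segs$start), segs$family), ]
  claimed <- IRanges::IRanges()
  out <- list()
  for (j in seq_len(nrow(segs))) {
    ival <- IRanges::IRanges(segs$start[j] + 1L, segs$end[j])
    free <- IRanges::setdiff(ival, claimed)
    free <- free[BiocGenerics::width(free) >= min_len]
    if (length(free) == 0L) next
    claimed <- IRanges::union(claimed, free)
    out[[length(out) + 1L]] <- data.frame(
      read_id = read_id, start = BiocGenerics::start(free) - 1L,
      end = BiocGenerics::end(free), family = segs$family[j],
      score = segs$score[j], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$start), ]
}

#' Annotate repeat intervals on a single read
#'
#' @param sequence read sequence.
#' @param index a [build_repeat_index()].
#' @param min_score minimum ungapped alignment score (+1/-3).
#' @param read_id id used in the output.
#' @return data.frame as in [annotate_reads()].
#' @export
annotate_repeats <- function(sequence, index, min_score = 30,
                             read_id = "read") {
  annotate_reads(data.frame(id = read_id, sequence = sequence,
                            stringsAsFactors = FALSE), index, min_score)
}

#' Fraction of a read covered by repeat annotations
#'
#' @param read_length read length in bp.
#' @param annotations annotation rows for this read.
#' @return union length of annotated intervals divided by read length,
#'   in [0, 1].
#' @export
repeat_fraction <- function(read_length, annotations) {
  if (read_length <= 0) stopf("read_length must be positive")
  if (is.null(annotations) || nrow(annotations) == 0L) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(annotations$start + 1L,
                                         annotations$end))
  min(sum(BiocGenerics::width(ir)) / read_length, 1)
}
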