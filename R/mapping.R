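# Built-in read mapper: exact k-mer seeds grouped per (chromosome, strand,
# diagonal), ungapped extension scored match +1 / mismatch -3 (the best-
# scoring segment on the diagonal), and a Karlin-Altschul E-value analogue
# E = K * m * n * exp(-lambda * S) with fixed (lambda = 1.28, K = 0.46).
# The substitution-only read model makes exact-diagonal grouping and
# ungapped extension sufficient. A brute-force exhaustive scanner over
# small genomes serves as the independent oracle.

#' Build a reference index for mapping
#'
#' Prepares the reference for k-mer seed lookup. Seeds harvested from
#' reads (and their reverse complements) are streamed against the
#' reference with a constant-width dictionary scan, which is equivalent to
#' a k-mer position index lookup.
#'
#' @param reference named character vector of chromosomes, or a records
#'   data.frame from [read_fasta()].
#' @param k seed length (>= 11).
#' @return a `seed_index` list (k, chromosome names/lengths, raw
#'   sequences, total length).
#' @export
build_seed_index <- function(reference, k = 16L) {
  if (is.data.frame(reference)) reference <- as_genome(reference)
  if (k < 11) stopf("seed length k must be >= 11")
  structure(list(
    k = as.integer(k),
    chrom_names = names(reference),
    chrom_len = setNames(nchar(reference), names(reference)),
    subjects = lapply(reference, Biostrings::DNAString),
    raw = lapply(reference, charToRaw),
    total_len = sum(nchar(reference))
  ), class = "seed_index")
}

karlin_evalue <- function(score, m, n, lambda = 1.28, K = 0.46) {
  K * m * n * exp(-lambda * score)
}

# Best-scoring contiguous segment of a +1/-3 match indicator vector
# (optimal ungapped local alignment on a fixed diagonal). Returns
# c(score, start, end) with a 0-based half-open segment, or NULL if all
# positions mismatch.
best_segment <- function(match_vec) {
  x <- ifelse(match_vec, 1, -3)
  s <- cumsum(x)
  prior <- cummin(c(0, s[-length(s)]))
  best <- s - prior
  b <- which.max(best)
  if (best[b] <= 0) return(NULL)
  a <- which.min(c(0, s)[seq_len(b)]) - 1L  # prefix length before segment
  c(score = best[b], start = a, end = b)
}

# Harvest constant-width seeds from a set of oriented read sequences,
# skipping masked intervals (0-based half-open on the oriented read).
# Returns a data.frame(pattern, item, offset) where item indexes the
# caller's bookkeeping.
harvest_seeds <- function(seqs, k, stride, masks = NULL) {
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    len <- nchar(seqs[i])
    if (len < k) next
    offs <- seq(0L, len - k, by = stride)
    if (!is.null(masks) && !is.null(masks[[i]]) && nrow(masks[[i]])) {
      m <- masks[[i]]
      keep <- !vapply(offs, function(o) {
        any(m$start < o + k & m$end > o)
      }, logical(1))
      offs <- offs[keep]
    }
    if (!length(offs)) next
    pats <- substring(seqs[i], offs + 1L, offs + k)
    ok <- !grepl("[^ACGT]", pats)
    if (!any(ok)) next
    out[[i]] <- data.frame(pattern = pats[ok], item = i, offset = offs[ok],
                           stringsAsFactors = FALSE)
  }
  if (all(vapply(out, is.null, logical(1)))) {
    return(data.frame(pattern = character(0), item = integer(0),
                      offset = integer(0)))
  }
  do.call(rbind, out)
}

#' Map reads onto a reference
#'
#' Seeds are taken from each read and its reverse complement at a fixed
#' stride, matched exactly against the reference, grouped by (chromosome,
#' strand, diagonal), and extended ungapped (match +1, mismatch -3,
#' best-scoring segment). Hits with E-value above `max_evalue` are
#' dropped; within each (chromosome, strand) only the best hit per
#' `hit_window` is retained, emulating one-HSP-per-locus reporting. Reads
#' shorter than the seed length yield no hits. Masked read intervals (e.g.
#' annotated repeats) contribute no seeds, but extension may run through
#' them.
#'
#' @param reads data.frame with `id` and `sequence` columns.
#' @param index a [build_seed_index()] object.
#' @param cfg a [bes_config()] (stride, E-value cutoff, Karlin-Altschul
#'   parameters, hit window).
#' @param masks optional named list (by read id) of data.frames with
#'   `start`/`end` columns: read intervals to exclude from seeding.
#' @return an alignment table, sorted by read then score descending.
#' @export
map_reads <- function(reads, index, cfg = bes_config(), masks = NULL) {
  hits <- seed_extend_hits(reads, index, cfg$map_seed_stride, cfg, masks)
  hits <- hits[hits$evalue <= cfg$max_evalue, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty_alignments())
  dedup_hits(hits, cfg$hit_window)
}

# Seed-and-extend core shared by genome mapping and repeat annotation:
# harvest read seeds (both orientations), match them exactly against the
# subject set, group per (subject, orientation, diagonal) and extend
# ungapped. Returns all extensions scoring at least the seed length,
# unfiltered.
seed_extend_hits <- function(reads, index, stride, cfg = bes_config(),
                             masks = NULL) {
  stopifnot(inherits(index, "seed_index"))
  k <- index$k
  n_reads <- nrow(reads)
  if (n_reads == 0L) return(empty_alignments())
  oriented <- c(reads$sequence, reverse_complement(reads$sequence))
  omask <- NULL
  if (!is.null(masks)) {
    omask <- vector("list", 2L * n_reads)
    for (i in seq_len(n_reads)) {
      m <- masks[[reads$id[i]]]
      if (!is.null(m) && nrow(m)) {
        len <- nchar(reads$sequence[i])
        omask[[i]] <- m
        omask[[n_reads + i]] <- data.frame(start = len - m$end,
                                           end = len - m$start)
      }
    }
  }
  seeds <- harvest_seeds(oriented, k, stride, omask)
  if (nrow(seeds) == 0L) return(empty_alignments())
  pdict <- Biostrings::PDict(Biostrings::DNAStringSet(seeds$pattern))
  cand <- list()
  for (ci in seq_along(index$subjects)) {
    m <- Biostrings::matchPDict(pdict, index$subjects[[ci]])
    sidx <- Biostrings::startIndex(m)  # plain list: cheap accessor
    counts <- lengths(sidx)
    hit_pat <- which(counts > 0)
    if (!length(hit_pat)) next
    pat_idx <- rep(hit_pat, counts[hit_pat])
    ref_pos <- unlist(sidx[hit_pat], use.names = FALSE) - 1L
    cand[[length(cand) + 1L]] <- data.frame(
      item = seeds$item[pat_idx], chrom_i = ci,
      diag = ref_pos - seeds$offset[pat_idx])
  }
  if (!length(cand)) return(empty_alignments())
  cand <- unique(do.call(rbind, cand))

  hits <- vector("list", nrow(cand))
  for (j in seq_len(nrow(cand))) {
    item <- cand$item[j]
    read_i <- if (item > n_reads) item - n_reads else item
    orient_rev <- item > n_reads
    oseq <- oriented[item]
    len <- nchar(oseq)
    diag <- cand$diag[j]
    clen <- index$chrom_len[cand$chrom_i[j]]
    ostart <- max(0L, -diag)
    oend <- min(len, clen - diag)
    if (oend - ostart < k) next
    rr <- charToRaw(substr(oseq, ostart + 1L, oend))
    ref_raw <- index$raw[[cand$chrom_i[j]]][(diag + ostart + 1L):(diag + oend)]
    seg <- best_segment(rr == ref_raw)
    if (is.null(seg) || seg[["score"]] < k) next
    score <- seg[["score"]]
    ev <- karlin_evalue(score, len, index$total_len,
                        cfg$karlin_lambda, cfg$karlin_k)
    os <- ostart + seg[["start"]]; oe <- ostart + seg[["end"]]
    aln_len <- oe - os
    mism <- as.integer((aln_len - score) / 4)
    if (orient_rev) {
      qs <- len - oe; qe <- len - os; strand <- "-"
    } else {
      qs <- os; qe <- oe; strand <- "+"
    }
    hits[[j]] <- data.frame(
      query_id = reads$id[read_i], query_start = as.integer(qs),
      query_end = as.integer(qe),
      chrom = index$chrom_names[cand$chrom_i[j]],
      ref_start = as.integer(diag + os), ref_end = as.integer(diag + oe),
      strand = strand, score = score, evalue = ev,
      pident = 100 * (aln_len - mism) / aln_len, mismatches = mism,
      stringsAsFactors = FALSE)
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) return(empty_alignments())
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

# Keep the best hit per (read, chromosome, strand, window): hits within
# `window` bp of a better hit on the same chromosome and strand are
# suppressed.
dedup_hits <- function(hits, window) {
  hits <- hits[order(hits$query_id, -hits$score, hits$chrom, hits$ref_start), ]
  keep <- logical(nrow(hits))
  for (q in unique(hits$query_id)) {
    idx <- which(hits$query_id == q)
    kept <- integer(0)
    for (i in idx) {
      near <- kept[hits$chrom[kept] == hits$chrom[i] &
                     hits$strand[kept] == hits$strand[i] &
                     abs(hits$ref_start[kept] - hits$ref_start[i]) < window]
      if (!length(near)) {
        keep[i] <- TRUE
        kept <- c(kept, i)
      }
    }
  }
  out <- hits[keep, ]
  rownames(out) <- NULL
  out
}

#' Map a single read
#'
#' Convenience wrapper around [map_reads()] for one sequence.
#'
#' @param sequence read sequence (character scalar).
#' @param index a [build_seed_index()] object.
#' @param cfg a [bes_config()].
#' @param id read id used in the output table.
#' @return an alignment table sorted by score descending.
#' @export
map_read <- function(sequence, index, cfg = bes_config(), id = "read") {
  map_reads(data.frame(id = id, sequence = sequence,
                       stringsAsFactors = FALSE), index, cfg)
}

#' Brute-force read placement (test oracle)
#'
#' Exhaustively scans both strands of a small genome for full-length read
#' windows with at most `max_mismatch` mismatches, via a complete
#' sliding-window comparison. Intended as an independent oracle for
#' [map_reads()] on genomes of a few megabases.
#'
#' @param sequence read sequence.
#' @param genome named character vector of chromosomes.
#' @param max_mismatch maximum mismatches per window.
#' @param cfg a [bes_config()] (Karlin-Altschul parameters for the
#'   reported E-value).
#' @param id read id used in the output table.
#' @return an alignment table (all qualifying windows, unfiltered).
#' @export
brute_force_map <- function(sequence, genome, max_mismatch = 0,
                            cfg = bes_config(), id = "read") {
  out <- list()
  len <- nchar(sequence)
  total_len <- sum(nchar(genome))
  if (len == 0L || length(genome) == 0L || total_len == 0L) {
    return(empty_alignments())
  }
  variants <- c(`+` = sequence, `-` = reverse_complement(sequence))
  for (ch in names(genome)) {
    subject <- Biostrings::DNAString(genome[[ch]])
    if (length(subject) < len) next
    for (strand in c("+", "-")) {
      mm <- Biostrings::matchPattern(variants[[strand]], subject,
                                     max.mismatch = max_mismatch,
                                     with.indels = FALSE)
      if (length(mm) == 0L) next
      starts <- BiocGenerics::start(mm)
      for (s1 in starts) {
        window <- substr(genome[[ch]], s1, s1 + len - 1L)
        nmis <- sum(charToRaw(window) != charToRaw(variants[[strand]]))
        score <- (len - nmis) - 3 * nmis
        out[[length(out) + 1L]] <- data.frame(
          query_id = id, query_start = 0L, query_end = len,
          chrom = ch, ref_start = s1 - 1L, ref_end = s1 - 1L + len,
          strand = strand, score = score,
          evalue = karlin_evalue(score, len, total_len,
                                 cfg$karlin_lambda, cfg$karlin_k),
          pident = 100 * (len - nmis) / len, mismatches = as.integer(nmis),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_alignments())
  res <- do.call(rbind, out)
  res[order(-res$score, res$chrom, res$ref_start), ]
}
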