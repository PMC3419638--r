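# Read quality control: vector trimming (terminal run-through from the
# cloning site), sliding-window quality trimming, and organelle
# contamination screening (E-value plus query-coverage rule, reported per
# clone). Every stage reports in/out counts so filter accounting can be
# audited.

count_mismatches <- function(a_raw, b_raw) sum(a_raw != b_raw)

# Longest terminal match length: the largest l in [min_seed, max_l] such
# that the read terminus of length l matches a vector terminus with at
# most max_mismatch mismatches. `read_term(l)` and `vec_term(l)` supply
# the two l-length candidates.
longest_terminal_match <- function(read_term, vec_term, min_seed,
                                   max_mismatch, max_l) {
  for (l in seq(max_l, min_seed)) {
    if (count_mismatches(read_term(l), vec_term(l)) <= max_mismatch) return(l)
  }
  0L
}

# Trim vector run-through from one sequence; returns the kept 0-based
# half-open interval. The read prefix may match a substring of the vector
# ending at either terminus (either orientation); same for the suffix at
# a vector start. An interior full vector occurrence leaves the longer
# flank.
trim_vector_one <- function(sequence, vector_raw, vector_rc_raw, min_seed,
                            max_mismatch) {
  len <- nchar(sequence)
  if (len < min_seed) return(c(0L, len))
  read_raw <- charToRaw(sequence)
  vlen <- length(vector_raw)
  max_l <- min(len - 1L, vlen, 250L)
  keep_start <- 0L; keep_end <- len
  if (max_l >= min_seed) {
    # prefix of the read vs a vector 3' terminus (either strand)
    pre <- 0L
    for (vr in list(vector_raw, vector_rc_raw)) {
      l <- longest_terminal_match(
        function(l) read_raw[seq_len(l)],
        function(l) vr[(vlen - l + 1L):vlen],
        min_seed, max_mismatch, max_l)
      pre <- max(pre, l)
    }
    # suffix of the read vs a vector 5' terminus (either strand)
    suf <- 0L
    for (vr in list(vector_raw, vector_rc_raw)) {
      l <- longest_terminal_match(
        function(l) read_raw[(len - l + 1L):len],
        function(l) vr[seq_len(l)],
        min_seed, max_mismatch, max_l)
      suf <- max(suf, l)
    }
    keep_start <- pre
    keep_end <- len - suf
    if (keep_start >= keep_end) return(c(0L, 0L))
  }
  # interior vector occurrence: seed on a vector terminus k-mer inside the
  # read and keep the longer flank
  for (term in list(vector_raw[seq_len(min_seed)],
                    vector_raw[(vlen - min_seed + 1L):vlen],
                    vector_rc_raw[seq_len(min_seed)],
                    vector_rc_raw[(vlen - min_seed + 1L):vlen])) {
    pat <- Biostrings::DNAString(rawToChar(term))
    mm <- Biostrings::matchPattern(pat, Biostrings::DNAString(sequence),
                                   max.mismatch = 0)
    for (s1 in BiocGenerics::start(mm)) {
      hit_start <- s1 - 1L; hit_end <- hit_start + min_seed
      if (hit_start <= keep_start || hit_end >= keep_end) next
      left <- hit_start - keep_start
      right <- keep_end - hit_end
      if (left >= right) keep_end <- hit_start else keep_start <- hit_end
    }
  }
  c(keep_start, keep_end)
}

#' Trim vector run-through from reads
#'
#' Removes the longest read prefix/suffix matching a vector terminus with
#' at least `min_seed` matching bases and at most `max_mismatch`
#' mismatches. An interior vector hit leaves the longer flank. Reads
#' shorter than `min_seed` are returned unchanged.
#'
#' @param reads reads data.frame (`id`, `sequence`, optional `quality`).
#' @param vector_seq vector sequence (character scalar or named vector of
#'   length 1).
#' @param min_seed minimum terminal match length (>= 12).
#' @param max_mismatch mismatches tolerated in the terminal match.
#' @return the reads data.frame with sequences/qualities trimmed and a
#'   `vector_trimmed` column of removed base counts.
#' @export
trim_vector <- function(reads, vector_seq, min_seed = 16L, max_mismatch = 2L) {
  if (min_seed < 12) stopf("min_seed must be >= 12")
  vector_seq <- toupper(unname(vector_seq[1]))
  v_raw <- charToRaw(vector_seq)
  vrc_raw <- charToRaw(reverse_complement(vector_seq))
  has_q <- "quality" %in% names(reads)
  trimmed <- integer(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    keep <- trim_vector_one(reads$sequence[i], v_raw, vrc_raw,
                            min_seed, max_mismatch)
    len <- nchar(reads$sequence[i])
    trimmed[i] <- len - (keep[2] - keep[1])
    if (trimmed[i] > 0L) {
      if (has_q) {
        q <- get_quality(reads, i)
        reads$quality[[i]] <- if (keep[2] > keep[1]) {
          q[(keep[1] + 1L):keep[2]]
        } else integer(0)
      }
      reads$sequence[i] <- substr(reads$sequence[i], keep[1] + 1L, keep[2])
    }
  }
  reads$vector_trimmed <- trimmed
  reads
}

# Quality-trim one read: keep the largest contiguous segment in which
# every sliding window of `window` bases has mean quality >= min_mean_q.
# Returns the kept 0-based half-open interval (possibly empty).
trim_quality_one <- function(quality, window, min_mean_q) {
  len <- length(quality)
  if (len == 0L) return(c(0L, 0L))
  if (len < window) {
    return(if (mean(quality) >= min_mean_q) c(0L, len) else c(0L, 0L))
  }
  cs <- cumsum(c(0, quality))
  wmean <- (cs[(window + 1L):(len + 1L)] - cs[seq_len(len - window + 1L)]) / window
  good <- wmean >= min_mean_q
  if (!any(good)) return(c(0L, 0L))
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  # segment covered by run of good windows [i..j] is [i, j + window - 1]
  seg_len <- r$lengths[runs] + window - 1L
  best <- runs[which.max(seg_len)]
  s <- starts[best] - 1L
  e <- ends[best] + window - 1L
  # windows straddling the segment boundary can drag in a few low-quality
  # bases; clip terminal bases below the threshold so exactly the
  # high-quality core is kept
  while (s < e && quality[s + 1L] < min_mean_q) s <- s + 1L
  while (e > s && quality[e] < min_mean_q) e <- e - 1L
  c(s, e)
}

#' Quality-trim reads
#'
#' Keeps, for each read, the largest contiguous segment whose every
#' sliding window of `window` bases has mean phred quality at least
#' `min_mean_q`. Reads whose kept segment is shorter than `min_length`
#' are rejected (rejection is a normal outcome, reported in the
#' accounting).
#'
#' @param reads reads data.frame.
#' @param window sliding window width in bases (>= 1).
#' @param min_mean_q minimum window mean quality.
#' @param min_length minimum post-trim read length.
#' @return list with `passed` (trimmed reads), `rejected` (ids) and
#'   `accounting` (n_input, n_passed, n_rejected).
#' @export
trim_quality <- function(reads, window = 20L, min_mean_q = 20,
                         min_length = 100L) {
  if (window < 1) stopf("window must be >= 1")
  n <- nrow(reads)
  keep_rows <- logical(n)
  for (i in seq_len(n)) {
    q <- get_quality(reads, i)
    keep <- trim_quality_one(q, window, min_mean_q)
    if (keep[2] - keep[1] >= min_length) {
      keep_rows[i] <- TRUE
      if (keep[1] > 0L || keep[2] < length(q)) {
        reads$sequence[i] <- substr(reads$sequence[i], keep[1] + 1L, keep[2])
        if ("quality" %in% names(reads)) {
          reads$quality[[i]] <- q[(keep[1] + 1L):keep[2]]
        }
      }
    }
  }
  list(passed = reads[keep_rows, , drop = FALSE],
       rejected = reads$id[!keep_rows],
       accounting = c(n_input = n, n_passed = sum(keep_rows),
                      n_rejected = sum(!keep_rows)))
}

#' Flag organelle-contaminated reads
#'
#' A read is flagged if any of its hits against the organelle genome has
#' E-value at most `max_evalue` and an aligned query span of at least
#' `min_coverage` times the read length. A clone is contaminated if
#' either end is flagged (per-clone reporting).
#'
#' @param reads reads data.frame.
#' @param organelle_hits alignment table of the reads against the
#'   organelle genome(s).
#' @param max_evalue E-value cutoff.
#' @param min_coverage minimum aligned fraction of the read.
#' @return named logical vector (by read id).
#' @export
screen_organelle <- function(reads, organelle_hits, max_evalue = 1e-20,
                             min_coverage = 0.80) {
  flags <- setNames(logical(nrow(reads)), reads$id)
  if (nrow(organelle_hits) == 0L) return(flags)
  lens <- setNames(nchar(reads$sequence), reads$id)
  h <- organelle_hits[organelle_hits$evalue <= max_evalue, , drop = FALSE]
  if (nrow(h) == 0L) return(flags)
  span <- h$query_end - h$query_start
  ok <- span >= min_coverage * lens[h$query_id]
  flags[unique(h$query_id[ok])] <- TRUE
  flags
}

#' Run the full QC stage
#'
#' Vector trimming, quality trimming and organelle screening in sequence,
#' with per-stage accounting. Organelle screening maps the trimmed reads
#' against the organelle genome with the built-in mapper.
#'
#' @param reads raw reads data.frame.
#' @param cfg a [bes_config()].
#' @param vector_seq optional vector sequence; NULL skips vector trimming.
#' @param organelle_genome optional named character vector; NULL skips the
#'   contamination screen.
#' @param clone_of optional named vector mapping read id to clone id (for
#'   per-clone contamination reporting).
#' @return list: reads (trimmed, passing), contaminated_reads,
#'   contaminated_clones, report (QC summary data.frame), accounting.
#' @export
qc_reads <- function(reads, cfg = bes_config(), vector_seq = NULL,
                     organelle_genome = NULL, clone_of = NULL) {
  n_input <- nrow(reads)
  if (!is.null(vector_seq)) {
    reads <- trim_vector(reads, vector_seq, cfg$vector_min_seed,
                         cfg$vector_max_mismatch)
  }
  tq <- trim_quality(reads, cfg$trim_window, cfg$trim_min_mean_q,
                     cfg$trim_min_length)
  passed <- tq$passed
  contaminated_reads <- character(0)
  if (!is.null(organelle_genome) && nrow(passed) > 0L) {
    org_index <- build_seed_index(organelle_genome, cfg$map_k)
    org_hits <- map_reads(passed, org_index, cfg)
    flags <- screen_organelle(passed, org_hits, cfg$max_evalue,
                              cfg$organelle_min_coverage)
    contaminated_reads <- names(flags)[flags]
  }
  contaminated_clones <- character(0)
  n_clones <- NA_integer_
  if (!is.null(clone_of)) {
    contaminated_clones <- unique(clone_of[contaminated_reads])
    n_clones <- length(unique(clone_of))
  }
  lens <- nchar(passed$sequence)
  report <- data.frame(
    n_input_reads = n_input,
    n_passing_reads = nrow(passed),
    mean_length_passing = if (nrow(passed)) round(mean(lens), 1) else NA_real_,
    min_length_passing = if (nrow(passed)) min(lens) else NA_integer_,
    n_contaminated_clones = length(contaminated_clones),
    contamination_percent = if (!is.na(n_clones) && n_clones > 0) {
      round(100 * length(contaminated_clones) / n_clones, 1)
    } else NA_real_)
  list(reads = passed,
       contaminated_reads = contaminated_reads,
       contaminated_clones = contaminated_clones,
       report = report,
       accounting = tq$accounting)
}
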