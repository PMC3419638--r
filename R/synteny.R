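# Paired-end microsynteny classification. A clone's two end reads are
# placed on the reference; the pair's orientation pattern and outer span
# (max end - min start, the projected insert size) determine its class:
#
#   C1  same chrom, opposite-inward (> <), span 20-300 kb   concordant
#   C2  same chrom, same orientation (<< or >>), 20-300 kb  discordant
#   C3  same chrom, opposite-inward, span > 300 kb          discordant
#   C4  same chrom, same orientation, span > 300 kb         discordant
#   C5  same chrom, opposite-outward (< >), span > 300 kb   discordant
#   C6  both ends aligned, different chromosomes            discordant
#   C7  one end aligned, single hit
#   C8  one end aligned, multiple hits
#   C9  no end aligned
#
# Combinations the class grid leaves out (spans below 20 kb, and
# opposite-outward spans up to 300 kb) get extension labels X1-X4; they are
# reported distinctly and count as discordant, never folded into C1-C6.

#' Orientation pattern of a mapped pair
#'
#' Let U be the hit with the smaller ref_start and D the other.
#' `opposite_in` is U on '+' and D on '-' (reads point toward each other,
#' the concordant pattern), `opposite_out` the reverse, `same` equal
#' strands.
#'
#' @param hit_a,hit_b single-row alignment hits on the same chromosome.
#' @return one of "opposite_in", "opposite_out", "same".
#' @export
pair_orientation <- function(hit_a, hit_b) {
  if (hit_a$chrom != hit_b$chrom) {
    stopf("pair_orientation requires hits on the same chromosome")
  }
  if (hit_a$ref_start <= hit_b$ref_start) {
    u <- hit_a; d <- hit_b
  } else {
    u <- hit_b; d <- hit_a
  }
  if (u$strand == d$strand) return("same")
  if (u$strand == "+") "opposite_in" else "opposite_out"
}

# span-band classification shared by the classifier and the simulator's
# geometric truth. Window boundaries are closed on the concordant side:
# 20,000 <= span <= 300,000 is "in range".
class_from_geometry <- function(orientation, span, min_span, max_span) {
  band <- if (span < min_span) "short" else if (span <= max_span) "in" else "long"
  switch(orientation,
    opposite_in  = c(short = "X1", "in" = "C1", long = "C3")[[band]],
    same         = c(short = "X2", "in" = "C2", long = "C4")[[band]],
    opposite_out = c(short = "X3", "in" = "X4", long = "C5")[[band]])
}

#' Classify a mapped pair into a synteny class
#'
#' @param hit_f,hit_r single-row alignment hits for the two ends, already
#'   filtered for E-value and repeat exclusion. Must be on the same
#'   chromosome (different chromosomes are class C6, decided by the
#'   caller).
#' @param min_span,max_span concordance span window in bp (closed window;
#'   spans above `max_span` are "long").
#' @return list with class_label, orientation, span, concordant.
#' @export
classify_pair <- function(hit_f, hit_r, min_span = 20000, max_span = 300000) {
  orientation <- pair_orientation(hit_f, hit_r)
  span <- max(hit_f$ref_end, hit_r$ref_end) -
    min(hit_f$ref_start, hit_r$ref_start)
  label <- class_from_geometry(orientation, span, min_span, max_span)
  list(class_label = label, orientation = orientation, span = span,
       concordant = identical(label, "C1"))
}

#' Select the best placement for a read pair
#'
#' Over all same-chromosome combinations of one hit per end, returns the
#' pair maximising the score sum. Ties are broken by (1) concordant class
#' first, (2) smaller span, (3) lexicographic chromosome name, then by
#' leftmost position for full determinism. Returns NULL if no
#' same-chromosome pairing exists.
#'
#' @param hits_f,hits_r alignment tables for the forward and reverse end.
#' @param min_span,max_span concordance window used for the tie-break.
#' @return list(hit_f, hit_r, score_sum, span, orientation, chrom) or NULL.
#' @export
select_best_placement <- function(hits_f, hits_r,
                                  min_span = 20000, max_span = 300000) {
  if (nrow(hits_f) == 0L || nrow(hits_r) == 0L) return(NULL)
  cand <- expand.grid(i = seq_len(nrow(hits_f)), j = seq_len(nrow(hits_r)))
  cand <- cand[hits_f$chrom[cand$i] == hits_r$chrom[cand$j], , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  score_sum <- hits_f$score[cand$i] + hits_r$score[cand$j]
  span <- pmax(hits_f$ref_end[cand$i], hits_r$ref_end[cand$j]) -
    pmin(hits_f$ref_start[cand$i], hits_r$ref_start[cand$j])
  concordant <- vapply(seq_len(nrow(cand)), function(k) {
    classify_pair(hits_f[cand$i[k], ], hits_r[cand$j[k], ],
                  min_span, max_span)$concordant
  }, logical(1))
  ord <- order(-score_sum, !concordant, span, hits_f$chrom[cand$i],
               pmin(hits_f$ref_start[cand$i], hits_r$ref_start[cand$j]))
  k <- ord[1]
  hit_f <- hits_f[cand$i[k], ]; hit_r <- hits_r[cand$j[k], ]
  list(hit_f = hit_f, hit_r = hit_r,
       score_sum = score_sum[k], span = span[k],
       orientation = pair_orientation(hit_f, hit_r), chrom = hit_f$chrom)
}

#' Classify every clone of a library
#'
#' Applies best-score-sum placement and the class grid to each clone's
#' surviving hits. Ends listed in `excluded_reads` (e.g. repeat-saturated
#' or contamination-flagged reads) are treated as unaligned. By default a
#' same-chromosome pairing, when one exists, wins over any cross-chromosome
#' combination regardless of score (C6 is assigned only when no
#' same-chromosome pairing exists); set `require_same_chrom = FALSE` in the
#' config to let a higher-scoring cross-chromosome pair force C6.
#'
#' @param pairs data.frame with columns clone_id, read_f, read_r.
#' @param hits alignment table covering all reads (already E-value
#'   filtered).
#' @param cfg a [bes_config()] (span window, require_same_chrom).
#' @param excluded_reads character vector of read ids to treat as
#'   unaligned.
#' @return data.frame with one row per clone: clone_id, class_label,
#'   concordant, chrom, ref_start, ref_end, span, orientation, score_sum,
#'   n_hits_f, n_hits_r.
#' @export
classify_library <- function(pairs, hits, cfg = bes_config(),
                             excluded_reads = character(0)) {
  if (anyDuplicated(pairs$clone_id)) {
    stopf("clone %s appears more than once",
          pairs$clone_id[duplicated(pairs$clone_id)][1])
  }
  extra <- setdiff(unique(hits$query_id),
                   c(pairs$read_f, pairs$read_r))
  if (length(extra)) {
    stopf("alignment table contains reads not paired to any clone: %s",
          paste(head(extra, 3), collapse = ", "))
  }
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    hf <- hits[hits$query_id == pairs$read_f[i] &
                 !(pairs$read_f[i] %in% excluded_reads), , drop = FALSE]
    hr <- hits[hits$query_id == pairs$read_r[i] &
                 !(pairs$read_r[i] %in% excluded_reads), , drop = FALSE]
    row <- data.frame(clone_id = pairs$clone_id[i], class_label = NA_character_,
                      concordant = FALSE, chrom = NA_character_,
                      ref_start = NA_integer_, ref_end = NA_integer_,
                      span = NA_integer_, orientation = NA_character_,
                      score_sum = NA_real_, n_hits_f = nrow(hf),
                      n_hits_r = nrow(hr), stringsAsFactors = FALSE)
    if (nrow(hf) == 0L && nrow(hr) == 0L) {
      row$class_label <- "C9"
    } else if (nrow(hf) == 0L || nrow(hr) == 0L) {
      solo <- if (nrow(hf)) hf else hr
      row$class_label <- if (nrow(solo) == 1L) "C7" else "C8"
      best <- solo[which.max(solo$score), ]
      row$chrom <- best$chrom; row$ref_start <- best$ref_start
      row$ref_end <- best$ref_end; row$score_sum <- best$score
    } else {
      placement <- select_best_placement(hf, hr, cfg$min_span, cfg$max_span)
      force_c6 <- FALSE
      if (!cfg$require_same_chrom && !is.null(placement)) {
        # allow a higher-scoring cross-chromosome combination to win
        best_cross <- max(outer(hf$score, hr$score, "+"))
        if (best_cross > placement$score_sum) force_c6 <- TRUE
      }
      if (is.null(placement) || force_c6) {
        row$class_label <- "C6"
        bf <- hf[which.max(hf$score), ]; br <- hr[which.max(hr$score), ]
        row$score_sum <- bf$score + br$score
        row$chrom <- paste(bf$chrom, br$chrom, sep = ";")
      } else {
        cls <- classify_pair(placement$hit_f, placement$hit_r,
                             cfg$min_span, cfg$max_span)
        row$class_label <- cls$class_label
        row$concordant <- cls$concordant
        row$chrom <- placement$chrom
        row$ref_start <- min(placement$hit_f$ref_start,
                             placement$hit_r$ref_start)
        row$ref_end <- max(placement$hit_f$ref_end, placement$hit_r$ref_end)
        row$span <- cls$span
        row$orientation <- cls$orientation
        row$score_sum <- placement$score_sum
      }
    }
    res[[i]] <- row
  }
  do.call(rbind, res)
}

#' Class count table with accounting identities
#'
#' Tabulates synteny calls by class and derives the aligned-BES and no-hit
#' totals: every clone in C1-C6 contributes two aligned ends, C7/C8 one
#' aligned and one unaligned end, C9 two unaligned ends. The class counts
#' always partition the clone set.
#'
#' @param calls data.frame from [classify_library()].
#' @return list with `counts` (data.frame class_label, n) and the derived
#'   totals n_clones, aligned_bes, nohit_bes.
#' @export
class_count_table <- function(calls) {
  levels_all <- c(paste0("C", 1:9), paste0("X", 1:4))
  tab <- table(factor(calls$class_label, levels = levels_all))
  counts <- data.frame(class_label = names(tab), n = as.integer(tab),
                       stringsAsFactors = FALSE)
  n <- function(lbl) sum(counts$n[counts$class_label %in% lbl])
  both <- n(c("C1", "C2", "C3", "C4", "C5", "C6", "X1", "X2", "X3", "X4"))
  single <- n(c("C7", "C8"))
  none <- n("C9")
  list(counts = counts[counts$n > 0 | counts$class_label %in% paste0("C", 1:9), ],
       n_clones = nrow(calls),
       aligned_bes = 2L * both + single,
       nohit_bes = 2L * none + single)
}
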