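# One-call dataset generator: query genome, rearrangement plan, derived
# reference, clones planted per synteny class, end reads, contamination
# and repeats -- everything written to disk together with the ground
# truth, reproducibly from (config, seed).
#
# Planting mechanisms per class:
#   C1  clone inside one ordinary block, projected span inside the window
#   C2  as C1 with one end reverse-complemented (small terminal inversion
#       of the query relative to the reference)
#   C3  clone inside a strongly expanded ("jumbo") block: span > 300 kb
#   C4  jumbo block + one end flipped
#   C5  jumbo block + both ends flipped (opposite-outward)
#   C6  clone straddling a block boundary whose two blocks map to
#       different reference chromosomes (translocation)
#   C7  one end replaced by query-specific sequence; the other intact
#   C8  as C7, with two extra copies of the intact end's footprint
#       written elsewhere in the reference (multi-hit end)
#   C9  both ends query-specific
#
# End-read footprints are resampled until they avoid block boundaries and
# expansion/contraction edit points, so each read is contiguous in the
# reference and the planted class is exact by construction.

counts_from_mix <- function(mix, n) {
  raw <- mix * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac_order <- order(raw - counts, decreasing = TRUE)
    counts[frac_order[seq_len(rem)]] <- counts[frac_order[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

opposite_strand <- function(s) ifelse(s == "+", "-", "+")

# Geometric truth class of a planted clone: projects both end footprints
# through the block map and applies the same orientation/span grid as the
# classifier. Returns NULL when a footprint fails to project (caller
# retries the placement).
truth_classify <- function(map, chrom, cs, ce, lf, lr, flip_f, flip_r,
                           novel_f, novel_r, n_copies, cfg) {
  if (novel_f && novel_r) return(list(class_label = "C9"))
  if (novel_f || novel_r) {
    return(list(class_label = if (n_copies > 0) "C8" else "C7"))
  }
  pf <- project_interval(map, chrom, cs, cs + lf)
  pr <- project_interval(map, chrom, ce - lr, ce)
  if (is.null(pf) || is.null(pr)) return(NULL)
  if (pf$chrom != pr$chrom) return(list(class_label = "C6"))
  strand_f <- if (flip_f) opposite_strand(pf$strand) else pf$strand
  strand_r <- if (flip_r) pr$strand else opposite_strand(pr$strand)
  hit_f <- data.frame(chrom = pf$chrom, ref_start = pf$start,
                      ref_end = pf$end, strand = strand_f)
  hit_r <- data.frame(chrom = pr$chrom, ref_start = pr$start,
                      ref_end = pr$end, strand = strand_r)
  cls <- classify_pair(hit_f, hit_r, cfg$min_span, cfg$max_span)
  cls
}

# Sample one clone of the requested class; errors after max_attempts.
plant_clone <- function(class, map, cfg, boundaries, max_attempts = 1000L) {
  blocks <- map$blocks
  normal <- blocks[!blocks$jumbo, , drop = FALSE]
  jumbo <- blocks[blocks$jumbo, , drop = FALSE]
  flip_f <- class %in% c("C2", "C4", "C5")
  flip_r <- class %in% "C5"
  novel_f <- class %in% "C9"
  novel_r <- class %in% c("C7", "C8", "C9")
  n_copies <- if (class == "C8") 2L else 0L
  pool <- if (class %in% c("C3", "C4", "C5")) jumbo else normal
  if (nrow(pool) == 0L) stopf("no blocks available to plant class %s", class)
  for (attempt in seq_len(max_attempts)) {
    insert <- sample_insert_sizes(1, cfg)
    lf <- sample_read_lengths(1, cfg, insert)
    lr <- sample_read_lengths(1, cfg, insert)
    if (class == "C6") {
      if (nrow(boundaries) == 0L) {
        stopf("plan has no translocation boundary to plant class C6")
      }
      b <- boundaries[sample.int(nrow(boundaries), 1), ]
      lo <- max(b$block_start, b$boundary - insert + lr)
      hi <- min(b$boundary - lf, b$block2_end - insert)
      if (lo > hi) next
      cs <- floor(runif(1, lo, hi + 1))
      chrom <- b$chrom
    } else {
      blen <- pool$query_end - pool$query_start
      ok <- blen >= insert + 2L
      if (!any(ok)) next
      cand <- pool[ok, , drop = FALSE]
      bi <- sample.int(nrow(cand), 1, prob = cand$query_end - cand$query_start)
      b <- cand[bi, ]
      cs <- floor(runif(1, b$query_start, b$query_end - insert + 1))
      chrom <- b$query_chrom
    }
    ce <- cs + insert
    if (!interval_is_contiguous(map, chrom, cs, cs + lf)) next
    if (!interval_is_contiguous(map, chrom, ce - lr, ce)) next
    cls <- truth_classify(map, chrom, cs, ce, lf, lr, flip_f, flip_r,
                          novel_f, novel_r, n_copies, cfg)
    if (is.null(cls) || cls$class_label != class) next
    return(list(chrom = chrom, start = cs, end = ce,
                insert_size = as.integer(insert),
                lf = as.integer(lf), lr = as.integer(lr),
                flip_f = flip_f, flip_r = flip_r,
                novel_f = novel_f, novel_r = novel_r,
                n_copies = n_copies, truth_class = class))
  }
  stopf("could not plant a class %s clone after %d attempts",
        class, max_attempts)
}

# Adjacent same-chromosome block pairs whose reference chromosomes
# differ; clones straddling such a boundary become class C6.
find_c6_boundaries <- function(blocks) {
  out <- list()
  for (ch in unique(blocks$query_chrom)) {
    b <- blocks[blocks$query_chrom == ch, ]
    b <- b[order(b$query_start), ]
    if (nrow(b) < 2) next
    for (i in seq_len(nrow(b) - 1)) {
      if (b$ref_chrom[i] != b$ref_chrom[i + 1]) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, boundary = b$query_end[i],
          block_start = b$query_start[i], block2_end = b$query_end[i + 1],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), boundary = integer(0),
                      block_start = integer(0), block2_end = integer(0)))
  }
  do.call(rbind, out)
}

#' Generate a complete synthetic BES dataset with ground truth
#'
#' Builds the query genome (optionally repeat-laden), a rearrangement
#' plan, the derived reference, clones planted according to the
#' configured class mix, finished end reads (vector flank, quality decay,
#' base-call errors) and organelle contamination, and writes everything
#' plus the truth tables to `out_dir`. Identical (config, seed) produce
#' byte-identical outputs.
#'
#' @param cfg a [bes_config()]; `seed` is mandatory.
#' @param out_dir output directory (created if needed).
#' @return invisible list: file paths, the query/reference genomes, the
#'   truth set (plan, edits, clones, repeat intervals, contaminated clone
#'   ids, planted mean expansion) and the finished reads.
#' @export
make_dataset <- function(cfg = bes_config(), out_dir) {
  seed <- require_seed(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  repeat_library <- if (cfg$repeat_density > 0) {
    simulate_repeat_library(substream_seed(seed, "lib"))
  } else NULL
  organelle <- simulate_organelle_genome(cfg$organelle_len,
                                         substream_seed(seed, "org"))
  vector_seq <- simulate_vector(seed = substream_seed(seed, "vec"))

  qg <- generate_query_genome(cfg$n_chroms, cfg$chrom_len, cfg$gc,
                              repeat_library, cfg$repeat_density,
                              substream_seed(seed, "genome"),
                              cfg$repeat_divergence)

  counts <- counts_from_mix(cfg$class_mix, cfg$n_clones)
  names(counts) <- names(cfg$class_mix)
  n_long <- sum(counts[intersect(names(counts), c("C3", "C4", "C5"))])
  n_jumbo <- if (n_long > 0) max(2L, ceiling(n_long / 10)) else 0L

  plan <- make_rearrangement_plan(qg$genome, cfg,
                                  substream_seed(seed, "plan"), n_jumbo)
  # guarantee a translocation boundary when C6 clones are requested
  n_c6 <- if ("C6" %in% names(counts)) counts[["C6"]] else 0L
  if (n_c6 > 0 && nrow(find_c6_boundaries(plan)) == 0L) {
    with_substream(seed, "force_transloc", {
      cand <- which(!plan$jumbo)
      i <- cand[sample.int(length(cand), 1)]
      others <- setdiff(unique(plan$ref_chrom), plan$ref_chrom[i])
      plan$ref_chrom[i] <- others[sample.int(length(others), 1)]
    })
  }
  ref <- derive_reference_genome(qg$genome, plan,
                                 substream_seed(seed, "ref"), cfg$gc)
  map <- ref$map
  boundaries <- find_c6_boundaries(map$blocks)

  class_seq <- rep(names(counts), counts)
  clones <- vector("list", length(class_seq))
  with_substream(seed, "plant", {
    for (i in seq_along(class_seq)) {
      clones[[i]] <- plant_clone(class_seq[i], map, cfg, boundaries)
    }
  })
  clones <- do.call(rbind, lapply(clones, as.data.frame,
                                  stringsAsFactors = FALSE))
  clones <- cbind(clone_id = sprintf("BAC%04d", seq_len(nrow(clones))),
                  clones, stringsAsFactors = FALSE)
  clones$origin <- "genome"

  # A multi-hit (C8) clone's intact-end footprint is copied elsewhere in
  # the reference; if that footprint overlapped another read's footprint
  # in the query, the copies would duplicate the other read too and give
  # it spurious hits. Re-place C8 clones until their source footprints
  # are footprint-disjoint from every other read.
  with_substream(seed, "c8_disjoint", {
    footprint_table <- function(cl) {
      data.frame(chrom = rep(cl$chrom, 2L),
                 start = c(cl$start, cl$end - cl$lr),
                 end = c(cl$start + cl$lf, cl$end),
                 clone = rep(cl$clone_id, 2L))
    }
    fps <- do.call(rbind, lapply(seq_len(nrow(clones)),
                                 function(i) footprint_table(clones[i, ])))
    for (i in which(clones$n_copies > 0)) {
      for (attempt in 1:50) {
        cl <- clones[i, ]
        other <- fps[fps$clone != cl$clone_id, ]
        clash <- any(other$chrom == cl$chrom &
                       other$start < cl$start + cl$lf &
                       other$end > cl$start)
        if (!clash) break
        repl <- plant_clone(cl$truth_class, map, cfg, boundaries)
        clones[i, names(repl)] <- repl
        fps[fps$clone == cl$clone_id, c("chrom", "start", "end")] <-
          footprint_table(clones[i, ])[, c("chrom", "start", "end")]
      }
    }
  })

  # organelle contamination replaces whole clones
  clones <- inject_contamination(clones, cfg$organelle_len,
                                 cfg$contamination_rate,
                                 substream_seed(seed, "contam"))
  contaminated <- clones$origin == "chloroplast"
  clones$truth_class[contaminated] <- NA_character_
  clones$n_copies[contaminated] <- 0L

  # extract the end reads
  reads <- with_substream(seed, "extract", {
    fwd <- character(nrow(clones)); rev <- character(nrow(clones))
    for (i in seq_len(nrow(clones))) {
      cl <- clones[i, ]
      if (cl$origin == "chloroplast") {
        f <- circular_substr(organelle[[1]], cl$start, cl$start + cl$lf)
        r <- reverse_complement(circular_substr(organelle[[1]],
                                                cl$end - cl$lr, cl$end))
      } else {
        g <- qg$genome[[cl$chrom]]
        f <- substr(g, cl$start + 1, cl$start + cl$lf)
        r <- reverse_complement(substr(g, cl$end - cl$lr + 1, cl$end))
        if (cl$novel_f) f <- random_dna(cl$lf, cfg$gc)
        if (cl$novel_r) r <- random_dna(cl$lr, cfg$gc)
        if (cl$flip_f) f <- reverse_complement(f)
        if (cl$flip_r) r <- reverse_complement(r)
      }
      fwd[i] <- f; rev[i] <- r
    }
    data.frame(
      id = c(rbind(paste0(clones$clone_id, "_f"),
                   paste0(clones$clone_id, "_r"))),
      description = "",
      sequence = c(rbind(fwd, rev)), stringsAsFactors = FALSE)
  })

  # multi-hit (C8) ends: write extra copies of the intact end's footprint
  # into free reference locations, clear of every projected footprint
  reference <- ref$reference
  with_substream(seed, "copies", {
    occupied <- list()  # per ref chrom: claimed intervals
    add_iv <- function(ch, s, e) {
      occupied[[ch]] <<- rbind(occupied[[ch]], c(s, e))
    }
    for (i in seq_len(nrow(clones))) {
      cl <- clones[i, ]
      if (cl$origin == "chloroplast") next
      for (iv in list(c(cl$start, cl$start + cl$lf),
                      c(cl$end - cl$lr, cl$end))) {
        p <- project_interval(map, cl$chrom, iv[1], iv[2])
        if (!is.null(p)) add_iv(p$chrom, p$start, p$end)
      }
    }
    margin <- cfg$hit_window + 2000
    for (i in which(clones$n_copies > 0)) {
      cl <- clones[i, ]
      src <- substr(qg$genome[[cl$chrom]], cl$start + 1, cl$start + cl$lf)
      len <- nchar(src)
      for (copy in seq_len(cl$n_copies)) {
        for (attempt in 1:200) {
          ch <- sample(names(reference), 1, prob = nchar(reference))
          pos <- floor(runif(1, 0, nchar(reference[[ch]]) - len))
          occ <- occupied[[ch]]
          clash <- !is.null(occ) &&
            any(occ[, 1] < pos + len + margin & occ[, 2] > pos - margin)
          if (clash) next
          substr(reference[[ch]], pos + 1, pos + len) <- src
          add_iv(ch, pos, pos + len)
          break
        }
      }
    }
  })

  reads <- finish_reads(reads, cfg, vector_seq,
                        substream_seed(seed, "finish"))

  # ground truth and outputs
  planted_mean_expansion <- {
    nb <- map$blocks[!map$blocks$jumbo, ]
    sum(nb$scale * (nb$query_end - nb$query_start)) /
      sum(nb$query_end - nb$query_start)
  }
  truth <- list(plan = map$blocks, edits = map$edits, clones = clones,
                repeats = qg$repeats,
                contaminated_clones = clones$clone_id[contaminated],
                planted_mean_expansion = planted_mean_expansion)

  paths <- list(
    reads = file.path(out_dir, "reads.fastq"),
    reference = file.path(out_dir, "reference.fasta"),
    query = file.path(out_dir, "query.fasta"),
    inserts = file.path(out_dir, "inserts.tsv"),
    vector = file.path(out_dir, "vector.fasta"),
    organelle = file.path(out_dir, "organelle.fasta"),
    repeat_library = file.path(out_dir, "repeat_library.fasta"),
    truth_clones = file.path(out_dir, "truth_clones.tsv"),
    truth_repeats = file.path(out_dir, "truth_repeats.tsv"),
    plan = file.path(out_dir, "plan.tsv"),
    config = file.path(out_dir, "config.yaml"))

  write_fastq(reads, paths$reads)
  write_fasta(reference, paths$reference)
  write_fasta(qg$genome, paths$query)
  write_tsv(clones[, c("clone_id", "insert_size")], paths$inserts)
  write_fasta(vector_seq, paths$vector)
  write_fasta(organelle, paths$organelle)
  if (!is.null(repeat_library)) {
    lineages <- vapply(repeat_library$family, function(f) {
      paste(taxonomy_lineage(default_repeat_taxonomy(), f), collapse = ";")
    }, character(1))
    write_fasta(data.frame(id = repeat_library$family,
                           description = lineages,
                           sequence = repeat_library$sequence),
                paths$repeat_library)
  } else paths$repeat_library <- NULL
  write_tsv(clones, paths$truth_clones)
  write_tsv(qg$repeats, paths$truth_repeats)
  write_tsv(map$blocks, paths$plan)
  save_config(cfg, paths$config)

  invisible(list(paths = paths, reference = reference, query = qg$genome,
                 reads = reads, truth = truth, cfg = cfg))
}
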