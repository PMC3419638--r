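# Synthetic genome generation. The query genome stands in for the sequenced
# (clone-library) genome; the reference genome is derived from it through a
# block-wise rearrangement plan (per-block expansion/contraction realised by
# random-sequence insertion/deletion, plus inversions and translocations),
# so that every clone's true reference placement is known exactly.

#' Simulate a repeat library with taxonomy lineages
#'
#' Generates one consensus sequence per family. Family lengths and genome
#' weights are calibrated so that, at the default density, repeat bases in
#' the genome are dominated by LTR retrotransposons (Copia + Gypsy), with
#' minor non-LTR, DNA-transposon, viral and satellite fractions -- the mix
#' reported for grass BAC-end surveys.
#'
#' @param seed integer RNG seed.
#' @param gc GC content of consensus sequences.
#' @return data.frame with columns family, length, weight (target share of
#'   repeat bases), sequence.
#' @export
simulate_repeat_library <- function(seed, gc = 0.46) {
  fams <- data.frame(
    family = c("Copia", "Gypsy", "L1", "RTE", "SINE", "SINE2/tRNA",
               "EnSpm", "Harbinger", "Helitron", "MuDr", "hAT",
               "Caulimoviridae", "Satellite"),
    length = c(4800L, 5200L, 3000L, 2500L, 300L, 250L,
               1500L, 1200L, 2000L, 1800L, 1000L, 1500L, 350L),
    # target share of repeat bases, from the surveyed repeat ledger
    weight = c(0.402, 0.432, 0.016, 0.018, 0.0014, 0.0014,
               0.033, 0.017, 0.0073, 0.0154, 0.019, 0.0075, 0.0117),
    stringsAsFactors = FALSE)
  fams$weight <- fams$weight / sum(fams$weight)
  with_substream(seed, "repeat_library", {
    fams$sequence <- vapply(fams$length, random_dna, character(1), gc = gc)
  })
  fams
}

# Overwrite a copy of `consensus` with substitutions at the given rate
# (each substituted base becomes one of the three other bases).
diverge_copy <- function(consensus, rate) {
  if (rate <= 0) return(consensus)
  n <- nchar(consensus)
  k <- rbinom(1, n, rate)
  if (k == 0L) return(consensus)
  raw <- charToRaw(consensus)
  pos <- sample.int(n, k)
  cur <- strsplit(rawToChar(raw[pos]), "")[[1]]
  altmat <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
  known <- cur %in% rownames(altmat)
  new <- character(k)
  new[known] <- altmat[cbind(match(cur[known], rownames(altmat)),
                             sample.int(3, sum(known), replace = TRUE))]
  if (any(!known)) {
    new[!known] <- c("A", "C", "G", "T")[sample.int(4, sum(!known),
                                                    replace = TRUE)]
  }
  raw[pos] <- charToRaw(paste(new, collapse = ""))
  rawToChar(raw)
}

#' Generate a query genome with planted repeats
#'
#' Background bases are i.i.d. at the requested GC content. Repeat copies
#' are placed at exponentially spaced (Poisson-process) positions, each copy
#' diverged from its family consensus by uniform substitutions at a rate
#' drawn from `divergence`, and optionally reverse-complemented. Planted
#' intervals are recorded as ground truth.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_len length of each chromosome (bp).
#' @param gc background GC content in (0, 1).
#' @param repeat_library data.frame from [simulate_repeat_library()], or
#'   NULL for a repeat-free genome.
#' @param repeat_density target fraction of bases covered by repeats, in
#'   [0, 0.9]; densities above 0.9 are rejected.
#' @param seed integer RNG seed.
#' @param divergence range of per-copy substitution rates.
#' @return list with `genome` (named character vector, chromosomes
#'   q01..qNN) and `repeats` (data.frame chrom, start, end, family, strand,
#'   divergence; 0-based half-open).
#' @export
generate_query_genome <- function(n_chroms, chrom_len, gc,
                                  repeat_library = NULL, repeat_density = 0,
                                  seed, divergence = c(0.02, 0.12)) {
  if (gc <= 0 || gc >= 1) stopf("gc must be in (0, 1)")
  if (repeat_density > 0.9) {
    stopf("repeat_density %.2f would exceed 90%% of a chromosome", repeat_density)
  }
  if (repeat_density > 0 && is.null(repeat_library)) {
    stopf("repeat_density > 0 requires a repeat library")
  }
  chrom_names <- sprintf("q%02d", seq_len(n_chroms))
  genome <- setNames(character(n_chroms), chrom_names)
  planted <- list()
  with_substream(seed, "query_genome", {
    for (ci in seq_len(n_chroms)) {
      seq_str <- random_dna(chrom_len, gc)
      if (repeat_density > 0) {
        raw <- charToRaw(seq_str)
        copy_prob <- repeat_library$weight / repeat_library$length
        # expected copy length under the sampling distribution, so the
        # renewal process realises the requested coverage density
        mean_len <- sum(copy_prob * repeat_library$length) / sum(copy_prob)
        gap_mean <- mean_len * (1 - repeat_density) / repeat_density
        pos <- 0
        rows <- list()
        repeat {
          pos <- pos + stats::rexp(1, 1 / gap_mean)
          fam <- sample.int(nrow(repeat_library), 1, prob = copy_prob)
          flen <- repeat_library$length[fam]
          start <- floor(pos)
          if (start + flen > chrom_len) break
          div <- runif(1, divergence[1], divergence[2])
          copy <- diverge_copy(repeat_library$sequence[fam], div)
          strand <- if (runif(1) < 0.5) "+" else "-"
          if (strand == "-") copy <- reverse_complement(copy)
          raw[(start + 1):(start + flen)] <- charToRaw(copy)
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom_names[ci], start = start, end = start + flen,
            family = repeat_library$family[fam], strand = strand,
            divergence = div, stringsAsFactors = FALSE)
          pos <- start + flen
        }
        seq_str <- rawToChar(raw)
        if (length(rows)) planted[[length(planted) + 1L]] <- do.call(rbind, rows)
      }
      genome[ci] <- seq_str
    }
  })
  repeats <- if (length(planted)) do.call(rbind, planted) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               family = character(0), strand = character(0),
               divergence = numeric(0), stringsAsFactors = FALSE)
  list(genome = genome, repeats = repeats)
}

#' Draw a block-wise rearrangement plan
#'
#' Tiles each query chromosome into equal blocks and assigns each block a
#' scale factor (a mixture of mildly contracted and expanded components
#' whose mean is the target mean expansion), an inversion flag and a
#' reference chromosome (translocated blocks map to a different chromosome).
#' Optionally marks `n_jumbo` blocks as strongly expanded; these host
#' long-span discordant clones and are excluded from the concordant pool.
#'
#' @param genome named character vector of query chromosomes.
#' @param cfg a [bes_config()] (uses blocks_per_chrom, scale mixture,
#'   p_invert, p_transloc, jumbo_scale).
#' @param seed integer RNG seed.
#' @param n_jumbo number of strongly expanded blocks.
#' @return data.frame of blocks: block_id, query_chrom, query_start,
#'   query_end, ref_chrom, scale, inverted, jumbo. Blocks tile each query
#'   chromosome without overlap; scales lie in [0.1, 10].
#' @export
make_rearrangement_plan <- function(genome, cfg = bes_config(), seed,
                                    n_jumbo = 0L) {
  chrom_names <- names(genome)
  ref_names <- sub("^q", "r", chrom_names)
  per <- cfg$blocks_per_chrom
  rows <- list()
  with_substream(seed, "plan", {
    for (ci in seq_along(genome)) {
      len <- nchar(genome[[ci]])
      bounds <- round(seq(0, len, length.out = per + 1))
      for (b in seq_len(per)) {
        contract <- runif(1) < cfg$p_contract
        s <- if (contract) runif(1, cfg$contract_scale[1], cfg$contract_scale[2])
             else runif(1, cfg$expand_scale[1], cfg$expand_scale[2])
        rc <- if (runif(1) < cfg$p_transloc && length(genome) > 1) {
          sample(setdiff(ref_names, ref_names[ci]), 1)
        } else ref_names[ci]
        rows[[length(rows) + 1L]] <- data.frame(
          query_chrom = chrom_names[ci], query_start = bounds[b],
          query_end = bounds[b + 1], ref_chrom = rc, scale = s,
          inverted = runif(1) < cfg$p_invert, jumbo = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    plan <- do.call(rbind, rows)
    plan$block_id <- seq_len(nrow(plan))
    if (n_jumbo > 0) {
      jm <- sample.int(nrow(plan), n_jumbo)
      plan$jumbo[jm] <- TRUE
      plan$scale[jm] <- runif(n_jumbo, cfg$jumbo_scale[1], cfg$jumbo_scale[2])
    }
    validate_plan(plan, genome)
  })
}

validate_plan <- function(plan, genome) {
  if (any(plan$scale < 0.1 | plan$scale > 10)) {
    stopf("plan scale factors must lie in [0.1, 10]")
  }
  for (ch in names(genome)) {
    b <- plan[plan$query_chrom == ch, ]
    b <- b[order(b$query_start), ]
    if (nrow(b) == 0L) stopf("plan does not cover chromosome %s", ch)
    if (b$query_start[1] != 0 || b$query_end[nrow(b)] != nchar(genome[[ch]]) ||
        (nrow(b) > 1 && any(b$query_end[-nrow(b)] != b$query_start[-1]))) {
      stopf("plan blocks do not tile chromosome %s", ch)
    }
  }
  plan
}

# Draw the per-block edit list realising a scale factor: insertions of
# random sequence (scale > 1) or deletions (scale < 1), in at most 50
# chunks placed uniformly within the block. Edits are expressed in block
# offsets: an insertion adds `len` bases immediately before offset `pos`;
# a deletion removes [pos, pos + len).
draw_block_edits <- function(block_id, block_len, delta) {
  if (delta == 0) {
    return(data.frame(block_id = integer(0), type = character(0),
                      pos = integer(0), len = integer(0)))
  }
  total <- abs(delta)
  n_chunks <- min(50L, max(1L, ceiling(total / 5000)))
  sizes <- diff(round(seq(0, total, length.out = n_chunks + 1)))
  sizes <- sizes[sizes > 0]
  n_chunks <- length(sizes)
  if (delta > 0) {
    pos <- sort(sample.int(block_len + 1L, n_chunks, replace = TRUE) - 1L)
    return(data.frame(block_id = block_id, type = "ins", pos = pos,
                      len = as.integer(sizes), stringsAsFactors = FALSE))
  }
  # deletions: non-overlapping intervals inside the block
  for (attempt in 1:100) {
    starts <- sort(sample.int(block_len - max(sizes), n_chunks))
    ends <- starts + sizes
    if (n_chunks == 1L || all(starts[-1] > ends[-n_chunks])) {
      return(data.frame(block_id = block_id, type = "del", pos = starts,
                        len = as.integer(sizes), stringsAsFactors = FALSE))
    }
  }
  stopf("could not place %d non-overlapping deletions in block %d",
        n_chunks, block_id)
}

#' Derive the reference genome from a query genome and a plan
#'
#' Each block of the query is copied to its reference chromosome in plan
#' order. Scale factors above 1 are realised by inserting random sequence
#' at uniform positions within the block copy, below 1 by deleting uniform
#' chunks; inverted blocks are reverse-complemented after editing. The
#' returned map records every edit, giving an exact query-to-reference
#' coordinate correspondence outside edited bases.
#'
#' @param query named character vector of query chromosomes.
#' @param plan block plan from [make_rearrangement_plan()].
#' @param seed integer RNG seed (edit placement and inserted sequence).
#' @param gc GC content of inserted random sequence.
#' @return list with `reference` (named character vector) and `map` (list
#'   of `blocks` -- the plan with realised ref_len/ref_start -- and `edits`).
#' @export
derive_reference_genome <- function(query, plan, seed, gc = 0.44) {
  validate_plan(plan, query)
  plan <- plan[order(match(plan$query_chrom, names(query)), plan$query_start), ]
  with_substream(seed, "reference", {
    edits_list <- vector("list", nrow(plan))
    realized <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
      b <- plan[i, ]
      lq <- b$query_end - b$query_start
      lr <- round(b$scale * lq)
      ed <- draw_block_edits(b$block_id, lq, lr - lq)
      edits_list[[i]] <- ed
      raw <- charToRaw(substr(query[[b$query_chrom]], b$query_start + 1,
                              b$query_end))
      if (nrow(ed)) {
        dels <- ed[ed$type == "del", ]
        if (nrow(dels)) {
          drop <- unlist(mapply(function(p, l) seq(p + 1L, p + l),
                                dels$pos, dels$len, SIMPLIFY = FALSE))
          raw <- raw[-drop]
        }
        ins <- ed[ed$type == "ins", ]
        if (nrow(ins)) {
          # apply from the rightmost insertion so earlier offsets stay valid
          for (j in rev(seq_len(nrow(ins)))) {
            p <- ins$pos[j]
            chunk <- charToRaw(random_dna(ins$len[j], gc))
            raw <- c(raw[seq_len(p)], chunk,
                     if (p < length(raw)) raw[(p + 1L):length(raw)])
          }
        }
      }
      seq_block <- rawToChar(raw)
      if (b$inverted) seq_block <- reverse_complement(seq_block)
      realized[[i]] <- seq_block
      plan$ref_len[i] <- nchar(seq_block)
    }
    edits <- do.call(rbind, edits_list)
    # lay blocks onto reference chromosomes in plan order
    ref_names <- unique(sub("^q", "r", names(query)))
    reference <- setNames(character(length(ref_names)), ref_names)
    plan$ref_start <- NA_integer_
    for (rn in ref_names) {
      idx <- which(plan$ref_chrom == rn)
      offset <- 0L
      pieces <- character(0)
      for (i in idx) {
        plan$ref_start[i] <- offset
        offset <- offset + plan$ref_len[i]
        pieces <- c(pieces, realized[[i]])
      }
      reference[rn] <- paste(pieces, collapse = "")
    }
    list(reference = reference, map = list(blocks = plan, edits = edits))
  })
}

# Locate the plan block containing query position `pos` on `chrom`.
find_block <- function(map, chrom, pos) {
  b <- map$blocks
  hit <- which(b$query_chrom == chrom & b$query_start <= pos & pos < b$query_end)
  if (length(hit) != 1L) return(NA_integer_)
  hit
}

# Project one query position (0-based) into reference coordinates.
# Returns list(chrom, pos, strand) or NULL if the base was deleted.
project_point <- function(map, chrom, pos) {
  i <- find_block(map, chrom, pos)
  if (is.na(i)) return(NULL)
  b <- map$blocks[i, ]
  o <- pos - b$query_start
  ed <- map$edits[map$edits$block_id == b$block_id, , drop = FALSE]
  shift <- 0L
  if (nrow(ed)) {
    dels <- ed[ed$type == "del", , drop = FALSE]
    if (nrow(dels)) {
      inside <- dels$pos <= o & o < dels$pos + dels$len
      if (any(inside)) return(NULL)
      shift <- shift - sum(dels$len[dels$pos + dels$len <= o])
    }
    ins <- ed[ed$type == "ins", , drop = FALSE]
    if (nrow(ins)) shift <- shift + sum(ins$len[ins$pos <= o])
  }
  o2 <- o + shift
  if (b$inverted) o2 <- b$ref_len - 1L - o2
  list(chrom = b$ref_chrom, pos = b$ref_start + o2,
       strand = if (b$inverted) "-" else "+", block_id = b$block_id)
}

# Project a query interval [start, end) into the reference. The interval
# must sit inside a single block and neither endpoint may be deleted;
# interior edits are allowed (they realise expansion/contraction of the
# projected span). Returns list(chrom, start, end, strand) or NULL.
project_interval <- function(map, chrom, start, end) {
  p1 <- project_point(map, chrom, start)
  p2 <- project_point(map, chrom, end - 1L)
  if (is.null(p1) || is.null(p2) || p1$block_id != p2$block_id) return(NULL)
  list(chrom = p1$chrom, start = min(p1$pos, p2$pos),
       end = max(p1$pos, p2$pos) + 1L, strand = p1$strand)
}

# TRUE iff the query interval [start, end) projects contiguously: one
# block, no deletion overlapping it and no insertion point strictly inside.
# Contiguous intervals are preserved verbatim in the reference, which is
# what planted read footprints require.
interval_is_contiguous <- function(map, chrom, start, end) {
  i1 <- find_block(map, chrom, start)
  i2 <- find_block(map, chrom, end - 1L)
  if (is.na(i1) || is.na(i2) || i1 != i2) return(FALSE)
  b <- map$blocks[i1, ]
  o1 <- start - b$query_start; o2 <- end - b$query_start  # offsets, half-open
  ed <- map$edits[map$edits$block_id == b$block_id, , drop = FALSE]
  if (nrow(ed) == 0L) return(TRUE)
  dels <- ed[ed$type == "del", , drop = FALSE]
  if (nrow(dels) && any(dels$pos < o2 & dels$pos + dels$len > o1)) return(FALSE)
  ins <- ed[ed$type == "ins", , drop = FALSE]
  if (nrow(ins) && any(ins$pos > o1 & ins$pos < o2)) return(FALSE)
  TRUE
}
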