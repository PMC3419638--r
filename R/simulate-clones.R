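# BAC clone and end-read simulation. Insert sizes follow a truncated
# normal calibrated to the surveyed library (mean 125 kb, observed range
# 29-293 kb, ~88% of inserts above 90 kb); end reads follow a truncated
# normal with mean 944 bp and a 312 bp floor, capped at half the insert.

# Truncated-normal sampler by rejection (truncation mass is tiny at the
# default calibration, so rejection is cheap).
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n - length(out) + 16L, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  round(out[seq_len(n)])
}

sample_insert_sizes <- function(n, cfg) {
  rnorm_trunc(n, cfg$insert_mean, cfg$insert_sd, cfg$insert_min, cfg$insert_max)
}

sample_read_lengths <- function(n, cfg, insert_size) {
  cap <- floor(insert_size / 2)
  pmin(rnorm_trunc(n, cfg$read_mean, cfg$read_sd, cfg$read_min, Inf), cap)
}

#' Sample BAC clones uniformly over a genome
#'
#' Clone positions are uniform over chromosomes (weighted by length);
#' insert sizes are drawn from the configured truncated-normal model. No
#' clone crosses a chromosome end.
#'
#' @param genome named character vector of chromosomes.
#' @param n number of clones (>= 0).
#' @param cfg a [bes_config()] (insert-size model).
#' @param seed integer RNG seed.
#' @return data.frame: clone_id, chrom, start, end, insert_size, origin
#'   (0-based half-open coordinates on the query genome).
#' @export
sample_bac_clones <- function(genome, n, cfg = bes_config(), seed) {
  if (n < 0) stopf("number of clones must be non-negative")
  if (n == 0) {
    return(data.frame(clone_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      insert_size = integer(0), origin = character(0),
                      stringsAsFactors = FALSE))
  }
  lens <- nchar(genome)
  with_substream(seed, "clones", {
    inserts <- sample_insert_sizes(n, cfg)
    chrom_i <- sample.int(length(genome), n, replace = TRUE, prob = lens)
    start <- vapply(seq_len(n), function(i) {
      room <- lens[chrom_i[i]] - inserts[i]
      if (room < 0) stopf("insert larger than chromosome %s",
                          names(genome)[chrom_i[i]])
      floor(runif(1, 0, room + 1))
    }, numeric(1))
    data.frame(clone_id = sprintf("BAC%04d", seq_len(n)),
               chrom = names(genome)[chrom_i],
               start = as.integer(start),
               end = as.integer(start + inserts),
               insert_size = as.integer(inserts),
               origin = "genome", stringsAsFactors = FALSE)
  })
}

#' Extract paired end reads from clones
#'
#' The forward read is the 5' end of the insert on its strand; the reverse
#' read is the reverse complement of the 3' end, so a concordant pair maps
#' to the reference in opposite-inward orientation. Base-call errors
#' (uniform substitutions) and a 3'-decaying quality profile are applied by
#' [finish_reads()].
#'
#' @param genome named character vector the clones were sampled from.
#' @param clones data.frame from [sample_bac_clones()].
#' @param cfg a [bes_config()] (read-length model).
#' @param seed integer RNG seed.
#' @return list with `reads` (data.frame id, description, sequence) and
#'   `footprints` (data.frame read_id, clone_id, end, chrom, start, end_pos,
#'   flipped -- the exact query interval each read was copied from).
#' @export
extract_bes <- function(genome, clones, cfg = bes_config(), seed) {
  n <- nrow(clones)
  if (any(clones$insert_size < 2 * cfg$read_min)) {
    bad <- clones$clone_id[clones$insert_size < 2 * cfg$read_min][1]
    stopf("insert of clone %s shorter than twice the minimum read length", bad)
  }
  with_substream(seed, "bes", {
    lf <- sample_read_lengths(n, cfg, clones$insert_size)
    lr <- sample_read_lengths(n, cfg, clones$insert_size)
    fwd <- substr(genome[clones$chrom], clones$start + 1, clones$start + lf)
    rev_raw <- substr(genome[clones$chrom], clones$end - lr + 1, clones$end)
    rev <- reverse_complement(rev_raw)
    reads <- data.frame(
      id = c(rbind(paste0(clones$clone_id, "_f"), paste0(clones$clone_id, "_r"))),
      description = "",
      sequence = c(rbind(unname(fwd), unname(rev))),
      stringsAsFactors = FALSE)
    fp <- data.frame(
      read_id = reads$id,
      clone_id = rep(clones$clone_id, each = 2),
      end = rep(c("f", "r"), n),
      chrom = rep(clones$chrom, each = 2),
      start = c(rbind(clones$start, clones$end - lr)),
      end_pos = c(rbind(clones$start + lf, clones$end)),
      flipped = FALSE, stringsAsFactors = FALSE)
    list(reads = reads, footprints = fp)
  })
}

#' Replace clones with organelle-derived inserts
#'
#' Each clone is independently replaced with probability `rate`,
#' emulating organelle (chloroplast) contamination of the library.
#' Replaced clones keep their insert size; their origin becomes the
#' organelle label and their coordinates refer to the (circular) organelle
#' genome.
#'
#' @param clones data.frame from [sample_bac_clones()].
#' @param organelle_len length of the organelle genome (bp).
#' @param rate per-clone replacement probability in [0, 1].
#' @param seed integer RNG seed.
#' @return the clones data.frame with `origin`/coordinates updated.
#' @export
inject_contamination <- function(clones, organelle_len, rate, seed) {
  if (rate < 0 || rate > 1) stopf("contamination rate must be in [0, 1]")
  if (nrow(clones) == 0L || rate == 0) return(clones)
  with_substream(seed, "contamination", {
    hit <- runif(nrow(clones)) < rate
    if (any(hit)) {
      clones$origin[hit] <- "chloroplast"
      clones$chrom[hit] <- "chloroplast"
      # circular genome: start anywhere, insert wraps if needed
      clones$start[hit] <- floor(runif(sum(hit), 0, organelle_len))
      clones$end[hit] <- clones$start[hit] + clones$insert_size[hit]
    }
    clones
  })
}

# Substring of a circular sequence, 0-based half-open, end may exceed length.
circular_substr <- function(seq_str, start, end) {
  len <- nchar(seq_str)
  s <- start %% len
  e <- end - start + s
  if (e <= len) return(substr(seq_str, s + 1, e))
  paste0(substr(seq_str, s + 1, len),
         strrep(seq_str, (e - len) %/% len),
         substr(seq_str, 1, (e - 1) %% len + 1))
}

#' Simulate an organelle (chloroplast-like) genome
#'
#' @param len genome length in bp.
#' @param seed integer RNG seed.
#' @param gc GC content (plastid genomes are AT-rich).
#' @return named character vector of length 1 ("chloroplast").
#' @export
simulate_organelle_genome <- function(len = 150000L, seed, gc = 0.38) {
  with_substream(seed, "organelle", {
    setNames(random_dna(len, gc), "chloroplast")
  })
}

#' Simulate a cloning-vector sequence
#'
#' Only the termini flanking the cloning site matter for trimming; a short
#' random plasmid-like sequence suffices.
#'
#' @param len vector length in bp.
#' @param seed integer RNG seed.
#' @return named character vector of length 1 ("vector").
#' @export
simulate_vector <- function(len = 3000L, seed) {
  with_substream(seed, "vector", {
    setNames(random_dna(len, 0.5), "vector")
  })
}

# Simulated base-call quality: high and flat over the first half of the
# read, decaying toward the 3' end as trace quality degrades.
quality_profile <- function(len) {
  x <- seq_len(len) / len
  q <- round(45 - 28 * x^1.5)
  pmax(q, 8L)
}

# Finish raw extracted reads for sequencing realism: prepend a vector
# flank (the run-through from the cloning site), attach qualities and
# apply uniform substitution errors. Returns the reads data.frame with a
# quality list-column and a vector_flank column recording the planted
# flank length.
finish_reads <- function(reads, cfg, vector_seq = NULL, seed) {
  n <- nrow(reads)
  if (n == 0L) return(reads)
  with_substream(seed, "finish_reads", {
    flanks <- integer(n)
    if (!is.null(vector_seq) && cfg$vector_flank[2] > 0) {
      vlen <- nchar(vector_seq)
      flanks <- sample(seq(cfg$vector_flank[1], cfg$vector_flank[2]), n,
                       replace = TRUE)
      prefix <- substr(rep(vector_seq, n), vlen - flanks + 1, vlen)
      reads$sequence <- paste0(prefix, reads$sequence)
    }
    lens <- nchar(reads$sequence)
    quals <- lapply(lens, function(l) {
      if (cfg$quality_decay) quality_profile(l) else rep(40L, l)
    })
    if (cfg$base_error_rate > 0) {
      for (i in seq_len(n)) {
        reads$sequence[i] <- diverge_copy(reads$sequence[i],
                                          cfg$base_error_rate)
      }
    }
    reads$quality <- quals
    reads$vector_flank <- flanks
    reads
  })
}
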