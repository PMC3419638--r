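# Shared builders for the test suite. Unit tests run on a scaled-down
# clone library (short chromosomes, 12-40 kb inserts, a 5-60 kb
# concordance window) so each file stays fast; the acceptance suite uses
# the full study-scale conditions.

small_cfg <- function(seed = 11, ...) {
  bes_config(seed = seed, n_chroms = 4, chrom_len = 400000,
             blocks_per_chrom = 4, n_clones = 30,
             insert_mean = 30000, insert_sd = 6000,
             insert_min = 12000, insert_max = 40000,
             min_span = 5000, max_span = 60000,
             repeat_density = 0, base_error_rate = 0,
             contamination_rate = 0,
             class_mix = c(C1 = 0.5, C2 = 0.1, C3 = 0.1, C6 = 0.1,
                           C7 = 0.1, C8 = 0.05, C9 = 0.05),
             ...)
}

random_reads <- function(genome, n, len_range = c(600, 1000), seed = 1) {
  withr::with_seed(seed, {
    lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
    chroms <- sample(names(genome), n, replace = TRUE,
                     prob = nchar(genome))
    data.frame(
      id = sprintf("read%04d", seq_len(n)),
      sequence = vapply(seq_len(n), function(i) {
        l <- lens[i]
        s <- sample(nchar(genome[[chroms[i]]]) - l, 1)
        seq_str <- substr(genome[[chroms[i]]], s, s + l - 1)
        if (runif(1) < 0.5) seq_str else reverse_complement(seq_str)
      }, character(1)),
      stringsAsFactors = FALSE)
  })
}

hit_key <- function(hits) {
  if (nrow(hits) == 0L) return(character(0))
  sort(paste(hits$chrom, hits$ref_start, hits$ref_end, hits$strand))
}

# one uniform-quality read row
one_read <- function(sequence, quality = NULL, id = "r1") {
  df <- data.frame(id = id, description = "", sequence = sequence,
                   stringsAsFactors = FALSE)
  df$quality <- list(if (is.null(quality)) rep(40L, nchar(sequence))
                     else as.integer(quality))
  df
}

fixtures_dir <- function() {
  system.file("extdata", "ss_sba", package = "besmap")
}

# mini alignment-hit row for synteny unit tests
mk_hit <- function(chrom, start, end, strand, score = 100,
                   id = "q", qlen = 500) {
  data.frame(query_id = id, query_start = 0L, query_end = qlen,
             chrom = chrom, ref_start = as.integer(start),
             ref_end = as.integer(end), strand = strand, score = score,
             evalue = 1e-50, pident = 100, mismatches = 0L,
             stringsAsFactors = FALSE)
}

# cache for expensive shared runs (used by the acceptance suite)
.shared <- new.env(parent = emptyenv())

shared_recovery_run <- function() {
  if (!is.null(.shared$recovery)) return(.shared$recovery)
  cfg <- bes_config(seed = 101, repeat_density = 0, base_error_rate = 0,
                    contamination_rate = 0)
  dir <- file.path(tempdir(), "besmap_recovery")
  ds <- make_dataset(cfg, dir)
  res <- run_analyze(ds$paths$reads, ds$paths$reference, ds$paths$inserts,
                     cfg, file.path(dir, "report"),
                     vector_path = ds$paths$vector,
                     organelle_path = ds$paths$organelle)
  .shared$recovery <- list(cfg = cfg, ds = ds, res = res)
  .shared$recovery
}
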