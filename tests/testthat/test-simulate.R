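test_that("query genome generation honours GC, density and determinism", {
  g0 <- generate_query_genome(2, 50000, 0.44, seed = 5)
  expect_equal(nrow(g0$repeats), 0L)
  expect_equal(unname(nchar(g0$genome)), c(50000L, 50000L))

  g1 <- generate_query_genome(1, 1000000, 0.5, seed = 6)
  bases <- table(strsplit(g1$genome[[1]], "")[[1]])
  gc <- (bases[["G"]] + bases[["C"]]) / 1e6
  expect_lt(abs(gc - 0.5), 0.01)  # binomial concentration at 1 Mb

  g2a <- generate_query_genome(2, 50000, 0.44, seed = 7)
  g2b <- generate_query_genome(2, 50000, 0.44, seed = 7)
  expect_identical(g2a, g2b)

  lib <- simulate_repeat_library(1)
  expect_error(
    generate_query_genome(1, 50000, 0.44, lib, 0.95, seed = 1),
    "90%")
})

test_that("planted repeats land where recorded", {
  lib <- simulate_repeat_library(2)
  g <- generate_query_genome(1, 300000, 0.44, lib, 0.3, seed = 8,
                             divergence = c(0, 0))
  expect_gt(nrow(g$repeats), 5)
  # zero divergence: planted intervals carry the exact consensus
  for (i in sample(nrow(g$repeats), 5)) {
    r <- g$repeats[i, ]
    planted <- substr(g$genome[[r$chrom]], r$start + 1, r$end)
    consensus <- lib$sequence[lib$family == r$family]
    if (r$strand == "-") consensus <- reverse_complement(consensus)
    expect_identical(planted, consensus)
  }
})

test_that("rearrangement plans tile the genome and conserve length", {
  g <- generate_query_genome(3, 200000, 0.44, seed = 3)
  cfg <- small_cfg()
  plan <- make_rearrangement_plan(g$genome, cfg, seed = 4)
  expect_equal(sum(plan$query_end - plan$query_start),
               sum(nchar(g$genome)))
  expect_true(all(plan$scale >= 0.1 & plan$scale <= 10))
  for (ch in names(g$genome)) {
    b <- plan[plan$query_chrom == ch, ]
    b <- b[order(b$query_start), ]
    expect_equal(b$query_start[1], 0)
    expect_equal(b$query_end[nrow(b)], nchar(g$genome[[ch]]))
  }
})

test_that("mean expansion of a many-block plan concentrates near 1.3", {
  # law of large numbers: 300 equal blocks with mixture mean 1.30
  # (mixture sd 0.24 => sd of the mean ratio ~0.014, so the 0.05 band
  # holds for essentially any seed)
  g <- generate_query_genome(30, 500000, 0.44, seed = 12)
  cfg <- bes_config(blocks_per_chrom = 10L, chrom_len = 3000000L)
  plan <- make_rearrangement_plan(g$genome, cfg, seed = 13)
  expect_gte(nrow(plan), 50)
  ref <- derive_reference_genome(g$genome, plan, seed = 14)
  ratio <- sum(nchar(ref$reference)) / sum(nchar(g$genome))
  expect_lt(abs(ratio - 1.3), 0.05)
})

test_that("reference derivation realises scale, inversion and identity", {
  g <- list(genome = setNames(besmap:::random_dna(100000, 0.5), "q01"))
  identity_plan <- data.frame(
    block_id = 1L, query_chrom = "q01", query_start = 0L,
    query_end = 100000L, ref_chrom = "r01", scale = 1,
    inverted = FALSE, jumbo = FALSE, stringsAsFactors = FALSE)
  ref <- derive_reference_genome(g$genome, identity_plan, seed = 1)
  expect_identical(unname(ref$reference[["r01"]]), unname(g$genome[["q01"]]))

  scaled <- identity_plan; scaled$scale <- 1.3
  ref13 <- derive_reference_genome(g$genome, scaled, seed = 2)
  expect_equal(nchar(ref13$reference[["r01"]]), 130000L)

  inv <- identity_plan; inv$inverted <- TRUE
  refi <- derive_reference_genome(g$genome, inv, seed = 3)
  expect_identical(unname(refi$reference[["r01"]]),
                   reverse_complement(unname(g$genome[["q01"]])))
})

test_that("coordinate projection is exact outside edited bases", {
  g <- list(genome = setNames(besmap:::random_dna(60000, 0.5), "q01"))
  plan <- data.frame(block_id = 1L, query_chrom = "q01", query_start = 0L,
                     query_end = 60000L, ref_chrom = "r01", scale = 1.4,
                     inverted = FALSE, jumbo = FALSE,
                     stringsAsFactors = FALSE)
  ref <- derive_reference_genome(g$genome, plan, seed = 5)
  # any contiguous query interval must appear verbatim at its projection
  withr::with_seed(6, {
    found <- 0
    for (i in 1:20) {
      s <- sample(59000, 1); e <- s + 500
      if (!besmap:::interval_is_contiguous(ref$map, "q01", s, e)) next
      p <- besmap:::project_interval(ref$map, "q01", s, e)
      expect_identical(
        substr(ref$reference[[p$chrom]], p$start + 1, p$end),
        substr(g$genome[["q01"]], s + 1, e))
      found <- found + 1
    }
    expect_gt(found, 5)
  })
})

test_that("insert-size model matches the library calibration", {
  g <- generate_query_genome(2, 3000000, 0.44, seed = 20)
  cfg <- bes_config()
  clones <- sample_bac_clones(g$genome, 1000, cfg, seed = 21)
  expect_equal(nrow(clones), 1000L)
  expect_lt(abs(mean(clones$insert_size) - 125000), 4000)
  expect_true(all(clones$insert_size >= 29000 &
                    clones$insert_size <= 293000))
  # ~88% of inserts above 90 kb, as surveyed
  expect_lt(abs(mean(clones$insert_size > 90000) - 0.88), 0.05)
  expect_true(all(clones$end <= nchar(g$genome[clones$chrom])))

  expect_equal(nrow(sample_bac_clones(g$genome, 0, cfg, seed = 1)), 0L)
  expect_error(sample_bac_clones(g$genome, -1, cfg, seed = 1),
               "non-negative")
})

test_that("end reads are exact oriented substrings at error rate zero", {
  g <- generate_query_genome(2, 3000000, 0.44, seed = 22)
  cfg <- bes_config()
  clones <- sample_bac_clones(g$genome, 378, cfg, seed = 23)
  bes <- extract_bes(g$genome, clones, cfg, seed = 24)
  expect_equal(nrow(bes$reads), 756L)
  lens <- nchar(bes$reads$sequence)
  expect_lt(abs(mean(lens) - 944), 15)  # CLT at sd 150, n 756
  expect_gte(min(lens), 312)
  for (i in sample(nrow(clones), 10)) {
    cl <- clones[i, ]
    f <- bes$reads$sequence[bes$reads$id == paste0(cl$clone_id, "_f")]
    r <- bes$reads$sequence[bes$reads$id == paste0(cl$clone_id, "_r")]
    expect_identical(f, substr(g$genome[[cl$chrom]], cl$start + 1,
                               cl$start + nchar(f)))
    expect_identical(reverse_complement(r),
                     substr(g$genome[[cl$chrom]], cl$end - nchar(r) + 1,
                            cl$end))
  }
  tiny <- clones[1, ]; tiny$insert_size <- 500L
  expect_error(extract_bes(g$genome, tiny, cfg, seed = 1),
               "twice the minimum read length")
})

test_that("contamination injection follows the configured rate", {
  g <- generate_query_genome(1, 3000000, 0.44, seed = 30)
  clones <- sample_bac_clones(g$genome, 192, bes_config(), seed = 31)
  expect_identical(inject_contamination(clones, 150000, 0, seed = 1),
                   clones)
  all_in <- inject_contamination(clones, 150000, 1, seed = 2)
  expect_true(all(all_in$origin == "chloroplast"))
  # binomial mean: 192 x 0.005 = 0.96 contaminated clones on average
  counts <- vapply(1:1000, function(i) {
    sum(inject_contamination(clones, 150000, 0.005,
                             seed = i)$origin == "chloroplast")
  }, numeric(1))
  expect_lt(abs(mean(counts) - 0.96), 0.1)
})

test_that("datasets are reproducible to the byte and plant the class mix", {
  cfg <- small_cfg(seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ds1 <- make_dataset(cfg, d1)
  ds2 <- make_dataset(cfg, d2)
  for (f in c("reads.fastq", "reference.fasta", "inserts.tsv",
              "truth_clones.tsv", "plan.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  planted <- table(ds1$truth$clones$truth_class)
  mix_counts <- besmap:::counts_from_mix(cfg$class_mix, cfg$n_clones)
  names(mix_counts) <- names(cfg$class_mix)
  expect_equal(as.integer(planted[names(mix_counts)]),
               unname(mix_counts))
  expect_equal(nrow(ds1$reads), 2L * cfg$n_clones)
  # clone ids are unique and every read belongs to one clone
  expect_false(anyDuplicated(ds1$truth$clones$clone_id) > 0)
  expect_setequal(ds1$reads$id,
                  c(paste0(ds1$truth$clones$clone_id, "_f"),
                    paste0(ds1$truth$clones$clone_id, "_r")))
})
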