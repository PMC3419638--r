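test_that("exact substrings map to their true position and strand", {
  withr::with_seed(50, {
    genome <- setNames(c(besmap:::random_dna(200000, 0.44),
                         besmap:::random_dna(150000, 0.44)),
                       c("r01", "r02"))
  })
  index <- build_seed_index(genome)
  fwd <- substr(genome[["r02"]], 5001, 5800)
  hits <- map_read(fwd, index)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$chrom, "r02")
  expect_equal(hits$ref_start, 5000L)
  expect_equal(hits$ref_end, 5800L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score, 800)

  rev <- reverse_complement(substr(genome[["r01"]], 40001, 40900))
  rhits <- map_read(rev, index)
  expect_equal(rhits$strand, "-")
  expect_equal(c(rhits$ref_start, rhits$ref_end), c(40000L, 40900L))

  withr::with_seed(51, alien <- besmap:::random_dna(800, 0.44))
  expect_equal(nrow(map_read(alien, index)), 0L)
})

test_that("mapper agrees with the brute-force oracle on clean reads", {
  withr::with_seed(52, {
    genome <- setNames(c(besmap:::random_dna(120000, 0.44),
                         besmap:::random_dna(80000, 0.44)), c("r01", "r02"))
  })
  index <- build_seed_index(genome)
  reads <- random_reads(genome, 50, seed = 53)
  cfg <- bes_config()
  for (i in seq_len(nrow(reads))) {
    mine <- map_read(reads$sequence[i], index, cfg)
    oracle <- brute_force_map(reads$sequence[i], genome, 0, cfg)
    oracle <- oracle[oracle$evalue <= cfg$max_evalue, ]
    expect_identical(hit_key(mine), hit_key(oracle), label = reads$id[i])
  }
})

test_that("brute-force scan handles the degenerate inputs", {
  expect_equal(nrow(brute_force_map("ACGT", character(0))), 0L)
  genome <- c(r01 = "ACGTACGTACGTACGTAAAACCCC")
  full <- brute_force_map(genome[["r01"]], genome)
  expect_equal(nrow(full), 1L)
  expect_equal(c(full$ref_start, full$ref_end), c(0L, 24L))
  expect_equal(full$strand, "+")
})

test_that("mapping the reverse complement flips strands, keeps intervals", {
  withr::with_seed(54, {
    genome <- setNames(besmap:::random_dna(150000, 0.44), "r01")
  })
  index <- build_seed_index(genome)
  reads <- random_reads(genome, 20, seed = 55)
  for (i in seq_len(nrow(reads))) {
    a <- map_read(reads$sequence[i], index)
    b <- map_read(reverse_complement(reads$sequence[i]), index)
    expect_identical(
      sort(paste(a$chrom, a$ref_start, a$ref_end)),
      sort(paste(b$chrom, b$ref_start, b$ref_end)))
    key_a <- paste(a$chrom, a$ref_start, a$ref_end)
    expect_identical(setNames(a$strand, key_a)[order(key_a)],
                     setNames(ifelse(b$strand == "+", "-", "+"),
                              paste(b$chrom, b$ref_start,
                                    b$ref_end))[order(key_a)])
  }
})

test_that("raising the E-value cutoff never removes hits", {
  withr::with_seed(56, {
    genome <- setNames(besmap:::random_dna(100000, 0.44), "r01")
  })
  index <- build_seed_index(genome)
  read <- substr(genome[["r01"]], 2001, 2700)
  strict <- map_read(read, index, bes_config(max_evalue = 1e-80))
  loose <- map_read(read, index, bes_config(max_evalue = 1e-10))
  expect_true(all(hit_key(strict) %in% hit_key(loose)))
})

test_that("reads shorter than the seed yield no hits", {
  genome <- c(r01 = strrep("ACGTT", 2000))
  index <- build_seed_index(genome, k = 16)
  expect_equal(nrow(map_read("ACGTACGTAC", index)), 0L)
})

test_that("multi-copy sequences report one hit per locus", {
  withr::with_seed(57, {
    bg <- besmap:::random_dna(120000, 0.44)
    copy <- besmap:::random_dna(700, 0.44)
  })
  genome <- c(r01 = paste0(substr(bg, 1, 30000), copy,
                           substr(bg, 30701, 80000), copy,
                           substr(bg, 80701, 120000)))
  index <- build_seed_index(genome)
  hits <- map_read(copy, index)
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$ref_start, c(30000L, 80000L))
})
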