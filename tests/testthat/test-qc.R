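test_that("vector trimming removes exact terminal run-through", {
  withr::with_seed(1, {
    vec <- besmap:::random_dna(3000, 0.5)
    insert <- besmap:::random_dna(500, 0.44)
  })
  read <- one_read(paste0(substr(vec, 2971, 3000), insert))
  out <- trim_vector(read, vec)
  expect_identical(out$sequence, insert)
  expect_equal(out$vector_trimmed, 30L)

  clean <- one_read(insert)
  expect_identical(trim_vector(clean, vec)$sequence, insert)

  short <- one_read("ACGTACGT")
  expect_identical(trim_vector(short, vec)$sequence, "ACGTACGT")
})

test_that("vector trimming recovers planted inserts on random reads", {
  withr::with_seed(2, {
    vec <- besmap:::random_dna(3000, 0.5)
    n <- 200
    inserts <- vapply(sample(300:900, n, replace = TRUE), function(l) {
      besmap:::random_dna(l, 0.44)
    }, character(1))
    flanks <- sample(20:80, n, replace = TRUE)
    reads <- data.frame(
      id = sprintf("r%03d", 1:n), description = "",
      sequence = paste0(substr(rep(vec, n), 3000 - flanks + 1, 3000),
                        inserts),
      stringsAsFactors = FALSE)
  })
  out <- trim_vector(reads, vec)
  expect_identical(out$sequence, unname(inserts))
  # idempotence: a second pass changes nothing
  again <- trim_vector(out[, c("id", "description", "sequence")], vec)
  expect_identical(again$sequence, out$sequence)
})

test_that("quality trimming keeps exactly the high-quality core", {
  uniform <- one_read(strrep("ACGT", 100))  # quality 40 everywhere
  tq <- trim_quality(uniform)
  expect_equal(nrow(tq$passed), 1L)
  expect_identical(tq$passed$sequence, uniform$sequence)

  low <- one_read(strrep("ACGT", 100), quality = rep(10L, 400))
  expect_equal(nrow(trim_quality(low)$passed), 0L)
  expect_equal(trim_quality(low)$rejected, "r1")

  # planted core: 150 low + 400 high + 150 low
  seq_str <- strrep("A", 700)
  q <- c(rep(5L, 150), rep(40L, 400), rep(5L, 150))
  tq <- trim_quality(one_read(seq_str, q), window = 20, min_mean_q = 20,
                     min_length = 100)
  expect_equal(nchar(tq$passed$sequence), 400L)
  expect_equal(tq$passed$quality[[1]], rep(40L, 400))

  # idempotence
  tq2 <- trim_quality(tq$passed)
  expect_identical(tq2$passed$sequence, tq$passed$sequence)
})

test_that("filter accounting balances input, passed and rejected", {
  withr::with_seed(3, {
    n <- 40
    reads <- data.frame(id = sprintf("r%02d", 1:n), description = "",
                        sequence = vapply(rep(400, n), besmap:::random_dna,
                                          character(1), gc = 0.5),
                        stringsAsFactors = FALSE)
    reads$quality <- lapply(1:n, function(i) {
      if (i <= 10) rep(8L, 400) else rep(40L, 400)
    })
  })
  tq <- trim_quality(reads)
  acc <- tq$accounting
  expect_equal(acc[["n_input"]], acc[["n_passed"]] + acc[["n_rejected"]])
  expect_equal(acc[["n_rejected"]], 10)
})

test_that("organelle screen applies the E-value and 80% coverage rule", {
  reads <- one_read(strrep("ACGT", 250))  # length 1000
  base <- mk_hit("chloroplast", 100, 200, "+", id = "r1")
  # coverage 0.85, strong E-value: flagged
  h1 <- base; h1$query_start <- 0L; h1$query_end <- 850L; h1$evalue <- 1e-30
  expect_true(screen_organelle(reads, h1)[["r1"]])
  # coverage 0.79: below the rule's boundary
  h2 <- h1; h2$query_end <- 790L
  expect_false(screen_organelle(reads, h2)[["r1"]])
  # weak E-value
  h3 <- h1; h3$evalue <- 1e-10
  expect_false(screen_organelle(reads, h3)[["r1"]])
  expect_false(screen_organelle(reads, empty_alignments())[["r1"]])
})

test_that("full QC stage finds planted organelle clones per clone", {
  cfg <- small_cfg(seed = 41, contamination_rate = 0.1,
                   class_mix = c(C1 = 1))
  ds <- make_dataset(cfg, withr::local_tempdir())
  reads <- ds$reads
  clone_of <- setNames(rep(ds$truth$clones$clone_id, each = 2),
                       c(rbind(paste0(ds$truth$clones$clone_id, "_f"),
                               paste0(ds$truth$clones$clone_id, "_r"))))
  organelle <- as_genome(read_fasta(ds$paths$organelle))
  vec <- as_genome(read_fasta(ds$paths$vector))[1]
  qc <- qc_reads(reads, cfg, vec, organelle, clone_of)
  expect_setequal(qc$contaminated_clones, ds$truth$contaminated_clones)
  expect_equal(qc$report$n_contaminated_clones,
               length(ds$truth$contaminated_clones))
  expect_equal(qc$report$contamination_percent,
               round(100 * length(ds$truth$contaminated_clones) /
                       cfg$n_clones, 1))
})
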