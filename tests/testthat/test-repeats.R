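test_that("planted repeat copies are annotated with correct extent", {
  lib <- simulate_repeat_library(3)
  rindex <- build_repeat_index(lib)
  withr::with_seed(70, {
    bg1 <- besmap:::random_dna(200, 0.44)
    bg2 <- besmap:::random_dna(300, 0.44)
    copia <- lib$sequence[lib$family == "Copia"]
    planted <- besmap:::diverge_copy(substr(copia, 501, 1400), 0.05)
  })
  read <- paste0(bg1, planted, bg2)
  ann <- annotate_repeats(read, rindex)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$family, "Copia")
  expect_lt(abs(ann$start - 200), 10)
  expect_lt(abs(ann$end - 1100), 10)
  lineage <- taxonomy_lineage(default_repeat_taxonomy(), ann$family)
  expect_equal(lineage, c("Total", "Transposable Element", "RNA transposon",
                          "LTR Retrotransposon", "Copia"))

  withr::with_seed(71, clean <- besmap:::random_dna(900, 0.44))
  expect_equal(nrow(annotate_repeats(clean, rindex)), 0L)
})

test_that("two disjoint planted repeats yield two disjoint annotations", {
  lib <- simulate_repeat_library(4)
  rindex <- build_repeat_index(lib)
  withr::with_seed(72, {
    gypsy <- substr(lib$sequence[lib$family == "Gypsy"], 1, 400)
    hat <- substr(lib$sequence[lib$family == "hAT"], 1, 350)
    mid <- besmap:::random_dna(300, 0.44)
  })
  read <- paste0(gypsy, mid, hat)
  ann <- annotate_repeats(read, rindex)
  ann <- ann[order(ann$start), ]
  expect_equal(ann$family, c("Gypsy", "hAT"))
  expect_true(all(ann$end[-nrow(ann)] <= ann$start[-1]))
  # reverse-complemented copies are found on the other strand
  ann_rc <- annotate_repeats(reverse_complement(read), rindex)
  expect_setequal(ann_rc$family, c("Gypsy", "hAT"))
})

test_that("repeat fraction is the interval-union share of the read", {
  expect_equal(repeat_fraction(300, NULL), 0)
  one <- data.frame(start = 0L, end = 300L, family = "Copia")
  expect_equal(repeat_fraction(300, one), 1)
  overlapping <- data.frame(start = c(0L, 50L), end = c(100L, 150L),
                            family = c("Copia", "Copia"))
  expect_equal(repeat_fraction(300, overlapping), 0.5)
})

test_that("ledger aggregation rolls counts and bases up the taxonomy", {
  ann <- data.frame(
    read_id = "r1",
    start = c(0L, 500L, 1200L, 2000L, 2600L),
    end = c(400L, 1100L, 1700L, 2500L, 2800L),
    family = c("Copia", "Gypsy", "L1", "EnSpm", "Satellite"),
    stringsAsFactors = FALSE)
  led <- summarize_repeats(ann, total_read_bases = 10000)
  bp <- setNames(led$length_bp, led$node)
  expect_equal(bp[["Copia"]], 400)
  expect_equal(bp[["LTR Retrotransposon"]], 1000)
  expect_equal(bp[["RNA transposon"]], 1500)
  expect_equal(bp[["Transposable Element"]], 2000)
  expect_equal(bp[["Total"]], 2200)
  n <- setNames(led$n_elements, led$node)
  expect_equal(n[["Transposable Element"]], 4)
  expect_equal(n[["Total"]], 5)
  pct <- setNames(led$percent_of_total_bases, led$node)
  expect_equal(pct[["Total"]], 22)
  # permutation invariance
  led2 <- summarize_repeats(ann[sample(nrow(ann)), ], 10000)
  expect_equal(as.data.frame(led2), as.data.frame(led))
  # unknown family is an error naming the family
  bad <- ann; bad$family[1] <- "Mariner"
  expect_error(summarize_repeats(bad, 10000), "Mariner")
})

test_that("empty annotation sets give an all-zero ledger", {
  led <- summarize_repeats(empty_ann <- data.frame(
    read_id = character(0), start = integer(0), end = integer(0),
    family = character(0)), total_read_bases = 5000)
  expect_true(all(led$length_bp == 0))
  expect_true(all(led$n_elements == 0))
})

test_that("internal nodes may hold bases unattributed to leaves", {
  tab <- data.frame(node = c("Total", "Transposable Element",
                             "RNA transposon", "LTR Retrotransspoon"),
                    n_elements = 1, length_bp = 1)
  expect_error(ledger_from_table(tab), "LTR Retrotransspoon")
  ok <- data.frame(node = c("Total", "Transposable Element",
                            "RNA transposon", "LTR Retrotransposon",
                            "Copia", "Gypsy"),
                   n_elements = c(10, 10, 10, 10, 4, 4),
                   length_bp = c(1000, 1000, 1000, 1000, 450, 450))
  led <- ledger_from_table(ok)
  expect_equal(fraction_of(led, "Copia", "LTR Retrotransposon"), 45)
  # child exceeding parent is rejected
  broken <- ok; broken$length_bp[5] <- 800
  expect_error(ledger_from_table(broken), "sum to more")
})

test_that("fraction_of validates the descendant relationship", {
  nodes <- read_tsv_fixture <- read.delim(
    file.path(fixtures_dir(), "repeat_ledger_nodes.tsv"))
  led <- ledger_from_table(nodes)
  expect_equal(fraction_of(led, "Copia", "Copia"), 100)
  expect_error(fraction_of(led, "Copia", "DNA transposon"),
               "not a descendant")
})
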