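mk_call <- function(clone_id, class_label = "C1", chrom = "r01",
                    span = NA_integer_) {
  data.frame(clone_id = clone_id, class_label = class_label,
             concordant = class_label == "C1", chrom = chrom,
             ref_start = 0L, ref_end = span, span = span,
             orientation = "opposite_in", score_sum = 100,
             n_hits_f = 1L, n_hits_r = 1L, stringsAsFactors = FALSE)
}

test_that("regions compare insert size with the placement outer span", {
  calls <- rbind(mk_call("b1", span = 192480L),
                 mk_call("b2", span = 90000L),
                 mk_call("b3", "C3", span = 400000L))
  sizes <- c(b1 = 105911, b2 = 90000, b3 = 120000)
  regions <- build_regions(calls, sizes)
  expect_equal(nrow(regions), 2L)  # non-C1 ignored
  r1 <- regions[regions$clone_id == "b1", ]
  expect_equal(r1$delta_bp, 86569)
  expect_equal(r1$direction, "expanded")
  # a tie counts as contracted: expanded strictly means larger
  expect_equal(regions$direction[regions$clone_id == "b2"], "contracted")

  expect_equal(nrow(build_regions(calls[3, ], sizes)), 0L)
  expect_error(build_regions(calls, sizes[-1]), "b1")
})

test_that("chromosome aggregation is permutation-invariant and additive", {
  withr::with_seed(80, {
    regions <- data.frame(
      clone_id = sprintf("b%02d", 1:40),
      chrom = sample(sprintf("r%02d", 1:5), 40, replace = TRUE),
      query_bp = sample(50000:200000, 40),
      stringsAsFactors = FALSE)
    regions$ref_bp <- round(regions$query_bp * runif(40, 0.7, 1.8))
    regions$delta_bp <- regions$ref_bp - regions$query_bp
    regions$direction <- ifelse(regions$delta_bp > 0, "expanded",
                                "contracted")
  })
  a <- aggregate_by_chromosome(regions)
  b <- aggregate_by_chromosome(regions[sample(nrow(regions)), ])
  expect_equal(a, b)
  expect_equal(a$grand_totals[["sum_delta_bp"]], sum(regions$delta_bp))
  expect_equal(a$grand_totals[["sum_delta_bp"]],
               sum(a$by_chromosome$sum_delta_bp))
  one <- aggregate_by_chromosome(regions[1, ])
  expect_equal(one$grand_totals[["sum_query_bp"]], regions$query_bp[1])
})

test_that("expansion percent follows the grand-total ratio", {
  gt <- c(n_regions = 2, sum_query_bp = 1000, sum_ref_bp = 1300,
          sum_delta_bp = 300)
  expect_equal(total_expansion_percent(gt), 30)
  expect_equal(total_expansion_percent(
    c(sum_query_bp = 500, sum_ref_bp = 500, sum_delta_bp = 0)), 0)
  expect_error(total_expansion_percent(
    c(sum_query_bp = 0, sum_ref_bp = 10)), "denominator")
  # alternative conventions
  expect_equal(total_expansion_percent(gt, "reference_denominator"),
               round(100 * 300 / 1300, 2))
  regions <- data.frame(query_bp = c(100, 100), ref_bp = c(150, 110),
                        delta_bp = c(50, 10))
  expect_equal(total_expansion_percent(regions, "per_region_mean"), 30)
})

test_that("coverage estimates bracket the library's genome equivalents", {
  expect_equal(round(coverage_estimate(36864, 125000, 760e6), 2), 6.06)
  expect_equal(round(coverage_estimate(36864, 125000, 930e6), 2), 4.95)
  expect_equal(coverage_estimate(100, 1000, 100 * 1000), 1)
  expect_error(coverage_estimate(0, 1000, 1e6), "positive")
})

test_that("contamination rate reports per-clone percent to one decimal", {
  expect_equal(contamination_rate(1, 192), 0.5)
  expect_equal(contamination_rate(0, 192), 0)
  expect_equal(contamination_rate(192, 192), 100)
  expect_error(contamination_rate(1, 0), "positive")
  expect_error(contamination_rate(-1, 10), "lie in")
})
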