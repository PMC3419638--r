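test_that("pair orientation follows the upstream/downstream strand grid", {
  u <- mk_hit("r01", 100000, 101000, "+")
  d <- mk_hit("r01", 220000, 221000, "-")
  expect_equal(pair_orientation(u, d), "opposite_in")
  expect_equal(pair_orientation(d, u), "opposite_in")  # order-free
  expect_equal(pair_orientation(mk_hit("r01", 1, 10, "+"),
                                mk_hit("r01", 50, 60, "+")), "same")
  expect_equal(pair_orientation(mk_hit("r01", 1, 10, "-"),
                                mk_hit("r01", 50, 60, "+")), "opposite_out")
  expect_error(pair_orientation(u, mk_hit("r02", 1, 10, "+")),
               "same chromosome")
})

test_that("the class grid maps orientation and span band correctly", {
  cases <- list(
    # opposite_in: upstream + / downstream -
    list(s1 = "+", s2 = "-", span = 150000, class = "C1", conc = TRUE),
    list(s1 = "+", s2 = "-", span = 20000, class = "C1", conc = TRUE),
    list(s1 = "+", s2 = "-", span = 300000, class = "C1", conc = TRUE),
    list(s1 = "+", s2 = "-", span = 300001, class = "C3", conc = FALSE),
    list(s1 = "+", s2 = "-", span = 10000, class = "X1", conc = FALSE),
    # same orientation
    list(s1 = "+", s2 = "+", span = 150000, class = "C2", conc = FALSE),
    list(s1 = "-", s2 = "-", span = 400000, class = "C4", conc = FALSE),
    list(s1 = "+", s2 = "+", span = 5000, class = "X2", conc = FALSE),
    # opposite_out: upstream - / downstream +
    list(s1 = "-", s2 = "+", span = 400000, class = "C5", conc = FALSE),
    list(s1 = "-", s2 = "+", span = 150000, class = "X4", conc = FALSE),
    list(s1 = "-", s2 = "+", span = 8000, class = "X3", conc = FALSE))
  for (cs in cases) {
    f <- mk_hit("r01", 100000, 101000, cs$s1)
    r <- mk_hit("r01", 100000 + cs$span - 1000, 100000 + cs$span, cs$s2)
    got <- classify_pair(f, r)
    expect_equal(got$class_label, cs$class,
                 label = sprintf("%s/%s span %d", cs$s1, cs$s2, cs$span))
    expect_equal(got$concordant, cs$conc)
    expect_equal(got$span, cs$span)
  }
})

test_that("best placement equals exhaustive enumeration over pairings", {
  withr::with_seed(60, {
    for (rep in 1:20) {
      hits_f <- do.call(rbind, lapply(1:3, function(i) {
        mk_hit(sample(c("r01", "r02"), 1), s <- sample(1e6, 1), s + 800,
               sample(c("+", "-"), 1), score = round(runif(1, 50, 800)))
      }))
      hits_r <- do.call(rbind, lapply(1:3, function(i) {
        mk_hit(sample(c("r01", "r02"), 1), s <- sample(1e6, 1), s + 800,
               sample(c("+", "-"), 1), score = round(runif(1, 50, 800)))
      }))
      got <- select_best_placement(hits_f, hits_r)
      # brute force over all 9 pairings
      best <- NULL
      for (i in 1:3) for (j in 1:3) {
        if (hits_f$chrom[i] != hits_r$chrom[j]) next
        ss <- hits_f$score[i] + hits_r$score[j]
        if (is.null(best) || ss > best$ss) best <- list(ss = ss)
      }
      if (is.null(best)) {
        expect_null(got)
      } else {
        expect_equal(got$score_sum, best$ss)
      }
    }
  })
})

test_that("placement ties prefer the concordant pairing", {
  f1 <- mk_hit("r01", 100000, 101000, "+", score = 500)
  r_conc <- mk_hit("r01", 199000, 200000, "-", score = 500)   # C1
  r_disc <- mk_hit("r01", 199000, 200000, "+", score = 500)   # same orient
  got <- select_best_placement(f1, rbind(r_disc, r_conc))
  expect_equal(got$orientation, "opposite_in")
  one <- select_best_placement(f1, r_conc)
  expect_equal(one$span, 100000)
})

test_that("library classification covers single-end and no-hit clones", {
  pairs <- data.frame(clone_id = c("b1", "b2", "b3", "b4"),
                      read_f = c("b1_f", "b2_f", "b3_f", "b4_f"),
                      read_r = c("b1_r", "b2_r", "b3_r", "b4_r"),
                      stringsAsFactors = FALSE)
  hits <- rbind(
    # b1: proper concordant pair
    mk_hit("r01", 100000, 101000, "+", id = "b1_f"),
    mk_hit("r01", 199000, 200000, "-", id = "b1_r"),
    # b2: one end, single hit -> C7
    mk_hit("r02", 5000, 6000, "+", id = "b2_f"),
    # b3: one end, three hits -> C8
    mk_hit("r01", 10000, 11000, "+", id = "b3_r", score = 90),
    mk_hit("r02", 500000, 501000, "+", id = "b3_r", score = 80),
    mk_hit("r03", 20000, 21000, "-", id = "b3_r", score = 70))
  calls <- classify_library(pairs, hits)
  lab <- setNames(calls$class_label, calls$clone_id)
  expect_equal(unname(lab[c("b1", "b2", "b3", "b4")]),
               c("C1", "C7", "C8", "C9"))
  expect_equal(calls$n_hits_r[calls$clone_id == "b3"], 3L)

  counts <- class_count_table(calls)
  expect_equal(sum(counts$counts$n), 4L)
  expect_equal(counts$aligned_bes, 2L * 1L + 2L)   # C1 both + C7 + C8
  expect_equal(counts$nohit_bes, 2L * 1L + 2L)

  too_many <- rbind(pairs, data.frame(clone_id = "b1", read_f = "b1_f",
                                      read_r = "b1_r"))
  expect_error(classify_library(too_many, hits), "more than once")
})

test_that("cross-chromosome ends give C6 only without a same-chrom pair", {
  pairs <- data.frame(clone_id = "b1", read_f = "b1_f", read_r = "b1_r",
                      stringsAsFactors = FALSE)
  hits_c6 <- rbind(mk_hit("r01", 1000, 2000, "+", id = "b1_f"),
                   mk_hit("r02", 1000, 2000, "-", id = "b1_r"))
  expect_equal(classify_library(pairs, hits_c6)$class_label, "C6")
  # a weaker same-chromosome pairing still wins by default
  hits_mixed <- rbind(
    mk_hit("r01", 100000, 101000, "+", id = "b1_f", score = 900),
    mk_hit("r03", 100000, 101000, "+", id = "b1_r", score = 900),
    mk_hit("r01", 199000, 200000, "-", id = "b1_r", score = 100))
  expect_equal(classify_library(pairs, hits_mixed)$class_label, "C1")
  cfg_cross <- bes_config(require_same_chrom = FALSE)
  expect_equal(classify_library(pairs, hits_mixed, cfg_cross)$class_label,
               "C6")
})

test_that("class labels are invariant to swapping forward/reverse ends", {
  run <- shared_recovery_run()
  pairs <- besmap:::pairs_from_clones(run$ds$truth$clones$clone_id,
                                      run$res$qc$reads$id)
  swapped <- pairs
  names(swapped)[2:3] <- c("read_r", "read_f")
  calls_a <- classify_library(pairs, run$res$hits, run$cfg)
  calls_b <- classify_library(swapped, run$res$hits, run$cfg)
  expect_equal(calls_a$class_label, calls_b$class_label)
})

test_that("widening the span window never evicts a concordant clone", {
  run <- shared_recovery_run()
  pairs <- besmap:::pairs_from_clones(run$ds$truth$clones$clone_id,
                                      run$res$qc$reads$id)
  base <- classify_library(pairs, run$res$hits, run$cfg)
  wide <- classify_library(pairs, run$res$hits,
                           bes_config(min_span = 10000, max_span = 500000))
  was_c1 <- base$clone_id[base$class_label == "C1"]
  expect_true(all(wide$class_label[wide$clone_id %in% was_c1] == "C1"))
})
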