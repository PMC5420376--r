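# Screening values, exact Fisher test, criterion evaluation, table recovery.

test_that("dichotomization is strict with ties negative", {
  expect_identical(dichotomize(c(1, 2, 3), 2, "greater"),
                   c(FALSE, FALSE, TRUE))
  expect_identical(dichotomize(c(1, 2, 3), 5, "greater"),
                   c(FALSE, FALSE, FALSE))
  expect_identical(dichotomize(c(1, 2, 3), 2, "less"),
                   c(TRUE, FALSE, FALSE))
  # pivot-shift positivity: grade >= 1 via the default zero threshold
  expect_identical(dichotomize(c(0, 1, 2, 3), 0, "greater"),
                   c(FALSE, TRUE, TRUE, TRUE))
})

test_that("screening values follow the Altman-Bland definitions with
           undefined cells flagged", {
  r <- screening_values(contingency_table(tp = 5, fp = 1, fn = 1, tn = 23))
  expect_equal(unname(r$rounded), c(83, 96, 83, 96))
  expect_equal(unname(r$values),
               100 * c(5 / 6, 23 / 24, 5 / 6, 23 / 24))
  perfect <- screening_values(contingency_table(10, 0, 0, 10))
  expect_equal(unname(perfect$rounded), c(100, 100, 100, 100))
  deg <- screening_values(contingency_table(tp = 0, fp = 2, fn = 0, tn = 8))
  expect_true(is.na(deg$values[["sensitivity"]]))
  expect_identical(deg$undefined, "sensitivity")
  expect_equal(deg$values[["specificity"]], 80)
  expect_error(contingency_table(1, -1, 0, 0), "nonnegative")
  expect_error(contingency_table(0, 0, 0, 0), "at least one")
})

test_that("the exact Fisher p matches hand enumeration and an independent
           oracle", {
  expect_equal(fisher_exact(contingency_table(1, 1, 1, 1)), 1)
  # margins 6/24: only X = 5 and X = 6 are at most as probable as observed
  expect_equal(fisher_exact(contingency_table(5, 1, 1, 23)), 145 / 593775,
               tolerance = 1e-12)
  # a zero margin leaves a single possible table
  expect_equal(fisher_exact(contingency_table(0, 0, 3, 7)), 1)
  set.seed(33)
  for (i in 1:200) {
    cells <- as.integer(rmultinom(1, sample(2:20, 1), runif(4, 0.05, 1)))
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    expect_equal(fisher_exact(t),
                 oracle_fisher(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
    expect_equal(fisher_exact(t),
                 stats::fisher.test(matrix(cells, 2))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("the Fisher p is invariant under transposition and joint row/column
           swaps", {
  set.seed(44)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, sample(4:40, 1), runif(4, 0.05, 1)))
    tp <- cells[1]; fp <- cells[2]; fn <- cells[3]; tn <- cells[4]
    p <- fisher_exact(contingency_table(tp, fp, fn, tn))
    expect_equal(fisher_exact(contingency_table(tp, fn, fp, tn)), p,
                 tolerance = 1e-12)
    expect_equal(fisher_exact(contingency_table(tn, fn, fp, tp)), p,
                 tolerance = 1e-12)
  }
  # the doubling two-sided variant is a valid p and at least the one-tail mass
  expect_gte(fisher_exact(contingency_table(5, 1, 1, 23), method = "doubling"),
             fisher_exact(contingency_table(5, 1, 1, 23)) / 2)
})

test_that("-log p from Fisher and chi-square agree in ordering on
           well-filled tables", {
  set.seed(55)
  tabs <- replicate(100, sample(5:30, 4, replace = TRUE), simplify = FALSE)
  pf <- sapply(tabs, function(c4)
    fisher_exact(contingency_table(c4[1], c4[2], c4[3], c4[4])))
  pc <- sapply(tabs, function(c4)
    suppressWarnings(stats::chisq.test(matrix(c4, 2),
                                       correct = FALSE)$p.value))
  expect_gt(cor(-log(pf), -log(pc), method = "spearman"), 0.95)
})

test_that("criterion evaluation labels limbs correctly and finds separated
           effects", {
  # deterministic analysis table: 6 condition positives with high JPE,
  # one overlapping control
  an <- data.frame(
    subject_id = sprintf("S%02d", 1:15)[c(1:15, 1:15)],
    limb = rep(c("reconstructed", "healthy"), each = 15),
    group = rep(c(rep(1L, 9), rep(2L, 6)), 2),
    jpe_mmdeg = c(rep(600, 9), rep(1200, 6), rep(650, 9), 700, 1150,
                  rep(620, 4)),
    pivot_shift_grade = 0L)
  res <- evaluate_criterion(an, "jpe", threshold = "search")
  expect_s3_class(res, "screening_result")
  tab <- res$table
  expect_equal(tab$tp + tab$fn, 6L)            # six condition positives
  expect_equal(tab$fp + tab$tn, 24L)           # twenty-four negatives
  expect_gte(res$values[["sensitivity"]], 90)
  expect_gte(res$values[["specificity"]], 90)
  expect_lt(res$p_value, 0.001)
  # a constant criterion is uninformative at every threshold
  an$jpe_mmdeg <- 700
  expect_equal(evaluate_criterion(an, "jpe", threshold = "search")$p_value, 1)
  # group 3 exclusion and degenerate classes are rejected
  an$group <- 1L
  expect_error(evaluate_criterion(an, "jpe"), "condition-positive")
})

test_that("threshold search prefers the smaller positive count on ties", {
  an <- data.frame(
    subject_id = sprintf("S%02d", 1:4)[c(1:4, 1:4)],
    limb = rep(c("reconstructed", "healthy"), each = 4),
    group = rep(c(1L, 1L, 2L, 2L), 2),
    jpe_mmdeg = c(1, 2, 9, 10, 3, 4, 5, 6))
  res <- evaluate_criterion(an, "jpe", threshold = "search")
  # perfect separation is achievable at several cuts; the chosen threshold
  # must keep only true positives test-positive
  expect_equal(res$table$tp, 2L)
  expect_equal(res$table$fp, 0L)
})

test_that("rounded published screening rows are recovered exactly and
           consistently", {
  # unique table at 6 diseased of 30 limbs
  hit <- recover_table(c(83, 96, 83, 96), diseased = 6, n_total = 30)
  expect_equal(nrow(hit), 1L)
  expect_equal(unlist(hit[1, c("tp", "fp", "fn", "tn")]),
               c(tp = 5, fp = 1, fn = 1, tn = 23))
  # degenerate perfect row
  perf <- recover_table(c(100, 100, 100, 100), diseased = 2, n_total = 4)
  expect_equal(unlist(perf[1, c("tp", "fp", "fn", "tn")]),
               c(tp = 2, fp = 0, fn = 0, tn = 2))
  # the printed total-rotation row is inconsistent with 6 diseased of 30 -
  # indeed with every integer table up to n = 200; the audit reports the
  # empty result rather than erroring
  miss <- recover_table(c(29, 92, 83, 59), diseased = 6, n_total = 30)
  expect_equal(nrow(miss), 0L)
  broad <- recover_table(c(29, 92, 83, 59), n_max = 200)
  expect_equal(nrow(broad), 0L)
  # round trip: screening_values of every recovered table reproduces the
  # rounded inputs
  some <- recover_table(c(67, 92, 67, 92), n_max = 40)
  expect_gt(nrow(some), 0L)
  for (i in seq_len(nrow(some))) {
    sv <- screening_values(contingency_table(some$tp[i], some$fp[i],
                                             some$fn[i], some$tn[i]))
    expect_equal(unname(sv$rounded), c(67, 92, 67, 92))
  }
})

test_that("the screening report covers the four study criteria", {
  co <- generate_cohort(study_cohort_spec(seed = 9))
  rep <- screening_report(build_analysis_table(co))
  expect_equal(rep$criterion,
               c("kt_manmax", "pivot_shift", "total_rotation", "jpe"))
  expect_true(all(rep$p_value > 0 & rep$p_value <= 1))
  expect_true(all(rep$sensitivity >= 0 & rep$sensitivity <= 100, na.rm = TRUE))
})
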