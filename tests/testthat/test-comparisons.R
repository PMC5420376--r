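# Paired/unpaired feature comparisons and pointwise curve tests.

test_that("degenerate and constructed comparisons behave as designed", {
  x <- c(3, 5, 7, 9)
  same <- compare_feature(x, x, design = "paired")
  expect_equal(same$diff, 0)
  expect_true(is.na(same$p_value))
  expect_identical(same$flags, "zero_variance")
  # constant within-pair shift is recovered exactly
  delta <- 2.75
  y <- x + rnorm(4)
  shifted <- compare_feature(y + delta, y, design = "paired")
  expect_equal(shifted$diff, delta)
  expect_true(is.na(shifted$p_value))  # zero within-pair variance
  expect_error(compare_feature(1:3, 1:4, design = "paired"), "pairs")
  expect_error(compare_feature(1, 1:4), "at least 2")
})

test_that("paired and Welch tests agree with textbook closed forms", {
  set.seed(66)
  for (i in 1:50) {
    nx <- sample(3:12, 1)
    ny <- sample(3:12, 1)
    x <- rnorm(nx, 0, runif(1, 0.5, 3))
    y <- rnorm(ny, runif(1, -1, 1), runif(1, 0.5, 3))
    u <- compare_feature(x, y, design = "unpaired")
    o <- oracle_welch(x, y)
    expect_equal(u$p_value, o$p, tolerance = 1e-9)
    expect_equal(u$statistic, o$t, tolerance = 1e-9)
    z <- rnorm(nx)
    p <- compare_feature(x, z, design = "paired")
    op <- oracle_paired_t(x, z)
    expect_equal(p$p_value, op$p, tolerance = 1e-9)
  }
})

test_that("groups simulated at the published separation are reliably
           distinguished", {
  # healthy-limb max ER means 48.7 vs 64.5, SD 8, moderate n: the unpaired
  # test must detect the separation essentially always
  set.seed(77)
  ps <- replicate(20, {
    a <- rnorm(40, 48.7, 8)
    b <- rnorm(40, 64.5, 8)
    compare_feature(a, b, design = "unpaired")$p_value
  })
  expect_gt(mean(ps < 0.001), 0.95)
})

test_that("torque registration is exact on linear curves and accurate against
           a dense oracle", {
  rec <- linear_recording(slope = 0.1, limit = 5.65, step = 0.25)
  grid <- seq(-5, 5, by = 0.5)
  reg <- register_curves(list(lin = rec), grid = grid)
  expect_equal(as.numeric(reg$angles[1, ]), 10 * grid, tolerance = 1e-9)
  # registering onto (a subset of) its own sampled torques is the identity
  b <- rec[rec$direction == 1L, ]
  own <- sort(b$torque_Nm[seq(5, nrow(b), by = 7)])
  reg2 <- register_curves(list(lin = rec), grid = own)
  expect_equal(as.numeric(reg2$angles[1, ]), 10 * own, tolerance = 1e-9)
  # exponential limb, device-resolution sampling vs closed-form inverse
  p <- limb_params(scale_er = 1, shape_er = 0.05, hysteresis_offset = 0.25,
                   torque_noise_sd = 0, angle_step = 0.01)
  recd <- simulate_rotation_test(p)
  regd <- register_curves(list(e = recd), grid = seq(0.5, 5, by = 0.5))
  truth <- log1p((seq(0.5, 5, by = 0.5) - 0.25) / 1) / 0.05
  expect_lt(max(abs(regd$angles[1, ] - truth)), 0.05)
})

test_that("limbs not covering the grid are excluded with a warning", {
  p <- limb_params(hysteresis_offset = 1.5, torque_noise_sd = 0)
  rec <- simulate_rotation_test(p)  # ER-ward branch starts at -L + 2h
  expect_warning(
    expect_error(register_curves(list(a = rec), grid = seq(-5, 5, 1)),
                 "no limb covers"),
    "excluded")
  reg <- register_curves(list(a = rec), grid = seq(-2, 5, 1))
  expect_equal(reg$ids, "a")
})

test_that("pointwise tests flag self-comparison, localize real differences and
           ignore limb order", {
  p <- limb_params(scale_er = 1, shape_er = 0.05, torque_noise_sd = 0.01)
  make_set <- function(params, seeds) {
    recs <- lapply(seeds, function(s)
      simulate_rotation_test(params, seed = s))
    names(recs) <- paste0("L", seeds)
    register_curves(recs, grid = seq(-4, 5, by = 0.5))
  }
  a <- make_set(p, 1:6)
  self <- pointwise_t(a, a)
  expect_true(all(is.na(self$p_value) | self$p_value > 0.999))
  # a stiffer limb differs from the base mostly in the high-torque region
  p2 <- limb_params(scale_er = 1, shape_er = 0.062, torque_noise_sd = 0.01)
  b <- make_set(p2, 11:16)
  res <- pointwise_t(a, b)
  hi <- res$torque_Nm >= 4
  expect_true(all(res$p_value[hi] < 0.05))
  # invariant under reordering of limbs within an arm
  a_perm <- a
  perm <- c(3, 1, 6, 2, 5, 4)
  a_perm$angles <- a$angles[perm, ]
  a_perm$ids <- a$ids[perm]
  expect_equal(pointwise_t(a_perm, b)$p_value, res$p_value, tolerance = 1e-12)
  # bonferroni only scales the reported adjusted p
  adj <- pointwise_t(a, b, adjust = "bonferroni")
  expect_equal(adj$p_adjusted,
               pmin(res$p_value * sum(!is.na(res$p_value)), 1))
})

test_that("under the null the pointwise rejection rate sits at the nominal
           level", {
  p <- limb_params(scale_er = 1, shape_er = 0.05, hysteresis_offset = 0.25,
                   torque_noise_sd = 0.01, angle_step = 0.5)
  grid <- seq(-3, 5, by = 1)
  n_rep <- 200
  rej <- matrix(NA, n_rep, length(grid))
  for (r in seq_len(n_rep)) {
    recs <- lapply(1:10, function(k)
      simulate_rotation_test(p, seed = 10000 + r * 100 + k))
    a <- register_curves(recs[1:5], grid = grid)
    b <- register_curves(recs[6:10], grid = grid)
    rej[r, ] <- pointwise_t(a, b)$p_value < 0.05
  }
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("the comparison battery runs the study design on a cohort", {
  co <- generate_cohort(study_cohort_spec(seed = 21))
  an <- build_analysis_table(co)
  cmp <- comparison_battery(an)
  expect_true(all(c("name", "design", "mean_a", "mean_b", "diff", "p_value")
                  %in% names(cmp)))
  expect_true(any(cmp$design == "paired") && any(cmp$design == "unpaired"))
  # built-in separation: healthy max ER group 1 vs 2 favours group 2
  row <- cmp[cmp$name == "max_er_deg: group 1 vs 2, healthy limbs", ]
  expect_lt(row$diff, 0)
})
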