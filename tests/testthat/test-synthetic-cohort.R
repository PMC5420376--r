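# Generative hysteresis model and cohort simulation.

test_that("backbone torque follows the exponential-stiffening closed form", {
  p <- limb_params(neutral_angle = 10, scale_er = 1, shape_er = 0.05,
                   scale_ir = 1, shape_ir = 0.05)
  expect_identical(backbone_torque(p, 10), 0)
  # S (e^{beta |delta|} - 1) at delta = +20 deg
  expect_equal(backbone_torque(p, 30), exp(1) - 1, tolerance = 1e-12)
  # odd symmetry about neutral when ER and IR parameters coincide
  d <- seq(0.5, 40, by = 0.5)
  expect_equal(backbone_torque(p, 10 + d), -backbone_torque(p, 10 - d),
               tolerance = 1e-12)
  # strictly increasing in angle
  expect_true(all(diff(backbone_torque(p, seq(-40, 60, 0.25))) > 0))
  expect_error(backbone_torque(p, NaN), "finite")
})

test_that("simulated recordings reverse at the closed-form angles and are
           deterministic under a seed", {
  p <- limb_params(scale_er = 1, shape_er = 0.05, scale_ir = 0.8,
                   shape_ir = 0.07, hysteresis_offset = 0.25,
                   torque_noise_sd = 0.005)
  prot <- protocol_config(torque_limit = 5.65)
  rec <- simulate_rotation_test(p, prot, seed = 7)
  expect_s3_class(rec, "rotation_recording")
  expect_equal(max(rec$angle_deg), log1p((5.65 - 0.25) / 1) / 0.05,
               tolerance = 1e-9)
  expect_equal(min(rec$angle_deg), -log1p((5.65 - 0.25) / 0.8) / 0.07,
               tolerance = 1e-9)
  # measured torque never strays past limit + 3 noise SD (noise is clamped)
  expect_lte(max(abs(rec$torque_Nm)), 5.65 + 3 * 0.005 + 1e-12)
  expect_identical(simulate_rotation_test(p, prot, seed = 7), rec)
  expect_false(identical(simulate_rotation_test(p, prot, seed = 8), rec))
})

test_that("zero hysteresis collapses the loop onto a single curve", {
  p <- limb_params(hysteresis_offset = 0, torque_noise_sd = 0)
  rec <- simulate_rotation_test(p)
  fwd <- rec[rec$direction == 1L, ]
  bwd <- rec[rec$direction == -1L, ]
  # the two directional branches trace the same torque-angle curve
  on_fwd <- approx(fwd$angle_deg, fwd$torque_Nm, xout = bwd$angle_deg,
                   ties = mean)$y
  # residual discrepancy is pure sampling-grid interpolation error
  expect_lt(max(abs(on_fwd - bwd$torque_Nm), na.rm = TRUE), 1e-4)
  expect_equal(extract_features(rec)$play0_deg, 0, tolerance = 1e-4)
})

test_that("unreachable reversal torque is rejected", {
  p <- limb_params(hysteresis_offset = 0.5)
  expect_error(simulate_rotation_test(p, protocol_config(torque_limit = 0.4)),
               "unreachable")
})

test_that("feature-target inversion round-trips through simulation and
           extraction", {
  set.seed(101)
  prot <- protocol_config()
  for (i in 1:25) {
    tgt <- random_target()
    p <- params_from_features(tgt, prot, torque_noise_sd = 0)
    f <- extract_features(simulate_rotation_test(p, prot))
    expect_equal(f$max_er_deg, tgt$max_er, tolerance = 0.1)
    expect_equal(f$max_ir_deg, tgt$max_ir, tolerance = 0.1)
    expect_equal(f$play0_deg, tgt$play0, tolerance = 0.1)
  }
})

test_that("inversion handles boundary and published-mean targets", {
  # zero play inverts to zero hysteresis offset
  p0 <- params_from_features(list(max_er = 40, max_ir = 30, play0 = 0,
                                  slope = 0.4))
  expect_identical(p0$hysteresis_offset, 0)
  # the published healthy-limb means are a feasible design point, even when
  # the printed stiffness is read as Nm/deg
  expect_s3_class(params_from_features(list(max_er = 48.7, max_ir = 28.2,
                                            play0 = 2, slope = 1.6)),
                  "limb_params")
  # a slope below the secant torque/rotation ratio is geometrically impossible
  expect_error(params_from_features(list(max_er = 40, max_ir = 30, play0 = 5,
                                         slope = 0.1)),
               "infeasible")
  expect_error(params_from_features(list(max_er = 40, max_ir = 30, play0 = 69,
                                         slope = 0.4)),
               "play")
})

test_that("more friction widens the loop and more shape steepens the endpoint", {
  base <- list(scale_er = 1, shape_er = 0.05, torque_noise_sd = 0)
  plays <- sapply(c(0, 0.2, 0.5, 1), function(h) {
    p <- limb_params(scale_er = 1, shape_er = 0.05, hysteresis_offset = h,
                     torque_noise_sd = 0)
    extract_features(simulate_rotation_test(p))$play0_deg
  })
  expect_true(all(diff(plays) > 0))
  slopes <- sapply(c(0.03, 0.05, 0.08, 0.12), function(b) {
    p <- limb_params(scale_er = 1, shape_er = b, hysteresis_offset = 0.25,
                     torque_noise_sd = 0)
    extract_features(simulate_rotation_test(p))$slope_er_nm_per_deg
  })
  expect_true(all(diff(slopes) > 0))
})

test_that("study-shaped cohorts have the right size, structure and
           determinism", {
  spec <- study_cohort_spec(seed = 11)
  co <- generate_cohort(spec)
  expect_equal(nrow(co$subjects), 34L)   # 17 subjects, two limbs each
  expect_equal(length(co$recordings), 34L)
  expect_equal(as.vector(table(co$subjects$group[co$subjects$limb ==
                                                   "healthy"])),
               c(9L, 6L, 2L))
  # KT nondecreasing across 67 -> 89 -> 133 -> manual max in every limb
  kt <- co$subjects[, c("kt_67", "kt_89", "kt_133", "kt_manmax")]
  expect_true(all(apply(kt, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(co$subjects$vas >= 0 & co$subjects$vas <= 100))
  # identical seeds give bit-identical cohorts
  expect_identical(generate_cohort(study_cohort_spec(seed = 11)), co)
})

test_that("degenerate dispersion pins every limb at its group means", {
  spec <- cohort_spec(n_group1 = 2, n_group2 = 2, n_group3 = 0,
                      sds = c(rotation = 0, slope = 0, play = 0, kt = 0),
                      seed = 3)
  co <- generate_cohort(spec, torque_noise_sd = 0)
  feats <- features_df(co)
  merged <- merge(merge(feats, co$subjects[, c("subject_id", "limb", "group")],
                        by = c("subject_id", "limb")),
                  spec$targets, by = c("group", "limb"))
  expect_equal(merged$max_er_deg, merged$max_er, tolerance = 0.02)
  expect_equal(merged$max_ir_deg, merged$max_ir, tolerance = 0.02)
  expect_equal(merged$play0_deg, merged$play0, tolerance = 0.02)
  m2 <- merge(co$subjects, spec$targets, by = c("group", "limb"))
  expect_equal(m2$kt_manmax.x, m2$kt_manmax.y)
})

test_that("cohort specs validate their inputs", {
  expect_error(cohort_spec(), "seed")
  expect_error(cohort_spec(seed = 1, sds = c(rotation = -1, slope = 0,
                                             play = 0, kt = 0)),
               "SDs")
  expect_error(cohort_spec(seed = 1,
                           vas_ranges = list(`1` = c(10, 20),
                                             `2` = c(50, 80),
                                             `3` = c(0, 50))),
               "inconsistent")
})
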