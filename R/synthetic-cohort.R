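# Synthetic limb and cohort generation.
#
# The generative model for a limb's axial-rotation load-deformation behaviour
# is an exponential-stiffening elastic backbone with additive frictional
# (Coulomb-style) hysteresis:
#
#   backbone(theta) = S_d * sign(delta) * (exp(beta_d * |delta|) - 1),
#       delta = theta - neutral,  d = ER for delta > 0, IR for delta < 0
#   measured torque = backbone(theta) + h * direction + noise
#
# where h >= 0 is the half-width of the hysteresis loop in torque and
# direction is +1 while the motor drives toward external rotation (ER) and
# -1 toward internal rotation (IR). The backbone is concave toward the torque
# axis, matching the morphology of robotic lower-limb laxity curves, and every
# extracted curve feature has a closed form in (S, beta, h), which makes the
# model invertible: limbs can be designed to hit prescribed feature targets.

#' Limb compliance parameters for the hysteresis curve model
#'
#' Bundles the parameters of the exponential-stiffening backbone with
#' frictional hysteresis used to simulate a limb's torque-angle behaviour
#' during robotic axial-rotation testing.
#'
#' @param neutral_angle Rotational position (degrees) of zero backbone torque.
#'   External rotation is positive by convention.
#' @param scale_er,scale_ir Backbone torque scale (Nm) for the external- and
#'   internal-rotation directions; must be positive.
#' @param shape_er,shape_ir Exponential stiffening rate (1/degree) per
#'   direction; must be positive. Larger values give a steeper endpoint.
#' @param hysteresis_offset Half-width of the frictional hysteresis loop in
#'   torque (Nm), `>= 0`. The loading and unloading branches of the loop sit
#'   `2 * hysteresis_offset` apart in torque.
#' @param torque_noise_sd Standard deviation (Nm) of additive Gaussian torque
#'   measurement noise. Draws are clamped at three standard deviations so a
#'   recording never strays materially past the torque limit.
#' @param angle_step Sampling resolution in degrees; must be at least the
#'   device resolution of 0.01 degrees.
#' @return An object of class `limb_params`.
#' @seealso [backbone_torque()], [simulate_rotation_test()],
#'   [params_from_features()]
#' @export
limb_params <- function(neutral_angle = 0,
                        scale_er = 1, scale_ir = scale_er,
                        shape_er = 0.05, shape_ir = shape_er,
                        hysteresis_offset = 0.25,
                        torque_noise_sd = 0.001,
                        angle_step = 0.05) {
  check_number(neutral_angle, "neutral_angle")
  check_number(scale_er, "scale_er", lower = 0, strict_lower = TRUE)
  check_number(scale_ir, "scale_ir", lower = 0, strict_lower = TRUE)
  check_number(shape_er, "shape_er", lower = 0, strict_lower = TRUE)
  check_number(shape_ir, "shape_ir", lower = 0, strict_lower = TRUE)
  check_number(hysteresis_offset, "hysteresis_offset", lower = 0)
  check_number(torque_noise_sd, "torque_noise_sd", lower = 0)
  check_number(angle_step, "angle_step", lower = 0.01)
  structure(
    list(neutral_angle = neutral_angle,
         scale_er = scale_er, scale_ir = scale_ir,
         shape_er = shape_er, shape_ir = shape_ir,
         hysteresis_offset = hysteresis_offset,
         torque_noise_sd = torque_noise_sd,
         angle_step = angle_step),
    class = "limb_params")
}

#' Testing protocol configuration
#'
#' @param torque_limit Peak rotational torque (Nm) at which the drive
#'   direction reverses. The study protocol uses 5.65 Nm.
#' @param kt_forces Standardized KT-1000 anterior forces in Newtons.
#' @param kt_manmax_force Nominal force (N) assumed for the examiner
#'   manual-maximum test; its magnitude is not standardized, 180 N is a
#'   configurable nominal value.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(torque_limit = 5.65,
                            kt_forces = c(67, 89, 133),
                            kt_manmax_force = 180) {
  check_number(torque_limit, "torque_limit", lower = 0, strict_lower = TRUE)
  stopifnot(is.numeric(kt_forces), all(kt_forces > 0),
            !is.unsorted(kt_forces, strictly = TRUE))
  check_number(kt_manmax_force, "kt_manmax_force", lower = max(kt_forces))
  structure(list(torque_limit = torque_limit,
                 kt_forces = kt_forces,
                 kt_manmax_force = kt_manmax_force),
            class = "protocol_config")
}

#' Elastic backbone torque of the limb model
#'
#' Evaluates the noiseless, hysteresis-free backbone torque at one or more
#' rotational positions. The backbone is odd-symmetric about `neutral_angle`
#' when the ER and IR parameters coincide and is strictly increasing in angle.
#'
#' @param params A [limb_params()] object.
#' @param angle Rotational position(s) in degrees (ER positive).
#' @return Torque in Nm, same length as `angle`.
#' @export
backbone_torque <- function(params, angle) {
  stopifnot(inherits(params, "limb_params"))
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    stop_bad("`angle` must be finite numeric")
  }
  d <- angle - params$neutral_angle
  S <- ifelse(d >= 0, params$scale_er, params$scale_ir)
  b <- ifelse(d >= 0, params$shape_er, params$shape_ir)
  sign(d) * S * expm1(b * abs(d))
}

# Angle (relative to neutral) at which the loading branch reaches the torque
# limit, per direction; log1p keeps the small-shape (near-linear) limit exact.
.reversal_extent <- function(S, beta, torque_limit, h) {
  log1p((torque_limit - h) / S) / beta
}

#' Closed-form curve features implied by limb parameters
#'
#' Predicts, without simulation, every feature that [extract_features()]
#' measures on a noiseless recording of the limb: reversal angles, zero-torque
#' crossings, play, and endpoint slopes. Two slope variants are returned: the
#' analytic derivative of the loading branch at the reversal
#' (`slope_*_deriv`), and the slope of a continuous least-squares line fitted
#' over the last `ls_window` fraction of the total rotation range
#' (`slope_er_nm_per_deg`, `slope_ir_nm_per_deg`) - the latter is what a
#' windowed linear fit on the sampled curve estimates.
#'
#' @param params A [limb_params()] object.
#' @param protocol A [protocol_config()] object.
#' @param ls_window Fraction of the total rotation range used as the
#'   endpoint-slope fitting window (default 0.1, i.e. the last 10%).
#' @return A list of named feature values (degrees and Nm/degree).
#' @export
closed_form_features <- function(params, protocol = protocol_config(),
                                 ls_window = 0.1) {
  stopifnot(inherits(params, "limb_params"),
            inherits(protocol, "protocol_config"))
  L <- protocol$torque_limit
  h <- params$hysteresis_offset
  if (L <= h) stop_bad("torque_limit must exceed hysteresis_offset")
  n0 <- params$neutral_angle
  M_er <- .reversal_extent(params$scale_er, params$shape_er, L, h)
  M_ir <- .reversal_extent(params$scale_ir, params$shape_ir, L, h)
  # zero crossings of the measured loops: driving toward ER the measured
  # torque is backbone + h, so it crosses 0 on the IR side of neutral;
  # driving toward IR it crosses on the ER side.
  cross_erward <- n0 - log1p(h / params$scale_ir) / params$shape_ir
  cross_irward <- n0 + log1p(h / params$scale_er) / params$shape_er
  total <- M_er + M_ir
  w <- ls_window * total
  list(
    max_er_deg = n0 + M_er,
    max_ir_deg = M_ir - n0,
    pos0_deg = (cross_erward + cross_irward) / 2,
    play0_deg = cross_irward - cross_erward,
    slope_er_nm_per_deg = .ls_slope_exp(params$scale_er, params$shape_er,
                                        M_er - w, M_er),
    slope_ir_nm_per_deg = .ls_slope_exp(-params$scale_ir, -params$shape_ir,
                                        -M_ir, -M_ir + w),
    slope_er_deriv = params$shape_er * (params$scale_er + L - h),
    slope_ir_deriv = params$shape_ir * (params$scale_ir + L - h),
    total_rot_deg = total
  )
}

# Continuous least-squares slope of A * exp(B * u) over u in [a, b]:
# slope = A * (I1 - ubar * I0) / (w^3 / 12) with I0, I1 the zeroth and first
# moments of exp(B u) on the window. Constant torque offsets drop out.
.ls_slope_exp <- function(A, B, a, b) {
  w <- b - a
  if (abs(B) * w < 1e-10) return(A * B)  # linear limit
  e_a <- exp(B * a)
  e_b <- exp(B * b)
  I0 <- (e_b - e_a) / B
  I1 <- e_b * (b / B - 1 / B^2) - e_a * (a / B - 1 / B^2)
  ubar <- (a + b) / 2
  A * (I1 - ubar * I0) / (w^3 / 12)
}

#' Simulate one robotic axial-rotation test cycle
#'
#' Emulates the torque-limited protocol: the limb is driven toward external
#' rotation until the noiseless loading-branch torque reaches the torque
#' limit, the direction reverses and the limb is driven toward internal
#' rotation until the opposite limit, then reverses again and the loop is
#' closed by returning to the ER reversal. Measured torque is the backbone
#' plus the signed frictional offset plus clamped Gaussian noise.
#'
#' @param params A [limb_params()] object.
#' @param protocol A [protocol_config()] object; `torque_limit` must exceed
#'   `params$hysteresis_offset`, otherwise reversal is unreachable.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   recordings. `NULL` uses the ambient RNG stream.
#' @param subject_id,limb_status Identifiers attached to the recording.
#' @return A `rotation_recording` data frame with columns `sample_index`,
#'   `angle_deg`, `torque_Nm`, `direction` (+1 driving toward ER, -1 toward
#'   IR).
#' @export
simulate_rotation_test <- function(params, protocol = protocol_config(),
                                   seed = NULL,
                                   subject_id = NA_character_,
                                   limb_status = NA_character_) {
  stopifnot(inherits(params, "limb_params"),
            inherits(protocol, "protocol_config"))
  L <- protocol$torque_limit
  h <- params$hysteresis_offset
  if (L <= h) {
    stop_bad("torque_limit (", L, " Nm) must exceed hysteresis_offset (",
             h, " Nm): reversal torque is unreachable")
  }
  n0 <- params$neutral_angle
  theta_er <- n0 + .reversal_extent(params$scale_er, params$shape_er, L, h)
  theta_ir <- n0 - .reversal_extent(params$scale_ir, params$shape_ir, L, h)
  step <- params$angle_step

  seq_to <- function(from, to) {
    s <- seq(from, to, by = sign(to - from) * step)
    if (utils::tail(s, 1L) != to) s <- c(s, to)
    s
  }
  a1 <- seq_to(n0, theta_er)                      # initial ER-ward loading
  a2 <- seq_to(theta_er, theta_ir)[-1L]           # ER reversal -> IR reversal
  a3 <- seq_to(theta_ir, theta_er)[-1L]           # IR reversal -> loop closed
  angle <- c(a1, a2, a3)
  direction <- c(rep(1L, length(a1)), rep(-1L, length(a2)),
                 rep(1L, length(a3)))

  torque <- with_seed(seed, {
    noise <- if (params$torque_noise_sd > 0) {
      sd <- params$torque_noise_sd
      pmin(pmax(stats::rnorm(length(angle), 0, sd), -3 * sd), 3 * sd)
    } else {
      0
    }
    backbone_torque(params, angle) + h * direction + noise
  })
  rotation_recording(angle, torque, direction,
                     subject_id = subject_id, limb_status = limb_status)
}

#' Construct a rotation recording
#'
#' A recording is one full hysteresis cycle of a torque-limited axial-rotation
#' test: sampled angle (degrees, ER positive), measured torque (Nm) and the
#' drive direction flag (+1 toward ER, -1 toward IR).
#'
#' @param angle_deg,torque_Nm,direction Equal-length numeric vectors;
#'   `direction` must contain only +1 and -1 and both values must occur.
#' @param subject_id,limb_status Identifiers; `limb_status` is
#'   `"reconstructed"` or `"healthy"` when known.
#' @param validate Check the recording invariants (at least 20 samples, both
#'   directions present).
#' @return A data frame of class `rotation_recording`.
#' @export
rotation_recording <- function(angle_deg, torque_Nm, direction,
                               subject_id = NA_character_,
                               limb_status = NA_character_,
                               validate = TRUE) {
  n <- length(angle_deg)
  stopifnot(length(torque_Nm) == n, length(direction) == n)
  if (validate) {
    if (n < 20L) stop_bad("a recording needs at least 20 samples")
    if (any(!is.finite(angle_deg)) || any(!is.finite(torque_Nm))) {
      stop_bad("angle and torque must be finite")
    }
    if (anyNA(direction) || !all(direction %in% c(-1, 1))) {
      stop_bad("`direction` must be +1 or -1 for every sample")
    }
    if (length(unique(direction)) < 2L) {
      stop_bad("recording must contain both drive directions ",
               "(truncated before a reversal?)")
    }
  }
  structure(
    data.frame(sample_index = seq_len(n),
               angle_deg = angle_deg,
               torque_Nm = torque_Nm,
               direction = as.integer(direction)),
    subject_id = subject_id,
    limb_status = limb_status,
    class = c("rotation_recording", "data.frame"))
}

#' @export
print.rotation_recording <- function(x, ...) {
  cat(sprintf(
    "<rotation_recording> subject %s, %s limb: %d samples, angle [%.2f, %.2f] deg, torque [%.3f, %.3f] Nm\n",
    attr(x, "subject_id"), attr(x, "limb_status"), nrow(x),
    min(x$angle_deg), max(x$angle_deg), min(x$torque_Nm), max(x$torque_Nm)))
  invisible(x)
}

# Solve (S, beta) for one direction from the reversal extent M (deg from
# neutral) and the endpoint derivative `slope` (Nm/deg), at loading span
# Lh = torque_limit - h:
#   M = log1p(Lh / S) / beta,  slope = beta * (S + Lh)
# Eliminating beta gives g(S) = log1p(Lh/S) (S + Lh) / M, strictly decreasing
# from +Inf (S -> 0) to Lh / M (S -> Inf), so a root exists iff
# slope > Lh / M (the curve must stiffen beyond its secant).
.solve_direction <- function(M, slope, Lh, label) {
  if (M <= 0) stop_bad("target max rotation must be positive (", label, ")")
  if (slope * M <= Lh * (1 + 1e-9)) {
    stop_bad(sprintf(
      "infeasible target (%s): endpoint slope %.4g Nm/deg is not above the secant slope %.4g = (torque span %.4g Nm) / (%.4g deg); the backbone cannot stiffen that little",
      label, slope, Lh / M, Lh, M))
  }
  g <- function(S) log1p(Lh / S) * (S + Lh) / M - slope
  hi <- Lh
  while (g(hi) > 0) hi <- hi * 2
  lo <- hi
  while (g(lo) < 0) lo <- lo / 4
  S <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  list(S = S, beta = log1p(Lh / S) / M)
}

#' Design limb parameters that hit prescribed curve-feature targets
#'
#' Inverts the hysteresis curve model: finds `limb_params` whose noiseless
#' simulated recording reproduces given targets for maximum external and
#' internal rotation, play at 0 Nm, and endpoint slope. The inversion uses the
#' closed forms of the model (reversal extent `M = log(1 + (L - h)/S) / beta`,
#' play `sum(log(1 + h/S_d)/beta_d)`, endpoint derivative
#' `beta (S + L - h)`), solving each direction's scale and shape by
#' one-dimensional root finding nested inside a root find for the shared
#' hysteresis offset.
#'
#' @param target Named list or one-row data frame with elements `max_er`
#'   (deg), `max_ir` (deg, magnitude), `play0` (deg, `>= 0`), and `slope_er`,
#'   `slope_ir` (Nm/deg endpoint derivative; a single `slope` is applied to
#'   both directions).
#' @param protocol A [protocol_config()] object.
#' @param torque_noise_sd,angle_step Passed through to the returned
#'   [limb_params()].
#' @return A [limb_params()] object with `neutral_angle = 0`.
#' @export
params_from_features <- function(target, protocol = protocol_config(),
                                 torque_noise_sd = 0.001, angle_step = 0.05) {
  stopifnot(inherits(protocol, "protocol_config"))
  target <- as.list(target)
  if (is.null(target$slope_er)) target$slope_er <- target$slope
  if (is.null(target$slope_ir)) target$slope_ir <- target$slope
  for (nm in c("max_er", "max_ir", "play0", "slope_er", "slope_ir")) {
    if (is.null(target[[nm]])) stop_bad("target is missing `", nm, "`")
    check_number(target[[nm]], nm)
  }
  L <- protocol$torque_limit
  M_er <- target$max_er
  M_ir <- target$max_ir
  play <- target$play0
  if (play < 0) stop_bad("target play must be >= 0")
  if (play >= 0.9 * (M_er + M_ir)) {
    stop_bad("infeasible target: play at 0 Nm (", play,
             " deg) approaches the total rotation (", M_er + M_ir, " deg)")
  }

  solve_at_h <- function(h) {
    list(er = .solve_direction(M_er, target$slope_er, L - h, "ER"),
         ir = .solve_direction(M_ir, target$slope_ir, L - h, "IR"))
  }
  play_at_h <- function(h) {
    d <- solve_at_h(h)
    log1p(h / d$er$S) / d$er$beta + log1p(h / d$ir$S) / d$ir$beta
  }

  if (play < 1e-12) {
    h <- 0
  } else {
    # play is 0 at h = 0 and grows toward the total rotation as h -> L;
    # bracket the root by walking h toward the torque limit.
    hi <- NULL
    for (frac in c(0.25, 0.5, 0.75, 0.9, 0.99, 0.999)) {
      if (play_at_h(frac * L) >= play) { hi <- frac * L; break }
    }
    if (is.null(hi)) {
      stop_bad("infeasible target: requested play ", play,
               " deg cannot be reached at any hysteresis offset below the ",
               "torque limit")
    }
    h <- stats::uniroot(function(x) play_at_h(x) - play, c(0, hi),
                        tol = 1e-12)$root
  }
  d <- solve_at_h(h)
  limb_params(neutral_angle = 0,
              scale_er = d$er$S, scale_ir = d$ir$S,
              shape_er = d$er$beta, shape_ir = d$ir$beta,
              hysteresis_offset = h,
              torque_noise_sd = torque_noise_sd,
              angle_step = angle_step)
}

#' Per-group, per-limb feature targets shaped like the study cohort
#'
#' Mean curve-feature and KT-1000 targets for each satisfaction group and limb
#' status. Rotational means follow the published group means (healthy maximum
#' external rotation 48.7 vs 64.5 degrees in the higher- and
#' lower-satisfaction groups; total rotation 70.4 vs 92.2 degrees in the
#' reconstructed limbs, 76.9 vs 95.8 in the healthy limbs; the
#' lower-satisfaction reconstructed limb has 8.7 degrees less external
#' rotation than its healthy counterpart). Endpoint-slope means preserve the
#' published 1.6 : 1.3 stiffness ratio between groups at a magnitude
#' consistent with the 5.65 Nm torque limit (0.32 and 0.26 Nm/deg). Play at
#' 0 Nm and KT manual-maximum translations are not printed per group and use
#' realistic defaults, with the lower-satisfaction reconstructed limb carrying
#' the elevated anterior translation that separates it from every other limb
#' class.
#'
#' @return A data frame with one row per group x limb and columns `group`,
#'   `limb`, `max_er`, `max_ir`, `play0`, `slope`, `kt_manmax`.
#' @export
study_feature_targets <- function() {
  data.frame(
    group = c(1L, 1L, 2L, 2L, 3L, 3L),
    limb = rep(c("reconstructed", "healthy"), 3L),
    max_er = c(46.0, 48.7, 55.8, 64.5, 43.0, 48.7),
    max_ir = c(24.4, 28.2, 36.4, 31.3, 27.9, 28.2),
    play0 = c(9, 9, 9, 9, 7, 9),
    slope = c(0.32, 0.32, 0.26, 0.26, 0.34, 0.32),
    kt_manmax = c(9.5, 8.0, 13.0, 8.0, 11.0, 8.0),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic cohort
#'
#' @param n_group1,n_group2,n_group3 Subject counts per satisfaction group
#'   (study sizes 9, 6 and 2).
#' @param targets Data frame of per-group, per-limb feature means as produced
#'   by [study_feature_targets()].
#' @param sds Named numeric vector of between-limb standard deviations:
#'   `rotation` (deg, for max ER/IR), `slope` (Nm/deg), `play` (deg),
#'   `kt` (mm).
#' @param vas_ranges List of length-2 numeric ranges the VAS satisfaction
#'   score is drawn from (uniformly) per group; must be consistent with the
#'   grouping rules of [assign_group()].
#' @param pivot_positive_prob Named vector: probability that a
#'   lower-satisfaction reconstructed limb (`case`) or any other limb
#'   (`control`) shows a positive pivot shift (grade >= 1).
#' @param seed Mandatory integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group1 = 9L, n_group2 = 6L, n_group3 = 2L,
                        targets = study_feature_targets(),
                        sds = c(rotation = 8, slope = 0.04, play = 2, kt = 1.5),
                        vas_ranges = list(`1` = c(80, 100),
                                          `2` = c(50, 80),
                                          `3` = c(0, 50)),
                        pivot_positive_prob = c(case = 2 / 3, control = 1 / 12),
                        seed) {
  if (missing(seed)) stop_bad("`seed` is mandatory in a cohort spec")
  check_number(seed, "seed")
  for (n in c(n_group1, n_group2, n_group3)) check_number(n, "group size", 0)
  stopifnot(is.data.frame(targets),
            all(c("group", "limb", "max_er", "max_ir", "play0", "slope",
                  "kt_manmax") %in% names(targets)))
  if (any(!is.finite(as.matrix(targets[, -(1:2)])))) {
    stop_bad("all feature target means must be finite")
  }
  stopifnot(all(c("rotation", "slope", "play", "kt") %in% names(sds)))
  if (any(sds < 0)) stop_bad("all SDs must be >= 0")
  for (g in names(vas_ranges)) {
    r <- vas_ranges[[g]]
    stopifnot(length(r) == 2L, r[1] <= r[2], r[1] >= 0, r[2] <= 100)
    mid <- mean(r)
    if (assign_group(mid) != as.integer(g)) {
      stop_bad("vas_ranges[['", g, "']] is inconsistent with the VAS ",
               "grouping rules")
    }
  }
  structure(list(n_group1 = as.integer(n_group1),
                 n_group2 = as.integer(n_group2),
                 n_group3 = as.integer(n_group3),
                 targets = targets, sds = sds, vas_ranges = vas_ranges,
                 pivot_positive_prob = pivot_positive_prob,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Study-shaped cohort spec (9 / 6 / 2 subjects)
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
study_cohort_spec <- function(seed, ...) cohort_spec(seed = seed, ...)

# Draw one limb's feature targets around the group means, clamped away from
# infeasible corners of the model (slope must exceed the secant, play must
# stay well below total rotation).
.draw_limb_target <- function(mu, sds, torque_limit) {
  max_er <- max(stats::rnorm(1, mu$max_er, sds[["rotation"]]), 10)
  max_ir <- max(stats::rnorm(1, mu$max_ir, sds[["rotation"]]), 5)
  slope <- stats::rnorm(1, mu$slope, sds[["slope"]])
  slope <- max(slope, 1.1 * torque_limit / min(max_er, max_ir))
  play <- min(max(stats::rnorm(1, mu$play0, sds[["play"]]), 0),
              0.6 * (max_er + max_ir))
  kt <- max(stats::rnorm(1, mu$kt_manmax, sds[["kt"]]), 2)
  list(max_er = max_er, max_ir = max_ir, play0 = play,
       slope = slope, kt_manmax = kt)
}

#' Generate a seeded synthetic cohort
#'
#' Produces a full synthetic study: for every subject, a reconstructed and a
#' healthy limb, each with drawn feature targets (Normal around the group
#' means), inverse-designed limb parameters, a simulated torque-angle
#' recording, KT-1000 translations at all protocol forces (nondecreasing in
#' force), a VAS satisfaction score drawn within the group's range, and
#' pivot-shift / Lachman grades. Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param protocol A [protocol_config()].
#' @param torque_noise_sd,angle_step Recording noise level (Nm) and sampling
#'   step (deg) applied to every limb.
#' @return An object of class `jp_cohort`: a list with `subjects` (one row per
#'   subject x limb: identifiers, VAS, group, KT values, manual-exam grades),
#'   `recordings` (named list of `rotation_recording`), `targets` (the drawn
#'   true feature values per limb) and the `spec`/`protocol` used.
#' @export
generate_cohort <- function(spec, protocol = protocol_config(),
                            torque_noise_sd = 0.001, angle_step = 0.05) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(protocol, "protocol_config"))
  n_total <- spec$n_group1 + spec$n_group2 + spec$n_group3
  if (n_total < 1L) stop_bad("cohort must contain at least one subject")
  groups <- rep(c(1L, 2L, 3L),
                times = c(spec$n_group1, spec$n_group2, spec$n_group3))
  width <- max(2L, nchar(as.character(n_total)))

  with_seed(spec$seed, {
    subjects <- list()
    targets <- list()
    recordings <- list()
    for (i in seq_len(n_total)) {
      g <- groups[i]
      sid <- sprintf(paste0("S%0", width, "d"), i)
      r <- spec$vas_ranges[[as.character(g)]]
      vas <- stats::runif(1, r[1], r[2])
      for (limb in c("reconstructed", "healthy")) {
        mu <- spec$targets[spec$targets$group == g & spec$targets$limb == limb, ]
        if (nrow(mu) != 1L) {
          stop_bad("spec$targets must have exactly one row for group ", g,
                   ", limb ", limb)
        }
        tgt <- .draw_limb_target(mu, spec$sds, protocol$torque_limit)
        params <- params_from_features(tgt, protocol,
                                       torque_noise_sd = torque_noise_sd,
                                       angle_step = angle_step)
        rec <- simulate_rotation_test(params, protocol,
                                      subject_id = sid, limb_status = limb)
        recordings[[paste(sid, limb, sep = "_")]] <- rec

        kt_manmax <- tgt$kt_manmax
        kt_sub <- sort(kt_manmax * c(0.50, 0.60, 0.75) *
                         (1 + stats::rnorm(3, 0, 0.04)))
        kt_sub <- pmin(kt_sub, kt_manmax)

        is_case <- (g == 2L && limb == "reconstructed")
        p_pos <- spec$pivot_positive_prob[[if (is_case) "case" else "control"]]
        pivot <- if (stats::runif(1) < p_pos) {
          sample(1:3, 1, prob = c(0.5, 0.35, 0.15))
        } else 0L
        lachman <- if (stats::runif(1) <
                         (if (limb == "reconstructed") 0.3 else 0.05)) {
          sample(1:2, 1, prob = c(0.7, 0.3))
        } else 0L

        subjects[[length(subjects) + 1L]] <- data.frame(
          subject_id = sid, limb = limb, vas = vas,
          group = assign_group(vas),
          kt_67 = kt_sub[1], kt_89 = kt_sub[2], kt_133 = kt_sub[3],
          kt_manmax = kt_manmax,
          pivot_shift_grade = pivot, lachman_grade = lachman,
          stringsAsFactors = FALSE)
        targets[[length(targets) + 1L]] <- data.frame(
          subject_id = sid, limb = limb, group = g,
          max_er = tgt$max_er, max_ir = tgt$max_ir, play0 = tgt$play0,
          slope = tgt$slope, kt_manmax = tgt$kt_manmax,
          stringsAsFactors = FALSE)
      }
    }
    structure(list(subjects = do.call(rbind, subjects),
                   recordings = recordings,
                   targets = do.call(rbind, targets),
                   spec = spec, protocol = protocol),
              class = "jp_cohort")
  })
}

#' @export
print.jp_cohort <- function(x, ...) {
  tab <- table(x$subjects$group[x$subjects$limb == "reconstructed"])
  cat(sprintf("<jp_cohort> %d subjects (groups: %s), %d recordings\n",
              nrow(x$subjects) / 2L,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              length(x$recordings)))
  invisible(x)
}
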