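# Independent oracles and small fixture builders used across the suite.

# Brute-force two-sided Fisher p by explicit hypergeometric enumeration with
# dhyper (independent of the package's log-factorial implementation).
oracle_fisher <- function(tp, fp, fn, tn) {
  r1 <- tp + fp
  c1 <- tp + fn
  n <- tp + fp + fn + tn
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  x <- max(0, r1 + c1 - n):min(r1, c1)
  p <- dhyper(x, c1, n - c1, r1)
  pobs <- dhyper(tp, c1, n - c1, r1)
  min(sum(p[p <= pobs * (1 + 1e-12)]), 1)
}

# Exhaustive pairwise-scan zero-crossing oracle: walk every adjacent sample
# pair of an angle-sorted branch, interpolate each straddled crossing, return
# the median.
oracle_crossing <- function(angle, torque) {
  o <- order(angle)
  angle <- angle[o]
  torque <- torque[o]
  xs <- numeric()
  for (i in seq_len(length(angle) - 1L)) {
    t1 <- torque[i]
    t2 <- torque[i + 1L]
    if (t1 == 0) xs <- c(xs, angle[i])
    if (sign(t1) * sign(t2) < 0) {
      xs <- c(xs, angle[i] - t1 * (angle[i + 1L] - angle[i]) / (t2 - t1))
    }
  }
  if (torque[length(torque)] == 0) xs <- c(xs, angle[length(angle)])
  if (length(xs) == 0L) return(NA_real_)
  median(xs)
}

# Textbook closed-form t tests (independent of stats::t.test).
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# Exact hysteresis-free linear loop: torque = slope * angle, reversing at
# +/- limit, sampled on a regular angle grid.
linear_recording <- function(slope = 0.1, limit = 5.65, step = 0.5,
                             play_offset = 0) {
  amax <- limit / slope
  a1 <- seq(0, amax, by = step)
  a2 <- seq(amax, -amax, by = -step)[-1]
  a3 <- seq(-amax, amax, by = step)[-1]
  angle <- c(a1, a2, a3)
  dir <- c(rep(1L, length(a1)), rep(-1L, length(a2)), rep(1L, length(a3)))
  rotation_recording(angle, slope * angle + play_offset * dir, dir,
                     subject_id = "LIN", limb_status = "healthy")
}

# Random feasible feature targets for round-trip / recovery checks.
random_target <- function(torque_limit = 5.65) {
  max_er <- runif(1, 30, 80)
  max_ir <- runif(1, 20, 50)
  slope <- runif(1, 1.5, 4) * torque_limit / min(max_er, max_ir)
  play <- runif(1, 0, 0.35 * (max_er + max_ir))
  list(max_er = max_er, max_ir = max_ir, play0 = play, slope = slope)
}

# Random limb parameters with sane morphology.
random_params <- function(angle_step = 0.05, noise = 0) {
  limb_params(neutral_angle = runif(1, -5, 5),
              scale_er = runif(1, 0.2, 2),
              scale_ir = runif(1, 0.2, 2),
              shape_er = runif(1, 0.03, 0.12),
              shape_ir = runif(1, 0.03, 0.12),
              hysteresis_offset = runif(1, 0, 0.8),
              torque_noise_sd = noise,
              angle_step = angle_step)
}
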