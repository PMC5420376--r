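# Load-deformation curve feature extraction.
#
# A recording is one torque-limited hysteresis cycle. Features follow the
# standard annotation of robotic laxity curves: maximum external rotation (a),
# maximum internal rotation (b), rotational position at 0 Nm of torque (c),
# the amount of play at 0 Nm - the width of the hysteresis loop there (d),
# and the endpoint slope over the last 10% of the curve (e).

.validate_recording <- function(rec) {
  if (!inherits(rec, "rotation_recording")) {
    if (is.data.frame(rec) &&
        all(c("angle_deg", "torque_Nm", "direction") %in% names(rec))) {
      rec <- rotation_recording(rec$angle_deg, rec$torque_Nm, rec$direction,
                                subject_id = attr(rec, "subject_id") %||% NA,
                                limb_status = attr(rec, "limb_status") %||% NA)
    } else {
      stop_bad("`rec` must be a rotation_recording (angle_deg, torque_Nm, direction)")
    }
  }
  if (nrow(rec) < 20L) stop_bad("a recording needs at least 20 samples")
  if (anyNA(rec$direction) || !all(rec$direction %in% c(-1L, 1L))) {
    stop_bad("missing or invalid direction flags")
  }
  if (!all(c(-1L, 1L) %in% rec$direction)) {
    stop_bad("recording must contain both drive directions ",
             "(truncated before a reversal?)")
  }
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment a recording into hysteresis branches
#'
#' Partitions the samples of one cycle by drive direction and torque sign into
#' the four quarter-branches of the loop: `loading_er` (driving toward ER,
#' torque >= 0), `unloading_er` (toward IR, torque >= 0), `loading_ir` (toward
#' IR, torque < 0) and `unloading_ir` (toward ER, torque < 0). Each branch is
#' sorted by angle.
#'
#' @param rec A `rotation_recording`.
#' @param min_samples Minimum samples a branch must contain (default 5); a
#'   thinner branch indicates a truncated or degenerate recording and is
#'   rejected.
#' @return Named list of four data frames.
#' @export
segment_branches <- function(rec, min_samples = 5L) {
  rec <- .validate_recording(rec)
  pick <- function(dir, pos) {
    b <- rec[rec$direction == dir &
               (if (pos) rec$torque_Nm >= 0 else rec$torque_Nm < 0), ,
             drop = FALSE]
    b[order(b$angle_deg), , drop = FALSE]
  }
  out <- list(loading_er = pick(1L, TRUE),
              unloading_er = pick(-1L, TRUE),
              loading_ir = pick(-1L, FALSE),
              unloading_ir = pick(1L, FALSE))
  thin <- vapply(out, nrow, 0L) < min_samples
  if (any(thin)) {
    stop_bad("branch(es) with fewer than ", min_samples, " samples: ",
             paste(names(out)[thin], collapse = ", "))
  }
  out
}

# All zero-torque crossings of one directional branch (samples sorted by
# angle), each located by linear interpolation between the straddling pair;
# returns the median crossing angle, which is exact for a noiseless branch and
# robust when noise makes the torque wiggle around zero. Exact-zero samples
# count as crossings at their own angle.
.zero_crossing <- function(angle, torque) {
  exact <- angle[torque == 0]
  s <- sign(torque)
  i <- which(s[-length(s)] * s[-1L] < 0)
  interp <- angle[i] - torque[i] * (angle[i + 1L] - angle[i]) /
    (torque[i + 1L] - torque[i])
  xs <- c(exact, interp)
  if (length(xs) == 0L) return(NA_real_)
  stats::median(xs)
}

#' Extract load-deformation curve features
#'
#' Measures the five canonical features of a torque-angle hysteresis cycle
#' plus total leg rotation. Reversal angles are the extreme-angle samples
#' (first extreme on ties). Zero-torque crossings are located by linear
#' interpolation between straddling samples on each directional branch; play
#' at 0 Nm is the distance between the crossing of the IR-ward branch and that
#' of the ER-ward branch, and the position at 0 Nm is their midpoint. The
#' endpoint slope is the least-squares line slope over the last
#' `slope_window` fraction of the rotation range approaching each reversal on
#' its loading branch (driving toward that reversal); windows holding fewer
#' than 3 samples are widened to the 3 nearest samples with a warning.
#'
#' @param rec A `rotation_recording`.
#' @param slope_window Fraction of the total rotation range used for the
#'   endpoint fit (default 0.1).
#' @param signed_ir Report maximum internal rotation as a signed angle rather
#'   than a magnitude.
#' @return An object of class `curve_features`: a list with fields
#'   `max_er_deg`, `max_ir_deg`, `pos0_deg`, `play0_deg`,
#'   `slope_er_nm_per_deg`, `slope_ir_nm_per_deg`, `total_rot_deg`, plus the
#'   recording's identifiers. If a directional branch never crosses 0 Nm the
#'   play and position are `NA` and `flags` records the defect.
#' @export
extract_features <- function(rec, slope_window = 0.1, signed_ir = FALSE) {
  rec <- .validate_recording(rec)
  flags <- character()

  max_er <- max(rec$angle_deg)
  min_angle <- min(rec$angle_deg)
  total <- max_er - min_angle
  max_ir <- if (signed_ir) min_angle else -min_angle

  erward <- rec[rec$direction == 1L, , drop = FALSE]
  irward <- rec[rec$direction == -1L, , drop = FALSE]
  erward <- erward[order(erward$angle_deg), ]
  irward <- irward[order(irward$angle_deg), ]

  cross_erward <- .zero_crossing(erward$angle_deg, erward$torque_Nm)
  cross_irward <- .zero_crossing(irward$angle_deg, irward$torque_Nm)
  if (is.na(cross_erward) || is.na(cross_irward)) {
    flags <- c(flags, "no_zero_crossing")
    play <- NA_real_
    pos0 <- NA_real_
  } else {
    play <- abs(cross_irward - cross_erward)
    pos0 <- (cross_irward + cross_erward) / 2
  }

  w <- slope_window * total
  fit_slope <- function(branch, at_er) {
    lo <- if (at_er) max_er - w else min_angle
    hi <- if (at_er) max_er else min_angle + w
    in_win <- branch$angle_deg >= lo & branch$angle_deg <= hi
    if (sum(in_win) < 3L) {
      warning("fewer than 3 samples in the endpoint-slope window; ",
              "widening to the 3 nearest samples", call. = FALSE)
      ref <- if (at_er) max_er else min_angle
      in_win <- rank(abs(branch$angle_deg - ref), ties.method = "first") <= 3L
    }
    b <- branch[in_win, ]
    stats::cov(b$angle_deg, b$torque_Nm) / stats::var(b$angle_deg)
  }
  slope_er <- fit_slope(erward, at_er = TRUE)
  slope_ir <- fit_slope(irward, at_er = FALSE)

  structure(
    list(subject_id = attr(rec, "subject_id"),
         limb_status = attr(rec, "limb_status"),
         max_er_deg = max_er,
         max_ir_deg = max_ir,
         pos0_deg = pos0,
         play0_deg = play,
         slope_er_nm_per_deg = slope_er,
         slope_ir_nm_per_deg = slope_ir,
         total_rot_deg = total,
         flags = flags),
    class = "curve_features")
}

#' @export
print.curve_features <- function(x, ...) {
  cat(sprintf(
    "<curve_features> %s/%s: max ER %.2f deg, max IR %.2f deg, total %.2f deg, play %.2f deg at pos %.2f deg, slopes %.3f / %.3f Nm/deg%s\n",
    x$subject_id, x$limb_status, x$max_er_deg, x$max_ir_deg, x$total_rot_deg,
    x$play0_deg, x$pos0_deg, x$slope_er_nm_per_deg, x$slope_ir_nm_per_deg,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' Total leg rotation
#'
#' Maximum external rotation plus maximum internal rotation (both as
#' magnitudes), in degrees.
#'
#' @param f A `curve_features` object (or anything with `max_er_deg` and
#'   `max_ir_deg`).
#' @return Total rotation in degrees.
#' @export
total_leg_rotation <- function(f) {
  f$max_er_deg + abs(f$max_ir_deg)
}

#' Extract features for every recording of a cohort
#'
#' @param recordings A `jp_cohort` or a (named) list of `rotation_recording`s.
#' @param ... Passed to [extract_features()].
#' @return A data frame, one row per limb, with columns `subject_id`, `limb`,
#'   `max_er_deg`, `max_ir_deg`, `pos0_deg`, `play0_deg`,
#'   `slope_er_nm_per_deg`, `slope_ir_nm_per_deg`, `total_rot_deg`.
#' @export
features_df <- function(recordings, ...) {
  if (inherits(recordings, "jp_cohort")) recordings <- recordings$recordings
  rows <- lapply(recordings, function(rec) {
    f <- extract_features(rec, ...)
    data.frame(subject_id = f$subject_id, limb = f$limb_status,
               max_er_deg = f$max_er_deg, max_ir_deg = f$max_ir_deg,
               pos0_deg = f$pos0_deg, play0_deg = f$play0_deg,
               slope_er_nm_per_deg = f$slope_er_nm_per_deg,
               slope_ir_nm_per_deg = f$slope_ir_nm_per_deg,
               total_rot_deg = f$total_rot_deg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
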