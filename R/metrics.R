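# Composite laxity metric (Joint Play Envelope), VAS grouping and per-subject
# analysis records.

#' Joint Play Envelope
#'
#' The composite laxity statistic: total leg rotation (degrees) multiplied by
#' the KT-1000 anterior translation at manual-maximum force (mm), giving units
#' of mm-deg. It couples the rotational and translational laxity of a limb in
#' a single factor; both components are stored for audit as attributes.
#'
#' @param total_rotation Total leg rotation in degrees (`>= 0`).
#' @param kt_manmax KT manual-maximum anterior translation in mm (`>= 0`).
#' @return Numeric vector of JPE values (mm-deg) with the components attached
#'   as a `components` attribute.
#' @export
joint_play_envelope <- function(total_rotation, kt_manmax) {
  if (!is.numeric(total_rotation) || !is.numeric(kt_manmax) ||
      any(!is.finite(total_rotation)) || any(!is.finite(kt_manmax))) {
    stop_bad("both components must be finite numeric")
  }
  if (any(total_rotation < 0) || any(kt_manmax < 0)) {
    stop_bad("laxity magnitudes are nonnegative; got a negative component")
  }
  structure(total_rotation * kt_manmax,
            components = data.frame(total_rotation = total_rotation,
                                    kt_manmax = kt_manmax))
}

#' Assign a satisfaction group from a VAS score
#'
#' Group 1 (higher satisfaction): VAS `>= 80`. Group 2 (lower satisfaction):
#' `50 < VAS < 80`. Group 3 (outliers): `VAS < 50`. A score of exactly 50 is
#' not covered by those strict inequalities; by default it closes downward
#' into Group 3 (configurable via `vas50_group`).
#'
#' @param vas VAS satisfaction score(s) in `[0, 100]`.
#' @param vas50_group Group for the boundary score of exactly 50 (default 3).
#' @return Integer group labels (1, 2 or 3).
#' @export
assign_group <- function(vas, vas50_group = 3L) {
  if (!is.numeric(vas) || any(!is.finite(vas))) {
    stop_bad("`vas` must be finite numeric")
  }
  if (any(vas < 0 | vas > 100)) stop_bad("VAS scores must lie in [0, 100]")
  stopifnot(vas50_group %in% c(2L, 3L))
  out <- ifelse(vas >= 80, 1L, ifelse(vas > 50, 2L, 3L))
  out[vas == 50] <- as.integer(vas50_group)
  as.integer(out)
}

#' Side-to-side difference
#'
#' Signed difference of a measurement between the reconstructed and healthy
#' limb of one subject: `reconstructed - healthy`.
#'
#' @param reconstructed,healthy Same-type measurements (both mm or both
#'   degrees).
#' @param units Optional pair of unit strings; if both are given they must
#'   match.
#' @return Signed difference(s), same units as the inputs.
#' @export
side_to_side_difference <- function(reconstructed, healthy, units = NULL) {
  if (!is.null(units)) {
    stopifnot(length(units) == 2L)
    if (units[1] != units[2]) {
      stop_bad("unit mismatch: ", units[1], " vs ", units[2])
    }
  }
  if (!is.numeric(reconstructed) || !is.numeric(healthy)) {
    stop_bad("measurements must be numeric")
  }
  reconstructed - healthy
}

#' Assemble the per-limb analysis table
#'
#' Joins extracted curve features with the cohort table into one row per limb
#' carrying everything the screening and comparison stages need: total
#' rotation, KT manual maximum, JPE, VAS, group, and manual-exam grades.
#'
#' @param cohort A `jp_cohort`, or a data frame shaped like its `subjects`
#'   element (`subject_id`, `limb`, `vas`, `group`, `kt_manmax`, ...).
#' @param features A features data frame as from [features_df()]; extracted
#'   from the cohort's recordings when omitted.
#' @return A data frame with columns `subject_id`, `limb`, `total_rot_deg`,
#'   `kt_manmax_mm`, `jpe_mmdeg`, `vas`, `group`, `pivot_shift_grade`,
#'   `lachman_grade`, `max_er_deg`, `max_ir_deg`, `play0_deg`,
#'   `slope_er_nm_per_deg`, `slope_ir_nm_per_deg`.
#' @export
build_analysis_table <- function(cohort, features = NULL) {
  subjects <- if (inherits(cohort, "jp_cohort")) cohort$subjects else cohort
  stopifnot(is.data.frame(subjects),
            all(c("subject_id", "limb", "vas", "group", "kt_manmax")
                %in% names(subjects)))
  if (is.null(features)) {
    if (!inherits(cohort, "jp_cohort")) {
      stop_bad("`features` must be supplied when `cohort` is a plain table")
    }
    features <- features_df(cohort)
  }
  out <- merge(subjects, features, by = c("subject_id", "limb"),
               all.x = TRUE, sort = FALSE)
  if (anyNA(out$total_rot_deg)) {
    stop_bad("missing curve features for limb(s): ",
             paste(out$subject_id[is.na(out$total_rot_deg)], collapse = ", "))
  }
  out$kt_manmax_mm <- out$kt_manmax
  out$jpe_mmdeg <- as.numeric(
    joint_play_envelope(out$total_rot_deg, out$kt_manmax_mm))
  out <- out[order(out$subject_id, out$limb), ]
  rownames(out) <- NULL
  cols <- c("subject_id", "limb", "total_rot_deg", "kt_manmax_mm",
            "jpe_mmdeg", "vas", "group", "pivot_shift_grade", "lachman_grade",
            "max_er_deg", "max_ir_deg", "play0_deg",
            "slope_er_nm_per_deg", "slope_ir_nm_per_deg",
            "kt_67", "kt_89", "kt_133")
  out[, intersect(cols, names(out))]
}
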