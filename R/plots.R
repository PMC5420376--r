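# Diagnostic figures (base graphics).

#' Plot a torque-angle hysteresis recording with annotated features
#'
#' Draws the load-deformation loop and, when features are supplied (or
#' computable), marks the canonical features: maximum external rotation (a),
#' maximum internal rotation (b), position at 0 Nm (c), play at 0 Nm (d), and
#' the endpoint-slope windows (e).
#'
#' @param rec A `rotation_recording`.
#' @param features Optional `curve_features`; extracted from `rec` when `NULL`.
#' @param ... Passed to [graphics::plot()].
#' @return The features, invisibly.
#' @export
plot_recording <- function(rec, features = NULL, ...) {
  rec <- .validate_recording(rec)
  if (is.null(features)) features <- extract_features(rec)
  graphics::plot(rec$angle_deg, rec$torque_Nm, type = "n",
                 xlab = "rotation (deg, ER positive)", ylab = "torque (Nm)",
                 main = sprintf("%s / %s", attr(rec, "subject_id"),
                                attr(rec, "limb_status")), ...)
  graphics::abline(h = 0, col = "grey70")
  for (d in c(1L, -1L)) {
    b <- rec[rec$direction == d, ]
    b <- b[order(b$angle_deg), ]
    graphics::lines(b$angle_deg, b$torque_Nm,
                    col = if (d == 1L) "steelblue" else "tomato")
  }
  f <- features
  graphics::points(c(f$max_er_deg, -abs(f$max_ir_deg)), c(0, 0) * NA)
  graphics::abline(v = f$max_er_deg, lty = 3)
  graphics::abline(v = -abs(f$max_ir_deg), lty = 3)
  if (!is.na(f$play0_deg)) {
    graphics::segments(f$pos0_deg - f$play0_deg / 2, 0,
                       f$pos0_deg + f$play0_deg / 2, 0,
                       lwd = 3, col = "darkgreen")
    graphics::points(f$pos0_deg, 0, pch = 19, col = "darkgreen")
  }
  graphics::legend("topleft", bty = "n", lty = c(1, 1, 3, 1),
                   lwd = c(1, 1, 1, 3),
                   col = c("steelblue", "tomato", "black", "darkgreen"),
                   legend = c("driving toward ER", "driving toward IR",
                              "reversals (a, b)", "play at 0 Nm (c, d)"))
  invisible(features)
}

#' Scatter of KT manual maximum vs total rotation by satisfaction group
#'
#' The two JPE components plotted against each other, one point per limb,
#' with iso-JPE hyperbolas; clustering of lower-satisfaction reconstructed
#' limbs toward the upper right is the signature the composite statistic
#' exploits.
#'
#' @param analysis Analysis table (from [build_analysis_table()] or read back
#'   from `analysis.csv`).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_jpe_scatter <- function(analysis, ...) {
  stopifnot(all(c("total_rot_deg", "kt_manmax_mm", "group", "limb")
                %in% names(analysis)))
  col <- ifelse(analysis$group == 2 & analysis$limb == "reconstructed",
                "tomato", ifelse(analysis$group == 3, "grey60", "steelblue"))
  pch <- ifelse(analysis$limb == "reconstructed", 19, 1)
  graphics::plot(analysis$total_rot_deg, analysis$kt_manmax_mm,
                 col = col, pch = pch,
                 xlab = "total leg rotation (deg)",
                 ylab = "KT manual maximum (mm)", ...)
  for (j in stats::quantile(analysis$jpe_mmdeg, c(0.25, 0.5, 0.75))) {
    x <- seq(min(analysis$total_rot_deg), max(analysis$total_rot_deg),
             length.out = 100)
    graphics::lines(x, j / x, lty = 3, col = "grey70")
  }
  graphics::legend("topleft", bty = "n", pch = c(19, 19, 1),
                   col = c("tomato", "steelblue", "steelblue"),
                   legend = c("group 2 reconstructed (condition positive)",
                              "other reconstructed", "healthy"))
  invisible(NULL)
}
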