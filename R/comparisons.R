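# Group and limb comparisons: paired (reconstructed vs healthy within
# subject), unpaired (Group 1 vs Group 2, Welch form), and pointwise t tests
# along torque-registered load-deformation curves.

#' Compare a feature between two arms
#'
#' Two-sided t test of a curve feature or laxity measure. Paired design is
#' used when the arms are the reconstructed and healthy limbs of the same
#' subjects (in matching order); the unpaired design uses the Welch
#' (unequal-variance) form, appropriate for the small, unequal group sizes.
#'
#' @param x,y Numeric vectors for the two arms. For `design = "paired"` they
#'   must be complete pairs of equal length.
#' @param design `"unpaired"` (default) or `"paired"`.
#' @param name Label carried in the result.
#' @return An object of class `comparison_result`: list with `name`, `design`,
#'   `mean_a`, `mean_b`, `diff` (`mean(x) - mean(y)`; for paired, the mean
#'   within-pair difference), `p_value`, `statistic`, `df`, and `flags`. With
#'   zero variance in both arms the test is undefined and `p_value` is `NA`
#'   with a `zero_variance` flag.
#' @export
compare_feature <- function(x, y, design = c("unpaired", "paired"),
                            name = "") {
  design <- match.arg(design)
  stopifnot(is.numeric(x), is.numeric(y))
  if (anyNA(x) || anyNA(y)) stop_bad("arms must be complete (no NA)")
  if (design == "paired" && length(x) != length(y)) {
    stop_bad("paired design requires complete pairs (equal lengths)")
  }
  if (length(x) < 2L || length(y) < 2L) {
    stop_bad("each arm needs at least 2 observations")
  }
  flags <- character()
  diff <- if (design == "paired") mean(x - y) else mean(x) - mean(y)
  degenerate <- if (design == "paired") {
    stats::var(x - y) == 0
  } else {
    stats::var(x) == 0 && stats::var(y) == 0
  }
  p <- NA_real_
  stat <- NA_real_
  dfree <- NA_real_
  if (degenerate) {
    flags <- c(flags, "zero_variance")
  } else {
    # t.test itself rejects data constant to within floating-point residue;
    # treat that the same as exactly zero variance
    ht <- tryCatch(
      if (design == "paired") {
        stats::t.test(x, y, paired = TRUE)
      } else {
        stats::t.test(x, y, var.equal = FALSE)
      },
      error = function(e) {
        if (grepl("essentially constant", conditionMessage(e))) NULL
        else stop(e)
      })
    if (is.null(ht)) {
      flags <- c(flags, "zero_variance")
    } else {
      p <- ht$p.value
      stat <- unname(ht$statistic)
      dfree <- unname(ht$parameter)
    }
  }
  structure(list(name = name, design = design,
                 mean_a = mean(x), mean_b = mean(y), diff = diff,
                 p_value = p, statistic = stat, df = dfree, flags = flags),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s (%s): %.3f vs %.3f, diff %.3f, p = %s%s\n",
              if (nzchar(x$name)) x$name else "unnamed", x$design,
              x$mean_a, x$mean_b, x$diff,
              if (is.na(x$p_value)) "NA" else format(x$p_value, digits = 4),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

#' Register load-deformation curves onto a common torque grid
#'
#' Interpolates each recording's angle linearly onto a shared, strictly
#' increasing torque grid, separately per drive direction (the protocol is
#' torque-limited, so torque is the natural registration axis). A limb whose
#' chosen branch does not span the grid is excluded with a warning.
#'
#' @param recordings A `jp_cohort` or (named) list of `rotation_recording`s.
#' @param grid Strictly increasing torque grid (Nm). The default spans 90% of
#'   `torque_limit` symmetrically in 41 points, inside the span every limb's
#'   branch can cover for moderate hysteresis.
#' @param branch Which directional branch to register: `"erward"` (driving
#'   toward external rotation, the loading branch for the ER endpoint) or
#'   `"irward"`.
#' @param torque_limit Used only to build the default grid.
#' @return An object of class `registered_curves`: list with `grid`, `angles`
#'   (matrix, one row per limb), `ids`, and `branch`.
#' @export
register_curves <- function(recordings, grid = NULL,
                            branch = c("erward", "irward"),
                            torque_limit = 5.65) {
  branch <- match.arg(branch)
  if (inherits(recordings, "jp_cohort")) recordings <- recordings$recordings
  if (is.null(grid)) {
    grid <- seq(-0.9 * torque_limit, 0.9 * torque_limit, length.out = 41L)
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop_bad("`grid` must be strictly increasing")
  }
  dir_flag <- if (branch == "erward") 1L else -1L
  ids <- names(recordings) %||% as.character(seq_along(recordings))
  rows <- list()
  kept <- character()
  for (i in seq_along(recordings)) {
    rec <- .validate_recording(recordings[[i]])
    b <- rec[rec$direction == dir_flag, , drop = FALSE]
    if (min(b$torque_Nm) > grid[1L] || max(b$torque_Nm) < grid[length(grid)]) {
      warning("limb ", ids[i], " does not cover the torque grid; excluded",
              call. = FALSE)
      next
    }
    ang <- stats::approx(b$torque_Nm, b$angle_deg, xout = grid,
                         ties = mean)$y
    rows[[length(rows) + 1L]] <- ang
    kept <- c(kept, ids[i])
  }
  if (length(rows) == 0L) stop_bad("no limb covers the torque grid")
  structure(list(grid = grid,
                 angles = do.call(rbind, rows),
                 ids = kept, branch = branch),
            class = "registered_curves")
}

#' Pointwise t tests along registered curves
#'
#' Unpaired two-sided Welch t test of angle at every torque grid point between
#' two sets of registered curves. Uncorrected for multiplicity by default,
#' matching common practice for exploratory pointwise curve comparison; a
#' Bonferroni adjustment is available.
#'
#' @param set_a,set_b `registered_curves` on the same grid and branch.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return A data frame with one row per grid point: `torque_Nm`, `mean_a`,
#'   `mean_b`, `diff`, `statistic`, `p_value`, `p_adjusted`. Points where an
#'   arm has fewer than 2 limbs or both arms have zero variance get `NA` p.
#' @export
pointwise_t <- function(set_a, set_b, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(set_a, "registered_curves"),
            inherits(set_b, "registered_curves"))
  if (!isTRUE(all.equal(set_a$grid, set_b$grid)) ||
      set_a$branch != set_b$branch) {
    stop_bad("both sets must share the same torque grid and branch")
  }
  k <- length(set_a$grid)
  out <- data.frame(torque_Nm = set_a$grid, mean_a = NA_real_,
                    mean_b = NA_real_, diff = NA_real_,
                    statistic = NA_real_, p_value = NA_real_)
  for (j in seq_len(k)) {
    a <- set_a$angles[, j]
    b <- set_b$angles[, j]
    out$mean_a[j] <- mean(a)
    out$mean_b[j] <- mean(b)
    out$diff[j] <- mean(a) - mean(b)
    if (length(a) < 2L || length(b) < 2L) next
    if (stats::var(a) == 0 && stats::var(b) == 0) next
    ht <- stats::t.test(a, b, var.equal = FALSE)
    out$statistic[j] <- unname(ht$statistic)
    out$p_value[j] <- ht$p.value
  }
  out$p_adjusted <- if (adjust == "bonferroni") {
    pmin(out$p_value * sum(!is.na(out$p_value)), 1)
  } else {
    out$p_value
  }
  out
}

#' Standard battery of group and limb comparisons
#'
#' Runs the study's comparison design on an analysis table: paired
#' reconstructed-vs-healthy tests within each of groups 1 and 2, and unpaired
#' (Welch) Group 1 vs Group 2 tests per limb status, for a set of features.
#' Group 3 is excluded.
#'
#' @param analysis Analysis table from [build_analysis_table()].
#' @param features Character vector of feature columns to compare.
#' @return A data frame: one row per comparison with `name`, `design`,
#'   `mean_a`, `mean_b`, `diff`, `p_value`.
#' @export
comparison_battery <- function(analysis,
                               features = c("max_er_deg", "total_rot_deg",
                                            "kt_manmax_mm", "jpe_mmdeg")) {
  stopifnot(all(features %in% names(analysis)))
  df <- analysis[analysis$group %in% c(1L, 2L), , drop = FALSE]
  df <- df[order(df$subject_id), ]
  rows <- list()
  add <- function(res) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = res$name, design = res$design, mean_a = res$mean_a,
      mean_b = res$mean_b, diff = res$diff, p_value = res$p_value,
      stringsAsFactors = FALSE)
  }
  for (f in features) {
    for (g in c(1L, 2L)) {
      rec <- df[df$group == g & df$limb == "reconstructed", ]
      hea <- df[df$group == g & df$limb == "healthy", ]
      stopifnot(identical(rec$subject_id, hea$subject_id))
      if (nrow(rec) >= 2L) {
        add(compare_feature(rec[[f]], hea[[f]], design = "paired",
                            name = sprintf("%s: recon vs healthy, group %d",
                                           f, g)))
      }
    }
    for (limb in c("reconstructed", "healthy")) {
      a <- df[df$group == 1L & df$limb == limb, f]
      b <- df[df$group == 2L & df$limb == limb, f]
      if (length(a) >= 2L && length(b) >= 2L) {
        add(compare_feature(a, b, design = "unpaired",
                            name = sprintf("%s: group 1 vs 2, %s limbs",
                                           f, limb)))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
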