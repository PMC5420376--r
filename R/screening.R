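# Diagnostic screening evaluation: 2x2 tables, Altman-Bland screening values,
# the exact Fisher test by hypergeometric enumeration, and recovery of integer
# contingency tables from rounded published screening values.

#' 2x2 contingency table for a screening test
#'
#' Rows are test outcome (positive / negative), columns condition status
#' (lower satisfaction present / absent).
#'
#' @param tp,fp,fn,tn Nonnegative integer cell counts: true positives, false
#'   positives, false negatives, true negatives.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stop_bad("all cells must be nonnegative integers")
  }
  if (sum(cells) < 1) stop_bad("the table must contain at least one subject")
  structure(as.list(stats::setNames(as.integer(cells), names(cells))),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              condition = c("present", "absent")))
  print(m)
  invisible(x)
}

#' Altman-Bland screening values of a 2x2 table
#'
#' Sensitivity `100 tp / (tp + fn)`, specificity `100 tn / (tn + fp)`,
#' positive predictive value `100 tp / (tp + fp)` and negative predictive
#' value `100 tn / (tn + fn)`, each reported at full precision and rounded to
#' the nearest integer (halves away from zero). A value whose denominator is
#' zero is undefined and reported as `NA`, never as 0.
#'
#' @param t A [contingency_table()].
#' @param criterion,threshold Optional annotations carried in the result.
#' @return An object of class `screening_result` with elements `values`
#'   (percent, full precision), `rounded`, `table`, and `undefined` (names of
#'   any undefined values).
#' @export
screening_values <- function(t, criterion = NA_character_, threshold = NA) {
  stopifnot(inherits(t, "contingency_table"))
  safe <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  vals <- c(sensitivity = safe(t$tp, t$tp + t$fn),
            specificity = safe(t$tn, t$tn + t$fp),
            ppv = safe(t$tp, t$tp + t$fp),
            npv = safe(t$tn, t$tn + t$fn))
  structure(list(criterion = criterion, threshold = threshold,
                 values = vals, rounded = round_half_away(vals),
                 undefined = names(vals)[is.na(vals)],
                 table = t, p_value = NA_real_),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> %s%s\n",
              if (is.na(x$criterion)) "unnamed criterion" else x$criterion,
              if (is.na(x$threshold[1])) ""
              else paste0(" (threshold ", format(x$threshold), ")")))
  v <- ifelse(is.na(x$values), "undef",
              sprintf("%d (%.2f)", x$rounded, x$values))
  cat(sprintf("  sensitivity %s | specificity %s | PPV %s | NPV %s\n",
              v[1], v[2], v[3], v[4]))
  if (!is.na(x$p_value)) cat(sprintf("  Fisher exact p = %.4g\n", x$p_value))
  invisible(x)
}

# Log hypergeometric pmf over the support of the upper-left cell given the
# margins, built directly from log-factorials.
.log_hyper <- function(r1, c1, n) {
  lo <- max(0L, r1 + c1 - n)
  hi <- min(r1, c1)
  x <- lo:hi
  lp <- lgamma(r1 + 1) - lgamma(x + 1) - lgamma(r1 - x + 1) +
    lgamma(n - r1 + 1) - lgamma(c1 - x + 1) - lgamma(n - r1 - c1 + x + 1) -
    (lgamma(n + 1) - lgamma(c1 + 1) - lgamma(n - c1 + 1))
  list(x = x, lp = lp)
}

#' Exact Fisher test for a 2x2 table
#'
#' Two-sided exact test of association computed by full enumeration of the
#' hypergeometric distribution with the observed margins fixed, using
#' log-factorials. The default two-sided definition is the probability-mass
#' method: the p-value sums the probabilities of all tables at most as
#' probable as the observed one (with a relative tolerance of `1e-12` on the
#' comparison). The `"doubling"` method instead doubles the smaller tail
#' (capped at 1).
#'
#' @param t A [contingency_table()].
#' @param method Two-sided definition, `"prob"` (default) or `"doubling"`.
#' @return The p-value, in `(0, 1]`. If any margin is zero only one table is
#'   possible and the p-value is 1.
#' @export
fisher_exact <- function(t, method = c("prob", "doubling")) {
  stopifnot(inherits(t, "contingency_table"))
  method <- match.arg(method)
  r1 <- t$tp + t$fp
  c1 <- t$tp + t$fn
  n <- t$tp + t$fp + t$fn + t$tn
  if (r1 == 0L || c1 == 0L || r1 == n || c1 == n) return(1)
  d <- .log_hyper(r1, c1, n)
  lp_obs <- d$lp[d$x == t$tp]
  p <- if (method == "prob") {
    sum(exp(d$lp[d$lp <= lp_obs + log(1 + 1e-12)]))
  } else {
    lower <- sum(exp(d$lp[d$x <= t$tp]))
    upper <- sum(exp(d$lp[d$x >= t$tp]))
    2 * min(lower, upper)
  }
  min(max(p, exp(lp_obs)), 1)
}

#' Dichotomize a continuous criterion
#'
#' A limb is test-positive iff its value lies strictly beyond the threshold in
#' the stated direction; ties at the threshold are test-negative.
#'
#' @param values Finite numeric criterion values.
#' @param threshold Cut-off.
#' @param direction `"greater"`: positive iff `value > threshold`; `"less"`:
#'   positive iff `value < threshold`.
#' @return Logical vector of test outcomes.
#' @export
dichotomize <- function(values, threshold, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop_bad("`values` must be finite numeric")
  }
  check_number(threshold, "threshold")
  if (direction == "greater") values > threshold else values < threshold
}

# Build a contingency_table from logical test outcomes and condition labels.
.tabulate_test <- function(test_pos, condition_pos) {
  contingency_table(tp = sum(test_pos & condition_pos),
                    fp = sum(test_pos & !condition_pos),
                    fn = sum(!test_pos & condition_pos),
                    tn = sum(!test_pos & !condition_pos))
}

# Condition labels for the lower-satisfaction screening question: positives
# are the reconstructed limbs of Group 2; negatives are all Group 1 limbs
# plus the healthy limbs of Group 2 (patients report full satisfaction with
# the healthy knee); Group 3 is excluded from analysis by default.
.screening_labels <- function(df, exclude_group3 = TRUE) {
  stopifnot(all(c("group", "limb") %in% names(df)))
  if (exclude_group3) df <- df[df$group != 3L, , drop = FALSE]
  df$condition_pos <- df$group == 2L & df$limb == "reconstructed"
  df
}

#' Evaluate a per-limb criterion as a screening test for lower satisfaction
#'
#' Dichotomizes the chosen criterion, tabulates it against the
#' lower-satisfaction condition (reconstructed limbs of Group 2 are
#' condition-positive; all Group 1 limbs and Group 2 healthy limbs are
#' condition-negative; Group 3 is excluded by default), and computes the four
#' screening values plus the exact Fisher p. With `threshold = "search"` every
#' midpoint of consecutive sorted unique criterion values is tried and the
#' threshold minimizing the Fisher p is chosen, ties broken toward the
#' threshold yielding fewer test-positives.
#'
#' @param analysis Analysis table from [build_analysis_table()] (or any data
#'   frame with `group`, `limb` and the criterion column).
#' @param criterion One of `"jpe"`, `"kt_manmax"`, `"total_rotation"`,
#'   `"pivot_shift"`, or the name of a numeric column of `analysis`.
#' @param threshold Numeric cut-off or `"search"`. The default for
#'   `"pivot_shift"` is 0 (grade >= 1 is positive), otherwise `"search"`.
#' @param direction Passed to [dichotomize()].
#' @param exclude_group3 Drop Group 3 limbs before evaluation (default TRUE).
#' @return A `screening_result` with the Fisher `p_value` filled in and the
#'   threshold used.
#' @export
evaluate_criterion <- function(analysis,
                               criterion = c("jpe", "kt_manmax",
                                             "total_rotation", "pivot_shift"),
                               threshold = NULL,
                               direction = "greater",
                               exclude_group3 = TRUE) {
  col_map <- c(jpe = "jpe_mmdeg", kt_manmax = "kt_manmax_mm",
               total_rotation = "total_rot_deg",
               pivot_shift = "pivot_shift_grade")
  criterion <- if (length(criterion) > 1L) match.arg(criterion) else criterion
  col <- if (criterion %in% names(col_map)) col_map[[criterion]] else criterion
  if (!col %in% names(analysis)) {
    stop_bad("criterion column `", col, "` not found in the analysis table")
  }
  df <- .screening_labels(analysis, exclude_group3)
  if (sum(df$condition_pos) == 0L || sum(!df$condition_pos) == 0L) {
    stop_bad("screening needs both condition-positive and condition-negative ",
             "limbs; got ", sum(df$condition_pos), " positives of ", nrow(df))
  }
  values <- df[[col]]
  if (any(!is.finite(values))) {
    stop_bad("criterion `", criterion, "` has missing values for limb(s): ",
             paste(df$subject_id[!is.finite(values)], collapse = ", "))
  }
  if (is.null(threshold)) {
    threshold <- if (criterion == "pivot_shift") 0 else "search"
  }

  eval_at <- function(thr) {
    test_pos <- dichotomize(values, thr, direction)
    tab <- .tabulate_test(test_pos, df$condition_pos)
    list(thr = thr, tab = tab, p = fisher_exact(tab),
         n_pos = sum(test_pos))
  }

  if (identical(threshold, "search")) {
    u <- sort(unique(values))
    if (length(u) < 2L) {
      # constant criterion: any threshold gives an uninformative table
      best <- eval_at(u[1])
    } else {
      cand <- (u[-length(u)] + u[-1L]) / 2
      fits <- lapply(cand, eval_at)
      ps <- vapply(fits, `[[`, 0, "p")
      npos <- vapply(fits, `[[`, 0, "n_pos")
      best <- fits[[order(ps, npos)[1L]]]
    }
  } else {
    best <- eval_at(threshold)
  }
  out <- screening_values(best$tab, criterion = criterion,
                          threshold = best$thr)
  out$p_value <- best$p
  out
}

#' Recover integer 2x2 tables from rounded screening values
#'
#' Inverse audit of a published screening-value row: enumerates every integer
#' contingency table consistent with four rounded (nearest integer, halves
#' away from zero) percentages for sensitivity, specificity, PPV and NPV,
#' under a cap on total size and optional constraints on the number of
#' condition-positive subjects.
#'
#' @param rounded Numeric vector of the four rounded percents, in the order
#'   sensitivity, specificity, ppv, npv (names optional).
#' @param n_max Maximum total table size to search (`<= 200`).
#' @param diseased Optional integer vector of admissible condition-positive
#'   counts (`tp + fn`); all of `1:(n_max - 1)` when `NULL`.
#' @param n_total Optional exact total size; tables of any size up to `n_max`
#'   are returned when `NULL`.
#' @return A data frame of matching tables sorted by total size, with columns
#'   `tp`, `fp`, `fn`, `tn`, `n`, and the exact (unrounded) screening values.
#'   Zero rows when nothing matches.
#' @export
recover_table <- function(rounded, n_max = 200L, diseased = NULL,
                          n_total = NULL) {
  stopifnot(length(rounded) == 4L, all(is.finite(rounded)),
            all(rounded >= 0), all(rounded <= 100))
  if (n_max > 200L) stop_bad("n_max must be <= 200")
  names(rounded) <- c("sens", "spec", "ppv", "npv")

  # integer x with 100 x / (x + y) rounding to r, given the other cell y:
  # the rounding interval [r - 0.5, r + 0.5) on the percent scale (closed at
  # 100).
  in_interval <- function(val, r) {
    val >= r - 0.5 & (val < r + 0.5 | (r == 100 & val == 100))
  }
  d_opts <- if (is.null(diseased)) seq_len(n_max - 1L) else as.integer(diseased)
  d_opts <- d_opts[d_opts >= 1L & d_opts < n_max]

  rows <- list()
  for (d in d_opts) {
    tps <- 0:d
    tps <- tps[in_interval(100 * tps / d, rounded["sens"])]
    for (tp in tps) {
      fn <- d - tp
      healthy_max <- if (is.null(n_total)) n_max - d else n_total - d
      if (healthy_max < 1L) next
      for (fp in 0:healthy_max) {
        if (tp + fp > 0 && !in_interval(100 * tp / (tp + fp), rounded["ppv"]))
          next
        if (tp + fp == 0) next  # PPV undefined cannot match a printed value
        tns <- 0:(healthy_max - fp)
        if (!is.null(n_total)) {
          tns <- n_total - d - fp
          if (tns < 0) next
        }
        ok <- (tns + fp > 0) & (tns + fn > 0) &
          in_interval(100 * tns / pmax(tns + fp, 1L), rounded["spec"]) &
          in_interval(100 * tns / pmax(tns + fn, 1L), rounded["npv"])
        ok[is.na(ok)] <- FALSE
        for (tn in tns[ok]) {
          rows[[length(rows) + 1L]] <- data.frame(
            tp = tp, fp = fp, fn = fn, tn = tn, n = tp + fp + fn + tn,
            sensitivity = 100 * tp / d,
            specificity = 100 * tn / (tn + fp),
            ppv = 100 * tp / (tp + fp),
            npv = 100 * tn / (tn + fn))
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(tp = integer(), fp = integer(), fn = integer(),
                      tn = integer(), n = integer(),
                      sensitivity = numeric(), specificity = numeric(),
                      ppv = numeric(), npv = numeric()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$n, out$tp, out$fp), ]
  rownames(out) <- NULL
  out
}

#' Screening report across the four study criteria
#'
#' Convenience wrapper evaluating JPE, KT manual maximum, total leg rotation
#' and pivot-shift positivity as screening tests on one analysis table.
#'
#' @param analysis Analysis table from [build_analysis_table()].
#' @param threshold_policy `"search"` or a named numeric vector of fixed
#'   thresholds per criterion.
#' @param exclude_group3 Passed to [evaluate_criterion()].
#' @return A data frame mirroring a published screening-value table: one row
#'   per criterion with sensitivity, specificity, ppv, npv (rounded),
#'   `p_value` and the threshold used.
#' @export
screening_report <- function(analysis, threshold_policy = "search",
                             exclude_group3 = TRUE) {
  crits <- c("kt_manmax", "pivot_shift", "total_rotation", "jpe")
  rows <- lapply(crits, function(cr) {
    thr <- if (identical(threshold_policy, "search")) {
      if (cr == "pivot_shift") 0 else "search"
    } else {
      threshold_policy[[cr]]
    }
    res <- evaluate_criterion(analysis, cr, threshold = thr,
                              exclude_group3 = exclude_group3)
    data.frame(criterion = cr,
               sensitivity = res$rounded[["sensitivity"]],
               specificity = res$rounded[["specificity"]],
               ppv = res$rounded[["ppv"]],
               npv = res$rounded[["npv"]],
               p_value = res$p_value,
               threshold = as.numeric(res$threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
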