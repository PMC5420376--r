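# CSV dialects for recordings, cohort tables and derived products. Every file
# written by a pipeline run starts with '#'-prefixed header comments carrying
# the seed and config hash, so any output can be traced to its run.

write_csv_commented <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

read_csv_commented <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write recordings to the recordings CSV dialect
#'
#' One row per sample: `subject_id`, `limb`, `sample_index`, `angle_deg`,
#' `torque_Nm`, `direction` (+1 driving toward ER, -1 toward IR).
#'
#' @param recordings A `jp_cohort` or (named) list of `rotation_recording`s.
#' @param path Output file.
#' @param comments Header comment lines (without the leading `#`).
#' @return The path, invisibly.
#' @export
write_recordings_csv <- function(recordings, path, comments = character()) {
  if (inherits(recordings, "jp_cohort")) recordings <- recordings$recordings
  stacked <- do.call(rbind, lapply(recordings, function(rec) {
    data.frame(subject_id = attr(rec, "subject_id"),
               limb = attr(rec, "limb_status"),
               sample_index = rec$sample_index,
               angle_deg = rec$angle_deg,
               torque_Nm = rec$torque_Nm,
               direction = rec$direction,
               stringsAsFactors = FALSE)
  }))
  rownames(stacked) <- NULL
  invisible(write_csv_commented(stacked, path, comments))
}

#' Read recordings from the recordings CSV dialect
#'
#' @param path File written by [write_recordings_csv()].
#' @return Named list of `rotation_recording`s (names `subjectid_limb`).
#' @export
read_recordings_csv <- function(path) {
  df <- read_csv_commented(path)
  need <- c("subject_id", "limb", "angle_deg", "torque_Nm", "direction")
  if (!all(need %in% names(df))) {
    stop_bad("recordings CSV must have columns: ", paste(need, collapse = ", "))
  }
  key <- paste(df$subject_id, df$limb, sep = "_")
  out <- lapply(split(df, factor(key, levels = unique(key))), function(d) {
    d <- d[order(d$sample_index), ]
    rotation_recording(d$angle_deg, d$torque_Nm, d$direction,
                       subject_id = d$subject_id[1], limb_status = d$limb[1])
  })
  out[unique(key)]
}
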