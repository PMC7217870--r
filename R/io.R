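#' Write a subject's events as a BIDS-style TSV
#'
#' One row per screen event (scenario, gratitude rating, joy rating, null),
#' with \code{onset}, \code{duration}, \code{trial_type} and the modulator
#' columns (factor levels, 1/0/-1 codes, displayed percent and amount).
#'
#' @param design a \code{subject_design}.
#' @param file output path (one file; \code{run} column distinguishes runs).
#' @param ratings optional rating records; adds \code{gratitude_rating} and
#'   \code{joy_rating} columns.
#' @return the file path, invisibly.
#' @export
write_events_tsv <- function(design, file, ratings = NULL) {
  rows <- list()
  for (run in design$runs) {
    for (i in seq_len(nrow(run))) {
      tr <- run[i, ]
      if (tr$is_null) {
        rows[[length(rows) + 1L]] <- data.frame(
          run = tr$run_index, trial = tr$trial_index, onset = tr$onset,
          duration = TRIAL_SPAN, trial_type = "null",
          intention_level = NA, value_level = NA,
          intention_code = NA, value_code = NA,
          intention_percent = NA, value_amount = NA,
          gratitude_rating = NA, joy_rating = NA)
        next
      }
      g <- NA; j <- NA
      if (!is.null(ratings)) {
        r <- ratings[ratings$subject_id == design$subject_id &
                       ratings$run_index == tr$run_index &
                       ratings$trial_index == tr$trial_index, ]
        if (nrow(r)) { g <- r$gratitude; j <- r$joy }
      }
      base <- data.frame(
        run = tr$run_index, trial = tr$trial_index,
        intention_level = tr$intention_level, value_level = tr$value_level,
        intention_code = level_code(tr$intention_level, "intention"),
        value_code = level_code(tr$value_level, "value"),
        intention_percent = tr$intention_percent, value_amount = tr$value_amount,
        gratitude_rating = g, joy_rating = j)
      evg <- rating_event_times(tr, "gratitude")
      evj <- rating_event_times(tr, "joy")
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(onset = tr$onset, duration = tr$stim_duration,
                   trial_type = "scenario"), base)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(onset = evg$onset, duration = evg$duration,
                   trial_type = "gratitude_rating"), base)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(onset = evj$onset, duration = evj$duration,
                   trial_type = "joy_rating"), base)
    }
  }
  cols <- c("onset", "duration", "trial_type", "run", "trial",
            "intention_level", "value_level", "intention_code", "value_code",
            "intention_percent", "value_amount", "gratitude_rating", "joy_rating")
  out <- do.call(rbind, lapply(rows, function(r) r[, cols]))
  out <- out[order(out$run, out$onset), ]
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read an events TSV
#'
#' @param file path written by \code{\link{write_events_tsv}} (or any TSV
#'   with onset/duration/trial_type columns).
#' @return data.frame.
#' @export
read_events_tsv <- function(file) {
  read.delim(file, stringsAsFactors = FALSE)
}

#' Export a design matrix as CSV plus JSON sidecar
#'
#' @param dm a \code{design_matrix}.
#' @param csv_file,json_file output paths (sidecar defaults to the CSV path
#'   with extension .json).
#' @export
write_design_matrix <- function(dm, csv_file,
                                json_file = sub("\\.csv$", ".json", csv_file)) {
  write.table(dm$X, csv_file, sep = ",", quote = FALSE, row.names = FALSE,
              col.names = dm$names)
  meta <- list(tr = dm$tr, names = dm$names,
               condition_cols = dm$condition_cols,
               modulator_order = dm$modulator_order,
               orthogonalized = dm$orthogonalized,
               run_of_row = dm$run_of_row)
  jsonlite::write_json(meta, json_file, auto_unbox = TRUE, digits = NA)
  invisible(csv_file)
}

#' Write a cluster table as CSV
#'
#' @param tab a \code{cluster_table} or the \code{clusters} element of a
#'   weight map.
#' @param file output path.
#' @export
write_cluster_table <- function(tab, file) {
  write.csv(as.data.frame(tab), file, row.names = FALSE)
  invisible(file)
}

#' Write cross-validation results as JSON
#'
#' @param cv a \code{cv_result}.
#' @param file output path.
#' @param perm optional output of \code{\link{permutation_test}}.
#' @export
write_cv_result <- function(cv, file, perm = NULL) {
  out <- list(accuracy = cv$accuracy, specificity = cv$specificity,
              sensitivity = cv$sensitivity, n_subjects = cv$n_subjects,
              predictions = as.character(cv$predictions))
  if (!is.null(perm))
    out$permutation <- list(p = perm$p, n_perm = perm$n_perm,
                            scheme = perm$scheme, rule = perm$rule)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
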