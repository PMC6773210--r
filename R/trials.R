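# Trial-table schema: reading, writing and validation.

.trial_columns <- c(
  "subject_id", "experiment", "condition", "familiarization_group",
  "first_test", "trial_type", "trial_index",
  "familiarization_looking_s", "looking_s", "censored"
)

#' Validate a trial table
#'
#' Checks the schema invariants of a trial-level looking-time table: factor
#' levels, looking times in (0, censor limit], the censoring flag true exactly
#' when the looking time sits at the limit, exactly one one-change and one
#' two-change trial per subject with `trial_index` consistent with
#' `first_test`, and the shape-change condition restricted to the brightness
#' experiment. Errors name the first offending row.
#'
#' @param trials data.frame with the trial-table columns.
#' @param censor_limit_s Ceiling of the looking-time measurement (seconds).
#' @return The validated table, classed `lt_trials`, with the censor limit
#'   recorded in attribute `censor_limit_s`.
#' @export
validate_trials <- function(trials, censor_limit_s = 60) {
  trials <- as.data.frame(trials)
  missing <- setdiff(.trial_columns, names(trials))
  if (length(missing)) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  trials <- trials[.trial_columns]
  lv <- lt_levels()
  fail <- function(row, msg) {
    stop("trial table row ", row, ": ", msg, call. = FALSE)
  }
  chk_levels <- function(col) {
    bad <- which(!(trials[[col]] %in% lv[[col]]))
    if (length(bad)) {
      fail(bad[1], sprintf("invalid %s '%s'", col, trials[[col]][bad[1]]))
    }
  }
  if (nrow(trials) == 0) {
    out <- trials
    class(out) <- c("lt_trials", "data.frame")
    attr(out, "censor_limit_s") <- censor_limit_s
    return(out)
  }
  for (col in c("experiment", "condition", "familiarization_group",
                "first_test", "trial_type")) {
    chk_levels(col)
  }
  trials$censored <- as.logical(trials$censored)
  if (anyNA(trials$censored)) {
    fail(which(is.na(trials$censored))[1], "censored is not logical")
  }
  num_ok <- function(x) is.numeric(x) & is.finite(x)
  bad <- which(!num_ok(trials$looking_s) | trials$looking_s <= 0)
  if (length(bad)) fail(bad[1], "looking_s must be a positive number")
  bad <- which(trials$looking_s > censor_limit_s)
  if (length(bad)) {
    fail(bad[1], sprintf("looking_s %.3f exceeds the censor limit %g s",
                         trials$looking_s[bad[1]], censor_limit_s))
  }
  at_limit <- trials$looking_s == censor_limit_s
  bad <- which(at_limit != trials$censored)
  if (length(bad)) {
    fail(bad[1],
         "censored flag must be TRUE exactly when looking_s equals the limit")
  }
  bad <- which(!num_ok(trials$familiarization_looking_s) |
                 trials$familiarization_looking_s <= 0)
  if (length(bad)) {
    fail(bad[1], "familiarization_looking_s must be a positive number")
  }
  bad <- which(!(trials$trial_index %in% c(1L, 2L)))
  if (length(bad)) fail(bad[1], "trial_index must be 1 or 2")
  bad <- which(trials$condition == "shape_change" &
                 trials$experiment != "brightness")
  if (length(bad)) {
    fail(bad[1], "shape_change condition occurs only in the brightness experiment")
  }

  # per-subject structure (vectorised over subject pairs)
  counts <- table(trials$subject_id)
  if (any(counts != 2)) {
    sid <- names(counts)[counts != 2][1]
    fail(which(trials$subject_id == sid)[1], sprintf(
      "subject '%s' must contribute exactly one one_change and one two_change trial",
      sid
    ))
  }
  ord <- order(trials$subject_id, trials$trial_index)
  ia <- ord[seq(1, nrow(trials), 2)]
  ib <- ord[seq(2, nrow(trials), 2)]
  bad <- which(trials$trial_type[ia] == trials$trial_type[ib])
  if (length(bad)) {
    fail(ia[bad[1]], sprintf(
      "subject '%s' must contribute exactly one one_change and one two_change trial",
      trials$subject_id[ia[bad[1]]]
    ))
  }
  for (col in c("experiment", "condition", "familiarization_group",
                "first_test", "familiarization_looking_s")) {
    bad <- which(trials[[col]][ia] != trials[[col]][ib])
    if (length(bad)) {
      fail(ia[bad[1]], sprintf("subject '%s' has inconsistent %s",
                               trials$subject_id[ia[bad[1]]], col))
    }
  }
  want_first <- ifelse(trials$first_test[ia] == "two_change_first",
                       "two_change", "one_change")
  bad <- which(trials$trial_index[ia] != 1L | trials$trial_index[ib] != 2L |
                 trials$trial_type[ia] != want_first)
  if (length(bad)) {
    fail(ia[bad[1]], sprintf(
      "subject '%s': trial_index inconsistent with first_test '%s'",
      trials$subject_id[ia[bad[1]]], trials$first_test[ia[bad[1]]]
    ))
  }
  class(trials) <- c("lt_trials", "data.frame")
  attr(trials, "censor_limit_s") <- censor_limit_s
  trials
}

#' Read a trial table from CSV
#'
#' Reads the comma-separated, UTF-8, headered trial-table format (columns
#' `subject_id, experiment, condition, familiarization_group, first_test,
#' trial_type, trial_index, familiarization_looking_s, looking_s, censored`)
#' and validates it with [validate_trials()].
#'
#' @inheritParams validate_trials
#' @param path CSV file path.
#' @return An `lt_trials` data.frame (possibly zero rows).
#' @export
read_trial_table <- function(path, censor_limit_s = 60) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  validate_trials(raw, censor_limit_s = censor_limit_s)
}

#' Write a trial table to CSV
#'
#' Inverse of [read_trial_table()]: `read_trial_table(write_trial_table(x, f))`
#' is the identity on validated records. Seconds are written with at least two
#' decimal digits.
#'
#' @param trials An `lt_trials` table (or data.frame passing validation).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  trials <- validate_trials(trials,
                            censor_limit_s = attr(trials, "censor_limit_s") %||% 60)
  out <- as.data.frame(trials)
  for (col in c("familiarization_looking_s", "looking_s")) {
    out[[col]] <- formatC(out[[col]], format = "f", digits = 6)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.lt_trials <- function(x, ...) {
  cat("Trial table:", nrow(x), "trials,",
      length(unique(x$subject_id)), "subjects,",
      sum(x$censored), "censored at",
      attr(x, "censor_limit_s") %||% 60, "s\n")
  if (nrow(x)) {
    tab <- table(condition = x$condition, experiment = x$experiment) / 2
    cat("Subjects per condition x experiment:\n")
    print(tab)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
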