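DATASET_COLUMNS <- c("subject_id", "block_index", "block_threat",
                     "trial_in_block", "stimulus_id", "action_context",
                     "instruction", "valence", "required_go", "chosen_go",
                     "correct", "outcome_points", "rt_ms", "shock_event")

DATASET_BOOL <- c("required_go", "chosen_go", "correct", "shock_event")

#' Write a trial-level dataset
#'
#' Comma-delimited UTF-8 text with a header row and the fixed column order
#' of the dataset schema; logical columns are written as 0/1 and missing
#' reaction times as empty fields.
#'
#' @param trials Trial table (the `trials` element of [simulate_cohort()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(trials, path) {
  trials <- validate_trials(trials)
  out <- trials[, DATASET_COLUMNS]
  for (cl in DATASET_BOOL) out[[cl]] <- as.integer(out[[cl]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a trial-level dataset
#'
#' @param path File written by [write_dataset()] (or conforming to its
#'   schema).
#' @return A validated trial table; schema violations raise an error naming
#'   the offending column and row.
#' @export
read_dataset <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character"),
                         na.strings = "")
  missing_cols <- setdiff(DATASET_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("dataset schema violation: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cl in DATASET_BOOL) raw[[cl]] <- raw[[cl]] != 0L
  validate_trials(raw)
}

validate_trials <- function(trials) {
  missing_cols <- setdiff(DATASET_COLUMNS, names(trials))
  if (length(missing_cols))
    stop("dataset schema violation: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  check_levels <- function(col, levels) {
    bad <- which(!trials[[col]] %in% levels)
    if (length(bad))
      stop("dataset schema violation: column '", col, "', row ", bad[1],
           ": unknown value '", trials[[col]][bad[1]], "'", call. = FALSE)
  }
  check_levels("block_threat", c("safe", "threat"))
  check_levels("action_context", c("press", "lift"))
  check_levels("instruction", c("go", "nogo"))
  check_levels("valence", c("win", "avoid"))
  check_levels("outcome_points", c(-1L, 0L, 1L))
  # rt is recorded exactly when an overt (go) response was emitted
  bad_rt <- which(is.na(trials$rt_ms) & trials$chosen_go)
  if (length(bad_rt))
    stop("dataset schema violation: column 'rt_ms', row ", bad_rt[1],
         ": missing latency for a go choice", call. = FALSE)
  bad_rt2 <- which(!is.na(trials$rt_ms) & !trials$chosen_go)
  if (length(bad_rt2))
    stop("dataset schema violation: column 'rt_ms', row ", bad_rt2[1],
         ": latency recorded for a no-go choice", call. = FALSE)
  trials[, DATASET_COLUMNS]
}

#' Split a trial table into the four condition datasets
#'
#' The unit of model fitting: one dataset per TOS x action-context
#' condition (threat press, threat lift, safe press, safe lift), with the
#' condition's four stimuli renumbered 1..4 (go-win, go-avoid, nogo-win,
#' nogo-avoid) and trials kept in chronological order within subject.
#'
#' @param trials A validated trial table.
#' @return Named list of four objects of class `"condition_dataset"`, each
#'   holding `condition`, `trials` (subject_id, stim, chosen_go, outcome,
#'   required_go, valence) and `stim_info`.
#' @export
condition_datasets <- function(trials) {
  trials <- validate_trials(trials)
  trials$condition <- condition_of(trials$block_threat, trials$action_context)
  trials$stim <- condition_stim_index(trials$instruction, trials$valence)
  out <- lapply(condition_labels(), function(cond) {
    tr <- trials[trials$condition == cond, ]
    ord <- order(tr$subject_id, tr$block_index, tr$trial_in_block)
    tr <- tr[ord, ]
    ds <- list(
      condition = cond,
      trials = data.frame(subject_id = tr$subject_id,
                          stim = tr$stim,
                          chosen_go = tr$chosen_go,
                          outcome = tr$outcome_points,
                          required_go = tr$required_go,
                          valence = tr$valence,
                          row.names = NULL),
      stim_info = data.frame(stim = 1:4,
                             instruction = c("go", "go", "nogo", "nogo"),
                             valence = c("win", "avoid", "win", "avoid"),
                             required_go = c(TRUE, TRUE, FALSE, FALSE))
    )
    class(ds) <- "condition_dataset"
    ds
  })
  stats::setNames(out, condition_labels())
}

#' @export
print.condition_dataset <- function(x, ...) {
  cat("<condition_dataset ", x$condition, "> ",
      length(unique(x$trials$subject_id)), " subjects, ",
      nrow(x$trials), " trials\n", sep = "")
  invisible(x)
}
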