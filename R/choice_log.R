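## Canonical long-format choice log: one row per touch, plus DMTS trial rows
## co-stored in the same TSV behind a record_type column.

CHOICE_COLS <- c(
  "subject_id", "session_index", "block_id", "condition", "background_same",
  "source_block_id", "context", "trial_index", "choice_index", "phase",
  "chosen_label", "required_label", "ordinal_target", "is_correct", "rt"
)
DMTS_COLS <- c("subject_id", "session_index", "similarity", "delay", "n_test",
               "correct")
CONDITIONS <- c("new_early", "new_late", "repeat")
MAX_CHOICES_PER_TRIAL <- 15L
MAX_ERRORS_PER_TRIAL <- 10L

#' Construct a choice-log dataset
#'
#' Bundles the trial-level choice records of the sequence task with the
#' interleaved delayed match-to-sample (DMTS) records of the same sessions.
#' `choices` holds one row per touch; see [read_choice_log()] for the column
#' schema. All structural invariants of the task (at most 15 touches and at
#' most 10 erroneous touches per trial, strictly increasing choice index,
#' retouch-after-error rule, label consistency) are checked unless
#' `validate = FALSE`.
#'
#' @param choices Data frame of touch records.
#' @param dmts Optional data frame of DMTS trial records.
#' @param validate Run [validate_choice_log()]?
#' @return An object of class `choice_data`: a list with elements `choices`
#'   and `dmts` (tibbles).
#' @export
choice_data <- function(choices, dmts = NULL, validate = TRUE) {
  choices <- tibble::as_tibble(choices)
  missing_cols <- setdiff(CHOICE_COLS, names(choices))
  for (col in c("background_same", "source_block_id", "rt")) {
    if (col %in% missing_cols) {
      choices[[col]] <- if (col == "source_block_id") NA_character_ else NA
      missing_cols <- setdiff(missing_cols, col)
    }
  }
  if (length(missing_cols)) {
    stop("choice log is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  choices <- choices[CHOICE_COLS]
  choices$session_index <- as.integer(choices$session_index)
  choices$context <- as.integer(choices$context)
  choices$trial_index <- as.integer(choices$trial_index)
  choices$choice_index <- as.integer(choices$choice_index)
  choices$ordinal_target <- as.integer(choices$ordinal_target)
  choices$background_same <- as.logical(choices$background_same)
  choices$is_correct <- as.logical(choices$is_correct)
  choices$rt <- as.numeric(choices$rt)
  if (is.null(dmts)) {
    dmts <- tibble::tibble(
      subject_id = character(), session_index = integer(),
      similarity = character(), delay = numeric(), n_test = integer(),
      correct = logical()
    )
  }
  dmts <- tibble::as_tibble(dmts)
  missing_dmts <- setdiff(DMTS_COLS, names(dmts))
  if (length(missing_dmts)) {
    stop("DMTS records are missing column(s): ",
         paste(missing_dmts, collapse = ", "), call. = FALSE)
  }
  dmts <- dmts[DMTS_COLS]
  dmts$session_index <- as.integer(dmts$session_index)
  dmts$n_test <- as.integer(dmts$n_test)
  dmts$correct <- as.logical(dmts$correct)
  out <- structure(list(choices = choices, dmts = dmts), class = "choice_data")
  if (validate) validate_choice_log(out)
  out
}

#' @export
print.choice_data <- function(x, ...) {
  ch <- x$choices
  cat("<choice_data>\n")
  cat(sprintf("  %d touch records | %d blocks | %d sessions | %d subjects\n",
              nrow(ch), dplyr::n_distinct(ch$block_id),
              nrow(dplyr::distinct(ch, .data$subject_id, .data$session_index)),
              dplyr::n_distinct(ch$subject_id)))
  cat(sprintf("  %d DMTS records\n", nrow(x$dmts)))
  invisible(x)
}

## Normalise a choice_data object or bare data frame to the choices tibble.
as_choice_tbl <- function(data) {
  if (inherits(data, "choice_data")) return(data$choices)
  tibble::as_tibble(data)
}

#' Validate a choice log against the task's structural invariants
#'
#' Checks field domains and the per-trial invariants: labels among A-E plus
#' distractor X, `is_correct` consistent with chosen versus required label,
#' strictly increasing choice indices, at most 15 touches and at most 10
#' erroneous touches per trial, and the retouch rule (every incorrect search
#' touch is followed, if the trial continues, by a retouch record requiring
#' the last correctly chosen object). Violations raise an error citing the
#' offending row number(s).
#'
#' @param data A `choice_data` object or choices data frame.
#' @return Invisibly `TRUE` when valid.
#' @export
validate_choice_log <- function(data) {
  ch <- as_choice_tbl(data)
  if (nrow(ch) == 0) return(invisible(TRUE))
  fail <- function(rows, msg) {
    stop(sprintf("invalid choice log (row %s): %s",
                 paste(utils::head(rows, 5), collapse = ", "), msg),
         call. = FALSE)
  }
  row <- seq_len(nrow(ch))
  bad <- which(!ch$context %in% c(1L, 2L))
  if (length(bad)) fail(bad, "context must be 1 or 2")
  bad <- which(!ch$condition %in% CONDITIONS)
  if (length(bad)) fail(bad, "condition must be new_early, new_late or repeat")
  bad <- which(!ch$phase %in% c("search", "retouch"))
  if (length(bad)) fail(bad, "phase must be search or retouch")
  bad <- which(!ch$chosen_label %in% ALL_LABELS)
  if (length(bad)) fail(bad, "chosen_label must be one of A-E or X")
  bad <- which(!ch$required_label %in% SEQ_LABELS)
  if (length(bad)) fail(bad, "required_label must be one of A-E")
  bad <- which(is.na(ch$trial_index) | ch$trial_index < 1L |
                 ch$trial_index > MAX_CHOICES_PER_TRIAL)
  if (length(bad)) fail(bad, "trial_index must lie in 1..15")
  bad <- which(is.na(ch$choice_index) | ch$choice_index < 1L |
                 ch$choice_index > MAX_CHOICES_PER_TRIAL)
  if (length(bad)) fail(bad, "choice_index must lie in 1..15")
  bad <- which(is.na(ch$ordinal_target) | ch$ordinal_target < 1L |
                 ch$ordinal_target > 5L)
  if (length(bad)) fail(bad, "ordinal_target must lie in 1..5")
  bad <- which(ch$is_correct != (ch$chosen_label == ch$required_label))
  if (length(bad)) fail(bad, "is_correct must equal (chosen_label == required_label)")
  bad <- which(!is.na(ch$rt) & ch$rt < 0)
  if (length(bad)) fail(bad, "rt must be >= 0 seconds")

  ## per-trial invariants
  key <- paste(ch$subject_id, ch$session_index, ch$block_id, ch$context,
               ch$trial_index, sep = "\r")
  for (idx in split(row, key)) {
    tr <- ch[idx, ]
    o <- order(tr$choice_index)
    tr <- tr[o, ]; idx <- idx[o]
    if (anyDuplicated(tr$choice_index)) {
      fail(idx[duplicated(tr$choice_index)],
           "choice_index must strictly increase within a trial")
    }
    if (nrow(tr) > MAX_CHOICES_PER_TRIAL) {
      fail(idx[MAX_CHOICES_PER_TRIAL + 1L], "at most 15 choices per trial")
    }
    n_err <- sum(!tr$is_correct)
    if (n_err > MAX_ERRORS_PER_TRIAL) {
      fail(idx[which(cumsum(!tr$is_correct) == MAX_ERRORS_PER_TRIAL + 1L)[1]],
           "at most 10 incorrect choices per trial")
    }
    ## retouch rule: incorrect search touch -> next record (if any) is a
    ## retouch of the last correctly chosen object; no retouch is expected
    ## when no object has been secured yet.
    last_correct <- NA_character_
    n <- nrow(tr)
    for (i in seq_len(n)) {
      if (tr$phase[i] == "search" && !tr$is_correct[i] &&
          !is.na(last_correct) && i < n) {
        if (tr$phase[i + 1L] != "retouch" ||
            tr$required_label[i + 1L] != last_correct) {
          fail(idx[i + 1L],
               "an incorrect search choice must be followed by a retouch of the last correct object")
        }
      }
      if (tr$phase[i] == "search" && tr$is_correct[i]) {
        last_correct <- tr$chosen_label[i]
      }
    }
  }
  invisible(TRUE)
}

#' Read a choice-log TSV
#'
#' Reads the canonical tab-delimited choice log written by
#' [write_choice_log()]: one row per touch plus DMTS rows flagged by the
#' `record_type` column. All structural invariants are validated; violations
#' raise an error naming the offending row.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @return A [choice_data()] object, with sessions identified by
#'   (`subject_id`, `session_index`).
#' @export
read_choice_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    record_type = readr::col_character(),
    subject_id = readr::col_character(),
    session_index = readr::col_integer(),
    block_id = readr::col_character(),
    condition = readr::col_character(),
    background_same = readr::col_logical(),
    source_block_id = readr::col_character(),
    context = readr::col_integer(),
    trial_index = readr::col_integer(),
    choice_index = readr::col_integer(),
    phase = readr::col_character(),
    chosen_label = readr::col_character(),
    required_label = readr::col_character(),
    ordinal_target = readr::col_integer(),
    is_correct = readr::col_logical(),
    rt = readr::col_double(),
    similarity = readr::col_character(),
    delay = readr::col_double(),
    n_test = readr::col_integer(),
    correct = readr::col_logical()
  ), progress = FALSE)
  needed <- c("record_type", CHOICE_COLS, DMTS_COLS)
  missing_cols <- setdiff(unique(needed), names(raw))
  if (length(missing_cols)) {
    stop("choice-log file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  choices <- raw[raw$record_type == "choice", CHOICE_COLS]
  dmts <- raw[raw$record_type == "dmts", DMTS_COLS]
  choice_data(choices, dmts)
}

#' Write a choice-log TSV
#'
#' Writes the dataset to a tab-delimited UTF-8 file with a deterministic
#' column and row order (session, block, context, trial, choice; DMTS rows
#' after the touch rows of each subject/session ordering). Two writes of the
#' same data produce byte-identical files, and the output is re-readable by
#' [read_choice_log()].
#'
#' @param data A `choice_data` object (or choices data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_choice_log <- function(data, path) {
  if (!inherits(data, "choice_data")) data <- choice_data(data)
  validate_choice_log(data)
  ch <- dplyr::arrange(data$choices, .data$subject_id, .data$session_index,
                       .data$block_id, .data$context, .data$trial_index,
                       .data$choice_index)
  dm <- dplyr::arrange(data$dmts, .data$subject_id, .data$session_index)
  ch$record_type <- "choice"
  dm$record_type <- "dmts"
  all_cols <- c("record_type", CHOICE_COLS, setdiff(DMTS_COLS, CHOICE_COLS))
  for (col in setdiff(all_cols, names(ch))) ch[[col]] <- NA
  for (col in setdiff(all_cols, names(dm))) dm[[col]] <- NA
  out <- rbind(ch[all_cols], dm[all_cols])
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Session-level DMTS accuracy
#'
#' @param data A `choice_data` object with DMTS records.
#' @return Tibble with one row per (subject, session): number of DMTS trials
#'   and mean accuracy.
#' @export
dmts_accuracy <- function(data) {
  stopifnot(inherits(data, "choice_data"))
  dplyr::summarise(
    dplyr::group_by(data$dmts, .data$subject_id, .data$session_index),
    n_trials = dplyr::n(),
    accuracy = mean(.data$correct),
    .groups = "drop"
  )
}
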