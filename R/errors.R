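## Error taxonomy: every erroneous touch is assigned exactly one of four
## types. Overlapping definitions are resolved by the fixed precedence
## rule_breaking > perseverative > distractor > exploration.

ERROR_TYPES <- c("exploration", "rule_breaking", "distractor", "perseverative")

## classify all incorrect records of one trial (rows ordered by choice_index);
## returns a character vector aligned with the rows (NA for correct rows)
classify_trial_errors <- function(phase, chosen, correct) {
  n <- length(phase)
  out <- rep(NA_character_, n)
  secured <- character(0)
  last_error <- NA_character_
  for (i in seq_len(n)) {
    if (!correct[i]) {
      out[i] <- if (phase[i] == "retouch") {
        "rule_breaking"                      # failed to re-select last correct
      } else if (chosen[i] %in% secured) {
        "rule_breaking"                      # re-selected an already-secured object
      } else if (!is.na(last_error) && chosen[i] == last_error) {
        "perseverative"                      # repeated the pre-retouch error
      } else if (chosen[i] == "X") {
        "distractor"
      } else {
        "exploration"                        # wrong object among those not yet secured
      }
    }
    if (phase[i] == "search") {
      if (correct[i]) secured <- c(secured, chosen[i]) else last_error <- chosen[i]
    }
  }
  out
}

#' Classify the erroneous touches of a choice log
#'
#' Adds an `error_type` column (`NA` for correct touches): `rule_breaking`
#' (failing the forced retouch of the last correct object, or re-selecting an
#' already-secured object), `perseverative` (repeating the same incorrect
#' object as the last choice before the forced re-selection), `distractor`
#' (choosing the sequence-irrelevant object X) or `exploration` (an incorrect
#' choice among objects not yet secured this trial). When several definitions
#' apply, precedence is rule_breaking > perseverative > distractor >
#' exploration.
#'
#' @param data A `choice_data` object or choices data frame.
#' @return The choices tibble with an added `error_type` column.
#' @export
classify_errors <- function(data) {
  ch <- as_choice_tbl(data)
  ch <- dplyr::arrange(ch, .data$subject_id, .data$session_index,
                       .data$block_id, .data$context, .data$trial_index,
                       .data$choice_index)
  key <- paste(ch$subject_id, ch$session_index, ch$block_id, ch$context,
               ch$trial_index, sep = "\r")
  ch$error_type <- unsplit(
    lapply(split(seq_len(nrow(ch)), key), function(idx) {
      classify_trial_errors(ch$phase[idx], ch$chosen_label[idx],
                            ch$is_correct[idx])
    }),
    key
  )
  ch
}

#' Classify a single erroneous touch
#'
#' @param record One-row data frame: the incorrect touch to classify.
#' @param history Data frame of the preceding records of the same trial
#'   (may have zero rows).
#' @return One of `"exploration"`, `"rule_breaking"`, `"distractor"`,
#'   `"perseverative"`.
#' @export
classify_error <- function(record, history = NULL) {
  record <- tibble::as_tibble(record)
  if (nrow(record) != 1) stop("`record` must be a single row", call. = FALSE)
  if (isTRUE(record$is_correct)) {
    stop("classify_error() expects an incorrect record", call. = FALSE)
  }
  if (is.null(history)) {
    history <- record[0, ]
  }
  tr <- rbind(tibble::as_tibble(history)[, c("phase", "chosen_label", "is_correct")],
              record[, c("phase", "chosen_label", "is_correct")])
  classify_trial_errors(tr$phase, tr$chosen_label, tr$is_correct)[nrow(tr)]
}

#' Error-type proportions by trial
#'
#' The proportion of each error type relative to all errors, as a function of
#' the trial within a block, pooled across blocks. Within any trial index with
#' at least one error the four proportions sum to 1.
#'
#' @param data A `choice_data` object or choices data frame.
#' @param context Optional context filter (default: both).
#' @return Tibble of class `error_breakdown` with `trial_index`,
#'   `error_type`, `n` and `prop` (NA for trials without errors).
#' @export
error_breakdown <- function(data, context = NULL) {
  ch <- classify_errors(data)
  if (!is.null(context)) ch <- ch[ch$context %in% context, ]
  err <- ch[!is.na(ch$error_type), ]
  grid <- tidyr::expand_grid(trial_index = sort(unique(ch$trial_index)),
                             error_type = ERROR_TYPES)
  got <- dplyr::count(err, .data$trial_index, .data$error_type, name = "n")
  out <- dplyr::left_join(grid, got, by = c("trial_index", "error_type"))
  out$n[is.na(out$n)] <- 0L
  out <- dplyr::mutate(dplyr::group_by(out, .data$trial_index),
                       total = sum(.data$n),
                       prop = ifelse(.data$total > 0, .data$n / .data$total,
                                     NA_real_))
  out <- dplyr::ungroup(out)
  out$total <- NULL
  class(out) <- c("error_breakdown", class(out))
  out
}

#' Exponential decay fit to an error-type curve
#'
#' Least-squares fit of `a * exp(-b * x) + c` to the per-trial proportion of
#' one error type, where `a` is the decay amplitude, `b` the decay speed and
#' `c` the asymptotic baseline. `b` is reported even when non-positive;
#' non-convergence is flagged, never an error.
#'
#' @param breakdown An [error_breakdown()] result (or a data frame with
#'   `trial_index` and `prop`, in which case `error_type` may be omitted).
#' @param error_type Which error type to fit.
#' @return List of class `decay_fit`: `a`, `b`, `c`, `rss`, `converged`.
#' @export
fit_error_decay <- function(breakdown, error_type = "exploration") {
  df <- tibble::as_tibble(breakdown)
  if ("error_type" %in% names(df)) {
    df <- df[df$error_type == error_type, ]
  }
  df <- df[is.finite(df$prop), ]
  if (nrow(df) < 4) {
    stop("need at least 4 trials with defined proportions", call. = FALSE)
  }
  x <- df$trial_index; y <- df$prop
  starts <- list(
    c(a = max(y) - min(y), b = 0.2, c = min(y)),
    c(a = y[1] - y[length(y)], b = 0.05, c = y[length(y)]),
    c(a = max(y) - min(y), b = 1, c = min(y))
  )
  best <- NULL
  for (st in starts) {
    if (!all(is.finite(st))) next
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-b * x) + c, start = as.list(st),
                        control = nls.control(maxiter = 200, warnOnly = TRUE)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(coef = coef(fit), rss = rss, converged = fit$convInfo$isConv)
    }
  }
  if (is.null(best)) {
    return(structure(list(a = 0, b = 0, c = mean(y), rss = sum((y - mean(y))^2),
                          converged = FALSE), class = "decay_fit"))
  }
  structure(list(a = best$coef[["a"]], b = best$coef[["b"]],
                 c = best$coef[["c"]], rss = best$rss,
                 converged = isTRUE(best$converged)),
            class = "decay_fit")
}
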