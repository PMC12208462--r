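## Learning curves, criterion trials, ordinal-position accuracy, chance
## levels, RT summaries and proficiency partitions.

## per-trial completion flags and error counts, one row per
## (subject, session, block, context, trial)
trial_summary <- function(data, context = NULL) {
  ch <- as_choice_tbl(data)
  if (!is.null(context)) ch <- ch[ch$context %in% context, ]
  dplyr::summarise(
    dplyr::group_by(ch, .data$subject_id, .data$session_index, .data$block_id,
                    .data$condition, .data$background_same,
                    .data$source_block_id, .data$context, .data$trial_index),
    completed = any(.data$is_correct & .data$ordinal_target == 5L &
                      .data$phase == "search"),
    n_errors = sum(!.data$is_correct),
    .groups = "drop"
  )
}

#' Completion learning curve
#'
#' Proportion of blocks whose trial *t* was completed (the full five-object
#' sequence finished within the 15-choice / 10-error limit), per trial.
#'
#' @param data A `choice_data` object or choices data frame.
#' @param context Context (1 or 2) to restrict to.
#' @return A tibble of class `learning_curve` with columns `trial_index`,
#'   `prop` and `n`.
#' @export
completion_curve <- function(data, context = 1L) {
  ts <- trial_summary(data, context)
  if (nrow(ts) == 0) {
    stop("no trials found for context ", context, call. = FALSE)
  }
  out <- dplyr::summarise(dplyr::group_by(ts, .data$trial_index),
                          prop = mean(.data$completed), n = dplyr::n(),
                          .groups = "drop")
  out <- dplyr::arrange(out, .data$trial_index)
  class(out) <- c("learning_curve", class(out))
  out
}

#' First trial reaching a sustained completion criterion
#'
#' Scans the completion curve for the first trial `t` whose completion
#' proportion is at least `threshold` with the following `sustain` trials also
#' at or above threshold (the "80% completion sustained for three consecutive
#' subsequent trials" learning criterion). The raw curve is used, not a
#' smoothed fit.
#'
#' @param curve A [completion_curve()] result or a numeric vector of per-trial
#'   completion proportions.
#' @param threshold Completion proportion required (default 0.8).
#' @param sustain Number of subsequent trials that must also meet it.
#' @return A list of class `criterion_result`: `criterion_trial` (integer, or
#'   `NA` when censored), `censored`, `threshold` and `sustain`.
#' @export
trials_to_criterion <- function(curve, threshold = 0.8, sustain = 3L) {
  y <- if (inherits(curve, "learning_curve")) curve$prop else as.numeric(curve)
  stopifnot(length(y) > 0, threshold > 0, threshold <= 1, sustain >= 0)
  n <- length(y)
  hit <- NA_integer_
  for (t in seq_len(n - sustain)) {
    if (all(y[t:(t + sustain)] >= threshold)) { hit <- t; break }
  }
  structure(list(criterion_trial = hit, censored = is.na(hit),
                 threshold = threshold, sustain = as.integer(sustain)),
            class = "criterion_result")
}

#' Per-block criterion trials
#'
#' Applies [trials_to_criterion()] to each block's own binary completion
#' sequence; with the default 0.8 threshold a block's criterion trial is the
#' first of `sustain + 1` consecutive completed trials. Blocks never reaching
#' criterion are censored (`criterion_trial = NA`).
#'
#' @inheritParams completion_curve
#' @inheritParams trials_to_criterion
#' @return Tibble with one row per block: metadata, `criterion_trial`,
#'   `censored`, plus the block's completion rate and mean errors per trial.
#' @export
block_criteria <- function(data, context = 1L, threshold = 0.8, sustain = 3L) {
  ts <- trial_summary(data, context)
  if (nrow(ts) == 0) {
    return(tibble::tibble(
      subject_id = character(), session_index = integer(),
      block_id = character(), condition = character(),
      background_same = logical(), source_block_id = character(),
      context = integer(), criterion_trial = integer(), censored = logical(),
      completion_rate = numeric(), errors_per_trial = numeric()
    ))
  }
  dplyr::summarise(
    dplyr::group_by(ts, .data$subject_id, .data$session_index, .data$block_id,
                    .data$condition, .data$background_same,
                    .data$source_block_id, .data$context),
    criterion_trial = trials_to_criterion(
      .data$completed[order(.data$trial_index)], threshold, sustain
    )$criterion_trial,
    censored = is.na(criterion_trial),
    completion_rate = mean(.data$completed),
    errors_per_trial = sum(.data$n_errors) / dplyr::n(),
    .groups = "drop"
  )
}

#' Four-parameter logistic fit to a learning curve
#'
#' Descriptive least-squares sigmoid `lo + (hi - lo) / (1 + exp(-k (t - m)))`
#' with asymptotes bounded in \[0, 1\], fitted with bounded Levenberg-
#' Marquardt from three starting points. The learning criterion is computed
#' from the raw curve (see [trials_to_criterion()]); the sigmoid is retained
#' as a descriptive output only. Non-convergence is flagged, never an error.
#'
#' @param curve A [completion_curve()] result or numeric vector.
#' @return List of class `sigmoid_fit`: `lower`, `upper`, `midpoint`,
#'   `slope`, `rss`, `converged`.
#' @export
fit_sigmoid <- function(curve) {
  y <- if (inherits(curve, "learning_curve")) curve$prop else as.numeric(curve)
  t <- if (inherits(curve, "learning_curve")) curve$trial_index else seq_along(y)
  ok <- is.finite(y)
  y <- y[ok]; t <- t[ok]
  if (length(y) < 4) stop("need at least 4 trials with data", call. = FALSE)
  starts <- list(
    c(lo = max(min(y), 1e-3), hi = min(max(y), 1 - 1e-3), m = mean(range(t)), k = 1),
    c(lo = 0.05, hi = 0.95, m = stats::quantile(t, 0.25, names = FALSE), k = 0.5),
    c(lo = 0.05, hi = 0.95, m = stats::quantile(t, 0.75, names = FALSE), k = 2)
  )
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ lo + (hi - lo) / (1 + exp(-k * (t - m))),
        start = as.list(st),
        lower = c(lo = 0, hi = 0, m = min(t) - 10, k = 0),
        upper = c(lo = 1, hi = 1, m = max(t) + 10, k = 50),
        control = nls.control(maxiter = 200, warnOnly = TRUE)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(coef = coef(fit), rss = rss,
                   converged = fit$convInfo$isConv)
    }
  }
  if (is.null(best)) {
    m <- mean(y)
    return(structure(list(lower = m, upper = m, midpoint = mean(range(t)),
                          slope = 0, rss = sum((y - m)^2), converged = FALSE),
                     class = "sigmoid_fit"))
  }
  cf <- best$coef
  lo <- min(cf[["lo"]], cf[["hi"]]); hi <- max(cf[["lo"]], cf[["hi"]])
  structure(list(lower = lo, upper = hi, midpoint = cf[["m"]],
                 slope = cf[["k"]], rss = best$rss,
                 converged = isTRUE(best$converged)),
            class = "sigmoid_fit")
}

#' Forward-looking chance level
#'
#' Chance probability of a correct first attempt at ordinal position `p`
#' assuming already-secured objects are never re-chosen: a uniform pick among
#' the 6 on-screen objects minus the `p - 1` already-secured ones, i.e.
#' `1 / (7 - p)`. At position 1 this equals the absolute chance level 1/6.
#'
#' @param position Integer ordinal position(s) in 1..5.
#' @return Numeric chance probability.
#' @export
#' @examples
#' forward_chance(1:5)
forward_chance <- function(position) {
  if (any(!position %in% 1:5)) {
    stop("position must lie in 1..5", call. = FALSE)
  }
  1 / (7 - position)
}

#' Accuracy by ordinal position
#'
#' For each ordinal position 1..5, the proportion of *first* search attempts
#' at that position that were correct, pooled over the given trials (by
#' default the last four trials, 12-15, where learning has asymptoted).
#'
#' @param data A `choice_data` object or choices data frame.
#' @param trials Integer vector of trial indices to pool.
#' @param context Context to restrict to.
#' @param conf_level Confidence level for the binomial CI.
#' @return Tibble with `ordinal_target`, `n`, `prop`, `lower`, `upper` and
#'   `defined` (FALSE where no attempts were pooled; `prop` is then `NA`, not
#'   0).
#' @export
ordinal_accuracy <- function(data, trials = 12:15, context = 1L,
                             conf_level = 0.95) {
  stopifnot(all(trials %in% 1:15))
  ch <- as_choice_tbl(data)
  ch <- ch[ch$phase == "search" & ch$context %in% context &
             ch$trial_index %in% trials, ]
  first <- dplyr::slice_min(
    dplyr::group_by(ch, .data$subject_id, .data$session_index, .data$block_id,
                    .data$context, .data$trial_index, .data$ordinal_target),
    .data$choice_index, n = 1, with_ties = FALSE
  )
  first <- dplyr::ungroup(first)
  got <- dplyr::summarise(dplyr::group_by(first, .data$ordinal_target),
                          n = dplyr::n(), k = sum(.data$is_correct),
                          .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(ordinal_target = 1:5), got,
                          by = "ordinal_target")
  out$n[is.na(out$n)] <- 0L
  ci <- proportion_ci(ifelse(out$n > 0, out$k, 0L), pmax(out$n, 1L), conf_level)
  out$prop <- ifelse(out$n > 0, out$k / out$n, NA_real_)
  out$lower <- ifelse(out$n > 0, ci$lower, NA_real_)
  out$upper <- ifelse(out$n > 0, ci$upper, NA_real_)
  out$defined <- out$n > 0
  out$k <- NULL
  out
}

#' Reaction-time summary by ordinal position, before and after learning
#'
#' Mean reaction time of correct search touches at each ordinal position,
#' split into trials before versus at-or-after each block's criterion trial
#' (censored blocks contribute all trials to "before"), with a Welch test per
#' position.
#'
#' @inheritParams completion_curve
#' @param threshold,sustain Criterion definition passed to [block_criteria()].
#' @return Tibble with per-position, per-period mean RT, 95% CI and n, plus
#'   Welch `statistic`, `df` and `p` per position (`NA` where a period has
#'   insufficient data). Positions without RT data are flagged via `defined`.
#' @export
rt_summary <- function(data, context = 1L, threshold = 0.8, sustain = 3L) {
  ch <- as_choice_tbl(data)
  ch <- ch[ch$phase == "search" & ch$is_correct & ch$context %in% context, ]
  if (all(is.na(ch$rt)) || nrow(ch) == 0) {
    message("rt_summary: no reaction-time data; skipping")
    return(tibble::tibble(ordinal_target = integer(), period = character(),
                          n = integer(), mean_rt = numeric()))
  }
  crit <- block_criteria(data, context, threshold, sustain)
  ch <- dplyr::left_join(
    ch, crit[c("subject_id", "session_index", "block_id", "context",
               "criterion_trial")],
    by = c("subject_id", "session_index", "block_id", "context")
  )
  ch$period <- ifelse(is.na(ch$criterion_trial) |
                        ch$trial_index < ch$criterion_trial,
                      "before", "after")
  ch <- ch[!is.na(ch$rt), ]
  sm <- dplyr::summarise(
    dplyr::group_by(ch, .data$ordinal_target, .data$period),
    n = dplyr::n(), mean_rt = mean(.data$rt), sd_rt = sd(.data$rt),
    .groups = "drop"
  )
  half <- ifelse(sm$n > 1, qt(0.975, sm$n - 1) * sm$sd_rt / sqrt(sm$n), NA_real_)
  sm$lower <- sm$mean_rt - half
  sm$upper <- sm$mean_rt + half
  tests <- lapply(1:5, function(p) {
    a <- ch$rt[ch$ordinal_target == p & ch$period == "before"]
    b <- ch$rt[ch$ordinal_target == p & ch$period == "after"]
    if (length(a) >= 2 && length(b) >= 2 && (var(a) > 0 || var(b) > 0)) {
      w <- welch_t(a, b)
      tibble::tibble(ordinal_target = p, statistic = w$statistic, df = w$df,
                     p = w$p)
    } else {
      tibble::tibble(ordinal_target = p, statistic = NA_real_, df = NA_real_,
                     p = NA_real_)
    }
  })
  out <- dplyr::left_join(sm, dplyr::bind_rows(tests), by = "ordinal_target")
  out$defined <- out$n > 0
  out
}

#' Partition blocks by learning proficiency
#'
#' Ranks blocks by their mean number of erroneous touches per trial and
#' assigns each to the `good`, `mid` or `poor` group. With
#' `method = "threshold"` the published cut-offs are used (good: at most 5.33
#' errors per trial; poor: more than 6.6); with `method = "tercile"` empirical
#' terciles are formed, ties broken deterministically by `block_id` order.
#'
#' @inheritParams completion_curve
#' @param method `"threshold"` or `"tercile"`.
#' @param thresholds Length-2 numeric: the good and poor cut-offs.
#' @return Tibble of class `proficiency_partition`: block metadata,
#'   `errors_per_trial` and `group`; the thresholds used are stored in the
#'   `"thresholds"` attribute.
#' @export
partition_by_proficiency <- function(data, context = 1L,
                                     method = c("threshold", "tercile"),
                                     thresholds = c(good = 5.33, poor = 6.6)) {
  method <- match.arg(method)
  bl <- block_criteria(data, context)
  if (nrow(bl) < 3) stop("need at least 3 blocks", call. = FALSE)
  if (method == "threshold") {
    bl$group <- ifelse(bl$errors_per_trial <= thresholds[[1]], "good",
                       ifelse(bl$errors_per_trial > thresholds[[2]], "poor",
                              "mid"))
    used <- thresholds
  } else {
    o <- order(bl$errors_per_trial, bl$block_id)
    r <- integer(nrow(bl)); r[o] <- seq_len(nrow(bl))
    cut1 <- ceiling(nrow(bl) / 3); cut2 <- ceiling(2 * nrow(bl) / 3)
    bl$group <- ifelse(r <= cut1, "good", ifelse(r > cut2, "poor", "mid"))
    used <- c(good = max(bl$errors_per_trial[bl$group == "good"]),
              poor = min(bl$errors_per_trial[bl$group == "poor"]))
  }
  attr(bl, "thresholds") <- used
  class(bl) <- c("proficiency_partition", class(bl))
  bl
}
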