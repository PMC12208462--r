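## Conditional transition probabilities and the pro-/retro-active swap
## indices that quantify positional re-indexing versus serial chaining in
## context 2.

TRANSITION_EVENTS <- c("after_correct_A", "after_error_B", "after_correct_D")

## search-phase rows annotated with the next free search choice of the same
## trial (forced retouches are skipped: after an error the transition target
## is the next genuine search choice, not the mandatory re-touch)
next_search_choice <- function(ch) {
  s <- ch[ch$phase == "search", ]
  s <- dplyr::arrange(s, .data$subject_id, .data$session_index, .data$block_id,
                      .data$context, .data$trial_index, .data$choice_index)
  s <- dplyr::mutate(
    dplyr::group_by(s, .data$subject_id, .data$session_index, .data$block_id,
                    .data$context, .data$trial_index),
    next_label = dplyr::lead(.data$chosen_label)
  )
  dplyr::ungroup(s)
}

## conditioning events with their transition targets; trials = "pre_criterion",
## "all", or an integer vector of trial indices
transition_events <- function(data, event, context = 2L,
                              trials = "pre_criterion") {
  event <- match.arg(event, TRANSITION_EVENTS)
  ch <- as_choice_tbl(data)
  s <- next_search_choice(ch)
  s <- s[s$context %in% context, ]
  if (identical(trials, "pre_criterion")) {
    crit <- block_criteria(data, context = context)
    s <- dplyr::left_join(
      s, crit[c("subject_id", "session_index", "block_id", "context",
                "criterion_trial")],
      by = c("subject_id", "session_index", "block_id", "context")
    )
    s <- s[is.na(s$criterion_trial) | s$trial_index < s$criterion_trial, ]
  } else if (!identical(trials, "all")) {
    s <- s[s$trial_index %in% trials, ]
  }
  cond <- switch(event,
    after_correct_A = s$chosen_label == "A" & s$is_correct &
      s$ordinal_target == 1L,
    after_error_B = s$chosen_label == "B" & !s$is_correct &
      s$ordinal_target == 2L,
    after_correct_D = s$chosen_label == "D" & s$is_correct &
      s$ordinal_target == 2L
  )
  ev <- s[cond & !is.na(s$next_label), ]
  ev[c("subject_id", "session_index", "block_id", "condition",
       "background_same", "context", "trial_index", "next_label")]
}

#' Transition probabilities after a conditioning choice
#'
#' Probability of each object being the next free search choice after a
#' conditioning event: a correct choice of A at the first position
#' (`after_correct_A`), an erroneous choice of B at the second position
#' (`after_error_B`) or a correct choice of D at the second position
#' (`after_correct_D`). Forced retouches are skipped, so the transition
#' target after an error is the next genuine search choice. By default the
#' analysis pools context-2 trials before each block's learning criterion.
#'
#' @param data A `choice_data` object or choices data frame.
#' @param event Conditioning event; one of the three above.
#' @param context Context filter (default 2).
#' @param trials `"pre_criterion"` (default), `"all"`, or an integer vector
#'   of trial indices.
#' @param conf_level Binomial CI level (normal approximation, Wilson for
#'   counts below 5).
#' @return Tibble of class `transition_table` with one row per object label:
#'   `count`, `prob`, `lower`, `upper`; the number of conditioning events is
#'   in attribute `"n_events"` (0 rows of counts flagged by attribute
#'   `"empty"`).
#' @export
transition_after <- function(data, event = "after_correct_A", context = 2L,
                             trials = "pre_criterion", conf_level = 0.95) {
  ev <- transition_events(data, event, context, trials)
  n <- nrow(ev)
  out <- tibble::tibble(label = ALL_LABELS)
  got <- dplyr::count(ev, label = .data$next_label)
  out <- dplyr::left_join(out, got, by = "label")
  out$n[is.na(out$n)] <- 0L
  names(out)[names(out) == "n"] <- "count"
  if (n > 0) {
    out$prob <- out$count / n
    ci <- proportion_ci(out$count, n, conf_level)
    out$lower <- ci$lower; out$upper <- ci$upper
  } else {
    out$prob <- NA_real_; out$lower <- NA_real_; out$upper <- NA_real_
  }
  attr(out, "event") <- event
  attr(out, "n_events") <- n
  attr(out, "empty") <- n == 0
  class(out) <- c("transition_table", class(out))
  out
}

## indices from two event tables (data frames with next_label)
indices_from_events <- function(ev_a, ev_b) {
  pa <- function(lab) if (nrow(ev_a)) mean(ev_a$next_label == lab) else NA_real_
  pb <- function(lab) if (nrow(ev_b)) mean(ev_b$next_label == lab) else NA_real_
  tibble::tibble(
    proactive = pa("D") - pa("B"),
    serial_contrast = pa("D") - pa("C"),
    retroactive = pb("D") - pb("C"),
    n_proactive_events = nrow(ev_a),
    n_retroactive_events = nrow(ev_b)
  )
}

#' Pro-active and retro-active swap indices
#'
#' The pro-active swapping index is `P(D) - P(B)` for the next choice after
#' correctly choosing A (choosing the re-indexed object D rather than the
#' stale context-1 object B); the retro-active index is `P(D) - P(C)` for the
#' next free choice after erroneously choosing B (re-indexing in response to
#' error feedback rather than serial inference); the serial contrast is
#' `P(D) - P(C)` after a correct A. Indices lie in \[-1, 1\] and are `NA`
#' where a scope has no conditioning events.
#'
#' @inheritParams transition_after
#' @param scope `"pooled"` (one row), `"block"` or `"session"`.
#' @return Tibble of class `swap_indices` with the three indices, event
#'   counts and (for non-pooled scopes) the grouping metadata.
#' @export
swap_indices <- function(data, scope = c("pooled", "block", "session"),
                         context = 2L, trials = "pre_criterion") {
  scope <- match.arg(scope)
  ev_a <- transition_events(data, "after_correct_A", context, trials)
  ev_b <- transition_events(data, "after_error_B", context, trials)
  if (scope == "pooled") {
    out <- indices_from_events(ev_a, ev_b)
  } else {
    keys <- if (scope == "block") {
      c("subject_id", "session_index", "block_id", "condition",
        "background_same")
    } else {
      c("subject_id", "session_index")
    }
    groups <- dplyr::distinct(rbind(ev_a[keys], ev_b[keys]))
    if (nrow(groups) == 0) {
      out <- dplyr::bind_cols(groups, indices_from_events(ev_a, ev_b)[0, ])
      class(out) <- c("swap_indices", class(out))
      return(out)
    }
    out <- dplyr::bind_cols(groups, dplyr::bind_rows(lapply(
      seq_len(nrow(groups)),
      function(i) {
        sel <- function(ev) {
          keep <- rep(TRUE, nrow(ev))
          for (k in keys) keep <- keep & vec_equal_na(ev[[k]], groups[[k]][i])
          ev[keep, ]
        }
        indices_from_events(sel(ev_a), sel(ev_b))
      }
    )))
  }
  class(out) <- c("swap_indices", class(out))
  out
}

## equality that treats NA == NA as TRUE (for grouping keys)
vec_equal_na <- function(x, v) {
  if (is.na(v)) is.na(x) else !is.na(x) & x == v
}

## per-block first choice at the second ordinal position of one trial,
## conditioned on the trial opening with a correct choice of A
first_choice_at_two <- function(ch, context, trial) {
  s <- next_search_choice(ch)
  s <- s[s$context == context, ]
  first <- dplyr::slice_min(
    dplyr::group_by(s, .data$subject_id, .data$session_index, .data$block_id,
                    .data$trial_index),
    .data$choice_index, n = 1, with_ties = FALSE
  )
  first <- dplyr::ungroup(first)
  if (identical(trial, "last")) {
    first <- dplyr::slice_max(
      dplyr::group_by(first, .data$subject_id, .data$session_index,
                      .data$block_id),
      .data$trial_index, n = 1, with_ties = FALSE
    )
    first <- dplyr::ungroup(first)
  } else {
    first <- first[first$trial_index == trial, ]
  }
  ok <- first$chosen_label == "A" & first$is_correct & !is.na(first$next_label)
  list(events = first[ok, c("subject_id", "session_index", "block_id",
                            "next_label")],
       n_excluded = sum(!ok))
}

#' First-choice analysis at the context switch
#'
#' Compares the first choice at the second ordinal position (immediately
#' after a correct A, before any feedback about the swap) between the last
#' trial of context 1 and the first trial of context 2. Blocks whose relevant
#' trial did not open with a correct choice of A are excluded (count
#' reported). Per-label Welch tests on the block-level indicators are FDR
#' corrected.
#'
#' @param data A `choice_data` object or choices data frame.
#' @return List of class `first_choice_analysis`: `table` (per label:
#'   probability in each context, difference, Welch statistic, raw and
#'   BH-adjusted p), `n_blocks` per context and `n_excluded`.
#' @export
first_choice_analysis <- function(data) {
  ch <- as_choice_tbl(data)
  g1 <- first_choice_at_two(ch, 1L, "last")
  g2 <- first_choice_at_two(ch, 2L, 1L)
  tab <- lapply(ALL_LABELS, function(lab) {
    x1 <- as.numeric(g1$events$next_label == lab)
    x2 <- as.numeric(g2$events$next_label == lab)
    w <- welch_t(x2, x1)
    tibble::tibble(label = lab,
                   p_context1 = mean(x1), p_context2 = mean(x2),
                   difference = mean(x2) - mean(x1),
                   statistic = w$statistic, df = w$df, p = w$p)
  })
  tab <- dplyr::bind_rows(tab)
  tab$p_adjusted <- adjust_p(tab$p, "bh_fdr")
  structure(list(table = tab,
                 n_blocks = c(context1 = nrow(g1$events),
                              context2 = nrow(g2$events)),
                 n_excluded = g1$n_excluded + g2$n_excluded),
            class = "first_choice_analysis")
}

#' Trial-by-trial first-choice difference curves in context 2
#'
#' For every context-2 trial, the block-level first choice at the second
#' ordinal position (after a correct A) yields the difference curves D-B,
#' C-B and D-C with t-based CIs. The first trial at which the D-C interval
#' excludes zero - the point where re-indexing reliably dominates serial
#' inference - is reported.
#'
#' @param data A `choice_data` object or choices data frame.
#' @param conf_level CI level.
#' @return List of class `trialwise_first_choice`: `curves` (tibble with
#'   trial, contrast, mean, lower, upper, n) and `dc_crossing_trial` (first
#'   trial whose D-C CI excludes 0; `NA` when none).
#' @export
trialwise_first_choice <- function(data, conf_level = 0.95) {
  ch <- as_choice_tbl(data)
  trials <- sort(unique(ch$trial_index[ch$context == 2L]))
  rows <- list()
  for (t in trials) {
    ev <- first_choice_at_two(ch, 2L, t)$events
    if (nrow(ev) == 0) next
    for (cmp in c("D-B", "C-B", "D-C")) {
      lab <- strsplit(cmp, "-")[[1]]
      x <- as.numeric(ev$next_label == lab[1]) -
        as.numeric(ev$next_label == lab[2])
      ci <- mean_ci(x, conf_level)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        trial_index = t, contrast = cmp, mean = ci$mean,
        lower = ci$lower, upper = ci$upper, n = ci$n
      )
    }
  }
  curves <- dplyr::bind_rows(rows)
  dc <- curves[curves$contrast == "D-C" & !is.na(curves$lower), ]
  dc <- dc[dc$lower > 0 | dc$upper < 0, ]
  structure(list(curves = curves,
                 dc_crossing_trial = if (nrow(dc)) min(dc$trial_index)
                                     else NA_integer_),
            class = "trialwise_first_choice")
}

#' Distractor choices by ordinal position
#'
#' Proportion of search touches that chose the sequence-irrelevant distractor
#' X at each ordinal position, separately for context 1 and context 2, with a
#' two-proportion Z test per position. The distractor resembles object B, so
#' distractor choices are expected to peak at the position where B is
#' required (position 2 in context 1, position 4 in context 2).
#'
#' @param data A `choice_data` object or choices data frame.
#' @return Tibble of class `distractor_analysis`: per ordinal position the
#'   counts and proportions in both contexts and the Z statistic with its p
#'   value (`NA` where a denominator is zero).
#' @export
distractor_analysis <- function(data) {
  ch <- as_choice_tbl(data)
  s <- ch[ch$phase == "search", ]
  out <- lapply(1:5, function(p) {
    r <- lapply(c(1L, 2L), function(ctx) {
      sel <- s$ordinal_target == p & s$context == ctx
      c(n = sum(sel), k = sum(sel & s$chosen_label == "X"))
    })
    zt <- two_prop_z(r[[1]][["k"]], r[[1]][["n"]], r[[2]][["k"]], r[[2]][["n"]])
    tibble::tibble(
      ordinal_target = p,
      n_context1 = r[[1]][["n"]], prop_context1 =
        if (r[[1]][["n"]] > 0) r[[1]][["k"]] / r[[1]][["n"]] else NA_real_,
      n_context2 = r[[2]][["n"]], prop_context2 =
        if (r[[2]][["n"]] > 0) r[[2]][["k"]] / r[[2]][["n"]] else NA_real_,
      z = zt$statistic, p = zt$p
    )
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("distractor_analysis", class(out))
  out
}

#' Per-session counts of the choice following a correct A in context 2
#'
#' Extracts, for each session, how often each object was the next free search
#' choice after a correct choice of A in context-2 trials before the block's
#' learning criterion. These are the counts modelled by the Bayesian
#' strategy analysis; the rare re-selections of A are dropped, leaving the
#' components B, C, D, E and X.
#'
#' @param data A `choice_data` object or choices data frame.
#' @param trials Trial filter as in [transition_after()].
#' @return Tibble with `session_id` (subject and session), `subject_id`,
#'   `label` and `count`, five rows per session.
#' @export
second_position_counts <- function(data, trials = "pre_criterion") {
  ev <- transition_events(data, "after_correct_A", context = 2L,
                          trials = trials)
  ev <- ev[ev$next_label != "A", ]
  ev$session_id <- paste(ev$subject_id, ev$session_index, sep = "_")
  labs <- setdiff(ALL_LABELS, "A")
  grid <- tidyr::expand_grid(
    dplyr::distinct(ev, .data$session_id, .data$subject_id),
    label = labs
  )
  got <- dplyr::count(ev, .data$session_id, label = .data$next_label,
                      name = "count")
  out <- dplyr::left_join(grid, got, by = c("session_id", "label"))
  out$count[is.na(out$count)] <- 0L
  out
}
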