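# Fixture builders and deliberately naive oracles used across the suite.

# Build the touch records of one trial from the sequence of *search* choices.
# Correct retouches of the last correct object are inserted automatically
# after every error (when an object has already been secured). `chosen` may
# stop early (incomplete trial).
make_trial <- function(chosen, context = 1L, trial_index = 1L,
                       block_id = "b1", subject_id = "s1",
                       session_index = 1L, condition = "new_early",
                       background_same = NA, source_block_id = NA_character_,
                       rt = NA_real_, retouch_fail = integer(0)) {
  ord <- required_order(context)
  rows <- list()
  p <- 1L
  secured <- character(0)
  ci <- 0L
  n_retouch <- 0L
  add <- function(phase, ch, req, ordt, ok) {
    ci <<- ci + 1L
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      subject_id = subject_id, session_index = session_index,
      block_id = block_id, condition = condition,
      background_same = background_same, source_block_id = source_block_id,
      context = as.integer(context), trial_index = as.integer(trial_index),
      choice_index = ci, phase = phase, chosen_label = ch,
      required_label = req, ordinal_target = as.integer(ordt),
      is_correct = ok, rt = rt
    )
  }
  for (ch in chosen) {
    req <- ord[p]
    ok <- ch == req
    add("search", ch, req, p, ok)
    if (ok) {
      secured <- c(secured, ch)
      p <- p + 1L
      if (p > 5L) break
    } else if (length(secured)) {
      n_retouch <- n_retouch + 1L
      last <- secured[length(secured)]
      if (n_retouch %in% retouch_fail) {
        wrong <- setdiff(c("A", "B", "C", "D", "E", "X"), last)[1]
        add("retouch", wrong, last, length(secured), FALSE)
      }
      add("retouch", last, last, length(secured), TRUE)
    }
  }
  dplyr::bind_rows(rows)
}

# Build a block: `trials1` / `trials2` are lists of search-choice vectors.
make_block <- function(trials1, trials2 = list(), block_id = "b1", ...) {
  rows <- list()
  for (t in seq_along(trials1)) {
    rows[[length(rows) + 1L]] <- make_trial(trials1[[t]], context = 1L,
                                            trial_index = t,
                                            block_id = block_id, ...)
  }
  for (t in seq_along(trials2)) {
    rows[[length(rows) + 1L]] <- make_trial(trials2[[t]], context = 2L,
                                            trial_index = t,
                                            block_id = block_id, ...)
  }
  dplyr::bind_rows(rows)
}

perfect_trial <- function(context = 1L) required_order(context)

# ---- independent brute-force oracles ---------------------------------------

# completion proportion per trial by explicit looping over blocks
oracle_completion_curve <- function(choices, context) {
  ch <- as.data.frame(choices)
  ch <- ch[ch$context == context, ]
  blocks <- unique(ch$block_id)
  trials <- sort(unique(ch$trial_index))
  sapply(trials, function(t) {
    done <- vapply(blocks, function(b) {
      tr <- ch[ch$block_id == b & ch$trial_index == t, ]
      if (nrow(tr) == 0) return(NA)
      any(tr$phase == "search" & tr$is_correct & tr$ordinal_target == 5)
    }, logical(1))
    mean(done, na.rm = TRUE)
  })
}

# first-attempt accuracy per ordinal position by explicit looping
oracle_ordinal_accuracy <- function(choices, trials, context) {
  ch <- as.data.frame(choices)
  ch <- ch[ch$context == context & ch$trial_index %in% trials &
             ch$phase == "search", ]
  sapply(1:5, function(p) {
    hits <- c()
    for (key in unique(paste(ch$block_id, ch$trial_index))) {
      parts <- strsplit(key, " ")[[1]]
      tr <- ch[ch$block_id == parts[1] & ch$trial_index == as.integer(parts[2]), ]
      tr <- tr[order(tr$choice_index), ]
      at_p <- tr[tr$ordinal_target == p, ]
      if (nrow(at_p)) hits <- c(hits, at_p$is_correct[1])
    }
    if (length(hits)) mean(hits) else NA_real_
  })
}

# next-free-search-choice counts after a conditioning event, by looping
oracle_transition_counts <- function(choices, event, context = 2L,
                                     trials = NULL) {
  ch <- as.data.frame(choices)
  ch <- ch[ch$context == context, ]
  if (!is.null(trials)) ch <- ch[ch$trial_index %in% trials, ]
  out <- c(A = 0, B = 0, C = 0, D = 0, E = 0, X = 0)
  for (key in unique(paste(ch$block_id, ch$trial_index))) {
    parts <- strsplit(key, " ")[[1]]
    tr <- ch[ch$block_id == parts[1] & ch$trial_index == as.integer(parts[2]), ]
    tr <- tr[order(tr$choice_index), ]
    s <- tr[tr$phase == "search", ]
    for (i in seq_len(nrow(s) - 1)) {
      hit <- switch(event,
        after_correct_A = s$chosen_label[i] == "A" && s$is_correct[i] &&
          s$ordinal_target[i] == 1,
        after_error_B = s$chosen_label[i] == "B" && !s$is_correct[i] &&
          s$ordinal_target[i] == 2,
        after_correct_D = s$chosen_label[i] == "D" && s$is_correct[i] &&
          s$ordinal_target[i] == 2)
      if (hit) out[s$chosen_label[i + 1]] <- out[s$chosen_label[i + 1]] + 1
    }
  }
  out
}

# Welch statistic and df from the textbook formulas
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# random small choice log from the simulator, for property tests
random_log <- function(seed, n_blocks = 3, agent = NULL) {
  if (is.null(agent)) agent <- agent_params()
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(n_blocks), function(k) {
    simulate_block(agent, block_id = sprintf("b%02d", k))$choices
  }))
}
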