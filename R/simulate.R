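## Generative stand-in for animal behaviour on the context-cued sequence
## reordering task. Agents learn object values per ordinal position by
## reinforcement and, at the context switch, mix two strategies observed in
## behaviour: positional re-indexing (swap the non-adjacent items B and D)
## and serial chaining (shift to the next-in-chain item), with a carryover
## fallback that perseverates on the context-1 values.

#' Agent parameters for the task simulator
#'
#' @param w_position Probability, per context-2 trial, that the agent applies
#'   positional re-indexing (mentally swapping objects B and D). If `NULL`,
#'   it is coupled to working-memory ability as
#'   `0.05 + 0.6 * wm_ability` (a linear coupling; the study motivating this
#'   package reports a positive working-memory/swapping correlation but no
#'   quantitative form).
#' @param w_serial Probability of the serial-chaining fallback at the context
#'   switch; `w_position + w_serial` must be at most 1, the remainder being
#'   carryover/exploratory choice driven by the stale context-1 values.
#' @param learning_rate Value-update step in (0, 1].
#' @param softmax_temperature Softmax temperature (> 0) for choice among
#'   not-yet-secured objects; lower is greedier.
#' @param lapse_rate Probability in \[0, 1) of a uniform random lapse on any
#'   touch (including forced retouches).
#' @param wm_ability Working-memory ability in \[0, 1\]; drives DMTS accuracy
#'   and, under the default coupling, `w_position`.
#' @param retention Fraction of a sequence's learned values retained when the
#'   sequence is repeated later in the session (0 = none, 1 = perfect).
#' @param context_bonus Additive retention bonus when a repeat is shown on the
#'   same background context (total retention is clamped to 1).
#' @param distractor_confusability Weight with which the distractor X borrows
#'   the effective value of object B (the object it resembles).
#' @param pretrained Start blocks with perfect knowledge of the context-1
#'   sequence instead of zero values.
#' @param generate_rt Attach log-normal reaction times to touches?
#' @param rt_meanlog,rt_sdlog Log-normal RT parameters (seconds).
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(w_position = NULL, w_serial = 0.3,
                         learning_rate = 0.12, softmax_temperature = 0.4,
                         lapse_rate = 0.08, wm_ability = 0.6,
                         retention = 0.8, context_bonus = 0.15,
                         distractor_confusability = 0.35,
                         pretrained = FALSE, generate_rt = TRUE,
                         rt_meanlog = log(0.75), rt_sdlog = 0.25) {
  if (is.null(w_position)) w_position <- 0.05 + 0.6 * wm_ability
  stopifnot(w_position >= 0, w_position <= 1, w_serial >= 0, w_serial <= 1,
            learning_rate > 0, learning_rate <= 1, softmax_temperature > 0,
            lapse_rate >= 0, lapse_rate < 1, wm_ability >= 0, wm_ability <= 1,
            retention >= 0, retention <= 1, context_bonus >= 0,
            distractor_confusability >= 0)
  if (w_position + w_serial > 1 + 1e-12) {
    stop("w_position + w_serial must be <= 1", call. = FALSE)
  }
  structure(list(
    w_position = w_position, w_serial = w_serial,
    learning_rate = learning_rate, softmax_temperature = softmax_temperature,
    lapse_rate = lapse_rate, wm_ability = wm_ability, retention = retention,
    context_bonus = context_bonus,
    distractor_confusability = distractor_confusability,
    pretrained = pretrained, generate_rt = generate_rt,
    rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog
  ), class = "agent_params")
}

#' Generator configuration: the session skeleton
#'
#' Defaults reproduce the study's session structure: ten sequence pairs per
#' session (half before, half after the working-memory task), 15 trials per
#' context, six on-screen objects (five sequence-relevant plus a distractor),
#' 120 DMTS trials, and roughly half of the late sequence pairs being repeats
#' of early pairs, mostly on the same background.
#'
#' @param n_sessions Number of sessions for [simulate_experiment()].
#' @param blocks_per_session Sequence pairs per session.
#' @param trials_per_context Trials per context within a pair.
#' @param n_objects On-screen objects (5 sequence-relevant + 1 distractor).
#' @param repeat_fraction Fraction of late blocks that repeat early blocks.
#' @param background_same_fraction Fraction of repeats shown on the same
#'   background context.
#' @param dmts_trials DMTS trials per session.
#' @param dmts_delays Possible DMTS delays in seconds.
#' @param dmts_n_test Number of DMTS test objects (chance = 1/n_test).
#' @param dmts_ceiling Maximum attainable DMTS accuracy.
#' @param similarity_factors Named vector scaling the above-chance range for
#'   low/high sample-test similarity; the defaults place accuracy near 0.70
#'   (low) and 0.47 (high) for an agent with `wm_ability = 0.6`.
#' @param theta_override Optional probability vector over A-E, X used by
#'   [simulate_strategy_counts()]-style direct categorical sampling.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_sessions = 1L, blocks_per_session = 10L,
                             trials_per_context = 15L, n_objects = 6L,
                             repeat_fraction = 0.5,
                             background_same_fraction = 0.6,
                             dmts_trials = 120L,
                             dmts_delays = c(0.5, 1.25, 1.75),
                             dmts_n_test = 3L, dmts_ceiling = 0.95,
                             similarity_factors = c(low = 0.99, high = 0.37),
                             theta_override = NULL) {
  stopifnot(blocks_per_session >= 1, trials_per_context >= 1,
            trials_per_context <= 15, n_objects == 6L,
            repeat_fraction >= 0, repeat_fraction <= 1,
            background_same_fraction >= 0, background_same_fraction <= 1,
            dmts_trials >= 0, dmts_n_test %in% c(2L, 3L),
            dmts_ceiling > 0, dmts_ceiling <= 1,
            all(c("low", "high") %in% names(similarity_factors)))
  if (!is.null(theta_override)) {
    stopifnot(length(theta_override) == 6, all(theta_override >= 0),
              abs(sum(theta_override) - 1) < 1e-9)
  }
  structure(list(
    n_sessions = as.integer(n_sessions),
    blocks_per_session = as.integer(blocks_per_session),
    trials_per_context = as.integer(trials_per_context),
    n_objects = as.integer(n_objects),
    repeat_fraction = repeat_fraction,
    background_same_fraction = background_same_fraction,
    dmts_trials = as.integer(dmts_trials), dmts_delays = dmts_delays,
    dmts_n_test = as.integer(dmts_n_test), dmts_ceiling = dmts_ceiling,
    similarity_factors = similarity_factors, theta_override = theta_override
  ), class = "generator_config")
}

## integer object coding: 1..5 = A..E, 6 = X
OBJ_X <- 6L
REQ_INT <- list(`1` = c(1L, 2L, 3L, 4L, 5L), `2` = c(1L, 4L, 3L, 2L, 5L))
POS_SWAP_ROWS <- c(1L, 4L, 3L, 2L, 5L, 6L)  # B <-> D re-indexing

## softmax draw among `avail` (integer ids) given values u (same length)
softmax_pick <- function(avail, u, temperature) {
  w <- exp((u - max(u)) / temperature)
  avail[sample.int(length(avail), 1L, prob = w)]
}

## simulate the two contexts of one sequence pair; V0 is the 6 x 5 starting
## value matrix. Returns the touch records and the end-of-context-1 values
## (the agent's long-term knowledge of the sequence).
sim_block_impl <- function(agent, cfg, V0 = NULL) {
  n_trials <- cfg$trials_per_context
  V <- if (is.null(V0)) matrix(0, 6, 5) else V0
  if (agent$pretrained && is.null(V0)) {
    for (p in 1:5) V[REQ_INT[["1"]][p], p] <- 1
  }
  lr <- agent$learning_rate
  conf <- agent$distractor_confusability
  cap <- 2L * MAX_CHOICES_PER_TRIAL * n_trials
  ctx_v <- trial_v <- choice_v <- ord_v <- integer(cap)
  chosen_v <- req_v <- integer(cap)
  phase_v <- character(cap)
  corr_v <- logical(cap)
  k <- 0L
  V1_end <- NULL

  for (ctx in 1:2) {
    req_order <- REQ_INT[[as.character(ctx)]]
    if (ctx == 2L) {
      W2 <- matrix(0, 6, 5)
      prior_pos <- V[POS_SWAP_ROWS, ]
      prior_ser <- V[, c(1L, 3L, 4L, 5L, 5L)]
      prior_car <- V
    }
    for (tr in seq_len(n_trials)) {
      pick_prior <- function() {
        s <- runif(1)
        if (s < agent$w_position) prior_pos
        else if (s < agent$w_position + agent$w_serial) prior_ser
        else prior_car
      }
      if (ctx == 2L) prior <- pick_prior()
      secured <- integer(0)
      tried <- matrix(FALSE, 6, 5)   # wrong (object, position) pairs this trial
      p <- 1L; nch <- 0L; nerr <- 0L
      retouch <- NA_integer_
      while (p <= 5L && nch < MAX_CHOICES_PER_TRIAL &&
             nerr < MAX_ERRORS_PER_TRIAL) {
        nch <- nch + 1L
        k <- k + 1L
        if (!is.na(retouch)) {
          ok <- runif(1) >= agent$lapse_rate
          ch <- if (ok) retouch else sample((1:6)[-retouch], 1L)
          ctx_v[k] <- ctx; trial_v[k] <- tr; choice_v[k] <- nch
          phase_v[k] <- "retouch"; chosen_v[k] <- ch; req_v[k] <- retouch
          ord_v[k] <- length(secured); corr_v[k] <- ch == retouch
          if (ch == retouch) retouch <- NA_integer_ else nerr <- nerr + 1L
        } else {
          req <- req_order[p]
          avail <- if (length(secured)) (1:6)[-secured] else 1:6
          U <- if (ctx == 1L) V else W2 + prior
          ## error feedback excludes an (object, position) pair for the rest
          ## of the trial; the distractor borrows the (possibly excluded)
          ## effective value of object B, which it resembles
          inh <- tried[, p] * 1e3
          u <- U[avail, p] - inh[avail]
          u[avail == OBJ_X] <- u[avail == OBJ_X] + conf * (U[2L, p] - inh[2L])
          ch <- if (runif(1) < agent$lapse_rate) {
            avail[sample.int(length(avail), 1L)]
          } else {
            softmax_pick(avail, u, agent$softmax_temperature)
          }
          correct <- ch == req
          r <- as.numeric(correct)
          if (ctx == 1L) {
            V[ch, p] <- V[ch, p] + lr * (r - V[ch, p])
          } else {
            W2[ch, p] <- W2[ch, p] + lr * (r - (W2[ch, p] + prior[ch, p]))
          }
          ctx_v[k] <- ctx; trial_v[k] <- tr; choice_v[k] <- nch
          phase_v[k] <- "search"; chosen_v[k] <- ch; req_v[k] <- req
          ord_v[k] <- p; corr_v[k] <- correct
          if (correct) {
            secured <- c(secured, ch); p <- p + 1L
          } else {
            nerr <- nerr + 1L
            tried[ch, p] <- TRUE
            if (length(secured)) retouch <- secured[length(secured)]
            ## error feedback prompts a fresh strategy draw for the rest of
            ## the trial: retro-active re-indexing after an error on B
            if (ctx == 2L) prior <- pick_prior()
          }
        }
      }
    }
    if (ctx == 1L) V1_end <- V
  }
  idx <- seq_len(k)
  rec <- tibble::tibble(
    context = ctx_v[idx], trial_index = trial_v[idx],
    choice_index = choice_v[idx], phase = phase_v[idx],
    chosen_label = ALL_LABELS[chosen_v[idx]],
    required_label = ALL_LABELS[req_v[idx]],
    ordinal_target = ord_v[idx], is_correct = corr_v[idx],
    rt = if (agent$generate_rt) {
      round(rlnorm(k, agent$rt_meanlog, agent$rt_sdlog), 6)
    } else NA_real_
  )
  list(records = rec, values = V1_end)
}

#' Simulate one sequence-pair block
#'
#' Simulates the 15 context-1 trials (sequence A-B-C-D-E) followed by the 15
#' context-2 trials (A-D-C-B-E) of one sequence pair. The agent learns
#' object-by-ordinal-position values with softmax choice over objects not yet
#' secured in the current trial; after each error the forced retouch of the
#' last correct object is generated with accuracy `1 - lapse_rate`. At the
#' context switch the agent applies, per trial, positional re-indexing with
#' probability `w_position`, serial chaining with probability `w_serial`, and
#' otherwise carries over the stale context-1 values.
#'
#' @param agent An [agent_params()] object.
#' @param cfg A [generator_config()] object.
#' @param block_id,subject_id,session_index,condition,background_same,source_block_id
#'   Block metadata stored on the records.
#' @param values Optional 6 x 5 starting value matrix (rows A-E, X; columns
#'   ordinal positions), e.g. the retained values of an earlier block.
#' @param seed Optional integer seed.
#' @return A `choice_data` object holding the block's touch records; the
#'   agent's end-of-context-1 value matrix is attached as attribute
#'   `"values"` on the object.
#' @export
simulate_block <- function(agent, cfg = generator_config(),
                           block_id = "b01", subject_id = "sim",
                           session_index = 1L, condition = "new_early",
                           background_same = NA, source_block_id = NA_character_,
                           values = NULL, seed = NULL) {
  stopifnot(inherits(agent, "agent_params"), inherits(cfg, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  sim <- sim_block_impl(agent, cfg, values)
  rec <- sim$records
  rec$subject_id <- subject_id
  rec$session_index <- as.integer(session_index)
  rec$block_id <- block_id
  rec$condition <- condition
  rec$background_same <- background_same
  rec$source_block_id <- source_block_id
  out <- choice_data(rec, validate = FALSE)
  attr(out, "values") <- sim$values
  out
}

#' Simulate delayed match-to-sample trials
#'
#' Correctness is Bernoulli with
#' `accuracy = chance + (ceiling - chance) * wm_ability * similarity_factor`,
#' where chance is `1 / n_test`. With the default calibration an agent with
#' `wm_ability = 0.6` scores about 0.70 in the low-similarity and 0.47 in the
#' high-similarity condition; accuracy does not depend on the delay.
#'
#' @param agent An [agent_params()] object.
#' @param n_trials Number of DMTS trials.
#' @param cfg A [generator_config()] object.
#' @param subject_id,session_index Metadata columns.
#' @param seed Optional integer seed.
#' @return Tibble of DMTS records (similarity, delay, n_test, correct).
#' @export
simulate_dmts <- function(agent, n_trials = 120L, cfg = generator_config(),
                          subject_id = "sim", session_index = 1L,
                          seed = NULL) {
  stopifnot(n_trials > 0)
  if (!is.null(seed)) set.seed(seed)
  similarity <- sample(c("low", "high"), n_trials, replace = TRUE)
  delay <- sample(cfg$dmts_delays, n_trials, replace = TRUE)
  chance <- 1 / cfg$dmts_n_test
  acc <- chance + (cfg$dmts_ceiling - chance) * agent$wm_ability *
    cfg$similarity_factors[similarity]
  tibble::tibble(
    subject_id = subject_id, session_index = as.integer(session_index),
    similarity = similarity, delay = delay, n_test = cfg$dmts_n_test,
    correct = runif(n_trials) < acc
  )
}

#' Simulate a full session
#'
#' A session comprises `blocks_per_session` sequence pairs: the first half are
#' new sequences (`new_early`), followed by the DMTS task, followed by late
#' blocks of which a fraction `repeat_fraction` repeat early sequences
#' (condition `repeat`) and the rest are new (`new_late`). Repeated blocks
#' restart from the early block's learned values scaled by the agent's
#' retention factor, plus `context_bonus` when the repeat is shown on the same
#' background.
#'
#' @inheritParams simulate_block
#' @param session_index Session number stored on the records.
#' @return A `choice_data` object with the session's touch and DMTS records.
#' @export
simulate_session <- function(agent, cfg = generator_config(),
                             subject_id = "sim", session_index = 1L,
                             seed = NULL) {
  stopifnot(inherits(agent, "agent_params"), inherits(cfg, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  bps <- cfg$blocks_per_session
  n_early <- bps %/% 2L
  n_late <- bps - n_early
  n_repeat <- min(n_early, round(cfg$repeat_fraction * n_late))
  bid <- function(k) sprintf("%s_s%02d_b%02d", subject_id, session_index, k)

  recs <- vector("list", bps)
  early_values <- vector("list", n_early)
  for (k in seq_len(n_early)) {
    sim <- sim_block_impl(agent, cfg)
    early_values[[k]] <- sim$values
    rec <- sim$records
    rec$block_id <- bid(k); rec$condition <- "new_early"
    rec$background_same <- NA; rec$source_block_id <- NA_character_
    recs[[k]] <- rec
  }

  dmts <- simulate_dmts(agent, cfg$dmts_trials, cfg, subject_id, session_index)

  repeat_src <- sample(seq_len(n_early), n_repeat)
  late_kind <- sample(c(rep("repeat", n_repeat),
                        rep("new_late", n_late - n_repeat)))
  for (j in seq_len(n_late)) {
    k <- n_early + j
    if (late_kind[j] == "repeat") {
      src <- repeat_src[sum(late_kind[seq_len(j)] == "repeat")]
      same_bg <- runif(1) < cfg$background_same_fraction
      keep <- min(1, agent$retention + if (same_bg) agent$context_bonus else 0)
      sim <- sim_block_impl(agent, cfg, V0 = keep * early_values[[src]])
      rec <- sim$records
      rec$block_id <- bid(k); rec$condition <- "repeat"
      rec$background_same <- same_bg; rec$source_block_id <- bid(src)
    } else {
      sim <- sim_block_impl(agent, cfg)
      rec <- sim$records
      rec$block_id <- bid(k); rec$condition <- "new_late"
      rec$background_same <- NA; rec$source_block_id <- NA_character_
    }
    recs[[k]] <- rec
  }
  choices <- dplyr::bind_rows(recs)
  choices$subject_id <- subject_id
  choices$session_index <- as.integer(session_index)
  choice_data(choices, dmts, validate = FALSE)
}

#' Simulate multiple sessions
#'
#' @param agent A single [agent_params()] object, or a list with one agent per
#'   session (e.g. to let ability change across sessions).
#' @param cfg A [generator_config()]; `cfg$n_sessions` sets the session count
#'   when `agent` is not a list.
#' @param subject_id Subject label, recycled across sessions, or a vector with
#'   one label per session.
#' @param seed Optional integer seed (a single stream drives all sessions).
#' @return A `choice_data` object pooling all sessions.
#' @export
simulate_experiment <- function(agent, cfg = generator_config(),
                                subject_id = "sim", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  agents <- if (inherits(agent, "agent_params")) {
    rep(list(agent), cfg$n_sessions)
  } else {
    agent
  }
  n <- length(agents)
  subject_id <- rep_len(subject_id, n)
  per_subj <- stats::ave(seq_len(n), subject_id, FUN = seq_along)
  out <- vector("list", n)
  for (s in seq_len(n)) {
    out[[s]] <- simulate_session(agents[[s]], cfg, subject_id = subject_id[s],
                                 session_index = per_subj[s])
  }
  choice_data(dplyr::bind_rows(lapply(out, function(x) x$choices)),
              dplyr::bind_rows(lapply(out, function(x) x$dmts)),
              validate = FALSE)
}

#' Multinomial counts from a categorical choice distribution
#'
#' Draws `n` independent categorical choices with probability vector `theta`
#' over the object labels and returns the counts. This is the direct sampler
#' used for parameter-recovery checks of the posterior sampler.
#'
#' @param theta Probability vector (must sum to 1 within 1e-9); names default
#'   to A-E, X when of length 6.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Named integer vector of counts summing to `n`.
#' @export
sample_categorical_counts <- function(theta, n, seed = NULL) {
  if (any(theta < 0)) stop("theta must be non-negative", call. = FALSE)
  if (abs(sum(theta) - 1) > 1e-9) {
    stop("theta must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  stopifnot(n > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(theta))) {
    names(theta) <- if (length(theta) == 6) ALL_LABELS
                    else paste0("k", seq_along(theta))
  }
  counts <- as.integer(stats::rmultinom(1, n, theta))
  names(counts) <- names(theta)
  counts
}

#' Per-session categorical counts for strategy-recovery studies
#'
#' Generates `n_sessions` sessions of `events_per_session` second-position
#' choices drawn directly from a categorical distribution over
#' \{B, C, D, E, X\} (bypassing the task agent), as used to test whether the
#' posterior strategy classifier recovers a known dominant strategy.
#'
#' @param theta Probability vector over B, C, D, E, X (sums to 1).
#' @param n_sessions Number of sessions.
#' @param events_per_session Conditioning events per session.
#' @param seed Optional integer seed.
#' @return Tibble with columns `session_id`, `label`, `count`.
#' @export
simulate_strategy_counts <- function(theta, n_sessions = 200L,
                                     events_per_session = 150L, seed = NULL) {
  stopifnot(length(theta) == 5, abs(sum(theta) - 1) < 1e-9, all(theta >= 0))
  if (is.null(names(theta))) names(theta) <- c("B", "C", "D", "E", "X")
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rmultinom(n_sessions, events_per_session, theta)
  tibble::tibble(
    session_id = rep(sprintf("s%03d", seq_len(n_sessions)), each = 5),
    label = rep(names(theta), n_sessions),
    count = as.integer(counts)
  )
}
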