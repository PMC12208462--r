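## Memory, experience, context and working-memory analyses at the block and
## session level.

## pairwise Welch tests with Bonferroni adjustment over condition pairs
pairwise_welch <- function(values, groups) {
  lv <- unique(groups)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  out <- dplyr::bind_rows(lapply(pairs, function(pr) {
    w <- welch_t(values[groups == pr[1]], values[groups == pr[2]])
    tibble::tibble(group_a = pr[1], group_b = pr[2],
                   statistic = w$statistic, df = w$df, p = w$p)
  }))
  out$p_adjusted <- adjust_p(out$p, "bonferroni")
  out
}

#' Compare new-early, new-late and repeated sequences
#'
#' Summarises, per presentation condition, how fast blocks reached the
#' learning criterion and how strongly they expressed pro-active and
#' retro-active swapping, with all pairwise Welch tests
#' (Bonferroni-adjusted). Blocks that never reached criterion are excluded
#' from the criterion means (their count is reported).
#'
#' @param data A `choice_data` object or choices data frame.
#' @param context Context for the criterion (default 1, initial learning).
#' @return List of class `condition_comparison`: `summary` (per condition:
#'   mean trials-to-criterion with 95% CI, mean swap indices with CI, block
#'   counts), `criterion_tests`, `proactive_tests`, `retroactive_tests`.
#' @export
compare_conditions <- function(data, context = 1L) {
  crit <- block_criteria(data, context = context)
  idx <- swap_indices(data, scope = "block")
  bl <- dplyr::left_join(
    crit,
    idx[c("subject_id", "session_index", "block_id", "proactive",
          "retroactive")],
    by = c("subject_id", "session_index", "block_id")
  )
  present <- intersect(CONDITIONS, unique(bl$condition))
  if (length(present) < 2) {
    message("compare_conditions: fewer than 2 conditions present")
  }
  summ <- dplyr::bind_rows(lapply(present, function(cond) {
    b <- bl[bl$condition == cond, ]
    ct <- mean_ci(b$criterion_trial)
    pa <- mean_ci(b$proactive)
    ra <- mean_ci(b$retroactive)
    tibble::tibble(
      condition = cond, n_blocks = nrow(b), n_censored = sum(b$censored),
      criterion_mean = ct$mean, criterion_lower = ct$lower,
      criterion_upper = ct$upper,
      proactive_mean = pa$mean, proactive_lower = pa$lower,
      proactive_upper = pa$upper,
      retroactive_mean = ra$mean, retroactive_lower = ra$lower,
      retroactive_upper = ra$upper
    )
  }))
  structure(list(
    summary = summ,
    criterion_tests = pairwise_welch(bl$criterion_trial, bl$condition),
    proactive_tests = pairwise_welch(bl$proactive, bl$condition),
    retroactive_tests = pairwise_welch(bl$retroactive, bl$condition)
  ), class = "condition_comparison")
}

#' Learning proficiency versus swapping
#'
#' Regresses each block-level swap index on the block's context-1 completion
#' rate (does better initial learning predict re-indexing?), and contrasts
#' the good versus poor proficiency terciles with a Welch test. Blocks whose
#' index is undefined (no conditioning events) are excluded and counted.
#'
#' @param data A `choice_data` object or choices data frame.
#' @param method Proficiency partition method (see
#'   [partition_by_proficiency()]).
#' @return List of class `proficiency_swap`: per index a
#'   `regression_result`, the tercile Welch test, and exclusion counts.
#' @export
proficiency_vs_swap <- function(data, method = "tercile") {
  crit <- block_criteria(data, context = 1L)
  idx <- swap_indices(data, scope = "block")
  part <- partition_by_proficiency(data, context = 1L, method = method)
  bl <- dplyr::left_join(
    crit,
    idx[c("subject_id", "session_index", "block_id", "proactive",
          "retroactive")],
    by = c("subject_id", "session_index", "block_id")
  )
  bl <- dplyr::left_join(
    bl, part[c("subject_id", "session_index", "block_id", "group")],
    by = c("subject_id", "session_index", "block_id")
  )
  one <- function(index) {
    y <- bl[[index]]
    ok <- is.finite(y)
    reg <- if (sum(ok) >= 3 && var(bl$completion_rate[ok]) > 0) {
      simple_regression(bl$completion_rate[ok], y[ok])
    } else NULL
    tct <- welch_t(y[ok & bl$group == "good"], y[ok & bl$group == "poor"])
    list(regression = reg, tercile_test = tct, n_used = sum(ok),
         n_excluded = sum(!ok))
  }
  structure(list(proactive = one("proactive"),
                 retroactive = one("retroactive")),
            class = "proficiency_swap")
}

#' Swap-index trend across sessions
#'
#' Per-session pooled swap index tested against zero (one-sample Student's t)
#' and regressed on the session number, with Cohen's f-squared, to quantify
#' whether the re-indexing rule is applied more strongly with task
#' experience.
#'
#' @param data A `choice_data` object or choices data frame.
#' @param index `"proactive"` or `"retroactive"`.
#' @return List of class `session_trend`: `sessions` (per-session values),
#'   `t_vs_zero` (statistic, df, p, mean with CI) and `regression`.
#' @export
across_session_trend <- function(data, index = c("proactive", "retroactive")) {
  index <- match.arg(index)
  per <- swap_indices(data, scope = "session")
  per <- per[is.finite(per[[index]]), ]
  per <- dplyr::arrange(per, .data$subject_id, .data$session_index)
  if (nrow(per) < 3) {
    stop("need at least 3 sessions with a defined index", call. = FALSE)
  }
  y <- per[[index]]
  tt <- if (sd(y) > 0) {
    t0 <- t.test(y, mu = 0)
    list(statistic = unname(t0$statistic), df = unname(t0$parameter),
         p = t0$p.value, mean = mean(y),
         lower = t0$conf.int[1], upper = t0$conf.int[2])
  } else {
    # a perfectly constant index: infinitely strong evidence unless it is 0
    list(statistic = if (mean(y) == 0) 0 else Inf * sign(mean(y)),
         df = length(y) - 1, p = if (mean(y) == 0) 1 else 0,
         mean = mean(y), lower = mean(y), upper = mean(y))
  }
  reg <- if (var(per$session_index) > 0) {
    simple_regression(per$session_index, y)
  } else NULL
  structure(list(
    index = index, sessions = per,
    t_vs_zero = tt,
    regression = reg
  ), class = "session_trend")
}

#' Working memory versus pro-active swapping
#'
#' Regresses the session-level pro-active swap index on the session's DMTS
#' accuracy: pooled across subjects, per subject (subjects with at least 3
#' sessions), and - as an adjunct - a linear mixed model with a random
#' intercept per subject fitted by a standard library, of which only the
#' slope and its p value are reported.
#'
#' @param data A `choice_data` object with DMTS records.
#' @return List of class `dmts_correlation`: `sessions` (per-session DMTS
#'   accuracy and swap index), `pooled` regression, `per_subject` list of
#'   regressions, and `mixed` (slope, p; `NULL` when the model cannot be
#'   fitted).
#' @export
dmts_correlation <- function(data) {
  stopifnot(inherits(data, "choice_data"))
  acc <- dmts_accuracy(data)
  idx <- swap_indices(data, scope = "session")
  per <- dplyr::inner_join(acc, idx, by = c("subject_id", "session_index"))
  per <- per[is.finite(per$proactive) & is.finite(per$accuracy), ]
  if (nrow(per) < 3) stop("need at least 3 sessions", call. = FALSE)
  pooled <- simple_regression(per$accuracy, per$proactive)
  per_subject <- lapply(split(per, per$subject_id), function(df) {
    if (nrow(df) < 3 || var(df$accuracy) == 0) return(NULL)
    simple_regression(df$accuracy, df$proactive)
  })
  per_subject <- per_subject[!vapply(per_subject, is.null, logical(1))]
  mixed <- NULL
  if (dplyr::n_distinct(per$subject_id) >= 2) {
    mixed <- tryCatch({
      fit <- lmerTest::lmer(proactive ~ accuracy + (1 | subject_id),
                            data = per)
      cf <- summary(fit)$coefficients
      list(slope = cf["accuracy", "Estimate"],
           p = cf["accuracy", "Pr(>|t|)"])
    }, error = function(e) NULL, warning = function(w) NULL)
  }
  structure(list(sessions = per, pooled = pooled, per_subject = per_subject,
                 mixed = mixed),
            class = "dmts_correlation")
}

#' Effect of repeating a sequence on the same versus a different background
#'
#' For repeated sequence pairs, contrasts same- versus different-background
#' repeats on (1) the completion gain - the repeat block's context-1
#' completion rate minus its matched early block's - and (2) the repeat
#' block's pro-active and retro-active swap indices, each with a Welch test.
#'
#' @param data A `choice_data` object or choices data frame.
#' @param context Context whose completion rate defines the gain (default 1).
#' @return List of class `context_effects`: `blocks` (per repeat block:
#'   gain, indices, background flag), per-measure group means and Welch
#'   tests.
#' @export
context_effects <- function(data, context = 1L) {
  crit <- block_criteria(data, context = context)
  reps <- crit[crit$condition == "repeat" & !is.na(crit$background_same), ]
  if (nrow(reps) == 0) {
    message("context_effects: no repeat blocks with background information")
    return(structure(list(blocks = reps, tests = NULL),
                     class = "context_effects"))
  }
  early <- crit[c("subject_id", "session_index", "block_id",
                  "completion_rate")]
  names(early)[3:4] <- c("source_block_id", "early_completion_rate")
  reps <- dplyr::left_join(reps, early,
                           by = c("subject_id", "session_index",
                                  "source_block_id"))
  reps$completion_gain <- reps$completion_rate - reps$early_completion_rate
  idx <- swap_indices(data, scope = "block")
  reps <- dplyr::left_join(
    reps,
    idx[c("subject_id", "session_index", "block_id", "proactive",
          "retroactive")],
    by = c("subject_id", "session_index", "block_id")
  )
  one <- function(col) {
    a <- reps[[col]][reps$background_same]
    b <- reps[[col]][!reps$background_same]
    list(same = mean_ci(a), different = mean_ci(b), test = welch_t(a, b))
  }
  structure(list(
    blocks = reps,
    completion_gain = one("completion_gain"),
    proactive = one("proactive"),
    retroactive = one("retroactive")
  ), class = "context_effects")
}

#' Build a consolidated analysis report
#'
#' Serialises a named list of analysis results, together with provenance
#' (package version, R version, configuration and seed), to JSON and a
#' companion markdown summary. Reports are deterministic: the same results
#' and seed produce byte-identical files.
#'
#' @param results Named list of analysis results (any mix of this package's
#'   result objects and plain values).
#' @param path Output path without extension; `"<path>.json"` and
#'   `"<path>.md"` are written. `NULL` returns the report object only.
#' @param config Optional configuration list recorded as provenance.
#' @param seed Optional seed recorded as provenance.
#' @return The report list, invisibly when written.
#' @export
build_report <- function(results = list(), path = NULL, config = NULL,
                         seed = NULL) {
  stopifnot(is.list(results))
  report <- list(
    provenance = list(
      package = "seqswap",
      package_version = as.character(utils::packageVersion("seqswap")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = seed, config = config
    ),
    sections = names(results),
    results = results
  )
  if (!is.null(path)) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(strip_classes(report), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", force = TRUE)
    md <- c("# seqswap analysis report", "",
            sprintf("- package version: %s",
                    report$provenance$package_version),
            sprintf("- seed: %s", if (is.null(seed)) "none" else seed),
            "", "## Sections", "",
            if (length(results)) paste0("- ", names(results))
            else "- (no analyses)")
    writeLines(md, paste0(path, ".md"))
    return(invisible(report))
  }
  report
}

## recursively drop S3 classes and coerce to JSON-friendly structures
strip_classes <- function(x) {
  if (inherits(x, "theta_posterior")) {
    x <- x[c("labels", "mean", "ci_lower", "ci_upper", "rhat", "accept_rate")]
  }
  if (is.data.frame(x)) return(as.data.frame(unclass(x)))
  if (is.list(x)) {
    x <- unclass(x)
    x$draws <- NULL
    return(lapply(x, strip_classes))
  }
  x
}
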