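test_that("condition comparison reproduces hand-computed criterion means", {
  fast <- replicate(15, perfect_trial(1), simplify = FALSE)
  slow <- c(list(c("A", "B", "C"), c("A", "B", "C")),
            replicate(13, perfect_trial(1), simplify = FALSE))
  ch <- dplyr::bind_rows(
    make_block(slow, block_id = "e1", condition = "new_early"),
    make_block(slow, block_id = "e2", condition = "new_early"),
    make_block(fast, block_id = "r1", condition = "repeat",
               background_same = TRUE, source_block_id = "e1"),
    make_block(slow, block_id = "l1", condition = "new_late")
  )
  cc <- compare_conditions(ch)
  s <- cc$summary
  expect_equal(s$criterion_mean[s$condition == "new_early"], 3)  # trials 1-2 fail
  expect_equal(s$criterion_mean[s$condition == "repeat"], 1)
  expect_equal(s$criterion_mean[s$condition == "new_late"], 3)
  expect_true(all(cc$criterion_tests$p_adjusted >= cc$criterion_tests$p,
                  na.rm = TRUE))
})

test_that("identical behaviour across conditions yields non-significant tests", {
  set.seed(61)
  d <- simulate_experiment(agent_params(retention = 0, context_bonus = 0),
                           generator_config(n_sessions = 2), seed = 61)
  cc <- compare_conditions(d)
  expect_true(all(cc$criterion_tests$p > 0.001, na.rm = TRUE))
})

test_that("proficiency-coupled generators show the predicted swap regression", {
  set.seed(71)
  agents <- lapply(runif(24, 0.05, 0.95), function(w) {
    agent_params(w_position = 0.05 + 0.6 * w, wm_ability = w)
  })
  ch <- dplyr::bind_rows(lapply(seq_along(agents), function(k) {
    simulate_block(agents[[k]], block_id = sprintf("pv%02d", k),
                   session_index = k)$choices
  }))
  ps <- proficiency_vs_swap(ch)
  expect_true(is.list(ps$proactive))
  expect_true(ps$proactive$n_used + ps$proactive$n_excluded == 24)
  # perfectly linear constructed data recover R^2 = 1 through the same path
  r <- simple_regression(seq(0.1, 0.9, length.out = 9),
                         0.5 * seq(0.1, 0.9, length.out = 9) - 0.1)
  expect_equal(r$r_squared, 1)
})

test_that("across-session trend detects a constant positive index", {
  mk_session <- function(s, nxt) {
    dplyr::bind_rows(lapply(1:3, function(b) {
      make_block(list(), lapply(nxt, function(l) c("A", l)),
                 block_id = sprintf("s%d_b%d", s, b), session_index = s)
    }))
  }
  # every session: P(D) = 0.75, P(B) = 0.25 -> index 0.5, no trend
  ch <- dplyr::bind_rows(lapply(1:6, function(s) {
    mk_session(s, c("D", "D", "D", "B"))
  }))
  tr <- across_session_trend(ch)
  expect_lt(tr$t_vs_zero$p, 1e-6)
  expect_equal(tr$t_vs_zero$mean, 0.5)
  expect_equal(tr$regression$beta, 0, tolerance = 1e-12)

  # alternating positive/negative index: mean test non-significant
  ch2 <- dplyr::bind_rows(lapply(1:6, function(s) {
    mk_session(s, if (s %% 2) c("D", "D", "B") else c("B", "B", "D"))
  }))
  tr2 <- across_session_trend(ch2)
  expect_gt(tr2$t_vs_zero$p, 0.9)
})

test_that("session trends grow when re-indexing strengthens with experience", {
  set.seed(81)
  wps <- seq(0.1, 0.9, length.out = 10)
  agents <- lapply(wps, function(w) agent_params(w_position = w,
                                                 w_serial = 0.1))
  d <- simulate_experiment(agents,
                           generator_config(blocks_per_session = 4,
                                            dmts_trials = 20), seed = 81)
  # read the index from the first context-2 trials, where strategy is purest
  per <- swap_indices(d, scope = "session", trials = 1:3)
  reg <- simple_regression(per$session_index, per$proactive)
  expect_gt(reg$beta, 0)
})

test_that("working-memory coupling drives the DMTS regression slope", {
  set.seed(91)
  wms <- runif(10, 0.1, 0.95)
  coupled <- lapply(wms, function(w) agent_params(wm_ability = w))
  d <- simulate_experiment(coupled,
                           generator_config(blocks_per_session = 4,
                                            dmts_trials = 60),
                           subject_id = rep(c("mA", "mB"), 5), seed = 91)
  dc <- dmts_correlation(d)
  expect_gt(dc$pooled$beta, 0)
  expect_true(is.numeric(dc$pooled$p))
  # the mixed-model adjunct reports a slope of the same sign
  if (!is.null(dc$mixed)) expect_gt(dc$mixed$slope, 0)
  # constant DMTS accuracy surfaces as a clean error
  flat <- d
  flat$dmts$correct <- TRUE
  expect_error(dmts_correlation(flat), "constant")
})

test_that("context effects contrast same- versus different-background repeats", {
  fast <- replicate(15, perfect_trial(1), simplify = FALSE)
  slow <- c(list(c("A", "B"), c("A", "B"), c("A", "B")),
            replicate(12, perfect_trial(1), simplify = FALSE))
  mid <- c(list(c("A", "B")), replicate(14, perfect_trial(1), simplify = FALSE))
  ch <- dplyr::bind_rows(
    make_block(slow, block_id = "e1", condition = "new_early"),
    make_block(slow, block_id = "e2", condition = "new_early"),
    make_block(fast, block_id = "r1", condition = "repeat",
               background_same = TRUE, source_block_id = "e1"),
    make_block(mid, block_id = "r2", condition = "repeat",
               background_same = FALSE, source_block_id = "e2")
  )
  cx <- context_effects(ch)
  # gains: same 15/15 - 12/15 = 0.2; different 14/15 - 12/15 ~ 0.133
  expect_equal(cx$completion_gain$same$mean, 3 / 15)
  expect_equal(cx$completion_gain$different$mean, 2 / 15)
  empty <- ch[ch$condition != "repeat", ]
  expect_message(context_effects(empty), "no repeat blocks")
})

test_that("reports are complete and byte-identical across identical runs", {
  set.seed(5)
  d <- simulate_session(agent_params(), generator_config(blocks_per_session = 2,
                                                         dmts_trials = 10),
                        seed = 5)
  res <- list(curve = completion_curve(d, 1),
              indices = swap_indices(d, trials = "all"),
              chance = forward_chance(1:5))
  p1 <- file.path(tempdir(), "rep1"); p2 <- file.path(tempdir(), "rep2")
  build_report(res, p1, seed = 5)
  build_report(res, p2, seed = 5)
  expect_identical(readLines(paste0(p1, ".json")),
                   readLines(paste0(p2, ".json")))
  parsed <- jsonlite::read_json(paste0(p1, ".json"))
  expect_equal(parsed$provenance$seed, 5)
  expect_setequal(unlist(parsed$sections), c("curve", "indices", "chance"))
  minimal <- build_report(list())
  expect_equal(minimal$provenance$package, "seqswap")
})
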