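test_that("transition table matches hand counts on a built fixture", {
  # 10 context-2 trials erring on B at position 2; next free choices:
  # 4x D, 3x C, 2x E, 1x X (retouches of A are skipped)
  nxt <- c(rep("D", 4), rep("C", 3), rep("E", 2), "X")
  trials2 <- lapply(nxt, function(l) c("A", "B", l))
  ch <- make_block(list(c("A", "B", "C")), trials2, block_id = "h1")
  tb <- transition_after(ch, "after_error_B", trials = "all")
  expect_equal(attr(tb, "n_events"), 10)
  expect_equal(tb$prob[match(c("D", "C", "E", "X", "A", "B"), tb$label)],
               c(0.4, 0.3, 0.2, 0.1, 0, 0))
  # the forced retouch of A was never counted as a transition target
  expect_equal(tb$count[tb$label == "A"], 0)
})

test_that("transition counts equal a brute-force recount on random logs", {
  for (seed in c(3, 29)) {
    ch <- random_log(seed, n_blocks = 3)
    for (ev in c("after_correct_A", "after_error_B", "after_correct_D")) {
      tb <- transition_after(ch, ev, trials = "all")
      oracle <- oracle_transition_counts(ch, ev, context = 2)
      expect_equal(setNames(tb$count, tb$label), oracle,
                   label = paste(ev, seed))
    }
  }
})

test_that("deterministic post-A transitions give probability one", {
  trials2 <- replicate(6, c("A", "D", "C", "B", "E"), simplify = FALSE)
  ch <- make_block(list(perfect_trial(1)), trials2)
  tb <- transition_after(ch, "after_correct_A", trials = "all")
  expect_equal(tb$prob[tb$label == "D"], 1)
  expect_equal(sum(tb$prob), 1)
  empty <- transition_after(ch, "after_error_B", trials = "all")
  expect_true(attr(empty, "empty"))
})

test_that("swap indices are the stated differences of transition entries", {
  # after correct A: D 5x, B 2x, C 3x; after error B: D 45x, C 36x (of 100)
  trials2 <- c(lapply(c(rep("D", 5), rep("B", 2), rep("C", 3)),
                      function(l) c("A", l)))
  ch <- make_block(list(), trials2)
  si <- swap_indices(ch, trials = "all")
  expect_equal(si$proactive, 0.5 - 0.2)
  expect_equal(si$serial_contrast, 0.5 - 0.3)
  expect_true(is.na(si$retroactive))
  # indices recomputed from the transition table agree exactly
  tb <- transition_after(ch, "after_correct_A", trials = "all")
  expect_equal(si$proactive,
               tb$prob[tb$label == "D"] - tb$prob[tb$label == "B"])
  # published post-error transition probabilities imply a 0.094 retro index
  expect_equal(0.450 - 0.356, 0.094)
})

test_that("per-block indices line up with their pooled counterpart", {
  ch <- dplyr::bind_rows(
    make_block(list(), replicate(4, c("A", "D"), simplify = FALSE),
               block_id = "k1"),
    make_block(list(), replicate(4, c("A", "B", "C"), simplify = FALSE),
               block_id = "k2")
  )
  per <- swap_indices(ch, scope = "block", trials = "all")
  expect_equal(nrow(per), 2)
  expect_equal(per$proactive[per$block_id == "k1"], 1)
  expect_equal(per$proactive[per$block_id == "k2"], -1)
  pooled <- swap_indices(ch, trials = "all")
  expect_equal(pooled$proactive, 0)
})

test_that("a re-indexing agent prefers D over C after an error on B", {
  set.seed(13)
  a <- agent_params(w_position = 1, w_serial = 0)
  ch <- dplyr::bind_rows(lapply(1:50, function(k) {
    simulate_block(a, block_id = sprintf("r%02d", k))$choices
  }))
  tb <- transition_after(ch, "after_error_B", trials = "all")
  expect_gt(tb$prob[tb$label == "D"], tb$prob[tb$label == "C"])
  expect_gt(attr(tb, "n_events"), 10)
})

test_that("first-choice analysis recovers hand-computable probabilities", {
  # ctx1 last trial first choice after A: B; ctx2 first trial: D or C
  mk <- function(id, first2) {
    make_block(replicate(15, perfect_trial(1), simplify = FALSE),
               c(list(c("A", first2)),
                 replicate(14, c("A", "D", "C", "B", "E"), simplify = FALSE)),
               block_id = id)
  }
  ch <- dplyr::bind_rows(mk("f1", "D"), mk("f2", "D"), mk("f3", "C"),
                         mk("f4", "D"))
  fc <- first_choice_analysis(ch)
  tab <- fc$table
  expect_equal(tab$p_context1[tab$label == "B"], 1)
  expect_equal(tab$p_context2[tab$label == "D"], 0.75)
  expect_equal(tab$p_context2[tab$label == "C"], 0.25)
  expect_equal(tab$difference[tab$label == "B"], -1)
  expect_true(all(tab$p_adjusted >= tab$p, na.rm = TRUE))
  expect_equal(unname(fc$n_blocks), c(4, 4))
})

test_that("an agent that never re-indexes shows a near-zero first-choice shift", {
  set.seed(41)
  a <- agent_params(w_position = 0, w_serial = 0, lapse_rate = 0.02)
  ch <- dplyr::bind_rows(lapply(1:40, function(k) {
    simulate_block(a, block_id = sprintf("n%02d", k))$choices
  }))
  fc <- first_choice_analysis(ch)
  d_shift <- fc$table$difference[fc$table$label == "D"]
  expect_lt(abs(d_shift), 0.25)
})

test_that("trialwise first-choice curves are exact on a deterministic log", {
  mk <- function(id, t1, t2) {
    make_block(list(), list(c("A", t1), c("A", t2)), block_id = id)
  }
  ch <- dplyr::bind_rows(mk("t1", "D", "D"), mk("t2", "C", "D"),
                         mk("t3", "B", "D"))
  tw <- trialwise_first_choice(ch)
  c1 <- tw$curves[tw$curves$trial_index == 1, ]
  expect_equal(c1$mean[c1$contrast == "D-B"], 1 / 3 - 1 / 3)
  expect_equal(c1$mean[c1$contrast == "D-C"], 0)
  c2 <- tw$curves[tw$curves$trial_index == 2, ]
  expect_equal(c2$mean[c2$contrast == "D-C"], 1)
  expect_equal(tw$dc_crossing_trial, 2L)
})

test_that("distractor choices peak where the distractor resembles object B", {
  set.seed(55)
  a <- agent_params(distractor_confusability = 0.8)
  ch <- dplyr::bind_rows(lapply(1:40, function(k) {
    simulate_block(a, block_id = sprintf("x%02d", k))$choices
  }))
  # once the sequence is learned, distractor confusions concentrate at the
  # position where object B (which X resembles) is expected
  da <- distractor_analysis(ch[ch$trial_index %in% 8:15, ])
  expect_equal(which.max(da$prop_context1), 2)
  expect_equal(which.max(da$prop_context2), 4)
  # formula oracle: 30/100 vs 20/100
  z <- two_prop_z(30, 100, 20, 100)
  pp <- 50 / 200
  z_hand <- (0.3 - 0.2) / sqrt(pp * (1 - pp) * (1 / 100 + 1 / 100))
  expect_equal(z$statistic, z_hand, tolerance = 1e-12)
  # equal proportions give Z = 0
  expect_equal(two_prop_z(10, 50, 10, 50)$statistic, 0)
})

test_that("welch test matches the formula and the reference implementation", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  w <- welch_t(a, b)
  o <- oracle_welch(a, b)
  expect_equal(w$statistic, o$t, tolerance = 1e-12)
  expect_equal(w$df, o$df, tolerance = 1e-12)
  ref <- t.test(a, b)
  expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  degenerate <- welch_t(c(1, 1, 1), c(2, 2, 2))
  expect_false(degenerate$defined)

  # large balanced samples converge to the pooled-variance Student test
  set.seed(9)
  x <- rnorm(5000); y <- rnorm(5000, 0.02)
  expect_lt(abs(welch_t(x, y)$p - t.test(x, y, var.equal = TRUE)$p.value),
            1e-6)
})

test_that("p-value adjustment reproduces the step formulas and ordering", {
  expect_equal(adjust_p(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_p(c(0.01, 0.02, 0.03), "bonferroni"),
               c(0.03, 0.06, 0.09))
  expect_equal(adjust_p(c(0.01, 0.02, 0.03), "bh_fdr"), c(0.03, 0.03, 0.03))
  set.seed(10)
  p <- runif(20)
  bon <- adjust_p(p, "bonferroni"); bh <- adjust_p(p, "bh_fdr")
  expect_true(all(bon >= bh - 1e-15))
  expect_true(all(bh >= min(p) - 1e-15))
  expect_error(adjust_p(c(0.5, 1.2)), "0, 1")
})

test_that("regression reports exact fits and a calibrated null", {
  x <- 1:10
  r <- simple_regression(x, 2 * x + 1)
  expect_equal(r$beta, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)
  # the published effect-size identity: R^2 = 0.0214 -> f^2 = 0.0220
  expect_lt(abs(0.0214 / (1 - 0.0214) - 0.0220), 5e-4)
  r2 <- simple_regression(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
  expect_equal(r2$f_squared, r2$r_squared / (1 - r2$r_squared))
  expect_error(simple_regression(rep(1, 5), rnorm(5)), "constant")

  # null p values are uniform
  set.seed(77)
  ps <- replicate(400, simple_regression(rnorm(12), rnorm(12))$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
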