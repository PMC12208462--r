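quick_cfg <- function(...) {
  mcmc_config(n_iter = 20000L, burn_in = 8000L, n_chains = 2L, ...)
}

test_that("log posterior matches closed forms", {
  cfg <- mcmc_config(alpha = 2, beta = 5)
  th <- c(0.3, 0.2, 0.25, 0.15, 0.1)
  # zero counts: the Beta prior alone
  prior <- sum((2 - 1) * log(th) + (5 - 1) * log(1 - th))
  expect_equal(log_posterior(th, rep(0, 5), cfg), prior, tolerance = 1e-12)
  # K = 2, flat prior: binomial log likelihood at the normalised vector
  flat <- mcmc_config(alpha = 1, beta = 1)
  th2 <- c(0.6, 0.2)
  p <- 0.6 / 0.8
  expect_equal(log_posterior(th2, c(3, 1), flat),
               3 * log(p) + 1 * log(1 - p), tolerance = 1e-12)
  # the likelihood term is invariant to the scale of theta
  expect_equal(log_posterior(c(0.2, 0.3), c(5, 7), flat),
               log_posterior(c(0.4, 0.6), c(5, 7), flat), tolerance = 1e-12)
  # components outside (0, 1) are rejected outright
  expect_identical(log_posterior(c(1.2, 0.3), c(1, 1), cfg), -Inf)
  expect_identical(log_posterior(c(0, 0.3), c(1, 1), cfg), -Inf)
})

test_that("flat-prior posterior means match the conjugate Dirichlet", {
  y <- c(A = 40, B = 30, C = 20, D = 10)
  post <- mh_sample(y, quick_cfg(alpha = 1, beta = 1, seed = 5))
  expect_lt(max(abs(post$mean - (y + 1) / sum(y + 1))), 0.01)
  expect_equal(sum(post$mean), 1, tolerance = 1e-9)
  # draws live on the simplex
  sums <- apply(post$draws, c(1, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("zero counts with a symmetric prior give uniform posterior means", {
  post <- suppressWarnings(mh_sample(setNames(rep(0, 4), c("B", "C", "D", "E")),
                                     quick_cfg(seed = 6)))
  expect_lt(max(abs(post$mean - 0.25)), 0.01)
})

test_that("acceptance rate stays in the expected band for typical counts", {
  for (tot in c(100, 1000, 10000)) {
    y <- sample_categorical_counts(c(0.35, 0.3, 0.2, 0.1, 0.05), tot,
                                   seed = tot)
    post <- suppressWarnings(mh_sample(y, quick_cfg(seed = tot + 1)))
    expect_gt(min(post$accept_rate), 0.05)
    expect_lt(max(post$accept_rate), 0.8)
  }
})

test_that("gelman-rubin diagnoses convergence and divergence", {
  set.seed(3)
  x <- rnorm(4000)
  perm <- cbind(x, sample(x), sample(x))
  expect_lt(abs(gelman_rubin(perm) - 1), 0.01)

  far <- cbind(rnorm(200, 0), rnorm(200, 10))
  # hand formula on the same arrays
  W <- mean(c(var(far[, 1]), var(far[, 2])))
  B <- 200 * var(colMeans(far))
  expect_equal(gelman_rubin(far), sqrt((199 / 200 * W + B / 200) / W),
               tolerance = 1e-12)
  expect_gt(gelman_rubin(far), 1.1)

  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)), "2 chains")
})

test_that("running mean traces are exact and stabilise for converged chains", {
  expect_equal(as.numeric(running_mean(c(1, 2, 3))), c(1, 1.5, 2))
  const <- running_mean(rep(0.4, 100))
  expect_equal(as.numeric(const), rep(0.4, 100))
  expect_lt(attr(const, "stability"), 1e-12)
  post <- mh_sample(c(B = 300, C = 250, D = 450), quick_cfg(seed = 11))
  rm1 <- running_mean(post$draws[, 3, 1])
  expect_lt(attr(rm1, "stability"), 0.005)
})

test_that("ordering probabilities match a conjugate closed form", {
  y <- c(B = 0, C = 40, D = 60, E = 0, X = 0)
  post <- mh_sample(y, mcmc_config(alpha = 1, beta = 1, n_iter = 60000L,
                                   burn_in = 20000L, n_chains = 2L, seed = 12))
  # flat prior: P(theta_D > theta_C) = P(Beta(61, 41) > 1/2)
  expect_lt(abs(ordering_probability(post, "D", "C") -
                  (1 - pbeta(0.5, 61, 41))), 0.01)
  expect_error(ordering_probability(post, "D", "Z"), "unknown label")
  # a posterior symmetric in B and E puts the ordering probability at 1/2
  sym <- mh_sample(c(B = 20, C = 30, D = 30, E = 20),
                   quick_cfg(alpha = 1, beta = 1, seed = 16))
  pij <- ordering_probability(sym, "B", "E")
  pji <- ordering_probability(sym, "E", "B")
  expect_equal(pij + pji, 1)
  expect_lt(abs(pij - 0.5), 0.02)
})

test_that("strategy classification follows the posterior ordering regions", {
  pos <- mh_sample(c(B = 10, C = 20, D = 60, E = 5, X = 5),
                   quick_cfg(seed = 13))
  call_pos <- classify_strategy(pos)
  expect_equal(call_pos$label, "position_coding")
  expect_equal(sum(call_pos$region_prob), 1, tolerance = 1e-12)

  ser <- mh_sample(c(B = 10, C = 60, D = 20, E = 5, X = 5),
                   quick_cfg(seed = 14))
  expect_equal(classify_strategy(ser)$label, "serial_inference")
})

test_that("aggregation pools counts and classifies sessions per group", {
  tbl <- tibble::tibble(
    session_id = rep(c("s1", "s2"), each = 5),
    subject_id = rep(c("mA", "mB"), each = 5),
    label = rep(c("B", "C", "D", "E", "X"), 2),
    count = c(5, 10, 40, 3, 2,   5, 40, 10, 3, 2)
  )
  cfg <- quick_cfg(seed = 15)
  agg <- aggregate_posteriors(tbl, grouping = "subject", cfg = cfg,
                              session_cfg = cfg)
  expect_setequal(names(agg$posteriors), c("mA", "mB"))
  calls <- agg$session_calls
  expect_equal(calls$label[calls$session_id == "s1"], "position_coding")
  expect_equal(calls$label[calls$session_id == "s2"], "serial_inference")
  props <- agg$strategy_proportions
  expect_equal(props$position_coding[props$group == "mA"], 1)
  expect_equal(props$serial_inference[props$group == "mB"], 1)

  # a single session pools to itself
  one <- aggregate_posteriors(tbl[tbl$session_id == "s1", ], cfg = cfg,
                              session_cfg = cfg)
  expect_equal(one$posteriors$pooled$mean,
               agg$posteriors$mA$mean, tolerance = 0.02)

  # sessions below the minimum event count are excluded and counted
  small <- tbl
  small$count[small$session_id == "s2"] <- c(1, 1, 1, 0, 0)
  agg2 <- aggregate_posteriors(small, cfg = cfg, session_cfg = cfg,
                               min_events = 5)
  expect_equal(agg2$n_excluded, 1)
  expect_equal(nrow(agg2$session_calls), 1)
})

test_that("second-position counts recount the conditioning events", {
  nxt <- c("D", "D", "C", "X", "E", "D")
  trials2 <- lapply(nxt, function(l) c("A", l))
  ch <- make_block(list(), trials2, block_id = "c1")
  counts <- second_position_counts(ch, trials = "all")
  expect_equal(counts$count[counts$label == "D"], 3L)
  expect_equal(counts$count[counts$label == "C"], 1L)
  expect_equal(counts$count[counts$label == "B"], 0L)
  expect_equal(sum(counts$count), 6L)
  expect_setequal(counts$label, c("B", "C", "D", "E", "X"))
})
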