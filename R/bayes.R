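## Bayesian estimation of the choice-probability vector at the second ordinal
## position in context 2: multinomial likelihood, Beta(alpha, beta) priors on
## the components, random-walk Metropolis-Hastings on the probability
## simplex, Gelman-Rubin diagnostics and posterior strategy classification.

#' Sampler configuration
#'
#' Defaults follow the analysis this package implements: Beta(2, 5) priors on
#' each component of the choice-probability vector, 200,000 iterations per
#' chain with the first 100,000 discarded as burn-in, a Gaussian random-walk
#' step of 0.05, four chains (the first initialised at the maximum-likelihood
#' estimate, the rest at dispersed draws from the prior), and no thinning.
#'
#' @param alpha,beta Beta prior shape parameters (> 0).
#' @param n_iter Iterations per chain.
#' @param burn_in Burn-in iterations discarded per chain (< `n_iter`).
#' @param step Random-walk proposal scale (> 0).
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param seed Optional integer seed.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(alpha = 2, beta = 5, n_iter = 200000L,
                        burn_in = 100000L, step = 0.05, n_chains = 4L,
                        seed = NULL) {
  stopifnot(alpha > 0, beta > 0, n_iter >= 1, burn_in >= 0, burn_in < n_iter,
            step > 0, n_chains >= 1)
  structure(list(alpha = alpha, beta = beta, n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), step = step,
                 n_chains = as.integer(n_chains), seed = seed),
            class = "mcmc_config")
}

#' Unnormalised log posterior of the choice-probability vector
#'
#' Multinomial log likelihood evaluated at `theta / sum(theta)` (the
#' likelihood is invariant to the scale of `theta`) plus independent
#' Beta(`alpha`, `beta`) log prior densities on the raw components. Any
#' component outside the open interval (0, 1) yields `-Inf`, so such
#' proposals are always rejected.
#'
#' @param theta Positive vector of K components in (0, 1).
#' @param counts Non-negative count vector of length K.
#' @param cfg An [mcmc_config()] (only `alpha` and `beta` are used).
#' @return Unnormalised log posterior density (scalar).
#' @export
log_posterior <- function(theta, counts, cfg = mcmc_config()) {
  stopifnot(length(theta) == length(counts), all(counts >= 0))
  if (any(theta <= 0) || any(theta >= 1)) return(-Inf)
  phi <- theta / sum(theta)
  sum(counts * log(phi)) +
    sum((cfg$alpha - 1) * log(theta) + (cfg$beta - 1) * log1p(-theta))
}

## vectorised log posterior over chains: th is K x C, columns on the simplex
log_post_cols <- function(th, counts, alpha, beta) {
  colSums(counts * log(th)) +
    colSums((alpha - 1) * log(th) + (beta - 1) * log1p(-th))
}

#' Metropolis-Hastings sampler for multinomial choice probabilities
#'
#' Random-walk Metropolis-Hastings on the probability simplex. Each
#' iteration proposes a Gaussian mass transfer of scale `cfg$step` between a
#' randomly chosen pair of components (a symmetric move that stays on the
#' simplex), rejecting proposals in which a component leaves (0, 1). The
#' first chain starts at the empirical-proportion maximum-likelihood
#' estimate (zero counts floored at 1e-3); the remaining chains start at
#' dispersed draws from the Beta(`alpha`, `beta`) prior, normalised. With
#' flat priors (`alpha = beta = 1`) the invariant distribution is exactly
#' Dirichlet(`counts + 1`), which anchors the conjugacy checks of the
#' sampler.
#'
#' @param counts Named non-negative count vector (length K >= 2).
#' @param cfg An [mcmc_config()].
#' @param labels Component labels; defaults to `names(counts)`.
#' @return Object of class `theta_posterior`: retained draws
#'   (`draws`: iterations x K x chains array on the simplex), posterior
#'   `mean` and 95% credible intervals, per-component Gelman-Rubin `rhat`,
#'   pairwise `ordering` probabilities P(theta_i > theta_j), per-chain
#'   acceptance rates, a thinned running-mean trace and the configuration.
#' @export
mh_sample <- function(counts, cfg = mcmc_config(), labels = names(counts)) {
  K <- length(counts)
  if (K < 2) stop("counts must have at least 2 components", call. = FALSE)
  stopifnot(all(counts >= 0))
  if (is.null(labels)) labels <- paste0("k", seq_len(K))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  C <- cfg$n_chains
  n_iter <- cfg$n_iter
  counts <- as.numeric(counts)

  theta <- matrix(NA_real_, K, C)
  mle <- pmax(counts / max(sum(counts), 1), 1e-3)
  theta[, 1] <- mle / sum(mle)
  if (C > 1) {
    for (c in 2:C) {
      d <- rbeta(K, cfg$alpha, cfg$beta)
      d <- pmax(d, 1e-6)
      theta[, c] <- d / sum(d)
    }
  }
  draws <- array(NA_real_, c(n_iter, K, C))
  accept <- numeric(C)
  a1 <- cfg$alpha - 1; b1 <- cfg$beta - 1
  pair_i <- sample.int(K, n_iter, replace = TRUE)
  pair_j_raw <- sample.int(K - 1L, n_iter, replace = TRUE)
  pair_j <- pair_j_raw + (pair_j_raw >= pair_i)
  for (it in seq_len(n_iter)) {
    i <- pair_i[it]; j <- pair_j[it]
    e <- rnorm(C, 0, cfg$step)
    ti <- theta[i, ]; tj <- theta[j, ]
    ti2 <- ti + e; tj2 <- tj - e
    ok <- ti2 > 0 & tj2 > 0
    dlp <- rep(-Inf, C)
    if (any(ok)) {
      dlp[ok] <-
        (counts[i] + a1) * (log(ti2[ok]) - log(ti[ok])) +
        (counts[j] + a1) * (log(tj2[ok]) - log(tj[ok])) +
        b1 * (log1p(-ti2[ok]) - log1p(-ti[ok]) +
                log1p(-tj2[ok]) - log1p(-tj[ok]))
    }
    acc <- log(runif(C)) < dlp
    if (any(acc)) {
      theta[i, acc] <- ti2[acc]
      theta[j, acc] <- tj2[acc]
      accept[acc] <- accept[acc] + 1
    }
    draws[it, , ] <- theta
  }
  accept <- accept / n_iter
  if (any(accept < 0.05 | accept > 0.8)) {
    warning(sprintf("MH acceptance rate outside (0.05, 0.8): %s",
                    paste(sprintf("%.3f", accept), collapse = ", ")),
            call. = FALSE)
  }

  keep <- (cfg$burn_in + 1L):n_iter
  retained <- draws[keep, , , drop = FALSE]
  pooled <- matrix(aperm(retained, c(1, 3, 2)), ncol = K)  # (iter*chain) x K
  post_mean <- colMeans(pooled)
  ci <- apply(pooled, 2, stats::quantile, probs = c(0.025, 0.975))
  rhat <- vapply(seq_len(K), function(k) {
    gelman_rubin(retained[, k, , drop = TRUE])
  }, numeric(1))
  ordering <- matrix(NA_real_, K, K, dimnames = list(labels, labels))
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (i != j) ordering[i, j] <- mean(pooled[, i] > pooled[, j])
    }
  }
  thin <- max(1L, n_iter %/% 2000L)
  trace_idx <- seq(thin, n_iter, by = thin)
  run_trace <- array(NA_real_, c(length(trace_idx), K, C))
  for (c in seq_len(C)) {
    cm <- apply(draws[, , c, drop = FALSE], 2, cumsum) / seq_len(n_iter)
    run_trace[, , c] <- cm[trace_idx, ]
  }

  structure(list(
    draws = retained, labels = labels,
    mean = setNames(post_mean, labels),
    ci_lower = setNames(ci[1, ], labels), ci_upper = setNames(ci[2, ], labels),
    rhat = setNames(rhat, labels), ordering = ordering,
    accept_rate = accept, counts = setNames(counts, labels),
    running_mean_trace = run_trace, trace_iterations = trace_idx,
    config = cfg
  ), class = "theta_posterior")
}

#' @export
print.theta_posterior <- function(x, ...) {
  cat("<theta_posterior>\n")
  tab <- data.frame(mean = round(x$mean, 4),
                    `2.5%` = round(x$ci_lower, 4),
                    `97.5%` = round(x$ci_upper, 4),
                    rhat = round(x$rhat, 4), check.names = FALSE)
  print(tab)
  cat(sprintf("chains: %d, retained draws/chain: %d, acceptance: %s\n",
              dim(x$draws)[3], dim(x$draws)[1],
              paste(sprintf("%.2f", x$accept_rate), collapse = " ")))
  invisible(x)
}

#' Gelman-Rubin potential-scale-reduction statistic
#'
#' Standard between/within-chain variance estimate of R-hat for one scalar
#' quantity from two or more parallel chains; values near 1 indicate
#' convergence and values below 1.1 are conventionally considered
#' satisfactory.
#'
#' @param chains Matrix of draws (iterations x chains), or a list of equal-
#'   length numeric vectors.
#' @return R-hat (scalar).
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  m <- ncol(chains); n <- nrow(chains)
  if (m < 2) stop("gelman_rubin() needs at least 2 chains", call. = FALSE)
  if (n < 10) stop("gelman_rubin() needs at least 10 draws per chain",
                   call. = FALSE)
  W <- mean(apply(chains, 2, var))
  B <- n * var(colMeans(chains))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Running mean of a chain
#'
#' Cumulative mean per iteration, with a stability metric: the maximum
#' absolute change of the running mean over the final 10% of iterations
#' (small values indicate a stabilised chain).
#'
#' @param x Numeric vector of draws from one chain.
#' @return Numeric vector of cumulative means with attribute `"stability"`.
#' @export
running_mean <- function(x) {
  stopifnot(length(x) > 0)
  rm <- cumsum(x) / seq_along(x)
  tail_idx <- seq(max(1L, ceiling(0.9 * length(x))), length(x))
  stab <- if (length(tail_idx) > 1) diff(range(rm[tail_idx])) else 0
  attr(rm, "stability") <- stab
  rm
}

#' Posterior ordering probability
#'
#' Fraction of retained draws (pooled across chains) in which component `i`
#' exceeds component `j`.
#'
#' @param posterior A [mh_sample()] result.
#' @param i,j Component labels.
#' @return Probability in \[0, 1\].
#' @export
ordering_probability <- function(posterior, i, j) {
  stopifnot(inherits(posterior, "theta_posterior"))
  ki <- match(i, posterior$labels); kj <- match(j, posterior$labels)
  if (is.na(ki) || is.na(kj)) {
    stop("unknown label: ", paste(c(i, j)[is.na(c(ki, kj))], collapse = ", "),
         call. = FALSE)
  }
  mean(posterior$draws[, ki, ] > posterior$draws[, kj, ])
}

#' Classify the choice strategy from a posterior
#'
#' Partitions the posterior over the second-position choice probabilities
#' into three ordering regions: position coding (swapping), where
#' `P(D) > P(B)` and `P(D) > P(C)`; serial inference, where `P(C) > P(B)`
#' and `P(C) > P(D)`; and everything else. The strategy call is the region
#' with the largest posterior mass (ties go to `other`).
#'
#' @param posterior A [mh_sample()] result containing components B, C and D.
#' @return List of class `strategy_call`: `label` and the three
#'   `region_prob` values (summing to 1).
#' @export
classify_strategy <- function(posterior) {
  stopifnot(inherits(posterior, "theta_posterior"))
  need <- c("B", "C", "D")
  if (!all(need %in% posterior$labels)) {
    stop("posterior must contain components B, C and D", call. = FALSE)
  }
  idx <- match(need, posterior$labels)
  b <- posterior$draws[, idx[1], ]
  c_ <- posterior$draws[, idx[2], ]
  d <- posterior$draws[, idx[3], ]
  p_pos <- mean(d > b & d > c_)
  p_ser <- mean(c_ > b & c_ > d)
  p_other <- 1 - p_pos - p_ser
  probs <- c(position_coding = p_pos, serial_inference = p_ser,
             other = p_other)
  top <- which(probs == max(probs))
  label <- if (length(top) > 1) "other" else names(probs)[top]
  structure(list(label = label, region_prob = probs), class = "strategy_call")
}

#' Aggregate posteriors and strategy calls over sessions
#'
#' Pools per-session choice counts (grouped per subject or over all sessions)
#' and runs the sampler on the pooled counts; in addition, each session with
#' at least `min_events` conditioning events is classified individually and
#' the per-group proportions of strategy labels are reported. Sessions below
#' the minimum are excluded and counted.
#'
#' @param counts Tibble with columns `session_id`, `label`, `count` and,
#'   for `grouping = "subject"`, `subject_id` (as produced by
#'   [second_position_counts()] or [simulate_strategy_counts()]).
#' @param grouping `"pooled"` or `"subject"`.
#' @param cfg An [mcmc_config()] used for every sampler run.
#' @param min_events Minimum total events for a session to be classified.
#' @param session_cfg Optional lighter [mcmc_config()] for the per-session
#'   runs (defaults to `cfg`).
#' @return List of class `aggregate_posterior`: `posteriors` (per group),
#'   `session_calls` (tibble with one row per valid session),
#'   `strategy_proportions` (per group), and `n_excluded`.
#' @export
aggregate_posteriors <- function(counts, grouping = c("pooled", "subject"),
                                 cfg = mcmc_config(), min_events = 5L,
                                 session_cfg = NULL) {
  grouping <- match.arg(grouping)
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("session_id", "label", "count") %in% names(counts)))
  if (grouping == "subject" && !"subject_id" %in% names(counts)) {
    stop("grouping = \"subject\" needs a subject_id column", call. = FALSE)
  }
  if (is.null(session_cfg)) session_cfg <- cfg
  counts$group <- if (grouping == "pooled") "pooled" else counts$subject_id

  totals <- dplyr::summarise(dplyr::group_by(counts, .data$session_id),
                             total = sum(.data$count), .groups = "drop")
  valid <- totals$session_id[totals$total >= min_events]
  n_excluded <- sum(totals$total < min_events)
  if (length(valid) == 0) {
    message("aggregate_posteriors: no session meets the minimum event count")
    return(structure(list(posteriors = list(), session_calls = NULL,
                          strategy_proportions = NULL,
                          n_excluded = n_excluded),
                     class = "aggregate_posterior"))
  }
  keep <- counts[counts$session_id %in% valid, ]

  to_vec <- function(df) {
    v <- tapply(df$count, df$label, sum)
    v[is.na(v)] <- 0
    v
  }
  posteriors <- lapply(split(keep, keep$group), function(df) {
    mh_sample(to_vec(df), cfg)
  })

  calls <- lapply(split(keep, keep$session_id), function(df) {
    post <- mh_sample(to_vec(df), session_cfg)
    call <- classify_strategy(post)
    tibble::tibble(session_id = df$session_id[1], group = df$group[1],
                   label = call$label,
                   p_position_coding = call$region_prob[["position_coding"]],
                   p_serial_inference = call$region_prob[["serial_inference"]],
                   p_other = call$region_prob[["other"]])
  })
  session_calls <- dplyr::bind_rows(calls)
  props <- dplyr::summarise(
    dplyr::group_by(session_calls, .data$group),
    n_sessions = dplyr::n(),
    position_coding = mean(.data$label == "position_coding"),
    serial_inference = mean(.data$label == "serial_inference"),
    other = mean(.data$label == "other"),
    .groups = "drop"
  )
  structure(list(posteriors = posteriors, session_calls = session_calls,
                 strategy_proportions = props, n_excluded = n_excluded),
            class = "aggregate_posterior")
}
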