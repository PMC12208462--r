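---
title: "Methods: sequence learning, context-cued reordering, and Bayesian strategy inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence learning, context-cued reordering, and Bayesian strategy inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqswap)
```

## The task and what the package measures

`seqswap` analyses serial-order learning tasks in which a subject must touch
five objects (labelled A--E by their serial role, plus a sixth distractor X)
in a fixed order. Each sequence pair comprises 15 trials of A-B-C-D-E on one
background ("context 1") followed by 15 trials of the same objects on a new
background ("context 2"), where the non-adjacent items B and D swap ordinal
positions, giving the required order A-D-C-B-E. A trial allows at most 15
touches and at most 10 erroneous touches; after any error the subject must
re-touch the last correctly chosen object before searching on.

The scientific question is *how* subjects adjust at the context switch.
Two strategies leave distinct fingerprints in the choice made at the second
ordinal position, immediately after a correct choice of A:

* **positional re-indexing (position coding)** — the subject represents an
  abstract sequence of ordinal slots and re-assigns object D to slot 2:
  it proactively chooses D;
* **serial inference (chaining)** — the subject represents item-to-item
  links and, knowing B is no longer correct, slides to the next item in the
  chain: it chooses C.

Two summary indices quantify this. With `P(L | E)` the probability that
object `L` is the next free search choice after conditioning event `E`
(forced retouches are skipped):

* pro-active swap index = `P(D | correct A) - P(B | correct A)`;
* retro-active swap index = `P(D | error on B) - P(C | error on B)`.

Both lie in [-1, 1]; positive values indicate re-indexing.

## The generative simulator

No behavioural data ship with the package, so a generative agent stands in
for the animals. The agent is deliberately simple — the empirical study
describes behaviour, not a mechanism — but its parameters mirror the two
observed strategies so that recovery tests are interpretable.

**Value learning.** The agent maintains a value matrix `V[object, position]`
(6 x 5, initialised at 0). At ordinal position `p` it chooses among the
objects not yet secured this trial with softmax probability
`exp(V/tau)`, temperature `tau`, and updates
`V[chosen, p] <- V[chosen, p] + eta * (r - V[chosen, p])` with reward `r` of
1 or 0. An erroneous (object, position) pair is excluded for the remainder
of the trial — the forced-retouch design makes error feedback unambiguous,
and trained subjects essentially never repeat the same error within a trial.

**The context switch.** On each context-2 trial the agent draws a strategy:
positional re-indexing with probability `w_position` (it uses `V` with the
B and D rows swapped), serial chaining with probability `w_serial` (values
shifted one ordinal position leftward from position 2 on, so C is expected
at position 2), otherwise carryover (the stale context-1 values, which
reproduce the characteristic erroneous B choice). After every error the
strategy is re-drawn for the rest of the trial; this is what produces
retro-active re-indexing in response to error feedback, and it makes the
retro-active index track `w_position` the way the pro-active index does.

**Distractor.** X resembles object B, so its effective value at position
`p` is its own value plus `distractor_confusability` times the effective
value of B at `p`. Once the sequence is learned this concentrates
distractor choices at the position where B is expected — position 2 in
context 1 and position 4 in context 2.

**Sessions.** A session is `blocks_per_session` sequence pairs: the first
half new (`new_early`), then 120 delayed match-to-sample (DMTS) trials,
then the late half, of which `repeat_fraction` repeat early pairs (their
starting values are the early block's learned values scaled by
`retention`, plus `context_bonus` when the background is the same) and the
rest are new (`new_late`).

**DMTS.** Correctness is Bernoulli with accuracy
`1/3 + (0.95 - 1/3) * wm_ability * similarity_factor`, with similarity
factors 0.99 (low) and 0.37 (high). At `wm_ability = 0.6` this places
accuracy near 0.70 and 0.47 in the two conditions, the observed operating
point of trained macaques; accuracy does not depend on the delay, matching
the reported null effect of delay. `wm_ability` also drives `w_position`
under the default linear coupling `0.05 + 0.6 * wm_ability` — the study
reports a positive session-level correlation between working memory and
pro-active swapping but no functional form, so the coupling is a modelling
choice exposed in the parameters.

**Calibration.** Defaults were fixed once against the study's headline
descriptive statistics: learning rate 0.12, temperature 0.4, lapse 0.08 and
`w_serial` 0.3 give a context-1 criterion near 5--7 trials (reported: 6.6),
late-trial ordinal accuracies between roughly 0.5 and 0.85, and a
post-error transition split favouring D over C of about 0.5 versus 0.3
(reported: 0.45 versus 0.36). The simulated agents adjust to context 2
faster than the animals did (criterion at trial 1--2 versus 3.4), because
per-trial strategy draws resolve the swap quickly; analyses that need early
context-2 behaviour therefore support explicit trial filters (e.g.
`trials = 1:3`) in addition to the default pre-criterion pool.

What the generator does *not* emulate: reaction-time structure beyond
i.i.d. log-normal draws, motivational drift within a session, spatial
choice biases, and any dependence between the distractor and objects other
than B. Passing recovery tests therefore show that the analysis pipeline
measures what it claims on data with the assumed structure — not that real
animals satisfy those assumptions.

## Learning metrics

* **Completion curve** — the proportion of blocks completing the full
  sequence on trial *t*. The learning criterion is the first trial with
  completion at or above 0.8 sustained for the next three trials,
  computed on the **raw** per-trial proportions. A four-parameter logistic
  (asymptotes bounded in [0, 1], bounded Levenberg-Marquardt, three starts)
  is fitted as a descriptive summary only; using the fit for the criterion
  would make the criterion depend on fit convergence.
* **Per-block criterion** — applied to a block's own binary completion
  sequence; "pre-criterion trials" for the transition analyses are trials
  strictly before that trial, with censored blocks contributing all 15.
* **Ordinal accuracy** — the proportion of *first* search attempts at each
  position that were correct, pooled over trials 12--15 by default. The
  forward-looking chance level `1/(7 - p)` assumes secured objects are not
  re-chosen; at position 1 it equals the absolute chance level 1/6.
* **Error taxonomy** — every erroneous touch is exactly one of
  rule-breaking (failed retouch or re-selection of a secured object),
  perseverative (repeat of the last pre-retouch error), distractor (chose
  X), or exploration (any other not-yet-secured object). The definitions
  overlap (a repeated distractor touch is both perseverative and
  distractor), so a fixed precedence resolves them:
  rule_breaking > perseverative > distractor > exploration. "Not yet
  learned" is operationalised as not yet correctly chosen in the current
  trial. Per-trial error-type proportions are fitted with
  `a * exp(-b * x) + c`; `b` is reported even when non-positive, and for a
  constant curve the identifiable statement of "no decay" is `a ~ 0`
  (with `a ~ 0` the speed `b` is unidentifiable).

## Transition statistics

Transition tables condition on one of three events in context 2 — a correct
A at position 1, an erroneous B at position 2, or a correct D at position 2
— and tabulate the next free search choice. Forced retouches are *not*
transition targets: after an error the subject must re-touch the last
correct object, so counting it would place nearly all post-error mass on A,
which is incompatible with the near-zero observed post-error probability of
A. Binomial CIs use the normal approximation with a Wilson fallback below
5 counts. Welch's t test (with Welch-Satterthwaite degrees of freedom) is
the default two-sample comparison; fixed label contrasts use Bonferroni
correction and the first-choice analyses use Benjamini-Hochberg FDR,
matching each analysis's stated usage. The first-choice analyses condition
on the trial opening with a correct A and compare the last context-1 trial
with the first context-2 trial, before any feedback about the swap.

## Bayesian strategy inference

Counts `y = (y_B, y_C, y_D, y_E, y_X)` of the choice following a correct A
(pooled over pre-criterion context-2 trials; rare re-selections of A are
dropped) are modelled with a multinomial likelihood governed by
`theta = (theta_B, ..., theta_X)` and independent Beta(`alpha = 2`,
`beta = 5`) priors on the components.

**Sampler.** Random-walk Metropolis-Hastings on the probability simplex:
each iteration transfers `e ~ N(0, 0.05^2)` between one randomly chosen
pair of components, rejecting moves that push a component out of (0, 1).
This move is symmetric and keeps the draws exactly on the simplex, so with
flat priors the invariant distribution is exactly Dirichlet(`y + 1`) — the
anchor for the package's conjugacy checks. A joint perturbation of all
components at the same scale was rejected during development: its
acceptance rate collapses to ~0 on counts of total 10,000 and the chains
fail to converge, whereas the pairwise move accepts at ~0.5 / 0.2 / 0.05
for totals of 100 / 1,000 / 10,000 (acceptance is logged and a warning is
emitted outside (0.05, 0.8)). Four chains run 200,000 iterations with the
first 100,000 discarded and no thinning; chain 1 starts at the
empirical-proportion MLE (zero counts floored at 1e-3) and the others at
normalised draws from the prior, giving dispersed starting points.

**Diagnostics.** Per-component Gelman-Rubin R-hat from the post-burn-in
draws (values below 1.1 taken as satisfactory convergence, below 1.05
typical here) and running-mean traces with a stability metric (maximum
drift over the final 10% of iterations).

**Strategy calls.** The posterior mass of the ordering regions
`{theta_D > theta_B and theta_D > theta_C}` (position coding) and
`{theta_C > theta_B and theta_C > theta_D}` (serial inference) is computed
from the pooled retained draws; the remaining mass is `other`, and the call
is the region with the largest mass (ties go to `other`). Sessions
contribute individually when they have at least 5 conditioning events —
the minimum is a package convention, since "valid session" is not defined
quantitatively in the source analyses — and group-level posteriors pool
counts across sessions (no hyperparameters are estimated; pooling by count
aggregation is the only hierarchy).

## Session-level analyses

Condition comparisons (new-early / repeat / new-late criterion speed and
swap indices, pairwise Welch with Bonferroni), proficiency terciles and
regressions of swap indices on context-1 completion, across-session trends
(one-sample Student's t against zero plus OLS on session number with
Cohen's `f^2 = R^2 / (1 - R^2)`), DMTS correlations (pooled and per-subject
OLS, plus a random-intercept linear mixed model fitted by `lmerTest`, of
which only the slope and p value are reported — mixed modelling is
delegated, not reimplemented), and same- versus different-background
contrasts for repeats (completion gain is the repeat block's completion
rate minus its matched early block's, paired by block identity).

## Numerical choices and degenerate inputs

* Proportion CIs: normal approximation, Wilson below 5 counts.
* Welch test on samples with fewer than 2 values or two zero variances:
  flagged undefined (`NA`), never an error.
* Regression with a constant predictor: a clean error; perfect fits report
  `f^2 = Inf` with p = 0.
* Sigmoid and decay fits: bounded Levenberg-Marquardt with three starting
  points; non-convergence returns the best iterate with
  `converged = FALSE`.
* Criterion scans are invariant to trials appended after a satisfied
  criterion; censored results are explicit, never coerced to a number.
* Ties in the proficiency terciles break deterministically by block id.
* All simulation is driven by a single seeded RNG stream; identical seeds
  give byte-identical choice logs and reports.

## Problem sizes used by the test suite

Unit tests run on handcrafted fixtures and small simulated logs (tens of
blocks). The quantitative end-to-end checks use: 10,000 Monte-Carlo first
attempts for the chance level; one full-default sampler run each on counts
of 1,000 and 10,000; 20 flat-prior sampler runs at full defaults for the
conjugacy oracle (totals 100--10,000), with batch-means Monte-Carlo
standard errors; 200 synthetic sessions of 150 events per strategy for
classification recovery (dominant component 0.42 versus 0.22, comfortably
inside its ordering region relative to multinomial noise at that size); and
200 replicates per generator knob for the sign tests, with sessions scaled
to 3--8 blocks so each replicate isolates the knob's effect.

## Known limitations

* The agent's strategy mixture is an idealisation; real animals likely
  blend strategies within a trial and drift across sessions.
* The pre-criterion pool can be small when a block adjusts to context 2
  within a trial or two, which the simulated agents often do; early-trial
  filters are provided for that case.
* The per-session classification at reduced iteration counts trades
  Monte-Carlo precision for runtime; calls near a region boundary should
  be re-run at full settings.
* The mixed-model adjunct can be singular for small designs; it is
  reported only when the fit succeeds.
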