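---
title: "Cancer-topic survival models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cancer-topic survival models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survtopics)
```

## The problem

Bulk expression cohorts pair tens of thousands of probe or gene measurements
with right-censored survival labels for at most a few thousand patients.
Fitting a survival model directly on the expression matrix overfits badly, so
the practical question is how to compress the expression profile into a
handful of features that still carry prognostic signal. This package
implements a topic-modelling answer: treat each patient as a "document" whose
"words" are discretized deviations of gene expression from the cohort norm,
summarize the cohort by a small set of *cancer topics* (distributions over
those gene-words), and describe each patient by their topic mixture. Those
few loadings — optionally together with clinical covariates and supervised
principal components — feed a survival learner: multi-task logistic
regression (MTLR), which outputs a full individual survival distribution, or
a (ridge) Cox model.

## Preprocessing

Clinical features are mean-imputed (numeric) or mode-imputed then one-hot
encoded with one column per observed level (categorical). Expression values
are optionally `log2`-transformed and then standardized with a **single
global** mean and standard deviation over all `n x p` entries (denominator
`np - 1`). The global transform matters: a per-gene z-score would equalize
every gene's spread and make the next step vacuous. A gene whose z-scores
all sit inside the closed band `[-1, 1]` never deviates meaningfully from
the cohort norm and is removed. All of this state (mean, sd, retained genes,
imputation values, level orders, bin edges) is kept in a `preprocess_state`
so a novel patient is transformed with the *training* statistics,
deterministically. A categorical level never seen in training encodes as an
all-zero block, with a warning — there is no trained column it could light up.

## Discretization and encodings

For each retained gene, the non-trivial positive z-scores (`z >= 1`) span a
range that is cut into ten equal-width bins; values in `(-1, 1)` map to bin
0 and the negative side mirrors the positive one, giving integer dGEVs in
`{-10, ..., 10}`. The bin rule is
`bin = min(10, 1 + floor((z - min+) / (delta+/10)))`, so the top edge is
inclusive; at prediction time values outside the training range clamp to the
extreme bins (bin 10 above, bin 1 below the training minimum — the training
range simply did not cover them, and clamping is the only monotone choice
that needs no new state). A side with a single training value has width zero
and maps to bin 1.

Topic models need non-negative counts. Two encodings are supported:
`enc_a` uses one word per gene with count `|b|` (magnitude only), and
`enc_b` uses two words per gene — `OVER-<gene>` and `UNDER-<gene>` — so +2
becomes (2, 0) and -3 becomes (0, 3). `enc_b` preserves the direction of
deviation at the cost of doubling the vocabulary; which one wins is an
empirical question answered by cross-validation.

## The topic model

Topics are fitted by batch variational EM for latent Dirichlet allocation:
mean-field factors `q(theta) = Dirichlet(gamma)` per patient and implicit
word-assignment factors. The document-topic prior is symmetric
`Dirichlet(alpha)` with `alpha = 0.1` initially and re-estimated during EM by
Newton updates on the bound. Two numerical points deserve note:

* **Prior estimation is delayed** (default: from EM iteration 10). Early in
  the fit the topics are still near-symmetric, the mixture weights carry no
  information, and the maximum-likelihood `alpha` runs off to infinity —
  which then freezes the model at the uniform saddle point. Estimating the
  prior only after the topics have started to separate (and capping it to a
  plausible range) avoids this failure mode entirely.
* **E-steps are warm-started and partial.** After the first EM iteration the
  per-patient `gamma` from the previous iteration seeds the next E-step,
  which is capped at a small number of coordinate updates. Every update
  increases the bound, so the procedure is a monotone generalized EM; the
  recorded `bound_trace` is non-decreasing (this is asserted in the tests).
  The M-step adds a small pseudocount (`beta_smooth = 0.01`) so no word has
  probability exactly zero; the tracked bound includes the matching
  log-prior term.

Patient loadings are, by default, the normalized posterior proportions
`gamma / sum(gamma)` — scale-free features for the downstream learners; the
raw Dirichlet parameters are available with `raw = TRUE`. An empty document
(every dGEV zero) has posterior equal to the prior: uniform proportions.
Held-out corpora are scored by the mean per-document variational bound, the
tractable stand-in for held-out log-likelihood. For a single topic the
variational family is exact (a one-word document under a uniform basis
scores exactly `-log V`); for more topics the bound sits strictly below the
exact likelihood.

## Choosing the encoding and the topic count

`select_basis()` runs the full grid — encodings crossed with candidate topic
counts, default `K in {5, 10, ..., 150}` — under event-stratified five-fold
cross-validation. Per fold it fits the topic model on 4/5 of the patients,
projects the held-out fifth, fits a Cox model on loadings plus clinical
features, and records held-out concordance and the held-out per-document
bound. The encoding with the best mean concordance anywhere on the grid
wins. For the topic count, the likelihood-best `K_hat` defines a candidate
set — every `K <= K_hat` whose mean likelihood is within one standard
deviation of `K_hat`'s — and the chosen `K*` is the **smallest candidate
whose concordance is within one standard error of the best candidate's**.
The softened rule is deliberate: in our simulations the concordance
differences between the true topic count and larger ones are an order of
magnitude smaller than fold-to-fold noise, so a strict argmax flips between
neighbouring `K` by chance, while "essentially as good, prefer parsimony"
recovers the planted count reliably. Singleton grids skip the search.

## Survival learners

**Cox.** The log partial likelihood (Breslow convention for tied event
times; a patient is at risk at their own event time) is maximized by Newton
iterations with step halving from `w = 0`, optionally with an L2 penalty
`lambda * ||w||^2`, to a gradient norm below 1e-8. One-hot blocks that
encode every level, and topic loadings that sum to one, make the information
matrix rank-deficient along directions the likelihood is flat in; the Newton
step uses the eigen-pseudo-inverse, which is the minimum-norm step and is
well defined because the gradient has no component along flat directions. A
monotone (separable) likelihood at `lambda = 0` is detected and reported as
an error advising regularization. Survival curves come from the
Kalbfleisch-Prentice baseline: at each distinct event time the survival
factor solves the KP estimating equation (closed form for a single event,
root-finding under ties), which reduces exactly to Kaplan-Meier at `w = 0`.

**Ridge Cox** is the same machinery with the penalty weight chosen by
internal cross-validation on concordance (default grid 0.01-10).

**MTLR.** A time grid of `m = floor(sqrt(n))` points sits at evenly spaced
quantiles of the observed times (deduplicated). The model keeps one logistic
weight vector per grid point; the probability of death in interval `k` is
proportional to `exp(sum of the scores from k+1 to m)`. For a patient
censored at `c`, the likelihood term marginalizes exactly over every label
vector consistent with death after `c` — computed with the same
cumulative-score trick as the partition function, so censoring costs
nothing extra. The objective (L2 penalty on the weights, biases free) is
convex; it is minimized by BFGS with the analytic gradient from `W = 0`,
and seeded random restarts reach the same optimum to 1e-6 (tested). The
regularization weight `C` comes from internal cross-validation on
concordance (default grid 0.01-10).

**Curves and risks.** An MTLR curve starts at exactly 1 at `t = 0` and
steps down by the interval PMF at each grid point. The final interval
`[t_m, Inf)` holds whatever mass remains — typically 5-15% under a
quantile grid — and the emitted curve releases it linearly over one further
mean grid spacing, ending at 0. This keeps the curve a complete
distribution: predicted probabilities at observed death times can be read
off (and inverted) exactly, which is what makes the calibration null below
hold by construction rather than approximately. Beyond the terminal point
the curve is held. The risk score is the negative trapezoidal area under
the curve — the negative expected survival time — so every learner,
including Cox through its KP baseline, yields both a curve and a risk.

## Evaluation

**Concordance** is the fraction of comparable ordered pairs ranked
correctly by risk: both patients uncensored with different times, or the
earlier patient uncensored and the later one censored afterwards. The
indicator is strict — tied risks score zero — with an optional
half-credit flag for comparison with other software.

**D-calibration** asks whether predicted survival probabilities at observed
death times are uniform. Each uncensored patient's `P(D >= d_i)` is read
off their own curve and binned into `G = 20` equal-width bins; the
Hosmer-Lemeshow statistic compares observed counts `E_g` with the expected
`N/G`:

$$\mathrm{HL} = \sum_{g=1}^{G} \frac{(E_g - N/G)^2}{N \pi_g (1 - \pi_g)},
\qquad \pi_g = 1/G,$$

referred to a chi-square with `G - 2` degrees of freedom. The denominator
uses the total count `N` times the binomial variance factor: that is the
reading under which the statistic actually follows the stated chi-square
distribution (each bin count is Binomial(`N`, `1/G`) under the null), and
the only one consistent with published values of the statistic at these
degrees of freedom. Censored patients are excluded; censoring-aware
variants are out of scope.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the method assumes,
so every stage is testable without external cohorts. Each of `k_true = 3`
planted topics concentrates 90% of its mass on its own signature of 20
over-/under-expression gene-words (mild Zipf weights within the signature);
patients draw topic mixtures from `Dirichlet(0.3)` and a Poisson(50) number
of gene-words from the mixture. The counts are inverted through the
encoding and binning into z-like values (uniform jitter within a synthetic
bin geometry spanning `|z|` in 1-4, Gaussian noise inside the trivial band)
and de-standardized to a microarray-like range around 8. With these
defaults roughly 80-85% of entries fall inside the trivial band after
re-standardization, mimicking the skew of real cohorts where a substantial
minority of normalized values exceed one standard deviation. Survival times
are exponential with log-hazard `theta' w_true + clinical effects`
(`w_true = (-1.5, 0, 1.5)`, 0.02 per year of age, 0.1 for male sex);
censoring is an independent exponential whose rate is solved numerically so
the expected censored fraction hits the target (default 30%). A 5% missing
rate in the clinical table exercises imputation.

What the generator does *not* emulate: probe-level microarray noise,
count overdispersion, batch effects, or correlated gene modules beyond the
topic structure. Passing tests on these cohorts therefore demonstrate the
machinery — recovery of a planted low-dimensional structure and correct
propagation to calibrated survival predictions — not performance on any
real platform. One realistic distortion *is* retained: per-gene binning
stretches each gene's observed range to ten bins, so reconstructed counts
are per-gene rescalings of the planted ones. Topic recovery against the
planted distributions on the planted count corpus reaches a median matched
row-correlation above 0.9 across seeded runs (individual seeds vary);
through the full expression-inversion path the correlation is somewhat
lower, yet the topic-count selection still recovers `k_true` reliably.

`generate_mtlr_consistent()` samples death times from each patient's own
predicted curve by inverse-transform sampling, which makes the predicted
probabilities at those times uniform by construction — the null of the
calibration test. A fraction of patients can be censored uniformly before
their death to exercise the censored paths.

## Problem sizes and numerical defaults

The test-suite and acceptance computations run at the cohort sizes stated
above (n of 400-1000 patients, 200 genes, 3 topics, 5-fold selection over
small topic grids, 100 calibration replicates) — sizes at which every
property we assert is statistically comfortable on a single core. Key
numerical defaults, chosen once: EM stops at a relative bound change of
1e-6 (cap 200 iterations); per-document inference runs at most 100 updates
to a scaled tolerance of 1e-6; Newton stops at gradient norm 1e-8; BFGS at
machine-level relative tolerance with a 500-iteration cap; ties in the
mode imputation and in selection break toward the first level and the
smaller `K`, respectively. All stochastic steps — topic initialization,
fold assignment, cohort generation, consistent-label sampling — take
explicit integer seeds, and identical seeds reproduce results bit-for-bit,
including serialized bundles.

## Known limitations

* The variational bound is a biased stand-in for held-out likelihood and
  generally keeps improving with `K`; the selection therefore leans on the
  concordance arm (with the parsimony rule) rather than the likelihood arm
  for pinpointing the topic count.
* Cox curves end at the last training event time (the KP baseline is
  defined there); only MTLR curves carry an explicit terminal release.
* D-calibration ignores censored patients; on heavily censored cohorts the
  test loses power.
* The generator's hazard is exponential given covariates; no Weibull shape
  misspecification scenarios are built in.
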