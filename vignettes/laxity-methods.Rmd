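---
title: "Methods: paired-comparison scaling of facial skin laxity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-comparison scaling of facial skin laxity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laxipair)
```

`laxipair` quantifies facial skin laxity from three sources of evidence —
expert labels, consumer paired-comparison judgments, and noninvasive skin
physiological measurements — and fuses them into one latent index. This
vignette documents the statistical model behind each stage, the defaults
and why they were chosen, the design decisions that were genuinely open,
and what the package's synthetic validation does and does not establish.

## 1. The perception design

Evaluator sample size follows the classical one-sided discrimination
formula based on the normal approximation of the binomial: under no real
difference an evaluator picks the target with probability $p_0 = 0.5$;
if a proportion $p_d$ of evaluators truly discriminates, the correct-choice
probability is $p_1 = p_d + (1-p_d)/2$, and

$$n \approx \left( \frac{z_{1-\alpha}\sqrt{p_0(1-p_0)} +
z_{1-\beta}\sqrt{p_1(1-p_1)}}{p_1 - p_0} \right)^2 .$$

```{r}
minimum_evaluators(alpha = 0.05, beta = 0.5, pd = 0.20)
```

Two conventions matter here. First, quantiles default to their two-decimal
sensory-practice values ($z_{0.95} = 1.64$) so that the canonical worked
example (67.24, rounded up to 68) is reproduced digit for digit;
`exact_quantiles = TRUE` switches to full-precision `qnorm()`. Second,
$p_d = 0$ makes $p_1 = p_0$ and is rejected as a degenerate input rather
than returned as infinity.

The design itself is balanced: participants, expert-labeled "more" or
"less" facial skin laxity in equal numbers, are randomly divided into
groups (default 8 groups of 4 + 4); every cross-label pair within a group
is enumerated (16 per group) and presented twice with positions exchanged
(32 events per group, 256 in total). How the original study formed its
groups is not documented beyond "randomly divided"; the package uses
seeded uniform shuffling within each label class, the simplest scheme
satisfying the stated balance. The whole 256-event list is shuffled
globally, again seeded, which generalizes the idea of randomly disrupting
pair order across the presentation atlas.

## 2. Quantifying choices

Responses are positional (A/B). Each pair's two presentation orders are
pooled into a single count pair $(k_T, n)$ — equivalent to averaging the
two orders' proportions at equal response counts, and stated explicitly
because averaging *logits* instead would not be equivalent. The choice
probability is mapped to the log-odds scale:

$$\mathrm{Logit}(T) = \ln\frac{P_T}{1-P_T}.$$

Pairs with very large perceived differences are routinely unanimous, which
would give infinite logits. The default remedy is the Haldane-Anscombe
correction $P_T = (k_T + 1/2)/(n+1)$ applied **only** at the boundary
$k_T \in \{0, n\}$: interior pairs are untouched, boundary pairs stay
finite, and the correction is symmetric, preserving the antisymmetry
$\mathrm{Logit}(k, n) = -\mathrm{Logit}(n-k, n)$. Alternatives (`always`,
`clamp` with configurable $\varepsilon$) are available; `none` documents
the uncorrected divergence.

Per-pair significance uses the exact two-tailed binomial test on the
pooled counts. Whether the original analysis tested pooled (144-response)
or per-orientation (72-response) counts is not stated; pooled is the
default because pooling is also what the logit uses. No multiplicity
correction is applied across pairs, matching the reporting style of such
studies; a Bonferroni/BH adjustment can be applied to the returned
p-values with `p.adjust()` if desired.

Evaluator-expert concordance is Cohen's kappa per evaluator against the
expert key, summarized by a mean with a t-based 95% interval over the
evaluator sample (the interval construction is not documented in this
literature; the t interval is the standard choice at n = 72). Backgrounds
are compared with a two-tailed Mann-Whitney U test — exact for group
sizes below 8, normal approximation with tie correction otherwise, and a
fully tied comparison reports the test's maximal value 1.

## 3. Bradley-Terry scaling and the FSLI

The Bradley-Terry model gives each participant a positive worth $\pi_i$
with $P(i \text{ judged more lax than } j) = \pi_i/(\pi_i+\pi_j)$. The
package fits log-worths $s_i = \ln \pi_i$ by maximizing

$$\ell(s) = \sum_{i \neq j} w_{ij} \ln \frac{\pi_i}{\pi_i + \pi_j}
\;-\; \lambda \sum_i s_i^2,$$

where the effective wins $w_{ij}$ redistribute each pair's pooled count by
the sigmoid of its (corrected) logit — identical to the raw counts
whenever no correction fired, a deliberate property: the sigmoid-of-logit
route and the raw-count route are both implemented (`mode = "sigmoid"` /
`"counts"`) because the upstream literature describes the former without
stating whether corrected or raw logits entered it.

Numerical choices: damped Newton iteration on the full (at most
64-dimensional) system with step halving, which guarantees a
non-decreasing penalized log-likelihood; convergence at gradient max-norm
below $10^{-8}$; at most 1000 iterations, with a hard error (carrying the
last iterate's likelihood) beyond that. With $\lambda = 0$ the common
shift is removed by centering; with $\lambda > 0$ the optimum is
automatically mean-zero because the likelihood gradient sums to zero.
Tests verify the fitter against a closed form (two items) and a dense
two-stage grid search (three items) to $10^{-3}$ in probability space.

Two structural issues deserve emphasis:

* **Disconnected comparison graph.** Comparisons happen only within each
  8-person group, so the graph has one component per group and the
  likelihood alone cannot place the groups on a common scale. The ridge
  prior (default $\lambda = 0.01 \times$ the mean comparison count per
  item) anchors every component to the common zero mean. Cross-group FSLI
  differences are therefore comparable only through this prior — a
  documented limitation of the design, not of the fitter. Rank recovery
  across the whole cohort consequently tops out slightly below what a
  connected design would give.
* **Separation.** A participant judged more lax in every response (or
  less lax in every response) has an infinite unpenalized estimate. Such
  items are detected from the raw counts (zero losses or zero wins),
  reported in `separated_ids`, kept finite by the prior, and — under the
  default `separation = "drop"` policy, which mirrors how such
  participants are handled in practice — excluded from downstream
  regression. `"shrink"` retains them under the prior.

The FSLI itself is $\mathrm{offset} + \mathrm{scale}\cdot\ln\pi_i$ with
defaults (0, 1): the centered natural-log worth. The log base is absorbed
by `scale`; published FSLI values on other numeric ranges imply an
unstated affine convention, so the transform is exposed rather than
guessed.

## 4. Linking the index to skin physiology

Collinearity screening computes $\mathrm{VIF}_j = 1/(1-R_j^2)$ by
regressing each column on the others and iteratively removes the worst
column until all VIFs fall below 5. The Cutometer F3 and R5 readouts are
excluded a priori (they are near-duplicates of F4 and R2 by
construction); exactly collinear columns get an infinite VIF and ties
break alphabetically so the screen is deterministic.

The regression is an $\varepsilon$-insensitive support-vector regression
with **linear kernel** by default. The choice is deliberate: the
published relationship between the index and the parameters is described
as linear, and at cohort sizes of a few dozen a radial-basis kernel with
the conventional width $1/p$ markedly underfits (about half the
leave-one-out $R^2$ of the linear kernel across a cost/width sweep).
The radial kernel remains available (`kernel = "radial"`, `gamma`
configurable, default $1/p$). Remaining defaults: cost 1, $\varepsilon$
0.1 on the index scale.

Validation is leave-one-out, with feature standardization re-estimated
inside every training fold so the held-out row leaks nothing. The
reported $R^2 = 1 - SSE/SST$ is computed on the LOO predictions
(predictive $R^2$); the in-sample $R^2$ of the final model is reported
alongside because published "model accuracy" figures are ambiguous
between the two. Forward selection greedily minimizes LOO RMSE up to a
model-size cap (default 8, the size of the published composition) and
records the per-step RMSE path; stopping strictly at the first
non-improving step was rejected because single-step RMSE differences at
these sample sizes are noise-dominated. Expert apparent age (AA) stays in
the candidate pool — its exclusion, where warranted, is left to the
selection, which is also what happened in the reference study's own
composition.

## 5. Efficacy evaluation

Paired pre/post changes per endpoint use a Shapiro-Wilk gate on the
paired *differences* (the standard construction; gating on raw visit
values was rejected as nonstandard): paired t-test when the differences
are compatible with normality at $\alpha_{normality} = 0.05$, Wilcoxon
signed-rank otherwise, both two-tailed. Zero differences are dropped by
the signed-rank convention; an all-zero endpoint returns a flagged
degenerate result with $p = 1$. No multiplicity correction is applied
across the nine default endpoints, matching reporting practice. Star
annotations are a pure function of $p$ at 0.05 / 0.01 / 0.001.
Improvement directions are endpoint-specific: wrinkle volumes, the F4
suction area and the FSLI improve downward; elasticity (R2, Q1), collagen
(CC2) and epidermal thickness (ET) improve upward.

## 6. The synthetic generator

The generator emulates the reference geometry end to end: 64
participants in 8 groups, 72 evaluators (half professional, half lay), a
15-subject paired efficacy study, and per-parameter marginals anchored to
the published 142-subject distribution table.

Its trait model is hierarchical. Each of the eight signal parameters
(CC2, F4, Q1, R2, UEW_V, ML_V, NF_V, ET) has its own standard-normal
aging component $u_p$, measured by the instrument at reliability
$\alpha = 0.95$; the latent laxity trait aggregates the signed components
(weight 0.95) plus an age axis (weight 0.3, age drawn uniformly on 18-60)
plus residual. Non-signal columns are generated directly as
$\mathrm{loading} \times \mathrm{latent} + \text{independent noise}$ with
default loadings of magnitude 0.1 (0.3 for apparent age). A single-factor
variant — every column a noisy copy of one latent — was rejected: it
makes the *identity* of informative columns unidentifiable, because any
signal column is statistically exchangeable with any other. The
hierarchical form is also the physiologically sensible reading: laxity
manifests through distinct processes (elasticity loss, collagen decline,
wrinkle formation), each tracked by its own instrument. Signs are fixed
by skin-aging physiology — negatively loaded elasticity R2 and positively
loaded F4 are the two relationships the field treats as established; the
remaining signs are plausibility conventions of the generator, not
empirical claims. F3 and R5 are generated as near-copies (r = 0.97) of F4
and R2 to reproduce their collinearity, and value-scale columns are
clipped to their physical support (positive, or negative for wrinkle
depths), with the clip count recorded.

Choices follow the Bradley-Terry/Thurstonian link
$P(i \text{ over } j) = \sigma((\ell_i - \ell_j)/\tau)$ with temperature
$\tau = 0.5$, chosen so that unanimous pairs occur at realistic frequency
and the boundary-correction path is genuinely exercised. Expert labels
are a balanced median split of the latent, so every "more" participant
truly exceeds every "less" participant.

The efficacy study shifts each endpoint 0.15 marginal SD in its
improvement direction with paired noise of the same magnitude (a one-SD
paired effect, about 95% power at n = 15), and the index by −0.05 with
paired SD 0.05. The paired noise is independent of the shift, so a
zero-effect configuration remains a proper null for type-I checks.

What passing tests on this generator **do not** show: real instrument
error structure (the generator's noise is additive Gaussian), real
between-parameter correlations beyond the single trait plus the F3/R5
duplicates, cultural or panel composition effects, or the reference
study's specific numerical results (its concordance, fit metrics, index
distribution and efficacy p-values depend on human data that is not
redistributable; the suite checks the corresponding *properties* —
oracle equivalence, rank recovery, power and type-I control — instead).

## 7. Problem sizes and runtimes

The test suite validates at the full study geometry (64 × 8 × 72,
18,432 responses) for design, scaling and pipeline checks; regression
recovery runs on one 64-participant cohort; power uses 200 efficacy
replicates and the type-I check 500; normality-gate behavior uses 200
replicates; Shapiro-Wilk calibration uses 100 draws of n = 5000 (null)
and n = 500 (skewed alternative). These sizes give Monte-Carlo standard
errors small enough for the asserted bounds while keeping a full run in
the low minutes on one core.

## 8. Known limitations

* Cross-group comparability of the index rests entirely on the ridge
  prior; a connected (cross-group) comparison design would remove this
  dependence and is worth considering in new studies.
* The index has no absolute anchor: only differences (up to the exposed
  affine transform) are meaningful.
* Greedy forward selection is myopic; with strongly redundant candidate
  sets the selected composition is one of several near-equivalent ones,
  and the recorded RMSE path should be inspected before interpreting
  membership.
* The efficacy module assumes complete pairs; dropout handling is limited
  to removing incomplete rows.
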