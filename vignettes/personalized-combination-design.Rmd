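---
title: "Designing personalized drug combinations from marker-stratified response rates"
author: "persotx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing personalized drug combinations from marker-stratified response rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persotx)
```

## The problem

Targeted cancer therapies come with companion biomarkers, and a patient
profiled for hundreds of markers will typically be positive for several,
each nominating a different drug. Treating with everything nominated is
toxic; treating with one drug leaves response rates low. `persotx`
formalizes the middle ground: choose, for every drug in a catalog, a
small set of markers and a Boolean decision rule, such that when every
patient takes the `c` best drugs suggested for them, the cohort-wide
response rate is maximal.

This vignette documents the model, the estimators, the optimizer, the
numerical choices, and what the synthetic validation does and does not
establish.

## Response model

A sample's marker profile is a binary vector; a drug's protocol is an
ordered marker list plus a Boolean function with one input per marker.
Only *non-degenerate* functions — those whose output depends on every
input — are admitted, since a rule ignoring an input is equivalent to a
rule on fewer markers. There are 2 such functions on one input, 10 on
two, 218 on three (`enumerate_functions()` reproduces these counts by
construction; the test suite re-derives them by brute force).

Given single-agent response probabilities $p_{ij}$ and the inclusion
matrix $e_{ij}$ produced by the decision rules plus the top-$c$
selection, independent drug action gives

$$P_i = 1 - \prod_j (1 - p_{ij})^{e_{ij}},
\qquad O = \frac{1}{s}\sum_i P_i .$$

A pairwise interaction matrix $J_{jk}$ can be supplied, entering as
$P_i = 1 - \exp\!\big(\sum_j e_{ij}\ln(1-p_{ij}) +
\sum_{j<k} e_{ij}e_{ik}J_{jk}\big)$, clamped to $[0,1]$; $J<0$ raises the
combination response (synergy), $J>0$ lowers it (antagonism). Estimating
$J$ from data is out of scope — it is a user input, zero by default. Any
chosen drug with $p = 1$ forces $P_i = 1$ regardless of $J$ (the
$\ln(1-p) \to -\infty$ limit).

### Response by marker

The optimizer never sees $p_{ij}$ directly — clinically one only knows
marker-stratified rates. Samples are grouped by their joint status on a
drug's assigned markers (group index $s = \sum_k x_k 2^{k-1}$), and the
drug's rate for the group is the mean of $p_{ij}$ over its members.
Groups smaller than `min_group_size` (default 10, configurable) are
shrunk to $q = 0$: a deliberately blunt guard against overfitting tiny
strata, which also means a marker split that isolates fewer than 10
samples is worthless to the optimizer. Untreated samples contribute
$P_i = 0$.

Ranking for the top-$c$ rule uses these same by-marker estimates, not the
hidden truth — mirroring the information actually available when
deploying such a catalog. Ties go to the lower drug index, a determinism
choice with no scientific content.

## Pharmacokinetic response from a logIC50 screen

For screen-derived cohorts, drug $j$ is dosed at
$y_j = \overline{\log IC50}_j + \log h$; the dose fold-change default
$h = 2$ reflects a highest-tolerated dose about two-fold above the
typical activity concentration. Patient-to-patient pharmacokinetic
variation makes the log-dose reaching the tumor
$Z_j \sim \mathcal{N}(y_j, \sigma^2)$, and a response (≥ 50% growth
inhibition) occurs when $Z_j$ exceeds the sample's logIC50:

$$p_{ij} = \tfrac12\,\mathrm{erfc}\!\left(
  \frac{\log IC50_{ij} - y_j}{\sqrt{2}\,\sigma}\right).$$

One interpretive choice is worth flagging: $\sigma$ is treated as the
*standard deviation* of the log-dose. The $\sqrt{2}\sigma$ denominator is
only a valid normal survival function under that reading, and the tests
verify the erfc form against an independent `pnorm` survival oracle and
against Monte-Carlo dose draws. Everything is on the natural-log scale;
$h$ enters as $\ln h$. Reference values of $\sigma = 1$ (modest
variation) and $\sigma = 10$ (ten-fold larger) bracket reported
pharmacokinetic variability.

## Imputation of missing screen entries

Screens are incomplete (a 20% missing rate motivates the generator
default). A missing $(i,j)$ is filled by a weighted average of other
samples' values for drug $j$, with weights
$e^{-\alpha_{sample} d_{ikj}}$; the sample distance $d_{ikj}$ is a
weighted mean of squared differences across drugs $l \neq j$, weighted by
$e^{-\alpha_{drug} d_{jl}}$ so that drugs behaving like the target drug
dominate. Drug distances $d_{jl}$ are mean squared differences over
shared samples.

Numerical and edge-case choices:

- **Empty overlaps.** A drug pair with no shared sample is excluded from
  the sample-distance sum (weight 0); a target cell with no usable donor
  falls back to the mean of the column's present values. This keeps the
  operator total without inventing information.
- **Weight stabilization.** Weights are computed as
  $e^{-\alpha(d - d_{min})}$ row-wise — mathematically identical (the
  normalization cancels the shift) but immune to underflow at large
  $\alpha$.
- **Convexity.** Every imputed value is a convex combination of present
  column values, hence provably within their range; present entries are
  never touched.
- **Validation.** `evaluate_imputation()` re-estimates every *present*
  entry (self-exclusion is built into the $k \neq i$ sum) and reports the
  Pearson correlation with the observed values; an optional hold-out mode
  masks a random fraction instead, for stricter validation. The default
  grid for $(\alpha_{sample}, \alpha_{drug})$ spans integers 1–22; ties
  resolve toward smaller values, preferring flatter weighting when it
  costs nothing.

The estimator borrows strength *across correlated drugs*: a column
uncorrelated with every other column is unrecoverable beyond its mean,
no matter the parameters. The synthetic fidelity checks therefore plant
marker effects on *pairs* of drugs — the analogue of drugs sharing a
target in real screens.

## The annealer

The search space is the cross-product of per-drug protocols (marker
lists up to `k_max`, default 2, with a compatible non-degenerate
function). Moves mutate one uniformly drawn drug:

- **add** a uniformly drawn unassigned marker, appended at the last input
  position, with a function drawn uniformly from the set of
  non-degenerate extensions compatible with the current function;
- **remove** a uniformly drawn position, with a function drawn uniformly
  from the compatible restrictions (removing the only marker empties the
  protocol);
- **change** the function to a uniformly drawn different one with the
  same input count.

The compatibility sets are computed generically for any $K$ by
restriction semantics — for every reduced input state the surviving rule
must output a value the original rule attains over the two extensions at
the removed position — rather than transcribed as fixed tables, which
removes transcription risk and makes the add/remove maps exact inverses
by construction. Function identity is the truth table; the integer index
$b = \sum_a o_a 2^a$ is informational only.

Energy is $E = -sO$. Moves are accepted when $E$ does not increase, and
with probability $e^{-\beta \Delta E}$ otherwise; $\beta$ starts at
`beta0` (default 0) and rises by `dbeta` (default 0.01) every
`schedule_interval` steps (default: the drug count $d$), over
`steps_per_drug`·$d$ total steps (default 10,000 per drug). Runs start
from all-empty protocols. Two pragmatic strengthenings:

- **Best-state tracking.** The best state visited is returned, not the
  final one — harmless and standard.
- **Dead-weight pruning.** When the drawn drug carries markers but treats
  nobody, the proposal is forced to be a removal. Such moves can only
  enlarge other candidates' opportunities, so $\Delta E \le 0$ always
  (the suite asserts this); the rule prevents unused drugs from
  accumulating markers, though zero-cost re-additions mean a final state
  may still carry a transient marker on an unused drug.

Restarts differ only by seed (`base_seed + r`), making multi-start runs
reproducible and shardable; the reported solution is the minimum-energy
state across restarts, with ties broken toward fewer assigned markers — a
minimal-complexity preference for equally good catalogs. The per-restart
trace of best-so-far $O^*$ lets users check convergence: a flat tail
means more initial conditions are unlikely to help.

## Synthetic cohorts: what they do and do not show

`generate_cohort()` draws independent Bernoulli marker columns;
`generate_ic50()` adds per-drug background means, additive logIC50
shifts for marker carriers (additivity on the log scale matches the
lognormal dose world and keeps group means analytic), Gaussian noise, and
uniform missingness (default 20%). `generate_iid_responses()` provides
the null world in which the expected number of used drugs is
$d^* = d[1 - (1 - c/d)^s]$ exactly.

Two fixture-design points the validation hinges on:

- **Recovery needs identifiability.** With independent half-prevalence
  markers, the planted catalog is provably *not* the unique optimum of
  the estimated $O$: rules that blanket-cover unmarked samples through
  negations on other drugs tie with it. The marker-recovery checks
  therefore use a tissue-like fixture — three mutually exclusive,
  covering markers plus independent noise markers — where the planted
  assignment is the strict optimum. `k_max = 2` matters there too: at
  `k_max = 1` the landscape has deep local minima escapable only through
  two consecutive worsening moves, while a second marker slot opens a
  strictly improving path.
- **Imputability needs correlation**, as discussed above.

What passing these tests shows: the algebra, estimators and optimizer do
what their definitions say, and the optimizer finds exact optima on
exhaustively enumerable instances (verified on instances of ≤ 729
assignment states) and planted optima on identifiable ones. What they do
not show: behavior under real screens' marker co-occurrence, tissue
hierarchies, non-uniform missingness, or miscalibrated group rates —
none of which the generators attempt to mimic.

## Problem sizes and runtime choices

Validation runs use cohorts of 20–100 samples, 3–6 markers, 3–5 drugs,
annealing schedules of 200–600 steps per drug and 8–100 restarts; the
acceptance script uses an 80 × 6 cohort with 4 drugs, 300 steps per drug
and 10 restarts. These sizes keep every check exact or
well-powered (3-SE bands on Monte-Carlo comparisons) while the whole
suite runs in minutes on one core. The annealing defaults
(`steps_per_drug = 10000`, `restarts = 100`) are sized for real
screen-scale problems, where evaluation cost per step is dominated by the
changed drug's group re-estimation, $O(s)$ via cached suggestion and
rate matrices.

## Known limitations

- Interaction terms beyond pairwise are not modeled; $J$ must be
  supplied, not estimated.
- The sample protocol is fixed to "top-$c$ by estimated rate"; the
  optimizer does not search over sample protocols.
- Group-rate shrinkage to zero is abrupt; small informative strata are
  discarded rather than partially pooled.
- The imputation estimator has no notion of systematic (non-random)
  missingness.
- Marker construction from raw genomics (variant calling, CNA
  segmentation) is upstream of this package: markers arrive as opaque
  binary labels.
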