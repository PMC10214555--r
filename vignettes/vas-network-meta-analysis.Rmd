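---
title: "Methods: Bayesian network meta-analysis of VAS pain outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian network meta-analysis of VAS pain outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vasnma` synthesizes arm-level aggregate trial data on a continuous
visual-analog-scale (VAS, 0–10 cm, lower is better) pain outcome in two
stages: frequentist pairwise random-effects meta-analysis for each direct
comparison, and a Bayesian random-effects network meta-analysis (NMA)
under the consistency assumption for the whole treatment network. It
ships an eight-study greater trochanteric pain syndrome (GTPS) network of
six conservative treatments (PRP-U, CSI-U, CSI-B, ESWT, EX, UC) as a
packaged fixture, and a simulator that draws networks from the model's
own data-generating process so every stage can be validated against known
ground truth.

```{r, eval = FALSE}
library(vasnma)
net <- load_gtps_fixture()
pairwise_meta(net, c("ESWT", "EX"))
fit <- sample_posterior(build_model(net), desk_settings(seed = 1))
league_table(fit)
rank_probabilities(fit)
```

## Data model

One row per treatment arm: study id, treatment code, per-arm `n`, mean
and SD of the VAS score, and an optional `outcome_label` for studies that
report the same scale under several conditions. Invariants enforced at
ingestion: `n >= 2` (a sample SD must be definable), `sd > 0`, finite
means, and uniqueness of (study, treatment, outcome label). The
comparison graph must be connected; `build_network()` reports the
components when it is not.

Two data-entry conventions matter for the packaged fixture:

* **Equal arm splits.** The source trial reports print only the total
  randomized per study. `split_total_n()` divides the total as equally as
  possible, giving the first-listed (treatment) arm the extra patient
  when the total is odd. This is a symmetric, documented convention; the
  true per-arm allocations are not recoverable from the published
  summaries, which bounds how exactly downstream estimates can reproduce
  published ones (see *Known limitations*).
* **Within-study outcome merging.** One trial (Brinks 2011) reports VAS
  both at rest and with activity for the same 120 patients. The two rows
  are stored under distinct outcome labels and merged before any
  between-study synthesis by fixed-effect inverse-variance pooling,
  treating the rows as independent because their correlation is
  unpublished. This choice reproduces the published pooled estimate for
  that comparison to printed precision.

## Pairwise stage

For arms t and c of one study, the mean difference is
$y = \bar x_t - \bar x_c$ with variance $v = s_t^2/n_t + s_c^2/n_c$.
Studies sharing a comparison are pooled with the DerSimonian–Laird (DL)
moment estimator: fixed weights $w_i = 1/v_i$, Cochran's
$Q = \sum_i w_i (y_i - \bar y_{FE})^2$ on $k - 1$ df,

$$\hat\tau^2_{DL} = \max\!\left(0,\; \frac{Q - (k-1)}
 {\sum w_i - \sum w_i^2 / \sum w_i}\right),
 \qquad I^2 = \max\!\left(0, \frac{Q - (k-1)}{Q}\right),$$

random-effects weights $w_i^* = 1/(v_i + \hat\tau^2)$, and a Wald
interval $\hat\mu \pm z \cdot se$ with $z = 1.96$ (matching the 95% CIs
of the published tables; no Knapp–Hartung adjustment). $\tau^2$ and
$I^2$ truncate at zero when $Q \le k-1$; rounding happens only at
presentation (2 decimals), never in computation. The implementation is
checked against both a literal re-evaluation of these formulas and
`metafor::rma(method = "DL")`.

## Network stage: the consistency model

Each study contributes its baseline contrasts. For a two-arm study $i$
comparing treatment $k$ to baseline $b$:

$$y_i \sim N(\delta_i, v_i), \qquad
  \delta_i \sim N(d_k - d_b, \tau^2),$$

with basic parameters $d_k$ relative to a reference treatment whose
$d$ is fixed at 0. A study with $a$ arms contributes an $(a-1)$-vector of
contrasts whose random-effects covariance is $\tau^2$ on the diagonal and
$\tau^2/2$ off it (the exchangeable-heterogeneity structure), and whose
likelihood covariance carries $s_b^2/n_b$ off-diagonal from the shared
baseline arm. Consistency holds by construction: every functional
contrast is $d_c - d_r$ within one draw, so the identity
$d_{AC} = d_{AB} + d_{BC}$ is exact per draw.

**Priors.** The published analysis names its software but not its
priors, so the package uses explicit vague priors on an automatic
outcome scale $S = \max_i (|y_i| + 1.96\sqrt{v_i})$ (5.94 VAS cm on the
fixture): $d_k \sim N(0, (c_d S)^2)$ with $c_d = 15$, and
$\tau \sim U(0, c_\tau S)$ with $c_\tau = 5$. Both multipliers are
arguments of `build_model()`; sensitivity to $c_\tau$ (5 vs the common
mixed-treatment-comparison default of 1) moves fixture rank
probabilities by under one percentage point, because the heterogeneity
posterior is dominated by the likelihood.

**Sampler.** A blocked Gibbs scheme owned by the package (so the
seeding contract is explicit): the $\delta_i$ and the vector $d$ have
normal/multivariate-normal full conditionals and are drawn exactly
(two-arm studies batched and vectorized; $d$ drawn jointly via a
Cholesky solve); $\tau$ is updated by shrinkage slice sampling on its
bounded prior support, whose conditional density
$\propto \tau^{-\nu} \exp(-S_r / 2\tau^2)$ needs no tuning. Chains start
over-dispersed — chain $j$ offsets every $d_k$ by up to
$\pm 2\sigma_d/10$ with alternating sign, and starts $\tau$ at spread
quantiles of its prior — and are run sequentially from a single seeded
stream, so identical (seed, settings, data) give bit-identical draws.
Non-finite states abort with the offending parameter named.

**Settings.** The long-run protocol (`paper_settings()`) is 4 chains ×
50000 iterations, 20000 burn-in, thinning 10 — 3000 retained draws per
chain, 12000 in total. `desk_settings()` (4 × 6000, 1000 burn-in, thin
5; 4000 retained draws) gives rank probabilities with Monte-Carlo error
well under a percentage point on the fixture and is the default for the
end-to-end driver. Both run in well under a minute on the fixture on one
CPU.

**Summaries.** League-table cells are posterior medians with equal-tail
95% credible intervals of the per-draw contrast $d_c - d_r$ (column
relative to row; the published league table's asymmetric intervals imply
quantile-based summaries, ruling out mean ± z·se). `tau_summary()`
reports the heterogeneity SD the same way.

## Diagnostics and ranking

Convergence uses the classic Gelman–Rubin potential scale reduction
factor without the later degrees-of-freedom correction or
rank-normalization: $W$ the mean within-chain variance, $B/n$ the
variance of chain means, $\hat R = \sqrt{((n-1)/n \cdot W + B/n)/W}$.
This form is hand-checkable (two identical chains of `1:3` give exactly
$\sqrt{2/3}$); the pass threshold defaults to 1.05 and is configurable.
Degenerate cases: all-constant agreeing chains give 1 by convention;
constant disagreeing chains give `Inf` with a warning.

Rank probabilities follow the convention that **rank 1 is worst and rank
N is best**: per draw, treatments are ordered by their effect versus the
reference, the largest (worst, for a pain score) taking rank 1; ties —
measure-zero in practice — break by treatment order, which keeps the
rank table exactly doubly stochastic. Flipping `lower_is_better`
reverses the rank index. `best_probability()` reads off the rank-N
column; SUCRA-style curves are deliberately not drawn (numeric tables
only).

## The synthetic generator

`simulate_network()` draws data from exactly the model the NMA assumes:
study-level true contrasts from
$N(d^*_k - d^*_b, \tau^{*2})$ (correlation 1/2 within multi-arm
studies), observed means with $N(0, \sigma^2_{arm}/n)$ error, and
observed SDs from the scaled chi-square law
$\sigma_{arm}\sqrt{X/(n-1)}$, $X \sim \chi^2_{n-1}$, so the estimation
error of the $v_i$ is realistically present (`fixed_sd = TRUE` switches
it off for sharp oracle tests). Baseline means are fixed per design
(default 5.0 VAS cm, within-arm SD 2.0 VAS cm — mid-scale values typical
of moderate chronic pain cohorts): baseline variation is nuisance for
contrast-based models. What the generator does **not** emulate: floor
and ceiling effects at VAS 0/10, dropout, skewness, or reporting bias —
so passing recovery tests validate the estimation machinery, not
robustness to real-data pathologies.

The test suite's recovery benchmark uses a 2-treatment, 20-study design
with $d^* = 1$, $\tau^* = 0.3$, $n = 50$ per arm, 50 repetitions at 2
chains × 3000 iterations per fit: empirical 95%-interval coverage lands
in the binomial band around nominal and absolute bias is well under 0.1
VAS cm.

## Numerical choices and degenerate inputs

* $\tau^2 = 0$ designs, single-study edges ($Q = 0$, df 0) and $k = 1$
  pools are all well-defined and tested.
* The slice sampler shrinks from the full bounded support; a collapse of
  the bracket below 1e-300 returns the current value (never observed in
  practice).
* Quantile summaries use R's default type-7 order statistics, making
  league antisymmetry exact to floating-point roundoff (tested at
  1e-12).
* Presentation formatting uses ASCII hyphen-minus and two decimals;
  canonical CSV outputs keep full precision, and the league CSV encodes
  `median|lower|upper` per cell.

## Known limitations

* **Arm-split reconstruction bounds fidelity.** With equal splits from
  published totals, the single-study and ESWT-vs-EX comparisons of the
  fixture reproduce their published estimates to printed precision, but
  the PRP-U vs CSI-U edge is more heterogeneous than the published
  analysis reports ($I^2$ 77.6% vs 58.3%): the original per-arm inputs
  evidently differ from anything reconstructable from the published
  summaries. Because all edges share one network $\tau$, this excess
  heterogeneity widens every fixture credible interval relative to the
  published league table and correspondingly softens the extreme rank
  probabilities computed by the acceptance script (P(PRP-U best) ≈ 0.96
  vs 0.99; P(EX worst) ≈ 0.77 vs 0.84). The pairwise PRP-U estimate is
  therefore held to sign and magnitude only.
* A study reporting several outcome labels is supported for two-arm
  studies; multi-arm multi-label studies are rejected rather than
  guessed at.
* Continuous mean-difference outcomes only; no binary/count/survival
  likelihoods, no node-splitting inconsistency assessment, no
  meta-regression, and no small-study/publication-bias diagnostics.
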