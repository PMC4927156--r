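---
title: "chemscreen: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chemscreen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemscreen)
```

## The measurement and its artifacts

An arrayed chemical-genomic screen pins a genome-wide mutant library onto
agar plates containing a stress (an antibiotic, a temperature, a solvent),
grows the colonies, photographs the plates, and quantifies each colony.
The growth readout used throughout this package is *opacity* — the summed
pixel intensity over the colony — which tracks biomass better than area
alone. One plate corresponds to one (condition, replicate) pair; the grid
position of each colony identifies the mutant through a layout map.

Colony opacity is strictly positive, and the dominant artifacts are
multiplicative: pinning pressure, agar thickness and drying gradients
produce smooth spatial biases across the plate, and the outermost colonies
grow larger because they face less nutrient competition. `chemscreen`
therefore models everything on the log scale, where these effects are
additive:

$$\log y_{gp} \;=\; \log b_g \;+\; \log e_{gc} \;+\; s_p(r, c)
  \;+\; \varepsilon,\qquad \varepsilon \sim N(0, \sigma^2),$$

with $b_g$ the mutant's baseline opacity, $e_{gc}$ the gene-by-condition
effect of interest (1 for most pairs), and $s_p$ a smooth per-plate
surface.

## The normalization stack

The cleaning stages run in a fixed order: read, positional filtering,
surface smoothing, power transformation, variance scaling.

**Positional masking** (`apply_position_mask`) excludes grid positions
with known recurrent pinning problems. Masked records stay in the table
with a `masked` flag; they are invisible to every downstream fit, so a
mask is exactly equivalent to deleting those colonies (a property the
test suite asserts).

**Surface normalization** (`surface_normalize`) fits a bivariate
polynomial of total degree 4 — 15 coefficients on grid coordinates scaled
to $[-1,1]^2$ — to log-opacity by iteratively trimmed least squares.
A quartic is the lowest order that captures the saddle- and bowl-shaped
pinning artifacts seen on high-density arrays while remaining a strict
linear least-squares problem. The robustness scheme drops points whose
residual exceeds 3 MAD and refits, at most 5 times: dead colonies are
data, but they must not drag the surface estimate down. The fitted
surface is removed after centering (`opacity / exp(fit - mean(fit))`), so
the removed component has geometric mean 1 and the plate's overall level
is preserved. Fits are refused below 30 reliable colonies — with 15
coefficients anything less has no degrees-of-freedom headroom.

**Power transformation** (`power_transform_fit`) chooses a Box–Cox
exponent on the grid $[-2, 2]$ in steps of 0.05 by profile likelihood
(via `MASS::boxcox`), per condition rather than per plate: the transform
exists to tame the tails of the condition-level distribution that the
scoring stage consumes. On lognormal-like opacity data the selected
exponent lands near 0 (a log transform), and the transform is strictly
monotone, so ranks are never disturbed.

**Variance normalization** (`variance_normalize`) centers each plate on
its median and rescales it so its interquartile range matches the median
IQR across plates. Median/IQR rather than mean/SD keeps a handful of
strong phenotypes from inflating a plate's scale. A zero-IQR group is
pathological (a plate with no spread carries no information); it is
centered, left unscaled, and flagged with a warning.

**Reliability filtering** (`filter_low_coverage`) removes genes and then
conditions with fewer than 75% reliable measurements, iterating to a
fixed point, since dropping a poor condition changes every gene's
reliable fraction. The boundary is exclusive: exactly 75% survives.

## Fitness scores and phenotype calls

The score for gene $g$ in condition $c$ is a regularized Welch-style
statistic,

$$S_{gc} = \frac{\mu_t - \mu_r}
  {\sqrt{\max(s_t^2,\; s^2_{\min})/n_t + s_r^2/n_r}},$$

negative for sensitivity, positive for resistance. The reference set
defaults to the same gene's measurements across the *other* conditions of
the batch — the gene's typical behavior — because arrayed screens rarely
carry a dedicated untreated plate per batch; an explicit control
condition can be selected instead (`reference = "control"`). The variance
floor $s^2_{\min}$, the median per-gene treated variance within the
condition, is what makes a 2–3-replicate design workable: without it,
pairs of replicates that agree by chance produce enormous spurious
scores. With the floor disabled the statistic is exactly antisymmetric
under exchanging the treated and reference roles, and it is invariant to
rescaling the whole normalized matrix.

Phenotypes are called per condition at an empirical false-discovery rate.
The null is a robust Gaussian, $N(\mathrm{median},\ 1.4826\cdot\mathrm{MAD})$,
fitted to the condition's own score distribution — self-calibrating, and
robust to the minority of real phenotypes in the tails. For each tail
independently, the estimated FDR at cutoff $c$ is the expected null count
beyond $c$ over the observed count beyond $c$ (capped at 1), and the
cutoff is the smallest $|c|$ on a 0.01 grid with estimated FDR at most
$\alpha$. Treating the tails independently allows the asymmetric
sensitivity/resistance cutoffs that real conditions show. When no grid
point qualifies — the expected outcome for a condition with no real
signal — the cutoff is placed beyond the most extreme score and the
condition yields no calls. Calls use inclusive boundaries. A *responsive
gene* is a gene with at least one call anywhere in the dataset.

## Correlation networks

Gene–gene Pearson correlations are computed pairwise-complete over the
conditions where both genes are reliable, with pairs below a minimum
overlap — 75% of conditions by default, matching the reliability filter —
omitted, because small overlaps generate spuriously extreme $r$.

Significance is again an empirical FDR: the null recomputes all pairwise
correlations after independently permuting each gene's profile across its
own unmasked conditions. This destroys shared condition structure while
preserving the mask pattern and every gene's marginal distribution
exactly (asserted as a multiset-equality test). The cutoff is the
smallest $|r|$ on a 0.01 grid where (mean null tail count)/(observed tail
count) drops to $\alpha$. Two points follow from this construction and
are worth stating plainly:

* On a matrix with **no** correlation structure, observed and permuted
  tails coincide and no cutoff qualifies; the function reports this
  honestly rather than inventing a threshold. Test fixtures that need a
  defined cutoff therefore contain correlated gene modules, which is also
  what real screens look like.
* The cutoff tightens as conditions accumulate: more conditions shrink
  the null correlation spread, which is exactly the behavior
  `condition_sampling_curve` quantifies (sampling N conditions without
  replacement, 4 repeats per N, reporting the mean IQR of pair
  correlations, the mean permutation-FDR cutoff, and the mean
  Bonferroni-style threshold from inverting the two-sided t-test at
  $\alpha/n_{\text{pairs}}$).

Hierarchical clustering uses the field-standard organization: distance
$1 - r$, average linkage (`stats::hclust`), for both genes and
conditions, with Cluster 3.0-compatible `.cdt`/`.gtr`/`.atr` output
readable by Java TreeView. Tie handling in merge order is `hclust`'s own;
the oracle tests use tie-free fixtures.

## Gene-set enrichment

For one condition's score vector, `gsea_es` computes the weighted
Kolmogorov–Smirnov running sum: genes ranked by decreasing score, set
members add $|s|^p$ (normalized over members), non-members subtract
$1/(N - N_{hit})$, and the enrichment score is the signed maximum
excursion. The default weight $p = 1$ is the classic magnitude-weighted
statistic; $p = 0$ is rank-only and invariant to monotone rescaling.
Because the input is a single condition's vector, the only available null
is set-membership permutation at fixed set size; `gsea_pvalue` uses the
plus-one convention $p = (1 + k)/(n_{perm} + 1)$ so $p$ is never zero.
When the number of distinct sets is at most `n_perm` the null is
enumerated exhaustively instead and the p-value is exact.

## Assay models

**MIC** (`call_mic`): ODs are normalized as
$(\mathrm{OD} - \mathrm{blank})/(\mathrm{control} - \mathrm{blank})$ —
which makes the call invariant to affine rescaling of all ODs — and the
MIC is the first concentration, scanning the 2-fold series upward, whose
normalized density falls strictly below 10%. If none does, the result is
right-censored ("> max tested"). Growth recovery above the first crossing
is reported as a warning but does not move the call.

**Inhibition kinetics** (`fit_decay`, `select_decay_model`): normalized
activity traces are fit with $A e^{-kt} + C$ or
$A_1 e^{-k_1 t} + A_2 e^{-k_2 t} + C$, all parameters non-negative and
$k_1 > k_2$ by convention (the two-rate model is otherwise
label-degenerate). Fitting is Levenberg–Marquardt (`minpack.lm::nlsLM`)
with seeded multi-start, plus a closed-form flat candidate because a
constant trace makes the optimizer's Jacobian singular. Model choice is
by AICc — appropriate for unequal parameter counts at small $n$ — with a
parsimony tie-break: within 2 AICc units the single exponential wins.
The plateau $C$ is a free non-negative parameter rather than pinned at
zero, since saturating uptake assays often stabilize above background.

**Ligand-depletion binding** (`fit_binding`): when protein and ligand
concentrations are comparable, free ligand cannot be approximated by
total ligand and the 1:1 equilibrium gives the quadratic isotherm

$$F(L) = \Delta F_{max}\,
  \frac{(P + L + K_d) - \sqrt{(P + L + K_d)^2 - 4PL}}{2P}.$$

The fit requires $P$ as an input rather than assuming a value. In the
dilute limit $P \ll K_d$ the model collapses to the hyperbola
$\Delta F_{max} L/(L + K_d)$, and the half-maximal effective ligand
concentration has the closed form $K_d + P/2$ — both used as checks.
A numerically negative discriminant is clamped at zero with a warning.

## The synthetic screen generator

`sim_config`/`simulate_screen` generate screens under exactly the model
the pipeline assumes: per-gene lognormal baselines (meanlog $\log 10^4$,
sdlog 0.25), sparse planted multiplicative gene-by-condition effects, a
random quartic plate surface per plate, an edge multiplier (default 1.3
on the outermost 2 rows/columns — colony arrays show nutrient-driven edge
growth that a smooth polynomial does not fully capture), lognormal noise,
and random dropout emitted as opacity-0/`missing` records. Defaults:
32 × 48 grid (1536 format), noise sd 0.15 on log-opacity, 2% dropout.
The surface amplitude parameter scales each plate's log-surface to
standard deviation $\log(1 + a)$, so $a = 0.3$ means typical ±30%
multiplicative bias. The truth (baselines, surfaces, effects) is
materialized from the config seed; re-simulating with a different run
seed redraws only noise and dropout, which is what makes
recovery experiments cleanly repeatable.

What the generator deliberately does **not** emulate: spatially
correlated dropout (real pinning failures cluster), batch-to-batch drift
of the edge effect, condition-specific global growth inhibition, and
colony-to-colony competition. Passing recovery tests on these
simulations therefore demonstrates correctness of the *statistical
machinery* under its stated model, not robustness to every failure mode
of real plates.

## Validation scale and results

The end-to-end validation scenario used by the test suite and the
acceptance script is a screen of 200 conditions × 1,000 genes × 3
replicate plates (32 × 32 grid), surface amplitude 0.3, noise sd 0.15, 2%
dropout — large enough for stable per-condition FDR estimation (the
cutoff search requires at least 500 finite scores per condition) while
keeping a full pipeline run under a minute on one core. On the null
version of this screen the mean fraction of genes falsely called per
condition is ~0.3%, well under the 7.5% bound implied by the 5% FDR
target; with 2-fold effects planted on 1% of gene-condition pairs,
recall is ≳0.99 with no sign errors. Noiseless planted surfaces are
recovered to machine precision, and after normalization the planted
surface explains <0.1% of residual log-opacity variance (from >50%
before).

## Known limitations

* The fitness score's reference-from-other-conditions scheme assumes
  most conditions leave most genes unaffected; a batch dominated by one
  drug family would bias the reference. Use an explicit control
  condition in that setting.
* The empirical-FDR cutoff is undefined (by design) when a condition or
  correlation matrix carries no signal; callers must handle the
  sentinel.
* Correlation p-values are not provided per pair — only the global FDR
  cutoff and the Bonferroni threshold; per-pair inference was out of
  scope.
* The binding model is a single-site 1:1 isotherm; competitive or
  multi-site schemes are not modeled.
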