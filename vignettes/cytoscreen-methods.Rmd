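---
title: "From cytometry profiles to screening rules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From cytometry profiles to screening rules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoscreen)
```

## The problem

A cohort of patients is profiled by multiparameter flow cytometry: after
gating, each patient is summarized by on the order of a hundred continuous
population expressions (activation, polarization, trafficking and memory
markers on CD4+ and CD8+ T cells). Each patient also carries a binary
clinical phenotype — in the motivating setting, interstitial lung disease
(ILD) in systemic sclerosis, defined upstream from pulmonary-function
criteria and coded 1 = ILD, 0 = no-ILD. The association between any single
expression and the phenotype is weak (a "flat" estimation problem: the
best single-variable correlations are around |r| ≈ 0.2–0.3), variables are
strongly inter-correlated because subsets are nested within gating
hierarchies, and the cohort is small relative to the number of variables.

`cytoscreen` implements a four-stage analysis built for exactly this
regime:

1. **Variable ranking.** A conditional-inference forest produces a mean
   variable importance list (VIL) over multiple seeded runs.
2. **Set scoring.** Top-down sets from the VIL are scored with a
   feature-set enrichment random walk against the correlation-ranked
   variable list; the set size with the supremum enrichment score is
   retained, with significance from phenotype permutation.
3. **Screening-tool design.** Simple "any marker out of bounds" threshold
   rules over small subsets of the retained set are designed by uniform
   random search, selected by a two-level metric (overall
   misclassification rate, ties broken by true-positive rate).
4. **Validation**, optionally after Gini/CART pre-partitioning of patients
   into subgroups with subgroup-specific tools.

## The forest and its importance measure

Trees separate split-*variable* selection from split-*point* selection. At
a node with members $i$ and candidate variable $x$, the association with
the binary response $y$ is measured by the permutation-form linear
statistic $T = \sum_i x_i y_i$, standardized by its conditional mean
$\mathbb{E}(T) = \bar x \sum_i y_i$ and variance
$\mathrm{Var}(T) = \frac{V_x V_y}{n-1}$ (with $V_x, V_y$ the node sums of
squares), and referred to the standard normal. `mtry` candidates are drawn
per node; the global null — no candidate is associated with the response —
is rejected only if the minimal Bonferroni-adjusted p-value falls below
`alpha` (default 0.05). Only then does splitting continue, with the split
point chosen to maximize the standardized two-sample statistic over the
observed values of the selected variable. This hypothesis-testing gate is
what keeps selection honest among many correlated candidates, and it acts
as the stopping rule: degenerate or uninformative nodes become leaves
carrying class fractions (no hard votes).

Numerical choices worth knowing:

* The normal reference is asymptotic; `split_test = "montecarlo"` replaces
  it with a Monte-Carlo permutation p-value (default 499 draws per
  candidate), which calibrates small nodes better at a compute cost. Full
  enumeration is never attempted.
* `min_node` (default 7) bounds child size; a node smaller than
  `2 * min_node` is a leaf.
* Bootstrap is size-$n$ with replacement by default; `"subsample"` draws
  $0.632\,n$ without replacement; `"none"` gives full-sample trees (no OOB
  set), which is how the package itself verifies the stop-test calibration
  on null data — on bootstrap resamples the root split rate reflects each
  dataset's own sampling noise rather than the nominal level.

Importance is **unconditional out-of-bag permutation importance**: per tree,
OOB accuracy at the 0.5 probability cut minus the accuracy after permuting
one variable's OOB values, averaged over all trees (a variable unused by a
tree contributes exactly zero there). Conditional permutation schemes exist
but in this correlated-cytometry setting produce virtually identical
rankings at a much higher cost, so they are deliberately not implemented.
Because single-forest rankings are stochastic, `mean_vil()` averages
`n_runs` (default 20) independently seeded forests; ties in the mean are
broken lexicographically by variable name so the list is reproducible.

## Enrichment over the correlation-ranked list

All $N$ variables are ranked by (Pearson by default, optionally Spearman)
correlation with the phenotype, from largest positive to largest negative;
ties break lexicographically so permutation p-values are order-stable. For
a feature set of size $G$, the walk traverses the ranked list adding
$\sqrt{(N-G)/G}$ at members and subtracting $\sqrt{G/(N-G)}$ elsewhere, so
it always closes at zero. The enrichment score is the supremum of the
running sum: it is bounded by $\sqrt{G(N-G)}$, attained exactly when all
members occupy the top $G$ ranks, and a set concentrated at the bottom
scores 0 (the supremum is the final, zero-valued step). The signed
supremum — not the maximum absolute displacement — is used, so only
coordinated movement toward the top of the list scores; an absolute-value
correlation ranking (`mode = "absolute"`), under which only upward moves
are possible, is available for sign-agnostic questions.

Significance is by **class-label randomization**: each of `n_perm`
(default 10,000) permutations shuffles the phenotype, re-ranks *all*
variables against the permuted labels, and re-runs the walk for the fixed
set; the p-value is the fraction of permuted scores strictly exceeding the
observed one (an add-one-smoothed estimate is available via
`smooth = TRUE`). Randomizing variable labels instead would ignore the
inter-variable correlation and be anti-conservative, which is why it is
not offered. In the size scan (`scan_set_sizes()`), ES ties across sizes
resolve toward the smaller, more parsimonious set.

Note the two distinct ranked lists: the VIL (which *forms* sets, top-down)
and the correlation ranking (which the walk *traverses*). A set can only
score highly if the forest's important variables are also coordinately
correlated with the phenotype. With mixed-sign effects under the signed
ranking, negatively correlated members sit at the bottom of the list; the
ES optimum then reflects the positively correlated portion of the planted
signal, which is the expected behaviour, not a defect.

## Screening tools by stochastic search

A screening tool is $k$ variables with one negative lower and one positive
upper threshold each, in standardized units; a patient is flagged iff
*any* member expression falls strictly above its upper or strictly below
its lower threshold (values exactly at a threshold count as in-bounds —
an arbitrary but fixed convention). Thresholds are drawn uniformly on
$(0, z_{\max}]$ and $[z_{\min}, 0)$ per variable, where $z_{\min}, z_{\max}$
are the standardized *training* minima and maxima — an agnostic
exploration of the observed expression range, anchored at zero. Validation
data are always standardized with the training parameters; group-specific
searches standardize against the group's own training members.

Subsets of the candidate pool (by default sizes 3–6, where the pool is the
best enrichment set) are enumerated lexicographically —
$\sum_s \binom{27}{s} = 397{,}215$ tools-worth at the published pool size,
versus $2^{27}-1 = 134{,}217{,}727$ for a full expansion, which is why the
scan is configurable and desk-scale by default. Each subset receives
`realizations` random tools (default 1000), with draws consumed
realization-by-realization from a per-subset seed derived from the master
seed and the subset's enumeration index: a shorter run explores a prefix
of a longer one, distributed execution reproduces serial results, and the
best OMR is non-increasing in the realization budget. Selection is
two-level — minimize OMR, break ties by maximal TPR — and *all* co-optimal
tools are retained, because best tools are frequently not unique. Of the
four candidate metrics the package computes, the first (a ratio of
predicted-positive counts, implemented as $(TP+FP)/(TP+FN)$ under a
documented reading of an ambiguous definition) and its product with TPR
are reported but never used for selection. When a group has no true cases
the TPR tie-break is undefined and a fixed 0 is substituted, keeping the
ordering total.

## CART pre-partitioning

`fit_cart()` is deliberately minimal Gini-impurity recursive partitioning:
split candidates are the *observed data values* (patients strictly below
the value go left), ties in impurity decrease break by variable name then
value, and nodes are addressed `level-index` with children of `L-i` at
`(L+1)-(2i-1)` and `(L+1)-(2i)`. "Level $L$ groups" are all depth-$L$
nodes plus earlier leaves carried down unchanged, so every level
partitions the full cohort. Cost-complexity pruning is out of scope: depth
is capped by configuration and the effective depth is chosen by
*validating the screening tools*, not the tree.

Per-group search inherits a parent's tool when the parent achieved OMR = 0
(a perfect rule cannot be improved on its own members), and a child search
that fails to beat the parent's tool on the child's members keeps the
parent's tool — this refinement guarantee makes pooled training OMR
non-increasing in level. Validation patients are routed through the
training tree's splits, standardized with the training group's parameters,
and classified with the training group's tool; the level-wise training and
validation error curves, the level minimizing validation error, and
whether the curves cross (the over-fitting diagnostic) are reported.
Degenerate groups (too few members, or every pool variable constant)
inherit the parent tool with a warning.

## The synthetic-data generator

Every downstream stage is testable without any external download because
the generator plants known ground truth. Variables are built from one
standard-normal latent factor per block:
$x = \sqrt{\rho}\,f_{\mathrm{block}} + \sqrt{1-\rho}\,\varepsilon$, giving
unit marginal variance, within-block correlation $\rho$ and independence
across blocks — the simplest structure reproducing the "many highly
correlated covariates" regime. Defaults mirror the study conditions the
package targets: 119 patients, 112 variables, phenotype prevalence 0.48,
blocks of 8 at $\rho = 0.3$, and ten informative variables (six at +0.8 SD,
four at −0.8 SD) so the top of a recovered importance list mixes
positively and negatively correlated members. Effects are in SD units and
therefore survive standardization unchanged.

The alternative **threshold-rule model** generates the phenotype
deterministically from a planted any-out-of-bounds rule, so rule recovery
can be scored exactly; by construction a planted rule classifies its own
cohort with OMR = 0. Planted bounds default to the tails (−2.2 / +2.0 SD),
mirroring screening rules that flag clinically extreme expressions. The
rule accepts a separation `margin` (test fixtures use 0.4 SD): values
within the margin of a planted bound are displaced away from it, carving
an empty band around each decision boundary. This matters because uniform
random threshold search carries an intrinsic error floor on margin-free
continuous data — each of the $2k$ thresholds must fall between two
adjacent order statistics, so boundary-adjacent patients contribute
$O(1/n)$ error per threshold no matter how many realizations are drawn.
With a margin the planted rule is recoverable to zero held-out error at
desk-scale budgets. Real cohorts have no such band: passing recovery tests
demonstrates correctness of the search machinery, not that real screening
tools will reach these error rates.

What the generator does *not* emulate: event-level FCS data, gating
hierarchies (correlation is block-equicorrelated, not nested),
heavy-tailed or bounded marginal distributions, batch effects, or
label noise in the clinical phenotype.

## Problem sizes and reproducibility

Every stochastic stage draws its seed deterministically from one master
seed plus a stage label (`derive_seed()`), and the pipeline logs each
derived seed, so any stage can be replayed in isolation; identical
configurations produce byte-identical artifacts. The test-suite and
acceptance problem sizes are chosen so the full analysis remains
desk-scale: forests of 100–500 trees averaged over 3–20 runs,
permutation tests of 300–2,000 draws (10,000 remains the analysis
default), screening searches of a few hundred to 2,000 realizations per
subset over pools of up to 12 variables, and CART depths of 1–2 on
cohorts of 90–400 patients. The published-scale sweep (27-variable pool,
full 3–6 size range, HPC-scale realization counts) is reachable through
the same configuration objects.

## Known limitations

* The split-selection p-value is asymptotic; very small nodes are handled
  by the stop rule or, if desired, the Monte-Carlo option.
* The enrichment walk is unweighted (every member contributes the same
  increment); correlation-weighted variants are out of scope.
* Random search makes no claim of optimality — fidelity to the original
  design was preferred over smarter optimizers, and the error floor
  discussed above is a property of the method, not a bug.
* MAE/MSE are computed on probability-scale predictions against 0/1
  labels, and both out-of-bag and resubstitution variants are reported;
  resubstitution error of a flexible forest is optimistic by nature.
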