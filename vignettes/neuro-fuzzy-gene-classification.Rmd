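---
title: "Wrapper feature selection and neuro-fuzzy classification of gene expression"
author: "anfisFS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapper feature selection and neuro-fuzzy classification of gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anfisFS)
```

## The problem

Microarray (and bulk RNA) studies produce matrices with thousands of gene
columns and a few dozen sample rows, each sample carrying a binary phenotype
(tumour/normal, subtype A/B).  Two difficulties dominate: almost all genes
are irrelevant to the phenotype, and any sufficiently flexible classifier
can interpolate so few samples.  `anfisFS` addresses both with a two-stage
procedure:

1. **Wrapper feature selection.**  A grey wolf optimizer (GWO) searches the
   space of gene subsets, scoring each candidate by the cross-validated
   accuracy of a fast classifier trained on those genes only, plus a mild
   reward for shorter subsets.  The incumbent best subset is refined each
   iteration by adaptive β-hill climbing (AβHC), a greedy local search with
   a shrinking neighbourhood.
2. **Neuro-fuzzy classification.**  The selected genes feed a first-order
   Sugeno adaptive neuro-fuzzy inference system (ANFIS) with generalized
   bell membership functions.  Its premise (membership) parameters are
   tuned by a chimp-style population metaheuristic; its linear consequent
   parameters are estimated by least squares.

Everything is seeded: one master seed per fit, from which each stage derives
an independent stream (`derive_seed()`), so results are bit-for-bit
reproducible.

## Preprocessing

Each gene is standardized to z-scores, $(x - \mu)/\sigma$, with the
*population* standard deviation (divide by $n$, no Bessel correction); the
choice is arbitrary at these sample sizes but is fixed and tested so that
results are reproducible.  Zero-variance genes (flat probes, common in real
chips) are mapped to all-zero columns rather than raising an error — the
selection stage can still discard them.  Standardized values mostly fall in
about $[-3, 3]$ for roughly Gaussian genes, but no clipping is applied.

By default the transform is fit on the full matrix before cross-validation
splitting (the conventional, preprocessing-first microarray practice).
This leaks a small amount of test information through the gene means;
`evaluate_pipeline(..., normalize_per_fold = TRUE)` fits the transform on
each training fold only when a leakage-free protocol is wanted.

## The feature-selection stage

Each of `pack_size` wolves is a point in $[0,1]^D$ over the $D$ genes.  A
position becomes a subset by thresholding at 0.5 (strictly greater selects
the gene); an empty mask is repaired by forcing on the gene with the largest
coordinate.  A subset $S$ is scored by

$$\mathrm{fitness} = \alpha\,\gamma_S + (1-\alpha)\,\frac{|D|-|S|}{|D|},
\qquad \alpha = 0.9,$$

where $\gamma_S$ is the accuracy of the wrapper classifier under seeded
stratified 3-fold cross-validation on the selected columns.  The wrapper
classifier is pluggable; the default is 5-nearest-neighbour — fast,
parameter-free, deterministic given the fold assignment, and standard in
the wrapper-selection literature.  The final classifier (ANFIS) is far too
costly to train inside the fitness, which is the usual reason wrapper
methods pair a cheap internal learner with an expensive final one.

Wolves move toward the three best solutions found so far (the α, β, δ
leaders; ties broken by evaluation order) under the classic encircling
update with the attack coefficient decaying linearly from 2 to 0 over the
run.  Leaders are best-so-far, so the best-fitness trace is monotone
non-decreasing; all positions are clipped to the unit hypercube after every
move.  The same update family is sometimes written twice with different
symbol sets; it is implemented once (`gwo_leader_update()`).

### Adaptive β-hill climbing

Once per outer iteration the best position is refined by AβHC
(`abhc_refine()`).  Each inner iteration builds one candidate:

* the **N-operator** perturbs *one randomly chosen coordinate* by
  $\pm U(0,1)\cdot N(t)$, with bandwidth
  $N(t) = 1 - t^{1/K}/T^{1/K}$ shrinking from 1 to 0 ($K = 4$ by default);
* the **β-operator** then independently resets each coordinate to a fresh
  $U(0,1)$ draw with probability `beta_rate`.

The candidate replaces the incumbent only on a strict fitness improvement.
Two choices here deserve justification.  First, the N-operator moves a
single coordinate rather than all $D$ at once: with hundreds of genes, a
simultaneous perturbation of every coordinate is rejected almost surely
once the accuracy term has saturated, and the search stalls; the
single-coordinate form (the form in which β-hill climbing was originally
described) keeps the acceptance rate useful and lets the search strip noise
genes one at a time.  Second, the default reset probability inside
`igwo_fs()` is $1/D$ rather than a fixed constant, so a candidate resets
one coordinate in expectation regardless of the gene count; a fixed rate of
a few percent resets ~10 coordinates per candidate at $D = 200$ and drowns
the single-coordinate improvements.  (`abhc_refine()` used standalone in a
few dimensions keeps a conventional fixed default of 0.05.)

### Budgets

Defaults are `pack_size = 20` and `fs_iters = 300` with 50 hill-climbing
candidates per iteration — a few thousand subset evaluations, in line with
what wrapper-selection studies typically spend, and chosen after watching
convergence traces on the synthetic recovery problem below: the
best-subset size is still decreasing at 100–200 iterations, so shorter runs
systematically return larger, noisier subsets.  One selection run on a
60 × 200 matrix takes a few seconds on one core.

## The classifier

A first-order Sugeno system over the $d$ selected genes with $R$ rules.
Rule $r$ has one generalized bell membership per input,

$$\mu(x) = \frac{1}{1 + \left|\frac{x - c}{a}\right|^{2b}},$$

and a linear consequent $f_r(x) = p_r^\top x + r_r$.  The five layers are:
membership degrees; rule firing strengths $w_r = \prod_j \mu_{rj}(x_j)$;
normalized strengths $\bar w_r = w_r / \sum_k w_k$ (summing to 1); weighted
rule outputs $\bar w_r f_r(x)$; and their sum, the crisp output $f$.
Class labels are regressed as 0/1 and thresholded at $f \ge 0.5$ (the
boundary goes to class 1).

**Rule generation.**  The textbook grid partition (one membership per input
per linguistic level, rules for every combination) is exponential in $d$
and unusable beyond a handful of inputs, so rules are generated by scatter
partitioning: seeded k-means places `n_rules` (default 4) cluster centres;
each rule's bell centres sit at the cluster centre, widths equal the
within-cluster SD per dimension floored at
$\max(10^{-3},\,0.1\cdot\text{column SD})$, and the shape exponent starts
at 2.  The width floor matters: single-member clusters otherwise produce
spike memberships whose products underflow.  Firing strengths are
normalized in log space for the same reason — with tens of inputs the raw
product of memberships can underflow double precision even for reasonable
bells.

**Consequent estimation.**  With premises fixed, the output is linear in
the consequents; all $R(d+1)$ of them are solved jointly by least squares
on the regressor blocks $\bar w_r [x, 1]$.  When the system is
rank-deficient — routine, since $R(d+1)$ often exceeds $n$ — the
minimum-norm solution is taken rather than failing.  The minimum-norm
choice behaves like an implicit ridge at zero and is the main guard against
wild extrapolation, but overfitting on very small folds remains the
method's chief risk (see Limitations).

## Parameter tuning

The premise parameters are tuned by a population metaheuristic in the chimp
style: the four best agents act as *attacker*, *barrier*, *chaser* and
*driver*; every agent moves to the clipped mean of four candidates
$x_k' = x_k - a_k\,|c_k x_k - m_k x|$, with $a = 2fr_1 - f$, $c = 2r_2$,
and $m$ drawn from a per-agent chaotic stream.  Numerical choices that the
update family leaves open, fixed here once:

* the hunt coefficient declines along $f(t) = 2.5\,(1-t/T)^2$, a quadratic
  satisfying the required endpoints (2.5 down to 0) and front-loading
  exploration;
* the chaotic stream is the logistic map $m' = 4m(1-m)$, one independent
  stream per agent (initialized from the seeded uniform stream, with states
  that escape $(0,1)$ — the map's image of exactly 0.5 is 1, then 0 — reset
  to `chaotic_seed`);
* the final four-candidate combination is their arithmetic mean;
* non-finite objective values are treated as $+\infty$ (candidate
  rejected).

Search bounds: bell centres within each input's observed range widened by
one SD; widths in $[10^{-3}, 3\,\mathrm{SD}]$; shapes in $[0.5, 5]$ (the
exponent $2b$ keeps the bell defined and numerically sane in that range);
consequents in $[-10, 10]$ when searched directly.  Two tuning modes are
exposed because "the optimizer adjusts the network parameters" genuinely
underdetermines the split: `"hybrid"` (default) searches only the premise
parameters and refits consequents by least squares inside every objective
evaluation; `"full"` searches the flattened full vector.  Hybrid is the
classical ANFIS arrangement and converges much faster per evaluation; full
is cheaper per evaluation but needs many more iterations.  The incumbent
model is always injected into the initial population, so the tuned training
MSE cannot exceed the initial model's; a zero-iteration budget returns the
initial model with consequents refit.

## Evaluation

`confusion_matrix()` tallies actual × predicted counts;
`class_metrics()` reports accuracy, recall, specificity, precision,
F-score and G-measure per class, and `macro_metrics()` their unweighted
means.  The G-measure is defined as $\sqrt{PR}$, the geometric mean of
precision and recall: among the definitions in circulation this is the one
whose values are internally consistent with the accompanying recall and
specificity columns of the reference tables the test suite reproduces (the
$\sqrt{\text{recall}\cdot\text{specificity}}$ alternative is not).
Undefined precision (no predicted positives) is reported as 0 with an
explicit flag so macro averages stay defined.  In the binary case
specificity of one class equals recall of the other; the tests assert this
duality on random matrices.  Percentages are displayed rounded half-up to
two decimals; raw fractions are kept internally.

Both a stratified k-fold protocol (pooling test predictions into a single
confusion matrix) and a single stratified holdout split are provided —
small-cohort studies report either, and the two can disagree noticeably at
these sample sizes, so neither is anointed.

## What the synthetic generator does and does not emulate

`synthetic_expression()` reproduces the *shape* of two-class microarray
data: $n_{\text{genes}} \gg n_{\text{samples}}$, imbalanced classes
(default 40% class 1), a small planted set of informative genes whose
class-1 mean is shifted (default 2 SD), everything else standard normal.
It does **not** emulate gene–gene correlation, batch effects, heavy-tailed
intensity distributions, or probe-level artefacts; passing the recovery
tests therefore demonstrates that the search and classifier machinery work
as specified, not that the pipeline attains any particular accuracy on
real chips.

The packaged study conditions are 60 samples × 200 genes with 10
informative genes at shift 2.  At this size the full 10-fold pipeline runs
in about a minute on one core, which is also the problem size the test
suite and the acceptance script use.  (The real datasets this shape mimics
are an order of magnitude wider; the method scales in the number of
genes mainly through the wrapper CV cost.)

## Known limitations

* **Run-to-run variability of the selection stage.**  Under the study
  conditions the wrapper accuracy saturates at 1.0 early, after which only
  the weak parsimony term drives the search across a plateau riddled with
  strict local optima (subsets where *every* single-gene removal breaks CV
  perfection).  Typical seeded runs enrich the planted genes 5–20-fold over
  random expectation, but occasional runs stall on such an optimum at
  ~3-fold.  This is a property of the greedy-acceptance fitness landscape,
  not of the implementation; sideways moves would cure it but are excluded
  by the strict-improvement rule.
* **Overfitting of the consequents.**  $R(d+1)$ free consequents against a
  few dozen samples relies on the minimum-norm solution for regularization;
  very small training folds can still produce optimistic training MSE.
* Binary phenotypes only; no missing-value handling (reject at load); no
  multi-class macro metrics.
* The tuning stage optimizes training MSE; no early stopping or validation
  split exists inside the fit, so model selection must happen through the
  outer protocol.
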