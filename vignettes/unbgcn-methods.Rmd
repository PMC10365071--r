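---
title: "Atrophy-pattern biomarkers and population-graph classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atrophy-pattern biomarkers and population-graph classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unbgcn)
```

# Overview

`unbgcn` implements a two-stage framework for studying Alzheimer's-disease
(AD) related cortical atrophy from vertex-wise cortical-thickness data:

1. a **univariate neurodegeneration biomarker (UNB)** per region of
   interest (ROI), scoring how similar an individual's vertex-wise atrophy
   pattern is to the AD-group atrophy pattern, and
2. a **semi-supervised graph convolutional network (GCN)** that classifies
   subjects on a *population graph* — nodes are subjects carrying their
   34-dimensional UNB vectors as features, edges count matching phenotypes
   (age, gender, APOE $\varepsilon4$ count) — with an embedded dot-product
   attention module that reweights ROIs and makes the model's regional
   focus inspectable.

A statistical evaluation suite (minimum sample size, change rates, paired
effect sizes, Pearson correlations, rank-based ROC/AUC) and a synthetic
cohort generator complete the package, so every stage is testable without
access to any clinical dataset.

# The biomarker

## Covariate adjustment

Thickness at each registered vertex is adjusted by an ordinary
least-squares model on age and a binary gender indicator
(`adjust_glm()`). Two details matter:

* In the **group-pattern path** the model is fitted on the pooled
  AD + CU (cognitively unimpaired) sample with *group indicators retained
  as covariates*, so that the diagnostic difference of interest is not
  absorbed into the age/gender estimates and regressed away.
* In the **individual path** the model is fitted on the CU reference only
  and its coefficients are applied to all subjects, so each test subject
  is adjusted by the reference population's covariate structure.

The returned values subtract only the age and gender terms, centred at
the fitting sample's means — the output stays on the millimetre scale of
the input. A single-gender or collinear design raises an explicit
degenerate-design error rather than producing silently unstable
estimates.

## Atrophy patterns and the t-to-z map

The **group atrophy pattern** is the vertex-wise pooled-variance
two-sample t statistic for (AD mean − CU mean), and the **individual
pattern** standardizes one subject against the CU reference with the
prediction-interval denominator

$$ t_v = \frac{x_v - \bar{x}^{CU}_v}{s^{CU}_v\sqrt{1 + 1/n_{CU}}},
\qquad \mathrm{df} = n_{CU} - 1, $$

which treats the subject as a new draw from the CU population; under the
null the resulting scores are standard normal (verified by a
Kolmogorov–Smirnov check in the test suite). Both kinds of t statistics
pass through the exact quantile transform
$z = \Phi^{-1}(F_t(t;\mathrm{df}))$ (`t_to_z()`), evaluated on the log
scale of the nearer tail so that extreme statistics map to finite,
accurate z-scores instead of saturating at infinity. Thinner-than-reference
cortex yields negative z by construction.

## The per-ROI score

For ROI $k$ with vertices $i = 1,\dots,m_k$,

$$ \mathrm{UNB}_k \;=\; \frac{1}{100}\sum_{i=1}^{m_k}
   Z^{\mathrm{ind}}_{k i}\; Z^{\mathrm{grp}}_{k i}. $$

Concordant atrophy — both patterns negative at the same vertices —
contributes positively, so a larger score means the individual's atrophy
topography is closer to the AD group's. The divisor 100 is a fixed scale
constant, kept verbatim and deliberately not configurable: it affects
only the feature scale seen by the classifier. The implementation is a
vectorized grouped inner product; the test suite pins it against a naive
double loop to $10^{-12}$ relative error. `compute_unb()` is bilinear in
its inputs, which the property tests exploit.

# The population graph

Edges count matching phenotypes (`build_adjacency()`):
$W(m,n) = \sum_{l=1}^{P} \alpha\!\left(M_l(m), M_l(n)\right)$, with
$\alpha$ a Kronecker delta for categorical phenotypes and a *strict* unit
step $1[|a-b| < \theta]$ for numeric ones — a tie at exactly $\theta$
scores 0, as the step's printed inequality demands. The default
specification uses age ($\theta = 2$ years), gender (categorical) and
APOE $\varepsilon4$ allele count (numeric, same $\theta$; a categorical
treatment is one configuration flag away, since a threshold of 2 on a
0/1/2 count only separates the two homozygous extremes).

Two operators are derived from $W$:

* `normalized_laplacian()`: $L = I - D^{-1/2} W D^{-1/2}$, the spectral
  reference object, eigenvalues in $[0,2]$. Isolated nodes resolve the
  0/0 limit to an identity row.
* `renormalized_propagation()`:
  $S = \tilde D^{-1/2}(W + I)\tilde D^{-1/2}$, the self-looped first-order
  realization of spectral graph convolution used inside every network
  layer. It is symmetric with spectral radius at most 1. Note that its
  *row sums* may legitimately exceed 1 on irregular graphs (a low-degree
  node attached to high-degree hubs); the invariant worth testing is the
  spectral bound, and that is what the suite asserts.

A full eigendecomposition filter is kept as the reference oracle in the
tests (reconstruction of $L$ and the graph Fourier round-trip), not as
the runtime path: the first-order form costs $O(|E|)$ per layer and is
the standard realization of the generic spectral convolution.

# The classifier

## Architecture

With node features $X \in \mathbb{R}^{N\times M}$:

1. **Attention module** (optional): pairwise node similarities
   $Y = XX^\top$, a learnable linear map
   $\mathbb{R}^N \to \mathbb{R}^M$ applied row-wise, a row-wise softmax
   giving the attention map $A$ (each subject's ROI weights form a
   distribution), and elementwise refinement $Z = X \odot A$. The softmax
   runs over the feature axis so that the column means of $A$ are
   directly interpretable as ROI weights, which is what
   `rank_roi_attention()` reports (normalized to sum to 1, descending,
   with entries below the 0.05 display threshold flagged rather than
   dropped).
2. $K$ hidden layers $H^{(k+1)} = \mathrm{ReLU}(S H^{(k)} \Theta^{(k)})$
   (default $K = 3$, width 16),
3. a linear graph-convolution output layer followed by a row-wise
   softmax.

Training is whole-graph and transductive: all nodes propagate, the
cross-entropy loss is computed on train-mask nodes only, so held-out
labels cannot influence gradients — asserted bit-for-bit in the tests by
flipping every test label and comparing trained weights.

## Optimization choices

The optimizer is Adam (learning rate 0.01, weight decay $5\times10^{-4}$
added to the gradient), 200 epochs, dropout 0.3 applied to the input of
each hidden layer during training only. Layer weights use symmetric
uniform (Glorot) initialization. The backward pass is hand-derived and
was verified against central finite differences (max absolute error
$\sim 10^{-10}$) before the implementation was frozen.

The **attention linear map is zero-initialized** (weights and bias). This
is a deliberate design choice: entries of $Y = XX^\top$ are $O(M)$, so a
fan-in-scaled random map saturates the row softmax at initialization; the
gradient through a saturated softmax is negligible, the weight-decay term
dominates, and the ReLU stack collapses into its all-zero fixed point
from which no signal recovers. Zero initialization instead starts the
module at the uniform map $A = 1/M$ — exactly the plain-GCN operating
point scaled by $1/M$ — and lets the attention weights move only as the
loss demands. With `attention_enabled = FALSE` the module is absent
entirely and the training path is bit-identical to a plain GCN (asserted
against an independently coded trainer in the tests).

Prediction is the argmax of the deterministic forward pass; exact
probability ties resolve to the lowest class index.

## Validation protocol

`cross_validate()` implements the repeated-random-split reading of the
protocol: stratified 90/10 train/test splits repeated 10 times, each
split training transductively with the test nodes present but unlabeled,
reporting ACC/SEN/SPE/AUC with mean and SD. Where a k-fold procedure is
preferred it can be emulated by setting `test_fraction = 1/k` and
`n_repeats = k` with distinct seeds; the repeated-split form is the
default because it is the one fully specified by the protocol
description. `grid_search()` evaluates an exhaustive parameter grid via
the same routine and breaks accuracy ties toward the smaller model, then
toward the earlier grid entry, so results are reproducible.

# The evaluation suite

* **Minimum sample size**: $N = \lceil C\,\sigma^2/(m-b)^2\rceil$, with
  $\sigma$ the SD of per-subject 24-month change in the total biomarker
  and $m - b$ its mean. The constant $C$ is not fixed by the formula's
  usual presentation; the default is the standard power convention
  $C = (z_{0.975} + z_{0.80})^2 \approx 7.8489$ (80% power, two-sided
  $\alpha = 0.05$), exposed via `power_constant()` and configurable
  everywhere it is consumed. Published cohort values of this quantity
  depend on that convention and on cohort-specific variability, so only
  the *ordering* across diagnostic groups is a portable prediction.
* **Change rate**: $R_f = (f_\mathrm{second} - f_\mathrm{first}) /
  f_\mathrm{first}$.
* **Paired comparison**: two-sided paired t-test p-value plus paired
  Cohen's d, $\bar{d}/s_d$.
* **ROC/AUC**: the rank (Mann–Whitney) formulation with ties counted one
  half — exactly the all-pairs concordance probability, which the tests
  assert against an $O(n^2)$ pair loop and against an independent ROC
  implementation. The 95% CI uses a stratified bootstrap (positives and
  negatives resampled separately; 2000 resamples; seeded), since no
  closed-form convention is mandated.
* **ICV adjustment** for the volume baseline: volume divided by
  intracranial vault volume.

# The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the method
assumes: vertex-wise thickness around a 2.5 mm cortical baseline with
per-vertex offsets shared across subjects, linear age thinning, a gender
offset, a per-subject global offset, independent Gaussian measurement
noise, a planted group atrophy effect (AD strongest, MCI intermediate,
CU none) on a random subset of "affected" ROIs, and a 24-month follow-up
that deepens the thinning on affected ROIs by a group-specific amount
plus a subject-level deviation.

Default conditions (fixed once, not revisited): 40 subjects per group,
34 ROIs with 100 vertices each, atrophy effects 0.3 / 0.15 mm on 30% of
ROIs, noise SD 0.25 mm, age slope −0.005 mm/year, gender offset 0.05 mm,
declines 0.12 / 0.06 / 0.02 mm with a 0.08 mm between-subject decline SD.
The decline SD is essential: without between-subject heterogeneity in the
rate of change, the minimum-sample-size formula degenerates to $N = 1$
for every group. With it, the $\sigma/\Delta$ ratios place the group
sample sizes in the single-to-low-hundreds range with the ordering
$N_{AD} < N_{MCI} < N_{CU}$ — the qualitative pattern a more sensitive
biomarker should show — while individual-cohort estimates of $N$ remain
visibly noisy at 40 subjects per group, exactly as ratio estimators are.

`planted_feature_graph()` is the classifier's sanity fixture: two classes
of nodes whose feature means are separated by a Mahalanobis distance of
`separation` noise-SDs, with phenotypes whose class-assortativity scales
with the *same* knob. This single-knob coupling is deliberate: at
`separation = 0` the fixture is an exact null (features uninformative
*and* graph class-independent, so chance-level accuracy is the correct
outcome), while at `separation = 5` the phenotype graph is strongly
assortative. The latter matters because the GCN applies $K + 1 = 4$
propagation steps; on a dense weakly-assortative graph the self-loop
weight is $O(1/\text{degree})$ and repeated neighbourhood averaging
erases class structure (oversmoothing) no matter how separable the raw
features are.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: spatial correlation of
thickness between neighbouring vertices, registration or segmentation
error, scanner/site effects, non-Gaussian heavy-tailed noise,
age-by-group interactions, and diagnostic label noise. Results on the
synthetic cohorts validate the *implementation* of the pipeline and the
internal consistency of its statistics, not clinical performance.

# Numerical and degenerate-input conventions

* `t_to_z()` works on the log-CDF of the nearer tail; monotone, exact,
  sign-preserving, finite for $|t|$ far beyond practical ranges.
* Zero pooled variance (group pattern) or zero reference variance
  (individual pattern) raises an error naming the offending vertex and
  ROI.
* Isolated graph nodes: identity row in $L$; always well-defined in $S$
  because renormalization adds a self-loop.
* Softmaxes subtract the row maximum before exponentiation.
* Probabilities are floored at $10^{-300}$ inside the loss only.
* Ties: strict inequality in the phenotype unit step; lowest class index
  at prediction; smaller-model-then-first-listed at grid-search ties.
* Determinism: every stochastic routine takes a seed and restores the
  caller's RNG state; identical config + seed reproduces cohorts, splits,
  training histories and bootstrap CIs bit for bit.

# Problem sizes used by the tests

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own verification conditions: planted graphs of 100 nodes
with 10 features, cohorts of 40 subjects per group at 34 ROIs × 100
vertices, 10–20 seed replicates per property, 200-epoch whole-graph
training. At these sizes the complete suite runs in well under a minute
per module on one CPU.

# Graph informativeness and depth: an honest caveat

The transductive GCN's usefulness depends on the population graph
carrying class structure. On the synthetic cohorts generated with
*realistic* phenotype distributions — age distributions that overlap
heavily between diagnostic groups, gender unrelated to diagnosis, APOE
moderately enriched in AD — the phenotype graph is dense (over 90% of
pairs share at least one phenotype) and only weakly assortative (mean
within-class edge weight barely above between-class). Each of the
$K + 1$ propagation steps then attenuates node-specific signal by
roughly the assortativity contrast, and at the default depth $K = 3$ the
classifier cannot beat chance on such cohorts *even when the raw UNB
features separate the groups perfectly* — we verified that the identical
model with an edgeless graph ($S = I$) classifies the same features
flawlessly. This is the well-known oversmoothing behaviour of deep
mean-aggregating graph networks, not an implementation defect, and it is
why the classifier's recovery guarantees are stated on the
`planted_feature_graph()` fixture, whose assortativity is controlled.
On real cohorts the practical mitigations are the ones the protocol
itself provides: grid-search the depth (shallower models tolerate
uninformative graphs far better) and choose phenotypes whose similarity
actually correlates with diagnosis. The biomarker and the statistical
suite are unaffected — on the same cohorts the total UNB separates the
groups with AUC near 1 and yields clean longitudinal orderings.

# Known limitations

* The attention map's linear layer is tied to the number of nodes $N$,
  so a trained model transfers only to graphs of the same size — an
  inherent property of this attention design, acceptable in the
  transductive setting it serves.
* Whole-graph training only; no mini-batching, no GPU path. Intended
  scale is hundreds to a few thousand subjects.
* Binary AUC only in the cross-validation report; multi-class splits
  report accuracy but leave AUC as `NA`.
* The volume-biomarker baseline is supported through `icv_adjust()` plus
  the same graph/classifier machinery; no volumetric extraction from
  images is provided — the package consumes already-extracted tables.
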