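---
title: "Ising-formulated classification: model, solvers, and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ising-formulated classification: model, solvers, and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isingml)
```

# The model and its assumptions

`isingml` trains multinomial classifiers whose weights are spins. The
probability model is the pivot softmax: with $K$ classes, only the first
$K-1$ classes carry weight vectors $w_k \in \mathbb{R}^M$ and

$$\Pr(y=k\mid x) = \frac{e^{w_k^\top x}}{1+\sum_{k'=1}^{K-1} e^{w_{k'}^\top x}},
\qquad \Pr(y=K\mid x)=\frac{1}{1+\sum_{k'} e^{w_{k'}^\top x}}.$$

The pivot is the *last* class in `class_names` order; relabeling a
dataset therefore changes the encoded problem, which is why
`labeled_dataset` fixes the class order explicitly.

Training minimizes the negative log likelihood (in nats throughout). A
second-order Taylor expansion around $w = 0$ gives a quadratic form in
the $D = M(K-1)$ weights with coefficients

$$b_k = -\sum_{i:y_i=k} x_i,\quad h = \tfrac1K \sum_i x_i,\quad
J' = \tfrac{K-1}{2K^2}\sum_i x_i x_i^\top,\quad
J'' = \tfrac{1}{2K^2}\sum_i x_i x_i^\top,$$

assembled as
$\sum_k w_k^\top(b_k+h) + \sum_k w_k^\top J' w_k
 - \sum_k\sum_{j\ne k} w_j^\top J'' w_k$.
Restricting each weight to $\{-1,+1\}$ turns this into an Ising
Hamiltonian. Two bookkeeping conventions matter and are easy to get
wrong:

* **Pair counting.** The quadratic form $w_k^\top J' w_k$ visits each
  unordered intra-block pair twice, and the double sum over
  $j \neq k$ visits each unordered block pair in both orders. The
  strictly-upper-triangular storage therefore holds $2J'_{mn}$
  (intra-block) and $-2J''_{mn}$ (inter-block) per stored pair. The
  binomial sanity check — for $K=2$ the encoded objective must equal the
  closed-form second-order Taylor expansion of the logistic negative log
  likelihood, gradient $\sum_i(\tfrac12 - \mathbf{1}[y_i{=}1])x_i$ and
  Hessian $\tfrac14\sum_i x_i x_i^\top$ — only holds with this factor of
  two, and the test suite asserts it to $10^{-12}$.
* **Diagonal folding.** Under $\pm 1$ spins $w_{km}^2 = 1$, so the
  diagonal of $J'$ is a constant. It is moved into the scalar `offset`,
  keeping the quadratic strictly pairwise as annealing hardware
  requires. Energies reported by all solvers include the offset.

The expansion is around zero, so it is most faithful when features are
standardized — the evaluation pipeline z-scores every training split —
and it degrades as $K$ grows (the neglected higher-order terms carry
factors of the class count), which is a known limitation of the
approach rather than of this implementation.

Assumptions, in short: continuous standardized features; a linear
decision structure per class; training signal expressible through first
and second moments; and a tolerance for weights quantized to $\pm 1$ or
small rational averages thereof.

# Solvers

All solvers operate on the *scaled* problem: `scale_to_unit` divides
every coefficient by $\max(|h|_\infty, |J|_\infty)$, mimicking the
automatic rescaling of annealing hardware, so that one
inverse-temperature grid behaves consistently across datasets. Positive
scaling preserves the complete energy ordering (asserted exhaustively in
the tests for small $D$).

**Simulated annealing** uses single-spin Metropolis updates. Per read:
random $\pm1$ start, then `n_sweeps` (default 1000) full passes over the
spins in fixed index order; the inverse temperature rises linearly from
`beta_initial` (default 0.01) to `beta_final`, evaluated once per sweep.
A flip is accepted with probability $\min(1, e^{-\beta\,\Delta E})$,
with $\Delta E$ computed exactly from cached local fields. The update
order is not specified by the classical SA literature this follows;
sequential order was chosen for bitwise determinism — agreement with a
random-order implementation is statistical, not bitwise. One `mt19937`
stream per call consumes draws in (read, spin) order, with one uniform
per proposed flip, so results are a pure function of
(problem, schedule, reads, seed). `beta_final` is the only tuned
hyperparameter, over the grid $\{0.03, 0.1, 0.3, 1, 3\}$, by stratified
10-fold cross-validation scored on balanced accuracy; ties resolve to
the smaller value (the less aggressive optimizer).

**Random** draws each spin from a fair coin (`u < 0.5` maps to $-1$) and
sorts the reads by energy — a control for how much of the method's value
lies in the Ising objective itself rather than in optimizing it well.
**Field** sets $s_i = -\mathrm{sign}(h_i)$ (ties to $+1$), the exact
minimizer when couplings vanish. **Exhaustive** enumerates all $2^D$
configurations for $D \le 20$ with lexicographic tie-breaks and serves
as the oracle in the tests.

# From spin ensembles to classifiers

Low Ising energy is a surrogate: the quadratic objective approximates
the likelihood, so the lowest-energy read is not necessarily the best
classifier. `postprocess_average` therefore deduplicates the reads,
keeps the `n_keep = 20` lowest-energy configurations, and greedily scans
them in ascending energy, adding a configuration to the running average
only if the enlarged element-wise mean *strictly lowers the exact
negative log likelihood* on the training data. The objective for this
test is deliberately the exact likelihood, not the Ising surrogate, and
the greedy scan (rather than a $2^{20}$ subset search) keeps
postprocessing cheap. The result never has higher training NLL than the
single best-energy configuration — a contract the suite checks on a
thousand random instances.

# The classification RBM

The fourth Ising-family classifier is a restricted Boltzmann machine
with the one-hot label block appended to the visible layer. Training is
one-step contrastive divergence, batch size 32: hidden units are
*sampled* as Bernoulli variables in the positive phase (the binarization
that plausibly contributes to the family's overfitting resistance),
while the negative phase reconstructs feature units as sigmoid means and
label units as a softmax. Prediction clamps each candidate label,
computes the free energy with hidden units summed out analytically, and
normalizes $e^{-F(x, e_k)}$ over $k$ — this equals the exact conditional
$\Pr(\text{label}\mid\text{features})$ under the model, verified in the
tests against full $2^H$ enumeration to $10^{-10}$.

Design choices where the source protocol is silent: continuous features
are min-max rescaled to $[0,1]$ on the training split and used as
Bernoulli activation probabilities (Gaussian visible units are out of
scope); hidden-layer size defaults to 64, learning rate 0.1, 100
epochs; initialization is centered uniform scaled by
$1/\sqrt{M+K+H}$, seeded. Feature importance is not reported for RBMs —
there is no per-feature weight with a sign to read off.

# Evaluation protocol

The harness enforces a strict train/test separation: per stratified
split (per-class round-half-up at the requested fraction), z-scoring is
fitted on the training rows only (denominator $N-1$; constant columns
map to zero), PCA loadings come from the SVD of the centered training
matrix with a largest-loading-positive sign convention, and test rows
are projected with training statistics only. The tests assert the
transforms are *bitwise* unchanged when test rows are replaced.

Metrics: accuracy; balanced accuracy (unweighted mean of per-class
recall — the ranking metric throughout, robust to class imbalance); ROC
AUC (Mann–Whitney with mid-rank ties; macro one-vs-rest for $K>2$); F1
(positive class = second listed class for $K=2$, macro otherwise).
Classifiers are compared with two-sided Wilcoxon signed-rank tests
paired over identical splits, Bonferroni-corrected by the number of
classifier pairs within a metric. SEM uses the number of splits as $n$.
Training-fraction sweeps draw class-balanced subsamples of a fixed
training pool (50 replicates by default) and score against one held-out
test set; overfitting is summarized as the train-minus-test balanced
accuracy gap.

Standard baselines (unconstrained logistic regression via `glm`,
lasso/ridge via `glmnet`) are invoked through a thin adapter for
comparison runs only. Random forest, naive Bayes, and SVM adapters were
omitted: their canonical R implementations are not available in the
supported dependency set, and baselines are outside the package's
correctness contract.

Every random draw descends from one master seed through a documented
(stream, index) mixing scheme (`derive_seed`), so a full experiment
rerun with the same configuration is byte-identical, which the suite
checks on the emitted CSVs.

# The synthetic-data generator

`make_multiomics` emulates the statistical silhouette of a concatenated,
standardized multi-omics matrix: multivariate normal features with
block-constant correlation $\rho$ inside feature blocks (one block per
platform) and independence across blocks, via a shared per-block factor;
class-dependent mean shifts concentrated on a few informative features
with planted signs $s_j \in \{-1,+1\}$; marginal standardization of the
output. Class $k$ shifts informative feature $j$ by
$\delta\, s_j z_k$ with class scores $z_k$ equally spaced from $+1/2$
(class 1) to $-1/2$ (class K), so `effect_size` $\delta$ is the
between-extreme-class separation in noise-sd units. Defaults (e.g.
$\delta = 2$, a few informative features among tens of noise features,
$n$ from tens to a few hundred per class) reflect the regime the method
targets: real multi-omics cohorts have modest effect sizes spread over
correlated features and $n \ll M$ after feature explosion.

What the generator does *not* emulate — and hence what a green test does
not establish: heavy-tailed and zero-inflated platform distributions,
batch effects, label noise, nonlinear class structure, and the empirical
covariance of any real cohort. Green tests establish that the machinery
(encoding, optimization, postprocessing, leakage-free evaluation) is
correct and that qualitative phenomena (small-sample robustness of
discrete weights, parameter-sign recovery) appear under the stated
generative world; they do not certify performance numbers on real data.

`make_separable_toy` is a two-Gaussian oracle fixture for
exact-recovery tests, and `worked_fixture` pins the one-sample, one-
feature, two-class encoding that is fully hand-checkable
(linear $-0.5$, offset $0.125$, minimum at spin $+1$ with energy
$-0.375$).

# Numerical choices and degenerate inputs

* Softmax and RBM free energies use max-subtraction / `log1p` guards, so
  probabilities are strictly positive and sum to 1 within $10^{-12}$
  for any finite scores; a genuinely zero probability in an explicit
  probability table yields `Inf` NLL rather than an error.
* A perfect probability table gives *exactly* 0 nats (a `0 - x`
  formulation avoids IEEE signed zero).
* `scale_to_unit` of an all-zero problem returns it unchanged.
* Prediction ties break toward the lowest class index; field-solver
  ties at $h_i = 0$ break to $+1$; exhaustive enumeration breaks energy
  ties lexicographically ($-1$ before $+1$).
* Classes with fewer members than the fold count reduce the fold count
  to the minimum class size with a warning.
* Cross-validation subsets keep the full class indexing of their parent
  dataset, and encoding tolerates a class with no samples (its $b_k$ is
  empty); this also covers the single-sample worked fixture.

# Budget scaling in the test suite

The acceptance tests run the solver-oracle comparison at the protocol's
full scale (100 instances, 1000 reads, 1000 sweeps) and the
small-sample phenomenon with 20 seeds at $M = 44$; per-module unit tests
use reduced reads/sweeps purely to keep the suite fast. Reduced scale is
a runtime choice, never a tolerance change: thresholds (95% optimum hit
rate, 95% sign recovery, $p < 0.05$ paired one-sided tests) are the
stated ones wherever they are asserted.

# Known limitations

* The quadratic expansion degrades with many classes; for large $K$ the
  RBM (which does not share the approximation) is the better
  Ising-family choice.
* Weights are binary (or ensemble-averaged); with abundant training
  data, unconstrained baselines will typically win — the method's niche
  is the small-$n$, high-$M$ regime.
* The SA implementation is a plain sequential-sweep Metropolis
  annealer; no parallel tempering, no hardware submission, no graph
  embedding.
* Multiclass AUC is macro one-vs-rest; other multiclass AUC conventions
  exist and give different numbers.
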