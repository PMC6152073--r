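---
title: "Predicting drug-target interactions from PSSM bi-gram profiles with a relevance vector machine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-target interactions from PSSM bi-gram profiles with a relevance vector machine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtirvm)
```

## The problem

Experimentally mapping which drugs bind which protein targets is slow and
expensive, so computational screening of candidate drug-target
interactions (DTIs) is used to prioritize assays. A DTI collection is
naturally a bipartite network: drug nodes on one side, protein targets on
the other, with an edge for each experimentally confirmed interaction.
Confirmed edges are a tiny fraction of the drug x target grid (a typical
enzyme benchmark has 2,926 interactions among 445 x 664 = 295,480
possible pairs), so the learning problem is to score unobserved pairs
using only sequence-derived information about the targets.

`dtirvm` implements one sequence-based pipeline end to end:

1. protein profiles (PSSMs) from PSI-BLAST,
2. 400-dimensional bi-gram transition features per protein,
3. PCA reduction of the feature matrix (400 to 350 by default),
4. a sparse Bayesian relevance vector machine (RVM) on labeled pairs,
5. balanced negative sampling and stratified k-fold evaluation with
   accuracy (Ac), sensitivity (Sn), precision (Pe), Matthews correlation
   (Mcc) and ROC/AUC.

## Profiles and bi-gram features

A PSSM for a protein of length $L$ is an $L \times 20$ matrix of
log-odds substitution scores in PSI-BLAST column order. Raw scores are
integers of magnitude roughly $\pm 10$; positive entries mark conserved
positions. The package parses the `-out_ascii_pssm` dialect
(`parse_psiblast_pssm()`), keeping only the log-odds block and keeping
rows for nonstandard residues (X/B/Z/U) so that the row count always
equals the sequence length.

Bi-gram features need probability-like entries. The default mapping is
the element-wise logistic $p = 1/(1 + e^{-s})$, which sends log-odds
scores to $(0,1)$ monotonically; a shifted row-sum normalization (each
row shifted by its minimum and scaled to sum to 1) and the raw identity
are available for sensitivity analysis. The choice among these is a
genuinely open design point — simple "relative probability" recipes for
PSSMs are ambiguous — so all three are exposed, with sigmoid as the
default because it is the common practice in the bi-gram-from-PSSM
literature and requires no handling of non-positive row sums.

The bi-gram feature of a normalized profile $P$ is
$$
B_{mn} \;=\; \sum_{i=1}^{L-1} P_{i,m}\,P_{i+1,n},
\qquad 1 \le m, n \le 20,
$$
the expected rate of transitions from amino acid $m$ at one position to
amino acid $n$ at the next, flattened row-major ($u = 20(m-1)+n$) into a
400-vector. The flattening order is fixed so that feature indices are
comparable across implementations. Two useful exact properties follow
directly from the definition and are used as tests: scaling the profile
by $c$ scales every feature by $c^2$, and permuting amino-acid columns
by $\pi$ permutes feature $(m,n)$ to $(\pi(m), \pi(n))$.

PCA (centered, no scaling, via `stats::prcomp`) reduces the stacked
bi-gram matrix; component signs are fixed by making each component's
largest-magnitude loading positive, so that fitted models are
deterministic across BLAS implementations. PCA is fit on training folds
only by default; a `global` mode that fits once on the pooled dataset is
provided because either convention is defensible and published work
frequently leaves the choice unstated.

## The relevance vector machine

The classifier is a from-scratch sparse Bayesian kernel machine in
regression form on 0/1 labels: with design matrix
$\phi = [\,\mathbf{1}, k(x_i, x_j)\,]$ (bias column plus one basis
function per training point), the model is
$t = \phi w + \varepsilon$, $\varepsilon \sim N(0, \sigma^2 I)$, and each
weight carries an independent prior $w_i \sim N(0, \alpha_i^{-1})$. At
fixed hyperparameters the weight posterior is Gaussian with
$$
\Sigma = (\sigma^{-2}\phi^\top\phi + A)^{-1}, \qquad
u = \sigma^{-2}\,\Sigma\,\phi^\top t, \qquad A = \mathrm{diag}(\alpha),
$$
and type-II maximum likelihood re-estimates
$$
\gamma_i = 1 - \alpha_i \Sigma_{ii}, \qquad
\alpha_i \leftarrow \gamma_i / u_i^2, \qquad
\sigma^2 \leftarrow \frac{\|t - \phi u\|^2}{N - \sum_i \gamma_i},
$$
iterating until $\max_i |\Delta \log \alpha_i| < 10^{-3}$ (or 1000
iterations). Most $\alpha_i$ diverge; basis functions with
$\alpha_i > 10^{12}$ are pruned each iteration and the surviving
training points are the relevance vectors. The log marginal likelihood
$\log p(t \mid \alpha, \sigma^2)$ is recorded every iteration; on test
problems it is non-decreasing along the trajectory, which the suite
asserts to $10^{-6}$ slack.

The regression form (Gaussian likelihood on 0/1 targets, decision
threshold 0.5) is used deliberately rather than the logistic RVM with a
Laplace approximation: it is the simpler, exactly specified model whose
posterior has the closed form above, which makes every stage directly
testable against dense linear-algebra oracles. Its known cost is that
scores are uncalibrated regression outputs, not probabilities.

Defaults and their meaning:

* `kernel`: `poly2`, $(1 + x \cdot z / w)^2$ with width $w = 1$ — an
  inhomogeneous degree-2 polynomial, the conventional reading of a
  "poly2" kernel with a width parameter.
* `init_alpha = "1/N"`: all prior precisions start at 1/(number of
  training samples), a weak prior that lets the data drive sparsity.
* `init_sigma2 = max(0.1 var(t), 1e-3)`: the noise variance starts small
  but non-degenerate and is re-estimated each iteration. (Treating the
  noise precision as literally fixed at zero would make the likelihood
  improper; keeping the update active is the working interpretation.)
* `alpha_prune = 1e12`, `tol = 1e-3`, `max_iter = 1000`: standard
  sparse-Bayes practice; all surfaced in `rvm_control()`.

Numerical care: the posterior is computed by Cholesky factorization, and
on a near-singular system a single jitter of $10^{-10}\,\mathrm{tr}(H)/m$
is added before failing with a conditioning diagnostic — degree-2
polynomial Gram matrices on normalized features are routinely
ill-conditioned. $\gamma_i$ is clamped to $[0,1]$ and $\sigma^2$ floored
at $10^{-10}$ against floating-point excursions. The fit has no internal
randomness: identical inputs give bit-identical models.

## Pairs, negatives, cross-validation

Positive examples are the known edges. Negatives are sampled uniformly
without replacement from the non-edges, by default one negative per
positive (ratio 1), giving an exactly balanced dataset; sampling happens
once per experiment, before the fold split, so no fold sees resampled
negatives. The pair representation is the target protein's reduced
bi-gram vector; a drug-fingerprint concatenation hook exists in
`build_pair_dataset()` but no fingerprint computation is in scope, since
the sequence-only pipeline is self-contained. Folds are stratified by
label by default. Sensitivity is TP/(TP+FN) (recall); each metric is
reported per fold and aggregated as mean plus sample (n-1) standard
deviation, the convention used in published five-fold tables. Held-out
scores from all folds are pooled for one ROC curve, swept over unique
score thresholds with tie groups contributing diagonal segments, so the
trapezoidal AUC equals the Mann-Whitney statistic.

## What the synthetic generators emulate

The generators make every stage testable without downloads:

* `gen_pssm(L, seed)` — integer scores i.i.d. uniform on $[-10, 10]$,
  matching the magnitude of PSI-BLAST log-odds so sigmoid normalization
  operates in its realistic range. Real PSSMs have strong row structure
  (conservation) and inter-column correlation that i.i.d. scores do not
  reproduce; these matrices exercise parsing, normalization and feature
  shape, not biological signal.
* `gen_network(n_drugs, n_targets, n_positive, seed)` — uniformly random
  bipartite edge sets. Real DTI networks are heavy-tailed (hub drugs and
  promiscuous targets); uniform edges are sufficient for the counting,
  sampling and balance properties tested here.
* `gen_two_class_features(n_per_class, dim, separation, seed)` — two
  isotropic Gaussians whose mean vectors are `separation` apart in
  Euclidean distance (default 6, a well-separated regime with Bayes
  error about 0.1%). Class structure is injected at the feature level
  rather than by simulating sequence evolution, because the classifier
  consumes features and this gives a controllable effect size.

Consequently, passing tests demonstrate that the machinery is correct
and that the classifier recovers a signal that is present by
construction; they do not certify accuracy on real benchmark data, which
depends on PSI-BLAST profiles against a large sequence database.

## Problem sizes and the small-n regime

The shipped end-to-end checks use n = 200 pairs (100 per class) with
400-dimensional features reduced per fold to 10 components, and a
label-permutation control on the same data; RVM fits involve Gram
matrices of order ~160. These sizes make the full suite run in well
under a minute while leaving the separable-data accuracy criterion
(mean Ac >= 95%) comfortably met.

Two small-n effects are worth knowing. First, centered PCA requires more
samples than components, so the 350-component default is only usable
when training folds exceed 350 samples; the demonstration data has a
single informative direction (the class-mean axis), so a small
scree-consistent component count is appropriate there. Second, with only
~160 training samples the degree-2 polynomial kernel can interpolate
pure noise directions if many noise components are retained: ranking
(AUC) degrades gracefully but the fixed 0.5 threshold loses calibration.
This is a property of the regression-form RVM in the small-n regime, not
of the pipeline at benchmark scale (thousands of pairs).

A related exact-invariance caveat: duplicating every training point does
*not* leave the evidence optimum exactly unchanged — duplicated
observations double the Gaussian likelihood's weight and sharpen the
posterior — so decision scores shift at the $10^{-2}$ level while hard
classifications are stable. The suite asserts the stable quantity.

## Worked example

```{r example, eval = FALSE}
dir <- tempfile()
simulate_dataset(dir, seed = 5, n_drugs = 25, n_targets = 40,
                 n_positive = 120)
cmd_features(file.path(dir, "pssms"), file.path(dir, "features.csv"))

net <- gen_network(445, 664, 2926, seed = 1)
possible_pairs(net)                        # 295480
nrow(sample_negatives(net, 1, seed = 1))   # 2926 balanced negatives

g <- gen_two_class_features(100, 400, separation = 6, seed = 11)
report <- run_cv(as_pair_dataset(g$X, g$labels), k = 5,
                 pca_components = 10, seed = 11)
report
```

## Known limitations

* Running PSI-BLAST is out of scope; the package consumes its ASCII
  output. (For profile construction the conventional settings are an
  e-value threshold of 0.001 and three iterations.)
* No drug descriptors are computed; the default pair representation is
  protein-only, with a concatenation hook for externally supplied drug
  features.
* Scores are not calibrated probabilities; the 0.5 threshold is a
  convention, and threshold-free comparisons should use the ROC/AUC.
* The evidence iteration is the classic full-basis update, O(M^3) per
  iteration; the fast incremental (sequential) sparse-Bayes algorithm is
  not implemented, so fits beyond a few thousand training pairs are
  slow.
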