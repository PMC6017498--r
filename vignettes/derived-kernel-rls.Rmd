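---
title: "Predicting RNA-protein interactions with a derived string kernel and regularized least squares"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting RNA-protein interactions with a derived string kernel and regularized least squares}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpikrls)
```

## The problem

Whether a given RNA binds a given protein is expensive to establish
experimentally, yet the question arises for every newly annotated long
non-coding RNA. `rpikrls` implements a sequence-only classifier for
this task: it takes nothing but the primary sequences of a protein
chain and an RNA chain and returns a real-valued interaction score,
thresholded at zero into interacting (+1) versus non-interacting (-1).
Because it needs no structural information it can score any pair of
known sequences, including full bipartite grids for network
construction.

## The model

### Sequence similarity: a two-layer derived kernel

Fix an alphabet $A$ (20 amino acids, the 7-group reduced protein
alphabet, or 4 ribonucleotides) and a template size $k$. The first
layer compares $k$-mers by exact match. The second layer pools the
first over all contiguous windows of a sequence $f$ of length $n$,
giving the *neural response*

$$N_2(f)(t) = \frac{1}{n-k+1}\sum_{i=1}^{n-k+1}
  \mathbf{1}\{f_{i..i+k-1} = t\}, \qquad t \in A^k,$$

i.e. the relative frequency of each $k$-mer among the sequence's
windows. The layer-two kernel is the $L^2$ inner product of two
responses under the uniform measure on $A^k$, and with correlation
normalization

$$\hat K_2(f,g) = \frac{K_2(f,g)}{\sqrt{K_2(f,f)\,K_2(g,g)}}$$

the uniform-measure constant cancels and $\hat K_2$ is exactly the
cosine similarity of the two $k$-mer frequency vectors, so
$\hat K_2(f,f) = 1$ for every sequence. Responses are stored sparsely:
$A^k$ is never materialized ($20^4 = 160{,}000$ protein templates,
$4^8 = 65{,}536$ RNA templates), because the response is zero off the
observed $k$-mers. Higher derived-kernel layers are possible in
principle but deliberately not implemented; two layers already capture
composition and repeated-motif structure.

### Pair similarity: tensor product

An example is a pair $x = (r, p)$. Two pairs are compared by the
product of the two sequence kernels,

$$\hat K_{2dk}\big((r,p),(r',p')\big)
  = \hat K_2^R(r,r')\,\hat K_2^P(p,p'),$$

with RNA template size $l$ and protein template size $k$. A product of
positive semidefinite kernels is positive semidefinite, and the value
is 1 exactly when both factors are. This coupling lets the model share
information across proteins: an RNA with few known partners still
borrows strength from similar RNAs bound by similar proteins.

### The learner: kernel regularized least squares

Given $m$ labeled pairs with $y_i \in \{-1, +1\}$, the classifier
minimizes squared loss plus an RKHS penalty, whose representer solution
solves the linear system

$$(K + \lambda I)\,c = y, \qquad
  f(x) = \sum_{i=1}^m c_i K(x_i, x),$$

with class $+1$ predicted when $f(x) > 0$ and $-1$ otherwise (a score
of exactly zero predicts non-interaction). Some formulations divide
the loss by $m$, which only rescales $\lambda$; `scaling = "plain"`
(the default) solves the system above and `scaling = "mean"` uses
$\lambda m$, so reported $\lambda$ values can be interpreted under
either convention.

### Choosing $\lambda$: closed-form leave-one-out

$\lambda$ is selected from the grid $\{e^n : n = -15, \ldots, 15\}$ by
leave-one-out cross-validation, computed without refitting: with
$H = K(K+\lambda I)^{-1}$,

$$\hat y_i^{(-i)} = \frac{(Hy)_i - H_{ii} y_i}{1 - H_{ii}}.$$

One eigendecomposition of $K$ serves all 31 grid values, so selection
costs little beyond a single fit. The selection criterion is
leave-one-out classification accuracy of the sign rule; ties are broken
toward the largest (most regularized) $\lambda$. If $H_{ii} = 1$
(degenerate interpolation) that point's held-out prediction is taken
as 0. The module's central correctness property — the shortcut equals
explicit retrain-without-$i$ for every grid value — is asserted against
a brute-force oracle in the test suite.

## Tunable parameters

* `k` (protein template size) and `l` (RNA template size), unitless
  window lengths. Supported ranges are 1–4 (`full20`) or 1–6
  (`reduced7g`) for `k` and 1–8 for `l`; the template space grows as
  $|A|^k$, which is why the full alphabet caps `k` lower. Defaults are
  the operating points found best in the method's original evaluation:
  `k = 2, l = 5` under `full20` and `k = 3, l = 4` under `reduced7g`.
  `check_bounds = FALSE` lifts the caps for exploration.
* `alphabet`: `full20` keeps all 20 amino acids; `reduced7g` maps them
  to 7 physicochemical groups (dipole moment and side-chain volume:
  AGV / ILFP / YMTS / HNQW / RK / DE / C, encoded as digits 1–7),
  shrinking the template space and allowing larger `k` at some loss of
  discriminative detail.
* `lambda`: positive ridge parameter; `NULL` (default) triggers
  leave-one-out selection.
* Dataset-construction thresholds: pairs with protein $< 25$ aa or RNA
  $< 15$ nt are dropped (strict inequalities) before modelling;
  sequences shorter than the template size are a hard error rather
  than a silent zero vector, because user data need not respect the
  filters.

## The evaluation protocol

`rpi_cross_validate()` runs stratified $n$-fold cross-validation
(default 10). Folds are built by shuffling indices within each class
under a seeded RNG and dealing them round-robin, rotating the dealing
origin between classes; per-fold class counts and fold sizes are then
both within one of proportionality. Within each fold, $\lambda$ is
selected by leave-one-out on the training portion only — held-out
labels never influence any choice. Reported metrics are sensitivity
$TP/(TP+FN)$, specificity $TN/(TN+FP)$, accuracy, and rank-based AUC
with tied scores half-counted; a metric with a zero denominator is
reported as `NA`, never as 0. Per-fold means and standard deviations
are reported alongside pooled (confusion-sum) values, since the two
conventions differ slightly. `rpi_grid_search()` repeats the protocol
over a $(k, l)$ grid, reusing the per-size sequence kernel matrices
across cells, and selects the accuracy-maximizing cell with ties
broken toward smaller $k + l$.

## Dataset construction utilities

Real training sets are assembled from curated interface databases; the
package applies the same construction rules to any user-supplied
table: `dedupe_pairs()` removes pairs whose protein and RNA *residues*
both match an earlier pair (id-based matching is available),
`apply_length_filter()` enforces the length thresholds and returns a
drop log, and `sample_negatives()` builds a balanced negative set by
permuting the protein column over the fixed RNA column until the
result is disjoint from the positives. Pure rejection sampling can be
astronomically slow when a few hub proteins dominate, so after half
the allowed restarts a pairwise-swap repair pass is applied; if a
protein partners every RNA no conflict-free permutation exists and the
error says so. Only global disjointness from the positives is
enforced, not a per-protein derangement, since permutation marginals
already conserve both multisets.

## The synthetic generator: what it does and does not show

`simulate_rpi_data()` produces the fixture data every test runs on:
background sequences drawn i.i.d. from the alphabet (uniform by
default, or from a user composition table to emulate organism bias),
with a short protein motif (default `KWR`) and RNA motif (default
`UGCA`) planted — by replacement, preserving length — in interacting
pairs. Defaults (sequence lengths 50–200 aa / 30–120 nt, balanced
classes, `signal_rate = 1`, no label noise) were fixed once as a
plausible desk-scale caricature of curated interaction data.

Passing tests on this generator show that the pipeline recovers a
planted co-occurrence signal and finds nothing in permuted labels.
They do not show field performance: real binding involves structural
context, motif families rather than a single exact motif, shared
sequences across pairs, and heavily skewed degree distributions, none
of which the generator emulates. The composition table exists
precisely to probe one known failure mode — strongly biased amino-acid
composition degrades a composition-sensitive kernel.

## Numerical choices

* Self-kernels are asserted equal to 1 within $10^{-12}$ and then
  clamped to exactly 1 on Gram diagonals; off-diagonal cosines are
  clipped to $[0, 1]$ against rounding.
* Gram matrices are checked positive semidefinite within
  $-10^{-8} m$ on the smallest eigenvalue in the test suite.
* `rls_fit()` asserts the residual
  $\|(K+\lambda I)c - y\| \le 10^{-8}\|y\|$ on every solve.
* Kernel matrices among $N$ pairs touching $P$ proteins and $R$ RNAs
  cost $O(P^2 + R^2)$ sequence-kernel evaluations, not $O(N^2)$:
  responses are cached per distinct sequence and combined by indexing.
* Test and example problem sizes (60–200 pairs, 5–10 folds, grids up
  to $3 \times 4$) are the package's chosen desk scale; the same code
  runs unchanged on thousands of pairs, where the $m^3$
  eigendecomposition dominates.

## Known limitations

* Scores near zero are common for genuinely novel queries, so the
  fixed zero threshold yields lower accuracy than the ranking quality
  (AUC) suggests; on separable synthetic data leave-one-out AUC
  reaches 1.0 while zero-threshold accuracy plateaus near 0.8–0.9. Rank
  predictions, or calibrate a threshold on validation data, when a
  hard decision matters.
* The model is purely sequence-driven: structural and contextual
  determinants of binding are invisible to it — which is also why it
  can score any pair of known sequences.
* Ambiguous residues (X, B, Z, N, ...) are rejected or dropped
  whole-sequence by explicit policy; silent substitution is not
  offered because it would perturb k-mer profiles invisibly.

## A complete run

```{r, eval = FALSE}
sim <- simulate_rpi_data(n_pairs = 200, seed = 7)
cv <- rpi_cross_validate(sim$pairs, sim$proteins, sim$rnas,
                         k = 3, l = 4, seed = 7)
cv

fit <- rpirls(sim$pairs, sim$proteins, sim$rnas, k = 3, l = 4)
summary(fit)

scores <- predict(fit, NULL, sim$proteins[1:5], sim$rnas[1:5])
interaction_network(scores)
```
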