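---
title: "Predicting transition-state geometries from reactant and product structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting transition-state geometries from reactant and product structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Locating the transition state (TS) of a chemical reaction — the first-order
saddle point connecting the reactant and product minima on the potential
energy surface — is the expensive, failure-prone step of computational
reaction analysis. Quantum-chemical saddle-point optimizers converge only
from a good initial geometry, and building that initial guess is traditionally
manual. `tsgeom` implements a machine-learning shortcut: given an atom-mapped
reactant/product pair, it predicts all TS interatomic distances and rebuilds a
3-D geometry from them, suitable as a saddle-point starting structure or for
screening multiple reaction channels.

## Model

A reaction with $N$ atoms is represented by three conformations: the
reactant ($R$), the product ($P$), and their coordinate-wise linear
interpolation ($I$, by default the midpoint, fraction $0.5$). Each structure
contributes one feature row per unordered atom pair $(i, j)$, $i \ge j$
(diagonal pairs included, so $N(N+1)/2$ rows):

$$ f_{ij} = \big[\, e(Z_{\mathrm{hi}}) \,\|\, e(Z_{\mathrm{lo}}) \,\|\,
   g(d_{ij}) \,\big], $$

where $e(\cdot)$ is a learned entity embedding of the atomic number (width
32), and $g(d)$ is a Gaussian radial-basis expansion
$g_k(d) = \exp(-\gamma (d - \mu_k)^2)$ on 64 equidistant centers
$\mu_k \in [0, 8]\,\text{Å}$ with $\gamma = 1/(2\,\Delta\mu^2)$. The two
embedding blocks are ordered by atomic number (larger $Z$ first) rather than
by atom index, which makes the feature row — and therefore every model
output — exactly invariant under consistent relabeling of the atoms. The
default feature width is $2\cdot 32 + 64 = 128$.

The network is a stack of two *pair sequence interaction* (PSI) layers. Each
layer performs two updates:

1. a transformer-encoder block (4 heads, pre-normalization, feed-forward
   width $2w$), applied to each structure's pair set independently — a
   permutation-equivariant, size-extensive update over pairs;
2. a bidirectional GRU along the length-3 structure sequence
   $(R, I, P)$ for each pair independently, whose forward/backward state
   concatenation doubles the feature width.

With two layers the width runs $128 \to 256 \to 512$. A two-layer perceptron
(hidden width 256) reads the interpolated-structure slice of the final
features for pairs $i > j$ and emits a raw score $s_{ij}$; the predicted
distance ratio is $\exp(s_{ij}) = d^{TS}_{ij} / d^{I}_{ij}$. The exponential
makes positivity structural and places the zero-initialized model exactly at
the interpolated geometry — a sensible, chemically meaningful starting point.
An optional second head aggregates pair features to atoms
($f_i = \sum_j f_{ij}$, with the $i < j$ half recovered by symmetry) and
predicts per-atom contributions to the molecular energy and vibrational and
rotational entropies, summed to molecular values.

Because only atomic numbers and distances enter, every prediction is
rigorously invariant under rotations and translations of the inputs.

## Losses and metrics

Training minimizes $L = c\,L_1 + c'(L_2 + L_3)$ with defaults $c = 2000$,
$c' = 0$:

* $L_1$ — molecular MAE of predicted TS distances: the per-reaction mean
  absolute error over the $N(N-1)/2$ strict pairs (in pm), averaged over
  reactions, so small and large molecules weigh equally. The companion
  metric, molecular MAPE, divides each error by the true distance first and
  is the checkpoint-selection criterion (short, bonding-range distances
  matter most chemically).
* $L_2$ — the sum of MAEs of the property head over reactant and product
  labels; label components that are absent are skipped.
* $L_3$ — a Euclidean distance-matrix (EDM) penalty. For the matrix of
  squared predicted distances with eigenvalues $e_1 \dots e_N$ sorted by
  descending magnitude, $L_3 = \sum_{i \le m} e_i + \sum_{i > m} |e_i|$ with
  $m = \min(5, N)$. A distance set realizable by 3-D points has rank
  $\le 5$ and zero trace, so both terms vanish. Two consequences worth
  knowing: the penalty is provably nonnegative (the second term dominates
  the negated first), and it is *identically zero for $N \le 5$*, because
  the first sum then telescopes to the trace — so it can only discriminate
  non-embeddable distance sets with six or more atoms.

Optimization uses Adam with cosine learning-rate decay (defaults
$10^{-4}$, 300 epochs, batches of 16 reactions), with optional linear
warmup and decoupled weight decay applied to weight matrices only — on
small training sets the decay measurably improves generalization of the
heavily over-parameterized network. All settings are exposed as arguments
of `psi_fit()`. The five epochs with the best validation molecular MAPE are
retained as checkpoints; ensembles are formed from checkpoints across
hyperparameter combinations and seeds. The whole network, including the
attention and recurrent blocks, is implemented in base R with analytic
backpropagation; the gradients are validated against central finite
differences in the test suite (relative tolerance $10^{-4}$).

## Inference, TTA, reconstruction

`predict_tta()` averages the predicted distances of the forward and the
reversed reaction. With midpoint interpolation the interpolated structure is
direction-free, so this removes direction dependence *exactly* (bit-for-bit,
by symmetric accumulation). Ensembles retain each member's distance set; the
per-pair mean is used for metrics, and all member sets enter one joint
reconstruction:

$$ X^{*} = \arg\min_X \sum_k \sum_{i<j} w_{ij}
   \left| d^{(k)}_{ij} - \lVert X_i - X_j \rVert \right|, \qquad
   w_{ij} = e^{-\alpha \bar d_{ij}^{2}}, \; \alpha = 0.2\,\text{Å}^{-2}, $$

weighting short (bonding) distances most. The non-smooth absolute value is
replaced by $\sqrt{x^2 + \varepsilon^2} - \varepsilon$
($\varepsilon = 10^{-6}$ Å, exactly zero at zero); a smooth weighted
least-squares pass warm-starts two BFGS passes on the surrogate from the
interpolated geometry. Non-convergence returns the best-found geometry with
a diagnostics flag rather than an error. Mirror images have identical
distances, so chirality is not controlled — a known limitation of any
distance-based reconstruction.

## Exploration

`explore_ts()` samples thermally displaced reactant and product conformers
by normal-mode sampling: each real mode is displaced by
$a = \pm\sqrt{2 k_B T c / k}$ with $c \sim U(0,1)$, giving an expected
harmonic potential energy of exactly $k_B T / 2$ per mode. Sampled products
are Kabsch-aligned (proper rotations only) onto their sampled reactants,
TS distances are ensemble-predicted, geometries reconstructed, and the
results reduced to representatives by affinity propagation on the vector of
strict-pair distances (similarity = negative squared Euclidean distance,
median-similarity preference, damping 0.9). Affinity propagation is
implemented in the package in its standard responsibility/availability
message-passing form, with a deterministic tie-breaking jitter and a
medoid-per-connected-component fallback on non-convergence; exemplars are
always members of the input set.

## Synthetic data

`synthetic_reactions()` generates atom-mapped R/TS/P triples that make every
stage of the pipeline trainable and testable without external databases.
Reactant coordinates are sampled with a minimum separation of 0.8 Å;
products rotate and radially stretch a random atom subset, and with
probability 0.5 one atom pair is forced across the 156.6 pm bond threshold
(breakage or formation), so all four bond-change categories occur with
formation/breakage in the minority, as in real single-step reaction sets.
The reference TS is the midpoint geometry plus a bend: for each displaced
atom, the component of its centroid-relative position orthogonal to its
R→P displacement, scaled by `bend_scale` (default 0.3) and the displacement
length. Two properties of this construction matter:

* the TS is a real 3-D geometry, so its distance set is exactly
  EDM-realizable and the $L_3$ invariant holds by construction;
* the bend is built $O(3)$-equivariantly from the geometry itself, so TS
  distances are a deterministic function of the reactant/product distance
  profile — the ratio targets are learnable from distance-based features.
  (A cross-product construction would break mirror symmetry and make the
  targets unidentifiable from distances.)

Ratio targets are kept within $[0.5, 2]$ by halving the bend if necessary.
Property labels come from a smooth Morse-like pairwise toy energy with
element-dependent depths and radii; its analytic gradient and Hessian
support relaxation and normal-mode generation for the exploration tests.
What the generator does *not* emulate: real electronic structure, realistic
thermochemistry, conformational diversity of large molecules, or database
atom-mapping noise. Passing tests on this data demonstrates the mechanics
and invariances of the pipeline, not chemical accuracy on real reactions —
the latter requires training on a quantum-chemical reaction database.

## Numerical and design choices

* Interpolation fraction 0.5 and no pre-alignment by default (generated and
  database structures are consistently posed); `interpolate_structure()`
  exposes both, with optional Kabsch pre-alignment for arbitrary user input.
* Bond threshold 156.6 pm, configurable in `classify_pairs()`.
* The Gaussian grid (64 points on 0–8 Å) spans all chemically relevant
  distances in small organics; with embedding width 32 it reproduces the
  printed initial feature width of 128.
* Encoder internals (one block per PSI layer, 4 heads, FFN multiplier 2,
  pre-normalization) are the smallest standard transformer-encoder
  configuration; encoder and GRU parameters are not shared across layers.
* The property head covers reactant and product roles only (the roles that
  carry labels in training databases); it is enabled automatically when
  $c' > 0$ and labels are present.
* Eigenvalue sorting in $L_3$ is by descending magnitude; each eigenvalue is
  counted in exactly one of the two sums.
* Checkpoint selection keeps at most five parameter sets, sorted by
  validation molecular MAPE.
* Degenerate inputs: single-atom structures have empty pair sets and zero
  penalties; coincident atoms in reconstruction are guarded by a $10^{-12}$
  distance floor; all-imaginary mode sets refuse to sample.

## Scaled-down study sizes

The test suite and the acceptance script exercise the full pipeline at
sizes a laptop handles comfortably: reactions of 3–6 atoms, 200-reaction
training sets, a 32→64→128-width model instance for the learning
demonstration (40 epochs, Adam at $10^{-3}$ with 3 warmup epochs, batch 16,
weight decay $3\times10^{-3}$), and the full
128→256→512 architecture for forward-pass contracts. These sizes are the
package's own test-design choice: they keep every check reproducible from
scratch while leaving the defaults (`psi_config()`, `psi_fit()`) at the
full-scale settings described above.

## Worked example

```{r, eval = FALSE}
library(tsgeom)

rxns <- synthetic_reactions(200, n_atoms_range = c(3, 6), seed = 101)
fit <- psi_fit(rxns,
               config = psi_config(
                 n_heads = 4, head_width = 64,
                 fcfg = featurizer_config(n_embed = 8, n_rbf = 16)),
               epochs = 40, lr = 1e-3, seed = 1)
summary(fit)
plot(fit)

r <- rxns[[fit$split$test[1]]]
pred <- predict_tta(r, fit)
ts <- reconstruct_ts(pred, interpolate_structure(r, 0.5))
attr(ts, "diagnostics")
molecular_mape(pred$d_mean_pm, pair_distances(r$ts_ref, unit = "pm"))
```

## Limitations

* Chirality of reconstructed geometries is undetermined (distance
  information cannot distinguish enantiomers).
* Atom mapping is positional and assumed given; no mapping inference.
* The EDM penalty is inactive below six atoms (see above).
* Accuracy claims transfer to real reactions only after training on a real
  quantum-chemical reaction database; the bundled generator validates
  mechanics, not chemistry.
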