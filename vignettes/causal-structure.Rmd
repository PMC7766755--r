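---
title: "Measuring the causal structure of feedforward networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the causal structure of feedforward networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effectinfo)
```

## The model

A feedforward layer is treated as a causal mechanism: a weight matrix $W$
(edge $i \to j$ has weight $W_{ij}$), an activation $f$ at each output
node, and no biases by default. To ask *what does what* inside the
network — independently of any data distribution — we intervene: every
input node is forced, simultaneously and independently, into states drawn
uniformly over its activation range (the maximum-entropy intervention
distribution, written $do(L_1 = H^{max})$), and we record the joint
response of the downstream nodes. The **effective information** of the
connection $L_1 \to L_2$ is the mutual information between the binned
joint input states and the binned joint output states under that
intervention:

$$EI = I(L_1, L_2) \mid do(L_1 = H^{max}).$$

Because the inputs are randomized, every mutual bit is *caused* by the
intervention; EI is therefore a measure of the strength and
informativeness of the layer's causal relationships, in bits, and it
reflects how the layer would transmit out-of-distribution inputs.

EI decomposes into two interpretable components:

* **Sensitivity** is the sum over edges of the information each edge
  transmits in isolation:
  $\sum_{i,j} I(t_i, t_j) \mid do(i = H^{max})$, where node $i$ alone is
  perturbed and node $j$ is driven through the single edge $w_{ij}$ only.
* **Degeneracy** is `sensitivity − EI`: the information lost because
  overlapping connections make the upstream source of a perturbation hard
  to reconstruct from the outputs.

Plotting degeneracy (x) against sensitivity (y) gives the **causal
plane**. Since $EI = \text{sensitivity} - \text{degeneracy}$, movement
along the 45° line leaves EI unchanged — we call that line the EI
*nullcline* — while movement toward either axis raises or lowers EI.
Layers trace paths through this plane as they train.

Finally, **EI_parts** applies the same joint intervention as EI but sums
*pairwise* node-to-node mutual information instead of taking the joint
MI, and

$$\varphi_{\mathrm{feedforward}} = EI - EI_{\mathrm{parts}}$$

measures the irreducible *joint* effects of one layer on the next — a
feedforward analogue of integrated information. It is not bounded below
by zero: negative values indicate that higher-order joint effects are
mostly noisy rather than informative.

## Estimator conventions

**Binning.** Each node's activation interval is split into `n_bins`
equal-width bins, half-open on the left except the top bin, which is
closed; out-of-range values are clipped into the boundary bins. Sigmoid
nodes are binned over $(0,1)$ and tanh nodes over $(-1,1)$. The relu
range is unbounded and must be truncated: we bin relu activations over
$[0,1]$, the interval a unit-weight relu edge fills exactly when its
input is uniform on $[0,1]$. A network's first layer receives raw
features rather than activations and is perturbed over $[0,1]$ by the
same convention.

**The plug-in estimator.** MI is computed from empirical bin frequencies
(maximum-likelihood histogram estimator, log base 2), with joint states
stored sparsely — only observed bin tuples are counted, so memory scales
with the number of distinct observed states rather than with
$B^{n}$. No bias correction is applied: the estimator is biased upward
by roughly $(K-1)/(2 n \ln 2)$ bits at small $n$ ($K$ = occupied joint
cells). Instead of correcting, `converge_ei()` exposes a doubling
schedule — the sample count doubles until two successive estimates agree
within a tolerance — and flags non-convergence rather than failing.
The default injection length for protocol-scale measurements is $10^7$
samples; trajectory tracking defaults to $10^5$ per point, which is the
desk-scale compromise the convergence flag is there to audit.

**Shared and independent sample streams.** Within one `measure_layer()`
call, EI and EI_parts are computed from the *same* intervention samples,
so their difference ($\varphi$) benefits from common random numbers;
sensitivity uses independent per-edge sub-streams derived from the master
seed. Every random stage of the package (weights, task data, shuffling,
each perturbation) draws its seed through `derive_seed()`, a
deterministic hash of the master seed plus a stream label, so adding one
measurement never perturbs another. The batch size of the streaming
sampler is part of the stream definition: the same seed with a different
batch size yields a different (equally valid) sample sequence.

**Exactness short-cuts.** A constant label sequence has zero entropy, so
zero-weight edges and all-zero layers yield EI, sensitivity and EI_parts
of exactly 0 — not a Monte-Carlo approximation. Pairs with exactly zero
weight are skipped in the sensitivity and EI_parts sums for the same
reason. Degeneracy is *not* clamped: small negative values are honest
Monte-Carlo noise and are reported as-is. The identities
`degeneracy = sensitivity − EI` and `phi = EI − EI_parts` hold exactly by
construction on every result object.

**The quadrature oracle.** For layers with up to three inputs,
`quadrature_ei()` computes the same binned EI deterministically: the
input box is tiled with equal-mass midpoint cells (about $10^5$ in 1-D,
$2\times10^6$ in 2-D) and the exact bin-to-bin transition mass is
accumulated. It shares no code path with the sampler and serves as the
independent reference in the test suite; Monte-Carlo estimates at $10^6$
samples agree with it to well under 0.05 bits on all small layers we
check.

## The single-edge EI curve and the location of its maximum

For an isolated edge $A \to B$ the EI is a characteristic rise-and-decay
function of the weight: near zero weight the output barely responds to
perturbations, and at large weight the activation saturates, so EI peaks
at an intermediate weight. `ei_curve_single_edge()` tabulates this curve
on a weight grid, reusing one input sample across the grid so the curve
is smooth in $w$ and the grid argmax is not jittered by resampling.

The *location* of the maximum deserves care. The broad maximum sits near
$e \approx 2.7$ for sigmoid, near $\coth(1) \approx 1.3$ for tanh, and at
exactly 1 for relu (where the unit edge is a bin-for-bin bijection, with
$EI = \log_2 B$). For relu this location is exact and identical at every
bin count. For sigmoid and tanh, however, the binned-MI curve carries a
genuine fine structure: as the weight varies, the image interval of the
activation sweeps across bin boundaries, and the exact curve oscillates
by about a tenth of a bit around its broad hump. The grid argmax of the
exact curve therefore moves by several tenths of a weight unit as the
bin count changes (for the sigmoid edge it wanders roughly between 2.2
and 3.1 across 8–64 bins; for tanh between about 1.0 and 1.6). This is a
property of the estimator itself, not of sampling noise — our
deterministic quadrature reproduces it exactly — so we describe the
characteristic weights as the location of the broad maximum, and treat
only the relu peak as a sharp, bin-independent constant. The package's
acceptance suite asserts the sharp form of the claim for all three
activations and we leave the sigmoid/tanh assertions failing rather than
widen them, with this section as the analysis.

## The synthetic tasks

Two bundled generators reproduce the *separability contrast* of the two
classic benchmarks the training experiments are designed around, with no
downloads:

* `iris_like` — 4 features, 3 balanced classes (default 150 training
  samples), diagonal Gaussian blobs in $[0,1]^4$ with one class well
  separated and two slightly overlapping. Mostly linearly separable: a
  linear discriminant reaches ≥ 90% test accuracy.
* `mnist_like` — 25 features, 5 balanced classes built like coarse digit
  images: sparse positive class templates, each class with two
  "writing-style" variants whose second style is a 0.6 mixture toward
  the next class's template, plus per-sample intensity jitter and pixel
  noise. Class means alone mis-sort part of every class, so linear
  classifiers trail a small nonlinear network by a clear margin. The
  default training set is 6000 samples: the benchmark this stands in for
  presents hundreds of gradient updates per epoch, and the bias-free
  sigmoid network of the reference protocol needs that update count to
  escape its initial uniform-output plateau within 500 epochs.

What these generators do *not* emulate: pixel correlations of real
images, label noise, class imbalance, and any train/test distribution
shift. Passing the qualitative training claims on these tasks shows that
the measurement machinery resolves the separable-vs-degenerate contrast;
it does not certify behavior on real data.

## Training protocol

`train_network()` implements the reference protocol: MSE loss on one-hot
targets, vanilla mini-batch gradient descent at learning rate 0.01,
batch size 10 / 4000 epochs for the iris-shaped task and batch size 50 /
500 epochs for the mnist-shaped one, sigmoid activations, no biases, and
weights initialized $U(\pm 1/\sqrt{\mathrm{fanin}})$. Two conventions
the protocol leaves open are fixed as follows:

* **Loss normalization.** The loss is the per-sample squared error
  *summed over output nodes*, averaged over the batch. (Averaging over
  all elements instead divides the gradient by the output width; at
  learning rate 0.01 that variant leaves the iris-shaped network stuck
  at the uniform-output plateau for the whole 4000-epoch budget.)
* **Checkpoint schedule.** Geometric spacing (denser early), because EI
  and loss both move fastest in the early phase; the schedule always
  contains epoch 0 and the final epoch.

A finding worth knowing when adding redundant hidden layers
(`redundancy_experiment()`): bias-free sigmoid stacks deeper than three
weight layers do not reach the base network's loss under this protocol
at any update count we tried — the classic vanishing-gradient regime.
The causal-plane signature of redundancy (added layers nearly static
while the base network's layers travel) is visible regardless, and the
comparison table reports the final losses side by side so the
trainability gap is explicit rather than hidden.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use: $10^6$ samples per
point for single-edge curves and oracle comparisons (a full 0.01-step
curve scan takes on the order of a minute), $3\times10^4$ samples per
trajectory measurement point with ten geometric checkpoints, and three
seeds per qualitative claim. Every experiment is a pure function of its
master seed; rerunning any command with the same seed reproduces every
number, and the CLI writes a manifest with the resolved configuration
and md5 hashes of all outputs.

## Known limitations

* The plug-in MI estimator's upward bias grows with the occupied state
  space; for wide layers (25 inputs at 16 bins) the joint input entropy
  saturates at $\log_2 n$ and EI is effectively the output-side entropy.
  The convergence trace makes this visible; it does not remove it.
* Binless (k-nearest-neighbour) MI estimation, minimum-information
  partitions over all subsets, and partial information decomposition are
  deliberately out of scope.
* The relu binning range $[0,1]$ is a convention; activations beyond it
  clip into the top bin, which under-resolves very large weights.
* Only dense, feedforward, equal-activation layers are modelled — no
  convolutional, recurrent or attention structure.
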