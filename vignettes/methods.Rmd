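---
title: "Methods: model, sampling scheme and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, sampling scheme and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcatmd)
```

## The prediction problem

`lcatmd` scores unlabelled drug–microbe pairs in a sparse binary
association table `A` (`Nd` drugs × `Nm` microbes). Known associations are
positives; every other pair is an *unlabelled candidate*, not a verified
negative — public databases record no true negatives. Both the sampling
scheme and the evaluation protocol below follow from that asymmetry.

## Similarity network

The Gaussian interaction-profile (GIP) kernel treats each entity's binary
interaction vector as its fingerprint:

$$S(i,j) = \exp(-\mu\,\lVert p_i - p_j\rVert^2),\qquad
\mu = \mu' \Big/ \tfrac1N \sum_i \lVert p_i\rVert^2,$$

with raw bandwidth $\mu' = 1$ by convention. Drug profiles are rows of
`A`, microbe profiles are columns. The bandwidth normalization makes the
kernel scale-free in the number of interactions; it is undefined (and an
error) when every profile is all-zero, a cold-start condition the caller
must resolve.

Precomputed secondary similarities — drug chemical-structure similarity,
microbe protein-network functional similarity — enter as optional square
matrices and are **averaged entrywise** with the GIP similarity wherever
the secondary entry is nonzero, falling back to the GIP value elsewhere.
We read the nonzero condition per pair, not per matrix: under a
whole-matrix reading a single measured pair would change the integration
rule for every other pair, which contradicts the pairwise form of the
definition. Computing those secondary similarities from STRING or from
chemical fingerprints is out of scope; they are inputs.

The block network

$$Y = \begin{pmatrix} S_{\mathrm{drug}} & A \\ A^\top & S_{\mathrm{microbe}}\end{pmatrix}$$

is assembled once per fit (similarities do not depend on model
parameters), and its rows are the initial node features.

## Encoder

Each layer carries a weight matrix `W`, an attention vector `a`, and two
interpolation scalars $\lambda_1, \lambda_2 \in [0,1]$:

* pre-convolution:
  $\tilde Y_i = \dfrac{Y_i + \lambda_2 \sum_{j \in N(i),\, j \ne i} Y_j}
  {1 + \lambda_2\,|N(i)\setminus i|}$;
* attention logits:
  $e_{ij} = \lambda_1\,\mathrm{LeakyReLU}\!\big(a^\top [W\tilde Y_i \,\Vert\, W\tilde Y_j]\big)$;
* softmax over the neighborhood (self-loop included), then aggregation
  $\mathrm{out}_i = \phi\big(\sum_j \rho_{ij} W \tilde Y_j\big)$.

The counting convention matters: the convolution's sum and denominator run
over neighbors *excluding* self (the node's own feature enters as the
standalone term), while the attention softmax runs over the neighborhood
*including* the enforced self-loop. With one neighbor and $\lambda_2 = 1$
the convolved feature is exactly the two-row average, which pins the
convention down.

Boundary behaviour, verified to numerical tolerance in the test suite:
$\lambda_1 = 0$ gives uniform attention, i.e. mean aggregation over the
closed neighborhood; $\lambda_1 = 1, \lambda_2 = 0$ is a plain single-head
graph-attention layer; $\lambda_1 = \lambda_2 = 1$ is attention over
convolved features. Note the $\lambda_1 = 0$ limit is *uniform* neighbor
averaging, not the symmetric degree normalization $D^{-1/2} A D^{-1/2}$ of
textbook spectral convolutions — it is the "all attention weights equal"
characterization that the interpolation naturally produces.

Design points the literature leaves open, fixed here:

* **Layer count 2** (configurable). Two layers let drug information reach
  microbes and return; deeper stacks oversmooth on these dense similarity
  graphs.
* **Parameterization of the scalars**: sigmoid of an unconstrained raw
  value, initialized at 0, i.e. $\lambda = 0.5$, mid-interpolation. This
  keeps the convolution denominator positive and leaves both corners
  reachable by gradient descent. Frozen corners (`lambda_mode = "gcn"`,
  `"gat"`, `"cat"`) implement the ablation switches; under `"gcn"`,
  $\lambda_2$ remains trainable.
* **Graph sparsification**: edges are entries of `Y` above a threshold
  (default 0, all nonzero entries). GIP blocks are strictly positive, so
  same-type nodes are fully connected and cross-type edges are exactly the
  known associations.
* **Activations**: ELU between layers, identity at the output; LeakyReLU
  slope 0.2 in the attention score.
* **Attention uses topology only**: the similarity *values* already enter
  through the features (rows of `Y`), so edge weights are not additionally
  injected into the softmax. The weighted-softmax alternative would
  double-count the similarities.
* **Dropout** (rate 0.1) on layer inputs during training, inverted-mask
  convention, seeded and bit-reproducible.

Gradients for all parameters — including both interpolation scalars,
through the convolution's quotient rule and the attention gate — are
analytic; the test suite checks them against central finite differences.

## Decoder and loss

Pair scores are `sigmoid(W2 relu(W1 (E_m ⊙ E_d)))` with `W1` of shape
`F × F` and `W2` of length `F`. The training objective is the binary
cross entropy summed over the current sample set; scores are clipped to
`[1e-7, 1 - 1e-7]` before the logarithms (the reported log-loss is the
sum; the optimizer uses the mean by default so the step size does not
scale with `|P|`). The optimizer is Adam (0.9/0.999, eps 1e-8), full-batch
over the current sample set each epoch — at a few hundred samples per
epoch, mini-batching would only add variance.

## Self-paced negative sampling

Each epoch the candidate negatives are re-scored and re-bucketed:

1. hardness `H = (score − 0)²` per candidate;
2. `k = 10` equal-width buckets on `[0, 1]`. The bucket edges are
   half-open, `[(l−1)/k, l/k)`, with the top bucket closed at 1 — the
   published closed-interval form overlaps at the boundaries, and the
   half-open convention is the deterministic resolution;
3. self-paced factor `beta = −log((n − i)/n)` at epoch `i` of `n`; it is 0
   at the start and reaches `−log(1/n)` at the last epoch (the natural
   clamp of a schedule that formally diverges at `i = n`);
4. bucket weights `W_l = 1/(h_l + beta)` for occupied buckets (empty
   buckets get weight 0 — their mean hardness is undefined), normalized;
   an `1e-12` floor guards `h_l = beta = 0`;
5. allocations `W_l · |P|` rounded by largest remainder (ties to the lower
   bucket index) so the total is exactly `|P|`; allocations above a
   bucket's size are capped and the surplus redistributed proportionally
   among un-capped buckets, iterated to a fixpoint. The draw falls short
   of `|P|` only when the pool itself is smaller;
6. uniform without-replacement draws inside each bucket.

Epoch 0 has no predictions yet, so its negatives are a plain uniform
undersample. The "iteration" of the schedule is the training epoch, and
`n` is the configured epoch count; `resample_every` stretches the cadence
if desired. The scheme's intent: early, `beta ≈ 0` makes weights
concentrate on low-hardness (trivial) buckets, stabilizing the young
classifier; late, large `beta` flattens the weights toward the hard,
informative boundary samples while the `1/(h+beta)` form still discounts
the highest-hardness bucket, which likely contains false negatives. No
classifier ensemble is built: the procedure iteratively retrains a single
decoder, and nothing in the five steps averages models.

## Evaluation protocol

`mdassoc_cv()` shuffles positives into five round-robin folds (sizes
differ by at most one), masks each fold's positives out of the training
adjacency, refits from scratch, and evaluates on the fold's positives plus
an equal number of held-out candidate negatives, disjoint across folds
when the pool allows.

* **Leakage-free similarities by default**: the GIP kernel is recomputed
  per fold from the masked training adjacency. Computing it once from the
  full table (`similarity_scope = "full"`) would let test positives leak
  into training features through the kernel; the switch exists because the
  published protocols in this literature are typically silent on the
  point, and the two scopes bracket the honest range.
* **Balanced test sets by default**: reported AUPR values in this
  literature track AUC closely, which is only possible when test negatives
  are subsampled to match positives; the `all_negatives`-style imbalanced
  evaluation is available by scoring the full matrix directly. On balanced
  sets, AUPR ≈ AUC is expected and asserted as a sanity property.
* **Masked test positives stay in the candidate pool** (they are zeros of
  the training table, and the trainer cannot know they are special);
  `exclude_test_pairs = TRUE` gives the alternative. Each fold's fit is
  reproducible from its training table and per-fold seed alone, which the
  tests use to show training never touches test labels.
* AUC uses the midrank statistic (ties get half credit); AUPR is the
  step-function integral over distinct thresholds; MCC is defined as 0
  when its denominator vanishes; thresholded metrics use 0.5 with
  `score >= threshold` counted positive. Candidate rankings break score
  ties by microbe identifier so output is deterministic.

## Synthetic data: what it does and does not emulate

`simulate_mda_data()` plants non-negative Gamma(2, 2) factors `U`
(`Nd × r`) and `V` (`Nm × r`), draws `A_ij ~ Bernoulli(plogis((UV')_ij + c))`
with the offset `c` calibrated by root finding so the expected density hits
the target, and derives secondary similarities as cosine similarities of
the factor rows plus symmetric Gaussian noise, clipped to `[0, 1]` with
unit diagonal. This emulates the features that drive the method: a sparse
binary bipartite adjacency with recoverable low-rank structure, and
secondary similarities correlated with — but not identical to — the
planted signal, so entrywise integration has something real to add.
Setting the secondary matrices to zero exercises the GIP-only fallback.

It does **not** emulate: the long-tailed degree distributions of curated
databases (many drugs with one association), literature-driven correlated
sampling of which pairs get measured, block structure from taxonomic
families, or measurement noise in the positives themselves. Passing the
planted-recovery tests therefore shows the pipeline learns genuine
low-rank signal through the full encoder–sampler–decoder loop; it does not
certify performance on any real database.

The study configuration used in the tests and the acceptance script:
50 drugs × 20 microbes, rank 4, target density 0.08 (≈ 80 positives,
≈ 920 candidates), dataset seeds 11–15, 5-fold CV. Training uses embedding
width 32, two layers, learning rate 0.005, 200 epochs, `k = 10`, dropout
0.1. The published operating point (learning rate 0.0005, embedding 256)
remains the package default and suits database-scale graphs; on a 70-node
synthetic graph a 256-wide embedding is over-parameterized and the smaller
learning rate merely slows full-batch convergence, so the desk-scale
configuration narrows the width and raises the step size. These sizes are
stated here as the study definition so that every reported number is
reproducible from them.

## Numerical choices

* Attention softmax with per-row max subtraction; entries outside the
  neighborhood are exactly 0.
* Squared distances in the GIP kernel are clamped at 0 before
  exponentiation and the matrix is symmetrized, so `S = 1` on the diagonal
  exactly and round-off cannot push entries above 1.
* Glorot-uniform initialization for `W`, `a`, `W1`, `W2`.
* All randomness flows through R's RNG, seeded once at each entry point
  (`seed` arguments) and restored afterwards; per-fold seeds inside
  cross-validation are drawn up front so folds are individually
  reproducible. Identical seed + configuration is bit-identical output.
* Training aborts with a diagnostic on a non-finite loss rather than
  continuing from a poisoned state; there is no early stopping beyond
  that.

## Known limitations

* No verified negatives exist in this domain; the self-paced scheme
  mitigates but cannot eliminate false-negative contamination of the
  sampled negative set.
* The decoder's absolute scores are not calibrated probabilities (training
  is balanced, deployment is not); only the ranking should be consumed.
* Secondary similarities are trusted as given; garbage in, averaged
  garbage out.
* The encoder is single-head; multi-head attention is deliberately out of
  scope because the layer definition interpolates a single attention
  vector.
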