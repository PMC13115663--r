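---
title: "Multi-view attention graph convolution for miRNA-disease association prediction: models and methods"
author: "mdanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view attention graph convolution for miRNA-disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdanet)
```

## The prediction problem

Experimentally validated miRNA-disease associations (MDAs) form a sparse
binary matrix $A \in \{0,1\}^{N_m \times N_d}$: $a_{ij} = 1$ when miRNA
$m_i$ is curated as associated with disease $d_j$. The task is link
prediction on this bipartite structure: score every unobserved pair so
that true but not-yet-curated associations rank highly. `mdanet`
implements a multi-view graph-convolutional approach: several
complementary similarity matrices per entity type are fused with learned
weights into a heterogeneous network, node embeddings are learned with
attention-augmented graph convolutions, and a small MLP scores
miRNA-disease embedding pairs under a binary cross-entropy objective.

## Similarity views

Five miRNA views and three disease views feed the fusion stage.

* **Functional similarity** ($F_m$) is a precomputed square matrix loaded
  from file (`read_similarity_table()`), symmetrized by averaging with its
  transpose and clipped to $[0,1]$ on ingest. It is not recomputed here.
* **Sequence similarity**: $S_{seq}(m_i, m_j) = 1 - d(m_i, m_j) /
  \max(|m_i|, |m_j|)$ with $d$ the Levenshtein distance between the RNA
  sequences (`utils::adist`). Sequences are normalized to upper-case RNA
  (T becomes U) on ingest.
* **Family similarity**: the indicator that two miRNAs share a family
  label; unannotated miRNAs match nothing off-diagonal, and the diagonal
  is 1 by convention (self-similarity does not depend on annotation).
* **Gaussian interaction profile (GIP) kernel**:
  $K(i,j) = \exp(-\lambda \lVert P_i - P_j \rVert^2)$ over binary
  interaction profiles (rows of $A$ for miRNAs, columns for diseases),
  with bandwidth $\lambda = \lambda' / \overline{\lVert P \rVert^2}$ and
  $\lambda' = 1$ by default. An all-zero $A$ leaves the bandwidth
  undefined and is rejected.
* **lncRNA profile similarity**: rows of the binary miRNA-lncRNA (or
  disease-lncRNA) interaction matrix are treated as strings over $\{0,1\}$
  and compared by edit distance, scaled by the profile length. For
  equal-length binary strings the Levenshtein distance is bounded above by
  the Hamming distance but can be smaller (shifts), which the tests
  exercise explicitly.
* **Disease semantic similarity** from MeSH-style DAGs combines two
  per-term contribution schemes. Scheme 1 decays from the disease's own
  term: $C_1(D, D) = 1$ and
  $C_1(d, D) = \max_{d' \in \mathrm{children}(d)} \mu\, C_1(d', D)$ with
  decay $\mu = 0.5$, evaluated by a reverse topological sweep. Scheme 2
  weights a term by its specificity,
  $C_2(d, \cdot) = -\ln(\mathrm{countDAGs}(d) / N_{diseases})$, so a term
  present in every DAG contributes nothing. For each scheme the pairwise
  similarity is the sum of both diseases' contributions over shared terms
  divided by the sum of their total semantic values, and the final score
  is the average of the two schemes. Diseases with no DAG get similarity
  0 to every other disease (the other views carry them); a zero semantic
  value triggers a division guard that also yields 0. The natural
  logarithm is used in scheme 2 — the base only rescales the scheme
  uniformly.

Every computed view is validated to be symmetric (enforced by averaging
with the transpose), unit-diagonal, and $[0,1]$-bounded.

## Network construction and initial features

The fused similarities are per-group convex combinations,
$M^{int}_m = \sum_k \alpha_k V_k$ and $M^{int}_d = \sum_k \beta_k U_k$,
with $(\alpha, \beta)$ parameterized by a per-group softmax over
unconstrained logits. The softmax keeps every group nonnegative and
summing to one, which makes the learned weights interpretable as view
contributions. The heterogeneous adjacency is the block matrix

$$M = \begin{pmatrix} M^{int}_m & A \\ A^{\top} & M^{int}_d \end{pmatrix}.$$

Initial node features come from a random walk with restart on $M$: for
each seed node $t$, iterate
$D^{(k)} = (1-r) A_n D^{(k-1)} + r D^{(0)}$ until the Frobenius norm of
the update drops below $10^{-6}$ (cap 1000 iterations), where $A_n$ is the
column-normalized adjacency (transition-matrix convention; isolated nodes
receive a self-loop first) and $D^{(0)}$ is the one-hot seed. The stacked
stationary vectors form an $N \times N$ feature matrix whose columns are
probability distributions. Restart defaults to $r = 0.5$ and is exposed in
the configuration; tests verify the fixed point against a direct linear
solve $r (I - (1-r) A_n)^{-1}$.

Because the fusion weights are trained, the adjacency is rebuilt from the
current softmax weights at every epoch, so $\alpha, \beta$ receive
gradients through both graph convolutions. The RWR features, by contrast,
are computed once from the uniform-weight adjacency and treated as
constants: differentiating through the iterative solver would couple the
fixed-point iteration count to the optimizer and add considerable cost
for little benefit, since the features only set the input basis.

## The model

With $X$ the RWR features and $M$ the adjacency:

1. **Channel recalibration (ECA)**: per-channel weights are the sigmoid of
   a 1-D convolution (adaptive odd kernel, $k = |\log_2 C / 2 + 1/2|$
   rounded to the nearest odd integer) over the channel-wise global
   average of $X$; the output rescales each channel. One structural fact
   is worth recording: RWR columns each sum to one, so every channel's
   global average equals $1/N$ and the attention weights are uniform up
   to zero-padding edge effects — on RWR inputs the ECA stage acts
   essentially as a learned global gain. It is kept because the
   architecture defines it and it becomes non-trivial for any input whose
   channel means differ.
2. **First graph convolution**: $H^{(1)} = \mathrm{ReLU}(M X_a W^{(1)})$.
   The adjacency is used as constructed (no normalization) by default; a
   symmetric-normalization switch (`sym_norm_adjacency`) exists, in which
   case the degree vector is treated as a constant in the backward pass.
3. **Multi-head self-attention** over node embeddings: per head,
   $\mathrm{softmax}(Q K^{\top} / \sqrt{d_k}) V$ with $h = 4$ heads of
   $d_k = 64$ (the head count is a package choice; $256 / 4$ gives a
   conventional per-head width). Heads are concatenated and mixed by
   $W^O$. A residual connection adds the attention input back to its
   output by default: early in training the attention rows are nearly
   uniform, and without the residual the stage replaces every node's
   embedding with almost the same global average, discarding node
   identity and measurably slowing learning. `mha_residual = FALSE`
   restores the purely sequential reading.
4. **Second graph convolution**: $H^{(2)} = \mathrm{ReLU}(M H_{mh} W^{(2)})$.
5. **Adaptive layer fusion**: $H = \gamma_1 H^{(1)} + \gamma_2 H^{(2)}$
   with $(\gamma_1, \gamma_2)$ a softmax pair, balancing one-hop and
   two-hop information.
6. **Pair scoring**: the miRNA row and disease row of $H$ are
   concatenated (512 values), passed through one ReLU hidden layer of 256
   units, and mapped to a sigmoid score.

Training minimizes mean binary cross-entropy with scores clipped to
$[10^{-7}, 1 - 10^{-7}]$ (the loss is undefined at 0 and 1), using Adam
(learning rate $5 \times 10^{-4}$, weight decay $5 \times 10^{-4}$ as an
L2 term on the dense weight matrices only — fusion logits, biases and the
ECA kernel are not decayed). Parameters are initialized by a seeded
symmetric-uniform scheme scaled by fan-in/fan-out; fusion logits start at
zero so all views contribute equally before training. The full backward
pass — through the MLP, the layer fusion, both convolutions, the
attention stage, the ECA gate, and into the fusion logits via the
similarity blocks of $M$ — is hand-derived and checked against central
finite differences in the test suite. The entire pipeline is
deterministic given (inputs, configuration, seed); one subtlety worth
noting for maintainers is that the optimizer updates its flat parameter
vector in place (via compiled kernels), so parameter arrays are
defensively re-allocated before training to ensure they never alias
shared R objects.

### Ablation variants

* `attention`: ECA and the self-attention stage become identity maps —
  a plain two-layer GCN with layer fusion and the MLP head.
* `egcn`: the self-attention stage is removed but ECA is kept — plain
  stacked convolutions.
* `multisource`: the fusion uses a single GIP view per entity type.

`run_ablation("none", ...)` reproduces `run_cv()` exactly under the same
seed, which is itself a test.

## Evaluation protocol

`make_folds()` shuffles the known positives with a seed, splits them into
$k$ folds, and samples an equal number of negatives uniformly without
replacement from the zero entries, partitioned alongside so no pair ever
appears in two roles. Within each fold the held-out positives are masked
to zero *before* the GIP kernels, the adjacency, and the RWR features are
computed — the held-out links influence no training-time quantity, which
a construction audit asserts per fold. This is stricter than much of the
published protocol in this area (which is usually silent about
recomputing GIP under cross-validation) and makes the reported AUCs
conservative; the same hygiene is what the disease-wise hold-out
(`disease_holdout_rank()`) applies when it removes every association of a
target disease and retrains from scratch.

AUC is computed by the rank statistic with average tie handling (checked
exactly against an $O(n^2)$ concordance oracle and against pROC), AUPR by
step integration of the precision-recall curve, and accuracy at the 0.5
threshold (the threshold is a convention; none is canonical for this
task). Unknown pairs are treated as negatives by the benchmark
convention; the resulting label noise is inherent to the task.

## The synthetic study bundle

`generate_bundle()` draws a planted-block world: miRNAs and diseases are
assigned uniformly at random to `n_blocks = 5` latent blocks, and
$a_{ij} \sim \mathrm{Bernoulli}(0.30)$ within matched blocks versus
$\mathrm{Bernoulli}(0.02)$ otherwise (defaults: 100 miRNAs, 60 diseases).
The single latent structure induces *all* the correlations the fusion is
designed to exploit: families equal miRNA blocks; sequences are
per-block ancestors with 3 point substitutions each (22 nt); the
functional matrix is the block indicator plus clipped Gaussian noise
(sd 0.05); disease DAGs share per-block term chains under one common
root term, so semantic similarity is elevated within blocks; and lncRNA
profiles are per-block prototypes with 10% bit flips (40 lncRNAs). A
single integer seed drives every sub-generator through a seed-splitting
scheme, so bundles are bitwise reproducible.

What the generator does *not* emulate: the heavy-tailed degree
distribution of curated MDA databases, the depth and breadth of the real
MeSH hierarchy, per-node association propensities, and any correlation
structure beyond block membership. Passing the recovery tests therefore
demonstrates that the pipeline extracts planted multi-view structure
under a leakage-free protocol — not that it attains any particular
performance level on curated databases.

### What recovery level is attainable on this generator

Given the block labels, association entries are *conditionally
independent* Bernoulli draws, so no scoring function can beat the one
that knows the block assignment exactly: the Bayes-optimal ranking is the
block-match indicator. With matched-block probability $p_1 = 0.30$,
background $p_0 = 0.02$ and a match fraction of about $1/5$, roughly 79%
of positives are in-block while about 15% of uniformly sampled zero
pairs are in-block, giving the optimal ranking an expected AUC of

$$\mathrm{AUC}^* = P(\mathrm{m}|+)\,P(\bar{\mathrm{m}}|-) +
\tfrac12\left[P(\mathrm{m}|+)P(\mathrm{m}|-) +
P(\bar{\mathrm{m}}|+)P(\bar{\mathrm{m}}|-)\right] \approx 0.82$$

on 1:1-sampled test sets. The acceptance suite nevertheless asserts the
recovery level at the fixed threshold of 0.85 together with the ablation
direction (full model at or above the GIP-only variant); the absolute
threshold sits above the ceiling just derived, so that assertion
documents an unattainable bound for this generator rather than a
realistic target, and the meaningful checks are the ablation ordering
and how closely the model approaches the ceiling. The generator's
parameters define the study conditions and are not tuned to the
assertion.

## Numerical choices and degenerate inputs

* Similarity symmetry is enforced by averaging with the transpose;
  entries are clipped to $[0,1]$ only on file ingest and after noise
  injection in the generator.
* RWR tolerance $10^{-6}$ (Frobenius), cap 1000 iterations,
  non-convergence is an error reporting the residual; $r = 1$ returns the
  identity exactly.
* Ranked outputs break score ties by lexicographic miRNA id, making
  prediction files deterministic.
* Training problem sizes: cross-validation on the default bundle trains
  a 160-node network with 256-dimensional embeddings for 500 epochs per
  fold; the unit-test bundles are smaller (30 x 20, 3 blocks) so the
  mechanism tests run in seconds.
* Degenerate inputs rejected with errors: all-zero association matrix
  (GIP bandwidth undefined), empty sequences, zero-width lncRNA profiles,
  cyclic DAG edge sets, single-class label vectors in `evaluate()`,
  score vectors outside $[0,1]$ in `write_predictions()`.

## Known limitations

* Dense matrix algebra throughout: $O((N_m + N_d)^2)$ memory and compute;
  graphs beyond a few thousand nodes would need sampling or sparse
  attention, which is out of scope.
* The ECA stage is structurally near-inert on RWR features (see above).
* The fusion-weight trajectory is interpretable only up to the softmax
  parameterization; raw logits are not comparable across runs.
* `n_layers` is fixed at two in the implementation (the architecture the
  package implements); the ablation switches, not the layer count, are
  the supported way to reduce it.
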