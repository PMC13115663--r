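# mdanet

Multi-view attention graph convolutional networks for miRNA-disease
association prediction.

## The problem

MicroRNAs regulate gene expression post-transcriptionally, and their
dysregulation is implicated in many diseases. Curated databases record
experimentally validated miRNA-disease associations (MDAs) as a sparse
binary matrix `A` (miRNAs x diseases); systematically testing the missing
entries in the lab is infeasible, so ranking candidate pairs
computationally is a standard step in biomarker discovery. `mdanet` is
aimed at computational biologists who want a self-contained, reproducible
implementation of a multi-view graph-convolutional MDA predictor together
with a leakage-aware evaluation protocol.

## The model

Five miRNA similarity views (functional, sequence/Levenshtein, family,
Gaussian interaction profile, lncRNA interaction profile) and three
disease views (MeSH-DAG semantic, GIP, lncRNA profile) are fused by
softmax-constrained learned weights,

    Mm = sum_k alpha_k V_k,   Md = sum_k beta_k U_k,

and assembled with the association matrix into the heterogeneous
adjacency `M = [[Mm, A], [A', Md]]`. Initial node features are random
walk with restart (RWR) stationary distributions on `M`. Node embeddings
are learned with

    H1 = ReLU(M Xa W1)                      (graph convolution)
    Hm = MultiHead(H1) + H1                 (self-attention, 4 heads)
    H2 = ReLU(M Hm W2)                      (graph convolution)
    H  = gamma1 H1 + gamma2 H2              (adaptive layer fusion)

with an efficient-channel-attention (ECA) gate `Xa` on the input
features, and pairs are scored by an MLP on the concatenated miRNA and
disease embedding rows, trained with Adam under binary cross-entropy
(learning rate 5e-4, weight decay 5e-4). Everything — including
backpropagation through the fusion weights into the similarity blocks of
`M` — is implemented in base R matrix algebra with a small compiled
optimizer kernel, and is bitwise reproducible given a seed.

Evaluation is 5-fold cross-validation with 1:1 negative sampling in
which held-out positives are masked *before* the GIP kernels, the
adjacency and the RWR features are computed, plus ablation variants
(no attention, plain convolutions, single-view) and disease-wise
hold-out ranking for cold diseases. A planted-block synthetic generator
produces a complete input bundle (associations, FASTA sequences, family
table, functional matrix, DAG edge list, lncRNA interaction matrices)
with known ground truth, so the whole pipeline runs and is tested
without any external download.

## Worked example

```r
library(mdanet)

# a self-contained study bundle: 100 miRNAs, 60 diseases, 5 latent blocks
bundle <- generate_bundle(synthetic_config(seed = 1))
dim(bundle$A)
#> [1] 100  60
sum(bundle$A)          # curated positives in this draw
#> [1] 449

# leakage-aware 5-fold cross-validation of the full model
config <- model_config(epochs = 500, seed = 1)
res <- run_cv(bundle, config, k = 5, seed = 1)
round(res$mean, 4)
#>    auc   aupr    acc
#> 0.8092 0.8155 0.7362

# the same protocol without multi-source fusion (GIP view only)
abl <- run_ablation(bundle, "multisource", config, k = 5, seed = 1)
round(abl$mean["auc"], 4)
#>    auc
#> 0.7282
```

The cross-validated AUC of about 0.81 sits just below the Bayes-optimal
level of about 0.82 attainable on this generator (given the latent blocks, associations
are independent Bernoulli draws, so no scorer can beat the block-match
indicator; the derivation is in the methods vignette), and removing the
multi-source fusion costs about 8 AUC points — the fusion is what lets
the model recover the block structure from the association-independent
views. Ranked per-disease candidate lists can be produced for a held-out
disease with `disease_holdout_rank(bundle, "dis-7", top_n = 50, config)`
and written with `write_predictions()`.

A command-line interface wrapping the same functions is installed at
`exec/mdanet` (subcommands `simulate`, `build-network`, `cv`,
`rank-disease`).

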