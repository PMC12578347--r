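# pepfusion

Multi-label prediction of therapeutic peptide function in R.

Short therapeutic peptides (5–50 residues) often carry several biological
activities at once — anti-microbial, anti-cancer, cell-penetrating, … — and
annotated corpora are severely imbalanced: the largest functional category
outnumbers the rarest by up to ~100:1, while only a minority of peptides
carry more than one label. `pepfusion` implements a multi-stream
neural predictor for this setting, trained end-to-end with a loss built for
imbalanced multi-label data, entirely in base R (its gradients come from a
compact tape-based reverse-mode autodiff core that ships with the package).

## The model

Eight feature streams are computed per sequence: learned residue
**embeddings**; embeddings + sinusoidal positions through masked multi-head
**self-attention**; **graph attention** over the residue chain graph;
per-residue **AAindex**, **PAAC** and **PC6** physicochemical vectors and
**BLOSUM62** substitution rows, each soft-mapped by a trainable Gaussian
membership function `f(x) = exp(-(x-c)²/2σ²)`; and the sequence-level
**amino-acid composition** tiled across positions. Streams are aligned by
per-stream affine projections and fused with learnable sigmoid gates:

    F_fused = (1/N) Σᵢ  Fᵢ ⊙ σ(gᵢ),   gᵢ ∈ R^d

The fused representation passes through a BiLSTM, parallel 1-D convolutions
(kernels 3/5/7, masked max-pooling), a residual feed-forward block with
layer normalization, and a 21-way independent-sigmoid classifier
(threshold 0.5).

Training minimizes the **marginal focal dice loss (MFDL)**: per class c,
logits are shifted by label-distribution-aware margins (minority side gets
the full margin `M_max`, majority side `M_max·w_maj/w_min`, with
`w = n^{-1/2}`), squashed to probabilities, clipped and focal-scaled, and
aggregated into positive/negative dice components

    L_pos(c) = 1 − 2·Σ p_pos·y / (Σ p_pos^P + Σ y + ε)

mixed as `α·L_pos + (1−α)·L_neg`, weighted by inverse-√-count class weights
and reduced (mean/sum/none). Comparators (BCE, focal, margin-free focal
dice, margin-adjusted cross-entropy, asymmetric loss) are included for the
loss-comparison harness.

Evaluation uses the seven standard multi-label metrics — Precision,
Coverage, Accuracy (Jaccard), Absolute true (exact match), Absolute false,
micro-F1, micro-MCC — plus per-class ROC AUC.

## Worked example

Generate a motif-labeled synthetic dataset (each class is defined by
containment of a class-specific 4-mer; imbalance and multi-label rate mimic
real corpora), train briefly, and evaluate:

```r
library(pepfusion)

ds <- generate_dataset(synthetic_config(n_sequences = 1500, n_classes = 4,
                                        prevalence = 0.3, seed = 42))
summarize_imbalance(ds$records, ds$label_space)$multi_label_fraction
#> [1] 0.3413333

sp  <- split_dataset(ds$records, 0.8, seed = 42)
cfg <- train_config(epochs = 15, seed = 42)
fit <- train_model(sp$train, sp$test, cfg, ds$label_space)   # ~3 min on 1 CPU
print(fit$report$metrics)
#> precision       0.7261
#> coverage        0.7400
#> accuracy        0.9561
#> absolute_true   0.9400
#> absolute_false  0.0167
#> f1              0.9733
#> mcc             0.9619
#> auc             0.9999 (mean over 4 defined classes)
```

`absolute_true` is the fraction of peptides whose *entire* predicted label
set matches the truth; `coverage` is the average fraction of true labels
recovered; `auc` averages per-class ranking quality. (Precision and
coverage sit below the Jaccard accuracy here because their empty-set
convention scores unlabeled background peptides as 0 even when the model
correctly predicts no label for them.) The 8-class recovery configuration
(2000 records, 10 epochs, three seeds) exercised by the test suite reaches
median micro-F1 ≈ 0.97 and exact-match ≈ 0.88.

A thin CLI over the same functions lives at `inst/cli/pepfusion.R`
(`simulate`, `encode`, `train`, `cv`, `evaluate`, `predict`, `ablate`,
`compare-losses`).

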