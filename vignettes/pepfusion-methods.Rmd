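---
title: "Multi-stream peptide function prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-stream peptide function prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepfusion)
```

## The problem

Therapeutic peptides are short amino-acid sequences (5–50 residues) that can
carry several biological activities at once — a single peptide may be both
anti-microbial and anti-cancer. Predicting the full set of functional
categories from sequence alone is a multi-label classification problem over
21 categories (anti-microbial AMP through tumor-homing THP in the default
label space), and the benchmark corpora in this field are severely
imbalanced: the most populous category outnumbers the rarest by up to two
orders of magnitude, and only a minority of peptides (roughly 15%) carry
more than one label.

`pepfusion` addresses this with two ideas: a *multi-stream sequence
representation* fused by learnable gates, and a *marginal focal dice loss*
(MFDL) that counteracts class imbalance during training.

## The eight feature streams

Every sequence is integer-encoded (residue `r` maps to its alphabetical rank
among the 20 standard amino acids, 0 is padding) and left-aligned into a
fixed window with an explicit validity mask. Eight per-position feature
streams are derived:

1. **Embedding** — a learned 20-row embedding table.
2. **Self-attention** — the embedding plus the sinusoidal positional
   encoding `PE(pos, 2i) = sin(pos / 10000^{2i/d})`,
   `PE(pos, 2i+1) = cos(pos / 10000^{2i/d})`, passed through masked
   multi-head scaled dot-product self-attention.
3. **Graph attention** — the peptide backbone as a chain graph (each residue
   connected bidirectionally to its sequence neighbours) processed by a
   multi-head graph-attention layer over the `{previous, self, next}`
   neighbourhood, with attention coefficients normalized per node. Node
   features are the token embeddings; this is a deliberate default — the
   chain topology is fixed, so the stream's value lies in learning
   *position-dependent neighbour weighting*, and embeddings are the richest
   per-residue description available before fusion.
4. **AAindex** — a per-residue physicochemical index vector. The shipped
   table is a reduced, representative subset of 11 widely used scales from
   the public AAindex collection (hydropathy, hydrophilicity, polarity,
   isoelectric point, volume, helix/sheet propensity, charge, flexibility,
   bulkiness, mutability), column-standardized at load. The loader accepts
   any table of the same layout, so a full-size index table can be plugged
   in; the stream's declared dimension follows the loaded table.
5. **PAAC** — the classic pseudo-amino-acid-composition property triplet
   (hydrophobicity, hydrophilicity, side-chain mass) *per residue*. We use
   the per-residue property vectors rather than Chou's sequence-level
   pseudo-composition because the fusion operates on aligned per-position
   streams; the sequence-level view is already covered by the AAC stream.
6. **PC6** — a six-property per-residue table (hydropathy, hydrophilicity,
   side-chain mass, pK1, pK2, isoelectric point), column-standardized.
7. **BLOSUM62** — each residue's 23-entry substitution-matrix row (20
   residues + B, Z, X), shipped verbatim: log-odds scores are already on a
   common scale.
8. **AAC** — the 20-dimensional residue-frequency composition of the whole
   sequence, broadcast (tiled) across its valid positions so it can join the
   per-position fusion.

### Gaussian-membership fuzzification

The five physicochemical streams pass through a Gaussian membership
function, `f(x) = exp(-(x - c)^2 / (2 sigma^2))`, applied per feature
dimension. This maps crisp standardized property values into soft membership
degrees in (0, 1], which blurs hard feature boundaries and improves noise
tolerance. Centers initialize at 0 and widths at 1 — the neutral choice for
standardized inputs — and both are trained end-to-end by default; whether to
train them is exposed as a switch. Inside the model the width is
parameterized as `sigma^2 = s^2 + 1e-6` so that gradient descent cannot
collapse it to zero.

## Gated fusion

Each stream is aligned to the shared model dimension `d` by its own affine
projection (the natural resolution of heterogeneous widths: gates need equal
dimensions before averaging). Stream `i` then carries one gate vector
`g_i` in `R^d`, shared across positions and batch. The fused representation
is

```
F_fused = (1/N) * sum_i  F_i ⊙ sigmoid(g_i)
```

Sigmoid gating keeps every effective gate in (0, 1): fusion can attenuate
but never amplify a stream, and the average keeps the fused features on the
scale of the inputs. Gates initialize uniformly in [-0.1, 0.1] — effective
gates start near the neutral 0.5 while symmetry between streams is broken.
Learned gates are exportable as a table (`gate_table()`) for inspecting
stream importance.

## The network

The fused per-position representation passes through, in order: a
bidirectional LSTM (contextual dependencies from both termini), a parallel
bank of 1-D convolutions with kernel widths 3/5/7 (ReLU, masked max-pooling
over positions — short contiguous motifs at several receptive fields), a
feed-forward block with residual connection and layer normalization, and a
one-hidden-layer MLP classifier ending in 21 independent sigmoid outputs. A
label is called when its probability exceeds 0.5 (strict inequality).

Masking is enforced throughout: padded positions receive no attention (their
scores are excluded before normalization), carry LSTM state through
unchanged, contribute zeros to convolutions and are excluded from pooling.
A property test perturbs the values stored at padded positions and verifies
that no logit moves by more than 1e-6.

Default architecture: `d_model = 64`, 4 attention heads, 2 graph-attention
heads, LSTM hidden 64 per direction, 64 channels per kernel, FFN width 256,
classifier hidden 128, dropout 0.1 (training only; heavier dropout is available but noticeably delays convergence at desk-scale training lengths). These defaults are sized
for CPU training; every dimension is configurable.

### Ablations

Mirroring the ablation protocol of multi-component sequence models, each
module (graph attention, BiLSTM, fuzzifier, gate fusion, CNN, FFN) and each
of the eight streams can be disabled from config. Module ablation removes
the component; gate-fusion ablation substitutes plain summation of the
aligned streams; feature ablation zeroes the stream in every batch while
keeping all shapes intact.

## Marginal focal dice loss

For training labels `Y` (N × C binary), let `n_c` be the positive count of
class c. Three imbalance mechanisms combine:

**Class weights** (switchable): `w_c = M_max * n_c^{-1/2} / max_c'
n_c'^{-1/2}` — inverse square root of the class size, normalized by the
largest weight. With weights off, `w_c = 1`.

**Margins**: each class is a binary sub-problem with side weights
`w_pos = n_pos^{-1/2}`, `w_neg = n_neg^{-1/2}`. The minority side receives
the full margin `M_max` and the majority side the proportionally smaller
`M_max * w_maj / w_min`; the margin is subtracted from the logit of the
side the sample belongs to, shifting the decision boundary in favour of the
minority side (positives, in imbalanced peptide data). The printed form of
the margin equations is ambiguous about whether the side weights are global
or per class; we resolve them per class, which is the only reading that
makes every class's minority side better protected. Margins apply during
training; evaluation uses raw logits, because a margin at test time would
shift the 0.5 threshold asymmetrically per class (a switch restores
margin-at-evaluation behaviour).

**Clipped focal dice components**: with `p = sigmoid(logit - margin)`,

```
p_pos = min(p + clip_pos, 1) * p          (positive entries)
p_neg = min((1-p) + clip_neg, 1) * (1-p)  (negative entries)

L_pos(c) = 1 - 2 * sum_i p_pos y  /  (sum_i p_pos^{P_pos} + sum_i y + eps)
L_neg(c) = 1 - 2 * sum_i p_neg (1-y) / (sum_i p_neg^{P_neg} + sum_i (1-y) + eps)
```

The per-class composite is `alpha * L_pos + (1-alpha) * L_neg`, weighted by
`w_c`, then reduced (mean/sum/none over classes). Dice is a set statistic, so
the components aggregate over the batch *within* each class and the weights
apply per class; this keeps the numerator/denominator sums well defined
while preserving the imbalance correction of per-sample weighting. A class
side that is empty in a batch contributes 0 (skipped) and all denominators
carry an additive `eps = 1e-8`, which leaves non-degenerate values unchanged
beyond 1e-7.

Defaults (tunable; the corresponding published experiments do not report
values): `alpha = 0.5`, `M_max = 0.5`, exponents `P_pos = P_neg = 2`, clips
`0.5`, class weights on, mean reduction. The clip default deserves a note:
the clipped probability `min(p + clip, 1) * p` behaves like `p^2` when the
clip is near zero, so the positive-side gradient vanishes as `p -> 0` and a
class the model currently ignores can never recover — we observed exactly
this dead-class stall on most training seeds with a clip of 0.05, while the
loss's clipping term exists precisely to prevent gradients from vanishing
at extreme probabilities. A clip of 0.5 restores a linear gradient term at
small `p` (a clip of 1 would recover plain dice) and leaves the
perfect-prediction limit unchanged; with it, training converges smoothly on
every seed we tested. For the same cold-start reason the trainer
initializes the classifier bias at the per-class prior log-odds, the
standard initialization for imbalanced classification.

Reference losses for the comparison harness — binary cross-entropy, binary
focal loss (exponent 2), the margin-free focal dice loss (exactly MFDL with
`M_max = 0` and uniform weights; verified by a configuration-equivalence
test), cross-entropy on margin-adjusted logits (the label-distribution-aware
margin scheme), and the asymmetric loss (negative exponent 4, probability
shift 0.05) — are implemented from their defining formulas on the same
autodiff graph, so each can also drive training.

## Metrics

Five set-based metrics averaged over samples — precision
`|L∩L*|/|L*|`, coverage `|L∩L*|/|L|`, accuracy (Jaccard)
`|L∩L*|/|L∪L*|`, absolute true (exact set match) and absolute false
(symmetric difference normalized by the label-space size `M` and averaged
over samples — the per-sample mean is the only reading consistent with
reported magnitudes of ~0.04) — plus micro-averaged F1 and Matthews
correlation over all label-instance pairs, and per-class ROC AUC in the
concordance (Mann–Whitney) formulation with ties at half credit, which is
equivalent to trapezoidal ROC integration and makes tie handling explicit.

Empty-set conventions: a term with zero denominator contributes 0, except
the Jaccard term when both sets are empty, which contributes 1 (the two sets
agree exactly). An all-zero MCC denominator yields 0. Classes lacking a
positive or a negative have undefined AUC and are reported `NA`.

## Synthetic data

The generator emulates the structure of the therapeutic-peptide benchmarks:
lengths uniform in 5–50, a configurable number of categories, strong
per-class imbalance (the default prevalence vector spans 0.30 down to 0.003,
a 100:1 ratio), and a minority of multi-label records (at least 15% by
default). Each class owns a distinct random motif (default length 4, so
chance containment is ~3 × 10⁻⁴ per sequence); motifs are implanted
independently per class with the class prevalence, extra motifs are
implanted until the multi-label quota is met, and the ground-truth label of
a record is *defined* as motif containment — so labels are exactly learnable
from sequence and recovery tests have a known target. Optional label noise
flips entries of the label matrix after construction.

What the generator does **not** emulate: homology and redundancy between
records, biased residue composition, real physicochemical constraints on
motifs, or correlated label structure. Passing the recovery tests therefore
demonstrates that the pipeline can extract sequence-determined signals under
imbalance — not that it reaches any particular accuracy on real peptides.

## Numerical and procedural choices

- **Autodiff**: all gradients come from a small tape-based reverse-mode
  engine over base-R matrices, with fused hand-derived backward passes for
  the attention, BiLSTM, convolution gather and max-pool operations. Every
  fused op and the end-to-end model are verified against central finite
  differences (tolerances 1e-6 on ops, 1e-3 end-to-end).
- **Optimizer**: Adam, learning rate 1e-3, default batch size 64 (the source
  experiments name no optimizer or schedule; the dice components of MFDL are
  per-class batch statistics, so they are markedly more stable at batch 64
  than at 32, which we observed to destabilize training). Gradients are
  clipped to a global L2 norm of 5. Batches are length-sorted and padded to
  their longest member; batch order is reshuffled every epoch. Training is
  fully deterministic given the seed (shuffling and dropout included);
  evaluation disables dropout.
- **Splits and folds** are uniform random without label stratification,
  matching the stated protocol of the benchmarks ("randomly divided");
  the fold assignment and the 80/20 split are functions of the seed alone.
- **Degenerate inputs**: empty sequences, unknown residues (policy:
  reject or mask), over-long sequences (policy: reject or truncate), empty
  graphs, classes with an empty side (smoothed count 1 with a warning) and
  unknown config names all raise typed errors or documented conventions
  rather than propagating NaNs.
- **Problem sizes in the test suite**: the oracle and gradient tests run on
  micro instances (N ≤ 8, C ≤ 5, d = 8); the label-recovery check trains the
  default model on 2000 generated peptides with 8 balanced classes for 10
  epochs (three seeds, median reported), and the loss comparison trains on
  1200 two-class peptides at a 50:1 ratio for 8 epochs — sizes chosen so
  that the full suite trains in minutes on one CPU core while leaving the
  learning signal unambiguous. At 50:1 the held-out fold can contain no
  minority positives at all, in which case that seed's coverage is undefined
  and excluded rather than imputed.

## Limitations

- The genetic-algorithm architecture search used by the original
  experiments is not reproduced (the procedure is unpublished); the default
  architecture is fixed and documented instead.
- The shipped AAindex table is a reduced subset; the full 500+ index
  collection is supported but not bundled.
- Headline benchmark numbers from the literature are measured on an external
  corpus after large-scale training and are not reproducible at desk scale;
  the package's tests verify exact formula-level behaviour and directional
  learning properties instead.
- Training in plain R is CPU-bound; the implementation is sized for
  thousands of short sequences, not hundreds of thousands.
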