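---
title: "Fragment-based DTI prediction with shared-weight cross-attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based DTI prediction with shared-weight cross-attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`fcadti` treats drug–target interaction (DTI) prediction as binary
classification: given a drug as a SMILES string $d$ and a protein as an
amino-acid sequence $p$, predict $I(d, p) \in \{0, 1\}$.  Both inputs are
first reduced to sequences of *fragments* — short substructure tokens — and
the classifier operates entirely on those fragment sequences.

### Drug fragmentation (branch-chain mining)

A SMILES string is tokenized (two-letter halogens and bracket atoms are
single tokens) and split into three typed fragment classes:

1. **Branch chains** — each maximal outermost parenthesised span.  Nested
   parentheses stay inside the fragment; recursing into them would multiply
   fragment counts without changing what the embedding can express.
2. **Common substructures** — literal, token-boundary-respecting matches of
   a small pattern table (benzene in aromatic and Kekulé spelling, the
   oxygen chain `COC`, the carboxyl group `C(=O)O`), scanned left-to-right
   and non-overlapping over the spliced main chain and over each branch
   chain.  The table ships as editable JSON
   (`default_pattern_table()` / `write_pattern_table()`).
3. **Synthetic fragments** — what remains of the main chain, grouped into
   atom units (a bond symbol attaches to the following atom, ring-closure
   digits to the preceding one) and chunked into windows of at most
   `max_synthetic_len = 3` atoms.  The window bound keeps the vocabulary
   finite; "cannot be split further" is otherwise not a well-defined
   criterion on strings.

A branch chain that contains a common substructure is decomposed into the
matched fragments plus its residual spans; an unmatched branch is kept
whole.  This is the only reading under which every atom token of the input
lands in exactly one output fragment — a conservation law that the test
suite checks over thousands of random molecules and that makes the
fragmentation auditable.

Two places where the rules are genuinely underdetermined are exposed as
flags rather than silently decided: whether the main chain is scanned for
common substructures at all (`scan_main`), and whether branch fragments are
emitted after the main-chain fragments (default) or interleaved at their
original string position (`positional_order`).  In positional mode the main
chain is matched per segment, so a pattern can no longer match across a
branch gap; the default mode matches the full spliced main chain.

### Protein fragmentation (category-fragment mining)

Amino acids are mapped onto eight physicochemical categories `A`–`H`
(small aliphatic, large hydrophobic, polar/hydroxyl, amide/aromatic-N,
basic, acidic, cysteine, and a fallback for nonstandard letters) and the
category string is partitioned into non-overlapping k-grams (default
$k = 3$, trailing remainder kept).  The 8-category grouping is a documented
default shipped as editable JSON, not a canonical constant: published
descriptions of this encoding name the eight classes without printing the
table, so we chose a standard physicochemical grouping and made it
configurable.  "Divided by k-gram" is read as a partition; a `stride`
argument exposes the sliding-window alternative.

### Network

Each fragment sequence is label-encoded against a vocabulary built from the
training split only (ids 0/1 reserved for padding/unknown, head-keep
truncation to a fixed length) and embedded.  Two parallel CNN blocks — three
(1-D convolution → batch normalisation → ELU) layers each, kernel sizes
3/3/3 for drugs and 4/6/8 for proteins, same-length padding — produce
feature matrices $D_{CNN} \in \mathbb{R}^{L_D \times d_{CNN}}$ and
$P_{CNN} \in \mathbb{R}^{L_P \times d_{CNN}}$.

The two branches are fused by *shared-weight multihead cross-attention*.
For head $i$ with width $d_h = d_{CNN}/h$:

$$Q_{D_i} = D_{CNN} W_{Q_i},\quad K_{D_i} = P_{CNN} W_{K_i},\quad
  V_{D_i} = P_{CNN} W_{V_i}$$
$$Z_{D_i} = \mathrm{softmax}\!\left(\frac{Q_{D_i} K_{D_i}^\top}{\sqrt{d_h}}\right) V_{D_i}$$

and symmetrically for the protein direction with queries from $P_{CNN}$ and
keys/values from $D_{CNN}$ — using the *same* $W_{Q_i}, W_{K_i}, W_{V_i}$
parameters, which is the defining constraint of the module (a
parameter-identity, tested by perturbing one matrix and observing both
attention maps move).  Heads are concatenated and projected by
$W_0 \in \mathbb{R}^{d_{CNN} \times d_{CNN}}$; we read the head-recombination
as one projection applied to the concatenation, which is the only shape
consistent with the concatenation itself.  The attended features are mixed
with the originals, $D_f = w M_D + (1 - w) D_{CNN}$ with $w = 0.5$, channel-wise
max-pooled over the sequence axis, concatenated to a $2 d_{CNN}$ vector and
passed through a three-layer FCN (dropout → linear → leaky-ReLU twice, then
a bare linear layer).  A final sigmoid produces the interaction probability;
training minimises mean binary cross-entropy.  Two ablation switches mirror
the architecture study: `no_cross_attention` removes the attention module
entirely and `no_original_feature` drops the residual term.

The network, backpropagation and AdamW are implemented in base-R matrix
algebra (no deep-learning runtime).  Analytic gradients are verified
against central finite differences to $10^{-3}$ relative error in the test
suite.

## Parameters that matter

| parameter | default | meaning / why |
|---|---|---|
| `emb_dim` | 512 (full), 32 (small preset) | embedding width |
| `conv_channels` | 128 / 32 | $d_{CNN}$; must be divisible by `heads` |
| `drug_kernels`, `protein_kernels` | 3,3,3 / 4,6,8 | conv windows over fragment positions |
| `heads` | 4 | attention heads, $d_h = d_{CNN}/h$ |
| `mix_weight` | 0.5 | residual mix of attended vs original features |
| `dropout` | 0.1 | FCN regularisation (training only) |
| `max_len_drug`, `max_len_protein` | 100 / 545 | fixed encoded lengths; truncation is head-keep |
| `lr`, `batch_size`, `weight_decay` | 1e-5, 64, 1e-4 | full-scale optimisation settings |
| `k` | 3 | protein k-gram length |
| `max_synthetic_len` | 3 | atoms per synthetic drug fragment |

The full-scale learning rate of 1e-5 is far too small to move a 32-unit
model on a few hundred pairs within 50 epochs, so the desk-scale preset
(`small_train_config()`) uses AdamW at 3e-3 with early-stopping patience 10
on validation AUC — chosen so that training *converges* (training loss
below 0.05, validation AUC plateau) within the epoch cap.  The optimiser
itself (Adam with decoupled weight decay) is our choice; only the learning
rate, batch size, weight decay and dropout values above are inherited
settings.

## Numerical choices

* Attention scores are scaled by $\sqrt{d_h}$ (the standard scaled
  dot-product reading); softmax subtracts the row maximum before
  exponentiating.
* Probabilities are clamped to $[10^{-7}, 1 - 10^{-7}]$ inside the loss;
  the training gradient uses the fused sigmoid-BCE form, which is exact and
  stable.
* The printed form of the loss in the source literature reads
  $-(y \log p + (1-y) \log p)$, which is minimised at $p \to 0$ regardless
  of the label and is therefore not a proper loss; we implement standard
  BCE with $\log(1-p)$ in the second term, which is what "BCELoss" names.
* Batch-norm statistics are per-channel over batch × sequence positions
  (biased variance, momentum 0.1); evaluation mode uses running statistics,
  so eval-mode forward passes are deterministic and batching-invariant.
* Max-pooling breaks ties at the first index; AUC uses the Mann–Whitney
  rank statistic with ties counting one half; AUPR is step-integrated over
  descending score thresholds with tied scores entering as one block;
  thresholded metrics count a score of exactly 0.5 as positive.
* Leaky-ReLU negative slope is 0.01 (conventional; unspecified upstream).
* Padded positions are embedded like ordinary tokens (the pad embedding is
  learned); with max-pooling this is harmless in practice and keeps the
  forward pass free of masking logic.
* Malformed SMILES fail fast with the offending position; no silent
  skipping.

## The synthetic benchmark and what a green test establishes

Real DTI benchmarks require external downloads and long stochastic
training, so validation rests on a synthetic dataset with a *planted,
learnable rule* (`generate_dataset()`): each pair carries both a drug motif
(`C(=O)O`, which exercises the branch-chain and common-substructure
fragment types) and a protein motif (`RKD`, whose category image `EEF`
spans the basic/acidic category boundary) with probability ½; the label is
1 with probability `p_signal = 0.95` when both motifs are present and
`p_noise = 0.05` otherwise.  Drugs are random branched chains over C/N/O
with benzene insertions (8–40 tokens; random branches never contain double
bonds, so the `=O` branch fragment is specific to the motif); proteins are
uniform 20-letter sequences of length 50–400.  The protein motif is spliced
at a k-gram-aligned offset: at a uniform offset the signal trigram would
fall into a single fragment for only a third of the positives, making the
rule only partially recoverable *by construction*, which would test the
generator's alignment luck rather than the model.

With motif prevalence $q$, the fraction of positives carrying the motif is
$a = q p_s / (q p_s + (1-q) p_n)$ and of negatives
$b = q(1-p_s) / (q(1-p_s) + (1-q)(1-p_n))$, giving the Bayes-optimal

$$\mathrm{AUC}^* = a(1-b) + \tfrac12\big(ab + (1-a)(1-b)\big)$$

(`bayes_auc()`), which is exactly **0.95** at the defaults.  No model can
beat this in expectation, and on an 80-pair held-out split the empirical
AUC of even the motif-presence oracle fluctuates around it with a standard
deviation of roughly 0.02.  The end-to-end check therefore asserts that the
trained small model reaches at least 95% of the Bayes AUC; at the
pre-registered seed the model attains 99.9% of the realised ceiling of its
test split, i.e. it recovers the planted rule essentially optimally.  An
additional acceptance assertion pins the threshold at the Bayes value 0.95
itself; because that sits exactly at the ceiling, it can fail by sampling
noise alone, and we keep it as an honest, documented knife-edge rather than
tuning seeds or slack around it.  A green synthetic run establishes that
the pipeline can extract and combine fragment-level signals end to end —
not that it reproduces published benchmark numbers, and not that the
generator's chemistry is realistic (molecules are not valence-checked;
proteins are i.i.d. letters).

The same reasoning applies to the ablation comparison: on this dataset both
the full model and the `no_cross_attention` variant can sit at the Bayes
ceiling (the planted rule is a simple conjunction that pooling plus an FCN
can represent), so their AUC difference on 80 pairs is ranking noise; the
directional assertion is made with a small slack and its outcome reported
as measured.

## Known limitations

* Fragmentation is string-level: no valence model, no canonicalisation, no
  ring-aware chemistry beyond the literal benzene patterns.
* The pure-R network is desk-scale; full-scale settings (embedding 512,
  length 545) install and run but training them on real benchmarks is out
  of scope.
* Vocabulary is closed at training time; unseen fragments map to a single
  unknown id.
* 5-fold cross-validation retrains from scratch per fold and is therefore
  the most expensive entry point.
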