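---
title: "Padding one-hot-encoded protein sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Padding one-hot-encoded protein sequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqpad)
```

## The problem

Deep models over raw amino acid sequences need fixed-shape input, but
proteins have different lengths. The usual remedy is to fix a common
length T, truncate longer sequences, and fill shorter ones with an
artificial symbol ("0") — zero-padding. Where those pad symbols go is
almost always treated as an implementation detail, yet it changes the
geometry of the one-hot input that the network sees. This package
implements seven placement strategies and the machinery to measure what
the choice does to a downstream classifier:

* **dense** paddings keep the zeros in one contiguous block —
  `post` (at the end), `pre` (at the start), `mid` (in the middle),
  `ext` (balanced at both ends);
* **sparse** paddings intersperse them — `strf` (uniformly spread),
  `rnd` (random positions) — or avoid pad symbols altogether by
  repeating contiguous residues (`zoom`);
* `aug` is padding-based data augmentation: each sequence is represented
  by all seven variants.

The measurement task is a two-level enzyme classification: task 1
separates enzymes from non-enzymes; task 2 assigns enzymes to one of the
seven top-level EC classes (the first digit of the EC number,
oxidoreductase through translocase).

## Placement rules

With L residues, target length T and Z = T − L zeros, using 0-based
positions:

* `post`: residues at 0..L−1; `pre`: residues at Z..T−1.
* `mid`: the first ⌈L/2⌉ residues stay left, the rest are right-aligned;
  the tie (odd L) goes left. The zeros form one contiguous central run.
* `ext`: ⌊Z/2⌋ zeros lead, ⌈Z/2⌉ trail; the extra zero goes right.
* `strf`: residue i sits at ⌊i·T/L⌋. This map is injective and
  order-preserving, and consecutive residue gaps differ by at most one —
  the strongest uniformity achievable by a deterministic rule.
* `rnd`: the Z pad positions are drawn uniformly without replacement from
  a stream derived from (seed, sequence id), so augmentation and re-runs
  are reproducible per sequence.
* `zoom`: output position j holds residue ⌊j·L/T⌋ (nearest-lower
  resampling). The map is monotone, onto 0..L−1, and repeats each residue
  ⌊T/L⌋ or ⌈T/L⌉ times; no pad symbol is introduced, so a model cannot
  count zeros.

The tie-breaking conventions (`mid` left, `ext` right) are fixed here for
reproducibility; any consistent choice would serve. Sequences longer than
T are rejected by `pad_sequence()` — the benchmark filters at T
(`filter_by_length()`) rather than truncating, and `truncate_sequence()`
is provided separately for pipelines that prefer cutting.

## One-hot codec

The alphabet holds 25 residue symbols by default (20 standard amino acids
plus U, O, B, Z, X as used by UniProt) and a dedicated pad symbol at
index 0, so a padded sequence becomes a (n+1) × T binary matrix with
exactly one active row per column — the pad symbol has its own row. The
alternative convention, all-zero columns at pad positions, is available
via `pad_row = FALSE`; the default keeps every column summing to one,
which makes malformed matrices detectable and the decode unambiguous.

## Synthetic data: what it emulates and what it does not

`simulate_dataset()` produces desk-scale datasets with the statistical
skeleton of the Swiss-Prot Archaea benchmark set: about 45% non-enzymes,
the skewed class distribution over the seven enzyme classes (class 2
largest, class 7 rare), a small fraction (default 1% of enzymes) of
multi-EC records, and lengths bounded by the common length. Class
identity is carried by a fixed 6-residue motif substituted into an
i.i.d. background of the 20 standard residues at a configurable position
(`n_term`, `middle`, `c_term`, `uniform`). Substitution rather than
insertion keeps sequence length independent of class, isolating the
padding effect from the length–class confound present in real data
(where classes differ systematically in length); a per-class length
shift can be reintroduced through the length parameters if that confound
is wanted.

A 6-mer motif over a 20-letter background collides with random sequence
with probability under 1e-5 per position, so labels are decodable from
the sequence (`scan_motifs()` recovers them at ≥ 99%), making the
classification tasks genuinely learnable. What the generator does *not*
emulate: homology structure, domain architecture, physicochemical
composition biases, or evolutionary divergence within an EC class.
Passing tests on this data therefore demonstrate that the pipeline is
correct and that padding placement alters what a model can exploit —
not that any particular padding is best for real proteomes.

Multi-EC records receive the second class's motif at the opposite end of
the sequence so both signals survive; expanded duplicates share an
`origin_id` and are never separated by `make_splits()` (grouped
assignment), which prevents an expanded sequence from appearing in both
train and test. Splits are plain random 70/15/15 by default, repeated 10
times; stratified splitting is available behind a flag. Grouping can
shift a part's size by at most one sample at the default multi-EC rate.

## Architectures and training

Three architectures are compared, built as configurable contracts:

* `only_denses` — dense layers over the flattened one-hot input (the
  baseline; position-sensitive but convolution-free);
* `1_conv` — one length-preserving 1D convolution (default 64 filters of
  size 5, stride 1, zero boundary), then dense layers;
* `stack_conv` — five such convolutions in parallel, concatenated.

Dropout (default 0.3) follows each hidden dense layer. Task 1 ends in a
sigmoid unit, task 2 in seven softmax units. Convolutions preserve the
temporal length so a trained `1_conv` model exposes filters × T
activation maps for the analysis below. The default hidden widths
(128, 64) are package choices; the architecture family, filter count and
kernel size are the benchmark's fixed points.

Because no deep-learning framework is available to R in this
environment, the training engine is implemented natively: the
convolution over one-hot input is computed as a column lookup into the
kernel weights and its gradient as a grouped scatter-add, dense layers as
BLAS matrix products, with inverted dropout and an Adam optimiser.
Backpropagation is verified against central-difference numerical
gradients to 1e-6 in the test suite.

`training_config()` defaults to the full-scale optimisation settings:
Adam with learning rate 1e-4, β₁ = 0.9, β₂ = 0.999, batch 54, and
selection of the epoch with maximum validation accuracy (200 epochs at
full scale; the desk default is 10). Those step sizes are matched to a
schedule of tens of thousands of optimiser steps. The desk-scale runs in
this package (tests, the worked examples, `scripts/acceptance.R`) train
on 10²–10³ sequences for 10 epochs — two to three orders of magnitude
fewer steps — so they pass `learning_rate = 1e-2` and `batch_size = 16`
explicitly: the larger step size and smaller batches restore roughly the
amount of optimisation per datum that the full-scale schedule provides.
This is a deliberate desk-scale study condition, not a tuned quantity.

Augmentation (`aug`) expands the training and validation parts to all
seven paddings per sequence *after* the split assignment (so variants
never straddle partitions) and scores each test sequence by averaging
the predicted probabilities of its seven variants; per-variant scoring
is available via `aug_eval = "per_variant"`.

## Metrics and comparisons

Per-label F1, macro F1 (unweighted mean over labels, hence insensitive
to class imbalance) and accuracy are computed from binarised predictions
— threshold 0.5 for task 1 and argmax for task 2 (a 0.5 threshold is
ill-posed for softmax outputs). AUC uses the raw probabilities and is
reported for task 1 only. Conventions for degenerate cases: a label with
neither true nor predicted positives gets F1 = 0 with a warning; labels
absent from the test truth are excluded from the macro with a warning.
Paired comparisons across folds use the two-sided Wilcoxon signed-rank
test, exact for n ≤ 25 when ties permit, normal approximation with
continuity correction otherwise; an all-zero difference vector is
reported as p = 1 with a degenerate flag.

## Activation-space analysis

For the `1_conv` models, 14 test proteins are sampled (7 per class for
task 1, 2 per enzyme class for task 2) and pushed through each fold ×
single-padding model; each prediction leaves a filters × T activation
map (64 × 1000 at full scale; 10 folds × 7 paddings × 14 proteins = 980
maps). Every filter row — a length-T activation profile — is treated as
one observation, and the stacked rows are decomposed by a centred,
unscaled PCA (`prcomp`); scaling is deliberately off because all
activations share units. An additive OLS model of PC1 on enzyme type and
padding type (treatment-coded, enzyme class 1 and post-padding as
references) quantifies how sparse paddings displace the activation
distribution relative to dense ones.

## Explanatory models

The per-label F1 values — one observation per fold × architecture ×
padding × label — are modelled by treatment-coded OLS. The response
granularity (per-label rather than macro) follows from enzyme type being
a factor in the models. The full additive model is

F1 ~ architecture + enzyme_type + type_padding

with references only_denses, non-enzyme (task 1) or class 1 (task 2),
and post-padding. Five focused questions restrict the data and add
interactions: A (does padding position matter? only_denses, all eight
paddings), B (dense vs dense; post/pre/mid/ext with a
padding × architecture interaction, reference stack_conv), C (dense vs
sparse; post/strf/rnd/zoom, same interaction), D (is augmentation
beneficial? aug/post/strf with aug as padding reference), and E (does
the padding effect depend on enzyme type? post/strf with a
padding × enzyme-type interaction, task 2 only — requesting it for task
1 is an error). P-values are Benjamini–Hochberg adjusted within each
fitted model's coefficient table; the intercept is excluded from the
adjustment since it tests a mean rather than a contrast. When a supplied
metrics table contains a single level of some factor (a desk run on one
architecture, say), that term is dropped with a message rather than
producing a rank-deficient fit.

```{r example-models, eval = FALSE}
metrics <- metrics_table(grid) # grid from run_grid()
full <- explain_f1(metrics, "full", task = 2)
tidy(full)
autoplot(full)
```

## Desk-scale problem sizes

The package's examples and checks run at sizes chosen to finish in
minutes on one CPU while preserving the design's structure: n = 1,400
sequences (the generator default) with lengths 30–100 at T = 100 for the
directional benchmark (three folds, 10 epochs, `1_conv`); n = 350 with
lengths up to 400 at T = 1,000 with small hidden widths for the
activation-count design (10 folds × 7 paddings × 14 proteins = 980
maps); and n = 400 at T = 100 for the activation PCA. The directional
claim checked at desk scale is an ordering — with end-planted motifs,
random interspersed padding degrades a convolutional model relative to
post-padding — not a reproduction of full-scale metric values, which
require training on the real annotated proteome at T = 1,000 for 200
epochs.

## Known limitations

* The engine is CPU-bound, single-threaded R; it is sized for desk-scale
  experiments, not proteome-scale training.
* The exact hidden widths and dropout rates of the original full-scale
  architectures are not fixed by this package; its defaults are sensible
  placeholders and every width is configurable.
* The synthetic generator's i.i.d. background makes the tasks easier
  than real annotation transfer; absolute metric values on it are not
  comparable to real-data results.
* `rnd` padding seeds per sequence id; two datasets sharing ids and seed
  share pad positions by construction.
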