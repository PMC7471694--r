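# seqpad

Padding strategies for one-hot-encoded amino acid sequences, and the
machinery to measure what the padding choice does to a sequence
classifier.

Deep models over raw protein sequences need fixed-shape input, so
sequences are brought to a common length T — longer ones truncated,
shorter ones filled with an artificial `"0"` symbol. Where those pad
symbols are placed is usually an afterthought, but it reshapes the
(n+1) × T binary matrix the model consumes. `seqpad` implements seven
placement strategies — the dense paddings **post**, **pre**, **mid**,
**ext** (zeros in one contiguous block) and the sparse paddings
**strf** (zeros spread uniformly: residue *i* of *L* sits at
⌊i·T/L⌋), **rnd** (random positions) and **zoom** (no zeros: residue
⌊j·L/T⌋ at output *j*, so contiguous residues repeat) — plus **aug**,
padding-based data augmentation that represents each sequence by all
seven variants.

Around the padding primitives the package provides the full benchmark
used to quantify their effect: a one-hot codec with a dedicated pad row,
FASTA/TSV ingestion of EC-number annotations (multi-EC entries expanded
per distinct first digit), grouped 70/15/15 split plans, a synthetic
motif-planted sequence generator that mirrors the class skew of the
Archaea benchmark set, three natively-trained neural architectures
(`only_denses`, `1_conv`, `stack_conv`) on two hierarchical tasks
(enzyme/non-enzyme; EC class 1–7), per-label/macro F1, accuracy and AUC
with paired Wilcoxon comparisons, PCA of convolutional filter
activations, and treatment-coded explanatory linear models
(`F1 ~ architecture + enzyme_type + type_padding`, with the
question-specific variants A–E) under Benjamini–Hochberg adjustment.

## Worked example

```r
library(seqpad)
library(dplyr)

pad_sequence("MKLVWYACD", 15, "strf")$symbols
#> [1] "MK0L0VW0Y0AC0D0"
pad_sequence("MKLVWYACD", 15, "zoom")$symbols
#> [1] "MMKKLVVWWYAACCD"

encode_one_hot("AC0", build_alphabet(c("A", "C", "D")))
#>   [,1] [,2] [,3]
#> 0    0    0    1
#> A    1    0    0
#> C    0    1    0
#> D    0    0    0
```

Each column carries a single 1; the pad symbol owns row 0. A desk-scale
benchmark — 400 synthetic sequences with class motifs planted at the
N-terminus, two split repetitions, a one-convolution model, post- vs
rnd-padding at T = 100:

```r
sim <- simulate_dataset(sim_config(n = 400, length_min = 30, length_max = 100, seed = 1))
samples <- simulated_samples(sim)
splits <- make_splits(samples, n_repeats = 2, seed = 1)
cfg <- training_config(epochs = 5, batch_size = 16, learning_rate = 1e-2, seed = 1)

grid <- run_grid(
  samples, splits, tasks = 1,
  archs = list(`1_conv` = architecture_spec("1_conv", dense_sizes = c(32))),
  modes = c("post", "rnd"), folds = 1:2, length = 100, config = cfg
)
metrics_table(grid) |>
  filter(metric %in% c("macro_f1", "auc")) |>
  group_by(padding, metric) |>
  summarise(mean = mean(value), .groups = "drop")
#> # A tibble: 4 × 3
#>   padding metric    mean
#>   <chr>   <chr>    <dbl>
#> 1 post    auc      0.997
#> 2 post    macro_f1 0.949
#> 3 rnd     auc      0.929
#> 4 rnd     macro_f1 0.855
```

With the class signal sitting at the sequence start, keeping the zeros
in one block (post) preserves it, while scattering zeros through the
sequence (rnd) breaks the motif the convolution must detect — the
macro F1 drops accordingly. `explain_f1(metrics, "C", task = 2)` fits
the corresponding explanatory model, `tidy()`/`glance()` return its
coefficient table and fit summary, and `autoplot()` draws the
coefficient tiles; `plot_metrics()` shows the per-padding boxplots.

A thin command-line wrapper lives at `inst/cli/seqpad.R`
(`pad`, `simulate`, `split` subcommands) for shell pipelines.

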