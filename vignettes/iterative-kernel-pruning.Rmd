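---
title: "Motif inference by iterative kernel pruning"
author: "MotifPruner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif inference by iterative kernel pruning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MotifPruner)
```

## The problem

Convolutional networks predict whether a short DNA sequence (for ChIP-seq
data, a 101-bp fragment) is bound by a DNA-binding protein. A single
convolutional layer with many kernels, ReLU, global max pooling, and a
sigmoid dense head performs well, and performance typically improves with
more kernels. But a true binding model usually involves only a handful of
motifs: most kernels act as *auxiliary* capacity that helps optimization
escape poor local optima and then contributes noise. Many-kernel models are
therefore hard to interpret — reading kernels as motifs yields mostly junk —
and a small model trained directly tends to get stuck at poor optima and is
very sensitive to initialization.

MotifPruner resolves this tension by *iterative kernel pruning*: train a
deliberately over-parameterized model with `2^k * d` kernels, then `k`
times (i) mask the less important half of the active kernels via a binary
mask on the pooled scores and (ii) fine-tune the survivors at a gently
decayed learning rate. The result is a `d`-kernel model that keeps the
optimization benefits of the big model while being small enough that each
kernel can be read as a position weight matrix (PWM).

## Model

A sequence of length $L$ is one-hot encoded into a $4 \times L$ matrix $S$
(rows A, C, G, T; the ambiguity code N becomes an all-zero column and thus
contributes nothing to any convolution). With kernels
$F^1,\dots,F^d \in \mathbb{R}^{4\times L_F}$:

$$
h_{pk} = \sum_{i=1}^{L_F}\sum_{j=1}^{4} S_{j,\,i+p-1}\,F^k_{ji},
\qquad a_{pk} = \max(0, h_{pk}),
$$
$$
z_k = \max_p a_{pk}, \qquad u_k = z_k m_k, \qquad
P(\text{bound}\mid S) = \sigma\!\Big(b + \sum_k w_k u_k\Big),
$$

where $m \in \{0,1\}^d$ is the mask. A masked kernel ($m_k = 0$) is
mathematically removed: its pooled score is zeroed, it receives no
gradient, and the compacted model with that kernel deleted makes identical
predictions. This connects directly to PWM scanning: a kernel whose entries
are $\log(\mathrm{PWM}_{ji}/0.25)$ computes exactly the sliding-window
log-likelihood ratio of that PWM against a uniform background, which the
test suite verifies against an independent scanner.

## Pruning criteria and schedule

Each pruning step masks exactly half of the currently active kernels,
ranked by one of three statistics:

* **weight** (default): $|w_k|$, the dense-layer magnitude;
* **score**: $|\mathrm{AVG}_P u_k - \mathrm{AVG}_N u_k|$, the separation of
  the mean pooled score between positive and negative training sequences;
* **score_weight**: $|\mathrm{AVG}_P u_k w_k - \mathrm{AVG}_N u_k w_k|$,
  the separation of the kernel's contribution to the sigmoid input.

The written rule "keep kernels above the median" retains exactly half only
when the median is untied; we instead rank descending and keep exactly the
top half, breaking ties toward the lower kernel index. This preserves the
halving guarantee deterministically and coincides with the median rule in
the untied case. Score summaries use the full training set. Masked kernels
carry a $-\infty$ sentinel so they can never be revived (the mask is
monotone), and their reported dense weight is exactly 0.

After the $t$-th prune the learning rate is $lr_0 / 1.2^t$ ("divide by 1.2
every pruning step"; division rather than subtraction keeps the rate
positive for any $k$ and matches the intent of gradually gentler
fine-tuning). Three modes exist: `finetune` (prune, then fine-tune, each
stage), `inter` (skip the final fine-tune — the diagnostic model "pruned
from twice the kernels without fine-tuning"), and `lottery` (each
fine-tune is replaced by rewinding surviving parameters bit-exactly to
their initialization snapshot and retraining, the lottery-ticket variant).
The over-parameterized model is trained to early-stopping convergence
before the first prune.

## Training

Binary cross-entropy without weight decay, minibatch Adam
(`lr = 0.01`, `beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`), batch size
256, and early stopping: training stops once the validation loss has not
improved for 15 consecutive epochs, and the weights of the best validation
epoch are restored (the standard reading of "stop when the validation loss
has stopped decreasing"). A hard cap of 200 epochs guards degenerate runs;
in practice patience fires first. Kernel length defaults to 24 bp for
simulated data and 15 bp for 101-bp ChIP-seq sequences. Initialization is
Glorot-uniform for kernels and dense weights with zero bias; since
training is sensitive to initialization, every stochastic component
(initialization, batch shuffling, simulation) flows from one integer seed
and runs single-threaded, so a (config, seed) pair reproduces a run
bit-exactly. An 18-seed sweep (`defaultSeeds()`) is packaged for
robustness summaries.

One numerical note: with Adam, a gradient that is zero *in exact
arithmetic* but computed as $10^{-18}$ floating-point dust still produces
learning-rate-sized steps, because Adam normalizes the step by the
gradient's own magnitude. Tests of the early-stopping rule therefore
assert the stop-at-`bestEpoch + patience` contract on real traces rather
than trying to manufacture an exactly flat loss.

## The simulator

`makeDataset()` emulates the standard motif-insertion benchmark:
backgrounds are i.i.d. uniform over A, C, G, T (probability 0.25 each);
each positive sequence receives exactly one instance sampled column-wise
from one PWM chosen uniformly from the recipe's motif set; the instance
overwrites the background at an offset uniform over all fully contained
placements (no edge clipping, so sequence length is preserved). Splits are
balanced half positive / half negative, train and test equally sized by
default, and a validation split (default 10% of the training count) serves
early stopping. The five standard recipes use 2, 2, 2, 4, and 8 motifs
(`presetRecipe()`). For real data, negatives come from
Altschul–Erickson dinucleotide shuffling of the positives, which preserves
mono- and dinucleotide counts exactly.

Choices the benchmark sources leave open, fixed here once: sequence length
101 bp (matching the real-data fragments and motivating `d = 4` as roughly
one 24-bp kernel per quarter sequence); 10,000 train / 10,000 test by
default; one insertion per positive (the minimal reading, matching the
single-max-pool architecture); and a bundled set of eight *synthetic* toy
PWMs (widths 6–12, consensus-style columns of varying information content,
pairwise best-alignment correlation below 0.8) because the original motif
identities are unpublished — any JASPAR or MEME-minimal file can be
substituted. The simulator does not model motif–motif interactions,
variable insertion counts, positional bias, or GC-matched backgrounds;
consequently, passing benchmarks here demonstrates the optimization and
interpretability claims under the PWM generative model, not performance on
real chromatin data.

## Visualization

Kernels are turned into motifs the DeepBind way: every window whose ReLU
activation reaches at least a fraction (default 0.5) of the kernel's
global maximum over the supplied sequences (conventionally positive test
sequences) is harvested; per-position base counts plus a 0.25 pseudocount
give the kernel's PWM; per-column information content is
$2 + \sum_j p_j \log_2 p_j$ bits under a uniform background. A
`per_sequence` thresholding variant is exposed because the harvesting
procedure is under-specified in the visualization literature. Motifs are
exported in MEME minimal format for downstream Tomtom-style comparison;
recovered motifs are matched to truths by maximum Pearson correlation over
all ungapped offsets, forward strand only (the model scans one strand).

## Scaled-down study sizes

The test suite and `scripts/acceptance.R` run the benchmark at a desk
scale chosen once: 2,000 train / 2,000 test sequences, the two-motif
recipe, five seeds, pruning 32 → 4 kernels (`k = 3`) against a directly
trained 4-kernel baseline. At this scale the package's central claims are
checked as orderings: mean test AUC of the pruned 4-kernel model is at
least the baseline's, its across-seed variance is no larger, and the two
top-information-content recovered PWMs match the two distinct true motifs
(Pearson ≥ 0.75) with near-background flanks (< 0.3 bits mean IC) — the
"extra kernel positions contain no noise" property. Schedule arithmetic
(256 → 4 through six exact halvings) and the masked-weight-is-zero
reporting contract are checked exactly.

## Worked example

```{r example, eval = FALSE}
library(MotifPruner)

ds <- makeDataset(datasetRecipe(toyMotifs()[1:2],
                                nTrain = 2000, nTest = 2000, seed = 101))
cfg <- trainConfig(seed = 0)                 # batch 256, lr 0.01, Lf 24
stages <- runIterativePrune(newMotifModel(32, 24, seed = 0), ds,
                            pruneSchedule(k = 3, d = 4), cfg)
vapply(stages, `[[`, 0, "testAuc")           # AUC at 32, 16, 8, 4 kernels
trainBaseline(4, ds, cfg)$testAuc            # direct 4-kernel baseline

pos <- sequences(ds$test)[labels01(ds$test) == 1]
motifs <- kernelMotifs(stages[[4]]$model, pos)
bestMatchSimilarity(motifs[[1]]$pwm, toyMotifs()[[2]])
exportMeme(motifs, "recovered.meme")
```

## Limitations

* The architecture has no hidden layer, so motif–motif interactions are
  not representable; on real data where interactions matter the pruned
  model can trail a large baseline.
* Whole kernels are pruned via the dense layer; unstructured weight-level
  sparsity and one-shot pruning to arbitrary ratios are out of scope.
* Training runs on one CPU thread for determinism; the problem sizes here
  make that practical, but the implementation is not tuned for
  genome-scale sweeps.
* The bundled toy motifs are synthetic stand-ins; conclusions about
  specific transcription factors require supplying real PWM files.
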