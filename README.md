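# MotifPruner

Interpretable DNA-protein binding prediction by **iterative kernel pruning**
of a single-convolutional-layer network.

CNN-based motif models predict whether a DNA fragment is bound by a protein
by scanning its one-hot encoding with convolutional kernels, max-pooling
each kernel's activation profile, and passing the pooled scores through a
sigmoid dense head. Many kernels make optimization easy but interpretation
hard: only a few kernels correspond to real motifs, the rest are auxiliary
capacity that turns into noise. Training a small model directly, however,
gets stuck in poor local optima and is highly sensitive to initialization.

MotifPruner trains an over-parameterized model with `2^k · d` kernels, then
`k` times masks the weaker half of the active kernels and fine-tunes the
survivors, ending with a `d`-kernel model whose kernels can be read as
position weight matrices. It is aimed at computational biologists studying
transcription-factor binding from ChIP-seq-style data or simulated
benchmarks.

## Model

For a one-hot sequence matrix `S` (4 × L) and kernels `F^k` (4 × L_F):

    h_pk = Σ_i Σ_j S[j, i+p−1] · F^k[j, i]      (convolution, valid mode)
    a_pk = max(0, h_pk)                          (ReLU)
    z_k  = max_p a_pk                            (global max pooling)
    u_k  = z_k · m_k                             (mask layer, m_k ∈ {0,1})
    P(bound | S) = σ(b + Σ_k w_k u_k)            (dense sigmoid head)

Each pruning step keeps exactly the top half of the active kernels under
one of three criteria — `|w_k|` (default), `|AVG_P u_k − AVG_N u_k|`, or
`|AVG_P u_k·w_k − AVG_N u_k·w_k|` — then fine-tunes with the learning rate
divided by 1.2 per step. Masked kernels receive no gradient, report weight
exactly 0, and can be dropped (`compactModel()`) without changing any
prediction. Variants: `inter` (skip the final fine-tune) and `lottery`
(rewind survivors to their initialization and retrain). Training is Adam
(lr 0.01, batch 256) with 15-epoch-patience early stopping restoring the
best-validation weights.

## Worked example

Simulate the two-motif benchmark, prune 32 → 4 kernels, compare with a
directly trained 4-kernel baseline, and recover the motifs:

```r
library(MotifPruner)

ds  <- makeDataset(datasetRecipe(toyMotifs()[1:2],
                                 nTrain = 2000, nTest = 2000, seed = 101))
cfg <- trainConfig(seed = 0)                      # batch 256, lr 0.01, Lf 24

stages <- runIterativePrune(newMotifModel(32, 24, seed = 0), ds,
                            pruneSchedule(k = 3, d = 4), cfg)
round(vapply(stages, `[[`, 0, "testAuc"), 4)
#> [1] 0.7177 0.6912 0.6668 0.6713                # AUC at 32, 16, 8, 4 kernels

round(trainBaseline(4, ds, cfg)$testAuc, 4)
#> [1] 0.6783                                     # direct 4-kernel baseline

stages[[4]]$model
#> MotifModel: 32 kernel slots ( 4 active ), kernel length 24 bp
#>   seed: 0
#>   bias: -0.03429

pos    <- sequences(ds$test)[labels01(ds$test) == 1]
motifs <- kernelMotifs(stages[[4]]$model, pos)    # ordered by information content
round(bestMatchSimilarity(motifs[[1]]$pwm, toyMotifs()[[2]]), 3)
#> [1] 0.999
round(bestMatchSimilarity(motifs[[2]]$pwm, toyMotifs()[[1]]), 3)
#> [1] 0.816
exportMeme(motifs, "recovered.meme")              # for Tomtom-style comparison
```

The two highest-information-content kernels of the pruned model recover the
two inserted motifs almost exactly (Pearson 0.999 and 0.816 at the best
ungapped alignment). A single seed can favor either method — the claim is
about the distribution: over seeds 0–4 on this recipe the pruned model's
mean test AUC exceeds the baseline's and its across-seed variance is
smaller (the robustness property; see the vignette for the study sizes).

A thin command-line interface wraps the same functions
(`inst/scripts/motifpruner`): subcommands `simulate`, `train`, `evaluate`,
`compare`, `visualize`.

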