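Package: MotifPruner
Title: Interpretable Motif Inference by Iterative Kernel Pruning of
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains a single-convolutional-layer neural network for
    DNA-protein binding prediction, then iteratively masks (prunes) half of
    the convolutional kernels via median-based criteria on the dense layer
    and fine-tunes, yielding small models whose kernels can be read as
    sequence motifs. Includes a motif-insertion simulator for benchmark
    datasets, dinucleotide shuffling for negative-set construction,
    evaluation utilities (AUC, paired one-sided Wilcoxon signed-rank
    comparison), and kernel-to-PWM visualization with MEME-format export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
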