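# Loss, Adam fitting with best-epoch early stopping, the directly trained
# baseline, and lottery-ticket retraining.

#' Training configuration
#'
#' Defaults are the benchmark settings: batch size 256, Adam with initial
#' learning rate 0.01 (beta1 0.9, beta2 0.999, eps 1e-8), early stopping
#' once the validation loss has not improved for 15 consecutive epochs
#' (restoring the best-validation-epoch weights), kernel length 24 bp. A
#' cap of 200 epochs guards runs where early stopping never fires.
#'
#' @param batchSize minibatch size.
#' @param lr initial Adam learning rate.
#' @param patience early-stopping patience in epochs.
#' @param maxEpochs hard cap on epochs.
#' @param kernelLen kernel length Lf in bp (24 simulated / 15 real).
#' @param seed integer seed for initialization and batch shuffling.
#' @param beta1,beta2,eps Adam moment parameters.
#' @return a list of class `"TrainConfig"`.
#' @export
trainConfig <- function(batchSize = 256L, lr = 0.01, patience = 15L,
                        maxEpochs = 200L, kernelLen = 24L, seed = 1L,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  stopifnot(batchSize >= 1, patience >= 1, lr > 0, maxEpochs >= 1,
            kernelLen >= 1)
  structure(list(batchSize = as.integer(batchSize), lr = lr,
                 patience = as.integer(patience),
                 maxEpochs = as.integer(maxEpochs),
                 kernelLen = as.integer(kernelLen),
                 seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "TrainConfig")
}

#' The default 18-seed sweep used for robustness summaries
#' @return integer vector of 18 seeds.
#' @export
defaultSeeds <- function() {
  c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 100L, 123L, 1000L, 1234L,
    10000L, 12345L, 100000L, 123456L, 1000000L)
}

#' Mean binary cross-entropy
#'
#' `mean(-(y * log(p) + (1 - y) * log(1 - p)))`, with probabilities
#' clipped to `[1e-12, 1 - 1e-12]` before the logs.
#'
#' @param probs predicted probabilities in (0, 1).
#' @param labels 0/1 vector of the same length.
#' @return a scalar loss.
#' @examples
#' binaryCrossEntropy(rep(0.5, 4), c(0, 1, 0, 1))  # log(2)
#' @export
binaryCrossEntropy <- function(probs, labels) {
  if (length(probs) != length(labels))
    stop("probs and labels must have equal length")
  cpp_mean_bce(as.numeric(probs), as.numeric(labels))
}

# Split container -> encoded array + labels, validating both classes.
encodedSplit <- function(data, what) {
  if (methods::is(data, "MotifDataset")) {
    y <- labels01(data)
    X <- encodeSequences(sequences(data))
  } else if (is.list(data) && !is.null(data$X)) {
    X <- data$X
    y <- as.integer(data$labels)
  } else stop(what, " must be a MotifDataset or list(X=, labels=)")
  if (length(unique(y)) < 2)
    stop(what, " data must contain both classes")
  list(X = X, y = y)
}

#' Fit a model by Adam with early stopping
#'
#' Minimizes binary cross-entropy by minibatch Adam. Training stops when
#' the validation loss has not improved for `cfg$patience` consecutive
#' epochs (or at `cfg$maxEpochs`), and the parameters of the best
#' validation epoch are restored. Masked kernels receive no gradient and
#' are bit-unchanged on return.
#'
#' @param model a [MotifModel-class].
#' @param train,val training / validation data: [MotifDataset-class]
#'   objects (or `list(X = 4 x L x n array, labels = 0/1)`); both classes
#'   must be present in each.
#' @param cfg a [trainConfig()].
#' @param lr overrides `cfg$lr` (used by the pruning loop's learning-rate
#'   decay).
#' @return list with `model` (trained) and `trace` (per-epoch `trainLoss`,
#'   `valLoss`, plus `bestEpoch`, `stoppedEpoch`).
#' @export
fitModel <- function(model, train, val, cfg = trainConfig(), lr = NULL) {
  tr <- encodedSplit(train, "train")
  vl <- encodedSplit(val, "val")
  if (is.null(lr)) lr <- cfg$lr
  # one derived sub-seed so init (R side) and shuffling (C++ side) both
  # flow from cfg$seed without colliding
  shufSeed <- (cfg$seed * 7919L + 13L) %% .Machine$integer.max
  fit <- cpp_train(tr$X, as.numeric(tr$y), vl$X, as.numeric(vl$y),
                   model@kernels, as.numeric(model@mask),
                   model@denseWeights, model@bias,
                   lr, cfg$batchSize, cfg$patience, cfg$maxEpochs,
                   as.integer(shufSeed), cfg$beta1, cfg$beta2, cfg$eps)
  out <- model
  out@kernels <- array(fit$kernels, dim = dim(model@kernels))
  out@denseWeights <- as.numeric(fit$w)
  out@bias <- as.numeric(fit$b)
  out@metadata$lastFit <- list(bestEpoch = fit$best_epoch,
                               stoppedEpoch = fit$stopped_epoch,
                               bestValLoss = fit$best_val_loss, lr = lr)
  trace <- list(trainLoss = as.numeric(fit$train_loss),
                valLoss = as.numeric(fit$val_loss),
                bestEpoch = as.integer(fit$best_epoch),
                stoppedEpoch = as.integer(fit$stopped_epoch))
  list(model = out, trace = trace)
}

#' Train a directly initialized d-kernel baseline
#'
#' Initializes a fresh model with `d` kernels (mask all ones) and fits it;
#' the comparison point for iteratively pruned models of the same size.
#'
#' @param d kernel count.
#' @param splits list with `train`, `val`, `test` ([makeDataset()]
#'   layout).
#' @param cfg a [trainConfig()].
#' @return list with `model`, `trace`, and `testAuc`.
#' @export
trainBaseline <- function(d, splits, cfg = trainConfig()) {
  model <- newMotifModel(d, cfg$kernelLen, seed = cfg$seed)
  fit <- fitModel(model, splits$train, splits$val, cfg)
  scores <- predictProb(fit$model, splits$test)
  list(model = fit$model, trace = fit$trace,
       testAuc = aucScore(scores, labels01(splits$test)))
}

#' Rewind surviving parameters to initialization and retrain
#'
#' Lottery-ticket retraining: the unmasked kernels, their dense weights,
#' and the bias are reset bit-exactly to the values captured at
#' initialization; masked kernels stay masked with dense weight 0; then
#' the subnetwork is fitted as usual.
#'
#' @param model a trained, pruned [MotifModel-class] (must carry its
#'   `initSnapshot`).
#' @inheritParams fitModel
#' @return list with `model` and `trace`.
#' @export
lotteryRetrain <- function(model, train, val, cfg = trainConfig(),
                           lr = NULL) {
  snap <- model@initSnapshot
  if (is.null(snap$kernels)) stop("model has no initialization snapshot")
  rewound <- model
  act <- activeKernels(model)
  rewound@kernels[, , act] <- snap$kernels[, , act]
  rewound@denseWeights[act] <- snap$denseWeights[act]
  rewound@denseWeights[-act] <- 0
  rewound@bias <- snap$bias
  fitModel(rewound, train, val, cfg, lr = lr)
}
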