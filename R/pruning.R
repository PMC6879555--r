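# Mask-update criteria and the iterative halving schedule.

#' Per-kernel class-mean pooled scores
#'
#' For every kernel, the mean masked pooled score `u_k` over the positive
#' and over the negative training sequences. Masked kernels yield 0 in
#' both means. These feed the `"score"` and `"score_weight"` pruning
#' criteria, which are computed over the full training set.
#'
#' @param model a [MotifModel-class].
#' @param data a [MotifDataset-class] containing both classes.
#' @return list with numeric vectors `avgPosU` and `avgNegU`.
#' @export
computeScoreSummary <- function(model, data) {
  y <- labels01(data)
  if (length(unique(y)) < 2) stop("data must contain both classes")
  u <- pooledScores(model, data)
  list(avgPosU = colMeans(u[y == 1L, , drop = FALSE]),
       avgNegU = colMeans(u[y == 0L, , drop = FALSE]))
}

#' Per-kernel pruning statistic
#'
#' The three criteria rank active kernels by:
#' \describe{
#'   \item{weight}{`|w_k|` — dense-layer weight magnitude.}
#'   \item{score}{`|AVG_P u_k - AVG_N u_k|` — class separation of the
#'     pooled score.}
#'   \item{score_weight}{`|AVG_P u_k w_k - AVG_N u_k w_k|` — class
#'     separation of the kernel's contribution to the sigmoid input.}
#' }
#' Masked kernels are assigned `-Inf` so they can never be retained.
#'
#' @param model a [MotifModel-class].
#' @param criterion `"weight"`, `"score"`, or `"score_weight"`.
#' @param summary result of [computeScoreSummary()]; required unless
#'   `criterion == "weight"`.
#' @return numeric vector, one statistic per kernel slot.
#' @export
criterionStatistic <- function(model, criterion = c("weight", "score",
                                                    "score_weight"),
                               summary = NULL) {
  criterion <- match.arg(criterion)
  if (criterion != "weight" && is.null(summary))
    stop("criterion \"", criterion, "\" needs a score summary ",
         "(computeScoreSummary)")
  stat <- switch(criterion,
    weight = abs(model@denseWeights),
    score = abs(summary$avgPosU - summary$avgNegU),
    score_weight = abs(summary$avgPosU * model@denseWeights -
                       summary$avgNegU * model@denseWeights))
  stat[model@mask == 0L] <- -Inf
  stat
}

#' Mask the lower half of the active kernels
#'
#' Exactly half of the currently active kernels are retained — the top
#' half by the supplied statistic, ties broken toward the lower kernel
#' index — and the rest are masked. Newly masked kernels get dense weight
#' 0; previously masked kernels stay masked (the mask is monotone
#' non-increasing across prunings). Keeping exactly the top half is
#' equivalent to the strict `statistic > median(active statistics)`
#' threshold whenever the median is not tied, and resolves ties
#' deterministically so the halving guarantee always holds.
#'
#' @param model a [MotifModel-class] with an even number (>= 2) of active
#'   kernels.
#' @param statistic per-kernel statistic from [criterionStatistic()].
#' @return the pruned [MotifModel-class].
#' @export
pruneHalf <- function(model, statistic) {
  act <- activeKernels(model)
  if (length(act) < 2 || length(act) %% 2 != 0)
    stop("active kernel count must be even and >= 2; got ", length(act))
  if (length(statistic) != nKernels(model))
    stop("statistic length must equal the kernel count")
  keepN <- length(act) %/% 2
  ord <- act[order(-statistic[act], act)]
  keep <- ord[seq_len(keepN)]
  out <- model
  out@mask <- rep(0L, nKernels(model))
  out@mask[keep] <- 1L
  out@denseWeights[out@mask == 0L] <- 0
  out
}

#' Iterative prune-and-fine-tune
#'
#' Starting from an untrained over-parameterized model with `2^k * d`
#' kernels, first trains it to early-stopping convergence, then iterates
#' `k` times: compute the criterion statistic, mask the lower half of the
#' active kernels, divide the learning rate by `lrDecayFactor`, and
#' fine-tune (mode `"finetune"`); mode `"inter"` skips the fine-tune of
#' the final stage, and mode `"lottery"` replaces every fine-tune by
#' rewinding the surviving parameters to their initialization and
#' retraining.
#'
#' @param model an untrained [MotifModel-class] with `2^k * d` active
#'   kernels (see [newMotifModel()]). A pre-trained model may be passed
#'   with `trainFirst = FALSE`.
#' @param splits list with `train`, `val`, `test` ([makeDataset()]
#'   layout).
#' @param schedule a [pruneSchedule()].
#' @param cfg a [trainConfig()].
#' @param trainFirst train the full model before the first prune
#'   (default `TRUE`).
#' @return list of `k + 1` stages; each stage is a list with
#'   `activeCount`, `model`, `testAuc`, `lr`, and `trace` (`NULL` for a
#'   stage that was not fitted).
#' @examples
#' \donttest{
#' ds <- makeDataset(datasetRecipe(toyMotifs()[1:2], nTrain = 200,
#'                                 nTest = 200, seed = 1))
#' cfg <- trainConfig(seed = 1, maxEpochs = 5)
#' stages <- runIterativePrune(newMotifModel(8, 24, 1), ds,
#'                             pruneSchedule(k = 1, d = 4), cfg)
#' }
#' @export
runIterativePrune <- function(model, splits, schedule,
                              cfg = trainConfig(), trainFirst = TRUE) {
  stopifnot(methods::is(schedule, "PruneSchedule"))
  d0 <- sum(model@mask)
  if (d0 != 2L^schedule@k * schedule@d)
    stop("schedule expects ", 2L^schedule@k * schedule@d,
         " active kernels (2^k * d); model has ", d0)
  yTest <- labels01(splits$test)
  stageAuc <- function(m)
    aucScore(predictProb(m, splits$test), yTest)

  stages <- vector("list", schedule@k + 1L)
  trace0 <- NULL
  if (trainFirst) {
    fit0 <- fitModel(model, splits$train, splits$val, cfg)
    model <- fit0$model
    trace0 <- fit0$trace
  }
  stages[[1]] <- list(activeCount = sum(model@mask), model = model,
                      testAuc = stageAuc(model), lr = cfg$lr,
                      trace = trace0)

  for (t in seq_len(schedule@k)) {
    summ <- if (schedule@criterion == "weight") NULL else
      computeScoreSummary(model, splits$train)
    stat <- criterionStatistic(model, schedule@criterion, summ)
    model <- pruneHalf(model, stat)
    lr_t <- cfg$lr / schedule@lrDecayFactor^t
    trace <- NULL
    finalInter <- schedule@mode == "inter" && t == schedule@k
    if (!finalInter) {
      fit <- if (schedule@mode == "lottery") {
        lotteryRetrain(model, splits$train, splits$val, cfg, lr = lr_t)
      } else {
        fitModel(model, splits$train, splits$val, cfg, lr = lr_t)
      }
      model <- fit$model
      trace <- fit$trace
    }
    stages[[t + 1L]] <- list(activeCount = sum(model@mask), model = model,
                             testAuc = stageAuc(model), lr = lr_t,
                             trace = trace)
  }
  stages
}

#' Stage log of an iterative pruning run
#'
#' Tidies the output of [runIterativePrune()] into one row per stage:
#' stage index, active kernel count, learning rate, best validation loss,
#' test AUC, and the per-kernel `|w|` columns (masked kernels report
#' exactly 0).
#'
#' @param stages result of [runIterativePrune()].
#' @param path optional TSV output path.
#' @return a data.frame, invisibly written to `path` when given.
#' @export
stageLog <- function(stages, path = NULL) {
  rows <- lapply(seq_along(stages), function(i) {
    st <- stages[[i]]
    vl <- if (!is.null(st$trace)) min(st$trace$valLoss) else NA_real_
    absW <- abs(denseWeights(st$model))
    df <- data.frame(stage = i - 1L, activeCount = st$activeCount,
                     lr = st$lr, valLoss = vl, testAuc = st$testAuc)
    wdf <- as.data.frame(t(absW))
    colnames(wdf) <- paste0("absW", seq_along(absW))
    cbind(df, wdf)
  })
  log <- do.call(rbind, rows)
  if (!is.null(path))
    write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(log)
}
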