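makeModelWithWeights <- function(w, mask = NULL, Lf = 4) {
  d <- length(w)
  m <- newMotifModel(d, Lf, seed = 1)
  m@denseWeights <- w
  if (!is.null(mask)) m@mask <- as.integer(mask)
  m
}

test_that("criterion statistics follow their definitions", {
  m <- makeModelWithWeights(c(0.5, -0.8, 0.1, 0.2))
  expect_equal(criterionStatistic(m, "weight"), c(0.5, 0.8, 0.1, 0.2))

  summ <- list(avgPosU = c(1, 2, 3, 4), avgNegU = c(1, 2, 3, 4))
  expect_equal(criterionStatistic(m, "score", summ), rep(0, 4))

  set.seed(51)
  for (i in 1:20) {
    w <- rnorm(6)
    mm <- makeModelWithWeights(w, Lf = 3)
    s <- list(avgPosU = runif(6), avgNegU = runif(6))
    expect_lt(max(abs(criterionStatistic(mm, "score_weight", s) -
                        abs(w) * abs(s$avgPosU - s$avgNegU))), 1e-12)
  }

  expect_error(criterionStatistic(m, "score"), "score summary")
  # masked kernels get the -Inf sentinel
  mm <- makeModelWithWeights(c(1, 2, 3, 4), mask = c(1, 0, 1, 1))
  expect_identical(criterionStatistic(mm, "weight")[2], -Inf)
})

test_that("pruneHalf keeps exactly the top half, ties to lower index", {
  m <- makeModelWithWeights(c(0.9, 0.1, 0.5, 0.4))
  pruned <- pruneHalf(m, criterionStatistic(m, "weight"))
  expect_identical(activeKernels(pruned), c(1L, 3L))
  expect_identical(denseWeights(pruned)[c(2, 4)], c(0, 0))

  # all-equal statistics: deterministic lowest-index retention
  m2 <- makeModelWithWeights(rep(0.5, 8))
  pruned2 <- pruneHalf(m2, criterionStatistic(m2, "weight"))
  expect_identical(activeKernels(pruned2), 1:4L)

  # odd active count is rejected
  m3 <- makeModelWithWeights(c(1, 2, 3), mask = c(1, 1, 1))
  expect_error(pruneHalf(m3, c(1, 2, 3)), "even")
})

test_that("retained sets agree with a sorting oracle", {
  set.seed(52)
  for (i in 1:25) {
    d <- sample(c(4, 8, 16), 1)
    w <- rnorm(d)
    m <- makeModelWithWeights(w, Lf = 3)
    stat <- criterionStatistic(m, "weight")
    pruned <- pruneHalf(m, stat)
    oracle <- order(-stat, seq_along(stat))[seq_len(d / 2)]
    expect_identical(activeKernels(pruned), sort(as.integer(oracle)))
  }
})

test_that("six halvings walk 256 kernels down to 4", {
  m <- makeModelWithWeights(rnorm(256), Lf = 3)
  counts <- sum(kernelMask(m))
  cur <- m
  for (t in 1:6) {
    cur <- pruneHalf(cur, criterionStatistic(cur, "weight"))
    counts <- c(counts, sum(kernelMask(cur)))
  }
  expect_identical(counts, c(256L, 128L, 64L, 32L, 16L, 8L, 4L))
  # monotone mask: once pruned, never revived
  expect_true(all(kernelMask(cur)[denseWeights(m) == 0] == 0))
})

test_that("mask monotonicity holds across successive prunings", {
  set.seed(53)
  m <- makeModelWithWeights(rnorm(16), Lf = 3)
  prev <- kernelMask(m)
  cur <- m
  for (t in 1:3) {
    cur <- pruneHalf(cur, criterionStatistic(cur, "weight"))
    expect_true(all(kernelMask(cur) <= prev))
    prev <- kernelMask(cur)
  }
})

test_that("score summaries are per-class means of pooled scores", {
  set.seed(54)
  m <- newMotifModel(1, 4, seed = 2)
  ds <- motifDataset(randomDna(2, 20), c(1L, 0L),
                     provenance = data.frame(index = 1L, motif = "m",
                                             offset = 0L))
  summ <- computeScoreSummary(m, ds)
  u <- pooledScores(m, ds)
  expect_equal(summ$avgPosU, u[1, ])
  expect_equal(summ$avgNegU, u[2, ])

  # duplicating every sequence leaves the means unchanged
  seqs <- randomDna(6, 20)
  labs <- c(1L, 1L, 1L, 0L, 0L, 0L)
  prov <- data.frame(index = 1:3, motif = "m", offset = 0L)
  d1 <- motifDataset(seqs, labs, prov)
  d2 <- motifDataset(c(seqs, seqs), c(labs, labs),
                     data.frame(index = c(1:3, 7:9), motif = "m",
                                offset = 0L))
  m2 <- newMotifModel(3, 5, seed = 3)
  expect_equal(computeScoreSummary(m2, d1), computeScoreSummary(m2, d2))

  # accumulation oracle: per-sequence loop
  m3 <- newMotifModel(4, 6, seed = 4)
  seqs <- randomDna(20, 30)
  labs <- rep(c(1L, 0L), 10)
  d3 <- motifDataset(seqs, labs,
                     data.frame(index = which(labs == 1L), motif = "m",
                                offset = 0L))
  summ3 <- computeScoreSummary(m3, d3)
  loopPos <- matrix(0, 0, 4); loopNeg <- matrix(0, 0, 4)
  for (i in seq_along(seqs)) {
    fp <- forwardPass(m3, seqs[i])
    if (labs[i] == 1L) loopPos <- rbind(loopPos, fp$u)
    else loopNeg <- rbind(loopNeg, fp$u)
  }
  expect_lt(max(abs(summ3$avgPosU - colMeans(loopPos))), 1e-10)
  expect_lt(max(abs(summ3$avgNegU - colMeans(loopNeg))), 1e-10)

  # masked kernels report zero means
  m4 <- newMotifModel(4, 6, seed = 5)
  m4@mask <- c(1L, 0L, 1L, 0L)
  s4 <- computeScoreSummary(m4, d3)
  expect_identical(s4$avgPosU[c(2, 4)], c(0, 0))
})

test_that("a minimal schedule prunes 2 kernels to 1 with a fine-tune", {
  sp <- separableSplits(n = 60, L = 20, seed = 13)
  cfg <- trainConfig(batchSize = 20, kernelLen = 5, seed = 1,
                     maxEpochs = 3, patience = 3)
  stages <- runIterativePrune(newMotifModel(2, 5, seed = 1), sp,
                              pruneSchedule(k = 1, d = 1), cfg)
  expect_length(stages, 2)
  expect_identical(vapply(stages, `[[`, 1L, "activeCount"), c(2L, 1L))
  expect_identical(stages[[2]]$lr, cfg$lr / 1.2)
  # schedule/state mismatch errors
  expect_error(runIterativePrune(newMotifModel(3, 5, seed = 1), sp,
                                 pruneSchedule(k = 1, d = 1), cfg),
               "2\\^k")
})

test_that("every stage model equals its compacted form on probes", {
  sp <- separableSplits(n = 80, L = 20, seed = 14)
  cfg <- trainConfig(batchSize = 32, kernelLen = 5, seed = 2,
                     maxEpochs = 3, patience = 3)
  stages <- runIterativePrune(newMotifModel(8, 5, seed = 2), sp,
                              pruneSchedule(k = 2, d = 2), cfg)
  expect_identical(vapply(stages, `[[`, 1L, "activeCount"),
                   c(8L, 4L, 2L))
  probes <- randomDna(10, 20)
  for (st in stages) {
    direct <- predictProb(st$model, probes)
    compacted <- predictProb(compactModel(st$model), probes)
    expect_lt(max(abs(direct - compacted)), 1e-10)
    # masked invariance at each stage
    pert <- st$model
    off <- which(kernelMask(pert) == 0L)
    if (length(off)) {
      pert@kernels[, , off] <- 99
      expect_identical(predictProb(pert, probes), direct)
    }
  }
  # learning-rate ladder lr0 / 1.2^t
  expect_equal(vapply(stages, `[[`, 0, "lr"),
               cfg$lr / 1.2^(0:2))
})

test_that("inter mode skips the final fine-tune", {
  sp <- separableSplits(n = 60, L = 20, seed = 15)
  cfg <- trainConfig(batchSize = 20, kernelLen = 5, seed = 3,
                     maxEpochs = 3, patience = 3)
  stages <- runIterativePrune(newMotifModel(4, 5, seed = 3), sp,
                              pruneSchedule(k = 1, d = 2, mode = "inter"),
                              cfg)
  expect_null(stages[[2]]$trace) # pruned, not fine-tuned
  # the inter model is the trained full model with the mask applied
  full <- stages[[1]]$model
  inter <- stages[[2]]$model
  act <- activeKernels(inter)
  expect_identical(kernels(inter)[, , act], kernels(full)[, , act])
})

test_that("stage logs report masked weights as exactly zero", {
  sp <- separableSplits(n = 60, L = 20, seed = 16)
  cfg <- trainConfig(batchSize = 20, kernelLen = 5, seed = 4,
                     maxEpochs = 3, patience = 3)
  stages <- runIterativePrune(newMotifModel(4, 5, seed = 4), sp,
                              pruneSchedule(k = 2, d = 1), cfg)
  log <- stageLog(stages)
  expect_identical(nrow(log), 3L)
  expect_identical(log$activeCount, c(4L, 2L, 1L))
  for (i in seq_len(nrow(log))) {
    mask <- kernelMask(stages[[i]]$model)
    wCols <- as.numeric(log[i, paste0("absW", 1:4)])
    expect_identical(wCols[mask == 0L], rep(0, sum(mask == 0L)))
  }
})
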