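test_that("convolution matches the nested-loop double sum", {
  enc <- oneHotEncode("AACG")
  expect_equal(convolveScan(enc, matrix(0, 4, 2)), rep(0, 3))
  # kernel = one-hot "AC": counts matching letters per window
  expect_equal(convolveScan(enc, oneHotEncode("AC")), c(1, 2, 0))

  set.seed(31)
  for (i in 1:100) {
    L <- sample(10:40, 1)
    Lf <- sample(2:8, 1)
    S <- matrix(rnorm(4 * L), 4, L)
    K <- matrix(rnorm(4 * Lf), 4, Lf)
    expect_lt(max(abs(convolveScan(S, K) - convOracle(S, K))), 1e-10)
  }
  expect_error(convolveScan(oneHotEncode("ACG"), matrix(0, 4, 5)),
               "shorter")
})

test_that("forward pass composes conv, ReLU, max-pool, mask, sigmoid", {
  set.seed(32)
  model <- newMotifModel(6, 5, seed = 1)
  s <- randomDna(1, 30)
  fp <- forwardPass(model, s)
  expect_equal(fp$a, pmax(fp$h, 0))
  expect_equal(fp$z, apply(fp$a, 2, max))
  expect_equal(fp$u, fp$z * kernelMask(model))
  manual <- 1 / (1 + exp(-(modelBias(model) +
                             sum(denseWeights(model) * fp$u))))
  expect_lt(abs(fp$prob - manual), 1e-8)
  expect_gt(fp$prob, 0); expect_lt(fp$prob, 1)

  # batch forward agrees with per-sequence forward
  seqs <- randomDna(10, 30)
  probs <- predictProb(model, seqs)
  for (i in 1:10)
    expect_lt(abs(probs[i] - forwardPass(model, seqs[i])$prob), 1e-8)
})

test_that("a fully masked model predicts sigmoid(bias) everywhere", {
  model <- newMotifModel(3, 4, seed = 2)
  model@mask <- rep(0L, 3)
  model@bias <- 0.7
  probs <- predictProb(model, randomDna(5, 20))
  expect_equal(probs, rep(1 / (1 + exp(-0.7)), 5))
})

test_that("single active kernel with unit weight gives sigmoid(z)", {
  model <- newMotifModel(1, 3, seed = 3)
  model@denseWeights <- 1
  model@bias <- 0
  s <- randomDna(1, 15)
  fp <- forwardPass(model, s)
  expect_equal(fp$prob, 1 / (1 + exp(-fp$z[1])))
})

test_that("compaction preserves predictions and is idempotent", {
  set.seed(33)
  model <- newMotifModel(16, 6, seed = 4)
  expect_identical(compactModel(model), model) # all-ones mask
  model@mask <- as.integer(seq_len(16) %in% c(2, 7, 11, 16))
  small <- compactModel(model)
  expect_identical(nKernels(small), 4L)
  expect_identical(sum(kernelMask(small)), 4L)
  probes <- randomDna(50, 25)
  expect_lt(max(abs(predictProb(model, probes) -
                      predictProb(small, probes))), 1e-10)
  expect_identical(compactModel(small), small)
  model@mask <- rep(0L, 16)
  expect_error(compactModel(model), "fully masked")
})

test_that("initialization is seeded and captures a snapshot", {
  a <- newMotifModel(8, 10, seed = 5)
  b <- newMotifModel(8, 10, seed = 5)
  expect_identical(kernels(a), kernels(b))
  expect_identical(denseWeights(a), denseWeights(b))
  expect_identical(sum(kernelMask(a)), 8L)
  expect_identical(modelBias(a), 0)
  expect_identical(a@initSnapshot$kernels, kernels(a))
  c <- newMotifModel(8, 10, seed = 6)
  expect_false(identical(kernels(a), kernels(c)))
})

test_that("masked kernels are invisible to the forward pass", {
  set.seed(34)
  model <- newMotifModel(10, 5, seed = 7)
  model@mask <- as.integer(seq_len(10) %% 2 == 0)
  probes <- randomDna(20, 30)
  base <- predictProb(model, probes)
  perturbed <- model
  off <- which(kernelMask(model) == 0L)
  perturbed@kernels[, , off] <- rnorm(length(perturbed@kernels[, , off]))
  perturbed@denseWeights[off] <- rnorm(length(off)) * 100
  expect_identical(predictProb(perturbed, probes), base)
})

test_that("log-odds kernels reproduce the PWM log-likelihood-ratio scan", {
  # pre-ReLU pooled score of a log(PWM/0.25) kernel equals the best-window
  # LLR of a sliding PWM scanner
  set.seed(35)
  p <- randomPwm(6)
  K <- log(p / 0.25)
  llrScan <- function(s) {
    ch <- strsplit(s, "")[[1]]
    vapply(seq_len(nchar(s) - 5), function(off) {
      sum(vapply(1:6, function(i)
        log(p[match(ch[off + i - 1], c("A", "C", "G", "T")), i] / 0.25),
        0))
    }, 0)
  }
  for (s in randomDna(15, 40)) {
    scan <- convolveScan(oneHotEncode(s), K)
    expect_lt(max(abs(scan - llrScan(s))), 1e-10)
    expect_lt(abs(max(scan) - max(llrScan(s))), 1e-10)
  }
})

test_that("prediction is monotone in pooled score for positive weight", {
  model <- newMotifModel(2, 3, seed = 8)
  model@denseWeights <- c(0.8, -0.3)
  z <- c(1.0, 0.5)
  pAt <- function(z) 1 / (1 + exp(-(model@bias +
                                      sum(model@denseWeights * z))))
  expect_gt(pAt(z + c(1e-4, 0)), pAt(z)) # w1 > 0: increasing
  expect_lt(pAt(z + c(0, 1e-4)), pAt(z)) # w2 < 0: decreasing
})

test_that("checkpoints round-trip bit-exactly", {
  model <- newMotifModel(5, 7, seed = 9)
  model@mask <- c(1L, 0L, 1L, 1L, 0L)
  model@denseWeights[c(2, 5)] <- 0
  model@bias <- pi / 7
  path <- tempfile(fileext = ".json")
  saveModel(model, path)
  back <- readModel(path)
  expect_identical(kernels(back), kernels(model))
  expect_identical(denseWeights(back), denseWeights(model))
  expect_identical(modelBias(back), modelBias(model))
  expect_identical(kernelMask(back), kernelMask(model))
  expect_identical(back@initSnapshot$kernels, model@initSnapshot$kernels)
  expect_error(readModel(tempfile()), "not found")
})

test_that("analytic gradients match finite differences", {
  set.seed(36)
  seqs <- randomDna(6, 12)
  y <- c(1, 1, 1, 0, 0, 0)
  X <- encodeSequences(seqs)
  model <- newMotifModel(2, 3, seed = 10)
  kern <- kernels(model); w <- denseWeights(model); b <- modelBias(model)
  lossAt <- function(kern, w, b)
    binaryCrossEntropy(predictProb(
      new("MotifModel", kernels = kern, mask = c(1L, 1L),
          denseWeights = w, bias = b, initSnapshot = list(),
          metadata = list()), X), y)
  pool <- MotifPruner:::cpp_pool_batch(X, kern)
  z <- matrix(pool$z, ncol = 2)
  am <- matrix(pool$argmax, ncol = 2)
  probs <- predictProb(model, X)
  dsv <- (probs - y) / length(y)
  gw <- colSums(dsv * z)
  gb <- sum(dsv)
  gK <- array(0, dim(kern))
  for (i in seq_along(y))
    for (k in 1:2)
      if (z[i, k] > 0) {
        pstar <- am[i, k]
        gK[, , k] <- gK[, , k] + dsv[i] * w[k] * X[, pstar:(pstar + 2), i]
      }
  eps <- 1e-6
  for (idx in sample(seq_along(kern), 20)) {
    kp <- kern; kp[idx] <- kp[idx] + eps
    km <- kern; km[idx] <- km[idx] - eps
    expect_lt(abs(gK[idx] - (lossAt(kp, w, b) - lossAt(km, w, b)) /
                    (2 * eps)), 1e-6)
  }
  for (k in 1:2) {
    wp <- w; wp[k] <- wp[k] + eps
    wm <- w; wm[k] <- wm[k] - eps
    expect_lt(abs(gw[k] - (lossAt(kern, wp, b) - lossAt(kern, wm, b)) /
                    (2 * eps)), 1e-6)
  }
  expect_lt(abs(gb - (lossAt(kern, w, b + eps) -
                        lossAt(kern, w, b - eps)) / (2 * eps)), 1e-6)
})
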