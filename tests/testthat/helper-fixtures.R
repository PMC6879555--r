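# Shared fixtures, built in code at test time.

dinucCounts <- MotifPruner:::dinucCounts

# a random column-stochastic PWM
randomPwm <- function(w, seed = NULL, name = "rnd") {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(runif(4 * w, 0.05, 1), nrow = 4)
  pwm(sweep(m, 2, colSums(m), "/"), name = name)
}

randomDna <- function(n, L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    "")
}

# a tiny balanced two-motif dataset for fast training tests
tinySplits <- function(nTrain = 200, nTest = 200, seed = 7) {
  makeDataset(datasetRecipe(toyMotifs()[1:2], nTrain = nTrain,
                            nTest = nTest, seed = seed))
}

# a linearly separable toy problem: positives all carry an exact CCCCCC run
separableSplits <- function(n = 200, L = 30, seed = 3) {
  set.seed(seed)
  neg <- randomDna(n, L)
  neg <- vapply(neg, function(s) gsub("CCCC", "ACGT", s), "",
                USE.NAMES = FALSE)
  pos <- vapply(randomDna(n, L), function(s) {
    off <- sample.int(L - 6 + 1, 1)
    paste0(substr(s, 1, off - 1), "CCCCCC", substr(s, off + 6, L))
  }, "", USE.NAMES = FALSE)
  mk <- function(p, ng) motifDataset(c(p, ng),
                                     c(rep(1L, length(p)),
                                       rep(0L, length(ng))))
  list(train = mk(pos[seq_len(n / 2)], neg[seq_len(n / 2)]),
       val = mk(pos[(n / 2 + 1):(3 * n / 4)], neg[(n / 2 + 1):(3 * n / 4)]),
       test = mk(pos[(3 * n / 4 + 1):n], neg[(3 * n / 4 + 1):n]))
}

# nested-loop convolution oracle: the double sum written out directly
convOracle <- function(S, K) {
  Lf <- ncol(K)
  P <- ncol(S) - Lf + 1
  out <- numeric(P)
  for (p in seq_len(P))
    for (i in seq_len(Lf))
      for (j in 1:4)
        out[p] <- out[p] + S[j, i + p - 1] * K[j, i]
  out
}

# exhaustive pair-counting AUC oracle
aucOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos)
    for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exact one-sided signed-rank p by brute enumeration of all 2^n sign
# patterns (midranks, ties allowed)
wilcoxonEnumOracle <- function(diffs) {
  dz <- diffs[diffs != 0]
  n <- length(dz)
  r <- rank(abs(dz))
  wObs <- sum(r[dz > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  mean(ws >= wObs - 1e-9)
}

# best-offset Pearson similarity oracle: plain loop over all placements
similarityOracle <- function(a, b) {
  if (ncol(a) > ncol(b)) { tmp <- a; a <- b; b <- tmp }
  best <- -Inf
  for (off in 0:(ncol(b) - ncol(a))) {
    x <- as.numeric(a)
    y <- as.numeric(b[, (off + 1):(off + ncol(a))])
    r <- if (sd(x) == 0 || sd(y) == 0) 0 else cor(x, y)
    best <- max(best, r)
  }
  best
}
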