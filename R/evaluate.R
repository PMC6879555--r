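# AUC, the one-sided Wilcoxon signed-rank test, and paired method
# comparison across datasets/seeds.

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic: the probability
#' that a uniformly chosen positive outscores a uniformly chosen negative,
#' with ties credited 1/2.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 vector; both classes must be present.
#' @return the AUC in `[0, 1]`.
#' @examples
#' aucScore(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
#' @export
aucScore <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  nPos <- sum(labels == 1L)
  nNeg <- sum(labels == 0L)
  if (nPos == 0 || nNeg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# Exact null distribution of W+ (sum of signed midranks, doubled to stay
# integer) by dynamic programming over the 2^n equiprobable sign patterns.
signrankNullPmf <- function(ranks2) {
  total <- sum(ranks2)
  pmf <- numeric(total + 1) # index i <-> statistic value i - 1
  pmf[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), pmf[seq_len(total + 1 - r)])
    pmf <- (pmf + shifted) / 2
  }
  pmf
}

#' One-sided Wilcoxon signed-rank test
#'
#' Tests the alternative that the median difference is positive. Zero
#' differences are dropped before ranking; absolute differences are
#' midranked. For `n <= 25` remaining differences the p-value is exact —
#' the null distribution of the signed-rank sum is enumerated over all
#' `2^n` sign patterns (by convolution, which handles tied ranks) — and
#' for larger `n` the normal approximation with tie and continuity
#' correction is used.
#'
#' @param diffs numeric vector of paired differences; at least 5 nonzero
#'   values are required.
#' @param exact force (`TRUE`) or suppress (`FALSE`) the exact
#'   enumeration; default picks exact for `n <= 25`.
#' @return list with `statistic` (W+, the positive-rank sum), `n` (nonzero
#'   differences used), `pValue`, and `method` (`"exact"` or
#'   `"normal_approx"`).
#' @examples
#' wilcoxonOneSided(c(1, 2, 3, 4, 5, 6))$pValue  # 1/64
#' @export
wilcoxonOneSided <- function(diffs, exact = NULL) {
  diffs <- as.numeric(diffs)
  if (all(diffs == 0)) {
    warning("all differences are zero; degenerate test, p = 1")
    return(list(statistic = 0, n = 0L, pValue = 1, method = "degenerate"))
  }
  dz <- diffs[diffs != 0]
  n <- length(dz)
  if (n < 5)
    stop("need at least 5 nonzero differences; got ", n)
  r <- rank(abs(dz), ties.method = "average")
  wPlus <- sum(r[dz > 0])
  if (is.null(exact)) exact <- n <= 25
  if (exact) {
    ranks2 <- as.integer(round(2 * r))
    pmf <- signrankNullPmf(ranks2)
    w2 <- as.integer(round(2 * wPlus))
    p <- sum(pmf[(w2 + 1):length(pmf)]) # P(W+ >= observed)
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    tie <- sum(tapply(r, r, length)^3 - tapply(r, r, length))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - tie / 48
    p <- pnorm((wPlus - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
    method <- "normal_approx"
  }
  list(statistic = wPlus, n = n, pValue = min(max(p, 0), 1),
       method = method)
}

#' Paired comparison of two methods over datasets/seeds
#'
#' Pairs evaluation records on `(dataset, seed)` at a given kernel count,
#' computes per-pair AUC differences (`methodA - methodB`), the fraction
#' of pairs where A strictly wins (ties count toward neither method), and
#' the one-sided Wilcoxon signed-rank p-value for the alternative that A's
#' AUC is higher.
#'
#' @param records data.frame with columns `dataset`, `method`,
#'   `activeKernels`, `seed`, `auc` (the [evalRecord()] layout).
#' @param methodA,methodB method labels to compare.
#' @param activeKernels kernel count at which to compare (`NULL` uses all
#'   records).
#' @param exact passed to [wilcoxonOneSided()].
#' @return list with `pairs` (data.frame of paired AUCs and differences),
#'   `meanAucA`, `meanAucB`, `fractionImproved`, `pValue`, `nPairs`.
#' @export
compareMethods <- function(records, methodA, methodB,
                           activeKernels = NULL, exact = NULL) {
  need <- c("dataset", "method", "seed", "auc")
  if (!all(need %in% colnames(records)))
    stop("records needs columns ", paste(need, collapse = ", "))
  if (!is.null(activeKernels))
    records <- records[records$activeKernels == activeKernels, ,
                       drop = FALSE]
  a <- records[records$method == methodA, , drop = FALSE]
  b <- records[records$method == methodB, , drop = FALSE]
  key <- function(df) paste(df$dataset, df$seed, sep = "\r")
  ka <- key(a); kb <- key(b)
  if (anyDuplicated(ka) || anyDuplicated(kb))
    stop("duplicate (dataset, seed) records for one method")
  missing <- union(setdiff(ka, kb), setdiff(kb, ka))
  if (length(missing))
    stop("unpaired (dataset, seed) combinations: ",
         paste(gsub("\r", "/", missing), collapse = ", "))
  b <- b[match(ka, kb), , drop = FALSE]
  diffs <- a$auc - b$auc
  pairs <- data.frame(dataset = a$dataset, seed = a$seed,
                      aucA = a$auc, aucB = b$auc, diff = diffs)
  p <- if (all(diffs == 0)) {
    warning("methods are identical on every pair; p = 1")
    1
  } else wilcoxonOneSided(diffs, exact = exact)$pValue
  list(pairs = pairs,
       meanAucA = mean(a$auc), meanAucB = mean(b$auc),
       fractionImproved = mean(diffs > 0),
       pValue = p, nPairs = nrow(pairs))
}

#' Construct one evaluation record
#'
#' @param dataset dataset identifier.
#' @param method a label naming the training procedure, e.g. `"baseline"`,
#'   `"pruned"`, `"pruned_inter"`, `"lottery"`.
#' @param activeKernels active kernel count of the evaluated model.
#' @param seed training seed.
#' @param auc test AUC in `[0, 1]`.
#' @return one-row data.frame.
#' @export
evalRecord <- function(dataset, method, activeKernels, seed, auc) {
  if (auc < 0 || auc > 1) stop("auc must lie in [0, 1]")
  data.frame(dataset = dataset, method = method,
             activeKernels = as.integer(activeKernels),
             seed = as.integer(seed), auc = auc)
}
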