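# Kernel-to-motif recovery: harvest high-activation subsequences per
# kernel, convert them to count matrices / PWMs, score information
# content, and export MEME-format motifs.

#' Harvest high-activation subsequences for each kernel
#'
#' For every active kernel, collects each length-Lf window whose ReLU
#' activation reaches at least `frac` of a reference maximum — by default
#' the kernel's global maximum activation over all supplied sequences
#' (`scope = "global"`); `scope = "per_sequence"` thresholds against each
#' sequence's own maximum instead. Masked kernels yield empty site lists.
#'
#' @param model a [MotifModel-class] with at least one active kernel.
#' @param x sequences: a `MotifDataset`, `DNAStringSet`, character vector,
#'   or 4 x L x n array. Conventionally the positive test sequences.
#' @param frac activation threshold as a fraction of the reference
#'   maximum, in (0, 1]; default 0.5.
#' @param scope `"global"` or `"per_sequence"` reference maximum.
#' @return named list (one element per kernel slot) of character vectors
#'   of Lf-mers; empty for masked kernels.
#' @export
harvestKernelSites <- function(model, x, frac = 0.5,
                               scope = c("global", "per_sequence")) {
  scope <- match.arg(scope)
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  if (sum(model@mask) == 0) stop("model has no active kernels")
  X <- asEncodedArray(x)
  Lf <- kernelLength(model)
  n <- dim(X)[3]
  # decode once; windows are substrings
  seqStrings <- vapply(seq_len(n),
                       function(i) oneHotDecode(X[, , i, drop = TRUE]),
                       "")
  out <- vector("list", nKernels(model))
  names(out) <- paste0("kernel", seq_len(nKernels(model)))
  for (k in seq_len(nKernels(model))) {
    if (model@mask[k] == 0L) {
      out[[k]] <- character()
      next
    }
    H <- cpp_activation_matrix(X, model@kernels[, , k, drop = TRUE])
    A <- pmax(H, 0)
    thr <- if (scope == "global") {
      rep(frac * max(A), n)
    } else {
      frac * apply(A, 1, max)
    }
    sites <- character()
    for (i in seq_len(n)) {
      hit <- which(A[i, ] >= thr[i] & A[i, ] > 0)
      if (length(hit))
        sites <- c(sites, vapply(hit, function(p)
          substr(seqStrings[i], p, p + Lf - 1), ""))
    }
    out[[k]] <- sites
  }
  out
}

#' Convert harvested sites to a count matrix and PWM
#'
#' Per-position base counts over the sites; the PWM is
#' `(counts + pseudocount) / (nSites + 4 * pseudocount)` per column. An
#' empty site list yields the pseudocount-only (uniform for equal
#' pseudocounts) PWM.
#'
#' @param sites character vector of equal-length subsequences.
#' @param pseudocount per-cell pseudocount (default 0.25).
#' @param width site width, required only when `sites` is empty.
#' @param name motif name.
#' @return list with `counts` (4 x Lf integer matrix), `pwm`, `nSites`,
#'   and `icPerColumn` (bits).
#' @export
sitesToPwm <- function(sites, pseudocount = 0.25, width = NULL,
                       name = "kernel") {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (length(sites) == 0) {
    if (is.null(width)) stop("width is required for an empty site list")
    counts <- matrix(0L, 4, width, dimnames = list(BASES, NULL))
    if (pseudocount == 0)
      stop("empty site list with zero pseudocount leaves the PWM undefined")
  } else {
    w <- unique(nchar(sites))
    if (length(w) != 1) stop("all sites must have equal length")
    ch <- matrix(unlist(strsplit(sites, "", fixed = TRUE)),
                 nrow = w, ncol = length(sites))
    counts <- vapply(seq_len(w), function(i)
      tabulate(match(ch[i, ], BASES), nbins = 4), integer(4))
    dimnames(counts) <- list(BASES, NULL)
  }
  p <- counts + pseudocount
  pw <- pwm(sweep(p, 2, colSums(p), "/"), name = name)
  list(counts = counts, pwm = pw, nSites = length(sites),
       icPerColumn = informationContent(pw))
}

#' Per-column information content of a PWM
#'
#' Under a uniform background: `IC_i = 2 + sum_j p_ji * log2(p_ji)` bits,
#' with `0 * log 0 = 0`. Ranges from 0 (uniform column) to 2
#' (deterministic column).
#'
#' @param pwm a PWM.
#' @return numeric vector of length `ncol(pwm)`, in bits.
#' @examples
#' informationContent(pwm(matrix(c(1, 0, 0, 0), 4, 1)))  # 2 bits
#' @export
informationContent <- function(pwm) {
  stopifnot(isValidPwm(pwm))
  apply(pwm, 2, function(p) {
    nz <- p > 0
    2 + sum(p[nz] * log2(p[nz]))
  })
}

#' Recover motifs from a trained model
#'
#' Runs [harvestKernelSites()] and [sitesToPwm()] for every active kernel
#' and orders the results by total information content (descending).
#'
#' @inheritParams harvestKernelSites
#' @param pseudocount passed to [sitesToPwm()].
#' @return list of kernel motifs (as from [sitesToPwm()], plus
#'   `kernelIndex`), ordered by decreasing total IC.
#' @export
kernelMotifs <- function(model, x, frac = 0.5, pseudocount = 0.25,
                         scope = c("global", "per_sequence")) {
  scope <- match.arg(scope)
  sites <- harvestKernelSites(model, x, frac = frac, scope = scope)
  act <- activeKernels(model)
  motifs <- lapply(act, function(k) {
    km <- sitesToPwm(sites[[k]], pseudocount = pseudocount,
                     width = kernelLength(model),
                     name = paste0("kernel", k))
    km$kernelIndex <- k
    km
  })
  motifs[order(-vapply(motifs, function(m) sum(m$icPerColumn), 0))]
}

#' Export kernel motifs to MEME minimal format
#'
#' One MOTIF block per supplied kernel motif, carrying its PWM and site
#' count; the output round-trips through [readMemeMotifs()] and is
#' consumable by Tomtom-style comparison tools.
#'
#' @param motifs list from [kernelMotifs()] (or of bare PWMs).
#' @param path output path; `NULL` returns the text.
#' @param background length-4 background frequencies.
#' @return the path (or text), invisibly.
#' @export
exportMeme <- function(motifs, path = NULL, background = rep(0.25, 4)) {
  if (length(motifs) == 0) stop("no motifs to export")
  pwms <- lapply(motifs, function(m) if (is.matrix(m)) m else m$pwm)
  nsites <- vapply(motifs, function(m)
    if (is.matrix(m)) 20L else as.integer(max(m$nSites, 1L)), 1L)
  writeMemeMotifs(pwms, path, background = background, nsites = nsites)
}

#' Best ungapped alignment similarity between two PWMs
#'
#' Slides the shorter PWM along the longer one (forward strand only) and
#' returns the maximum Pearson correlation of the flattened overlapping
#' columns. A zero-variance overlap (e.g. against a uniform PWM) scores 0.
#'
#' @param recovered,truth PWMs.
#' @param details return the best offset as well.
#' @return the similarity in `[-1, 1]`; with `details = TRUE`, a list
#'   with `similarity`, `offset` (0-based offset of the shorter PWM
#'   within the longer), and `shorterIsRecovered`.
#' @export
bestMatchSimilarity <- function(recovered, truth, details = FALSE) {
  stopifnot(isValidPwm(recovered), isValidPwm(truth))
  if (ncol(recovered) <= ncol(truth)) {
    short <- recovered; long <- truth; shortIsRec <- TRUE
  } else {
    short <- truth; long <- recovered; shortIsRec <- FALSE
  }
  wS <- ncol(short); wL <- ncol(long)
  best <- -Inf; bestOff <- 0L
  for (off in 0:(wL - wS)) {
    a <- as.numeric(short)
    b <- as.numeric(long[, (off + 1):(off + wS), drop = FALSE])
    r <- if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
    if (r > best) { best <- r; bestOff <- off }
  }
  if (!details) return(best)
  list(similarity = best, offset = bestOff,
       shorterIsRecovered = shortIsRec)
}

#' Per-kernel information content table
#'
#' @param motifs list from [kernelMotifs()].
#' @param path optional TSV output path.
#' @return data.frame with `kernel`, `nSites`, `totalIC`, `meanIC`,
#'   `maxIC`.
#' @export
icTable <- function(motifs, path = NULL) {
  df <- do.call(rbind, lapply(motifs, function(m)
    data.frame(kernel = m$kernelIndex, nSites = m$nSites,
               totalIC = sum(m$icPerColumn),
               meanIC = mean(m$icPerColumn),
               maxIC = max(m$icPerColumn))))
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
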