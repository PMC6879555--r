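# Model construction, forward computation, compaction, serialization.

#' Initialize a MotifModel
#'
#' Kernels and dense weights are drawn Glorot-uniform (kernels from
#' `U(-l, l)` with `l = sqrt(6 / (4*Lf + Lf))`, dense weights with
#' `l = sqrt(6 / (d + 1))`), the bias starts at 0, and the mask is all
#' ones. A frozen copy of the initial parameters is stored for
#' lottery-ticket rewinding.
#'
#' @param dTotal total number of kernels (for an iteratively pruned model,
#'   `2^k * d`).
#' @param kernelLen kernel length Lf in bp (24 for the simulated
#'   benchmarks, 15 for 101-bp ChIP-seq data).
#' @param seed integer seed controlling the draw.
#' @return a [MotifModel-class].
#' @examples
#' m <- newMotifModel(8, 24, seed = 1)
#' sum(kernelMask(m))
#' @export
newMotifModel <- function(dTotal, kernelLen, seed = 1L) {
  stopifnot(dTotal >= 1, kernelLen >= 1)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  limK <- sqrt(6 / (4 * kernelLen + kernelLen))
  kern <- array(runif(4 * kernelLen * dTotal, -limK, limK),
                dim = c(4, kernelLen, dTotal))
  limW <- sqrt(6 / (dTotal + 1))
  w <- runif(dTotal, -limW, limW)
  snap <- list(kernels = kern, denseWeights = w, bias = 0)
  new("MotifModel", kernels = kern, mask = rep(1L, dTotal),
      denseWeights = w, bias = 0, initSnapshot = snap,
      metadata = list(seed = as.integer(seed)))
}

#' Valid-mode cross-correlation of a sequence with one kernel
#'
#' Position `p` (1-based) scores the window `[p, p + Lf)`:
#' `h_p = sum_{i,j} S[j, i+p-1] * K[j, i]`.
#'
#' @param enc 4 x L one-hot matrix (from [oneHotEncode()]), or a sequence
#'   coercible to one.
#' @param kernel 4 x Lf numeric matrix.
#' @return numeric vector of length `L - Lf + 1`.
#' @export
convolveScan <- function(enc, kernel) {
  if (is.character(enc) || methods::is(enc, "XString")) {
    enc <- oneHotEncode(enc)
  }
  if (ncol(enc) < ncol(kernel))
    stop("sequence length ", ncol(enc), " is shorter than kernel length ",
         ncol(kernel))
  as.numeric(cpp_conv_scan(enc, kernel))
}

#' Forward pass over one sequence, with the full activation profile
#'
#' Computes `h` (pre-activation scores), `a = max(0, h)`,
#' `z_k = max_p a[p,k]` (global max pooling), `u_k = z_k * m_k` (mask
#' layer), and `prob = sigmoid(b + sum_k w_k u_k)`.
#'
#' @param model a [MotifModel-class].
#' @param enc a 4 x L one-hot matrix or a single sequence.
#' @return list with `prob`, `h` ((L-Lf+1) x d), `a`, `z`, `u`.
#' @export
forwardPass <- function(model, enc) {
  if (is.character(enc) || methods::is(enc, "XString")) {
    enc <- oneHotEncode(enc)
  }
  d <- nKernels(model)
  h <- vapply(seq_len(d),
              function(k) as.numeric(
                cpp_conv_scan(enc, model@kernels[, , k, drop = TRUE])),
              numeric(ncol(enc) - kernelLength(model) + 1))
  h <- matrix(h, ncol = d)
  a <- pmax(h, 0)
  z <- apply(a, 2, max)
  u <- z * model@mask
  s <- model@bias + sum(model@denseWeights * u)
  list(prob = 1 / (1 + exp(-s)), h = h, a = a, z = z, u = u)
}

#' Predicted positive-class probabilities for a batch of sequences
#'
#' @param model a [MotifModel-class].
#' @param x a `MotifDataset`, `DNAStringSet`, character vector, or a
#'   pre-encoded 4 x L x n array.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predictProb <- function(model, x) {
  X <- asEncodedArray(x)
  as.numeric(cpp_forward_batch(X, model@kernels,
                               as.numeric(model@mask),
                               model@denseWeights, model@bias))
}

# Coerce the accepted sequence containers to a 4 x L x n array.
asEncodedArray <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  if (methods::is(x, "MotifDataset")) x <- sequences(x)
  encodeSequences(x)
}

#' Pooled masked scores u for a batch of sequences
#'
#' Row i, column k holds `u_k = z_k * m_k` for sequence i: the masked
#' global-max-pooled ReLU activation of kernel k.
#'
#' @inheritParams predictProb
#' @return numeric n x d matrix.
#' @export
pooledScores <- function(model, x) {
  X <- asEncodedArray(x)
  z <- cpp_pool_batch(X, model@kernels)$z
  sweep(z, 2, as.numeric(model@mask), "*")
}

#' Drop masked kernels from a model
#'
#' Returns an equivalent model containing only the active kernels (mask
#' all ones, same bias); predictions are identical on every input because
#' masked kernels contribute nothing.
#'
#' @param model a [MotifModel-class] with at least one active kernel.
#' @return a [MotifModel-class] with `sum(mask)` kernels.
#' @export
compactModel <- function(model) {
  keep <- activeKernels(model)
  if (length(keep) == 0) stop("cannot compact a fully masked model")
  if (length(keep) == nKernels(model)) return(model)
  snap <- model@initSnapshot
  snap$kernels <- snap$kernels[, , keep, drop = FALSE]
  snap$denseWeights <- snap$denseWeights[keep]
  new("MotifModel",
      kernels = model@kernels[, , keep, drop = FALSE],
      mask = rep(1L, length(keep)),
      denseWeights = model@denseWeights[keep],
      bias = model@bias,
      initSnapshot = snap,
      metadata = c(model@metadata, list(compactedFrom = nKernels(model))))
}

# ---- checkpoint serialization -------------------------------------------
# Text-only single-file format: a JSON document whose numeric arrays are
# base64-encoded IEEE-754 little-endian doubles, giving bit-exact round
# trips through a plain-text file.

encodeDoubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                endian = "little"))
}

decodeDoubles <- function(s) {
  raw <- jsonlite::base64_dec(s)
  readBin(raw, "double", n = length(raw) %/% 8L, size = 8,
          endian = "little")
}

#' Save a model checkpoint
#'
#' Writes a single JSON file holding kernels, mask, dense weights, bias,
#' the initialization snapshot, and metadata. Doubles are stored as
#' base64-encoded IEEE-754 bytes, so [readModel()] restores them
#' bit-exactly.
#'
#' @param model a [MotifModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
saveModel <- function(model, path) {
  doc <- list(
    format = "MotifPruner-checkpoint",
    version = 1L,
    dims = dim(model@kernels),
    kernels = encodeDoubles(model@kernels),
    mask = as.integer(model@mask),
    denseWeights = encodeDoubles(model@denseWeights),
    bias = encodeDoubles(model@bias),
    initSnapshot = list(
      kernels = encodeDoubles(model@initSnapshot$kernels),
      denseWeights = encodeDoubles(model@initSnapshot$denseWeights),
      bias = encodeDoubles(model@initSnapshot$bias)
    ),
    metadata = model@metadata
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model checkpoint written by [saveModel()]
#'
#' @param path checkpoint path.
#' @return a [MotifModel-class], bit-identical to the saved one.
#' @export
readModel <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "MotifPruner-checkpoint"))
    stop("not a MotifPruner checkpoint: ", path)
  dims <- as.integer(doc$dims)
  kern <- array(decodeDoubles(doc$kernels), dim = dims)
  snap <- list(
    kernels = array(decodeDoubles(doc$initSnapshot$kernels), dim = dims),
    denseWeights = decodeDoubles(doc$initSnapshot$denseWeights),
    bias = decodeDoubles(doc$initSnapshot$bias)
  )
  meta <- doc$metadata
  if (is.null(meta)) meta <- list()
  new("MotifModel", kernels = kern, mask = as.integer(doc$mask),
      denseWeights = decodeDoubles(doc$denseWeights),
      bias = decodeDoubles(doc$bias),
      initSnapshot = snap, metadata = as.list(meta))
}
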