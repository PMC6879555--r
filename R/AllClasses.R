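#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' MotifModel: a single-convolutional-layer network with a kernel mask
#'
#' The model scans a one-hot encoded sequence with \code{d} convolutional
#' kernels (4 x Lf matrices), applies ReLU and global max pooling, multiplies
#' the pooled scores by a binary mask, and feeds them into a dense sigmoid
#' head. Masked kernels contribute nothing to the prediction and are frozen
#' during training. A snapshot of the parameters at initialization is kept so
#' that pruned subnetworks can be rewound and retrained from their original
#' draw (lottery-ticket retraining).
#'
#' @slot kernels numeric array of dimension \code{c(4, Lf, d)}; row order
#'   A, C, G, T.
#' @slot mask integer vector of length \code{d} with entries 0/1.
#' @slot denseWeights numeric vector of length \code{d}; entries for masked
#'   kernels are reported as exactly 0.
#' @slot bias numeric scalar.
#' @slot initSnapshot list with elements \code{kernels}, \code{denseWeights},
#'   \code{bias}: the parameters as drawn at initialization.
#' @slot metadata list of free-form provenance (seed, training history).
#'
#' @seealso [newMotifModel()], [forwardPass()], [compactModel()]
#' @export
setClass("MotifModel",
  representation(
    kernels = "array",
    mask = "integer",
    denseWeights = "numeric",
    bias = "numeric",
    initSnapshot = "list",
    metadata = "list"
  )
)

setValidity("MotifModel", function(object) {
  msg <- character()
  dm <- dim(object@kernels)
  if (length(dm) != 3 || dm[1] != 4)
    msg <- c(msg, "kernels must be a 4 x Lf x d array")
  d <- dm[3]
  if (length(object@mask) != d)
    msg <- c(msg, "mask length must equal the number of kernels")
  if (!all(object@mask %in% c(0L, 1L)))
    msg <- c(msg, "mask entries must be 0 or 1")
  if (length(object@denseWeights) != d)
    msg <- c(msg, "denseWeights length must equal the number of kernels")
  if (length(object@bias) != 1)
    msg <- c(msg, "bias must be a scalar")
  if (length(msg)) msg else TRUE
})

#' @describeIn MotifModel number of kernel slots (active + masked)
#' @param object,x a \code{MotifModel}
#' @export
setGeneric("nKernels", function(x) standardGeneric("nKernels"))

#' @export
setMethod("nKernels", "MotifModel", function(x) dim(x@kernels)[3])

#' @describeIn MotifModel kernel length Lf in bp
#' @export
setGeneric("kernelLength", function(x) standardGeneric("kernelLength"))

#' @export
setMethod("kernelLength", "MotifModel", function(x) dim(x@kernels)[2])

#' @describeIn MotifModel the 4 x Lf x d kernel array
#' @export
setGeneric("kernels", function(x) standardGeneric("kernels"))

#' @export
setMethod("kernels", "MotifModel", function(x) x@kernels)

#' @describeIn MotifModel the binary mask vector
#' @export
setGeneric("kernelMask", function(x) standardGeneric("kernelMask"))

#' @export
setMethod("kernelMask", "MotifModel", function(x) x@mask)

#' @describeIn MotifModel dense-layer weights (0 for masked kernels)
#' @export
setGeneric("denseWeights", function(x) standardGeneric("denseWeights"))

#' @export
setMethod("denseWeights", "MotifModel", function(x) x@denseWeights)

#' @describeIn MotifModel dense-layer bias
#' @export
setGeneric("modelBias", function(x) standardGeneric("modelBias"))

#' @export
setMethod("modelBias", "MotifModel", function(x) x@bias)

#' @describeIn MotifModel indices of unmasked kernels
#' @export
setGeneric("activeKernels", function(x) standardGeneric("activeKernels"))

#' @export
setMethod("activeKernels", "MotifModel", function(x) which(x@mask == 1L))

setMethod("show", "MotifModel", function(object) {
  cat("MotifModel:", nKernels(object), "kernel slots (",
      sum(object@mask), "active ), kernel length",
      kernelLength(object), "bp\n")
  if (!is.null(object@metadata$seed))
    cat("  seed:", object@metadata$seed, "\n")
  cat("  bias:", format(object@bias, digits = 4), "\n")
})

#' MotifDataset: labeled sequences with insertion provenance
#'
#' A container pairing a \code{DNAStringSet} with binary labels and, for
#' positive (label 1) sequences, a record of which motif was inserted and at
#' which 0-based offset.
#'
#' @slot sequences a \code{\link[Biostrings]{DNAStringSet}}.
#' @slot labels integer vector of 0/1, one per sequence.
#' @slot provenance data.frame with columns \code{index}, \code{motif},
#'   \code{offset} (0-based), one row per positive sequence; zero rows for a
#'   purely negative set.
#'
#' @export
setClass("MotifDataset",
  representation(
    sequences = "DNAStringSet",
    labels = "integer",
    provenance = "data.frame"
  )
)

setValidity("MotifDataset", function(object) {
  msg <- character()
  if (length(object@sequences) != length(object@labels))
    msg <- c(msg, "sequences and labels must have equal length")
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 or 1")
  if (nrow(object@provenance) > 0) {
    if (!all(c("index", "motif", "offset") %in% colnames(object@provenance)))
      msg <- c(msg, "provenance needs columns index, motif, offset")
    else if (!all(object@labels[object@provenance$index] == 1L))
      msg <- c(msg, "provenance rows must point at positive sequences")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MotifDataset the sequences
#' @param x a \code{MotifDataset}
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @export
setMethod("sequences", "MotifDataset", function(x) x@sequences)

#' @describeIn MotifDataset the 0/1 label vector
#' @export
setGeneric("labels01", function(x) standardGeneric("labels01"))

#' @export
setMethod("labels01", "MotifDataset", function(x) x@labels)

#' @describeIn MotifDataset insertion provenance for positives
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @export
setMethod("provenance", "MotifDataset", function(x) x@provenance)

setMethod("show", "MotifDataset", function(object) {
  cat("MotifDataset:", length(object@sequences), "sequences (",
      sum(object@labels), "positive ), width",
      unique(Biostrings::width(object@sequences))[1], "bp\n")
})

#' @describeIn MotifDataset number of sequences
#' @export
setMethod("length", "MotifDataset", function(x) length(x@sequences))

#' PruneSchedule: the iterative halving plan
#'
#' Describes how an over-parameterized model with \code{2^k * d} kernels is
#' reduced to \code{d} kernels: \code{k} halvings, a mask-update criterion,
#' the factor by which the learning rate is divided at each pruning step,
#' and the fine-tuning mode.
#'
#' @slot k integer, number of halvings (>= 1).
#' @slot d integer, final kernel count (>= 1).
#' @slot criterion one of \code{"weight"}, \code{"score"},
#'   \code{"score_weight"}.
#' @slot lrDecayFactor numeric > 1; the learning rate after the t-th prune is
#'   \code{lr0 / lrDecayFactor^t} (default 1.2).
#' @slot mode one of \code{"finetune"} (prune then fine-tune each stage),
#'   \code{"inter"} (skip the final fine-tune: the last model is evaluated
#'   immediately after the last mask update), \code{"lottery"} (each
#'   fine-tune rewinds surviving parameters to their initialization and
#'   retrains).
#'
#' @export
setClass("PruneSchedule",
  representation(
    k = "integer",
    d = "integer",
    criterion = "character",
    lrDecayFactor = "numeric",
    mode = "character"
  )
)

setValidity("PruneSchedule", function(object) {
  msg <- character()
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (object@d < 1L) msg <- c(msg, "d must be >= 1")
  if (!object@criterion %in% c("weight", "score", "score_weight"))
    msg <- c(msg, "criterion must be weight, score or score_weight")
  if (object@lrDecayFactor <= 1)
    msg <- c(msg, "lrDecayFactor must be > 1")
  if (!object@mode %in% c("finetune", "inter", "lottery"))
    msg <- c(msg, "mode must be finetune, inter or lottery")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PruneSchedule", function(object) {
  cat("PruneSchedule:", 2L^object@k * object@d, "->", object@d,
      "kernels in", object@k, "halvings; criterion:", object@criterion,
      "; mode:", object@mode, "\n")
})

#' Construct a PruneSchedule
#'
#' @param k number of halvings; the starting model must have `2^k * d`
#'   kernels.
#' @param d final kernel count.
#' @param criterion mask-update criterion: `"weight"` ranks kernels by
#'   `|w_k|`; `"score"` by `|AVG_P u_k - AVG_N u_k|` (class-mean pooled
#'   scores); `"score_weight"` by `|AVG_P u_k w_k - AVG_N u_k w_k|`.
#' @param lrDecayFactor learning-rate division factor per pruning step.
#' @param mode `"finetune"`, `"inter"` or `"lottery"` (see
#'   [PruneSchedule-class]).
#' @return a [PruneSchedule-class] object.
#' @examples
#' pruneSchedule(k = 6, d = 4)
#' @export
pruneSchedule <- function(k, d, criterion = "weight",
                          lrDecayFactor = 1.2, mode = "finetune") {
  new("PruneSchedule", k = as.integer(k), d = as.integer(d),
      criterion = criterion, lrDecayFactor = lrDecayFactor, mode = mode)
}

#' Construct a MotifDataset
#'
#' @param sequences a `DNAStringSet` or character vector.
#' @param labels 0/1 vector, one per sequence.
#' @param provenance optional data.frame (`index`, `motif`, `offset`)
#'   describing motif insertions in the positive sequences.
#' @return a [MotifDataset-class] object.
#' @export
motifDataset <- function(sequences, labels,
                         provenance = data.frame(index = integer(),
                                                 motif = character(),
                                                 offset = integer())) {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  new("MotifDataset", sequences = sequences, labels = as.integer(labels),
      provenance = provenance)
}
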