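# Benchmark simulator: i.i.d. background sequences with one PWM-sampled
# motif instance overwritten into each positive at a uniform offset.

#' Describe a simulated dataset
#'
#' A recipe fixes everything needed to regenerate a benchmark dataset
#' bit-identically: the candidate motifs (one is chosen uniformly per
#' positive sequence), sequence length, split sizes, background base
#' probabilities, and the seed.
#'
#' @param motifs list of PWMs; each positive sequence carries exactly one
#'   instance sampled from one of them (uniform choice).
#' @param seqLen sequence length in bp (default 101).
#' @param nTrain,nTest total training/test sequences; each split is half
#'   positive, half negative, so the counts must be even.
#' @param nVal validation sequences (default 10\% of `nTrain`, rounded to
#'   the nearest even count), used for early stopping.
#' @param background length-4 probability vector for A, C, G, T (default
#'   uniform 0.25).
#' @param seed integer seed; all randomness in [makeDataset()] flows from
#'   it.
#' @return a list of class `"DatasetRecipe"`.
#' @examples
#' r <- datasetRecipe(toyMotifs()[1:2], nTrain = 200, nTest = 200, seed = 7)
#' @export
datasetRecipe <- function(motifs, seqLen = 101L, nTrain = 10000L,
                          nTest = 10000L, nVal = NULL,
                          background = rep(0.25, 4), seed = 1L) {
  if (is.matrix(motifs)) motifs <- list(motifs)
  stopifnot(length(motifs) >= 1)
  for (m in motifs) {
    if (!isValidPwm(m)) stop("invalid PWM in recipe")
    if (ncol(m) > seqLen)
      stop("motif ", pwmName(m), " is wider (", ncol(m),
           ") than seqLen (", seqLen, ")")
  }
  if (abs(sum(background) - 1) > 1e-9)
    stop("background probabilities must sum to 1")
  if (is.null(nVal)) nVal <- max(2L, 2L * ceiling(0.1 * nTrain / 2))
  counts <- c(nTrain = nTrain, nVal = nVal, nTest = nTest)
  if (any(counts < 2)) stop("split sizes must be >= 2")
  odd <- counts[counts %% 2 != 0]
  if (length(odd))
    stop("split sizes must be even for balanced labels; got ",
         paste(names(odd), odd, sep = "=", collapse = ", "))
  structure(list(motifs = motifs, seqLen = as.integer(seqLen),
                 nTrain = as.integer(nTrain), nVal = as.integer(nVal),
                 nTest = as.integer(nTest), background = background,
                 seed = as.integer(seed)),
            class = "DatasetRecipe")
}

#' Sample i.i.d. background sequences
#'
#' @param n number of sequences.
#' @param L length in bp.
#' @param probs length-4 base probability vector (A, C, G, T).
#' @return character vector of `n` sequences. Uses the current RNG state;
#'   call `set.seed()` for reproducibility.
#' @export
sampleBackground <- function(n, L, probs = rep(0.25, 4)) {
  stopifnot(n >= 1, L >= 1, length(probs) == 4)
  if (abs(sum(probs) - 1) > 1e-9) stop("probs must sum to 1")
  m <- matrix(sample(BASES, n * L, replace = TRUE, prob = probs),
              nrow = L, ncol = n)
  apply(m, 2, paste, collapse = "")
}

#' Sample one motif instance from a PWM
#'
#' Each position is drawn independently from the corresponding PWM column.
#'
#' @param pwm a PWM.
#' @return a string of length `ncol(pwm)`.
#' @export
sampleMotifInstance <- function(pwm) {
  stopifnot(isValidPwm(pwm))
  paste(vapply(seq_len(ncol(pwm)),
               function(i) sample(BASES, 1, prob = pwm[, i]), ""),
        collapse = "")
}

#' Generate one positive sequence under a recipe
#'
#' A background sequence of length `seqLen` with the window
#' `[offset, offset + W)` overwritten by an instance sampled from a
#' uniformly chosen recipe motif; the offset is uniform over
#' `{0, ..., seqLen - W}` so the instance is always fully contained.
#'
#' @param recipe a [datasetRecipe()].
#' @return list with `seq` (character), `motif` (name), `offset` (0-based).
#' @export
makePositive <- function(recipe) {
  stopifnot(inherits(recipe, "DatasetRecipe"))
  mIdx <- sample.int(length(recipe$motifs), 1)
  m <- recipe$motifs[[mIdx]]
  W <- ncol(m)
  inst <- sampleMotifInstance(m)
  bg <- sampleBackground(1, recipe$seqLen, recipe$background)
  offset <- sample.int(recipe$seqLen - W + 1L, 1) - 1L
  seq <- paste0(substr(bg, 1, offset), inst,
                substr(bg, offset + W + 1L, recipe$seqLen))
  list(seq = seq, motif = pwmName(m), offset = offset)
}

# One balanced split of n sequences (n/2 positives then n/2 negatives).
makeSplit <- function(recipe, n, prefix) {
  npos <- n %/% 2L
  pos <- lapply(seq_len(npos), function(i) makePositive(recipe))
  neg <- sampleBackground(n - npos, recipe$seqLen, recipe$background)
  seqs <- Biostrings::DNAStringSet(c(vapply(pos, `[[`, "", "seq"), neg))
  names(seqs) <- paste0(prefix, "_", c(rep("pos", npos),
                                       rep("neg", n - npos)),
                        "_", c(seq_len(npos), seq_len(n - npos)))
  motifDataset(
    seqs,
    labels = c(rep(1L, npos), rep(0L, n - npos)),
    provenance = data.frame(
      index = seq_len(npos),
      motif = vapply(pos, `[[`, "", "motif"),
      offset = vapply(pos, `[[`, 0L, "offset")
    )
  )
}

#' Generate train/validation/test splits from a recipe
#'
#' Splits are generated independently (disjoint by construction), each
#' balanced half positive / half negative, fully reproducible from
#' `recipe$seed`.
#'
#' @param recipe a [datasetRecipe()].
#' @return list with elements `train`, `val`, `test`
#'   ([MotifDataset-class] objects) and `recipe`.
#' @export
makeDataset <- function(recipe) {
  stopifnot(inherits(recipe, "DatasetRecipe"))
  withr_seed <- recipe$seed
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(withr_seed)
  list(train = makeSplit(recipe, recipe$nTrain, "train"),
       val = makeSplit(recipe, recipe$nVal, "val"),
       test = makeSplit(recipe, recipe$nTest, "test"),
       recipe = recipe)
}

# Column probabilities for a consensus string; `dominant` is recycled over
# positions, remaining mass split evenly over the other three bases.
consensusPwm <- function(consensus, dominant = 0.85, name = consensus) {
  ch <- strsplit(consensus, "", fixed = TRUE)[[1]]
  stopifnot(all(ch %in% BASES))
  dom <- rep_len(dominant, length(ch))
  m <- matrix((1 - rep(dom, each = 4)) / 3, nrow = 4,
              dimnames = list(BASES, NULL))
  for (i in seq_along(ch)) m[ch[i], i] <- dom[i]
  pwm(m, name = name)
}

#' Bundled toy motifs
#'
#' Eight synthetic PWMs (widths 6-12, varying information content) built
#' from transcription-factor-like consensus patterns. They are stand-ins
#' constructed in code — not matrices from any motif database — and exist
#' so every simulated benchmark recipe can be instantiated without
#' downloads; any PWM file read with [readMotifs()] can be substituted.
#'
#' @return list of 8 PWMs.
#' @examples
#' length(toyMotifs())
#' @export
toyMotifs <- function() {
  list(
    consensusPwm("CACGTG", dominant = 0.92, name = "toy01_ebox"),
    consensusPwm("TGACTCAT", dominant = c(0.9, 0.9, 0.9, 0.9,
                                          0.8, 0.9, 0.85, 0.7),
                 name = "toy02_ap1"),
    consensusPwm("AGATAAGA", dominant = c(0.7, 0.9, 0.95, 0.9,
                                          0.9, 0.95, 0.8, 0.6),
                 name = "toy03_gata"),
    consensusPwm("GGGACTTTCC", dominant = 0.82, name = "toy04_rel"),
    consensusPwm("ATTGGCTAGC", dominant = c(0.85, 0.85, 0.9, 0.95, 0.95,
                                            0.8, 0.6, 0.8, 0.85, 0.7),
                 name = "toy05_ccaat"),
    consensusPwm("TAATTAG", dominant = c(0.95, 0.95, 0.9, 0.9,
                                         0.9, 0.85, 0.55),
                 name = "toy06_hbox"),
    consensusPwm("CCGCGCAGAA", dominant = c(0.75, 0.8, 0.85, 0.85, 0.9,
                                            0.85, 0.8, 0.75, 0.7, 0.65),
                 name = "toy07_gc"),
    consensusPwm("ACGTCATCGATG", dominant = c(0.6, 0.7, 0.8, 0.85, 0.9,
                                              0.9, 0.85, 0.85, 0.8, 0.75,
                                              0.65, 0.55),
                 name = "toy08_long")
  )
}

#' The five standard simulated-benchmark recipes
#'
#' Recipes 1-3 each use a distinct pair of bundled motifs, recipe 4 uses
#' four, and recipe 5 uses eight, mirroring the benchmark layout of two-,
#' four- and eight-motif mixtures.
#'
#' @param which recipe number 1-5.
#' @param motifs motif pool (default [toyMotifs()]); needs >= 8 entries.
#' @param ... overrides passed to [datasetRecipe()] (`nTrain`, `seed`, ...).
#' @return a [datasetRecipe()].
#' @export
presetRecipe <- function(which, motifs = toyMotifs(), ...) {
  stopifnot(which %in% 1:5, length(motifs) >= 8)
  pick <- switch(which,
                 `1` = motifs[1:2], `2` = motifs[3:4], `3` = motifs[5:6],
                 `4` = motifs[1:4], `5` = motifs[1:8])
  datasetRecipe(pick, ...)
}

#' Write a simulated dataset to FASTA files plus a JSON sidecar
#'
#' Each split becomes `<prefix>_<split>_pos.fa` / `_neg.fa`; the sidecar
#' `<prefix>_manifest.json` records the recipe (motif matrices included),
#' seed, and per-positive provenance.
#'
#' @param ds result of [makeDataset()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"sim"`).
#' @return the manifest path, invisibly.
#' @export
writeDataset <- function(ds, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    recipe = list(
      seqLen = ds$recipe$seqLen, nTrain = ds$recipe$nTrain,
      nVal = ds$recipe$nVal, nTest = ds$recipe$nTest,
      background = ds$recipe$background, seed = ds$recipe$seed,
      motifs = lapply(ds$recipe$motifs, function(m)
        list(name = pwmName(m), probs = unclass(m)))
    ),
    files = list(), provenance = list()
  )
  for (split in c("train", "val", "test")) {
    d <- ds[[split]]
    lab <- labels01(d)
    posPath <- file.path(dir, sprintf("%s_%s_pos.fa", prefix, split))
    negPath <- file.path(dir, sprintf("%s_%s_neg.fa", prefix, split))
    writeFastaSequences(sequences(d)[lab == 1L], posPath)
    writeFastaSequences(sequences(d)[lab == 0L], negPath)
    manifest$files[[split]] <- list(pos = basename(posPath),
                                    neg = basename(negPath))
    manifest$provenance[[split]] <- provenance(d)
  }
  mPath <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(manifest, mPath, auto_unbox = TRUE, digits = NA)
  invisible(mPath)
}

#' Read a dataset written by [writeDataset()]
#'
#' @param dir directory holding the FASTA files and manifest.
#' @param prefix the prefix used when writing.
#' @return list with `train`, `val`, `test` [MotifDataset-class] objects
#'   and the recipe fields from the manifest.
#' @export
readDataset <- function(dir, prefix = "sim") {
  mPath <- file.path(dir, paste0(prefix, "_manifest.json"))
  if (!file.exists(mPath)) stop("manifest not found: ", mPath)
  manifest <- jsonlite::read_json(mPath, simplifyVector = TRUE)
  out <- list()
  for (split in c("train", "val", "test")) {
    pos <- readFastaSequences(file.path(dir, manifest$files[[split]]$pos))
    neg <- readFastaSequences(file.path(dir, manifest$files[[split]]$neg))
    prov <- manifest$provenance[[split]]
    prov <- data.frame(index = as.integer(prov$index),
                       motif = as.character(prov$motif),
                       offset = as.integer(prov$offset))
    out[[split]] <- motifDataset(
      c(pos, neg), c(rep(1L, length(pos)), rep(0L, length(neg))), prov)
  }
  out$recipe <- manifest$recipe
  out
}
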