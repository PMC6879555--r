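# PWM containers and motif file formats (MEME minimal, JASPAR matrices).
#
# A PWM is represented as a plain 4 x W column-stochastic numeric matrix
# with rownames A, C, G, T and a "name" attribute; lists of such matrices
# are the currency between the simulator and the visualizer.

#' Construct and validate a PWM
#'
#' @param probs 4 x W matrix of column probabilities (row order A,C,G,T).
#' @param name motif name.
#' @return the validated PWM matrix (rownames set, `name` attribute).
#' @export
pwm <- function(probs, name = "motif") {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stop("a PWM must have 4 rows (A,C,G,T)")
  if (any(probs < 0)) stop("PWM entries must be >= 0")
  cs <- colSums(probs)
  if (any(abs(cs - 1) > 1e-9))
    stop("PWM columns must each sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  rownames(probs) <- BASES
  attr(probs, "name") <- name
  probs
}

#' Test PWM validity
#' @param x object to check.
#' @return `TRUE` if `x` is a 4-row nonnegative column-stochastic matrix.
#' @export
isValidPwm <- function(x) {
  is.matrix(x) && nrow(x) == 4 && all(x >= 0) &&
    all(abs(colSums(x) - 1) <= 1e-9)
}

#' Name of a PWM
#' @param x a PWM.
#' @export
pwmName <- function(x) {
  nm <- attr(x, "name")
  if (is.null(nm)) "motif" else nm
}

#' Convert a count matrix to a PWM with pseudocounts
#'
#' @param counts 4 x W nonnegative matrix of base counts.
#' @param pseudocount added to every cell before normalization
#'   (default 0.5).
#' @param name motif name.
#' @export
countsToPwm <- function(counts, pseudocount = 0.5, name = "motif") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("count matrix must have 4 rows")
  if (any(counts < 0)) stop("counts must be >= 0")
  p <- counts + pseudocount
  pwm(sweep(p, 2, colSums(p), "/"), name = name)
}

#' Read motifs from a MEME minimal motif file
#'
#' Parses the `MEME version` / `ALPHABET` / `MOTIF` + `letter-probability
#' matrix` layout. Only the DNA alphabet is supported.
#'
#' @param path path to a MEME minimal format file.
#' @return a list of PWMs.
#' @export
readMemeMotifs <- function(path) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^MEME version", lines)))
    stop("not a MEME minimal file (missing 'MEME version' line): ", path)
  motifIdx <- grep("^MOTIF\\b", lines)
  if (length(motifIdx) == 0) stop("no MOTIF blocks in ", path)
  out <- list()
  for (mi in motifIdx) {
    header <- strsplit(trimws(lines[mi]), "\\s+")[[1]]
    name <- if (length(header) >= 2) header[2] else "motif"
    li <- mi + 1
    while (li <= length(lines) &&
           !grepl("^letter-probability matrix", lines[li])) li <- li + 1
    if (li > length(lines))
      stop("MOTIF ", name, " lacks a letter-probability matrix (line ", mi,
           ")")
    w <- suppressWarnings(
      as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[li])))
    rows <- list()
    li <- li + 1
    while (li <= length(lines) && length(rows) < ifelse(is.na(w), 1e9, w)) {
      tl <- trimws(lines[li])
      if (tl == "" || grepl("^(MOTIF|URL)", lines[li])) break
      vals <- suppressWarnings(as.numeric(strsplit(tl, "\\s+")[[1]]))
      if (any(is.na(vals)) || length(vals) != 4) break
      rows[[length(rows) + 1]] <- vals
      li <- li + 1
    }
    if (length(rows) == 0)
      stop("MOTIF ", name, ": empty probability matrix (line ", mi, ")")
    m <- t(do.call(rbind, rows)) # MEME rows are positions; transpose to 4 x W
    m <- sweep(m, 2, colSums(m), "/") # renormalize printed roundings
    out[[length(out) + 1]] <- pwm(m, name = name)
  }
  out
}

#' Write motifs to a MEME minimal motif file
#'
#' @param pwms list of PWMs (or a single PWM).
#' @param path output path; if `NULL` the text is returned invisibly
#'   instead of written.
#' @param background length-4 background frequency vector (A,C,G,T).
#' @param nsites optional integer vector of site counts per motif.
#' @return the file path (or the text when `path` is `NULL`), invisibly.
#' @export
writeMemeMotifs <- function(pwms, path = NULL,
                            background = rep(0.25, 4), nsites = NULL) {
  if (is.matrix(pwms)) pwms <- list(pwms)
  if (length(pwms) == 0) stop("no motifs to write")
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-6)
  txt <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: +", "",
    "Background letter frequencies",
    paste(sprintf("%s %.5f", BASES, background), collapse = " "), ""
  )
  for (i in seq_along(pwms)) {
    p <- pwms[[i]]
    stopifnot(isValidPwm(p))
    ns <- if (is.null(nsites)) 20L else nsites[i]
    txt <- c(txt,
      paste("MOTIF", pwmName(p)),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
              ncol(p), ns),
      apply(p, 2, function(col)
        paste(sprintf("%.6f", col), collapse = "  ")),
      "")
  }
  if (is.null(path)) return(invisible(paste(txt, collapse = "\n")))
  writeLines(txt, path)
  invisible(path)
}

#' Read motifs from JASPAR-style count matrix files
#'
#' Accepts the JASPAR 2016+ layout: a `>ID name` header followed by four
#' lines `A [ 4 19 0 ... ]` (brackets optional). Counts are converted to
#' probabilities with a 0.5 pseudocount per cell.
#'
#' @param path path to a JASPAR matrix file (may hold several matrices).
#' @param pseudocount per-cell pseudocount used in normalization.
#' @return a list of PWMs.
#' @export
readJasparMotifs <- function(path, pseudocount = 0.5) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no '>' headers in JASPAR file ", path)
  out <- list()
  for (h in heads) {
    fields <- strsplit(sub("^>", "", trimws(lines[h])), "\\s+")[[1]]
    name <- paste(fields, collapse = "_")
    block <- lines[(h + 1):min(h + 4, length(lines))]
    if (length(block) < 4)
      stop("JASPAR matrix ", name, " truncated (line ", h, ")")
    rows <- matrix(NA_real_, 4, 0)
    parsed <- lapply(block, function(ln) {
      ln <- gsub("[][]", " ", ln)
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      base <- parts[1]
      vals <- suppressWarnings(as.numeric(parts[-1]))
      if (!base %in% BASES || any(is.na(vals)))
        stop("malformed JASPAR count line near line ", h, ": ", ln)
      list(base = base, vals = vals)
    })
    ord <- match(BASES, vapply(parsed, `[[`, "", "base"))
    if (any(is.na(ord)))
      stop("JASPAR matrix ", name, " must have rows A, C, G, T")
    counts <- do.call(rbind, lapply(parsed[ord], `[[`, "vals"))
    out[[length(out) + 1]] <- countsToPwm(counts, pseudocount, name = name)
  }
  out
}

#' Read motifs from MEME minimal or JASPAR files by sniffing the format
#' @param path motif file.
#' @return list of PWMs.
#' @export
readMotifs <- function(path) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  first <- readLines(path, n = 25, warn = FALSE)
  if (any(grepl("^MEME version", first))) readMemeMotifs(path)
  else if (any(grepl("^>", first))) readJasparMotifs(path)
  else stop("unrecognized motif file format: ", path)
}
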