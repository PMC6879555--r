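# FASTA in/out, one-hot encoding, dinucleotide shuffling.

BASES <- c("A", "C", "G", "T")

#' Read DNA sequences from a FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet()]; sequences are uppercased on
#' ingest and record order is preserved. Header text after the first
#' whitespace is dropped from the name.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] with one element per record.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgt"), fa)
#' as.character(readFastaSequences(fa))
#' @export
readFastaSequences <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta", use.names = TRUE),
    error = function(e)
      stop("malformed FASTA in ", path, ": ", conditionMessage(e),
           call. = FALSE)
  )
  if (length(x) == 0)
    stop("FASTA file ", path, " contains no records (line 1)")
  out <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs a `DNAStringSet` (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFastaSequences <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path, format = "fasta")
  invisible(path)
}

#' One-hot encode a DNA sequence
#'
#' Maps A, C, G, T to the four indicator vectors (row order A, C, G, T);
#' an N yields an all-zero column, so it contributes nothing to any
#' convolution.
#'
#' @param seq a single sequence: character string, `DNAString`, or a
#'   length-one `DNAStringSet`.
#' @return a 4 x L numeric matrix with rownames `c("A","C","G","T")`.
#' @examples
#' oneHotEncode("ACGT")  # the 4 x 4 identity matrix
#' @export
oneHotEncode <- function(seq) {
  s <- toupper(as.character(seq))
  if (length(s) != 1) stop("oneHotEncode expects a single sequence")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(ch) < 1) stop("sequence must have length >= 1")
  bad <- setdiff(unique(ch), c(BASES, "N"))
  if (length(bad))
    stop("sequence contains letters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ","))
  m <- matrix(0, nrow = 4, ncol = length(ch),
              dimnames = list(BASES, NULL))
  for (j in seq_along(BASES)) m[j, ch == BASES[j]] <- 1
  m
}

#' Decode a one-hot matrix back to a DNA sequence
#'
#' Inverse of [oneHotEncode()] on pure-ACGT input; all-zero columns decode
#' to `N`.
#'
#' @param enc a 4 x L matrix whose columns are one-hot or all-zero.
#' @return a character string of length L.
#' @export
oneHotDecode <- function(enc) {
  if (nrow(enc) != 4) stop("encoded matrix must have 4 rows")
  cs <- colSums(enc)
  if (!all(cs %in% c(0, 1)) || !all(enc %in% c(0, 1)))
    stop("columns must be one-hot or all-zero")
  out <- rep("N", ncol(enc))
  hit <- cs == 1
  out[hit] <- BASES[apply(enc[, hit, drop = FALSE], 2, which.max)]
  paste(out, collapse = "")
}

#' One-hot encode a set of sequences into a 4 x L x n array
#'
#' All sequences must have equal length. This is the batch container the
#' model and training routines consume.
#'
#' @param seqs a `DNAStringSet` or character vector of equal-length
#'   sequences.
#' @return numeric array of dimension `c(4, L, n)`.
#' @export
encodeSequences <- function(seqs) {
  s <- toupper(as.character(seqs))
  L <- unique(nchar(s))
  if (length(L) != 1)
    stop("all sequences must have equal length; got widths ",
         paste(L, collapse = ","))
  n <- length(s)
  ch <- matrix(unlist(strsplit(s, "", fixed = TRUE)), nrow = L, ncol = n)
  arr <- array(0, dim = c(4, L, n))
  for (j in seq_along(BASES)) arr[j, , ] <- (ch == BASES[j]) * 1
  arr
}

# Overlapping dinucleotide count table (16 cells) of one sequence string.
dinucCounts <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  di <- paste0(ch[-length(ch)], ch[-1])
  table(factor(di, levels = as.vector(outer(BASES, BASES, paste0))))
}

#' Dinucleotide-preserving shuffle (Altschul-Erickson)
#'
#' Produces a random permutation of the input with exactly the same
#' multiset of overlapping dinucleotides, hence identical mono- and
#' dinucleotide counts, first base, and last base. Used to build negative
#' sequences from ChIP-seq positives. The construction is the
#' Altschul-Erickson Eulerian-walk method: the sequence is viewed as an
#' Euler path in the multigraph whose edges are its dinucleotides; a random
#' arborescence toward the terminal base fixes each vertex's final exit
#' edge, the remaining exits are randomly permuted, and the walk is read
#' off.
#'
#' @param seq a single sequence (character, `DNAString`).
#' @param ifN what to do when the sequence contains N: `"error"` (default)
#'   or `"skip"` (return the input unchanged).
#' @return the shuffled sequence as a character string.
#' @examples
#' set.seed(1)
#' dinucShuffle("ACGTACGTACGT")
#' @export
dinucShuffle <- function(seq, ifN = c("error", "skip")) {
  ifN <- match.arg(ifN)
  s <- toupper(as.character(seq))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(ch) < 2) stop("sequence must have length >= 2")
  if (any(ch == "N")) {
    if (ifN == "skip") return(s)
    stop("sequence contains N; set ifN = \"skip\" to pass it through")
  }
  if (!all(ch %in% BASES))
    stop("sequence contains letters outside {A,C,G,T}")

  first <- ch[1]
  last <- ch[length(ch)]
  # adjacency: for each source base, the multiset of target bases
  edges <- split(ch[-1], factor(ch[-length(ch)], levels = BASES))
  vertices <- BASES[vapply(edges, length, 1L) > 0 | BASES == last]

  if (length(unique(ch)) == 1) return(s) # single Eulerian arrangement

  repeat {
    # Pick a random candidate "last exit" edge for every non-terminal
    # vertex, then keep the draw only if these edges form an arborescence
    # into `last` (every vertex can reach it) — the A-E acceptance step.
    lastEdge <- setNames(rep(NA_character_, 4), BASES)
    for (v in vertices) {
      if (v == last || length(edges[[v]]) == 0) next
      lastEdge[v] <- sample(edges[[v]], 1)
    }
    ok <- TRUE
    for (v in vertices) {
      if (v == last || is.na(lastEdge[v])) next
      seen <- character()
      cur <- v
      while (!is.na(lastEdge[cur]) && cur != last && !(cur %in% seen)) {
        seen <- c(seen, cur)
        cur <- lastEdge[cur]
      }
      if (cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }

  # Shuffle the remaining exits; append each vertex's fixed last exit.
  walkLists <- lapply(BASES, function(v) {
    e <- edges[[v]]
    if (length(e) == 0) return(character())
    if (!is.na(lastEdge[v])) {
      drop <- match(lastEdge[v], e)
      e <- e[-drop]
    }
    e <- if (length(e) > 1) sample(e) else e
    c(e, if (!is.na(lastEdge[v])) lastEdge[v])
  })
  names(walkLists) <- BASES

  ptr <- setNames(rep(1L, 4), BASES)
  out <- character(length(ch))
  out[1] <- first
  cur <- first
  for (i in 2:length(ch)) {
    nxt <- walkLists[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Build a dinucleotide-shuffled negative set from positives
#'
#' @param seqs a `DNAStringSet` of positive sequences.
#' @param ifN passed to [dinucShuffle()].
#' @return a `DNAStringSet` of the same length, names suffixed `_shuf`.
#' @export
shuffledNegatives <- function(seqs, ifN = c("error", "skip")) {
  ifN <- match.arg(ifN)
  out <- vapply(as.character(seqs), dinucShuffle, "", ifN = ifN,
                USE.NAMES = FALSE)
  res <- Biostrings::DNAStringSet(out)
  nm <- names(seqs)
  if (!is.null(nm)) names(res) <- paste0(nm, "_shuf")
  res
}
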