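#' @include AllClasses.R pairwise.R
NULL

#' Center-star progressive multiple alignment
#'
#' Desk-scale progressive aligner used to build cluster-specific profile
#' HMMs: the center sequence is the member with the highest total pairwise
#' alignment score against the others; every other member is aligned to
#' the center globally and the pairwise alignments are merged by padding
#' insertions relative to the center. Deterministic.
#'
#' @param seqs named character vector or \code{AAStringSet} (>= 1).
#' @param matrix,gapOpen,gapExt scoring system (BLOSUM62, 11, 1).
#' @return named character vector of aligned (equal-length) sequences.
#' @export
centerStarAlign <- function(seqs, matrix = "BLOSUM62", gapOpen = 11,
                            gapExt = 1) {
  chars <- as.character(seqs)
  ids <- names(seqs)
  stopifnot(length(chars) >= 1, !is.null(ids))
  if (length(chars) == 1) return(stats::setNames(chars, ids))
  sub <- .subMatrix(matrix)
  n <- length(chars)
  # center = sequence with maximal total alignment score to the rest
  tot <- numeric(n)
  for (i in seq_len(n)) {
    others <- chars[-i]
    tot[i] <- sum(as.numeric(Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(others), chars[i], type = "global",
      substitutionMatrix = sub, gapOpening = gapOpen,
      gapExtension = gapExt, scoreOnly = TRUE)))
  }
  ci <- which.max(tot)
  center <- chars[ci]
  L <- nchar(center)
  othersIdx <- setdiff(seq_len(n), ci)

  # per-alignment: insertion run lengths after each center position (0..L)
  insRuns <- matrix(0L, length(othersIdx), L + 1L)
  alnP <- alnS <- character(length(othersIdx))
  for (k in seq_along(othersIdx)) {
    pal <- Biostrings::pairwiseAlignment(
      chars[othersIdx[k]], center, type = "global",
      substitutionMatrix = sub, gapOpening = gapOpen, gapExtension = gapExt)
    alnP[k] <- as.character(Biostrings::alignedPattern(pal))
    alnS[k] <- as.character(Biostrings::alignedSubject(pal))
    sc <- strsplit(alnS[k], "")[[1]]
    pos <- 0L
    run <- 0L
    for (c in sc) {
      if (c == "-") run <- run + 1L
      else {
        insRuns[k, pos + 1L] <- run
        pos <- pos + 1L
        run <- 0L
      }
    }
    insRuns[k, L + 1L] <- run
  }
  maxIns <- apply(insRuns, 2, max)

  pad <- function(alignedSeq, alignedCen) {
    sc <- strsplit(alignedCen, "")[[1]]
    sp <- strsplit(alignedSeq, "")[[1]]
    out <- character(0)
    pos <- 0L
    runChars <- character(0)
    flush <- function(pos, runChars) {
      need <- maxIns[pos + 1L] - length(runChars)
      c(runChars, rep("-", need))
    }
    for (i in seq_along(sc)) {
      if (sc[i] == "-") runChars <- c(runChars, sp[i])
      else {
        out <- c(out, flush(pos, runChars), sp[i])
        runChars <- character(0)
        pos <- pos + 1L
      }
    }
    out <- c(out, flush(pos, runChars))
    paste(out, collapse = "")
  }

  res <- character(n)
  res[ci] <- pad(center, center)
  for (k in seq_along(othersIdx)) res[othersIdx[k]] <- pad(alnP[k], alnS[k])
  stats::setNames(res, ids)
}
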