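#' @include AllClasses.R hmm.R topology.R
NULL

#' Annotate domains on a sequence with a profile library
#'
#' Runs each domain profile locally against the sequence, keeps calls
#' passing the E-value cutoff, and resolves overlapping calls greedily by
#' best bit score. Envelope coordinates come from the Viterbi alignment.
#'
#' @param seq amino-acid string.
#' @param profiles named list of \linkS4class{ProfileHMM}s (names are the
#'   domain names).
#' @param evalueCutoff default 1e-5 (the Pfam-style domain cutoff).
#' @param recordId identifier carried into the result.
#' @param nSeqs effective search-space size for E-values (default 1:
#'   single-sequence annotation).
#' @return data.frame (record_id, domain, start, end, bit_score, evalue)
#'   sorted by start, pairwise non-overlapping.
#' @export
annotateDomains <- function(seq, profiles, evalueCutoff = 1e-5,
                            recordId = "seq", nSeqs = 1) {
  stopifnot(length(profiles) >= 1)
  if (is.null(names(profiles)))
    names(profiles) <- vapply(profiles, function(p) p@name, character(1))
  calls <- lapply(names(profiles), function(nm) {
    hmm <- profiles[[nm]]
    if (length(hmm@calibration) != 2) hmm <- calibrateProfile(hmm)
    bits <- forwardBits(hmm, seq)
    ev <- evalueFromBits(hmm, bits, nSeqs)
    if (ev > evalueCutoff) return(NULL)
    vit <- viterbiBits(hmm, seq)
    data.frame(record_id = recordId, domain = nm,
               start = as.integer(vit$start), end = as.integer(vit$end),
               bit_score = bits, evalue = ev, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  if (is.null(calls) || nrow(calls) == 0) {
    return(data.frame(record_id = character(0), domain = character(0),
                      start = integer(0), end = integer(0),
                      bit_score = numeric(0), evalue = numeric(0),
                      stringsAsFactors = FALSE))
  }
  # greedy best-score non-overlap resolution
  calls <- calls[order(-calls$bit_score, calls$domain), , drop = FALSE]
  kept <- calls[0, ]
  for (i in seq_len(nrow(calls))) {
    ov <- nrow(kept) > 0 &&
      any(calls$start[i] <= kept$end & calls$end[i] >= kept$start)
    if (!ov) kept <- rbind(kept, calls[i, ])
  }
  kept <- kept[order(kept$start), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Render a domain annotation as an architecture string
#'
#' @param annotation table from \code{\link{annotateDomains}}.
#' @return tokens joined by \code{|} in coordinate order (e.g.
#'   \code{"HRM|GAIN|7TM"}); empty string for no calls.
#' @export
renderArchitecture <- function(annotation) {
  paste(annotation$domain[order(annotation$start)], collapse = "|")
}

#' Parse an architecture string back into tokens
#'
#' @param arch string as produced by \code{\link{renderArchitecture}}.
#' @return character vector of domain tokens.
#' @export
parseArchitecture <- function(arch) {
  if (identical(arch, "")) return(character(0))
  strsplit(arch, "|", fixed = TRUE)[[1]]
}

#' Classify the adhesion-GPCR HRM/GAIN/7TM module
#'
#' \code{GAIN_7TM} requires a GAIN call ending within \code{adjacencyTol}
#' residues of the first transmembrane helix ("directly N-terminal" to the
#' 7TM); \code{HRM_GAIN_7TM} additionally requires an HRM call N-terminal
#' to the GAIN with no other domain between them. The diagnostic spacing is
#' TM1 start minus HRM end, which in adhesion GPCRs typically falls around
#' 280-330 residues.
#'
#' @param annotation domain table for one record
#'   (\code{\link{annotateDomains}}).
#' @param topo the record's \linkS4class{TMTopology}.
#' @param adjacencyTol maximum residues between GAIN end and TM1 start
#'   (default 50).
#' @return list with \code{module} (one of \code{"HRM_GAIN_7TM"},
#'   \code{"GAIN_7TM"}, \code{"none"}) and \code{spacing} (TM1 start -
#'   HRM end; NA without an HRM call).
#' @export
detectHrmGainModule <- function(annotation, topo, adjacencyTol = 50) {
  if (nHelices(topo) < 1L)
    return(list(module = "none", spacing = NA_integer_))
  tm1 <- helices(topo)[1, "start"]
  gain <- annotation[annotation$domain == "GAIN" &
                     annotation$end < tm1 &
                     tm1 - annotation$end - 1L <= adjacencyTol, ,
                     drop = FALSE]
  if (nrow(gain) == 0) return(list(module = "none", spacing = NA_integer_))
  gain <- gain[which.max(gain$bit_score), ]
  hrm <- annotation[annotation$domain == "HRM" &
                    annotation$end < gain$start, , drop = FALSE]
  spacing <- if (nrow(hrm)) as.integer(tm1 - max(hrm$end)) else NA_integer_
  if (nrow(hrm) == 0) return(list(module = "GAIN_7TM", spacing = spacing))
  hrm <- hrm[which.max(hrm$end), ]
  between <- annotation[annotation$start > hrm$end &
                        annotation$end < gain$start, , drop = FALSE]
  module <- if (nrow(between) == 0) "HRM_GAIN_7TM" else "GAIN_7TM"
  list(module = module, spacing = as.integer(tm1 - hrm$end))
}

# ---- motif grammar ----------------------------------------------------

# Tokenize a motif pattern: literal residues, x = any residue,
# A/B/C or {A/B/C} alternatives (one position), (x)_m[,n][_] bounded gaps.
.parseMotif <- function(motif) {
  chars <- strsplit(motif, "")[[1]]
  tokens <- list()
  i <- 1L
  n <- length(chars)
  bad <- function(i) stop("malformed motif pattern at position ", i,
                          ": '", motif, "'", call. = FALSE)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "x") {
      tokens[[length(tokens) + 1L]] <- list(type = "any")
      i <- i + 1L
    } else if (ch %in% AA20) {
      set <- ch
      i <- i + 1L
      while (i + 1L <= n && chars[i] == "/" &&
             chars[i + 1L] %in% AA20) {
        set <- c(set, chars[i + 1L])
        i <- i + 2L
      }
      tokens[[length(tokens) + 1L]] <- list(type = "set", set = set)
    } else if (ch == "{") {
      j <- i + 1L
      set <- character(0)
      while (j <= n && chars[j] != "}") {
        if (chars[j] %in% AA20) set <- c(set, chars[j])
        else if (chars[j] != "/") bad(j)
        j <- j + 1L
      }
      if (j > n || !length(set)) bad(i)
      tokens[[length(tokens) + 1L]] <- list(type = "set", set = set)
      i <- j + 1L
    } else if (ch == "(") {
      if (i + 2L > n || chars[i + 1L] != "x" || chars[i + 2L] != ")") bad(i)
      i <- i + 3L
      if (i > n || chars[i] != "_") bad(i)
      i <- i + 1L
      j <- i
      while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
      if (j == i) bad(i)
      m <- as.integer(paste(chars[i:(j - 1L)], collapse = ""))
      mx <- m
      i <- j
      if (i <= n && chars[i] == ",") {
        i <- i + 1L
        j <- i
        while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
        if (j == i) bad(i)
        mx <- as.integer(paste(chars[i:(j - 1L)], collapse = ""))
        i <- j
      }
      if (i <= n && chars[i] == "_") i <- i + 1L  # closing subscript mark
      if (mx < m) bad(i)
      tokens[[length(tokens) + 1L]] <- list(type = "gap", min = m, max = mx)
    } else bad(i)
  }
  if (!length(tokens)) bad(1L)
  tokens
}

# Match tokens against chars starting at pos; returns end index of the
# shortest match, or NA. Bounded gaps try their smallest expansion first.
.matchTokensAt <- function(tokens, chars, pos) {
  rec <- function(t, p) {
    if (t > length(tokens)) return(p - 1L)
    if (p > length(chars) + 1L) return(NA_integer_)
    tok <- tokens[[t]]
    if (tok$type == "gap") {
      for (g in tok$min:tok$max) {
        if (p + g - 1L > length(chars)) break
        r <- rec(t + 1L, p + g)
        if (!is.na(r)) return(r)
      }
      return(NA_integer_)
    }
    if (p > length(chars)) return(NA_integer_)
    ok <- switch(tok$type, any = TRUE, set = chars[p] %in% tok$set)
    if (!ok) return(NA_integer_)
    rec(t + 1L, p + 1L)
  }
  rec(1L, pos)
}

#' Scan a region for a sequence motif
#'
#' Pattern grammar: literal residues; \code{x} matches any residue;
#' \code{A/B} or \code{\{A/B\}} matches one position against alternatives;
#' \code{(x)_m,n} (or \code{(x)_m}) matches a bounded spacer of m to n
#' arbitrary residues. Reports all non-overlapping matches, leftmost first,
#' taking the shortest expansion at each start.
#'
#' @param region amino-acid string.
#' @param motif pattern, e.g. \code{"NPxxY(x)_5,6_FR"}, \code{"E/DRY"},
#'   \code{"LR(x)_9_GI"}.
#' @return data.frame (offset, length, match) with 1-based offsets.
#' @export
motifScan <- function(region, motif) {
  tokens <- .parseMotif(motif)
  chars <- strsplit(toupper(region), "")[[1]]
  offs <- integer(0); lens <- integer(0)
  p <- 1L
  while (p <= length(chars)) {
    e <- .matchTokensAt(tokens, chars, p)
    if (!is.na(e)) {
      offs <- c(offs, p); lens <- c(lens, e - p + 1L)
      p <- e + 1L
    } else p <- p + 1L
  }
  data.frame(offset = offs, length = lens,
             match = if (length(offs))
               substring(region, offs, offs + lens - 1L) else character(0),
             stringsAsFactors = FALSE)
}

# ---- position frequency tables and logos ------------------------------

#' Position frequency table with gappy-column trimming
#'
#' Computes per-column residue frequencies and gap fractions of an
#' alignment, removing columns whose gap fraction exceeds the limit
#' (gappy-mode trimming, default 0.9) before reporting. Unknown residues
#' (X) count toward the gap fraction.
#'
#' @param aln aligned equal-length sequences (\code{AAStringSet} or
#'   character).
#' @param gapLimit columns with gap fraction above this are removed
#'   (default 0.9).
#' @return list with \code{freq} (20 x C matrix: per-column residue
#'   frequencies), \code{gapFraction} (per kept column),
#'   \code{columns} (original column indices kept), \code{nSequences}.
#'   Each column's frequencies plus its gap fraction sum to 1.
#' @export
buildPositionFrequencyTable <- function(aln, gapLimit = 0.9) {
  aln <- toupper(as.character(aln))
  if (!length(aln)) stop("empty alignment")
  stopifnot(length(unique(nchar(aln))) == 1L)
  mat <- do.call(rbind, strsplit(aln, ""))
  mat[mat == "."] <- "-"
  nseq <- nrow(mat)
  gapish <- !matrix(mat %in% AA20, nrow(mat), ncol(mat))
  gapFrac <- colMeans(gapish)
  keep <- which(gapFrac <= gapLimit)
  if (!length(keep)) stop("no columns survive gap trimming")
  freq <- vapply(keep, function(j) {
    as.numeric(table(factor(mat[, j], levels = AA20))) / nseq
  }, numeric(20))
  rownames(freq) <- AA20
  list(freq = freq, gapFraction = gapFrac[keep], columns = keep,
       nSequences = nseq)
}

#' Consensus sequence of a position frequency table
#'
#' Per column, the most frequent residue (ties broken alphabetically); a
#' \code{+} marks columns whose top residue frequency is below 0.5
#' (unresolvable consensus).
#'
#' @param pft result of \code{\link{buildPositionFrequencyTable}}.
#' @return character string, one symbol per kept column.
#' @export
consensusFromPFT <- function(pft) {
  syms <- apply(pft$freq, 2, function(col) {
    top <- which.max(col)      # which.max breaks ties by first = alphabetical
    if (col[top] < 0.5) "+" else AA20[top]
  })
  paste(syms, collapse = "")
}

#' Extract the GAIN-domain logo region from an adhesion-GPCR alignment
#'
#' Finds the first alignment column that is at least 90 percent cysteine
#' (the conserved N-terminal cysteine of the C-terminal GAIN subdomain) and
#' the first downstream 7-column window whose consensus matches the
#' tethered-agonist consensus TxFAVLM, and returns the columns from the
#' cysteine through the end of that window.
#'
#' @param aln aligned adhesion-GPCR sequences.
#' @param cysFraction required cysteine fraction for the anchor column
#'   (default 0.9).
#' @return list with \code{aln} (sub-alignment, character vector),
#'   \code{from}, \code{to} (column indices).
#' @export
extractGainLogoRegion <- function(aln, cysFraction = 0.9) {
  aln <- toupper(as.character(aln))
  stopifnot(length(aln) >= 1, length(unique(nchar(aln))) == 1L)
  mat <- do.call(rbind, strsplit(aln, ""))
  nc <- ncol(mat)
  cFrac <- colMeans(mat == "C")
  c0 <- which(cFrac >= cysFraction)[1]
  # per-column consensus over residues (gaps excluded)
  cons <- apply(mat, 2, function(col) {
    col <- col[col %in% AA20]
    if (!length(col)) return("-")
    tb <- table(factor(col, levels = AA20))
    AA20[which.max(tb)]
  })
  ta <- c("T", NA, "F", "A", "V", "L", "M")   # NA = any
  taMatch <- function(w) {
    win <- cons[w:(w + 6L)]
    all(is.na(ta) | win == ta)
  }
  starts <- if (nc >= 7L)
    which(vapply(seq_len(nc - 6L), taMatch, logical(1)))
  else integer(0)
  if (is.na(c0)) {
    stop("anchor not found: no alignment column with >= ",
         cysFraction * 100, "% conserved cysteine")
  }
  if (!length(starts))
    stop("anchor not found: no TxFAVLM tethered-agonist consensus window")
  after <- starts[starts > c0]
  if (!length(after))
    stop("anchor order violated: TxFAVLM consensus window lies upstream ",
         "of the conserved cysteine column")
  to <- after[1] + 6L
  list(aln = substring(aln, c0, to), from = c0, to = to)
}
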