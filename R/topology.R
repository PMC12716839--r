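#' @include AllClasses.R utils.R
NULL

#' Predict transmembrane helices by hydropathy
#'
#' Kyte-Doolittle hydropathy averaged over a sliding window; maximal runs of
#' above-threshold window centers are expanded to the window extent, close
#' runs merged, over-long runs split at their hydropathy minimum, and each
#' candidate trimmed at its least hydrophobic end residues to the maximum
#' helix length. Deterministic.
#'
#' @param seq amino-acid string.
#' @param recordId identifier carried into the result.
#' @param window sliding-window width (default 19).
#' @param threshold mean window hydropathy for a transmembrane call
#'   (default 1.6).
#' @param mergeGap runs separated by fewer than this many below-threshold
#'   positions are merged (default 4).
#' @param minLen,maxLen retained helix length bounds (defaults 17, 25).
#' @param splitLen runs longer than this are split at the hydropathy
#'   minimum (default 35).
#' @return a \linkS4class{TMTopology}; sequences shorter than the window
#'   give zero helices with a warning.
#' @export
predictTM <- function(seq, recordId = "seq", window = 19, threshold = 1.6,
                      mergeGap = 4, minLen = 17, maxLen = 25, splitLen = 35) {
  n <- nchar(seq)
  emptyTopo <- new("TMTopology", recordId = recordId,
                   helices = matrix(integer(0), 0, 2,
                                    dimnames = list(NULL, c("start", "end"))))
  if (n < window) {
    warning("sequence shorter than hydropathy window; no helices called",
            call. = FALSE)
    return(emptyTopo)
  }
  kd <- unname(KD_SCALE[strsplit(toupper(seq), "")[[1]]])
  kd[is.na(kd)] <- 0
  h <- as.numeric(stats::filter(kd, rep(1 / window, window), sides = 2))
  half <- (window - 1) %/% 2
  centers <- which(!is.na(h) & h >= threshold)
  if (!length(centers)) return(emptyTopo)

  # maximal runs of above-threshold centers
  runs <- split(centers, cumsum(c(1, diff(centers) != 1)))
  runs <- lapply(runs, range)
  # merge runs separated by small below-threshold gaps
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] - 1 < mergeGap)
      merged[[length(merged)]] <- c(last[1], r[2])
    else merged <- c(merged, list(r))
  }
  # split over-long center runs (two helices fused across a short loop) at
  # the interior hydropathy minimum, recursively
  splitLong <- function(a, b) {
    if (b - a + 1 <= splitLen) return(list(c(a, b)))
    margin <- min(8L, (b - a) %/% 3)
    inner <- (a + margin):(b - margin)
    hi <- h[inner]
    hi[is.na(hi)] <- kd[inner][is.na(hi)]
    cut <- inner[which.min(hi)]
    c(splitLong(a, cut), splitLong(cut + 1L, b))
  }
  merged <- unlist(lapply(merged, function(r) splitLong(r[1], r[2])),
                   recursive = FALSE)
  # expand to window extent, clipping adjacent expansions at the midpoint
  iv <- do.call(rbind, lapply(merged, function(r)
    c(max(1L, r[1] - half), min(n, r[2] + half))))
  if (nrow(iv) > 1) {
    for (i in seq_len(nrow(iv) - 1)) {
      if (iv[i + 1, 1] <= iv[i, 2]) {
        mid <- (iv[i, 2] + iv[i + 1, 1]) %/% 2
        iv[i, 2] <- mid
        iv[i + 1, 1] <- mid + 1L
      }
    }
  }
  # trim: first shed non-hydrophobic end residues picked up by the window
  # expansion, then enforce the maximum length at the weaker end
  trim <- function(a, b) {
    while (b - a + 1 > minLen && kd[a] < 1.0) a <- a + 1L
    while (b - a + 1 > minLen && kd[b] < 1.0) b <- b - 1L
    while (b - a + 1 > maxLen) {
      if (kd[a] <= kd[b]) a <- a + 1L else b <- b - 1L
    }
    c(a, b)
  }
  iv <- t(apply(iv, 1, function(r) trim(r[1], r[2])))
  iv <- iv[iv[, 2] - iv[, 1] + 1 >= minLen, , drop = FALSE]
  storage.mode(iv) <- "integer"
  dimnames(iv) <- list(NULL, c("start", "end"))
  new("TMTopology", recordId = recordId, helices = iv)
}

#' Apply the six-to-eight transmembrane-helix retention rule
#'
#' Candidates are retained when they carry six to eight predicted helices:
#' seven is the GPCR hallmark, six tolerates a missed helix, and eight
#' allows an uncleaved N-terminal signal anchor.
#'
#' @param topo a \linkS4class{TMTopology}.
#' @return TRUE iff 6 <= n_helices <= 8.
#' @export
passHelixFilter <- function(topo) {
  n <- nHelices(topo)
  n >= 6L && n <= 8L
}

#' Extract the 7TM region of a record
#'
#' Returns the residues from the N-terminal end of transmembrane helix 1
#' through the C-terminal end of helix 7. For records with eight predicted
#' helices the first is treated as a signal anchor and skipped, so the 7TM
#' spans helices 2-8 (more generally, the last seven helices).
#'
#' @param seq amino-acid string.
#' @param topo its \linkS4class{TMTopology} (needs at least 7 helices).
#' @return list with \code{seq}, \code{start}, \code{end} (1-based
#'   inclusive).
#' @export
extract7TM <- function(seq, topo) {
  n <- nHelices(topo)
  if (n < 7L) stop("no 7TM region: only ", n, " helices")
  h <- helices(topo)
  first <- n - 6L
  start <- unname(h[first, "start"])
  end <- unname(h[n, "end"])
  list(seq = substring(seq, start, end), start = start, end = end)
}

#' Extract the N-terminal fragment (NTF)
#'
#' Residues from the start of the protein to just before the first
#' transmembrane helix; empty when TM1 starts at residue 1.
#'
#' @inheritParams extract7TM
#' @return amino-acid string (possibly empty).
#' @export
extractNTF <- function(seq, topo) {
  if (nHelices(topo) < 1L) stop("no transmembrane helix predicted")
  start1 <- helices(topo)[1, "start"]
  if (start1 == 1L) "" else substring(seq, 1L, start1 - 1L)
}

#' Write topologies as TSV
#'
#' @param topos list of \linkS4class{TMTopology} objects.
#' @param path output TSV (record_id, n_helices, semicolon-joined
#'   "start-end" intervals).
#' @export
writeTopologyTSV <- function(topos, path) {
  df <- data.frame(
    record_id = vapply(topos, function(t) t@recordId, character(1)),
    n_helices = vapply(topos, nHelices, integer(1)),
    helices = vapply(topos, function(t) {
      h <- helices(t)
      paste(h[, 1], h[, 2], sep = "-", collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
  writeTSV(df, path)
  invisible(path)
}
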