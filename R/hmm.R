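#' @include AllClasses.R utils.R
NULL

.tmCols <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

.newProfileHMM <- function(name, me, tm, background,
                           insertEmissions = background) {
  colnames(me) <- AA20
  colnames(tm) <- .tmCols
  new("ProfileHMM", name = name, matchEmissions = me,
      insertEmissions = unname(insertEmissions[AA20]),
      transitions = tm, background = unname(background[AA20]))
}

.uniformBackground <- stats::setNames(rep(1 / 20, 20), AA20)

#' Build a profile HMM from a multiple alignment
#'
#' Alignment columns with gap fraction at most 0.5 become match states; the
#' rest are treated as insertions. Match emissions are observed residue
#' frequencies plus a Laplace pseudocount; transition probabilities are
#' counted from the per-sequence state paths with the same pseudocount.
#' Insert emissions are tied to the background. Deterministic for a fixed
#' input.
#'
#' @param aln aligned sequences (equal length; \code{AAStringSet} or
#'   character vector), gaps as \code{-} or \code{.}.
#' @param name model name.
#' @param background 20-vector of background frequencies (default uniform,
#'   matching the Laplace pseudocount prior).
#' @param gapThreshold columns with gap fraction above this become inserts.
#' @param pseudocount Laplace pseudocount added to every emission and
#'   transition count.
#' @return a \linkS4class{ProfileHMM}.
#' @export
buildProfileHMM <- function(aln, name = "profile",
                            background = .uniformBackground,
                            gapThreshold = 0.5, pseudocount = 1) {
  aln <- toupper(as.character(aln))
  stopifnot(length(aln) >= 1, length(unique(nchar(aln))) == 1L)
  mat <- do.call(rbind, strsplit(aln, ""))
  mat[mat == "."] <- "-"
  isGap <- mat == "-"
  gapFrac <- colMeans(isGap)
  matchCol <- gapFrac <= gapThreshold
  L <- sum(matchCol)
  if (L == 0) stop("alignment has zero retained (match) columns")
  background <- background[AA20] / sum(background[AA20])

  me <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  mc <- which(matchCol)
  for (j in seq_len(L)) {
    res <- mat[, mc[j]]
    res <- res[res %in% AA20]           # gaps and X carry no count
    cnt <- table(factor(res, levels = AA20))
    me[j, ] <- (as.numeric(cnt) + pseudocount) /
      (sum(cnt) + 20 * pseudocount)
  }

  # transition counts from per-sequence state paths
  cnt <- matrix(0, L, 7, dimnames = list(NULL, .tmCols))
  colState <- ifelse(matchCol, cumsum(matchCol), NA)
  for (s in seq_len(nrow(mat))) {
    prev <- NULL   # c(type, j)
    for (cidx in seq_len(ncol(mat))) {
      if (matchCol[cidx]) {
        j <- colState[cidx]
        cur <- c(if (isGap[s, cidx]) "D" else "M", j)
      } else {
        if (isGap[s, cidx]) next
        cur <- c("I", if (is.null(prev)) 0 else as.integer(prev[2]))
        if (cur[2] == "0") { prev <- cur; next }  # N-terminal insert: skip
      }
      if (!is.null(prev) && as.integer(prev[2]) >= 1) {
        pj <- as.integer(prev[2])
        lab <- paste0(prev[1], cur[1])
        if (lab %in% .tmCols && pj <= L) {
          # transitions out of column j lead to column j+1 (or stay, for I)
          ok <- switch(lab,
                       MM = , MD = , IM = , DM = , DD =
                         as.integer(cur[2]) == pj + 1L,
                       MI = , II = as.integer(cur[2]) == pj)
          if (isTRUE(ok)) cnt[pj, lab] <- cnt[pj, lab] + 1
        }
      }
      prev <- cur
    }
  }
  tm <- matrix(0, L, 7, dimnames = list(NULL, .tmCols))
  tm[, 1:3] <- (cnt[, 1:3] + pseudocount) /
    (rowSums(cnt[, 1:3, drop = FALSE]) + 3 * pseudocount)
  tm[, 4:5] <- (cnt[, 4:5] + pseudocount) /
    (rowSums(cnt[, 4:5, drop = FALSE]) + 2 * pseudocount)
  tm[, 6:7] <- (cnt[, 6:7] + pseudocount) /
    (rowSums(cnt[, 6:7, drop = FALSE]) + 2 * pseudocount)
  .newProfileHMM(name, me, tm, background)
}

#' Build the 7TM topology-grammar HMM
#'
#' A generic membrane-topology model that mimics the common architecture of
#' GPCRs rather than any one family: seven helix blocks with
#' hydrophobic-biased emissions, connected by loops with mildly polar-biased
#' emissions. Scored locally like any other profile, it recovers
#' multi-spanning membrane proteins regardless of family membership.
#'
#' @param config list of tunables: \code{nHelix} (7), \code{helixLen} (21),
#'   \code{loopLen} (15), \code{hydrophobicMass} (total emission probability
#'   given to A/F/I/L/M/V inside helices, 0.75), \code{polarBias}
#'   (multiplier on polar residues in loops, 1.2), \code{background}.
#' @return a \linkS4class{ProfileHMM}.
#' @export
buildTopologyHMM <- function(config = list()) {
  cf <- utils::modifyList(list(
    nHelix = 7L, helixLen = 21L, loopLen = 15L,
    hydrophobicMass = 0.75, polarBias = 1.2,
    background = AA_COMPOSITION), config)
  bg <- cf$background[AA20] / sum(cf$background[AA20])

  helixEm <- numeric(20); names(helixEm) <- AA20
  hset <- AA20 %in% HYDROPHOBIC_AA
  helixEm[hset] <- cf$hydrophobicMass * bg[hset] / sum(bg[hset])
  helixEm[!hset] <- (1 - cf$hydrophobicMass) * bg[!hset] / sum(bg[!hset])

  loopEm <- bg
  loopEm[!hset] <- loopEm[!hset] * cf$polarBias
  loopEm <- loopEm / sum(loopEm)

  isHelix <- logical(0)
  for (k in seq_len(cf$nHelix)) {
    isHelix <- c(isHelix, rep(FALSE, cf$loopLen), rep(TRUE, cf$helixLen))
  }
  isHelix <- c(isHelix, rep(FALSE, cf$loopLen))
  L <- length(isHelix)
  me <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  me[isHelix, ] <- matrix(helixEm, sum(isHelix), 20, byrow = TRUE)
  me[!isHelix, ] <- matrix(loopEm, sum(!isHelix), 20, byrow = TRUE)

  tm <- matrix(0, L, 7, dimnames = list(NULL, .tmCols))
  tm[isHelix, 1:3] <- matrix(c(0.96, 0.02, 0.02), sum(isHelix), 3,
                             byrow = TRUE)
  tm[!isHelix, 1:3] <- matrix(c(0.88, 0.06, 0.06), sum(!isHelix), 3,
                              byrow = TRUE)
  tm[, 4:5] <- 0.5
  tm[, 6:7] <- 0.5
  .newProfileHMM("topology7tm", me, tm, bg)
}

.oddsMatrix <- function(hmm) {
  sweep(hmm@matchEmissions, 2, hmm@background, "/")
}

#' Local forward score in bits
#'
#' Log-odds (model versus background) forward score over all local
#' alignments of the sequence to the profile: entry at any match state,
#' exit at any match state, a uniform prior over the alignment start
#' position, and flanking residues emitted by the background (so a
#' background-composition sequence scores at or below zero bits on
#' average).
#'
#' @param hmm a \linkS4class{ProfileHMM}.
#' @param seq an amino-acid string (X scores as background).
#' @return score in bits.
#' @export
forwardBits <- function(hmm, seq) {
  stopifnot(nchar(seq) > 0)
  hmm_forward_cpp(.oddsMatrix(hmm), hmm@transitions, digitizeAA(seq))
}

#' Local Viterbi score and envelope
#'
#' Best single local alignment; the envelope is the 1-based inclusive
#' residue interval covered by that alignment. Always bounded above by
#' \code{\link{forwardBits}} (a maximum never exceeds a sum).
#'
#' @inheritParams forwardBits
#' @return list with \code{bits}, \code{start}, \code{end}.
#' @export
viterbiBits <- function(hmm, seq) {
  stopifnot(nchar(seq) > 0)
  hmm_viterbi_cpp(.oddsMatrix(hmm), hmm@transitions, digitizeAA(seq))
}

#' Calibrate the E-value null of a profile
#'
#' Scores background-sampled sequences with the profile and fits a Gumbel
#' (location, scale) to the score distribution, weighting the upper tail
#' (exceedances over the 70th percentile) where E-values are actually
#' evaluated. E-values are then \code{nSeqs * P(score >= s)} under this
#' null. Calibrate against the composition of the proteomes that will be
#' searched; a null drawn from a different composition miscalibrates the
#' tail.
#'
#' @param hmm a \linkS4class{ProfileHMM}.
#' @param n number of background draws (default 200).
#' @param len length of each background draw.
#' @param seed RNG seed for the draws (default 1789).
#' @param background composition to draw from; defaults to the profile's
#'   own background.
#' @return the profile with its \code{calibration} slot filled.
#' @export
calibrateProfile <- function(hmm, n = 200, len = 350, seed = 1789,
                             background = NULL) {
  bg <- if (is.null(background)) stats::setNames(hmm@background, AA20)
        else background[AA20] / sum(background[AA20])
  scores <- localSeed(seed, {
    vapply(seq_len(n),
           function(i) forwardBits(hmm, randomAASeq(len, bg)),
           numeric(1))
  })
  hmm@calibration <- fitGumbelTail(scores)
  hmm
}

# evaluate an expression under a local RNG seed without disturbing the
# caller's RNG stream
localSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' E-values from calibrated bit scores
#'
#' @param hmm a calibrated \linkS4class{ProfileHMM}.
#' @param bits bit scores.
#' @param nSeqs number of target sequences searched.
#' @return E-values (strictly positive).
#' @export
evalueFromBits <- function(hmm, bits, nSeqs) {
  if (length(hmm@calibration) != 2)
    stop("profile '", hmm@name, "' is not calibrated")
  nSeqs * gumbelUpperTail(bits, hmm@calibration[["mu"]],
                          hmm@calibration[["beta"]])
}

#' Search a proteome with a profile HMM
#'
#' Scores every record with the local forward algorithm, converts scores to
#' E-values under the profile's fitted Gumbel null, and reports hits passing
#' the cutoff, sorted by ascending E-value. Envelope coordinates come from
#' the Viterbi alignment of each hit.
#'
#' @param hmm a \linkS4class{ProfileHMM}; calibrated automatically (seed
#'   1789) if it is not already.
#' @param proteome a \linkS4class{Proteome}.
#' @param evalueCutoff report hits with E-value at or below this (default
#'   0.01, the family-screen cutoff; pathway-component screens use 1e-5).
#' @param nSeqs effective database size for the E-value (defaults to the
#'   proteome size; pass the total when searching many proteomes).
#' @return data.frame: record_id, species, profile, bit_score, evalue,
#'   env_start, env_end.
#' @export
searchProfile <- function(hmm, proteome, evalueCutoff = 0.01,
                          nSeqs = length(proteome)) {
  stopifnot(evalueCutoff > 0)
  empty <- data.frame(record_id = character(0), species = character(0),
                      profile = character(0), bit_score = numeric(0),
                      evalue = numeric(0), env_start = integer(0),
                      env_end = integer(0), stringsAsFactors = FALSE)
  if (length(proteome) == 0) return(empty)
  if (length(hmm@calibration) != 2) hmm <- calibrateProfile(hmm)
  seqs <- as.character(proteome)
  bits <- vapply(seqs, function(s) forwardBits(hmm, s), numeric(1),
                 USE.NAMES = FALSE)
  ev <- evalueFromBits(hmm, bits, nSeqs)
  keep <- which(ev <= evalueCutoff)
  if (!length(keep)) return(empty)
  env <- lapply(seqs[keep], function(s) viterbiBits(hmm, s))
  out <- data.frame(
    record_id = names(proteome)[keep],
    species = rep(speciesName(proteome), length(keep)),
    profile = rep(hmm@name, length(keep)),
    bit_score = bits[keep],
    evalue = ev[keep],
    env_start = vapply(env, function(e) as.integer(e$start), integer(1)),
    env_end = vapply(env, function(e) as.integer(e$end), integer(1)),
    stringsAsFactors = FALSE)
  out[order(out$evalue, -out$bit_score, out$record_id), , drop = FALSE]
}

#' Serialize a profile HMM to a plain-text file
#'
#' Documented text format: header lines (NAME, LENG, ALPH, BACKGROUND,
#' INSERT, optional CALIBRATION), then one MATCH and one TRANS line per
#' state. Round-trips exactly.
#'
#' @param hmm a \linkS4class{ProfileHMM}.
#' @param path output file.
#' @export
writeProfileHMM <- function(hmm, path) {
  num <- function(x) paste(format(x, digits = 17, scientific = TRUE),
                           collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("NAME", hmm@name),
    paste("LENG", nrow(hmm@matchEmissions)),
    paste("ALPH", paste(AA20, collapse = "")),
    paste("BACKGROUND", num(hmm@background)),
    paste("INSERT", num(hmm@insertEmissions)),
    if (length(hmm@calibration) == 2)
      paste("CALIBRATION", num(hmm@calibration))), con)
  for (j in seq_len(nrow(hmm@matchEmissions))) {
    writeLines(paste("MATCH", num(hmm@matchEmissions[j, ])), con)
    writeLines(paste("TRANS", num(hmm@transitions[j, ])), con)
  }
  invisible(path)
}

#' Read a profile HMM written by \code{\link{writeProfileHMM}}
#'
#' @param path input file.
#' @return a \linkS4class{ProfileHMM}.
#' @export
readProfileHMM <- function(path) {
  ln <- readLines(path)
  field <- function(key) {
    x <- ln[startsWith(ln, paste0(key, " "))]
    sub(paste0("^", key, " "), "", x)
  }
  nums <- function(x) as.numeric(strsplit(x, " +")[[1]])
  L <- as.integer(field("LENG"))
  me <- do.call(rbind, lapply(field("MATCH"), nums))
  tm <- do.call(rbind, lapply(field("TRANS"), nums))
  stopifnot(nrow(me) == L, nrow(tm) == L)
  bg <- nums(field("BACKGROUND")); names(bg) <- AA20
  ins <- nums(field("INSERT")); names(ins) <- AA20
  hmm <- .newProfileHMM(field("NAME"), me, tm, bg, ins)
  cal <- field("CALIBRATION")
  if (length(cal)) {
    v <- nums(cal)
    hmm@calibration <- c(mu = v[1], beta = v[2])
  }
  hmm
}

#' Write a profile search hit table as TSV
#'
#' @param hits hit table from \code{\link{searchProfile}}.
#' @param path output TSV.
#' @export
writeHitsTSV <- function(hits, path) {
  writeTSV(hits[, c("record_id", "profile", "bit_score", "evalue",
                    "env_start", "env_end")], path)
  invisible(path)
}
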