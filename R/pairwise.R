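#' @include AllClasses.R utils.R
NULL

.pkgCache <- new.env(parent = emptyenv())

.subMatrix <- function(matrix = "BLOSUM62") {
  if (is.matrix(matrix)) return(matrix)
  key <- paste0("SUB_", matrix)
  if (is.null(.pkgCache[[key]])) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    .pkgCache[[key]] <- get(matrix, envir = e)
  }
  .pkgCache[[key]]
}

#' Karlin-Altschul parameters for a scoring system
#'
#' Fits lambda and K once per (matrix, gap) scoring system from the Gumbel
#' distribution of optimal local scores of background-sampled sequence
#' pairs, so pairwise E-values \code{K m n exp(-lambda S)} are available
#' without precomputed gapped parameters. Deterministic (fixed seed) and
#' cached for the session.
#'
#' @param matrix substitution matrix name or matrix (default BLOSUM62).
#' @param gapOpen,gapExt affine gap costs (defaults 11, 1).
#' @param nPairs number of shuffled pairs scored (default 500).
#' @param len length of each sampled sequence (default 200).
#' @param seed RNG seed (default 1789).
#' @return named vector \code{lambda}, \code{K}.
#' @export
karlinAltschulParams <- function(matrix = "BLOSUM62", gapOpen = 11,
                                 gapExt = 1, nPairs = 500, len = 200,
                                 seed = 1789) {
  key <- paste("KA", if (is.matrix(matrix)) "custom" else matrix,
               gapOpen, gapExt, nPairs, len, seed, sep = "_")
  if (!is.null(.pkgCache[[key]])) return(.pkgCache[[key]])
  sub <- .subMatrix(matrix)
  scores <- localSeed(seed, {
    vapply(seq_len(nPairs), function(i) {
      a <- randomAASeq(len); b <- randomAASeq(len)
      as.numeric(Biostrings::pairwiseAlignment(
        a, b, type = "local", substitutionMatrix = sub,
        gapOpening = gapOpen, gapExtension = gapExt, scoreOnly = TRUE))
    }, numeric(1))
  })
  g <- fitGumbelTail(scores)
  lambda <- 1 / g[["beta"]]
  K <- exp(lambda * g[["mu"]]) / (len * len)
  out <- c(lambda = lambda, K = K)
  .pkgCache[[key]] <- out
  out
}

.kaEvalue <- function(score, m, n, ka) {
  pmax(ka[["K"]] * m * n * exp(-ka[["lambda"]] * score), 1e-320)
}

.kaBits <- function(score, ka) {
  (ka[["lambda"]] * score - log(ka[["K"]])) / log(2)
}

#' Optimal local pairwise alignment
#'
#' Smith-Waterman local alignment with affine gaps (BLOSUM62, open 11,
#' extend 1 by default), with identity, coverage and Karlin-Altschul
#' statistics. When no residue pair scores positively the alignment is
#' empty with raw score 0.
#'
#' @param q,s amino-acid strings (query, subject).
#' @param queryId,subjectId identifiers for the report.
#' @param matrix,gapOpen,gapExt scoring system.
#' @return one-row data.frame: query_id, subject_id, raw_score, bit_score,
#'   evalue, pct_identity (over aligned columns), query_coverage (percent
#'   of query residues aligned), q_start, q_end, s_start, s_end (1-based
#'   inclusive).
#' @export
localAlign <- function(q, s, queryId = "query", subjectId = "subject",
                       matrix = "BLOSUM62", gapOpen = 11, gapExt = 1) {
  stopifnot(nchar(q) > 0, nchar(s) > 0)
  sub <- .subMatrix(matrix)
  ka <- karlinAltschulParams(matrix, gapOpen, gapExt)
  pal <- Biostrings::pairwiseAlignment(
    q, s, type = "local", substitutionMatrix = sub,
    gapOpening = gapOpen, gapExtension = gapExt)
  sc <- Biostrings::score(pal)
  if (sc <= 0) {
    return(data.frame(query_id = queryId, subject_id = subjectId,
                      raw_score = 0, bit_score = 0,
                      evalue = .kaEvalue(0, nchar(q), nchar(s), ka),
                      pct_identity = 0, query_coverage = 0,
                      q_start = 0L, q_end = 0L, s_start = 0L, s_end = 0L,
                      stringsAsFactors = FALSE))
  }
  pr <- pal@pattern@range
  sr <- pal@subject@range
  alnLen <- nchar(as.character(Biostrings::alignedPattern(pal)))
  data.frame(
    query_id = queryId, subject_id = subjectId,
    raw_score = sc, bit_score = .kaBits(sc, ka),
    evalue = .kaEvalue(sc, nchar(q), nchar(s), ka),
    pct_identity = 100 * Biostrings::nmatch(pal) / alnLen,
    query_coverage = 100 * (BiocGenerics::end(pr) -
                            BiocGenerics::start(pr) + 1) / nchar(q),
    q_start = BiocGenerics::start(pr), q_end = BiocGenerics::end(pr),
    s_start = BiocGenerics::start(sr), s_end = BiocGenerics::end(sr),
    stringsAsFactors = FALSE)
}

# score-only database scan: E-values of the query against every database
# record passing the seed-word prefilter (whole-database search space).
# Returns a data.frame (subject_id, score, evalue) sorted by E-value.
# kmerSets may be precomputed with seqKmers to amortize repeated scans.
.scanHits <- function(query, dbChars, dbNames, sub, ka, wordSize = 4,
                      kmerSets = NULL) {
  qk <- seqKmers(query, wordSize)
  if (is.null(kmerSets)) {
    cand <- which(vapply(dbChars, function(s)
      any(qk %in% seqKmers(s, wordSize)), logical(1), USE.NAMES = FALSE))
  } else {
    cand <- which(vapply(kmerSets, function(ks) any(qk %in% ks),
                         logical(1), USE.NAMES = FALSE))
  }
  if (!length(cand)) {
    return(data.frame(subject_id = character(0), score = numeric(0),
                      evalue = numeric(0), stringsAsFactors = FALSE))
  }
  scores <- as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(dbChars[cand]), query, type = "local",
    substitutionMatrix = sub, gapOpening = 11, gapExtension = 1,
    scoreOnly = TRUE))
  ev <- .kaEvalue(scores, nchar(query), sum(nchar(dbChars)), ka)
  ord <- order(ev, -scores, dbNames[cand])
  data.frame(subject_id = dbNames[cand][ord], score = scores[ord],
             evalue = ev[ord], stringsAsFactors = FALSE)
}

# indices of db entries sharing at least minShared k-mers with the query
.kmerCandidates <- function(query, dbChars, wordSize = 4, minShared = 1) {
  qk <- seqKmers(query, wordSize)
  if (!length(qk)) return(integer(0))
  hits <- vapply(dbChars, function(s) {
    sum(qk %in% seqKmers(s, wordSize)) >= minShared
  }, logical(1), USE.NAMES = FALSE)
  which(hits)
}

#' Ranked database search with one query
#'
#' Scores the query against every database record that shares a seed word
#' (k-mer prefilter, BLAST-style seeding), ranks by E-value then bit score,
#' and reports up to \code{k} hits passing the cutoff. E-values use the
#' whole-database search space (query length x total database residues).
#'
#' @param query amino-acid string.
#' @param db a \linkS4class{Proteome} or named \code{AAStringSet}.
#' @param k maximum number of hits (default 10).
#' @param evalueCutoff report hits with E at or below this (default 1e-5).
#' @param queryId identifier for the report.
#' @param matrix,gapOpen,gapExt scoring system.
#' @param wordSize seed word length for the prefilter (default 4).
#' @return data.frame of up to k rows in rank order (columns as
#'   \code{\link{localAlign}}).
#' @export
topHits <- function(query, db, k = 10, evalueCutoff = 1e-5,
                    queryId = "query", matrix = "BLOSUM62", gapOpen = 11,
                    gapExt = 1, wordSize = 4) {
  stopifnot(k >= 1)
  empty <- localAlign("A", "A")[0, ]
  if (length(db) == 0) return(empty)
  sub <- .subMatrix(matrix)
  ka <- karlinAltschulParams(matrix, gapOpen, gapExt)
  dbChars <- as.character(db)
  nDb <- sum(nchar(dbChars))
  cand <- .kmerCandidates(query, dbChars, wordSize)
  if (!length(cand)) return(empty)
  scores <- as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(dbChars[cand]), query, type = "local",
    substitutionMatrix = sub, gapOpening = gapOpen, gapExtension = gapExt,
    scoreOnly = TRUE))
  ev <- .kaEvalue(scores, nchar(query), nDb, ka)
  ord <- order(ev, -scores, names(db)[cand])
  keep <- ord[ev[ord] <= evalueCutoff]
  keep <- utils::head(keep, k)
  if (!length(keep)) return(empty)
  out <- do.call(rbind, lapply(keep, function(i) {
    hit <- localAlign(query, dbChars[cand[i]], queryId = queryId,
                      subjectId = names(db)[cand[i]], matrix = matrix,
                      gapOpen = gapOpen, gapExt = gapExt)
    hit$evalue <- ev[i]   # whole-database search space
    hit
  }))
  out
}

#' Homology-hit rule for reference searches
#'
#' A hit counts as homology evidence when it covers at least 70 percent of
#' the query and is at least 30 percent identical over aligned columns
#' (both boundaries inclusive).
#'
#' @param hit one or more rows as returned by \code{\link{localAlign}}.
#' @return logical vector.
#' @export
isHomologHit <- function(hit) {
  hit$query_coverage >= 70 & hit$pct_identity >= 30
}

#' Greedy incremental identity clustering
#'
#' Longest-first greedy clustering: each record joins the first existing
#' representative with global (ends-free) identity at or above the
#' threshold, where identity is matches over the length of the shorter
#' sequence; otherwise it founds a new cluster. Both the isoform-removal
#' step of candidate validation (threshold 0.9) and phylogenetic dataset
#' reduction (threshold 0.8, word size 5) use this scheme. Ties in length
#' are broken by lexicographic id.
#'
#' @param seqs named \code{AAStringSet} or named character vector.
#' @param threshold identity fraction in (0, 1].
#' @param wordSize k-mer length of the candidate prefilter (default 5).
#' @return list with \code{representatives} (ids, in creation order) and
#'   \code{membership} (data.frame id, representative).
#' @export
greedyIdentityCluster <- function(seqs, threshold = 0.9, wordSize = 5) {
  stopifnot(threshold > 0, threshold <= 1)
  chars <- as.character(seqs)
  ids <- names(seqs)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  ord <- order(-nchar(chars), ids)
  chars <- chars[ord]; ids <- ids[ord]
  sub <- .subMatrix("BLOSUM62")
  reps <- integer(0)
  assign_to <- integer(length(ids))
  kmerSets <- lapply(chars, seqKmers, k = wordSize)
  for (i in seq_along(ids)) {
    joined <- 0L
    for (r in reps) {
      if (!any(kmerSets[[i]] %in% kmerSets[[r]])) next
      pal <- Biostrings::pairwiseAlignment(
        chars[i], chars[r], type = "overlap", substitutionMatrix = sub,
        gapOpening = 11, gapExtension = 1)
      idn <- Biostrings::nmatch(pal) / min(nchar(chars[i]), nchar(chars[r]))
      if (idn >= threshold) { joined <- r; break }
    }
    if (joined == 0L) { reps <- c(reps, i); assign_to[i] <- i }
    else assign_to[i] <- joined
  }
  list(representatives = ids[reps],
       membership = data.frame(id = ids, representative = ids[assign_to],
                               stringsAsFactors = FALSE))
}
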