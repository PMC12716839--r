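#' @include AllClasses.R seqio.R hmm.R topology.R pairwise.R clans.R msa.R
NULL

#' Estimate amino-acid background composition from proteomes
#'
#' @param proteomes list of \linkS4class{Proteome}s.
#' @return named 20-vector of frequencies.
#' @export
estimateBackground <- function(proteomes) {
  counts <- stats::setNames(rep(0, 20), AA20)
  for (p in proteomes) {
    if (!length(p)) next
    lf <- colSums(Biostrings::letterFrequency(p, letters = AA20))
    counts <- counts + lf
  }
  if (sum(counts) == 0) return(stats::setNames(rep(1 / 20, 20), AA20))
  counts / sum(counts)
}

#' Default screening / validation parameters
#'
#' The printed defaults of the study design: family-profile screen at
#' E <= 0.01, topology screen at E <= 0.01, reference-homology validation
#' at E <= 1e-5 with a GPCR required within the top 10 hits, retention of
#' candidates with 6-8 transmembrane helices, isoform removal at 90 percent
#' identity, fragment flagging below 60 percent of the best-matching
#' reference length.
#'
#' @return named list.
#' @export
defaultScreenParams <- function() {
  list(familyCutoff = 0.01, topologyCutoff = 0.01,
       refCutoff = 1e-5, topK = 10L,
       helixMin = 6L, helixMax = 8L,
       isoformThreshold = 0.9, isoformWordSize = 5L,
       fragmentFraction = 0.6,
       calibN = 200L, calibSeed = 1789L,
       clansCutoff = 1e-6, clansCycles = 2000L, clansSeed = 1789L,
       clusterMinSize = 4L, sdLimit = 0.5,
       repsPerCluster = 3L)
}

# pool all proteome sequences / species labels, keeping record ids as names
.poolSeqs <- function(proteomes) {
  do.call(c, unname(lapply(proteomes, function(p)
    stats::setNames(as.character(p), names(p)))))
}
.poolSpecies <- function(proteomes) {
  do.call(c, unname(lapply(proteomes, function(p)
    stats::setNames(rep(speciesName(p), length(p)), names(p)))))
}

.emptyHits <- function() {
  data.frame(record_id = character(0), species = character(0),
             profile = character(0), bit_score = numeric(0),
             evalue = numeric(0), env_start = integer(0),
             env_end = integer(0), stringsAsFactors = FALSE)
}

# calibrate a profile against the proteome background unless already done
.calibrated <- function(hmm, bg, len, params) {
  if (length(hmm@calibration) == 2) return(hmm)
  calibrateProfile(hmm, n = params$calibN, len = len,
                   seed = params$calibSeed, background = bg)
}

#' Run the two-track GPCR screen
#'
#' Track A searches every proteome with each family-specific 7TM profile;
#' track B searches with the generic membrane-topology HMM. Hits are pooled
#' per track, the two candidate sets are merged, and exact duplicate
#' records (same species and sequence) are collapsed to the first-seen id,
#' yielding the unique candidate set of the audited ledger.
#'
#' @param proteomes named list of \linkS4class{Proteome}s.
#' @param familyProfiles list of family \linkS4class{ProfileHMM}s.
#' @param topologyHMM the topology-grammar profile
#'   (\code{\link{buildTopologyHMM}}), or NULL to skip track B.
#' @param params list from \code{\link{defaultScreenParams}} (entries
#'   override defaults).
#' @return a \linkS4class{CandidateLedger} with the merged round-1
#'   candidate set (not yet validated).
#' @export
runTwoTrackScreen <- function(proteomes, familyProfiles,
                              topologyHMM = buildTopologyHMM(),
                              params = list()) {
  stopifnot(length(familyProfiles) >= 1)
  params <- utils::modifyList(defaultScreenParams(), params)
  bg <- estimateBackground(proteomes)
  nSeqs <- sum(vapply(proteomes, length, integer(1)))
  medLen <- stats::median(unlist(lapply(proteomes, Biostrings::width)))

  screenA <- .emptyHits()
  for (hmm in familyProfiles) {
    hmm <- .calibrated(hmm, bg, medLen, params)
    for (p in proteomes)
      screenA <- rbind(screenA,
                       searchProfile(hmm, p, params$familyCutoff, nSeqs))
  }
  screenB <- .emptyHits()
  if (!is.null(topologyHMM)) {
    topologyHMM <- .calibrated(topologyHMM, bg, medLen, params)
    for (p in proteomes)
      screenB <- rbind(screenB,
                       searchProfile(topologyHMM, p, params$topologyCutoff,
                                     nSeqs))
  }

  ids <- union(unique(screenA$record_id), unique(screenB$record_id))
  allSeqs <- Biostrings::AAStringSet(.poolSeqs(proteomes))
  spOf <- .poolSpecies(proteomes)
  cand <- allSeqs[ids]
  dd <- dedupExact(cand, spOf[ids])
  merged <- data.frame(record_id = names(dd$kept),
                       species = unname(dd$species),
                       round = 1L, stringsAsFactors = FALSE)
  new("CandidateLedger", screenA = screenA, screenB = screenB,
      merged = merged, mergedPairs = dd$mergedPairs,
      removed = data.frame(record_id = character(0), species = character(0),
                           reason = character(0), round = integer(0),
                           stringsAsFactors = FALSE),
      validated = data.frame(record_id = character(0),
                             species = character(0), round = integer(0),
                             stringsAsFactors = FALSE),
      candidates = dd$kept, rounds = 0L)
}

# 7TM region of a validated record; records with six helices fall back to
# the full TM1..TMn span
.tmRegion <- function(seq, topo) {
  n <- nHelices(topo)
  if (n >= 7) {
    r <- extract7TM(seq, topo)
    r$seq
  } else {
    h <- helices(topo)
    substring(seq, h[1, "start"], h[n, "end"])
  }
}

#' Validate merged candidates
#'
#' Applies the multi-criterion validation filter to the candidates of the
#' current round, logging every removal with a reason code:
#' \describe{
#'   \item{helix_count}{not 6-8 predicted transmembrane helices;}
#'   \item{no_gpcr_blast_hit}{no reference GPCR among the top 10 local
#'     alignment hits at E <= 1e-5 (a structure-comparison rescue hook may
#'     reinstate such candidates; the default hook rescues nothing);}
#'   \item{fragment}{shorter than 60 percent of its best-matching
#'     reference receptor;}
#'   \item{isoform}{within-species greedy identity clustering at 0.9 keeps
#'     only the longest representative of near-identical records.}
#' }
#'
#' @param ledger a \linkS4class{CandidateLedger} with unvalidated
#'   candidates (from \code{\link{runTwoTrackScreen}} or a refinement
#'   round).
#' @param referenceGPCRs named \code{AAStringSet} of known GPCRs.
#' @param params list from \code{\link{defaultScreenParams}}.
#' @param structureRescue optional hook \code{function(seqs, ids)} returning
#'   the ids to reinstate among homology failures; NULL rescues nothing.
#' @return the ledger with this round's validated and removed sets filled.
#' @export
validateCandidates <- function(ledger, referenceGPCRs, params = list(),
                               structureRescue = NULL) {
  params <- utils::modifyList(defaultScreenParams(), params)
  r <- ledger@rounds + 1L
  cand <- ledger@merged[ledger@merged$round == r, , drop = FALSE]
  if (nrow(cand) == 0) {
    ledger@rounds <- r
    methods::validObject(ledger)
    return(ledger)
  }
  seqs <- as.character(ledger@candidates[cand$record_id])
  names(seqs) <- cand$record_id
  removed <- list()
  drop <- function(ids, reason) {
    if (!length(ids)) return(NULL)
    data.frame(record_id = ids,
               species = cand$species[match(ids, cand$record_id)],
               reason = rep(reason, length(ids)),
               round = rep(r, length(ids)), stringsAsFactors = FALSE)
  }

  # 1. topology: 6-8 transmembrane helices
  topo <- lapply(names(seqs), function(id) predictTM(seqs[[id]], id))
  names(topo) <- names(seqs)
  nh <- vapply(topo, nHelices, integer(1))
  badHelix <- names(seqs)[nh < params$helixMin | nh > params$helixMax]
  removed$helix <- drop(badHelix, "helix_count")
  alive <- setdiff(names(seqs), badHelix)

  # 2. reference homology: a GPCR within the top hits at the cutoff
  # (score-only scan; only the best reference identity is needed)
  refChars <- as.character(referenceGPCRs)
  refNames <- names(referenceGPCRs)
  refKmers <- lapply(refChars, seqKmers, k = 4)
  sub <- .subMatrix("BLOSUM62")
  ka <- karlinAltschulParams()
  bestRef <- stats::setNames(rep(NA_character_, length(alive)), alive)
  noHit <- character(0)
  for (id in alive) {
    hits <- .scanHits(seqs[[id]], refChars, refNames, sub, ka,
                      kmerSets = refKmers)
    hits <- hits[hits$evalue <= params$refCutoff, , drop = FALSE]
    if (nrow(hits) == 0) noHit <- c(noHit, id)
    else bestRef[id] <- hits$subject_id[1]
  }
  if (!is.null(structureRescue) && length(noHit)) {
    rescued <- intersect(structureRescue(seqs[noHit], noHit), noHit)
    noHit <- setdiff(noHit, rescued)
  }
  removed$blast <- drop(noHit, "no_gpcr_blast_hit")
  alive <- setdiff(alive, noHit)

  # 3. fragments: short relative to the best-matching reference receptor
  # (rescued candidates have no reference hit and are exempt)
  lens <- nchar(seqs[alive])
  refLen <- nchar(refChars)[match(bestRef[alive], refNames)]
  frag <- alive[!is.na(refLen) & lens < params$fragmentFraction * refLen]
  removed$fragment <- drop(frag, "fragment")
  alive <- setdiff(alive, frag)

  # 4. isoforms: within-species identity clustering, longest-first
  iso <- character(0)
  for (sp in unique(cand$species)) {
    ids <- alive[cand$species[match(alive, cand$record_id)] == sp]
    if (length(ids) < 2) next
    cl <- greedyIdentityCluster(stats::setNames(seqs[ids], ids),
                                threshold = params$isoformThreshold,
                                wordSize = params$isoformWordSize)
    iso <- c(iso, setdiff(ids, cl$representatives))
  }
  removed$iso <- drop(iso, "isoform")
  alive <- setdiff(alive, iso)

  remDf <- do.call(rbind, removed)
  if (is.null(remDf))
    remDf <- data.frame(record_id = character(0), species = character(0),
                        reason = character(0), round = integer(0),
                        stringsAsFactors = FALSE)
  ledger@removed <- rbind(ledger@removed, remDf)
  ledger@validated <- rbind(
    ledger@validated,
    data.frame(record_id = alive,
               species = cand$species[match(alive, cand$record_id)],
               round = rep(r, length(alive)), stringsAsFactors = FALSE))
  ledger@rounds <- r
  methods::validObject(ledger)
  ledger
}

#' Cluster the validated receptors by their 7TM regions
#'
#' Extracts the 7TM region of every validated record, builds the all-vs-all
#' similarity graph, computes the force-directed layout, and detects the
#' convex clusters that define GPCR families.
#'
#' @param ledger a validated \linkS4class{CandidateLedger}.
#' @param params list from \code{\link{defaultScreenParams}}.
#' @return list with \code{tms} (named AAStringSet of 7TM regions),
#'   \code{topologies}, \code{graph}, \code{layout}, \code{clusters}.
#' @export
clusterValidated <- function(ledger, params = list()) {
  params <- utils::modifyList(defaultScreenParams(), params)
  ids <- ledger@validated$record_id
  seqs <- as.character(ledger@candidates[ids])
  names(seqs) <- ids
  topo <- lapply(ids, function(id) predictTM(seqs[[id]], id))
  names(topo) <- ids
  tms <- vapply(ids, function(id) .tmRegion(seqs[[id]], topo[[id]]),
                character(1))
  tmSet <- Biostrings::AAStringSet(tms)
  graph <- buildSimilarityGraph(tmSet, evalueCutoff = params$clansCutoff)
  lay <- layoutGraph(graph, cycles = params$clansCycles,
                     seed = params$clansSeed)
  clusters <- findConvexClusters(graph, lay, minSize = params$clusterMinSize,
                                 sdLimit = params$sdLimit)
  list(tms = tmSet, topologies = topo, graph = graph, layout = lay,
       clusters = clusters)
}

#' Family assignment table from a clustering
#'
#' @param clusters a \linkS4class{ClusterSet}.
#' @param ledger the validated \linkS4class{CandidateLedger} (for species
#'   and rounds).
#' @return data.frame (record_id, species, family, round); unclustered
#'   records carry family \code{"unclustered"}.
#' @export
assignFamilies <- function(clusters, ledger) {
  ct <- clusterTable(clusters)
  v <- ledger@validated
  data.frame(record_id = ct$record_id,
             species = v$species[match(ct$record_id, v$record_id)],
             family = ifelse(ct$cluster_label == "unclustered",
                             "unclustered", ct$cluster_label),
             round = v$round[match(ct$record_id, v$record_id)],
             stringsAsFactors = FALSE)
}

# representatives nearest the cluster centroid in layout space
.clusterReps <- function(clusters, layout, nReps) {
  lapply(clusterMembers(clusters), function(members) {
    xy <- layout[members, , drop = FALSE]
    centroid <- colMeans(xy)
    d <- sqrt(rowSums(sweep(xy, 2, centroid)^2))
    members[order(d, members)][seq_len(min(nReps, length(members)))]
  })
}

#' Iterative refinement with lineage-specific cluster HMMs
#'
#' Each round clusters the validated 7TM regions, aligns every cluster with
#' the center-star progressive aligner, builds one cluster-specific profile
#' HMM per cluster plus a single-sequence profile per unclustered record,
#' and re-screens the proteomes with the new profiles and with
#' representative sequences (nearest the cluster centroid in layout space)
#' as pairwise queries. Candidates never seen before are validated with
#' the standard filter, survivors join the ledger, and iteration stops when
#' a round adds nothing or \code{maxRounds} is reached.
#'
#' @param ledger a validated \linkS4class{CandidateLedger}.
#' @param proteomes the screened proteomes.
#' @param referenceGPCRs reference set for homology validation; validated
#'   receptors from earlier rounds are added to it automatically.
#' @param params list from \code{\link{defaultScreenParams}}.
#' @param maxRounds maximum refinement rounds (default 3; 0 leaves the
#'   ledger unchanged).
#' @return the extended \linkS4class{CandidateLedger}.
#' @export
iterateRefinement <- function(ledger, proteomes, referenceGPCRs,
                              params = list(), maxRounds = 3) {
  params <- utils::modifyList(defaultScreenParams(), params)
  if (maxRounds < 1) return(ledger)
  bg <- estimateBackground(proteomes)
  nSeqs <- sum(vapply(proteomes, length, integer(1)))
  medLen <- stats::median(unlist(lapply(proteomes, Biostrings::width)))
  spOf <- .poolSpecies(proteomes)
  allSeqs <- Biostrings::AAStringSet(.poolSeqs(proteomes))

  for (round in seq_len(maxRounds)) {
    cl <- clusterValidated(ledger, params)
    tms <- as.character(cl$tms)

    profiles <- list()
    for (lab in names(clusterMembers(cl$clusters))) {
      members <- clusterMembers(cl$clusters)[[lab]]
      aln <- centerStarAlign(tms[members])
      profiles[[lab]] <- buildProfileHMM(aln, name = lab, background = bg)
    }
    for (id in unclustered(cl$clusters)) {
      profiles[[id]] <- buildProfileHMM(tms[id], name = id,
                                        background = bg)
    }

    hitIds <- character(0)
    for (hmm in profiles) {
      hmm <- .calibrated(hmm, bg, medLen, params)
      for (p in proteomes) {
        h <- searchProfile(hmm, p, params$familyCutoff, nSeqs)
        hitIds <- c(hitIds, h$record_id)
      }
    }
    reps <- unlist(.clusterReps(cl$clusters, cl$layout,
                                params$repsPerCluster), use.names = FALSE)
    fullSeqs <- as.character(ledger@candidates[reps])
    sub <- .subMatrix("BLOSUM62")
    ka <- karlinAltschulParams()
    poolChars <- as.character(allSeqs)
    poolKmers <- lapply(poolChars, seqKmers, k = 4)
    for (i in seq_along(reps)) {
      h <- .scanHits(fullSeqs[i], poolChars, names(allSeqs), sub, ka,
                     kmerSets = poolKmers)
      hitIds <- c(hitIds, h$subject_id[h$evalue <= params$refCutoff])
    }

    newIds <- setdiff(unique(hitIds), ledger@merged$record_id)
    if (!length(newIds)) break
    # drop exact duplicates of already-ledgered candidates
    seen <- paste0(spOf[ledger@merged$record_id], "\r",
                   as.character(ledger@candidates[ledger@merged$record_id]))
    newTag <- paste0(spOf[newIds], "\r", as.character(allSeqs[newIds]))
    newIds <- newIds[!newTag %in% seen]
    if (!length(newIds)) break

    r <- ledger@rounds + 1L
    ledger@merged <- rbind(ledger@merged, data.frame(
      record_id = newIds, species = unname(spOf[newIds]), round = r,
      stringsAsFactors = FALSE))
    ledger@candidates <- c(ledger@candidates, allSeqs[newIds])
    refPlus <- c(referenceGPCRs,
                 ledger@candidates[ledger@validated$record_id])
    before <- nrow(ledger@validated)
    ledger <- validateCandidates(ledger, refPlus, params)
    if (nrow(ledger@validated) == before) break
  }
  ledger
}

#' Generic profile-set screen (pathway components)
#'
#' Searches the proteomes with an arbitrary profile library at a single
#' cutoff, as used for heterotrimeric G proteins and the positive and
#' negative regulators of G-protein signaling (default cutoff 1e-5).
#'
#' @param proteomes named list of \linkS4class{Proteome}s.
#' @param profiles list of \linkS4class{ProfileHMM}s (possibly empty).
#' @param evalueCutoff default 1e-5.
#' @param params list from \code{\link{defaultScreenParams}}.
#' @return hit table (as \code{\link{searchProfile}}).
#' @export
screenProfileSet <- function(proteomes, profiles, evalueCutoff = 1e-5,
                             params = list()) {
  params <- utils::modifyList(defaultScreenParams(), params)
  hits <- .emptyHits()
  if (!length(profiles) || !length(proteomes)) return(hits)
  bg <- estimateBackground(proteomes)
  nSeqs <- sum(vapply(proteomes, length, integer(1)))
  medLen <- stats::median(unlist(lapply(proteomes, Biostrings::width)))
  for (hmm in profiles) {
    hmm <- .calibrated(hmm, bg, medLen, params)
    for (p in proteomes)
      hits <- rbind(hits, searchProfile(hmm, p, evalueCutoff, nSeqs))
  }
  hits
}

#' Per-profile hit counts of a screen
#'
#' @param hits hit table.
#' @return named integer vector: unique records per profile.
#' @export
countsByProfile <- function(hits) {
  if (nrow(hits) == 0) return(stats::setNames(integer(0), character(0)))
  vapply(split(hits$record_id, hits$profile),
         function(x) length(unique(x)), integer(1))
}

#' Write every ledger stage as TSV
#'
#' @param ledger a \linkS4class{CandidateLedger}.
#' @param dir output directory; writes screen_family.tsv,
#'   screen_topology.tsv, merged.tsv, merged_pairs.tsv, removed.tsv,
#'   validated.tsv and counts.tsv.
#' @export
writeLedgerTSV <- function(ledger, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTSV(ledger@screenA, file.path(dir, "screen_family.tsv"))
  writeTSV(ledger@screenB, file.path(dir, "screen_topology.tsv"))
  writeTSV(ledger@merged, file.path(dir, "merged.tsv"))
  writeTSV(ledger@mergedPairs, file.path(dir, "merged_pairs.tsv"))
  writeTSV(ledger@removed, file.path(dir, "removed.tsv"))
  writeTSV(ledger@validated, file.path(dir, "validated.tsv"))
  writeTSV(ledgerCounts(ledger), file.path(dir, "counts.tsv"))
  invisible(dir)
}

#' Assemble a ledger directly from screen id sets
#'
#' Low-level constructor for audits over printed screen tallies: takes the
#' two screens' candidate id sets (and optionally their species), merges
#' them, and returns a ledger whose arithmetic is checked by the class
#' validity. Sequences are not required.
#'
#' @param idsA,idsB candidate ids recovered by the family-profile screen
#'   and the topology screen.
#' @param species named species lookup (defaults to a single species).
#' @return a \linkS4class{CandidateLedger}.
#' @export
ledgerFromScreens <- function(idsA, idsB, species = NULL) {
  u <- union(idsA, idsB)
  sp <- if (is.null(species)) stats::setNames(rep("sp", length(u)), u)
        else species
  mk <- function(ids) data.frame(record_id = ids,
                                 species = unname(sp[ids]),
                                 profile = "screen", bit_score = NA_real_,
                                 evalue = NA_real_, env_start = NA_integer_,
                                 env_end = NA_integer_,
                                 stringsAsFactors = FALSE)
  new("CandidateLedger", screenA = mk(idsA), screenB = mk(idsB),
      merged = data.frame(record_id = u, species = unname(sp[u]),
                          round = 1L, stringsAsFactors = FALSE),
      removed = data.frame(record_id = character(0), species = character(0),
                           reason = character(0), round = integer(0),
                           stringsAsFactors = FALSE),
      validated = data.frame(record_id = character(0),
                             species = character(0), round = integer(0),
                             stringsAsFactors = FALSE),
      candidates = Biostrings::AAStringSet(), rounds = 0L)
}

#' Record a validation round on a ledger by explicit removal lists
#'
#' Low-level ledger operation mirroring \code{\link{validateCandidates}}
#' for audits where the removals are given rather than computed: candidates
#' of the current round not removed become validated; the set arithmetic
#' is enforced by the class validity.
#'
#' @param ledger a \linkS4class{CandidateLedger}.
#' @param removals data.frame (record_id, reason).
#' @return the updated ledger.
#' @export
ledgerApplyRemovals <- function(ledger, removals) {
  r <- ledger@rounds + 1L
  cand <- ledger@merged[ledger@merged$round == r, , drop = FALSE]
  stopifnot(all(removals$record_id %in% cand$record_id),
            !anyDuplicated(removals$record_id))
  sp <- cand$species[match(removals$record_id, cand$record_id)]
  ledger@removed <- rbind(ledger@removed, data.frame(
    record_id = removals$record_id, species = sp,
    reason = removals$reason, round = rep(r, nrow(removals)),
    stringsAsFactors = FALSE))
  keep <- setdiff(cand$record_id, removals$record_id)
  ledger@validated <- rbind(ledger@validated, data.frame(
    record_id = keep, species = cand$species[match(keep, cand$record_id)],
    round = rep(r, length(keep)), stringsAsFactors = FALSE))
  ledger@rounds <- r
  methods::validObject(ledger)
  ledger
}

#' Append a refinement round of candidates to a ledger
#'
#' @param ledger a \linkS4class{CandidateLedger}.
#' @param ids new candidate ids (must be unseen).
#' @param species named species lookup (defaults to a single species).
#' @return the updated ledger (candidates of the new round unvalidated).
#' @export
ledgerAddRound <- function(ledger, ids, species = NULL) {
  stopifnot(!any(ids %in% ledger@merged$record_id))
  sp <- if (is.null(species)) stats::setNames(rep("sp", length(ids)), ids)
        else species
  ledger@merged <- rbind(ledger@merged, data.frame(
    record_id = ids, species = unname(sp[ids]),
    round = ledger@rounds + 1L, stringsAsFactors = FALSE))
  methods::validObject(ledger)
  ledger
}
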