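#' @include AllClasses.R utils.R hmm.R evolution.R
NULL

# Extracellular/loop residue composition: database composition with the
# strongly hydrophobic residues down-weighted, as in real soluble loops and
# ectodomains. Keeps simulated loops and N-terminal fragments from
# spuriously crossing the transmembrane hydropathy threshold.
.loopComposition <- local({
  comp <- AA_COMPOSITION
  comp[HYDROPHOBIC_AA] <- comp[HYDROPHOBIC_AA] * 0.25
  comp / sum(comp)
})

#' Default configuration of the synthetic GPCRome study
#'
#' The default emulates the shape of a multi-species receptor survey:
#' 20 species on a bifurcating tree (3 of them transcriptome-only), 8
#' planted GPCR families of 10-40 members with family-specific 7TM
#' emission profiles and shared-ancestry divergence, 2 families carrying
#' HRM/GAIN ectodomain modules, 2000 decoys (soluble proteins, 5-helix
#' membrane proteins, 7TM-only fragments) and a 5 percent isoform-twin
#' rate.
#'
#' @return named list of generator settings.
#' @export
defaultSyntheticConfig <- function() {
  list(
    nSpecies = 20L, nTranscriptome = 3L,
    nFamilies = 8L, familySizeRange = c(10L, 40L),
    nAGPCRFamilies = 2L, maxLosses = 2L,
    decoys = c(soluble = 1700L, few_helix = 200L, fragment = 100L),
    isoformRate = 0.05,
    divergence = 0.35, refDivergence = 0.25, memberDivergence = 0.12,
    refsPerFamily = 4L,
    helixLen = 21L, loopLenRange = c(15L, 22L),
    ntfLenRange = c(30L, 80L), ctermLenRange = c(25L, 60L),
    helixPoolSize = 3L,
    background = AA_COMPOSITION)
}

# substitute a fraction p of sites; helix sites stay inside the family's
# hydrophobic pool (so the membrane topology stays detectable under
# divergence), all other sites resample from the loop composition
.mutateChars <- function(chars, p, helixMask, pool) {
  hit <- which(stats::runif(length(chars)) < p)
  if (!length(hit)) return(chars)
  hh <- hit[helixMask[hit]]
  oo <- hit[!helixMask[hit]]
  if (length(hh)) chars[hh] <- sample(pool, length(hh), replace = TRUE)
  if (length(oo)) chars[oo] <- sample(AA20, length(oo), replace = TRUE,
                                      prob = .loopComposition[AA20])
  chars
}

.randomChars <- function(n, comp) {
  sample(AA20, n, replace = TRUE, prob = comp[AA20])
}

# architecture of one family ancestor: (chars, helixMask, tm matrix,
# domain table)
.familyAncestor <- function(cf, aGPCR, pool, hrmAnc, gainAnc) {
  loops <- sample(cf$loopLenRange[1]:cf$loopLenRange[2], 6, replace = TRUE)
  ctermLen <- sample(cf$ctermLenRange[1]:cf$ctermLenRange[2], 1)
  if (aGPCR) {
    ntf <- c(.randomChars(40, .loopComposition), hrmAnc,
             .randomChars(30, .loopComposition), gainAnc,
             .randomChars(30, .loopComposition))
    domains <- data.frame(
      domain = c("HRM", "GAIN"),
      start = c(41L, 41L + length(hrmAnc) + 30L),
      end = c(40L + length(hrmAnc),
              40L + length(hrmAnc) + 30L + length(gainAnc)),
      stringsAsFactors = FALSE)
  } else {
    ntfLen <- sample(cf$ntfLenRange[1]:cf$ntfLenRange[2], 1)
    ntf <- .randomChars(ntfLen, .loopComposition)
    domains <- data.frame(domain = character(0), start = integer(0),
                          end = integer(0), stringsAsFactors = FALSE)
  }
  chars <- ntf
  helixMask <- rep(FALSE, length(ntf))
  tm <- matrix(0L, 7, 2, dimnames = list(NULL, c("start", "end")))
  for (h in 1:7) {
    tm[h, 1] <- length(chars) + 1L
    chars <- c(chars, sample(pool, cf$helixLen, replace = TRUE))
    tm[h, 2] <- length(chars)
    helixMask <- c(helixMask, rep(TRUE, cf$helixLen))
    if (h < 7) {
      chars <- c(chars, .randomChars(loops[h], .loopComposition))
      helixMask <- c(helixMask, rep(FALSE, loops[h]))
    }
  }
  chars <- c(chars, .randomChars(ctermLen, .loopComposition))
  helixMask <- c(helixMask, rep(FALSE, ctermLen))
  list(chars = chars, helixMask = helixMask, tm = tm, domains = domains)
}

# sample a Dollo history (origin branch + loss branches) on the tree such
# that the history is recoverable: the origin is the MRCA of the surviving
# tips and every loss clade is genome-backed
.sampleHistory <- function(tree, tipsUnder, parents, genomeTips, maxLosses) {
  ntip <- length(tree$tip.label)
  nodes <- seq_len(max(tree$edge))
  cand <- nodes[vapply(tipsUnder, length, integer(1)) >= 4]
  origin <- if (length(cand) > 1) sample(cand, 1) else cand
  under <- tipsUnder[[origin]]
  losses <- integer(0)
  lost <- integer(0)
  nLoss <- sample(0:maxLosses, 1)
  below <- setdiff(which(vapply(seq_along(tipsUnder), function(nd)
    all(tipsUnder[[nd]] %in% under) && nd != origin, logical(1))), 0L)
  below <- below[vapply(below, function(nd) {
    tu <- tipsUnder[[nd]]
    length(tu) <= length(under) %/% 2 && all(tu %in% genomeTips)
  }, logical(1))]
  for (k in seq_len(nLoss)) {
    ok <- below[vapply(below, function(nd) {
      tu <- tipsUnder[[nd]]
      if (any(tu %in% lost)) return(FALSE)
      # losses must be maximal-recoverable: parent clade keeps a present tip
      remaining <- setdiff(under, c(lost, tu))
      if (length(remaining) < 2) return(FALSE)
      par <- parents[nd]
      if (!is.na(par) && !any(setdiff(tipsUnder[[par]], tu) %in% remaining))
        return(FALSE)
      mrca <- if (length(remaining) == 1) remaining
              else ape::getMRCA(tree, remaining)
      identical(mrca, origin)
    }, logical(1))]
    if (!length(ok)) break
    pick <- if (length(ok) > 1) sample(ok, 1) else ok
    losses <- c(losses, pick)
    lost <- c(lost, tipsUnder[[pick]])
  }
  list(origin = origin, losses = sort(losses),
       present = setdiff(under, lost))
}

#' Generate a synthetic GPCRome study with full ground truth
#'
#' Simulates predicted proteomes for a clade of species: GPCR families are
#' evolved from family ancestors along a species tree under a known
#' origin/loss history (per-branch substitution, hydropathy-class-preserving
#' inside helices), decoys are planted (soluble proteins, 5-helix membrane
#' proteins derived from members, 7TM-only fragments, near-identical
#' isoform twins), and the screening inputs of a real study are emitted:
#' a family-profile library built from diverged reference homolog seed
#' alignments, a reference GPCR set for homology validation, and HRM/GAIN
#' domain profiles. Byte-identical output for a fixed seed.
#'
#' @param config list of settings; see \code{\link{defaultSyntheticConfig}}.
#'   Entries override the defaults. An explicit \code{histories} list
#'   (per-family \code{origin} and \code{losses} branch labels) is
#'   validated and used as given.
#' @param seed generator seed.
#' @return list with \code{proteomes} (list of \linkS4class{Proteome}),
#'   \code{truth} (\linkS4class{SyntheticTruth}), \code{familyProfiles}
#'   (list of \linkS4class{ProfileHMM}), \code{referenceGPCRs} (named
#'   AAStringSet), \code{domainProfiles} (HRM and GAIN
#'   \linkS4class{ProfileHMM}s) and \code{taxa} (named source vector).
#' @export
simulateGPCRome <- function(config = list(), seed = 1789) {
  cf <- utils::modifyList(defaultSyntheticConfig(), config)
  localSeed(seed, .simulateGPCRome(cf, seed))
}

.simulateGPCRome <- function(cf, seed) {
  bg <- cf$background[AA20] / sum(cf$background[AA20])
  tree <- ape::rtree(cf$nSpecies,
                     tip.label = sprintf("sp%02d", seq_len(cf$nSpecies)))
  # rescale so the deepest root-to-tip path is 1 expected unit
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree <- readSpeciesTree(tree)
  ntip <- length(tree$tip.label)
  parents <- .parents(tree)
  tipsUnder <- .tipsUnder(tree)
  trTips <- sort(sample(seq_len(ntip), cf$nTranscriptome))
  taxa <- stats::setNames(rep("genome", ntip), tree$tip.label)
  taxa[trTips] <- "transcriptome"
  genomeTips <- which(taxa == "genome")

  # shared ectodomain ancestors (one HRM, one GAIN) across aGPCR families
  hrmAnc <- .randomChars(70, .loopComposition)
  gainAnc <- .randomChars(250, .loopComposition)

  registry <- list()
  families <- list()
  proteomeRecs <- stats::setNames(
    replicate(ntip, list(ids = character(0), seqs = character(0)),
              simplify = FALSE), tree$tip.label)
  addRecord <- function(sp, id, seq) {
    proteomeRecs[[sp]]$ids <<- c(proteomeRecs[[sp]]$ids, id)
    proteomeRecs[[sp]]$seqs <<- c(proteomeRecs[[sp]]$seqs, seq)
  }
  memberSeqs <- character(0)   # flat lookup for decoy derivation
  memberMeta <- list()

  refSeqs <- character(0)
  familyProfiles <- list()

  edgesPre <- tree$edge   # cladewise: parents before children

  for (f in seq_len(cf$nFamilies)) {
    fam <- sprintf("fam%02d", f)
    aGPCR <- f <= cf$nAGPCRFamilies
    pool <- sort(sample(HYDROPHOBIC_AA, cf$helixPoolSize))
    anc <- .familyAncestor(cf, aGPCR, pool, hrmAnc, gainAnc)

    if (!is.null(cf$histories)) {
      h <- cf$histories[[f]]
      origin <- .nodeNumber(tree, h$origin)
      losses <- vapply(h$losses, function(x) .nodeNumber(tree, x),
                       integer(1))
      under <- tipsUnder[[origin]]
      for (l in losses) {
        if (!all(tipsUnder[[l]] %in% under) || l == origin)
          stop("infeasible config: loss branch '", .nodeLabel(tree, l),
               "' is not under origin '", h$origin, "' for ", fam)
      }
      lost <- unlist(tipsUnder[losses])
      hist <- list(origin = origin, losses = sort(unname(losses)),
                   present = setdiff(under, lost))
    } else {
      hist <- .sampleHistory(tree, tipsUnder, parents, genomeTips,
                             cf$maxLosses)
    }

    # evolve the ancestor down the tree (per-branch substitution)
    nodeSeq <- vector("list", max(tree$edge))
    nodeSeq[[ntip + 1L]] <- anc$chars
    for (i in seq_len(nrow(edgesPre))) {
      a <- edgesPre[i, 1]; b <- edgesPre[i, 2]
      p <- cf$divergence * tree$edge.length[i]
      nodeSeq[[b]] <- .mutateChars(nodeSeq[[a]], p, anc$helixMask, pool)
    }

    size <- max(sample(cf$familySizeRange[1]:cf$familySizeRange[2], 1),
                length(hist$present))
    extra <- size - length(hist$present)
    alloc <- rep(1L, length(hist$present))
    if (extra > 0) {
      more <- table(factor(sample(seq_along(hist$present), extra,
                                  replace = TRUE),
                           levels = seq_along(hist$present)))
      alloc <- alloc + as.integer(more)
    }

    members <- list()
    for (k in seq_along(hist$present)) {
      tp <- hist$present[k]
      sp <- tree$tip.label[tp]
      for (m in seq_len(alloc[k])) {
        chars <- .mutateChars(nodeSeq[[tp]], cf$memberDivergence,
                              anc$helixMask, pool)
        id <- sprintf("%s_%s_m%02d", sp, fam, m)
        seq <- paste(chars, collapse = "")
        addRecord(sp, id, seq)
        memberSeqs[id] <- seq
        memberMeta[[id]] <- list(species = sp, family = fam,
                                 tm = anc$tm, domains = anc$domains,
                                 aGPCR = aGPCR)
        members[[id]] <- data.frame(
          record_id = id, species = sp,
          tm_intervals = paste(anc$tm[, 1], anc$tm[, 2], sep = "-",
                               collapse = ";"),
          domains = if (nrow(anc$domains))
            paste(anc$domains$domain, anc$domains$start, anc$domains$end,
                  sep = ":", collapse = ";") else "",
          stringsAsFactors = FALSE)
        registry[[id]] <- data.frame(
          record_id = id, species = sp, type = "gpcr", family = fam,
          partner = NA_character_, stringsAsFactors = FALSE)
      }
    }

    # reference homologs (the biased seed set standing in for the
    # published family profiles) and the family profile built from them
    refs <- vapply(seq_len(cf$refsPerFamily), function(r) {
      paste(.mutateChars(anc$chars, cf$refDivergence, anc$helixMask, pool),
            collapse = "")
    }, character(1))
    names(refs) <- sprintf("ref_%s_%d", fam, seq_along(refs))
    refSeqs <- c(refSeqs, refs)
    tmRegion <- substring(refs, anc$tm[1, 1], anc$tm[7, 2])
    familyProfiles[[fam]] <- buildProfileHMM(tmRegion, name = fam,
                                             background = bg)

    families[[fam]] <- list(
      ancestor = paste(anc$chars, collapse = ""),
      helixMask = anc$helixMask,
      tm = anc$tm, domains = anc$domains, pool = pool,
      origin = .nodeLabel(tree, hist$origin),
      losses = as.character(.nodeLabel(tree, hist$losses)),
      members = do.call(rbind, members))
  }

  # isoform twins: truncated, lightly edited copies of members
  memberIds <- names(memberSeqs)
  nIso <- floor(cf$isoformRate * length(memberIds))
  isoOf <- if (nIso > 0) sort(sample(memberIds, nIso)) else character(0)
  for (src in isoOf) {
    meta <- memberMeta[[src]]
    seq <- memberSeqs[[src]]
    # C-terminal truncation that keeps the 7TM core intact
    cut <- max(floor(0.88 * nchar(seq)), meta$tm[7, 2] + 3L)
    chars <- strsplit(substring(seq, 1, cut), "")[[1]]
    nEd <- max(1L, floor(0.01 * cut))
    posEd <- sample(cut, nEd)
    chars[posEd] <- sample(AA20, nEd, replace = TRUE, prob = bg)
    id <- paste0(src, "_iso")
    addRecord(meta$species, id, paste(chars, collapse = ""))
    registry[[id]] <- data.frame(
      record_id = id, species = meta$species, type = "isoform",
      family = meta$family, partner = src, stringsAsFactors = FALSE)
  }

  # decoys
  dk <- cf$decoys
  for (d in seq_len(dk[["soluble"]])) {
    sp <- tree$tip.label[sample(ntip, 1)]
    id <- sprintf("%s_sol%04d", sp, d)
    addRecord(sp, id, randomAASeq(sample(150:450, 1), bg))
    registry[[id]] <- data.frame(
      record_id = id, species = sp, type = "soluble",
      family = NA_character_, partner = NA_character_,
      stringsAsFactors = FALSE)
  }
  # 5-helix membrane proteins: members with helices 6-7 excised, so they
  # keep homology to the family but fail the helix-count rule
  for (d in seq_len(dk[["few_helix"]])) {
    src <- sample(memberIds, 1)
    meta <- memberMeta[[src]]
    sp <- tree$tip.label[sample(ntip, 1)]
    seq <- memberSeqs[[src]]
    cutFrom <- meta$tm[6, 1] - sample(3:8, 1)
    cutTo <- meta$tm[7, 2] + sample(3:8, 1)
    id <- sprintf("%s_fh%04d", sp, d)
    addRecord(sp, id, paste0(substring(seq, 1, cutFrom - 1),
                             substring(seq, cutTo + 1, nchar(seq))))
    registry[[id]] <- data.frame(
      record_id = id, species = sp, type = "few_helix",
      family = meta$family, partner = src, stringsAsFactors = FALSE)
  }
  # fragments: bare 7TM regions of (long) adhesion-family members
  agIds <- memberIds[vapply(memberIds, function(i) memberMeta[[i]]$aGPCR,
                            logical(1))]
  fragSrc <- if (length(agIds)) agIds else memberIds
  for (d in seq_len(dk[["fragment"]])) {
    src <- sample(fragSrc, 1)
    meta <- memberMeta[[src]]
    sp <- tree$tip.label[sample(ntip, 1)]
    seq <- memberSeqs[[src]]
    a <- max(1L, meta$tm[1, 1] - sample(0:5, 1))
    b <- min(nchar(seq), meta$tm[7, 2] + sample(0:5, 1))
    id <- sprintf("%s_fr%04d", sp, d)
    addRecord(sp, id, substring(seq, a, b))
    registry[[id]] <- data.frame(
      record_id = id, species = sp, type = "fragment",
      family = meta$family, partner = src, stringsAsFactors = FALSE)
  }

  proteomes <- lapply(tree$tip.label, function(sp) {
    recs <- proteomeRecs[[sp]]
    ord <- order(recs$ids)
    Proteome(stats::setNames(recs$seqs[ord], recs$ids[ord]), species = sp,
             source = unname(taxa[sp]))
  })
  names(proteomes) <- tree$tip.label

  domainProfiles <- list(
    HRM = buildProfileHMM(vapply(1:6, function(i)
      paste(.mutateChars(hrmAnc, 0.15, rep(FALSE, length(hrmAnc)), NULL),
            collapse = ""), character(1)), name = "HRM", background = bg),
    GAIN = buildProfileHMM(vapply(1:6, function(i)
      paste(.mutateChars(gainAnc, 0.15, rep(FALSE, length(gainAnc)), NULL),
            collapse = ""), character(1)), name = "GAIN", background = bg))

  truth <- new("SyntheticTruth", tree = tree, families = families,
               registry = do.call(rbind, c(registry,
                                           list(stringsAsFactors = FALSE))),
               seed = as.integer(seed))
  refs <- Biostrings::AAStringSet(refSeqs)
  list(proteomes = proteomes, truth = truth,
       familyProfiles = familyProfiles, referenceGPCRs = refs,
       domainProfiles = domainProfiles, taxa = taxa)
}

#' Recovery metrics of pipeline outputs against planted truth
#'
#' Standard precision/recall/F1 of validated records against the planted
#' GPCR registry, adjusted Rand index of detected families against planted
#' families (matched by maximum member overlap), and origin/loss accuracy
#' of the inferred gain/loss map.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param validatedIds character vector of validated record ids.
#' @param clusters optional \linkS4class{ClusterSet} over validated
#'   records.
#' @param gainLoss optional \linkS4class{GainLossMap} whose family labels
#'   are cluster labels.
#' @return list with \code{precision}, \code{recall}, \code{f1},
#'   \code{ari} (NA without clusters), \code{originAccuracy},
#'   \code{lossAccuracy} (NA without a map), \code{familyMap} (cluster
#'   label -> planted family).
#' @export
truthMetrics <- function(truth, validatedIds, clusters = NULL,
                         gainLoss = NULL) {
  reg <- truth@registry
  planted <- reg$record_id[reg$type == "gpcr"]
  tp <- length(intersect(validatedIds, planted))
  precision <- if (length(validatedIds)) tp / length(validatedIds) else NA
  recall <- if (length(planted)) tp / length(planted) else NA
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) NA
        else 2 * precision * recall / (precision + recall)

  ari <- NA_real_
  familyMap <- NULL
  if (!is.null(clusters)) {
    ct <- clusterTable(clusters)
    # unclustered records count as singleton labels
    singles <- ct$cluster_label == "unclustered"
    ct$cluster_label[singles] <- paste0("u_", ct$record_id[singles])
    keep <- ct$record_id %in% planted
    truthFam <- reg$family[match(ct$record_id[keep], reg$record_id)]
    ari <- mclust::adjustedRandIndex(ct$cluster_label[keep], truthFam)
    # maximum-overlap assignment of cluster labels to planted families
    tb <- table(ct$cluster_label[keep], truthFam)
    familyMap <- character(0)
    if (nrow(tb)) {
      for (cl in rownames(tb)[order(-apply(tb, 1, max))]) {
        fams <- colnames(tb)[order(-tb[cl, ])]
        fams <- fams[!(fams %in% familyMap)]
        if (length(fams) && tb[cl, fams[1]] > 0)
          familyMap[cl] <- fams[1]
      }
    }
  }

  originAcc <- lossAcc <- NA_real_
  if (!is.null(gainLoss) && !is.null(familyMap)) {
    ev <- glEvents(gainLoss)
    okO <- okL <- logical(0)
    for (fam in names(truth@families)) {
      cl <- names(familyMap)[familyMap == fam]
      tf <- truth@families[[fam]]
      if (!length(cl)) { okO <- c(okO, FALSE); okL <- c(okL, FALSE); next }
      evf <- ev[ev$family == cl[1], , drop = FALSE]
      okO <- c(okO, identical(evf$branch[evf$event == "origin"], tf$origin))
      okL <- c(okL, setequal(evf$branch[evf$event == "loss"], tf$losses))
    }
    originAcc <- mean(okO)
    lossAcc <- mean(okL)
  }
  list(precision = precision, recall = recall, f1 = f1, ari = ari,
       originAccuracy = originAcc, lossAccuracy = lossAcc,
       familyMap = familyMap)
}
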