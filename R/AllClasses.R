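#' @import methods
#' @importFrom Rcpp evalCpp
#' @importClassesFrom Biostrings AAStringSet
#' @useDynLib GPCRome, .registration = TRUE
NULL

setOldClass("phylo")

#' Proteome: identified amino-acid sequences for one species
#'
#' A \code{Proteome} is an \linkS4class{AAStringSet} whose names are unique
#' record identifiers, annotated with the species it was predicted from and
#' its provenance (assembled genome vs transcriptome). Transcriptome-derived
#' proteomes carry weaker absence semantics downstream: failure to detect a
#' family there is reported as "not detected" rather than a true zero.
#'
#' @slot speciesName single species label shared by all records.
#' @slot provenance \code{"genome"} or \code{"transcriptome"}.
#' @export
setClass("Proteome",
  contains = "AAStringSet",
  representation(speciesName = "character", provenance = "character"),
  prototype(speciesName = NA_character_, provenance = "genome")
)

setValidity("Proteome", function(object) {
  msg <- character()
  ids <- names(object)
  if (length(object) > 0 && (is.null(ids) || anyDuplicated(ids)))
    msg <- c(msg, "record ids must be present and unique within a Proteome")
  if (length(object) > 0 && any(Biostrings::width(object) == 0L))
    msg <- c(msg, "sequences must be non-empty")
  if (length(object@provenance) != 1L ||
      !object@provenance %in% c("genome", "transcriptome"))
    msg <- c(msg, "provenance must be 'genome' or 'transcriptome'")
  if (length(object@speciesName) != 1L)
    msg <- c(msg, "speciesName must be a single string")
  if (length(msg)) msg else TRUE
})

#' ProfileHMM: match/insert/delete profile hidden Markov model
#'
#' Log-odds scoring engine used for both family screens and domain
#' annotation. Emissions and transitions are plain probabilities (every
#' emission row and outgoing-transition group sums to 1); scores are
#' reported in bits against the \code{background} composition.
#'
#' @slot name model name.
#' @slot matchEmissions L x 20 matrix of match-state emission probabilities.
#' @slot insertEmissions shared 20-vector of insert-state emissions.
#' @slot transitions L x 7 matrix with columns MM, MI, MD, IM, II, DM, DD.
#' @slot background 20-vector of background amino-acid frequencies.
#' @slot calibration fitted Gumbel null (\code{mu}, \code{beta}) for E-values,
#'   or an empty vector before \code{\link{calibrateProfile}} is run.
#' @export
setClass("ProfileHMM",
  representation(name = "character", matchEmissions = "matrix",
                 insertEmissions = "numeric", transitions = "matrix",
                 background = "numeric", calibration = "numeric"),
  prototype(calibration = numeric(0))
)

setValidity("ProfileHMM", function(object) {
  msg <- character()
  L <- nrow(object@matchEmissions)
  if (is.null(L) || L < 1) msg <- c(msg, "at least one match state required")
  if (ncol(object@matchEmissions) != 20L)
    msg <- c(msg, "matchEmissions must have 20 columns")
  if (length(object@insertEmissions) != 20L ||
      length(object@background) != 20L)
    msg <- c(msg, "insertEmissions and background must be 20-vectors")
  tol <- 1e-9
  if (L >= 1 && ncol(object@matchEmissions) == 20L) {
    if (any(abs(rowSums(object@matchEmissions) - 1) > tol))
      msg <- c(msg, "match emission rows must sum to 1")
    if (any(object@matchEmissions <= 0))
      msg <- c(msg, "all emission probabilities must be > 0")
  }
  if (!is.null(nrow(object@transitions)) && ncol(object@transitions) == 7L) {
    tm <- object@transitions
    grp <- cbind(tm[, 1] + tm[, 2] + tm[, 3],  # M ->
                 tm[, 4] + tm[, 5],            # I ->
                 tm[, 6] + tm[, 7])            # D ->
    if (any(abs(grp - 1) > tol))
      msg <- c(msg, "each outgoing-transition group must sum to 1")
    if (any(tm <= 0)) msg <- c(msg, "all transition probabilities must be > 0")
  } else msg <- c(msg, "transitions must be an L x 7 matrix")
  if (abs(sum(object@background) - 1) > tol)
    msg <- c(msg, "background must sum to 1")
  if (length(msg)) msg else TRUE
})

#' TMTopology: predicted transmembrane helices of one record
#'
#' @slot recordId sequence identifier.
#' @slot helices integer matrix with columns \code{start}, \code{end}
#'   (1-based inclusive), rows sorted and non-overlapping.
#' @export
setClass("TMTopology",
  representation(recordId = "character", helices = "matrix"))

setValidity("TMTopology", function(object) {
  h <- object@helices
  if (ncol(h) != 2L) return("helices must have two columns (start, end)")
  if (nrow(h) > 0) {
    if (any(h[, 1] > h[, 2])) return("helix start must be <= end")
    if (nrow(h) > 1 && any(h[-1, 1] <= h[-nrow(h), 2]))
      return("helices must be sorted and non-overlapping")
  }
  TRUE
})

#' CandidateLedger: audited bookkeeping of the GPCR screen
#'
#' Tracks every candidate from the two screening tracks through merging,
#' validation removals (with reason codes), and iterative refinement
#' additions. The set arithmetic of the stages is enforced by the class
#' validity method, so a ledger whose counts do not reconcile cannot be
#' constructed.
#'
#' @slot screenA hit table of the family-profile screen
#'   (record_id, species, profile, bit_score, evalue).
#' @slot screenB hit table of the topology-HMM screen.
#' @slot merged data.frame (record_id, species, round) of unique candidates.
#' @slot removed data.frame (record_id, species, reason, round); reasons are
#'   \code{no_gpcr_blast_hit}, \code{helix_count}, \code{isoform},
#'   \code{fragment}.
#' @slot validated data.frame (record_id, species, round).
#' @slot candidates AAStringSet of all candidate sequences seen so far.
#' @slot rounds number of completed validation/refinement rounds.
#' @export
setClass("CandidateLedger",
  representation(screenA = "data.frame", screenB = "data.frame",
                 merged = "data.frame", mergedPairs = "data.frame",
                 removed = "data.frame", validated = "data.frame",
                 candidates = "AAStringSet", rounds = "integer"),
  prototype(rounds = 0L,
            mergedPairs = data.frame(duplicate_id = character(0),
                                     kept_id = character(0),
                                     stringsAsFactors = FALSE)))

.reasonCodes <- c("no_gpcr_blast_hit", "helix_count", "isoform", "fragment")

setValidity("CandidateLedger", function(object) {
  msg <- character()
  idsA <- unique(object@screenA$record_id)
  idsB <- unique(object@screenB$record_id)
  m1 <- object@merged$record_id[object@merged$round == 1L]
  if (nrow(object@merged) > 0 && anyDuplicated(object@merged$record_id))
    msg <- c(msg, "merged candidate ids must be unique")
  if (length(idsA) || length(idsB)) {
    u <- union(idsA, idsB)
    nDup <- sum(object@mergedPairs$duplicate_id %in% u)
    if (length(m1) != length(u) - nDup)
      msg <- c(msg, "|merged| must equal |A| + |B| - |A intersect B|")
  }
  if (nrow(object@removed) > 0 &&
      !all(object@removed$reason %in% .reasonCodes))
    msg <- c(msg, "unknown removal reason code")
  if (length(intersect(object@validated$record_id,
                       object@removed$record_id)))
    msg <- c(msg, "validated and removed sets must be disjoint")
  for (r in seq_len(object@rounds)) {
    nm <- sum(object@merged$round == r)
    nv <- sum(object@validated$round == r)
    nr <- sum(object@removed$round == r)
    if (nm != nv + nr)
      msg <- c(msg, sprintf("round %d: |candidates| != |validated| + |removed|", r))
  }
  if (length(msg)) msg else TRUE
})

#' SimilarityGraph: all-vs-all significance-weighted sequence graph
#'
#' Undirected graph over sequence records; an edge carries attraction
#' weight \code{-log10(E)} of the better of the two pairwise search
#' directions and exists only when that E-value beats the cutoff.
#'
#' @slot nodes record ids.
#' @slot edges data.frame (id1, id2, weight).
#' @slot cutoff E-value cutoff used for edge inclusion.
#' @export
setClass("SimilarityGraph",
  representation(nodes = "character", edges = "data.frame",
                 cutoff = "numeric"))

setValidity("SimilarityGraph", function(object) {
  e <- object@edges
  if (nrow(e) == 0) return(TRUE)
  if (any(e$id1 == e$id2)) return("self-edges are not allowed")
  if (!all(c(e$id1, e$id2) %in% object@nodes))
    return("edge endpoints must be graph nodes")
  if (any(e$weight <= -log10(object@cutoff) - 1e-9))
    return("kept edges must have weight above -log10(cutoff)")
  key <- paste(pmin(e$id1, e$id2), pmax(e$id1, e$id2))
  if (anyDuplicated(key)) return("duplicate undirected edges")
  TRUE
})

#' ClusterSet: convex clusters (families) plus unclustered records
#'
#' @slot clusters named list, label -> member record ids (each of size
#'   at least the min_size used at detection).
#' @slot unclustered record ids assigned to no cluster.
#' @export
setClass("ClusterSet",
  representation(clusters = "list", unclustered = "character"))

setValidity("ClusterSet", function(object) {
  all_ids <- c(unlist(object@clusters, use.names = FALSE), object@unclustered)
  if (anyDuplicated(all_ids))
    return("clusters and unclustered must partition the node set")
  TRUE
})

#' PresenceAbsenceMatrix: family x taxon counts with missing-data semantics
#'
#' Counts of detected members per family and taxon. A zero is a genuine
#' absence and is only allowed for genome-backed taxa; transcriptome-only
#' taxa store \code{NA} ("not detected") because non-expression cannot be
#' distinguished from gene loss there.
#'
#' @slot counts integer matrix, families x taxa; \code{NA} = not detected.
#' @slot taxonSource named character, \code{"genome"} or
#'   \code{"transcriptome"} per taxon.
#' @export
setClass("PresenceAbsenceMatrix",
  representation(counts = "matrix", taxonSource = "character"))

setValidity("PresenceAbsenceMatrix", function(object) {
  msg <- character()
  cn <- colnames(object@counts)
  if (is.null(cn) || !setequal(cn, names(object@taxonSource)))
    msg <- c(msg, "taxonSource must name every matrix column")
  else {
    src <- object@taxonSource[cn]
    tr <- cn[src == "transcriptome"]
    if (length(tr) &&
        any(object@counts[, tr, drop = FALSE] == 0L, na.rm = TRUE))
      msg <- c(msg, "transcriptome taxa must use NA (not detected), never 0")
  }
  if (!all(object@taxonSource %in% c("genome", "transcriptome")))
    msg <- c(msg, "taxonSource entries must be 'genome' or 'transcriptome'")
  if (length(msg)) msg else TRUE
})

#' GainLossMap: Dollo origins and losses of families on a species tree
#'
#' One origin branch per family (Dollo: a family is gained once) and a
#' minimal set of loss branches explaining all genome-backed absences.
#' Branches are identified by the label of their child node.
#'
#' @slot events data.frame (family, branch, event) with event one of
#'   \code{"origin"}, \code{"loss"}.
#' @slot tree the rooted species tree the branches refer to.
#' @export
setClass("GainLossMap",
  representation(events = "data.frame", tree = "phylo"))

setValidity("GainLossMap", function(object) {
  ev <- object@events
  if (nrow(ev) == 0) return(TRUE)
  if (!all(ev$event %in% c("origin", "loss"))) return("unknown event type")
  no <- tapply(ev$event == "origin", ev$family, sum)
  if (any(no != 1L)) return("exactly one origin per family required")
  TRUE
})

#' SyntheticTruth: complete ground truth of a simulated GPCRome study
#'
#' @slot tree the species tree the histories were generated on.
#' @slot families per-family list: ancestor sequence, origin/loss branches,
#'   member table with planted helix intervals and domain segments.
#' @slot registry data.frame of every planted record (record_id, species,
#'   class, family, type) where type is \code{gpcr} or a decoy type
#'   (\code{soluble}, \code{few_helix}, \code{fragment}, \code{isoform}).
#' @slot seed the generator seed.
#' @export
setClass("SyntheticTruth",
  representation(tree = "phylo", families = "list", registry = "data.frame",
                 seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  if (nrow(object@registry) > 0 &&
      anyDuplicated(object@registry$record_id))
    return("every planted record must appear in exactly one registry row")
  TRUE
})
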