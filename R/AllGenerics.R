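#' @include AllClasses.R
NULL

#' Accessors for GPCRome classes
#'
#' Small accessor generics used across the package: \code{speciesName} and
#' \code{provenance} of a \linkS4class{Proteome}; \code{records} as a
#' per-record summary table; \code{nHelices} and \code{helices} of a
#' \linkS4class{TMTopology}; \code{ledgerCounts} and \code{finalIds} of a
#' \linkS4class{CandidateLedger}; \code{clusterMembers} and
#' \code{unclustered} of a \linkS4class{ClusterSet}; \code{pamCounts} of a
#' \linkS4class{PresenceAbsenceMatrix}; \code{glEvents} of a
#' \linkS4class{GainLossMap}.
#'
#' @param x an object of the documented class.
#' @return See the individual methods.
#' @name accessors
#' @aliases speciesName provenance records nHelices helices ledgerCounts
#'   finalIds clusterMembers unclustered pamCounts glEvents
NULL

#' @rdname accessors
#' @export
setGeneric("speciesName", function(x) standardGeneric("speciesName"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("nHelices", function(x) standardGeneric("nHelices"))
#' @rdname accessors
#' @export
setGeneric("helices", function(x) standardGeneric("helices"))
#' @rdname accessors
#' @export
setGeneric("ledgerCounts", function(x) standardGeneric("ledgerCounts"))
#' @rdname accessors
#' @export
setGeneric("finalIds", function(x) standardGeneric("finalIds"))
#' @rdname accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))
#' @rdname accessors
#' @export
setGeneric("unclustered", function(x) standardGeneric("unclustered"))
#' @rdname accessors
#' @export
setGeneric("pamCounts", function(x) standardGeneric("pamCounts"))
#' @rdname accessors
#' @export
setGeneric("glEvents", function(x) standardGeneric("glEvents"))

#' @rdname accessors
setMethod("speciesName", "Proteome", function(x) x@speciesName)
#' @rdname accessors
setMethod("provenance", "Proteome", function(x) x@provenance)

#' @rdname accessors
setMethod("records", "Proteome", function(x) {
  data.frame(id = as.character(names(x)),
             species = rep(x@speciesName, length(x)),
             length = Biostrings::width(x),
             source = rep(x@provenance, length(x)),
             stringsAsFactors = FALSE, row.names = NULL)
})

#' @rdname accessors
setMethod("nHelices", "TMTopology", function(x) nrow(x@helices))
#' @rdname accessors
setMethod("helices", "TMTopology", function(x) x@helices)

#' @rdname accessors
setMethod("ledgerCounts", "CandidateLedger", function(x) {
  data.frame(
    stage = c("screen_family", "screen_topology", "merged_round1", "removed",
              "validated_round1", "refinement_additions", "final"),
    n = c(length(unique(x@screenA$record_id)),
          length(unique(x@screenB$record_id)),
          sum(x@merged$round == 1L),
          nrow(x@removed),
          sum(x@validated$round == 1L),
          sum(x@validated$round > 1L),
          nrow(x@validated)),
    stringsAsFactors = FALSE)
})

#' @rdname accessors
setMethod("finalIds", "CandidateLedger", function(x) x@validated$record_id)

#' @rdname accessors
setMethod("clusterMembers", "ClusterSet", function(x) x@clusters)
#' @rdname accessors
setMethod("unclustered", "ClusterSet", function(x) x@unclustered)
#' @rdname accessors
setMethod("pamCounts", "PresenceAbsenceMatrix", function(x) x@counts)
#' @rdname accessors
setMethod("glEvents", "GainLossMap", function(x) x@events)

setMethod("show", "Proteome", function(object) {
  cat(sprintf("Proteome of %s (%s): %d records\n", object@speciesName,
              object@provenance, length(object)))
})

setMethod("show", "ProfileHMM", function(object) {
  cat(sprintf("ProfileHMM '%s': %d match states%s\n", object@name,
              nrow(object@matchEmissions),
              if (length(object@calibration)) ", calibrated" else ""))
})

setMethod("show", "TMTopology", function(object) {
  cat(sprintf("TMTopology %s: %d helices\n", object@recordId,
              nrow(object@helices)))
  if (nrow(object@helices))
    cat(" ", paste(object@helices[, 1], object@helices[, 2], sep = "-",
                   collapse = "; "), "\n")
})

setMethod("show", "CandidateLedger", function(object) {
  cat("CandidateLedger\n")
  print(ledgerCounts(object), row.names = FALSE)
})

setMethod("show", "SimilarityGraph", function(object) {
  cat(sprintf("SimilarityGraph: %d nodes, %d edges (E < %g)\n",
              length(object@nodes), nrow(object@edges), object@cutoff))
})

setMethod("show", "ClusterSet", function(object) {
  sizes <- vapply(object@clusters, length, integer(1))
  cat(sprintf("ClusterSet: %d clusters (sizes %s), %d unclustered\n",
              length(object@clusters),
              paste(sizes, collapse = ", "), length(object@unclustered)))
})

setMethod("show", "PresenceAbsenceMatrix", function(object) {
  cat(sprintf("PresenceAbsenceMatrix: %d families x %d taxa (%d genome, %d transcriptome)\n",
              nrow(object@counts), ncol(object@counts),
              sum(object@taxonSource == "genome"),
              sum(object@taxonSource == "transcriptome")))
})

setMethod("show", "GainLossMap", function(object) {
  ev <- object@events
  cat(sprintf("GainLossMap: %d families, %d losses\n",
              sum(ev$event == "origin"), sum(ev$event == "loss")))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d species, %d families, %d planted records (seed %d)\n",
              length(object@tree$tip.label), length(object@families),
              nrow(object@registry), object@seed))
})
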