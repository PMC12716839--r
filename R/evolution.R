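#' @include AllClasses.R utils.R
NULL

#' Read / label a rooted species tree
#'
#' Reads a Newick species tree and assigns deterministic internal node
#' labels (\code{N1}, \code{N2}, ... in node-number order) when absent, so
#' branches can be identified by the label of their child node. The branch
#' above the root carries the root node's label.
#'
#' @param x a Newick file path, a Newick string, or a \code{phylo} object.
#' @return a labeled \code{phylo} tree.
#' @export
readSpeciesTree <- function(x) {
  tree <- if (inherits(x, "phylo")) x
          else if (file.exists(x)) ape::read.tree(x)
          else ape::read.tree(text = x)
  if (is.null(tree)) stop("could not parse species tree")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  nInt <- tree$Nnode
  if (is.null(tree$node.label) || any(tree$node.label == "") ||
      anyDuplicated(c(tree$tip.label, tree$node.label)))
    tree$node.label <- paste0("N", seq_len(nInt))
  tree
}

#' Write a species tree as Newick
#'
#' @param tree a \code{phylo} object.
#' @param path output file.
#' @export
writeSpeciesTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# label of a node number (tip or internal)
.nodeLabel <- function(tree, node) {
  ntip <- length(tree$tip.label)
  vapply(as.integer(node), function(nd) {
    if (nd <= ntip) tree$tip.label[nd] else tree$node.label[nd - ntip]
  }, character(1))
}

.nodeNumber <- function(tree, label) {
  ntip <- length(tree$tip.label)
  i <- match(label, tree$tip.label)
  ifelse(is.na(i), match(label, tree$node.label) + ntip, i)
}

# parent lookup vector: parent[node] = parent node number (NA for root)
.parents <- function(tree) {
  p <- rep(NA_integer_, max(tree$edge))
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

# tip numbers descending from each node (list indexed by node number)
.tipsUnder <- function(tree) {
  ntip <- length(tree$tip.label)
  out <- vector("list", max(tree$edge))
  for (t in seq_len(ntip)) out[[t]] <- t
  edge <- stats::reorder(tree, "postorder")$edge  # children before parents
  for (i in seq_len(nrow(edge))) {
    a <- edge[i, 1]; b <- edge[i, 2]
    out[[a]] <- c(out[[a]], out[[b]])
  }
  out
}

#' Build the family x taxon presence/absence matrix
#'
#' Counts assigned members per family and taxon. Zero counts become true
#' absences for genome-backed taxa but "not detected" (\code{NA}) for
#' transcriptome-only taxa, where failure to detect cannot be separated
#' from non-expression.
#'
#' @param assignments data.frame (record_id, species, family); rows with
#'   family \code{"unclustered"} are ignored.
#' @param taxa named character vector: taxon -> \code{"genome"} or
#'   \code{"transcriptome"} (or a data.frame with columns taxon, source).
#' @return a \linkS4class{PresenceAbsenceMatrix}.
#' @export
buildPresenceAbsence <- function(assignments, taxa) {
  if (is.data.frame(taxa))
    taxa <- stats::setNames(taxa$source, taxa$taxon)
  a <- assignments[assignments$family != "unclustered", , drop = FALSE]
  missing <- setdiff(unique(a$species), names(taxa))
  if (length(missing))
    stop("taxon missing metadata: ", paste(missing, collapse = ", "))
  fams <- sort(unique(a$family))
  counts <- matrix(0L, length(fams), length(taxa),
                   dimnames = list(fams, names(taxa)))
  if (nrow(a)) {
    tb <- table(factor(a$family, levels = fams),
                factor(a$species, levels = names(taxa)))
    counts[] <- as.integer(tb)
  }
  nd <- names(taxa)[taxa == "transcriptome"]
  for (tx in nd) counts[counts[, tx] == 0L, tx] <- NA_integer_
  new("PresenceAbsenceMatrix", counts = counts,
      taxonSource = taxa[colnames(counts)])
}

#' Dollo parsimony mapping of family origins and losses
#'
#' Under Dollo parsimony each family is gained exactly once: the origin is
#' placed on the branch above the most recent common ancestor of all tips
#' carrying the family, and losses are the minimal set of branches below
#' the origin explaining every constrained absence. Genome-backed zeros
#' always constrain; "not detected" transcriptome entries constrain
#' nothing under \code{missingPolicy = "ignore"} (the default) or count as
#' absences under \code{"as_absent"}.
#'
#' @param pam a \linkS4class{PresenceAbsenceMatrix}.
#' @param tree a labeled rooted species tree covering all matrix taxa
#'   (\code{\link{readSpeciesTree}}).
#' @param missingPolicy \code{"ignore"} or \code{"as_absent"}.
#' @return a \linkS4class{GainLossMap}.
#' @export
dolloMap <- function(pam, tree, missingPolicy = c("ignore", "as_absent")) {
  missingPolicy <- match.arg(missingPolicy)
  tree <- readSpeciesTree(tree)
  counts <- pam@counts
  if (!all(colnames(counts) %in% tree$tip.label))
    stop("matrix taxa must be a subset of tree tips")
  ntip <- length(tree$tip.label)
  parents <- .parents(tree)
  tipsUnder <- .tipsUnder(tree)
  root <- ntip + 1L

  events <- data.frame(family = character(0), branch = character(0),
                       event = character(0), stringsAsFactors = FALSE)
  for (fam in rownames(counts)) {
    row <- counts[fam, ]
    presentTaxa <- names(row)[!is.na(row) & row > 0L]
    if (!length(presentTaxa))
      stop("family '", fam, "' has zero present tips")
    absentTaxa <- names(row)[!is.na(row) & row == 0L]
    if (missingPolicy == "as_absent")
      absentTaxa <- c(absentTaxa, names(row)[is.na(row)])
    presentTips <- match(presentTaxa, tree$tip.label)
    absentTips <- match(absentTaxa, tree$tip.label)

    origin <- if (length(presentTips) == 1L) presentTips
              else ape::getMRCA(tree, presentTips)
    underOrigin <- tipsUnder[[origin]]
    losses <- integer(0)
    for (tp in intersect(absentTips, underOrigin)) {
      cur <- tp
      repeat {
        par <- parents[cur]
        if (is.na(par) || par == origin) break
        if (any(tipsUnder[[par]] %in% presentTips)) break
        cur <- par
      }
      losses <- c(losses, cur)
    }
    losses <- sort(unique(losses))
    events <- rbind(events, data.frame(
      family = fam,
      branch = c(.nodeLabel(tree, origin), .nodeLabel(tree, losses)),
      event = c("origin", rep("loss", length(losses))),
      stringsAsFactors = FALSE))
  }
  rownames(events) <- NULL
  new("GainLossMap", events = events, tree = tree)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining agglomeration (deterministic tie-break by
#' index, as implemented in ape).
#'
#' @param dist symmetric distance matrix with zero diagonal, at least 3
#'   taxa.
#' @return unrooted \code{phylo} tree.
#' @export
njTree <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) < 3) stop("at least 3 taxa required")
  if (any(abs(dist - t(dist)) > 1e-9) || any(diag(dist) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  ape::nj(dist)
}

# pairwise 1 - fractional identity over columns where both sequences carry
# a canonical residue (no rate correction: desk-scale distance)
.alnDistance <- function(mat) {
  n <- nrow(mat)
  ok <- matrix(mat %in% AA20, n, ncol(mat))
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- ok[i, ] & ok[j, ]
      d[i, j] <- d[j, i] <-
        if (!any(both)) 1 else mean(mat[i, both] != mat[j, both])
    }
  }
  d
}

#' Alignment distance matrix (1 - fractional identity)
#'
#' @param aln named aligned sequences.
#' @return symmetric distance matrix.
#' @export
alnDistance <- function(aln) {
  aln <- toupper(as.character(aln))
  mat <- do.call(rbind, strsplit(aln, ""))
  rownames(mat) <- names(aln)
  .alnDistance(mat)
}

#' Bootstrap split support for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement, recomputes the
#' mismatch-fraction distance and the neighbor-joining tree, and reports
#' the percentage of replicates supporting each internal node of the tree
#' built from the full alignment.
#'
#' @param aln named aligned sequences (>= 4).
#' @param nReps bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @return list with \code{tree} (NJ tree of the full alignment) and
#'   \code{support} (percent support per internal node, in
#'   \code{tree$node.label} order).
#' @export
bootstrapSupport <- function(aln, nReps = 100, seed = 1789) {
  stopifnot(nReps >= 1)
  aln <- toupper(as.character(aln))
  mat <- do.call(rbind, strsplit(aln, ""))
  rownames(mat) <- names(aln)
  mainTree <- njTree(.alnDistance(mat))
  bootTrees <- localSeed(seed, {
    lapply(seq_len(nReps), function(r) {
      cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      njTree(.alnDistance(mat[, cols, drop = FALSE]))
    })
  })
  class(bootTrees) <- "multiPhylo"
  cl <- ape::prop.clades(mainTree, bootTrees, rooted = FALSE)
  cl[is.na(cl)] <- 0
  list(tree = mainTree, support = 100 * cl / nReps)
}

#' Write presence/absence and gain/loss tables
#'
#' @param pam a \linkS4class{PresenceAbsenceMatrix}.
#' @param map a \linkS4class{GainLossMap}.
#' @param dir output directory; writes presence_absence.tsv (counts with
#'   \code{nd} for not-detected) and gain_loss_events.tsv
#'   (family, branch, event).
#' @export
writeEvolutionTSV <- function(pam, map, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- pam@counts
  chr <- matrix(as.character(m), nrow(m), dimnames = dimnames(m))
  chr[is.na(m)] <- "nd"
  df <- data.frame(family = rownames(chr), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeTSV(df, file.path(dir, "presence_absence.tsv"))
  writeTSV(map@events, file.path(dir, "gain_loss_events.tsv"))
  invisible(dir)
}
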