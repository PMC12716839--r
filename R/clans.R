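#' @include AllClasses.R pairwise.R
NULL

#' Build the all-vs-all similarity graph
#'
#' Computes optimal local alignment scores for every sequence pair passing
#' a seed-word prefilter, converts them to E-values, and keeps an
#' undirected edge with attraction weight \code{-log10(E)} whenever the
#' E-value beats the cutoff. The per-pair E-value is the minimum over the
#' two query directions; with a symmetric scoring system and pair-wise
#' search space the two directions coincide, so each pair is scored once.
#'
#' Two significance nulls are available. The default \code{"background"}
#' uses the generic Karlin-Altschul fit; because multi-spanning membrane
#' proteins are hydrophobic-rich, unrelated 7TM regions then connect by
#' weak edges, exactly as the published cluster maps show faint
#' inter-family lines, and the attraction-value limit of the cluster
#' search separates families from that background. The
#' \code{"shuffled"} null refits the Gumbel on composition-preserving
#' shuffles of the input sequences themselves (composition-based
#' statistics), which removes those compositional edges entirely.
#'
#' @param seqs named \code{AAStringSet} (typically extracted 7TM regions);
#'   at least 2 sequences.
#' @param evalueCutoff edge-inclusion cutoff (default 1e-6; subfamily-level
#'   analyses use 1e-12 or 1e-20).
#' @param matrix,gapOpen,gapExt scoring system (BLOSUM62, 11, 1).
#' @param wordSize,minShared seed-word prefilter: pairs sharing fewer than
#'   \code{minShared} words of length \code{wordSize} are not aligned.
#' @param null \code{"background"} (default) or \code{"shuffled"}
#'   (composition-corrected).
#' @param nullPairs,nullSeed shuffled-null fit: number of shuffled pairs
#'   and RNG seed.
#' @return a \linkS4class{SimilarityGraph}.
#' @export
buildSimilarityGraph <- function(seqs, evalueCutoff = 1e-6,
                                 matrix = "BLOSUM62", gapOpen = 11,
                                 gapExt = 1, wordSize = 4, minShared = 2,
                                 null = c("background", "shuffled"),
                                 nullPairs = 200, nullSeed = 1789) {
  null <- match.arg(null)
  stopifnot(length(seqs) >= 2)
  ids <- names(seqs)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  chars <- as.character(seqs)
  sub <- .subMatrix(matrix)
  ka <- if (null == "background") {
    karlinAltschulParams(matrix, gapOpen, gapExt)
  } else {
    .shuffledNull(chars, sub, gapOpen, gapExt, nullPairs, nullSeed)
  }
  kmerSets <- lapply(chars, seqKmers, k = wordSize)
  n <- length(chars)
  lens <- nchar(chars)
  e1 <- character(0); e2 <- character(0); ww <- numeric(0)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    shared <- vapply(js, function(j)
      sum(kmerSets[[i]] %in% kmerSets[[j]]) >= minShared, logical(1))
    js <- js[shared]
    if (!length(js)) next
    scores <- as.numeric(Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(chars[js]), chars[i], type = "local",
      substitutionMatrix = sub, gapOpening = gapOpen,
      gapExtension = gapExt, scoreOnly = TRUE))
    ev <- .kaEvalue(scores, lens[i], lens[js], ka)
    keep <- ev < evalueCutoff
    if (any(keep)) {
      e1 <- c(e1, rep(ids[i], sum(keep)))
      e2 <- c(e2, ids[js[keep]])
      ww <- c(ww, -log10(ev[keep]))
    }
  }
  new("SimilarityGraph", nodes = ids,
      edges = data.frame(id1 = e1, id2 = e2, weight = ww,
                         stringsAsFactors = FALSE),
      cutoff = evalueCutoff)
}

# Gumbel null of local scores between composition-preserving shuffles of
# the input sequences; returns Karlin-Altschul-style (lambda, K)
.shuffledNull <- function(chars, sub, gapOpen, gapExt, nPairs, seed) {
  n <- length(chars)
  localSeed(seed, {
    i <- sample.int(n, nPairs, replace = TRUE)
    j <- sample.int(n, nPairs, replace = TRUE)
    shuf <- function(s) paste(sample(strsplit(s, "")[[1]]), collapse = "")
    scores <- vapply(seq_len(nPairs), function(k) {
      as.numeric(Biostrings::pairwiseAlignment(
        shuf(chars[i[k]]), shuf(chars[j[k]]), type = "local",
        substitutionMatrix = sub, gapOpening = gapOpen,
        gapExtension = gapExt, scoreOnly = TRUE))
    }, numeric(1))
    g <- fitGumbelTail(scores)
    lambda <- 1 / g[["beta"]]
    K <- exp(lambda * g[["mu"]]) /
      (mean(nchar(chars[i])) * mean(nchar(chars[j])))
    c(lambda = lambda, K = K)
  })
}

#' Force-directed layout of a similarity graph
#'
#' CLANS-style iterative optimization: attraction along edges proportional
#' to weight times distance, uniform pairwise repulsion proportional to the
#' inverse distance, and a linearly cooling step size. Coordinates are
#' initialized uniformly in the unit cube; deterministic for a fixed seed.
#'
#' @param graph a \linkS4class{SimilarityGraph}.
#' @param cycles optimization cycles (the full-study setting is 20000;
#'   pipeline defaults use fewer because cluster detection does not depend
#'   on the layout).
#' @param dims 2 (default) or 3.
#' @param seed RNG seed for the initial configuration (default 1789).
#' @param attract,repulse,step0 force and cooling constants.
#' @return numeric matrix of coordinates, one row per node, rownames = ids.
#' @export
layoutGraph <- function(graph, cycles = 2000, dims = 2, seed = 1789,
                        attract = 1, repulse = 0.05, step0 = 0.05) {
  stopifnot(cycles >= 1, dims %in% c(2, 3))
  n <- length(graph@nodes)
  # initial coordinates are assigned per sorted node id, so the layout is
  # equivariant under node reordering / relabeling
  ord <- order(graph@nodes)
  initSorted <- localSeed(seed, matrix(stats::runif(n * dims), n, dims))
  init <- matrix(0, n, dims)
  init[ord, ] <- initSorted
  rownames(init) <- graph@nodes
  if (n == 1) return(init)
  # normalize attraction weights so force constants are scale-free
  w <- graph@edges$weight
  wn <- if (length(w)) w / max(w) else numeric(0)
  edges <- cbind(match(graph@edges$id1, graph@nodes),
                 match(graph@edges$id2, graph@nodes)) - 1L
  storage.mode(edges) <- "integer"
  out <- clans_layout_cpp(init, edges, wn, as.integer(cycles),
                          attract, repulse, step0)
  rownames(out) <- graph@nodes
  out
}

#' Detect convex clusters (GPCR families) in the similarity graph
#'
#' Operative convex-cluster rule: edges whose attraction is at least
#' \code{mean + sd_limit x SD} of all edge attractions are kept, and the
#' connected components of the kept subgraph with at least \code{minSize}
#' members become clusters; everything else is unclustered. As
#' \code{sdLimit} decreases toward -Inf this reduces to plain connected
#' components of size >= minSize.
#'
#' Cluster labels are assigned deterministically: decreasing size, ties by
#' the lexicographically smallest member id.
#'
#' @param graph a \linkS4class{SimilarityGraph}.
#' @param layout optional coordinates from \code{\link{layoutGraph}}
#'   (carried for downstream representative picking; not used by the
#'   component rule).
#' @param minSize minimum cluster size (default 4).
#' @param sdLimit attraction-value limit in standard deviations
#'   (default 0.5).
#' @return a \linkS4class{ClusterSet}.
#' @export
findConvexClusters <- function(graph, layout = NULL, minSize = 4,
                               sdLimit = 0.5) {
  e <- graph@edges
  if (nrow(e) == 0) {
    return(new("ClusterSet", clusters = list(),
               unclustered = graph@nodes))
  }
  thr <- if (is.infinite(sdLimit) && sdLimit < 0) -Inf
         else mean(e$weight) + sdLimit * stats::sd(e$weight)
  if (is.na(thr)) thr <- -Inf   # a single edge has no SD
  keep <- e$weight >= thr
  g <- igraph::graph_from_data_frame(
    e[keep, c("id1", "id2"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = graph@nodes))
  comp <- igraph::components(g)
  memb <- split(names(comp$membership), comp$membership)
  big <- memb[vapply(memb, length, integer(1)) >= minSize]
  big <- lapply(big, sort)
  ord <- order(-vapply(big, length, integer(1)),
               vapply(big, function(x) x[1], character(1)))
  big <- big[ord]
  names(big) <- if (length(big)) paste0("C", seq_along(big)) else character(0)
  new("ClusterSet", clusters = big,
      unclustered = sort(setdiff(graph@nodes,
                                 unlist(big, use.names = FALSE))))
}

#' Write graph, layout and cluster tables as TSV
#'
#' @param graph a \linkS4class{SimilarityGraph}.
#' @param layout coordinates from \code{\link{layoutGraph}}.
#' @param clusters a \linkS4class{ClusterSet}.
#' @param dir output directory (created if needed); writes edges.tsv,
#'   layout.tsv, clusters.tsv.
#' @export
writeClansTSV <- function(graph, layout, clusters, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTSV(graph@edges, file.path(dir, "edges.tsv"))
  lay <- data.frame(id = rownames(layout), layout, stringsAsFactors = FALSE)
  colnames(lay) <- c("id", c("x", "y", "z")[seq_len(ncol(layout))])
  writeTSV(lay, file.path(dir, "layout.tsv"))
  cl <- clusterTable(clusters)
  writeTSV(cl, file.path(dir, "clusters.tsv"))
  invisible(dir)
}

#' Cluster membership as a flat table
#'
#' @param clusters a \linkS4class{ClusterSet}.
#' @return data.frame (record_id, cluster_label) with "unclustered" rows
#'   last.
#' @export
clusterTable <- function(clusters) {
  cl <- clusters@clusters
  data.frame(
    record_id = c(unlist(cl, use.names = FALSE), clusters@unclustered),
    cluster_label = c(rep(names(cl), vapply(cl, length, integer(1))),
                      rep("unclustered", length(clusters@unclustered))),
    stringsAsFactors = FALSE)
}
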