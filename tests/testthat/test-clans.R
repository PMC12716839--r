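makeFamilies <- function(nFam = 2, size = 8, len = 120, div = 0.2,
                         seed = 67) {
  set.seed(seed)
  mutate <- function(s, p) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(ch)) < p)
    ch[hit] <- sample(GPCRome:::AA20, length(hit), replace = TRUE)
    paste(ch, collapse = "")
  }
  out <- character(0)
  for (f in seq_len(nFam)) {
    anc <- GPCRome:::randomAASeq(len)
    fam <- vapply(seq_len(size), function(i) mutate(anc, div), character(1))
    names(fam) <- sprintf("f%d_m%02d", f, seq_len(size))
    out <- c(out, fam)
  }
  Biostrings::AAStringSet(out)
}

test_that("similarity graph is symmetric, self-edge free, above-cutoff", {
  seqs <- makeFamilies()
  g <- buildSimilarityGraph(seqs, evalueCutoff = 1e-6)
  expect_s4_class(g, "SimilarityGraph")
  e <- g@edges
  expect_false(any(e$id1 == e$id2))
  key <- paste(pmin(e$id1, e$id2), pmax(e$id1, e$id2))
  expect_false(anyDuplicated(key) > 0)
  expect_true(all(e$weight > -log10(1e-6)))
})

test_that("an identical pair carries the maximal edge weight", {
  seqs <- makeFamilies(nFam = 1, size = 6, div = 0.3)
  seqs <- c(seqs, Biostrings::AAStringSet(stats::setNames(
    as.character(seqs[1]), "twin")))
  g <- buildSimilarityGraph(seqs)
  e <- g@edges
  twinEdge <- e$weight[(e$id1 == names(seqs)[1] & e$id2 == "twin") |
                       (e$id2 == names(seqs)[1] & e$id1 == "twin")]
  expect_equal(max(e$weight), twinEdge)
})

test_that("composition-corrected null leaves unrelated families unlinked", {
  seqs <- makeFamilies(nFam = 2, size = 8, div = 0.2)
  g <- buildSimilarityGraph(seqs, null = "shuffled")
  fam <- sub("_.*", "", g@nodes)
  e <- g@edges
  expect_equal(sum(sub("_.*", "", e$id1) != sub("_.*", "", e$id2)), 0L)
  # and within-family edges are present
  expect_gt(nrow(e), 0L)
})

test_that("two cliques separate in the layout by at least 3x", {
  seqs <- makeFamilies(nFam = 2, size = 6, div = 0.15, seed = 71)
  g <- buildSimilarityGraph(seqs)
  lay <- layoutGraph(g, cycles = 20000, seed = 1789)
  fam <- sub("_.*", "", rownames(lay))
  dists <- as.matrix(stats::dist(lay))
  same <- outer(fam, fam, "==") & upper.tri(dists)
  diff <- outer(fam, fam, "!=") & upper.tri(dists)
  expect_gt(mean(dists[diff]), 3 * mean(dists[same]))
})

test_that("layout is deterministic, order-invariant, single-node stable", {
  seqs <- makeFamilies(nFam = 1, size = 5)
  g <- buildSimilarityGraph(seqs)
  l1 <- layoutGraph(g, cycles = 200, seed = 5)
  l2 <- layoutGraph(g, cycles = 200, seed = 5)
  expect_identical(l1, l2)

  # permuting node order permutes coordinates identically
  perm <- sample(length(g@nodes))
  g2 <- new("SimilarityGraph", nodes = g@nodes[perm], edges = g@edges,
            cutoff = g@cutoff)
  l3 <- layoutGraph(g2, cycles = 200, seed = 5)
  expect_equal(l3[rownames(l1), ], l1)

  g1 <- new("SimilarityGraph", nodes = "only",
            edges = data.frame(id1 = character(0), id2 = character(0),
                               weight = numeric(0)), cutoff = 1e-6)
  init <- layoutGraph(g1, cycles = 100, seed = 7)
  expect_equal(dim(init), c(1L, 2L))
})

test_that("convex clusters recover planted families; small parts stay out", {
  # membrane-protein families: the attraction-value limit is designed to
  # separate strong family edges from the weak compositional background
  # that all multi-spanning membrane proteins share
  set.seed(73)
  mkfam <- function(nFam, size, div = 0.15) {
    out <- character(0)
    for (f in seq_len(nFam)) {
      anc <- strsplit(makeMembraneProtein(7)$seq, "")[[1]]
      for (i in seq_len(size)) {
        ch <- anc
        hit <- which(stats::runif(length(ch)) < div)
        ch[hit] <- sample(GPCRome:::AA20, length(hit), replace = TRUE)
        out[sprintf("f%d_m%02d", f, i)] <- paste(ch, collapse = "")
      }
    }
    Biostrings::AAStringSet(out)
  }
  seqs <- mkfam(3, 6)
  # add three isolated singletons (background)
  iso <- Biostrings::AAStringSet(stats::setNames(
    vapply(1:3, function(i) GPCRome:::randomAASeq(300), character(1)),
    paste0("iso", 1:3)))
  g <- buildSimilarityGraph(c(seqs, iso))
  cl <- findConvexClusters(g, minSize = 4, sdLimit = 0.5)
  expect_length(clusterMembers(cl), 3L)
  got <- lapply(clusterMembers(cl), function(m) unique(sub("_.*", "", m)))
  expect_true(all(lengths(got) == 1L))
  expect_true(all(paste0("iso", 1:3) %in% unclustered(cl)))
  # partition invariant
  expect_setequal(c(unlist(clusterMembers(cl)), unclustered(cl)), g@nodes)
})

test_that("a component of size three stays unclustered", {
  seqs <- makeFamilies(nFam = 1, size = 3, div = 0.1)
  g <- buildSimilarityGraph(seqs)
  cl <- findConvexClusters(g, minSize = 4, sdLimit = -Inf)
  expect_length(clusterMembers(cl), 0L)
  expect_setequal(unclustered(cl), g@nodes)
})

test_that("sdLimit -> -Inf reduces to connected components of size >= 4", {
  seqs <- makeFamilies(nFam = 2, size = 5, div = 0.25, seed = 79)
  g <- buildSimilarityGraph(seqs)
  cl <- findConvexClusters(g, sdLimit = -Inf)
  ig <- igraph::graph_from_data_frame(g@edges[, 1:2], directed = FALSE,
                                      vertices = data.frame(name = g@nodes))
  comp <- igraph::components(ig)
  memb <- split(names(comp$membership), comp$membership)
  big <- Filter(function(x) length(x) >= 4, memb)
  expect_equal(length(clusterMembers(cl)), length(big))
  expect_setequal(unlist(clusterMembers(cl), use.names = FALSE),
                  unlist(big, use.names = FALSE))
})

test_that("clans TSV writers round-trip tables", {
  seqs <- makeFamilies(nFam = 1, size = 5)
  g <- buildSimilarityGraph(seqs)
  lay <- layoutGraph(g, cycles = 100)
  cl <- findConvexClusters(g)
  d <- withr::local_tempdir()
  writeClansTSV(g, lay, cl, d)
  expect_equal(nrow(read.delim(file.path(d, "edges.tsv"))), nrow(g@edges))
  expect_equal(read.delim(file.path(d, "layout.tsv"))$id, rownames(lay))
  expect_setequal(read.delim(file.path(d, "clusters.tsv"))$record_id,
                  g@nodes)
})
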