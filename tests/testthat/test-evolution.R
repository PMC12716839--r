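treeOf <- function(txt) readSpeciesTree(txt)

test_that("presence/absence matrix applies missing-data semantics", {
  asg <- data.frame(
    record_id = c("r1", "r2", "r3", "r4"),
    species = c("gA", "gA", "gA", "tB"),
    family = c("F1", "F1", "F1", "F2"),
    stringsAsFactors = FALSE)
  taxa <- c(gA = "genome", tB = "transcriptome")
  pam <- buildPresenceAbsence(asg, taxa)
  m <- pamCounts(pam)
  expect_equal(m["F1", "gA"], 3L)            # present(3)
  expect_equal(m["F2", "gA"], 0L)            # genome zero = absent
  expect_true(is.na(m["F1", "tB"]))          # transcriptome zero = nd
  expect_equal(m["F2", "tB"], 1L)

  expect_error(buildPresenceAbsence(
    data.frame(record_id = "r", species = "zz", family = "F1"), taxa),
    "missing metadata")
})

test_that("Dollo mapping places origins and losses on small examples", {
  tr <- treeOf("((A,B),(C,D));")
  taxa <- stats::setNames(rep("genome", 4), c("A", "B", "C", "D"))
  mk <- function(counts) {
    m <- matrix(counts, 1, 4, dimnames = list("F1", c("A", "B", "C", "D")))
    new("PresenceAbsenceMatrix", counts = m, taxonSource = taxa)
  }
  # present in every tip: origin at root, zero losses
  gl <- dolloMap(mk(c(1L, 2L, 1L, 3L)), tr)
  ev <- glEvents(gl)
  expect_equal(ev$branch[ev$event == "origin"], "N1")
  expect_equal(sum(ev$event == "loss"), 0L)

  # presence {A,B}, genome-backed absence {C,D}: origin at MRCA(A,B)
  gl2 <- dolloMap(mk(c(1L, 1L, 0L, 0L)), tr)
  ev2 <- glEvents(gl2)
  expect_equal(ev2$branch[ev2$event == "origin"], "N2")
  expect_equal(sum(ev2$event == "loss"), 0L)

  # presence {A,B,D}, absence {C}: origin at root, one loss on C
  gl3 <- dolloMap(mk(c(2L, 1L, 0L, 1L)), tr)
  ev3 <- glEvents(gl3)
  expect_equal(ev3$branch[ev3$event == "origin"], "N1")
  expect_equal(ev3$branch[ev3$event == "loss"], "C")
  expect_equal(oracleDolloMin(tr, c("A", "B", "D"), "C"), 1)

  # zero present tips is an error
  expect_error(dolloMap(mk(c(0L, 0L, 0L, 0L)), tr), "zero present")
})

test_that("not-detected tips constrain nothing under ignore", {
  tr <- treeOf("((A,B),(C,D));")
  taxa <- c(A = "genome", B = "genome", C = "transcriptome", D = "genome")
  m <- matrix(c(1L, 1L, NA, 1L), 1, 4,
              dimnames = list("F1", c("A", "B", "C", "D")))
  pam <- new("PresenceAbsenceMatrix", counts = m, taxonSource = taxa)
  expect_equal(sum(glEvents(dolloMap(pam, tr))$event == "loss"), 0L)
  # under as_absent the nd tip needs a loss
  expect_equal(sum(glEvents(dolloMap(pam, tr,
                                     missingPolicy = "as_absent"))$event ==
                   "loss"), 1L)
})

test_that("Dollo equals the exhaustive event-set minimum on random cases", {
  set.seed(103)
  nCases <- 150
  for (i in seq_len(nCases)) {
    ntips <- sample(4:8, 1)
    tr <- readSpeciesTree(ape::rtree(ntips))
    tips <- tr$tip.label
    nPres <- sample(seq_len(ntips - 1), 1)
    present <- sample(tips, nPres)
    absent <- setdiff(tips, present)
    taxa <- stats::setNames(rep("genome", ntips), tips)
    m <- matrix(ifelse(tips %in% present, 1L, 0L), 1, ntips,
                dimnames = list("F1", tips))
    pam <- new("PresenceAbsenceMatrix", counts = m, taxonSource = taxa)
    gl <- dolloMap(pam, tr)
    ev <- glEvents(gl)
    expect_equal(sum(ev$event == "loss"),
                 oracleDolloMin(tr, present, absent),
                 label = sprintf("case %d (%s | %s)", i,
                                 paste(present, collapse = ","),
                                 paste(absent, collapse = ",")))
    # invariants: losses under origin, present tips reachable
    origin <- ev$branch[ev$event == "origin"]
    lossBranches <- ev$branch[ev$event == "loss"]
    parents <- GPCRome:::.parents(tr)
    tipsUnder <- GPCRome:::.tipsUnder(tr)
    originNode <- GPCRome:::.nodeNumber(tr, origin)
    for (lb in lossBranches) {
      nd <- GPCRome:::.nodeNumber(tr, lb)
      expect_true(all(tipsUnder[[nd]] %in% tipsUnder[[originNode]]))
      expect_false(any(tr$tip.label[tipsUnder[[nd]]] %in% present))
    }
  }
})

test_that("loss count grows weakly when an absent tip is added", {
  set.seed(107)
  for (i in 1:20) {
    tr <- readSpeciesTree(ape::rtree(7))
    tips <- tr$tip.label
    present <- sample(tips, 3)
    rest <- setdiff(tips, present)
    absent1 <- rest[1]
    taxa <- stats::setNames(rep("genome", 7), tips)
    mkpam <- function(absent) {
      m <- matrix(ifelse(tips %in% present, 1L,
                         ifelse(tips %in% absent, 0L, NA)), 1, 7,
                  dimnames = list("F1", tips))
      taxa2 <- taxa
      taxa2[tips[is.na(m[1, ])]] <- "transcriptome"
      new("PresenceAbsenceMatrix", counts = m, taxonSource = taxa2)
    }
    n1 <- sum(glEvents(dolloMap(mkpam(absent1), tr))$event == "loss")
    n2 <- sum(glEvents(dolloMap(mkpam(rest[1:2]), tr))$event == "loss")
    expect_gte(n2, n1)
  }
})

test_that("neighbor joining recovers a 4-taxon additive topology", {
  # additive distances generated on ((A,B),(C,D)) with internal branch 3
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 2
  d["C", "D"] <- d["D", "C"] <- 2.4
  d["A", "C"] <- d["C", "A"] <- 1 + 3 + 1.2
  d["A", "D"] <- d["D", "A"] <- 1 + 3 + 1.2
  d["B", "C"] <- d["C", "B"] <- 1 + 3 + 1.2
  d["B", "D"] <- d["D", "B"] <- 1 + 3 + 1.2
  tr <- njTree(d)
  want <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(want))[1], 0)
  expect_error(njTree(d[1:2, 1:2]), "at least 3")
  expect_error(njTree(matrix(c(0, 1, 2, 0, 0, 1, 0, 0, 0), 3)), "symmetric")
})

test_that("identical distances resolve deterministically", {
  d <- matrix(1, 5, 5); diag(d) <- 0
  dimnames(d) <- list(letters[1:5], letters[1:5])
  t1 <- njTree(d); t2 <- njTree(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("a long internal branch earns high bootstrap support", {
  set.seed(109)
  # two clades separated by many fixed differences
  base <- strsplit(GPCRome:::randomAASeq(120), "")[[1]]
  shifted <- base
  shifted[1:40] <- sample(GPCRome:::AA20, 40, replace = TRUE)
  jitter <- function(ch, k) {
    pos <- sample(length(ch), k)
    ch[pos] <- sample(GPCRome:::AA20, k, replace = TRUE)
    paste(ch, collapse = "")
  }
  aln <- c(a1 = jitter(base, 3), a2 = jitter(base, 3), a3 = jitter(base, 3),
           b1 = jitter(shifted, 3), b2 = jitter(shifted, 3),
           b3 = jitter(shifted, 3))
  bs <- bootstrapSupport(aln, nReps = 200, seed = 1789)
  # the clade split (deep internal node support) reaches 95%
  expect_gte(max(bs$support, na.rm = TRUE), 95)
})

test_that("species-tree IO assigns stable internal labels", {
  tr <- treeOf("((A,B),(C,D));")
  expect_equal(tr$node.label, c("N1", "N2", "N3"))
  f <- withr::local_tempfile(fileext = ".nwk")
  writeSpeciesTree(tr, f)
  back <- readSpeciesTree(f)
  expect_equal(back$tip.label, tr$tip.label)
  expect_equal(back$node.label, tr$node.label)
})

test_that("evolution TSV writer encodes nd and events", {
  tr <- treeOf("((A,B),(C,D));")
  taxa <- c(A = "genome", B = "genome", C = "transcriptome", D = "genome")
  m <- matrix(c(1L, 1L, NA, 0L), 1, 4,
              dimnames = list("F1", c("A", "B", "C", "D")))
  pam <- new("PresenceAbsenceMatrix", counts = m, taxonSource = taxa)
  gl <- dolloMap(pam, tr)
  d <- withr::local_tempdir()
  writeEvolutionTSV(pam, gl, d)
  tab <- read.delim(file.path(d, "presence_absence.tsv"),
                    colClasses = "character")
  expect_equal(tab$C, "nd")
  expect_equal(tab$D, "0")
  ev <- read.delim(file.path(d, "gain_loss_events.tsv"))
  expect_true("origin" %in% ev$event)
})
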