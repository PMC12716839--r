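test_that("profile build: states, pseudocount emissions, normalization", {
  # single ungapped sequence -> one match state per residue
  h1 <- buildProfileHMM("MKVLIWAGHD", name = "single")
  expect_equal(nrow(h1@matchEmissions), 10L)

  # a column of four identical L with Laplace alpha = 1: P(L) = 5/24
  h2 <- buildProfileHMM(c("L", "L", "L", "L"))
  expect_equal(unname(h2@matchEmissions[1, "L"]), 5 / 24)

  # two-sequence toy alignment equals the hand-computed table
  h3 <- buildProfileHMM(c("MK", "ML"))
  expect_equal(unname(h3@matchEmissions[1, "M"]), (2 + 1) / (2 + 20))
  expect_equal(unname(h3@matchEmissions[2, "K"]), (1 + 1) / (2 + 20))
  expect_equal(unname(h3@matchEmissions[2, "L"]), (1 + 1) / (2 + 20))
  expect_equal(unname(h3@matchEmissions[2, "A"]), 1 / 22)

  # normalization invariants hold after any build (validity enforces them,
  # so constructing without error is the assertion)
  set.seed(3)
  for (i in 1:5) {
    aln <- vapply(1:4, function(k) {
      s <- strsplit(GPCRome:::randomAASeq(12), "")[[1]]
      s[sample(12, 3)] <- "-"
      paste(s, collapse = "")
    }, character(1))
    expect_s4_class(buildProfileHMM(aln), "ProfileHMM")
  }
})

test_that("gappy columns become inserts; all-gap alignments error", {
  aln <- c("M-KV", "M-LV", "MA-V", "M--V")  # col 2: 75% gap, col 3: 50%
  h <- buildProfileHMM(aln)
  expect_equal(nrow(h@matchEmissions), 3L)
  expect_error(buildProfileHMM(c("--", "--")), "zero retained")
})

test_that("forward score equals exhaustive path enumeration on toys", {
  hmms <- list(toyHMM(c("ML", "ML", "MV")),
               toyHMM(c("MKV", "MLV", "M-V")),
               buildProfileHMM("AC", name = "pair"))
  seqs <- c("MLV", "AML", "KVMLX", "AC", "M")
  for (hmm in hmms) {
    for (s in seqs) {
      expect_equal(forwardBits(hmm, s), oracleForwardBits(hmm, s),
                   tolerance = 1e-6,
                   label = sprintf("forward(%s, %s)", hmm@name, s))
    }
  }
})

test_that("forward >= Viterbi for every (hmm, seq) pair", {
  set.seed(5)
  hmm <- toyHMM(c("MKVLW", "MKVLW", "MKALW", "MRVLW"))
  for (i in 1:20) {
    s <- GPCRome:::randomAASeq(sample(5:40, 1))
    expect_gte(forwardBits(hmm, s), viterbiBits(hmm, s)$bits - 1e-9)
  }
})

test_that("Viterbi envelope brackets the matching region", {
  hmm <- buildProfileHMM(c("MKVLIWAGHD", "MKVLIWAGHD"))
  v <- viterbiBits(hmm, "EEEEEMKVLIWAGHDEEEEE")
  expect_equal(v$start, 6)
  expect_equal(v$end, 15)
})

test_that("a training-set member outscores background draws and shuffles", {
  set.seed(9)
  train <- vapply(1:4, function(i) {
    s <- strsplit("MKVLIWAGHDMKVLIWAGHD", "")[[1]]
    s[sample(20, 3)] <- sample(GPCRome:::AA20, 3, replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  hmm <- buildProfileHMM(train)
  memberScore <- forwardBits(hmm, train[1])
  bg <- vapply(1:100, function(i)
    forwardBits(hmm, GPCRome:::randomAASeq(20)), numeric(1))
  expect_true(all(bg <= memberScore))
  shuf <- vapply(1:50, function(i)
    forwardBits(hmm, paste(sample(strsplit(train[1], "")[[1]]),
                           collapse = "")), numeric(1))
  expect_true(all(shuf < memberScore))
})

test_that("search applies the E-value cutoff and sorts ascending", {
  set.seed(13)
  fam <- vapply(1:4, function(i) {
    s <- strsplit(GPCRome:::randomAASeq(60), "")[[1]]
    paste(s, collapse = "")
  }, character(1))
  hmm <- calibrateProfile(buildProfileHMM(rep(fam[1], 3), name = "fam"),
                          len = 60)
  member <- fam[1]
  prot <- Proteome(c(hit = member,
                     d1 = GPCRome:::randomAASeq(60),
                     d2 = GPCRome:::randomAASeq(60)), "spX")
  hits <- searchProfile(hmm, prot, evalueCutoff = 0.01)
  expect_true("hit" %in% hits$record_id)
  expect_equal(hits$evalue, sort(hits$evalue))
  expect_true(all(hits$evalue <= 0.01))
  expect_true(all(hits$evalue > 0))
  # empty proteome -> empty hit list
  empty <- Proteome(Biostrings::AAStringSet(), "spX")
  expect_equal(nrow(searchProfile(hmm, empty)), 0L)
})

test_that("false-hit rate on background matches the calibrated E-value", {
  set.seed(1789)
  hmm <- buildProfileHMM(vapply(1:3, function(i) GPCRome:::randomAASeq(80),
                                character(1)))
  # calibrate on the same composition the targets are drawn from
  hmm <- calibrateProfile(hmm, len = 100,
                          background = GPCRome:::AA_COMPOSITION)
  n <- 1000
  prot <- Proteome(stats::setNames(
    vapply(seq_len(n), function(i) GPCRome:::randomAASeq(100), character(1)),
    paste0("bg", seq_len(n))), "spX")
  hits <- searchProfile(hmm, prot, evalueCutoff = 0.5, nSeqs = n)
  # expected false hits ~ cutoff (0.5); observed at most 5x that
  expect_lte(nrow(hits), 5 * 0.5)
})

test_that("topology grammar separates 7TM, few-helix and polar sequences", {
  set.seed(17)
  th <- buildTopologyHMM()
  p7 <- makeMembraneProtein(7)
  # scores above its own shuffle
  expect_gt(forwardBits(th, p7$seq),
            forwardBits(th, paste(sample(strsplit(p7$seq, "")[[1]]),
                                  collapse = "")))
  # all-polar sequences score at most 0 bits
  polar <- vapply(1:100, function(i)
    paste(sample(POLAR10, 250, replace = TRUE), collapse = ""), character(1))
  expect_true(all(vapply(polar, function(s) forwardBits(th, s),
                         numeric(1)) <= 0))
  # a 3-helix protein scores below a 7-helix protein
  p3 <- makeMembraneProtein(3)
  expect_lt(forwardBits(th, p3$seq), forwardBits(th, p7$seq))
})

test_that("profile serialization round-trips exactly", {
  hmm <- calibrateProfile(toyHMM(c("MKVL", "MKVL", "MRVL")), len = 30)
  f <- withr::local_tempfile(fileext = ".hmm")
  writeProfileHMM(hmm, f)
  back <- readProfileHMM(f)
  expect_identical(back@matchEmissions, hmm@matchEmissions)
  expect_identical(back@transitions, hmm@transitions)
  expect_identical(back@background, hmm@background)
  expect_identical(back@calibration, hmm@calibration)
  expect_identical(back@name, hmm@name)
})

test_that("E-values decrease monotonically with bit score", {
  hmm <- calibrateProfile(toyHMM(), len = 30)
  bits <- seq(-5, 50, by = 5)
  ev <- evalueFromBits(hmm, bits, nSeqs = 100)
  expect_true(all(diff(ev) < 0))
})
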