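test_that("planted domain segments are annotated at the right place", {
  sim <- smallSim()
  reg <- sim$truth@registry
  fam <- names(sim$truth@families)[1]    # adhesion-like family
  tf <- sim$truth@families[[fam]]
  id <- tf$members$record_id[1]
  seqs <- GPCRome:::.poolSeqs(sim$proteomes)
  ann <- annotateDomains(seqs[[id]], sim$domainProfiles, recordId = id)
  expect_true(all(c("HRM", "GAIN") %in% ann$domain))
  planted <- tf$domains
  for (dm in c("HRM", "GAIN")) {
    call <- ann[ann$domain == dm, ]
    tr <- planted[planted$domain == dm, ]
    ov <- max(0, min(call$end, tr$end) - max(call$start, tr$start) + 1)
    expect_gte(ov / (tr$end - tr$start + 1), 0.9)
  }
  # calls stay inside the sequence and are pairwise non-overlapping
  expect_true(all(ann$start >= 1 & ann$end <= nchar(seqs[[id]])))
  if (nrow(ann) > 1)
    expect_true(all(ann$start[-1] > ann$end[-nrow(ann)]))
})

test_that("background sequences yield almost no domain calls at 1e-5", {
  sim <- smallSim()
  set.seed(83)
  nCalls <- vapply(1:100, function(i) {
    nrow(annotateDomains(GPCRome:::randomAASeq(300), sim$domainProfiles))
  }, integer(1))
  expect_gte(mean(nCalls == 0), 0.95)
})

test_that("overlapping calls resolve to the higher score", {
  set.seed(89)
  seg <- GPCRome:::randomAASeq(80)
  profA <- calibrateProfile(buildProfileHMM(rep(seg, 3), name = "A"),
                            len = 100)
  # B is a weaker model of the same segment (fewer, noisier seeds)
  noisy <- strsplit(seg, "")[[1]]
  noisy[sample(80, 25)] <- sample(GPCRome:::AA20, 25, replace = TRUE)
  profB <- calibrateProfile(
    buildProfileHMM(paste(noisy, collapse = ""), name = "B"), len = 100)
  ann <- annotateDomains(paste0(GPCRome:::randomAASeq(30), seg,
                                GPCRome:::randomAASeq(30)),
                         list(A = profA, B = profB))
  expect_equal(ann$domain, "A")
})

test_that("HRM/GAIN/7TM module rules follow domain order and adjacency", {
  topo <- new("TMTopology", recordId = "x",
              helices = cbind(start = c(430, 470, 510, 550, 590, 630, 670),
                              end = c(450, 490, 530, 570, 610, 650, 690)))
  ann <- data.frame(record_id = "x",
                    domain = c("HRM", "GAIN"),
                    start = c(50, 150), end = c(120, 400),
                    bit_score = c(50, 80), evalue = c(1e-20, 1e-30))
  r <- detectHrmGainModule(ann, topo)
  expect_equal(r$module, "HRM_GAIN_7TM")
  expect_equal(r$spacing, 430L - 120L)   # within the ~280-330 window
  expect_true(r$spacing >= 280 && r$spacing <= 330)

  # GAIN alone
  r2 <- detectHrmGainModule(ann[ann$domain == "GAIN", ], topo)
  expect_equal(r2$module, "GAIN_7TM")

  # HRM C-terminal to GAIN: ordering violated
  ann3 <- ann
  ann3[ann3$domain == "HRM", c("start", "end")] <- c(405, 425)
  expect_equal(detectHrmGainModule(ann3, topo)$module, "GAIN_7TM")

  # GAIN too far from TM1
  ann4 <- ann
  ann4[ann4$domain == "GAIN", c("start", "end")] <- c(100, 300)
  expect_equal(detectHrmGainModule(ann4, topo)$module, "none")

  # an intervening domain breaks the HRM-GAIN linkage
  ann5 <- rbind(ann, data.frame(record_id = "x", domain = "EGF",
                                start = 125, end = 145, bit_score = 30,
                                evalue = 1e-10))
  expect_equal(detectHrmGainModule(ann5, topo)$module, "GAIN_7TM")
})

test_that("motif grammar matches the catalogued receptor motifs", {
  # NPxxY(x)_5,6_FR with a 5-residue spacer
  m <- motifScan("NPIIYCCCCCFR", "NPxxY(x)_5,6_FR")
  expect_equal(m$offset, 1L)
  expect_equal(m$length, 12L)
  # and with a 6-residue spacer
  expect_equal(nrow(motifScan("ANPIIYCCCCCCFRA", "NPxxY(x)_5,6_FR")), 1L)

  expect_equal(nrow(motifScan("ADRYA", "E/DRY")), 1L)
  expect_equal(nrow(motifScan("AERYA", "E/DRY")), 1L)
  expect_equal(nrow(motifScan("AKRYA", "E/DRY")), 0L)
  expect_equal(nrow(motifScan("ADRYA", "{E/D}RY")), 1L)

  expect_equal(nrow(motifScan(paste0("LR", strrep("A", 9), "GI"),
                              "LR(x)_9_GI")), 1L)
  expect_equal(nrow(motifScan(paste0("LR", strrep("A", 8), "GI"),
                              "LR(x)_9_GI")), 0L)
  expect_equal(nrow(motifScan(paste0("LR", strrep("A", 10), "GI"),
                              "LR(x)_9_GI")), 0L)

  expect_error(motifScan("AAAA", "N(x_3"), "malformed")
  expect_error(motifScan("AAAA", "N-P"), "malformed")
})

test_that("motif scan equals window brute force on random strings", {
  set.seed(97)
  motifs <- c("E/DRY", "CWxPY", "NPxxY(x)_5,6_FR", "WCWI/V/L",
              "LR(x)_9_GI", "NxLQxxMNxL")
  for (i in 1:40) {
    region <- paste(sample(c("N", "P", "Y", "C", "W", "F", "R", "E", "D",
                             "L", "I", "G", "A", "Q", "M", "V", "S"),
                           sample(20:50, 1), replace = TRUE), collapse = "")
    motif <- sample(motifs, 1)
    got <- motifScan(region, motif)
    want <- oracleMotifScan(region, motif)
    expect_equal(got[, c("offset", "length")], want,
                 label = sprintf("motifScan(%s, %s)", region, motif))
  }
})

test_that("position frequency tables trim gappy columns and normalize", {
  # hand-built 3 x 5 toy alignment
  aln <- c("MK-VD", "ML-VD", "M--V-")
  pft <- buildPositionFrequencyTable(aln, gapLimit = 0.9)
  expect_equal(pft$columns, c(1L, 2L, 4L, 5L))  # col 3 is 100% gaps
  expect_equal(unname(pft$freq["M", 1]), 1)
  expect_equal(unname(pft$freq["K", 2]), 1 / 3)
  expect_equal(unname(pft$freq["L", 2]), 1 / 3)
  expect_equal(unname(pft$gapFraction[2]), 1 / 3)
  expect_equal(unname(colSums(pft$freq) + pft$gapFraction),
               rep(1, 4), tolerance = 1e-9)

  # a column that is 95% gaps at limit 0.9 is removed
  aln2 <- c(rep("A-", 19), "AC")
  pft2 <- buildPositionFrequencyTable(aln2, gapLimit = 0.9)
  expect_equal(pft2$columns, 1L)
  expect_error(buildPositionFrequencyTable(character(0)), "empty")
})

test_that("consensus uses argmax with '+' below half frequency", {
  pft <- buildPositionFrequencyTable(c("CA", "CA", "CG", "CT", "CT"))
  expect_equal(consensusFromPFT(pft), "C+")   # top frequency 0.4 < 0.5
  pft2 <- buildPositionFrequencyTable(c("CA", "CA", "CA", "CG"))
  expect_equal(consensusFromPFT(pft2), "CA")
})

test_that("architecture strings round-trip through parse/render", {
  ann <- data.frame(domain = c("HRM", "GAIN", "7TM"),
                    start = c(1, 100, 400), end = c(70, 350, 650))
  arch <- renderArchitecture(ann)
  expect_equal(arch, "HRM|GAIN|7TM")
  expect_equal(parseArchitecture(arch), c("HRM", "GAIN", "7TM"))
  expect_equal(parseArchitecture(renderArchitecture(ann[0, ])), character(0))
})

test_that("GAIN logo region extraction anchors on cysteine and TxFAVLM", {
  set.seed(101)
  n <- 12
  left <- vapply(1:n, function(i) GPCRome:::randomAASeq(39), character(1))
  mid <- vapply(1:n, function(i) GPCRome:::randomAASeq(73), character(1))
  right <- vapply(1:n, function(i) GPCRome:::randomAASeq(20), character(1))
  ta <- vapply(1:n, function(i)
    paste0("T", sample(GPCRome:::AA20, 1), "FAVLM"), character(1))
  aln <- paste0(left, "C", mid, ta, right)
  r <- extractGainLogoRegion(aln)
  expect_equal(r$from, 40L)
  expect_equal(r$to, 40L + 73L + 7L)
  expect_equal(unique(nchar(r$aln)), r$to - r$from + 1L)

  # no conserved cysteine column
  noC <- gsub("C", "A", aln)
  expect_error(extractGainLogoRegion(noC), "cysteine")

  # TA window upstream of the cysteine column
  rev <- paste0(left, ta, mid, "C", right)
  expect_error(extractGainLogoRegion(rev), "upstream")
})
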