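smallRun <- function() memo("smallRun", {
  sim <- smallSim()
  ledger <- runTwoTrackScreen(sim$proteomes, sim$familyProfiles)
  ledger <- validateCandidates(ledger, sim$referenceGPCRs)
  list(sim = sim, ledger = ledger)
})

test_that("ledger merge arithmetic holds for disjoint/identical screens", {
  led <- ledgerFromScreens(paste0("a", 1:3), paste0("b", 1:4))
  expect_equal(ledgerCounts(led)$n[3], 7L)
  led2 <- ledgerFromScreens(paste0("a", 1:5), paste0("a", 1:5))
  expect_equal(ledgerCounts(led2)$n[3], 5L)
})

test_that("ledger validity rejects inconsistent set arithmetic", {
  led <- ledgerFromScreens(paste0("a", 1:3), paste0("b", 1:4))
  bad <- led
  bad@merged <- bad@merged[-1, ]
  expect_error(methods::validObject(bad), "merged")
  # removals of unknown candidates are rejected
  expect_error(ledgerApplyRemovals(led, data.frame(record_id = "zz",
                                                   reason = "isoform")))
})

test_that("the two-track screen recovers planted receptors and decoys", {
  run <- smallRun()
  reg <- run$sim$truth@registry
  cnt <- ledgerCounts(run$ledger)
  planted <- reg$record_id[reg$type == "gpcr"]
  merged <- run$ledger@merged$record_id
  # all planted members are candidates, soluble decoys almost never
  expect_true(all(planted %in% merged))
  sol <- reg$record_id[reg$type == "soluble"]
  expect_lte(sum(sol %in% merged), 0.02 * length(sol))
  # ledger arithmetic: candidates = validated + removed in round 1
  expect_equal(cnt$n[cnt$stage == "merged_round1"],
               cnt$n[cnt$stage == "validated_round1"] +
                 nrow(run$ledger@removed))
})

test_that("validation keeps members, removes decoys with their reasons", {
  run <- smallRun()
  reg <- run$sim$truth@registry
  led <- run$ledger
  valid <- finalIds(led)
  planted <- reg$record_id[reg$type == "gpcr"]
  expect_gte(mean(planted %in% valid), 0.95)
  # every 5-helix decoy that entered the screen was removed for helix count
  fh <- intersect(reg$record_id[reg$type == "few_helix"],
                  led@merged$record_id)
  rem <- led@removed
  expect_true(all(fh %in% rem$record_id[rem$reason == "helix_count"]))
  # fragments never validate
  fr <- reg$record_id[reg$type == "fragment"]
  expect_length(intersect(fr, valid), 0L)
  # exactly one survivor per isoform pair
  iso <- reg[reg$type == "isoform", ]
  nSurv <- (iso$record_id %in% valid) + (iso$partner %in% valid)
  expect_true(all(nSurv == 1L))
})

test_that("the structure-comparison rescue hook reinstates candidates", {
  run <- smallRun()
  sim <- run$sim
  ledger <- runTwoTrackScreen(sim$proteomes, sim$familyProfiles)
  # an empty reference set fails every candidate's homology check ...
  emptyRefs <- Biostrings::AAStringSet()
  led0 <- validateCandidates(ledger, emptyRefs)
  expect_equal(nrow(led0@validated), 0L)
  # ... and the rescue hook can reinstate chosen ids
  reg <- sim$truth@registry
  keep <- intersect(reg$record_id[reg$type == "gpcr"],
                    ledger@merged$record_id)[1:5]
  led1 <- validateCandidates(ledger, emptyRefs,
                             structureRescue = function(seqs, ids) keep)
  expect_true(all(keep %in% finalIds(led1)))
})

test_that("maxRounds = 0 leaves the ledger unchanged", {
  run <- smallRun()
  led2 <- iterateRefinement(run$ledger, run$sim$proteomes,
                            run$sim$referenceGPCRs, maxRounds = 0)
  expect_identical(ledgerCounts(led2), ledgerCounts(run$ledger))
})

test_that("cluster HMM refinement recovers members missed by seed profiles", {
  # divergent families with a single distant seed homolog per profile and
  # no topology track: round 1 misses members, the cluster-specific HMMs
  # and representative queries recover them
  cfg <- list(nSpecies = 5L, nTranscriptome = 0L, nFamilies = 2L,
              familySizeRange = c(10L, 14L), nAGPCRFamilies = 0L,
              decoys = c(soluble = 40L, few_helix = 5L, fragment = 0L),
              isoformRate = 0, maxLosses = 0L,
              divergence = 0.55, refDivergence = 0.75, refsPerFamily = 1L)
  sim <- simulateGPCRome(cfg, seed = 1234)
  reg <- sim$truth@registry
  planted <- reg$record_id[reg$type == "gpcr"]
  ledger <- runTwoTrackScreen(sim$proteomes, sim$familyProfiles,
                              topologyHMM = NULL)
  ledger <- validateCandidates(ledger, sim$referenceGPCRs)
  r1 <- mean(planted %in% finalIds(ledger))
  expect_lt(r1, 1)
  ledger <- iterateRefinement(ledger, sim$proteomes, sim$referenceGPCRs)
  r2 <- mean(planted %in% finalIds(ledger))
  expect_gt(r2, r1)
})

test_that("profile-set screens count hits per profile", {
  run <- smallRun()
  sim <- run$sim
  hits <- screenProfileSet(sim$proteomes, sim$domainProfiles,
                           evalueCutoff = 1e-5)
  cnt <- countsByProfile(hits)
  # the adhesion-like family carries both planted domains
  reg <- sim$truth@registry
  agFam <- names(sim$truth@families)[1]
  nAg <- sum(reg$type == "gpcr" & reg$family == agFam)
  expect_gte(cnt[["GAIN"]], nAg)
  expect_gte(cnt[["HRM"]], nAg)
  # empty profile set gives an empty table
  expect_equal(nrow(screenProfileSet(sim$proteomes, list())), 0L)
})

test_that("ledger TSVs capture every stage", {
  run <- smallRun()
  d <- withr::local_tempdir()
  writeLedgerTSV(run$ledger, d)
  expect_setequal(list.files(d),
                  c("screen_family.tsv", "screen_topology.tsv", "merged.tsv",
                    "merged_pairs.tsv", "removed.tsv", "validated.tsv",
                    "counts.tsv"))
  counts <- read.delim(file.path(d, "counts.tsv"))
  expect_identical(counts$n, ledgerCounts(run$ledger)$n)
})
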