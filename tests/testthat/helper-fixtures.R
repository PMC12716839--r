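# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# residue pools used to write synthetic sequences by hand
POLAR10 <- c("D", "E", "K", "S", "T", "N", "Q", "G", "P", "R")
HPOOL <- c("I", "L", "V", "F", "A", "M")

# a hand-made membrane protein: nHelix hydrophobic 21-mers separated by
# polar loops, with polar termini
makeMembraneProtein <- function(nHelix = 7, helixLen = 21, loopLen = 15,
                                nterm = 20, cterm = 20) {
  parts <- paste(sample(POLAR10, nterm, replace = TRUE), collapse = "")
  starts <- integer(0)
  pos <- nterm
  for (h in seq_len(nHelix)) {
    starts <- c(starts, pos + 1L)
    parts <- paste0(parts,
                    paste(sample(HPOOL, helixLen, replace = TRUE),
                          collapse = ""))
    pos <- pos + helixLen
    if (h < nHelix) {
      parts <- paste0(parts,
                      paste(sample(POLAR10, loopLen, replace = TRUE),
                            collapse = ""))
      pos <- pos + loopLen
    }
  }
  parts <- paste0(parts,
                  paste(sample(POLAR10, cterm, replace = TRUE),
                        collapse = ""))
  list(seq = parts, tm = cbind(start = starts, end = starts + helixLen - 1L))
}

# tiny profile HMM handy for enumeration oracles
toyHMM <- function(seqs = c("ML", "ML", "MV"), name = "toy") {
  buildProfileHMM(seqs, name = name)
}

# a reduced synthetic study for module-level pipeline tests (small enough
# to screen in seconds)
smallSimConfig <- function() {
  list(nSpecies = 6L, nTranscriptome = 1L, nFamilies = 3L,
       familySizeRange = c(6L, 10L), nAGPCRFamilies = 1L,
       decoys = c(soluble = 120L, few_helix = 20L, fragment = 10L),
       isoformRate = 0.08, maxLosses = 1L)
}

smallSim <- function() memo("smallSim", simulateGPCRome(smallSimConfig(),
                                                        seed = 421))

# full default-config study + pipeline (acceptance conditions, seed 1789);
# built once and reused by the acceptance tests
acceptanceRun <- function() memo("acceptanceRun", {
  sim <- simulateGPCRome(seed = 1789)
  ledger <- runTwoTrackScreen(sim$proteomes, sim$familyProfiles)
  ledger <- validateCandidates(ledger, sim$referenceGPCRs)
  ledger <- iterateRefinement(ledger, sim$proteomes, sim$referenceGPCRs)
  cl <- clusterValidated(ledger)
  asg <- assignFamilies(cl$clusters, ledger)
  pam <- buildPresenceAbsence(asg, sim$taxa)
  gl <- dolloMap(pam, sim$truth@tree)
  metrics <- truthMetrics(sim$truth, finalIds(ledger), cl$clusters, gl)
  list(sim = sim, ledger = ledger, clustering = cl, assignments = asg,
       pam = pam, gainLoss = gl, metrics = metrics)
})

# run the small-config pipeline end to end, writing every stage TSV into
# dir (used by the determinism suite)
runSmallPipeline <- function(dir) {
  sim <- simulateGPCRome(smallSimConfig(), seed = 99)
  ledger <- runTwoTrackScreen(sim$proteomes, sim$familyProfiles)
  ledger <- validateCandidates(ledger, sim$referenceGPCRs)
  ledger <- iterateRefinement(ledger, sim$proteomes, sim$referenceGPCRs,
                              maxRounds = 1)
  cl <- clusterValidated(ledger)
  asg <- assignFamilies(cl$clusters, ledger)
  pam <- buildPresenceAbsence(asg, sim$taxa)
  gl <- dolloMap(pam, sim$truth@tree)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLedgerTSV(ledger, dir)
  writeClansTSV(cl$graph, cl$layout, cl$clusters, dir)
  GPCRome:::writeTSV(asg, file.path(dir, "assignments.tsv"))
  writeEvolutionTSV(pam, gl, dir)
  for (sp in names(sim$proteomes))
    writeProteome(sim$proteomes[[sp]], file.path(dir, paste0(sp, ".fasta")))
  invisible(dir)
}
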