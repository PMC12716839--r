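---
title: "Methods: screening, classifying and mapping GPCR repertoires"
author: "GPCRome package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, classifying and mapping GPCR repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and of the design
choices that were genuinely open: what each engine computes, which
parameters matter and why their defaults are what they are, what the
synthetic-study generator does and does not emulate, and where the
implementation knowingly simplifies.

## The profile-HMM engine

`buildProfileHMM` compiles a multiple alignment into a match/insert/delete
profile. Columns with gap fraction at most 0.5 become match states (the
usual profile-construction heuristic); match emissions are observed
frequencies with a Laplace pseudocount ($\alpha = 1$, so a column of four
identical leucines gives $P(L) = 5/24$); transitions are counted from the
per-sequence state paths with the same pseudocount; insert emissions are
tied to the background, the standard practice that makes inserted residues
score zero.

Scoring is local log-odds in bits. The local model enters any match state
$j$ with probability $1/L$ and exits from match state $j$ with probability
$1/(L-j+1)$, the remaining mass rescaling the core transitions so every
outgoing group still sums to one; residues outside the aligned core are
emitted by the background and contribute nothing. One non-obvious term: the
alignment start position in the target carries a uniform $1/n$ prior.
Without it, a sum over $n$ start positions hands every sequence roughly
$\log_2 n$ free bits from trivial one-state episodes, and no emission
design can keep background sequences at or below zero bits. With it, the
engine satisfies the properties the tests assert: forward equals complete
path enumeration on small models, forward never falls below Viterbi, a
training-set member outscores its own shuffles, and all-polar sequences
score at or below zero against the topology grammar.

The forward recursion runs in probability space with per-row rescaling
(C++, via Rcpp, as the field's sequence packages do for inner loops);
Viterbi additionally propagates the start coordinate of the best path so
envelope coordinates come out of a single pass.

**E-values.** `calibrateProfile` scores background-sampled sequences
(default 200, seed 1789) and fits a Gumbel (location, scale). The fit is
tail-weighted: the scale is the mean exceedance over the 70th percentile
and the location matches the empirical tail mass there. A plain moments
fit is dominated by the bulk of the distribution and overestimates tail
probabilities by an order of magnitude where E-values are actually used;
the exceedance fit keeps the miscalibration within a small factor and on
the conservative side. Calibration must use the composition of the
proteomes being searched — the pipeline estimates it with
`estimateBackground` — because a null drawn from a different composition
shifts the whole tail.

## The topology grammar

`buildTopologyHMM` builds a membrane-topology profile rather than a family
model: seven 21-state helix blocks whose emissions concentrate 75% of
their mass on A/F/I/L/M/V, joined by 15-state loops with a mild (1.2x)
polar bias, with loop states tolerating insertions and deletions more than
helix states. Scored locally, a 5-helix protein simply matches five
consecutive blocks, which is exactly what lets the helix-count filter —
not the screen — be the step that rejects such decoys, with the reason
code the audit expects.

## Transmembrane prediction and region extraction

`predictTM` is a deliberately simple, deterministic hydropathy caller:
Kyte-Doolittle means over a 19-residue window, threshold 1.6; maximal
above-threshold center runs are merged across gaps shorter than 4, runs
longer than 35 centers (two helices fused across a short loop) are split
at their interior hydropathy minimum, each run is expanded to the window
extent, overlapping expansions are clipped at the midpoint, and each
candidate first sheds non-hydrophobic end residues (per-residue
Kyte-Doolittle below 1.0) before the 17-25 length bounds are enforced. The
split-before-expansion order matters: splitting expanded intervals turns
every clean 21-residue helix whose run of window centers exceeds ~17 into
two spurious calls. On planted helices the caller recovers intervals
within two residues of truth.

Retention keeps candidates with six to eight helices — seven is the
hallmark, six tolerates one missed helix, eight an uncleaved N-terminal
signal anchor. `extract7TM` returns TM1-start through TM7-end; with eight
helices the first is treated as the signal anchor and skipped (the last
seven are used). `extractNTF` returns everything before the first helix,
so NTF + 7TM + C-tail exactly partition a 7-helix record.

## Pairwise statistics

Local alignment is Smith-Waterman with affine gaps (BLOSUM62, open 11,
extend 1), computed by `Biostrings::pairwiseAlignment`; identity is
counted over aligned columns and coverage over the query. E-values follow
Karlin-Altschul, $E = K m n e^{-\lambda S}$, with $\lambda, K$ fitted once
per scoring system from the Gumbel of background-pair scores (500 pairs of
length 200, seed 1789) — the precomputed gapped constants of the standard
tools are tool-internal and not portable. Greedy identity clustering
(`greedyIdentityCluster`) is longest-first with identity defined over the
shorter sequence, the convention of the usual redundancy-removal tools.

## The audited ledger and validation order

`CandidateLedger` enforces its own arithmetic as a validity invariant: the
merged set is the exact union of the two screens after (species, sequence)
deduplication, each round's candidates split exactly into validated plus
removed, and the final set is round-1 survivors plus refinement additions.
A ledger whose counts do not reconcile cannot be constructed, which is the
point of an audit.

Validation applies, in order: helix count (6-8), reference homology (a
known GPCR within the top 10 local hits at $E \le 10^{-5}$; a structure
-comparison rescue hook exists and defaults to rescuing nothing), fragment
removal, and within-species isoform removal (greedy clustering at 90%
identity, longest kept). The order is deliberate: membrane-protein decoys
that are homologous to real receptors must be rejected for their helix
count, not their homology, for the reason codes to be interpretable.

Two rules needed a decision the study description leaves open:

* **Fragments** are records shorter than 60% of their best-matching
  reference receptor. A cluster-median rule is not available at validation
  time (clusters do not exist yet), and grouping by best reference lets a
  reference subgroup consisting mostly of fragments certify itself; the
  reference-length comparison has neither problem.
* **Isoform removal is scoped within species.** Splice isoforms are
  same-gene and therefore same-species; a global sweep at 90% identity
  deletes true orthologs between shallowly diverged sister species.

## Refinement

Each round: cluster the validated 7TM regions, align each cluster with the
center-star progressive aligner (the center maximizes total pairwise
score; everything else is merged through pairwise alignments to it), build
one profile per cluster plus single-sequence profiles for unclustered
records, re-screen every proteome with the new profiles (E <= 0.01) and
with three representatives per cluster — those nearest the cluster
centroid in layout space — as pairwise queries (E <= 1e-5). Only records
never seen before become candidates; they pass the same validation, with
previously validated receptors added to the reference set (they are, by
this point, known receptors). Iteration stops after a round that adds
nothing, or at `maxRounds` (default 3). This is the step that recovers
family members a biased seed alignment misses: in the divergent-family
test scenario round-one recall is ~0.3 and refinement takes it to 1.0.

## Similarity clustering

`buildSimilarityGraph` scores all pairs (after a shared-4-mer prefilter)
and keeps edges with $E < 10^{-6}$, weighted $-\log_{10} E$. Two nulls are
offered, and the choice is a real methodological fork:

* `"background"` (default) uses the generic Karlin-Altschul fit. Because
  7TM regions are hydrophobic-rich, unrelated membrane proteins then
  connect through weak compositional edges — precisely the faint
  inter-family lines visible in published cluster maps.
* `"shuffled"` refits the null on composition-preserving shuffles of the
  input itself (the analogue of composition-based statistics), which
  removes the compositional edges entirely: unrelated families share not
  a single edge at $10^{-6}$.

The convex-cluster rule — keep edges with attraction at least
$\mathrm{mean} + 0.5\,\mathrm{SD}$ of all edge attractions, then take
connected components of size at least 4 — presupposes the background
regime: the threshold lands between the compositional background and the
family edges and recovers planted families exactly (ARI 1.0). Under the
shuffled null every surviving edge is already a family edge, the
threshold sits above the median family attraction, and families
fracture. The pipeline therefore clusters under the background null and
the sd-limit as printed; the shuffled null remains available (and tested)
as the composition-corrected significance engine.

The force-directed layout (attraction proportional to weight times
distance, repulsion to inverse distance, linear cooling, displacement
capped per cycle) is initialized uniformly in the unit cube from a seed
assigned per sorted node id, making the layout equivariant under node
reordering. Cluster detection does not depend on the layout, so the
pipeline default of 2000 cycles only affects representative picking; the
full-study setting of 20000 cycles is what the two-clique separation test
uses.

## Domains, modules and motifs

Domain annotation runs each profile locally and resolves overlaps greedily
by bit score. The adhesion-receptor module rule: `GAIN_7TM` requires a
GAIN call ending within 50 residues of TM1 ("directly N-terminal" is not
quantified anywhere; 50 residues tolerates linker jitter without letting a
mid-NTF call qualify), and `HRM_GAIN_7TM` additionally requires an HRM
call N-terminal of the GAIN with no other domain between; the diagnostic
spacing TM1-start minus HRM-end falls in the ~280-330 residue window
characteristic of these receptors.

The motif grammar covers literal residues, `x`, one-position alternatives
(`E/D` or `{E/D}`), and bounded spacers `(x)_m,n`; matching is
leftmost-first, shortest expansion at each start, non-overlapping — and is
checked against an independent window-enumeration oracle. Logo utilities
compute per-column frequency tables with gappy-column trimming (columns
above 90% gaps dropped; unknown residues count toward the gap fraction),
consensus by argmax with `+` marking columns whose top frequency is below
0.5, and the GAIN logo region is anchored between the first column with at
least 90% cysteine and the downstream `TxFAVLM` tethered-agonist
consensus window.

## Presence/absence and Dollo mapping

Zero detected members is a different observation in a genome than in a
transcriptome: the matrix stores a genome-backed absence as `0` and a
transcriptome zero as "not detected" (`NA`/`nd`), and the default
`missingPolicy = "ignore"` lets `nd` constrain nothing — a transcriptome
can fail to sample a gene that is present. Under Dollo parsimony each
family is gained once, on the branch above the MRCA of its carrier tips;
losses are the maximal subtrees below the origin containing no carrier,
one loss per subtree, which is the minimal consistent set (verified
against exhaustive event-set search on a thousand random trees).
Horizontal transfer is not modeled; a transferred family would simply
surface as an implausibly deep origin.

Neighbor joining (via ape) with the mismatch-fraction distance and
column-bootstrap support is the deliberate desk-scale stand-in for
likelihood/Bayesian tree inference, which is out of scope.

## The synthetic study

`simulateGPCRome` generates the conditions the pipeline assumes, with full
ground truth. Defaults: 20 species on a random bifurcating tree rescaled
to unit depth, 3 transcriptome-only species, 8 families of 10-40 members
(at least one member per carrier species, so the true presence matrix
matches the true history), 2 families carrying HRM/GAIN ectodomain
modules at the canonical spacing, 2000 decoys (1700 soluble, 200 5-helix,
100 bare-7TM fragments) and a 5% isoform-twin rate.

Choices worth knowing about:

* **Family-specific helix pools.** Each family's helices draw from its own
  3-residue subset of the hydrophobic alphabet, and helix substitutions
  stay inside the pool. This keeps helices detectable under divergence
  (the real constraint on 7TM evolution) while keeping the *expected*
  cross-family helix alignment score near zero, so families are separable
  at all. With a shared pool, any two unrelated 7TM sequences align with
  strongly positive expected score per column.
* **Polar loops and termini.** Loops, ectodomains and tails draw from a
  composition with strongly hydrophobic residues down-weighted to a
  quarter, as in real extracellular regions. Database-average loops are
  ~25% strongly hydrophobic, and at that rate short loops stochastically
  fuse adjacent helices in any hydropathy caller.
* **Divergence.** Root-to-tip expected substitution rate 0.35 per site,
  plus 0.12 within-species paralog divergence (real paralogs are not
  97% identical; at 97% they are indistinguishable from splice isoforms
  by any identity rule, including the 90% rule this pipeline uses).
* **Decoys are derived from members** where homology matters: 5-helix
  decoys are members with helices 6-7 excised, fragments are bare 7TM
  regions of adhesion-family members. Decoys that no filter would ever
  see (random soluble polymers) only calibrate the screens' false-positive
  behavior.
* **Recoverable histories.** Sampled loss branches cover only genome-
  backed tips and always leave each origin-child subtree with a carrier,
  so the generating origin stays the MRCA of the carriers and the loss
  set is exactly what Dollo mapping must return. Explicit histories are
  validated and rejected as infeasible when a loss is not under the
  origin.

What the generator does **not** emulate: indel evolution (members differ
by substitution only, so alignment columns never shift), rate
heterogeneity across sites, compositional drift between lineages,
contamination, and assembly artifacts beyond simple truncation. Passing
the recovery tests therefore demonstrates that the machinery is correct
under the stated model, not that real proteomes will behave as cleanly;
on real data the screens' sensitivity is bounded by the hydropathy
caller and the seed alignments, exactly as in the original tool chain.

## Problem sizes and determinism

The shipped tests run the full pipeline on the default 20-species study
(about 2500 records; a few minutes on one core) and a reduced 6-species
study for the determinism suite, which requires every stage table,
layout, FASTA and event list to be byte-identical across two runs with
the same seed. All stochastic steps — generator, null calibrations,
layout initialization — take explicit seeds (calibration and layout
default to 1789); everything else is deterministic, including every
tie-break (E-value, then bit score, then lexicographic id; alphabetical
consensus ties; index-order NJ agglomeration).

## Known limitations

* E-value calibration is empirical; absolute E-values are comparable
  within a run, conservative in the far tail, and not exchangeable with
  any external tool's E-values.
* The convex-cluster rule is an operative reading (threshold on edge
  attractions plus components); the original interactive tool's internal
  routine is not specified precisely enough to reproduce.
* Region extraction is per-sequence; the alignment-guided variant (align
  first, then transfer helix boundaries) is noted but not implemented.
* The structure-based rescue of candidates without sequence-level
  reference hits is a hook only (`structureRescue`), defaulting to no
  rescue.
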