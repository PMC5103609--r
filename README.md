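# xenoLR — cancer–stroma interactome profiling from xenograft RNA-seq

In a xenograft tumour, human cancer cells grow inside mouse-derived stroma.
Because human and mouse exon sequences differ by roughly 15%, a single bulk
RNA-seq library of such a tumour can be split by species of origin,
yielding matched expression profiles of the cancer compartment (human
reads) and the stromal compartment (mouse reads). `xenoLR` turns those two
profiles into a quantitative map of ligand–receptor signalling between
cancer and stroma — the kind of map used to prioritise stromal drug
targets. It is written for computational biologists analysing xenograft
(or similar two-species) RNA-seq experiments.

## What it computes

1. **Species/gene assignment.** Paired-end alignments against the combined
   human+mouse transcript set are resolved by a deterministic best-hit
   rule: a pair is assigned when its minimum-mismatch placements all fall
   in one gene of one species; equal-mismatch ties across species or genes
   are excluded. Per-gene coverage `c` and read-start `c'` counts are
   accumulated in distance-from-poly-A coordinates.
2. **Mappability.** Per-nucleotide 50 bp mappability `m` across the
   combined transcript database (k-mer hashing, pigeonhole for one
   mismatch), so reads lost to cross-species homology do not deflate
   expression.
3. **Bias-corrected copy numbers.** A positional Poisson model
   `log E[c_ij] = log(m_ij / Σ_k m_ik) + log v_i + α·g_ij + β·d_ij`
   with GC (`g`) and poly-A-distance (`d`) coefficients shared across genes
   and species, fitted by alternating a Poisson GLM with closed-form
   per-gene expression updates. Final copy numbers use read starts,
   `v_i = Σ_k c'_ik / Σ_k exp(α g_ik + β d_ik)` over mappable positions,
   normalised per species so that genes at or below the 95th percentile sum
   to 300,000 copies (≈ mRNA content of an average cell).
4. **Interactome indices.** For every curated ligand–receptor pair and each
   direction (cancer→stroma, stroma→cancer): ligand dependency
   `X = L_C/(L_C+L_S)`, receptor dependency `Y = R_S/(R_C+R_S)`, signal
   strength `Z = √(L_C·R_S)` (and the mirrored forms). Zones cut the (X, Y)
   unit square at 0.5; zone 1 ("mutually dependent", both ≥ 0.5) marks
   signals that exist only when both compartments are present — the prime
   druggable class. Screens use strict thresholds (Z > 10 / > 50; mutual
   dependency X > 0.75, Y > 0.75, Z > 50).
5. **Functional modules.** GO categories are tested for zone enrichment
   with a one-sided binomial test against the background zone rate, ranked
   by zone fraction then mean signal, with Storey or Benjamini–Hochberg
   q-values.

A seeded simulator (`simulateTranscriptomes()` / `simulateReads()`)
generates two-species transcriptomes with shared homologous blocks and
reads carrying known GC/poly-A biases, so the whole chain is testable with
known truth.

## Worked example

Simulate a 50/50 human:mouse sample, run the chain, and score a small
interaction set:

```r
library(xenoLR)

cfg    <- simulationConfig(seed = 42, nGenes = 40, pairs = 60000, nLongGenes = 8)
sim    <- simulateTranscriptomes(cfg)
tracks <- mappabilityTracks(sim$ts)
reads  <- simulateReads(cfg, sim, tracks = tracks)

counts <- accumulateCounts(assignPairs(reads$placements), sim$ts)
unlist(summarizeSample(counts))
#>        total        human        mouse mousePercent
#>     60125.00     30926.00     28925.00        48.33

model <- fitBiasModel(counts, sim$ts, tracks)
model
#> BiasModel: alpha = -2.00186 (GC), beta = -0.000996349 (/nt), 64 genes,
#> converged after 40 iterations

prof <- estimateCopyNumbers(counts, sim$ts, tracks, model)

db <- data.frame(ligand = names(sim$vHuman)[1:10],
                 receptor = names(sim$vHuman)[11:20])
mv <- collapseMouseHomologs(expressionOf(prof, "mouse"), sim$homologMap)
iprof <- computeInteractionScores(db, expressionOf(prof, "human"), mv)
iprof
#> InteractionProfile: 10 interactions x 2 directions
#>   CS: 10 defined, zone1 4, zone2 2, zone3 1, zone4 3
#>   SC: 10 defined, zone1 3, zone2 1, zone3 2, zone4 4

head(extractMutuallyDependent(iprof, zMin = 10), 1)
#>     ligand receptor direction         X         Y        Z zone
#> 1 HGENE009 HGENE019        CS 0.8026208 0.8284676 22281.67    1
```

The sample was simulated with a 48/52 species mix, GC coefficient −2 and
poly-A-distance coefficient −0.001/nt: the fitted model recovers both
(−2.002, −0.000996), and the strongest mutually dependent interaction is a
cancer→stroma pair whose ligand and receptor are both >80% compartment-
specific with a geometric-mean expression of ~2.2×10⁴ copies.

Real data enter through `readTranscriptSet()` (combined `hs|`/`mm|`
FASTA), `readSamPlacements()` (SAM) and `loadInteractionDB()` /
`loadHomologMap()` / `loadGOTable()` (TSV); `inst/extdata/` ships small
curated-style fixtures of each format. A thin command-line wrapper lives at
`inst/cli/xenoLR.R`:

```sh
Rscript inst/cli/xenoLR.R all out=run1 seed=3
```

## Package layout

| Path | Contents |
| --- | --- |
| `R/lrdb.R` | interaction database and homolog map |
| `R/assignment.R` | SAM/placements input, best-hit assignment, counts, summaries |
| `R/mappability.R` | window uniqueness and per-nucleotide tracks |
| `R/quantify.R` | covariates, training filters, Poisson bias fit, copy numbers |
| `R/interactome.R` | indices, zones, screens, averaging, viewer export |
| `R/enrichment.R` | GO zone enrichment, q-values, ranking |
| `R/synthetic.R` | seeded two-species simulator (FASTA/SAM/FASTQ emitters) |
| `R/pipeline.R` | file-based stage runner (`xlrRun()`) |
| `vignettes/xenoLR-methods.Rmd` | model, assumptions, design choices, limitations |
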