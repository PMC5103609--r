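---
title: "Profiling the cancer-stroma interactome from xenograft RNA-seq"
author: "xenoLR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the cancer-stroma interactome from xenograft RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenoLR)
```

# The problem

In a xenograft tumour, human cancer cells grow inside mouse stroma
(fibroblasts, endothelium, immune cells). Bulk RNA-seq of such a tumour
mixes transcripts of both species, but because human and mouse exons differ
by roughly 15% of their sequence, reads can be assigned to their species of
origin. That makes it possible to measure cancer and stroma expression from
a single library and, from there, to ask a question single-species
expression data cannot answer: for each ligand-receptor pair, which
compartment sends the signal and which receives it, and how strong is it?

xenoLR implements that analysis end to end: species/gene assignment of
aligned read pairs, bias-corrected absolute expression estimation,
ligand-receptor scoring in both signalling directions, zone classification,
extraction of mutually dependent (candidate druggable) interactions, and GO
functional-module enrichment over zones. A seeded simulator generates
two-species data with known truth so that every stage is testable without
external downloads.

# Read assignment

Read pairs are aligned (externally) to the combined human+mouse transcript
set; `xenoLR` consumes the placements, either from SAM
(`readSamPlacements()`) or from a pre-tabulated TSV. A placement is valid
only when both mates hit the same transcript. Assignment is deterministic
best-hit: among a pair's placements the minimum-mismatch set is taken; if
all of its placements fall in one gene of one species the pair is assigned
there (multiple splice variants of one gene count once). Equal-mismatch ties
across species, or across different genes of one species, are excluded —
this is what keeps misassignment negligible at the cost of losing reads in
homologous regions, which the quantification model compensates for via
mappability. Pairs assigned to a gene are accumulated on the gene's longest
transcript in distance-from-poly-A coordinates (j = 1 at the 3' terminus):
coverage `c` over the fragment span and a read-start count `c'` at the
fragment end nearest the poly-A tail, matching the poly-A-primed library
chemistry.

# Mappability

A 50 bp window of a transcript is *unique* if its k-mer occurs nowhere else
in the combined database — outside transcripts of the same gene and species
— within one mismatch. Exact duplicates are found by k-mer hashing;
one-mismatch occurrences by a pigeonhole split into two 25-mers (any
occurrence with at most one mismatch matches one half exactly) followed by
verification; reverse-complement occurrences also count (configurable). The
per-nucleotide mappability m_j is the number of unique windows covering the
nucleotide, between 0 and 50. Splice-variant self-hits do not destroy
uniqueness: the model is gene-level, and shared exons would otherwise zero
out most multi-isoform genes. The implementation is checked against a
brute-force all-pairs Hamming scan in the test suite.

# Quantification model

Coverage counts are modelled per gene i and position j (distance from the
poly-A tail) as Poisson with

log E[c_ij] = log(m_ij / sum_k m_ik) + log v_i + alpha * g_ij + beta * d_ij

where g_ij is the GC fraction of the 50 nt window centred on the position,
d_ij = j, v_i is the gene's expression, and alpha, beta are shared across
all genes *and both species* within one sample — the sequencing chemistry,
not the genome, causes the bias. beta captures the dominant effect: poly-A
primed libraries lose coverage with distance from the tail, the more so the
more degraded the RNA. alpha captures the (usually slight) GC effect.

Fitting alternates (a) a Poisson GLM with log link of the coverage counts on
(g, d), offset by the mappability-and-expression term, updating alpha and
beta, with (b) a closed-form maximum-likelihood update of each v_i given
alpha and beta. The regression carries an intercept whose scale is folded
back into v at each update. Convergence is declared when the relative change
of (alpha, beta) drops below 1e-6, with a 50-iteration cap (deterministic
and cheap); the `converged` flag records a cap hit. Coverage counts drive
the fit because read starts are too sparse; the final estimator uses read
starts because they localise the fragment exactly.

Training transcripts must (i) have no splice variant, (ii) exceed 8 kb and
(iii) be >80% covered. These filters target deep libraries; when fewer than
10 genes qualify (common at simulation depth), thresholds relax to 2 kb/50%
with a warning — coefficients estimated from a handful of transcripts are
too unstable to be useful. Initial values of v use the mappability-weighted
count sum over the first N' = min(N, 3000) positions from the tail, where
the distance bias is weakest.

Two numerical choices deserve a note:

* **Edge trimming.** Positions within 250 nt (about one fragment length) of
  either transcript end are excluded from the regression design. Coverage
  there is truncated at fragment scale — the poly-A-proximal pile-up builds
  up over one fragment length, and the 5' tail cannot be spanned by a
  fragment — which the positional model does not describe; leaving those
  positions in biases beta toward zero by several percent. The full
  transcript still feeds the expression updates and the final estimator.
* **Final estimator.** The estimated copy number is
  v_i = sum_k c'_ik / sum_k exp(alpha g_ik + beta d_ik) with the denominator
  over *mappable* positions (m_ik > 0). Reads falling in unmappable
  (cross-species identical) regions are discarded by assignment, so summing
  the bias term over positions where no read can be observed would deflate
  exactly the genes with homologous blocks — the mappable-length rationale
  of the design. This is why masking a homologous block leaves a uniformly
  covered gene's estimate unchanged (a property the tests assert).

Each species is then normalised separately (cancer-to-stroma ratios differ
between samples): Z is chosen so that normalised copy numbers of genes at or
below the species' 95th percentile sum to 300,000, roughly the mRNA content
of an average cell. The percentile is computed over genes with positive
expression with the linear-interpolation definition, and the boundary gene
is included in the sum; these conventions are fixed for reproducibility.
Normalised values are invariant under uniform rescaling of counts.

# Interactome indices

With normalised ligand expression L_C (cancer/human) and L_S (stroma/mouse,
homolog-collapsed onto human gene ids, summing when several mouse genes map
to one human gene) and receptor expression R_C, R_S, the three indices in
the cancer-to-stroma direction are

* ligand dependency X = L_C / (L_C + L_S),
* receptor dependency Y = R_S / (R_C + R_S),
* signal strength Z = sqrt(L_C * R_S),

and mirrored for stroma-to-cancer. X and Y are fractions in [0, 1]; Z is on
the copy-number scale, interpretable as the typical number of mRNA molecules
of the interacting genes. When a denominator is zero the dependency is
reported as undefined rather than 0 or 0.5 — 0/0 has no privileged value —
and undefined scores are excluded from zones, counts and plots. Zones cut
the (X, Y) unit square at 0.5, boundary-inclusive for "strong": zone 1
(both >= 0.5) is the mutually dependent class, the prime candidate for
therapeutic intervention; zones 2 and 3 are autoregulation of the sending
and receiving compartment; zone 4 is neither. Screening thresholds are
strict inequalities exactly as they are conventionally quoted (signal
strength > 10 or > 50; mutual dependency X > 0.75, Y > 0.75, Z > 50).

Multi-sample summaries average each index per interaction and direction over
the samples where it is defined (pairwise-available mean — one silent gene
should not delete an interaction from the summary), and zones are
*recomputed from the averaged indices* rather than majority-voted; the
output metadata records the number of samples averaged.

# Functional-module enrichment

An interaction belongs to a GO category when its ligand *or* receptor does.
For a category with n classified member interactions, k of them in a target
zone set, and a background rate p0 equal to the fraction of *all* classified
interactions of that direction in the zone set, the enrichment p-value is
the one-sided binomial upper tail P(Bin(n, p0) >= k). The null (members fall
into zones at the background rate, per direction) is the natural
zone-enrichment null; it is recorded in the output since the choice was
open. p-values become q-values either by Storey's method (pi0 estimated on a
lambda grid with a cubic-spline smoother — implemented in the package — the
default) or Benjamini-Hochberg. Categories are ranked by the fraction of
members in the target zones, ties broken by mean signal strength, and
categories with mean signal below 10 are dropped; representative genes are
those appearing in at least 2 ranked categories with at least one
interaction above signal strength 10. All categories are used as given,
without DAG propagation.

# What the simulator emulates — and what it does not

`simulateTranscriptomes()` / `simulateReads()` generate the study
conditions: two species of single-isoform genes (50 per species by default;
100 per species at validation scale), lengths 1.5-4 kb with a subset forced
to 9 kb so the training filter has candidates, a configurable fraction of
human-mouse gene pairs sharing an identical block (homology), true copy
numbers drawn log-normally and scaled to a chosen human:mouse mix, and
50 bp paired-end fragments of 100-200 nt whose start positions follow
exactly the model the quantifier fits: weight proportional to
1[m > 0] * exp(alpha g + beta d), counts Poisson, defaults alpha = -2 per
GC fraction and beta = -1e-3 per nt (a strong poly-A decay and a slight GC
effect, the regime the method targets). Sequencing errors are applied after
placement, at most one per mate, so alignments respect the one-mismatch
contract. Reads falling entirely inside a shared block receive the twin
placement on the other species, which assignment must exclude as a
cross-species tie.

Two generator choices matter for interpretation:

* GC content drifts smoothly (anchors every 2 kb, linear interpolation)
  rather than varying independently per base. Coverage at a position
  aggregates fragments starting up to one fragment length away, so GC
  structure varying *faster* than the fragment length makes the positional
  GC covariate unrepresentative of the fragments that produce the coverage,
  attenuating any coverage-based GC estimate — an errors-in-variables
  effect, not an estimator defect. Real transcript GC varies on longer
  scales.
* G/C positions are placed by error diffusion along the drifting profile,
  so the windowed GC read off the sequence *is* the profile that generated
  the reads. With fully random bases the 50 nt window GC carries binomial
  noise (sd about 0.07) comparable to the regional signal, which again
  attenuates coverage-based estimates of the GC coefficient.

Consequently, passing recovery tests show that the estimator is consistent
when the data obey its model at fragment scale. They do not show robustness
to fragment-level GC selection bias (amplification effects acting on whole
fragments rather than positions), isoform mixtures, positional error
hot-spots, or PCR duplicates — none of which the generator emulates. The
misassignment checks likewise certify the assignment *rule*, not the
upstream aligner.

# Problem sizes and determinism

The validation simulations use 100 genes per species and 2e5 read pairs
(about a minute of mappability hashing and a minute of fitting), the scale
at which the recovery targets (bias coefficients within 10%, expression
Pearson r > 0.95) are comfortably met; unit fixtures are a few hundred
bases. All randomness flows from explicit integer seeds; mappability,
assignment, scoring and enrichment are fully deterministic, and rerunning
any stage on the same inputs reproduces identical bytes.

# Known limitations

* Assignment is deterministic; an EM-style probabilistic assignment would
  recover some of the excluded homologous-region reads.
* One representative (longest) transcript per gene; isoform-level
  quantification is out of scope, and variant counts are projected onto the
  representative by distance from the poly-A tail.
* The ligand-receptor table shipped in `inst/extdata` is a small
  curated-style fixture for demonstration and testing, not a full curated
  interactome; users should supply their own database in the same TSV
  format.
* Cross-species reactivity of individual ligand-receptor pairs is not
  modelled: a strong score says both sides are expressed, not that mouse
  ligand activates human receptor.
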