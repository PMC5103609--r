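Package: xenoLR
Title: Cancer-Stroma Interactome Profiling from Xenograft RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies human (cancer) and mouse (stroma) gene expression from
    RNA-seq of xenograft tumours and scores curated ligand-receptor
    interactions in both signalling directions. Read pairs aligned to the
    combined two-species transcript set are assigned to a single species and
    gene by a deterministic best-hit rule; per-gene copy numbers are estimated
    with an iterative Poisson regression that corrects coverage biases from
    regional GC content, distance from the poly-A tail, and cross-species
    sequence mappability. Each ligand-receptor pair is summarised by ligand
    dependency, receptor dependency and signal strength in the cancer-to-stroma
    and stroma-to-cancer directions, classified into dependency zones, and
    screened for mutually dependent, potentially druggable interactions.
    Gene Ontology functional modules are tested for zone enrichment with a
    one-sided binomial test and false discovery rate q-values. A seeded
    simulator generates two-species transcriptomes with homologous blocks and
    bias-carrying reads for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    Rsamtools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
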