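#' @import methods
#' @importFrom stats approx coef median pbinom p.adjust quantile rlnorm rpois
#'   runif setNames smooth.spline predict cor glm.fit poisson rbinom
#' @importFrom utils read.delim write.table head
NULL

#' TranscriptSet: a two-species transcript database
#'
#' Holds the combined human/mouse transcript sequences together with their
#' gene and species annotation. Sequences are stored 5'->3'; all positional
#' bookkeeping downstream (counts, mappability, covariates) is indexed by
#' distance from the poly-A tail, j = 1 being the 3'-terminal nucleotide.
#'
#' @slot seqs A \link[Biostrings]{DNAStringSet}; names are transcript ids.
#' @slot txGene character, gene id per transcript (parallel to \code{seqs}).
#' @slot txSpecies character, \code{"human"} or \code{"mouse"} per transcript.
#'
#' @exportClass TranscriptSet
setClass("TranscriptSet",
    representation(
        seqs = "DNAStringSet",
        txGene = "character",
        txSpecies = "character"
    )
)

setValidity("TranscriptSet", function(object) {
    n <- length(object@seqs)
    msg <- character()
    if (length(object@txGene) != n || length(object@txSpecies) != n)
        msg <- c(msg, "txGene and txSpecies must be parallel to seqs")
    if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
        msg <- c(msg, "transcript names must be present and unique")
    bad <- setdiff(unique(object@txSpecies), c("human", "mouse"))
    if (length(bad))
        msg <- c(msg, paste0("unknown species: ", paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct a TranscriptSet
#'
#' @param seqs DNAStringSet (or named character vector) of transcript
#'   sequences, 5'->3'.
#' @param gene character vector of gene ids, one per transcript.
#' @param species character vector, \code{"human"}/\code{"mouse"} per
#'   transcript.
#' @return A \linkS4class{TranscriptSet}.
#' @examples
#' ts <- TranscriptSet(c(tx1 = "ACGTACGT"), gene = "G1", species = "human")
#' @export
TranscriptSet <- function(seqs, gene, species) {
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    new("TranscriptSet", seqs = seqs, txGene = as.character(gene),
        txSpecies = as.character(species))
}

#' PairCounts: positional read-pair counts per gene
#'
#' Per-gene coverage counts (c, fragments covering each nucleotide) and
#' read-start counts (c', fragments whose 3'-proximal end begins at each
#' nucleotide) on the gene's representative transcript, indexed by distance
#' from the poly-A tail. Also carries the assignment tallies for the sample.
#'
#' @slot gene character, gene ids.
#' @slot species character, parallel to \code{gene}.
#' @slot cov list of integer vectors, coverage per position (j from 3' end).
#' @slot starts list of integer vectors, read starts per position.
#' @slot tallies named numeric: total, assignedHuman, assignedMouse and the
#'   exclusion reasons.
#'
#' @exportClass PairCounts
setClass("PairCounts",
    representation(
        gene = "character",
        species = "character",
        cov = "list",
        starts = "list",
        tallies = "numeric"
    )
)

setValidity("PairCounts", function(object) {
    n <- length(object@gene)
    msg <- character()
    if (length(object@species) != n || length(object@cov) != n ||
        length(object@starts) != n)
        msg <- c(msg, "gene, species, cov, starts must be parallel")
    if (n && any(vapply(object@cov, function(x) any(x < 0), logical(1))))
        msg <- c(msg, "coverage counts must be nonnegative")
    if (n && any(vapply(object@starts, function(x) any(x < 0), logical(1))))
        msg <- c(msg, "read-start counts must be nonnegative")
    if (n && any(lengths(object@cov) != lengths(object@starts)))
        msg <- c(msg, "cov and starts vectors must have equal lengths")
    if (length(msg)) msg else TRUE
})

#' BiasModel: fitted coverage-bias coefficients
#'
#' The coefficients of the positional Poisson coverage model shared across
#' species within one sample: \code{alpha} multiplies the windowed GC
#' fraction, \code{beta} the distance (nt) from the poly-A tail; \code{v}
#' holds the per-gene expression levels at the last iterate (unnormalised).
#'
#' @slot alpha numeric(1), GC-content coefficient (per unit GC fraction).
#' @slot beta numeric(1), poly-A-distance coefficient (per nucleotide).
#' @slot v named numeric, per-gene expression at convergence.
#' @slot iterations integer(1).
#' @slot converged logical(1).
#'
#' @exportClass BiasModel
setClass("BiasModel",
    representation(
        alpha = "numeric",
        beta = "numeric",
        v = "numeric",
        iterations = "integer",
        converged = "logical"
    )
)

setValidity("BiasModel", function(object) {
    msg <- character()
    if (length(object@alpha) != 1L || !is.finite(object@alpha))
        msg <- c(msg, "alpha must be a finite scalar")
    if (length(object@beta) != 1L || !is.finite(object@beta))
        msg <- c(msg, "beta must be a finite scalar")
    if (any(object@v < 0)) msg <- c(msg, "expression levels must be >= 0")
    if (length(msg)) msg else TRUE
})

#' ExpressionProfile: normalised per-gene copy numbers
#'
#' Bias-corrected expression per gene and species. Within each species the
#' normalisation constant Z is chosen so the normalised copy numbers of genes
#' at or below the species' 95th percentile sum to the per-cell mRNA target
#' (300,000 by default).
#'
#' @slot table data.frame with columns gene, species, raw, norm.
#' @slot z named numeric, normalisation constant per species.
#' @slot target numeric(1), the per-cell mRNA sum the normalisation hits.
#' @slot percentile numeric(1), the percentile bounding the summed genes.
#'
#' @exportClass ExpressionProfile
setClass("ExpressionProfile",
    representation(
        table = "data.frame",
        z = "numeric",
        target = "numeric",
        percentile = "numeric"
    )
)

setValidity("ExpressionProfile", function(object) {
    msg <- character()
    need <- c("gene", "species", "raw", "norm")
    if (!all(need %in% names(object@table)))
        msg <- c(msg, "table must have columns gene, species, raw, norm")
    else if (any(object@table$norm < 0))
        msg <- c(msg, "normalised copy numbers must be >= 0")
    if (length(msg)) msg else TRUE
})

#' InteractionProfile: scored ligand-receptor interactome
#'
#' One row per interaction and signalling direction, carrying the three
#' evaluation indices: ligand dependency X, receptor dependency Y (fractions
#' in [0,1]) and signal strength Z (geometric-mean copy number), plus the
#' dependency zone (1-4 at the 0.5 boundary) and a defined flag.
#'
#' @slot scores data.frame with columns ligand, receptor, direction ("CS" for
#'   cancer-to-stroma, "SC" for stroma-to-cancer), X, Y, Z, defined, zone.
#' @slot nSamples integer(1), number of samples averaged into the profile.
#'
#' @exportClass InteractionProfile
setClass("InteractionProfile",
    representation(
        scores = "data.frame",
        nSamples = "integer"
    )
)

setValidity("InteractionProfile", function(object) {
    s <- object@scores
    need <- c("ligand", "receptor", "direction", "X", "Y", "Z",
              "defined", "zone")
    msg <- character()
    if (!all(need %in% names(s)))
        msg <- c(msg, paste("scores must have columns",
                            paste(need, collapse = ", ")))
    else {
        if (!all(s$direction %in% c("CS", "SC")))
            msg <- c(msg, "direction must be CS or SC")
        ok <- s$defined
        if (any(ok & (s$X < 0 | s$X > 1 | s$Y < 0 | s$Y > 1), na.rm = TRUE))
            msg <- c(msg, "defined X and Y must lie in [0,1]")
        if (any(s$Z < 0, na.rm = TRUE))
            msg <- c(msg, "Z must be >= 0")
    }
    if (length(msg)) msg else TRUE
})
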