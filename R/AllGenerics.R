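#' Transcript ids of a TranscriptSet
#' @param x A \linkS4class{TranscriptSet}.
#' @return Character vector of transcript ids.
#' @export
setGeneric("txIds", function(x) standardGeneric("txIds"))

#' Gene ids (one per transcript, or the unique set)
#' @param x A \linkS4class{TranscriptSet} or \linkS4class{PairCounts}.
#' @param unique logical; return unique gene ids only.
#' @return Character vector.
#' @export
setGeneric("geneIds", function(x, unique = FALSE) standardGeneric("geneIds"))

#' Species annotation
#' @param x A \linkS4class{TranscriptSet} or \linkS4class{PairCounts}.
#' @return Character vector of "human"/"mouse".
#' @export
setGeneric("speciesOf", function(x) standardGeneric("speciesOf"))

#' Representative transcript per gene
#'
#' The longest transcript of each gene; counts from any splice variant are
#' projected onto it by distance-from-poly-A coordinate.
#' @param x A \linkS4class{TranscriptSet}.
#' @return Named character: representative transcript id per gene id.
#' @export
setGeneric("repTranscripts", function(x) standardGeneric("repTranscripts"))

#' Coverage counts of one gene
#' @param x A \linkS4class{PairCounts}.
#' @param gene Gene id.
#' @return Integer vector indexed by distance from the poly-A tail.
#' @export
setGeneric("coverageCounts", function(x, gene) standardGeneric("coverageCounts"))

#' Read-start counts of one gene
#' @param x A \linkS4class{PairCounts}.
#' @param gene Gene id.
#' @return Integer vector indexed by distance from the poly-A tail.
#' @export
setGeneric("startCounts", function(x, gene) standardGeneric("startCounts"))

#' Assignment tallies of a sample
#' @param x A \linkS4class{PairCounts}.
#' @return Named numeric vector of pair tallies.
#' @export
setGeneric("tallies", function(x) standardGeneric("tallies"))

#' Normalised expression of one species
#' @param x An \linkS4class{ExpressionProfile}.
#' @param species "human" or "mouse".
#' @param normalized logical; raw values if FALSE.
#' @return Named numeric vector keyed by gene id.
#' @export
setGeneric("expressionOf", function(x, species, normalized = TRUE)
    standardGeneric("expressionOf"))

#' Interaction score table
#' @param x An \linkS4class{InteractionProfile}.
#' @return data.frame of per-direction interaction scores.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

setMethod("txIds", "TranscriptSet", function(x) names(x@seqs))

setMethod("geneIds", "TranscriptSet", function(x, unique = FALSE) {
    if (unique) unique(x@txGene) else x@txGene
})

setMethod("geneIds", "PairCounts", function(x, unique = FALSE) {
    if (unique) unique(x@gene) else x@gene
})

setMethod("speciesOf", "TranscriptSet", function(x) x@txSpecies)
setMethod("speciesOf", "PairCounts", function(x) x@species)

setMethod("repTranscripts", "TranscriptSet", function(x) {
    len <- Biostrings::width(x@seqs)
    ord <- order(x@txGene, -len, names(x@seqs))
    first <- !duplicated(x@txGene[ord])
    setNames(names(x@seqs)[ord][first], x@txGene[ord][first])
})

setMethod("coverageCounts", "PairCounts", function(x, gene) {
    i <- match(gene, x@gene)
    if (is.na(i)) stop("gene not present in counts: ", gene)
    x@cov[[i]]
})

setMethod("startCounts", "PairCounts", function(x, gene) {
    i <- match(gene, x@gene)
    if (is.na(i)) stop("gene not present in counts: ", gene)
    x@starts[[i]]
})

setMethod("tallies", "PairCounts", function(x) x@tallies)

setMethod("expressionOf", "ExpressionProfile",
    function(x, species, normalized = TRUE) {
        tab <- x@table[x@table$species == species, ]
        setNames(if (normalized) tab$norm else tab$raw, tab$gene)
    })

setMethod("scores", "InteractionProfile", function(x) x@scores)

setMethod("show", "TranscriptSet", function(object) {
    cat("TranscriptSet with", length(object@seqs), "transcripts,",
        length(unique(object@txGene)), "genes\n")
    for (sp in c("human", "mouse")) {
        sel <- object@txSpecies == sp
        if (any(sel))
            cat(sprintf("  %s: %d transcripts, %d genes, %d nt total\n", sp,
                        sum(sel), length(unique(object@txGene[sel])),
                        sum(Biostrings::width(object@seqs)[sel])))
    }
})

setMethod("show", "PairCounts", function(object) {
    cat("PairCounts over", length(object@gene), "genes\n")
    t <- object@tallies
    cat(sprintf("  pairs: %d total, %d human, %d mouse, %d excluded\n",
                as.integer(t[["total"]]), as.integer(t[["assignedHuman"]]),
                as.integer(t[["assignedMouse"]]),
                as.integer(t[["total"]] - t[["assignedHuman"]] -
                           t[["assignedMouse"]])))
})

setMethod("show", "BiasModel", function(object) {
    cat(sprintf(
        "BiasModel: alpha = %.6g (GC), beta = %.6g (/nt), %d genes, %s after %d iterations\n",
        object@alpha, object@beta, length(object@v),
        if (object@converged) "converged" else "NOT converged",
        object@iterations))
})

setMethod("show", "ExpressionProfile", function(object) {
    cat("ExpressionProfile:", nrow(object@table), "gene records\n")
    for (sp in names(object@z)) {
        sel <- object@table$species == sp
        cat(sprintf("  %s: %d genes, Z = %.6g\n", sp, sum(sel),
                    object@z[[sp]]))
    }
})

setMethod("show", "InteractionProfile", function(object) {
    s <- object@scores
    cat("InteractionProfile:", sum(s$direction == "CS"), "interactions x 2 directions")
    if (object@nSamples > 1L)
        cat(" (average of", object@nSamples, "samples)")
    cat("\n")
    for (d in c("CS", "SC")) {
        sel <- s$direction == d & s$defined
        if (any(sel))
            cat(sprintf("  %s: %d defined, zone1 %d, zone2 %d, zone3 %d, zone4 %d\n",
                        d, sum(sel),
                        sum(s$zone[sel] == 1), sum(s$zone[sel] == 2),
                        sum(s$zone[sel] == 3), sum(s$zone[sel] == 4)))
    }
})
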