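#' Load a ligand-receptor interaction database
#'
#' Reads a curated ligand-receptor interaction table (tab-separated, header
#' row). Required columns are \code{ligand} and \code{receptor} (human gene
#' symbols); \code{source} and \code{pmid} are carried through when present.
#' Duplicate ordered (ligand, receptor) pairs are collapsed to a single
#' record with their evidence fields merged. Matching is case-insensitive;
#' symbols are stored uppercase (HGNC style). Autocrine pairs
#' (ligand == receptor) are allowed.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns ligand, receptor, source, pmid; one row
#'   per unique ordered pair.
#' @examples
#' db <- loadInteractionDB(system.file("extdata", "lr_interactions.tsv",
#'                                     package = "xenoLR"))
#' nrow(db)
#' @export
loadInteractionDB <- function(path) {
    if (!file.exists(path)) stop("interaction database not found: ", path)
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (nrow(tab) == 0L) stop("interaction database is empty: ", path)
    names(tab) <- tolower(names(tab))
    if (!all(c("ligand", "receptor") %in% names(tab)))
        stop("interaction database must have 'ligand' and 'receptor' columns")
    if (!"source" %in% names(tab)) tab$source <- ""
    if (!"pmid" %in% names(tab)) tab$pmid <- ""
    tab$ligand <- toupper(trimws(tab$ligand))
    tab$receptor <- toupper(trimws(tab$receptor))
    if (any(tab$ligand == "" | tab$receptor == ""))
        stop("interaction database has empty ligand or receptor symbols")
    key <- paste(tab$ligand, tab$receptor, sep = "\r")
    merged <- function(x) paste(unique(x[nzchar(x)]), collapse = ";")
    out <- data.frame(
        ligand = tab$ligand[!duplicated(key)],
        receptor = tab$receptor[!duplicated(key)],
        source = as.vector(tapply(as.character(tab$source), key, merged)[
            key[!duplicated(key)]]),
        pmid = as.vector(tapply(as.character(tab$pmid), key, merged)[
            key[!duplicated(key)]]),
        stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
}

#' Write a ligand-receptor interaction database
#'
#' Inverse of \code{\link{loadInteractionDB}}; load -> write -> load
#' round-trips bit-identically.
#'
#' @param db data.frame as returned by \code{\link{loadInteractionDB}}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeInteractionDB <- function(db, path) {
    write.table(db[, c("ligand", "receptor", "source", "pmid")], path,
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Load a mouse-to-human homolog map
#'
#' Reads a Homologene-style two-column TSV (\code{mouse_gene},
#' \code{human_gene}). Many mouse genes may map to one human gene.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns mouse_gene, human_gene (both stored
#'   uppercase for case-insensitive matching).
#' @export
loadHomologMap <- function(path) {
    if (!file.exists(path)) stop("homolog map not found: ", path)
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    names(tab) <- tolower(names(tab))
    if (!all(c("mouse_gene", "human_gene") %in% names(tab)))
        stop("homolog map must have 'mouse_gene' and 'human_gene' columns")
    out <- data.frame(mouse_gene = toupper(trimws(tab$mouse_gene)),
                      human_gene = toupper(trimws(tab$human_gene)),
                      stringsAsFactors = FALSE)
    out <- out[!duplicated(out$mouse_gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Collapse mouse expression onto human gene ids
#'
#' Converts a mouse-gene-keyed expression vector to human gene ids via the
#' homolog map. When several mouse genes are homologous to one human gene
#' their expression values are summed. Mouse genes absent from the map are
#' dropped with a warning; the dropped ids are attached as the
#' \code{"unmapped"} attribute.
#'
#' @param expr Named numeric vector of nonnegative expression values keyed by
#'   mouse gene id.
#' @param map data.frame from \code{\link{loadHomologMap}}.
#' @return Named numeric vector keyed by human gene id, with attribute
#'   \code{unmapped} listing dropped mouse genes.
#' @examples
#' map <- data.frame(mouse_gene = c("FABP5", "ACTB"),
#'                   human_gene = c("FABP5", "ACTB"))
#' collapseMouseHomologs(c(Fabp5 = 5, Actb = 7), map)
#' @export
collapseMouseHomologs <- function(expr, map) {
    if (is.null(names(expr))) stop("expression vector must be named")
    if (any(expr < 0)) stop("expression values must be nonnegative")
    keys <- toupper(names(expr))
    hit <- match(keys, toupper(map$mouse_gene))
    unmapped <- names(expr)[is.na(hit)]
    if (length(unmapped))
        warning(length(unmapped), " mouse gene(s) without human homolog ",
                "dropped: ", paste(head(unmapped, 5), collapse = ", "),
                if (length(unmapped) > 5) ", ..." else "")
    keep <- !is.na(hit)
    human <- toupper(map$human_gene)[hit[keep]]
    out <- tapply(expr[keep], human, sum)
    out <- setNames(as.numeric(out), names(out))
    attr(out, "unmapped") <- unmapped
    out
}
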