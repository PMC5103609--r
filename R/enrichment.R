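#' Load a GO category membership table
#'
#' Two-column TSV (\code{category}, \code{gene}; an optional \code{name}
#' column is carried through). All categories are used as given,
#' irrespective of their position in the GO hierarchy — no propagation up
#' the DAG beyond what the file encodes.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns category, gene (uppercased), name.
#' @export
loadGOTable <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    if (!all(c("category", "gene") %in% names(tab)))
        stop("GO table must have 'category' and 'gene' columns")
    if (!"name" %in% names(tab)) tab$name <- tab$category
    tab$gene <- toupper(trimws(tab$gene))
    unique(tab[, c("category", "gene", "name")])
}

# member interactions of a category in one direction: an interaction belongs
# when its ligand OR receptor gene is in the category
.memberRows <- function(s, genes) {
    s$ligand %in% genes | s$receptor %in% genes
}

#' Zone-enrichment test of one GO category
#'
#' One-sided (upper tail) binomial test of whether the category's member
#' interactions fall into the target zone set more often than all classified
#' interactions do: with k members in the zone set out of n classified
#' members and background rate p0 (fraction of all classified interactions
#' of that direction in the zone set), p = P(Bin(n, p0) >= k).
#'
#' @param memberGenes Character vector of the category's genes.
#' @param profile An \linkS4class{InteractionProfile}.
#' @param zoneSet Integer vector of target zones (e.g. \code{c(1, 2)}).
#' @param direction "CS" or "SC".
#' @param p0 Background rate; computed from the profile when NULL.
#' @return List with n, k, fraction, zone counts z1..z4, p, meanSignal (mean
#'   signal strength over all member interactions of the direction), or NULL
#'   when the category has no classified member.
#' @export
testZoneEnrichment <- function(memberGenes, profile, zoneSet = 1L,
                               direction = c("CS", "SC"), p0 = NULL) {
    direction <- match.arg(direction)
    s <- scores(profile)
    s <- s[s$direction == direction, , drop = FALSE]
    cls <- s[s$defined, , drop = FALSE]
    if (is.null(p0)) {
        if (!nrow(cls)) stop("profile has no classified interaction")
        p0 <- mean(cls$zone %in% zoneSet)
    }
    memberGenes <- toupper(memberGenes)
    memAll <- s[.memberRows(s, memberGenes), , drop = FALSE]
    mem <- memAll[memAll$defined, , drop = FALSE]
    n <- nrow(mem)
    if (n == 0L) return(NULL)
    k <- sum(mem$zone %in% zoneSet)
    zc <- vapply(1:4, function(z) sum(mem$zone == z), integer(1))
    list(n = n, k = k, fraction = k / n,
         z1 = zc[1], z2 = zc[2], z3 = zc[3], z4 = zc[4],
         p = pbinom(k - 1, n, p0, lower.tail = FALSE),
         meanSignal = mean(memAll$Z))
}

#' False discovery rate q-values
#'
#' Storey q-values (default): pi0 is estimated on a lambda grid as
#' mean(p > lambda) / (1 - lambda) and smoothed with a cubic spline, the
#' value at the largest lambda (capped to [0, 1]) taken as the estimate;
#' q-values are the usual step-up minima of pi0 * m * p_(i) / i. With
#' \code{method = "BH"} the Benjamini-Hochberg adjustment is returned
#' (pi0 = 1). Sorting by q always equals sorting by p.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param method "storey" or "BH".
#' @param lambda Grid for the pi0 smoother.
#' @return Numeric vector of q-values, same order as \code{p}.
#' @export
computeQvalues <- function(p, method = c("storey", "BH"),
                           lambda = seq(0.05, 0.95, 0.05)) {
    method <- match.arg(method)
    if (!length(p)) return(numeric())
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0,1]")
    if (method == "BH") return(p.adjust(p, method = "BH"))
    m <- length(p)
    if (m < 2L || length(unique(p)) < 4L) {
        pi0 <- 1
    } else {
        pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
        fit <- try(smooth.spline(lambda, pi0l, df = 3), silent = TRUE)
        pi0 <- if (inherits(fit, "try-error")) min(1, pi0l[length(pi0l)])
               else predict(fit, x = max(lambda))$y
        pi0 <- min(1, max(pi0, 1e-8))
    }
    o <- order(p, decreasing = TRUE)
    qd <- cummin(pi0 * m * p[o] / rank(p, ties.method = "max")[o])
    q <- numeric(m)
    q[o] <- qd
    pmin(q, 1)
}

#' Zone-enrichment analysis of all GO categories
#'
#' Runs \code{\link{testZoneEnrichment}} for every category of the
#' membership table against one direction and zone set, then attaches
#' q-values. Categories without a classified member interaction are omitted.
#'
#' @param goTable data.frame from \code{\link{loadGOTable}}.
#' @param profile An \linkS4class{InteractionProfile}.
#' @param zoneSet Integer vector of target zones.
#' @param direction "CS" or "SC".
#' @param qMethod "storey" or "BH".
#' @return data.frame: category, name, n, k, fraction, z1..z4, p, q,
#'   meanSignal.
#' @export
analyzeGOModules <- function(goTable, profile, zoneSet = 1L,
                             direction = c("CS", "SC"),
                             qMethod = "storey") {
    direction <- match.arg(direction)
    emptyRes <- data.frame(category = character(), name = character(),
                           n = integer(), k = integer(),
                           fraction = numeric(), z1 = integer(),
                           z2 = integer(), z3 = integer(), z4 = integer(),
                           p = numeric(), q = numeric(),
                           meanSignal = numeric(), stringsAsFactors = FALSE)
    s <- scores(profile)
    s <- s[s$direction == direction & s$defined, , drop = FALSE]
    if (!nrow(s)) {
        warning("profile has no classified interaction in direction ",
                direction)
        return(emptyRes)
    }
    p0 <- mean(s$zone %in% zoneSet)
    cats <- split(goTable$gene, goTable$category)
    nm <- goTable$name[match(names(cats), goTable$category)]
    rows <- lapply(seq_along(cats), function(i) {
        r <- testZoneEnrichment(cats[[i]], profile, zoneSet, direction,
                                p0 = p0)
        if (is.null(r)) return(NULL)
        data.frame(category = names(cats)[i], name = nm[i],
                   n = r$n, k = r$k, fraction = r$fraction,
                   z1 = r$z1, z2 = r$z2, z3 = r$z3, z4 = r$z4,
                   p = r$p, meanSignal = r$meanSignal,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) return(emptyRes)
    out$q <- computeQvalues(out$p, method = qMethod)
    out <- out[, c("category", "name", "n", "k", "fraction", "z1", "z2",
                   "z3", "z4", "p", "q", "meanSignal")]
    rownames(out) <- NULL
    out
}

#' Rank GO categories by zone occupancy
#'
#' Sorts categories by the fraction of member interactions in the target
#' zone set (descending), ties broken by mean signal strength (descending),
#' and removes categories whose mean signal strength is below
#' \code{meanSignalMin}.
#'
#' @param results data.frame from \code{\link{analyzeGOModules}}.
#' @param meanSignalMin Categories with mean signal strength <
#'   \code{meanSignalMin} are removed (default 10).
#' @param topN Optional: keep only the first \code{topN} categories.
#' @return The ranked, filtered data.frame.
#' @export
rankCategories <- function(results, meanSignalMin = 10, topN = NULL) {
    out <- results[results$meanSignal >= meanSignalMin, , drop = FALSE]
    out <- out[order(-out$fraction, -out$meanSignal, out$category), ,
               drop = FALSE]
    if (!is.null(topN)) out <- head(out, topN)
    rownames(out) <- NULL
    out
}

#' Representative genes of a ranked category group
#'
#' Genes that appear in at least \code{minCategories} of the ranked
#' categories and take part in at least one interaction with signal strength
#' above \code{zMin}.
#'
#' @param ranked data.frame from \code{\link{rankCategories}}.
#' @param goTable data.frame from \code{\link{loadGOTable}}.
#' @param profile An \linkS4class{InteractionProfile}.
#' @param direction "CS" or "SC".
#' @param minCategories Minimum number of categories (default 2).
#' @param zMin Signal-strength threshold, strict (default 10).
#' @return data.frame: gene, nCategories, maxZ, categories
#'   (semicolon-joined).
#' @export
representativeGenes <- function(ranked, goTable, profile,
                                direction = c("CS", "SC"),
                                minCategories = 2L, zMin = 10) {
    direction <- match.arg(direction)
    s <- scores(profile)
    s <- s[s$direction == direction, , drop = FALSE]
    tab <- goTable[goTable$category %in% ranked$category, , drop = FALSE]
    # only genes that actually take part in a member interaction count
    inProfile <- unique(c(s$ligand, s$receptor))
    tab <- tab[tab$gene %in% inProfile, , drop = FALSE]
    if (!nrow(tab))
        return(data.frame(gene = character(), nCategories = integer(),
                          maxZ = numeric(), categories = character(),
                          stringsAsFactors = FALSE))
    ncat <- tapply(tab$category, tab$gene, function(x) length(unique(x)))
    maxZ <- vapply(names(ncat), function(g)
        suppressWarnings(max(s$Z[s$ligand == g | s$receptor == g],
                             na.rm = TRUE)), numeric(1))
    maxZ[!is.finite(maxZ)] <- 0
    keep <- ncat >= minCategories & maxZ > zMin
    out <- data.frame(
        gene = names(ncat)[keep],
        nCategories = as.integer(ncat[keep]),
        maxZ = maxZ[keep],
        categories = vapply(names(ncat)[keep], function(g)
            paste(sort(unique(tab$category[tab$gene == g])),
                  collapse = ";"), character(1)),
        stringsAsFactors = FALSE)
    out <- out[order(-out$nCategories, -out$maxZ, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}
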