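#' Positional covariates of a transcript
#'
#' For each nucleotide (indexed by distance j from the poly-A tail, j = 1 at
#' the 3' terminus) computes g_j, the GC fraction of the k-nt window centred
#' on the nucleotide (clipped at the transcript ends), and d_j = j, the
#' distance from the poly-A tail in nucleotides.
#'
#' @param seq Transcript sequence (character or DNAString), 5'->3'.
#' @param k GC window width (default 50).
#' @return List with numeric \code{g} and integer \code{d}, both indexed by j.
#' @examples
#' computeCovariates(strrep("G", 60))$g[1]   # 1.0
#' @export
computeCovariates <- function(seq, k = 50L) {
    s <- as.character(seq)
    L <- nchar(s)
    base <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    isgc <- as.integer(base %in% c("G", "C"))
    cs <- c(0L, cumsum(isgc))
    p <- seq_len(L)
    half <- k %/% 2L
    lo <- pmax(1L, p - (half - 1L))
    hi <- pmin(L, p + (k - half))
    g <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    list(g = rev(g), d = p)
}

.geneCovariates <- function(ts, gene, k = 50L) {
    tx <- repTranscripts(ts)[[gene]]
    computeCovariates(ts@seqs[[tx]], k = k)
}

#' Select transcripts for bias-parameter training
#'
#' Keeps genes that (i) have no splice variant, (ii) have a transcript longer
#' than \code{minLength} bp and (iii) have at least one read covering more
#' than \code{minCoverage} of the transcript. If no gene qualifies, the
#' thresholds are relaxed to \code{relaxLength}/\code{relaxCoverage} with a
#' warning (splice-variant-free is still required).
#'
#' @param counts A \linkS4class{PairCounts}.
#' @param ts A \linkS4class{TranscriptSet}.
#' @param minLength Minimum transcript length, bp (default 8000).
#' @param minCoverage Minimum covered fraction (default 0.8).
#' @param relaxLength,relaxCoverage Fallback thresholds.
#' @param minGenes Relax when fewer than this many genes qualify (bias
#'   coefficients estimated from a handful of transcripts are unstable).
#' @return Character vector of gene ids, with attribute \code{relaxed}.
#' @export
selectTrainingGenes <- function(counts, ts, minLength = 8000L,
                                minCoverage = 0.8, relaxLength = 2000L,
                                relaxCoverage = 0.5, minGenes = 10L) {
    nvar <- table(ts@txGene)
    single <- names(nvar)[nvar == 1L]
    reps <- repTranscripts(ts)
    lens <- setNames(Biostrings::width(ts@seqs), names(ts@seqs))[reps]
    names(lens) <- names(reps)
    covfrac <- vapply(names(reps), function(g) {
        cv <- coverageCounts(counts, g)
        mean(cv >= 1L)
    }, numeric(1))
    pick <- function(minL, minC)
        intersect(single,
                  names(reps)[lens > minL & covfrac > minC])
    sel <- pick(minLength, minCoverage)
    relaxed <- FALSE
    if (length(sel) < minGenes) {
        warning("only ", length(sel), " gene(s) meet the training filters; ",
                "relaxing to length > ", relaxLength, " and coverage > ",
                relaxCoverage)
        sel <- pick(relaxLength, relaxCoverage)
        relaxed <- TRUE
        if (!length(sel))
            stop("no usable training transcript even after relaxing filters")
    }
    attr(sel, "relaxed") <- relaxed
    sel
}

#' Initial expression value of one gene
#'
#' Mappability-weighted count sum over the 3'-proximal window: with
#' N' = min(N, \code{maxInit}) positions from the poly-A tail,
#' v0 = sum_k [ (sum_l m_l) / (N' m_k) ] c_k over k = 1..N' with m_k > 0.
#' Restricting to the 3' end keeps the initial value away from the strong
#' poly-A-distance bias affecting distal positions.
#'
#' @param cov Integer coverage vector (distance-from-poly-A indexed).
#' @param m Integer mappability vector, same indexing.
#' @param maxInit Number of 3'-proximal positions used (default 3000).
#' @return Nonnegative numeric scalar; 0 when no position is mappable.
#' @examples
#' initializeExpression(rep(5L, 1000), rep(1L, 1000))   # 5000
#' @export
initializeExpression <- function(cov, m, maxInit = 3000L) {
    N <- length(cov)
    Np <- min(N, maxInit)
    k <- seq_len(Np)
    mk <- m[k]
    ok <- mk > 0L
    if (!any(ok)) return(0)
    sum(sum(mk) / (Np * mk[ok]) * cov[k][ok])
}

#' Fit the coverage-bias Poisson model
#'
#' Alternating optimisation of the positional coverage model
#' log E[c_ij] = log(m_ij / sum_k m_ik) + log v_i + alpha g_ij + beta d_ij:
#' (a) Poisson regression (log link) of the coverage counts on the GC and
#' poly-A-distance covariates with the mappability-plus-expression term as
#' offset updates alpha and beta; (b) the per-gene expression v_i is updated
#' in closed form given alpha and beta. Human and mouse training genes are
#' fitted jointly: the bias coefficients are shared because the sequencing
#' process is the same. Coverage counts (not the sparser read starts) drive
#' the fit.
#'
#' @param counts A \linkS4class{PairCounts}.
#' @param ts A \linkS4class{TranscriptSet}.
#' @param tracks Mappability tracks from \code{\link{mappabilityTracks}}.
#' @param trainGenes Genes to fit on; default
#'   \code{\link{selectTrainingGenes}}.
#' @param stride Position-thinning stride for the regression design (default
#'   1 = all mappable positions).
#' @param tol Convergence tolerance on the relative change of (alpha, beta).
#' @param maxIter Maximum iterations (default 50).
#' @param gcWindow GC covariate window width.
#' @param edgeTrim Positions within \code{edgeTrim} nt of either transcript
#'   end are excluded from the regression design (default 250): coverage
#'   there is truncated at fragment scale (poly-A-proximal pile-up builds up
#'   over one fragment length; the 5' tail cannot be spanned), which the
#'   positional model does not describe. The full transcript still feeds the
#'   expression updates and the final estimator.
#' @return A \linkS4class{BiasModel}; \code{converged} is FALSE when the
#'   iteration limit was hit.
#' @export
fitBiasModel <- function(counts, ts, tracks, trainGenes = NULL, stride = 1L,
                         tol = 1e-6, maxIter = 50L, gcWindow = 50L,
                         edgeTrim = 250L) {
    if (is.null(trainGenes))
        trainGenes <- selectTrainingGenes(counts, ts)
    if (length(trainGenes) < 2L)
        stop("need at least 2 training genes")

    per <- lapply(trainGenes, function(gn) {
        cv <- coverageCounts(counts, gn)
        m <- tracks[[gn]]
        covar <- .geneCovariates(ts, gn, k = gcWindow)
        msum <- sum(m)
        k <- seq(1L, length(cv), by = stride)
        k <- k[m[k] > 0L & k > edgeTrim & k <= length(cv) - edgeTrim]
        list(gene = gn, c = cv[k], g = covar$g[k], d = covar$d[k],
             m = m[k], msum = msum,
             v0 = initializeExpression(cv, m))
    })
    per <- per[vapply(per, function(x) x$v0 > 0 && length(x$c) > 0,
                      logical(1))]
    if (length(per) < 2L)
        stop("fewer than 2 training genes with positive initial expression")

    y <- unlist(lapply(per, `[[`, "c"))
    g <- unlist(lapply(per, `[[`, "g"))
    d <- unlist(lapply(per, `[[`, "d"))
    lm0 <- unlist(lapply(per, function(x) log(x$m / x$msum)))
    gidx <- rep(seq_along(per), vapply(per, function(x) length(x$c),
                                       integer(1)))
    v <- vapply(per, `[[`, numeric(1), "v0")
    X <- cbind(1, g, d)

    idxList <- split(seq_along(y), gidx)
    ySum <- vapply(idxList, function(i) sum(y[i]), numeric(1))

    alpha <- 0; beta <- 0
    converged <- FALSE
    it <- 0L
    for (it in seq_len(maxIter)) {
        fit <- glm.fit(X, y, family = poisson(),
                       offset = lm0 + log(v)[gidx])
        a0 <- fit$coefficients[[1]]
        aNew <- fit$coefficients[[2]]
        bNew <- fit$coefficients[[3]]
        # closed-form v update given the bias coefficients; the regression
        # intercept is absorbed into v so the scale stays with the genes
        w <- exp(a0 + aNew * g + bNew * d + lm0)
        v <- vapply(idxList, function(i) sum(w[i]), numeric(1))
        v <- ySum / v
        delta <- max(abs(aNew - alpha), abs(bNew - beta)) /
            max(abs(aNew), abs(bNew), 1e-8)
        alpha <- aNew; beta <- bNew
        if (delta < tol) { converged <- TRUE; break }
    }
    new("BiasModel", alpha = alpha, beta = beta,
        v = setNames(v, vapply(per, `[[`, character(1), "gene")),
        iterations = it, converged = converged)
}

#' Estimate normalised per-gene copy numbers
#'
#' Applies the fitted bias coefficients to the read-start counts:
#' v_i = sum_k c'_ik / sum_k exp(alpha g_ik + beta d_ik), the denominator
#' running over mappable positions (m_ik > 0) so that masked homologous
#' blocks do not deflate the estimate. Each species is then normalised
#' separately: Z is chosen so the normalised copy numbers of genes at or
#' below the species' 95th percentile (computed over genes with positive
#' expression, linear-interpolation percentile) sum to \code{target},
#' roughly the number of mRNA molecules in an average cell.
#'
#' @param counts A \linkS4class{PairCounts}.
#' @param ts A \linkS4class{TranscriptSet}.
#' @param tracks Mappability tracks.
#' @param model A fitted \linkS4class{BiasModel}.
#' @param target Per-cell mRNA sum (default 300000).
#' @param percentile Upper bound of the summed genes (default 0.95).
#' @param gcWindow GC covariate window width.
#' @return An \linkS4class{ExpressionProfile}.
#' @export
estimateCopyNumbers <- function(counts, ts, tracks, model, target = 3e5,
                                percentile = 0.95, gcWindow = 50L) {
    genes <- geneIds(counts)
    speciesv <- speciesOf(counts)
    raw <- vapply(seq_along(genes), function(i) {
        gn <- genes[[i]]
        st <- startCounts(counts, gn)
        tot <- sum(st)
        if (tot == 0) return(0)
        m <- tracks[[gn]]
        ok <- m > 0L
        if (!any(ok)) return(0)
        covar <- .geneCovariates(ts, gn, k = gcWindow)
        tot / sum(exp(model@alpha * covar$g[ok] + model@beta * covar$d[ok]))
    }, numeric(1))

    tab <- data.frame(gene = genes, species = speciesv, raw = raw,
                      norm = NA_real_, stringsAsFactors = FALSE)
    z <- c()
    for (sp in unique(speciesv)) {
        sel <- tab$species == sp
        vals <- tab$raw[sel]
        if (all(vals == 0))
            stop("all-zero expression for species ", sp)
        p95 <- quantile(vals[vals > 0], percentile, type = 7, names = FALSE)
        zz <- sum(vals[vals <= p95]) / target
        tab$norm[sel] <- vals / zz
        z[sp] <- zz
    }
    new("ExpressionProfile", table = tab, z = z, target = target,
        percentile = percentile)
}

#' Write an expression profile as TSV
#'
#' One row per gene and species, 6-significant-digit numeric formatting.
#'
#' @param profile An \linkS4class{ExpressionProfile}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionProfile <- function(profile, path) {
    tab <- profile@table
    tab$raw <- signif(tab$raw, 6)
    tab$norm <- signif(tab$norm, 6)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
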