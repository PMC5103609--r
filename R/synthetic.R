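#' Simulation configuration
#'
#' Study conditions for the two-species simulator. Defaults emulate the
#' sequencing design the pipeline targets: 50 bp paired-end reads primed
#' from the poly-A tail, coverage decaying with distance from the tail
#' (beta < 0), a slight GC effect (alpha), and cross-species homologous
#' blocks shared verbatim between one human and one mouse gene.
#'
#' @param seed Integer seed; fully determines all output.
#' @param nGenes Genes per species.
#' @param lengthRange Transcript length range, nt (uniform).
#' @param nLongGenes Number of genes per species forced to
#'   \code{longLength} nt so the >8 kb training filter has candidates.
#' @param longLength Length of the long genes.
#' @param homologFraction Fraction of human-mouse gene pairs sharing an
#'   identical block.
#' @param homologLength Shared-block length, nt.
#' @param alpha True GC coefficient (per unit GC fraction).
#' @param beta True poly-A-distance coefficient (per nt).
#' @param vMeanlog,vSdlog Log-normal parameters of the true copy numbers.
#' @param mixHuman Human fraction of the total RNA mix (0.25/0.5/0.75 mirror
#'   mixing experiments).
#' @param pairs Expected number of read pairs.
#' @param fragmentRange Fragment length range, nt.
#' @param readLength Read length (50).
#' @param errorRate Per-base sequencing error rate; at most one error per
#'   mate is realised so alignments stay within the one-mismatch contract.
#' @param gcBlockLength Length of the regional GC blocks, nt.
#' @param gcRange Range of the per-block GC probability.
#' @return A list of class \code{xlrSimConfig}.
#' @export
simulationConfig <- function(seed = 1L, nGenes = 50L,
                             lengthRange = c(1500L, 4000L),
                             nLongGenes = 10L, longLength = 9000L,
                             homologFraction = 0.2, homologLength = 300L,
                             alpha = -2, beta = -1e-3,
                             vMeanlog = log(50), vSdlog = 1,
                             mixHuman = 0.5, pairs = 50000L,
                             fragmentRange = c(100L, 200L),
                             readLength = 50L, errorRate = 0.001,
                             gcBlockLength = 2000L, gcRange = c(0.3, 0.7)) {
    cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
                lengthRange = as.integer(lengthRange),
                nLongGenes = as.integer(nLongGenes),
                longLength = as.integer(longLength),
                homologFraction = homologFraction,
                homologLength = as.integer(homologLength),
                alpha = alpha, beta = beta, vMeanlog = vMeanlog,
                vSdlog = vSdlog, mixHuman = mixHuman,
                pairs = as.integer(pairs),
                fragmentRange = as.integer(fragmentRange),
                readLength = as.integer(readLength),
                errorRate = errorRate,
                gcBlockLength = as.integer(gcBlockLength),
                gcRange = gcRange)
    if (cfg$homologLength > min(cfg$lengthRange))
        stop("homolog block longer than the shortest transcript")
    if (cfg$mixHuman < 0 || cfg$mixHuman > 1)
        stop("mixHuman must be in [0,1]")
    class(cfg) <- "xlrSimConfig"
    cfg
}

# one random sequence with smoothly drifting regional GC: the per-position GC
# probability interpolates linearly between anchors placed every blockLen nt,
# emulating the slow GC drift of real transcripts
.simSeq <- function(len, blockLen, gcRange) {
    nAnchor <- max(2L, ceiling(len / blockLen) + 1L)
    anchors <- runif(nAnchor, gcRange[1], gcRange[2])
    at <- seq(1L, len, length.out = nAnchor)
    gcp <- approx(at, anchors, xout = seq_len(len))$y
    # error-diffusion placement of G/C positions: windowed GC then follows
    # the regional profile with O(1/window) noise instead of binomial noise,
    # so the GC covariate the model reads off the sequence is the profile
    # that generated it
    cum <- cumsum(gcp)
    isgc <- diff(c(0, floor(cum))) >= 1
    base <- character(len)
    base[isgc] <- sample(c("G", "C"), sum(isgc), replace = TRUE)
    base[!isgc] <- sample(c("A", "T"), sum(!isgc), replace = TRUE)
    paste(base, collapse = "")
}

#' Simulate a two-species transcriptome with homologous blocks
#'
#' Deterministic given the config seed. Each species gets \code{nGenes}
#' single-transcript genes; a configured fraction of human-mouse gene pairs
#' shares an identical block whose coordinates are recorded as ground truth.
#' True copy numbers are drawn log-normally and scaled so the human share of
#' the total equals \code{mixHuman}.
#'
#' @param config From \code{\link{simulationConfig}}.
#' @return List: \code{ts} (\linkS4class{TranscriptSet}), \code{vHuman},
#'   \code{vMouse} (named true copy numbers), \code{homologMap} (data.frame
#'   mouse_gene, human_gene), \code{blocks} (data.frame of shared-block
#'   coordinates), \code{config}.
#' @export
simulateTranscriptomes <- function(config) {
    stopifnot(inherits(config, "xlrSimConfig"))
    set.seed(config$seed)
    n <- config$nGenes
    mkGenes <- function(prefix) {
        cand <- seq(config$lengthRange[1], config$lengthRange[2])
        lens <- cand[sample.int(length(cand), n, replace = TRUE)]
        if (config$nLongGenes > 0)
            lens[seq_len(min(config$nLongGenes, n))] <- config$longLength
        genes <- sprintf("%s%03d", prefix, seq_len(n))
        seqs <- vapply(lens, .simSeq, character(1),
                       blockLen = config$gcBlockLength,
                       gcRange = config$gcRange)
        list(genes = genes, lens = lens, seqs = seqs)
    }
    hs <- mkGenes("HGENE")
    mm <- mkGenes("MGENE")

    nShared <- round(config$homologFraction * n)
    blocks <- NULL
    if (nShared > 0) {
        pick <- sample(seq_len(n), nShared)
        bl <- config$homologLength
        rows <- lapply(pick, function(i) {
            hL <- hs$lens[i]; mL <- mm$lens[i]
            hStart <- sample(seq_len(hL - bl + 1L), 1L)
            mStart <- sample(seq_len(mL - bl + 1L), 1L)
            block <- substring(hs$seqs[i], hStart, hStart + bl - 1L)
            mm$seqs[i] <<- paste0(substring(mm$seqs[i], 1L, mStart - 1L),
                                  block,
                                  substring(mm$seqs[i], mStart + bl, mL))
            data.frame(human_gene = hs$genes[i], mouse_gene = mm$genes[i],
                       hStart = hStart, hEnd = hStart + bl - 1L,
                       mStart = mStart, mEnd = mStart + bl - 1L,
                       stringsAsFactors = FALSE)
        })
        blocks <- do.call(rbind, rows)
    }
    if (is.null(blocks))
        blocks <- data.frame(human_gene = character(),
                             mouse_gene = character(), hStart = integer(),
                             hEnd = integer(), mStart = integer(),
                             mEnd = integer(), stringsAsFactors = FALSE)

    tx <- c(paste0(hs$genes, ".t1"), paste0(mm$genes, ".t1"))
    seqs <- Biostrings::DNAStringSet(setNames(c(hs$seqs, mm$seqs), tx))
    ts <- new("TranscriptSet", seqs = seqs,
              txGene = c(hs$genes, mm$genes),
              txSpecies = rep(c("human", "mouse"), each = n))

    vH <- rlnorm(n, config$vMeanlog, config$vSdlog)
    vM <- rlnorm(n, config$vMeanlog, config$vSdlog)
    vH <- vH / sum(vH) * config$mixHuman
    vM <- vM / sum(vM) * (1 - config$mixHuman)
    list(ts = ts,
         vHuman = setNames(vH, hs$genes),
         vMouse = setNames(vM, mm$genes),
         homologMap = data.frame(mouse_gene = mm$genes,
                                 human_gene = hs$genes,
                                 stringsAsFactors = FALSE),
         blocks = blocks, config = config)
}

#' Simulate biased paired-end read placements
#'
#' Realises exactly the coverage model the quantifier fits: for gene i the
#' expected read-start count at distance j from the poly-A tail is
#' proportional to v_i * 1[m_ij > 0] * exp(alpha g_ij + beta d_ij); counts
#' are Poisson. Pairs are emitted as already-placed alignments; a pair whose
#' fragment falls entirely inside a shared homologous block additionally
#' receives the equivalent placement on the partner species' transcript
#' (equal mismatch count), which the assignment stage must exclude as a
#' cross-species tie. Sequencing errors are applied post-placement with at
#' most one mismatch per mate.
#'
#' @param config From \code{\link{simulationConfig}}.
#' @param sim From \code{\link{simulateTranscriptomes}}.
#' @param tracks Optional precomputed mappability tracks (computed from
#'   \code{sim$ts} when NULL).
#' @param seed Seed for the read-level randomness; defaults to
#'   \code{config$seed + 1}.
#' @return List: \code{placements} (data.frame for
#'   \code{\link{assignPairs}}), \code{truth} (data.frame read_id, species,
#'   gene), \code{tracks}.
#' @export
simulateReads <- function(config, sim, tracks = NULL,
                          seed = config$seed + 1L) {
    stopifnot(inherits(config, "xlrSimConfig"))
    if (is.null(tracks)) tracks <- mappabilityTracks(sim$ts)
    set.seed(seed)
    ts <- sim$ts
    reps <- repTranscripts(ts)
    lens <- setNames(Biostrings::width(ts@seqs), names(ts@seqs))
    fmin <- config$fragmentRange[1]; fmax <- config$fragmentRange[2]
    vAll <- c(sim$vHuman, sim$vMouse)
    genes <- names(vAll)
    spec <- c(rep("human", length(sim$vHuman)),
              rep("mouse", length(sim$vMouse)))

    # per-gene start-position weights
    wlist <- lapply(seq_along(genes), function(i) {
        g <- genes[[i]]
        tx <- reps[[g]]
        L <- lens[[tx]]
        m <- tracks[[g]]
        covar <- computeCovariates(ts@seqs[[tx]])
        jmax <- L - fmax + 1L
        if (jmax < 1L) return(numeric(0))
        j <- seq_len(jmax)
        (m[j] > 0L) * exp(config$alpha * covar$g[j] + config$beta * j)
    })
    tot <- sum(vAll * vapply(wlist, sum, numeric(1)))
    scale <- config$pairs / tot

    out <- vector("list", length(genes))
    blocks <- sim$blocks
    rid0 <- 0L
    for (i in seq_along(genes)) {
        w <- wlist[[i]]
        if (!length(w)) next
        lam <- scale * vAll[[i]] * w
        cnt <- rpois(length(lam), lam)
        npair <- sum(cnt)
        if (npair == 0L) next
        j <- rep.int(seq_along(cnt), cnt)
        fcand <- seq(fmin, fmax)
        flen <- fcand[sample.int(length(fcand), npair, replace = TRUE)]
        g <- genes[[i]]
        tx <- reps[[g]]
        L <- lens[[tx]]
        fend <- L - j + 1L
        fstart <- fend - flen + 1L
        e1 <- as.integer(runif(npair) < config$errorRate * config$readLength)
        e2 <- as.integer(runif(npair) < config$errorRate * config$readLength)
        ids <- sprintf("p%07d", rid0 + seq_len(npair))
        rid0 <- rid0 + npair
        pl <- data.frame(read_id = ids, species = spec[[i]], tx = tx,
                         gene = g, fstart = fstart, fend = fend,
                         mm = e1 + e2, e1 = e1, e2 = e2,
                         stringsAsFactors = FALSE)
        # homologous-block double placement
        if (nrow(blocks)) {
            if (spec[[i]] == "human") {
                b <- blocks[blocks$human_gene == g, , drop = FALSE]
                if (nrow(b) == 1L) {
                    hit <- pl$fstart >= b$hStart & pl$fend <= b$hEnd
                    if (any(hit)) {
                        twin <- pl[hit, , drop = FALSE]
                        off <- b$mStart - b$hStart
                        twin$species <- "mouse"
                        twin$gene <- b$mouse_gene
                        twin$tx <- reps[[b$mouse_gene]]
                        twin$fstart <- twin$fstart + off
                        twin$fend <- twin$fend + off
                        pl <- rbind(pl, twin)
                    }
                }
            } else {
                b <- blocks[blocks$mouse_gene == g, , drop = FALSE]
                if (nrow(b) == 1L) {
                    hit <- pl$fstart >= b$mStart & pl$fend <= b$mEnd
                    if (any(hit)) {
                        twin <- pl[hit, , drop = FALSE]
                        off <- b$hStart - b$mStart
                        twin$species <- "human"
                        twin$gene <- b$human_gene
                        twin$tx <- reps[[b$human_gene]]
                        twin$fstart <- twin$fstart + off
                        twin$fend <- twin$fend + off
                        pl <- rbind(pl, twin)
                    }
                }
            }
        }
        out[[i]] <- pl
    }
    pl <- do.call(rbind, out)
    if (is.null(pl))
        pl <- data.frame(read_id = character(), species = character(),
                         tx = character(), gene = character(),
                         fstart = integer(), fend = integer(),
                         mm = integer(), e1 = integer(), e2 = integer(),
                         stringsAsFactors = FALSE)
    rownames(pl) <- NULL
    truth <- pl[!duplicated(pl$read_id), c("read_id", "species", "gene")]
    truth <- truth[order(truth$read_id), , drop = FALSE]
    rownames(truth) <- NULL
    list(placements = pl, truth = truth, tracks = tracks)
}

#' Write the simulated transcriptome as FASTA
#'
#' Reference names carry the species prefix (\code{hs|} / \code{mm|}).
#'
#' @param sim From \code{\link{simulateTranscriptomes}}.
#' @param path Output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeSimulatedFasta <- function(sim, path) {
    ts <- sim$ts
    pre <- ifelse(ts@txSpecies == "human", "hs|", "mm|")
    seqs <- ts@seqs
    names(seqs) <- paste0(pre, names(ts@seqs))
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

# mutate n random bases of a read sequence (used when emitting SAM/FASTQ so
# the written sequence realises the placement's mismatch count)
.mutate <- function(seqchar, n) {
    if (n == 0L) return(seqchar)
    pos <- sample(nchar(seqchar), n)
    for (p in pos) {
        old <- substr(seqchar, p, p)
        substr(seqchar, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old),
                                        1L)
    }
    seqchar
}

#' Write simulated pairs as SAM
#'
#' Emits each placement as a properly paired FR alignment (50M CIGAR, NM
#' tags from the realised per-mate errors); additional placements of the
#' same pair are written as secondary alignments. The result can be read
#' back with \code{\link{readSamPlacements}}.
#'
#' @param reads From \code{\link{simulateReads}}.
#' @param sim From \code{\link{simulateTranscriptomes}}.
#' @param path Output SAM path.
#' @param seed Seed for the error-base placement in the written sequences.
#' @return \code{path}, invisibly.
#' @export
writeSimulatedSam <- function(reads, sim, path, seed = 99L) {
    set.seed(seed)
    ts <- sim$ts
    rl <- sim$config$readLength
    pre <- ifelse(ts@txSpecies == "human", "hs|", "mm|")
    refname <- setNames(paste0(pre, names(ts@seqs)), names(ts@seqs))
    lens <- setNames(Biostrings::width(ts@seqs), names(ts@seqs))
    seqs <- .txStrings(ts)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("@HD\tVN:1.6\tSO:unknown", con)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", refname, lens), con)
    pl <- reads$placements
    primary <- !duplicated(pl$read_id)
    qual <- strrep("I", rl)
    lines <- character(2L * nrow(pl))
    for (r in seq_len(nrow(pl))) {
        sec <- if (primary[r]) 0L else 256L
        p1 <- pl$fstart[r]
        p2 <- pl$fend[r] - rl + 1L
        s1 <- .mutate(substring(seqs[[pl$tx[r]]], p1, p1 + rl - 1L),
                      pl$e1[r])
        s2 <- .mutate(substring(seqs[[pl$tx[r]]], p2, p2 + rl - 1L),
                      pl$e2[r])
        rn <- refname[[pl$tx[r]]]
        tlen <- pl$fend[r] - pl$fstart[r] + 1L
        lines[2L * r - 1L] <- paste(pl$read_id[r], 99L + sec, rn, p1, 60L,
                                    paste0(rl, "M"), "=", p2, tlen, s1,
                                    qual, paste0("NM:i:", pl$e1[r]),
                                    sep = "\t")
        lines[2L * r] <- paste(pl$read_id[r], 147L + sec, rn, p2, 60L,
                               paste0(rl, "M"), "=", p1, -tlen, s2, qual,
                               paste0("NM:i:", pl$e2[r]), sep = "\t")
    }
    writeLines(lines, con)
    invisible(path)
}

#' Write simulated pairs as FASTQ
#'
#' Primary placements only; mate 2 is written reverse-complemented (FR
#' layout) with constant quality.
#'
#' @param reads From \code{\link{simulateReads}}.
#' @param sim From \code{\link{simulateTranscriptomes}}.
#' @param prefix Output prefix; writes \code{<prefix>_1.fastq} and
#'   \code{<prefix>_2.fastq}.
#' @param seed Seed for the error-base placement.
#' @return Character vector of the two paths, invisibly.
#' @export
writeSimulatedFastq <- function(reads, sim, prefix, seed = 99L) {
    set.seed(seed)
    rl <- sim$config$readLength
    seqs <- .txStrings(sim$ts)
    pl <- reads$placements[!duplicated(reads$placements$read_id), ,
                           drop = FALSE]
    qual <- strrep("I", rl)
    f1 <- paste0(prefix, "_1.fastq"); f2 <- paste0(prefix, "_2.fastq")
    s1 <- s2 <- character(nrow(pl))
    for (r in seq_len(nrow(pl))) {
        p1 <- pl$fstart[r]
        p2 <- pl$fend[r] - rl + 1L
        s1[r] <- .mutate(substring(seqs[[pl$tx[r]]], p1, p1 + rl - 1L),
                         pl$e1[r])
        rc <- .mutate(substring(seqs[[pl$tx[r]]], p2, p2 + rl - 1L),
                      pl$e2[r])
        s2[r] <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(rc)))
    }
    writeLines(paste0("@", pl$read_id, "/1\n", s1, "\n+\n", qual), f1)
    writeLines(paste0("@", pl$read_id, "/2\n", s2, "\n+\n", qual), f2)
    invisible(c(f1, f2))
}
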