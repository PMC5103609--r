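#' Read a pre-tabulated placements table
#'
#' A placements TSV lists every candidate alignment of every read pair, one
#' row per (pair, transcript) placement, with columns \code{read_id},
#' \code{species}, \code{tx}, \code{gene}, \code{fstart}, \code{fend}
#' (fragment span in 1-based 5'->3' transcript coordinates) and \code{mm}
#' (total mismatches of the two mates).
#'
#' @param path Path to the TSV file.
#' @return data.frame of placements.
#' @export
readPlacements <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("read_id", "species", "tx", "gene", "fstart", "fend", "mm")
    if (!all(need %in% names(tab)))
        stop("placements table must have columns ",
             paste(need, collapse = ", "))
    tab
}

# cigar -> aligned reference width; only M/I/S/=/X/D/N handled (no hard clips
# in our SAM output)
.cigarRefWidth <- function(cigar) {
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)
    vapply(seq_along(cigar), function(i) {
        m <- regmatches(cigar[i], ops[i])[[1]]
        n <- as.integer(sub("[A-Z=]$", "", m))
        o <- sub("^[0-9]+", "", m)
        sum(n[o %in% c("M", "D", "N", "=", "X")])
    }, integer(1))
}

#' Read paired-end placements from a SAM file
#'
#' Parses a SAM file of paired-end alignments against the combined
#' two-species transcript set (reference names prefixed \code{hs|} /
#' \code{mm|}) and returns the placements table consumed by
#' \code{\link{assignPairs}}. Only placements where both mates hit the same
#' transcript are retained; per-pair mismatches are the sum of the mates' NM
#' tags.
#'
#' @param path Path to the SAM file.
#' @param ts A \linkS4class{TranscriptSet} giving the gene of each transcript.
#' @return data.frame with the \code{\link{readPlacements}} columns.
#' @export
readSamPlacements <- function(path, ts) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
    p <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "cigar"),
        tag = "NM")
    b <- Rsamtools::scanBam(bam, param = p)[[1]]
    if (!length(b$qname)) {
        return(data.frame(read_id = character(), species = character(),
                          tx = character(), gene = character(),
                          fstart = integer(), fend = integer(),
                          mm = integer(), stringsAsFactors = FALSE))
    }
    ref <- as.character(b$rname)
    species <- ifelse(startsWith(ref, "hs|"), "human",
                      ifelse(startsWith(ref, "mm|"), "mouse", NA))
    tx <- sub("^(hs|mm)\\|", "", ref)
    gene <- ts@txGene[match(tx, names(ts@seqs))]
    nm <- b$tag$NM
    if (is.null(nm)) nm <- rep(0L, length(ref))
    nm[is.na(nm)] <- 0L
    mate1 <- bitwAnd(b$flag, 64L) > 0L
    end <- b$pos + .cigarRefWidth(b$cigar) - 1L
    dt <- data.table(read_id = b$qname, species = species, tx = tx,
                     gene = gene, pos = b$pos, end = end, mm = nm,
                     mate1 = mate1)
    dt <- dt[!is.na(species) & !is.na(gene)]
    # both mates on the same transcript make one placement
    pl <- dt[, list(n1 = sum(mate1), n2 = sum(!mate1),
                    fstart = min(pos), fend = max(end), mm = sum(mm)),
             by = c("read_id", "species", "tx", "gene")]
    pl <- pl[pl$n1 >= 1L & pl$n2 >= 1L]
    as.data.frame(pl[, c("read_id", "species", "tx", "gene", "fstart",
                         "fend", "mm")])
}

#' Assign read pairs to a species and gene
#'
#' Deterministic best-hit assignment: among each pair's placements the
#' minimum-mismatch set is taken; if all its placements belong to one gene of
#' one species the pair is assigned there (multiple splice variants of that
#' gene are allowed and count once), a strictly better (fewer-mismatch)
#' placement winning over worse ones. Pairs whose minimum-mismatch placements
#' are tied across species are excluded as \code{cross_species_tie}; ties
#' across different genes of one species as \code{multi_gene_tie}; pairs with
#' no placements as \code{unmapped}. Output is independent of the input row
#' order.
#'
#' @param placements data.frame from \code{\link{readPlacements}} or
#'   \code{\link{readSamPlacements}}.
#' @param readIds Optional character vector of all evaluated pair ids;
#'   ids absent from \code{placements} are reported as unmapped.
#' @return data.frame with one row per pair: read_id, status ("assigned",
#'   "cross_species_tie", "multi_gene_tie", "unmapped"), species, gene, tx,
#'   fstart, fend (NA unless assigned; coordinates are those of the chosen
#'   placement, preferring the gene's lexicographically first transcript).
#' @export
assignPairs <- function(placements, readIds = NULL) {
    dt <- data.table(placements)
    if (nrow(dt) == 0L) {
        out <- data.frame(read_id = character(), status = character(),
                          species = character(), gene = character(),
                          tx = character(), fstart = integer(),
                          fend = integer(), stringsAsFactors = FALSE)
        if (!is.null(readIds) && length(readIds))
            out <- data.frame(read_id = sort(readIds), status = "unmapped",
                              species = NA_character_, gene = NA_character_,
                              tx = NA_character_, fstart = NA_integer_,
                              fend = NA_integer_, stringsAsFactors = FALSE)
        return(out)
    }
    # canonical order makes the result independent of input order
    dt <- dt[order(dt$read_id, dt$mm, dt$species, dt$gene, dt$tx,
                   dt$fstart)]
    res <- dt[, {
        best <- mm == min(mm)
        sp <- unique(species[best])
        gn <- unique(gene[best])
        if (length(sp) > 1L) {
            list(status = "cross_species_tie", species = NA_character_,
                 gene = NA_character_, tx = NA_character_,
                 fstart = NA_integer_, fend = NA_integer_)
        } else if (length(gn) > 1L) {
            list(status = "multi_gene_tie", species = NA_character_,
                 gene = NA_character_, tx = NA_character_,
                 fstart = NA_integer_, fend = NA_integer_)
        } else {
            i <- which(best)[1L]
            list(status = "assigned", species = species[i], gene = gene[i],
                 tx = tx[i], fstart = as.integer(fstart[i]),
                 fend = as.integer(fend[i]))
        }
    }, by = "read_id"]
    out <- as.data.frame(res)
    if (!is.null(readIds)) {
        missing <- setdiff(readIds, out$read_id)
        if (length(missing))
            out <- rbind(out, data.frame(
                read_id = missing, status = "unmapped",
                species = NA_character_, gene = NA_character_,
                tx = NA_character_, fstart = NA_integer_,
                fend = NA_integer_, stringsAsFactors = FALSE))
    }
    out[order(out$read_id), , drop = FALSE]
}

#' Accumulate positional counts from assigned pairs
#'
#' Builds per-gene coverage counts c (fragments covering nucleotide j) and
#' read-start counts c' (fragments whose 3'-proximal end is at j) on the
#' representative transcript, with j = 1 the 3'-terminal nucleotide. Counts
#' from a splice variant are projected onto the representative transcript by
#' the distance-from-poly-A coordinate; fragments that fall outside its
#' bounds are dropped with a warning.
#'
#' @param assignments data.frame from \code{\link{assignPairs}}.
#' @param ts A \linkS4class{TranscriptSet}.
#' @return A \linkS4class{PairCounts} covering every gene in \code{ts}.
#' @export
accumulateCounts <- function(assignments, ts) {
    reps <- repTranscripts(ts)
    lens <- setNames(Biostrings::width(ts@seqs), names(ts@seqs))
    genes <- names(reps)
    gspecies <- ts@txSpecies[match(reps, names(ts@seqs))]
    repLen <- lens[reps]

    a <- assignments[assignments$status == "assigned", , drop = FALSE]
    Ltx <- lens[a$tx]
    j1 <- Ltx - a$fend + 1L      # 3'-proximal fragment end
    j2 <- Ltx - a$fstart + 1L
    Lrep <- repLen[match(a$gene, genes)]
    oob <- j1 < 1L | j2 > Lrep
    if (any(oob)) {
        warning(sum(oob), " pair(s) outside representative transcript ",
                "bounds dropped")
        a <- a[!oob, , drop = FALSE]
        j1 <- j1[!oob]; j2 <- j2[!oob]
    }

    cov <- lapply(repLen, function(L) integer(L))
    sta <- lapply(repLen, function(L) integer(L))
    names(cov) <- names(sta) <- genes
    if (nrow(a)) {
        sp <- split(seq_len(nrow(a)), a$gene)
        for (g in names(sp)) {
            idx <- sp[[g]]
            L <- repLen[[match(g, genes)]]
            delta <- integer(L + 1L)
            t1 <- tabulate(j1[idx], nbins = L)
            t2 <- tabulate(j2[idx] + 1L, nbins = L + 1L)
            delta[seq_len(L)] <- t1
            delta <- delta - t2
            cov[[g]] <- as.integer(cumsum(delta[seq_len(L)]))
            sta[[g]] <- t1
        }
    }

    st <- table(factor(assignments$status,
                       levels = c("assigned", "cross_species_tie",
                                  "multi_gene_tie", "unmapped")))
    asp <- table(factor(a$species, levels = c("human", "mouse")))
    tal <- c(total = nrow(assignments),
             assignedHuman = as.numeric(asp[["human"]]),
             assignedMouse = as.numeric(asp[["mouse"]]),
             excludedCrossSpecies = as.numeric(st[["cross_species_tie"]]),
             excludedMultiGene = as.numeric(st[["multi_gene_tie"]]),
             excludedUnmapped = as.numeric(st[["unmapped"]]),
             dropped = as.numeric(sum(oob)))
    new("PairCounts", gene = genes, species = unname(gspecies), cov = cov,
        starts = sta, tallies = tal)
}

#' Summarise species assignment of a sample
#'
#' Computes the mouse read percentage 100 d / (c + d) from the human (c) and
#' mouse (d) assigned-pair counts, rounded to 2 decimals, and — when the true
#' species of a single-species sample is declared — the misassignment rate
#' (share of pairs assigned to the wrong species), rounded to 4 decimals.
#'
#' @param x A \linkS4class{PairCounts}, or the number of pairs assigned to
#'   human.
#' @param mouse Number of pairs assigned to mouse (numeric input only).
#' @param truthSpecies Optional "human" or "mouse" for single-species
#'   samples.
#' @param total Optional total evaluated pairs (defaults to human + mouse for
#'   numeric input).
#' @return List with total, human, mouse, mousePercent and (if truth given)
#'   misassignmentPercent.
#' @examples
#' summarizeSample(18147400, 2041946)$mousePercent   # 10.11
#' @export
summarizeSample <- function(x, mouse = NULL, truthSpecies = NULL,
                            total = NULL) {
    if (is(x, "PairCounts")) {
        t <- tallies(x)
        human <- t[["assignedHuman"]]
        mouse <- t[["assignedMouse"]]
        if (is.null(total)) total <- t[["total"]]
    } else {
        human <- as.numeric(x)
        mouse <- as.numeric(mouse)
        if (is.null(total)) total <- human + mouse
    }
    if (human + mouse <= 0)
        stop("no assigned pairs: summary undefined")
    if (human + mouse > total)
        stop("assigned pairs exceed total")
    out <- list(total = total, human = human, mouse = mouse,
                mousePercent = round(100 * mouse / (human + mouse), 2))
    if (!is.null(truthSpecies)) {
        truthSpecies <- match.arg(truthSpecies, c("human", "mouse"))
        wrong <- if (truthSpecies == "human") mouse else human
        out$misassignmentPercent <- round(100 * wrong / (human + mouse), 4)
    }
    out
}
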