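#' @importFrom data.table data.table setkey setnames rbindlist :=
NULL

# Internal: per-transcript character sequences and gene/species group labels.
.txStrings <- function(ts) {
    s <- as.character(ts@seqs)
    names(s) <- names(ts@seqs)
    s
}

.txGroups <- function(ts) paste(ts@txSpecies, ts@txGene, sep = "\r")

# Hamming distance between equal-width string vectors, vectorised over pairs.
.hamming <- function(x, y, k) {
    mm <- integer(length(x))
    for (i in seq_len(k))
        mm <- mm + (substr(x, i, i) != substr(y, i, i))
    mm
}

#' Uniqueness flags for every k-bp window of every transcript
#'
#' A window is unique (mappable) iff its k-mer does not occur, within
#' \code{maxMismatch} mismatches, anywhere else in the combined two-species
#' transcript database outside transcripts of the same gene and species.
#' Splice-variant self-hits therefore do not destroy uniqueness. Exact
#' duplicates are found by k-mer hashing; single-mismatch occurrences by a
#' pigeonhole split into two half-windows (an occurrence with at most one
#' mismatch matches at least one half exactly) followed by verification.
#'
#' @param ts A \linkS4class{TranscriptSet}.
#' @param k Window length in bp (default 50, the read length).
#' @param maxMismatch 0 or 1 mismatches tolerated in a colliding occurrence.
#' @param checkRevComp Also treat reverse-complement occurrences as
#'   collisions (default TRUE).
#' @return Named list (per transcript) of logical vectors over window start
#'   positions 1..L-k+1 in 5'->3' coordinates; TRUE = unique. Transcripts
#'   shorter than k get a zero-length vector.
#' @export
windowUniqueFlags <- function(ts, k = 50L, maxMismatch = 1L,
                              checkRevComp = TRUE) {
    stopifnot(k >= 2L, maxMismatch %in% c(0L, 1L))
    seqs <- .txStrings(ts)
    grps <- .txGroups(ts)
    lens <- nchar(seqs)

    # subjects: forward transcripts, plus reverse complements as collision
    # sources only
    subj <- data.frame(sid = names(seqs), seq = unname(seqs), grp = grps,
                       len = unname(lens), stringsAsFactors = FALSE)
    if (checkRevComp) {
        rc <- as.character(Biostrings::reverseComplement(ts@seqs))
        subj <- rbind(subj, data.frame(
            sid = paste0(names(seqs), ":rc"), seq = unname(rc), grp = grps,
            len = unname(lens), stringsAsFactors = FALSE))
    }

    winStarts <- function(L) if (L >= k) seq_len(L - k + 1L) else integer()

    # windows to classify (forward strand only)
    wtab <- rbindlist(lapply(seq_along(seqs), function(i) {
        st <- winStarts(lens[[i]])
        if (!length(st)) return(NULL)
        data.table(tx = names(seqs)[[i]], s = st, grp = grps[[i]],
                   kmer = substring(seqs[[i]], st, st + k - 1L))
    }))
    flags <- lapply(lens, function(L) rep(TRUE, max(0L, L - k + 1L)))
    names(flags) <- names(seqs)
    if (is.null(wtab) || nrow(wtab) == 0L) return(flags)

    # exact collisions: every occurrence of a full k-mer in the database is a
    # window of some subject
    occ <- rbindlist(lapply(seq_len(nrow(subj)), function(i) {
        st <- winStarts(subj$len[[i]])
        if (!length(st)) return(NULL)
        data.table(kmer = substring(subj$seq[[i]], st, st + k - 1L),
                   ogrp = subj$grp[[i]])
    }))
    kg <- unique(occ, by = c("kmer", "ogrp"))
    ngrp <- kg[, list(n = .N), by = "kmer"]
    multi <- ngrp$kmer[ngrp$n > 1L]
    bad <- wtab$kmer %in% multi
    # a k-mer seen in exactly one group collides only if that group differs
    one <- ngrp$kmer[ngrp$n == 1L]
    og <- setNames(kg$ogrp[match(one, kg$kmer)], one)
    in1 <- !bad & wtab$kmer %in% one
    bad[in1] <- og[wtab$kmer[in1]] != wtab$grp[in1]
    # (forward self-occurrence is always in own group, so same-group single
    # means no foreign exact hit)

    if (maxMismatch >= 1L) {
        h <- k %/% 2L
        h2 <- k - h
        halfIndex <- function(width) {
            rbindlist(lapply(seq_len(nrow(subj)), function(i) {
                L <- subj$len[[i]]
                if (L < k) return(NULL)
                st <- seq_len(L - width + 1L)
                data.table(half = substring(subj$seq[[i]], st,
                                            st + width - 1L),
                           sidx = i, pos = st)
            }))
        }
        idx1 <- halfIndex(h)
        idx2 <- if (h2 == h) idx1 else halfIndex(h2)

        todo <- which(!bad)
        if (length(todo)) {
            w <- wtab[todo]
            w[, wid := todo]
            w[, half1 := substring(kmer, 1L, h)]
            w[, half2 := substring(kmer, h + 1L, k)]
            c1 <- merge(w[, list(wid, grp, kmer, half = half1)], idx1,
                        by = "half", allow.cartesian = TRUE)
            c1[, qstart := pos]
            c2 <- merge(w[, list(wid, grp, kmer, half = half2)], idx2,
                        by = "half", allow.cartesian = TRUE)
            c2[, qstart := pos - h]
            cand <- rbind(c1[, list(wid, grp, kmer, sidx, qstart)],
                          c2[, list(wid, grp, kmer, sidx, qstart)])
            cand <- cand[qstart >= 1L & qstart + k - 1L <= subj$len[sidx]]
            cand <- cand[grp != subj$grp[sidx]]
            cand <- unique(cand, by = c("wid", "sidx", "qstart"))
            if (nrow(cand)) {
                other <- substring(subj$seq[cand$sidx], cand$qstart,
                                   cand$qstart + k - 1L)
                hit <- .hamming(cand$kmer, other, k) <= maxMismatch
                bad[unique(cand$wid[hit])] <- TRUE
            }
        }
    }

    wt <- data.frame(tx = wtab$tx, s = wtab$s, bad = bad,
                     stringsAsFactors = FALSE)
    for (txid in unique(wt$tx)) {
        sel <- wt$tx == txid
        flags[[txid]][wt$s[sel]] <- !wt$bad[sel]
    }
    flags
}

#' Is one k-bp window uniquely mappable?
#'
#' Single-window form of \code{\link{windowUniqueFlags}}.
#'
#' @param ts A \linkS4class{TranscriptSet}.
#' @param tx Transcript id.
#' @param start Window start (1-based, 5'->3').
#' @param k Window length.
#' @param maxMismatch Mismatch tolerance (0 or 1).
#' @param checkRevComp Also check reverse-complement occurrences.
#' @return 1L if unique, 0L otherwise.
#' @export
windowUnique <- function(ts, tx, start, k = 50L, maxMismatch = 1L,
                         checkRevComp = TRUE) {
    i <- match(tx, names(ts@seqs))
    if (is.na(i)) stop("unknown transcript: ", tx)
    L <- Biostrings::width(ts@seqs)[i]
    if (k > L) stop("window length ", k, " exceeds transcript length ", L)
    if (start < 1L || start + k - 1L > L) stop("window outside transcript")
    flags <- windowUniqueFlags(ts, k = k, maxMismatch = maxMismatch,
                               checkRevComp = checkRevComp)
    as.integer(flags[[tx]][start])
}

#' Per-nucleotide mappability from window flags
#'
#' m_j = number of unique k-bp windows covering nucleotide j; an interior
#' nucleotide of an all-unique transcript has m = k, a terminal one m = 1.
#'
#' @param flags Logical vector over window starts (5'->3'), as one element of
#'   \code{\link{windowUniqueFlags}} output.
#' @param len Transcript length.
#' @param k Window length used to compute \code{flags}.
#' @return Integer vector of length \code{len}, 5'->3' orientation.
#' @export
mappablePerNucleotide <- function(flags, len, k = 50L) {
    if (len < k) return(integer(len))
    u <- as.integer(flags)
    cs <- c(0L, cumsum(u))
    p <- seq_len(len)
    lo <- pmax(1L, p - k + 1L)
    hi <- pmin(p, len - k + 1L)
    out <- cs[hi + 1L] - cs[lo]
    out[hi < lo] <- 0L
    as.integer(out)
}

#' Mappability tracks for all genes
#'
#' Computes, for the representative (longest) transcript of every gene, the
#' per-nucleotide 50 bp mappability m_j against the combined two-species
#' database, indexed by distance from the poly-A tail (j = 1 is the
#' 3'-terminal nucleotide). Deterministic and bit-exact across runs.
#'
#' @inheritParams windowUniqueFlags
#' @return Named list per gene id of integer vectors (length = representative
#'   transcript length) in distance-from-poly-A orientation.
#' @export
mappabilityTracks <- function(ts, k = 50L, maxMismatch = 1L,
                              checkRevComp = TRUE) {
    flags <- windowUniqueFlags(ts, k = k, maxMismatch = maxMismatch,
                               checkRevComp = checkRevComp)
    reps <- repTranscripts(ts)
    lens <- setNames(Biostrings::width(ts@seqs), names(ts@seqs))
    out <- lapply(names(reps), function(g) {
        tx <- reps[[g]]
        rev(mappablePerNucleotide(flags[[tx]], lens[[tx]], k = k))
    })
    names(out) <- names(reps)
    out
}

#' Write mappability tracks as TSV
#'
#' Run-length encoded per-gene track (gene, start_j, end_j, m) so identical
#' runs collapse to one row; bit-exact across runs.
#'
#' @param tracks Output of \code{\link{mappabilityTracks}}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeMappabilityTracks <- function(tracks, path) {
    rows <- lapply(names(tracks), function(g) {
        r <- rle(tracks[[g]])
        e <- cumsum(r$lengths)
        data.frame(gene = g, start_j = e - r$lengths + 1L, end_j = e,
                   m = r$values, stringsAsFactors = FALSE)
    })
    write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
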