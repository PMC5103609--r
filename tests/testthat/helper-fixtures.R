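# shared fixtures built in code

# random sequence of given length (seeded by caller)
randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

# tiny two-species transcript set: one gene per species, unrelated sequences
tinyTs <- function(seed = 42, len = 300) {
    set.seed(seed)
    TranscriptSet(c(hTX1 = randSeq(len), mTX1 = randSeq(len)),
                  gene = c("HG1", "MG1"),
                  species = c("human", "mouse"))
}

writeTsv <- function(df, path = tempfile(fileext = ".tsv")) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

# brute-force mappability oracle: for every window, scan every other-group
# window (forward and reverse complement) and compare by Hamming distance
bruteUniqueFlags <- function(ts, k = 50L, maxMismatch = 1L,
                             checkRevComp = TRUE) {
    seqs <- as.character(ts@seqs)
    grp <- paste(speciesOf(ts), geneIds(ts))
    lens <- nchar(seqs)
    hamming <- function(a, b) {
        sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }
    subj <- data.frame(seq = unname(seqs), grp = grp,
                       stringsAsFactors = FALSE)
    if (checkRevComp) {
        rc <- as.character(Biostrings::reverseComplement(ts@seqs))
        subj <- rbind(subj, data.frame(seq = unname(rc), grp = grp,
                                       stringsAsFactors = FALSE))
    }
    lapply(seq_along(seqs), function(i) {
        L <- lens[[i]]
        if (L < k) return(logical(0))
        vapply(seq_len(L - k + 1L), function(s) {
            w <- substring(seqs[[i]], s, s + k - 1L)
            for (r in seq_len(nrow(subj))) {
                if (subj$grp[[r]] == grp[[i]]) next
                Lr <- nchar(subj$seq[[r]])
                if (Lr < k) next
                for (q in seq_len(Lr - k + 1L)) {
                    o <- substring(subj$seq[[r]], q, q + k - 1L)
                    if (hamming(w, o) <= maxMismatch) return(FALSE)
                }
            }
            TRUE
        }, logical(1))
    })
}

# brute-force oracle for the pair assignment rule: enumerate the minimum
# mismatch placements and apply the exclusion conditions literally
bruteAssign <- function(placements) {
    best <- placements[placements$mm == min(placements$mm), , drop = FALSE]
    if (length(unique(best$species)) > 1L) return("cross_species_tie")
    if (length(unique(best$gene)) > 1L) return("multi_gene_tie")
    "assigned"
}

# a PairCounts built directly from per-gene start-count vectors (uniform
# coverage equal to starts), bypassing assignment
countsFromStarts <- function(ts, starts) {
    reps <- repTranscripts(ts)
    lens <- setNames(Biostrings::width(ts@seqs), names(ts@seqs))
    genes <- names(reps)
    sp <- speciesOf(ts)[match(reps, txIds(ts))]
    sta <- lapply(genes, function(g) {
        v <- integer(lens[[reps[[g]]]])
        if (!is.null(starts[[g]])) v[seq_along(starts[[g]])] <- starts[[g]]
        v
    })
    names(sta) <- genes
    tot <- sum(vapply(sta, sum, numeric(1)))
    new("PairCounts", gene = genes, species = unname(sp), cov = sta,
        starts = sta,
        tallies = c(total = tot,
                    assignedHuman = sum(vapply(which(sp == "human"),
                        function(i) sum(sta[[i]]), numeric(1))),
                    assignedMouse = sum(vapply(which(sp == "mouse"),
                        function(i) sum(sta[[i]]), numeric(1))),
                    excludedCrossSpecies = 0, excludedMultiGene = 0,
                    excludedUnmapped = 0, dropped = 0))
}

# all-mappable tracks for a TranscriptSet (used when the test controls the
# counts directly and mappability is not under test)
onesTracks <- function(ts) {
    reps <- repTranscripts(ts)
    lens <- setNames(Biostrings::width(ts@seqs), names(ts@seqs))
    out <- lapply(names(reps), function(g) rep(1L, lens[[reps[[g]]]]))
    names(out) <- names(reps)
    out
}
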