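mkPlacement <- function(read_id, species, gene, mm, tx = paste0(gene, ".t1"),
                        fstart = 1L, fend = 150L) {
    data.frame(read_id = read_id, species = species, tx = tx, gene = gene,
               fstart = fstart, fend = fend, mm = mm,
               stringsAsFactors = FALSE)
}

test_that("pair assignment follows the best-hit / tie-exclusion rule", {
    # single candidate
    a <- assignPairs(mkPlacement("r1", "human", "GENE1", 0L))
    expect_equal(a$status, "assigned")
    expect_equal(a$gene, "GENE1")

    # equal-mismatch cross-species tie is excluded
    a <- assignPairs(rbind(mkPlacement("r1", "human", "GENE1", 0L),
                           mkPlacement("r1", "mouse", "Gene2", 0L)))
    expect_equal(a$status, "cross_species_tie")

    # strictly better placement wins across species
    a <- assignPairs(rbind(mkPlacement("r1", "human", "GENE1", 0L),
                           mkPlacement("r1", "mouse", "Gene2", 1L)))
    expect_equal(a$status, "assigned")
    expect_equal(a$species, "human")

    # tie across two genes of one species is excluded
    a <- assignPairs(rbind(mkPlacement("r1", "human", "GENE1", 0L),
                           mkPlacement("r1", "human", "GENE3", 0L)))
    expect_equal(a$status, "multi_gene_tie")

    # multiple splice variants of one gene are fine
    a <- assignPairs(rbind(mkPlacement("r1", "human", "GENE1", 0L,
                                       tx = "GENE1.t1"),
                           mkPlacement("r1", "human", "GENE1", 0L,
                                       tx = "GENE1.t2")))
    expect_equal(a$status, "assigned")

    # no placements at all -> unmapped
    a <- assignPairs(mkPlacement("r1", "human", "GENE1", 0L)[0, ],
                     readIds = "r1")
    expect_equal(a$status, "unmapped")
})

test_that("assignment agrees with brute-force rule over all mismatch combos", {
    # two candidate placements (human GENE1, mouse Gene2) with every
    # mismatch combination in {0,1,2}^2, plus three-placement cases
    for (m1 in 0:2) for (m2 in 0:2) {
        pl <- rbind(mkPlacement("r", "human", "GENE1", m1),
                    mkPlacement("r", "mouse", "Gene2", m2))
        expect_equal(assignPairs(pl)$status, bruteAssign(pl),
                     info = sprintf("mm=(%d,%d)", m1, m2))
    }
    set.seed(7)
    for (i in 1:20) {
        pl <- rbind(mkPlacement("r", "human", "GENE1", sample(0:2, 1)),
                    mkPlacement("r", "human", "GENE3", sample(0:2, 1)),
                    mkPlacement("r", "mouse", "Gene2", sample(0:2, 1)))
        expect_equal(assignPairs(pl)$status, bruteAssign(pl))
    }
})

test_that("assignment is order-independent and partitions all pairs", {
    set.seed(11)
    pl <- do.call(rbind, lapply(1:50, function(i) {
        n <- sample(1:3, 1)
        do.call(rbind, lapply(seq_len(n), function(j)
            mkPlacement(sprintf("r%02d", i),
                        sample(c("human", "mouse"), 1),
                        sample(c("GENE1", "GENE2", "GENE3"), 1),
                        sample(0:2, 1), fstart = 1L, fend = 100L)))
    }))
    a1 <- assignPairs(pl)
    a2 <- assignPairs(pl[sample(nrow(pl)), ])
    expect_identical(a1, a2)
    # partition: every evaluated pair has exactly one status
    expect_equal(nrow(a1), length(unique(pl$read_id)))
    expect_true(all(a1$status %in% c("assigned", "cross_species_tie",
                                     "multi_gene_tie")))
})

test_that("count accumulation uses distance-from-poly-A coordinates", {
    set.seed(5)
    ts <- TranscriptSet(c(TX1 = randSeq(1000)), gene = "G1",
                        species = "human")
    # one pair spanning positions 1-100 (genomic orientation) of 1000 nt:
    # distances from the poly-A tail are 901..1000
    a <- assignPairs(data.frame(read_id = "r1", species = "human",
                                tx = "TX1", gene = "G1", fstart = 1L,
                                fend = 100L, mm = 0L,
                                stringsAsFactors = FALSE))
    cnt <- accumulateCounts(a, ts)
    cv <- coverageCounts(cnt, "G1")
    expect_equal(which(cv == 1L), 901:1000)
    # the read start (3'-proximal fragment end) is at distance 901
    expect_equal(which(startCounts(cnt, "G1") == 1L), 901L)

    # zero assignments give all-zero counts
    cnt0 <- accumulateCounts(a[0, ], ts)
    expect_true(all(coverageCounts(cnt0, "G1") == 0L))

    # 10 identical pairs put c' = 10 at one position
    a10 <- assignPairs(do.call(rbind, lapply(1:10, function(i)
        data.frame(read_id = paste0("r", i), species = "human", tx = "TX1",
                   gene = "G1", fstart = 801L, fend = 950L, mm = 0L,
                   stringsAsFactors = FALSE))))
    cnt10 <- accumulateCounts(a10, ts)
    expect_equal(max(startCounts(cnt10, "G1")), 10L)
    expect_equal(sum(startCounts(cnt10, "G1")), 10L)
})

test_that("splice-variant counts project onto the representative transcript", {
    set.seed(6)
    long <- randSeq(500)
    ts <- TranscriptSet(c(T1 = long, T2 = substring(long, 201, 500)),
                        gene = c("G1", "G1"), species = c("human", "human"))
    # a pair on the short variant at its 3' end: distance coordinates agree
    # with the representative (longest) transcript
    a <- assignPairs(data.frame(read_id = "r1", species = "human",
                                tx = "T2", gene = "G1", fstart = 251L,
                                fend = 300L, mm = 0L,
                                stringsAsFactors = FALSE))
    cnt <- accumulateCounts(a, ts)
    expect_equal(which(coverageCounts(cnt, "G1") == 1L), 1:50)
})

test_that("sample summaries reproduce the published arithmetic", {
    expect_equal(summarizeSample(18147400, 2041946)$mousePercent, 10.11)
    expect_equal(summarizeSample(11713564, 9796740)$mousePercent, 45.54)
    s <- summarizeSample(32194053, 1821, truthSpecies = "human")
    expect_equal(s$misassignmentPercent, 0.0057)
    expect_error(summarizeSample(0, 0), "undefined")
})
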