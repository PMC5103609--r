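test_that("covariates follow the window-GC and poly-A-distance conventions", {
    cv <- computeCovariates(strrep("G", 80))
    expect_true(all(cv$g == 1))
    expect_true(all(computeCovariates(strrep("A", 80))$g == 0))
    # d is 1-based distance from the 3' terminus
    expect_equal(cv$d[1], 1L)
    expect_equal(cv$d[80], 80L)
    # mixed sequence: window clipped at the ends still a fraction in [0,1]
    set.seed(31)
    g <- computeCovariates(randSeq(200))$g
    expect_true(all(g >= 0 & g <= 1))
})

test_that("initial expression evaluates the mappability-weighted formula", {
    # uniform coverage 5, full mappability, N = 1000: each term is 5
    expect_equal(initializeExpression(rep(5L, 1000), rep(1L, 1000)), 5000)
    # zero counts give zero
    expect_equal(initializeExpression(integer(100), rep(1L, 100)), 0)
    # all positions unmappable give zero
    expect_equal(initializeExpression(rep(3L, 100), integer(100)), 0)
    # only the first min(N, 3000) positions from the poly-A tail are used
    cov <- c(rep(1L, 3000), rep(1000L, 7000))
    expect_equal(initializeExpression(cov, rep(1L, 10000)), 3000)
    # non-uniform mappability reweights: m = c(1,2), c = c(2,4)
    # sum_l m = 3, N' = 2; terms 3/(2*1)*2 + 3/(2*2)*4 = 3 + 3
    expect_equal(initializeExpression(c(2L, 4L), c(1L, 2L)), 6)
})

test_that("training-transcript filters apply conditions (i)-(iii)", {
    set.seed(32)
    seqs <- c(A.t1 = randSeq(9000),          # long, will be well covered
              B.t1 = randSeq(9000),          # long, poorly covered
              C.t1 = randSeq(9000),          # has a splice variant
              C.t2 = randSeq(4000),
              D.t1 = randSeq(3000))          # too short
    ts <- TranscriptSet(seqs, gene = c("A", "B", "C", "C", "D"),
                        species = rep("human", 5))
    starts <- list(A = rep(1L, 8500), B = c(rep(1L, 900), integer(8000)),
                   C = rep(1L, 8500), D = rep(1L, 2900))
    cnt <- countsFromStarts(ts, starts)
    sel <- selectTrainingGenes(cnt, ts, minGenes = 1L)
    expect_equal(sel, "A", ignore_attr = TRUE)
    expect_false(attr(sel, "relaxed"))
    # when too few qualify, thresholds relax with a warning
    starts$A <- c(rep(1L, 900), integer(8000))
    cnt2 <- countsFromStarts(ts, starts)
    expect_warning(sel2 <- selectTrainingGenes(cnt2, ts, minGenes = 1L),
                   "relaxing")
    expect_true(attr(sel2, "relaxed"))
    expect_true("D" %in% sel2)
    expect_false("C" %in% sel2)   # splice variants stay excluded
})

test_that("null-bias data give near-zero fitted coefficients", {
    set.seed(33)
    n <- 40
    seqs <- setNames(vapply(rep(2500, n), function(L) randSeq(L),
                            character(1)), paste0("G", 1:n, ".t1"))
    ts <- TranscriptSet(seqs, gene = paste0("G", 1:n),
                        species = rep(c("human", "mouse"), n / 2))
    v <- rlnorm(n, log(30), 0.8)
    starts <- lapply(seq_len(n), function(i) rpois(2500, v[i] / 20))
    names(starts) <- paste0("G", 1:n)
    cnt <- countsFromStarts(ts, starts)
    tracks <- onesTracks(ts)
    m <- fitBiasModel(cnt, ts, tracks,
                      trainGenes = paste0("G", 1:n), edgeTrim = 0L)
    expect_lt(abs(m@alpha), 0.15)
    expect_lt(abs(m@beta), 2e-5)
    expect_true(m@converged)
})

test_that("copy-number normalization hits the per-cell target exactly", {
    set.seed(34)
    n <- 20
    seqs <- setNames(vapply(rep(1200, n), function(L) randSeq(L),
                            character(1)), paste0("G", 1:n, ".t1"))
    ts <- TranscriptSet(seqs, gene = paste0("G", 1:n),
                        species = rep(c("human", "mouse"), each = n / 2))
    starts <- lapply(seq_len(n), function(i) rpois(1200, runif(1, 0.01, 3)))
    names(starts) <- paste0("G", 1:n)
    cnt <- countsFromStarts(ts, starts)
    tracks <- onesTracks(ts)
    model <- new("BiasModel", alpha = 0, beta = 0,
                 v = setNames(rep(1, n), paste0("G", 1:n)),
                 iterations = 1L, converged = TRUE)
    prof <- estimateCopyNumbers(cnt, ts, tracks, model)
    for (sp in c("human", "mouse")) {
        vals <- expressionOf(prof, sp)
        p95 <- quantile(vals[vals > 0], 0.95, type = 7, names = FALSE)
        expect_equal(sum(vals[vals <= p95]), 3e5, tolerance = 1e-9)
    }
    # with two genes the 1:3 ratio is preserved and the sum over genes at or
    # below the 95th percentile (here: the smaller gene) hits the target
    ts2 <- TranscriptSet(c(A.t1 = randSeq(600), B.t1 = randSeq(600)),
                         gene = c("A", "B"), species = rep("human", 2))
    cnt2 <- countsFromStarts(ts2, list(A = rep(10L, 10), B = rep(30L, 10)))
    model2 <- new("BiasModel", alpha = 0, beta = 0, v = c(A = 1, B = 1),
                  iterations = 1L, converged = TRUE)
    prof2 <- estimateCopyNumbers(cnt2, ts2, onesTracks(ts2), model2)
    vals2 <- expressionOf(prof2, "human")
    expect_equal(unname(vals2["B"] / vals2["A"]), 3)
    p95b <- quantile(vals2, 0.95, type = 7, names = FALSE)
    expect_equal(sum(vals2[vals2 <= p95b]), 3e5)

    # doubling every read-start count leaves normalised values unchanged
    cnt2x <- countsFromStarts(ts2, list(A = rep(20L, 10), B = rep(60L, 10)))
    prof2x <- estimateCopyNumbers(cnt2x, ts2, onesTracks(ts2), model2)
    expect_equal(expressionOf(prof2x, "human"), vals2)

    # all-zero expression is an error
    cnt0 <- countsFromStarts(ts2, list(A = integer(10), B = integer(10)))
    expect_error(estimateCopyNumbers(cnt0, ts2, onesTracks(ts2), model2),
                 "all-zero")
})

test_that("masking a homologous block leaves the estimate unchanged", {
    set.seed(35)
    ts <- TranscriptSet(c(A.t1 = randSeq(2000), B.t1 = randSeq(2000)),
                        gene = c("A", "B"), species = rep("human", 2))
    starts <- list(A = rep(2L, 2000), B = rep(2L, 2000))
    cnt <- countsFromStarts(ts, starts)
    model <- new("BiasModel", alpha = 0, beta = 0, v = c(A = 1, B = 1),
                 iterations = 1L, converged = TRUE)
    full <- onesTracks(ts)
    # mask a 400 nt block of gene A (reads there are lost too)
    masked <- full
    masked$A[800:1199] <- 0L
    startsM <- starts
    startsM$A[800:1199] <- 0L
    cntM <- countsFromStarts(ts, startsM)
    p1 <- estimateCopyNumbers(cnt, ts, full, model)
    p2 <- estimateCopyNumbers(cntM, ts, masked, model)
    v1 <- expressionOf(p1, "human")
    v2 <- expressionOf(p2, "human")
    expect_equal(unname(v2["A"] / v2["B"]), unname(v1["A"] / v1["B"]),
                 tolerance = 1e-10)
})
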