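test_that("evaluation indices match hand-evaluated formulas", {
    # pure cancer-ligand -> stromal-receptor signal
    i1 <- computeIndices(100, 0, 0, 100)
    expect_equal(i1$X_CS, 1); expect_equal(i1$Y_CS, 1)
    expect_equal(i1$Z_CS, 100)
    expect_equal(i1$X_SC, 0); expect_equal(i1$Y_SC, 0)
    expect_equal(i1$Z_SC, 0)

    # symmetric expression
    i2 <- computeIndices(10, 10, 10, 10)
    expect_equal(unlist(i2[c("X_CS", "Y_CS", "X_SC", "Y_SC")]),
                 c(X_CS = 0.5, Y_CS = 0.5, X_SC = 0.5, Y_SC = 0.5))
    expect_equal(i2$Z_CS, 10); expect_equal(i2$Z_SC, 10)

    # general case evaluated by hand
    i3 <- computeIndices(4, 12, 9, 16)
    expect_equal(i3$X_CS, 0.25)
    expect_equal(i3$Y_CS, 0.64)
    expect_equal(i3$Z_CS, 8)
    expect_equal(i3$X_SC, 0.75)
    expect_equal(i3$Y_SC, 0.36)
    expect_equal(i3$Z_SC, sqrt(108))

    # zero denominators leave the dependency undefined, Z still computed
    i4 <- computeIndices(0, 0, 5, 5)
    expect_true(is.na(i4$X_CS) && is.na(i4$X_SC))
    expect_equal(i4$Z_CS, 0)

    expect_error(computeIndices(-1, 0, 0, 0), "nonnegative")
})

test_that("index identities hold over randomized inputs", {
    set.seed(41)
    LC <- runif(200, 0, 100); LS <- runif(200, 0, 100)
    RC <- runif(200, 0, 100); RS <- runif(200, 0, 100)
    idx <- computeIndices(LC, LS, RC, RS)
    expect_equal(idx$X_CS + idx$X_SC, rep(1, 200))
    expect_equal(idx$Y_CS + idx$Y_SC, rep(1, 200))
    expect_equal(idx$Z_CS * idx$Z_SC, sqrt(LC * LS * RC * RS))
})

test_that("zone classification is boundary-inclusive and partitions", {
    expect_equal(classifyZone(0.5, 0.5), 1L)
    expect_equal(classifyZone(0.49, 0.51), 3L)
    expect_equal(classifyZone(0.2, 0.2), 4L)
    expect_equal(classifyZone(0.7, 0.3), 2L)
    expect_true(is.na(classifyZone(NA_real_, 0.4)))
    # every defined point gets exactly one zone
    set.seed(42)
    x <- runif(500); y <- runif(500)
    z <- classifyZone(x, y)
    expect_true(all(z %in% 1:4))
    expect_equal(zoneLabel("CS", 1L), "CS1")
})

test_that("strong-zone counting uses a strict threshold", {
    sc <- data.frame(ligand = c("A", "B", "C"), receptor = c("R1", "R2", "R3"),
                     direction = "CS", X = 0.8, Y = 0.8,
                     Z = c(5, 11, 60), defined = TRUE, zone = 1L,
                     stringsAsFactors = FALSE)
    prof <- new("InteractionProfile", scores = sc, nSamples = 1L)
    expect_equal(countStrongByZone(prof, zones = 1L, zMin = 10,
                                   direction = "CS"), 2L)
    expect_equal(countStrongByZone(prof, zones = 1L, zMin = 50,
                                   direction = "CS"), 1L)
    empty <- new("InteractionProfile", scores = sc[0, ], nSamples = 1L)
    expect_equal(countStrongByZone(empty, zones = 1L, zMin = 10,
                                   direction = "CS"), 0L)
})

test_that("mutually dependent extraction filters strictly and sorts by Z", {
    sc <- data.frame(
        ligand = c("SEMA3C", "X1", "X2", "X3"),
        receptor = c("NRP1", "R1", "R2", "R3"),
        direction = "CS",
        X = c(0.8, 0.75, 0.9, 0.9),
        Y = c(0.8, 0.9, 0.9, 0.9),
        Z = c(101.5, 100, 49, 200),
        defined = TRUE, zone = 1L, stringsAsFactors = FALSE)
    prof <- new("InteractionProfile", scores = sc, nSamples = 1L)
    got <- extractMutuallyDependent(prof)
    # X = 0.75 dropped (strict >), Z = 49 dropped, rest sorted by Z desc
    expect_equal(got$ligand, c("X3", "SEMA3C"))
    expect_equal(got$Z, c(200, 101.5))
})

test_that("profile averaging is pairwise-available and order-invariant", {
    mk <- function(X, Y, Z) {
        sc <- data.frame(ligand = "L", receptor = "R",
                         direction = c("CS", "SC"), X = X, Y = Y, Z = Z,
                         stringsAsFactors = FALSE)
        sc$defined <- !is.na(sc$X) & !is.na(sc$Y)
        sc$zone <- classifyZone(sc$X, sc$Y)
        new("InteractionProfile", scores = sc, nSamples = 1L)
    }
    p1 <- mk(c(0.2, 0.8), c(0.4, 0.6), c(10, 20))
    p2 <- mk(c(0.8, 0.2), c(0.6, 0.4), c(30, 40))
    avg <- averageProfiles(list(p1, p2))
    s <- scores(avg)
    expect_equal(s$X[s$direction == "CS"], 0.5)
    expect_equal(s$Z[s$direction == "CS"], 20)
    # 0.5 falls on the boundary and classifies as "strong"
    expect_equal(s$zone[s$direction == "CS"], 1L)
    # identical samples average to themselves; single sample is identity
    same <- averageProfiles(list(p1, p1))
    expect_equal(scores(same)$X, scores(p1)$X)
    expect_identical(averageProfiles(list(p1)), p1)
    # permuting samples leaves the result bit-identical
    expect_identical(scores(averageProfiles(list(p1, p2))),
                     scores(averageProfiles(list(p2, p1))))
    # an index undefined in one sample averages over the defined ones
    p3 <- mk(c(NA, 0.4), c(NA, 0.2), c(0, 5))
    avg3 <- averageProfiles(list(p1, p3))
    s3 <- scores(avg3)
    expect_equal(s3$X[s3$direction == "CS"], 0.2)
})

test_that("interaction scoring joins expression onto the database", {
    db <- data.frame(ligand = c("SHH", "HGF"), receptor = c("PTCH1", "MET"),
                     source = "", pmid = "", stringsAsFactors = FALSE)
    hv <- c(SHH = 100, PTCH1 = 0, HGF = 0, MET = 80)
    mv <- c(SHH = 0, PTCH1 = 100, HGF = 40, MET = 20)
    prof <- computeInteractionScores(db, hv, mv)
    s <- scores(prof)
    expect_equal(nrow(s), 4L)
    shh <- s[s$ligand == "SHH" & s$direction == "CS", ]
    expect_equal(shh$X, 1); expect_equal(shh$Y, 1)
    expect_equal(shh$Z, 100); expect_equal(shh$zone, 1L)
    # genes absent from the expression vectors count as zero
    db2 <- rbind(db, data.frame(ligand = "NOPE", receptor = "NADA",
                                source = "", pmid = ""))
    s2 <- scores(computeInteractionScores(db2, hv, mv))
    expect_false(any(s2$defined[s2$ligand == "NOPE"]))

    # viewer export holds both directions with log-scaled radii
    f <- tempfile(fileext = ".json")
    writeViewerJson(prof, f)
    j <- jsonlite::read_json(f, simplifyVector = TRUE)
    expect_named(j, c("CS", "SC"))
    expect_equal(j$CS$radius, log10(1 + j$CS$z))
})
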