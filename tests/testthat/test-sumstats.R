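test_that("SFS statistics match hand-enumerated values at n = 4", {
    # one site at each derived count 1, 2, 3
    s <- sfsStats(c(1L, 2L, 3L), n = 4)
    expect_equal(unname(s["pi"]), 20 / 12)
    expect_equal(unname(s["thetaH"]), 28 / 12)
    expect_equal(unname(s["faywuH"]), -8 / 12)
    expect_equal(unname(s["thetaW"]), 3 / (1 + 1 / 2 + 1 / 3))
    expect_identical(unname(s["S"]), 3)
    expect_identical(unname(s["S1"]), 1)
})

test_that("SFS statistics reject invariant sites and handle empty windows", {
    expect_error(sfsStats(c(0L, 2L), 4), "invariant")
    expect_error(sfsStats(c(1L, 4L), 4), "invariant")
    e <- sfsStats(integer(0), 10)
    expect_identical(unname(e["S"]), 0)
    expect_identical(unname(e["pi"]), 0)
    expect_true(is.na(e["tajD"]))
    expect_true(is.na(e["Hprime"]))
})

test_that("SFS pi equals brute-force pairwise differences on random samples", {
    set.seed(3)
    for (k in 1:100) {
        s <- randomSample(n = sample(4:10, 1), S = sample(3:20, 1))
        G <- genotypeMatrix(s)
        sf <- sfsStats(derivedCounts(s), nrow(G))
        expect_equal(unname(sf["pi"]), bruteForcePi(G), tolerance = 1e-12)
    }
})

test_that("haplotype statistics: degenerate, all-distinct and mixed cases", {
    expect_equal(haplotypeStats(matrix(0L, 5, 3)),
                 c(K = 1, hapDiv = 0))
    G <- diag(1L, 6)  # all distinct
    expect_equal(unname(haplotypeStats(G)["hapDiv"]), 1)
    G2 <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 1L), c(1L, 1L))
    hs <- haplotypeStats(G2)
    expect_identical(unname(hs["K"]), 3)
    expect_equal(unname(hs["hapDiv"]), (4 / 3) * (1 - (1 / 4 + 1 / 16 + 1 / 16)))
})

test_that("LD statistics match the 2x2 haplotype table", {
    # perfect LD
    G <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 1L), c(1L, 1L))
    ld <- ldStats(G)
    expect_equal(unname(ld["D"]), 0.25)
    expect_equal(unname(ld["r2"]), 1)
    expect_equal(unname(ld["Dprime"]), 1)
    # independence
    G2 <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
    ld2 <- ldStats(G2)
    expect_equal(unname(ld2["D"]), 0)
    expect_equal(unname(ld2["r2"]), 0)
    # fewer than two sites
    expect_true(all(is.na(ldStats(matrix(1L, 4, 1)))))
})

test_that("r2 is invariant to swapping allele labels at either site", {
    set.seed(9)
    for (k in 1:50) {
        s <- randomSample(n = 8, S = 2)
        G <- genotypeMatrix(s)
        if (ncol(G) < 2) next
        base <- ldStats(G[, 1:2])
        flip1 <- G[, 1:2]; flip1[, 1] <- 1L - flip1[, 1]
        expect_equal(unname(ldStats(flip1)["r2"]), unname(base["r2"]),
                     tolerance = 1e-12)
    }
})

test_that("LD means agree with the brute-force pair loop", {
    set.seed(13)
    for (k in 1:30) {
        s <- randomSample(n = 10, S = 8)
        G <- genotypeMatrix(s)
        if (ncol(G) < 2) next
        ld <- ldStats(G)
        pairs <- combn(ncol(G), 2)
        ora <- apply(pairs, 2, function(p)
            unlist(bruteForceLD(G[, p[1]], G[, p[2]])))
        expect_equal(unname(ld["D"]), mean(ora["D", ]), tolerance = 1e-12)
        expect_equal(unname(ld["r2"]), mean(ora["r2", ]), tolerance = 1e-12)
        expect_equal(unname(ld["Dprime"]), mean(ora["Dprime", ]),
                     tolerance = 1e-12)
    }
})

test_that("statistics are invariant under haplotype permutation", {
    set.seed(17)
    s <- randomSample(n = 10, S = 15)
    G <- genotypeMatrix(s)
    perm <- G[sample(nrow(G)), ]
    expect_equal(sfsStats(colSums(perm), nrow(G)),
                 sfsStats(derivedCounts(s), nrow(G)))
    expect_equal(haplotypeStats(perm), haplotypeStats(G))
    expect_equal(ldStats(perm), ldStats(G))
})

test_that("aggregation matches a two-pass mean/variance oracle", {
    set.seed(23)
    reps <- lapply(1:4, function(r) {
        s <- randomSample(n = 10, S = 40, L = 8000)
        windowStats(s, 2000L)
    })
    agg <- aggregateStats(reps)
    # oracle: explicit two-stage accumulation for one statistic
    repPi <- vapply(reps, function(df) mean(df$piSite, na.rm = TRUE),
                    numeric(1))
    expect_equal(unname(agg["mean_pi"]), mean(repPi), tolerance = 1e-12)
    expect_equal(unname(agg["var_pi"]), var(repPi), tolerance = 1e-12)
    # identical windows give zero variance
    agg2 <- aggregateStats(list(reps[[1]], reps[[1]]))
    expect_equal(unname(agg2["var_S"]), 0)
    # aggregate of aggregates: means are stable under repetition
    expect_equal(unname(aggregateStats(c(reps, reps))[paste0("mean_",
        statPanel())]), unname(agg[paste0("mean_", statPanel())]),
        tolerance = 1e-12)
})

test_that("pair subsampling approximates full-pair LD", {
    set.seed(31)
    s <- randomSample(n = 20, S = 40)
    G <- genotypeMatrix(s)
    full <- ldStats(G)
    sub <- ldStats(G, maxPairs = 200)
    expect_lt(abs(sub["r2"] - full["r2"]), 0.15)
})
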