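test_that("exon masking removes exonic sites and leaves 49,512 callable bp", {
    lay <- buildLayout()
    ex <- layoutRanges(lay, "exon")
    # sites: one inside each of the first 5 exons, one per first 4 introns
    exPos <- IRanges::start(ex)[1:5] + 10L - 1L  # 0-based inside exon
    inPos <- IRanges::start(layoutRanges(lay, "intron"))[1:4] + 10L - 1L
    pos <- sort(c(exPos, inPos))
    G <- matrix(0L, 6, length(pos)); G[1:3, ] <- 1L
    s <- haplotypeSample(G, pos, segmentLength(lay))
    m <- maskExons(s, lay)
    expect_identical(length(sitePositions(m)), 4L)
    expect_true(all(sitePositions(m) %in% inPos))
    expect_identical(sum(IRanges::width(callableRegions(m))),
                     99012L - 33L * 1500L)  # 49,512
    # idempotence
    m2 <- maskExons(m, lay)
    expect_identical(sitePositions(m2), sitePositions(m))
    expect_identical(sum(IRanges::width(callableRegions(m2))), 49512L)
})

test_that("masking a sample with only intronic sites is a no-op on sites", {
    lay <- buildLayout()
    inPos <- IRanges::start(layoutRanges(lay, "intron"))[1:6] + 3L - 1L
    G <- matrix(rbinom(8 * 6, 1, 0.5), 8, 6)
    G[1, ] <- 1L; G[2, ] <- 0L  # keep counts off the boundaries
    s <- haplotypeSample(G, sort(inPos), segmentLength(lay))
    m <- maskExons(s, lay)
    expect_identical(sitePositions(m), sitePositions(s))
    expect_identical(genotypeMatrix(m), genotypeMatrix(s))
})

test_that("singleton ascertainment removes exactly round(f * S1) singletons", {
    set.seed(5)
    n <- 12
    # 99 singletons + 40 doubletons
    G1 <- vapply(1:99, function(i) {
        v <- integer(n); v[sample(n, 1)] <- 1L; v
    }, integer(n))
    G2 <- vapply(1:40, function(i) {
        v <- integer(n); v[sample(n, 2)] <- 1L; v
    }, integer(n))
    G <- cbind(G1, G2)
    pos <- sort(sample(0:9999, ncol(G)))
    s <- haplotypeSample(G, pos, 10000)
    out <- ascertainSingletons(s, 1 / 3)
    cnt <- derivedCounts(out)
    expect_identical(sum(cnt == 1L), 66L)          # 99 - round(99/3)
    expect_identical(sum(cnt == 2L), 40L)          # untouched
    expect_identical(ncol(genotypeMatrix(out)), 106L)
    # SFS classes >= 2 identical before/after
    expect_identical(table(derivedCounts(s)[derivedCounts(s) >= 2]),
                     table(cnt[cnt >= 2]))
})

test_that("ascertainment degenerate cases", {
    n <- 6
    G <- vapply(1:5, function(i) {
        v <- integer(n); v[c(1, 2)] <- 1L; v
    }, integer(n))
    s <- haplotypeSample(G, sort(sample(0:999, 5)), 1000)
    out <- ascertainSingletons(s, 1 / 3)  # no singletons at all
    expect_identical(genotypeMatrix(out), genotypeMatrix(s))
    out2 <- ascertainSingletons(s, 0)
    expect_identical(sitePositions(out2), sitePositions(s))
})

test_that("expected retained-singleton fraction follows the rounding rule", {
    set.seed(11)
    for (S1 in c(1, 2, 7, 30)) {
        n <- 10
        G <- vapply(seq_len(S1), function(i) {
            v <- integer(n); v[sample(n, 1)] <- 1L; v
        }, integer(n))
        s <- haplotypeSample(G, sort(sample(0:999, S1)), 1000)
        out <- ascertainSingletons(s, 1 / 3)
        expect_identical(ncol(genotypeMatrix(out)),
                         as.integer(S1 - round(S1 / 3)))
    }
})

test_that("window partition: counts, degenerate width, boundary convention", {
    lay <- buildLayout()
    pos <- c(0L, 1999L, 2000L, 98999L)
    G <- matrix(0L, 4, 4); G[1:2, ] <- 1L
    s <- haplotypeSample(G, pos, segmentLength(lay))
    wp <- windowPartition(s, 2000L)
    expect_identical(nrow(wp), 50L)
    expect_identical(wp$end[50L] - wp$start[50L], 1012L)
    expect_identical(wp$sites[[1L]], c(1L, 2L))   # 0 and 1999
    expect_identical(wp$sites[[2L]], 3L)          # 2000 -> window 2 (half-open)
    expect_identical(wp$sites[[50L]], 4L)
    one <- windowPartition(s, segmentLength(s))
    expect_identical(nrow(one), 1L)
    expect_identical(one$sites[[1L]], 1:4)
    expect_error(windowPartition(s, 0), "positive")
})

test_that("masking commutes with windowing on per-window statistics", {
    set.seed(21)
    lay <- buildLayout(2)
    L <- segmentLength(lay)
    pos <- sort(sample(0:(L - 1), 60))
    G <- matrix(rbinom(10 * 60, 1, 0.4), 10, 60)
    keep <- colSums(G) >= 1 & colSums(G) <= 9
    s <- haplotypeSample(G[, keep, drop = FALSE], pos[keep], L)
    m <- maskExons(s, lay)
    wsm <- windowStats(m, 2000L)
    # windowing the masked sample must see exactly the non-exonic sites
    exonic <- IRanges::overlapsAny(
        IRanges::IRanges(sitePositions(s) + 1L, sitePositions(s) + 1L),
        layoutRanges(lay, "exon"))
    expect_identical(sum(wsm$S), as.numeric(sum(!exonic)))
})
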