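test_that("pairwise diversity matches theta for n = 2 without recombination", {
    lay <- buildLayout(1)
    L <- segmentLength(lay)
    N <- 1000; mu <- 1e-6
    theta <- 4 * N * mu
    sims <- simulateNeutral(demographyConstant(N), lay, n = 2, mu = mu,
                            rec = 0, replicates = 10000, seed = 12)
    pis <- vapply(sims, function(s) length(sitePositions(s)) / L, numeric(1))
    se <- sd(pis) / sqrt(length(pis))
    expect_lt(abs(mean(pis) - theta), 3 * se)
})

test_that("segregating sites match Watterson's expectation at n = 10", {
    lay <- buildLayout(1)
    L <- segmentLength(lay)
    N <- 1000; mu <- 1e-6
    sims <- sharedFixture("coal_n10", function()
        simulateNeutral(demographyConstant(1000), buildLayout(1), n = 10,
                        mu = 1e-6, rec = 0, replicates = 4000, seed = 33))
    Ss <- vapply(sims, function(s) length(sitePositions(s)), numeric(1))
    ES <- 4 * N * mu * L * sum(1 / (1:9))
    se <- sd(Ss) / sqrt(length(Ss))
    expect_lt(abs(mean(Ss) - ES), 3 * se)
})

test_that("Tajima's D numerator is centered on zero at neutral equilibrium", {
    # the unbiased neutral-equilibrium property is E[pi - theta_W] = 0; the
    # normalized D itself has a small intrinsic negative mean (the
    # denominator is correlated with the numerator), so it is only
    # sanity-bounded here
    sims <- sharedFixture("coal_n10", function()
        simulateNeutral(demographyConstant(1000), buildLayout(1), n = 10,
                        mu = 1e-6, rec = 0, replicates = 4000, seed = 33))
    st <- vapply(sims, function(s) {
        cnt <- derivedCounts(s)
        if (length(cnt) < 3) return(c(num = NA_real_, D = NA_real_))
        x <- sfsStats(cnt, 10)
        c(num = unname(x["pi"] - x["thetaW"]), D = unname(x["tajD"]))
    }, numeric(2))
    num <- st["num", ][is.finite(st["num", ])]
    expect_lt(abs(mean(num)), 3 * sd(num) / sqrt(length(num)))
    D <- st["D", ][is.finite(st["D", ])]
    expect_lt(abs(mean(D)), 0.2)
})

test_that("SFS means match the closed-form neutral expectation at n = 10", {
    # E[xi_i] = theta L / i: the standard-coalescent oracle
    sims <- sharedFixture("coal_n10", function()
        simulateNeutral(demographyConstant(1000), buildLayout(1), n = 10,
                        mu = 1e-6, rec = 0, replicates = 4000, seed = 33))
    L <- segmentLength(buildLayout(1))
    thetaL <- 4 * 1000 * 1e-6 * L
    xi <- sapply(sims, function(s) tabulate(derivedCounts(s), nbins = 9))
    for (i in 1:9) {
        se <- sd(xi[i, ]) / sqrt(ncol(xi))
        expect_lt(abs(mean(xi[i, ]) - thetaL / i), 3.5 * se)
    }
})

test_that("recombination leaves the mean diversity unchanged", {
    lay <- buildLayout(1)
    L <- segmentLength(lay)
    sims <- simulateNeutral(demographyConstant(1000), lay, n = 10,
                            mu = 1e-6, rec = 1e-6, replicates = 800,
                            seed = 44)
    pis <- vapply(sims, function(s) {
        cnt <- derivedCounts(s)
        sum(2 * cnt * (10 - cnt)) / 90 / L
    }, numeric(1))
    se <- sd(pis) / sqrt(length(pis))
    expect_lt(abs(mean(pis) - 0.004), 3 * se)
})

test_that("size-change demographies distort Tajima's D in the known directions", {
    lay <- buildLayout(1)
    tajd <- function(dem, seed) {
        sims <- simulateNeutral(dem, lay, n = 20, mu = 4e-6, rec = 0,
                                replicates = 600, seed = seed)
        D <- vapply(sims, function(s) {
            cnt <- derivedCounts(s)
            if (length(cnt) < 3) return(NA_real_)
            unname(sfsStats(cnt, 20)["tajD"])
        }, numeric(1))
        mean(D, na.rm = TRUE)
    }
    # decline: old lineages coalesce slowly -> intermediate-frequency excess
    expect_gt(tajd(demographyTwoEpoch(5000, 250, tau = 400), 55), 0.2)
    # expansion: star-like genealogy -> rare-variant excess
    expect_lt(tajd(demographyTwoEpoch(250, 5000, tau = 400), 66), -0.2)
})

test_that("haplotype labels are exchangeable", {
    s <- simulateNeutral(demographyConstant(500), buildLayout(1), n = 8,
                         mu = 5e-6, rec = 1e-6, seed = 77)
    G <- genotypeMatrix(s)
    perm <- G[sample(nrow(G)), , drop = FALSE]
    expect_equal(sfsStats(colSums(perm), 8), sfsStats(colSums(G), 8))
})

test_that("forward and coalescent simulators agree on the neutral SFS", {
    # cross-simulator equivalence at n = 10 (selection disabled)
    lay <- buildLayout(1)
    N <- 50L; mu <- 5e-6
    cfg <- tinyScenario(N = N, mu = mu, rec = 5e-6, n = 10L)
    fwd <- sapply(1:250, function(r) {
        s <- runForward(cfg, seed = 4000 + r)@sample
        tabulate(derivedCounts(s), nbins = 9)
    })
    coa <- sapply(simulateNeutral(demographyConstant(N), lay, n = 10,
                                  mu = mu, rec = 5e-6, replicates = 250,
                                  seed = 91),
                  function(s) tabulate(derivedCounts(s), nbins = 9))
    for (i in 1:9) {
        se <- sqrt(var(fwd[i, ]) / ncol(fwd) + var(coa[i, ]) / ncol(coa))
        expect_lt(abs(mean(fwd[i, ]) - mean(coa[i, ])), 3.5 * se)
    }
})

test_that("coalescent runs are reproducible and respect input checks", {
    lay <- buildLayout(1)
    a <- simulateNeutral(demographyConstant(100), lay, 6, 1e-5, 1e-6,
                         seed = 5)
    b <- simulateNeutral(demographyConstant(100), lay, 6, 1e-5, 1e-6,
                         seed = 5)
    expect_identical(genotypeMatrix(a), genotypeMatrix(b))
    expect_error(simulateNeutral(demographyConstant(100), lay, 1, 1e-5, 0),
                 "n must")
    expect_error(simulateNeutral(demographyConstant(100), lay, 4, -1e-5, 0),
                 "non-negative")
})
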