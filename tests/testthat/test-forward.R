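test_that("heterozygosity decays at rate 1 - 1/(2N) under pure drift", {
    # mu = 0, standing variation only: E[sum 2p(1-p)] shrinks by (1-1/2N)^t
    N <- 50L
    cfg <- tinyScenario(N = N, mu = 0, rec = 0, n = 2L * N)
    hetSum <- function(tgens, reps, seed0) {
        vapply(seq_len(reps), function(r) {
            s <- runForward(cfg, totalGenerations = tgens, seed = seed0 + r,
                            initPolyCount = 30L, initPolyFreq = 0.5)@sample
            p <- derivedCounts(s) / (2 * N)
            sum(2 * p * (1 - p))
        }, numeric(1))
    }
    h1 <- hetSum(20L, 150, 1000)
    h2 <- hetSum(120L, 150, 5000)
    lograt <- log(mean(h2) / mean(h1))
    expected <- 100 * log(1 - 1 / (2 * N))
    se <- sqrt(var(h2) / (150 * mean(h2)^2) + var(h1) / (150 * mean(h1)^2))
    expect_lt(abs(lograt - expected), 3 * se)
})

test_that("neutral equilibrium diversity matches the coalescent expectation", {
    cfg <- tinyScenario(N = 50, mu = 5e-6, rec = 5e-6, n = 10L)
    L <- segmentLength(cfg@layout)
    theta <- 4 * 50 * 5e-6
    pis <- vapply(1:150, function(r) {
        s <- runForward(cfg, seed = 100 + r)@sample
        cnt <- derivedCounts(s)
        sum(2 * cnt * (10 - cnt)) / (10 * 9) / L
    }, numeric(1))
    se <- sd(pis) / sqrt(length(pis))
    expect_lt(abs(mean(pis) - theta), 3 * se)
})

test_that("allele bookkeeping is conserved exactly", {
    cfg <- tinyScenario(N = 40, mu = 1e-5)
    r <- runForward(cfg, totalGenerations = 2000, seed = 7)
    cnt <- r@counters
    expect_identical(cnt$introduced, cnt$fixed + cnt$lost + cnt$segregating)
})

test_that("neutral fixation rate per site is mu, independent of N", {
    for (N in c(25L, 75L)) {
        cfg <- tinyScenario(N = N, mu = 2e-5, rec = 0)
        L <- segmentLength(cfg@layout)
        tg <- 30L * N
        r <- runForward(cfg, totalGenerations = tg, seed = N)
        # discard ~4N generations of transient: fixations need standing input
        fg <- r@fixations$fixGen
        span <- tg - 8L * N
        nfix <- sum(fg > 8L * N)
        expected <- 2e-5 * L * span
        expect_lt(abs(nfix - expected), 4 * sqrt(expected))
    }
})

test_that("selected mutation classes arise only in exons", {
    cfg <- tinyScenario(N = 40, mu = 4e-5,
                        dfe = dfeConfig(deleterious = TRUE, gamma = 10,
                                        fpos = 0.05, Nanc = 40))
    r <- runForward(cfg, totalGenerations = 1200, seed = 9)
    cls <- r@counters$siteClass
    pos <- sitePositions(r@sample)
    exonic <- IRanges::overlapsAny(IRanges::IRanges(pos + 1L, pos + 1L),
                                   layoutRanges(cfg@layout, "exon"))
    sel <- cls != "neutral"
    expect_true(all(exonic[sel]))
    # deleterious fixations carry negative s, beneficial positive
    fx <- r@fixations
    expect_true(all(fx$s[grepl("deleterious", fx$class)] <= 0))
    expect_true(all(fx$s[fx$class == "beneficial"] > 0))
})

test_that("progeny skew assigns exactly floor(psi N) offspring to the focal parent", {
    op <- offspringParents(1000L, 0.1, seed = 1)
    expect_identical(op$n_skew, 100L)
    expect_true(all(op$parent1[1:100] == op$focal))
    # skew slots beyond floor(psi N) draw parents independently
    expect_lt(mean(op$parent1[101:1000] == op$focal), 0.02)
    op0 <- offspringParents(500L, 0, seed = 2)
    expect_identical(op0$n_skew, 0L)
    expect_identical(op0$focal, 0L)
    expect_warning(offspringParents(5L, 0.1, seed = 3), "no effect")
})

test_that("skew reduces diversity and inflates the singleton fraction", {
    mk <- function(psi) tinyScenario(N = 60, mu = 8e-6, rec = 0, n = 20L,
                                     psi = psi)
    run1 <- function(cfg, seed) {
        s <- runForward(cfg, totalGenerations = 2500, seed = seed)@sample
        cnt <- derivedCounts(s)
        c(pi = sum(2 * cnt * (20 - cnt)) / (20 * 19),
          sf = if (length(cnt)) mean(cnt == 1) else NA_real_)
    }
    base <- vapply(1:500, function(r) run1(mk(0), r), numeric(2))
    skew <- vapply(1:500, function(r) run1(mk(0.1), 70000 + r), numeric(2))
    expect_lt(mean(skew["pi", ]), mean(base["pi", ]))
    expect_gt(mean(skew["sf", ], na.rm = TRUE),
              mean(base["sf", ], na.rm = TRUE))
})

test_that("forward runs are reproducible for a fixed seed", {
    cfg <- tinyScenario(N = 30, mu = 1e-5)
    a <- runForward(cfg, totalGenerations = 500, seed = 42)
    b <- runForward(cfg, totalGenerations = 500, seed = 42)
    expect_identical(genotypeMatrix(a@sample), genotypeMatrix(b@sample))
    expect_identical(a@fixations, b@fixations)
})

test_that("demographic decline is applied at the scheduled generation", {
    lay <- buildLayout(1)
    rates <- drawRateMap(lay, meanMu = 1e-5, meanRec = 0, cv = 0)
    cfg <- new("ScenarioConfig", name = "dec", layout = lay, rates = rates,
               demography = demographyTwoEpoch(60, 10, tau = 50),
               dfe = neutralDFE(), psi = 0, singletonDrop = 0,
               sampleSize = 20L, seed = NA_integer_)
    r <- runForward(cfg, totalGenerations = 600, seed = 5)
    expect_identical(r@counters$finalN, 10L)
})

test_that("realized lambda follows the Methods formula", {
    expect_identical(realizedLambda(0, 0.001, 1e-6, 1e5), 0)
    expect_equal(realizedLambda(0.999 * 1e-6 * 1e5, 1e-3, 1e-6, 1e5), 0.5)
    expect_error(realizedLambda(0.1, 0.001, 1e-6, 0), "positive")
})
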