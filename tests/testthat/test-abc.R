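# a fast synthetic simulator: statistics are deterministic functions of the
# parameters plus optional noise, padded to a few uninformative features
toySimulator <- function(noise = 0) function(params, seed, replicates) {
    set.seed(seed)
    th <- log(unlist(params))
    stats <- c(s1 = th[[1]] + rnorm(1, 0, noise),
               s2 = sum(th) + rnorm(1, 0, noise),
               s3 = rnorm(1))
    list(stats = stats, extras = NULL)
}

toyPrior <- function() {
    list(model = "custom",
         params = list(a = list(dist = "loguniform", min = 1, max = 1000)),
         infer = "a", inferExtras = character(0))
}

test_that("prior draws are loguniform and respect linked bounds", {
    set.seed(1)
    pr <- demographicPrior()
    d <- drawPrior(pr, 5000)
    expect_true(all(d$tau <= d$Ncur))
    expect_true(all(d$tau >= 10))
    ks <- ks.test(log(d$Nanc), "punif", log(10), log(50000))
    expect_gt(ks$p.value, 0.01)
    ks2 <- ks.test(log(d$gamma <- drawPrior(sweepPrior(), 5000)$gamma),
                   "punif", log(0.1), log(10000))
    expect_gt(ks2$p.value, 0.01)
})

test_that("reference-table bookkeeping: one row per draw, errors skipped", {
    calls <- 0L
    sim <- function(params, seed, replicates) {
        calls <<- calls + replicates
        list(stats = c(s1 = log(params$a), s2 = 0, s3 = 1), extras = NULL)
    }
    tab <- buildReferenceTable(toyPrior(), sim, draws = 10, replicates = 2,
                               seed = 3)
    expect_identical(nrow(tab@params), 10L)
    expect_equal(calls, 20)
    failing <- function(params, seed, replicates) {
        if (params$a > 100) stop("boom")
        list(stats = c(s1 = log(params$a), s2 = 0, s3 = 1), extras = NULL)
    }
    w <- capture_warnings(tab2 <- buildReferenceTable(toyPrior(), failing,
                                                      draws = 30, seed = 4))
    expect_true(any(grepl("skipped", w)))
    expect_true(all(tab2@params$a <= 100))
    expect_identical(nrow(tab2@params), nrow(tab2@stats))
})

test_that("rejection accepts exactly ceiling(tolerance * rows)", {
    set.seed(5)
    tab <- buildReferenceTable(toyPrior(), toySimulator(0.05), draws = 1000,
                               seed = 6)
    obs <- tab@stats[17, ]
    rej <- abcReject(tab, obs, tolerance = 0.05)
    expect_length(rej$accepted, 50L)
    expect_identical(rej$accepted[1L], 17L)       # exact match has distance 0
    expect_equal(rej$distances[1L], 0)
    all50 <- abcReject(tab, obs, tolerance = 1)
    expect_length(all50$accepted, 1000L)
    expect_error(abcReject(tab, obs, tolerance = 0), "tolerance")
})

test_that("tolerance 1 with rejection reproduces the prior", {
    set.seed(7)
    tab <- buildReferenceTable(toyPrior(), toySimulator(1), draws = 2000,
                               seed = 8)
    obs <- tab@stats[1, ]
    post <- abcFit(tab, obs, tolerance = 1, method = "rejection")
    fresh <- drawPrior(toyPrior(), 2000)$a
    ks <- ks.test(post@adjusted[, "a"], fresh)
    expect_gt(ks$p.value, 0.01)
})

test_that("zero-variance features are dropped with a warning", {
    sim <- function(params, seed, replicates)
        list(stats = c(s1 = log(params$a), s2 = 5, s3 = 5), extras = NULL)
    tab <- buildReferenceTable(toyPrior(), sim, draws = 50, seed = 9)
    expect_warning(rej <- abcReject(tab, tab@stats[1, ], 0.2), "zero-variance")
    expect_identical(rej$features, "s1")
})

test_that("local-linear adjustment collapses a noiseless linear problem", {
    set.seed(10)
    tab <- buildReferenceTable(toyPrior(), toySimulator(0), draws = 300,
                               seed = 11)
    aTrue <- 77
    obs <- c(s1 = log(aTrue), s2 = log(aTrue), s3 = 0)
    post <- abcFit(tab, obs, tolerance = 0.5, method = "loclinear")
    expect_lt(max(abs(log(post@adjusted[, "a"]) - log(aTrue))), 1e-6)
    expect_equal(unname(pointEstimate(post)["a"]), aTrue, tolerance = 1e-6)
})

test_that("local-linear equals an independent weighted-least-squares oracle", {
    set.seed(12)
    tab <- buildReferenceTable(toyPrior(), toySimulator(0.3), draws = 400,
                               seed = 13)
    obs <- c(s1 = log(50), s2 = log(50) + 0.1, s3 = 0.2)
    rej <- abcReject(tab, obs, tolerance = 0.25)
    post <- regressionAdjust(rej, method = "loclinear")
    # oracle: solve the weighted normal equations directly
    w <- 1 - (rej$distances / max(rej$distances))^2
    X <- cbind(1, rej$X)
    y <- log(tab@params$a[rej$accepted])
    beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
    adj <- y - drop(X %*% beta) + drop(c(1, rej$xObs) %*% beta)
    expect_equal(unname(log(post@adjusted[, "a"])), unname(adj),
                 tolerance = 1e-8)
})

test_that("a zero-distance accepted row is left unchanged by adjustment", {
    set.seed(14)
    tab <- buildReferenceTable(toyPrior(), toySimulator(0.2), draws = 300,
                               seed = 15)
    obs <- tab@stats[42, ]
    rej <- abcReject(tab, obs, tolerance = 0.3)
    post <- regressionAdjust(rej, method = "loclinear")
    expect_equal(unname(post@adjusted[1L, "a"]), tab@params$a[42L],
                 tolerance = 1e-8)
})

test_that("adjusted draws never leave the prior support", {
    set.seed(16)
    tab <- buildReferenceTable(toyPrior(), toySimulator(0.5), draws = 300,
                               seed = 17)
    obs <- c(s1 = log(5000), s2 = log(5000), s3 = 0)  # far outside
    post <- abcFit(tab, obs, tolerance = 0.3)
    expect_true(all(post@adjusted[, "a"] >= 1 - 1e-9))
    expect_true(all(post@adjusted[, "a"] <= 1000 + 1e-9))
})

test_that("neural-net adjustment handles a nonlinear mapping", {
    sim <- function(params, seed, replicates) {
        th <- log(params$a)
        list(stats = c(s1 = th + 0.05 * th^2, s2 = sqrt(abs(th)), s3 = 1e-9 * seed),
             extras = NULL)
    }
    set.seed(18)
    tab <- buildReferenceTable(toyPrior(), sim, draws = 400, seed = 19)
    aTrue <- 120
    obs <- c(s1 = log(aTrue) + 0.05 * log(aTrue)^2, s2 = sqrt(log(aTrue)),
             s3 = 0)
    set.seed(20)
    post <- abcFit(tab, obs, tolerance = 0.3, method = "neuralnet")
    pe <- pointEstimate(post)
    expect_lt(abs(log(pe["a"]) - log(aTrue)), 0.35)
})

test_that("weighted medians and intervals match the brute-force scan", {
    set.seed(21)
    for (k in 1:25) {
        x <- rlnorm(40)
        w <- runif(40)
        post <- new("Posterior", draws = cbind(a = x),
                    adjusted = cbind(a = x), weights = w / sum(w),
                    distances = numeric(40), method = "rejection",
                    prior = toyPrior(),
                    extras = data.frame(row.names = seq_len(40)))
        expect_identical(unname(pointEstimate(post)["a"]),
                         bruteForceWeightedQuantile(x, w, 0.5))
        ci <- credibleInterval(post)
        expect_identical(unname(ci["a", "lower"]),
                         bruteForceWeightedQuantile(x, w, 0.025))
        expect_identical(unname(ci["a", "upper"]),
                         bruteForceWeightedQuantile(x, w, 0.975))
    }
    # degenerate cases
    one <- new("Posterior", draws = cbind(a = 3), adjusted = cbind(a = 3),
               weights = 1, distances = 0, method = "rejection",
               prior = toyPrior(), extras = data.frame(row.names = 1L))
    expect_identical(unname(pointEstimate(one)["a"]), 3)
    xs <- c(5, 1, 9, 2, 7)
    eq <- new("Posterior", draws = cbind(a = xs), adjusted = cbind(a = xs),
              weights = rep(0.2, 5), distances = numeric(5),
              method = "rejection", prior = toyPrior(),
              extras = data.frame(row.names = 1:5))
    expect_identical(unname(pointEstimate(eq)["a"]), median(xs))
})

test_that("tolerance cross-validation prefers small tolerance on a noiseless problem", {
    set.seed(22)
    tab <- buildReferenceTable(toyPrior(), toySimulator(0), draws = 300,
                               seed = 23)
    cv <- crossValidateTolerance(tab, tolerances = c(0.1, 0.4, 0.8),
                                 folds = 25, method = "rejection", seed = 24)
    errs <- cv$errors
    expect_true(errs["0.1"] <= errs["0.4"])
    expect_true(errs["0.4"] <= errs["0.8"])
    # determinism
    cv2 <- crossValidateTolerance(tab, tolerances = c(0.1, 0.4, 0.8),
                                  folds = 25, method = "rejection", seed = 24)
    expect_identical(cv$errors, cv2$errors)
    one <- crossValidateTolerance(tab, tolerances = 0.07)
    expect_identical(one$tolerance, 0.07)
    expect_error(crossValidateTolerance(tab, c(0.1, 0.2), folds = 1000),
                 "folds")
})
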