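# Independent brute-force oracles used across the test files.

# pairwise-difference diversity: mean Hamming distance over all haplotype
# pairs (equals the SFS-based pi for the same sites)
bruteForcePi <- function(G) {
    n <- nrow(G)
    if (ncol(G) == 0L || n < 2L) return(0)
    tot <- 0
    for (i in seq_len(n - 1L))
        for (j in (i + 1L):n)
            tot <- tot + sum(G[i, ] != G[j, ])
    tot / choose(n, 2)
}

# 2x2 haplotype-table LD for one site pair
bruteForceLD <- function(a, b) {
    n <- length(a)
    pA <- mean(a); pB <- mean(b)
    pAB <- mean(a == 1 & b == 1)
    D <- pAB - pA * pB
    r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
    dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    list(D = D, r2 = r2, Dprime = abs(D / dmax))
}

# weighted median / quantile by cumulative-weight scan
bruteForceWeightedQuantile <- function(x, w, p) {
    o <- order(x)
    x <- x[o]; w <- w[o] / sum(w)
    cw <- 0
    for (i in seq_along(x)) {
        cw <- cw + w[i]
        if (cw >= p) return(x[i])
    }
    x[length(x)]
}

# random small haplotype sample for property tests
randomSample <- function(n = 8, S = 12, L = 1000) {
    repeat {
        G <- matrix(rbinom(n * S, 1, runif(1, 0.2, 0.8)), n, S)
        cnt <- colSums(G)
        keep <- cnt >= 1 & cnt <= n - 1
        if (sum(keep) >= 2) break
    }
    G <- G[, keep, drop = FALSE]
    pos <- sort(sample(0:(L - 1), ncol(G)))
    haplotypeSample(G, pos, L)
}

# tiny scenario construction shortcut
tinyScenario <- function(N = 50, layout = buildLayout(1), mu = 5e-6,
                         rec = 5e-6, dfe = neutralDFE(), psi = 0,
                         n = 10L, drop = 0) {
    rates <- drawRateMap(layout, meanMu = mu, meanRec = rec, cv = 0)
    new("ScenarioConfig", name = "tiny", layout = layout, rates = rates,
        demography = demographyConstant(N), dfe = dfe, psi = psi,
        singletonDrop = drop, sampleSize = as.integer(n),
        seed = NA_integer_)
}

# memoized expensive shared fixtures (built on first use within a test run)
.shared <- new.env(parent = emptyenv())
sharedFixture <- function(name, builder) {
    if (!exists(name, envir = .shared)) assign(name, builder(), envir = .shared)
    get(name, envir = .shared)
}
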