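#' The versioned summary-statistic panel
#'
#' Order of the ABC feature space (schema version 1): nucleotide diversity
#' pi, Watterson's theta and Fay--Wu's theta_H (each per callable bp),
#' Tajima's D, the normalized Fay--Wu H', segregating-site and singleton
#' counts, haplotype count K and haplotype diversity, and the mean pairwise
#' LD summaries r^2, D and |D'|.  The feature vector holds the mean and
#' variance of each across windows/replicates, in this order.
#'
#' @return character vector of panel statistic names.
#' @export
statPanel <- function() {
    c("pi", "thetaW", "thetaH", "tajD", "Hprime", "S", "S1", "K", "hapDiv",
      "r2", "D", "Dprime")
}

tajimaConstants <- function(n) {
    i <- seq_len(n - 1)
    a1 <- sum(1 / i); a2 <- sum(1 / i^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Site-frequency-spectrum statistics for one window
#'
#' Given the derived-allele counts of the segregating sites in a window,
#' computes the unfolded-SFS panel:
#' `pi = sum 2 i (n - i) xi_i / (n (n - 1))`,
#' `theta_W = S / a_1`, `theta_H = sum 2 i^2 xi_i / (n (n - 1))`,
#' `theta_L = sum i xi_i / (n - 1)`, Fay--Wu's `H = pi - theta_H`,
#' Tajima's `D` with the standard normalization (Tajima 1989), and the
#' normalized `H' = (pi - theta_L) / sqrt(Var)` (Zeng et al. 2006).
#' Normalizing constants are computed from `n` and `S` per window; no
#' tabulated approximations.  An empty window reports zero counts and
#' missing normalized statistics.
#'
#' @param counts integer derived-allele counts, each in `[1, n - 1]`.
#' @param n haploid sample size (>= 4).
#' @return named numeric: `S`, `S1`, `pi`, `thetaW`, `thetaH`, `thetaL`,
#'   `faywuH`, `tajD`, `Hprime`.
#' @export
sfsStats <- function(counts, n) {
    if (n < 4) stop("n must be >= 4")
    if (length(counts) && (any(counts < 1) || any(counts > n - 1)))
        stop("derived counts must be in [1, n-1]; invariant sites are not SFS entries")
    S <- length(counts)
    if (S == 0L)
        return(c(S = 0, S1 = 0, pi = 0, thetaW = 0, thetaH = 0, thetaL = 0,
                 faywuH = NA_real_, tajD = NA_real_, Hprime = NA_real_))
    i <- seq_len(n - 1)
    xi <- tabulate(counts, nbins = n - 1)
    pi <- sum(2 * i * (n - i) * xi) / (n * (n - 1))
    thetaH <- sum(2 * i^2 * xi) / (n * (n - 1))
    thetaL <- sum(i * xi) / (n - 1)
    tc <- tajimaConstants(n)
    thetaW <- S / tc$a1
    varD <- tc$e1 * S + tc$e2 * S * (S - 1)
    tajD <- if (varD > 0) (pi - thetaW) / sqrt(varD) else NA_real_
    # Zeng et al. (2006) variance of pi - theta_L
    bn1 <- sum(1 / seq_len(n)^2)
    theta <- thetaW
    theta2 <- S * (S - 1) / (tc$a1^2 + tc$a2)
    varHL <- (n - 2) / (6 * (n - 1)) * theta +
        (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
        (9 * n * (n - 1)^2) * theta2
    Hprime <- if (varHL > 0) (pi - thetaL) / sqrt(varHL) else NA_real_
    c(S = S, S1 = sum(counts == 1L), pi = pi, thetaW = thetaW,
      thetaH = thetaH, thetaL = thetaL, faywuH = pi - thetaH, tajD = tajD,
      Hprime = Hprime)
}

#' Haplotype count and diversity for one window
#'
#' `K` distinct haplotype strings and the sample-size-corrected diversity
#' `(n / (n - 1)) (1 - sum p_k^2)`.
#'
#' @param G 0/1 matrix, haplotypes in rows, window sites in columns.
#' @return named numeric `K`, `hapDiv`.
#' @export
haplotypeStats <- function(G) {
    n <- nrow(G)
    if (n < 1) stop("need at least one haplotype")
    if (ncol(G) == 0L) return(c(K = 1, hapDiv = 0))
    key <- apply(G, 1L, function(r) rawToChar(as.raw(r + 65L)))
    p <- table(key) / n
    c(K = length(p), hapDiv = n / (n - 1) * (1 - sum(p^2)))
}

#' Pairwise linkage-disequilibrium summaries for one window
#'
#' For each site pair: `D = p_AB - p_A p_B`,
#' `r^2 = D^2 / (p_A q_A p_B q_B)`, and `D' = D / D_max` with the standard
#' `D_max`.  The window value is the unweighted mean over pairs (signed for
#' D, absolute for D', since the sign of D' depends on arbitrary allele
#' phase).  All within-window pairs are used by default; when the pair count
#' exceeds `maxPairs` a uniform random subset of pairs is evaluated (R RNG).
#' Fewer than two sites yields missing values.
#'
#' @param G 0/1 matrix, haplotypes x sites, derived coding.
#' @param maxPairs cap on the number of evaluated pairs.
#' @return named numeric `D`, `Dprime`, `r2` (means over pairs).
#' @export
ldStats <- function(G, maxPairs = Inf) {
    S <- ncol(G)
    if (S < 2L) return(c(D = NA_real_, Dprime = NA_real_, r2 = NA_real_))
    n <- nrow(G)
    npairs <- S * (S - 1) / 2
    if (npairs <= maxPairs) {
        p <- colMeans(G)
        pAB <- crossprod(G) / n
        D <- pAB - tcrossprod(p)
        denom <- tcrossprod(p * (1 - p))
        r2 <- D^2 / denom
        dmax <- ifelse(D >= 0,
                       pmin(tcrossprod(p, 1 - p), tcrossprod(1 - p, p)),
                       pmin(tcrossprod(p), tcrossprod(1 - p)))
        dprime <- abs(D / dmax)
        up <- upper.tri(D)
        c(D = mean(D[up]), Dprime = mean(dprime[up]), r2 = mean(r2[up]))
    } else {
        k <- as.integer(maxPairs)
        # sample linear indices of the strict upper triangle
        lin <- sample(npairs, k)
        # invert: for pair index m (1-based) find (i, j), i < j
        j <- ceiling((1 + sqrt(1 + 8 * lin)) / 2)
        i <- lin - (j - 1) * (j - 2) / 2
        pi_ <- colMeans(G)[i]; pj <- colMeans(G)[j]
        pAB <- colMeans(G[, i, drop = FALSE] * G[, j, drop = FALSE])
        D <- pAB - pi_ * pj
        r2 <- D^2 / (pi_ * (1 - pi_) * pj * (1 - pj))
        dmax <- ifelse(D >= 0, pmin(pi_ * (1 - pj), (1 - pi_) * pj),
                       pmin(pi_ * pj, (1 - pi_) * (1 - pj)))
        c(D = mean(D), Dprime = mean(abs(D / dmax)), r2 = mean(r2))
    }
}

#' Windowed summary statistics of a haplotype sample
#'
#' Computes the full panel in nonoverlapping windows.  Per-bp versions of
#' pi, theta_W and theta_H are normalized by *callable* bp (not window
#' width), so masking is reflected in the rates; windows with no callable
#' sequence report missing rates.
#'
#' @param sample a [HaplotypeSample].
#' @param width window width in bp.
#' @param maxPairs LD pair cap per window (see [ldStats]).
#' @return data.frame, one row per window, with raw and per-site columns.
#' @export
windowStats <- function(sample, width = 2000L, maxPairs = Inf) {
    wp <- windowPartition(sample, width)
    n <- nrow(sample@genotypes)
    cnt <- colSums(sample@genotypes)
    rows <- lapply(seq_len(nrow(wp)), function(w) {
        idx <- wp$sites[[w]]
        sf <- sfsStats(cnt[idx], n)
        Gw <- sample@genotypes[, idx, drop = FALSE]
        hp <- haplotypeStats(Gw)
        ld <- ldStats(Gw, maxPairs = maxPairs)
        cb <- wp$callable[w]
        c(sf, hp, ld,
          callable = cb,
          piSite = if (cb > 0) unname(sf["pi"]) / cb else NA_real_,
          thetaWSite = if (cb > 0) unname(sf["thetaW"]) / cb else NA_real_,
          thetaHSite = if (cb > 0) unname(sf["thetaH"]) / cb else NA_real_)
    })
    out <- as.data.frame(do.call(rbind, rows))
    cbind(wp[c("window", "start", "end")], out)
}

# map panel names to windowStats columns
panelColumn <- c(pi = "piSite", thetaW = "thetaWSite", thetaH = "thetaHSite",
                 tajD = "tajD", Hprime = "Hprime", S = "S", S1 = "S1",
                 K = "K", hapDiv = "hapDiv", r2 = "r2", D = "D",
                 Dprime = "Dprime")

#' Aggregate windowed statistics into the ABC feature vector
#'
#' Two-stage pooling by default: window values are averaged within each
#' replicate (missing values excluded), then the mean and variance of the
#' replicate-level means are taken across replicates -- matching a design
#' in which each parameter combination is simulated repeatedly.  With
#' `pooling = "flat"` (or a single replicate) all windows are pooled
#' directly and the variance is across windows.
#'
#' @param repStats one `windowStats` data.frame or a list of them (one per
#'   replicate).
#' @param pooling "two-stage" or "flat".
#' @return named numeric of length 24: `mean_<stat>` then `var_<stat>` in
#'   [statPanel] order.
#' @export
aggregateStats <- function(repStats, pooling = c("two-stage", "flat")) {
    pooling <- match.arg(pooling)
    if (is.data.frame(repStats)) repStats <- list(repStats)
    panel <- statPanel()
    mat <- lapply(repStats, function(df) {
        m <- as.matrix(df[, panelColumn, drop = FALSE])
        colnames(m) <- panel
        m
    })
    if (pooling == "flat" || length(mat) == 1L) {
        all <- do.call(rbind, mat)
        if (nrow(all) < 2L) stop("need at least 2 windows for variances")
        mu <- colMeans(all, na.rm = TRUE)
        vv <- apply(all, 2, var, na.rm = TRUE)
    } else {
        repMeans <- t(vapply(mat, function(m) colMeans(m, na.rm = TRUE),
                             numeric(length(panel))))
        mu <- colMeans(repMeans, na.rm = TRUE)
        vv <- apply(repMeans, 2, var, na.rm = TRUE)
    }
    bad <- panel[!is.finite(mu)]
    if (length(bad))
        stop("statistic(s) with no defined values: ",
             paste(bad, collapse = ", "))
    vv[!is.finite(vv)] <- 0
    setNames(c(mu, vv), c(paste0("mean_", panel), paste0("var_", panel)))
}
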