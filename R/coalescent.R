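#' Neutral coalescent simulation under piecewise-constant demography
#'
#' Backward-in-time simulator for a single population: the genealogy at the
#' left end of the segment is drawn from the exact coalescent under the
#' piecewise-constant demography, and recombination along the sequence is
#' handled by the sequentially Markov approximation (a pruned-and-regrafted
#' marginal genealogy at each recombination breakpoint).  With `rec = 0` the
#' single-tree path is the exact coalescent.  Mutations are Poisson on
#' branches; positions are drawn continuously, snapped to distinct integer
#' bp (collisions resampled).  Mutation and recombination rates are constant
#' across the segment, matching the reference-model assumption of the
#' demographic inference.
#'
#' @param demography a [Demography].
#' @param layout a [GenomeLayout] (only the segment length is used; the
#'   neutral model has no functional structure).
#' @param n haploid sample size (>= 2).
#' @param mu,rec per-bp per-generation rates.
#' @param replicates number of independent replicates.
#' @param seed integer seed for the simulator RNG (R RNG when `NULL`).
#' @return a [HaplotypeSample] (`replicates = 1`) or a list of them.
#' @examples
#' dem <- demographyConstant(1000)
#' s <- simulateNeutral(dem, buildLayout(1), n = 10, mu = 1e-6, rec = 0,
#'                      seed = 1)
#' nHaplotypes(s)
#' @export
simulateNeutral <- function(demography, layout, n, mu, rec,
                            replicates = 1L, seed = NULL) {
    validObject(demography)
    if (n < 2) stop("n must be >= 2")
    if (mu < 0 || rec < 0) stop("rates must be non-negative")
    if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
    L <- layout@segmentLength
    ep <- demography@epochs
    out <- coalescent_sim_cpp(as.integer(n), as.integer(L),
                              mu, rec, ep$size, ep$time,
                              as.integer(replicates), as.double(seed))
    res <- lapply(out, function(r)
        haplotypeSample(r$genotypes, r$positions, L))
    if (replicates == 1L) res[[1L]] else res
}
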