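#' @useDynLib baselineABC, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

mutClassLabels <- c("neutral", "deleterious-1", "deleterious-2",
                    "deleterious-3", "deleterious-4", "beneficial")

#' Construct a HaplotypeSample
#'
#' @param genotypes n x S 0/1 matrix, haplotypes in rows.
#' @param positions 0-based site coordinates.
#' @param segmentLength segment length in bp.
#' @param callable optional [IRanges::IRanges] of callable intervals
#'   (defaults to the whole segment).
#' @param ancestralKnown is the 0/1 coding ancestral/derived?
#' @return a [HaplotypeSample].
#' @export
haplotypeSample <- function(genotypes, positions, segmentLength,
                            callable = NULL, ancestralKnown = TRUE) {
    if (is.null(callable))
        callable <- IRanges::IRanges(1L, as.integer(segmentLength))
    storage.mode(genotypes) <- "integer"
    new("HaplotypeSample", genotypes = genotypes,
        positions = as.integer(positions),
        callable = callable, segmentLength = as.integer(segmentLength),
        ancestralKnown = ancestralKnown)
}

# backward epochs -> forward (size, start generation) schedule
forwardSchedule <- function(demography, totalGens) {
    ep <- demography@epochs
    k <- nrow(ep)
    sizes <- rev(ep$size)
    starts <- if (k > 1L) c(1, totalGens - rev(ep$time[-1L]) + 1) else 1
    keep <- starts <= totalGens
    list(sizes = as.integer(round(sizes[keep])),
         starts = as.integer(pmax(1, starts[keep])))
}

#' Run the forward Wright--Fisher simulation of a scenario
#'
#' Simulates `totalGenerations` discrete generations under the scenario's
#' demography, DFE, rate maps and progeny skew, then draws
#' `config@sampleSize` haplotypes without replacement from the final
#' generation.  Fitness is multiplicative across sites (heterozygote factor
#' `1 + h s`, homozygote `1 + s`, on the homozygous coefficient `s`);
#' individuals whose product drops to zero or below are inviable.  Fixed
#' mutations are harvested every `purgeInterval` generations into the
#' fixation log, from which the realized beneficial substitution rate `d_a`
#' (per exonic site) and
#' `lambda = d_a / (d_a + (1 - f_pos) mu T)` are computed.
#'
#' @param config a [ScenarioConfig] (already at the scale to be simulated;
#'   see [rescaleScenario] for desk-scale runs).
#' @param totalGenerations run length; defaults to [totalGenerations] of the
#'   config (20 N_anc + timed events, minimum +100).
#' @param seed integer seed for the simulator's own RNG; drawn from R's RNG
#'   when `NULL`.
#' @param trackNeutral keep neutral mutations in the genomes.  Disabling
#'   this skips all neutral bookkeeping -- neutral sites never affect the
#'   dynamics of selected sites -- and is the cheap way to measure fixation
#'   counts and lambda; the returned sample then contains selected sites
#'   only.
#' @param purgeInterval generations between fixation/loss sweeps.
#' @param psiFitnessWeighted choose the skew focal parent by fitness rather
#'   than uniformly (relevant only when selection is active).
#' @param initPolyCount,initPolyFreq optional standing neutral variation
#'   inserted at generation 0 (`initPolyCount` sites at frequency
#'   `initPolyFreq`), for drift experiments with `mu = 0`.
#' @return a [SimResult].
#' @export
runForward <- function(config, totalGenerations = NULL, seed = NULL,
                       trackNeutral = TRUE, purgeInterval = 25L,
                       psiFitnessWeighted = FALSE,
                       initPolyCount = 0L, initPolyFreq = 0.5) {
    validObject(config)
    if (is.null(totalGenerations))
        totalGenerations <- baselineABC::totalGenerations(config)
    if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
    sched <- forwardSchedule(config@demography, totalGenerations)
    if (config@psi > 0 && floor(config@psi * min(sched$sizes)) < 1)
        warning("psi * N < 1: progeny skew has no effect at this size")
    lay <- config@layout
    dfe <- config@dfe
    res <- forward_sim_cpp(
        L = lay@segmentLength,
        exonic = exonMaskVector(lay),
        mu_block = config@rates@mu,
        rec_block = config@rates@rec,
        block_len = config@rates@blockLength,
        del_enabled = dfe@deleterious,
        del_weights = dfe@delWeights,
        del_lower = dfe@delBounds[, "lower"],
        del_upper = dfe@delBounds[, "upper"],
        gamma = dfe@gamma, fpos = dfe@fpos, hdom = dfe@h,
        dfe_two_n = 2 * config@demography@epochs$size[nrow(config@demography@epochs)],
        epoch_sizes = sched$sizes, epoch_starts = sched$starts,
        total_gens = as.integer(totalGenerations),
        psi = config@psi, psi_fitness_weighted = psiFitnessWeighted,
        n_sample = config@sampleSize,
        track_neutral = trackNeutral,
        purge_interval = as.integer(purgeInterval),
        init_poly_count = as.integer(initPolyCount),
        init_poly_freq = initPolyFreq,
        seed = as.double(seed))

    fixations <- data.frame(
        class = factor(mutClassLabels[res$fix_class + 1L],
                       levels = mutClassLabels),
        s = res$fix_s, originGen = res$fix_origin, fixGen = res$fix_gen)
    exonBp <- sum(IRanges::width(layoutRanges(lay, "exon")))
    dA <- sum(fixations$class == "beneficial") / exonBp
    muMean <- weightedMeanRate(config@rates)
    lambda <- realizedLambda(dA, fpos = dfe@fpos, mu = muMean,
                             generations = totalGenerations)
    samp <- haplotypeSample(res$genotypes, res$positions, lay@segmentLength)
    new("SimResult", sample = samp, fixations = fixations, dA = dA,
        lambda = lambda,
        counters = list(introduced = res$total_introduced,
                        fixed = res$total_fixed, lost = res$total_lost,
                        segregating = res$segregating,
                        finalN = res$final_N,
                        siteClass = factor(mutClassLabels[res$site_class + 1L],
                                           levels = mutClassLabels)),
        config = config, totalGenerations = totalGenerations,
        seed = as.numeric(seed))
}

# length-weighted mean per-bp mutation rate of a map
weightedMeanRate <- function(rates) {
    L <- rates@segmentLength
    nb <- length(rates@mu)
    lens <- pmin(rates@blockLength, L - (seq_len(nb) - 1L) * rates@blockLength)
    sum(rates@mu * lens) / L
}

#' Realized fraction of substitutions due to beneficial mutations
#'
#' `lambda = d_a / (d_a + (1 - f_pos) * mu * T)`: the beneficial
#' substitution count per site against the neutral-rate expectation over the
#' same `T` generations used to accumulate `d_a`.
#'
#' @param dA beneficial substitutions per (exonic) site.
#' @param fpos beneficial fraction of new mutations.
#' @param mu per-bp per-generation mutation rate.
#' @param generations elapsed generations T.
#' @return lambda in `[0, 1]`.
#' @examples
#' realizedLambda(0, 0.001, 1e-6, 1e5)               # 0
#' realizedLambda(0.999 * 1e-6 * 1e5, 0.001, 1e-6, 1e5)  # 0.5
#' @export
realizedLambda <- function(dA, fpos, mu, generations) {
    if (generations <= 0) stop("generations must be positive")
    neutral <- (1 - fpos) * mu * generations
    if (dA == 0 && neutral == 0) return(0)
    dA / (dA + neutral)
}

#' One generation of offspring-parent assignment under progeny skew
#'
#' Exactly `floor(psi * N)` offspring are assigned a single focal parent
#' (chosen uniformly, or fitness-weighted when `psiFitnessWeighted`), each
#' paired with an independently drawn mate; the remaining offspring draw
#' both parents by fitness-weighted Wright--Fisher sampling (uniform when
#' all fitnesses are equal).  `psi * N < 1` is a no-op with a warning.
#'
#' @param N number of offspring to assign.
#' @param psi progeny-skew fraction in `[0, 1)`.
#' @param fitness parental fitness vector (defaults to neutral).
#' @param psiFitnessWeighted fitness-weighted focal-parent choice.
#' @param seed integer seed (R RNG when `NULL`).
#' @return list with integer vectors `parent1`, `parent2`, the `focal`
#'   parent index (0 if none) and `n_skew`.
#' @export
offspringParents <- function(N, psi, fitness = rep(1, N),
                             psiFitnessWeighted = FALSE, seed = NULL) {
    if (psi < 0 || psi >= 1) stop("psi must be in [0, 1)")
    if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
    if (psi > 0 && floor(psi * N) < 1)
        warning("psi * N < 1: skew has no effect")
    offspring_parents_cpp(N, psi, fitness, psiFitnessWeighted,
                          as.double(seed))
}
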