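#' @import methods
#' @importClassesFrom IRanges IRanges
#' @importFrom stats median mad quantile rnorm runif var integrate ks.test
#'   binom.test setNames lm.wfit predict weighted.mean
#' @importFrom utils head tail write.table read.table
NULL

#' Genome architecture of the simulated segment
#'
#' An intron--exon--intergenic tiling of a single chromosomal segment,
#' Drosophila-like in its default dimensions: each gene is 5 exons of 300 bp
#' separated by 4 introns of 100 bp, genes are separated by 1,068-bp
#' intergenic blocks, and one extra intergenic block flanks the segment start,
#' so that 33 genes give a 99,012-bp segment.  Coordinates are 0-based
#' half-open throughout.
#'
#' @slot elements [IRanges::IRanges] tiling `[0, segmentLength)` with no gaps
#'   or overlaps; element class in `mcols(elements)$type`
#'   (exon/intron/intergenic).
#' @slot segmentLength total length in bp.
#' @slot geneCount number of genes.
#' @slot elementLengths named integer vector recording the construction
#'   parameters (exon, intron, intergenic lengths; exons and introns per gene).
#' @export
setClass("GenomeLayout",
    representation(elements = "IRanges",
                   segmentLength = "integer",
                   geneCount = "integer",
                   elementLengths = "integer"))

setValidity("GenomeLayout", function(object) {
    el <- object@elements
    L <- object@segmentLength
    msgs <- character()
    if (length(el) == 0L) return("empty element set")
    st <- IRanges::start(el)
    en <- IRanges::end(el)
    if (st[1L] != 1L || en[length(el)] != L)
        msgs <- c(msgs, "elements must span the whole segment")
    if (length(el) > 1L && any(st[-1L] != en[-length(el)] + 1L))
        msgs <- c(msgs, "elements must tile without gaps or overlaps")
    type <- S4Vectors::mcols(el)$type
    if (is.null(type) || !all(type %in% c("exon", "intron", "intergenic")))
        msgs <- c(msgs, "element types must be exon/intron/intergenic")
    if (length(msgs)) msgs else TRUE
})

#' Block-wise mutation and recombination rate map
#'
#' Per-bp mutation and recombination rates assigned to consecutive blocks
#' (10 kb by default); the final block may be shorter than `blockLength` but
#' carries a full rate draw.  `cv = 0` encodes a constant map.
#'
#' @slot blockLength block width in bp.
#' @slot mu,rec numeric per-bp per-generation rates, one per block.
#' @slot meanMu,meanRec the means the map was drawn around.
#' @slot cv coefficient of variation of the (pre-truncation) sampling
#'   distribution.
#' @slot segmentLength segment length the map covers.
#' @export
setClass("RateMap",
    representation(blockLength = "integer", mu = "numeric", rec = "numeric",
                   meanMu = "numeric", meanRec = "numeric", cv = "numeric",
                   segmentLength = "integer"))

setValidity("RateMap", function(object) {
    nb <- ceiling(object@segmentLength / object@blockLength)
    msgs <- character()
    if (length(object@mu) != nb || length(object@rec) != nb)
        msgs <- c(msgs, sprintf("expected %d blocks", nb))
    if (any(object@mu < 0) || any(object@rec < 0))
        msgs <- c(msgs, "rates must be non-negative")
    if (object@cv < 0) msgs <- c(msgs, "cv must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' Piecewise-constant single-population demography
#'
#' Epochs are measured backward from the sampling generation: row `i` gives
#' the diploid size holding on `[time_i, time_{i+1})` generations before
#' sampling; the last row is the open-ended ancestral epoch.
#'
#' @slot epochs data.frame with columns `size` (diploids) and `time`
#'   (backward start, generations; first row has `time = 0`).
#' @export
setClass("Demography", representation(epochs = "data.frame"))

setValidity("Demography", function(object) {
    ep <- object@epochs
    msgs <- character()
    if (!all(c("size", "time") %in% names(ep)))
        msgs <- c(msgs, "epochs need columns size, time")
    else {
        if (nrow(ep) < 1L || ep$time[1L] != 0)
            msgs <- c(msgs, "first epoch must start at time 0")
        if (any(ep$size < 2)) msgs <- c(msgs, "diploid sizes must be >= 2")
        if (nrow(ep) > 1L && any(diff(ep$time) <= 0))
            msgs <- c(msgs, "epoch start times must be strictly increasing")
    }
    if (length(msgs)) msgs else TRUE
})

#' Distribution of fitness effects of new exonic mutations
#'
#' Selection coefficients are population-scaled *heterozygous* effects
#' (2 N_anc s_het); with semidominance (`h = 0.5` on the homozygous
#' coefficient) the homozygote carries twice the heterozygous effect.  The
#' deleterious side is a 4-class discrete DFE on the 2Ns scale --
#' effectively neutral (-1, 0], weakly (-10, -1], moderately (-100, -10] and
#' strongly (<= -100) deleterious, each class uniform and contributing
#' equally to new mutations.  The beneficial side is an exponential with
#' population-scaled mean `gamma`, making up a fraction `fpos` of new exonic
#' mutations.  Introns and intergenic DNA are always neutral.
#'
#' @slot deleterious logical; is the 4-class deleterious DFE active.
#' @slot delWeights class weights (sum to 1).
#' @slot delBounds 4 x 2 matrix of scaled bounds (lower, upper), negative.
#' @slot gamma population-scaled mean heterozygous beneficial effect.
#' @slot fpos fraction of new exonic mutations that are beneficial.
#' @slot h dominance coefficient applied to the homozygous effect.
#' @export
setClass("DFEConfig",
    representation(deleterious = "logical", delWeights = "numeric",
                   delBounds = "matrix", gamma = "numeric", fpos = "numeric",
                   h = "numeric"))

setValidity("DFEConfig", function(object) {
    msgs <- character()
    if (length(object@delWeights) != 4L ||
        abs(sum(object@delWeights) - 1) > 1e-9)
        msgs <- c(msgs, "delWeights must be 4 values summing to 1")
    if (!identical(dim(object@delBounds), c(4L, 2L)))
        msgs <- c(msgs, "delBounds must be 4 x 2")
    if (object@gamma < 0) msgs <- c(msgs, "gamma must be >= 0")
    if (object@fpos < 0 || object@fpos > 1)
        msgs <- c(msgs, "fpos must be in [0, 1]")
    if (length(msgs)) msgs else TRUE
})

#' Complete generative model for one simulated scenario
#'
#' Bundles the genome layout, rate map, demography, DFE, progeny skew,
#' observation settings and sample size.  All values are in the rescaled
#' units actually simulated (the named presets are pre-rescaled by the
#' standard factor of 200 from the Drosophila-like base parameters).
#'
#' @slot name preset name or "custom".
#' @slot layout a [GenomeLayout].
#' @slot rates a [RateMap].
#' @slot demography a [Demography].
#' @slot dfe a [DFEConfig].
#' @slot psi fraction of each generation replaced by offspring of a single
#'   parent (progeny skew); 0 disables.
#' @slot singletonDrop fraction of sample singletons removed by the
#'   ascertainment operator.
#' @slot sampleSize haploid sample size n.
#' @slot seed optional integer seed recorded with the scenario.
#' @export
setClass("ScenarioConfig",
    representation(name = "character", layout = "GenomeLayout",
                   rates = "RateMap", demography = "Demography",
                   dfe = "DFEConfig", psi = "numeric",
                   singletonDrop = "numeric", sampleSize = "integer",
                   seed = "integer"))

setValidity("ScenarioConfig", function(object) {
    msgs <- character()
    if (object@psi < 0 || object@psi >= 1)
        msgs <- c(msgs, "psi must be in [0, 1)")
    if (object@singletonDrop < 0 || object@singletonDrop > 1)
        msgs <- c(msgs, "singletonDrop must be in [0, 1]")
    if (object@sampleSize < 2)
        msgs <- c(msgs, "sampleSize must be >= 2")
    if (object@sampleSize > 2 * object@demography@epochs$size[1L])
        msgs <- c(msgs, "sampleSize exceeds 2 x current diploid size")
    if (object@rates@segmentLength != object@layout@segmentLength)
        msgs <- c(msgs, "rate map and layout disagree on segment length")
    if (length(msgs)) msgs else TRUE
})

#' A sample of haplotypes over segregating sites
#'
#' `genotypes` is an n x S 0/1 matrix (haplotypes in rows) of derived-allele
#' indicators; `positions` are 0-based bp coordinates, strictly increasing;
#' `callable` records which intervals of the segment remain observable after
#' masking.  Every retained site has derived count between 1 and n-1.
#'
#' @slot genotypes integer matrix, haplotypes x sites.
#' @slot positions integer vector of site coordinates (0-based).
#' @slot callable [IRanges::IRanges] of callable intervals (1-based, closed,
#'   as is usual for IRanges; converted at the coordinate boundary).
#' @slot segmentLength segment length in bp.
#' @slot ancestralKnown logical; TRUE for simulator output (derived coding).
#' @export
setClass("HaplotypeSample",
    representation(genotypes = "matrix", positions = "integer",
                   callable = "IRanges", segmentLength = "integer",
                   ancestralKnown = "logical"))

setValidity("HaplotypeSample", function(object) {
    G <- object@genotypes
    msgs <- character()
    if (ncol(G) != length(object@positions))
        msgs <- c(msgs, "positions must match genotype columns")
    if (ncol(G) > 0) {
        if (is.unsorted(object@positions))
            msgs <- c(msgs, "positions must be sorted")
        if (min(object@positions) < 0 ||
            max(object@positions) >= object@segmentLength)
            msgs <- c(msgs, "positions outside the segment")
        cnt <- colSums(G)
        if (any(cnt < 1) || any(cnt > nrow(G) - 1))
            msgs <- c(msgs, "derived counts must be in [1, n-1]")
    }
    if (length(msgs)) msgs else TRUE
})

#' Result of one forward simulation
#'
#' @slot sample the [HaplotypeSample] drawn at the end of the run.
#' @slot fixations data.frame of fixed mutations (class, s, origin and
#'   fixation generation).
#' @slot dA beneficial substitutions per exonic site.
#' @slot lambda realized fraction of substitutions due to beneficial
#'   mutations, from the fixation counts.
#' @slot counters bookkeeping list (mutations introduced / fixed / lost /
#'   segregating).
#' @slot config the [ScenarioConfig] actually simulated (after any extra
#'   rescaling).
#' @slot totalGenerations run length in generations.
#' @slot seed the seed used.
#' @export
setClass("SimResult",
    representation(sample = "HaplotypeSample", fixations = "data.frame",
                   dA = "numeric", lambda = "numeric", counters = "list",
                   config = "ScenarioConfig", totalGenerations = "numeric",
                   seed = "numeric"))

#' ABC reference table
#'
#' One row per parameter draw; `stats` holds the aggregated summary-statistic
#' vector over `replicates` independent simulations at that draw.  `extras`
#' carries derived per-row quantities (for the sweep model, the realized
#' beneficial substitution rate `dA` and `lambda`).
#'
#' @slot params data.frame of parameter draws (natural scale).
#' @slot stats numeric matrix of features, one row per draw.
#' @slot extras data.frame of derived per-row quantities (0 columns if none).
#' @slot model "demographic" or "sweep" (or a custom label).
#' @slot replicates simulations aggregated per row.
#' @slot prior the prior specification the draws came from.
#' @export
setClass("ReferenceTable",
    representation(params = "data.frame", stats = "matrix",
                   extras = "data.frame", model = "character",
                   replicates = "integer", prior = "list"))

setValidity("ReferenceTable", function(object) {
    if (nrow(object@params) != nrow(object@stats))
        return("params and stats must have matching rows")
    if (anyNA(object@stats)) return("stats must be complete (no NA)")
    TRUE
})

#' Weighted ABC posterior sample
#'
#' @slot draws accepted parameter draws, natural scale (matrix).
#' @slot adjusted regression-adjusted draws, natural scale; equal to `draws`
#'   for rejection-only posteriors.
#' @slot weights non-negative importance weights summing to 1.
#' @slot distances standardized Euclidean distances of the accepted rows.
#' @slot method "rejection", "loclinear" or "neuralnet".
#' @slot prior the prior specification (used to clamp adjusted draws).
#' @slot extras adjusted derived quantities (e.g. lambda for the sweep model).
#' @export
setClass("Posterior",
    representation(draws = "matrix", adjusted = "matrix", weights = "numeric",
                   distances = "numeric", method = "character",
                   prior = "list", extras = "data.frame"))

setValidity("Posterior", function(object) {
    msgs <- character()
    if (length(object@weights) != nrow(object@adjusted))
        msgs <- c(msgs, "one weight per draw required")
    if (any(object@weights < 0)) msgs <- c(msgs, "weights must be >= 0")
    if (length(object@weights) &&
        abs(sum(object@weights) - 1) > 1e-8)
        msgs <- c(msgs, "weights must sum to 1")
    if (length(msgs)) msgs else TRUE
})
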