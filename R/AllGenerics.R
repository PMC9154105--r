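#' @rdname GenomeLayout-class
#' @param x,object a package object.
#' @export
setGeneric("segmentLength", function(x) standardGeneric("segmentLength"))

#' @rdname GenomeLayout-class
#' @export
setGeneric("geneCount", function(x) standardGeneric("geneCount"))

#' @rdname HaplotypeSample-class
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' @rdname HaplotypeSample-class
#' @export
setGeneric("sitePositions", function(x) standardGeneric("sitePositions"))

#' @rdname HaplotypeSample-class
#' @export
setGeneric("genotypeMatrix", function(x) standardGeneric("genotypeMatrix"))

#' @rdname HaplotypeSample-class
#' @export
setGeneric("callableRegions", function(x) standardGeneric("callableRegions"))

#' @rdname HaplotypeSample-class
#' @export
setGeneric("derivedCounts", function(x) standardGeneric("derivedCounts"))

#' Weighted-median point estimate of a posterior
#'
#' The point estimate of each parameter is the weighted median of the
#' (adjusted) posterior draws: the smallest value whose cumulative weight
#' reaches 0.5.
#'
#' @param object a [Posterior].
#' @param ... unused.
#' @return named numeric vector of point estimates on the natural scale.
#' @export
setGeneric("pointEstimate", function(object, ...) standardGeneric("pointEstimate"))

#' Central credible interval of a posterior
#'
#' Weighted 0.025/0.975 quantiles (or `level`-adjusted) of the adjusted
#' draws, per parameter.
#'
#' @param object a [Posterior].
#' @param level interval mass (default 0.95).
#' @param ... unused.
#' @return matrix with columns `lower`, `upper`, one row per parameter.
#' @export
setGeneric("credibleInterval",
           function(object, level = 0.95, ...) standardGeneric("credibleInterval"))

#' @rdname Posterior-class
#' @export
setGeneric("posteriorDraws", function(object, ...) standardGeneric("posteriorDraws"))

#' @rdname GenomeLayout-class
#' @export
setMethod("segmentLength", "GenomeLayout", function(x) x@segmentLength)

#' @rdname GenomeLayout-class
#' @export
setMethod("geneCount", "GenomeLayout", function(x) x@geneCount)

#' @rdname ScenarioConfig-class
#' @export
setMethod("segmentLength", "ScenarioConfig", function(x) x@layout@segmentLength)

#' @rdname HaplotypeSample-class
#' @export
setMethod("segmentLength", "HaplotypeSample", function(x) x@segmentLength)

#' @rdname HaplotypeSample-class
#' @export
setMethod("nHaplotypes", "HaplotypeSample", function(x) nrow(x@genotypes))

#' @rdname HaplotypeSample-class
#' @export
setMethod("sitePositions", "HaplotypeSample", function(x) x@positions)

#' @rdname HaplotypeSample-class
#' @export
setMethod("genotypeMatrix", "HaplotypeSample", function(x) x@genotypes)

#' @rdname HaplotypeSample-class
#' @export
setMethod("callableRegions", "HaplotypeSample", function(x) x@callable)

#' @rdname HaplotypeSample-class
#' @export
setMethod("derivedCounts", "HaplotypeSample", function(x) {
    cnt <- colSums(x@genotypes)
    names(cnt) <- NULL
    as.integer(cnt)
})

setMethod("show", "GenomeLayout", function(object) {
    tab <- table(S4Vectors::mcols(object@elements)$type)
    cat("GenomeLayout:", object@segmentLength, "bp,",
        object@geneCount, "genes\n")
    cat("  elements:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
        collapse = ", "), "\n")
})

setMethod("show", "RateMap", function(object) {
    cat(sprintf("RateMap: %d blocks of %d bp (cv = %g)\n",
        length(object@mu), object@blockLength, object@cv))
    cat(sprintf("  mu: mean %.3g  rec: mean %.3g (per bp per generation)\n",
        mean(object@mu), mean(object@rec)))
})

setMethod("show", "Demography", function(object) {
    cat("Demography (backward epochs):\n")
    print(object@epochs, row.names = FALSE)
})

setMethod("show", "DFEConfig", function(object) {
    if (object@deleterious)
        cat("DFE: 4-class deleterious (weights",
            paste(object@delWeights, collapse = "/"), ")\n")
    else cat("DFE: no deleterious classes\n")
    if (object@fpos > 0)
        cat(sprintf("  beneficial: exponential, gamma = %g, fpos = %g\n",
            object@gamma, object@fpos))
    else cat("  beneficial: none\n")
})

setMethod("show", "ScenarioConfig", function(object) {
    cat("ScenarioConfig <", object@name, ">\n", sep = "")
    cat(sprintf("  segment %d bp, n = %d haploid genomes\n",
        object@layout@segmentLength, object@sampleSize))
    cat(sprintf("  N_cur = %g diploids (%d epoch(s)), psi = %g, singleton drop = %g\n",
        object@demography@epochs$size[1L], nrow(object@demography@epochs),
        object@psi, object@singletonDrop))
    show(object@dfe)
})

setMethod("show", "HaplotypeSample", function(object) {
    cat(sprintf("HaplotypeSample: %d haplotypes x %d segregating sites (%d bp segment)\n",
        nrow(object@genotypes), ncol(object@genotypes), object@segmentLength))
    cat(sprintf("  callable: %d bp in %d interval(s)\n",
        sum(IRanges::width(object@callable)), length(object@callable)))
})

setMethod("show", "SimResult", function(object) {
    cat("SimResult:", object@totalGenerations, "generations\n")
    cat(sprintf("  fixations: %d (beneficial: %d), d_a = %.4g, lambda = %.4g\n",
        nrow(object@fixations), sum(object@fixations$class == "beneficial"),
        object@dA, object@lambda))
    show(object@sample)
})

setMethod("show", "ReferenceTable", function(object) {
    cat(sprintf("ReferenceTable (%s model): %d draws x %d features, %d replicate(s)/draw\n",
        object@model, nrow(object@params), ncol(object@stats),
        object@replicates))
    cat("  parameters:", paste(names(object@params), collapse = ", "), "\n")
})

setMethod("show", "Posterior", function(object) {
    cat(sprintf("Posterior (%s): %d weighted draws\n", object@method,
        nrow(object@adjusted)))
    pe <- pointEstimate(object)
    ci <- credibleInterval(object)
    for (p in seq_along(pe))
        cat(sprintf("  %s: %.4g  [%.4g, %.4g]\n", names(pe)[p], pe[p],
            ci[p, 1L], ci[p, 2L]))
})

#' @rdname Posterior-class
#' @export
setMethod("posteriorDraws", "Posterior", function(object, ...) object@adjusted)
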