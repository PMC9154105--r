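#' Mask directly selected (exonic) sites
#'
#' Removes all sites falling in exons and subtracts the exon intervals from
#' the callable mask, mirroring the study design in which inference uses
#' neutral (intronic/intergenic) regions only.  Idempotent.
#'
#' @param sample a [HaplotypeSample].
#' @param layout the [GenomeLayout] describing the exon structure.
#' @return the masked [HaplotypeSample].
#' @export
maskExons <- function(sample, layout) {
    if (layout@segmentLength != sample@segmentLength)
        stop("layout and sample disagree on segment length")
    ex <- layoutRanges(layout, "exon")
    pos1 <- sample@positions + 1L  # to 1-based for IRanges overlap
    hits <- IRanges::overlapsAny(IRanges::IRanges(pos1, pos1), ex)
    keep <- !hits
    callable <- IRanges::setdiff(sample@callable, ex)
    haplotypeSample(sample@genotypes[, keep, drop = FALSE],
                    sample@positions[keep], sample@segmentLength,
                    callable = callable,
                    ancestralKnown = sample@ancestralKnown)
}

#' Singleton ascertainment error
#'
#' Models the undercalling of rare variants in low-coverage data: exactly
#' `round(dropFraction * S1)` of the `S1` sites with derived-allele count 1
#' are removed, chosen uniformly without replacement; all other sites are
#' untouched.  With `folded = TRUE` sites at derived count `n - 1` are also
#' treated as singletons (minor-allele count 1); the default is unfolded
#' since the simulators know the ancestral state.
#'
#' @param sample a [HaplotypeSample].
#' @param dropFraction fraction of singletons to remove (default 1/3).
#' @param folded treat derived count `n - 1` as a singleton too.
#' @param seed integer seed (R RNG used; respects `set.seed` when `NULL`).
#' @return the ascertained [HaplotypeSample].
#' @export
ascertainSingletons <- function(sample, dropFraction = 1 / 3, folded = FALSE,
                                seed = NULL) {
    if (dropFraction < 0 || dropFraction > 1)
        stop("dropFraction must be in [0, 1]")
    if (!is.null(seed)) {
        old <- .Random.seed_save()
        on.exit(.Random.seed_restore(old), add = TRUE)
        set.seed(seed)
    }
    cnt <- colSums(sample@genotypes)
    n <- nrow(sample@genotypes)
    singles <- which(cnt == 1L | (folded & cnt == n - 1L))
    ndrop <- round(dropFraction * length(singles))
    if (ndrop == 0) return(sample)
    drop <- singles[sample.int(length(singles), ndrop)]
    keep <- setdiff(seq_along(sample@positions), drop)
    haplotypeSample(sample@genotypes[, keep, drop = FALSE],
                    sample@positions[keep], sample@segmentLength,
                    callable = sample@callable,
                    ancestralKnown = sample@ancestralKnown)
}

.Random.seed_save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Partition the segment into nonoverlapping windows
#'
#' `ceiling(L / width)` half-open windows anchored at coordinate 0 (the last
#' window may be shorter).  Returns per-window site membership and callable
#' bp under the sample's mask.
#'
#' @param sample a [HaplotypeSample].
#' @param width window width in bp (default 2,000).
#' @return data.frame with columns `window`, `start`, `end` (0-based
#'   half-open), `callable` (bp) and a list-column `sites` of site indices.
#' @export
windowPartition <- function(sample, width = 2000L) {
    if (width <= 0) stop("width must be positive")
    L <- sample@segmentLength
    nw <- ceiling(L / width)
    start <- (seq_len(nw) - 1L) * width
    end <- pmin(start + width, L)
    win <- IRanges::IRanges(start + 1L, end)  # 1-based closed
    callable <- integer(nw)
    ov <- IRanges::findOverlaps(win, sample@callable)
    if (length(ov)) {
        pw <- IRanges::width(IRanges::pintersect(
            win[S4Vectors::queryHits(ov)],
            sample@callable[S4Vectors::subjectHits(ov)]))
        agg <- rowsum(pw, S4Vectors::queryHits(ov))
        callable[as.integer(rownames(agg))] <- as.integer(agg)
    }
    idx <- findInterval(sample@positions, start)  # window index per site
    sites <- lapply(seq_len(nw), function(i) which(idx == i))
    out <- data.frame(window = seq_len(nw), start = start, end = end,
                      callable = as.integer(callable))
    out$sites <- sites
    out
}
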