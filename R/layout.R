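#' Build the intron--exon--intergenic genome layout
#'
#' Constructs the element tiling of the simulated segment.  Each gene is
#' `exonsPerGene` exons alternating with `intronsPerGene` introns (starting
#' and ending with an exon); genes are separated by one intergenic block and
#' one extra intergenic block is placed at the segment start, so
#' `segmentLength = geneCount * (5*300 + 4*100 + 1068) + 1068 = 2968 g + 1068`
#' with the defaults.  The defaults with `geneCount = 33` give the standard
#' 99,012-bp segment.
#'
#' @param geneCount number of genes (>= 1).
#' @param exonLength,intronLength,intergenicLength element lengths in bp.
#' @param exonsPerGene,intronsPerGene elements per gene.
#' @return a [GenomeLayout].
#' @examples
#' layout <- buildLayout()
#' segmentLength(layout)  # 99012
#' @export
buildLayout <- function(geneCount = 33L, exonLength = 300L,
                        intronLength = 100L, intergenicLength = 1068L,
                        exonsPerGene = 5L, intronsPerGene = 4L) {
    geneCount <- as.integer(geneCount)
    if (geneCount < 1L) stop("geneCount must be >= 1")
    lens <- c(exon = as.integer(exonLength), intron = as.integer(intronLength),
              intergenic = as.integer(intergenicLength))
    if (any(lens <= 0L)) stop("element lengths must be positive")
    if (exonsPerGene < 1L || intronsPerGene != exonsPerGene - 1L)
        stop("need exonsPerGene >= 1 and intronsPerGene = exonsPerGene - 1")

    gene <- rep(c("exon", "intron"), length.out = 2L * exonsPerGene - 1L)
    types <- c("intergenic", rep(c(gene, "intergenic"), geneCount))
    widths <- lens[types]
    starts <- cumsum(c(1L, widths[-length(widths)]))
    elements <- IRanges::IRanges(start = starts, width = widths)
    S4Vectors::mcols(elements)$type <- types
    new("GenomeLayout", elements = elements,
        segmentLength = as.integer(sum(widths)),
        geneCount = geneCount,
        elementLengths = c(lens, exonsPerGene = as.integer(exonsPerGene),
                           intronsPerGene = as.integer(intronsPerGene)))
}

#' Exonic intervals of a layout
#'
#' @param layout a [GenomeLayout].
#' @param type element class to extract.
#' @return an [IRanges::IRanges] (1-based closed coordinates).
#' @export
layoutRanges <- function(layout, type = c("exon", "intron", "intergenic")) {
    type <- match.arg(type)
    layout@elements[S4Vectors::mcols(layout@elements)$type == type]
}

#' Logical per-bp exon indicator (0-based position i at index i + 1)
#' @noRd
exonMaskVector <- function(layout) {
    m <- logical(layout@segmentLength)
    ex <- layoutRanges(layout, "exon")
    for (i in seq_along(ex))
        m[IRanges::start(ex)[i]:IRanges::end(ex)[i]] <- TRUE
    m
}

#' Rescale population-genetic parameters
#'
#' Divides the population size and multiplies the per-generation rates and
#' selection coefficients by the rescaling factor `Q`, keeping the scaled
#' compound parameters theta = 4 N mu, rho = 4 N r and gamma = 2 N s exactly
#' invariant.  The standard parameterization rescales the Drosophila-like
#' base (N_e = 1e6, mu = 4.5e-9, r = 1e-8) by Q = 200 to N = 5,000,
#' mu = 9e-7, r = 2e-6.  Selection--drift dynamics are only approximately
#' scale-invariant, so large `Q` is applied with a warning.
#'
#' @param N diploid population size.
#' @param mu,r per-bp per-generation rates.
#' @param s selection coefficient(s), optional.
#' @param Q rescaling factor (>= 1).
#' @param warnLarge warn when `Q` exceeds this (set `Inf` to silence).
#' @return list with elements `N`, `mu`, `r`, `s`, `Q` and the invariant
#'   products `theta`, `rho`.
#' @examples
#' rescaleParameters(N = 1e6, mu = 4.5e-9, r = 1e-8, Q = 200)$N  # 5000
#' @export
rescaleParameters <- function(N, mu, r, s = numeric(0), Q = 200,
                              warnLarge = 1000) {
    if (Q < 1) stop("Q must be >= 1")
    if (Q > N) stop("Q exceeds N: rescaled population would vanish")
    if (Q > warnLarge)
        warning("large rescaling factor Q = ", Q,
                ": selection-drift dynamics are only approximately scale-invariant")
    list(N = N / Q, mu = mu * Q, r = r * Q, s = s * Q, Q = Q,
         theta = 4 * N * mu, rho = 4 * N * r)
}

#' Draw a heterogeneous mutation/recombination rate map
#'
#' Assigns each block (10 kb by default) an independent per-bp mutation and
#' recombination rate drawn from a Gaussian with the requested mean and
#' coefficient of variation; negative draws are truncated to 0.  `cv = 0`
#' returns a constant map.  The final partial block receives a full draw.
#' Uses R's RNG (respects `set.seed`).
#'
#' @param layout a [GenomeLayout].
#' @param meanMu,meanRec mean per-bp per-generation rates.
#' @param cv coefficient of variation of the sampling distribution.
#' @param blockLength block width in bp (default 10,000).
#' @return a [RateMap].
#' @export
drawRateMap <- function(layout, meanMu = 9e-7, meanRec = 2e-6, cv = 0,
                        blockLength = 10000L) {
    if (cv < 0) stop("cv must be >= 0")
    if (blockLength <= 0) stop("blockLength must be positive")
    nb <- as.integer(ceiling(layout@segmentLength / blockLength))
    if (cv == 0) {
        mu <- rep(meanMu, nb)
        rec <- rep(meanRec, nb)
    } else {
        mu <- pmax(0, rnorm(nb, meanMu, cv * meanMu))
        rec <- pmax(0, rnorm(nb, meanRec, cv * meanRec))
    }
    new("RateMap", blockLength = as.integer(blockLength), mu = mu, rec = rec,
        meanMu = meanMu, meanRec = meanRec, cv = cv,
        segmentLength = layout@segmentLength)
}

#' Export layout intervals as BED
#'
#' Writes the element tiling as a 4-column BED file (0-based half-open),
#' with the element class in the name column -- convenient for masking
#' interoperability with external tools.
#'
#' @param layout a [GenomeLayout].
#' @param file output path.
#' @param seqname chromosome label to use.
#' @return the file path, invisibly.
#' @export
layoutToBed <- function(layout, file, seqname = "segment") {
    el <- layout@elements
    bed <- data.frame(chrom = seqname,
                      start = IRanges::start(el) - 1L,
                      end = IRanges::end(el),
                      name = S4Vectors::mcols(el)$type)
    write.table(bed, file, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(file)
}
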