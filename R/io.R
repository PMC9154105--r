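#' Export / import haplotype samples in ms format
#'
#' `writeMs` writes one or more samples as ms-style output: a `//` block per
#' replicate with `segsites:` and `positions:` (scaled to `[0, 1)`) followed
#' by 0/1 haplotype rows.  `readMs` parses such a file back; positions are
#' restored as `floor(p * segmentLength)`, so the round trip preserves
#' integer coordinates for samples written by this package.
#'
#' @param samples a [HaplotypeSample] or list of them.
#' @param file path.
#' @param segmentLength segment length in bp used to rescale positions on
#'   reading.
#' @return `writeMs`: the path, invisibly; `readMs`: list of
#'   [HaplotypeSample].
#' @export
writeMs <- function(samples, file) {
    if (is(samples, "HaplotypeSample")) samples <- list(samples)
    n <- nHaplotypes(samples[[1L]])
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(sprintf("ms %d %d", n, length(samples)), con)
    writeLines("0 0 0", con)
    for (s in samples) {
        writeLines("", con)
        writeLines("//", con)
        S <- length(s@positions)
        writeLines(sprintf("segsites: %d", S), con)
        if (S > 0) {
            writeLines(paste("positions:",
                paste(sprintf("%.8f", s@positions / s@segmentLength),
                      collapse = " ")), con)
            rows <- apply(s@genotypes, 1, paste, collapse = "")
            writeLines(rows, con)
        } else {
            writeLines("positions:", con)
        }
    }
    invisible(file)
}

#' @rdname writeMs
#' @export
readMs <- function(file, segmentLength) {
    lines <- readLines(file)
    starts <- which(lines == "//")
    out <- vector("list", length(starts))
    for (k in seq_along(starts)) {
        i <- starts[k]
        S <- as.integer(sub("segsites: *", "", lines[i + 1L]))
        if (S == 0L) {
            out[[k]] <- haplotypeSample(matrix(0L, 0, 0), integer(0),
                                        segmentLength)
            next
        }
        pos <- as.numeric(strsplit(sub("positions: *", "", lines[i + 2L]),
                                   " +")[[1L]])
        j <- i + 3L
        rows <- character(0)
        while (j <= length(lines) && grepl("^[01]+$", lines[j])) {
            rows <- c(rows, lines[j])
            j <- j + 1L
        }
        G <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
        out[[k]] <- haplotypeSample(G, floor(pos * segmentLength),
                                    segmentLength)
    }
    out
}

#' Minimal VCF export with ancestral-allele annotation
#'
#' Writes a sample as an uncompressed VCFv4.2 file: 1-based positions,
#' REF = ancestral (A), ALT = derived (T), `INFO AA=A`, and phased diploid
#' genotype columns built from consecutive haplotype pairs (an odd final
#' haplotype is written as a haploid column).
#'
#' @param sample a [HaplotypeSample].
#' @param file path.
#' @param seqname chromosome label.
#' @return the path, invisibly.
#' @export
writeVcf <- function(sample, file, seqname = "segment") {
    n <- nHaplotypes(sample)
    nd <- n %/% 2L
    odd <- n %% 2L == 1L
    ids <- c(sprintf("ind%03d", seq_len(nd)),
             if (odd) sprintf("hap%03d", n))
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 sprintf("##contig=<ID=%s,length=%d>", seqname,
                         sample@segmentLength),
                 "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", ids), collapse = "\t")),
               con)
    G <- sample@genotypes
    for (s in seq_along(sample@positions)) {
        gt <- vapply(seq_len(nd), function(i)
            sprintf("%d|%d", G[2L * i - 1L, s], G[2L * i, s]), character(1))
        if (odd) gt <- c(gt, as.character(G[n, s]))
        writeLines(paste(c(seqname, sample@positions[s] + 1L, ".", "A", "T",
                           ".", "PASS", "AA=A", "GT", gt), collapse = "\t"),
                   con)
    }
    invisible(file)
}

#' Write a fixation log as TSV
#'
#' @param result a [SimResult].
#' @param file path.
#' @return the path, invisibly.
#' @export
writeFixationLog <- function(result, file) {
    write.table(result@fixations, file, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(file)
}
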