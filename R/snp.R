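#' Windowed female heterozygous-SNP density
#'
#' Counts variants whose allele frequency lies inside the heterozygote
#' band (0.2-0.8, inclusive) in fixed windows aligned to the depth-window
#' grid. In exon-restricted mode (when `exons` is supplied, e.g. for
#' RNA-seq-derived calls) only exonic variants are counted and the density
#' denominator is the exonic bp per window rather than the window size.
#'
#' @param variants [GenomicRanges::GRanges] of single-base variants with
#'   metadata column `af`.
#' @param windowSize window width in bp (default 50 kb).
#' @param afBand inclusive allele-frequency band defining heterozygotes.
#' @param seqlengths optional named vector overriding the chromosome
#'   lengths carried by `variants`.
#' @param exons optional `GRanges` of exons enabling exon-restricted mode.
#' @return `GRanges` of windows with metadata columns `count`, `denomBp`
#'   and `density` (= count / denomBp).
#' @export
snpDensityTrack <- function(variants, windowSize = 5e4,
                            afBand = c(0.2, 0.8), seqlengths = NULL,
                            exons = NULL) {
    stopifnot(is(variants, "GRanges"))
    if (!"af" %in% names(S4Vectors::mcols(variants)))
        stop("variants must carry an 'af' column")
    keep <- variants$af >= afBand[1] & variants$af <= afBand[2]
    v <- variants[keep]
    if (is.null(seqlengths)) {
        seqlengths <- GenomeInfoDb::seqlengths(variants)
        if (any(is.na(seqlengths)))
            seqlengths[is.na(seqlengths)] <- vapply(
                names(seqlengths)[is.na(seqlengths)],
                function(chr) {
                    x <- variants[GenomeInfoDb::seqnames(variants) == chr]
                    if (length(x)) max(GenomicRanges::end(x)) else windowSize
                }, numeric(1))
    }
    out <- list()
    for (chr in names(seqlengths)) {
        len <- seqlengths[[chr]]
        starts <- seq(1, len, by = windowSize)
        w <- GenomicRanges::GRanges(
            chr, IRanges::IRanges(starts, pmin(starts + windowSize - 1, len)))
        GenomeInfoDb::seqlevels(w) <- names(seqlengths)
        vc <- v[GenomeInfoDb::seqnames(v) == chr]
        if (!is.null(exons)) {
            ex <- GenomicRanges::reduce(
                exons[GenomeInfoDb::seqnames(exons) == chr])
            vc <- vc[GenomicRanges::countOverlaps(vc, ex) > 0]
            denom <- numeric(length(w))
            hits <- GenomicRanges::findOverlaps(ex, w)
            if (length(hits)) {
                pi <- GenomicRanges::pintersect(
                    ex[S4Vectors::queryHits(hits)],
                    w[S4Vectors::subjectHits(hits)])
                agg <- rowsum(GenomicRanges::width(pi),
                              S4Vectors::subjectHits(hits))
                denom[as.integer(rownames(agg))] <- agg[, 1]
            }
        } else {
            denom <- GenomicRanges::width(w)
        }
        w$count <- GenomicRanges::countOverlaps(w, vc)
        w$denomBp <- denom
        w$density <- ifelse(denom > 0, w$count / denom, NA_real_)
        out[[chr]] <- w
    }
    do.call(c, unname(out))
}

#' Cross-check a PAR/DR annotation against SNP density
#'
#' The DR is hemizygous in females and should show essentially no
#' heterozygous SNPs; W-derived reads mismapping onto a degenerating DR
#' instead inflate apparent heterozygosity. Windows are assigned to the
#' PAR or DR by their midpoint and the median per-window count is compared
#' between segments: the annotation is flagged `"consistent"` when the DR
#' median is at most `consistentMax` times the PAR median,
#' `"elevated-DR"` when it lies between `consistentMax` and `ambiguousMin`
#' times the PAR median (residual heterozygosity, the mismapping
#' signature), and `"ambiguous"` when the two segments are essentially
#' indistinguishable (ratio at or above `ambiguousMin`) or the PAR itself
#' shows no heterozygosity.
#'
#' @param annotation a [RegionAnnotation] with a boundary.
#' @param densityTrack `GRanges` from [snpDensityTrack()] for the same
#'   chromosome.
#' @param consistentMax,ambiguousMin thresholds on the DR/PAR median
#'   ratio (defaults 0.05 and 0.95).
#' @return The annotation with a flag appended and the segment medians
#'   stored in its `metadata` (`snpParMedian`, `snpDrMedian`).
#' @export
verifyBoundaryWithSnps <- function(annotation, densityTrack,
                                   consistentMax = 0.05,
                                   ambiguousMin = 0.95) {
    stopifnot(is(annotation, "RegionAnnotation"))
    w <- densityTrack[as.character(GenomeInfoDb::seqnames(densityTrack)) ==
                      annotation@chromosome]
    mid <- (GenomicRanges::start(w) + GenomicRanges::end(w)) / 2
    inPar <- IRanges::overlapsAny(IRanges::IRanges(mid, width = 1),
                                  annotation@parInterval)
    inDr <- IRanges::overlapsAny(IRanges::IRanges(mid, width = 1),
                                 annotation@drInterval)
    parMed <- if (any(inPar)) median(w$count[inPar]) else NA_real_
    drMed <- if (any(inDr)) median(w$count[inDr]) else NA_real_
    flag <- if (annotation@noDR || !any(inDr)) {
        "snp-not-assessed"
    } else if (!is.finite(parMed) || parMed <= 0) {
        "ambiguous"
    } else {
        ratio <- drMed / parMed
        if (ratio <= consistentMax) "consistent"
        else if (ratio < ambiguousMin) "elevated-DR"
        else "ambiguous"
    }
    annotation@flags <- c(annotation@flags, flag)
    annotation@metadata$snpParMedian <- parMed
    annotation@metadata$snpDrMedian <- drMed
    validObject(annotation)
    annotation
}
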