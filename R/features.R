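#' Per-window density of genomic intervals
#'
#' Computes, for each window of a grid, the fraction of window bases
#' covered by a set of intervals (TEs, exons, ...). Overlapping intervals
#' are merged before summing, and an interval straddling a window edge
#' contributes only its overlapping bases, so total covered bp is
#' conserved: the densities times the window sizes sum to the merged
#' overlap with the grid.
#'
#' @param intervals [GenomicRanges::GRanges] of features (BED semantics).
#' @param windows `GRanges` window grid, or a [WindowTrack] whose grid is
#'   reused.
#' @return The window `GRanges` with metadata columns `coveredBp` and
#'   `density`.
#' @export
intervalDensityWindows <- function(intervals, windows) {
    if (is(windows, "WindowTrack"))
        windows <- GenomicRanges::granges(trackWindows(windows))
    stopifnot(is(intervals, "GRanges"), is(windows, "GRanges"))
    merged <- GenomicRanges::reduce(intervals)
    covered <- numeric(length(windows))
    hits <- GenomicRanges::findOverlaps(merged, windows)
    if (length(hits)) {
        pi <- GenomicRanges::pintersect(merged[S4Vectors::queryHits(hits)],
                                        windows[S4Vectors::subjectHits(hits)])
        agg <- rowsum(GenomicRanges::width(pi), S4Vectors::subjectHits(hits))
        covered[as.integer(rownames(agg))] <- agg[, 1]
    }
    out <- windows
    out$coveredBp <- covered
    out$density <- covered / GenomicRanges::width(windows)
    out
}

#' Per-gene intron sizes from gene models
#'
#' Introns are the gaps between consecutive exons of the same transcript.
#' For genes with multiple transcripts the longest transcript (by summed
#' exon length) is used. Genes whose chosen transcript has overlapping
#' exons are skipped with a warning.
#'
#' @param exons [GenomicRanges::GRanges] of exons with metadata column
#'   `gene_id` (and optionally `transcript_id`).
#' @return Named list, gene id -> numeric vector of intron lengths
#'   (empty for single-exon genes).
#' @export
intronSizes <- function(exons) {
    stopifnot(is(exons, "GRanges"))
    if (!"gene_id" %in% names(S4Vectors::mcols(exons)))
        stop("exons must carry a gene_id column")
    hasTx <- "transcript_id" %in% names(S4Vectors::mcols(exons))
    byGene <- split(seq_along(exons), exons$gene_id)
    out <- vector("list", length(byGene))
    names(out) <- names(byGene)
    skipped <- character()
    for (g in names(byGene)) {
        ex <- exons[byGene[[g]]]
        if (hasTx && length(unique(ex$transcript_id)) > 1) {
            splen <- tapply(GenomicRanges::width(ex), ex$transcript_id, sum)
            ex <- ex[ex$transcript_id == names(which.max(splen))]
        }
        ex <- sort(ex)
        if (length(ex) > 1 &&
            any(GenomicRanges::start(ex)[-1] <=
                GenomicRanges::end(ex)[-length(ex)])) {
            skipped <- c(skipped, g)
            out[[g]] <- NULL
            next
        }
        out[[g]] <- if (length(ex) < 2) numeric(0)
                    else GenomicRanges::start(ex)[-1] -
                         GenomicRanges::end(ex)[-length(ex)] - 1
    }
    if (length(skipped))
        warning(length(skipped), " gene(s) skipped (overlapping exons): ",
                paste(head(skipped, 5), collapse = ", "))
    out[!vapply(out, is.null, logical(1))]
}

#' Region-versus-reference feature contrast
#'
#' Two-sided Wilcoxon rank-sum test of a per-gene or per-window feature
#' between a region (e.g. PAR) and a reference (e.g. chr4/5), as used for
#' TE density, intron size, GC3s and ENC contrasts.
#'
#' @param valuesRegion,valuesReference numeric vectors (each length >= 2).
#' @param feature optional feature label carried into the result.
#' @param alpha significance level for the direction call.
#' @return One-row data.frame: `feature`, `median_region`,
#'   `median_reference`, `p_value`, `direction`
#'   (higher/lower/ns), `n_region`, `n_reference`.
#' @export
regionFeatureTest <- function(valuesRegion, valuesReference,
                              feature = NA_character_, alpha = 0.05) {
    if (length(valuesRegion) < 2 || length(valuesReference) < 2)
        stop("both groups need at least 2 values")
    p <- suppressWarnings(
        wilcox.test(valuesRegion, valuesReference,
                    alternative = "two.sided")$p.value)
    if (is.na(p)) p <- 1    # fully tied inputs
    mR <- median(valuesRegion)
    mF <- median(valuesReference)
    direction <- if (p >= alpha) "ns" else if (mR > mF) "higher" else "lower"
    data.frame(feature = feature, median_region = mR,
               median_reference = mF, p_value = p, direction = direction,
               n_region = length(valuesRegion),
               n_reference = length(valuesReference),
               stringsAsFactors = FALSE)
}

#' Chromosome-size correlation of a genomic feature
#'
#' Correlation between chromosome size and a per-chromosome feature
#' summary (e.g. mean TE density or GC3s); chromosome size tracks
#' recombination rate inversely in birds, so these correlations probe
#' recombination-linked forces.
#'
#' @param sizes numeric chromosome sizes in bp (length >= 3).
#' @param values per-chromosome feature summaries, same length.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Named list `r` (correlation) and `p` (two-sided p-value).
#' @export
chromosomeSizeCorrelation <- function(sizes, values,
                                      method = c("pearson", "spearman")) {
    method <- match.arg(method)
    stopifnot(length(sizes) == length(values))
    if (length(sizes) < 3)
        stop("need at least 3 chromosomes")
    if (sd(sizes) == 0 || sd(values) == 0)
        stop("zero variance: correlation undefined")
    ct <- suppressWarnings(cor.test(sizes, values, method = method))
    list(r = unname(ct$estimate), p = ct$p.value)
}
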