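#' Aggregate interval depths into fixed windows
#'
#' Bins a per-base or per-interval depth signal (bedGraph semantics: the
#' `score` column is the depth over each interval) into fixed-width
#' windows. The window mean is taken over covered bases only; windows with
#' fewer than `minCovered` covered bases are dropped, mirroring the
#' practice of discarding sparse assembly windows.
#'
#' @param depth [GenomicRanges::GRanges] with numeric `score`; intervals
#'   must be sorted and non-overlapping within each chromosome. Seqlengths,
#'   when present, define the window grid extent; otherwise the last
#'   covered base does.
#' @param windowSize window width in bp (default 50 kb).
#' @param minCovered minimum covered bp for a window to be kept
#'   (default 5 kb).
#' @param sequences optional named [Biostrings::DNAStringSet] of chromosome
#'   sequences used to attach per-window GC fractions.
#' @return A [WindowTrack]. The number of windows dropped by the coverage
#'   filter is recorded in `metadata(trackWindows(x))$droppedWindows`.
#' @examples
#' d <- GenomicRanges::GRanges("Z", IRanges::IRanges(1, 150000), score = 30)
#' trackWindows(computeDepthWindows(d))
#' @export
computeDepthWindows <- function(depth, windowSize = 5e4, minCovered = 5e3,
                                sequences = NULL) {
    stopifnot(is(depth, "GRanges"), windowSize > 0)
    if (!"score" %in% names(S4Vectors::mcols(depth)))
        stop("depth input must carry a numeric 'score' column")
    if (length(depth) > 1) {
        if (S4Vectors::isSorted(GenomicRanges::granges(depth)) == FALSE)
            stop("depth intervals must be sorted")
        if (any(GenomicRanges::countOverlaps(depth, depth) > 1))
            stop("depth intervals must not overlap")
    }
    out <- list()
    dropped <- 0L
    allChroms <- as.character(unique(GenomeInfoDb::seqnames(depth)))
    for (chr in allChroms) {
        d <- depth[GenomeInfoDb::seqnames(depth) == chr]
        len <- GenomeInfoDb::seqlengths(depth)[chr]
        if (is.na(len)) len <- max(GenomicRanges::end(d))
        starts <- seq(1, len, by = windowSize)
        ends <- pmin(starts + windowSize - 1, len)
        w <- GenomicRanges::GRanges(chr, IRanges::IRanges(starts, ends))
        GenomeInfoDb::seqlevels(w) <- allChroms
        hits <- GenomicRanges::findOverlaps(d, w)
        covered <- numeric(length(w))
        weighted <- numeric(length(w))
        if (length(hits)) {
            pi <- GenomicRanges::pintersect(d[S4Vectors::queryHits(hits)],
                                            w[S4Vectors::subjectHits(hits)])
            bp <- GenomicRanges::width(pi)
            sc <- d$score[S4Vectors::queryHits(hits)]
            j <- S4Vectors::subjectHits(hits)
            covered <- as.numeric(rowsum(bp, j, reorder = TRUE)[
                match(seq_along(w), sort(unique(j))), 1])
            covered[is.na(covered)] <- 0
            weighted <- as.numeric(rowsum(bp * sc, j, reorder = TRUE)[
                match(seq_along(w), sort(unique(j))), 1])
            weighted[is.na(weighted)] <- 0
        }
        keep <- covered >= minCovered
        dropped <- dropped + sum(!keep)
        w <- w[keep]
        if (!length(w)) next
        w$meanDepth <- weighted[keep] / covered[keep]
        w$coveredBases <- covered[keep]
        w$gcFraction <- NA_real_
        if (!is.null(sequences) && chr %in% names(sequences)) {
            sub <- Biostrings::extractAt(
                sequences[[chr]],
                IRanges::IRanges(GenomicRanges::start(w),
                                 GenomicRanges::end(w)))
            fr <- Biostrings::letterFrequency(sub, c("GC", "ACGT"))
            w$gcFraction <- fr[, "G|C"] / pmax(fr[, "A|C|G|T"], 1)
        }
        w$normalizedRatio <- NA_real_
        out[[chr]] <- w
    }
    if (!length(out))
        stop("no windows passed the covered-bases filter")
    gr <- sort(do.call(c, unname(out)))
    S4Vectors::metadata(gr)$droppedWindows <- dropped
    WindowTrack(gr)
}

#' Normalize a depth track against an autosomal baseline
#'
#' Divides each window's mean depth by the median window depth pooled over
#' the autosomal tracks, yielding a ratio near 1 on diploid sequence and
#' near 0.5 on female hemizygous (DR) sequence. With `gcCorrect = TRUE`
#' each window is instead divided by the median autosomal depth of its GC
#' bin (2% bins, pooled over autosomes), which removes a linear or
#' nonlinear GC-depth trend before boundary detection; bins with no
#' autosomal windows fall back to the global median.
#'
#' @param zTrack [WindowTrack] to normalize (typically the Z chromosome).
#' @param autosomeTracks a `WindowTrack` or list of them providing the
#'   baseline.
#' @param gcCorrect logical, apply GC-binned correction (requires
#'   `gcFraction` on both tracks).
#' @param gcBinWidth GC bin width (default 0.02).
#' @return The input `WindowTrack` with `normalizedRatio` filled in.
#' @export
normalizeDepth <- function(zTrack, autosomeTracks, gcCorrect = FALSE,
                           gcBinWidth = 0.02) {
    stopifnot(is(zTrack, "WindowTrack"))
    if (is(autosomeTracks, "WindowTrack"))
        autosomeTracks <- list(autosomeTracks)
    if (!length(autosomeTracks))
        stop("autosomeTracks must be non-empty")
    aDepth <- unlist(lapply(autosomeTracks,
                            function(t) trackWindows(t)$meanDepth))
    aGC <- unlist(lapply(autosomeTracks,
                         function(t) trackWindows(t)$gcFraction))
    baseline <- median(aDepth)
    if (!is.finite(baseline) || baseline <= 0)
        stop("autosomal median depth is zero; cannot normalize")
    w <- trackWindows(zTrack)
    if (gcCorrect) {
        if (any(is.na(w$gcFraction)) || any(is.na(aGC)))
            stop("gcCorrect requires gcFraction on all windows")
        bin <- function(g) floor(g / gcBinWidth)
        aBin <- bin(aGC)
        binMed <- tapply(aDepth, aBin, median)
        zBin <- as.character(bin(w$gcFraction))
        denom <- as.numeric(binMed[zBin])
        denom[is.na(denom)] <- baseline
        w$normalizedRatio <- w$meanDepth / denom
    } else {
        w$normalizedRatio <- w$meanDepth / baseline
    }
    new("WindowTrack", windows = w)
}
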