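## Least-squares two-segment changepoint: the operational form of the
## "position where the half-coverage pattern starts to appear" rule.

## exhaustive scan over all breakpoints k (segments 1..k, k+1..n),
## minimizing the summed within-segment squared error; O(n) via cumsums
.twoSegmentSplit <- function(x) {
    n <- length(x)
    stopifnot(n >= 2)
    s1 <- cumsum(x)
    s2 <- cumsum(x^2)
    k <- seq_len(n - 1)
    sseL <- s2[k] - s1[k]^2 / k
    sseR <- (s2[n] - s2[k]) - (s1[n] - s1[k])^2 / (n - k)
    sse <- sseL + sseR
    kBest <- which.min(sse)
    list(k = kBest,
         meanLeft = s1[kBest] / kBest,
         meanRight = (s1[n] - s1[kBest]) / (n - kBest),
         sse = sse[kBest])
}

.regionAnnotation <- function(chromosome, chromLength, boundary, drLeft,
                              method, drMeanRatio = NA_real_,
                              support = integer(), flags = character(),
                              noDR = FALSE, metadata = list()) {
    if (noDR || is.na(boundary)) {
        par <- IRanges::IRanges(1, chromLength)
        dr <- IRanges::IRanges()
        boundary <- NA_real_
        noDR <- TRUE
    } else if (drLeft) {
        dr <- IRanges::IRanges(1, boundary - 1)
        par <- IRanges::IRanges(boundary, chromLength)
    } else {
        par <- IRanges::IRanges(1, boundary - 1)
        dr <- IRanges::IRanges(boundary, chromLength)
    }
    new("RegionAnnotation", chromosome = chromosome,
        chromLength = chromLength, boundary = boundary,
        parInterval = par, drInterval = dr, method = method,
        drMeanRatio = drMeanRatio, support = support, flags = flags,
        noDR = noDR, metadata = metadata)
}

#' Infer the PAR/DR boundary from normalized female depth
#'
#' Runs an exhaustive two-segment least-squares changepoint scan on the
#' normalized depth ratios of a female track. The segment whose mean is
#' closer to 0.5 is the DR candidate; it is accepted only when its mean
#' falls inside `drBand` and it spans at least `minRun` windows, otherwise
#' the annotation reports "no DR". The boundary is the start coordinate of
#' the first window of the right-hand segment, i.e. the first base of the
#' DR when the PAR lies at the chromosome start (the reported position is
#' resolved to window resolution; the window width is its uncertainty).
#'
#' @param track a [WindowTrack] with `normalizedRatio` set (see
#'   [normalizeDepth()]).
#' @param drBand,parBand acceptance bands for the DR and PAR segment means
#'   (defaults `[0.35, 0.65]` and `[0.8, 1.2]`); a PAR segment outside its
#'   band only raises a flag.
#' @param minRun minimum DR run length in windows.
#' @return A [RegionAnnotation] with method `"coverage"`.
#' @examples
#' p <- SimParams(seed = 1, zLength = 20e6, autosomeLengths = c(CHR4 = 20e6),
#'                depthCV = 0)
#' lay <- simulateLayout(p)
#' tr <- simulateCoverage(lay, p, "female")
#' z <- normalizeDepth(tr$Z, tr["CHR4"])
#' inferBoundaryFromCoverage(z)
#' @export
inferBoundaryFromCoverage <- function(track, drBand = c(0.35, 0.65),
                                      parBand = c(0.8, 1.2), minRun = 10) {
    stopifnot(is(track, "WindowTrack"))
    w <- trackWindows(track)
    r <- w$normalizedRatio
    if (any(is.na(r)))
        stop("normalizedRatio must be present on every window; ",
             "run normalizeDepth() first")
    chrom <- as.character(unique(GenomeInfoDb::seqnames(w)))
    if (length(chrom) != 1)
        stop("boundary inference expects a single-chromosome track")
    chromLength <- GenomeInfoDb::seqlengths(w)[chrom]
    if (is.na(chromLength)) chromLength <- max(GenomicRanges::end(w))
    n <- length(r)
    if (n < 2 * minRun)
        stop(sprintf("insufficient data: %d windows; need at least %d",
                     n, 2 * minRun))
    sp <- .twoSegmentSplit(r)
    drLeft <- abs(sp$meanLeft - 0.5) < abs(sp$meanRight - 0.5)
    drMean <- if (drLeft) sp$meanLeft else sp$meanRight
    parMean <- if (drLeft) sp$meanRight else sp$meanLeft
    drRun <- if (drLeft) sp$k else n - sp$k
    meta <- list(k = sp$k, meanLeft = sp$meanLeft,
                 meanRight = sp$meanRight, sse = sp$sse)
    flags <- character()
    if (drMean < drBand[1] || drMean > drBand[2] || drRun < minRun) {
        return(.regionAnnotation(chrom, unname(chromLength), NA_real_,
                                 FALSE, "coverage", noDR = TRUE,
                                 flags = "no-DR", metadata = meta,
                                 support = c(par = as.integer(n), dr = 0L)))
    }
    if (parMean < parBand[1] || parMean > parBand[2])
        flags <- c(flags, "par-out-of-band")
    boundary <- GenomicRanges::start(w)[sp$k + 1]
    .regionAnnotation(chrom, unname(chromLength), boundary, drLeft,
                      "coverage", drMeanRatio = drMean,
                      support = c(par = as.integer(n - drRun),
                                  dr = as.integer(drRun)),
                      flags = flags, metadata = meta)
}

#' Windowed male/female expression ratios along a chromosome
#'
#' Averages per-gene log2 male/female expression ratios in consecutive,
#' non-overlapping windows of `windowGenes` genes ordered by chromosomal
#' position; sliding gene windows damp transcriptional noise and genuine
#' sex-biased expression of individual genes. A trailing partial window is
#' kept when it holds at least half of `windowGenes` genes.
#'
#' @param geneRatios data.frame with columns `gene_id`, `start` (bp) and
#'   `ratio` (linear male/female ratio, > 0), one row per gene.
#' @param windowGenes genes per window (default 20).
#' @return data.frame with one row per window: `window`, `meanLog2`,
#'   `nGenes`, `spanStart`, `spanEnd`, `firstGeneStart`.
#' @export
mfExpressionWindows <- function(geneRatios, windowGenes = 20) {
    if (!NROW(geneRatios))
        stop("geneRatios is empty")
    stopifnot(all(c("start", "ratio") %in% names(geneRatios)),
              windowGenes >= 1)
    if (any(geneRatios$ratio <= 0))
        stop("ratios must be > 0")
    geneRatios <- geneRatios[order(geneRatios$start), , drop = FALSE]
    n <- nrow(geneRatios)
    win <- ceiling(seq_len(n) / windowGenes)
    sizes <- tabulate(win)
    lastWin <- max(win)
    if (sizes[lastWin] < windowGenes / 2 && lastWin > 1) {
        keep <- win < lastWin
        geneRatios <- geneRatios[keep, , drop = FALSE]
        win <- win[keep]
    }
    l2 <- log2(geneRatios$ratio)
    agg <- data.frame(
        window = sort(unique(win)),
        meanLog2 = as.numeric(tapply(l2, win, mean)),
        nGenes = as.integer(tapply(l2, win, length)),
        spanStart = as.numeric(tapply(geneRatios$start, win, min)),
        spanEnd = as.numeric(tapply(geneRatios$start, win, max)),
        firstGeneStart = as.numeric(tapply(geneRatios$start, win,
                                           function(s) s[1])))
    rownames(agg) <- NULL
    agg
}

#' Infer the PAR/DR boundary from windowed expression ratios
#'
#' Applies the same two-segment least-squares scan as the coverage method
#' to windowed log2 male/female ratios (see [mfExpressionWindows()]). In
#' the absence of global dosage compensation DR genes are expressed higher
#' in males, so the higher segment is the DR candidate; it is accepted
#' only when its mean log2 ratio is at least `drMinLog2`. The boundary is
#' the start position of the first gene of the right-hand segment's first
#' window.
#'
#' @param windowRatios data.frame from [mfExpressionWindows()].
#' @param drMinLog2 minimum DR-segment mean log2 ratio (default 0.2).
#' @param chromosome chromosome name recorded in the annotation.
#' @param chromLength chromosome length; defaults to the last window's
#'   span end.
#' @return A [RegionAnnotation] with method `"expression"`.
#' @export
inferBoundaryFromExpression <- function(windowRatios, drMinLog2 = 0.2,
                                        chromosome = "Z",
                                        chromLength = NA_real_) {
    n <- nrow(windowRatios)
    if (is.null(n) || n < 4)
        stop("insufficient data: need at least 4 expression windows")
    if (is.na(chromLength))
        chromLength <- max(windowRatios$spanEnd)
    x <- windowRatios$meanLog2
    sp <- .twoSegmentSplit(x)
    drLeft <- sp$meanLeft > sp$meanRight
    drMean <- max(sp$meanLeft, sp$meanRight)
    drRun <- if (drLeft) sp$k else n - sp$k
    meta <- list(k = sp$k, meanLeft = sp$meanLeft,
                 meanRight = sp$meanRight, sse = sp$sse)
    if (drMean < drMinLog2) {
        return(.regionAnnotation(chromosome, chromLength, NA_real_, FALSE,
                                 "expression", noDR = TRUE, flags = "no-DR",
                                 metadata = meta,
                                 support = c(par = as.integer(n), dr = 0L)))
    }
    boundary <- windowRatios$firstGeneStart[sp$k + 1]
    .regionAnnotation(chromosome, chromLength, boundary, drLeft,
                      "expression",
                      support = c(par = as.integer(n - drRun),
                                  dr = as.integer(drRun)),
                      metadata = meta)
}
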