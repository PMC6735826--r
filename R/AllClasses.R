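#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom IRanges IRanges
#' @importFrom stats median rnorm rlnorm rpois rbinom rnbinom rbeta rgamma
#'   runif quantile var sd p.adjust pt pnorm wilcox.test fisher.test cor.test
#'   setNames complete.cases lm coef
#' @importFrom utils read.delim write.table head tail
NULL

## Region classes used throughout. PAR/DR partition the Z; CHR4/CHR5 are the
## size-matched autosomal references; AUTOSOME_MACRO pools the remaining
## macrochromosomes when present.
REGION_CLASSES <- c("PAR", "DR", "CHR4", "CHR5", "AUTOSOME_MACRO", "OTHER")

#' Simulation parameters for the synthetic-data generator
#'
#' Container for every knob of the generator: chromosome sizes, PAR fraction,
#' read-depth model, divergence model, expression model, variant rates, and
#' feature densities. Defaults encode the study conditions the package is
#' designed around: a 75 Mb Z with the PAR/DR boundary at 40 Mb, autosomal
#' references of 97 Mb (chr4) and 63 Mb (chr5), 30x female depth with CV
#' 0.08 and half depth in the DR, equal dN/dS across classes (no faster-Z),
#' and incomplete dosage compensation with a DR male/female ratio of 1.4.
#'
#' @slot seed integer master seed; identical parameters (including seed)
#'   give bit-identical simulated data.
#' @slot zLength,parFraction Z chromosome length (bp) and the fraction of it
#'   occupied by the PAR (boundary at `parFraction * zLength`).
#' @slot autosomeLengths named numeric, autosome name -> length in bp.
#' @slot windowSize depth/feature window width in bp.
#' @slot depthMean,depthCV mean read depth and lognormal coefficient of
#'   variation of per-window depth.
#' @slot gcDepthSlope linear depth trend per unit (GC - 0.5); 0 disables.
#' @slot gcMean,gcSD per-window GC fraction distribution.
#' @slot omegaByClass named numeric, true dN/dS per region class.
#' @slot dsMean,dsShape mean per-gene dS and gamma shape of its
#'   gene-to-gene variation.
#' @slot genesPerMb expected gene density.
#' @slot exonRange integer length-2, uniform range of exon count per gene.
#' @slot exonMeanlog,exonSdlog lognormal exon length parameters.
#' @slot intronMeanlogByClass,intronSdlog class-specific lognormal intron
#'   sizes (the intron-size contrast is a simulated signal).
#' @slot teDensityByClass,teMeanLen class-specific TE densities and mean TE
#'   length (bp).
#' @slot gc3ByClass class-specific expected GC3s used when coding sequences
#'   are generated.
#' @slot dosageRatioDR true male/female expression ratio of DR genes,
#'   in (1, 2].
#' @slot sexbiasFraction,sexbiasFold fraction of PAR/autosomal genes with
#'   genuine sex-biased expression and their fold change.
#' @slot nbDispersion negative-binomial dispersion of counts; 0 selects a
#'   noise-free diagnostic mode in which counts equal their expectations.
#' @slot exprMeanlog,exprSdlog lognormal baseline expression level.
#' @slot libSizeCV lognormal spread of per-sample library-size factors;
#'   0 means exactly equal libraries.
#' @slot hetRatePar female heterozygous-SNP rate per bp in PAR/autosomes.
#' @slot drLeakRate spurious heterozygous-SNP rate per bp in the DR
#'   (emulates W-derived read mismapping); 0 for a clean DR.
#'
#' @seealso [simulateLayout()], [simulateCoverage()], [simulateDivergence()],
#'   [simulateExpression()], [simulateVariants()]
#' @export
setClass("SimParams", representation(
    seed = "integer",
    zLength = "numeric",
    parFraction = "numeric",
    autosomeLengths = "numeric",
    windowSize = "numeric",
    depthMean = "numeric",
    depthCV = "numeric",
    gcDepthSlope = "numeric",
    gcMean = "numeric",
    gcSD = "numeric",
    omegaByClass = "numeric",
    dsMean = "numeric",
    dsShape = "numeric",
    genesPerMb = "numeric",
    exonRange = "integer",
    exonMeanlog = "numeric",
    exonSdlog = "numeric",
    intronMeanlogByClass = "numeric",
    intronSdlog = "numeric",
    teDensityByClass = "numeric",
    teMeanLen = "numeric",
    gc3ByClass = "numeric",
    dosageRatioDR = "numeric",
    sexbiasFraction = "numeric",
    sexbiasFold = "numeric",
    nbDispersion = "numeric",
    exprMeanlog = "numeric",
    exprSdlog = "numeric",
    libSizeCV = "numeric",
    hetRatePar = "numeric",
    drLeakRate = "numeric"
))

setValidity("SimParams", function(object) {
    msg <- character()
    if (length(object@parFraction) != 1 || object@parFraction <= 0 ||
        object@parFraction >= 1)
        msg <- c(msg, "parFraction must lie strictly in (0, 1)")
    if (object@zLength <= 0 || any(object@autosomeLengths <= 0))
        msg <- c(msg, "all chromosome lengths must be > 0")
    if (is.null(names(object@autosomeLengths)) ||
        any(!nzchar(names(object@autosomeLengths))))
        msg <- c(msg, "autosomeLengths must be named")
    if (object@windowSize <= 0)
        msg <- c(msg, "windowSize must be > 0")
    if (object@dosageRatioDR <= 1 || object@dosageRatioDR > 2)
        msg <- c(msg, "dosageRatioDR must lie in (1, 2]")
    if (object@nbDispersion < 0)
        msg <- c(msg, "nbDispersion must be >= 0")
    if (object@depthCV < 0 || object@depthMean <= 0)
        msg <- c(msg, "depthMean must be > 0 and depthCV >= 0")
    if (any(object@omegaByClass < 0))
        msg <- c(msg, "omegaByClass values must be >= 0")
    if (object@hetRatePar < 0 || object@drLeakRate < 0)
        msg <- c(msg, "variant rates must be >= 0")
    if (object@sexbiasFraction < 0 || object@sexbiasFraction > 1)
        msg <- c(msg, "sexbiasFraction must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimParams-class Constructor; any slot can be overridden by
#'   name, all others keep their defaults.
#' @param seed integer master seed.
#' @param ... named slot overrides (see slots above).
#' @return A validated `SimParams` object.
#' @examples
#' p <- SimParams(seed = 1, zLength = 10e6, parFraction = 0.5)
#' trueBoundary(simulateLayout(p))
#' @export
SimParams <- function(seed = 1L, ...) {
    defaults <- list(
        seed = as.integer(seed),
        zLength = 75e6,
        parFraction = 8 / 15,      # boundary at 40 Mb on a 75 Mb Z
        autosomeLengths = c(CHR4 = 97e6, CHR5 = 63e6),
        windowSize = 5e4,
        depthMean = 30,
        depthCV = 0.08,
        gcDepthSlope = 0,
        gcMean = 0.42,
        gcSD = 0.04,
        omegaByClass = c(PAR = 0.15, DR = 0.15, CHR4 = 0.15, CHR5 = 0.15),
        dsMean = 0.1,
        dsShape = 4,
        genesPerMb = 10,
        exonRange = c(2L, 12L),
        exonMeanlog = log(200),
        exonSdlog = 0.5,
        intronMeanlogByClass = c(PAR = log(1950), DR = log(1950),
                                 CHR4 = log(1500), CHR5 = log(1400)),
        intronSdlog = 0.6,
        teDensityByClass = c(PAR = 0.13, DR = 0.14, CHR4 = 0.10,
                             CHR5 = 0.08),
        teMeanLen = 800,
        gc3ByClass = c(PAR = 0.45, DR = 0.47, CHR4 = 0.52, CHR5 = 0.56),
        dosageRatioDR = 1.4,
        sexbiasFraction = 0,
        sexbiasFold = 4,
        nbDispersion = 0.05,
        exprMeanlog = log(100),
        exprSdlog = 1,
        libSizeCV = 0.05,
        hetRatePar = 1e-4,
        drLeakRate = 0
    )
    override <- list(...)
    bad <- setdiff(names(override), names(defaults))
    if (length(bad))
        stop("unknown SimParams field(s): ", paste(bad, collapse = ", "))
    defaults[names(override)] <- override
    defaults$seed <- as.integer(defaults$seed)
    defaults$exonRange <- as.integer(defaults$exonRange)
    do.call(new, c(list("SimParams"), defaults))
}

setMethod("show", "SimParams", function(object) {
    cat("SimParams\n")
    cat("  seed:", object@seed, "\n")
    cat(sprintf("  Z: %.1f Mb, PAR fraction %.3f (boundary %.2f Mb)\n",
                object@zLength / 1e6, object@parFraction,
                object@zLength * object@parFraction / 1e6))
    cat("  autosomes:",
        paste(sprintf("%s=%.0f Mb", names(object@autosomeLengths),
                      object@autosomeLengths / 1e6), collapse = ", "), "\n")
    cat(sprintf("  depth %g (CV %g), window %g kb, genes/Mb %g\n",
                object@depthMean, object@depthCV, object@windowSize / 1e3,
                object@genesPerMb))
    cat("  omega:",
        paste(sprintf("%s=%.3g", names(object@omegaByClass),
                      object@omegaByClass), collapse = ", "), "\n")
    cat(sprintf("  dosage ratio (DR) %g, NB dispersion %g\n",
                object@dosageRatioDR, object@nbDispersion))
    invisible(NULL)
})

#' Simulated genome layout
#'
#' Chromosome set with region-class intervals, gene models (gene and exon
#' ranges), TE intervals, and the true PAR/DR boundary on Z. Produced by
#' [simulateLayout()]; consumed by every other simulator.
#'
#' @slot regions [GenomicRanges::GRanges] partitioning each chromosome, with
#'   metadata column `regionClass`.
#' @slot genes `GRanges` of gene spans with `gene_id`, `regionClass`,
#'   `nExons`, `cdsLength`.
#' @slot exons `GRanges` of exons with `gene_id` and `exon_rank`.
#' @slot tes `GRanges` of transposable-element intervals with `regionClass`.
#' @slot trueBoundary numeric, bp position of the PAR/DR transition on Z
#'   (first base of the DR, 1-based).
#' @slot params the [SimParams] that generated the layout.
#' @export
setClass("GenomeLayout", representation(
    regions = "GRanges",
    genes = "GRanges",
    exons = "GRanges",
    tes = "GRanges",
    trueBoundary = "numeric",
    params = "SimParams"
))

setValidity("GenomeLayout", function(object) {
    msg <- character()
    if (!"regionClass" %in% names(S4Vectors::mcols(object@regions)))
        msg <- c(msg, "regions must carry a regionClass column")
    ## region intervals must partition each chromosome exactly
    sl <- GenomeInfoDb::seqlengths(object@regions)
    for (chr in GenomeInfoDb::seqlevels(object@regions)) {
        r <- object@regions[GenomeInfoDb::seqnames(object@regions) == chr]
        r <- sort(r)
        if (length(r) == 0) next
        if (GenomicRanges::start(r)[1] != 1 ||
            GenomicRanges::end(r)[length(r)] != sl[[chr]] ||
            (length(r) > 1 &&
             any(GenomicRanges::start(r)[-1] !=
                 GenomicRanges::end(r)[-length(r)] + 1)))
            msg <- c(msg, sprintf("region intervals do not partition %s", chr))
    }
    if (!is.na(object@trueBoundary) &&
        (object@trueBoundary <= 1 || object@trueBoundary >= object@params@zLength))
        msg <- c(msg, "trueBoundary must lie inside the Z chromosome")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GenomeLayout", function(object) {
    cat("GenomeLayout\n")
    sl <- GenomeInfoDb::seqlengths(object@regions)
    cat("  chromosomes:",
        paste(sprintf("%s (%.1f Mb)", names(sl), sl / 1e6), collapse = ", "),
        "\n")
    cat(sprintf("  true PAR/DR boundary: %.2f Mb\n",
                object@trueBoundary / 1e6))
    cat(sprintf("  %d genes, %d exons, %d TE intervals\n",
                length(object@genes), length(object@exons),
                length(object@tes)))
    invisible(NULL)
})

#' Windowed depth track
#'
#' Fixed-width genomic windows carrying mean read depth, covered-base
#' counts, GC fraction, and (after [normalizeDepth()]) the depth ratio
#' relative to the autosomal baseline.
#'
#' @slot windows sorted, non-overlapping [GenomicRanges::GRanges] with
#'   metadata columns `meanDepth`, `coveredBases`, `gcFraction` and
#'   `normalizedRatio` (NA until normalized).
#' @export
setClass("WindowTrack", representation(windows = "GRanges"))

setValidity("WindowTrack", function(object) {
    w <- object@windows
    msg <- character()
    need <- c("meanDepth", "coveredBases", "gcFraction", "normalizedRatio")
    if (!all(need %in% names(S4Vectors::mcols(w))))
        return(paste("windows must carry columns:",
                     paste(need, collapse = ", ")))
    if (length(w) > 1 && S4Vectors::isSorted(w) == FALSE)
        msg <- c(msg, "windows must be sorted")
    if (length(w) > 1) {
        ov <- GenomicRanges::countOverlaps(w, w)
        if (any(ov > 1)) msg <- c(msg, "windows must not overlap")
    }
    if (any(w$coveredBases > GenomicRanges::width(w)))
        msg <- c(msg, "coveredBases cannot exceed window width")
    r <- w$normalizedRatio
    if (any(!is.na(r) & r <= 0))
        msg <- c(msg, "normalizedRatio must be > 0 where present")
    if (length(msg)) msg else TRUE
})

#' Construct a WindowTrack from a GRanges of windows
#'
#' @param windows `GRanges` with at least a `meanDepth` column; missing
#'   `coveredBases` defaults to the full window width, missing `gcFraction`
#'   and `normalizedRatio` default to NA.
#' @return A `WindowTrack`.
#' @export
WindowTrack <- function(windows) {
    mc <- S4Vectors::mcols(windows)
    if (!"meanDepth" %in% names(mc))
        stop("windows must carry a meanDepth column")
    if (!"coveredBases" %in% names(mc))
        windows$coveredBases <- GenomicRanges::width(windows)
    if (!"gcFraction" %in% names(mc))
        windows$gcFraction <- NA_real_
    if (!"normalizedRatio" %in% names(mc))
        windows$normalizedRatio <- NA_real_
    new("WindowTrack", windows = sort(windows))
}

setMethod("show", "WindowTrack", function(object) {
    w <- object@windows
    cat(sprintf("WindowTrack: %d windows on %s\n", length(w),
                paste(GenomeInfoDb::seqlevels(w), collapse = ", ")))
    if (length(w)) {
        cat(sprintf("  mean depth: %.2f", mean(w$meanDepth)))
        if (any(!is.na(w$normalizedRatio)))
            cat(sprintf("; mean normalized ratio: %.3f",
                        mean(w$normalizedRatio, na.rm = TRUE)))
        cat("\n")
    }
    invisible(NULL)
})

#' @rdname WindowTrack-class
#' @param x a `WindowTrack`.
#' @return `trackWindows()` returns the underlying `GRanges`.
#' @export
trackWindows <- function(x) {
    stopifnot(is(x, "WindowTrack"))
    x@windows
}

setMethod("length", "WindowTrack", function(x) length(x@windows))

#' PAR/DR region annotation of one chromosome
#'
#' The inferred PAR/DR boundary of a (Z) chromosome together with the two
#' region intervals, the inference method, segment support and consistency
#' flags. When no differentiated region is detected the boundary is NA,
#' `noDR` is TRUE and the PAR interval covers the chromosome.
#'
#' @slot chromosome chromosome name.
#' @slot chromLength chromosome length in bp.
#' @slot boundary bp position of the first DR base (NA if no DR).
#' @slot parInterval,drInterval [IRanges::IRanges] (empty when absent).
#' @slot method one of `"coverage"`, `"expression"`, `"snp"`, `"projected"`.
#' @slot drMeanRatio mean normalized depth ratio of the DR segment
#'   (coverage method only, NA otherwise).
#' @slot support named integer, windows per segment.
#' @slot flags character vector of consistency warnings.
#' @slot noDR logical, TRUE when no differentiated region was accepted.
#' @slot metadata list of method-specific details (segment means, SNP
#'   density medians, ...).
#' @export
setClass("RegionAnnotation", representation(
    chromosome = "character",
    chromLength = "numeric",
    boundary = "numeric",
    parInterval = "IRanges",
    drInterval = "IRanges",
    method = "character",
    drMeanRatio = "numeric",
    support = "integer",
    flags = "character",
    noDR = "logical",
    metadata = "list"
))

setValidity("RegionAnnotation", function(object) {
    msg <- character()
    if (!object@method %in% c("coverage", "expression", "snp", "projected"))
        msg <- c(msg, "unknown annotation method")
    tot <- sum(IRanges::width(object@parInterval)) +
        sum(IRanges::width(object@drInterval))
    if (tot != object@chromLength)
        msg <- c(msg, "PAR and DR intervals must cover the chromosome")
    if (length(object@parInterval) && length(object@drInterval)) {
        ov <- IRanges::countOverlaps(object@parInterval, object@drInterval)
        if (any(ov > 0)) msg <- c(msg, "PAR and DR intervals overlap")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "RegionAnnotation", function(object) {
    cat(sprintf("RegionAnnotation (%s) for %s [%.2f Mb]\n", object@method,
                object@chromosome, object@chromLength / 1e6))
    if (object@noDR) {
        cat("  no DR detected\n")
    } else {
        cat(sprintf("  boundary: %s bp\n",
                    format(object@boundary, big.mark = ",")))
        cat(sprintf("  PAR: %.2f Mb, DR: %.2f Mb\n",
                    sum(IRanges::width(object@parInterval)) / 1e6,
                    sum(IRanges::width(object@drInterval)) / 1e6))
        if (!is.na(object@drMeanRatio))
            cat(sprintf("  DR mean depth ratio: %.3f\n", object@drMeanRatio))
    }
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
    invisible(NULL)
})

#' @rdname RegionAnnotation-class
#' @param x a `RegionAnnotation`.
#' @return `boundaryPosition()` the boundary bp (NA if no DR);
#'   `parInterval()`/`drInterval()` the region `IRanges`;
#'   `annotationFlags()` the flag vector.
#' @export
boundaryPosition <- function(x) {
    stopifnot(is(x, "RegionAnnotation"))
    x@boundary
}

#' @rdname RegionAnnotation-class
#' @export
parInterval <- function(x) {
    stopifnot(is(x, "RegionAnnotation"))
    x@parInterval
}

#' @rdname RegionAnnotation-class
#' @export
drInterval <- function(x) {
    stopifnot(is(x, "RegionAnnotation"))
    x@drInterval
}

#' @rdname RegionAnnotation-class
#' @export
annotationFlags <- function(x) {
    stopifnot(is(x, "RegionAnnotation"))
    x@flags
}

#' @rdname GenomeLayout-class
#' @param x a `GenomeLayout`.
#' @return `trueBoundary()` the simulated boundary bp; `layoutRegions()`,
#'   `layoutGenes()`, `layoutExons()`, `layoutTEs()` the component `GRanges`.
#' @export
trueBoundary <- function(x) {
    stopifnot(is(x, "GenomeLayout"))
    x@trueBoundary
}

#' @rdname GenomeLayout-class
#' @export
layoutRegions <- function(x) {
    stopifnot(is(x, "GenomeLayout"))
    x@regions
}

#' @rdname GenomeLayout-class
#' @export
layoutGenes <- function(x) {
    stopifnot(is(x, "GenomeLayout"))
    x@genes
}

#' @rdname GenomeLayout-class
#' @export
layoutExons <- function(x) {
    stopifnot(is(x, "GenomeLayout"))
    x@exons
}

#' @rdname GenomeLayout-class
#' @export
layoutTEs <- function(x) {
    stopifnot(is(x, "GenomeLayout"))
    x@tes
}

## internal: region class of positions on a chromosome of a layout
.regionClassAt <- function(layout, chrom, pos) {
    r <- layout@regions[as.character(
        GenomeInfoDb::seqnames(layout@regions)) == chrom]
    hit <- GenomicRanges::findOverlaps(
        GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1),
                               seqinfo = GenomeInfoDb::seqinfo(layout@regions)),
        r, select = "first")
    as.character(r$regionClass[hit])
}
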