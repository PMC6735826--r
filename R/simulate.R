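## Synthetic-data generator: genome layout, depth tracks, female variants.
## Every simulator derives its own stream from params@seed plus a fixed
## stage offset, so the same SimParams give bit-identical output no matter
## which simulators are called, or in which order.

.STAGE_SEED <- c(layout = 101L, coverage_female = 211L, coverage_male = 223L,
                 divergence = 307L, expression = 401L, variants = 503L,
                 cds = 601L)

## evaluate code under a temporary seed, restoring the caller's RNG state
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    code
}

.stageSeed <- function(params, stage) {
    params@seed * 1000L + .STAGE_SEED[[stage]]
}

.simSeqinfo <- function(params) {
    lens <- c(Z = params@zLength, params@autosomeLengths)
    GenomeInfoDb::Seqinfo(seqnames = names(lens), seqlengths = lens)
}

## cumulative sum restarting at each group (groups given by run lengths)
.groupCumsum <- function(v, runs) {
    cs <- cumsum(v)
    first <- cumsum(c(1L, runs[-length(runs)]))
    base <- rep(cs[first] - v[first], runs)
    cs - base
}

#' Simulate a genome layout with region classes, genes and TEs
#'
#' Partitions the Z chromosome into a single PAR block followed by a DR
#' block at `parFraction * zLength`, labels each autosome with its own
#' region class, places multi-exon genes uniformly at the configured
#' density (intron sizes drawn from a class-specific lognormal), and places
#' TE intervals at class-specific densities.
#'
#' @param params a [SimParams] object.
#' @return A [GenomeLayout].
#' @examples
#' layout <- simulateLayout(SimParams(seed = 1, zLength = 10e6,
#'                                    autosomeLengths = c(CHR4 = 10e6)))
#' layout
#' @export
simulateLayout <- function(params) {
    stopifnot(is(params, "SimParams"))
    validObject(params)
    si <- .simSeqinfo(params)
    parLen <- round(params@parFraction * params@zLength)
    boundary <- parLen + 1   # first DR base, 1-based

    regions <- c(
        GenomicRanges::GRanges("Z", IRanges::IRanges(1, parLen),
                               regionClass = "PAR", seqinfo = si),
        GenomicRanges::GRanges("Z",
                               IRanges::IRanges(boundary, params@zLength),
                               regionClass = "DR", seqinfo = si))
    for (chr in names(params@autosomeLengths)) {
        cls <- if (chr %in% REGION_CLASSES) chr else "AUTOSOME_MACRO"
        regions <- c(regions, GenomicRanges::GRanges(
            chr, IRanges::IRanges(1, params@autosomeLengths[[chr]]),
            regionClass = cls, seqinfo = si))
    }
    regions <- sort(regions)

    .withSeed(.stageSeed(params, "layout"), {
        genes <- .placeGenes(params, si, regions)
        tes <- .placeTEs(params, si, regions)
        new("GenomeLayout", regions = regions, genes = genes$genes,
            exons = genes$exons, tes = tes, trueBoundary = boundary,
            params = params)
    })
}

.classOfPosition <- function(regions, chrom, pos) {
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1),
                                seqinfo = GenomeInfoDb::seqinfo(regions))
    hit <- GenomicRanges::findOverlaps(q, regions, select = "first")
    as.character(regions$regionClass[hit])
}

.placeGenes <- function(params, si, regions) {
    lens <- GenomeInfoDb::seqlengths(si)
    geneRows <- list()
    exonRows <- list()
    for (chr in names(lens)) {
        n <- rpois(1, params@genesPerMb * lens[[chr]] / 1e6)
        if (n == 0) next
        start0 <- floor(runif(n, 1, lens[[chr]]))
        cls <- .classOfPosition(regions, chr, start0)
        nEx <- sample(seq(params@exonRange[1], params@exonRange[2]),
                      n, replace = TRUE)
        idx <- rep(seq_len(n), nEx)
        rank <- sequence(nEx)
        exLen <- pmax(30, round(rlnorm(length(idx), params@exonMeanlog,
                                       params@exonSdlog)))
        iml <- params@intronMeanlogByClass
        gml <- iml[cls]
        gml[is.na(gml)] <- mean(iml)
        inLen <- pmax(30, round(rlnorm(length(idx), gml[idx],
                                       params@intronSdlog)))
        inLen[rank == 1] <- 0
        prevEx <- .groupCumsum(exLen, nEx) - exLen
        cumIn <- .groupCumsum(inLen, nEx)
        exOffset <- prevEx + cumIn
        lastIdx <- cumsum(nEx)
        totLen <- (exOffset + exLen)[lastIdx]
        gStart <- pmax(1, pmin(start0, lens[[chr]] - totLen + 1))
        cls <- .classOfPosition(regions, chr, gStart)
        id <- sprintf("g%s_%05d", chr, rank(gStart, ties.method = "first"))
        cdsLen <- .groupCumsum(exLen, nEx)[lastIdx]
        cdsLen <- cdsLen - cdsLen %% 3
        geneRows[[chr]] <- data.frame(
            chrom = chr, start = gStart, end = gStart + totLen - 1,
            gene_id = id, regionClass = cls, nExons = nEx,
            cdsLength = cdsLen, splicedLength = .groupCumsum(exLen, nEx)[lastIdx],
            stringsAsFactors = FALSE)
        exonRows[[chr]] <- data.frame(
            chrom = chr, start = gStart[idx] + exOffset,
            end = gStart[idx] + exOffset + exLen - 1,
            gene_id = id[idx], exon_rank = rank, stringsAsFactors = FALSE)
    }
    if (!length(geneRows)) {
        empty <- GenomicRanges::GRanges(seqinfo = si)
        empty$gene_id <- character(0)
        empty$regionClass <- character(0)
        exEmpty <- GenomicRanges::GRanges(seqinfo = si)
        exEmpty$gene_id <- character(0)
        exEmpty$exon_rank <- integer(0)
        empty$nExons <- integer(0)
        empty$cdsLength <- numeric(0)
        empty$splicedLength <- numeric(0)
        return(list(genes = empty, exons = exEmpty))
    }
    gdf <- do.call(rbind, geneRows)
    edf <- do.call(rbind, exonRows)
    genes <- GenomicRanges::GRanges(gdf$chrom,
                                    IRanges::IRanges(gdf$start, gdf$end),
                                    strand = "+", seqinfo = si)
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
        gene_id = gdf$gene_id, regionClass = gdf$regionClass,
        nExons = gdf$nExons, cdsLength = gdf$cdsLength,
        splicedLength = gdf$splicedLength)
    exons <- GenomicRanges::GRanges(edf$chrom,
                                    IRanges::IRanges(edf$start, edf$end),
                                    strand = "+", seqinfo = si)
    S4Vectors::mcols(exons) <- S4Vectors::DataFrame(
        gene_id = edf$gene_id, exon_rank = edf$exon_rank)
    list(genes = sort(genes), exons = sort(exons))
}

.placeTEs <- function(params, si, regions) {
    out <- list()
    sdlog <- 0.6
    for (i in seq_along(regions)) {
        r <- regions[i]
        cls <- as.character(r$regionClass)
        dens <- params@teDensityByClass[cls]
        if (is.na(dens) || dens <= 0) next
        w <- GenomicRanges::width(r)
        n <- rpois(1, dens * w / params@teMeanLen)
        if (n == 0) next
        len <- pmax(50, round(rlnorm(n, log(params@teMeanLen) - sdlog^2 / 2,
                                     sdlog)))
        st <- floor(runif(n, GenomicRanges::start(r),
                          GenomicRanges::end(r) - len + 1))
        st <- pmax(st, GenomicRanges::start(r))
        en <- pmin(st + len - 1, GenomicRanges::end(r))
        gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(r),
                                     IRanges::IRanges(st, en), seqinfo = si)
        gr$regionClass <- cls
        out[[length(out) + 1]] <- gr
    }
    if (!length(out))
        return(GenomicRanges::GRanges(seqinfo = si))
    sort(do.call(c, out))
}

#' Simulate windowed read-depth tracks
#'
#' Female DR windows have expected depth `depthMean / 2`; every other
#' window (and every male window) has expected depth `depthMean`. Windows
#' straddling the PAR/DR boundary get the length-weighted mixture. Noise is
#' multiplicative lognormal with the configured CV; an optional linear GC
#' trend (slope per unit GC - 0.5) can be superimposed.
#'
#' @param layout a [GenomeLayout].
#' @param params the [SimParams] used for the layout.
#' @param sex `"female"` or `"male"`.
#' @return Named list of [WindowTrack] objects, one per chromosome.
#' @examples
#' p <- SimParams(seed = 1, zLength = 5e6, autosomeLengths = c(CHR4 = 5e6),
#'                depthCV = 0)
#' tr <- simulateCoverage(simulateLayout(p), p, "female")
#' range(trackWindows(tr$Z)$meanDepth)
#' @export
simulateCoverage <- function(layout, params, sex = c("female", "male")) {
    sex <- match.arg(sex)
    stopifnot(is(layout, "GenomeLayout"))
    stage <- if (sex == "female") "coverage_female" else "coverage_male"
    si <- GenomeInfoDb::seqinfo(layout@regions)
    dr <- layout@regions[layout@regions$regionClass == "DR"]
    .withSeed(.stageSeed(params, stage), {
        out <- list()
        for (chr in GenomeInfoDb::seqlevels(si)) {
            len <- GenomeInfoDb::seqlengths(si)[[chr]]
            starts <- seq(1, len, by = params@windowSize)
            ends <- pmin(starts + params@windowSize - 1, len)
            w <- GenomicRanges::GRanges(chr, IRanges::IRanges(starts, ends),
                                        seqinfo = si)
            gc <- pmin(0.65, pmax(0.25, rnorm(length(w), params@gcMean,
                                              params@gcSD)))
            expected <- rep(params@depthMean, length(w))
            if (sex == "female" && length(dr)) {
                ovBp <- GenomicRanges::width(w) * 0
                hits <- GenomicRanges::findOverlaps(w, dr)
                if (length(hits)) {
                    pi <- GenomicRanges::pintersect(
                        w[S4Vectors::queryHits(hits)],
                        dr[S4Vectors::subjectHits(hits)])
                    ovBp[S4Vectors::queryHits(hits)] <-
                        GenomicRanges::width(pi)
                }
                frac <- ovBp / GenomicRanges::width(w)
                expected <- params@depthMean * (1 - 0.5 * frac)
            }
            if (params@gcDepthSlope != 0)
                expected <- expected *
                    (1 + params@gcDepthSlope * (gc - 0.5))
            depth <- expected
            if (params@depthCV > 0) {
                sdlog <- sqrt(log(1 + params@depthCV^2))
                depth <- expected * rlnorm(length(w), -sdlog^2 / 2, sdlog)
            }
            w$meanDepth <- depth
            w$coveredBases <- GenomicRanges::width(w)
            w$gcFraction <- gc
            w$normalizedRatio <- NA_real_
            out[[chr]] <- WindowTrack(w)
        }
        out
    })
}

#' Simulate female heterozygous variant calls
#'
#' Heterozygous sites are placed at `hetRatePar` per bp on PAR and
#' autosomal sequence and at `drLeakRate` per bp on the DR (emulating
#' W-derived read mismapping). Allele frequencies of true heterozygotes are
#' drawn from Beta(8, 8) (mass concentrated inside the 0.2-0.8 band used to
#' call heterozygotes); DR leak variants from the flatter Beta(2, 2).
#'
#' @inheritParams simulateCoverage
#' @return A sorted [GenomicRanges::GRanges] of single-base variants with
#'   metadata column `af` (alternate allele frequency).
#' @export
simulateVariants <- function(layout, params) {
    stopifnot(is(layout, "GenomeLayout"))
    si <- GenomeInfoDb::seqinfo(layout@regions)
    .withSeed(.stageSeed(params, "variants"), {
        out <- list()
        for (i in seq_along(layout@regions)) {
            r <- layout@regions[i]
            isDR <- as.character(r$regionClass) == "DR"
            rate <- if (isDR) params@drLeakRate else params@hetRatePar
            if (rate <= 0) next
            w <- GenomicRanges::width(r)
            n <- rpois(1, rate * w)
            if (n == 0) next
            pos <- sort(floor(runif(n, GenomicRanges::start(r),
                                    GenomicRanges::end(r) + 1)))
            af <- if (isDR) rbeta(n, 2, 2) else rbeta(n, 8, 8)
            af <- pmin(0.99, pmax(0.01, af))
            gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(r),
                                         IRanges::IRanges(pos, width = 1),
                                         seqinfo = si)
            gr$af <- af
            out[[length(out) + 1]] <- gr
        }
        if (!length(out)) {
            empty <- GenomicRanges::GRanges(seqinfo = si)
            empty$af <- numeric(0)
            return(empty)
        }
        sort(do.call(c, out))
    })
}
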