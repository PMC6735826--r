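## Format readers and writers. On-disk conventions follow each format
## (BED/bedGraph 0-based half-open, GFF3/VCF 1-based inclusive);
## rtracklayer and VariantAnnotation perform the conversions, and all
## in-memory coordinates are 1-based closed GRanges.

#' Write / read a windowed depth track as bedGraph
#'
#' @param track a [WindowTrack] (or list of them, concatenated).
#' @param path output path.
#' @return `readBedGraphTrack()` returns a `GRanges` with `score`,
#'   suitable for [computeDepthWindows()].
#' @export
writeBedGraphTrack <- function(track, path) {
    if (is.list(track)) {
        grs <- lapply(track, function(t) {
            w <- trackWindows(t)
            GenomicRanges::GRanges(GenomeInfoDb::seqnames(w),
                                   IRanges::IRanges(GenomicRanges::start(w),
                                                    GenomicRanges::end(w)),
                                   score = w$meanDepth,
                                   seqinfo = GenomeInfoDb::seqinfo(w))
        })
        gr <- sort(do.call(c, unname(grs)))
    } else {
        w <- trackWindows(track)
        gr <- GenomicRanges::granges(w)
        gr$score <- w$meanDepth
    }
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}

#' @rdname writeBedGraphTrack
#' @param seqlengths optional named chromosome lengths to attach.
#' @export
readBedGraphTrack <- function(path, seqlengths = NULL) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (!is.null(seqlengths)) {
        GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
        GenomeInfoDb::seqlengths(gr) <- seqlengths
    }
    sort(gr)
}

#' Write / read region-class intervals as BED
#'
#' The BED name column carries the region class.
#'
#' @param regions `GRanges` with `regionClass` (e.g. [layoutRegions()]).
#' @param path file path.
#' @export
writeRegionsBed <- function(regions, path) {
    gr <- GenomicRanges::granges(regions)
    gr$name <- as.character(regions$regionClass)
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' @rdname writeRegionsBed
#' @export
readRegionsBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    gr$regionClass <- gr$name
    gr$name <- NULL
    sort(gr)
}

#' Write / read TE intervals as BED
#' @param tes,path `GRanges` of TE intervals; file path.
#' @export
writeTeBed <- function(tes, path) {
    rtracklayer::export(GenomicRanges::granges(tes), path, format = "BED")
    invisible(path)
}

#' @rdname writeTeBed
#' @export
readTeBed <- function(path) {
    sort(rtracklayer::import(path, format = "BED"))
}

#' Write / read gene models as GFF3
#'
#' Genes and exons with ID/Parent attributes; coordinates 1-based
#' inclusive on disk per the format.
#'
#' @param layout a [GenomeLayout] (or a list with `genes` and `exons`
#'   `GRanges` carrying `gene_id`).
#' @param path file path.
#' @return `readGenesGff3()` returns `list(genes =, exons =)` with
#'   `gene_id` metadata columns.
#' @export
writeGenesGff3 <- function(layout, path) {
    genes <- if (is(layout, "GenomeLayout")) layoutGenes(layout)
             else layout$genes
    exons <- if (is(layout, "GenomeLayout")) layoutExons(layout)
             else layout$exons
    if (anyDuplicated(genes$gene_id))
        stop("duplicated gene ids")
    g <- GenomicRanges::granges(genes)
    g$type <- "gene"
    g$ID <- genes$gene_id
    g$Parent <- IRanges::CharacterList(vector("list", length(g)))
    e <- GenomicRanges::granges(exons)
    e$type <- "exon"
    e$ID <- sprintf("%s.exon%d", exons$gene_id, exons$exon_rank)
    e$Parent <- IRanges::CharacterList(as.list(exons$gene_id))
    out <- sort(c(g, e))
    rtracklayer::export(out, path, format = "GFF3")
    invisible(path)
}

#' @rdname writeGenesGff3
#' @export
readGenesGff3 <- function(path) {
    gr <- rtracklayer::import(path, format = "GFF3")
    genes <- gr[gr$type == "gene"]
    genes$gene_id <- genes$ID
    exons <- gr[gr$type == "exon"]
    exons$gene_id <- vapply(exons$Parent, function(p)
        if (length(p)) p[[1]] else NA_character_, character(1))
    if (anyDuplicated(genes$gene_id))
        stop("duplicated gene ids in ", path)
    keep <- c("gene_id")
    S4Vectors::mcols(genes) <- S4Vectors::mcols(genes)[, keep, drop = FALSE]
    S4Vectors::mcols(exons) <- S4Vectors::mcols(exons)[, keep, drop = FALSE]
    list(genes = sort(genes), exons = sort(exons))
}

#' Write / read female variant sites as VCF
#'
#' Minimal sites-only VCF 4.2 with an `AF` INFO field (the only quantity
#' the SNP-density analysis consumes); REF/ALT alleles are placeholders
#' in simulated output. Reading goes through VariantAnnotation.
#'
#' @param variants `GRanges` with `af` (see [simulateVariants()]).
#' @param path file path (uncompressed `.vcf`).
#' @export
writeVariantsVcf <- function(variants, path) {
    sl <- GenomeInfoDb::seqlengths(variants)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">"),
               con)
    if (length(sl) && !any(is.na(sl)))
        writeLines(sprintf("##contig=<ID=%s,length=%d>", names(sl), sl), con)
    writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
    if (length(variants))
        writeLines(sprintf("%s\t%d\t.\tA\tG\t.\tPASS\tAF=%.4f",
                           as.character(GenomeInfoDb::seqnames(variants)),
                           GenomicRanges::start(variants), variants$af),
                   con)
    invisible(path)
}

#' @rdname writeVariantsVcf
#' @export
readVariantsVcf <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    gr <- SummarizedExperiment::rowRanges(vcf)
    af <- VariantAnnotation::info(vcf)$AF
    gr$af <- vapply(as.list(af), function(x)
        if (length(x)) x[[1]] else NA_real_, numeric(1))
    S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, "af", drop = FALSE]
    names(gr) <- NULL
    sort(gr)
}

#' Write / read an expression count matrix with its sample sheet
#'
#' The counts TSV holds `gene_id`, `chrom`, `start`, `length` and one
#' column per sample; the sample sheet holds `sample_id`, `sex`,
#' `tissue`, `replicate`.
#'
#' @param se `SummarizedExperiment` from [simulateExpression()].
#' @param countsPath,samplesPath file paths.
#' @return `readCounts()` returns a `SummarizedExperiment`.
#' @export
writeCounts <- function(se, countsPath, samplesPath) {
    rd <- SummarizedExperiment::rowData(se)
    df <- data.frame(gene_id = rd$gene_id,
                     length = rd$length,
                     stringsAsFactors = FALSE)
    for (extra in c("chrom", "start", "regionClass"))
        if (extra %in% names(rd)) df[[extra]] <- rd[[extra]]
    df <- cbind(df, as.data.frame(.seCounts(se)))
    write.table(df, countsPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    write.table(cd[, intersect(c("sample_id", "sex", "tissue", "replicate"),
                               names(cd))],
                samplesPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(countsPath)
}

#' @rdname writeCounts
#' @export
readCounts <- function(countsPath, samplesPath) {
    df <- read.delim(countsPath, stringsAsFactors = FALSE,
                     check.names = FALSE)
    samples <- read.delim(samplesPath, stringsAsFactors = FALSE)
    if (anyDuplicated(df$gene_id)) stop("duplicated gene ids")
    if (!all(samples$sample_id %in% names(df)))
        stop("sample sheet lists samples absent from the counts table: ",
             paste(setdiff(samples$sample_id, names(df)), collapse = ", "))
    counts <- as.matrix(df[, samples$sample_id, drop = FALSE])
    rownames(counts) <- df$gene_id
    meta <- setdiff(names(df), samples$sample_id)
    rd <- S4Vectors::DataFrame(df[, meta, drop = FALSE])
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowData = rd,
        colData = S4Vectors::DataFrame(samples,
                                       row.names = samples$sample_id))
}

#' Write every simulated dataset of one configuration to a directory
#'
#' Materializes the full synthetic bundle (depth bedGraphs for both
#' sexes, region and TE BED, gene GFF3, variant VCF, divergence TSV,
#' counts and sample-sheet TSV, plus the configuration as YAML) so the
#' file-based pipeline entry point can be exercised end to end.
#'
#' @param params a [SimParams].
#' @param outdir output directory (created if needed).
#' @param nRepsPerSex replicates per sex for the expression matrix.
#' @return Invisibly, a named list of the file paths written.
#' @export
writeSimulatedBundle <- function(params, outdir, nRepsPerSex = 3L) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    layout <- simulateLayout(params)
    paths <- list(
        depth_female = file.path(outdir, "depth_female.bedGraph"),
        depth_male = file.path(outdir, "depth_male.bedGraph"),
        regions = file.path(outdir, "regions_true.bed"),
        genes = file.path(outdir, "genes.gff3"),
        te = file.path(outdir, "te.bed"),
        vcf = file.path(outdir, "female_variants.vcf"),
        divergence = file.path(outdir, "divergence.tsv"),
        counts = file.path(outdir, "counts.tsv"),
        samples = file.path(outdir, "samples.tsv"),
        config = file.path(outdir, "sim_config.yaml"))
    writeBedGraphTrack(simulateCoverage(layout, params, "female"),
                       paths$depth_female)
    writeBedGraphTrack(simulateCoverage(layout, params, "male"),
                       paths$depth_male)
    writeRegionsBed(layoutRegions(layout), paths$regions)
    writeGenesGff3(layout, paths$genes)
    writeTeBed(layoutTEs(layout), paths$te)
    writeVariantsVcf(simulateVariants(layout, params), paths$vcf)
    writeDivergenceTable(simulateDivergence(layout, params),
                         paths$divergence)
    se <- simulateExpression(layout, params, nRepsPerSex)
    rd <- SummarizedExperiment::rowData(se)
    rd$start <- GenomicRanges::start(layoutGenes(layout))
    rd$chrom <- as.character(GenomeInfoDb::seqnames(layoutGenes(layout)))
    SummarizedExperiment::rowData(se) <- rd
    writeCounts(se, paths$counts, paths$samples)
    yaml::write_yaml(simParamsAsList(params), paths$config,
                     precision = 15)
    invisible(paths)
}

#' Convert simulation parameters to / from a plain list
#'
#' Round-trippable YAML-friendly representation of a [SimParams].
#'
#' @param params a `SimParams`.
#' @return `simParamsAsList()`: a named list; `simParamsFromList()`: a
#'   `SimParams`.
#' @export
simParamsAsList <- function(params) {
    nm <- slotNames("SimParams")
    out <- lapply(nm, function(s) {
        v <- slot(params, s)
        if (!is.null(names(v))) as.list(v) else v
    })
    names(out) <- nm
    out
}

#' @rdname simParamsAsList
#' @param x a named list as produced by `simParamsAsList()`.
#' @export
simParamsFromList <- function(x) {
    x <- lapply(x, function(v) if (is.list(v)) unlist(v) else v)
    do.call(SimParams, x)
}
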