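#' Assign region classes to genes from a boundary annotation
#'
#' Z-linked genes are split into PAR and DR by the annotated boundary
#' (using the gene start position); autosomal genes get their chromosome's
#' class (`CHR4`, `CHR5`) or `AUTOSOME_MACRO` for other macrochromosomes.
#'
#' @param chrom,start per-gene chromosome names and start positions.
#' @param annotation a [RegionAnnotation] for the Z chromosome.
#' @param zChrom name of the Z chromosome (default `"Z"`).
#' @return Character vector of region classes.
#' @export
assignRegionClasses <- function(chrom, start, annotation, zChrom = "Z") {
    stopifnot(is(annotation, "RegionAnnotation"))
    cls <- ifelse(chrom %in% REGION_CLASSES, chrom, "AUTOSOME_MACRO")
    onZ <- chrom == zChrom
    inPar <- IRanges::overlapsAny(IRanges::IRanges(start, width = 1),
                                  annotation@parInterval)
    cls[onZ] <- ifelse(inPar[onZ], "PAR", "DR")
    cls
}

.annotationAsList <- function(x) {
    if (is.null(x)) return(NULL)
    list(chromosome = x@chromosome,
         chromLength = x@chromLength,
         boundary = if (is.na(x@boundary)) NULL else x@boundary,
         noDR = x@noDR,
         method = x@method,
         par = if (length(x@parInterval))
             c(IRanges::start(x@parInterval), IRanges::end(x@parInterval))
             else NULL,
         dr = if (length(x@drInterval))
             c(IRanges::start(x@drInterval), IRanges::end(x@drInterval))
             else NULL,
         drMeanRatio = if (is.na(x@drMeanRatio)) NULL else x@drMeanRatio,
         support = as.list(x@support),
         flags = as.list(x@flags))
}

.defaultPipelineConfig <- function() {
    list(seed = 1L, windowSize = 5e4, zChrom = "Z",
         reference = c("CHR4", "CHR5"), nBoot = 1000L, nPerm = 1000L,
         fdr = 0.05, gcCorrect = FALSE, useBackgroundEnc = FALSE,
         nRepsPerSex = 3L, minRun = 10, boundaryExclude = NULL,
         simulate = NULL, inputs = NULL)
}

## stable short fingerprint of the effective configuration
.configHash <- function(config) {
    txt <- paste(deparse(config[order(names(config))]), collapse = "")
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(txt, tf)
    toupper(substr(unname(tools::md5sum(tf)), 1, 12))
}

#' Run the full sex-chromosome analysis pipeline
#'
#' Orchestrates the stages in dependency order: PAR/DR boundary
#' annotation from female depth (plus expression-based annotation and
#' SNP-density verification), dosage-compensation and sex-biased-gene
#' analysis, faster-Z divergence testing against the autosomal reference,
#' and genomic-feature contrasts. Stages whose inputs are absent are
#' marked `"not run"`. The run is deterministic under a fixed
#' configuration, and the returned report serializes to byte-identical
#' JSON across repeated runs.
#'
#' @param config named list (or path to a YAML file). Either
#'   `config$simulate` (a list of [SimParams] overrides; the synthetic
#'   bundle is generated in memory) or `config$inputs` (named file paths:
#'   `depth_female`, `genes`, `te`, `vcf`, `divergence`, `counts`,
#'   `samples`) must be provided, plus optional analysis settings
#'   (`seed`, `windowSize`, `reference`, `nBoot`, `nPerm`, `fdr`,
#'   `gcCorrect`, `boundaryExclude`).
#' @return A nested list report: `provenance`, `stages`, `regions`,
#'   `dosage`, `sex_bias`, `divergence`, `features`.
#' @seealso [renderReport()], [writeSimulatedBundle()]
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- .defaultPipelineConfig()
    cfg[names(config)] <- config
    if (is.null(cfg$simulate) && is.null(cfg$inputs))
        stop("config must provide either $simulate or $inputs")
    stages <- list()

    ## ---- load or simulate inputs -------------------------------------
    cds <- NULL
    layout <- NULL
    if (!is.null(cfg$simulate)) {
        simArgs <- lapply(cfg$simulate,
                          function(v) if (is.list(v)) unlist(v) else v)
        if (is.null(simArgs$seed)) simArgs$seed <- cfg$seed
        params <- do.call(SimParams, simArgs)
        layout <- simulateLayout(params)
        tracksF <- simulateCoverage(layout, params, "female")
        variants <- simulateVariants(layout, params)
        divergence <- simulateDivergence(layout, params)
        se <- simulateExpression(layout, params, cfg$nRepsPerSex)
        rd <- SummarizedExperiment::rowData(se)
        rd$start <- GenomicRanges::start(layoutGenes(layout))
        rd$chrom <- as.character(GenomeInfoDb::seqnames(layoutGenes(layout)))
        SummarizedExperiment::rowData(se) <- rd
        tes <- layoutTEs(layout)
        exons <- layoutExons(layout)
        cdsSim <- simulateCodingSequences(layout, params)
        cds <- cdsSim$cds
        cdsBackground <- cdsSim$background
        geneChrom <- rd$chrom
        geneStart <- rd$start
        geneId <- rd$gene_id
    } else {
        inp <- cfg$inputs
        need <- function(x) !is.null(inp[[x]]) && file.exists(inp[[x]])
        tracksF <- NULL
        if (need("depth_female")) {
            depth <- readBedGraphTrack(inp$depth_female)
            wt <- computeDepthWindows(depth, windowSize = cfg$windowSize)
            w <- trackWindows(wt)
            tracksF <- lapply(
                split(w, as.character(GenomeInfoDb::seqnames(w))),
                function(x) WindowTrack(x))
        }
        gm <- if (need("genes")) readGenesGff3(inp$genes) else NULL
        tes <- if (need("te")) readTeBed(inp$te) else NULL
        variants <- if (need("vcf")) readVariantsVcf(inp$vcf) else NULL
        divergence <- if (need("divergence"))
            readDivergenceTable(inp$divergence) else NULL
        se <- if (need("counts") && need("samples"))
            readCounts(inp$counts, inp$samples) else NULL
        cdsBackground <- NULL
        if (need("cds")) cds <- Biostrings::readDNAStringSet(inp$cds)
        exons <- if (!is.null(gm)) gm$exons else NULL
        if (!is.null(se)) {
            rd <- SummarizedExperiment::rowData(se)
            geneChrom <- rd$chrom
            geneStart <- rd$start
            geneId <- rd$gene_id
        } else if (!is.null(gm)) {
            geneChrom <- as.character(GenomeInfoDb::seqnames(gm$genes))
            geneStart <- GenomicRanges::start(gm$genes)
            geneId <- gm$genes$gene_id
        } else {
            geneChrom <- geneStart <- geneId <- NULL
        }
    }

    ## ---- stage: region annotation ------------------------------------
    covAnn <- exprAnn <- NULL
    if (!is.null(tracksF) && cfg$zChrom %in% names(tracksF) &&
        length(tracksF) > 1) {
        zNorm <- normalizeDepth(tracksF[[cfg$zChrom]],
                                tracksF[names(tracksF) != cfg$zChrom],
                                gcCorrect = cfg$gcCorrect)
        covAnn <- inferBoundaryFromCoverage(zNorm, minRun = cfg$minRun)
        stages$coverage_boundary <- "run"
    } else stages$coverage_boundary <- "not run"

    ratios <- NULL
    if (!is.null(se) && !is.null(geneStart)) {
        ratios <- mfLog2Ratios(se)
        zr <- ratios[!is.na(ratios$start) &
                     geneChrom[match(ratios$gene_id, geneId)] == cfg$zChrom, ]
        if (nrow(zr) >= 80) {
            ew <- mfExpressionWindows(zr[, c("gene_id", "start", "ratio")])
            exprAnn <- inferBoundaryFromExpression(
                ew, chromosome = cfg$zChrom,
                chromLength = if (!is.null(covAnn)) covAnn@chromLength
                              else NA_real_)
            stages$expression_boundary <- "run"
        } else stages$expression_boundary <- "not run"
    } else stages$expression_boundary <- "not run"

    ann <- if (!is.null(covAnn) && !covAnn@noDR) covAnn else exprAnn
    if (!is.null(ann) && !is.null(variants) && length(variants)) {
        dens <- snpDensityTrack(variants, windowSize = cfg$windowSize)
        dens <- dens[as.character(GenomeInfoDb::seqnames(dens)) ==
                     cfg$zChrom]
        ann <- verifyBoundaryWithSnps(ann, dens)
        stages$snp_verification <- "run"
    } else stages$snp_verification <- "not run"

    ## ---- gene region classes -----------------------------------------
    geneClass <- NULL
    if (!is.null(geneChrom)) {
        if (!is.null(ann) && !ann@noDR) {
            geneClass <- assignRegionClasses(geneChrom, geneStart, ann,
                                             zChrom = cfg$zChrom)
        } else if (!is.null(layout)) {
            geneClass <- as.character(layoutGenes(layout)$regionClass)
        }
        names(geneClass) <- geneId
    }

    ## ---- stage: expression analyses ----------------------------------
    dosage <- sexBias <- enrichment <- NULL
    if (!is.null(ratios) && !is.null(geneClass)) {
        ratios$regionClass <- geneClass[ratios$gene_id]
        dosage <- dosageSummary(ratios)
        calls <- callSexBiased(se, fdr = cfg$fdr)
        calls$regionClass <- geneClass[calls$gene_id]
        sexBias <- as.list(table(calls$call))
        enr <- list()
        for (reg in list("PAR", "DR", c("PAR", "DR")))
            for (b in c("male", "female"))
                enr[[length(enr) + 1]] <-
                    parEnrichmentTest(calls, reg, b)
        enrichment <- do.call(rbind, enr)
        stages$expression_analysis <- "run"
    } else stages$expression_analysis <- "not run"

    ## ---- stage: divergence -------------------------------------------
    divReport <- NULL
    if (!is.null(divergence)) {
        if (!is.null(geneClass) && !is.null(ann) && !ann@noDR) {
            hit <- match(divergence$gene_id, names(geneClass))
            divergence$class <- ifelse(is.na(hit), divergence$class,
                                       geneClass[hit])
        }
        divReport <- fasterZReport(
            divergence, reference = cfg$reference, nPerm = cfg$nPerm,
            nBoot = cfg$nBoot, seed = cfg$seed,
            boundaryExclude = cfg$boundaryExclude,
            boundary = if (!is.null(ann) && !ann@noDR) ann@boundary
                       else NULL)
        stages$divergence <- "run"
    } else stages$divergence <- "not run"

    ## ---- stage: genomic features -------------------------------------
    features <- NULL
    if (!is.null(geneClass) || !is.null(tes)) {
        features <- list()
        ## per-window TE density grouped by region class
        if (!is.null(tes) && !is.null(ann)) {
            grid <- list()
            sl <- if (!is.null(layout)) {
                GenomeInfoDb::seqlengths(layoutRegions(layout))
            } else if (!is.null(tracksF)) {
                vapply(tracksF, function(t)
                    max(GenomicRanges::end(trackWindows(t))), numeric(1))
            } else {
                vapply(split(tes, as.character(
                    GenomeInfoDb::seqnames(tes))),
                    function(x) max(GenomicRanges::end(x)), numeric(1))
            }
            for (chr in names(sl)) {
                if (is.na(sl[[chr]])) next
                starts <- seq(1, sl[[chr]], by = cfg$windowSize)
                gw <- GenomicRanges::GRanges(
                    chr, IRanges::IRanges(starts,
                        pmin(starts + cfg$windowSize - 1, sl[[chr]])))
                GenomeInfoDb::seqlevels(gw) <- names(sl)
                grid[[chr]] <- gw
            }
            grid <- do.call(c, unname(grid))
            dens <- intervalDensityWindows(tes, grid)
            wcls <- assignRegionClasses(
                as.character(GenomeInfoDb::seqnames(dens)),
                GenomicRanges::start(dens), ann, zChrom = cfg$zChrom)
            refW <- dens$density[wcls %in% cfg$reference]
            teTests <- lapply(c("PAR", "DR"), function(cl) {
                v <- dens$density[wcls == cl]
                if (length(v) >= 2 && length(refW) >= 2) {
                    r <- regionFeatureTest(v, refW, feature = "te_density")
                    r$region <- cl
                    r
                }
            })
            features$te <- do.call(rbind, Filter(Negate(is.null), teTests))
            features$te_by_class <- lapply(
                split(dens$density, wcls), mean)
        }
        ## intron sizes by gene class
        if (!is.null(exons) && !is.null(geneClass)) {
            introns <- intronSizes(exons)
            byClass <- split(unlist(introns),
                             geneClass[rep(names(introns),
                                           lengths(introns))])
            ref <- unlist(byClass[intersect(cfg$reference, names(byClass))])
            inTests <- lapply(c("PAR", "DR"), function(cl) {
                v <- byClass[[cl]]
                if (length(v) >= 2 && length(ref) >= 2) {
                    r <- regionFeatureTest(log10(v), log10(ref),
                                           feature = "log10_intron_size")
                    r$region <- cl
                    r
                }
            })
            features$intron <- do.call(rbind,
                                       Filter(Negate(is.null), inTests))
        }
        ## codon-usage features per gene
        if (!is.null(cds) && !is.null(geneClass)) {
            ids <- intersect(names(cds), names(geneClass))
            gcv <- vapply(ids, function(g)
                gc3s(as.character(cds[[g]])), numeric(1))
            encv <- vapply(ids, function(g) {
                bg <- if (cfg$useBackgroundEnc && !is.null(cdsBackground))
                    cdsBackground[g, ] else NULL
                enc(as.character(cds[[g]]), background = bg)
            }, numeric(1))
            cl <- geneClass[ids]
            ref <- cl %in% cfg$reference
            codonTests <- list()
            for (feat in c("gc3s", "enc")) {
                vals <- if (feat == "gc3s") gcv else encv
                for (reg in c("PAR", "DR")) {
                    if (sum(cl == reg) >= 2 && sum(ref) >= 2) {
                        r <- regionFeatureTest(vals[cl == reg], vals[ref],
                                               feature = feat)
                        r$region <- reg
                        codonTests[[paste(feat, reg)]] <- r
                    }
                }
            }
            features$codon <- do.call(rbind, codonTests)
            rownames(features$codon) <- NULL
        }
        stages$features <- "run"
    } else stages$features <- "not run"

    list(
        provenance = list(
            package = as.character(utils::packageVersion("parZ")),
            seed = cfg$seed,
            config_hash = .configHash(cfg)),
        stages = stages,
        regions = list(coverage = .annotationAsList(covAnn),
                       expression = .annotationAsList(exprAnn),
                       consensus = .annotationAsList(ann)),
        dosage = dosage,
        sex_bias = list(calls = sexBias, enrichment = enrichment),
        divergence = divReport,
        features = features)
}

#' Significance stars for p-values
#'
#' `"*"` for p < 0.05, `"**"` for p < 0.01, `"***"` for p < 0.001,
#' `""` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return Character vector of star strings.
#' @export
pValueStars <- function(p) {
    ifelse(is.na(p), "NA",
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", ""))))
}

#' Render a pipeline report
#'
#' Produces a human-readable text summary (rates with confidence
#' intervals, permutation calls with significance stars, feature
#' contrasts, dosage and enrichment tables) and optionally writes the
#' machine-readable JSON form. JSON output excludes timestamps and is
#' byte-identical across reruns of the same configuration.
#'
#' @param report list from [runPipeline()].
#' @param jsonPath optional path for the JSON report.
#' @return Character vector of report lines (invisibly when printed).
#' @export
renderReport <- function(report, jsonPath = NULL) {
    fmt <- function(x) formatC(x, digits = 4, format = "g")
    lines <- c("== Sex-chromosome analysis report ==",
               sprintf("seed %s | config %s", report$provenance$seed,
                       report$provenance$config_hash))
    for (s in names(report$stages))
        lines <- c(lines, sprintf("  stage %-22s %s", s,
                                  report$stages[[s]]))
    cov <- report$regions$consensus
    if (!is.null(cov)) {
        lines <- c(lines, "", sprintf(
            "PAR/DR boundary (%s): %s",
            cov$method,
            if (isTRUE(cov$noDR)) "no DR detected"
            else format(cov$boundary, big.mark = ",")))
        if (length(cov$flags))
            lines <- c(lines, paste("  flags:",
                                    paste(unlist(cov$flags),
                                          collapse = ", ")))
    }
    if (!is.null(report$divergence)) {
        lines <- c(lines, "", "Rates (ratio-of-sums, 95% bootstrap CI):")
        r <- report$divergence$rates
        for (i in seq_len(nrow(r)))
            lines <- c(lines, sprintf(
                "  %-8s n=%4d  dN=%s  dS=%s  omega=%s [%s, %s]",
                r$group[i], r$n_genes[i], fmt(r$dn[i]), fmt(r$ds[i]),
                ifelse(is.na(r$omega[i]), "NA", fmt(r$omega[i])),
                fmt(r$omega_low[i]), fmt(r$omega_high[i])))
        lines <- c(lines, "Permutation contrasts vs autosomal reference:")
        cm <- report$divergence$comparisons
        for (i in seq_len(nrow(cm)))
            lines <- c(lines, sprintf(
                "  %-4s %-6s diff=%+0.4g  p=%s %s (%s)",
                cm$group[i], cm$statistic[i], cm$observed_difference[i],
                fmt(cm$p_value[i]), pValueStars(cm$p_value[i]),
                cm$direction[i]))
    }
    if (!is.null(report$dosage)) {
        lines <- c(lines, "", "Dosage compensation (log2 M/F by class):")
        d <- report$dosage$summary
        for (i in seq_len(nrow(d)))
            lines <- c(lines, sprintf(
                "  %-15s n=%4d  median log2=%+0.3f  (ratio %0.3f)",
                d$class[i], d$n[i], d$medianLog2[i], d$medianRatio[i]))
        lines <- c(lines, sprintf("  partial compensation flag: %s",
                                  report$dosage$partialCompensation))
    }
    enr <- report$sex_bias$enrichment
    if (!is.null(enr)) {
        lines <- c(lines, "", "Sex-biased-gene enrichment (Fisher exact):")
        for (i in seq_len(nrow(enr)))
            lines <- c(lines, sprintf(
                "  %-8s %-6s OR=%s  p=%s %s",
                enr$region[i], enr$bias[i],
                ifelse(is.na(enr$odds_ratio[i]), "NA",
                       fmt(enr$odds_ratio[i])),
                fmt(enr$p_value[i]), pValueStars(enr$p_value[i])))
    }
    feats <- report$features
    for (nm in c("te", "intron", "codon")) {
        f <- feats[[nm]]
        if (is.null(f)) next
        lines <- c(lines, "", sprintf("Feature contrasts (%s):", nm))
        for (i in seq_len(nrow(f)))
            lines <- c(lines, sprintf(
                "  %-18s %-4s median %s vs %s  p=%s %s (%s)",
                f$feature[i], f$region[i], fmt(f$median_region[i]),
                fmt(f$median_reference[i]), fmt(f$p_value[i]),
                pValueStars(f$p_value[i]), f$direction[i]))
    }
    if (!is.null(jsonPath))
        jsonlite::write_json(report, jsonPath, auto_unbox = TRUE,
                             digits = NA, null = "null", na = "null",
                             pretty = TRUE)
    lines
}
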