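#' TPM normalization
#'
#' Transcripts per million: per sample, each gene's count is divided by
#' its length, and the resulting rates are scaled to sum to one million.
#'
#' @param counts genes x samples numeric matrix.
#' @param lengths per-gene lengths in bp (> 0), recycled across samples.
#' @return Matrix of TPM values with the same dimnames; every column sums
#'   to 1e6.
#' @examples
#' tpmNormalize(cbind(s1 = c(10, 10)), c(1000, 2000))
#' @export
tpmNormalize <- function(counts, lengths) {
    counts <- as.matrix(counts)
    stopifnot(length(lengths) == nrow(counts), all(lengths > 0))
    rate <- counts / lengths
    tot <- colSums(rate)
    if (any(tot == 0))
        stop("sample(s) with all-zero counts: ",
             paste(colnames(counts)[tot == 0], collapse = ", "))
    sweep(rate, 2, tot, "/") * 1e6
}

.seCounts <- function(se) {
    SummarizedExperiment::assay(se, "counts")
}

#' Per-gene log2 male/female expression ratios
#'
#' Computes `log2((mean male TPM + pseudocount) / (mean female TPM +
#' pseudocount))` per gene; genes expressed below `minExpr` TPM in both
#' sexes are dropped as unreliably quantified.
#'
#' @param se [SummarizedExperiment::SummarizedExperiment] with a `counts`
#'   assay, `rowData` column `length` and `colData` column `sex`
#'   (`"M"`/`"F"`); alternatively pass a TPM matrix plus `sex`.
#' @param sex character vector of sample sexes (required when `se` is a
#'   matrix of TPM values).
#' @param minExpr minimum mean TPM in at least one sex (default 1).
#' @param pseudocount added to both means before the ratio (default 0.01).
#' @return data.frame with `gene_id`, `meanM`, `meanF`, `ratio`,
#'   `log2Ratio` (plus `regionClass` and `start` when available).
#' @export
mfLog2Ratios <- function(se, sex = NULL, minExpr = 1, pseudocount = 0.01) {
    if (is(se, "SummarizedExperiment")) {
        sex <- SummarizedExperiment::colData(se)$sex
        tpm <- tpmNormalize(.seCounts(se),
                            SummarizedExperiment::rowData(se)$length)
        rd <- SummarizedExperiment::rowData(se)
    } else {
        tpm <- as.matrix(se)
        rd <- NULL
        if (is.null(sex)) stop("sex labels are required")
    }
    if (!any(sex == "M") || !any(sex == "F"))
        stop("need at least one sample of each sex")
    mM <- rowMeans(tpm[, sex == "M", drop = FALSE])
    mF <- rowMeans(tpm[, sex == "F", drop = FALSE])
    out <- data.frame(
        gene_id = if (!is.null(rownames(tpm))) rownames(tpm)
                  else sprintf("gene%d", seq_len(nrow(tpm))),
        meanM = mM, meanF = mF,
        ratio = (mM + pseudocount) / (mF + pseudocount),
        stringsAsFactors = FALSE)
    out$log2Ratio <- log2(out$ratio)
    if (!is.null(rd)) {
        if ("regionClass" %in% names(rd)) out$regionClass <- rd$regionClass
        if ("start" %in% names(rd)) out$start <- rd$start
    }
    keep <- mM >= minExpr | mF >= minExpr
    rownames(out) <- NULL
    out[keep, , drop = FALSE]
}

#' Dosage-compensation summary by region class
#'
#' Summarizes per-gene log2 male/female ratios by region class (median
#' and mean, plus back-transformed ratios). Ratios are median-centered on
#' the autosomal reference classes first (by default), removing the
#' compositional shift that whole-sample normalization introduces when a
#' large gene class changes between sexes. A DR median log2 ratio lying
#' strictly between 0 and 1 (i.e. a male/female ratio strictly between 1
#' and 2) is flagged as partial dosage compensation.
#'
#' @param ratios data.frame from [mfLog2Ratios()] including a
#'   `regionClass` column (or supplied via `regionClass`).
#' @param regionClass optional per-gene classes overriding the column.
#' @param center logical, center log2 ratios on the autosomal median.
#' @param autosomeClasses classes forming the centering reference.
#' @return List with `summary` (data.frame: class, n, medianLog2,
#'   meanLog2, medianRatio, meanRatio) and `partialCompensation`
#'   (logical flag).
#' @export
dosageSummary <- function(ratios, regionClass = NULL, center = TRUE,
                          autosomeClasses = c("CHR4", "CHR5",
                                              "AUTOSOME_MACRO")) {
    if (!is.null(regionClass)) ratios$regionClass <- regionClass
    if (!"regionClass" %in% names(ratios))
        stop("region classes are required")
    l2 <- ratios$log2Ratio
    if (center) {
        auto <- ratios$regionClass %in% autosomeClasses
        if (any(auto)) l2 <- l2 - median(l2[auto])
    }
    cls <- ratios$regionClass
    present <- unique(cls)
    missing <- setdiff(c("PAR", "DR"), present)
    if (length(missing))
        warning("class(es) with no genes omitted: ",
                paste(missing, collapse = ", "))
    summ <- do.call(rbind, lapply(present, function(cl) {
        v <- l2[cls == cl]
        data.frame(class = cl, n = length(v), medianLog2 = median(v),
                   meanLog2 = mean(v), medianRatio = 2^median(v),
                   meanRatio = 2^mean(v), stringsAsFactors = FALSE)
    }))
    drMed <- if ("DR" %in% present)
        summ$medianLog2[summ$class == "DR"] else NA_real_
    list(summary = summ,
         partialCompensation = is.finite(drMed) && drMed > 0 && drMed < 1)
}

## median-of-ratios size factors (the standard count-normalization for
## two-group RNA-seq comparisons)
.sizeFactors <- function(counts) {
    logGeo <- rowMeans(log(counts))
    use <- is.finite(logGeo)
    if (!any(use)) return(rep(1, ncol(counts)))
    apply(counts, 2, function(cnt) {
        v <- (log(cnt) - logGeo)[use & cnt > 0]
        if (!length(v)) 1 else exp(median(v))
    })
}

#' Call sex-biased genes with a negative-binomial Wald test
#'
#' A deliberately simple two-group differential-expression test:
#' counts are normalized by median-of-ratios size factors; per-gene
#' dispersions are estimated by moments and a parametric mean-dispersion
#' trend `a0 + a1/mean` is fitted across genes; each gene is tested at
#' the trend dispersion unless its own moment estimate exceeds
#' `dispOutlier` times the trend, in which case the larger gene-wise
#' value is kept (an upward-only outlier guard: raw moment estimates at
#' 2-3 replicates are too noisy to use directly, while silently shrinking
#' a genuinely variable gene would anti-conservatively inflate its test).
#' The male versus female log fold change is tested with a Wald statistic
#' on log group means; Benjamini-Hochberg correction yields q-values and
#' genes are called at `q < fdr`. This is a documented stand-in for a
#' full differential-expression package, validated on simulations (null
#' false-discovery control and power) and cross-checked against DESeq2 in
#' the test suite; externally produced calls can be used instead wherever
#' a calls table is accepted.
#'
#' @param se `SummarizedExperiment` with a `counts` assay and `colData`
#'   column `sex`, or a counts matrix plus `sex`.
#' @param sex sample sexes (when `se` is a matrix).
#' @param fdr false-discovery-rate cutoff (default 0.05).
#' @param minMeanCount genes below this mean normalized count are not
#'   tested (reported as unbiased with NA p-value).
#' @param dispOutlier multiple of the trend above which a gene keeps its
#'   own moment dispersion (default 2).
#' @return data.frame with `gene_id`, `log2FoldChange`, `p_value`,
#'   `q_value`, `call` (male-biased/female-biased/unbiased) and
#'   `regionClass` when available.
#' @export
callSexBiased <- function(se, sex = NULL, fdr = 0.05, minMeanCount = 1,
                          dispOutlier = 2) {
    if (is(se, "SummarizedExperiment")) {
        sex <- SummarizedExperiment::colData(se)$sex
        counts <- .seCounts(se)
        rd <- SummarizedExperiment::rowData(se)
    } else {
        counts <- as.matrix(se)
        rd <- NULL
        if (is.null(sex)) stop("sex labels are required")
    }
    nM <- sum(sex == "M")
    nF <- sum(sex == "F")
    if (nM < 2 || nF < 2)
        stop("need >= 2 replicates per sex to estimate dispersion; ",
             "supply externally produced calls instead")
    sf <- .sizeFactors(counts)
    norm <- sweep(counts, 2, sf, "/")
    mM <- rowMeans(norm[, sex == "M", drop = FALSE])
    mF <- rowMeans(norm[, sex == "F", drop = FALSE])
    vM <- apply(norm[, sex == "M", drop = FALSE], 1, var)
    vF <- apply(norm[, sex == "F", drop = FALSE], 1, var)
    mu <- (mM * nM + mF * nF) / (nM + nF)
    pooledVar <- (vM * (nM - 1) + vF * (nF - 1)) / (nM + nF - 2)
    rawDisp <- pmax((pooledVar - mu) / mu^2, 1e-8)
    testable <- mu >= minMeanCount & is.finite(rawDisp)
    ## parametric trend a0 + a1/mu fitted on testable genes
    trend <- rep(1e-8, length(mu))
    if (sum(testable) >= 10) {
        fit <- lm(rawDisp[testable] ~ I(1 / mu[testable]))
        a <- pmax(coef(fit), 0)
        trend <- pmax(a[1] + a[2] / mu, 1e-8)
    }
    ## trend dispersion with an upward-only outlier guard
    disp <- ifelse(rawDisp > dispOutlier * trend, rawDisp, trend)
    pc <- 0.5
    lfc <- (log(mM + pc) - log(mF + pc)) / log(2)
    seLog <- sqrt((1 / pmax(mM, pc) + disp) / nM +
                  (1 / pmax(mF, pc) + disp) / nF)
    z <- (log(mM + pc) - log(mF + pc)) / seLog
    p <- 2 * pnorm(-abs(z))
    p[!testable] <- NA
    q <- rep(NA_real_, length(p))
    q[!is.na(p)] <- p.adjust(p[!is.na(p)], method = "BH")
    call <- rep("unbiased", length(p))
    call[!is.na(q) & q < fdr & lfc > 0] <- "male-biased"
    call[!is.na(q) & q < fdr & lfc < 0] <- "female-biased"
    out <- data.frame(
        gene_id = if (!is.null(rownames(counts))) rownames(counts)
                  else sprintf("gene%d", seq_len(nrow(counts))),
        log2FoldChange = lfc, p_value = p, q_value = q, call = call,
        stringsAsFactors = FALSE)
    if (!is.null(rd) && "regionClass" %in% names(rd))
        out$regionClass <- rd$regionClass
    rownames(out) <- NULL
    out
}

#' Enrichment of sex-biased genes in a chromosome region
#'
#' Fisher's exact test on the 2x2 table (biased vs unbiased) x (region vs
#' autosomes), asking whether genes with the given bias direction are
#' over- or under-represented in a region (PAR, DR, or the whole Z)
#' relative to the autosomal background.
#'
#' @param calls data.frame from [callSexBiased()] with `call` and
#'   `regionClass` columns.
#' @param region region classes tested (e.g. `"PAR"`, `"DR"`, or
#'   `c("PAR", "DR")` for the whole Z).
#' @param bias `"male"` or `"female"`.
#' @param autosomeClasses classes forming the background.
#' @return One-row data.frame: `region`, `bias`, the four table cells
#'   (`biased_region`, `unbiased_region`, `biased_auto`,
#'   `unbiased_auto`), `odds_ratio` (sample OR; NA with flag when a
#'   margin is empty) and `p_value`.
#' @export
parEnrichmentTest <- function(calls, region, bias = c("male", "female"),
                              autosomeClasses = c("CHR4", "CHR5",
                                                  "AUTOSOME_MACRO")) {
    bias <- match.arg(bias)
    stopifnot(all(c("call", "regionClass") %in% names(calls)))
    target <- paste0(bias, "-biased")
    inRegion <- calls$regionClass %in% region
    inAuto <- calls$regionClass %in% autosomeClasses
    isBiased <- calls$call == target
    tab <- matrix(c(sum(isBiased & inRegion), sum(!isBiased & inRegion),
                    sum(isBiased & inAuto), sum(!isBiased & inAuto)),
                  nrow = 2,
                  dimnames = list(c("biased", "unbiased"),
                                  c("region", "auto")))
    emptyMargin <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    if (emptyMargin) {
        p <- 1
        or <- NA_real_
    } else {
        ft <- fisher.test(tab, alternative = "two.sided")
        p <- ft$p.value
        or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])  # sample OR
    }
    data.frame(region = paste(region, collapse = "+"), bias = bias,
               biased_region = tab[1, 1], unbiased_region = tab[2, 1],
               biased_auto = tab[1, 2], unbiased_auto = tab[2, 2],
               odds_ratio = or, p_value = p,
               or_undefined = emptyMargin, stringsAsFactors = FALSE)
}
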