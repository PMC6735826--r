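test_that("TPM normalization matches its closed form and sums to 1e6", {
    tpm <- tpmNormalize(cbind(s1 = c(10, 10)), c(1000, 2000))
    expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3))
    expect_equal(unname(tpmNormalize(cbind(s = 5), 700)[1, 1]), 1e6)
    set.seed(1)
    m <- matrix(rpois(600, 40), nrow = 100)
    lens <- runif(100, 300, 5000)
    t2 <- tpmNormalize(m, lens)
    expect_equal(unname(colSums(t2)), rep(1e6, 6))
    ## invariant to scaling a sample's counts
    m2 <- m
    m2[, 3] <- m2[, 3] * 7
    expect_equal(tpmNormalize(m2, lens)[, 3], t2[, 3])
    expect_error(tpmNormalize(cbind(a = c(0, 0)), c(100, 100)), "all-zero")
})

test_that("M/F ratios recover group means and drop unexpressed genes", {
    tpm <- rbind(gHigh = c(4, 4, 2, 2),
                 gFlat = c(3, 3, 3, 3),
                 gOff = c(0.1, 0.1, 0.2, 0.2))
    sex <- c("M", "M", "F", "F")
    r <- mfLog2Ratios(tpm, sex = sex, pseudocount = 0)
    expect_equal(nrow(r), 2)    # gOff below 1 TPM in both sexes
    expect_equal(r$log2Ratio[r$gene_id == "gHigh"], 1)
    expect_equal(r$log2Ratio[r$gene_id == "gFlat"], 0)
    expect_error(mfLog2Ratios(tpm, sex = c("M", "M", "M", "M")),
                 "each sex")
})

test_that("dosage summary flags partial compensation only strictly inside (1,2)", {
    mk <- function(drLog2) {
        data.frame(gene_id = sprintf("g%d", 1:40),
                   log2Ratio = c(rep(0, 20), rep(drLog2, 20)),
                   regionClass = rep(c("CHR4", "DR"), each = 20))
    }
    full <- dosageSummary(mk(0))          # ratio 1: compensated
    expect_false(full$partialCompensation)
    none <- dosageSummary(mk(1))          # ratio 2: uncompensated
    expect_false(none$partialCompensation)
    part <- dosageSummary(mk(0.5))
    expect_true(part$partialCompensation)
    expect_equal(part$summary$medianRatio[part$summary$class == "DR"],
                 2^0.5)
    expect_warning(dosageSummary(mk(0.5)[1:20, ]), "omitted")
})

test_that("dosage recovery from a simulated 1.4x DR is within 0.1 log2 units", {
    p <- smallParams(seed = 23, genesPerMb = 30)   # ~150 DR genes
    lay <- simulateLayout(p)
    se <- simulateExpression(lay, p, 3)
    ds <- dosageSummary(mfLog2Ratios(se))
    drMed <- ds$summary$medianLog2[ds$summary$class == "DR"]
    expect_lt(abs(drMed - log2(1.4)), 0.1)
    expect_true(ds$partialCompensation)
})

test_that("sex-bias calling is silent on null data and detects 4-fold changes", {
    ## constant counts: no calls
    const <- matrix(50, nrow = 30, ncol = 6,
                    dimnames = list(sprintf("g%d", 1:30), NULL))
    sex <- rep(c("M", "F"), each = 3)
    calls <- callSexBiased(const, sex = sex)
    expect_true(all(calls$call == "unbiased"))
    ## genuine 4-fold male-biased genes are mostly recovered
    set.seed(90)
    n <- 400
    mu <- rlnorm(n, log(100), 0.8)
    fold <- c(rep(4, 40), rep(1, n - 40))
    counts <- cbind(
        matrix(rnbinom(n * 3, mu = mu * fold, size = 1 / 0.05), nrow = n),
        matrix(rnbinom(n * 3, mu = mu, size = 1 / 0.05), nrow = n))
    rownames(counts) <- sprintf("g%03d", 1:n)
    calls2 <- callSexBiased(counts, sex = sex)
    expect_gte(mean(calls2$call[1:40] == "male-biased"), 0.7)
    expect_lte(mean(calls2$call[-(1:40)] != "unbiased"), 0.02)
    expect_error(callSexBiased(const, sex = c("M", rep("F", 5))),
                 "replicates")
})

test_that("enrichment tables match hypergeometric expectations", {
    mkCalls <- function(tab) {
        ## tab = c(biasedRegion, unbiasedRegion, biasedAuto, unbiasedAuto)
        data.frame(
            call = rep(c("male-biased", "unbiased", "male-biased",
                         "unbiased"), tab),
            regionClass = rep(c("PAR", "PAR", "CHR4", "CHR4"), tab),
            stringsAsFactors = FALSE)
    }
    flat <- parEnrichmentTest(mkCalls(c(10, 90, 10, 90)), "PAR", "male")
    expect_equal(flat$odds_ratio, 1)
    expect_equal(flat$p_value, 1)
    ## extreme table: p equals the hypergeometric tail enumeration
    ext <- parEnrichmentTest(mkCalls(c(5, 0, 0, 5)), "PAR", "male")
    pOracle <- sum(dhyper(0:5, 5, 5, 5)[
        dhyper(0:5, 5, 5, 5) <= dhyper(5, 5, 5, 5) + 1e-12])
    expect_equal(ext$p_value, pOracle)
    ## no biased genes at all: undefined OR, p = 1
    none <- parEnrichmentTest(mkCalls(c(0, 50, 0, 50)), "PAR", "male")
    expect_true(none$or_undefined)
    expect_true(is.na(none$odds_ratio))
    expect_equal(none$p_value, 1)
})

test_that("male-bias concentrates in the DR, not the PAR, on matched simulations", {
    ## uncompensated end of the observed dosage range: the Fig-2C-like case
    p <- smallParams(seed = 31, genesPerMb = 30, dosageRatioDR = 1.68)
    lay <- simulateLayout(p)
    se <- simulateExpression(lay, p, 3)
    calls <- callSexBiased(se)
    calls$regionClass <- SummarizedExperiment::rowData(se)$regionClass
    dr <- parEnrichmentTest(calls, "DR", "male")
    par <- parEnrichmentTest(calls, "PAR", "male")
    expect_lt(dr$p_value, 0.05)
    expect_gt(par$p_value, 0.05)
})

test_that("stand-in sex-bias test agrees with the reference DE package", {
    skip_if_not_installed("DESeq2")
    p <- smallParams(seed = 37, genesPerMb = 15, dosageRatioDR = 1.8)
    lay <- simulateLayout(p)
    se <- simulateExpression(lay, p, 4)
    counts <- round(SummarizedExperiment::assay(se, "counts"))
    sex <- SummarizedExperiment::colData(se)$sex
    mine <- callSexBiased(counts, sex = sex)
    dds <- DESeq2::DESeqDataSetFromMatrix(
        counts, S4Vectors::DataFrame(sex = factor(sex, c("F", "M"))),
        design = ~sex)
    res <- DESeq2::results(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)))
    ## per-gene fold changes track the reference implementation
    ok <- !is.na(res$log2FoldChange)
    expect_gt(cor(mine$log2FoldChange[ok], res$log2FoldChange[ok]), 0.9)
    ## and the DR-gene calls overlap substantially
    isDR <- SummarizedExperiment::rowData(se)$regionClass == "DR"
    myDR <- mine$call == "male-biased" & isDR
    refDR <- !is.na(res$padj) & res$padj < 0.05 &
        res$log2FoldChange > 0 & isDR
    expect_gt(sum(myDR & refDR) / max(1, sum(refDR)), 0.5)
})
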