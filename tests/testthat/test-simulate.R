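test_that("layout partitions chromosomes and places the boundary by parFraction", {
    p <- SimParams(seed = 7, parFraction = 0.73)
    lay <- simulateLayout(p)
    reg <- layoutRegions(lay)
    par <- reg[reg$regionClass == "PAR"]
    expect_equal(sum(GenomicRanges::width(par)), round(0.73 * 75e6))
    expect_equal(trueBoundary(lay), round(0.73 * 75e6) + 1)
    ## validity already enforces the exact partition; spot-check DR extent
    dr <- reg[reg$regionClass == "DR"]
    expect_equal(sum(GenomicRanges::width(par)) +
                 sum(GenomicRanges::width(dr)), 75e6)
    ## gene exons lie within gene bounds
    g <- layoutGenes(lay)
    e <- layoutExons(lay)
    hit <- match(e$gene_id, g$gene_id)
    expect_true(all(GenomicRanges::start(e) >= GenomicRanges::start(g)[hit]))
    expect_true(all(GenomicRanges::end(e) <= GenomicRanges::end(g)[hit]))
})

test_that("identical seeds give identical layouts and variants", {
    p <- smallParams(seed = 11, drLeakRate = 1e-5)
    a <- simulateLayout(p)
    b <- simulateLayout(p)
    expect_identical(as.data.frame(layoutGenes(a)),
                     as.data.frame(layoutGenes(b)))
    expect_identical(as.data.frame(layoutTEs(a)),
                     as.data.frame(layoutTEs(b)))
    expect_identical(as.data.frame(simulateVariants(a, p)),
                     as.data.frame(simulateVariants(b, p)))
    ## different seed changes the realization
    p2 <- smallParams(seed = 12)
    expect_false(identical(as.data.frame(layoutGenes(a)),
                           as.data.frame(layoutGenes(simulateLayout(p2)))))
})

test_that("gene counts fall in the Poisson 99% band of the configured density", {
    p <- SimParams(seed = 5, autosomeLengths = c(CHR4 = 1e6))
    lay <- simulateLayout(p)
    nZ <- sum(GenomeInfoDb::seqnames(layoutGenes(lay)) == "Z")
    band <- qpois(c(0.005, 0.995), lambda = 10 * 75)  # oracle: Poisson quantiles
    expect_gte(nZ, band[1])
    expect_lte(nZ, band[2])
})

test_that("noise-free coverage equals its expectation exactly, by sex and region", {
    p <- smallParams(seed = 2, depthCV = 0, genesPerMb = 1)
    lay <- simulateLayout(p)
    fem <- simulateCoverage(lay, p, "female")
    male <- simulateCoverage(lay, p, "male")
    wz <- trackWindows(fem$Z)
    b <- trueBoundary(lay)
    inDR <- GenomicRanges::start(wz) >= b
    inPAR <- GenomicRanges::end(wz) < b
    expect_true(all(wz$meanDepth[inDR] == 15))
    expect_true(all(wz$meanDepth[inPAR] == 30))
    expect_true(all(trackWindows(fem$CHR4)$meanDepth == 30))
    expect_true(all(trackWindows(male$Z)$meanDepth == 30))
})

test_that("noisy female DR depth averages depthMean/2 within 3 standard errors", {
    p <- SimParams(seed = 9, autosomeLengths = c(CHR4 = 1e6))
    lay <- simulateLayout(p)
    wz <- trackWindows(simulateCoverage(lay, p, "female")$Z)
    inDR <- GenomicRanges::start(wz) >= trueBoundary(lay)
    m <- mean(wz$meanDepth[inDR])
    se <- 15 * 0.08 / sqrt(sum(inDR))   # CLT oracle
    expect_lt(abs(m - 15), 3 * se)
})

test_that("divergence table honors degenerate rate settings", {
    p0 <- smallParams(seed = 3,
                      omegaByClass = c(PAR = 0, DR = 0, CHR4 = 0, CHR5 = 0))
    lay <- simulateLayout(p0)
    div <- simulateDivergence(lay, p0)
    expect_true(all(div$n_subs == 0))
    pS <- smallParams(seed = 3, dsMean = 0)
    div2 <- simulateDivergence(simulateLayout(pS), pS)
    expect_true(all(div2$s_subs == 0))
    expect_true(all(div2$n_subs == 0))
    ## missing class omega is a configuration error
    pBad <- smallParams(seed = 3, omegaByClass = c(PAR = 0.1))
    expect_error(simulateDivergence(simulateLayout(pBad), pBad),
                 "missing")
})

test_that("aggregated omega of simulated tables is calibrated (CLT over replicates)", {
    omegas <- vapply(1:20, function(s) {
        p <- SimParams(seed = s, zLength = 50e6, parFraction = 0.99,
                       autosomeLengths = c(CHR4 = 1e6), genesPerMb = 40,
                       omegaByClass = c(PAR = 0.15, DR = 0.15, CHR4 = 0.15,
                                        CHR5 = 0.15))
        lay <- simulateLayout(p)
        div <- simulateDivergence(lay, p)
        aggregateRates(div[div$class == "PAR", ])$omega
    }, numeric(1))
    se <- sd(omegas) / sqrt(length(omegas))
    expect_lt(abs(mean(omegas) - 0.15), 3 * se)
})

test_that("noise-free expression gives exact dosage ratios and no stray sex bias", {
    p <- smallParams(seed = 4, nbDispersion = 0, libSizeCV = 0,
                     dosageRatioDR = 2, sexbiasFraction = 0)
    lay <- simulateLayout(p)
    se <- simulateExpression(lay, p, 3)
    counts <- SummarizedExperiment::assay(se, "counts")
    rd <- SummarizedExperiment::rowData(se)
    sex <- SummarizedExperiment::colData(se)$sex
    ratio <- rowMeans(counts[, sex == "M"]) / rowMeans(counts[, sex == "F"])
    expect_equal(unname(ratio[rd$regionClass == "DR"]),
                 rep(2, sum(rd$regionClass == "DR")))
    expect_equal(unname(ratio[rd$regionClass != "DR"]),
                 rep(1, sum(rd$regionClass != "DR")))
    expect_true(all(rd$trueSexBias == "none"))
})

test_that("variant simulation respects rates, bands and the DR leak knob", {
    p <- SimParams(seed = 6, zLength = 20e6, parFraction = 0.5,
                   autosomeLengths = c(CHR4 = 1e6), hetRatePar = 1e-4,
                   drLeakRate = 0)
    lay <- simulateLayout(p)
    v <- simulateVariants(lay, p)
    onDR <- GenomeInfoDb::seqnames(v) == "Z" &
        GenomicRanges::start(v) >= trueBoundary(lay)
    expect_equal(sum(onDR), 0)
    nPar <- sum(GenomeInfoDb::seqnames(v) == "Z" & !onDR)
    band <- qpois(c(0.005, 0.995), lambda = 1e-4 * 10e6)  # Poisson oracle
    expect_gte(nPar, band[1])
    expect_lte(nPar, band[2])
    expect_true(all(v$af > 0 & v$af < 1))
    expect_gt(mean(v$af >= 0.2 & v$af <= 0.8), 0.9)
})
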