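test_that("two-segment scan equals brute-force enumeration of breakpoints", {
    for (s in 1:5) {
        set.seed(100 + s)
        n <- sample(20:200, 1)
        x <- c(rnorm(n %/% 2, 1, 0.2), rnorm(n - n %/% 2, 0.5, 0.2))
        sp <- parZ:::.twoSegmentSplit(x)
        ## independent oracle: direct SSE over every breakpoint
        sse <- vapply(seq_len(length(x) - 1), function(k) {
            sum((x[1:k] - mean(x[1:k]))^2) +
                sum((x[(k + 1):length(x)] - mean(x[(k + 1):length(x)]))^2)
        }, numeric(1))
        expect_equal(sp$k, which.min(sse))
        expect_equal(sp$sse, min(sse), tolerance = 1e-10)
    }
})

test_that("noise-free half-coverage step is located exactly", {
    ann <- inferBoundaryFromCoverage(ratioTrack(c(rep(1, 800), rep(0.5, 700))))
    expect_equal(boundaryPosition(ann), 800 * 5e4 + 1)
    expect_false(ann@noDR)
    expect_equal(ann@drMeanRatio, 0.5)
    expect_equal(unname(ann@support), c(800L, 700L))
    expect_equal(sum(IRanges::width(parInterval(ann))), 4e7)
})

test_that("a flat track near 1 reports no DR", {
    set.seed(1)
    ann <- inferBoundaryFromCoverage(ratioTrack(rnorm(100, 1, 0.02)))
    expect_true(ann@noDR)
    expect_true("no-DR" %in% annotationFlags(ann))
    expect_true(is.na(boundaryPosition(ann)))
    expect_equal(sum(IRanges::width(parInterval(ann))), 100 * 5e4)
})

test_that("boundary detection is equivariant under chromosome mirroring", {
    set.seed(21)
    x <- c(rnorm(60, 1, 0.05), rnorm(40, 0.5, 0.05))
    fwd <- inferBoundaryFromCoverage(ratioTrack(x))
    rev <- inferBoundaryFromCoverage(ratioTrack(rev(x)))
    n <- length(x)
    expect_equal(fwd@metadata$k + rev@metadata$k, n)
    expect_equal(boundaryPosition(fwd) - 1,
                 n * 5e4 - (boundaryPosition(rev) - 1))
    expect_equal(sum(IRanges::width(drInterval(fwd))),
                 sum(IRanges::width(drInterval(rev))))
})

test_that("short DR runs and out-of-band means are rejected", {
    ## DR run of 5 windows < minRun 10
    ann <- inferBoundaryFromCoverage(ratioTrack(c(rep(1, 95), rep(0.5, 5))))
    expect_true(ann@noDR)
    ## segment at 0.25 is below the DR acceptance band
    ann2 <- inferBoundaryFromCoverage(
        ratioTrack(c(rep(1, 50), rep(0.25, 50))))
    expect_true(ann2@noDR)
    expect_error(inferBoundaryFromCoverage(ratioTrack(rep(1, 15))),
                 "insufficient")
})

test_that("expression windows average log2 ratios in 20-gene blocks", {
    gr <- data.frame(gene_id = sprintf("g%d", 1:40),
                     start = seq(1e5, 4e6, length.out = 40), ratio = 1)
    ew <- mfExpressionWindows(gr)
    expect_equal(nrow(ew), 2)
    expect_equal(ew$meanLog2, c(0, 0))
    ew2 <- mfExpressionWindows(
        data.frame(gene_id = sprintf("g%d", 1:20),
                   start = 1:20 * 1e5, ratio = 2))
    expect_equal(nrow(ew2), 1)
    expect_equal(ew2$meanLog2, 1)
    ## step of log2(1.5) between windows 5 and 6 for a 100/100 split
    gr3 <- data.frame(gene_id = sprintf("g%d", 1:200),
                      start = 1:200 * 1e4,
                      ratio = c(rep(1, 100), rep(1.5, 100)))
    ew3 <- mfExpressionWindows(gr3)
    expect_equal(ew3$meanLog2[6] - ew3$meanLog2[5], log2(1.5))
    expect_equal(ew3$meanLog2[5], 0)
    ## trailing partial window: kept at >= half size, dropped below
    ew4 <- mfExpressionWindows(
        data.frame(gene_id = sprintf("g%d", 1:30),
                   start = 1:30 * 1e4, ratio = 1))
    expect_equal(nrow(ew4), 2)     # 20 + 10 (kept)
    ew5 <- mfExpressionWindows(
        data.frame(gene_id = sprintf("g%d", 1:25),
                   start = 1:25 * 1e4, ratio = 1))
    expect_equal(nrow(ew5), 1)     # trailing 5 dropped
    expect_error(mfExpressionWindows(data.frame()), "empty")
})

test_that("expression boundary finds the ratio step and honors the floor", {
    ew <- data.frame(window = 1:10,
                     meanLog2 = c(rep(0, 6), rep(0.5, 4)),
                     nGenes = 20,
                     spanStart = (0:9) * 1e6 + 1,
                     spanEnd = (1:10) * 1e6,
                     firstGeneStart = (0:9) * 1e6 + 1)
    ann <- inferBoundaryFromExpression(ew, chromLength = 1e7)
    expect_false(ann@noDR)
    expect_equal(boundaryPosition(ann), 6e6 + 1)
    expect_equal(sum(IRanges::width(drInterval(ann))), 4e6)
    ## all-zero ratios: no DR
    ewFlat <- transform(ew, meanLog2 = 0)
    expect_true(inferBoundaryFromExpression(ewFlat,
                                            chromLength = 1e7)@noDR)
    expect_error(inferBoundaryFromExpression(ew[1:3, ]), "insufficient")
})

test_that("coverage and expression boundaries agree on the same simulation", {
    hits <- 0L
    for (s in 1:10) {
        p <- SimParams(seed = 400 + s, autosomeLengths = c(CHR4 = 20e6))
        lay <- simulateLayout(p)
        tr <- simulateCoverage(lay, p, "female")
        cov <- inferBoundaryFromCoverage(
            normalizeDepth(tr$Z, tr["CHR4"]))
        se <- simulateExpression(lay, p, 3)
        r <- mfLog2Ratios(se)
        rd <- SummarizedExperiment::rowData(se)
        onZ <- rd$chrom[match(r$gene_id, rd$gene_id)] == "Z"
        ew <- mfExpressionWindows(r[onZ, c("gene_id", "start", "ratio")])
        expr <- inferBoundaryFromExpression(ew, chromLength = p@zLength)
        ## agreement within two 50 kb windows plus one 20-gene window span
        geneSpan <- stats::median(diff(ew$firstGeneStart))
        if (!cov@noDR && !expr@noDR &&
            abs(boundaryPosition(cov) - boundaryPosition(expr)) <=
            geneSpan + 2 * 5e4)
            hits <- hits + 1L
    }
    expect_gte(hits, 9L)
})
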