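test_that("interval densities merge overlaps and split across edges", {
    w <- grid50k(2)
    te <- GenomicRanges::GRanges("Z", IRanges::IRanges(1001, 6000))
    expect_equal(intervalDensityWindows(te, w)$density, c(0.1, 0))
    ## duplicated interval is merged, density unchanged
    te2 <- c(te, te)
    expect_equal(intervalDensityWindows(te2, w)$density, c(0.1, 0))
    ## straddling interval splits 60/40 and matches a per-bp oracle
    straddle <- GenomicRanges::GRanges("Z", IRanges::IRanges(47001, 57000))
    d <- intervalDensityWindows(straddle, w)
    expect_equal(d$coveredBp, c(3000, 7000))
    bp <- rep(0, 1e5)                      # per-bp brute force
    bp[47001:57000] <- 1
    expect_equal(d$coveredBp, c(sum(bp[1:5e4]), sum(bp[50001:1e5])))
})

test_that("total covered bp is conserved across random fixtures", {
    for (s in 1:5) {
        set.seed(600 + s)
        n <- 20
        w <- grid50k(n)
        starts <- sample.int(n * 5e4 - 2000, 50)
        iv <- GenomicRanges::GRanges(
            "Z", IRanges::IRanges(starts, starts + sample(50:5000, 50,
                                                          replace = TRUE)))
        iv <- GenomicRanges::restrict(iv, end = n * 5e4)
        d <- intervalDensityWindows(iv, w)
        merged <- GenomicRanges::reduce(iv)
        expect_equal(sum(d$density * GenomicRanges::width(w)),
                     sum(GenomicRanges::width(
                         GenomicRanges::intersect(merged, w))))
    }
})

test_that("intron sizes are exon gaps on the longest transcript", {
    ex <- GenomicRanges::GRanges("Z",
                                 IRanges::IRanges(c(1, 201), c(100, 300)))
    ex$gene_id <- "gA"
    expect_equal(intronSizes(ex), list(gA = 100))
    ## single-exon gene: empty vector
    ex1 <- GenomicRanges::GRanges("Z", IRanges::IRanges(1, 500))
    ex1$gene_id <- "gB"
    expect_equal(intronSizes(ex1), list(gB = numeric(0)))
    ## multi-transcript gene: longest spliced transcript wins
    exT <- GenomicRanges::GRanges(
        "Z", IRanges::IRanges(c(1, 201, 1, 901), c(100, 300, 600, 1000)))
    exT$gene_id <- "gC"
    exT$transcript_id <- c("t1", "t1", "t2", "t2")
    expect_equal(intronSizes(exT), list(gC = 300))   # t2: gap 601..900
    ## overlapping exons: skipped with a warning
    exBad <- GenomicRanges::GRanges("Z",
                                    IRanges::IRanges(c(1, 50), c(100, 200)))
    exBad$gene_id <- "gD"
    expect_warning(out <- intronSizes(exBad), "overlapping")
    expect_length(out, 0)
})

test_that("intron totals match a brute-force gap scan on random gene models", {
    set.seed(77)
    rows <- list()
    expected <- list()
    for (g in 1:50) {
        id <- sprintf("g%02d", g)
        nEx <- sample(1:8, 1)
        lens <- sample(50:300, nEx, replace = TRUE)
        gaps <- if (nEx > 1) sample(40:5000, nEx - 1, replace = TRUE)
                else integer(0)
        starts <- cumsum(c(sample(1:1e6, 1), head(lens, -1) + gaps))
        rows[[g]] <- data.frame(start = starts, end = starts + lens - 1,
                                gene_id = id)
        expected[[id]] <- as.numeric(gaps)
    }
    df <- do.call(rbind, rows)
    ex <- GenomicRanges::GRanges("Z", IRanges::IRanges(df$start, df$end))
    ex$gene_id <- df$gene_id
    got <- intronSizes(ex)
    for (id in names(expected))
        expect_equal(got[[id]], expected[[id]])
})

test_that("rank-sum contrasts report medians, p-values and direction", {
    same <- regionFeatureTest(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$p_value, 1)
    expect_equal(same$direction, "ns")
    ## fully separated small groups: p matches the exact rank-sum value
    sep <- regionFeatureTest(c(1, 2, 3), c(101, 102, 103))
    expect_equal(sep$p_value,
                 wilcox.test(c(1, 2, 3), c(101, 102, 103))$p.value)
    expect_equal(sep$p_value, 0.1)   # 2 * 1/choose(6,3)
    ## all values tied across groups
    tied <- regionFeatureTest(c(5, 5), c(5, 5))
    expect_equal(tied$p_value, 1)
    expect_error(regionFeatureTest(1, c(1, 2)), "at least 2")
})

test_that("a shifted feature distribution is detected with high power", {
    hits <- 0L
    for (s in 1:10) {
        set.seed(700 + s)
        par <- rlnorm(500, log(1950), 0.6)   # PAR introns 1.3x autosomal
        auto <- rlnorm(500, log(1500), 0.6)
        r <- regionFeatureTest(log10(par), log10(auto))
        if (r$p_value < 0.05 && r$direction == "higher") hits <- hits + 1L
    }
    expect_gte(hits, 8L)
})

test_that("chromosome-size correlations match the closed form", {
    expect_equal(chromosomeSizeCorrelation(1:5 * 1e6, 1:5 * 0.01)$r, 1)
    expect_equal(chromosomeSizeCorrelation(1:5 * 1e6, 5:1 * 0.01)$r, -1)
    set.seed(31)
    sizes <- runif(10, 10e6, 100e6)
    vals <- 0.1 + sizes / 1e9 + rnorm(10, 0, 0.01)
    got <- chromosomeSizeCorrelation(sizes, vals)
    ## textbook formula oracle
    r <- sum((sizes - mean(sizes)) * (vals - mean(vals))) /
        sqrt(sum((sizes - mean(sizes))^2) * sum((vals - mean(vals))^2))
    expect_equal(got$r, r)
    expect_equal(got$p, cor.test(sizes, vals)$p.value)
    expect_error(chromosomeSizeCorrelation(c(1, 2), c(1, 2)), "at least 3")
    expect_error(chromosomeSizeCorrelation(1:5, rep(1, 5)), "variance")
    sp <- chromosomeSizeCorrelation(sizes, vals, method = "spearman")
    expect_equal(sp$r, cor(sizes, vals, method = "spearman"))
})
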