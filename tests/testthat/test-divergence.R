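test_that("outlier filter removes only genes strictly above the threshold", {
    rec <- makeRecords(n_sites = rep(1000, 3), s_sites = rep(500, 3),
                       n_subs = c(999, 1000, 1001), s_subs = rep(500, 3))
    expect_message(out <- filterDivergenceOutliers(rec), "1 outlier")
    expect_equal(out$gene_id, c("g001", "g002"))
    expect_equal(attr(out, "removed"), 1L)
    ## exactly at the threshold is retained; empty input passes through
    expect_equal(nrow(filterDivergenceOutliers(rec[0, ])), 0)
})

test_that("aggregate rates are exact ratio-of-sums, not means of ratios", {
    one <- makeRecords(200, 100, 5, 10)
    r <- aggregateRates(one)
    expect_equal(r$ds, 0.1)
    expect_equal(r$dn, 0.025)
    expect_equal(r$omega, 0.25)
    ## unequal site counts: ratio-of-sums differs from per-gene mean
    two <- makeRecords(n_sites = c(300, 900), s_sites = c(100, 300),
                       n_subs = c(30, 9), s_subs = c(10, 3))
    r2 <- aggregateRates(two)
    expect_equal(r2$ds, 13 / 400)
    expect_equal(r2$dn, 39 / 1200)
    expect_false(isTRUE(all.equal(r2$dn, mean(two$dn))))
    ## zero nonsynonymous substitutions -> omega 0; zero synonymous -> NA
    expect_equal(aggregateRates(makeRecords(100, 50, 0, 5))$omega, 0)
    undef <- aggregateRates(makeRecords(100, 50, 3, 0))
    expect_true(is.na(undef$omega))
    expect_false(undef$omegaDefined)
})

test_that("aggregate rates equal a brute-force sum on random tables", {
    for (s in 1:5) {
        set.seed(s)
        n <- sample(2:50, 1)
        rec <- makeRecords(n_sites = runif(n, 100, 2000),
                           s_sites = runif(n, 50, 600),
                           n_subs = rpois(n, 10), s_subs = rpois(n, 20))
        r <- aggregateRates(rec)
        expect_equal(r$dn, sum(rec$n_subs) / sum(rec$n_sites))
        expect_equal(r$ds, sum(rec$s_subs) / sum(rec$s_sites))
        expect_equal(r$omega, (sum(rec$n_subs) / sum(rec$n_sites)) /
                              (sum(rec$s_subs) / sum(rec$s_sites)))
    }
})

test_that("bootstrap CI degenerates to the point estimate without variation", {
    one <- makeRecords(200, 100, 5, 10)
    ci <- bootstrapCI(one, "omega", nBoot = 100, seed = 3)
    expect_equal(as.numeric(ci), c(0.25, 0.25))
    same <- makeRecords(rep(200, 5), rep(100, 5), rep(5, 5), rep(10, 5))
    expect_equal(as.numeric(bootstrapCI(same, "omega", nBoot = 100,
                                        seed = 3)),
                 c(0.25, 0.25))
})

test_that("bootstrap is seed-reproducible and brackets the estimate", {
    set.seed(42)
    rec <- makeRecords(n_sites = runif(200, 300, 3000),
                       s_sites = runif(200, 100, 1000),
                       n_subs = rpois(200, 15), s_subs = rpois(200, 30))
    a <- bootstrapCI(rec, "omega", nBoot = 200, seed = 7)
    b <- bootstrapCI(rec, "omega", nBoot = 200, seed = 7)
    expect_identical(a, b)
    est <- attr(a, "estimate")
    expect_lt(a[["low"]], est)
    expect_gt(a[["high"]], est)
    expect_false(identical(a, bootstrapCI(rec, "omega", nBoot = 200,
                                          seed = 8)))
})

test_that("permutation p is 1 for identical groups and bounded below", {
    rec <- makeRecords(rep(200, 4), rep(100, 4), c(5, 6, 7, 8),
                       c(10, 11, 12, 13))
    r <- permutationTest(rec, rec, nPerm = 99, seed = 1)
    expect_equal(r$observed_difference, 0)
    expect_equal(r$p_value, 1)
    expect_equal(r$direction, "ns")
    ## add-one bound
    set.seed(5)
    rec2 <- makeRecords(runif(6, 100, 1000), runif(6, 50, 400),
                        rpois(6, 30), rpois(6, 10))
    r2 <- permutationTest(rec2[1:3, ], rec2[4:6, ], nPerm = 1000, seed = 2)
    expect_gte(r2$p_value, 1 / 1001)
    expect_lte(r2$p_value, 1)
    ## seed reproducibility
    expect_identical(r2, permutationTest(rec2[1:3, ], rec2[4:6, ],
                                         nPerm = 1000, seed = 2))
})

test_that("exhaustive permutation equals independent enumeration for 3 vs 3", {
    set.seed(9)
    rec <- makeRecords(runif(6, 100, 1000), runif(6, 50, 400),
                       rpois(6, 25), rpois(6, 12))
    r <- permutationTest(rec[1:3, ], rec[4:6, ], exhaustive = TRUE)
    expect_equal(r$n_permutations, choose(6, 3))
    ## oracle: enumerate every split by hand
    stat <- function(d) aggregateRates(d)$omega
    tObs <- stat(rec[1:3, ]) - stat(rec[4:6, ])
    splits <- utils::combn(6, 3)
    tAll <- apply(splits, 2, function(i)
        stat(rec[i, ]) - stat(rec[-i, ]))
    expect_equal(r$p_value, mean(abs(tAll) >= abs(tObs) - 1e-12))
    expect_equal(r$observed_difference, tObs)
})

test_that("faster-Z report assembles rates and contrasts, omitting empty classes", {
    set.seed(11)
    n <- 60
    rec <- makeRecords(runif(n, 500, 2000), runif(n, 150, 700),
                       rpois(n, 20), rpois(n, 25),
                       class = rep(c("PAR", "CHR4", "CHR5"), each = 20))
    expect_warning(rep1 <- fasterZReport(rec, nPerm = 99, nBoot = 99,
                                         seed = 1),
                   "DR")
    expect_setequal(rep1$rates$group, c("CHR4+CHR5", "Z", "PAR"))
    expect_false("DR" %in% rep1$rates$group)
    expect_true(all(rep1$comparisons$p_value > 0 &
                    rep1$comparisons$p_value <= 1))
    ## boundary robustness mode drops genes near the boundary
    rec$start <- rep(seq(1e6, 20e6, length.out = 20), 3)
    rep2 <- fasterZReport(rec, nPerm = 49, nBoot = 49, seed = 1,
                          boundaryExclude = 5e6, boundary = 10e6)
    nNear <- sum(rec$class == "PAR" & abs(rec$start - 10e6) <= 5e6)
    expect_equal(rep2$rates$n_genes[rep2$rates$group == "PAR"],
                 20 - nNear)
})

test_that("free-ratio output parsing reconstructs substitution counts", {
    ## synthetic codeml-style main output (standard branch-table layout)
    mlc <- c("Some header", "",
             " branch          t       N       S   dN/dS      dN      dS  N*dN  S*dS",
             "   6..7       0.034  4035.1  1325.9  0.0591  0.0017  0.0280   6.9  37.1",
             "   7..1       0.012  4035.1  1325.9  0.1200  0.0010  0.0083   4.0  11.0",
             "", "tree length = 1.2")
    tf <- tempfile(fileext = ".mlc")
    writeLines(mlc, tf)
    b <- parsePamlFreeRatio(tf)
    expect_equal(nrow(b), 2)
    expect_equal(b$N[1], 4035.1)
    expect_equal(b$n_subs[1], 6.9)
    one <- parsePamlFreeRatio(tf, branch = "7..1")
    expect_equal(one$s_subs, 11.0)
    expect_error(parsePamlFreeRatio(tf, branch = "9..9"), "not found")
    ## records assembled across files
    tf2 <- tempfile(fileext = ".mlc")
    writeLines(mlc, tf2)
    rec <- pamlRecordsFromFiles(c(geneA = tf, geneB = tf2),
                                branch = "7..1",
                                classes = c(geneA = "PAR", geneB = "DR"))
    expect_equal(rec$gene_id, c("geneA", "geneB"))
    expect_equal(rec$dn, rec$n_subs / rec$n_sites)
    unlink(c(tf, tf2))
})
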