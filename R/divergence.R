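## Chromosome-wide divergence statistics. A "divergence table" is a
## data.frame with one row per gene and columns gene_id, chrom, class,
## n_sites, s_sites, n_subs, s_subs, dn, ds (plus optionally start).

.DIV_COLS <- c("gene_id", "chrom", "class", "n_sites", "s_sites",
               "n_subs", "s_subs", "dn", "ds")

.checkRecords <- function(records) {
    need <- c("n_sites", "s_sites", "n_subs", "s_subs")
    if (!all(need %in% names(records)))
        stop("divergence records need columns: ",
             paste(need, collapse = ", "))
    invisible(records)
}

#' Remove substitution-count outliers
#'
#' Drops genes whose total substitution count (nonsynonymous plus
#' synonymous) strictly exceeds `maxTotalSubs`; such genes are typically
#' alignment artifacts and would dominate the chromosome-wide sums. The
#' default threshold is 1,500 substitutions; a gene at exactly the
#' threshold is retained.
#'
#' @param records divergence table (see [simulateDivergence()]).
#' @param maxTotalSubs numeric threshold (strict inequality).
#' @return The filtered table; the number of rows removed is reported via
#'   `message()` and stored in `attr(, "removed")`.
#' @export
filterDivergenceOutliers <- function(records, maxTotalSubs = 1500) {
    .checkRecords(records)
    tot <- records$n_subs + records$s_subs
    drop <- tot > maxTotalSubs
    if (any(drop))
        message(sum(drop), " outlier gene(s) removed (>",
                maxTotalSubs, " substitutions)")
    out <- records[!drop, , drop = FALSE]
    attr(out, "removed") <- sum(drop)
    out
}

#' Aggregate per-gene substitutions into chromosome-wide rates
#'
#' Computes dS as the ratio of total synonymous substitutions to total
#' synonymous sites across all genes, dN analogously, and omega = dN/dS.
#' This ratio-of-sums estimator is effectively a length-weighted average
#' of per-gene values and is not the mean of per-gene ratios. When the
#' summed synonymous substitutions are zero, omega is undefined and
#' returned as NA with `omegaDefined = FALSE`.
#'
#' @param records divergence table rows for one region class.
#' @return Named list: `dn`, `ds`, `omega`, `nGenes`, `omegaDefined`.
#' @examples
#' rec <- data.frame(n_sites = 200, s_sites = 100, n_subs = 5, s_subs = 10)
#' aggregateRates(rec)   # dS 0.1, dN 0.025, omega 0.25
#' @export
aggregateRates <- function(records) {
    .checkRecords(records)
    if (!nrow(records)) stop("no records to aggregate")
    sS <- sum(records$s_sites)
    nS <- sum(records$n_sites)
    if (sS <= 0 || nS <= 0) stop("total site counts must be > 0")
    ds <- sum(records$s_subs) / sS
    dn <- sum(records$n_subs) / nS
    defined <- ds > 0
    list(dn = dn, ds = ds,
         omega = if (defined) dn / ds else NA_real_,
         nGenes = nrow(records), omegaDefined = defined)
}

.aggStat <- function(records, statistic) {
    r <- aggregateRates(records)
    r[[statistic]]
}

#' Percentile bootstrap confidence interval for aggregated rates
#'
#' Resamples genes with replacement, recomputes the ratio-of-sums
#' statistic per replicate with [aggregateRates()], and returns the
#' percentile interval (BCa available via `type`). Driven by the `boot`
#' package; deterministic under `seed`.
#'
#' @param records divergence table rows for one region class.
#' @param statistic `"omega"`, `"dn"` or `"ds"`.
#' @param nBoot bootstrap replicates (default 1,000).
#' @param level confidence level (default 0.95).
#' @param seed integer RNG seed.
#' @param type `"perc"` (default) or `"bca"`.
#' @return Named numeric `c(low, high)` with attributes `estimate` and
#'   `nBoot`.
#' @export
bootstrapCI <- function(records, statistic = c("omega", "dn", "ds"),
                        nBoot = 1000, level = 0.95, seed = 1,
                        type = c("perc", "bca")) {
    statistic <- match.arg(statistic)
    type <- match.arg(type)
    .checkRecords(records)
    est <- .aggStat(records, statistic)
    ## matrix fast path: the per-replicate statistic is the same
    ## ratio-of-sums aggregateRates computes, on column sums of the
    ## resampled rows
    m <- as.matrix(records[, c("n_sites", "s_sites", "n_subs", "s_subs")])
    bt <- .withSeed(seed, boot::boot(
        data = m,
        statistic = function(d, i) {
            s <- colSums(d[i, , drop = FALSE])
            switch(statistic,
                   dn = s[3] / s[1],
                   ds = s[4] / s[2],
                   omega = if (s[4] > 0)
                       (s[3] / s[1]) / (s[4] / s[2]) else NA_real_)
        },
        R = nBoot))
    vals <- bt$t[, 1]
    if (mean(is.na(vals)) > 0.5)
        stop(sprintf(
            "statistic '%s' undefined in %.0f%% of bootstrap replicates",
            statistic, 100 * mean(is.na(vals))))
    if (stats::var(vals, na.rm = TRUE) == 0 || length(unique(vals)) == 1) {
        ci <- rep(vals[1], 2)    # degenerate resampling distribution
    } else {
        bc <- boot::boot.ci(bt, conf = level,
                            type = if (type == "perc") "perc" else "bca")
        ci <- if (type == "perc") bc$percent[4:5] else bc$bca[4:5]
    }
    structure(c(low = ci[1], high = ci[2]), estimate = est, nBoot = nBoot)
}

#' Permutation test for a rate difference between two gene sets
#'
#' Tests whether the aggregated statistic (omega by default) of a region
#' differs from that of a reference set by permuting region/reference
#' labels over the pooled genes, preserving group sizes. The two-sided
#' p-value uses the add-one estimator
#' p = (1 + #\{|T_perm| >= |T_obs|\}) / (nPerm + 1), which is never 0 and
#' never below 1/(nPerm+1). With `exhaustive = TRUE` all distinct label
#' assignments are enumerated instead and the p-value is exact.
#'
#' @param regionRecords,referenceRecords divergence table rows of the two
#'   groups.
#' @param statistic `"omega"`, `"dn"` or `"ds"`.
#' @param nPerm number of random permutations (ignored when exhaustive).
#' @param seed integer RNG seed.
#' @param exhaustive enumerate all splits (feasible for small groups).
#' @param alpha significance level for the faster/slower call.
#' @return One-row data.frame: `statistic`, `observed_difference`,
#'   `p_value`, `n_permutations`, `direction` (faster/slower/ns),
#'   `n_region`, `n_reference`, `seed`.
#' @export
permutationTest <- function(regionRecords, referenceRecords,
                            statistic = c("omega", "dn", "ds"),
                            nPerm = 1000, seed = 1, exhaustive = FALSE,
                            alpha = 0.05) {
    statistic <- match.arg(statistic)
    .checkRecords(regionRecords)
    .checkRecords(referenceRecords)
    if (!nrow(regionRecords) || !nrow(referenceRecords))
        stop("both groups must be non-empty")
    cols <- c("n_sites", "s_sites", "n_subs", "s_subs")
    pool <- as.matrix(rbind(regionRecords[, cols],
                            referenceRecords[, cols]))
    n1 <- nrow(regionRecords)
    n <- nrow(pool)
    statFromSums <- function(sums1, sums2) {
        ## sums columns: n_sites, s_sites, n_subs, s_subs
        v1 <- switch(statistic,
                     dn = sums1[3] / sums1[1],
                     ds = sums1[4] / sums1[2],
                     omega = (sums1[3] / sums1[1]) / (sums1[4] / sums1[2]))
        v2 <- switch(statistic,
                     dn = sums2[3] / sums2[1],
                     ds = sums2[4] / sums2[2],
                     omega = (sums2[3] / sums2[1]) / (sums2[4] / sums2[2]))
        v1 - v2
    }
    tot <- colSums(pool)
    s1 <- colSums(pool[seq_len(n1), , drop = FALSE])
    tObs <- statFromSums(s1, tot - s1)
    if (exhaustive) {
        splits <- utils::combn(n, n1)
        tPerm <- apply(splits, 2, function(i) {
            si <- colSums(pool[i, , drop = FALSE])
            statFromSums(si, tot - si)
        })
        exceed <- abs(tPerm) >= abs(tObs) - 1e-12
        p <- mean(exceed)
        nEff <- ncol(splits)
    } else {
        tPerm <- .withSeed(seed, vapply(seq_len(nPerm), function(b) {
            i <- sample.int(n, n1)
            si <- colSums(pool[i, , drop = FALSE])
            statFromSums(si, tot - si)
        }, numeric(1)))
        exceed <- abs(tPerm) >= abs(tObs) - 1e-12
        exceed[is.na(exceed)] <- TRUE   # undefined replicates: conservative
        p <- (1 + sum(exceed)) / (nPerm + 1)
        nEff <- nPerm
    }
    direction <- if (!is.finite(tObs) || p >= alpha) "ns"
                 else if (tObs > 0) "faster" else "slower"
    data.frame(statistic = statistic, observed_difference = tObs,
               p_value = p, n_permutations = nEff, direction = direction,
               n_region = n1, n_reference = n - n1, seed = seed,
               stringsAsFactors = FALSE)
}

#' Faster-Z / faster-PAR / faster-DR report
#'
#' For each of the Z chromosome (PAR + DR pooled), the PAR and the DR,
#' aggregates dN, dS and omega with bootstrap confidence intervals and
#' runs two-sided permutation tests against the pooled size-matched
#' autosomal reference (chr4 + chr5 by default). A boundary-robustness
#' mode drops Z-linked genes within `boundaryExclude` bp of the PAR/DR
#' boundary before recomputing, guarding against misassigned genes in the
#' transition zone.
#'
#' @param records divergence table with a `class` column (and `start` if
#'   the robustness mode is used).
#' @param reference character, region classes pooled as the autosomal
#'   reference.
#' @param statistics statistics to report.
#' @param nPerm,nBoot,level,seed resampling controls.
#' @param boundaryExclude optional distance in bp; with `boundary`, drops
#'   PAR/DR genes whose start lies within this distance of the boundary.
#' @param boundary PAR/DR boundary position in bp (required with
#'   `boundaryExclude`).
#' @param maxTotalSubs outlier threshold applied before any calculation.
#' @return List with data.frames `rates` (one row per group, point
#'   estimates and CIs) and `comparisons` (one row per group x statistic).
#' @export
fasterZReport <- function(records, reference = c("CHR4", "CHR5"),
                          statistics = c("dn", "ds", "omega"),
                          nPerm = 1000, nBoot = 1000, level = 0.95,
                          seed = 1, boundaryExclude = NULL,
                          boundary = NULL, maxTotalSubs = 1500) {
    stopifnot("class" %in% names(records))
    records <- filterDivergenceOutliers(records, maxTotalSubs)
    if (!is.null(boundaryExclude)) {
        if (is.null(boundary) || !"start" %in% names(records))
            stop("boundary robustness mode needs 'boundary' and a ",
                 "'start' column")
        onZ <- records$class %in% c("PAR", "DR")
        near <- onZ & abs(records$start - boundary) <= boundaryExclude
        records <- records[!near, , drop = FALSE]
    }
    ref <- records[records$class %in% reference, , drop = FALSE]
    if (!nrow(ref)) stop("no genes in the reference class(es)")
    groups <- list(Z = c("PAR", "DR"), PAR = "PAR", DR = "DR")
    rates <- list()
    comparisons <- list()
    refRates <- aggregateRates(ref)
    refRow <- data.frame(group = paste(reference, collapse = "+"),
                         n_genes = refRates$nGenes, dn = refRates$dn,
                         ds = refRates$ds, omega = refRates$omega,
                         stringsAsFactors = FALSE)
    for (s in statistics) {
        ci <- bootstrapCI(ref, s, nBoot = nBoot, level = level, seed = seed)
        refRow[[paste0(s, "_low")]] <- ci[["low"]]
        refRow[[paste0(s, "_high")]] <- ci[["high"]]
    }
    rates[["reference"]] <- refRow
    for (g in names(groups)) {
        sub <- records[records$class %in% groups[[g]], , drop = FALSE]
        if (!nrow(sub)) {
            warning("no genes in class ", g, "; row omitted")
            next
        }
        rr <- aggregateRates(sub)
        row <- data.frame(group = g, n_genes = rr$nGenes, dn = rr$dn,
                          ds = rr$ds, omega = rr$omega,
                          stringsAsFactors = FALSE)
        for (s in statistics) {
            ci <- bootstrapCI(sub, s, nBoot = nBoot, level = level,
                              seed = seed)
            row[[paste0(s, "_low")]] <- ci[["low"]]
            row[[paste0(s, "_high")]] <- ci[["high"]]
            cmp <- permutationTest(sub, ref, statistic = s, nPerm = nPerm,
                                   seed = seed)
            cmp <- cbind(data.frame(group = g,
                                    reference = refRow$group,
                                    stringsAsFactors = FALSE), cmp)
            comparisons[[paste(g, s)]] <- cmp
        }
        rates[[g]] <- row
    }
    list(rates = do.call(rbind, c(rates, list(make.row.names = FALSE))),
         comparisons = do.call(rbind, c(comparisons,
                                        list(make.row.names = FALSE))))
}

#' Read / write a per-gene divergence table
#'
#' Plain TSV with columns `gene_id`, `chrom`, `class`, `n_sites`,
#' `s_sites`, `n_subs`, `s_subs`, `dn`, `ds` (plus any extras, e.g.
#' `start`).
#'
#' @param path file path.
#' @return `readDivergenceTable()`: the data.frame.
#' @export
readDivergenceTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    missing <- setdiff(.DIV_COLS, names(df))
    if (length(missing))
        stop("divergence table is missing column(s): ",
             paste(missing, collapse = ", "))
    df
}

#' @rdname readDivergenceTable
#' @param records divergence table to write.
#' @export
writeDivergenceTable <- function(records, path) {
    write.table(records, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Parse a free-ratio branch-model output file
#'
#' Extracts the per-branch substitution table (columns branch, t, N, S,
#' dN/dS, dN, dS, N*dN, S*dS) printed by codeml's free-ratio model, from
#' which per-gene substitution counts are reconstructed as N*dN and S*dS.
#'
#' @param path path to a codeml main output (mlc) file.
#' @param branch optional branch label (e.g. `"7..8"`) to select one row.
#' @return data.frame with columns `branch`, `t`, `N`, `S`, `dNdS`, `dN`,
#'   `dS`, `n_subs` (= N*dN), `s_subs` (= S*dS).
#' @export
parsePamlFreeRatio <- function(path, branch = NULL) {
    lines <- readLines(path, warn = FALSE)
    hdr <- grep("^\\s*branch\\s+t\\s+N\\s+S\\s+dN/dS", lines)
    if (!length(hdr))
        stop("no free-ratio branch table found in ", path)
    rows <- list()
    i <- hdr[1] + 1
    while (i <= length(lines)) {
        ln <- trimws(lines[i])
        if (nzchar(ln) && grepl("^\\d+\\.\\.\\d+", ln)) {
            f <- strsplit(ln, "\\s+")[[1]]
            if (length(f) >= 9)
                rows[[length(rows) + 1]] <- data.frame(
                    branch = f[1], t = as.numeric(f[2]),
                    N = as.numeric(f[3]), S = as.numeric(f[4]),
                    dNdS = as.numeric(f[5]), dN = as.numeric(f[6]),
                    dS = as.numeric(f[7]), n_subs = as.numeric(f[8]),
                    s_subs = as.numeric(f[9]), stringsAsFactors = FALSE)
        } else if (!nzchar(ln) && length(rows)) {
            break
        }
        i <- i + 1
    }
    if (!length(rows)) stop("branch table in ", path, " is empty")
    df <- do.call(rbind, rows)
    if (!is.null(branch)) {
        df <- df[df$branch == branch, , drop = FALSE]
        if (!nrow(df)) stop("branch ", branch, " not found in ", path)
    }
    df
}

#' Build divergence records from parsed free-ratio outputs
#'
#' @param files named character vector of codeml output paths (names are
#'   gene ids).
#' @param branch branch label to extract for every gene.
#' @param classes named character vector gene id -> region class.
#' @param chrom optional named chromosome vector.
#' @return A divergence table (one row per gene).
#' @export
pamlRecordsFromFiles <- function(files, branch, classes,
                                 chrom = NULL) {
    rows <- lapply(names(files), function(g) {
        b <- parsePamlFreeRatio(files[[g]], branch = branch)
        data.frame(gene_id = g,
                   chrom = if (is.null(chrom)) NA_character_
                           else chrom[[g]],
                   class = classes[[g]],
                   n_sites = b$N, s_sites = b$S,
                   n_subs = b$n_subs, s_subs = b$s_subs,
                   dn = b$n_subs / b$N, ds = b$s_subs / b$S,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
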