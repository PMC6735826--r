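#' Simulate a per-gene divergence table
#'
#' Emulates the per-gene substitution summaries obtained by parsing
#' free-ratio branch-model output: synonymous sites are proportional to CDS
#' length (0.24 of coding sites; nonsynonymous 0.76), a per-gene expected
#' dS is drawn from a gamma distribution with mean `dsMean` and shape
#' `dsShape`, synonymous substitutions are Poisson with mean
#' `dS * s_sites`, and nonsynonymous substitutions are Poisson with mean
#' `omega_class * dS * n_sites`. The aggregated ratio-of-sums dN/dS of a
#' class is therefore consistent for the configured `omegaByClass` value.
#'
#' @inheritParams simulateCoverage
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `class`,
#'   `n_sites`, `s_sites`, `n_subs`, `s_subs`, `dn`, `ds`.
#' @examples
#' p <- SimParams(seed = 3, zLength = 5e6, autosomeLengths = c(CHR4 = 5e6))
#' head(simulateDivergence(simulateLayout(p), p))
#' @export
simulateDivergence <- function(layout, params) {
    stopifnot(is(layout, "GenomeLayout"))
    g <- layout@genes
    cls <- as.character(g$regionClass)
    omega <- params@omegaByClass[cls]
    if (any(is.na(omega)))
        stop("omegaByClass is missing value(s) for class(es): ",
             paste(unique(cls[is.na(omega)]), collapse = ", "))
    .withSeed(.stageSeed(params, "divergence"), {
        L <- pmax(g$cdsLength, 300)
        sSites <- 0.24 * L
        nSites <- 0.76 * L
        dsG <- if (params@dsMean > 0)
            rgamma(length(g), shape = params@dsShape,
                   rate = params@dsShape / params@dsMean)
        else rep(0, length(g))
        sSubs <- rpois(length(g), dsG * sSites)
        nSubs <- rpois(length(g), omega * dsG * nSites)
        data.frame(
            gene_id = g$gene_id,
            chrom = as.character(GenomeInfoDb::seqnames(g)),
            start = GenomicRanges::start(g),
            class = cls,
            n_sites = nSites, s_sites = sSites,
            n_subs = as.numeric(nSubs), s_subs = as.numeric(sSubs),
            dn = nSubs / nSites, ds = sSubs / sSites,
            stringsAsFactors = FALSE)
    })
}

#' Simulate an RNA-seq count matrix with sample metadata
#'
#' Generates negative-binomial counts for `nRepsPerSex` male and female
#' replicates. DR genes have male mean expression `dosageRatioDR` times the
#' female mean (incomplete dosage compensation); a `sexbiasFraction` of
#' PAR/autosomal genes carry genuine sex-biased expression at
#' `sexbiasFold`, with random direction. Per-sample library-size factors
#' are lognormal with CV `libSizeCV` (exactly equal when 0). With
#' `nbDispersion = 0` the counts equal their expectations exactly
#' (noise-free diagnostic mode; values need not be integers).
#'
#' @inheritParams simulateCoverage
#' @param nRepsPerSex integer >= 1, biological replicates per sex.
#' @param tissue tissue label recorded in the sample metadata.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, `rowData` columns `gene_id`, `regionClass`, `length`
#'   (spliced length used for TPM), `trueSexBias`; and `colData` columns
#'   `sample_id`, `sex`, `tissue`, `replicate`, `libFactor`.
#' @export
simulateExpression <- function(layout, params, nRepsPerSex = 3L,
                               tissue = "tissue1") {
    stopifnot(is(layout, "GenomeLayout"), nRepsPerSex >= 1)
    g <- layout@genes
    cls <- as.character(g$regionClass)
    .withSeed(.stageSeed(params, "expression"), {
        n <- length(g)
        mu <- rlnorm(n, params@exprMeanlog, params@exprSdlog)
        maleFactor <- ifelse(cls == "DR", params@dosageRatioDR, 1)
        bias <- rep("none", n)
        eligible <- which(cls != "DR")
        if (params@sexbiasFraction > 0 && length(eligible)) {
            sel <- eligible[runif(length(eligible)) < params@sexbiasFraction]
            dirMale <- runif(length(sel)) < 0.5
            bias[sel] <- ifelse(dirMale, "male", "female")
            maleFactor[sel][dirMale] <- params@sexbiasFold
            maleFactor[sel][!dirMale] <- 1 / params@sexbiasFold
        }
        nS <- 2L * nRepsPerSex
        sex <- rep(c("M", "F"), each = nRepsPerSex)
        lib <- if (params@libSizeCV > 0) {
            sdlog <- sqrt(log(1 + params@libSizeCV^2))
            rlnorm(nS, -sdlog^2 / 2, sdlog)
        } else rep(1, nS)
        mean_mat <- outer(mu, lib)
        isM <- sex == "M"
        mean_mat[, isM] <- mean_mat[, isM] * maleFactor
        counts <- if (params@nbDispersion > 0)
            matrix(rnbinom(n * nS, mu = mean_mat,
                           size = 1 / params@nbDispersion),
                   nrow = n)
        else mean_mat
        ids <- sprintf("%s_%s%d", tissue, sex, rep(seq_len(nRepsPerSex), 2))
        dimnames(counts) <- list(g$gene_id, ids)
        SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = counts),
            rowData = S4Vectors::DataFrame(
                gene_id = g$gene_id,
                chrom = as.character(GenomeInfoDb::seqnames(g)),
                start = GenomicRanges::start(g),
                regionClass = cls,
                length = g$splicedLength, trueSexBias = bias),
            colData = S4Vectors::DataFrame(
                sample_id = ids, sex = sex, tissue = tissue,
                replicate = rep(seq_len(nRepsPerSex), 2),
                libFactor = lib, row.names = ids))
    })
}

#' Simulate coding sequences with class-specific GC3
#'
#' Builds an in-frame CDS per gene whose third codon positions are G or C
#' with the class-specific probability `gc3ByClass`, along with a per-gene
#' background nucleotide-frequency vector standing in for intron-derived
#' composition (used by the background-corrected ENC). Stop codons are
#' avoided by construction. Sequence content is random: these are
#' statistical stand-ins, not evolved sequences.
#'
#' @inheritParams simulateCoverage
#' @return A list with elements `cds` (a named
#'   [Biostrings::DNAStringSet]) and `background` (matrix of A/C/G/T
#'   frequencies, one row per gene).
#' @export
simulateCodingSequences <- function(layout, params) {
    stopifnot(is(layout, "GenomeLayout"))
    g <- layout@genes
    cls <- as.character(g$regionClass)
    gc3 <- params@gc3ByClass[cls]
    gc3[is.na(gc3)] <- mean(params@gc3ByClass)
    .withSeed(.stageSeed(params, "cds"), {
        seqs <- character(length(g))
        for (i in seq_along(g)) {
            nc <- max(100L, g$cdsLength[i] %/% 3L)
            p1 <- sample(c("A", "C", "G", "T"), nc, replace = TRUE)
            p2 <- sample(c("A", "C", "G", "T"), nc, replace = TRUE)
            gcHit <- runif(nc) < gc3[i]
            p3 <- ifelse(gcHit,
                         sample(c("G", "C"), nc, replace = TRUE),
                         sample(c("A", "T"), nc, replace = TRUE))
            codons <- paste0(p1, p2, p3)
            stopc <- codons %in% c("TAA", "TAG", "TGA")
            ## repair stops without disturbing the GC3 target: TAA/TAG have
            ## A/G third base -> swap first base to C; TGA likewise
            codons[stopc] <- paste0("C", substr(codons[stopc], 2, 3))
            seqs[i] <- paste(codons, collapse = "")
        }
        cds <- Biostrings::DNAStringSet(seqs)
        names(cds) <- g$gene_id
        bgGC <- pmin(0.8, pmax(0.2, 0.8 * gc3))
        background <- cbind(A = (1 - bgGC) / 2, C = bgGC / 2,
                            G = bgGC / 2, T = (1 - bgGC) / 2)
        rownames(background) <- g$gene_id
        list(cds = cds, background = background)
    })
}
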