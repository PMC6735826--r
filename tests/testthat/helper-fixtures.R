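## Shared fixtures: small simulation configurations and hand-built tables.

## compact genome for fast unit tests
smallParams <- function(seed = 1L, ...) {
    SimParams(seed = seed, zLength = 10e6,
              autosomeLengths = c(CHR4 = 10e6, CHR5 = 8e6), ...)
}

## divergence table built directly (no simulation)
makeRecords <- function(n_sites, s_sites, n_subs, s_subs,
                        class = "PAR", gene_id = NULL) {
    n <- length(n_sites)
    data.frame(
        gene_id = if (is.null(gene_id)) sprintf("g%03d", seq_len(n))
                  else gene_id,
        chrom = "Z", class = rep_len(class, n),
        n_sites = n_sites, s_sites = s_sites,
        n_subs = n_subs, s_subs = s_subs,
        dn = n_subs / n_sites, ds = s_subs / s_sites,
        stringsAsFactors = FALSE)
}

## window track with given per-window normalized ratios (50 kb grid)
ratioTrack <- function(ratios, chrom = "Z", windowSize = 5e4) {
    n <- length(ratios)
    len <- n * windowSize
    si <- GenomeInfoDb::Seqinfo(chrom, len)
    starts <- seq(1, len, by = windowSize)
    w <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(starts,
                                                 starts + windowSize - 1),
                                seqinfo = si)
    w$meanDepth <- 30 * ratios
    w$coveredBases <- windowSize
    w$gcFraction <- NA_real_
    w$normalizedRatio <- ratios
    WindowTrack(w)
}

## variants GRanges from vectors
makeVariants <- function(chrom, pos, af, seqlengths = NULL) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
    gr$af <- af
    if (!is.null(seqlengths)) {
        GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
        GenomeInfoDb::seqlengths(gr) <- seqlengths
    }
    gr
}

## fixed 50 kb window grid
grid50k <- function(n, chrom = "Z") {
    starts <- seq(1, n * 5e4, by = 5e4)
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(starts, starts + 5e4 - 1))
}

## random in-frame CDS of n codons, avoiding stop codons
randomCds <- function(nCodons, seed = 1) {
    set.seed(seed)
    codons <- names(Biostrings::GENETIC_CODE)
    codons <- codons[Biostrings::GENETIC_CODE != "*"]
    paste(sample(codons, nCodons, replace = TRUE), collapse = "")
}
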