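## Codon-usage statistics: GC3s and the effective number of codons (ENC),
## optionally corrected for background nucleotide composition.

## synonymous-family table from the standard genetic code: amino acids
## grouped with their codons, excluding Met, Trp and stops. The 6-fold
## amino acids (Leu, Ser, Arg) are kept as single 6-fold families.
.codonFamilies <- local({
    gc <- Biostrings::GENETIC_CODE
    aa <- gc[!(gc %in% c("M", "W", "*"))]
    split(names(aa), aa)
})
.familySizes <- vapply(.codonFamilies, length, integer(1))
## redundancy-class composition of the standard code: 9 two-fold,
## 1 three-fold, 5 four-fold, 3 six-fold families
.CLASS_COUNT <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)

.splitCodons <- function(cds) {
    s <- toupper(as.character(cds))
    if (nchar(s) %% 3 != 0)
        stop("CDS length must be divisible by 3")
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

#' GC content at synonymous third codon positions (GC3s)
#'
#' Fraction of third-position G or C among codons belonging to synonymous
#' families. Codons for Met (ATG) and Trp (TGG), stop codons, and codons
#' containing N are excluded, following the codonW convention. GC3s serves
#' as a proxy for GC-biased gene conversion and hence recombination rate.
#'
#' @param cds an in-frame coding sequence (character or
#'   [Biostrings::DNAString]); length must be divisible by 3.
#' @return Numeric fraction in \[0, 1\].
#' @examples
#' gc3s("GGCGGG")   # two Gly codons, both G-ending -> 1
#' gc3s("GGAGGT")   # A/T-ending -> 0
#' @export
gc3s <- function(cds) {
    codons <- .splitCodons(cds)
    codons <- codons[!grepl("N", codons, fixed = TRUE)]
    syn <- codons[codons %in% unlist(.codonFamilies)]
    if (!length(syn))
        stop("GC3s undefined: no codons from synonymous families")
    third <- substring(syn, 3, 3)
    mean(third %in% c("G", "C"))
}

## Wright's codon homozygosity for one family's counts (n >= 2):
## F = (n * sum(p^2) - 1) / (n - 1)
.familyF <- function(counts) {
    n <- sum(counts)
    p <- counts / n
    (n * sum(p^2) - 1) / (n - 1)
}

## background-corrected homozygosity (chi-square deviation from codon
## frequencies expected under the background nucleotide composition):
## F = (X^2 + n - m) / (m * (n - 1)); reduces to Wright's F when the
## expected frequencies are uniform
.familyFBackground <- function(counts, expected) {
    n <- sum(counts)
    m <- length(counts)
    e <- expected / sum(expected)
    chi2 <- sum((counts - n * e)^2 / (n * e))
    (chi2 + n - m) / (m * (n - 1))
}

## expected within-family codon frequencies from background base
## frequencies (named A/C/G/T vector)
.expectedCodonFreqs <- function(codons, background) {
    background <- background / sum(background)
    vapply(codons, function(cd) {
        prod(background[strsplit(cd, "")[[1]]])
    }, numeric(1))
}

#' Effective number of codons (ENC)
#'
#' Wright's codon-usage-bias statistic,
#' `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, where `Fk` is the mean codon
#' homozygosity of the k-fold redundancy class. ENC ranges from 20 (one
#' codon per amino acid, maximal bias) to 61 (uniform usage); the result
#' is clamped to that range. With `background` supplied, each family's
#' homozygosity is replaced by a chi-square-based deviation from the codon
#' frequencies expected under the background nucleotide composition
#' (typically estimated from the gene's introns), which removes the
#' contribution of local base composition to apparent codon bias.
#'
#' Families observed fewer than twice are excluded from their class mean;
#' a class with no estimable family borrows the mean of the adjacent
#' classes (the conventional fallback for a missing three-fold class).
#'
#' @param cds an in-frame coding sequence (character or
#'   [Biostrings::DNAString]).
#' @param background optional named A/C/G/T frequency vector enabling the
#'   background-corrected estimator.
#' @return ENC value in \[20, 61\].
#' @export
enc <- function(cds, background = NULL) {
    codons <- .splitCodons(cds)
    codons <- codons[!grepl("N", codons, fixed = TRUE)]
    fVals <- numeric(0)
    fClass <- numeric(0)
    for (aa in names(.codonFamilies)) {
        fam <- .codonFamilies[[aa]]
        counts <- vapply(fam, function(cd) sum(codons == cd), numeric(1))
        n <- sum(counts)
        if (n < 2) next    # family not estimable
        f <- if (is.null(background)) .familyF(counts)
             else .familyFBackground(counts,
                                     .expectedCodonFreqs(fam, background))
        fVals <- c(fVals, f)
        fClass <- c(fClass, length(fam))
    }
    if (!length(fVals))
        stop("ENC undefined: no estimable codon family")
    classMeans <- vapply(c(2, 3, 4, 6), function(k) {
        v <- fVals[fClass == k]
        if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    names(classMeans) <- c("2", "3", "4", "6")
    ## borrow adjacent classes for a missing class mean
    for (i in which(is.na(classMeans))) {
        adj <- c(i - 1, i + 1)
        adj <- adj[adj >= 1 & adj <= 4]
        v <- classMeans[adj]
        v <- v[!is.na(v)]
        if (!length(v)) v <- classMeans[!is.na(classMeans)]
        classMeans[i] <- mean(v)
    }
    classMeans <- pmax(classMeans, 1e-8)
    encVal <- 2 + .CLASS_COUNT["2"] / classMeans["2"] +
        .CLASS_COUNT["3"] / classMeans["3"] +
        .CLASS_COUNT["4"] / classMeans["4"] +
        .CLASS_COUNT["6"] / classMeans["6"]
    unname(min(61, max(20, encVal)))
}
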