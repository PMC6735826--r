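---
title: "Methods: annotating and testing partially differentiated Z chromosomes"
author: "parZ package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and testing partially differentiated Z chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parZ)
```

## The scientific problem

Birds are female-heterogametic (males ZZ, females ZW). In most birds the W
chromosome has degenerated, leaving the Z hemizygous in females except for
a small pseudoautosomal region (PAR) that still recombines in both sexes.
Ratites and tinamous are the outstanding exception: several of them retain
very large PARs after >100 Myr, so a single Z chromosome is part
pseudoautosomal and part differentiated region (DR, the portion whose W
homolog has decayed). This package implements the analyses such a system
requires:

1. **Region annotation.** Locate the PAR/DR boundary from female
   sequencing depth (the DR is hemizygous in females, so female depth
   halves), from male/female expression ratios (without global dosage
   compensation DR genes are expressed higher in males), and verify it
   with female heterozygous-SNP density (a hemizygous DR has none).
2. **Faster-Z testing.** Compare chromosome-wide dN/dS of the Z, PAR and
   DR against size-matched autosomes with bootstrap confidence intervals
   and permutation tests.
3. **Efficacy-of-selection proxies.** Contrast GC3s, codon-usage bias
   (ENC), TE density and intron sizes between regions, and correlate them
   with chromosome size.
4. **Dosage compensation and sex bias.** Quantify M/F expression ratios
   by region and test for enrichment of sex-biased genes.

A seeded synthetic-data generator produces every input with known ground
truth, so each stage is verifiable without external data.

## Boundary detection as a changepoint problem

The field's informal rule — the boundary is where a half-coverage pattern
starts to appear — is operationalized here as an exhaustive two-segment
least-squares changepoint on windowed, autosome-normalized depth ratios:
the breakpoint `k` minimizes the summed within-segment squared error, and
the segment whose mean is nearer 0.5 is the DR candidate. The candidate is
accepted only when its mean lies in `[0.35, 0.65]` and it spans at least
10 windows (`minRun`); a PAR segment outside `[0.8, 1.2]` raises a flag
but does not invalidate the call. These bands make the rule explicit,
testable, and robust to isolated aberrant windows. The reported boundary
is the start of the first window of the right-hand segment; because
nothing inside a window localizes the transition further, the window width
(50 kb by default) is the resolution of the estimate.

Windowing follows standard practice: 50 kb fixed windows, window mean
taken over covered bases only, and windows with under 5 kb of covered
sequence discarded (sparse assembly windows produce unstable means). Depth
is normalized by the median autosomal window depth; optional GC correction
divides each window instead by the median autosomal depth of its 2% GC
bin. GC correction is off by default — the depth signal (a factor of two)
dwarfs typical GC trends, which field practice notes but does not correct.

The expression-based variant applies the same changepoint scan to mean
log2 M/F ratios in consecutive windows of 20 genes, accepting a DR whose
segment mean is at least 0.2 log2 units. Twenty-gene windows are the
package default; published figures in this area have used both 10- and
20-gene windows, so the width is a parameter. Per-gene ratios use
mean-across-replicate TPM with a 0.01 pseudocount.

SNP verification classifies the annotation by the ratio of DR to PAR
median per-window heterozygote counts (allele frequencies 0.2–0.8,
inclusive): `consistent` below 0.05, `elevated-DR` between 0.05 and 0.95
(residual heterozygosity, the signature of W-derived reads mismapping
onto a degenerating DR), and `ambiguous` at 0.95 or above (no contrast
between segments — the data cannot support the annotation) or when the
PAR itself shows no heterozygosity. The thresholds are deliberately
generous: the flag is a diagnostic, not an adjudication.

## Divergence statistics

Per-gene substitution summaries (nonsynonymous and synonymous
substitutions and sites, as produced by parsing free-ratio branch-model
output) are aggregated as **ratios of sums**: `dS = sum(s_subs) /
sum(s_sites)` over all genes of a region, `dN` analogously, and
`omega = dN/dS`. This is effectively a length-weighted average of
per-gene values and is deliberately not the mean of per-gene ratios,
which is unstable when `s_subs` is small. Genes with more than 1,500
total substitutions (summed across both types; the strict inequality and
the summing convention are package decisions where practice is silent)
are removed as alignment artifacts before any calculation.

Confidence intervals resample genes with replacement (1,000 replicates,
percentile interval via the `boot` package; BCa available behind a flag,
since the interval type is not standardized in this literature).
Permutation tests shuffle region/reference labels over the pooled genes,
preserving group sizes, and use the add-one two-sided estimator
`p = (1 + #{|T'| >= |T|}) / (nPerm + 1)`, which cannot return zero. An
exhaustive mode enumerates all label splits for small groups and is used
to validate the sampled version. Labels are permuted without stratifying
by gene length; the aggregated statistic is already length-weighted, and
a length-stratified alternative would test a subtly different null.

The faster-Z report contrasts Z (PAR + DR), PAR and DR against chromosome
4 plus chromosome 5 pooled — the autosomes size-matched to a ~75 Mb Z —
for dN, dS and omega, with a robustness mode that drops genes within a
configurable distance of the inferred boundary (guarding against
newly-differentiated genes misassigned to the PAR). Calls of
"faster"/"slower" use alpha = 0.05.

## Codon-usage statistics

GC3s is the fraction of third-position G/C among codons of synonymous
families, excluding Met, Trp, stop codons and codons containing N (the
codonW convention). ENC is Wright's estimator
`2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` with per-family homozygosity
`F = (n * sum(p^2) - 1) / (n - 1)`, six-fold families kept whole, stop
codons excluded, families observed fewer than twice dropped from their
class mean, and a missing class mean borrowed from adjacent classes
(Wright's convention for the three-fold class). Values are clamped to
[20, 61]. The background-corrected variant replaces `F` by
`(X^2 + n - m) / (m(n - 1))`, where `X^2` measures deviation from codon
frequencies expected under a background nucleotide composition (from
intron sequence); with a uniform background this reduces exactly to
Wright's `F`, which the test suite asserts.

## Expression analyses

TPM is the count/length rate scaled to one million per sample. M/F ratios
are computed per gene from mean TPM by sex; genes under 1 TPM in both
sexes are dropped. Class summaries report both medians and means (the
summary statistic is not standardized in this literature). Log2 ratios
are median-centered on the autosomal classes before summarizing: when a
fifth of the transcriptome (the DR) shifts between sexes, per-sample
normalization deflates every other gene's apparent ratio by several
percent, and autosomal centering removes that compositional artifact. A
DR median log2 ratio strictly inside (0, 1) raises the
partial-dosage-compensation flag.

Sex-biased genes are called by a simple negative-binomial Wald test:
median-of-ratios size factors, a parametric mean-dispersion trend
`a0 + a1/mean` fitted to per-gene moment estimates, each gene tested at
the trend dispersion unless its own estimate exceeds twice the trend (an
upward-only outlier guard), normal reference, Benjamini-Hochberg
correction at 5% FDR. This is a documented stand-in for a full
differential-expression package, kept deliberately small; the design was
chosen on simulation evidence (log-shrinkage toward the trend without a
floor was anticonservative under the null; a t reference was calibrated
but needlessly weak) and the test suite checks null false-discovery
control, power at 4-fold changes, and agreement of fold-change estimates
with DESeq2 on identical data. Pipelines with access to the original
tool can supply its calls instead wherever a calls table is accepted.
Enrichment of sex-biased genes in PAR, DR or the whole Z relative to
autosomes uses Fisher's exact test on the 2x2 biased/unbiased x
region/autosome table, both directions separately.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume, at
the study conditions: a 75 Mb Z with a single PAR/DR boundary at 40 Mb,
autosomes of 97 Mb (chr4) and 63 Mb (chr5), 50 kb windows, female depth
30 with lognormal multiplicative noise at CV 0.08 (depth cannot be
negative, hence lognormal) and half depth in the DR, optional linear GC
trend (off by default), genes placed uniformly at 10 per Mb with 2–12
exons and class-specific lognormal intron sizes, TE intervals at
class-specific densities (higher on the Z classes than autosomes, as
observed in this system), per-gene dS gamma-distributed with mean 0.1,
Poisson substitution counts with equal dN/dS of 0.15 in all classes (the
no-faster-Z null typical of large-PAR paleognaths), negative-binomial
expression counts with dispersion 0.05 and a DR male/female ratio of 1.4
(the middle of the observed 1.19–1.68 range of partial dosage
compensation), genuinely sex-biased genes optional and off by default,
female heterozygous SNPs at 1e-4 per bp on diploid sequence with
Beta(8, 8) allele frequencies, and a `drLeakRate` knob that plants
spurious DR heterozygotes to emulate W-read mismapping. Two
noise-free diagnostic modes exist: `depthCV = 0` makes depth exactly its
expectation, and `nbDispersion = 0` makes counts exactly their means.

Where no value is stated by the study conditions, defaults are what a
genomicist would call realistic for a bird genome (gene density ~10/Mb,
TE content 8–14%, intron medians 1.4–2 kb, GC3s 0.45–0.56 decreasing
with chromosome size) and were fixed once. Coding sequences for the
codon-usage features are random in-frame codons with class-specific
third-position GC — statistical stand-ins, not evolved sequences
(sequence-level evolution is out of scope), and the generator says so in
its documentation.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: read-level artifacts (mapping bias,
duplicates, GC curvature beyond a linear trend), assembly gaps and
misassemblies, scaffold ordering errors, evolutionary strata with
distinct ages inside the DR, tissue-dependent expression, correlated
genes, or W gametolog retention. Real analyses must still inspect the
depth and SNP tracks.

## Numerical and design choices

- Coordinates are 1-based closed in memory throughout, the native
  convention of the range containers used; each file format's own
  convention (BED/bedGraph half-open 0-based, GFF3/VCF 1-based) is
  handled at the I/O edge by the format libraries.
- The changepoint scan is O(n) via cumulative sums and is asserted equal
  to brute-force enumeration; ties in the scan are broken toward the
  leftmost minimizer (`which.min`), and mirror-equivariance is tested.
- The boundary position is reported as the first base of the right-hand
  segment's first window; window width is the stated uncertainty.
- Add-one permutation p-values keep p >= 1/(nPerm + 1); undefined
  statistics in a permutation replicate count as exceedances
  (conservative).
- Bootstrap replicates recompute the ratio-of-sums on resampled rows via
  column sums (an exact algebraic shortcut for the same statistic);
  degenerate resampling distributions return a zero-width interval at
  the point estimate.
- All simulators draw from per-stage seed streams derived from the
  master seed, so any subset of simulators, called in any order, is
  bit-reproducible; pipeline reports serialize to byte-identical JSON
  across reruns (timestamps are never embedded).
- Problem sizes in the test suite (a 75 Mb three-chromosome genome,
  100-replicate boundary studies, 500-replicate permutation calibration,
  300-replicate bootstrap coverage at 2,000 genes) were chosen as the
  smallest designs whose Monte-Carlo error is comfortably inside the
  asserted bands.

## Known limitations

- Only a single PAR/DR boundary is modelled; chromosomes with two PARs
  or recent DR expansions (the ambiguous kiwi-like configuration) will
  fit one changepoint and flag inconsistencies rather than segment
  further. Recursive segmentation was considered and deferred; the flags
  expose the ambiguity, the package does not adjudicate it.
- The sex-bias caller is a stand-in: it has no GLM machinery for
  covariates (tissue, batch), no independent filtering, and no
  moderated fold-change shrinkage.
- Projection of boundaries between species by synteny is a documented
  manual step, not code.
- The correlation between chromosome size and features defaults to
  Pearson on per-chromosome summaries (Spearman available); with few
  chromosomes these correlations are descriptive, not inferential.
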