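---
title: "Methods: multi-center WGS quality comparison and rare-LoF prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-center WGS quality comparison and rare-LoF prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgsbakeoff)
```

This vignette documents the models, parameter choices and numerical
conventions behind `wgsbakeoff`, and states explicitly what the synthetic
data used by the test suite does and does not demonstrate about real
sequencing data.

## Study design the package assumes

The pipeline targets a "bake-off" design: the same small cohort sequenced
independently by several centers at ~30x with 150 bp paired-end reads.
The cohort layout is eight affected cases plus the two healthy parents of
one case, so exactly one parent–offspring trio is available for
Mendelian-error checks, and the remaining seven cases are unrelated.
`cohort_design()` encodes this; all role-dependent steps (Mendel checks,
parental filters, case-specific duplications) read roles from that table
rather than from sample names.

## Raw-read QC from the k-mer spectrum

All raw-read QC is alignment-free and derives from the canonical 23-mer
multiplicity spectrum (`kmer_spectrum()`), plus two direct read scans.

**Error boundary.** The spectrum of a genuine sequencing run is bimodal:
an error tail at low multiplicity and a signal peak near the k-mer-space
coverage. We take the boundary *m* as the first strict local minimum
scanning upward in multiplicity. This is standard k-mer-spectrum
practice; no published rule fixes it more precisely, and the estimates
are insensitive to the exact valley position because counts there are
small. A spectrum with no signal peak above *m* (or one whose global
mode is multiplicity 1 with no interior minimum) is rejected as
uninterpretable rather than silently producing a coverage number.

**Non-repetitive window.** Mean and standard deviation of coverage are
weighted moments of the spectrum over multiplicities in (*m*, 2*M* − *m*],
*M* the spectrum mode above *m*. The window is symmetric about the mode,
so the repeat tail (multiplicities ≫ mode, from duplicated sequence)
is excluded — this operationalizes "coverage estimated over
non-repetitive regions" without an alignment.

**Space conversion and error-loss correction.** A read of length *L*
contributes *L* − *k* + 1 k-mers, so k-mer coverage understates base
coverage by (*L* − *k* + 1)/*L*; we convert by the reciprocal. A second,
less obvious bias matters at realistic error rates: a k-mer instance only
lands in the signal peaks if all 23 of its bases are correct, which
happens with probability (1 − *e*)^23 — at *e* = 1% that is already a
21% deficit. The error k-mer fraction *f* (instances at multiplicity
≤ *m* over all instances) estimates exactly the lost share, so all
coverage figures are additionally scaled by 1/(1 − *f*). The correction
is exact when errors are uniform, and a no-op on error-free data. Without
it the estimator cannot recover a 30x truth within 10% at 1% base error;
with it the package's coverage-recovery tests pass without any tuning.
The variance coefficient (sd/mean) is scale-free and unaffected by both
conversions.

**Gate.** `qc_gate()` applies the four inclusion criteria with inclusive
comparisons exactly as stated (≥ 0.95 clean pairs, ≥ 0.95 retained
pairs, ≤ 0.15 error k-mers, coverage mode ≥ 27); a read with mean Phred
exactly 20 is retained, a site with QUAL exactly 40 is *not* (the variant
filters use strict inequalities — see below). These boundary semantics
are asserted verbatim in the test suite.

**Adapters.** Adapter presence is detected (exact substring, plus
adapter prefixes of ≥ 12 bp at the read 3' end to catch partial
read-through) but never trimmed: at the observed sub-percent occurrence
rates trimming changes nothing downstream and would complicate
reconciliation against the simulator's injection log.

## Center statistics

`kruskal_by_center()` and `block_anova()` wrap `stats::kruskal.test()`
and `stats::aov()` respectively. The blocked ANOVA treats center as the
fixed factor of interest and the individual sample as a blocking factor
on the complete-case subset (samples measured in every center). For a
balanced design this F-test is identical to the one obtained from a
mixed model with a random sample effect, so no mixed-model machinery is
used. A numerically zero center sum of squares is reported as F = 0,
p = 1 rather than as the ratio of two rounding errors. Pairwise center
comparisons report the paired *t* interval and a paired Wilcoxon p-value
side by side, since with 6–10 shared samples either may be preferred and
no single choice is canonical. No multiple-testing correction is applied
across metrics, matching how such QC comparisons are usually reported.

## Genome masks

**Mappability.** The low-mappability mask asks, for each position, what
fraction of the 151-mers covering it are unique, masking positions below
0.5. "Unique" is exact canonical-sequence uniqueness over the whole
reference (the canonical form is the lexicographic minimum of a window
and its reverse complement). A real pipeline would define uniqueness via
an aligner's unique-mapping flag, which tolerates mismatches; exact
matching is a stricter, fully deterministic proxy that an independent
brute-force substring-count oracle can verify position by position — the
test suite does exactly that on references up to a few kb, including
planted duplications.

**Low complexity.** Union of (a) maximal homopolymer runs ≥ 7 bp,
(b) DUST-flagged windows (window 64 bp, step 32 bp, triplet score
Σc(c−1)/2 / (k−1) with threshold 2.0 — the classic DUST statistic), and
(c) an optional external BED of repeat/microsatellite annotations, since
full repeat annotation is the job of dedicated external tools and is
accepted as input rather than re-implemented. Every interval gets 10 bp
flanks, clipped to sequence bounds, before merging. Coordinates are
0-based half-open internally and in BED; conversion to 1-based happens
only at the VCF boundary.

## Variant normalization and filters

Normalization splits multiallelic records (re-coding each sample's
allele indices against the split-out allele), left-aligns indels through
repeat tracts by the standard trim/extend algorithm, and drops records
whose reference allele contradicts the reference sequence (logged, not
silently discarded). Normalization is idempotent; the tests verify it
against an independent "apply-the-variant-then-re-derive-the-minimal-
representation" oracle on random indel representations.

The SNV hard filter applies QUAL > 40, GQ > 20, DP > 10, SP < 20 — all
strict, exactly as printed. Because calls are jointly genotyped across
all samples, the per-sample FORMAT thresholds default to *every*
non-missing sample passing; an `any`-sample mode is provided because the
convention is genuinely ambiguous. The long-indel chain filters by
caller PASS flag, normalization success, |len(ref) − len(alt)| in
[20, 100] (both ends inclusive), QUAL > 40, minimum per-sample GQ > 20
(minimum over non-missing samples), and exclusion from the combined
low-complexity/low-mappability mask. Every filter emits a ledger row
(`filter_ledger()`), and the tests assert the chain conserves counts.

## Copy number and segmental duplications

Window copy number is 2·depth/mean(control depth) per sample, making the
control mean exactly 2; control windows are those outside known or
called duplications and masked regions. "Correction for dispersion" in
the duplication definition is not formulaic in the read-depth CNV
literature, so it is operationalized the standard way: the detection
threshold is mean + *k*·sd of control CN with *k* = 3 by default
(configurable). The minimum genomic span defaults to 10 kbp; a 1 kbp
alternative exists in the literature on this analysis style, so the span
is an explicit knob rather than a hard-coded constant, with the larger,
more conservative value as default.

Merging: flagged windows adjacent in the profile merge; a genomic gap
where windows are absent (masked sequence) is bridged up to one window's
worth of bp; a *measured* below-threshold window always breaks a run.
The distinction matters — bridging across measured baseline windows lets
isolated noise windows attach to a true duplication and degrades the
recovered interval, which is how the rule was first diagnosed.

Case-specific duplications are regions covered by a called duplication
in ≥ 2 case samples (configurable down to 1, since "shared" could be
read either way) and sharing no base with any duplication called in a
healthy sample.

## Replication-based LoF prioritization

The filter chain runs in a fixed order, attributing each exclusion to
the first failing step so the ledger is reproducible: (1) high-confidence
LoF; (2) every *present* population MAF ≤ 0.01 — absence from a database
is evidence of rarity, so missing MAFs pass (a variant absent from the
major databases can still be a legitimate hit); (3) ≥ 2 alternative
alleles among cases, or a homozygous case — the homozygous clause is
implemented as bypassing the count rule, though a single homozygote
already contributes 2 alleles, so the bypass only matters for
non-default thresholds; (4) zero parental alternative alleles, relaxed
to ≤ 2 when the trio child carries the allele (a carrier parent of a
carrier child is expected transmission, not contradiction); (5) genotype
replication concordance ≥ 0.98, computed per variant as the fraction of
concordant genotype comparisons over all unordered replicate pairs and
all individuals, *pooled* — a single individual contributes at most
`choose(R, 2)` pairs, far too few to assess a 98% threshold alone.

## What the synthetic data emulates — and what it does not

The generator (`sim_config()` and friends) reproduces the statistical
structure each stage consumes, with defaults fixed at the study
conditions: 150 bp pairs at 30x with a 400 bp insert; adapter
read-through at 0.6% of pairs, N-containing pairs at 0.2%, low-quality
reads (mean ~Q12 vs ~Q35, a two-state model — only the mean-Q20 gate
matters downstream) at 1%; per-base substitution errors at 0.1%
(configurable up to the 1–2% used in recovery tests); an
8-case + 2-parent cohort; replicate call sets corrupted per genotype at
1% (a corrupted genotype is resampled uniformly from the other two
biallelic diploid genotypes — the simplest symmetric model, as no error
model for inter-center discordance is established); trio Mendel errors
at 0.4%; and one planted causal insertion whose carrier pattern is the
published-style one — child homozygous, mother heterozygous, father
reference, one unrelated case heterozygous.

Two generator decisions deserve emphasis. First, the planted causal
variant is *exempt* from replicate corruption: it emulates a validated
variant that replicated across all centers, and its carrier pattern is
definitional truth the prioritization stage must recover, not a random
draw. Second, every corruption is logged, and the tests reconcile
observed discordance, adapter, quality and Mendel counts *exactly*
against those logs rather than only statistically.

Deliberately not emulated: haplotype structure and linkage
disequilibrium, indel-specific error profiles, per-cycle quality decay,
GC-coverage bias, and real repeat families (the planted duplication and
homopolymer are minimal exemplars). Consequently, passing tests show the
*computations* are correct under the assumed models — they do not show
that, e.g., the mappability proxy matches an aligner on a real genome,
or that 1% uniform genotype corruption matches real inter-center error
structure.

## Problem sizes and numerical conventions

The test suite and acceptance script run at deliberately small scales
chosen to exercise every code path with stable statistics: 20–200 kb
genomes, 5,000 pairs per QC run, 2,000–5,000 variant sites, 10-seed
grids for recovery properties, 1,000–2,000 null simulations for test
calibration. Tolerances follow the quantity: exact equality for counts
and boundary semantics, 3–4 standard errors for binomial reconciliation,
10% for coverage recovery at 30x, Jaccard ≥ 0.9 for interval recovery.
Genotypes are stored as unphased allele-index pairs (`a1`, `a2`, missing
as `NA`); the 1/2 coding of published genotype tables (1 = reference
allele, 2 = insertion allele) maps to 0/1 at I/O. Ties in the
Kruskal–Wallis test use the standard correction; an all-equal metric
short-circuits to H = 0, p = 1.

## Known limitations

* The mappability mask is stricter than aligner-based uniqueness; near-
  identical (but not exact) repeats are not masked.
* Coverage estimation assumes a unimodal signal peak; heavily
  contaminated or very low-coverage libraries are rejected rather than
  estimated.
* `replicate_concordance()` treats replicates symmetrically; it does not
  model center-specific error rates.
* The depth simulator draws window depths independently (no spatial
  autocorrelation), so duplication-recovery results are optimistic about
  breakpoint precision.
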