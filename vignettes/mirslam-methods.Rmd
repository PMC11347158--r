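---
title: "Quantifying newly synthesized miRNAs from T>C conversion sequencing"
author: "mirslam authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying newly synthesized miRNAs from T>C conversion sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirslam)
```

## The measurement model

Metabolic labeling with 4-thiouridine (4SU) marks RNA synthesized during
the labeling window. After chemical derivatization, incorporated 4SU is
read as C by reverse transcriptase, so each molecule made during the
window carries a random subset of its uridines as T>C conversions in the
sequenced read. For a miRNA whose molecules are "new" with fraction $f$
in a given condition, and whose incorporated uridines convert with
probability $p$ (the product of 4SU incorporation and chemical conversion
efficiency), the probability that a read shows C at a reference-T
position is

$$\Pr(C) \;=\; f\,p\,(1-e) \;+\; (1 - f\,p)\,\frac{e}{3},$$

where $e$ is the per-base sequencing error rate and errors substitute
uniformly among the three alternative bases (an error moves a converted
base *off* C, hence the $1-e$ factor). With $f \approx 0.2$ and
$p \approx 0.02$ this sits in the sub-percent regime, which is why the
design needs a no-4SU background condition: the observed rate in labeled
samples is only a few-fold above the error floor $e/3$.

The study design is three conditions with replicates: **Control** (no
4SU; measures the background conversion level), **DMSO** (4SU + vehicle)
and **PlaB** (4SU + drug; here an SF3B1 splicing inhibitor). The
estimand per miRNA is the background-subtracted **synthesis ratio**

$$\text{ratio} \;=\;
\frac{\bar r_{\text{PlaB}} - \bar r_{\text{Control}}}
     {\bar r_{\text{DMSO}} - \bar r_{\text{Control}}},$$

with $\bar r$ the replicate-mean conversion rate. Because both numerator
and denominator subtract the same background and share the per-miRNA
labeling efficiency $p$ and U content, the ratio cancels those nuisance
factors and estimates the relative change in the new-molecule fraction —
1 means synthesis unchanged, 0 fully suppressed. Ratios are deliberately
not clamped: sampling noise and genuinely increased synthesis can push
them above 1, and truncation would bias group summaries.

Replicates are aggregated as the mean of per-replicate rates (each
replicate weighted equally), not as a pooled-count rate; the pooled
variant would weight replicates by sequencing depth. The labeling test
below, in contrast, pools counts, because its exact null distribution is
defined on counts.

## Pipeline stages and their parameters

**Trimming** (`trim_params()`). Libraries are NEXTflex-style: 4
randomized nt on each side of the insert, then the 3' adapter, and the
fixed read length guarantees adapter read-through. Cleanup removes the
adapter (longest read suffix matching an adapter prefix, minimum overlap
3, mismatch rate ≤ 0.1 — common trimmer defaults), clips 4 nt from the 3'
end, discards anything still longer than 30 nt, clips 4 nt from the 5'
end, and discards inserts shorter than 16 nt. The order matters and is
preserved from the tools the protocol stacks together: the length cap
applies after the 3' clip but before the 5' clip. The 16 nt minimum is
our choice (no stated minimum exists); it admits the shortest annotated
mature miRNAs while excluding adapter dimers. Reads without a detectable
adapter are discarded by default — a genuine miRNA-length insert must
read through into adapter — with a `keep_no_adapter` escape hatch.

**Feature index** (`build_index()`). Quantification is against mature
miRNA sequences rather than a whole genome: for mature-miRNA counting
the two agree, and it keeps the package self-contained. Identical mature
sequences collapse into one counting unit, which is also how multi-locus
miRNAs are retained (they are counted once, not discarded as
multimappers). Each unit's template is its mature sequence plus a 3 nt
genomic flank, so templated end-variant reads (isomiRs with shifted
ends) still find a placement.

**Conversion-aware assignment** (`align_params()`). Each insert is
compared ungapped at every allowed offset of every template. A
template-T read as C counts as a match for scoring but is recorded as a
conversion; ties between units with different sequences leave the read
unassigned (identical sequences were already collapsed, so any remaining
tie is genuinely ambiguous). Reads are kept at ≤ 3 non-conversion
mismatches (`nm_max`) and mapping integrity ≥ 0.95 (`integrity_min`).

Whether the integrity fraction penalizes conversions is genuinely
ambiguous in the published pipeline, so both variants sit behind
`conv_in_integrity`. The default (TRUE) counts conversions as
mismatches, matching the behavior of a mapper identity filter — which is
exactly what makes the integrity filter dominate the mismatch filter for
~22 nt reads: a single non-conversion mismatch gives 20/22 ≈ 0.91 <
0.95. The consequence, verified in the test suite, is a small downward
bias in estimated conversion rates: reads carrying ≥ 2 conversions fail
0.95 integrity and are dropped, which at $f = 0.2$, $p = 0.02$ removes
about 0.2% of reads and depresses the rate by roughly $5\times10^{-4}$.
The non-penalizing variant (FALSE) is unbiased and is the one under
which the package's rate-recovery checks run at 3-binomial-SE tolerance.
The synthesis *ratio* is nearly immune to the choice because the bias
largely cancels between numerator and denominator.

**SNP masking** (`call_snp_mask()`). A heterozygous T/C SNP at a miRNA
position produces a ~50% "conversion" signal that would swamp the
sub-percent labeling signal. Positions with C fraction ≥ 0.4 at pooled
coverage ≥ 10 are masked from both numerator and denominator; 0.4
catches diploid heterozygous loci while genuine labeling stays an order
of magnitude below it. Masking uses only the no-4SU control samples —
a deliberate difference from per-sample masking: calling SNPs on labeled
samples could in principle mask genuinely hyper-labeled positions.
The scope is switchable by passing any sample set to `call_snp_mask()`.

**Dataset filters** (`filter_params()`). The *Initial* dataset requires
CPM > 100 in **every** sample (read strictly: per replicate, not per
condition mean) and membership in a curated high-confidence list, since
many catalogued miRNAs are questionable annotations. The *labeling test*
asks whether the DMSO conversion rate exceeds the Control rate, on
pooled counts, with the exact one-sided conditional (hypergeometric)
test on the 2×2 table of conversions vs non-conversions by condition,
BH-adjusted across units; the published analysis used a
count-model comparison from a differential-expression package here, and
the exact test is our fully specified, reproducible stand-in. A unit is
labeled when `p_adj < alpha` (0.05). The source description of this
threshold reads "> 0.05" in one place, which contradicts "significantly
labelled"; we implement `<` and record the direction in the output
metadata (`alpha_direction` attribute) rather than deciding silently.
The *Final* dataset additionally requires the mean PlaB rate to be at
least the mean Control rate; a unit exactly at the boundary is kept
(only strictly-below-background units are excluded). These filters
guarantee `bg_sub_dmso > 0` and `bg_sub_plab ≥ 0`, so ratios are finite
and non-negative by construction — `synthesis_ratio()` treats a
violation as a broken contract and errors rather than emitting NaN.

**Context analyses.** Units whose multiple loci disagree in genomic
context (or are annotated mixed) are excluded from context groupings but
stay in the ratio table. Group comparisons (intronic vs exonic, lncRNA
vs protein-coding host, each cis-motif present vs absent) use Welch's
two-sample t-test by default, with Mann–Whitney behind a flag because
ratio distributions are right-skewed; the five groupings are reported
without family-wise correction, mirroring how such panels are usually
presented, and each panel reports median and 10th/90th percentiles.
TSS-distance association uses Spearman correlation (Pearson by flag);
fully tied inputs return $\rho = 0$, $p = 1$ by convention. The PCA
attached to the fit is QC only: samples as observations on the centered,
unscaled unit × sample rate matrix — replicates of a condition should
cluster.

## What the simulator does and does not emulate

`sim_config()` defaults encode the study conditions: three conditions ×
4 replicates; mature lengths 20–23 nt; U content 0.20–0.35; heavy-tailed
expression (lognormal, sdlog 1.5, normalized); $p = 0.02$; vehicle
new-molecule fraction Beta(2, 8) (mean 0.2 — a plausible 4 h labeling
fraction for stable species, and the regime that puts rates at the
sub-percent level); drug suppression uniform on [0.2, 1] with a small
drug-insensitive subset (suppression ≡ 1, emulating unaffected miRNAs);
sequencing error $10^{-3}$ per base (Illumina-like); two T>C SNPs at
allele frequency 0.5 or 1; 4 randomized nt per side; read length 75 nt.
The read length is a free choice (the protocol's "SR100" mode only
bounds it at 100); any value long enough to guarantee adapter
read-through behaves identically after trimming. A subset of miRNAs gets
duplicated genomic loci (same or mixed context) and a subset is withheld
from the curated list, so the collapse, dedup and curation paths are all
exercised. Conversions are applied on the mature-strand sequence —
reads are sense to the mature miRNA, so minus-strand genomics only
matters in the synthetic genome and BED, where it is exercised.

Not modeled, hence not validated by passing tests: RNA secondary
structure and ligation bias, Dicer-offset isomiRs, degradation, quality
scores (constant), PCR duplicates, and any dependence of labeling on
transcription rate. Real libraries also have far more features (hundreds
of miRNAs, contaminating RNA classes) than the simulated 20–100; the
simulation validates the estimator's correctness, not its behavior under
every real-data pathology.

`simulate_profiles()` is the profile-level shortcut: it draws read
counts multinomially and conversion counts binomially at the analytic
expected rate, skipping read emission, trimming and alignment (which are
identity in expectation). It exists for calibration studies that need
hundreds of replicate studies — e.g. verifying that, with suppression ≡ 1
everywhere, the context group tests reject at the nominal 5% — where
read-level simulation would add hours of compute and no information.
SNPs are not applied on this path.

## Numerical and scale choices

Deduplicated alignment (unique inserts weighted by multiplicity) plus a
small C++ kernel keeps a 2×10⁵-read library at a few seconds; the test
suite's end-to-end recovery check runs the full 50-miRNA, 12-library,
2×10⁵-reads-per-library study in about a minute, and at that depth the
median absolute error of the ratio against simulation truth is ≈ 0.05
(the binomial noise floor at sub-percent rates; the suite asserts
< 0.15). Unit tests use 10³–5×10⁴ reads. Offset ties within a unit take
the smallest offset; `conversion_rate` is defined as 0 at zero coverage;
CPM sums to 10⁶ per sample whenever any read is assigned; empty inputs
(no miRNAs, no reads, empty Final set) propagate as empty tables rather
than errors. Per-sample seeds are derived deterministically from the
study seed, so any library can be regenerated in isolation and
byte-identical outputs follow from a fixed seed.

## Known limitations

* The labeling test pools counts across replicates; replicate-level
  overdispersion is not modeled (a unit with one aberrant replicate can
  pass or fail on pooled evidence alone).
* Feature-space alignment cannot see reads that would map better
  elsewhere in a real genome; contaminants that happen to resemble a
  template within the mismatch budget are counted.
* The exact conditional labeling test is conservative at very low
  counts, as exact tests are.
* Group tests assume exchangeability across miRNAs within a group;
  shared host transcripts (clustered miRNAs) violate independence and
  are not modeled.
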