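# mirslam

Quantification of newly synthesized miRNAs from nucleotide-conversion
(SLAMseq-style) small RNA sequencing.

## The problem

Mature miRNAs are extremely stable (half-lives of days), so short-term
perturbations of miRNA biogenesis are invisible in total small-RNA
abundance. Metabolic labeling solves this: cells are fed 4-thiouridine
(4SU), which is incorporated into RNA made during the labeling window;
after chemical derivatization, incorporated 4SU base-pairs as C during
reverse transcription, so *new* molecules are identified by T>C
conversions in sequencing reads. Adapted to mature miRNAs, this lets one
ask how a drug changes miRNA *synthesis* over a few hours — for example,
how inhibition of the splicing factor SF3B1 (by pladienolide B, "PlaB")
affects Microprocessor-dependent miRNA production — even though total
miRNA levels do not move.

`mirslam` implements the full quantification path for a three-condition
design with replicates:

* **Control** — no 4SU (background conversion level),
* **DMSO** — 4SU + vehicle (labeled, unperturbed synthesis),
* **PlaB** — 4SU + drug (labeled, perturbed synthesis),

together with a synthetic-data generator that emulates the whole study
(NEXTflex-style libraries with 4 randomized nt flanking the insert plus a
3' adapter, per-miRNA labeling fractions, sub-percent conversion rates,
sequencing error, SNPs) with full ground truth, so every stage is testable
offline.

## The statistic

For each miRNA (counting unit) and sample, the **T>C conversion rate** is

    rate = tc_count / t_coverage

the number of C observations at unmasked reference-T positions over the
total read coverage of those positions. With replicate-mean rates per
condition, the per-miRNA **synthesis ratio** is the background-subtracted
contrast

    ratio = (mean_PlaB − mean_Control) / (mean_DMSO − mean_Control)

1 means synthesis unchanged by the drug, 0 means fully suppressed.

The pipeline stages are:

1. **Trimming** (`trim_reads`): 3' adapter removal, 4 nt clipped from the
   3' end, reads longer than 30 nt discarded, 4 nt clipped from the 5'
   end, minimum insert length 16.
2. **Conversion-aware assignment** (`build_index`, `quantify_sample`):
   ungapped comparison against mature sequences (± a small genomic
   flank); a template-T read as C scores as a match but is recorded as a
   conversion; reads are kept at ≤ 3 non-conversion mismatches and
   mapping integrity ≥ 0.95; identical mature sequences collapse into one
   counting unit, so multi-locus miRNAs are retained.
3. **SNP masking** (`call_snp_mask`): reference-T positions with C
   fraction ≥ 0.4 at coverage ≥ 10 in the no-4SU controls are excluded
   from both numerator and denominator.
4. **Dataset filters** (`dataset_membership`): Initial dataset (CPM > 100
   in every sample, curated ids only), above-background labeling (exact
   one-sided test on pooled conversion counts, BH-adjusted, p_adj <
   0.05), and a drug-floor filter (mean PlaB rate ≥ mean Control rate)
   yielding the Final dataset.
5. **Synthesis fit** (`mirna_synthesis`): ratios for Final units, group
   comparisons by genomic-location class, host-gene class and
   Microprocessor cis-motifs (CNNC, basal UG, apical UGU), Spearman
   correlation with TSS distance, and a sample-level PCA for QC.

## Worked example

```r
library(mirslam)

cfg <- sim_config(n_mirnas = 20, reads_per_sample = 20000, seed = 42)
out <- run_pipeline(cfg)
print(out$fit)
```

```
miRNA synthesis fit (background-subtracted conversion ratios)
  units: 20 total -> 17 initial -> 13 labeled -> 13 final (11 context-eligible)
  median synthesis ratio: 0.651
```

Of 20 simulated miRNAs, 17 pass the expression + curation filter, 13 are
labeled above background and survive the drug floor, and 11 are eligible
for context grouping (the rest have mixed-context loci). The median
synthesis ratio of 0.651 says the simulated drug cut new-miRNA production
roughly by a third at the median — and can be compared against the
generator's per-miRNA truth:

```r
truth <- setNames(out$bundle$truth$true_ratio, out$bundle$truth$mirna_id)
median(abs(coef(out$fit) - truth[out$fit$results$unit]))
#> [1] 0.1055988
```

`summary(out$fit)` adds the group comparisons and TSS correlation;
`plot(out$fit, type = "ratio_box")` draws the per-group box plots
(median, 10th/90th percentiles); `write_report(out$fit, "report/")`
writes the ratio, comparison, matrix, top-expressed and membership TSVs.

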