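# dmrkit

Differential-methylation region calling and multi-omic integration for
two-group whole-genome bisulfite sequencing (WGBS) cohorts — built for
smoker-vs-nonsmoker blood studies, applicable to any case/control design
with per-CpG methylated/unmethylated read counts, an expression count
matrix, and (optionally) a cytokine panel.

## What it does

Bulk-blood WGBS at moderate depth (~12x) poses three linked problems:
single-CpG levels are too noisy to test directly, blood is a cell mixture
whose composition itself responds to smoking, and regional tests on
spatially correlated sites are easily miscalibrated. dmrkit addresses all
three:

1. **Site statistics** — methylation level `Nmc / (Nmc + Nnmc)` per CpG,
   removal of CpGs on common SNPs (MAF > 5%), depth-weighted local-linear
   smoothing (windows of >= 11 CpGs and >= 1 kb, broken at gaps > 2 kb),
   reference-based leukocyte deconvolution (non-negative least squares on
   six cell types), and per-site OLS of level on smoking + age + BMI +
   working condition + cell proportions.
2. **DMR calling** — candidate regions are maximal runs of >= 5 adjacent
   sites with p < 0.05 and inter-site gaps <= 200 bp; each candidate is
   scored with the Stouffer–Liptak–Kechris combination

   `z_i = qnorm(1 - p_i)`, `Z = sum(z_i) / sqrt(sum_ij Sigma_ij)`,

   where `Sigma` is a distance autocorrelation function estimated from the
   track, and kept at slk p <= 1e-4. Calling is *two-track*: the smoothed
   association locates candidates (power), the raw-level association
   supplies the scores (calibration) — see the methods vignette for the
   measurements behind this design.
3. **Enrichment** — DMRs vs annotation tracks (promoters, UTRs/exons/
   introns, CpG island/shore/shelf/open sea, 15-state chromatin
   segmentations) against 1,000 CpG-count- and length-matched (±5%) random
   region sets; empirical p = (r + 1)/(n + 1), fold = observed / mean null.
4. **Expression** — mean-CPM >= 1 filter, log-CPM with mean-variance
   precision weights (the standard lowess sd-trend recipe, reimplemented),
   covariate-adjusted weighted least squares, Benjamini–Hochberg FDR.
5. **Integration** — DMR-gene links via gene bodies (2 kb/1 kb margins),
   promoter windows (1.5 kb/500 bp, strand-aware) and enhancer-target maps;
   Spearman correlation of per-sample DMR methylation with log2 expression
   on the samples carrying both assays; Hyper-Up / Hyper-Down / Hypo-Up /
   Hypo-Down quadrant classification; hypergeometric gene-set tests.
6. **Cytokines** — covariate-adjusted per-analyte tests on log2
   intensities with 95% confidence intervals.

A seed-reproducible **synthetic cohort generator** (`simulate_cohort()`)
emulates the target study design — 36+36 WGBS samples at 12.5x, bimodal
baseline methylation, planted DMRs with mean |delta| 3.4% (range 0.3-20%)
at 3:1 hyper:hypo, 38+37 RNA samples overlapping WGBS in 30 subjects,
planted log2 fold changes up to 2.25, enhancer-mediated
methylation-expression coupling, and a 27-plex cytokine panel — and
returns a ground-truth ledger so every stage is testable end to end.

## Worked example

```r
library(dmrkit)

cohort <- simulate_cohort(sim_config(seed = 1))
counts <- filter_snp_overlap(cohort$meth$counts, cohort$genome$snps)
counts
#> methylation_counts: 29958 CpG sites x 72 samples on 2 chromosome(s)

smoothed <- smooth_profiles(counts)
raw      <- methylation_level(counts$meth, counts$unmeth)
bulk <- raw
rownames(bulk) <- paste(counts$sites$chrom, counts$sites$pos, sep = ":")
props <- estimate_cell_proportions(bulk, cohort$genome$cell_reference)

sel <- pvalue_track(counts, site_association(smoothed, cohort$meth$sheet, props))
inf <- pvalue_track(counts, site_association(raw, cohort$meth$sheet, props))
dmrs <- call_dmrs(inf, estimate_acf(inf), selection_track = sel)
dmrs[, c("chrom", "start", "end", "n_cpg", "slk_p", "mean_delta", "direction")]
#>   chrom   start     end n_cpg    slk_p mean_delta direction
#> 1  chr1  471221  472116    13 1.39e-08    -0.1047      hypo
#> 2  chr1  520812  522234    17 1.97e-07    -0.0650      hypo
#> 3  chr2  150077  151178    11 1.72e-17     0.1447     hyper
#> 4  chr2  962021  962933     9 4.65e-09     0.1196     hyper
#> 5  chr2 1243288 1244504    17 2.64e-07     0.0713     hyper
```

Each row is a called DMR: `n_cpg` member CpGs, the slk-combined p-value,
the mean adjusted smoker-minus-nonsmoker difference on the fraction scale
(`mean_delta`; e.g. +0.145 means smokers ~14.5 percentage points higher),
and the direction label derived from its sign. Three of the five calls here
recover planted regions with |delta| >= 0.10; the two at |delta| 0.065 and
0.071 are genuine mid-size planted signals. `run_pipeline(pipeline_config())`
drives all six stages and writes TSV outputs plus a JSON manifest.

The package also ships a 23-row worked example of regulatory-element
DMR-DEG pairs (`inst/extdata/regulatory_pair_examples.tsv`) whose block
counts and direction quadrants are reproduced by `pair_table_summary()`.

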