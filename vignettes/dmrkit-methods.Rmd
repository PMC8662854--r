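---
title: "Methods and models in dmrkit"
author: "dmrkit authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods and models in dmrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dmrkit analyses two-group (smoker vs nonsmoker) whole-genome bisulfite
sequencing cohorts together with matched RNA-seq and cytokine panels. This
vignette explains the statistical models behind each stage, the parameters
that matter, the design choices that were genuinely open, and what the
synthetic cohort generator does and does not emulate.

## From read counts to per-site statistics

The methylation level of a CpG in a sample is the fraction of methylated
reads, `Nmc / (Nmc + Nnmc)`, kept as a fraction in [0, 1] and missing when
the site has no coverage. CpGs whose dinucleotide (either base) carries a
SNP with minor allele frequency above 5% are removed before analysis,
because genotype differences at the cytosine mimic methylation differences.

Profiles are smoothed per sample with a depth-weighted, tricube-weighted
local linear fit. The window around each site is the smallest symmetric
window containing at least 11 CpGs and spanning at least 1,000 bp; a gap of
more than 2,000 bp between neighbouring CpGs splits the chromosome into
independent blocks and smoothing never crosses a block. Blocks with fewer
than 11 CpGs pass through unsmoothed. The estimator (local linear with
tricube x depth weights) is our choice; the window rules are the
conventional ones for low-coverage WGBS. At a mean depth of ~12x a single
site's level has a standard error of ~0.14, so borrowing strength from
neighbours is what makes ~5-10% differences detectable at all.

Whole blood is a cell mixture, and smoking shifts its composition
(granulocytes up), so a naive site test confounds composition with direct
methylation change. We estimate six leukocyte proportions (B, NK, CD4T,
CD8T, monocytes, granulocytes) per sample by non-negative least squares of
the bulk levels on a reference panel of cell-type-discriminating sites,
rescaled to the simplex, and include five of the six proportions (dropping
granulocytes to avoid the sum-to-one collinearity) as covariates.

The per-site association model is ordinary least squares of the methylation
level on smoking status, age, BMI, working condition (miner) and the five
cell proportions. The smoking coefficient is the adjusted
smoker-minus-nonsmoker difference on the fraction scale ("delta"); its
two-sided t test gives the site p-value. Sites are analysed on their
covered samples (at least 3 per group), never imputed; constant nuisance
covariates are dropped rather than left to break the fit.

## Two-track DMR calling

A called DMR must satisfy the merge rules — at least 5 consecutive sites
with p < 0.05, adjacent sites at most 200 bp apart — and score a combined
Stouffer–Liptak–Kechris (slk) p-value of at most 1e-4. The slk score maps
each site p to a probit score `z = qnorm(1 - p)` and refers
`sum(z) / sqrt(sum(Sigma))` to the standard normal, where `Sigma` is the
matrix of pairwise score correlations looked up from a distance
autocorrelation function (ACF) estimated from the track itself (Pearson
correlation of z-scores within distance bins, negative estimates truncated
to zero). With the identity `Sigma` this is the textbook Stouffer
combination; positive correlations inflate the variance and make the
combination conservative.

The calling is deliberately *two-track*:

* the **smoothed-level** association locates candidate runs (smoothing
  pools neighbouring CpGs, which is where the power to see 3-10%
  differences at 12x comes from), while
* the **raw-level** association supplies the p-values and the ACF for the
  slk score.

The reason is a selection effect we measured rather than assumed: smoothed
site z-scores are strongly correlated over the smoothing window, so "runs
of significant sites" arise whenever the local noise field is high, and
scoring those same smoothed p-values — even with a correctly estimated ACF —
is anti-conservative (about 1.2 spurious DMRs per 20,000-site null genome
at the 1e-4 threshold in our null simulations). Raw-level z-scores at
distinct CpGs are nearly independent (the ACF estimate confirms near-zero
correlations), so the combined score of a candidate is close to a genuine
independent-evidence Stouffer test and the spurious-call rate drops to zero
in the same simulations, while the smoothed track retains the discovery
power. Both single-track modes remain available
(`pipeline_config(association = "smoothed")` / `"raw"`).

The ACF distance bins extend to 1,000 bp (not just the 200 bp merge gap)
because smoothing correlates sites over roughly the window width; zeroing
the correlation beyond 200 bp would understate the variance of the summed
scores. Region direction is "hyper" when the mean site delta is positive
(smokers higher). Ties at the 1e-4 threshold are kept. No additional
Sidak/FDR layer is applied to regions: in our measurements it restores
calibration of the single-track smoothed score only at the cost of most
marginal (|delta| ~ 0.10) true regions, and the two-track score achieves
calibration without that cost.

Known limitation: the raw-level OLS t p-values are only approximately
uniform under the null. Read counts at depth ~12 are discrete and
beta-binomial residuals are heavier-tailed than Gaussian, so with 20,000
sites a Kolmogorov–Smirnov test detects a shape deviation of D ~ 0.01 in
roughly half of null cohorts, even though the fraction of sites with
p < 0.05 is 4.7-5.0% in every null cohort we generated and the
false-region rate at slk <= 1e-4 was zero across 20 null genomes. Users
should read the site p-values as well calibrated at conventional
thresholds, not as exactly uniform random variables.

## Matched-region enrichment

Whether DMRs concentrate in annotation classes (promoters, UTRs, exons,
introns, CpG islands/shores/shelves/open sea, chromatin states per cell
type) is tested against a matched empirical null: for each DMR and each of
1,000 draws, a surrogate region with exactly the same CpG count and a span
within ±5% of the DMR's length is sampled by anchoring on a random genome
CpG (sampling uniformly among anchors that satisfy the length band is
equivalent to rejection sampling on a uniform anchor; if no anchor
qualifies the nearest-length one is used and counted as a relaxation).
Anchoring on CpGs rather than uniform base pairs is what makes the
equal-CpG-count constraint satisfiable and controls for CpG density. Hyper-
and hypo-methylated DMRs are tested separately, sharing one null set per
stratum across all features.

The statistic is the number of query regions overlapping the feature by at
least 1 bp. The empirical p-value is `(r + 1) / (n + 1)` with `r` the
number of null draws at least as extreme as the observation (ties counted
as extreme, so the p-value is never 0 and is conservative); enrichment and
depletion are two one-sided tests reported side by side, with the reported
direction the smaller side. The fold change is the observed count divided
by the mean null count, with +Inf / NaN flags (never errors) for empty
nulls.

## Expression and integration

Transcripts are kept when their mean counts-per-million across all samples
is at least 1 (the "mean" reading of the inclusion rule; `all`, `any` and
`at_least_k` are available since the phrase is ambiguous). Normalisation
follows the standard mean-variance precision-weight recipe for count data:
log2 CPM with the half-count offset, a per-transcript linear fit on the
design, a lowess trend of sqrt(residual sd) against average log count, and
per-observation weights `1 / trend(fitted log count)^4`. The implementation
is our own and is cross-checked in the tests against the reference
implementation of the same recipe. Differential expression is weighted
least squares per transcript on [smoking, age, BMI, miner], with
Benjamini–Hochberg control across transcripts.

DMRs are linked to genes three ways: *body* links when the DMR overlaps the
gene allowing an upstream 2 kb / downstream 1 kb margin (the margin is read
on the stranded gene, since "upstream" is ill-defined for an unstranded
DMR; the DMR-extension reading is available as a switch); *promoter* links
through strand-aware promoter windows (1.5 kb upstream to 500 bp downstream
of the TSS); *enhancer* links through an enhancer-target interaction map,
one link per target so "commuting" enhancers that act on distal genes are
kept. For each regulatory link whose DMR passes slk <= 1e-4 and whose gene
has expression p < 0.05 (the deliberately relaxed set used for
integration), the per-sample mean methylation over the DMR's CpGs is
correlated with log2 expression by Spearman's rho (average-rank ties;
t approximation on n - 2 df, exact permutation available for n <= 9) over
the samples present in both assays. Pairs are classified into the four
direction quadrants (Hyper-Up, Hyper-Down, Hypo-Up, Hypo-Down). Gene-set
over-representation uses the hypergeometric upper tail with BH across sets,
against the annotated-gene universe by default.

Cytokine panels are tested analyte by analyte with the same covariate
model on log2 intensities; nominal p-values are reported without
multiplicity correction (the convention for small targeted panels), with a
BH column alongside for transparency.

## The synthetic cohort generator

Because the underlying human data cannot be redistributed, every stage is
exercised on synthetic cohorts with a known truth ledger. The generator
emulates the study's design: 36 + 36 WGBS samples at truncated-Poisson
depth (mean 12.5), 38 + 37 RNA samples overlapping WGBS in 12 + 18
subjects, and a 27-analyte cytokine panel on 9 + 13 subjects. Baseline
methylation is a two-component Beta mixture (modes near 0.02 and 0.98,
low component favoured inside CpG islands), giving the characteristic
bimodal genome-wide histogram with ~20% of CpGs in CpG-rich areas. Planted
DMRs are runs of 10-15 CpGs with gaps <= 200 bp spanning >= 1 kb; their
|delta| magnitudes follow a truncated-exponential quantile grid with mean
3.4% over the range 0.3-20% (a deterministic grid, so every cohort carries
the same effect-size spectrum), signed hyper with probability 0.75. Counts
are beta-binomial with overdispersion rho = 0.02 — a pure binomial would be
unrealistically tight at 12x — and each planted DMR also carries a
per-subject regional deviation (sd 0.05) shared across its CpGs,
representing inter-individual regional methylation variability.

Confounding is built in deliberately: age ~ N(41, 2.3^2), BMI ~
N(24.7, 3.4^2) and balanced miner status have small direct effects on
methylation (<= 0.01), and cell composition is Dirichlet with
granulocyte-dominant, group-shifted means (0.60 vs 0.50), loading on 15% of
sites. This makes the cell-composition adjustment consequential: the test
suite verifies that omitting it inflates the null. A designated reference
site set ties the deconvolution to a known mixing matrix.

Expression counts are negative binomial (size 10) around log-normal
baselines with a lowly-expressed tail; planted DEGs span |log2FC| 0.25-2.25
with the largest planted upregulated at exactly 2.25. Enhancers placed on a
subset of planted DMRs couple their targets' expression to the subject's
regional methylation at -10 log2 units per methylation unit, producing the
negative methylation-expression correlations the integration stage is meant
to recover. Cytokines are Gaussian on the log2 scale (residual sd 0.28,
chosen to reproduce the confidence-interval width typical of 27-plex panels
at n ~ 22) with planted smoker shifts (+0.26 on a VEGF-like analyte).

What the generator does **not** emulate: read-level artefacts (bisulfite
conversion failure, mapping bias), non-CpG methylation, correlated
methylation outside planted DMRs, linkage between SNPs and methylation,
isoform-level expression structure, and batch effects. Passing the
recovery suites therefore demonstrates that the pipeline's statistics do
what they claim under the study's sampling design — not that they are
robust to every artefact of real sequencing data.

## Numerical choices and scale of the test problems

Probabilities are clamped away from 0/1 before probit transforms; the slk
correlation matrix is projected to positive semi-definite when estimation
noise makes it indefinite; empirical p-values use the add-one rule and
never return 0; fold changes flag rather than throw on empty nulls;
zero-variance vectors yield missing correlations; and collinear designs
are reported as errors naming the offending columns rather than silently
dropped (except constant covariates, which carry no information and are
removed).

Simulated genomes used in the tests are 2 x 1.5 Mb with 30,000 CpGs
(20,000 for the null-calibration runs), 300 gene models and 1,200
transcripts — large enough for ~60 planted DMRs with realistic CpG spacing
and stable ACF estimation, small enough that the full suite runs in
minutes. Detection power at the slk <= 1e-4 threshold under this design is
~0.7 for |delta| = 0.10, ~0.85 at 0.117 and ~0.98 at 0.147 — marginal
10%-scale DMRs genuinely straddle the threshold at n = 36 + 36 and 12.5x,
which should be kept in mind when interpreting recovery rates.
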