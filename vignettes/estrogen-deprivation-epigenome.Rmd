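---
title: "Methods: epigenome remodelling under estrogen deprivation and re-stimulation"
author: "estroepi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenome remodelling under estrogen deprivation and re-stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estroepi)
```

# The analysis

Estrogen-receptor-positive breast-cancer cells deprived of estradiol (E2)
remodel their regulatory landscape: CpGs in enhancer regions gain DNA
methylation with time in deprivation, enhancer H3K27ac falls, transcription is
globally down-regulated, and most — but not all — of these changes revert when
E2 is restored. `estroepi` implements that full analysis chain as a reusable,
tested pipeline over four assays:

1. **Differential methylation** on beta-value matrices (fraction methylated
   per CpG probe, in $[0,1]$). Betas are mapped to M-values,
   $M = \log_2\{\beta/(1-\beta)\}$, the standard variance-stabilised scale
   for linear modelling; each probe is fit by ordinary least squares with a
   treatment indicator (deprived vs control) and a categorical timepoint
   covariate; the treatment coefficient is t-tested, BH-FDR is applied across
   probes, and a probe is a DMP when FDR $< 0.05$ and the pooled group-mean
   beta difference exceeds 10% in magnitude. Specificity is validated by the
   study's own control: shuffling the treatment labels (ten times) and
   refitting must produce no DMPs at all.
2. **Genomic context and overlap enrichment.** Sites are annotated by
   precedence promoter > exon > intron > intergenic and by CpG density
   (island / shore within 2 kb / shelf within 2–4 kb / open sea), and the
   association of differential sites with any interval collection (TF peaks,
   chromatin states, islands) is the differential/expected statistic: the
   overlap rate of the hits divided by the overlap rate of the whole
   background universe (all array probes, hits included), with a two-sided
   Fisher exact test on the corresponding 2×2 table (default alpha $10^{-5}$).
3. **Differential H3K27ac binding.** Replicate peak calls are filtered by the
   published rules (width $<$ 1.5 kb, $q<0.01$, fold-over-input $>5$),
   consolidated into reproducible consensus peaks by reciprocal-overlap
   matching, and a region × sample count matrix is tested per region with a
   Welch t on median-library normalized $\log_2$ counts, a pooled-variance
   floor, BH-FDR, and the joint FDR $<0.05$, $|\log_2\mathrm{FC}|>1$ call.
4. **Differential expression.** Genes pass a CPM filter and are tested with a
   hand-fitted negative-binomial log-linear model (IRLS, library-size
   offset), Wald test on the treatment coefficient, same joint thresholds.
5. **Reversibility.** The re-stimulated arm is contrasted against control;
   units are classified *retained* (called in both deprivation and
   re-stimulation contrasts with the same direction), *reversed* (deprivation
   only), or *new* (re-stimulation only), and hypermethylated DMPs are
   stratified into quartiles of control baseline methylation to show where
   retention concentrates.
6. **qPCR / oxBS quantification.** Closed forms: ChIP and hMeDIP
   percent-of-input $2^{(Ct_{\mathrm{input}} - \log_2(1/f)) -
   Ct_{\mathrm{IP}}} \times 100$ for an input fraction $f$ (the familiar 6.64
   and 3.32 cycle corrections are $\log_2 100$ and $\log_2 10$), ΔΔCt
   relative expression $2^{-\Delta\Delta Ct}$ against a housekeeping gene,
   siRNA knock-down efficiency, and 5hmC by oxidative-bisulfite subtraction
   $5hmC\% = 5mC\%_{BS} - 5mC\%_{oxBS}$ (negatives reported unclamped with a
   below-detection flag).

Everything runs end-to-end on a synthetic study generated by
`simulate_methylome()`, `simulate_annotation()` and `simulate_counts()`, so
the whole chain is testable with no external downloads. The numbered scripts
under `analysis/` narrate one full run; `run_pipeline()` performs the same
sequence programmatically and writes a digest manifest so repeat runs are
verifiably identical.

# The synthetic study design

The generator reproduces the design the analysis assumes, not merely its
formats:

* **Samples.** Control (CTR) at days 0, 4 and 14; deprived (E2D) at days 4
  and 14; re-stimulated (ReSt, deprived 4 days then re-stimulated) at day 14;
  three replicates each. The deprivation contrast is therefore 9 CTR vs
  6 E2D samples adjusted for timepoint.
* **Methylome.** 20,000 probes placed uniformly on a 100 Mb two-chromosome
  genome. Baselines follow a bimodal low/high mixture; the 500 planted
  hypermethylated and 25 planted hypomethylated probes (95.2% hyper,
  mirroring the strong hyper bias of deprivation) get intermediate baselines
  drawn uniformly on $[0.40, 0.70]$ — the enhancer-like regime in which the
  real hyperDMPs sit (baseline quartiles around 40–70%, mean ~55%). The
  planted effect is $+0.15$ beta at day 4 growing to $+0.20$ at day 14; in
  ReSt the effect reverts except for a retained fraction (default 0.2) which
  keeps the day-4 effect. Observed betas are Beta-distributed around the
  condition mean with concentration 300, i.e. a within-group SD of
  ~0.029 at intermediate methylation — typical replicate variability for
  methylation arrays on a cell line. The study itself reports no
  within-group variance, so this concentration is a documented free
  parameter, chosen once.
* **Annotation.** Non-overlapping gene models with strand-aware promoters
  ($[\mathrm{TSS}-2000, \mathrm{TSS}+500)$), exons/introns, CpG islands, a
  five-state chromatin segmentation, and one "TF" interval set planted to be
  9-fold enriched at planted probes. The planted coverage probability is
  solved self-consistently so that the *pipeline's* fold statistic — hits%
  over background% with the background including the hits — equals the
  target in expectation; TF footprints are kept narrow (20 bp) so they do
  not sweep up neighbouring probes and dilute the calibration.
* **Counts.** Negative-binomial counts with lognormal per-sample depth
  factors. RNA: 5,000 genes, baseline lognormal(log 200, 1), dispersion 0.1,
  400 planted DEGs at $|\log_2\mathrm{FC}| = 2$ with 70% down. ChIP: 2,000
  consensus regions at day 14 only (the timepoint at which differential
  binding is assessed), baseline lognormal(log 500, 0.5), dispersion 0.005,
  200 planted DB regions with 85% losses. The ChIP baseline and dispersion
  are deliberately tighter and higher than RNA: consensus-peak counts from
  deeply sequenced cell-line replicates are far more reproducible than RNA
  biological replicates, and a design-time power analysis shows a Welch t at
  $n=3$/group (Welch df ≈ 2–4) cannot reliably detect 4-fold changes
  through BH correction unless replicate noise is in this regime. In ReSt,
  planted count effects revert except for the retained fraction.
* **Determinism.** Every stream of randomness derives a sub-seed from the
  single master seed by a tagged LCG hash, so any stage can be regenerated
  independently and no call perturbs the caller's RNG state.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: array probe cross-reactivity and detection failures
(detection p-values are simulated as uniformly small), batch and
cell-culture drift (the real study saw a d0 vs d4/d14 control difference),
genomic covariation of methylation with CpG density, heteroskedastic beta
variance at extreme baselines beyond what the Beta noise implies, and
correlated fragments/peak width variation in ChIP. Threshold behaviour on
real data (e.g. the exact DMP count) is therefore out of scope by design;
the synthetic truth instead supports *recovery* statements — sensitivity,
false-discovery proportion, direction correctness, retention-fraction
estimation — at known effect sizes.

# Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `fdr_max` | 0.05 | BH-FDR threshold for every caller |
| `delta_min` | 0.10 | minimum pooled |Δβ| (fraction methylated) for DMPs |
| `lfc_min` | 1.0 | minimum |log2FC| for DB regions and DEGs |
| `alpha` | 1e-5 | Fisher significance for overlap enrichment |
| peak filters | 1500 bp, q 0.01, fold 5 | strict (<, <, >) as published |
| `cpm_min`, `min_samples` | 10, 2 | expression filter (CPM > 10 in ≥ 2 samples) |
| `noise_precision` | 300 | Beta concentration of probe noise |
| `nb_dispersion`, `chip_dispersion` | 0.1, 0.005 | NB dispersions (RNA, ChIP) |
| `retained_fraction` | 0.2 | fraction of planted effects persisting in ReSt |
| `min_reciprocal_overlap` | 0.5 | replicate-consensus reciprocal overlap |
| `var_floor_quantile` | 0.10 | pooled-variance floor for the DB Welch t |

# Numerical and design choices

* **Beta clipping.** Betas are clipped to $[10^{-6}, 1-10^{-6}]$ before the
  logit so boundary values map to finite M-values (±19.93).
* **Pooled Δβ.** The calling effect size is the difference of treatment
  group-mean betas over the timepoints shared by both treatments (day 0
  exists only for controls and informs the time adjustment, not the effect
  size); per-timepoint Δβ is reported alongside. Whether the original
  analysis pooled or gated per-timepoint is not derivable from its text;
  pooled is the default here.
* **Detection filter.** A probe is dropped when *any* sample fails the
  detection threshold (strictest reading; `mode = "all"` is available). A
  matrix without detection p-values passes through with a notice rather than
  failing.
* **No variance moderation.** The DMP model is plain OLS per probe, as a
  linear regression is what the analysis specifies; empirical-Bayes
  moderation is deliberately not applied so the permutation control and the
  OLS oracle tests pin down exactly one estimator.
* **Permutations** sample label assignments uniformly (the identity
  permutation is not excluded; with 15 samples it has probability
  1/5005 per draw) and derive per-shuffle sub-seeds from the master seed.
* **Fisher exact test** is two-sided by hypergeometric enumeration with the
  conventional $1+10^{-7}$ relative tie tolerance; whether the original
  test was one- or two-sided is not stated, so two-sided is used. The
  background universe for probe enrichments is all probes, hits included.
* **Promoter window** $[\mathrm{TSS}-2000, \mathrm{TSS}+500)$ on the gene
  strand; the exact window of the original annotation package is unstated,
  so this common default is a documented decision.
* **Window expansion** ("a 250 bp window around a site") is implemented as a
  total width centred on the site midpoint (±125 bp), clipped at chromosome
  bounds.
* **Consensus peaks.** True irreproducible-discovery-rate modelling is out
  of scope; the stand-in requires ≥ 50% reciprocal overlap in both
  directions and matches peak pairs greedily by descending fold-over-input,
  each peak used once.
* **DB test.** With $n = 2$–3 replicates per group an NB dispersion per
  region is not estimable; the Welch t on normalized log2 counts with a
  10th-percentile pooled-variance floor is the smallest defensible amount
  of stabilisation, and the floor quantile is exposed.
* **DE dispersion.** Gene-wise method-of-moments estimates on
  depth-normalized counts, shrunk 50/50 toward a lowess mean–dispersion
  trend; the Wald test uses the expected information at the final fit.
  Forcing dispersion 0 reduces the fit to a Poisson GLM, which the tests
  exploit as an oracle. Library size is the column total (no TMM); a
  documented simplification.
* **Expression filter wording.** The published sentence ("genes with ≤10 CPM
  in at least two samples were eliminated") contradicts standard practice
  for designs with many samples — read literally it removes nearly every
  gene. Both readings ship: `conventional` (keep if CPM > 10 in ≥ 2 samples,
  the default) and `literal`; the boundary case on which they must disagree
  is a test.
* **Knock-down efficiency.** The printed expression
  $(100 - (2^{-\Delta Ct_{siRNA}} - 2^{-\Delta Ct_{siNT}})) \times 100$ is
  dimensionally inconsistent (it is not a percentage — evaluating it at
  ΔCt 3 vs 1 gives 10,037.5); the default mode is the standard
  remaining-fraction form $(1 - 2^{-\Delta\Delta Ct}) \times 100$ and the
  literal printed form is preserved for auditability.
* **Persistence.** *Retained* requires same-direction significance in both
  contrasts by default. A unit significant in both contrasts with opposite
  directions is classified *reversed* (the original effect did not persist)
  — a case the strict status table does not cover. For *estimating* the
  retained fraction, the effect-size-only mode (`call_effects()`: |Δβ|
  above threshold in the re-stimulation contrast, no significance gate) is
  the right reading: with three ReSt samples the dual-significance
  definition confounds retention with detection power and is biased toward
  zero. The quartile stratification uses control group-mean beta at day 14,
  with ties broken by probe id.
* **Retention placement.** By default retained probes are drawn uniformly
  from the planted set; `retention_mode = "high_baseline"` concentrates
  retention in the highest-baseline planted probes, reproducing the
  observed pattern that high-baseline sites recover least.

# Problem sizes and what the suite demonstrates

The test and acceptance runs use the full default study (20,000 probes,
5,000 genes, 2,000 regions, 18 samples) — chosen so every recovery statement
is made at the design's own scale: DMP sensitivity ≥ 0.9 with FDP ≤ 0.1 at
planted Δβ 0.2, DB/DE sensitivity ≥ 0.9 with 100% direction correctness at
planted 4-fold effects, planted 9-fold enrichment estimated within
[7.6, 10.4], retention fraction recovered within ±0.05 of the planted 0.2
over ten seeds, zero calls on zero-effect data, and zero DMPs in every one
of ten label shuffles despite the planted signal. Exhaustive oracle checks
(Fisher vs enumeration over all 2×2 tables with margins ≤ 50; OLS vs `lm()`;
BH vs the step-up recursion) run alongside.

# Known limitations

* The paper-scale headline counts (995 DMPs, 3,053 DB regions, 547 DEGs…)
  depend on the deposited array/sequencing data and external annotation
  tracks and are not reproduced here; the pipeline reproduces the *methods*
  and validates them on planted truth.
* The DB test is a two-group comparison at one timepoint; no paired or
  time-course modelling of binding.
* No array normalization, probe masking, TMM, motif discovery, or external
  enrichment-database querying; interval sets for those analyses are
  accepted as user-supplied BED files instead.
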