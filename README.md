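# estroepi

Epigenome remodelling under estrogen deprivation and re-stimulation, as a
tested R pipeline.

Estrogen-receptor-positive breast-cancer cells that are deprived of estradiol
progressively hypermethylate enhancer CpGs, lose enhancer H3K27ac, and
down-regulate transcription; re-stimulation reverses most — but not all — of
these changes. `estroepi` implements the complete analysis chain behind such
a study and a synthetic-data generator that emulates its design (9 control vs
6 deprived samples across days 0/4/14, plus a re-stimulated arm at day 14),
so every step is testable end-to-end with no external data.

## What it computes

* **Differentially methylated positions (DMPs).** Per-probe OLS on M-values
  `M = log2(β/(1−β))` with a treatment term adjusted for timepoint; BH-FDR;
  a probe is a DMP when FDR < 0.05 **and** the pooled group-mean Δβ exceeds
  10%. Specificity is demonstrated by refitting after shuffling treatment
  labels ten times — a clean pipeline returns zero DMPs in every shuffle.
* **Overlap enrichment.** The differential/expected statistic
  `(hits% in regions) / (background% in regions)` over the all-probe
  universe, with an exact two-sided Fisher test (alpha 1e−5), plus feature
  annotation (promoter > exon > intron > intergenic), CpG island / shore /
  shelf classes, window expansion, proximity joins and nearest genes.
* **Differential H3K27ac binding.** narrowPeak filtering (< 1.5 kb,
  q < 0.01, fold-over-input > 5), reciprocal-overlap consensus peaks, and a
  per-region Welch t on median-library normalized log2 counts with a
  variance floor; called at FDR < 0.05, |log2FC| > 1.
* **Differential expression.** CPM filter (> 10 CPM in ≥ 2 samples), then a
  negative-binomial Wald GLM (IRLS, library-size offset, trend-shrunk
  method-of-moments dispersion); same joint thresholds.
* **Reversibility.** Persistence classification (reversed / retained / new)
  across the deprivation and re-stimulation contrasts for DMPs, bound
  regions and genes, and quartile-stratified recovery of hyperDMPs by
  control baseline methylation.
* **qPCR / oxBS formulas.** Percent-of-input
  `2^((Ct_input − log2(1/f)) − Ct_IP) × 100` (the printed 6.64 and 3.32
  cycle corrections are log2(100) and log2(10)), ΔΔCt relative expression,
  siRNA knock-down efficiency, and 5hmC = 5mC%_BS − 5mC%_oxBS.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic data
(master seed via the `STUDY_SEED` environment variable, default 1), writing
tables under `results/run/`:

```sh
Rscript analysis/01_simulate.R      # inputs: betas, sample sheet, BEDs, counts
Rscript analysis/02_methylation.R   # DMPs + permutation control
Rscript analysis/03_genomic_context.R
Rscript analysis/04_chromatin.R
Rscript analysis/05_expression.R
Rscript analysis/06_reversibility.R
```

Output of a run at seed 1:

```
525 DMPs (FDR < 0.05, |db| > 0.10): 500 hyper (95.2%), 25 hypo
mean delta-beta at d4 0.137 vs d14 0.181 (effects grow with time)
DMP counts over 10 treatment-label shuffles: 0 0 0 0 0 0 0 0 0 0
TF-set enrichment: 8.31-fold (Fisher p = 3.39e-194, significant at 1e-5: TRUE)
195 DB regions (E2D vs CTR): 165 losses (84.6%), 30 gains
399 DEGs (E2D vs CTR): 69.9% down-regulated
methylation: 421 reversed, 104 retained, 0 new (retained fraction 0.20)
```

Reading: the caller recovers the 525 planted probes (95.2% hypermethylated),
the label-shuffle control is perfectly clean, the planted ~9-fold TF-set
enrichment is estimated at 8.3 on this seed, differential binding is
dominated by losses and expression by down-regulation (as planted: 85% and
70%), and the planted 20% retention after re-stimulation is recovered as
0.20. The same sequence is available programmatically:

```r
library(estroepi)
manifest <- run_pipeline(sim_config(seed = 1), outdir = "results/run")
summarize_run("results/run")
```

`run_pipeline()` writes an md5 manifest; re-running the same configuration
reproduces identical digests.

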