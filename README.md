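# polysomics

Multi-layer post-transcriptional analysis of paired transcriptome /
translatome time courses.

Polysome profiling separates a tissue extract into total RNA (the
transcriptome) and polysome-bound RNA (the translatome, a proxy for actively
translated mRNA). Sequencing both fractions from the same subjects across an
ordered series of ages makes it possible to ask not just *which* genes
change, but *at which regulatory layer*: transcript abundance, translational
efficiency, alternative splicing, or 3′-end (polyadenylation site)
selection. `polysomics` implements that entire analysis as a tested R
package, exercised end-to-end on synthetic data with planted ground truth.

## What the package computes

* **Filtering/normalization** — genes kept at CPM ≥ N = median(8×10⁶ /
  library size) in ≥ 4 samples of either fraction; TMM normalization;
  log₂(CPM + 0.5).
* **QC** — PCA; outlier flagging when a sample's average pairwise
  correlation falls below Q₁ − 1.5·IQR of its fraction; a simplified
  location–scale empirical-Bayes batch adjustment.
* **Differential expression** — moderated linear models on log₂ CPM with
  batch in the design; moderated t per pairwise age contrast (6v3, 12v3,
  20v3, 12v6, 20v6, 20v12); selection at BH q < 0.05 and |FC| > log₂(1.2).
* **Regulatory modes** — per-gene analysis of partial variance on paired
  fractions: `polysome = α + β·total + γ·group`. Genes are classified per
  contrast as *translation* (polysome change not explained by total RNA),
  *buffering* (total change absent from polysomes), or *abundance*
  (congruent change in both).
* **Alternative splicing** — enumeration of SE, A5, A3, MX, RI, AF, AL
  events from transcript models; Ψ (percent spliced-in) =
  inclusion TPM / (inclusion + exclusion) TPM; an expression-stratified
  empirical ΔΨ test; Fisher overlap and χ² trend statistics.
* **Alternative polyadenylation** — terminal fragments (final two exons),
  3′ ends grouped within 25 nt into sites, positional ψ ∈ [0, 1]
  (0 = exclusively proximal, 1 = exclusively distal), Welch tests.
* **Trajectories** — z-scored 4-point age profiles, clustered by a circular
  self-organizing map under an interpolation-based co-expression
  similarity, with the cluster count selected by BIC.
* **Enrichment** — hypergeometric over-representation and permutation GSEA
  (NES, FDR) over ranked lists of the four regulatory axes.
* **Synthetic data** — generators for the paired design (5/6/4/5 subjects
  at 3/6/12/20 months), negative-binomial counts, transcript TPMs realizing
  planted Ψ/ψ, and trajectory shapes — all seeded and byte-reproducible.

## Worked example

Simulate a paired experiment with 30 planted genes per regulatory mode
(log₂ effect 1 at 20 months, noise sd 0.25) and classify the 20-vs-3-month
contrast:

```r
library(polysomics)

sim <- simulate_paired_profiles(
  n_genes = 500,
  mode_config = list(abundance = c(30, 1), translation = c(30, 1),
                     buffering = c(30, 1)),
  noise_sd = 0.25, seed = 42)
calls <- regmode_analysis(sim$total, sim$polysome, sim$samples,
                          contrasts = "20v3")
table(called = calls$mode, planted = truth_modes(sim$truth, "20v3"))
#>              planted
#> called        abundance buffering none translation
#>   abundance          30         0    0           0
#>   buffering           0        30    0           0
#>   none               0         0  409           0
#>   translation         0         0    1          30
```

All 90 planted genes are recovered in their planted mode, with one false
positive among the 410 null genes. The same machinery scores set overlaps;
on the margins of a transcriptome/translatome splicing-event comparison
(883 and 835 selected events sharing 244, from 65,311 enumerable events):

```r
ot <- overlap_test(883, 835, 244, 65311)
sprintf("expected overlap %.1f, log10 p = %.1f", ot$expected, ot$log10_p)
#> "expected overlap 11.3, log10 p = -257.0"
```

— an overlap twenty-fold above expectation with p ≈ 10⁻²⁵⁷.

## The analysis workflow

`analysis/01_simulate.R` … `analysis/08_enrichment.R` are thin numbered
drivers over the package that reproduce the full study workflow on the
synthetic experiment — simulation, preprocessing, differential expression,
regulatory modes, splicing, APA, trajectories, enrichment — each reading its
inputs from `results/` and writing its tables there:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

`run_pipeline(outdir, seed)` performs the same sequence in one call and
writes an md5 manifest; reruns under one seed are byte-identical.

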