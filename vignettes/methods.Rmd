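---
title: "Models and methods behind polysomics"
author: "polysomics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polysomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

polysomics analyzes paired total-RNA (transcriptome) and polysomal-RNA
(translatome) sequencing across an ordered series of age groups. The default
design has 5, 6, 4 and 5 subjects at 3, 6, 12 and 20 months, each
contributing one total and one polysome library (40 libraries), with
subjects allocated to processing batches. The pipeline covers filtering and
normalization, QC, differential expression over the six pairwise age
contrasts, regulatory-mode classification of paired total/polysome changes,
alternative-splicing PSI analysis, alternative-polyadenylation psi analysis,
temporal trajectory clustering, and gene-set enrichment. A synthetic-data
module generates all inputs with planted, recoverable ground truth; the test
suite and the acceptance script run the full machinery against that truth.

The package consumes count and TPM tables; read alignment and transcript
quantification are upstream of it.

# Filtering and normalization

Genes are retained when their (unnormalized) CPM reaches
`N = median(8e6 / lib_size)` — the CPM a gene with 8 counts would have in a
nominal 8-million-read library — in at least 4 samples of either fraction.
The threshold adapts to realized depth: deeper libraries imply a lower CPM
cut for the same count floor. `min_samples = 4` matches the smallest age
group, so a gene expressed in only one group can survive.

Between-sample normalization is the trimmed mean of M-values (TMM; 30%/5%
two-sided trims on M and A, inverse-variance weights, factors rescaled to
geometric mean 1), computed by edgeR and cross-checked in the tests against
an independent brute-force implementation of the trimmed weighted mean. TMM
factors are invariant to a pure depth change of a sample up to the
depth-dependent precision weights (observed agreement ~1e-4; the tests
assert 1e-3). Log expression is `log2(CPM + 0.5)`; the pseudocount is a
fixed convention of the package. Each fraction is normalized independently,
as the two RNA pools have different composition.

# QC: outliers, batch adjustment, PCA

A sample is an outlier when its average Pearson correlation to the other
samples of its fraction falls more than 1.5 interquartile ranges below the
first quartile of those averages (quartiles by linear interpolation,
type 7). Flagging is a single pass. Because the rule is relative to the
spread of the set, very homogeneous sets can flag samples whose absolute
correlation is still high; on simulated data with batch structure the rule
runs before batch adjustment, mirroring a QC-first workflow, and a few
flags there reflect batch-driven correlation blocks rather than planted
outliers.

Batch adjustment is a deliberately simplified location–scale empirical-Bayes
model, not a ComBat reimplementation. Per gene, batch coefficients are
estimated jointly with the age-group means by least squares (this handles
batch/group unbalance), shrunk toward their across-gene mean with precision
weights `w = tau^2 / (tau^2 + se^2)` where `tau^2` is the method-of-moments
between-gene variance of the batch effects, and subtracted. Residual scale
ratios per batch are log-centered across batches (sample-weighted, so the
overall scale is untouched), shrunk the same way, and divided out. A single
batch yields the identity; a batch perfectly confounded with age is refused.

PCA is the singular value decomposition of the gene-centered matrix.

# Moderated differential expression

Differential expression uses a moderated linear model on log2 CPM
(limma-trend style): per-gene least squares on a shared age-group + batch
design, then empirical-Bayes variance moderation
`s2_post = (d0*s0^2 + d*s2) / (d0 + d)` with the prior `(d0, s0^2)`
estimated by method of moments on `log s2` (trigamma inversion). A contrast
is tested with a moderated t on `d0 + d` degrees of freedom; BH correction
is applied within each contrast and fraction. Genes are selected at
`q < 0.05` and `|log2 FC| > log2(1.2)`, both strict. This engine is an
approximation of a quasi-likelihood negative-binomial count model; at the
replicate counts of this design it is well calibrated (the suite checks the
type-I error of the null test against the 99% binomial interval of 0.05 and
the uniformity of null p-values), and the same shrinkage machinery is reused
by the regulatory-mode tests, so the package has exactly one variance model.
The tests also cross-check the fit against limma on a shared design.

# Regulatory modes (analysis of partial variance)

For one pairwise age contrast, with fractions paired by subject, the
translation-direction model per gene is

    polysome = alpha + beta * total + gamma * I(later group)

`gamma` is the change in polysomal RNA not explained by total RNA — the
translational effect. The buffering direction swaps response and covariate.
`beta` is fit per gene within the contrast, and significance of `gamma` uses
the shared moderated-variance engine with BH within direction and contrast.

Classification per (gene, contrast), with `alpha = 0.05` and
`min_eff = log2(1.2)`:

* **translation**: `q(gamma) < alpha`, `|gamma| > min_eff`,
  `|dP| > min_eff`, and `|dP| > |dT|`;
* **buffering**: `q(gammaB) < alpha`, `|gammaB| > min_eff`,
  `|dT| > min_eff`, and `|dT| > |dP|`;
* **abundance**: both marginal fold changes significant with the same sign;
* otherwise **none**, with exclusive priority
  translation > buffering > abundance.

The two dominance conditions (`|dP| > |dT|` and its mirror) are a design
choice of this package: they make the directional calls mutually exclusive,
so that swapping the two fraction matrices swaps translation and buffering
calls exactly, and a buffering gene whose estimated polysome fold change
drifts past `min_eff` by noise (about a 10% event at these group sizes)
cannot be misrouted to translation. Without them both properties fail.

# Alternative splicing

Events are enumerated from pairwise comparison of transcript exon chains
within each gene, in the seven classical types (SE, A5, A3, MX, RI, AF,
AL), strand-resolved; duplicate events across transcript pairs are merged by
type and coordinates with transcript sets unioned. A5/A3 candidates require
the exons at the differing boundary to overlap, which prevents the flanking
introns of a skipped exon from masquerading as alternative splice sites.
PSI per event and sample is the inclusion share of the combined
inclusion+exclusion TPM, missing below a 1 TPM floor (configurable).

The dPSI test is empirical, in the spirit of transcript-based differential
splicing tools: observed `|dPSI|` (difference of group means) is referred to
a pooled null of within-group replicate differences, stratified into 10
expression bins by the event's mean log2 transcript TPM, with a +1
pseudo-count; BH across events per contrast. The replicate pairs are
rescaled by `sqrt((1/n1 + 1/n2)/2)` to the sampling scale of a between-group
mean difference: a replicate-pair difference has variance `2*sigma^2`
whereas the tested mean difference has `sigma^2*(1/n1 + 1/n2)`, so without
the factor the null is ~2.4x too wide at 6 replicates per group and the
test's type-I error collapses to ~0.005. With it the test holds its nominal
level (checked against the binomial interval in the suite). The null uses
within-group pairs only; an empty expression bin falls back to the global
null.

Overlap of event sets between fractions uses the one-sided hypergeometric
(Fisher) upper tail computed in log space — the same core as ORA — and the
age trend of event counts uses a Pearson chi-square against a uniform
expectation.

# Alternative polyadenylation

Each transcript's terminal fragment is its final two exons in transcription
direction; fragments with 3' ends within 25 nt (single-linkage, boundary
inclusive) define one APA site. Sites are ordered proximal to distal in
transcription direction with positional weights `w = m/(n-1)`; a gene's psi
per sample is the weighted site-usage average, so 0 is exclusive
most-proximal usage and 1 exclusive most-distal. Genes need two sites to be
testable; psi is missing when the gene's terminal abundance is below 1 TPM.
Significance is a two-sided Welch t per gene and contrast with BH: the
replicate structure here has no nesting, so a mixed model would add
parameters without information. Degenerate zero-variance cases return p = 1
(equal means) or p -> 0 (unequal), documented limits of the t statistic.

# Temporal trajectories

Per gene, the profile is the vector of age-group means of log2 CPM, z-scored
with the population sd over the 4 points; constant profiles are flagged and
excluded. Profile similarity is the Pearson correlation of the two profiles
after linear interpolation onto a uniform 101-point grid over real age
(3–20 months), evaluated with trapezoid quadrature weights. Trapezoid
weighting matters: with equal weights the grid correlation converges only
O(h) and can differ from a dense grid by up to 0.04 at 101 points; with
trapezoid weights it converges O(h^2) and agrees with a 10^4-point grid to
better than 1e-3, so the default grid is already effectively exact.

Clustering is a one-dimensional circular self-organizing map: k nodes on a
ring, distance `1 - similarity`, Gaussian ring-distance neighborhood whose
width decays exponentially from `k/2` to 0.5 while the learning rate decays
from 0.5 to 0.01 over 200 epochs, nodes initialized by sampling profiles
under a fixed seed. After annealing, a batch convergence step sets each node
to the mean of its members and recomputes assignments once; without it the
residual neighborhood pull (width 0.5 at the end) drags nodes toward each
other and inflates the quantization error at small k, which biases model
selection toward large k.

The cluster count minimizes the BIC of the spherical-Gaussian
classification likelihood at the SOM partition:

    BIC(k) = n*d*ln(RSS/(n*d)) + 2*sum_c n_c*ln(n/n_c) + k*(d+1)*ln(n)

with `n` profiles, `d = 4` ages, `RSS` the summed squared distance of
profiles to their node, and `n_c` the cluster sizes. The mixing-proportion
entropy term is essential: a pure quantization-error BIC
(`n*d*ln(RSS/(n*d)) + k*d*ln(n)`) always gains about `0.25*n_c*d` from
splitting a well-populated cluster in half — rivaling the `d*ln(n)` penalty
at every realistic size — and over-selects k on data whose clusters are not
perfectly spherical (we observed 15–40% over-selection across seeds at sizes
from 30 to 300, and a Gaussian-mixture cross-check with mclust selected the
planted k on 20/20 seeds where the quantization-error form did not). With
the classification-likelihood form, three planted shapes are recovered as
k = 3 across seeds and a single tight cloud yields a BIC monotone increasing
in k.

# Enrichment

ORA is the upper-tail hypergeometric of the overlap between a selected list
and each set against a fixed universe, BH across the collection — the same
log-space core as the splicing overlap test. GSEA is the weighted
Kolmogorov–Smirnov running sum (hit increments proportional to
`|score|^weight`, weight 1 by default) over ranked lists of the four
regulatory axes (total-RNA change, translated change, translation effect
gamma, buffering effect gammaB), with a gene-label permutation null
(ranked-list GSEA semantics), `NES = ES / mean(|null ES| of matching sign)`,
and the standard positive/negative-pool FDR. Sets outside 5–500 genes after
intersection are skipped. Annotation content arrives as user GMT files, as
database versions make term counts irreproducible.

# The synthetic-data generators

`simulate_experiment` draws negative-binomial counts with gene-wise
dispersions log-normal around the configured value, library sizes log-normal
around 8e6 reads (the operating point of the filter), additive per-gene
log2 batch offsets, and a subject-level log2 effect shared between a
subject's two fractions (the two libraries of a subject derive from one
tissue extract). Mode genes receive a log2 offset of magnitude `effect` with
random sign at the oldest age: translation genes in the polysome means only,
buffering genes in the total means only, abundance genes in both. Designated
outlier samples receive independent per-gene log2 perturbations (sd 2) that
depress their average inter-sample correlation. All generators restore the
global RNG state and are byte-reproducible under a fixed seed.

`simulate_paired_profiles` is the Gaussian log2-scale counterpart used for
recovery studies at a stated noise level. Its per-sample variance
`noise_sd^2` (default 0.25^2) splits into a subject-shared fraction
(`coupling`, default 0.85) and a fraction-specific library residual. The
decomposition reflects same-extract biology and is what makes the two halves
of the mode classifier simultaneously well-posed: the marginal DE tests
(which power the abundance call) see the full per-sample sd, while the APV
regression conditions away the shared part (slope near `coupling`), so an
abundance gene's adjusted effect `gamma ~ effect*(1 - beta)` stays below
`min_eff` and is not misread as translation. With weak coupling the same
classifier provably leaks abundance into translation; with a very large
independent subject term the marginal tests lose the abundance genes
instead.

`simulate_transcript_tpm` realizes planted per-age PSI and APA psi values
as transcript abundance shares, with zero-mean noise on the logit scale
(clipped to [0, 1]; exact at planted 0 and 1, where the logit is
degenerate), remaining transcripts splitting their gene's abundance evenly,
and sample columns normalized to 1e6. Logit noise avoids boundary
artifacts; near psi = 0.5 its PSI-scale sd is about a quarter of the logit
sd.

`simulate_trajectory_profiles` plants three mutually orthogonal z-scored
shape centroids (monotone up, monotone down, a mid-life peak; a V shape is
available) with isotropic truncated-normal (±2 sd) perturbations, 20 genes
per shape and sd 0.2 by default. The isotropy matches the spherical model
class of the BIC, and the truncation keeps the benchmark free of stray
between-cluster profiles: it probes recovery of clear structure, not
robustness to outliers. The benchmark sizes here (60 profiles) are the
package's chosen study conditions for structural validation.

What the generators do not emulate: mean–variance trends beyond the NB law,
correlated gene modules, length or GC biases, isoform-level quantification
uncertainty, and ambient or mapping noise. Passing recovery tests therefore
demonstrates correctness of the statistical machinery under its own model
assumptions, not performance on real libraries.

# Numerical conventions

Coordinates are 1-based inclusive (GTF) throughout the annotation tables;
event keys are plain coordinate strings, so reflection tests can assert
exact equality. Quartiles use type 7. BH is `p.adjust(method = "BH")`
everywhere. Hypergeometric tails are computed in log space and exponentiated
last. Permutation and empirical p-values carry a +1 pseudo-count so they are
never zero. Seeds: every public generator takes an explicit seed, evaluates
under it, and restores the caller's RNG state; internal stages derive child
seeds (kept below 2^31) from a master seed.

# Problem sizes used by the validation suite

Calibration runs use 2000 null genes (or ~2000 events) at the design's
replicate counts; recovery runs use 1000 genes with 50 planted genes per
mode, 70 events across the seven types, and 60 trajectory profiles. These
sizes give binomial confidence intervals narrow enough to detect
miscalibration of a 5% test while keeping each check fast to re-run.

# Known limitations

* The moderated linear model on log2 CPM approximates a count model; at very
  low counts its variance model is less faithful than a quasi-likelihood NB
  fit.
* The batch model is location–scale only; batch effects that alter
  correlation structure are out of scope.
* The empirical dPSI null pools within-group variability across events of
  similar expression; events with idiosyncratic technical variance inherit
  the pooled null.
* APA psi uses whole-transcript TPM as the terminal-fragment abundance
  proxy; with fragment-level quantification upstream the same interface
  applies.
* Mode classification evaluates each contrast independently; no longitudinal
  model links the six contrasts.
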