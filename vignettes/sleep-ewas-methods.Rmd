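---
title: "Methods: EWAS of sleep initiation with sleepewas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EWAS of sleep initiation with sleepewas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sleepewas` implements an epigenome-wide association (EWAS) pipeline for
sleep initiation in adolescents: nine sleep measures — bedtime, sleep
onset latency (SOL) and sleep onset time (SOT), each assessed by
self-report, wrist actigraphy and in-lab polysomnography — are regressed,
one CpG site at a time, on DNA-methylation levels derived from
RRBS-style bisulfite sequencing counts. This vignette is the package's
own account of the statistical procedure, its tunable parameters, the
synthetic-data generator used to validate it, and its known limitations.

## The measures and clock-time arithmetic

Bedtimes and SOTs straddle midnight, so all clock times live on a
continuous decimal-hour scale covering one evening-to-morning window:
`[12, 36)` hours, where 28.5 means 04:30 the next morning. `parse_clock()`
maps `"hh:mm"` text into this domain (hours below 12 are pushed forward by
+24; adolescent bedtimes between noon and 8 pm do not occur in the
populations this pipeline targets, so the threshold is safe), and
`format_clock()` renders it back, losslessly to the minute.

Three identities define the measures:

* habitual self-reported bedtime is the school-week weighted average
  `(5 * weekday + 2 * weekend) / 7` of the two questionnaire items;
* `SOT = bedtime + SOL / 60`, per method — the package treats this as a
  construction identity, re-checks it (to one minute) whenever
  precomputed SOTs are loaded, and preserves it in every simulation;
* consequently `mean(SOT) = mean(bedtime) + mean(SOL)/60` exactly over
  any subject set, which the acceptance suite uses as a worked check
  against the cohort summary statistics (PSG bedtime 22:00 + SOL
  25.7 min → SOT 22:26 to the nearest minute).

Self-reported SOL is a single questionnaire item, so no weekday/weekend
weighting applies to it. Whether a SOL arrives from a questionnaire, the
actigraphy scoring software or PSG epoch scoring is upstream of this
package: SOL and bedtime enter as numbers.

## Methylation levels and site filtering

Input is one Bismark-coverage-style TSV per sample (chrom, position,
position, percent, methylated count, unmethylated count; 1-based). The
percentage column is ignored and levels are always recomputed as
`meth / (meth + unmeth)`; a file whose percentages disagree with its own
counts triggers a warning, and the counts win.

The analyzability filter is two-stage, operationalizing the "below 10×
coverage or available from under 50% of samples" exclusion rule:

1. a site × sample cell is *available* iff its coverage is at least
   `min_coverage` (default 10; zero-coverage cells never count);
2. a site is *retained* iff it is available in at least
   `min_sample_fraction` of **all** samples (default 0.5, with
   exactly-50% retained — the exclusion is strictly-less-than).

The rule's source text does not say whether the 50% count is taken
before or after the 10× rule; the two-stage reading above (cell-level
availability first, fraction over all samples second) is the standard
RRBS practice and is what the brute-force filter oracle in the tests
encodes. At retained sites, unavailable cells are *masked*: they are
excluded from every downstream statistic and never imputed, so each
site's regression is complete-case. Imputation would inject model
assumptions the source design never made.

## The per-site association model

For each retained site \(s\) and measure \(m\),

\[ y_{im} = \alpha + \beta_{sm}\,x_{is} + \gamma^{\top} z_i +
\varepsilon_{im}, \]

fit by ordinary least squares over the site's unmasked samples, where
\(x_{is} \in [0,1]\) is the methylation proportion and \(z_i\) the
covariates: age (years), sex (1 = male), race (1 = non-minority), BMI
percentile (0–100, continuous) and assay batch (one-hot, first batch as
reference). Because \(x\) is a proportion, \(\beta\) is directly the
phenotype change per 100% change in methylation: minutes per unit for
SOL, hours per unit for bedtime and SOT. The reported p-value is the
two-sided t-test on the methylation coefficient with residual degrees of
freedom. Sites whose design is rank-deficient drop the aliased covariate
with a warning; sites with constant methylation or too few complete
observations are skipped, with the reason recorded, and never silently
imputed.

Benjamini–Hochberg FDR (`stats::p.adjust`, validated by a hand-written
step-up oracle in the tests) is applied **within each measure** across
its estimable sites, because significance is reported measure-by-measure;
pooling across the nine measures would couple their discovery lists.
Significance is `q < 0.05`. No genomic-inflation correction, cell-type
deconvolution or surrogate-variable adjustment is applied — the modelled
design includes none.

Numerically, each fit solves the normal equations by Cholesky (exact for
full-rank designs and fast enough for genome-scale loops), falling back
to pivoted QR when the cross-product is numerically rank-deficient
(relative pivot tolerance `1e-7`).

## Annotation and site groups

Gene bodies are extended by 1500 bp upstream and 500 bp downstream.
Whether the original analysis extended strand-aware is not stated; both
modes are implemented (`stranded` flag) and strand-aware is the default,
since the site reporting distinguishes "Upstream" from "Downstream",
which only makes sense relative to orientation. A site inside the
original body is *intragenic*; otherwise the extension containing it
names the zone. Sites overlapping no extended interval are intergenic
and never enter gene-level analyses. A site may map to several genes and
every mapping is kept, but enrichment counts a site once per group, so
multi-gene sites never double-count in the hypergeometric universe.
Overlap search uses `GenomicRanges::findOverlaps`; the test suite pins it
to an exhaustive O(S·G) scan.

BED6 input is 0-based half-open on disk and converted to the package's
1-based inclusive convention at the I/O boundary.

## Enrichment

For each measure, nominal hits are sites with association `p < 0.05`.
With universe \(N\) (analyzable non-intergenic sites), hits \(K\),
GWAS-informed group size \(n\) and observed overlap \(k\), the
hypergeometric p-value is the exact upper tail \(P(X \ge k)\),
\(X \sim \mathrm{Hypergeom}(N, K, n)\) — computed at the **site** level,
because the compared quantity is the distribution of CpG sites.

The permutation test (1000 permutations by default) resamples at the
**gene** level: random gene sets of the same gene count are drawn from
the annotated universe and the hit-site statistic recomputed, which
preserves intra-gene site correlation under the null. The resampled unit
is not stated in the source design; gene-level is this package's choice,
and a site-level variant is available (`null_unit = "site"`). The
p-value uses the add-one correction \((1 + \#\{\text{null} \ge
\text{obs}\})/(B + 1)\), so it is never 0 and never below \(1/(B+1)\),
and is bit-reproducible under a fixed seed. Under an exchangeable null
(uniform site p-values, equal-size genes) the two tests agree to within
±0.05 in ≥95% of seeded runs — an acceptance property.

GO over-representation is gene-level: the universe is every annotated
gene with at least one analyzable site, the significant set is genes
containing at least one `q < 0.05` site, each term gets the exact
hypergeometric upper tail, and BH runs within each ontology. The
gene→term map is supplied by the user and taken as given (no ontology
download, no graph propagation); whether "significant genes" should be
restricted to GWAS-informed hits is unstated, and the package uses all
annotated genes.

## The synthetic-data generator

Every stage is validated on synthetic studies with known ground truth;
`sim_config()` defaults *are* the emulated study conditions and are not
adjusted per test:

* cohort: n = 263 subjects; age 17.3 (SD 2.1, range 13–23); 55.9% male;
  23.2% racial/ethnic minority (the cohort table prints that percentage
  against its non-Hispanic-white row, but the running text describes it
  as the minority share — the text reading is used, and `race` is coded
  1 = non-minority); BMI percentile 64.5 (SD 29, range 0.7–99.8); four
  assay batches.
* phenotypes: truncated normal bedtimes and truncated log-normal SOLs
  calibrated to the published means/SDs (e.g. PSG SOL 25.7, SD 21.45
  min; PSG bedtime 22:00, SD 12 min within the 21:00–23:06 lab window);
  SOT constructed as `bedtime + SOL/60`. The three methods within a
  construct share a Gaussian copula with correlation 0.4 — the source
  reports cross-method correlations only as a figure, so this moderate
  positive default is configurable rather than calibrated.
* methylation: per-site mean methylation `Beta(0.8, 0.8)` (the bimodal
  profile typical of CpGs), subject-level proportions
  `Beta(mu*phi, (1-mu)*phi)` with precision 10, coverage negative
  binomial (mean 30, size 5 — over-dispersed, so a realistic share of
  cells falls below 10×), and 8% of cells dropped to zero coverage to
  exercise the availability filter.
* genome: desk-scale by default — 60 genes (~6 CpGs each, placed within
  the extended borders) plus 120 intergenic sites on two chromosomes,
  i.e. hundreds of sites rather than the ~10^5 of a real RRBS run. The
  calibration runs in the acceptance suite scale this up to ~2,000
  sites; these sizes are the package's validation design.

Planted effects re-generate the designated measure as `baseline +
effect × methylation + covariate terms + noise`, with two deliberate
choices. First, the effect multiplies the **observed** methylation level
(counts/coverage), not the latent beta proportion: the regression's
estimand is then exactly the planted effect, so unbiased-recovery checks
are meaningful. Had the effect been applied to the latent proportion,
binomial measurement error at 30× coverage would attenuate every OLS
estimate by its reliability (~0.6–0.7) and "recovery" would be testing
the attenuation factor, not the pipeline. Second, planting preserves the
SOT identity: a bedtime or SOL effect propagates into the corresponding
SOT, and a direct SOT effect holds SOL fixed and backs bedtime out.
Planted re-generation is a pure linear-model draw and is not truncated
to the phenotype's natural range — truncation would censor the outcome
and bias the very recovery the ground truth exists to verify.

What passing synthetic tests do **not** show about real data: no
cell-type composition, no genomic inflation from population structure,
no correlated methylation between neighbouring CpGs, no non-linear
dose–response, and phenotype noise that is exactly the generating model.

## Calibration behaviour and a known limitation

Under the complete null, the bulk of the per-site p-value distribution
is uniform (empirical `P(p < 0.05)` within [0.035, 0.065] at 2,000
sites, an acceptance property). Two caveats concern the extremes:

* even with perfect calibration, BH rejects at least one site per
  measure family with probability ≈ α under the global null (Simes'
  identity), so a fully empty significance table across all nine
  measures occurs with probability at most about `0.95^9 ≈ 0.63`, less
  when the far tail misbehaves (next point). The acceptance suite
  asserts the stricter all-measures-empty property and measures exactly
  this gap; the companion per-measure family-wise-error assertion holds.
* OLS t-tests on the strongly skewed (log-normal) SOL phenotypes are
  anti-conservative in the far tail that BH probes at its smallest
  ranks (`p < α/m ≈ 10^-4`), so SOL and SOT measure families reject a
  first site under the null more often than α. This is a property of
  ordinary least squares applied to skewed outcomes at n = 263 — i.e.
  of the modelled design itself — not of the implementation; bedtime
  (near-normal) families are calibrated. Robust or permutation-based
  per-site inference would remove it, but is deliberately out of scope
  because the modelled analysis used plain multivariable regression.

## Reproducibility

Every generator and the permutation test consume explicit seeds; a
pipeline run derives all stage seeds from one root seed, and rerunning
the same configuration is byte-identical down to the serialized
artifacts. RNG state of the calling session is saved and restored around
every seeded computation.

```{r, eval = FALSE}
library(sleepewas)
pe <- tibble::tibble(gene_id = "G0001", measure = "sol_sr", effect = 60)
cfg <- pipeline_config(
  simulate = sim_config(planted_effects = pe, seed = 1),
  n_perm = 1000, seed = 1)
run <- run_pipeline(cfg, out_dir = "ewas_run")
run$summary
run$enrichment
```
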