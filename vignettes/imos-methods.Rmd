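---
title: "Methods: the imos discovery cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the imos discovery cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what each stage computes,
which knobs matter, what the synthetic generator does and does not
emulate, and where a genuinely open design choice was settled.

## Immune scoring and stratification

`ssgsea_score()` computes a single-sample, rank-weighted enrichment
score. Within each sample, genes are ranked by descending expression
(ties receive average ranks; missing values rank last). Walking the
ranked list, `P_hit` accumulates `|rank|^alpha` over signature genes,
normalized by its total; `P_miss` accumulates a uniform step over
non-signature genes; the score is `sum(P_hit - P_miss)` over all
positions. Because only within-sample ranks enter, the score is
invariant under any strictly increasing per-sample transformation —
a useful robustness property across expression platforms. Genes tied in
expression are walked signature-members-first, then alphabetically, so
the result never depends on the storage order of the matrix.

* `alpha = 0.25` by default, the common single-sample weighting; `alpha
  = 0` gives unweighted steps and is what the brute-force test oracles
  enumerate.
* No fixed immune signature ships with the package: published signature
  lists are licensed data, and the scoring algorithm — not the list —
  is the computation. Signatures are user-supplied (GMT or plain list);
  the synthetic truth carries its own.
* Stratification: samples *above* the median score are immune-high;
  samples exactly at the median go to the low group. A deterministic
  tie rule matters more than which side ties land on. The quantile rule
  generalizes this: `q` is the *fraction labelled high* (cut at the
  `1 - q` quantile), so `q = 0.5` reproduces the median rule.

## Differential expression

`moderated_t_test()` implements the empirical-Bayes moderated t with a
scaled-inverse-chi-square variance prior. Per gene, the pooled two-group
variance `s²_g` on `d_g` degrees of freedom is shrunk to
`s~²_g = (d0 s0² + d_g s²_g)/(d0 + d_g)`; the statistic uses `d0 + d_g`
df. The prior `(d0, s0²)` is estimated by method-of-moments on
`log s²_g` (digamma/trigamma moments; trigamma inverted by Newton steps,
tolerance `1e-8`, at most 50 iterations). Degenerate inputs (fewer than
two usable variances) fall back to `d0 = 0` — the ordinary pooled t —
with a warning; a non-positive moment estimate yields `d0 = Inf`,
i.e. complete shrinkage to `s0²`. The test suite checks this fit against
an independent implementation of the same estimator.

The DEG gate is `|log2FC| > log2(1.5)` and `p < 0.05`, both tails. The
bulk RNA-seq path (`fpkm()`, `bulk_deg_select()`) uses the standard
FPKM definition — fragments divided by (mapped reads in millions ×
exon length in kb) — and a 2-fold gate with a pooled t on
`log2(FPKM + 1)`; for two groups the nested-model F test is exactly the
squared pooled t, so the t form is used. A pseudocount of `1e-6` guards
the linear fold-change ratio.

## Survival statistics

`km_estimate()` is the product-limit estimator over distinct event
times; times carrying only censored observations adjust the at-risk
counts but contribute no factor, and censored observations tied with
events at `t` are considered at risk at `t` (the standard convention).
`logrank_test()` accumulates, at each distinct event time, the
hypergeometric expectation `d_t n_gt / n_t` and variance, and refers
`(O - E)²/V` to chi-square on 1 df.

The direction call is deliberately nonparametric: the designated high
group is *harmful* iff its observed events exceed expectation
(`O_high > E_high`). This needs no hazards model and is exactly the
quantity the test already computes; significance is left to the caller's
alpha. Zero-event inputs return `chi2 = 0, p = 1, direction = "none"`
rather than erroring, because genome-wide screens must keep going.

`gene_survival_screen()` median-splits each gene (`q` is again the
high fraction, ties low), excludes missing-expression samples, and
records per-gene skips (absent gene, fewer than 4 informative samples,
zero variance) instead of failing. The default gate is the *raw*
`p < 0.05` — matching the screening convention of discovery studies —
with Benjamini–Hochberg correction available by flag
(`bh_fdr()` wraps the standard step-up; the suite verifies it against a
brute-force evaluation of the definition).

## Multi-omic evidence gates

* *Mutation*: frequency is distinct mutated samples over cohort size;
  any variant class counts (silent-variant filtering belongs to input
  preparation). The survival contrast needs at least two samples per
  group or it reports a skip.
* *Copy number*: "duplication" is thresholded state `> 0` — gain or
  amplification — since published calls rarely state their cutoff.
  Concordance is Pearson r of state vs expression with BH-FDR across
  the tested gene set; the flag requires `q < 0.05` *and* `r > 0`.
* *Methylation*: per-probe Pearson r of beta vs expression; the probe
  FDR pool defaults to all tested probes analysis-wide (a genome-wide
  screen), configurable to per-gene. A gene is methylation-repressed
  when any probe has `r < 0` at `q <` the gate. Probe-level survival
  reports its direction on the methylation scale
  (`low_methylation_worse` / `high_methylation_worse`).

## Single-cell stage

QC thresholds are strict inequalities: cells *below* 2000 UMIs or 500
detected genes, or *above* 10% mitochondrial fraction, are removed, and
doublet suspects must exceed 40,000 UMIs **and** 5,000 detected genes
(a single extreme criterion is not enough). Cells sitting exactly on a
threshold are kept. Most toolkits default to inclusive cuts, so the
boundary semantics are stated and tested explicitly. Filtering is
idempotent and logs a reason per removed cell.

Normalization scales each cell to 10,000 counts (the common library-size
convention) and applies natural `log1p`; base-e vs base-2 only rescales
all means by a constant, so the specificity score is unaffected. The
specificity score of a gene is `max(per-type mean) / (sum of means +
1e-9)`; the dominant type is the argmax with lexicographic tie-breaking,
and ties are flagged. Cell-type *labels are inputs*: clustering and
annotation are a separate, well-served problem and deliberately out of
scope.

## The cascade and candidate ranking

`run_imos()` chains the stages; any failure aborts naming the stage.
Validation uses a `k`-of-`n` rule (`k = 1` by default) with direction
consistency required — the natural conservative reading when a protocol
says only "validated in independent cohorts". The candidate pool
defaults to the credible harmful genes (checkpoints restrain anti-tumor
immunity, so high expression tracking shorter survival is the relevant
sign); a flag screens the beneficial side symmetrically. The five
evidence flags are equally weighted booleans: with evidence of
heterogeneous provenance and unknown reliability, a flat count is the
only weighting that does not pretend to knowledge the data do not
carry. Ties break by CNV correlation, then gene id.

The cascade only narrows: `DEG ⊇ IPG ⊇ IBG ∪ IHG ⊇ cIPG ⊇ candidates`
holds structurally, and the report is a pure function of (inputs,
config), so identical runs give byte-identical JSON.

## The synthetic generator

`simulation_truth()` + the `generate_*()` functions are first-class,
tested code — the package's instrument for verifying every stage at
desk scale.

* *Expression*: `x = a·u + noise + 8`, with a standard-normal latent
  immune factor `u` per sample. Signature and beneficial genes load
  `+a`, harmful genes `-a` (default `a = 1`). The sign split is a
  modelling necessity, not decoration: in a marginal screen, a gene's
  direction call follows its dominant correlate, so genes sharing one
  factor can only carry opposite survival directions if they load with
  opposite signs. The factor itself then comes out protective —
  immune-hot tumors fare better — which matches the survival skew such
  cohorts show (here 70 beneficial vs 20 harmful of 90 prognostic).
* *Survival*: exponential times with log-hazard `b0 + sum(beta·z)` over
  standardized planted expression, `|beta| = log 2` (hazard doubles per
  SD), baseline median 30 months; mutated prognostic genes multiply
  carrier hazard (HR 2 in 15% of samples). Exponential rather than
  Weibull keeps proportional hazards exact and the planted effects
  analytically transparent. Censoring is independent uniform with its
  upper bound calibrated by root-finding so the expected censored
  fraction hits the target (default 0.4).
* *Copy number*: states are drawn by thresholding a Gaussian copula on
  the gene's expression at fixed state frequencies (2/18/50/25/5% for
  -2..2). Discretization attenuates correlation, so the latent
  correlation is inflated by the analytically computed attenuation
  factor and the realized correlation is recorded; exact targets on
  discrete states are not generally achievable, and `|rho| > 0.95` is
  rejected.
* *Methylation*: beta values are `plogis` transforms of a latent
  Gaussian anticorrelated with expression (target r = -0.5, again with
  numeric attenuation compensation), 2–4 promoter probes per planted
  gene, guaranteeing `beta ∈ [0, 1]`.
* *Single cell*: per-type profiles from shared gamma gene weights with
  lognormal type jitter; the planted checkpoint is expressed essentially
  only in its mapped type; counts are Poisson at lognormal depth
  (mean 6,000 UMIs over ~6,000 genes, so detected-gene counts sit
  meaningfully between the QC thresholds). Known QC failures are
  injected — low-depth, high-mitochondrial, and summed-profile doublet
  cells — with the injected ids recorded, so filter exactness is
  testable.

Default cohort sizes mirror a realistic discovery design — 515
discovery samples, four validation cohorts totalling 530 — over a
500-gene universe; the survival-screen calibration and power checks run
at 1,000 genes × 200 samples and 50 planted genes × 400 samples × 10
seeds respectively. These sizes were chosen as the smallest at which
the planted effects operate in their asymptotic regime.

What the generator does **not** emulate: real platform noise, batch
effects, the empirical correlation structure of tumor transcriptomes,
informative censoring, copy-number segmentation artifacts, or ambient
RNA and empty droplets in single cell. Green tests certify the
machinery — estimator correctness, calibration, recovery of planted
structure — not performance on any particular real cohort.

## Known limitations

* No Cox regression or covariate adjustment; the screen is marginal by
  design, and confounded prognostic signal will pass it.
* Median splits discard within-group expression dose; optimal-cutpoint
  scanning is deliberately avoided (it inflates type I error).
* The chi-square log-rank p is asymptotic; at very small n an exact or
  permutation p is preferable (the suite quantifies the gap on a
  10-sample fixture).
* The k-of-1 validation default is permissive; with many validation
  cohorts, raising `validation_min_cohorts` is advisable.
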