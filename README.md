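# imos

Multi-omic and single-cell screening of candidate immune-checkpoint genes
in tumor cohorts.

## The problem

Immune checkpoints — genes whose products restrain anti-tumor immunity —
are rare needles in a genome-wide haystack. A practical discovery
strategy is a *cascade* of orthogonal filters over public tumor data:

1. **Immune stratification.** Each tumor gets a rank-based single-sample
   enrichment score for an immune gene signature (ssGSEA-style): genes
   are ranked by expression within the sample and the score is the
   summed difference between the weighted cumulative hit distribution
   over signature genes and the uniform step over the rest,
   `sum_i [P_hit(i) − P_miss(i)]` with hit weights `|rank|^alpha`.
   Samples above the median score are immune-high.
2. **Differential expression.** Genes separating immune-high from
   immune-low tumors (empirical-Bayes moderated t; gates FC > 1.5,
   p < 0.05). The moderated variance is
   `s~²_g = (d0·s0² + d_g·s²_g)/(d0 + d_g)` with the prior `(d0, s0²)`
   estimated across genes by method-of-moments on log variances.
3. **Survival screen.** Each DEG is median-split and tested with the
   log-rank (Mantel–Cox) statistic; significant genes are *immune-related
   prognostic genes* (IPG), split by their observed-vs-expected event
   balance into *beneficial* (IBG, high expression → longer survival)
   and *harmful* (IHG).
4. **Cross-cohort validation.** IPGs must replicate (p < 0.05, same
   direction) in at least `k` independent cohorts to become *credible*
   (cIPG = cIBG ∪ cIHG).
5. **Multi-omic evidence gates.** For each credible harmful gene:
   mutation frequency and mutated-vs-unmutated survival; Pearson
   correlation of thresholded copy-number states with expression
   (BH-FDR < 0.05, r > 0) and duplication-vs-rest survival; per-probe
   methylation/expression anticorrelation and probe-level survival.
6. **Single-cell localization.** After QC (cells below 2000 UMIs or 500
   detected genes or above 10% mitochondrial counts removed; doublets =
   more than 40,000 UMIs *and* 5,000 genes), library-size + log1p
   normalization, and a per-cell-type specificity score
   `max(mean)/sum(means)` that names the cell type expressing the
   candidate.

Candidates are ranked by the count of five equally weighted evidence
flags. Every stage is exposed as an ordinary R function, and a
synthetic-cohort generator with *planted, known-truth* signal (latent
immune factor, proportional-hazards survival, copy-number and
methylation coupling, labeled single-cell counts) makes the whole
cascade verifiable offline.

## Worked example

```r
library(imos)

dir <- tempfile()
truth <- simulation_truth()            # planted checkpoint: g0051, macrophage
simulate_bundle(dir, truth, seed = 1)  # writes TSV/GMT/MTX inputs + truth.json

report <- run_imos(dir, imos_config(seed = 1))
print(report)
#> iMOS discovery report
#>   DEG: 90   IPG: 90 (IBG 70 / IHG 20)
#>   credible: 90 (cIBG 70 / cIHG 20)
#>   top candidate: g0051 (evidence 5/5, macrophage)
head(report$candidates[, c("rank", "gene_id", "evidence_count",
                           "dominant_cell_type", "specificity_score")])
#>   rank gene_id evidence_count dominant_cell_type specificity_score
#> 1    1   g0051              5         macrophage         0.9921422
#> 2    2   g0056              4         epithelial         0.3098905
#> 3    3   g0055              4         macrophage         0.3455318
```

Reading: of 500 synthetic genes, 90 pass the immune DEG gate, all 90 are
prognostic (70 beneficial, 20 harmful), and all validate in the four
synthetic validation cohorts. The planted checkpoint gene `g0051` is the
only gene carrying all five evidence layers — copy-number concordance,
duplication-worse survival, methylation anticorrelation, low-methylation-worse
survival, and macrophage-specific single-cell expression — so it ranks
first; the decoys (other planted harmful genes) top out at 4 flags.

A thin CLI wrapper lives at `inst/cli/imos`
(`imos simulate --out DIR`, `imos run --in DIR --out DIR`).

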