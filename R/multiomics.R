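#' Mutation frequency per gene
#'
#' Fraction of cohort samples carrying at least one variant of the gene
#' (distinct-sample counting, any variant class); genes absent from the
#' table score 0.
#'
#' @param mutations mutation `data.frame` (`sample_id`, `gene_id`,
#'   `variant_class`).
#' @param cohort_samples character vector, the cohort sample universe.
#' @param genes genes to report (default: all genes in the table).
#' @return named numeric vector of fractions in `[0, 1]`.
#' @export
snv_frequency <- function(mutations, cohort_samples, genes = NULL) {
  if (!length(cohort_samples)) stop("empty cohort sample universe", call. = FALSE)
  mutations <- validate_mutations(mutations, cohort_samples)
  if (is.null(genes)) genes <- sort(unique(mutations$gene_id))
  counts <- vapply(genes, function(g)
    length(unique(mutations$sample_id[mutations$gene_id == g])), numeric(1))
  counts / length(cohort_samples)
}

## Wrap a log-rank delegation, remapping the generic high/low direction to
## domain terms; returns NULL with a skip reason when preconditions fail.
.logrank_or_skip <- function(times, events, in_group, group_name, other_name,
                             worse_label, better_label, min_group = 2L) {
  if (sum(in_group) < min_group || sum(!in_group) < min_group)
    return(structure(list(skip_reason = sprintf("fewer than %d samples per group",
                                                min_group)),
                     class = "imos_skip"))
  grp <- ifelse(in_group, group_name, other_name)
  lr <- logrank_test(times, events, grp, high_level = group_name)
  lr$direction <- switch(lr$direction,
                         high_worse = worse_label,
                         high_better = better_label,
                         "none")
  lr
}

#' Survival contrast of mutated vs unmutated samples
#'
#' @param mutations mutation `data.frame`.
#' @param cohort an `imos_cohort`.
#' @param gene gene id.
#' @param min_group minimum samples per group (default 2; smaller groups
#'   yield a skip, not an error).
#' @return `imos_logrank` with direction `mutated_worse` /
#'   `mutated_better`, or an `imos_skip` carrying the reason.
#' @export
mutation_survival <- function(mutations, cohort, gene, min_group = 2L) {
  mutations <- validate_mutations(mutations)
  samples <- cohort$clinical$sample_id
  carriers <- unique(mutations$sample_id[mutations$gene_id == gene])
  .logrank_or_skip(cohort$clinical$os_time, cohort$clinical$os_event,
                   samples %in% carriers, "mutated", "unmutated",
                   "mutated_worse", "mutated_better", min_group)
}

#' Copy-number / expression concordance screen
#'
#' Per gene, Pearson correlation between the thresholded copy-number state
#' and expression across shared samples; q-values by Benjamini-Hochberg
#' over the tested set.  A gene is flagged concordant when `q < fdr` and
#' `r > 0`.
#'
#' @param cnv integer genes x samples state matrix.
#' @param expr genes x samples expression matrix.
#' @param genes genes to test (default: genes shared by both matrices).
#' @param fdr FDR gate for the concordance flag (default 0.05).
#' @return `data.frame` (`gene_id`, `r`, `p`, `q`, `n`, `concordant`,
#'   `skip_reason`).
#' @export
cnv_expression_correlation <- function(cnv, expr, genes = NULL, fdr = 0.05) {
  if (is.null(genes)) genes <- intersect(rownames(cnv), rownames(expr))
  shared <- intersect(colnames(cnv), colnames(expr))
  if (length(shared) < 3L)
    stop("fewer than 3 samples shared between CNV and expression", call. = FALSE)
  rows <- lapply(genes, function(g) {
    if (!(g %in% rownames(cnv)) || !(g %in% rownames(expr)))
      return(data.frame(gene_id = g, r = NA_real_, p = NA_real_, n = NA_integer_,
                        skip_reason = "absent", stringsAsFactors = FALSE))
    pt <- pearson_test(as.numeric(cnv[g, shared]), as.numeric(expr[g, shared]))
    data.frame(gene_id = g, r = pt$r, p = pt$p, n = pt$n,
               skip_reason = pt$skip_reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$concordant <- !is.na(out$q) & out$q < fdr & out$r > 0
  out[, c("gene_id", "r", "p", "q", "n", "concordant", "skip_reason")]
}

#' Survival contrast of copy-number duplication vs non-duplication
#'
#' Duplication = thresholded state `> 0` (gain or amplification).
#'
#' @param cnv integer genes x samples state matrix.
#' @param cohort an `imos_cohort`.
#' @param gene gene id.
#' @param min_group minimum samples per group (default 2).
#' @return `imos_logrank` with direction `duplication_worse` /
#'   `duplication_better`, or an `imos_skip`.
#' @export
cnv_group_survival <- function(cnv, cohort, gene, min_group = 2L) {
  if (!gene %in% rownames(cnv))
    return(structure(list(skip_reason = "absent from CNV matrix"),
                     class = "imos_skip"))
  shared <- intersect(colnames(cnv), cohort$clinical$sample_id)
  if (!length(shared))
    return(structure(list(skip_reason = "no shared samples"), class = "imos_skip"))
  clin <- cohort$clinical[match(shared, cohort$clinical$sample_id), ]
  dup <- cnv[gene, shared] > 0
  .logrank_or_skip(clin$os_time, clin$os_event, dup,
                   "duplication", "no_duplication",
                   "duplication_worse", "duplication_better", min_group)
}

#' Methylation / expression anticorrelation per probe, flag per gene
#'
#' Pearson correlation of each mapped probe's beta values against the
#' gene's expression across shared samples.  Probe q-values come from a
#' Benjamini-Hochberg correction over either the analysis-wide probe pool
#' (default, a genome-wide screen) or each gene's own probes.  A gene is
#' flagged methylation-repressed when any probe has `r < 0` and `q < fdr`.
#'
#' @param meth an `imos_meth`.
#' @param expr genes x samples expression matrix.
#' @param genes genes to test (default: all genes in the probe map that
#'   are present in `expr`).
#' @param fdr FDR gate (default 0.05).
#' @param pool `"analysis"` (default) or `"gene"`.
#' @return list with `probes` (`probe_id`, `gene_id`, `region`, `r`, `p`,
#'   `q`, `negative_sig`, `skip_reason`) and `genes` (`gene_id`,
#'   `meth_negative_flag`, `n_probes`, `skip_reason`).
#' @export
methylation_expression_correlation <- function(meth, expr, genes = NULL,
                                               fdr = 0.05,
                                               pool = c("analysis", "gene")) {
  pool <- match.arg(pool)
  map <- meth$probe_map
  if (is.null(genes)) genes <- intersect(unique(map$gene_id), rownames(expr))
  shared <- intersect(colnames(meth$beta), colnames(expr))
  if (length(shared) < 3L)
    stop("fewer than 3 samples shared between methylation and expression",
         call. = FALSE)
  probe_rows <- list()
  gene_rows <- list()
  for (g in genes) {
    probes <- map$probe_id[map$gene_id == g]
    probes <- probes[probes %in% rownames(meth$beta)]
    if (!length(probes) || !(g %in% rownames(expr))) {
      gene_rows[[g]] <- data.frame(gene_id = g, meth_negative_flag = FALSE,
                                   n_probes = 0L, skip_reason = "unmapped",
                                   stringsAsFactors = FALSE)
      next
    }
    for (pr in probes) {
      pt <- pearson_test(as.numeric(meth$beta[pr, shared]),
                         as.numeric(expr[g, shared]))
      probe_rows[[length(probe_rows) + 1L]] <-
        data.frame(probe_id = pr, gene_id = g,
                   region = map$region[match(pr, map$probe_id)],
                   r = pt$r, p = pt$p, skip_reason = pt$skip_reason,
                   stringsAsFactors = FALSE)
    }
    gene_rows[[g]] <- data.frame(gene_id = g, meth_negative_flag = NA,
                                 n_probes = length(probes),
                                 skip_reason = NA_character_,
                                 stringsAsFactors = FALSE)
  }
  probes_df <- if (length(probe_rows)) do.call(rbind, probe_rows) else
    data.frame(probe_id = character(), gene_id = character(), region = character(),
               r = numeric(), p = numeric(), skip_reason = character(),
               stringsAsFactors = FALSE)
  if (pool == "analysis") {
    probes_df$q <- bh_fdr(probes_df$p)
  } else {
    probes_df$q <- NA_real_
    for (g in unique(probes_df$gene_id)) {
      i <- probes_df$gene_id == g
      probes_df$q[i] <- bh_fdr(probes_df$p[i])
    }
  }
  probes_df$negative_sig <- !is.na(probes_df$q) & probes_df$q < fdr & probes_df$r < 0
  genes_df <- do.call(rbind, gene_rows)
  for (i in seq_len(nrow(genes_df))) {
    g <- genes_df$gene_id[i]
    if (is.na(genes_df$meth_negative_flag[i]))
      genes_df$meth_negative_flag[i] <- any(probes_df$negative_sig[probes_df$gene_id == g])
  }
  rownames(genes_df) <- NULL
  list(probes = probes_df, genes = genes_df)
}

#' Survival contrast of high- vs low-methylation samples at one probe
#'
#' Samples are split at the probe's beta quantile (top fraction `q` high,
#' ties low); the direction is reported on the methylation scale:
#' `low_methylation_worse` when the high-beta group fares better.
#'
#' @param meth an `imos_meth`.
#' @param cohort an `imos_cohort`.
#' @param probe_id probe to test.
#' @param q fraction of samples labelled high-beta (default 0.5).
#' @param min_group minimum samples per group (default 2).
#' @return `imos_logrank` with direction `high_methylation_worse` /
#'   `low_methylation_worse`, or an `imos_skip`.
#' @export
probe_survival <- function(meth, cohort, probe_id, q = 0.5, min_group = 2L) {
  if (!probe_id %in% rownames(meth$beta))
    stop("probe '", probe_id, "' not in the beta matrix", call. = FALSE)
  shared <- intersect(colnames(meth$beta), cohort$clinical$sample_id)
  if (length(shared) < 2L * min_group)
    return(structure(list(skip_reason = "too few shared samples"),
                     class = "imos_skip"))
  b <- meth$beta[probe_id, shared]
  ok <- !is.na(b)
  b <- b[ok]; shared <- shared[ok]
  if (!length(b) || max(b) == min(b))
    return(structure(list(skip_reason = "constant beta"), class = "imos_skip"))
  thr <- stats::quantile(b, probs = 1 - q, names = FALSE, type = 7)
  clin <- cohort$clinical[match(shared, cohort$clinical$sample_id), ]
  .logrank_or_skip(clin$os_time, clin$os_event, b > thr,
                   "high_beta", "low_beta",
                   "high_methylation_worse", "low_methylation_worse", min_group)
}

#' Assemble the per-gene multi-omic evidence table
#'
#' Runs the mutation, copy-number and methylation gates for a set of
#' candidate genes against one cohort and flattens the results into one
#' row per gene (probe-level detail in a companion table).
#'
#' @param genes candidate gene ids.
#' @param cohort an `imos_cohort` (expression + survival).
#' @param cnv integer state matrix, or `NULL` to skip the CNV gates.
#' @param meth an `imos_meth`, or `NULL` to skip the methylation gates.
#' @param mutations mutation `data.frame`, or `NULL` to skip the SNV gates.
#' @param alpha survival-gate significance level (default 0.05).
#' @param cnv_fdr,meth_fdr FDR gates (defaults 0.05).
#' @param meth_pool FDR pool for probes (see
#'   [methylation_expression_correlation()]).
#' @return list with `genes` (one row per candidate) and `meth_probes`
#'   (per-probe correlation + survival detail).
#' @export
build_omics_evidence <- function(genes, cohort, cnv = NULL, meth = NULL,
                                 mutations = NULL, alpha = 0.05,
                                 cnv_fdr = 0.05, meth_fdr = 0.05,
                                 meth_pool = "analysis") {
  ev <- data.frame(gene_id = genes,
                   snv_fraction = NA_real_,
                   mutation_survival_p = NA_real_,
                   mutation_direction = NA_character_,
                   cnv_expr_r = NA_real_, cnv_expr_p = NA_real_,
                   cnv_expr_q = NA_real_, cnv_concordant = FALSE,
                   cnv_survival_p = NA_real_,
                   cnv_survival_direction = NA_character_,
                   meth_negative_flag = FALSE,
                   meth_low_worse_p = NA_real_,
                   stringsAsFactors = FALSE)
  probes_df <- NULL

  if (!is.null(mutations)) {
    freq <- snv_frequency(mutations, cohort$clinical$sample_id, genes = genes)
    ev$snv_fraction <- unname(freq[ev$gene_id])
    for (i in seq_along(genes)) {
      ms <- mutation_survival(mutations, cohort, genes[i])
      if (!inherits(ms, "imos_skip")) {
        ev$mutation_survival_p[i] <- ms$p
        ev$mutation_direction[i] <- ms$direction
      }
    }
  }
  if (!is.null(cnv)) {
    cc <- cnv_expression_correlation(cnv, cohort$expression, genes = genes,
                                     fdr = cnv_fdr)
    m <- match(ev$gene_id, cc$gene_id)
    ev$cnv_expr_r <- cc$r[m]
    ev$cnv_expr_p <- cc$p[m]
    ev$cnv_expr_q <- cc$q[m]
    ev$cnv_concordant <- !is.na(cc$concordant[m]) & cc$concordant[m]
    for (i in seq_along(genes)) {
      cs <- cnv_group_survival(cnv, cohort, genes[i])
      if (!inherits(cs, "imos_skip")) {
        ev$cnv_survival_p[i] <- cs$p
        ev$cnv_survival_direction[i] <- cs$direction
      }
    }
  }
  if (!is.null(meth)) {
    mc <- methylation_expression_correlation(meth, cohort$expression,
                                             genes = genes, fdr = meth_fdr,
                                             pool = meth_pool)
    m <- match(ev$gene_id, mc$genes$gene_id)
    ev$meth_negative_flag <- !is.na(mc$genes$meth_negative_flag[m]) &
      mc$genes$meth_negative_flag[m]
    probes_df <- mc$probes
    probes_df$survival_p <- NA_real_
    probes_df$survival_direction <- NA_character_
    for (i in seq_len(nrow(probes_df))) {
      ps <- probe_survival(meth, cohort, probes_df$probe_id[i])
      if (!inherits(ps, "imos_skip")) {
        probes_df$survival_p[i] <- ps$p
        probes_df$survival_direction[i] <- ps$direction
      }
    }
    for (i in seq_along(genes)) {
      pr <- probes_df[probes_df$gene_id == genes[i] &
                        !is.na(probes_df$survival_p) &
                        probes_df$survival_direction == "low_methylation_worse", ]
      if (nrow(pr)) ev$meth_low_worse_p[i] <- min(pr$survival_p)
    }
  }
  list(genes = ev, meth_probes = probes_df)
}
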