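# Independent brute-force oracles, written naively on purpose; they never
# share code with the package implementations they check.

## Running-sum enrichment score by direct enumeration over the ranked list.
naive_ssgsea <- function(values, gene_ids, signature_genes, alpha) {
  stopifnot(!anyDuplicated(gene_ids))
  r <- rank(values, ties.method = "average")
  in_sig <- gene_ids %in% signature_genes
  ord <- order(-values, !in_sig, gene_ids)
  score <- 0
  p_hit <- 0
  p_miss <- 0
  denom_hit <- sum(abs(r[in_sig])^alpha)
  denom_miss <- sum(!in_sig)
  for (i in ord) {
    if (in_sig[i]) p_hit <- p_hit + abs(r[i])^alpha / denom_hit
    else p_miss <- p_miss + 1 / denom_miss
    score <- score + (p_hit - p_miss)
  }
  score
}

## Benjamini-Hochberg by the literal step-up definition:
## q_(i) = min_{j >= i} p_(j) * m / j, clipped to 1.
naive_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[ord][i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

## Empirical survival function (no censoring): fraction still alive after t.
naive_surv <- function(times, t) mean(times > t)

## Exponential proportional-hazards survival data for a planted binary or
## continuous covariate effect; used by the multiomics survival tests.
simulate_surv <- function(n, loghr_per_unit, x, censor_frac = 0.3,
                          base_median = 30) {
  rate <- exp(log(log(2) / base_median) + loghr_per_unit * x)
  T_true <- stats::rexp(n, rate)
  if (censor_frac <= 0) return(list(time = T_true, event = rep(1L, n)))
  f <- function(cm) mean(pmin(T_true / cm, 1)) - censor_frac
  cm <- stats::uniroot(f, c(min(T_true) * 1e-9, max(T_true) * 1e9))$root
  C <- stats::runif(n, 0, cm)
  list(time = pmin(T_true, C), event = as.integer(T_true <= C))
}

## Cells placed exactly on and around the QC thresholds (2000 UMI / 500
## genes / 10% mito / 40000 UMI + 5000 genes doublet rule), with the
## hand-derived kept set.  Counts are spread so UMI and detected genes are
## controlled independently.
qc_boundary_dataset <- function() {
  n_genes <- 6000
  gene_ids <- c(sprintf("gene%05d", seq_len(n_genes - 1)), "MT-1")
  mk_cell <- function(umi, genes, mito = 0) {
    x <- numeric(n_genes)
    if (genes > 0) x[seq_len(genes)] <- diff(round(seq(0, umi - mito,
                                                       length.out = genes + 1)))
    x[n_genes] <- mito
    x
  }
  cells <- rbind(
    low_umi      = mk_cell(1500, 600),
    at_min_umi   = mk_cell(2000, 600),
    normal       = mk_cell(3000, 800),
    low_genes    = mk_cell(2500, 499),
    at_min_genes = mk_cell(2500, 500),
    high_mito    = mk_cell(3000, 800, mito = 400),
    at_max_mito  = mk_cell(3000, 800, mito = 300),
    doublet      = mk_cell(45000, 5200),
    at_doublet   = mk_cell(40000, 5000),
    umi_only     = mk_cell(45000, 4800)
  )
  colnames(cells) <- gene_ids
  labels <- stats::setNames(rep("a", nrow(cells)), rownames(cells))
  list(dataset = sc_dataset(cells, labels, mito_genes = "MT-1"),
       kept = c("at_min_umi", "normal", "at_min_genes", "at_max_mito",
                "at_doublet", "umi_only"),
       removed = c("low_umi", "low_genes", "high_mito", "doublet"))
}

## Small aligned cohort built directly (no generator involvement).
tiny_cohort <- function(n = 40, genes = paste0("g", 1:5), seed = 7) {
  set.seed(seed)
  expr <- matrix(rnorm(length(genes) * n, 8), length(genes), n,
                 dimnames = list(genes, sprintf("s%02d", 1:n)))
  clin <- clinical_table(colnames(expr),
                         os_time = rexp(n, 1 / 30),
                         os_event = rbinom(n, 1, 0.7))
  suppressMessages(align_cohort(expr, clin, "tiny"))
}
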