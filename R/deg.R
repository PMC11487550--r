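#' Empirical-Bayes moderated two-group t-test
#'
#' Per gene: `log2fc = mean(high) - mean(low)` on log2-scale expression,
#' pooled variance `s_g^2` on `d_g = n_h + n_l - 2` df, and the moderated
#' variance `s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)` with the prior
#' `(d0, s0^2)` estimated across genes by method-of-moments on the log
#' variances (scaled-inverse-chi-square prior; trigamma inversion by
#' Newton steps, tolerance 1e-8).  The statistic `log2fc / (s~_g
#' sqrt(1/n_h + 1/n_l))` is referred to a t distribution on `d0 + d_g`
#' df.  Forcing `d0 = 0` recovers the ordinary pooled t exactly;
#' `d0 = Inf` shrinks every gene to the common prior variance.
#'
#' Missing values are allowed; per-gene group sizes adapt, and genes with
#' fewer than 2 usable samples in either group are flagged.
#'
#' @param expr genes x samples matrix on the log2 scale.
#' @param groups character/factor along columns with levels `high`/`low`
#'   (any two labels; see `high_level`).
#' @param high_level label treated as the "high" group (default `"high"`,
#'   else the second sorted level).
#' @param d0 optional forced prior df; `NULL` (default) estimates it.
#' @return `data.frame` (`gene_id`, `log2fc`, `t`, `p`, `s2`, `s2_post`,
#'   `df`, `df_total`, `n_high`, `n_low`, `flag`) with attributes `d0` and
#'   `s02`.
#' @export
moderated_t_test <- function(expr, groups, high_level = NULL, d0 = NULL) {
  check_id_matrix(expr, "expression")
  groups <- as.character(groups)
  if (length(groups) != ncol(expr))
    stop("groups must label every column of expr", call. = FALSE)
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("need exactly two groups", call. = FALSE)
  if (is.null(high_level)) high_level <- if ("high" %in% lev) "high" else lev[2L]
  hi <- groups == high_level
  if (sum(hi) < 2L || sum(!hi) < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)

  Xh <- expr[, hi, drop = FALSE]
  Xl <- expr[, !hi, drop = FALSE]
  n_h <- rowSums(!is.na(Xh))
  n_l <- rowSums(!is.na(Xl))
  m_h <- rowMeans(Xh, na.rm = TRUE)
  m_l <- rowMeans(Xl, na.rm = TRUE)
  ss_h <- rowSums((Xh - m_h)^2, na.rm = TRUE)
  ss_l <- rowSums((Xl - m_l)^2, na.rm = TRUE)
  df_g <- n_h + n_l - 2
  s2 <- ifelse(df_g > 0, (ss_h + ss_l) / df_g, NA_real_)
  lfc <- m_h - m_l
  usable <- n_h >= 2 & n_l >= 2

  if (is.null(d0)) {
    fit <- fit_variance_prior(s2[usable], df_g[usable])
    d0 <- fit$d0
    s02 <- fit$s02
  } else {
    s02 <- if (is.finite(d0) && d0 > 0)
      fit_variance_prior(s2[usable], df_g[usable])$s02
    else mean(s2[usable & s2 > 0], na.rm = TRUE)
  }

  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + df_g * s2) / (d0 + df_g)
  se <- sqrt(s2_post * (1 / n_h + 1 / n_l))
  t_stat <- lfc / se
  df_total <- d0 + df_g
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)

  flag <- rep(NA_character_, nrow(expr))
  flag[!usable] <- "too_few_samples"
  degen <- usable & is.finite(s2_post) & s2_post == 0
  if (any(degen)) {
    p[degen] <- ifelse(lfc[degen] == 0, 1, 0)
    t_stat[degen] <- ifelse(lfc[degen] == 0, 0, Inf * sign(lfc[degen]))
    flag[degen] <- "zero_variance"
  }
  p[!usable] <- NA_real_
  t_stat[!usable] <- NA_real_

  out <- data.frame(gene_id = rownames(expr), log2fc = lfc, t = t_stat, p = p,
                    s2 = s2, s2_post = s2_post, df = df_g, df_total = df_total,
                    n_high = n_h, n_low = n_l, flag = flag,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

## Method-of-moments fit of the scaled-inverse-chi-square variance prior
## on log sample variances; returns d0 (possibly Inf) and s02.  Degenerate
## inputs fall back to d0 = 0 with a warning.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2L) {
    warning("variance prior estimation degenerate; falling back to d0 = 0",
            call. = FALSE)
    return(list(d0 = 0, s02 = if (any(ok)) mean(s2[ok]) else NA_real_))
  }
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  nn <- length(e)
  evar <- mean((e - emean)^2 * nn / (nn - 1) - trigamma(df[ok] / 2))
  if (!is.finite(evar)) {
    warning("variance prior estimation degenerate; falling back to d0 = 0",
            call. = FALSE)
    return(list(d0 = 0, s02 = mean(s2[ok])))
  }
  if (evar <= 0)
    return(list(d0 = Inf, s02 = exp(emean)))
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

## Newton inversion of trigamma(x) = y, tolerance 1e-8, max 50 iterations.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(50L)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

#' Select differentially expressed genes
#'
#' A gene passes iff `|log2fc| > log2(fc_threshold)` and
#' `p < p_threshold`; both tails are kept.
#'
#' @param results output of [moderated_t_test()].
#' @param fc_threshold linear fold-change gate (default 1.5).
#' @param p_threshold p-value gate (default 0.05).
#' @return character vector of selected gene ids.
#' @export
select_degs <- function(results, fc_threshold = 1.5, p_threshold = 0.05) {
  if (!nrow(results)) stop("empty DEG results", call. = FALSE)
  pass <- !is.na(results$p) &
    abs(results$log2fc) > log2(fc_threshold) &
    results$p < p_threshold
  results$gene_id[pass]
}

#' Fragments per kilobase of exon per million mapped reads
#'
#' `FPKM_gj = fragments_gj / (mapped_reads_millions_j * exon_length_kb_g)`.
#'
#' @param fragment_counts genes x samples matrix of non-negative integer
#'   fragment counts.
#' @param exon_length_kb positive exon length in kb per gene (recycled to
#'   rows).
#' @param mapped_reads_millions positive mapped-read totals in millions
#'   per sample (recycled to columns).
#' @return genes x samples FPKM matrix (linear scale).
#' @export
fpkm <- function(fragment_counts, exon_length_kb, mapped_reads_millions) {
  check_id_matrix(fragment_counts, "fragment counts", min_cols = 1L,
                  allow_na = FALSE)
  if (any(fragment_counts < 0) || any(fragment_counts != round(fragment_counts)))
    stop("fragment counts must be non-negative integers", call. = FALSE)
  exon_length_kb <- rep_len(exon_length_kb, nrow(fragment_counts))
  mapped_reads_millions <- rep_len(mapped_reads_millions, ncol(fragment_counts))
  if (any(exon_length_kb <= 0)) stop("exon lengths must be > 0", call. = FALSE)
  if (any(mapped_reads_millions <= 0))
    stop("mapped read totals must be > 0", call. = FALSE)
  out <- fragment_counts / (exon_length_kb %o% mapped_reads_millions)
  dimnames(out) <- dimnames(fragment_counts)
  attr(out, "scale") <- "linear"
  out
}

#' Fold-change + t gate on bulk FPKM
#'
#' Linear fold change `FC = (mean_high + eps) / (mean_low + eps)`; a gene
#' passes iff `FC > fc_high` or `FC < fc_low`, and a pooled two-sample
#' test on `log2(FPKM + 1)` gives `p < p_threshold` (for two groups the
#' nested-model F test equals the pooled t squared).
#'
#' @param fpkm_matrix genes x samples linear FPKM matrix.
#' @param groups two-level grouping along columns.
#' @param high_level label of the numerator group (default `"high"`, else
#'   the second sorted level).
#' @param p_threshold p gate (default 0.05).
#' @param fc_high,fc_low fold-change gates (defaults 2 and 0.5).
#' @param eps pseudocount guarding the ratio (default 1e-6).
#' @return `data.frame` (`gene_id`, `fc`, `p`, `selected`).
#' @export
bulk_deg_select <- function(fpkm_matrix, groups, high_level = NULL,
                            p_threshold = 0.05, fc_high = 2, fc_low = 0.5,
                            eps = 1e-6) {
  check_id_matrix(fpkm_matrix, "FPKM", min_cols = 2L)
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("need exactly two groups", call. = FALSE)
  if (is.null(high_level)) high_level <- if ("high" %in% lev) "high" else lev[2L]
  hi <- groups == high_level
  if (sum(hi) < 2L || sum(!hi) < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  m_h <- rowMeans(fpkm_matrix[, hi, drop = FALSE], na.rm = TRUE)
  m_l <- rowMeans(fpkm_matrix[, !hi, drop = FALSE], na.rm = TRUE)
  fc <- (m_h + eps) / (m_l + eps)
  logx <- log2(fpkm_matrix + 1)
  res <- moderated_t_test(logx, groups, high_level = high_level, d0 = 0)
  p <- res$p
  selected <- !is.na(p) & p < p_threshold & (fc > fc_high | fc < fc_low)
  data.frame(gene_id = rownames(fpkm_matrix), fc = fc, p = p,
             selected = selected, stringsAsFactors = FALSE, row.names = NULL)
}
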