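#' Single-sample rank-weighted enrichment score (ssGSEA-style immune score)
#'
#' For each sample, genes are ranked by descending expression (ties get
#' average ranks; missing values rank last).  Walking down the ranked
#' list, `P_hit(i)` accumulates `|rank|^alpha` over signature genes
#' (normalized by its total) and `P_miss(i)` accumulates a uniform step
#' over non-signature genes; the score is `sum_i [P_hit(i) - P_miss(i)]`.
#' The score depends on expression only through within-sample ranks, so it
#' is invariant under any strictly increasing per-sample transformation.
#'
#' Genes tied in expression are walked signature-members-first, then
#' alphabetically, so scores never depend on the storage order of the
#' matrix.
#'
#' @param expr genes x samples numeric matrix (any monotone scale).
#' @param signature an `imos_signature` (see [gene_signature()]); at least
#'   one signature gene must be present.
#' @param alpha rank-weighting exponent (default 0.25, the usual
#'   single-sample convention; 0 gives unweighted steps).
#' @return object of class `imos_scores`: named numeric vector of per-sample
#'   scores with attributes `signature` and `alpha`.
#' @export
ssgsea_score <- function(expr, signature, alpha = 0.25) {
  check_id_matrix(expr, "expression", min_cols = 1L)
  genes <- rownames(expr)
  if (length(genes) < 2L)
    stop("need at least 2 genes to score a sample", call. = FALSE)
  in_sig <- genes %in% signature$genes
  if (!any(in_sig))
    stop("no signature gene of '", signature$name, "' present in the matrix",
         call. = FALSE)
  n_sig <- sum(in_sig)
  n_miss <- length(genes) - n_sig
  if (n_miss == 0L)
    stop("signature covers every gene; enrichment is undefined", call. = FALSE)
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    x <- expr[, j]
    obs <- x[!is.na(x)]
    if (length(obs) == length(x) && max(obs) == min(obs)) {
      warning("sample '", colnames(expr)[j],
              "': constant expression, score set to 0", call. = FALSE)
      return(0)
    }
    x_filled <- ifelse(is.na(x), -Inf, x)         # missing values rank last
    r <- rank(x_filled, ties.method = "average")  # high expression = high rank
    ## deterministic walk order: descending expression, members first, then id
    ord <- order(-x_filled, !in_sig, genes)
    w <- abs(r[ord])^alpha
    hit <- in_sig[ord]
    p_hit <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
    p_miss <- cumsum(!hit) / n_miss
    sum(p_hit - p_miss)
  }, numeric(1))
  structure(stats::setNames(scores, colnames(expr)),
            signature = signature$name, alpha = alpha, class = "imos_scores")
}

#' Stratify samples into immune-high / immune-low groups
#'
#' Median rule: samples scoring above the median are `high`, the rest
#' (including exact ties at the median) `low`.  The quantile rule labels
#' the top fraction `q` as `high` (cut at the `1 - q` quantile, ties to
#' `low`); `q = 0.5` reproduces the median rule.
#'
#' @param scores named numeric vector of per-sample scores (e.g. from
#'   [ssgsea_score()]).
#' @param rule `"median"` (default) or `"quantile"`.
#' @param q top fraction labelled high under the quantile rule.
#' @return named character vector `sample -> "high"/"low"`.
#' @export
stratify_by_score <- function(scores, rule = c("median", "quantile"), q = 0.5) {
  rule <- match.arg(rule)
  if (length(scores) < 2L) stop("need at least 2 samples", call. = FALSE)
  s <- as.numeric(scores)
  if (max(s) == min(s))
    stop("all scores identical; no stratification possible", call. = FALSE)
  prob <- if (rule == "median") 0.5 else 1 - q
  thr <- stats::quantile(s, probs = prob, names = FALSE, type = 7)
  grp <- stats::setNames(ifelse(s > thr, "high", "low"), names(scores))
  imos_log("stratified %d samples: %d high / %d low",
           length(grp), sum(grp == "high"), sum(grp == "low"))
  grp
}
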