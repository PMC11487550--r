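#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times
#' `t_i`; times carrying only censored observations affect the at-risk
#' counts but contribute no factor.  Censored observations tied with
#' events at `t` are considered at risk at `t` (standard convention).
#'
#' @param times positive survival times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return object of class `imos_km`: `data.frame` with `time` (distinct
#'   event times), `n_risk`, `n_event`, `surv`.
#' @seealso [km_surv_at()] to evaluate the step function.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("km_estimate: empty input", call. = FALSE)
  if (length(times) != length(events))
    stop("times and events differ in length", call. = FALSE)
  if (any(!is.finite(times)) || any(times <= 0))
    stop("times must be finite and > 0", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  et <- sort(unique(times[events == 1]))
  n_risk <- vapply(et, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = et, n_risk = n_risk, n_event = n_event, surv = surv),
            class = c("imos_km", "data.frame"), n = length(times))
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve an `imos_km` object.
#' @param t times at which to evaluate the right-continuous step function.
#' @return survival probabilities (1 before the first event time).
#' @export
km_surv_at <- function(curve, t) {
  vapply(t, function(tt) {
    i <- sum(curve$time <= tt)
    if (i == 0L) 1 else curve$surv[i]
  }, numeric(1))
}

#' @export
plot.imos_km <- function(x, ..., xlab = "time (months)", ylab = "S(t)") {
  tt <- c(0, rep(x$time, each = 2))
  ss <- c(1, 1, rep(x$surv, each = 2)[-(2 * nrow(x))])
  plot(tt, ss, type = "l", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Two-group log-rank (Mantel-Cox) test with a direction call
#'
#' At each distinct event time the expected events per group follow the
#' hypergeometric mean `d_t n_gt / n_t` with the standard variance; the
#' statistic is `(O - E)^2 / V` on 1 df.  The direction is called from the
#' observed-vs-expected balance in the designated "high" group:
#' `high_worse` when `O_high > E_high`, `high_better` when `O_high <
#' E_high`, `none` when they balance or there are no events.
#'
#' @param times positive survival times.
#' @param events 0/1 event indicators.
#' @param groups two-level grouping vector (factor or character).
#' @param high_level which level plays "high" in the direction call;
#'   defaults to `"high"` when present, else the second level.
#' @return object of class `imos_logrank`: list with `chi2`, `p`,
#'   `obs`/`exp` per group, `var`, `direction`, `high_level`, `n`.
#' @export
logrank_test <- function(times, events, groups, high_level = NULL) {
  groups <- as.character(groups)
  if (length(unique(groups)) != 2L)
    stop("logrank_test: need exactly two groups, got ",
         length(unique(groups)), call. = FALSE)
  lev <- sort(unique(groups))
  if (is.null(high_level)) high_level <- if ("high" %in% lev) "high" else lev[2L]
  if (!high_level %in% lev)
    stop("high_level '", high_level, "' is not a group level", call. = FALSE)
  if (any(!is.finite(times)) || any(times <= 0))
    stop("times must be finite and > 0", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)

  g1 <- groups == high_level
  D <- sum(events)
  if (D == 0) {
    obs <- stats::setNames(c(0, 0), c(high_level, setdiff(lev, high_level)))
    return(structure(list(chi2 = 0, p = 1, obs = obs, exp = obs, var = 0,
                          direction = "none", high_level = high_level,
                          n = length(times), note = "no events"),
                     class = "imos_logrank"))
  }
  et <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in et) {
    at <- times >= t
    n_t <- sum(at)
    n1 <- sum(at & g1)
    d_t <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d_t * n1 / n_t
    if (n_t > 1)
      V <- V + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
  }
  chi2 <- if (V > 0) (O1 - E1)^2 / V else 0
  p <- if (V > 0) stats::pchisq(chi2, df = 1, lower.tail = FALSE) else 1
  direction <- if (O1 > E1) "high_worse" else if (O1 < E1) "high_better" else "none"
  other <- setdiff(lev, high_level)
  structure(list(chi2 = chi2, p = p,
                 obs = stats::setNames(c(O1, D - O1), c(high_level, other)),
                 exp = stats::setNames(c(E1, D - E1), c(high_level, other)),
                 var = V, direction = direction, high_level = high_level,
                 n = length(times)),
            class = "imos_logrank")
}

#' @export
print.imos_logrank <- function(x, ...) {
  cat(sprintf("<log-rank: chi2 = %.4g, p = %.4g, direction = %s (high = '%s')>\n",
              x$chi2, x$p, x$direction, x$high_level))
  invisible(x)
}

#' Split cohort samples by the expression of one gene
#'
#' The top fraction `q` of samples (expression above the `1 - q` quantile)
#' is labelled `high`; ties at the cut go to `low`, matching the
#' immune-score stratification rule.  Samples with missing expression are
#' excluded.
#'
#' @param cohort an `imos_cohort`.
#' @param gene_id gene to split on.
#' @param q fraction of samples labelled high (default 0.5, the median
#'   split).
#' @return named character vector (`sample -> "high"/"low"`), or
#'   `character(0)` with a `"skip_reason"` attribute for a zero-variance
#'   gene.
#' @export
split_by_gene_expression <- function(cohort, gene_id, q = 0.5) {
  if (!gene_id %in% rownames(cohort$expression))
    stop("gene '", gene_id, "' not in cohort '", cohort$name, "'", call. = FALSE)
  x <- cohort$expression[gene_id, ]
  x <- x[!is.na(x)]
  if (length(x) < 4L)
    stop("gene '", gene_id, "': fewer than 4 samples with non-missing expression",
         call. = FALSE)
  if (max(x) == min(x))
    return(structure(character(0), skip_reason = "zero_variance"))
  thr <- stats::quantile(x, probs = 1 - q, names = FALSE, type = 7)
  stats::setNames(ifelse(x > thr, "high", "low"), names(x))
}

#' Genome-wide per-gene survival screen
#'
#' For each gene: split samples at the expression quantile, run the
#' log-rank test, and call the direction.  Genes failing preconditions
#' (absent, < 4 informative samples, zero variance) are recorded as
#' skipped, not errors.  The significance gate uses the raw p by default;
#' `adjust = "BH"` gates on the Benjamini-Hochberg q instead.
#'
#' @param cohort an `imos_cohort`.
#' @param gene_ids genes to screen (default: all genes of the cohort).
#' @param q fraction of samples labelled high per gene (default 0.5).
#' @param alpha significance gate (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return `data.frame` with `gene_id`, `p`, (`q_value`,) `direction`,
#'   `n_high`, `n_low`, `significant`, `skip_reason`.
#' @export
gene_survival_screen <- function(cohort, gene_ids = NULL, q = 0.5,
                                 alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(gene_ids)) gene_ids <- rownames(cohort$expression)
  if (!length(gene_ids)) {
    out <- data.frame(gene_id = character(0), p = numeric(0),
                      direction = character(0), n_high = integer(0),
                      n_low = integer(0), skip_reason = character(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    attr(out, "alpha") <- alpha
    attr(out, "split_q") <- q
    return(out)
  }
  clin <- cohort$clinical
  res <- lapply(gene_ids, function(g) {
    row <- list(gene_id = g, p = NA_real_, direction = NA_character_,
                n_high = NA_integer_, n_low = NA_integer_,
                skip_reason = NA_character_)
    if (!g %in% rownames(cohort$expression)) {
      row$skip_reason <- "absent"
      return(row)
    }
    x <- cohort$expression[g, ]
    ok <- !is.na(x)
    if (sum(ok) < 4L) {
      row$skip_reason <- "too_few_samples"
      return(row)
    }
    if (max(x[ok]) == min(x[ok])) {
      row$skip_reason <- "zero_variance"
      return(row)
    }
    thr <- stats::quantile(x[ok], probs = 1 - q, names = FALSE, type = 7)
    grp <- ifelse(x[ok] > thr, "high", "low")
    if (length(unique(grp)) < 2L) {
      row$skip_reason <- "degenerate_split"
      return(row)
    }
    lr <- logrank_test(clin$os_time[ok], clin$os_event[ok], grp,
                       high_level = "high")
    row$p <- lr$p
    row$direction <- lr$direction
    row$n_high <- sum(grp == "high")
    row$n_low <- sum(grp == "low")
    row
  })
  out <- do.call(rbind, lapply(res, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  if (adjust == "BH") {
    out$q_value <- bh_fdr(out$p)
    out$significant <- !is.na(out$q_value) & out$q_value < alpha
  } else {
    out$significant <- !is.na(out$p) & out$p < alpha
  }
  attr(out, "alpha") <- alpha
  attr(out, "split_q") <- q
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} p_(j) m / j`, clipped to 1, returned in the input
#' order.  Missing values propagate as missing and do not count toward
#' `m`.
#'
#' @param pvalues p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  check_probs(pvalues, "bh_fdr: p")
  stats::p.adjust(pvalues, method = "BH")
}

#' Pearson correlation with a t-distribution p-value
#'
#' Pairwise-complete observations; `t = r sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` df, two-sided.  Degenerate inputs (fewer than 3 complete pairs,
#' or a constant variable) are reported as skipped rather than errors, so
#' screening loops can record them.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p`, `n` (complete pairs) and `skip_reason`
#'   (`NA` when the test ran).
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3L)
    return(list(r = NA_real_, p = NA_real_, n = n, skip_reason = "too_few_pairs"))
  xs <- x[ok]; ys <- y[ok]
  if (max(xs) == min(xs) || max(ys) == min(ys))
    return(list(r = NA_real_, p = NA_real_, n = n, skip_reason = "constant"))
  ct <- stats::cor.test(xs, ys, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, skip_reason = NA_character_)
}
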