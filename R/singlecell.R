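#' Per-cell quality-control metrics
#'
#' UMI total, number of detected genes (strictly positive counts) and
#' mitochondrial fraction (0 for an empty cell).
#'
#' @param dataset an `imos_sc`.
#' @return `data.frame` (`cell_id`, `umi_total`, `genes_detected`,
#'   `mito_fraction`, `cell_type`).
#' @export
compute_qc <- function(dataset) {
  counts <- dataset$counts
  umi <- Matrix::rowSums(counts)
  detected <- Matrix::rowSums(counts > 0)
  mito <- if (length(dataset$mito_genes))
    Matrix::rowSums(counts[, dataset$mito_genes, drop = FALSE]) else
    rep(0, nrow(counts))
  frac <- ifelse(umi > 0, mito / umi, 0)
  data.frame(cell_id = rownames(counts), umi_total = as.numeric(umi),
             genes_detected = as.integer(detected), mito_fraction = frac,
             cell_type = unname(dataset$labels[rownames(counts)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Quality-control filter
#'
#' Removes cells *below* `min_umi` UMIs or *below* `min_genes` detected
#' genes or *above* `max_mito` mitochondrial fraction, and, as a doublet
#' guard, cells with *more than* `doublet_umi` UMIs **and** more than
#' `doublet_genes` detected genes.  All comparisons are strict, so cells
#' sitting exactly on a threshold are kept (most toolkits default to
#' inclusive cuts; here the boundary is deliberately exclusive).
#' Filtering is idempotent.
#'
#' @param dataset an `imos_sc`.
#' @param min_umi,min_genes,max_mito,doublet_umi,doublet_genes thresholds
#'   (defaults 2000, 500, 0.10, 40000, 5000).
#' @return the filtered `imos_sc`, with attribute `"removal_log"`: a
#'   `data.frame` of removed cells and their comma-joined reasons.
#' @export
qc_filter <- function(dataset, min_umi = 2000, min_genes = 500,
                      max_mito = 0.10, doublet_umi = 40000,
                      doublet_genes = 5000) {
  qc <- compute_qc(dataset)
  reasons <- lapply(seq_len(nrow(qc)), function(i) {
    r <- character(0)
    if (qc$umi_total[i] < min_umi) r <- c(r, "low_umi")
    if (qc$genes_detected[i] < min_genes) r <- c(r, "low_genes")
    if (qc$mito_fraction[i] > max_mito) r <- c(r, "high_mito")
    if (qc$umi_total[i] > doublet_umi && qc$genes_detected[i] > doublet_genes)
      r <- c(r, "doublet")
    r
  })
  removed <- lengths(reasons) > 0
  if (all(removed))
    stop("qc_filter removed every cell; review the thresholds", call. = FALSE)
  log_df <- data.frame(cell_id = qc$cell_id[removed],
                       reasons = vapply(reasons[removed], paste,
                                        character(1), collapse = ","),
                       stringsAsFactors = FALSE, row.names = NULL)
  imos_log("qc_filter: kept %d / %d cells (removed %d)",
           sum(!removed), nrow(qc), sum(removed))
  out <- sc_dataset(dataset$counts[!removed, , drop = FALSE],
                    dataset$labels[!removed], dataset$mito_genes)
  attr(out, "removal_log") <- log_df
  out
}

#' Library-size normalization followed by log1p
#'
#' Each cell's counts are scaled to `target_sum` total, then `log(1 + x)`
#' is applied elementwise (natural log).  The result is scale-invariant:
#' doubling a cell's counts leaves its normalized vector unchanged.
#'
#' @param dataset a QC-filtered `imos_sc`; every cell must have at least
#'   one count.
#' @param target_sum per-cell total after scaling (default 10000).
#' @return dense cells x genes matrix of normalized log expression.
#' @export
normalize_log1p <- function(dataset, target_sum = 10000) {
  umi <- Matrix::rowSums(dataset$counts)
  if (any(umi == 0))
    stop("zero-UMI cell(s) present; run qc_filter first", call. = FALSE)
  scaled <- Matrix::Diagonal(x = target_sum / umi) %*% dataset$counts
  out <- log1p(as.matrix(scaled))
  dimnames(out) <- dimnames(dataset$counts)
  out
}

#' Cell-type specificity of one gene
#'
#' Mean normalized expression per cell-type label; the specificity score
#' is `max(mean) / (sum(means) + eps)` and the dominant label the argmax
#' (ties resolved to the lexicographically first label and flagged).
#'
#' @param normalized cells x genes matrix from [normalize_log1p()].
#' @param labels named character vector of cell-type labels (at least two
#'   distinct types).
#' @param gene_id gene to profile.
#' @param eps guard against all-zero genes (default 1e-9).
#' @return list with `gene_id`, `means` (named per label), `dominant_label`,
#'   `specificity_score`, `tie`.
#' @export
specificity_score <- function(normalized, labels, gene_id, eps = 1e-9) {
  if (!gene_id %in% colnames(normalized))
    stop("gene '", gene_id, "' not in the normalized matrix", call. = FALSE)
  labels <- labels[rownames(normalized)]
  types <- sort(unique(labels))
  if (length(types) < 2L)
    stop("need at least two distinct cell-type labels", call. = FALSE)
  x <- normalized[, gene_id]
  means <- vapply(types, function(l) mean(x[labels == l]), numeric(1))
  top <- max(means)
  tie <- sum(means == top) > 1L
  dominant <- types[which(means == top)[1L]]
  list(gene_id = gene_id, means = means, dominant_label = dominant,
       specificity_score = top / (sum(means) + eps), tie = tie)
}

#' Specificity table over a gene set
#'
#' @param normalized cells x genes normalized matrix.
#' @param labels named cell-type labels.
#' @param genes genes to profile (silently restricted to those present).
#' @return `data.frame` (`gene_id`, `dominant_label`, `specificity_score`,
#'   `tie`, one `mean_<type>` column per label).
#' @export
specificity_table <- function(normalized, labels, genes) {
  genes <- intersect(genes, colnames(normalized))
  rows <- lapply(genes, function(g) {
    s <- specificity_score(normalized, labels, g)
    cbind(data.frame(gene_id = g, dominant_label = s$dominant_label,
                     specificity_score = s$specificity_score, tie = s$tie,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(s$means,
                                                paste0("mean_", names(s$means))))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
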