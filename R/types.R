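#' Core data containers
#'
#' The pipeline moves a small set of plain containers between stages:
#'
#' * **expression matrix** — numeric genes x samples matrix with unique
#'   dimnames and an optional `"scale"` attribute (`"linear"` or `"log2"`).
#' * **clinical table** — `data.frame` with `sample_id`, `os_time`
#'   (overall-survival time in months, `> 0`) and `os_event` (1 = death
#'   observed, 0 = censored); further columns are carried as covariates.
#' * **cohort** — an aligned expression/clinical pair (see [align_cohort()]).
#' * **CNV matrix** — integer genes x samples matrix of thresholded
#'   copy-number states in `{-2, -1, 0, 1, 2}`; states `> 0` are gains
#'   ("duplication").
#' * **methylation set** — probes x samples beta matrix in `[0, 1]` plus a
#'   probe map (`probe_id`, `gene_id`, `region`).
#' * **mutation table** — `data.frame` of `(sample_id, gene_id,
#'   variant_class)` rows.
#' * **single-cell dataset** — cells x genes integer count matrix with a
#'   cell-type label per cell and a declared mitochondrial gene set.
#'
#' @name imos-containers
NULL

#' Construct a clinical survival table
#'
#' @param sample_id character vector of unique sample ids.
#' @param os_time overall-survival times in months, strictly positive.
#' @param os_event event indicators, 0 (censored) or 1 (death).
#' @param ... optional covariate columns (recycled by `data.frame`).
#' @return a validated clinical `data.frame`.
#' @export
clinical_table <- function(sample_id, os_time, os_event, ...) {
  df <- data.frame(sample_id = as.character(sample_id),
                   os_time = as.numeric(os_time),
                   os_event = as.integer(os_event),
                   ..., stringsAsFactors = FALSE)
  validate_clinical(df)
}

validate_clinical <- function(df, what = "clinical table") {
  req <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(what, ": missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop(what, ": duplicated sample_id", call. = FALSE)
  if (any(!is.finite(df$os_time)) || any(df$os_time <= 0))
    stop(what, ": os_time must be finite and > 0", call. = FALSE)
  if (!all(df$os_event %in% c(0L, 1L)))
    stop(what, ": os_event must be 0 or 1", call. = FALSE)
  df
}

#' Construct an aligned cohort from already-matching pieces
#'
#' Internal constructor; most callers should use [align_cohort()], which
#' intersects and reorders the two sample sets.
#'
#' @param name cohort name.
#' @param expression genes x samples numeric matrix.
#' @param clinical clinical `data.frame` (see [clinical_table()]) whose
#'   samples equal and match the column order of `expression`.
#' @return an object of class `imos_cohort`.
#' @export
new_cohort <- function(name, expression, clinical) {
  check_id_matrix(expression, "expression")
  clinical <- validate_clinical(clinical)
  if (!identical(colnames(expression), clinical$sample_id))
    stop("cohort '", name, "': expression samples and clinical samples differ; ",
         "use align_cohort()", call. = FALSE)
  structure(list(name = name, expression = expression, clinical = clinical),
            class = "imos_cohort")
}

#' @export
print.imos_cohort <- function(x, ...) {
  cat(sprintf("<imos_cohort '%s': %d genes x %d samples, %d events (%.0f%% censored)>\n",
              x$name, nrow(x$expression), ncol(x$expression),
              sum(x$clinical$os_event),
              100 * mean(x$clinical$os_event == 0)))
  invisible(x)
}

#' Gene signature
#'
#' @param name signature name.
#' @param genes non-empty character vector of gene ids (duplicates removed).
#' @return an object of class `imos_signature`.
#' @export
gene_signature <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("signature '", name, "' is empty", call. = FALSE)
  structure(list(name = name, genes = genes), class = "imos_signature")
}

validate_cnv <- function(states, what = "CNV matrix") {
  check_id_matrix(states, what, min_cols = 1L, allow_na = FALSE)
  bad <- !(states %in% c(-2L, -1L, 0L, 1L, 2L))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(states)), arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: invalid state '%s' at gene '%s', sample '%s' (allowed: -2..2)",
                 what, states[idx[1L], idx[2L]],
                 rownames(states)[idx[1L]], colnames(states)[idx[2L]]),
         call. = FALSE)
  }
  storage.mode(states) <- "integer"
  states
}

meth_regions <- c("TSS1500", "TSS200", "body", "other")

#' Construct a methylation set (beta matrix + probe map)
#'
#' @param beta probes x samples matrix of beta values in `[0, 1]`.
#' @param probe_map `data.frame` with columns `probe_id`, `gene_id`,
#'   `region` (one of `TSS1500`, `TSS200`, `body`, `other`) covering every
#'   probe of `beta`.
#' @return an object of class `imos_meth`.
#' @export
methylation_set <- function(beta, probe_map) {
  check_id_matrix(beta, "methylation beta", min_cols = 1L)
  bad <- which(beta < 0 | beta > 1)
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(beta))
    stop(sprintf("methylation beta: value %g outside [0, 1] at probe '%s', sample '%s'",
                 beta[bad[1L]], rownames(beta)[idx[1L]], colnames(beta)[idx[2L]]),
         call. = FALSE)
  }
  req <- c("probe_id", "gene_id", "region")
  miss <- setdiff(req, names(probe_map))
  if (length(miss))
    stop("probe map: missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  probe_map$probe_id <- as.character(probe_map$probe_id)
  probe_map$gene_id <- as.character(probe_map$gene_id)
  probe_map$region <- as.character(probe_map$region)
  if (!all(probe_map$region %in% meth_regions))
    stop("probe map: region must be one of ", paste(meth_regions, collapse = ", "),
         call. = FALSE)
  unmapped <- setdiff(rownames(beta), probe_map$probe_id)
  if (length(unmapped))
    stop("probe map: probes without mapping: ",
         paste(utils::head(unmapped, 5L), collapse = ", "), call. = FALSE)
  structure(list(beta = beta, probe_map = probe_map), class = "imos_meth")
}

validate_mutations <- function(df, cohort_samples = NULL) {
  req <- c("sample_id", "gene_id", "variant_class")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("mutation table: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$gene_id <- as.character(df$gene_id)
  df$variant_class <- as.character(df$variant_class)
  dup <- duplicated(df[req])
  if (any(dup)) {
    imos_log("mutation table: dropped %d fully duplicated rows", sum(dup))
    df <- df[!dup, , drop = FALSE]
    rownames(df) <- NULL
  }
  if (!is.null(cohort_samples)) {
    off <- setdiff(df$sample_id, cohort_samples)
    if (length(off))
      stop("mutation table: sample(s) outside the cohort universe: ",
           paste(utils::head(off, 5L), collapse = ", "), call. = FALSE)
  }
  df
}

#' Construct a single-cell dataset
#'
#' @param counts cells x genes matrix of non-negative integer UMI counts
#'   (dense or `Matrix` sparse); rownames are cell barcodes, colnames gene
#'   ids.
#' @param labels named character vector mapping every cell barcode to a
#'   cell-type label.
#' @param mito_genes character vector of mitochondrial gene ids (subset of
#'   the gene universe).
#' @return an object of class `imos_sc`.
#' @export
sc_dataset <- function(counts, labels, mito_genes = character()) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                                "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("single-cell counts need cell (row) and gene (column) ids", call. = FALSE)
  v <- counts@x
  if (any(v < 0) || any(v != round(v)))
    stop("single-cell counts must be non-negative integers", call. = FALSE)
  unlabeled <- setdiff(rownames(counts), names(labels))
  if (length(unlabeled))
    stop("unlabeled cell(s): ", paste(utils::head(unlabeled, 10L), collapse = ", "),
         call. = FALSE)
  labels <- labels[rownames(counts)]
  extra_mito <- setdiff(mito_genes, colnames(counts))
  if (length(extra_mito))
    stop("mito_genes not in the gene universe: ",
         paste(utils::head(extra_mito, 5L), collapse = ", "), call. = FALSE)
  structure(list(counts = counts, labels = labels,
                 mito_genes = as.character(mito_genes)),
            class = "imos_sc")
}

#' @export
print.imos_sc <- function(x, ...) {
  cat(sprintf("<imos_sc: %d cells x %d genes, %d cell types, %d mito genes>\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$labels)), length(x$mito_genes)))
  invisible(x)
}
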