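#' Read a genes-x-samples expression matrix
#'
#' TSV layout: genes as rows, first column gene ids, header row of sample
#' ids (GEO series-matrix convention).  GCT v1.2: a `#1.2` line, a
#' dimensions line, then `Name`/`Description` columns before the samples.
#' Duplicated gene ids are collapsed by keeping the highest-mean row (the
#' drop is logged); transposed input is never guessed at.
#'
#' @param path file to read.
#' @param format `"tsv"` (default) or `"gct"`.
#' @param scale declared scale of the stored values, `"linear"` or `"log2"`
#'   (recorded as an attribute, never transformed).
#' @return numeric matrix (genes x samples) with a `"scale"` attribute.
#' @export
read_expression <- function(path, format = c("tsv", "gct"), scale = c("linear", "log2")) {
  format <- match.arg(format)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "gct") {
    hdr <- readLines(path, n = 2L)
    if (length(hdr) < 2L || !identical(trimws(hdr[1L]), "#1.2"))
      stop(path, ": line 1 is not the GCT '#1.2' version header", call. = FALSE)
    dims <- suppressWarnings(as.integer(strsplit(trimws(hdr[2L]), "\t")[[1L]]))
    if (length(dims) < 2L || anyNA(dims[1:2]))
      stop(path, ": line 2 is not a valid GCT dimensions line", call. = FALSE)
    df <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (nrow(df) != dims[1L])
      stop(path, ": GCT dimensions line promises ", dims[1L], " rows, found ",
           nrow(df), call. = FALSE)
    df[["Description"]] <- NULL
    names(df)[1L] <- "gene_id"
    mat <- to_numeric_matrix(df, "gene_id", path)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
      stop(path, ": header row must list at least one sample column", call. = FALSE)
    names(df)[1L] <- "gene_id"
    mat <- to_numeric_matrix(df, "gene_id", path)
  }
  mat <- collapse_duplicate_rows(mat, what = basename(path))
  check_id_matrix(mat, basename(path))
  attr(mat, "scale") <- scale
  mat
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()] for the TSV layout.
#'
#' @param mat genes x samples numeric matrix.
#' @param path destination file.
#' @param id_col name of the id column in the header.
#' @export
write_expression <- function(mat, path, id_col = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical survival table
#'
#' Requires columns `sample_id`, `os_time`, `os_event`.  Rows with missing
#' time or event are dropped (count logged); rows with `os_time <= 0` are
#' rejected with a warning.
#'
#' @param path TSV file.
#' @param time_unit `"months"` (default) or `"days"`; days are divided by
#'   30.44.
#' @return validated clinical `data.frame`.
#' @export
read_clinical <- function(path, time_unit = c("months", "days")) {
  time_unit <- match.arg(time_unit)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(path, ": missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$os_time <- suppressWarnings(as.numeric(df$os_time))
  df$os_event <- suppressWarnings(as.integer(df$os_event))
  incomplete <- is.na(df$os_time) | is.na(df$os_event)
  if (any(incomplete)) {
    imos_log("%s: dropped %d row(s) with missing os_time/os_event",
             basename(path), sum(incomplete))
    df <- df[!incomplete, , drop = FALSE]
  }
  nonpos <- df$os_time <= 0
  if (any(nonpos)) {
    warning(basename(path), ": rejected ", sum(nonpos),
            " row(s) with os_time <= 0", call. = FALSE)
    df <- df[!nonpos, , drop = FALSE]
  }
  if (time_unit == "days") df$os_time <- df$os_time / 30.44
  rownames(df) <- NULL
  validate_clinical(df, basename(path))
}

#' Read a thresholded copy-number matrix
#'
#' Same layout as the expression TSV; values must be integer states in
#' `{-2, -1, 0, 1, 2}` (GISTIC-style thresholded calls, `> 0` = gain).
#'
#' @param path TSV file.
#' @return integer matrix (genes x samples).
#' @export
read_cnv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- "gene_id"
  mat <- to_numeric_matrix(df, "gene_id", path)
  validate_cnv(mat, basename(path))
}

#' Read a methylation beta matrix and its probe map
#'
#' @param beta_path TSV of beta values, probes as rows.
#' @param map_path TSV with columns `probe_id`, `gene_id`, `region`.
#' @return an `imos_meth` object (see [methylation_set()]).
#' @export
read_methylation <- function(beta_path, map_path) {
  df <- utils::read.delim(beta_path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- "probe_id"
  beta <- to_numeric_matrix(df, "probe_id", beta_path)
  map <- utils::read.delim(map_path, check.names = FALSE, stringsAsFactors = FALSE)
  methylation_set(beta, map)
}

#' Read a MAF-like mutation table
#'
#' Requires columns `sample_id`, `gene_id`, `variant_class`; fully
#' duplicated rows are dropped with a logged count.
#'
#' @param path TSV file.
#' @param cohort_samples optional sample universe; rows whose sample is
#'   outside it raise an error.
#' @return mutation `data.frame`.
#' @export
read_mutations <- function(path, cohort_samples = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_mutations(df, cohort_samples)
}

#' Read a single-cell counts bundle (MatrixMarket + sidecars)
#'
#' The MTX holds genes (features) as rows and cells (barcodes) as columns,
#' the usual sparse-counts convention; the returned dataset is transposed
#' to cells x genes.
#'
#' @param mtx_path MatrixMarket coordinate file of integer counts.
#' @param barcodes_path one barcode per line.
#' @param features_path one gene id per line.
#' @param labels_path TSV with columns `barcode`, `cell_type` labelling
#'   every barcode.
#' @param mito_prefix prefix marking mitochondrial genes (default `"MT-"`).
#' @return an `imos_sc` object.
#' @export
read_single_cell <- function(mtx_path, barcodes_path, features_path,
                             labels_path, mito_prefix = "MT-") {
  m <- Matrix::readMM(mtx_path)
  barcodes <- readLines(barcodes_path)
  features <- readLines(features_path)
  barcodes <- barcodes[nzchar(barcodes)]
  features <- features[nzchar(features)]
  if (nrow(m) != length(features) || ncol(m) != length(barcodes))
    stop(sprintf(
      "MTX is %d x %d but features/barcodes files list %d / %d ids",
      nrow(m), ncol(m), length(features), length(barcodes)), call. = FALSE)
  rownames(m) <- features
  colnames(m) <- barcodes
  lab <- utils::read.delim(labels_path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(c("barcode", "cell_type"), names(lab))
  if (length(miss))
    stop(labels_path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  labels <- stats::setNames(as.character(lab$cell_type), as.character(lab$barcode))
  mito <- features[startsWith(features, mito_prefix)]
  sc_dataset(Matrix::t(m), labels, mito)
}

#' Align an expression matrix with a clinical table into a cohort
#'
#' Samples are restricted to the intersection (order follows the
#' expression matrix); dropped counts are logged.  Aligning an aligned
#' cohort is a no-op.
#'
#' @param expression genes x samples numeric matrix.
#' @param clinical clinical `data.frame`.
#' @param name cohort name.
#' @return an `imos_cohort`.
#' @export
align_cohort <- function(expression, clinical, name = "cohort") {
  check_id_matrix(expression, "expression")
  clinical <- validate_clinical(clinical)
  shared <- intersect(colnames(expression), clinical$sample_id)
  if (!length(shared))
    stop("cohort '", name, "': no samples shared between expression and clinical",
         call. = FALSE)
  d_expr <- ncol(expression) - length(shared)
  d_clin <- nrow(clinical) - length(shared)
  if (d_expr + d_clin > 0)
    imos_log("cohort '%s': dropped %d expression-only and %d clinical-only samples",
             name, d_expr, d_clin)
  expr <- expression[, shared, drop = FALSE]
  attr(expr, "scale") <- attr(expression, "scale")
  clin <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  rownames(clin) <- NULL
  new_cohort(name, expr, clin)
}

#' Read a gene signature (GMT line or plain list)
#'
#' GMT: tab-separated `name`, `description`, then genes; the first line is
#' used.  Plain list: one gene id per line, the file name becomes the
#' signature name.
#'
#' @param path signature file.
#' @param format `"gmt"` or `"list"`; default guesses from the extension.
#' @return an `imos_signature`.
#' @export
read_signature <- function(path, format = c("auto", "gmt", "list")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "list"
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(path, ": empty signature file", call. = FALSE)
  if (format == "gmt") {
    fields <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(path, ": GMT line needs name, description and at least one gene",
           call. = FALSE)
    gene_signature(fields[1L], fields[-(1:2)])
  } else {
    gene_signature(sub("\\.[^.]*$", "", basename(path)), lines)
  }
}

#' Write a signature as a one-line GMT file
#'
#' @param signature an `imos_signature`.
#' @param path destination file.
#' @export
write_signature <- function(signature, path) {
  writeLines(paste(c(signature$name, "imos signature", signature$genes),
                   collapse = "\t"), path)
  invisible(path)
}
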