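# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

imos_log <- function(fmt, ...) {
  message("[imos] ", sprintf(fmt, ...))
}

## Validate a genes-x-samples (or probes-x-samples) numeric matrix with
## unique, non-empty dimnames.  `what` names the offending object in errors.
check_id_matrix <- function(x, what = "matrix", min_rows = 1L, min_cols = 2L,
                            allow_na = TRUE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must carry row and column ids as dimnames", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop(what, ": duplicated row ids", call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop(what, ": duplicated column (sample) ids", call. = FALSE)
  if (nrow(x) < min_rows || ncol(x) < min_cols)
    stop(what, sprintf(": need at least %d rows and %d columns", min_rows, min_cols),
         call. = FALSE)
  if (!allow_na && anyNA(x))
    stop(what, ": missing values not allowed here", call. = FALSE)
  bad <- !is.finite(x) & !is.na(x)
  if (any(bad))
    stop(what, ": non-finite values present", call. = FALSE)
  invisible(x)
}

## Convert the value block of a just-read table to a numeric matrix,
## reporting the first non-numeric cell by row/column name.
to_numeric_matrix <- function(df, id_col, path) {
  ids <- as.character(df[[id_col]])
  block <- df[, setdiff(names(df), id_col), drop = FALSE]
  mat <- suppressWarnings(
    vapply(block, function(col) as.numeric(as.character(col)), numeric(nrow(block)))
  )
  if (nrow(block) == 1L) mat <- matrix(mat, nrow = 1L, dimnames = list(NULL, names(block)))
  introduced <- is.na(mat) & !is.na(block) &
    !(toupper(trimws(as.matrix(block))) %in% c("NA", ""))
  if (any(introduced)) {
    idx <- which(introduced, arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: non-numeric value '%s' at row '%s', column '%s'",
                 path, as.character(as.matrix(block)[idx[1L], idx[2L]]),
                 ids[idx[1L]], names(block)[idx[2L]]), call. = FALSE)
  }
  rownames(mat) <- ids
  mat
}

## Collapse duplicated row ids, keeping the row with the highest mean.
collapse_duplicate_rows <- function(mat, what = "expression") {
  ids <- rownames(mat)
  if (!anyDuplicated(ids)) return(mat)
  means <- rowMeans(mat, na.rm = TRUE)
  ## stable pick: highest mean, first occurrence on ties
  ord <- order(ids, -means)
  keep <- ord[!duplicated(ids[ord])]
  keep <- sort(keep)
  imos_log("%s: collapsed %d duplicated ids (kept highest-mean row)",
           what, length(ids) - length(keep))
  mat[keep, , drop = FALSE]
}

check_probs <- function(p, what = "p") {
  if (length(p) && (any(p < 0 | p > 1, na.rm = TRUE)))
    stop(what, " values must lie in [0, 1]", call. = FALSE)
  invisible(p)
}
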