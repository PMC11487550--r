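#' Configuration of the discovery cascade
#'
#' @param deg_fc_threshold fold-change gate of the immune DEG stage
#'   (default 1.5).
#' @param deg_p_threshold p gate of the DEG stage (default 0.05).
#' @param survival_alpha significance gate of every survival screen
#'   (default 0.05, unadjusted).
#' @param split_quantile fraction of samples labelled high in per-gene
#'   splits (default 0.5, the median split).
#' @param ssgsea_alpha rank-weighting exponent of the immune score
#'   (default 0.25).
#' @param validation_min_cohorts `k`: a gene is credible when it validates
#'   in at least `k` cohorts (default 1).
#' @param require_direction_consistency demand the validation direction
#'   match discovery (default `TRUE`).
#' @param cnv_fdr,meth_fdr FDR gates of the omics stages (defaults 0.05).
#' @param meth_pool probe FDR pool, `"analysis"` or `"gene"`.
#' @param specificity_min single-cell specificity gate (default 0.5).
#' @param candidate_pool `"ihg"` (default; checkpoints are harmful genes)
#'   or `"ibg"` for the symmetric screen.
#' @param seed seed recorded in the report (default 1).
#' @return an object of class `imos_config`.
#' @export
imos_config <- function(deg_fc_threshold = 1.5, deg_p_threshold = 0.05,
                        survival_alpha = 0.05, split_quantile = 0.5,
                        ssgsea_alpha = 0.25, validation_min_cohorts = 1L,
                        require_direction_consistency = TRUE,
                        cnv_fdr = 0.05, meth_fdr = 0.05,
                        meth_pool = c("analysis", "gene"),
                        specificity_min = 0.5,
                        candidate_pool = c("ihg", "ibg"), seed = 1L) {
  meth_pool <- match.arg(meth_pool)
  candidate_pool <- match.arg(candidate_pool)
  stopifnot(deg_fc_threshold >= 1,
            deg_p_threshold >= 0, deg_p_threshold <= 1,
            survival_alpha > 0, survival_alpha < 1,
            split_quantile > 0, split_quantile < 1,
            ssgsea_alpha >= 0,
            validation_min_cohorts >= 1,
            cnv_fdr > 0, cnv_fdr < 1, meth_fdr > 0, meth_fdr < 1,
            specificity_min >= 0, specificity_min <= 1)
  structure(list(deg_fc_threshold = deg_fc_threshold,
                 deg_p_threshold = deg_p_threshold,
                 survival_alpha = survival_alpha,
                 split_quantile = split_quantile,
                 ssgsea_alpha = ssgsea_alpha,
                 validation_min_cohorts = as.integer(validation_min_cohorts),
                 require_direction_consistency = require_direction_consistency,
                 cnv_fdr = cnv_fdr, meth_fdr = meth_fdr,
                 meth_pool = meth_pool,
                 specificity_min = specificity_min,
                 candidate_pool = candidate_pool,
                 seed = as.integer(seed)),
            class = "imos_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Immune stratification and prognostic-gene screen (stages 1-2)
#'
#' Stage 1: per-sample immune score, median stratification, moderated-t
#' differential expression between immune-high and immune-low samples,
#' gated at the configured fold change and p.  Stage 2: per-gene
#' median-split log-rank survival screen restricted to the DEG set; genes
#' significant at the (unadjusted) alpha with a direction call are the
#' immune-related prognostic genes (IPG).
#'
#' @param discovery an `imos_cohort`.
#' @param immune_signature an `imos_signature`.
#' @param config an `imos_config`.
#' @return list with `scores`, `groups`, `deg_table`, `deg_set`,
#'   `screen`, `ipg` (screen rows passing the gate).
#' @export
screen_ipg <- function(discovery, immune_signature, config = imos_config()) {
  scores <- .stage("immune_score",
                   ssgsea_score(discovery$expression, immune_signature,
                                alpha = config$ssgsea_alpha))
  groups <- .stage("stratify", stratify_by_score(scores))
  deg_table <- .stage("deg",
                      moderated_t_test(discovery$expression,
                                       groups[colnames(discovery$expression)]))
  deg_set <- select_degs(deg_table, config$deg_fc_threshold,
                         config$deg_p_threshold)
  if (!length(deg_set)) {
    imos_log("DEG set empty; survival screen skipped")
    screen <- gene_survival_screen(discovery, character(0))
    ipg <- screen
  } else {
    screen <- .stage("survival_screen",
                     gene_survival_screen(discovery, deg_set,
                                          q = config$split_quantile,
                                          alpha = config$survival_alpha))
    ipg <- screen[screen$significant & !is.na(screen$direction) &
                    screen$direction != "none", , drop = FALSE]
  }
  rownames(ipg) <- NULL
  list(scores = scores, groups = groups, deg_table = deg_table,
       deg_set = deg_set, screen = screen, ipg = ipg)
}

#' Classify prognostic genes as beneficial or harmful
#'
#' `high_better` genes (higher expression, longer survival) are IBG;
#' `high_worse` genes are IHG; entries without a direction are excluded
#' with a warning.
#'
#' @param ipg IPG `data.frame` (from [screen_ipg()]).
#' @return list with `ibg`, `ihg` (character vectors) and `excluded`.
#' @export
classify_ibg_ihg <- function(ipg) {
  if (!nrow(ipg))
    return(list(ibg = character(0), ihg = character(0), excluded = character(0)))
  ibg <- ipg$gene_id[!is.na(ipg$direction) & ipg$direction == "high_better"]
  ihg <- ipg$gene_id[!is.na(ipg$direction) & ipg$direction == "high_worse"]
  excluded <- setdiff(ipg$gene_id, c(ibg, ihg))
  if (length(excluded))
    warning(length(excluded), " IPG entr(ies) without direction excluded",
            call. = FALSE)
  list(ibg = ibg, ihg = ihg, excluded = excluded)
}

#' Cross-cohort validation of prognostic genes
#'
#' A gene is credible when it is significant (p < alpha, same per-gene
#' split) in at least `k` validation cohorts and — when direction
#' consistency is required — its direction there matches discovery.
#' Genes missing from a cohort's matrix simply fail to validate in that
#' cohort.
#'
#' @param ipg IPG `data.frame` carrying `gene_id` and `direction`.
#' @param validation_cohorts list of `imos_cohort`s.
#' @param config an `imos_config`.
#' @return `data.frame` with per-cohort `p_*`/`dir_*` columns,
#'   `n_validated` and `credible`.
#' @export
validate_cross_cohort <- function(ipg, validation_cohorts,
                                  config = imos_config()) {
  if (!length(validation_cohorts))
    stop("need at least one validation cohort", call. = FALSE)
  out <- data.frame(gene_id = ipg$gene_id,
                    discovery_direction = ipg$direction,
                    stringsAsFactors = FALSE)
  n_val <- integer(nrow(out))
  for (co in validation_cohorts) {
    scr <- gene_survival_screen(co, ipg$gene_id, q = config$split_quantile,
                                alpha = config$survival_alpha)
    m <- match(out$gene_id, scr$gene_id)
    hit <- scr$significant[m] & !is.na(scr$direction[m]) &
      scr$direction[m] != "none"
    if (config$require_direction_consistency)
      hit <- hit & scr$direction[m] == out$discovery_direction
    hit[is.na(hit)] <- FALSE
    n_val <- n_val + as.integer(hit)
    out[[paste0("p_", co$name)]] <- scr$p[m]
    out[[paste0("dir_", co$name)]] <- scr$direction[m]
  }
  out$n_validated <- n_val
  out$credible <- n_val >= config$validation_min_cohorts
  out
}

#' Rank credible harmful genes by multi-omic + single-cell evidence
#'
#' Five equally-weighted boolean flags per gene: copy-number/expression
#' concordance (q below the CNV FDR, r > 0); duplication associated with
#' worse survival (p < alpha); methylation negatively correlated with
#' expression (any probe, q below the methylation FDR); at least one
#' probe where low methylation tracks worse survival (p < alpha); and
#' single-cell specificity at or above the configured minimum.  Rank by
#' flag count, ties by CNV correlation then gene id; missing evidence
#' counts as a false flag (logged).
#'
#' @param pool_genes candidate pool (normally the credible harmful genes).
#' @param evidence output of [build_omics_evidence()] for those genes.
#' @param specificity output of [specificity_table()] (may omit genes).
#' @param config an `imos_config`.
#' @return ranked `data.frame` with the flags, `evidence_count`, `rank`,
#'   `dominant_cell_type` and `specificity_score`.
#' @export
nominate_candidates <- function(pool_genes, evidence, specificity,
                                config = imos_config()) {
  ev <- evidence$genes[match(pool_genes, evidence$genes$gene_id), , drop = FALSE]
  missing_ev <- pool_genes[is.na(match(pool_genes, evidence$genes$gene_id))]
  if (length(missing_ev))
    imos_log("no omics evidence for %d gene(s); their flags are false",
             length(missing_ev))
  sp <- specificity[match(pool_genes, specificity$gene_id), , drop = FALSE]
  alpha <- config$survival_alpha
  flag <- function(x) !is.na(x) & x
  out <- data.frame(
    gene_id = pool_genes,
    flag_cnv_concordant = flag(ev$cnv_concordant),
    flag_cnv_survival = flag(ev$cnv_survival_direction == "duplication_worse" &
                               ev$cnv_survival_p < alpha),
    flag_meth_negative = flag(ev$meth_negative_flag),
    flag_meth_survival = flag(ev$meth_low_worse_p < alpha),
    flag_specificity = flag(sp$specificity_score >= config$specificity_min),
    cnv_expr_r = ev$cnv_expr_r,
    dominant_cell_type = sp$dominant_label,
    specificity_score = sp$specificity_score,
    stringsAsFactors = FALSE)
  out$evidence_count <- rowSums(out[, grep("^flag_", names(out))])
  r_for_ties <- ifelse(is.na(out$cnv_expr_r), -Inf, out$cnv_expr_r)
  ord <- order(-out$evidence_count, -r_for_ties, out$gene_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Read a pipeline input bundle from a directory
#'
#' Expects the layout written by [simulate_bundle()]:
#' `discovery_expression.tsv`, `discovery_clinical.tsv`, `signature.gmt`,
#' `validation<i>_{expression,clinical}.tsv`, `cnv.tsv`,
#' `methylation_beta.tsv` + `methylation_map.tsv`, `mutations.tsv`,
#' `sc_counts.mtx` + `sc_barcodes.tsv` + `sc_features.tsv` +
#' `sc_labels.tsv`, optional `truth.json`.  Missing optional layers load
#' as `NULL`.
#'
#' @param dir bundle directory.
#' @return named list of loaded inputs (`discovery`, `signature`,
#'   `validation`, `cnv`, `meth`, `mutations`, `sc`, `truth`).
#' @export
read_bundle <- function(dir) {
  p <- function(...) file.path(dir, ...)
  must <- function(f) {
    if (!file.exists(p(f))) stop("bundle is missing ", f, call. = FALSE)
    p(f)
  }
  opt <- function(f) if (file.exists(p(f))) p(f) else NULL
  discovery <- align_cohort(
    read_expression(must("discovery_expression.tsv"), scale = "log2"),
    read_clinical(must("discovery_clinical.tsv")), name = "discovery")
  signature <- read_signature(must("signature.gmt"))
  val_files <- sort(list.files(dir, "^validation[0-9]+_expression\\.tsv$"))
  validation <- lapply(val_files, function(f) {
    name <- sub("_expression\\.tsv$", "", f)
    align_cohort(read_expression(p(f), scale = "log2"),
                 read_clinical(must(paste0(name, "_clinical.tsv"))), name = name)
  })
  cnv <- if (!is.null(opt("cnv.tsv"))) read_cnv(p("cnv.tsv")) else NULL
  meth <- if (!is.null(opt("methylation_beta.tsv")))
    read_methylation(p("methylation_beta.tsv"), must("methylation_map.tsv")) else NULL
  mutations <- if (!is.null(opt("mutations.tsv"))) read_mutations(p("mutations.tsv")) else NULL
  sc <- if (!is.null(opt("sc_counts.mtx")))
    read_single_cell(p("sc_counts.mtx"), must("sc_barcodes.tsv"),
                     must("sc_features.tsv"), must("sc_labels.tsv")) else NULL
  truth <- if (!is.null(opt("truth.json")))
    jsonlite::fromJSON(p("truth.json")) else NULL
  list(discovery = discovery, signature = signature, validation = validation,
       cnv = cnv, meth = meth, mutations = mutations, sc = sc, truth = truth)
}

#' Run the full discovery cascade
#'
#' Executes immune scoring and stratification, the DEG and survival
#' screens, beneficial/harmful classification, cross-cohort validation,
#' the copy-number/methylation/mutation evidence gates, single-cell
#' specificity, and candidate ranking.  Any stage error aborts with the
#' stage named.  The run is deterministic given (inputs, config).
#'
#' @param inputs a bundle directory path, or the list returned by
#'   [read_bundle()].
#' @param config an `imos_config`.
#' @param out_dir optional directory; when given, the report tables and
#'   `report.json` are written there (see [write_imos_report()]).
#' @return an object of class `imos_report`.
#' @export
run_imos <- function(inputs, config = imos_config(), out_dir = NULL) {
  set.seed(config$seed)
  if (is.character(inputs)) inputs <- .stage("io", read_bundle(inputs))
  s12 <- screen_ipg(inputs$discovery, inputs$signature, config)
  cls <- .stage("classify", classify_ibg_ihg(s12$ipg))
  if (nrow(s12$ipg)) {
    val <- .stage("validate",
                  validate_cross_cohort(s12$ipg, inputs$validation, config))
    cipg <- val$gene_id[val$credible]
  } else {
    val <- data.frame(gene_id = character(0))
    cipg <- character(0)
  }
  cibg <- intersect(cipg, cls$ibg)
  cihg <- intersect(cipg, cls$ihg)
  pool <- if (config$candidate_pool == "ihg") cihg else cibg

  evidence <- .stage("omics", {
    if (is.null(inputs$cnv)) stop("CNV input missing")
    if (is.null(inputs$meth)) stop("methylation input missing")
    if (is.null(inputs$mutations)) stop("mutation input missing")
    build_omics_evidence(pool, inputs$discovery, cnv = inputs$cnv,
                         meth = inputs$meth, mutations = inputs$mutations,
                         alpha = config$survival_alpha,
                         cnv_fdr = config$cnv_fdr, meth_fdr = config$meth_fdr,
                         meth_pool = config$meth_pool)
  })
  specificity <- .stage("single_cell", {
    if (is.null(inputs$sc)) stop("single-cell input missing")
    filtered <- qc_filter(inputs$sc)
    norm <- normalize_log1p(filtered)
    specificity_table(norm, filtered$labels, pool)
  })
  candidates <- .stage("nominate",
                       nominate_candidates(pool, evidence, specificity, config))

  report <- structure(list(
    config = config,
    scores = s12$scores,
    groups = s12$groups,
    deg_table = s12$deg_table,
    deg_set = s12$deg_set,
    screen = s12$screen,
    ipg = s12$ipg,
    ibg = cls$ibg, ihg = cls$ihg,
    validation = val,
    cipg = cipg, cibg = cibg, cihg = cihg,
    evidence = evidence,
    specificity = specificity,
    candidates = candidates,
    truth = inputs$truth
  ), class = "imos_report")
  check_report_invariants(report)
  if (!is.null(out_dir)) write_imos_report(report, out_dir)
  report
}

## The cascade only ever narrows: DEG >= IPG >= IBG u IHG >= cIPG >= candidates.
check_report_invariants <- function(report) {
  stopifnot(all(report$ipg$gene_id %in% report$deg_set),
            all(c(report$ibg, report$ihg) %in% report$ipg$gene_id),
            all(report$cipg %in% report$ipg$gene_id),
            all(report$cihg %in% report$ihg),
            all(report$cibg %in% report$ibg),
            all(report$candidates$gene_id %in% c(report$cihg, report$cibg)))
  invisible(TRUE)
}

#' Write the cascade report to disk
#'
#' `report.json` carries the set sizes, gene lists, ranked candidates and
#' configuration; the stage tables go to TSV companions.  Output is
#' deterministic: identical runs produce byte-identical files.
#'
#' @param report an `imos_report`.
#' @param dir output directory (created if needed).
#' @return (invisibly) the directory.
#' @export
write_imos_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  tsv <- function(df, f) utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                                            row.names = FALSE)
  tsv(report$deg_table, "deg.tsv")
  tsv(report$screen, "survival_screen.tsv")
  tsv(report$ipg, "ipg.tsv")
  if (nrow(report$validation)) tsv(report$validation, "validation.tsv")
  tsv(report$evidence$genes, "evidence.tsv")
  if (!is.null(report$evidence$meth_probes))
    tsv(report$evidence$meth_probes, "evidence_meth_probes.tsv")
  tsv(report$specificity, "specificity.tsv")
  tsv(report$candidates, "candidates.tsv")
  js <- list(
    config = unclass(report$config),
    n_deg = length(report$deg_set),
    n_ipg = nrow(report$ipg),
    n_ibg = length(report$ibg), n_ihg = length(report$ihg),
    n_cipg = length(report$cipg),
    n_cibg = length(report$cibg), n_cihg = length(report$cihg),
    deg = report$deg_set,
    ibg = report$ibg, ihg = report$ihg,
    cibg = report$cibg, cihg = report$cihg,
    candidates = report$candidates
  )
  writeLines(jsonlite::toJSON(js, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             p("report.json"))
  invisible(dir)
}

#' @export
print.imos_report <- function(x, ...) {
  cat("iMOS discovery report\n")
  cat(sprintf("  DEG: %d   IPG: %d (IBG %d / IHG %d)\n",
              length(x$deg_set), nrow(x$ipg), length(x$ibg), length(x$ihg)))
  cat(sprintf("  credible: %d (cIBG %d / cIHG %d)\n",
              length(x$cipg), length(x$cibg), length(x$cihg)))
  if (nrow(x$candidates)) {
    top <- x$candidates[1L, ]
    ct <- if (is.na(top$dominant_cell_type)) "no cell type" else top$dominant_cell_type
    cat(sprintf("  top candidate: %s (evidence %d/5, %s)\n",
                top$gene_id, top$evidence_count, ct))
  } else cat("  no candidates nominated\n")
  invisible(x)
}

#' @export
summary.imos_report <- function(object, ...) {
  cat("iMOS cascade summary\n")
  print(object)
  if (nrow(object$candidates)) {
    cat("\nRanked candidates:\n")
    print(object$candidates[, c("rank", "gene_id", "evidence_count",
                                "dominant_cell_type", "specificity_score")],
          row.names = FALSE)
  }
  invisible(object)
}
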