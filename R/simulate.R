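#' Define the planted truth of a synthetic multi-omic study
#'
#' The truth object fixes which genes carry signal and how strong it is;
#' the generators ([generate_cohort()], [generate_multiomics()],
#' [generate_single_cell()]) are pure functions of (truth, parameters,
#' seed).  Defaults emulate a lung-adenocarcinoma-like discovery study:
#' an immune-infiltration latent factor that signature genes and planted
#' prognostic genes load on, survival effects of one hazard doubling per
#' standard deviation of expression, copy-number states concordant with
#' expression at r ~ 0.6, promoter methylation anticorrelated at r ~
#' -0.5, and a macrophage-specific planted checkpoint gene that carries
#' every evidence layer.
#'
#' @param n_genes gene universe size (default 500).
#' @param n_signature immune-signature genes (default 50).
#' @param n_harmful,n_beneficial planted prognostic genes per direction
#'   (defaults 20, 20).
#' @param beta_harmful,beta_beneficial per-SD log-hazard coefficients
#'   (defaults `log(2)`, `-log(2)`).
#' @param loading magnitude of the immune-factor loading (default 1;
#'   expression noise is standard normal).  Signature and beneficial
#'   genes load `+loading`, harmful genes `-loading`: immune-hot tumors
#'   fare better, harmful genes mark immune-cold tumors, and every
#'   planted gene's marginal survival direction matches its label.
#' @param n_cnv_planted,n_cnv_null genes with expression-concordant /
#'   independent copy-number states (defaults 10, 10; planted ones are the
#'   first harmful genes).
#' @param rho_cnv target copy-number/expression correlation (default 0.6;
#'   `|rho| > 0.95` is rejected as unreachable on thresholded states).
#' @param n_meth_planted,n_meth_null genes with anticorrelated /
#'   independent methylation probes (defaults 10, 10).
#' @param rho_meth target methylation/expression correlation (default
#'   -0.5, must be negative).
#' @param n_mutated mutated prognostic genes (default 3, drawn from the
#'   harmful set).
#' @param mutation_fraction carrier fraction per mutated gene (default
#'   0.15).
#' @param mutation_hr carrier hazard ratio (default 2).
#' @param cell_types cell-type labels of the single-cell arm.
#' @param checkpoint_cell_type cell type expressing the planted
#'   checkpoint (default `"macrophage"`).
#' @return an object of class `imos_truth`.
#' @export
simulation_truth <- function(n_genes = 500,
                             n_signature = 50,
                             n_harmful = 20, n_beneficial = 20,
                             beta_harmful = log(2), beta_beneficial = -log(2),
                             loading = 1,
                             n_cnv_planted = 10, n_cnv_null = 10, rho_cnv = 0.6,
                             n_meth_planted = 10, n_meth_null = 10,
                             rho_meth = -0.5,
                             n_mutated = 3, mutation_fraction = 0.15,
                             mutation_hr = 2,
                             cell_types = c("b_cell", "epithelial",
                                            "macrophage", "t_cell"),
                             checkpoint_cell_type = "macrophage") {
  need <- n_signature + n_harmful + n_beneficial + n_cnv_null + n_meth_null
  if (n_genes < need)
    stop("n_genes too small for the requested planted sets (need >= ", need, ")",
         call. = FALSE)
  if (abs(rho_cnv) > 0.95)
    stop("target CNV correlation |rho| > 0.95 unreachable on thresholded states",
         call. = FALSE)
  if (rho_meth >= 0) stop("rho_meth must be negative", call. = FALSE)
  if (abs(rho_meth) > 0.95)
    stop("target methylation correlation |rho| > 0.95 unreachable", call. = FALSE)
  if (n_cnv_planted > n_harmful || n_meth_planted > n_harmful)
    stop("planted CNV/methylation genes are drawn from the harmful set",
         call. = FALSE)
  if (n_mutated > n_harmful)
    stop("mutated prognostic genes are drawn from the harmful set", call. = FALSE)
  if (!checkpoint_cell_type %in% cell_types)
    stop("checkpoint_cell_type must be one of cell_types", call. = FALSE)

  genes <- sprintf("g%04d", seq_len(n_genes))
  i <- 0L
  take <- function(k) { out <- genes[i + seq_len(k)]; i <<- i + k; out }
  signature_genes <- take(n_signature)
  harmful <- take(n_harmful)
  beneficial <- take(n_beneficial)
  cnv_null <- take(n_cnv_null)
  meth_null <- take(n_meth_null)

  beta <- c(stats::setNames(rep(beta_harmful, n_harmful), harmful),
            stats::setNames(rep(beta_beneficial, n_beneficial), beneficial))
  loadings <- c(stats::setNames(rep(loading, n_signature), signature_genes),
                stats::setNames(rep(-loading, n_harmful), harmful),
                stats::setNames(rep(loading, n_beneficial), beneficial))
  checkpoint <- if (n_harmful > 0) harmful[1L] else NA_character_
  structure(list(
    genes = genes,
    signature = if (n_signature > 0)
      gene_signature("immune_signature", signature_genes) else NULL,
    loadings = loadings,
    beta = beta,
    planted_harmful = harmful,
    planted_beneficial = beneficial,
    cnv_genes = data.frame(gene_id = c(harmful[seq_len(n_cnv_planted)], cnv_null),
                           rho = c(rep(rho_cnv, n_cnv_planted),
                                   rep(0, n_cnv_null)),
                           stringsAsFactors = FALSE),
    meth_genes = data.frame(gene_id = c(harmful[seq_len(n_meth_planted)], meth_null),
                            rho = c(rep(rho_meth, n_meth_planted),
                                    rep(0, n_meth_null)),
                            stringsAsFactors = FALSE),
    mutated = data.frame(gene_id = harmful[seq_len(n_mutated)],
                         fraction = rep(mutation_fraction, n_mutated),
                         hr = rep(mutation_hr, n_mutated),
                         stringsAsFactors = FALSE),
    specific_map = if (n_harmful > 0)
      stats::setNames(checkpoint_cell_type, checkpoint) else
      stats::setNames(character(0), character(0)),
    cell_types = cell_types,
    checkpoint_gene = checkpoint
  ), class = "imos_truth")
}

#' Generate a synthetic survival cohort with planted signal
#'
#' Expression: `x_gj = a_g u_j + e_gj + 8` with a standard-normal latent
#' immune factor `u_j`, loadings `a_g` from the truth (0 for unplanted
#' genes) and standard-normal noise; the +8 offset mimics a log2
#' microarray scale.  Survival: exponential times with log-hazard `b0 +
#' sum_g beta_g z_gj + sum_m log(hr_m) carrier_mj` over standardized
#' planted expression `z`, baseline median `baseline_median` months.
#' Censoring: independent uniform on `(0, c_max)` with `c_max` calibrated
#' so the expected censored fraction matches `censoring_fraction`.
#'
#' @param truth an `imos_truth`.
#' @param n_samples cohort size (default 515, >= 20).
#' @param censoring_fraction target censored fraction in `[0, 1)`
#'   (default 0.4).
#' @param seed RNG seed.
#' @param name cohort name (default `"discovery"`).
#' @param baseline_median baseline median survival in months (default 30).
#' @param effect_attenuation multiplier on all survival coefficients
#'   (default 1; 0 gives a null cohort with the same expression structure).
#' @return list (class `imos_sim`) with `cohort` (an `imos_cohort`),
#'   `u` (latent factor), `carriers` (mutated gene -> sample ids), `seed`.
#' @export
generate_cohort <- function(truth, n_samples = 515, censoring_fraction = 0.4,
                            seed = 1, name = "discovery",
                            baseline_median = 30, effect_attenuation = 1) {
  if (n_samples < 20) stop("n_samples must be >= 20", call. = FALSE)
  if (censoring_fraction < 0 || censoring_fraction >= 1)
    stop("infeasible censoring target (need 0 <= fraction < 1)", call. = FALSE)
  set.seed(seed)
  genes <- truth$genes
  G <- length(genes)
  samples <- sprintf("%s_%03d", name, seq_len(n_samples))
  u <- stats::rnorm(n_samples)
  X <- matrix(stats::rnorm(G * n_samples), G, n_samples,
              dimnames = list(genes, samples))
  lg <- names(truth$loadings)
  X[lg, ] <- X[lg, ] + truth$loadings %o% u
  expr <- X + 8
  attr(expr, "scale") <- "log2"

  eta <- rep(log(log(2) / baseline_median), n_samples)
  for (g in names(truth$beta)) {
    z <- (X[g, ] - mean(X[g, ])) / stats::sd(X[g, ])
    eta <- eta + effect_attenuation * truth$beta[[g]] * z
  }
  carriers <- list()
  for (i in seq_len(nrow(truth$mutated))) {
    g <- truth$mutated$gene_id[i]
    k <- round(truth$mutated$fraction[i] * n_samples)
    carriers[[g]] <- sort(sample(samples, k))
    eta <- eta + effect_attenuation * log(truth$mutated$hr[i]) *
      as.numeric(samples %in% carriers[[g]])
  }
  T_true <- stats::rexp(n_samples, rate = exp(eta))
  if (censoring_fraction == 0) {
    os_time <- T_true
    os_event <- rep(1L, n_samples)
  } else {
    f <- function(cm) mean(pmin(T_true / cm, 1)) - censoring_fraction
    cm <- stats::uniroot(f, lower = min(T_true) * 1e-9,
                         upper = max(T_true) * 1e9, tol = 1e-12)$root
    C <- stats::runif(n_samples, 0, cm)
    os_time <- pmax(pmin(T_true, C), 1e-6)
    os_event <- as.integer(T_true <= C)
  }
  clin <- data.frame(sample_id = samples, os_time = os_time,
                     os_event = os_event, stringsAsFactors = FALSE)
  structure(list(cohort = new_cohort(name, expr, clin), u = u,
                 carriers = carriers, seed = seed),
            class = "imos_sim")
}

#' Generate independent validation cohorts from the same truth
#'
#' Cohorts are drawn independently (seeds derived from the master seed)
#' with all survival coefficients scaled by `effect_attenuation`
#' (0 = null validation cohorts).
#'
#' @param truth an `imos_truth`.
#' @param n_cohorts number of cohorts (default 4).
#' @param sizes cohort sizes (default 133/133/132/132, totalling 530).
#' @param effect_attenuation coefficient multiplier (default 1).
#' @param censoring_fraction target censored fraction (default 0.4).
#' @param seed master seed; cohort `i` uses `seed + 1000 * i`.
#' @return list of `imos_sim` objects.
#' @export
generate_validation_cohorts <- function(truth, n_cohorts = 4,
                                        sizes = c(133, 133, 132, 132),
                                        effect_attenuation = 1,
                                        censoring_fraction = 0.4, seed = 1) {
  sizes <- rep_len(sizes, n_cohorts)
  if (any(sizes <= 0)) stop("sizes must be positive", call. = FALSE)
  lapply(seq_len(n_cohorts), function(i)
    generate_cohort(truth, n_samples = sizes[i],
                    censoring_fraction = censoring_fraction,
                    seed = seed + 1000L * i,
                    name = sprintf("validation%d", i),
                    effect_attenuation = effect_attenuation))
}

## Analytic attenuation of a Pearson correlation when a standard-normal
## latent variable is discretized into CNV states at fixed quantile cuts.
.cnv_state_levels <- c(-2L, -1L, 0L, 1L, 2L)
.cnv_state_probs <- c(0.02, 0.18, 0.50, 0.25, 0.05)

.cnv_attenuation <- function() {
  p <- .cnv_state_probs
  s <- .cnv_state_levels
  cuts <- c(-Inf, stats::qnorm(cumsum(p)))
  cov_sw <- sum(s * (stats::dnorm(cuts[-length(cuts)]) - stats::dnorm(cuts[-1L])))
  sd_s <- sqrt(sum(p * s^2) - sum(p * s)^2)
  cov_sw / sd_s
}

## Attenuation of corr(plogis(scale * W), W) for W ~ N(0, 1).
.logistic_attenuation <- function(scale) {
  f <- function(z) stats::plogis(scale * z) * stats::dnorm(z)
  m <- stats::integrate(f, -Inf, Inf)$value
  cov_bw <- stats::integrate(function(z) stats::plogis(scale * z) * z * stats::dnorm(z),
                             -Inf, Inf)$value
  v <- stats::integrate(function(z) (stats::plogis(scale * z) - m)^2 * stats::dnorm(z),
                        -Inf, Inf)$value
  cov_bw / sqrt(v)
}

#' Generate copy-number, methylation and mutation layers for a cohort
#'
#' Copy-number states are drawn by thresholding a Gaussian copula against
#' the gene's (standardized) expression at fixed state frequencies
#' (2/18/50/25/5% for states -2..2); the latent correlation is inflated
#' by the analytic attenuation of the discretization so the realized
#' state/expression Pearson correlation lands near the target (and is
#' recorded).  Methylation probes are `plogis` transforms of a latent
#' anticorrelated Gaussian (2-4 promoter probes per planted gene);
#' mutation rows reproduce the carrier sets drawn at cohort generation
#' plus background mutations.
#'
#' @param sim an `imos_sim` from [generate_cohort()].
#' @param truth the `imos_truth` used to generate it.
#' @param seed RNG seed.
#' @param background_rate background mutation rate per gene (default 0.03).
#' @param meth_scale latent scale of the beta logistic (default 1.5).
#' @return list with `cnv` (integer matrix), `meth` (`imos_meth`),
#'   `mutations` (`data.frame`), `realized` (named realized correlations).
#' @export
generate_multiomics <- function(sim, truth, seed = 1, background_rate = 0.03,
                                meth_scale = 1.5) {
  set.seed(seed)
  cohort <- sim$cohort
  X <- cohort$expression
  samples <- colnames(X)
  n <- length(samples)
  genes <- truth$genes

  ## --- CNV ---
  atten <- .cnv_attenuation()
  cuts <- c(-Inf, stats::qnorm(cumsum(.cnv_state_probs)))
  cuts[length(cuts)] <- Inf
  states <- matrix(0L, length(genes), n, dimnames = list(genes, samples))
  draw_states <- function(w) .cnv_state_levels[findInterval(w, cuts,
                                                            rightmost.closed = TRUE)]
  planted_rho <- stats::setNames(truth$cnv_genes$rho, truth$cnv_genes$gene_id)
  realized_cnv <- c()
  for (g in genes) {
    rho <- if (g %in% names(planted_rho)) planted_rho[[g]] else 0
    if (rho != 0) {
      rho_lat <- rho / atten
      if (abs(rho_lat) > 0.995)
        stop("target CNV correlation unreachable after discretization", call. = FALSE)
      zx <- as.numeric(scale(X[g, ]))
      w <- rho_lat * zx + sqrt(1 - rho_lat^2) * stats::rnorm(n)
      states[g, ] <- draw_states(w)
      realized_cnv[g] <- stats::cor(states[g, ], X[g, ])
    } else {
      states[g, ] <- draw_states(stats::rnorm(n))
    }
  }

  ## --- methylation ---
  meth_atten <- .logistic_attenuation(meth_scale)
  probe_genes <- unique(c(truth$meth_genes$gene_id, truth$planted_harmful,
                          truth$planted_beneficial))
  planted_meth <- stats::setNames(truth$meth_genes$rho, truth$meth_genes$gene_id)
  beta_rows <- list()
  map_rows <- list()
  realized_meth <- c()
  probe_counter <- 0L
  for (g in probe_genes) {
    rho <- if (g %in% names(planted_meth)) planted_meth[[g]] else 0
    n_probes <- if (rho != 0) sample(2:4, 1L) else sample(1:3, 1L)
    zx <- as.numeric(scale(X[g, ]))
    best_r <- NA_real_
    for (k in seq_len(n_probes)) {
      probe_counter <- probe_counter + 1L
      pid <- sprintf("cg%08d", probe_counter)
      if (rho != 0) {
        rho_lat <- rho / meth_atten
        w <- rho_lat * zx + sqrt(1 - rho_lat^2) * stats::rnorm(n)
        region <- sample(c("TSS1500", "TSS200"), 1L)
      } else {
        w <- stats::rnorm(n)
        region <- sample(meth_regions, 1L)
      }
      b <- stats::plogis(meth_scale * w)
      beta_rows[[pid]] <- b
      map_rows[[pid]] <- data.frame(probe_id = pid, gene_id = g,
                                    region = region, stringsAsFactors = FALSE)
      if (rho != 0) {
        r <- stats::cor(b, X[g, ])
        if (is.na(best_r) || abs(r) > abs(best_r)) best_r <- r
      }
    }
    if (rho != 0) realized_meth[g] <- best_r
  }
  beta <- do.call(rbind, beta_rows)
  colnames(beta) <- samples
  meth <- methylation_set(beta, do.call(rbind, map_rows))

  ## --- mutations ---
  classes <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
               "Splice_Site")
  mut_rows <- list()
  for (g in names(sim$carriers)) {
    cs <- sim$carriers[[g]]
    if (length(cs))
      mut_rows[[g]] <- data.frame(sample_id = cs, gene_id = g,
                                  variant_class = sample(classes, length(cs),
                                                         replace = TRUE),
                                  stringsAsFactors = FALSE)
  }
  background_genes <- setdiff(unique(c(truth$planted_harmful,
                                       truth$planted_beneficial)),
                              names(sim$carriers))
  for (g in background_genes) {
    k <- stats::rbinom(1L, n, background_rate)
    if (k > 0)
      mut_rows[[g]] <- data.frame(sample_id = sample(samples, k), gene_id = g,
                                  variant_class = sample(classes, k, replace = TRUE),
                                  stringsAsFactors = FALSE)
  }
  mutations <- validate_mutations(do.call(rbind, c(mut_rows,
                                                   list(make.row.names = FALSE))),
                                  samples)
  list(cnv = states, meth = meth, mutations = mutations,
       realized = list(cnv = realized_cnv, meth = realized_meth))
}

#' Generate a labeled single-cell dataset with QC-fail injections
#'
#' Each cell type gets a mean expression profile (shared gamma-distributed
#' gene weights with type-specific lognormal jitter); genes in the truth's
#' `specific_map` are expressed essentially only in their mapped type.
#' Counts are Poisson at a lognormal per-cell depth.  Known QC failures
#' are injected and recorded: low-depth cells, high-mitochondrial cells,
#' and doublet-like cells (two profiles summed at high depth).
#'
#' @param truth an `imos_truth`.
#' @param n_cells_per_type cells per type (default 100).
#' @param n_filler_genes extra genes padding the universe so detected-gene
#'   QC thresholds are meaningful (default 5500).
#' @param depth mean UMI depth of normal cells (default 6000).
#' @param n_low_umi,n_high_mito,n_doublet injected QC failures (defaults
#'   10, 10, 5).
#' @param seed RNG seed.
#' @param specific_multiplier expression boost of a specific gene in its
#'   mapped type (default 20).
#' @return an `imos_sc` with attribute `"injected"`: list of the injected
#'   cell ids per failure class.
#' @export
generate_single_cell <- function(truth, n_cells_per_type = 100,
                                 n_filler_genes = 5500, depth = 6000,
                                 n_low_umi = 10, n_high_mito = 10,
                                 n_doublet = 5, seed = 1,
                                 specific_multiplier = 20) {
  set.seed(seed)
  mito_genes <- c("MT-CO1", "MT-CO2", "MT-ND1", "MT-ND4", "MT-CYB")
  features <- c(truth$genes, sprintf("fill%05d", seq_len(n_filler_genes)),
                mito_genes)
  Fg <- length(features)
  types <- truth$cell_types
  base_w <- stats::rgamma(Fg, shape = 2, rate = 2)
  names(base_w) <- features

  profile_for <- function(type, mito_share = 0.05) {
    w <- base_w * exp(stats::rnorm(Fg, 0, 0.3))
    names(w) <- features
    for (g in names(truth$specific_map)) {
      w[g] <- mean(base_w) * if (truth$specific_map[[g]] == type)
        specific_multiplier else 0.01
    }
    w[mito_genes] <- 0
    w[mito_genes] <- sum(w) * mito_share / (1 - mito_share) / length(mito_genes)
    w / sum(w)
  }
  profiles <- lapply(stats::setNames(types, types), profile_for)
  profiles_himito <- lapply(stats::setNames(types, types), profile_for,
                            mito_share = 0.25)

  cells <- list(); labels <- c(); injected <- list(low_umi = character(),
                                                  high_mito = character(),
                                                  doublet = character())
  idx <- 0L
  add_cell <- function(profile, d, type) {
    idx <<- idx + 1L
    id <- sprintf("cell%05d", idx)
    cells[[id]] <<- stats::rpois(Fg, d * profile)
    labels[id] <<- type
    id
  }
  for (type in types)
    for (k in seq_len(n_cells_per_type))
      add_cell(profiles[[type]], stats::rlnorm(1, log(depth), 0.2), type)
  for (k in seq_len(n_low_umi)) {
    type <- sample(types, 1L)
    injected$low_umi <- c(injected$low_umi, add_cell(profiles[[type]], 800, type))
  }
  for (k in seq_len(n_high_mito)) {
    type <- sample(types, 1L)
    injected$high_mito <- c(injected$high_mito,
                            add_cell(profiles_himito[[type]], depth, type))
  }
  for (k in seq_len(n_doublet)) {
    pair <- sample(types, 2L)
    mix <- (profiles[[pair[1L]]] + profiles[[pair[2L]]]) / 2
    injected$doublet <- c(injected$doublet, add_cell(mix, 50000, pair[1L]))
  }
  counts <- do.call(rbind, cells)
  dimnames(counts) <- list(names(cells), features)
  out <- sc_dataset(counts, labels, mito_genes)
  attr(out, "injected") <- injected
  out
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates a discovery cohort, validation cohorts, the multi-omic
#' layers and the single-cell arm, and writes them in the exact formats
#' the readers consume, plus `truth.json` recording the planted signal.
#' The bundle is a pure function of (truth, parameters, seed).
#'
#' @param dir output directory (created if needed).
#' @param truth an `imos_truth` (default [simulation_truth()]).
#' @param n_discovery discovery cohort size (default 515).
#' @param n_validation validation cohorts (default 4).
#' @param validation_sizes their sizes (default 133/133/132/132).
#' @param censoring_fraction target censored fraction (default 0.4).
#' @param seed master seed; stage seeds are derived from it.
#' @param sc_cells_per_type,sc_depth single-cell arm parameters.
#' @return (invisibly) list of written paths plus the truth.
#' @export
simulate_bundle <- function(dir, truth = simulation_truth(),
                            n_discovery = 515, n_validation = 4,
                            validation_sizes = c(133, 133, 132, 132),
                            censoring_fraction = 0.4, seed = 1,
                            sc_cells_per_type = 100, sc_depth = 6000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  disc <- generate_cohort(truth, n_discovery, censoring_fraction, seed = seed)
  write_expression(disc$cohort$expression, p("discovery_expression.tsv"))
  utils::write.table(disc$cohort$clinical, p("discovery_clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_signature(truth$signature, p("signature.gmt"))

  vals <- generate_validation_cohorts(truth, n_validation, validation_sizes,
                                      censoring_fraction = censoring_fraction,
                                      seed = seed)
  for (i in seq_along(vals)) {
    write_expression(vals[[i]]$cohort$expression,
                     p(sprintf("validation%d_expression.tsv", i)))
    utils::write.table(vals[[i]]$cohort$clinical,
                       p(sprintf("validation%d_clinical.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  omics <- generate_multiomics(disc, truth, seed = seed + 101L)
  utils::write.table(data.frame(gene_id = rownames(omics$cnv), omics$cnv,
                                check.names = FALSE),
                     p("cnv.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(probe_id = rownames(omics$meth$beta),
                                omics$meth$beta, check.names = FALSE),
                     p("methylation_beta.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(omics$meth$probe_map, p("methylation_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(omics$mutations, p("mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sc <- generate_single_cell(truth, n_cells_per_type = sc_cells_per_type,
                             depth = sc_depth, seed = seed + 202L)
  Matrix::writeMM(Matrix::t(sc$counts), p("sc_counts.mtx"))
  writeLines(rownames(sc$counts), p("sc_barcodes.tsv"))
  writeLines(colnames(sc$counts), p("sc_features.tsv"))
  utils::write.table(data.frame(barcode = rownames(sc$counts),
                                cell_type = unname(sc$labels)),
                     p("sc_labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  truth_json <- list(
    seed = seed,
    checkpoint_gene = truth$checkpoint_gene,
    planted_harmful = truth$planted_harmful,
    planted_beneficial = truth$planted_beneficial,
    signature_genes = truth$signature$genes,
    cnv_genes = truth$cnv_genes,
    meth_genes = truth$meth_genes,
    mutated = truth$mutated,
    specific_map = as.list(truth$specific_map),
    realized_correlations = omics$realized
  )
  writeLines(jsonlite::toJSON(truth_json, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), p("truth.json"))
  invisible(list(dir = dir, truth = truth,
                 injected_sc = attr(sc, "injected")))
}
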