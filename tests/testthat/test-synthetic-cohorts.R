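# The synthetic-data generators: determinism, calibration, planted-signal
# recovery.

test_that("cohort generation is a pure function of its seed", {
  truth <- simulation_truth(n_genes = 150, n_signature = 20, n_harmful = 5,
                            n_beneficial = 5, n_cnv_planted = 2, n_cnv_null = 2,
                            n_meth_planted = 2, n_meth_null = 2, n_mutated = 1)
  a <- generate_cohort(truth, n_samples = 50, seed = 5)
  b <- generate_cohort(truth, n_samples = 50, seed = 5)
  expect_identical(a$cohort$expression[, ], b$cohort$expression[, ])
  expect_identical(a$cohort$clinical, b$cohort$clinical)
  c <- generate_cohort(truth, n_samples = 50, seed = 6)
  expect_false(identical(a$cohort$clinical$os_time, c$cohort$clinical$os_time))
})

test_that("censoring lands near its target and rejects infeasible requests", {
  truth <- simulation_truth(n_genes = 150, n_signature = 20, n_harmful = 5,
                            n_beneficial = 5, n_cnv_planted = 0, n_cnv_null = 0,
                            n_meth_planted = 0, n_meth_null = 0, n_mutated = 0)
  for (target in c(0.2, 0.5, 0.7)) {
    sim <- generate_cohort(truth, n_samples = 600, censoring_fraction = target,
                           seed = 31)
    realized <- mean(sim$cohort$clinical$os_event == 0)
    expect_lt(abs(realized - target), 0.08)
  }
  sim0 <- generate_cohort(truth, n_samples = 50, censoring_fraction = 0, seed = 1)
  expect_true(all(sim0$cohort$clinical$os_event == 1))
  expect_error(generate_cohort(truth, 50, censoring_fraction = 1), "infeasible")
})

test_that("a null cohort triggers the screen at about the nominal rate", {
  truth <- simulation_truth(n_genes = 600, n_signature = 0, n_harmful = 0,
                            n_beneficial = 0, n_cnv_planted = 0, n_cnv_null = 0,
                            n_meth_planted = 0, n_meth_null = 0, n_mutated = 0)
  sim <- generate_cohort(truth, n_samples = 150, seed = 211)
  scr <- gene_survival_screen(sim$cohort)
  frac <- mean(scr$p < 0.05, na.rm = TRUE)
  half <- 2.576 * sqrt(0.05 * 0.95 / 600)
  expect_gt(frac, 0.05 - half)
  expect_lt(frac, 0.05 + half)
})

test_that("a single planted harmful gene is recovered in nearly every replicate", {
  truth <- simulation_truth(n_genes = 60, n_signature = 10, n_harmful = 1,
                            n_beneficial = 0, n_cnv_planted = 0, n_cnv_null = 0,
                            n_meth_planted = 0, n_meth_null = 0, n_mutated = 0)
  hits <- vapply(1:20, function(s) {
    sim <- generate_cohort(truth, n_samples = 400, seed = 300 + s)
    scr <- gene_survival_screen(sim$cohort, truth$planted_harmful)
    scr$p < 0.05 && scr$direction == "high_worse"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("planted effect signs always match the recovered direction", {
  truth <- simulation_truth(n_genes = 200, n_signature = 20, n_harmful = 10,
                            n_beneficial = 10, n_cnv_planted = 0, n_cnv_null = 0,
                            n_meth_planted = 0, n_meth_null = 0, n_mutated = 0)
  sim <- generate_cohort(truth, n_samples = 400, seed = 401)
  scr <- gene_survival_screen(sim$cohort,
                              c(truth$planted_harmful, truth$planted_beneficial))
  rec <- scr[scr$significant, ]
  expect_gt(nrow(rec), 10)
  expect_true(all(rec$direction[rec$gene_id %in% truth$planted_harmful] ==
                    "high_worse"))
  expect_true(all(rec$direction[rec$gene_id %in% truth$planted_beneficial] ==
                    "high_better"))
})

test_that("attenuated validation cohorts lose the planted signal", {
  truth <- simulation_truth(n_genes = 200, n_signature = 20, n_harmful = 10,
                            n_beneficial = 0, n_cnv_planted = 0, n_cnv_null = 0,
                            n_meth_planted = 0, n_meth_null = 0, n_mutated = 0)
  ## null part: zero factor loading so the planted genes are independent,
  ## giving a clean binomial bound on the false-validation rate
  truth0 <- simulation_truth(n_genes = 200, n_signature = 20, n_harmful = 40,
                             n_beneficial = 0, loading = 0,
                             n_cnv_planted = 0, n_cnv_null = 0,
                             n_meth_planted = 0, n_meth_null = 0, n_mutated = 0)
  vals <- generate_validation_cohorts(truth0, n_cohorts = 2, sizes = c(200, 200),
                                      effect_attenuation = 0, seed = 71)
  hits <- unlist(lapply(vals, function(v) {
    scr <- gene_survival_screen(v$cohort, truth0$planted_harmful)
    scr$significant
  }))
  expect_lt(mean(hits), 0.05 + 2.576 * sqrt(0.05 * 0.95 / length(hits)))

  vals1 <- generate_validation_cohorts(truth, n_cohorts = 2, sizes = c(200, 200),
                                       effect_attenuation = 1, seed = 71)
  hits1 <- vapply(vals1, function(v) {
    scr <- gene_survival_screen(v$cohort, truth$planted_harmful)
    mean(scr$significant & scr$direction == "high_worse")
  }, numeric(1))
  expect_gte(mean(hits1), 0.9)
})

test_that("copy-number coupling realizes its target correlation", {
  truth <- simulation_truth(n_genes = 150, n_signature = 20, n_harmful = 10,
                            n_beneficial = 0, n_cnv_planted = 10, n_cnv_null = 10,
                            n_meth_planted = 0, n_meth_null = 0, n_mutated = 0)
  sim <- generate_cohort(truth, n_samples = 300, seed = 81)
  om <- generate_multiomics(sim, truth, seed = 82)
  planted <- truth$cnv_genes$gene_id[truth$cnv_genes$rho != 0]
  expect_true(all(abs(om$realized$cnv[planted] - 0.6) < 0.1))
  expect_true(all(om$cnv %in% -2:2))
  expect_true(all(om$meth$beta >= 0 & om$meth$beta <= 1))
  expect_error(simulation_truth(rho_cnv = 0.97), "unreachable")
})

test_that("mutation layers reproduce the carrier sets drawn for the hazard", {
  truth <- simulation_truth(n_genes = 150, n_signature = 20, n_harmful = 5,
                            n_beneficial = 5, n_cnv_planted = 0, n_cnv_null = 0,
                            n_meth_planted = 0, n_meth_null = 0, n_mutated = 2)
  sim <- generate_cohort(truth, n_samples = 200, seed = 91)
  om <- suppressMessages(generate_multiomics(sim, truth, seed = 92))
  for (g in truth$mutated$gene_id) {
    listed <- sort(unique(om$mutations$sample_id[om$mutations$gene_id == g]))
    expect_identical(listed, sim$carriers[[g]])
  }
})

test_that("the single-cell generator is deterministic and QC-separable", {
  truth <- simulation_truth(n_genes = 150, n_signature = 20, n_harmful = 5,
                            n_beneficial = 5, n_cnv_planted = 2, n_cnv_null = 2,
                            n_meth_planted = 2, n_meth_null = 2, n_mutated = 1)
  sc1 <- generate_single_cell(truth, n_cells_per_type = 40, seed = 15)
  sc2 <- generate_single_cell(truth, n_cells_per_type = 40, seed = 15)
  expect_identical(as.matrix(sc1$counts), as.matrix(sc2$counts))

  injected <- attr(sc1, "injected")
  filtered <- suppressMessages(qc_filter(sc1))
  removed <- attr(filtered, "removal_log")$cell_id
  expect_setequal(removed, unlist(injected))

  norm <- normalize_log1p(filtered)
  s <- specificity_score(norm, filtered$labels, truth$checkpoint_gene)
  expect_identical(s$dominant_label, "macrophage")
  expect_gte(s$specificity_score, 0.5)

  ## byte-identical MTX from the same seed
  f1 <- tempfile(fileext = ".mtx"); f2 <- tempfile(fileext = ".mtx")
  Matrix::writeMM(Matrix::t(sc1$counts), f1)
  Matrix::writeMM(Matrix::t(sc2$counts), f2)
  expect_identical(readLines(f1), readLines(f2))
})
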