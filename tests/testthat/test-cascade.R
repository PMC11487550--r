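# Cascade orchestration: screens, classification, validation, nomination.

test_that("the immune screen recovers planted prognostic genes", {
  truth <- simulation_truth(n_genes = 500)
  sim <- generate_cohort(truth, n_samples = 400, seed = 101)
  out <- suppressMessages(screen_ipg(sim$cohort, truth$signature))
  planted <- c(truth$planted_harmful, truth$planted_beneficial)
  expect_true(all(planted %in% out$deg_set))
  recall <- mean(planted %in% out$ipg$gene_id)
  expect_gte(recall, 0.8)
  ## every screened gene came through the DEG gate
  expect_true(all(out$screen$gene_id %in% out$deg_set))
})

test_that("a closed DEG gate empties the downstream screen", {
  truth <- simulation_truth(n_genes = 200, n_signature = 20, n_harmful = 5,
                            n_beneficial = 5, n_cnv_planted = 0, n_cnv_null = 0,
                            n_meth_planted = 0, n_meth_null = 0, n_mutated = 0)
  sim <- generate_cohort(truth, n_samples = 60, seed = 103)
  cfg <- imos_config(deg_p_threshold = 0)
  out <- suppressMessages(screen_ipg(sim$cohort, truth$signature, cfg))
  expect_length(out$deg_set, 0L)
  expect_equal(nrow(out$ipg), 0L)
})

test_that("direction classification partitions the prognostic list", {
  ipg <- data.frame(gene_id = c("a", "b", "c", "d"),
                    p = c(0.01, 0.02, 0.03, 0.04),
                    direction = c("high_worse", "high_better", "none",
                                  "high_worse"))
  expect_warning(cls <- classify_ibg_ihg(ipg), "excluded")
  expect_identical(cls$ihg, c("a", "d"))
  expect_identical(cls$ibg, "b")
  expect_identical(cls$excluded, "c")
  expect_equal(length(cls$ibg) + length(cls$ihg) + length(cls$excluded),
               nrow(ipg))
})

test_that("cross-cohort validation enforces significance, direction and k", {
  truth <- simulation_truth(n_genes = 300, n_signature = 30, n_harmful = 10,
                            n_beneficial = 10, n_cnv_planted = 0,
                            n_cnv_null = 0, n_meth_planted = 0,
                            n_meth_null = 0, n_mutated = 0)
  sim <- generate_cohort(truth, n_samples = 400, seed = 107)
  out <- suppressMessages(screen_ipg(sim$cohort, truth$signature))
  vals <- generate_validation_cohorts(truth, n_cohorts = 2, sizes = c(150, 150),
                                      seed = 107)
  val <- validate_cross_cohort(out$ipg, lapply(vals, `[[`, "cohort"))
  planted <- c(truth$planted_harmful, truth$planted_beneficial)
  expect_gte(mean(val$credible[val$gene_id %in% planted]), 0.8)

  ## direction consistency: flipping the recorded discovery direction of a
  ## credible gene must kill its validation
  flipped <- out$ipg
  flipped$direction <- ifelse(flipped$direction == "high_worse",
                              "high_better", "high_worse")
  val_flip <- validate_cross_cohort(flipped, lapply(vals, `[[`, "cohort"))
  expect_lte(sum(val_flip$credible[val_flip$gene_id %in% planted]), 1)

  ## k larger than the number of significant cohorts is stricter
  cfg3 <- imos_config(validation_min_cohorts = 2)
  val_k2 <- validate_cross_cohort(out$ipg, lapply(vals, `[[`, "cohort"), cfg3)
  expect_true(all(val_k2$credible <= val$credible |
                    val_k2$n_validated >= 2))
  expect_error(validate_cross_cohort(out$ipg, list()), "validation cohort")
})

test_that("null genes pass single-cohort validation at about the alpha rate", {
  truth <- simulation_truth(n_genes = 400, n_signature = 0, n_harmful = 0,
                            n_beneficial = 0, n_cnv_planted = 0, n_cnv_null = 0,
                            n_meth_planted = 0, n_meth_null = 0, n_mutated = 0)
  sim <- generate_cohort(truth, n_samples = 200, seed = 109)
  fake_ipg <- data.frame(gene_id = truth$genes,
                         direction = sample(c("high_worse", "high_better"),
                                            length(truth$genes), replace = TRUE),
                         stringsAsFactors = FALSE)
  val <- validate_cross_cohort(fake_ipg, list(sim$cohort))
  rate <- mean(val$credible)
  ## direction must also match, so the false-pass rate is below alpha
  expect_lt(rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / 400))
})

test_that("candidate ranking counts flags and breaks ties by CNV correlation", {
  ev <- list(genes = data.frame(
    gene_id = c("full", "tie_hi", "tie_lo"),
    snv_fraction = 0.1, mutation_survival_p = 0.5,
    mutation_direction = "mutated_worse",
    cnv_expr_r = c(0.9, 0.8, 0.3), cnv_expr_p = 1e-5, cnv_expr_q = 1e-4,
    cnv_concordant = c(TRUE, TRUE, TRUE),
    cnv_survival_p = c(0.01, 0.2, 0.2),
    cnv_survival_direction = "duplication_worse",
    meth_negative_flag = c(TRUE, TRUE, TRUE),
    meth_low_worse_p = c(0.01, 0.01, 0.01),
    stringsAsFactors = FALSE))
  sp <- data.frame(gene_id = c("full", "tie_hi", "tie_lo"),
                   dominant_label = c("macrophage", "t_cell", "b_cell"),
                   specificity_score = c(0.9, 0.2, 0.2), tie = FALSE,
                   stringsAsFactors = FALSE)
  ranked <- nominate_candidates(c("full", "tie_hi", "tie_lo"), ev, sp)
  expect_identical(ranked$gene_id, c("full", "tie_hi", "tie_lo"))
  expect_equal(ranked$evidence_count[1], 5)
  expect_equal(ranked$evidence_count[2:3], c(3, 3))
  expect_identical(ranked$dominant_cell_type[1], "macrophage")

  ## a gene with no evidence rows at all gets zero flags, not an error
  ranked2 <- suppressMessages(
    nominate_candidates(c("full", "ghost"), ev, sp))
  expect_equal(ranked2$evidence_count[ranked2$gene_id == "ghost"], 0)
})

test_that("the full run recovers the planted checkpoint and is deterministic", {
  dir <- file.path(tempdir(), "imos_e2e")
  unlink(dir, recursive = TRUE)
  truth <- simulation_truth()
  bundle <- suppressMessages(suppressWarnings(
    simulate_bundle(dir, truth, n_discovery = 300, n_validation = 2,
                    validation_sizes = c(150, 150), seed = 11,
                    sc_cells_per_type = 60)))
  rep1 <- suppressMessages(suppressWarnings(
    run_imos(dir, imos_config(seed = 11), out_dir = file.path(dir, "out1"))))

  expect_identical(rep1$candidates$gene_id[1], truth$checkpoint_gene)
  expect_identical(rep1$candidates$dominant_cell_type[1], "macrophage")
  ## cascade set inclusions
  expect_true(all(rep1$ipg$gene_id %in% rep1$deg_set))
  expect_true(all(c(rep1$ibg, rep1$ihg) %in% rep1$ipg$gene_id))
  expect_true(all(rep1$cipg %in% rep1$ipg$gene_id))
  expect_true(all(rep1$candidates$gene_id %in% rep1$cihg))

  rep2 <- suppressMessages(suppressWarnings(
    run_imos(dir, imos_config(seed = 11), out_dir = file.path(dir, "out2"))))
  expect_identical(readLines(file.path(dir, "out1", "report.json")),
                   readLines(file.path(dir, "out2", "report.json")))
})

test_that("a missing omics layer aborts with the stage named", {
  dir <- file.path(tempdir(), "imos_missing_cnv")
  unlink(dir, recursive = TRUE)
  truth <- simulation_truth(n_genes = 200, n_signature = 20, n_harmful = 5,
                            n_beneficial = 5, n_cnv_planted = 2, n_cnv_null = 2,
                            n_meth_planted = 2, n_meth_null = 2, n_mutated = 1)
  suppressMessages(suppressWarnings(
    simulate_bundle(dir, truth, n_discovery = 100, n_validation = 1,
                    validation_sizes = 80, seed = 13, sc_cells_per_type = 30)))
  file.remove(file.path(dir, "cnv.tsv"))
  expect_error(suppressMessages(suppressWarnings(run_imos(dir))),
               "stage 'omics'")
})
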