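# SNV, copy-number and methylation evidence gates.

make_cohort_from <- function(time, event, expr_rows, name = "c") {
  n <- length(time)
  expr <- do.call(rbind, expr_rows)
  dimnames(expr) <- list(names(expr_rows), sprintf("s%03d", seq_len(n)))
  suppressMessages(align_cohort(
    expr, clinical_table(colnames(expr), time, event), name))
}

test_that("mutation frequency counts distinct samples", {
  mut <- data.frame(sample_id = c("s1", "s2", "s3", "s3"),
                    gene_id = c("gA", "gA", "gA", "gA"),
                    variant_class = c("Missense", "Missense", "Missense",
                                      "Nonsense"))
  f <- suppressMessages(snv_frequency(mut, paste0("s", 1:10),
                                      genes = c("gA", "gB")))
  expect_equal(unname(f["gA"]), 0.3)
  expect_equal(unname(f["gB"]), 0)
  expect_true(all(f <= 1))
  expect_error(snv_frequency(mut, paste0("s", 1:2)), "outside the cohort")
})

test_that("mutation survival skips tiny groups and finds planted carrier risk", {
  set.seed(41)
  n <- 300
  carrier <- rbinom(n, 1, 0.3)
  sv <- simulate_surv(n, log(2), carrier)
  co <- make_cohort_from(sv$time, sv$event,
                         list(gX = rnorm(n, 8)))
  mut <- data.frame(sample_id = co$clinical$sample_id[carrier == 1],
                    gene_id = "gX", variant_class = "Missense")
  ms <- mutation_survival(mut, co, "gX")
  expect_lt(ms$p, 0.05)
  expect_identical(ms$direction, "mutated_worse")

  mut1 <- mut[1, , drop = FALSE]
  expect_s3_class(mutation_survival(mut1, co, "gX"), "imos_skip")
})

test_that("null mutation survival rejects at roughly the nominal rate", {
  set.seed(43)
  n <- 150
  sv <- simulate_surv(n, 0, rep(0, n))
  co <- make_cohort_from(sv$time, sv$event, list(gX = rnorm(n, 8)))
  ps <- replicate(300, {
    carrier <- sample(co$clinical$sample_id, 40)
    mut <- data.frame(sample_id = carrier, gene_id = "gX",
                      variant_class = "Missense")
    mutation_survival(mut, co, "gX")$p
  })
  frac <- mean(ps < 0.05)
  expect_lt(frac, 0.05 + 2.58 * sqrt(0.05 * 0.95 / 300) + 0.01)
})

test_that("copy-number concordance flags near-deterministic coupling", {
  set.seed(47)
  n <- 60
  states <- matrix(sample(c(-1L, 0L, 1L, 2L), 2 * n, replace = TRUE), 2, n,
                   dimnames = list(c("gA", "gB"), sprintf("s%03d", 1:n)))
  states["gB", ] <- 0L
  expr <- rbind(gA = states["gA", ] + rnorm(n, 0, 1e-3),
                gB = rnorm(n, 8))
  colnames(expr) <- colnames(states)
  cc <- cnv_expression_correlation(states, expr)
  expect_gt(cc$r[cc$gene_id == "gA"], 0.999)
  expect_true(cc$concordant[cc$gene_id == "gA"])
  expect_identical(cc$skip_reason[cc$gene_id == "gB"], "constant")
  expect_false(cc$concordant[cc$gene_id == "gB"])
})

test_that("concordance recovery on planted correlation behaves as designed", {
  truth <- simulation_truth(n_genes = 200, n_signature = 20, n_harmful = 20,
                            n_beneficial = 0, n_cnv_planted = 20,
                            n_cnv_null = 60, n_meth_planted = 0,
                            n_meth_null = 0, n_mutated = 0)
  sim <- generate_cohort(truth, n_samples = 300, seed = 51)
  om <- generate_multiomics(sim, truth, seed = 52)
  cc <- cnv_expression_correlation(om$cnv, sim$cohort$expression,
                                   genes = truth$genes)
  planted <- truth$cnv_genes$gene_id[truth$cnv_genes$rho != 0]
  nulls <- setdiff(truth$genes, planted)
  expect_gte(mean(cc$concordant[cc$gene_id %in% planted]), 0.9)
  expect_lte(mean(cc$concordant[cc$gene_id %in% nulls]), 0.05)
})

test_that("duplication survival contrast works and skips when degenerate", {
  set.seed(53)
  n <- 400
  dup <- rbinom(n, 1, 0.3)
  sv <- simulate_surv(n, log(1.8), dup)
  co <- make_cohort_from(sv$time, sv$event, list(gD = rnorm(n, 8)))
  cnv <- matrix(as.integer(dup), 1, n,
                dimnames = list("gD", co$clinical$sample_id))
  cs <- cnv_group_survival(cnv, co, "gD")
  expect_lt(cs$p, 0.05)
  expect_identical(cs$direction, "duplication_worse")

  cnv0 <- matrix(0L, 1, n, dimnames = dimnames(cnv))
  expect_s3_class(cnv_group_survival(cnv0, co, "gD"), "imos_skip")
})

test_that("perfect anticorrelation of beta and expression is recovered", {
  n <- 30
  expr <- matrix(seq(0, 1, length.out = n) + 5, 1, n,
                 dimnames = list("gM", sprintf("s%03d", 1:n)))
  beta <- matrix(1 - (expr["gM", ] - 5), 1, n,
                 dimnames = list("cg1", colnames(expr)))
  meth <- methylation_set(beta, data.frame(probe_id = "cg1", gene_id = "gM",
                                           region = "TSS200"))
  mc <- methylation_expression_correlation(meth, expr)
  expect_equal(mc$probes$r, -1, tolerance = 1e-12)
  expect_true(mc$genes$meth_negative_flag)

  mc2 <- methylation_expression_correlation(meth, expr, genes = "gZ")
  expect_identical(mc2$genes$skip_reason, "unmapped")
})

test_that("planted promoter anticorrelation is flagged at high recall", {
  truth <- simulation_truth(n_genes = 200, n_signature = 20, n_harmful = 20,
                            n_beneficial = 0, n_cnv_planted = 0,
                            n_cnv_null = 0, n_meth_planted = 20,
                            n_meth_null = 40, n_mutated = 0)
  sim <- generate_cohort(truth, n_samples = 300, seed = 61)
  om <- generate_multiomics(sim, truth, seed = 62)
  mc <- methylation_expression_correlation(om$meth, sim$cohort$expression)
  planted <- truth$meth_genes$gene_id[truth$meth_genes$rho != 0]
  flags <- mc$genes$meth_negative_flag[mc$genes$gene_id %in% planted]
  expect_gte(mean(flags), 0.9)
})

test_that("probe-level survival reports direction on the methylation scale", {
  set.seed(67)
  n <- 400
  beta_vals <- runif(n)
  low_beta <- as.integer(beta_vals <= stats::median(beta_vals))
  sv <- simulate_surv(n, log(2), low_beta)   # low methylation doubles hazard
  co <- make_cohort_from(sv$time, sv$event, list(gM = rnorm(n, 8)))
  beta <- matrix(beta_vals, 1, n, dimnames = list("cg9", co$clinical$sample_id))
  meth <- methylation_set(beta, data.frame(probe_id = "cg9", gene_id = "gM",
                                           region = "TSS1500"))
  ps <- probe_survival(meth, co, "cg9")
  expect_lt(ps$p, 0.05)
  expect_identical(ps$direction, "low_methylation_worse")

  beta_c <- matrix(0.5, 1, n, dimnames = list("cgC", co$clinical$sample_id))
  meth_c <- methylation_set(beta_c, data.frame(probe_id = "cgC", gene_id = "gM",
                                               region = "body"))
  expect_s3_class(probe_survival(meth_c, co, "cgC"), "imos_skip")
})

test_that("the assembled evidence table carries every gate for a gene", {
  truth <- simulation_truth(n_genes = 150, n_signature = 20, n_harmful = 10,
                            n_beneficial = 10, n_cnv_planted = 5,
                            n_cnv_null = 5, n_meth_planted = 5,
                            n_meth_null = 5, n_mutated = 2)
  sim <- generate_cohort(truth, n_samples = 250, seed = 71)
  om <- suppressMessages(generate_multiomics(sim, truth, seed = 72))
  ev <- suppressMessages(
    build_omics_evidence(truth$planted_harmful[1:5], sim$cohort,
                         cnv = om$cnv, meth = om$meth,
                         mutations = om$mutations))
  expect_equal(nrow(ev$genes), 5L)
  chk <- ev$genes[ev$genes$gene_id == truth$checkpoint_gene, ]
  expect_true(chk$cnv_concordant)
  expect_true(chk$meth_negative_flag)
  expect_gt(chk$snv_fraction, 0.05)
  expect_true(all(ev$meth_probes$gene_id %in% truth$genes))
})
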