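test_that("truth configurations are validated", {
  expect_error(simulation_truth(deg_fraction_increasing = 0.7,
                                deg_fraction_decreasing = 0.5), "sum")
  expect_error(simulation_truth(deg_fraction_increasing = -0.1), "fractions")
  expect_error(simulation_truth(n_replicates = 1), "n_replicates")
  expect_error(simulation_truth(planted_set_enrichment_fold = 0.5), "fold")
  expect_error(simulation_truth(qpcr = list(r_true = 1.2)), "r_true")
})

test_that("the same seed reproduces every artifact byte-identically", {
  t1 <- simulation_truth(seed = 5, n_genes = 120)
  s1 <- simulate_study(t1)
  s2 <- simulate_study(simulation_truth(seed = 5, n_genes = 120))
  expect_identical(s1$expr$values, s2$expr$values)
  expect_identical(s1$meth$beta$betas, s2$meth$beta$betas)
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(s1$qpcr$ct, s2$qpcr$ct)
  expect_identical(s1$qpcr$outcomes, s2$qpcr$outcomes)
  s3 <- simulate_study(simulation_truth(seed = 6, n_genes = 120))
  expect_false(identical(s1$expr$values, s3$expr$values))
})

test_that("zero-noise expression means are exactly the planted steps", {
  truth <- simulation_truth(seed = 2, n_genes = 60, noise_sd = 0,
                            effect_size = 2, mid_fraction = 0.5)
  sim <- simulate_expression(truth)
  em <- sim$expr
  cm <- vapply(c("baseline", "mid", "high"), function(cond)
    rowMeans(em$values[, em$design$condition == cond, drop = FALSE]),
    numeric(nrow(em$values)))
  inc <- sim$labels$class == "increasing"
  dec <- sim$labels$class == "decreasing"
  nul <- sim$labels$class == "null"
  expect_equal(cm[inc, "mid"] - cm[inc, "baseline"],
               rep(1, sum(inc)), ignore_attr = TRUE)
  expect_equal(cm[inc, "high"] - cm[inc, "baseline"],
               rep(2, sum(inc)), ignore_attr = TRUE)
  expect_equal(cm[dec, "high"] - cm[dec, "baseline"],
               rep(-2, sum(dec)), ignore_attr = TRUE)
  expect_equal(cm[nul, "high"], cm[nul, "baseline"], ignore_attr = TRUE)
})

test_that("planted class counts equal the label bookkeeping", {
  truth <- simulation_truth(seed = 13, n_genes = 500,
                            deg_fraction_increasing = 0.08,
                            deg_fraction_decreasing = 0.12)
  sim <- simulate_expression(truth)
  counts <- table(sim$labels$class)
  expect_equal(unname(counts["increasing"]), round(0.08 * 500),
               ignore_attr = TRUE)
  expect_equal(unname(counts["decreasing"]), round(0.12 * 500),
               ignore_attr = TRUE)
  expect_equal(sum(counts), 500)
  expect_equal(nrow(sim$labels), nrow(sim$expr$values))
})

test_that("an all-null design yields almost no calls at 5% FDR", {
  truth <- simulation_truth(seed = 23, n_genes = 500,
                            deg_fraction_increasing = 0,
                            deg_fraction_decreasing = 0)
  sim <- simulate_expression(truth)
  expect_true(all(sim$labels$class == "null"))
  res <- rank_product_test(sim$expr, "high", "baseline", n_perm = 100,
                           seed = 23)
  calls <- call_degs(res, fdr = 0.05)
  expect_lt(length(unlist(calls)) / 500, 0.12)
})

test_that("coupled methylation moves against expression by the planted step", {
  truth <- simulation_truth(seed = 3, n_genes = 200, beta_noise_sd = 0,
                            meth_coupled_fraction = 1)
  sim <- simulate_expression(truth)
  meth <- simulate_methylation(truth, sim$labels)
  bt <- meth$beta
  d <- bt$design
  dbeta <- rowMeans(bt$betas[, d$condition == "high", drop = FALSE]) -
    rowMeans(bt$betas[, d$condition == "baseline", drop = FALSE])
  gene_of <- bt$probe_to_gene$gene[match(names(dbeta),
                                         bt$probe_to_gene$probe)]
  cls <- sim$labels$class[match(gene_of, sim$labels$gene)]
  coup <- meth$labels$coupled[match(gene_of, meth$labels$gene)]
  expect_true(all(dbeta[cls == "increasing" & coup] <= -0.25))
  expect_true(all(dbeta[cls == "decreasing" & coup] >= 0.25))
  expect_true(all(abs(dbeta[cls == "null"]) < 1e-12))
  expect_true(all(bt$betas >= 0 & bt$betas <= 1))
})

test_that("beta values are clipped into the unit interval at high baselines", {
  # decreasing-expression coupled genes shift +0.3 from baselines up to 0.8,
  # with noise on top: clipping must keep everything in [0, 1]
  truth <- simulation_truth(seed = 41, n_genes = 300, beta_noise_sd = 0.15,
                            meth_coupled_fraction = 1)
  sim <- simulate_expression(truth)
  meth <- simulate_methylation(truth, sim$labels)
  expect_true(all(meth$beta$betas >= 0 & meth$beta$betas <= 1))
})

test_that("planted annotation sets are flagged by the EASE screen", {
  hits <- vapply(1:100, function(s) {
    truth <- simulation_truth(seed = s, n_genes = 300,
                              planted_set_sizes = 30)
    sim <- simulate_expression(truth)
    an <- simulate_annotations(truth, sim$labels)
    inc <- sim$labels$gene[sim$labels$class == "increasing"]
    r <- ease_test(inc, an$gene_sets$planted_set_1, sim$labels$gene)
    r$ease_p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("simulated qPCR inverts exactly at zero noise", {
  truth <- simulation_truth(seed = 7, qpcr = list(ct_noise_sd = 0))
  qp <- simulate_qpcr(truth)
  # delta-delta Ct between the peak time and time 0 recovers the planted max
  series <- induction_series_from_ct(qp$ct, qp$design)
  for (g in rownames(qp$truth_max)) {
    for (u in colnames(qp$truth_max)) {
      s <- series[series$gene == g & series$unit == u, ]
      m <- max_induction(s[order(s$time), ], 72)
      expect_equal(m$fold, qp$truth_max[g, u], tolerance = 1e-10)
    }
  }
})

test_that("collinear planted outcomes give a sample correlation of one", {
  truth <- simulation_truth(seed = 9, qpcr = list(r_true = 1,
                                                  ct_noise_sd = 0))
  qp <- simulate_qpcr(truth)
  for (g in rownames(qp$truth_max)) {
    r <- correlate_induction(qp$truth_max[g, ], qp$outcomes[g, ])
    expect_equal(r$r, 1, tolerance = 1e-10)
  }
})

test_that("planted induction-outcome correlation is recovered on average", {
  rs <- vapply(1:200, function(s) {
    truth <- simulation_truth(seed = s,
                              qpcr = list(r_true = 0.95, n_units = 50,
                                          genes = "FOXQ1"))
    qp <- simulate_qpcr(truth)
    correlate_induction(qp$truth_max["FOXQ1", ], qp$outcomes["FOXQ1", ])$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.95), 0.03)
})
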