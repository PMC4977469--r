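two_group_design <- function(n_a, n_b) {
  data.frame(sample = c(paste0("a", seq_len(n_a)), paste0("b", seq_len(n_b))),
             condition = rep(c("a", "b"), c(n_a, n_b)),
             replicate = c(seq_len(n_a), seq_len(n_b)),
             stringsAsFactors = FALSE)
}

test_that("a gene ranked first in all pairings attains the minimal RP of 1", {
  d <- two_group_design(2, 2)
  set.seed(2)
  m <- toy_matrix(10, d, sd = 0.2)
  m[1, 1:2] <- m[1, 1:2] + 50                      # dominates every pairing
  res <- rank_product_test(m, "a", "b", n_perm = 10, seed = 1, design = d)
  expect_equal(res$rp[res$gene == "g001" & res$direction == "up"], 1)
  expect_true(all(res$rp >= 1))
})

test_that("RP is invariant under monotone transforms of the pairing values", {
  d <- two_group_design(3, 3)
  set.seed(4)
  m <- toy_matrix(30, d)
  r1 <- rank_product_test(m, "a", "b", n_perm = 5, seed = 7, design = d)
  # strictly increasing transform of the log2 values preserves within-pairing
  # order of differences only if applied to the differences; apply an affine
  # positive rescaling of the matrix instead (a monotone map of every
  # pairing's fold-change differences)
  r2 <- rank_product_test(2.5 * m + 3, "a", "b", n_perm = 5, seed = 7,
                          design = d)
  expect_equal(r2$rp, r1$rp)
  expect_equal(r2$pfp, r1$pfp)
})

test_that("swapping the conditions swaps up and down calls exactly", {
  d <- two_group_design(3, 3)
  set.seed(6)
  m <- toy_matrix(40, d)
  m[1:4, 1:3] <- m[1:4, 1:3] + 3
  r_ab <- rank_product_test(m, "a", "b", n_perm = 50, seed = 3, design = d)
  r_ba <- rank_product_test(m, "b", "a", n_perm = 50, seed = 3, design = d)
  up_ab <- r_ab[r_ab$direction == "up", ]
  dn_ba <- r_ba[r_ba$direction == "down", ]
  expect_equal(up_ab$rp, dn_ba$rp)
  expect_equal(up_ab$pfp, dn_ba$pfp)
})

test_that("permutation PFP converges to the exhaustive-enumeration oracle", {
  # 5 genes, 2 vs 2 replicates: the null expected count G * P(prod U <= r^K)
  # is enumerable over all G^K rank combinations
  d <- two_group_design(2, 2)
  set.seed(8)
  m <- toy_matrix(5, d, sd = 1)
  res <- rank_product_test(m, "a", "b", n_perm = 10000, seed = 42, design = d)
  for (dir in c("up", "down")) {
    sub <- res[res$direction == dir, ]
    expected <- vapply(sub$rp, oracle_expected_null_count, numeric(1),
                       G = 5, K = 4)
    oracle_pfp <- expected / rank(log(sub$rp), ties.method = "average")
    o <- order(sub$rp)
    oracle_pfp[o] <- cummax(oracle_pfp[o])
    oracle_pfp <- pmin(oracle_pfp, 1)
    expect_lt(max(abs(sub$pfp - oracle_pfp)), 0.02)
  }
})

test_that("PFP estimates tighten toward the oracle as permutations grow", {
  d <- two_group_design(2, 2)
  set.seed(12)
  m <- toy_matrix(6, d, sd = 1)
  oracle_for <- function(sub) {
    expected <- vapply(sub$rp, oracle_expected_null_count, numeric(1),
                       G = 6, K = 4)
    p <- expected / rank(log(sub$rp), ties.method = "average")
    o <- order(sub$rp)
    p[o] <- cummax(p[o])
    pmin(p, 1)
  }
  err <- vapply(c(20, 200, 4000), function(np) {
    res <- rank_product_test(m, "a", "b", n_perm = np, seed = 9, design = d)
    sub <- res[res$direction == "up", ]
    max(abs(sub$pfp - oracle_for(sub)))
  }, numeric(1))
  expect_lt(err[3], err[1] + 1e-9)
  expect_lt(err[3], 0.03)
})

test_that("results are deterministic under a fixed seed", {
  d <- two_group_design(3, 3)
  set.seed(10)
  m <- toy_matrix(25, d)
  r1 <- rank_product_test(m, "a", "b", n_perm = 20, seed = 5, design = d)
  r2 <- rank_product_test(m, "a", "b", n_perm = 20, seed = 5, design = d)
  expect_identical(r1, r2)
})

test_that("DEG calling respects the FDR gate and its boundaries", {
  res <- data.frame(gene = c("g1", "g2", "g3", "g1", "g2", "g3"),
                    direction = rep(c("up", "down"), each = 3),
                    rp = c(1, 5, 9, 9, 5, 1),
                    pfp = c(0.01, 0.2, 1, 1, 0.9, 0.04))
  calls <- call_degs(res, fdr = 0.05)
  expect_equal(calls$up, "g1")
  expect_equal(calls$down, "g3")
  expect_error(call_degs(res, fdr = 0), "fdr")
  expect_error(call_degs(res, fdr = 1.5), "fdr")
  all_called <- call_degs(res, fdr = 1)
  expect_setequal(c(all_called$up, all_called$down),
                  c("g1", "g2", "g3", "g1", "g2", "g3"))
  res_bad <- res
  res_bad$pfp <- 0.01
  expect_error(call_degs(res_bad, fdr = 0.05), "both directions")
})

test_that("planted differential signals are recovered at the study conditions", {
  # one seeded replicate of the planted design: 10% DEGs, effect 2, noise 0.5
  truth <- simulation_truth(seed = 77, n_genes = 800)
  sim <- simulate_expression(truth)
  res <- rank_product_test(sim$expr, "high", "baseline", n_perm = 100,
                           seed = 77)
  calls <- call_degs(res, fdr = 0.05)
  truth_up <- sim$labels$gene[sim$labels$class == "increasing"]
  truth_dn <- sim$labels$gene[sim$labels$class == "decreasing"]
  expect_gt(mean(truth_up %in% calls$up), 0.9)
  expect_gt(mean(truth_dn %in% calls$down), 0.9)
  called <- c(calls$up, calls$down)
  fdp <- mean(!called %in% c(truth_up, truth_dn))
  expect_lt(fdp, 0.2)   # anticonservatism of the permutation null is bounded
})

test_that("DMG calling applies both the FDR and beta-change gates", {
  # construct probes where one gate fails at a time
  truth <- simulation_truth(seed = 31, n_genes = 300,
                            meth_coupled_fraction = 1, beta_noise_sd = 0.02)
  sim <- simulate_expression(truth)
  meth <- simulate_methylation(truth, sim$labels)
  dmg <- call_dmgs(meth$beta, "high", "baseline", fdr = 0.05,
                   min_beta_change = 0.25, n_perm = 100, seed = 31)
  coupled <- meth$labels$gene[meth$labels$coupled]
  inc <- sim$labels$gene[sim$labels$class == "increasing"]
  dec <- sim$labels$gene[sim$labels$class == "decreasing"]
  # methylation moves opposite to expression
  recall_dn <- mean(intersect(coupled, inc) %in% dmg$genes$down)
  recall_up <- mean(intersect(coupled, dec) %in% dmg$genes$up)
  expect_gt(recall_dn, 0.9)
  expect_gt(recall_up, 0.9)
  # null genes essentially never pass the 0.25 beta gate
  null_genes <- sim$labels$gene[sim$labels$class == "null"]
  expect_lt(mean(null_genes %in% unlist(dmg$genes)), 0.02)
  # gate boundaries on the probe table
  pr <- dmg$probes
  expect_true(all(abs(pr$delta_beta[pr$called]) >= 0.25))
  expect_true(all(pr$pfp[pr$called] <= 0.05))
  expect_error(call_dmgs(meth$beta, "high", "baseline",
                         min_beta_change = 1.5), "min_beta_change")
})
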