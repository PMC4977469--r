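toy_models <- function() {
  # coordinates in the package's 0-based convention
  data.frame(gene = c("gp", "gm"), chrom = c("chr1", "chr1"),
             strand = c("+", "-"),
             tss = c(100000L, 210000L), end = c(110000L, 200000L),
             stringsAsFactors = FALSE)
}

test_that("TF window assignment respects half-open boundaries and strand", {
  models <- toy_models()
  peaks <- data.frame(
    chrom = "chr1",
    start = c(95000L,    # inside the upstream flank of gp
              89900L,    # touches the gp window boundary exactly: excluded
              215000L,   # inside the upstream flank of gm (genomic right)
              220001L),  # touches the gm boundary exactly: excluded
    end = c(95100L, 90000L, 215100L, 220101L),
    tf = c("TF1", "TF2", "TF3", "TF4"), stringsAsFactors = FALSE)
  t <- assign_tf_targets(peaks, models, upstream_bp = 10000,
                         downstream_bp = 3000)
  expect_equal(t$TF1, "gp")
  expect_length(t$TF2, 0)
  expect_equal(t$TF3, "gm")
  expect_length(t$TF4, 0)
  # 3' downstream flank, minus strand: left of the gene end in genome space
  peaks5 <- data.frame(chrom = "chr1", start = 197500L, end = 197600L,
                       tf = "TF5")
  expect_equal(assign_tf_targets(peaks5, models)$TF5, "gm")
  # gene body itself (introns and exons) is part of the window
  peaks6 <- data.frame(chrom = "chr1", start = 105000L, end = 105010L,
                       tf = "TF6")
  expect_equal(assign_tf_targets(peaks6, models)$TF6, "gp")
  models$strand[1] <- "*"
  expect_error(assign_tf_targets(peaks5, models), "strand")
})

test_that("TF window assignment is invariant under coordinate translation", {
  set.seed(17)
  models <- toy_models()
  peaks <- data.frame(chrom = "chr1",
                      start = as.integer(runif(20, 80000, 230000)))
  peaks$end <- peaks$start + 150L
  peaks$tf <- "TF"
  shift <- 1234567L
  models2 <- models
  models2$tss <- models2$tss + shift
  models2$end <- models2$end + shift
  peaks2 <- peaks
  peaks2$start <- peaks2$start + shift
  peaks2$end <- peaks2$end + shift
  expect_identical(assign_tf_targets(peaks, models),
                   assign_tf_targets(peaks2, models2))
})

test_that("EASE deflation reproduces the brute-force tail and its boundaries", {
  # k = 1 deflates to zero overlap and can never be significant
  bg <- sprintf("g%02d", 1:20)
  r <- ease_test(bg[1:5], bg[c(1, 10:15)], bg)
  expect_equal(r$k, 1)
  expect_equal(r$ease_p, 1)
  # the fold is the plain ratio of proportions
  bg2 <- sprintf("g%04d", 1:1000)
  r2 <- ease_test(bg2[1:100], bg2[c(1:10, 101:140)], bg2)
  expect_equal(r2$fold, 2.0)
  # membership and degeneracy contracts
  expect_error(ease_test(c("zz"), bg[1:3], bg), "background")
  r3 <- ease_test(character(0), bg[1:3], bg)
  expect_true(r3$degenerate)
  expect_equal(r3$ease_p, 1)
  expect_equal(r3$fold, 0)
})

test_that("EASE equals exhaustive hypergeometric summation on fuzzed tables", {
  set.seed(71)
  for (i in 1:200) {
    N <- sample(5:25, 1)
    bg <- sprintf("g%02d", seq_len(N))
    q <- sample(bg, sample(1:N, 1))
    a <- sample(bg, sample(1:N, 1))
    r <- ease_test(q, a, bg)
    expect_equal(r$ease_p,
                 oracle_ease(r$k, r$n, r$K, r$N), tolerance = 1e-12)
    # deflation can only raise the p-value over the classical Fisher tail
    expect_gte(r$ease_p,
               oracle_fisher_upper(r$k, r$n, r$K, r$N) - 1e-12)
  }
})

test_that("fold enrichment is invariant to proportional background scaling", {
  bg <- sprintf("g%04d", 1:500)
  q <- bg[1:50]
  a <- bg[c(1:20, 101:130)]
  r1 <- ease_test(q, a, bg)
  # double the background and the annotation's out-of-query part
  bg2 <- c(bg, sprintf("h%04d", 1:500))
  a2 <- c(a, sprintf("h%04d", 1:50))
  r2 <- ease_test(q, a2, bg2)
  expect_equal(r2$fold, r1$fold)
})

test_that("TF regulator calling applies both gates in order of significance", {
  res <- data.frame(tf = c("A", "B", "C", "D"),
                    fold = c(1.19, 3.0, 2.0, 1.5),
                    ease_p = c(0.001, 0.049, 0.002, 0.2))
  called <- call_tf_regulators(res)
  expect_equal(called, c("C", "B"))    # A fails fold, D fails p
})

test_that("planted TF target sets are recovered and called", {
  hits <- vapply(1:50, function(s) {
    truth <- simulation_truth(seed = s, n_genes = 300)
    sim <- simulate_expression(truth)
    an <- simulate_annotations(truth, sim$labels)
    targets <- assign_tf_targets(an$peaks, an$gene_models)
    expect_setequal(targets$TF_planted, an$tf_targets)
    inc <- sim$labels$gene[sim$labels$class == "increasing"]
    r <- ease_test(inc, targets$TF_planted, sim$labels$gene)
    r$fold > 1.2 && r$ease_p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("paired gene-set t equals the closed form and handles degeneracy", {
  a <- c(g1 = 2, g2 = 2.2, g3 = 1.8, g4 = 2)
  b <- c(g1 = 1, g2 = 1, g3 = 1, g4 = 1)
  r <- geneset_paired_ttest(a, b, names(a))
  oracle <- oracle_paired_t(c(1.0, 1.2, 0.8, 1.0))
  expect_equal(r$t, oracle$t)
  expect_equal(r$p, oracle$p)
  expect_equal(r$direction, 1)
  # identical vectors: t = 0, two-sided p = 1
  r0 <- geneset_paired_ttest(a, a, names(a))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # constant non-zero differences are flagged degenerate with p = 0
  rz <- geneset_paired_ttest(a, a - 1, names(a))
  expect_true(rz$degenerate)
  expect_equal(rz$p, 0)
  expect_error(geneset_paired_ttest(a[1:2], b[1:2], names(a)[1:2]),
               "fewer than 3")
})

test_that("a planted mesodermal shift is detected by the paired test", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    genes <- sprintf("g%02d", 1:40)
    b <- rnorm(40, 8, 1)
    a <- b + 0.8 + rnorm(40, 0, 0.5)
    names(a) <- names(b) <- genes
    geneset_paired_ttest(a, b, genes)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
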