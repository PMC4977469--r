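#' Rank-product differential test with permutation PFP
#'
#' Non-parametric two-condition test. For each of the K = n_a x n_b
#' cross-condition replicate pairings the per-gene fold-change difference
#' (log2 value in the `cond_a` replicate minus the `cond_b` replicate) is
#' ranked, rank 1 being the most extreme in the tested direction and ties
#' receiving average ranks. The rank product of gene g is the geometric mean
#' of its K ranks. Significance is expressed as the estimated proportion of
#' false positives (PFP) at each gene's position in the ranked list,
#' estimated from `n_perm` independent permutations of the within-pairing
#' ranks: pfp(g) = E\[number of null genes with RP <= RP_g\] / rank(g).
#' PFP is made monotone non-decreasing down the ranked list by a cumulative
#' maximum, so calls at any threshold form a contiguous prefix, and is
#' reported clipped to \[0, 1\]. Up- and down-regulation are tested
#' separately.
#'
#' @param x `expr_matrix`, `beta_table`, or a plain numeric matrix (then
#'   `design` is required).
#' @param cond_a,cond_b condition names; fold changes are `cond_a - cond_b`.
#' @param n_perm number of rank permutations (>= 1; default 100).
#' @param seed integer seed making the permutation estimate reproducible.
#' @param design design table, only for plain-matrix input.
#' @return data.frame with one row per feature and direction: `gene`,
#'   `direction` (`"up"`/`"down"`), `rp`, `pfp`.
#' @export
rank_product_test <- function(x, cond_a, cond_b, n_perm = 100, seed = 1,
                              design = NULL) {
  if (inherits(x, "expr_matrix")) { design <- x$design; x <- x$values }
  else if (inherits(x, "beta_table")) { design <- x$design; x <- x$betas }
  if (is.null(design)) stop("a design table is required for matrix input")
  design <- validate_design(design)
  if (n_perm < 1) stop("n_perm must be >= 1")
  a_cols <- condition_samples(design, cond_a)
  b_cols <- condition_samples(design, cond_b)
  if (length(a_cols) < 2 || length(b_cols) < 2)
    stop("both conditions need >= 2 replicates")
  G <- nrow(x)
  pairs <- expand.grid(a = a_cols, b = b_cols, stringsAsFactors = FALSE)
  K <- nrow(pairs)
  d <- vapply(seq_len(K),
              function(k) x[, pairs$a[k]] - x[, pairs$b[k]],
              numeric(G))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  out <- lapply(c("up", "down"), function(dir) {
    # one seeded stream per direction, so exchanging the conditions swaps
    # the up and down results exactly
    set.seed(seed)
    r <- if (dir == "up") apply(-d, 2, rank, ties.method = "average")
         else apply(d, 2, rank, ties.method = "average")
    r <- matrix(r, nrow = G)
    obs <- rowMeans(log(r))
    # permuted null columns are drawn from each pairing's sorted rank
    # multiset, so the null does not depend on the pairing enumeration order
    rs <- apply(r, 2, sort)
    null_lrp <- numeric(G * n_perm)
    for (p in seq_len(n_perm)) {
      perm <- vapply(seq_len(K), function(k) rs[sample.int(G), k], numeric(G))
      null_lrp[((p - 1) * G + 1):(p * G)] <- rowMeans(log(matrix(perm, G)))
    }
    ns <- sort(null_lrp)
    cnt <- findInterval(obs, ns) / n_perm
    rk <- rank(obs, ties.method = "average")
    pfp <- cnt / rk
    o <- order(obs)
    pfp[o] <- cummax(pfp[o])
    data.frame(gene = rownames(x) %||% as.character(seq_len(G)),
               direction = dir, rp = exp(obs), pfp = pmin(pfp, 1),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "comparison") <- c(a = cond_a, b = cond_b)
  attr(res, "n_perm") <- n_perm
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call differentially expressed genes at an FDR threshold
#'
#' @param results output of [rank_product_test()].
#' @param fdr accepted proportion of false positives, in (0, 1\].
#' @return list with character vectors `up` and `down`. A gene significant in
#'   both directions would indicate a broken ranking and raises an error.
#' @export
call_degs <- function(results, fdr = 0.05) {
  if (!is.numeric(fdr) || length(fdr) != 1 || fdr <= 0 || fdr > 1)
    stop("fdr must lie in (0, 1]")
  sig <- results[results$pfp <= fdr, , drop = FALSE]
  up <- sig$gene[sig$direction == "up"]
  down <- sig$gene[sig$direction == "down"]
  both <- intersect(up, down)
  # at fdr = 1 every gene passes both directions by construction; below it a
  # double call would mean a broken ranking
  if (fdr < 1 && length(both))
    stop("internal error: gene(s) significant in both directions: ",
         paste(both, collapse = ", "))
  list(up = up, down = down)
}

#' Call differentially methylated genes
#'
#' Probes must pass the rank-product FDR *and* carry an absolute mean beta
#' change of at least `min_beta_change` between the two conditions. Probe
#' calls are aggregated to genes: any passing probe calls the gene. The full
#' per-gene list of probe delta-betas is retained for the downstream
#' probe-consistency check.
#'
#' @param bt `beta_table`.
#' @param cond_a,cond_b condition names (delta beta = mean a - mean b).
#' @param fdr accepted proportion of false positives.
#' @param min_beta_change minimum |delta beta|, in \[0, 1\] (default 0.25).
#' @param n_perm,seed passed to [rank_product_test()].
#' @return list with `probes` (data.frame: probe, gene, direction, rp, pfp,
#'   delta_beta, called), `genes` (list `up`/`down` of gene ids) and
#'   `gene_delta_betas` (named list of per-gene probe delta-beta vectors).
#' @export
call_dmgs <- function(bt, cond_a, cond_b, fdr = 0.05, min_beta_change = 0.25,
                      n_perm = 100, seed = 1) {
  stopifnot(inherits(bt, "beta_table"))
  if (min_beta_change < 0 || min_beta_change > 1)
    stop("min_beta_change must lie in [0, 1]")
  res <- rank_product_test(bt, cond_a, cond_b, n_perm = n_perm, seed = seed)
  a_cols <- condition_samples(bt$design, cond_a)
  b_cols <- condition_samples(bt$design, cond_b)
  dbeta <- rowMeans(bt$betas[, a_cols, drop = FALSE]) -
    rowMeans(bt$betas[, b_cols, drop = FALSE])
  res$delta_beta <- dbeta[match(res$gene, rownames(bt$betas))]
  res$called <- res$pfp <= fdr & abs(res$delta_beta) >= min_beta_change &
    ifelse(res$direction == "up", res$delta_beta > 0, res$delta_beta < 0)
  names(res)[names(res) == "gene"] <- "probe"
  res$gene <- bt$probe_to_gene$gene[match(res$probe, bt$probe_to_gene$probe)]
  called <- res[res$called & !is.na(res$gene), , drop = FALSE]
  genes <- list(up = unique(called$gene[called$direction == "up"]),
                down = unique(called$gene[called$direction == "down"]))
  per_gene <- split(dbeta[bt$probe_to_gene$probe], bt$probe_to_gene$gene)
  list(probes = res, genes = genes, gene_delta_betas = per_gene)
}
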