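#' Classify regulation transition between two comparisons
#'
#' Classifies how a gene's regulation changes from one comparison (log2FC
#' `fc_mid`) to another (`fc_high`): with the same sign, a larger absolute
#' value is *increased* regulation and a smaller one *decreased*; a sign flip
#' (both values exceeding the tolerance) is *reversed*; anything else is
#' *unchanged*. A value within `tol` of zero inherits the sign of the other
#' value, so near-flat starting points such as (0.12, 2.17) classify as
#' increased.
#'
#' @param fc_mid,fc_high finite log2 fold changes (vectorized).
#' @param tol non-negative tolerance on comparisons (default 0).
#' @return character vector: `"increased"`, `"decreased"`, `"reversed"` or
#'   `"unchanged"`.
#' @export
classify_regulation <- function(fc_mid, fc_high, tol = 0) {
  stopifnot(tol >= 0, is.finite(fc_mid), is.finite(fc_high))
  n <- max(length(fc_mid), length(fc_high))
  fc_mid <- rep_len(fc_mid, n); fc_high <- rep_len(fc_high, n)
  s_mid <- ifelse(abs(fc_mid) <= tol, sign(fc_high), sign(fc_mid))
  s_high <- ifelse(abs(fc_high) <= tol, sign(fc_mid), sign(fc_high))
  out <- rep("unchanged", n)
  same <- s_mid == s_high
  out[same & abs(fc_high) > abs(fc_mid) + tol] <- "increased"
  out[same & abs(fc_high) < abs(fc_mid) - tol] <- "decreased"
  out[!same & abs(fc_mid) > tol & abs(fc_high) > tol] <- "reversed"
  out
}

#' Classify the monotone trend of a fold-change profile
#'
#' A gene is monotone-increasing across baseline, mid and high conditions iff
#' 0 <= fc_mid <= fc_high and fc_high exceeds the tolerance;
#' monotone-decreasing is the mirror image; everything else is `"other"`.
#'
#' @param fc_mid,fc_high finite log2 fold changes vs the shared baseline.
#' @param tol non-negative tolerance (default 0).
#' @return character vector: `"monotone-increasing"`, `"monotone-decreasing"`
#'   or `"other"`.
#' @export
classify_trend <- function(fc_mid, fc_high, tol = 0) {
  stopifnot(tol >= 0, is.finite(fc_mid), is.finite(fc_high))
  n <- max(length(fc_mid), length(fc_high))
  fc_mid <- rep_len(fc_mid, n); fc_high <- rep_len(fc_high, n)
  inc <- fc_mid >= 0 & fc_high >= fc_mid & fc_high > tol
  dec <- fc_mid <= 0 & fc_high <= fc_mid & fc_high < -tol
  ifelse(inc, "monotone-increasing",
         ifelse(dec, "monotone-decreasing", "other"))
}

#' K-means clustering with dot-product similarity
#'
#' Lloyd-style iteration on fold-change profiles where each profile is
#' assigned to the centroid maximizing the (un-normalized) dot product
#' `sum_j x_j c_j`; centroids are arithmetic means of their members. With
#' `metric = "cosine"` profiles and centroids are L2-normalized before the
#' similarity. Empty clusters are re-seeded from the point most dissimilar to
#' its current centroid. Deterministic under `seed` (initial centroids are a
#' seeded sample of k distinct profiles).
#'
#' @param profiles numeric matrix, rows = genes, columns = log2FC per
#'   non-baseline condition (or a [baseline_log2fc()] frame).
#' @param k number of clusters (>= 2).
#' @param seed integer seed.
#' @param max_iter iteration cap (default 100).
#' @param metric `"dot"` (default) or `"cosine"`.
#' @return list with `cluster` (integer vector, named by gene), `centers`
#'   (k x p matrix), `iterations`, and `objective` (the per-iteration summed
#'   member-centroid similarity, non-decreasing).
#' @export
kmeans_dot <- function(profiles, k, seed = 1, max_iter = 100,
                       metric = c("dot", "cosine")) {
  metric <- match.arg(metric)
  if (is.data.frame(profiles)) {
    rn <- if ("gene" %in% names(profiles)) profiles$gene else rownames(profiles)
    profiles <- as.matrix(profiles[, setdiff(names(profiles), "gene"),
                                   drop = FALSE])
    rownames(profiles) <- rn
  }
  if (k < 2) stop("k must be >= 2")
  X <- profiles
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(X^2))
    if (any(nrm == 0)) stop("cosine metric undefined for all-zero profiles")
    X <- X / nrm
  }
  G <- nrow(X)
  distinct <- !duplicated(X)
  if (sum(distinct) < k)
    stop("fewer distinct profiles (", sum(distinct), ") than k = ", k)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  cent <- X[sample(which(distinct), k), , drop = FALSE]
  norm_cent <- function(cent) {
    if (metric != "cosine") return(cent)
    nrm <- sqrt(rowSums(cent^2))
    nrm[nrm == 0] <- 1
    cent / nrm
  }
  cent <- norm_cent(cent)
  assign_prev <- integer(G)
  obj <- numeric(0)
  for (it in seq_len(max_iter)) {
    S <- X %*% t(cent)
    a <- max.col(S, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(a == j)) {                       # re-seed empty cluster
        worst <- which.min(S[cbind(seq_len(G), a)])
        cent[j, ] <- X[worst, ]
        cent <- norm_cent(cent)
        S <- X %*% t(cent)
        a <- max.col(S, ties.method = "first")
      }
    }
    obj <- c(obj, sum(S[cbind(seq_len(G), a)]))
    if (identical(a, assign_prev)) break
    assign_prev <- a
    for (j in seq_len(k))
      cent[j, ] <- colMeans(X[a == j, , drop = FALSE])
    cent <- norm_cent(cent)
  }
  names(a) <- rownames(profiles)
  list(cluster = a, centers = cent, iterations = it, objective = obj)
}

#' Check direction-consistency of a gene's methylation probes
#'
#' Only probes with |delta beta| above `min_delta` qualify; a gene is
#' consistent when all qualifying probes change in the same direction. Genes
#' on the exclusion list (by default the GNAS complex locus, whose probes are
#' exempted) are consistent by fiat, as are genes with at most one qualifying
#' probe.
#'
#' @param gene gene symbol.
#' @param probe_delta_betas numeric vector of per-probe delta betas.
#' @param min_delta qualifying threshold on |delta beta| (default 0.15).
#' @param exclusions character vector of exempted genes.
#' @return logical flag.
#' @export
probe_consistency <- function(gene, probe_delta_betas, min_delta = 0.15,
                              exclusions = c("GNAS")) {
  if (min_delta < 0 || min_delta > 1) stop("min_delta must lie in [0, 1]")
  if (gene %in% exclusions) return(TRUE)
  q <- probe_delta_betas[abs(probe_delta_betas) > min_delta]
  if (length(q) <= 1) return(TRUE)
  all(q > 0) || all(q < 0)
}

#' Association between expression and methylation dynamics classes
#'
#' Tests whether membership in an expression-dynamics class is associated
#' with membership in a methylation-dynamics class over a shared background
#' (the genes common to both platforms), using the two-sided Fisher exact
#' test on the 2x2 membership table.
#'
#' @param expr_class_members,meth_class_members character vectors, subsets of
#'   `background`.
#' @param background character vector of background genes.
#' @return list with `table` (2x2 counts), `p` (two-sided Fisher exact),
#'   `odds_ratio` (sample odds ratio, `NaN` when undefined) and `degenerate`
#'   flag.
#' @export
dynamics_association <- function(expr_class_members, meth_class_members,
                                 background) {
  background <- unique(background)
  bad <- setdiff(c(expr_class_members, meth_class_members), background)
  if (length(bad))
    stop("class member(s) not in background: ", paste(utils::head(bad, 5),
                                                      collapse = ", "))
  e <- background %in% expr_class_members
  m <- background %in% meth_class_members
  tab <- matrix(c(sum(e & m), sum(e & !m), sum(!e & m), sum(!e & !m)),
                nrow = 2, byrow = TRUE,
                dimnames = list(expr = c("in", "out"), meth = c("in", "out")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate)
    return(list(table = tab, p = 1, odds_ratio = NaN, degenerate = TRUE))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(table = tab, p = min(p, 1), odds_ratio = or, degenerate = FALSE)
}
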