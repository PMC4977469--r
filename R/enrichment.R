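#' Assign putative TF targets from ChIP peaks by a strand-aware window
#'
#' A gene is a putative target of a TF when any of that TF's peaks overlaps
#' the gene's regulatory window: the full gene body (TSS to gene end,
#' inclusive of introns and exons) extended `upstream_bp` on the 5' side and
#' `downstream_bp` on the 3' side, mirrored for minus-strand genes. Peaks and
#' gene coordinates use the package's 0-based half-open convention (see
#' [read_gene_models()]); overlap means a non-empty intersection of half-open
#' intervals.
#'
#' @param peaks data.frame from [read_bed_peaks()] (`chrom`, `start`, `end`,
#'   `tf`). Peaks with `NA` TF are grouped under `"(unnamed)"`.
#' @param gene_models data.frame with `gene`, `chrom`, `strand`, `tss`, `end`
#'   (0-based; minus-strand genes have `tss >= end`).
#' @param upstream_bp 5' flank in bp (default 10000).
#' @param downstream_bp 3' flank in bp (default 3000).
#' @return named list: one character vector of target genes per TF.
#' @export
assign_tf_targets <- function(peaks, gene_models, upstream_bp = 10000,
                              downstream_bp = 3000) {
  if (any(!gene_models$strand %in% c("+", "-")))
    stop("gene model missing strand for: ",
         gene_models$gene[!gene_models$strand %in% c("+", "-")][1])
  plus <- gene_models$strand == "+"
  win_start <- ifelse(plus, gene_models$tss - upstream_bp,
                      gene_models$end - downstream_bp)
  win_end_excl <- ifelse(plus, gene_models$end + 1 + downstream_bp,
                         gene_models$tss + 1 + upstream_bp)
  # 0-based half-open [s, e) -> 1-based closed [s+1, e], so boundary-touching
  # peaks do not overlap
  genes <- GenomicRanges::GRanges(
    seqnames = gene_models$chrom,
    ranges = IRanges::IRanges(start = win_start + 1, end = win_end_excl))
  tfs <- ifelse(is.na(peaks$tf), "(unnamed)", peaks$tf)
  out <- lapply(split(seq_len(nrow(peaks)), tfs), function(ix) {
    p <- peaks[ix, , drop = FALSE]
    pk <- GenomicRanges::GRanges(
      seqnames = p$chrom,
      ranges = IRanges::IRanges(start = p$start + 1, end = p$end))
    hits <- GenomicRanges::findOverlaps(genes, pk)
    sort(unique(gene_models$gene[unique(as.data.frame(hits)$queryHits)]))
  })
  out
}

#' EASE-score enrichment test
#'
#' Conservative variant of the one-sided Fisher exact (hypergeometric) test
#' used for gene-set enrichment: one gene is removed from the observed
#' overlap (floored at zero) before taking the upper hypergeometric tail, so
#' single-gene overlaps can never appear significant. Also reports the fold
#' enrichment (k/n)/(K/N).
#'
#' @param query character vector (e.g. a dynamics class), subset of
#'   `background`.
#' @param annotation character vector (an annotation or TF-target set),
#'   subset of `background`.
#' @param background character vector of mappable background genes.
#' @return data.frame row: `k` (overlap), `n` (query size), `K` (annotated in
#'   background), `N` (background size), `ease_p`, `fold`, `degenerate`.
#' @export
ease_test <- function(query, annotation, background) {
  background <- unique(background)
  query <- unique(query); annotation <- unique(annotation)
  bad <- setdiff(c(query, annotation), background)
  if (length(bad))
    stop("query/annotation gene(s) not in background: ",
         paste(utils::head(bad, 5), collapse = ", "))
  N <- length(background)
  n <- length(query)
  K <- length(annotation)
  k <- length(intersect(query, annotation))
  if (n == 0 || K == 0)
    return(data.frame(k = k, n = n, K = K, N = N, ease_p = 1, fold = 0,
                      degenerate = TRUE))
  k_def <- max(k - 1, 0)
  ease_p <- stats::phyper(k_def - 1, K, N - K, n, lower.tail = FALSE)
  fold <- (k / n) / (K / N)
  data.frame(k = k, n = n, K = K, N = N, ease_p = ease_p, fold = fold,
             degenerate = FALSE)
}

#' Call globally regulating TFs from enrichment results
#'
#' A TF is called a putative global regulator of the query class when its
#' target set is over-represented beyond both gates: fold enrichment above
#' `min_fold` and EASE p-value below `max_p`.
#'
#' @param results data.frame of [ease_test()] rows with a `tf` (or
#'   `set_name`) column.
#' @param min_fold fold-enrichment gate (default 1.2, i.e. >20% enrichment).
#' @param max_p EASE p-value gate (default 0.05).
#' @return character vector of TF names, sorted by ascending EASE p.
#' @export
call_tf_regulators <- function(results, min_fold = 1.2, max_p = 0.05) {
  name_col <- if ("tf" %in% names(results)) "tf" else "set_name"
  hit <- results$fold > min_fold & results$ease_p < max_p
  called <- results[hit, , drop = FALSE]
  called[[name_col]][order(called$ease_p)]
}

#' Paired t-test on a gene set between two conditions
#'
#' The average expression of each set gene in condition a is paired with its
#' average in condition b; the classical paired t statistic is computed on
#' the per-gene differences with m - 1 degrees of freedom.
#'
#' @param mean_expr_cond_a,mean_expr_cond_b named numeric vectors of per-gene
#'   mean expression (names = gene symbols).
#' @param gene_set character vector; at least 3 set genes must be measured in
#'   both conditions.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"` (a
#'   greater than b).
#' @return list: `t`, `df`, `p`, `minus_log10_p`, `direction` (sign of the
#'   mean difference), `m` (genes used), `degenerate` (zero-variance flag).
#' @export
geneset_paired_ttest <- function(mean_expr_cond_a, mean_expr_cond_b, gene_set,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  genes <- intersect(gene_set,
                     intersect(names(mean_expr_cond_a),
                               names(mean_expr_cond_b)))
  m <- length(genes)
  if (m < 3) stop("fewer than 3 usable genes in the set (", m, ")")
  d <- mean_expr_cond_a[genes] - mean_expr_cond_b[genes]
  direction <- sign(mean(d))
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, df = m - 1, p = 1, minus_log10_p = 0, direction = 0,
                  m = m, degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, df = m - 1, p = 0,
                minus_log10_p = Inf, direction = direction, m = m,
                degenerate = TRUE))
  }
  t_stat <- mean(d) / (stats::sd(d) / sqrt(m))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(abs(t_stat), m - 1,
                                        lower.tail = FALSE),
              greater = stats::pt(t_stat, m - 1, lower.tail = FALSE),
              less = stats::pt(t_stat, m - 1))
  list(t = t_stat, df = m - 1, p = p, minus_log10_p = -log10(p),
       direction = direction, m = m, degenerate = FALSE)
}
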