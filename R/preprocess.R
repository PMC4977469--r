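#' Filter probes on detection p-values
#'
#' A probe is retained when its detection p-value passes the threshold in at
#' least one sample (`mode = "any"`, the default, matching common Illumina
#' practice) or in every sample (`mode = "all"`, the strict alternative).
#'
#' @param em raw `expr_matrix`.
#' @param detection_pvals numeric matrix of detection p-values, same shape and
#'   dimnames as the expression values.
#' @param threshold detection p-value threshold (default 0.05).
#' @param mode `"any"` or `"all"`.
#' @return filtered `expr_matrix`; the number of removed probes is reported
#'   via `message()`.
#' @export
filter_detection <- function(em, detection_pvals, threshold = 0.05,
                             mode = c("any", "all")) {
  mode <- match.arg(mode)
  stopifnot(inherits(em, "expr_matrix"))
  x <- em$values
  if (!identical(dim(detection_pvals), dim(x)))
    stop("detection table shape ", paste(dim(detection_pvals), collapse = "x"),
         " does not match expression matrix ", paste(dim(x), collapse = "x"))
  if (!is.null(colnames(detection_pvals)))
    detection_pvals <- detection_pvals[, colnames(x), drop = FALSE]
  pass <- detection_pvals <= threshold
  keep <- if (mode == "any") rowSums(pass) >= 1 else rowSums(pass) == ncol(x)
  message(sum(!keep), " probes removed by detection filter (p > ", threshold,
          " in ", if (mode == "any") "all" else ">= 1", " samples)")
  expression_matrix(x[keep, , drop = FALSE], em$design, stage = em$stage)
}

#' Quantile normalization
#'
#' Forces every column onto the identical reference distribution: the row-wise
#' mean of the column order statistics. Within-column rank order is preserved
#' and ties receive the mean of their target quantiles. The operation is
#' idempotent.
#'
#' @param em `expr_matrix` with at least 2 columns and no missing values.
#' @return normalized `expr_matrix` (stage `"normalized"`).
#' @export
quantile_normalize <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  x <- em$values
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 columns")
  if (any(!is.finite(x)))
    stop("matrix contains missing/non-finite values; filter or impute first")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  expression_matrix(out, em$design, stage = "normalized")
}

#' Collapse probe rows to genes
#'
#' Unmapped probes are dropped; multi-probe genes are collapsed by the mean
#' across probes (default) or by keeping the probe with the largest mean
#' intensity (`rule = "max_mean"`).
#'
#' @param em `expr_matrix` keyed by probe id.
#' @param probe_to_gene data.frame with columns `probe`, `gene`.
#' @param rule `"mean"` or `"max_mean"`.
#' @return `expr_matrix` keyed by gene.
#' @export
collapse_probes <- function(em, probe_to_gene, rule = c("mean", "max_mean")) {
  rule <- match.arg(rule)
  stopifnot(inherits(em, "expr_matrix"))
  if (!nrow(probe_to_gene)) stop("empty probe-to-gene mapping")
  map <- probe_to_gene[probe_to_gene$probe %in% rownames(em$values), ,
                       drop = FALSE]
  dropped <- nrow(em$values) - length(unique(map$probe))
  message(dropped, " unmapped probes dropped during gene collapse")
  if (!nrow(map)) stop("no probes could be mapped to genes")
  x <- em$values[map$probe, , drop = FALSE]
  genes <- map$gene
  if (rule == "mean") {
    out <- rowsum(x, group = genes, reorder = TRUE) /
      as.vector(table(genes)[sort(unique(genes))])
  } else {
    rm_ <- rowMeans(x)
    pick <- vapply(split(seq_along(genes), genes),
                   function(ix) ix[which.max(rm_[ix])], integer(1))
    out <- x[pick, , drop = FALSE]
    rownames(out) <- names(pick)
    out <- out[sort(rownames(out)), , drop = FALSE]
  }
  expression_matrix(as.matrix(out), em$design, stage = em$stage)
}

#' Per-gene log2 fold changes against a baseline condition
#'
#' For every non-baseline condition, fc = mean(log2 values in condition) -
#' mean(log2 values in baseline), per gene. The baseline's own fold change is
#' identically zero and is not reported.
#'
#' @param em `expr_matrix` on the log2 scale.
#' @param baseline baseline condition name.
#' @return data.frame: `gene`, then one `fc_<condition>` column per
#'   non-baseline condition, in design order. Attribute `baseline` records
#'   the reference.
#' @export
baseline_log2fc <- function(em, baseline) {
  stopifnot(inherits(em, "expr_matrix"))
  design <- em$design
  if (!baseline %in% design$condition)
    stop("unknown condition: '", baseline, "'")
  conds <- unique(design$condition)
  others <- setdiff(conds, baseline)
  bmean <- rowMeans(em$values[, condition_samples(design, baseline),
                              drop = FALSE])
  out <- data.frame(gene = rownames(em$values), stringsAsFactors = FALSE)
  for (cond in others) {
    cmean <- rowMeans(em$values[, condition_samples(design, cond),
                                drop = FALSE])
    out[[paste0("fc_", cond)]] <- cmean - bmean
  }
  attr(out, "baseline") <- baseline
  out
}
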