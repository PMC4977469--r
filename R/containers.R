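#' Validate a sample design table
#'
#' A design table maps array/qPCR samples to experimental conditions. It is
#' attached to every matrix container in the package and drives all
#' between-condition comparisons.
#'
#' @param design data.frame with columns `sample`, `condition`, `replicate`.
#' @param baseline optional baseline condition name that must be present.
#' @return the validated design (invisibly usable), with `replicate` as integer.
#' @export
validate_design <- function(design, baseline = NULL) {
  req <- c("sample", "condition", "replicate")
  if (!is.data.frame(design) || !all(req %in% names(design)))
    stop("design must be a data.frame with columns sample, condition, replicate")
  design$sample <- as.character(design$sample)
  design$condition <- as.character(design$condition)
  design$replicate <- as.integer(design$replicate)
  if (anyDuplicated(design$sample))
    stop("design error: duplicated sample ids: ",
         paste(unique(design$sample[duplicated(design$sample)]), collapse = ", "))
  if (any(!is.finite(design$replicate)) || any(design$replicate < 1))
    stop("design error: replicate must be a positive integer")
  if (!is.null(baseline) && !baseline %in% design$condition)
    stop("design error: baseline condition '", baseline, "' not present in design")
  design
}

#' Construct an expression matrix container
#'
#' Holds a genes (or probes) x samples matrix of log2 intensities together
#' with its design. Modelled on the light list containers used for microarray
#' data (one numeric matrix, one annotation frame, a stage tag).
#'
#' @param values numeric matrix, rows = genes/probes, columns = samples.
#' @param design design table (see [validate_design()]).
#' @param stage `"raw"` or `"normalized"`.
#' @return object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, design, stage = c("raw", "normalized")) {
  stage <- match.arg(stage)
  design <- validate_design(design)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(colnames(values)))
    stop("values must carry sample ids as column names")
  if (!all(design$sample %in% colnames(values)))
    stop("design error: design samples missing from matrix: ",
         paste(setdiff(design$sample, colnames(values)), collapse = ", "))
  values <- values[, design$sample, drop = FALSE]
  if (stage == "normalized" && any(!is.finite(values)))
    stop("normalized matrix must contain only finite values")
  structure(list(values = values, design = design, stage = stage),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples (%s), conditions: %s\n",
              nrow(x$values), ncol(x$values), x$stage,
              paste(unique(x$design$condition), collapse = ", ")))
  invisible(x)
}

#' Construct a methylation beta-value container
#'
#' Beta values are per-probe methylation fractions in \[0, 1\]. The container
#' carries a probe-to-gene map so probe-level differential calls can be
#' aggregated to genes.
#'
#' @param betas numeric matrix, rows = probes, columns = samples, values in
#'   \[0, 1\].
#' @param probe_to_gene data.frame with columns `probe`, `gene` covering (a
#'   subset of) the probe rows.
#' @param design design table.
#' @return object of class `beta_table`.
#' @export
beta_table <- function(betas, probe_to_gene, design) {
  design <- validate_design(design)
  if (!is.matrix(betas) || !is.numeric(betas))
    stop("betas must be a numeric matrix")
  if (any(betas < 0 | betas > 1, na.rm = TRUE))
    stop("beta values must lie within [0, 1]")
  if (!all(c("probe", "gene") %in% names(probe_to_gene)))
    stop("probe_to_gene must have columns probe, gene")
  if (is.null(colnames(betas)))
    stop("betas must carry sample ids as column names")
  if (!all(design$sample %in% colnames(betas)))
    stop("design error: design samples missing from beta matrix")
  betas <- betas[, design$sample, drop = FALSE]
  structure(list(betas = betas,
                 probe_to_gene = data.frame(
                   probe = as.character(probe_to_gene$probe),
                   gene = as.character(probe_to_gene$gene)),
                 design = design),
            class = "beta_table")
}

#' @export
print.beta_table <- function(x, ...) {
  cat(sprintf("beta_table: %d probes x %d samples, %d mapped genes\n",
              nrow(x$betas), ncol(x$betas), length(unique(x$probe_to_gene$gene))))
  invisible(x)
}

# columns of a design belonging to one condition
condition_samples <- function(design, condition) {
  s <- design$sample[design$condition == condition]
  if (length(s) == 0) stop("unknown condition: '", condition, "'")
  s
}

# round half away from zero, the convention used when comparing against
# printed 2-decimal tables
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
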