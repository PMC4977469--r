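#' Reference-normalized qPCR expression (delta Ct)
#'
#' For one sample group, the relative log2 expression of each gene versus the
#' reference (housekeeping) gene is the average reference Ct minus the
#' average gene Ct over the group's replicates: a gene amplifying two cycles
#' earlier than the reference is at 4x the reference level. Non-finite Ct
#' values (non-detected wells) are excluded with a warning; a gene with no
#' usable replicate raises an error.
#'
#' @param ct_table numeric matrix of Ct values, rows = genes (including the
#'   reference), columns = samples; or a list with elements `ct` and
#'   `design`.
#' @param group character vector of sample ids, or a condition name when a
#'   design is attached.
#' @param reference reference gene name (default `"GAPDH"`).
#' @return named numeric vector of delta Ct (log2 expression vs reference),
#'   reference gene excluded.
#' @export
delta_ct <- function(ct_table, group, reference = "GAPDH") {
  design <- NULL
  if (is.list(ct_table) && !is.matrix(ct_table)) {
    design <- ct_table$design
    ct_table <- ct_table$ct
  }
  if (!reference %in% rownames(ct_table))
    stop("reference gene '", reference, "' not in Ct table")
  cols <- if (!is.null(design) && all(group %in% design$condition))
    design$sample[design$condition %in% group] else group
  missing <- setdiff(cols, colnames(ct_table))
  if (length(missing))
    stop("sample(s) not in Ct table: ", paste(missing, collapse = ", "))
  sub <- ct_table[, cols, drop = FALSE]
  grp_mean <- function(v, gene) {
    ok <- is.finite(v)
    if (!all(ok))
      warning(sum(!ok), " non-detected well(s) excluded for ", gene)
    if (!any(ok)) stop("all replicates non-detected for ", gene)
    mean(v[ok])
  }
  ref_mean <- grp_mean(sub[reference, ], reference)
  genes <- setdiff(rownames(sub), reference)
  out <- vapply(genes, function(g) ref_mean - grp_mean(sub[g, ], g),
                numeric(1))
  names(out) <- genes
  out
}

#' Between-condition log2 fold change from delta Ct (delta-delta Ct)
#'
#' @param delta_ct_a,delta_ct_b delta Ct values (scalars or named vectors for
#'   the same genes) for the two conditions.
#' @return list with `log2fc` (= delta Ct a - delta Ct b) and `fold`
#'   (= 2^log2fc).
#' @export
ddct_log2fc <- function(delta_ct_a, delta_ct_b) {
  if (!is.null(names(delta_ct_a)) && !is.null(names(delta_ct_b))) {
    common <- intersect(names(delta_ct_a), names(delta_ct_b))
    delta_ct_a <- delta_ct_a[common]
    delta_ct_b <- delta_ct_b[common]
  }
  l2 <- delta_ct_a - delta_ct_b
  list(log2fc = l2, fold = 2^l2)
}

#' Maximal induction within a time window
#'
#' @param series data.frame with columns `time` (hours, strictly increasing)
#'   and `fold` (linear fold change vs time 0, > 0).
#' @param window_end_hours right end of the window (default 72).
#' @return list with `fold` (the maximum) and `time` (its argmax, hours).
#' @export
max_induction <- function(series, window_end_hours = 72) {
  if (!all(c("time", "fold") %in% names(series)))
    stop("series needs columns time, fold")
  if (!nrow(series)) stop("empty induction series")
  if (is.unsorted(series$time, strictly = TRUE))
    stop("time points must be strictly increasing")
  if (any(series$fold <= 0)) stop("fold changes must be positive")
  w <- series[series$time <= window_end_hours, , drop = FALSE]
  if (!nrow(w)) stop("empty window: no time points at or before ",
                     window_end_hours, " h")
  i <- which.max(w$fold)
  list(fold = w$fold[i], time = w$time[i])
}

#' Reconstruct induction time-courses from a Ct table
#'
#' For every gene and experimental unit, computes the delta Ct at each time
#' point (over that unit/time group's replicates) and expresses it as the
#' linear fold change versus the unit's own time-0 value, the delta-delta-Ct
#' induction.
#'
#' @param ct_table numeric matrix of Ct values (genes + reference x samples).
#' @param design data.frame with columns `sample`, `unit`, `time` (hours).
#' @param reference reference gene name (default `"GAPDH"`).
#' @return data.frame with columns `gene`, `unit`, `time`, `fold`.
#' @export
induction_series_from_ct <- function(ct_table, design, reference = "GAPDH") {
  if (!all(c("sample", "unit", "time") %in% names(design)))
    stop("design needs columns sample, unit, time")
  units <- unique(design$unit)
  out <- list()
  for (u in units) {
    du <- design[design$unit == u, , drop = FALSE]
    times <- sort(unique(du$time))
    if (!0 %in% times) stop("unit ", u, " has no time-0 reference group")
    dct <- lapply(times, function(tt)
      delta_ct(ct_table, du$sample[du$time == tt], reference = reference))
    names(dct) <- times
    for (tt in times) {
      fc <- ddct_log2fc(dct[[as.character(tt)]], dct[["0"]])
      out[[length(out) + 1]] <- data.frame(
        gene = names(fc$fold), unit = u, time = tt, fold = unname(fc$fold),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$gene, res$unit, res$time), , drop = FALSE]
}

#' One-tailed Pearson correlation between induction and outcome
#'
#' Tests for a positive linear association between per-unit maximal
#' inductions and differentiation outcome proportions:
#' t = r sqrt(n - 2) / sqrt(1 - r^2) against the upper tail of the t
#' distribution with n - 2 degrees of freedom (`tail = "upper"`, the
#' default); a two-tailed mode is provided.
#'
#' @param max_inductions,outcome_proportions equal-length numeric vectors,
#'   n >= 3, each with non-zero variance.
#' @param tail `"upper"` (positive association) or `"two.sided"`.
#' @return list: `r`, `n`, `t`, `p` (and `p_one_tailed` alias when
#'   `tail = "upper"`).
#' @export
correlate_induction <- function(max_inductions, outcome_proportions,
                                tail = c("upper", "two.sided")) {
  tail <- match.arg(tail)
  x <- max_inductions; y <- outcome_proportions
  if (length(x) != length(y)) stop("vectors must have equal length")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input vector")
  r <- stats::cor(x, y)
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- if (tail == "upper") stats::pt(t_stat, n - 2, lower.tail = FALSE)
       else 2 * stats::pt(abs(t_stat), n - 2, lower.tail = FALSE)
  out <- list(r = r, n = n, t = t_stat, p = p)
  if (tail == "upper") out$p_one_tailed <- p
  out
}
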