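#' Signed signaling propensity of a single cascade component
#'
#' The relative signal-transduction effect of a component is the product of
#' its effect on its substrate (activation +1, inhibition -1) and its own
#' expression regulation (log2FC). A down-regulated inhibitor therefore
#' contributes positively: log2FC -2 on an inhibitory edge scores
#' -1 x (-2) = 2.
#'
#' @param log2fc finite log2 fold change of the component (vectorized).
#' @param outgoing_edge_sign +1 (activation) or -1 (inhibition).
#' @return signed propensity in log2FC units.
#' @export
component_propensity <- function(log2fc, outgoing_edge_sign) {
  if (!all(outgoing_edge_sign %in% c(-1, 1)))
    stop("edge sign must be +1 or -1")
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  outgoing_edge_sign * log2fc
}

#' Score a signaling cascade
#'
#' Each component with an outgoing edge is scored with its own log2FC and the
#' sign of that edge. When `include_terminal` is set (the default), the final
#' gene component is additionally scored with sign +1 toward its terminal
#' event, so a cascade of m genes yields m propensities; a free-text terminal
#' label is never scored. The cascade's summary is the arithmetic mean of the
#' propensities.
#'
#' @param cascade a [cascade_spec()].
#' @param fc_map named numeric vector mapping component symbols to log2FC.
#' @param include_terminal score the last gene component with sign +1
#'   (default TRUE).
#' @return object of class `cascade_score`: list with `cascade`, `components`,
#'   `signs`, `log2fc`, `propensities`, `mean_propensity`, `consistent`
#'   (all propensities > 0).
#' @export
cascade_propensity <- function(cascade, fc_map, include_terminal = TRUE) {
  stopifnot(inherits(cascade, "cascade_spec"))
  comps <- cascade$components
  signs <- cascade$signs
  if (include_terminal) signs <- c(signs, 1L) else comps <- utils::head(comps, -1)
  missing <- setdiff(comps, names(fc_map))
  if (length(missing))
    stop("missing log2FC for cascade component(s): ",
         paste(missing, collapse = ", "))
  fc <- unname(fc_map[comps])
  prop <- component_propensity(fc, signs)
  structure(list(cascade = cascade, components = comps, signs = signs,
                 log2fc = fc, propensities = prop,
                 mean_propensity = mean(prop),
                 consistent = all(prop > 0)),
            class = "cascade_score")
}

#' @export
print.cascade_score <- function(x, ...) {
  cat(sprintf("%s: mean propensity %.2f (%s)\n", x$cascade$name,
              x$mean_propensity,
              if (x$consistent) "consistent" else "inconsistent"))
  print(data.frame(component = x$components, sign = x$signs,
                   log2fc = x$log2fc, propensity = x$propensities))
  invisible(x)
}

#' Rank scored cascades by mean propensity
#'
#' A series of large positive propensities along a cascade indicates stronger
#' and more consistent differential signaling. Cascades are sorted by mean
#' propensity descending (ties broken by name); a cascade is flagged
#' consistent only when every component propensity is positive.
#'
#' @param scores list of `cascade_score` objects (at least one).
#' @return data.frame: `cascade`, `n_components`, `mean_propensity`,
#'   `consistent`, in rank order.
#' @export
rank_cascades <- function(scores) {
  if (inherits(scores, "cascade_score")) scores <- list(scores)
  if (!length(scores)) stop("need at least one cascade score")
  d <- data.frame(
    cascade = vapply(scores, function(s) s$cascade$name, character(1)),
    n_components = vapply(scores, function(s) length(s$propensities),
                          integer(1)),
    mean_propensity = vapply(scores, function(s) s$mean_propensity,
                             numeric(1)),
    consistent = vapply(scores, function(s) s$consistent, logical(1)),
    stringsAsFactors = FALSE)
  d <- d[order(-d$mean_propensity, d$cascade), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Tabulate cascade scores component-by-component
#'
#' Long-format report mirroring the package's TSV output: one row per scored
#' component with its edge sign, log2FC and propensity, plus the cascade mean
#' and consistency flag.
#'
#' @param scores list of `cascade_score` objects.
#' @return data.frame with columns `cascade`, `component`, `sign`, `log2fc`,
#'   `propensity`, `mean_propensity`, `consistent`.
#' @export
cascade_score_table <- function(scores) {
  if (inherits(scores, "cascade_score")) scores <- list(scores)
  do.call(rbind, lapply(scores, function(s) {
    data.frame(cascade = s$cascade$name, component = s$components,
               sign = s$signs, log2fc = s$log2fc, propensity = s$propensities,
               mean_propensity = s$mean_propensity, consistent = s$consistent,
               stringsAsFactors = FALSE)
  }))
}
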