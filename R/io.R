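#' Read a sample design table
#'
#' @param path TSV with columns `sample`, `condition`, `replicate`.
#' @param baseline optional baseline condition that must be present.
#' @return validated design data.frame.
#' @export
read_design <- function(path, baseline = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_design(d, baseline = baseline)
}

#' Write a design table
#' @param design design data.frame.
#' @param path output TSV path.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_numeric_table <- function(path, what = "value") {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(d[[1]])
  body <- d[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop(sprintf("parse error: non-numeric %s at (%s, %s): '%s'",
                   what, ids[bad[1]], names(body)[j], v[bad[1]]))
    }
    if (anyNA(v))
      stop(sprintf("parse error: missing %s at (%s, %s)",
                   what, ids[which(is.na(v))[1]], names(body)[j]))
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  m
}

#' Read an expression matrix with its design
#'
#' First column of the TSV holds gene/probe ids (duplicates are preserved as
#' distinct probe rows); remaining columns are samples. Design samples must be
#' a subset of the matrix columns; the matrix is restricted and reordered to
#' the design.
#'
#' @param path expression TSV.
#' @param design_path design TSV, or a design data.frame.
#' @param stage stage tag for the container.
#' @return [expression_matrix()] object.
#' @export
read_expression_table <- function(path, design_path, stage = "raw") {
  m <- read_numeric_table(path, what = "expression value")
  design <- if (is.data.frame(design_path)) validate_design(design_path)
            else read_design(design_path)
  missing <- setdiff(design$sample, colnames(m))
  if (length(missing))
    stop("design error: samples in design absent from matrix: ",
         paste(missing, collapse = ", "))
  expression_matrix(m, design, stage = stage)
}

#' Write an expression matrix
#'
#' Values are written with 6 significant digits, first column `id`.
#' @param em `expr_matrix` (or plain matrix).
#' @param path output TSV path.
#' @export
write_expression_table <- function(em, path) {
  m <- if (inherits(em, "expr_matrix")) em$values else em
  d <- data.frame(id = rownames(m), signif(m, 6), check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a methylation beta table
#'
#' @param path beta TSV (probe ids in first column).
#' @param map_path probe-to-gene TSV with columns `probe`, `gene`.
#' @param design_path design TSV or data.frame.
#' @return [beta_table()] object.
#' @export
read_beta_table <- function(path, map_path, design_path) {
  m <- read_numeric_table(path, what = "beta value")
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  design <- if (is.data.frame(design_path)) validate_design(design_path)
            else read_design(design_path)
  beta_table(m, map, design)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then members, tab-separated. Members are
#' de-duplicated; empty sets are dropped with a warning.
#'
#' @param path GMT file.
#' @return named list of character vectors (a gene-set collection).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(structure(list(), names = character(0)))
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2)
      stop("parse error: GMT line ", i, " has fewer than 2 fields")
    members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (!length(members)) {
      warning("dropping empty gene set '", f[1], "'")
      next
    }
    sets[[f[1]]] <- members
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional vector of descriptions (defaults to set names).
#' @export
write_gene_sets <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a signaling cascade specification
#'
#' An ordered chain of components joined by signed edges: activation (+1) or
#' inhibition (-1). The optional terminal label names the unscored downstream
#' event (e.g. "Mesoderm Induction").
#'
#' @param name cascade name.
#' @param components character vector of >= 2 component symbols.
#' @param signs integer vector of edge signs, length `length(components) - 1`,
#'   each +1 or -1.
#' @param terminal_label optional free-text label following the last component.
#' @return object of class `cascade_spec`.
#' @export
cascade_spec <- function(name, components, signs, terminal_label = NULL) {
  components <- as.character(components)
  if (length(components) < 2)
    stop("a cascade needs at least 2 components")
  if (any(!nzchar(components)))
    stop("component symbols must be non-empty")
  signs <- as.integer(signs)
  if (length(signs) != length(components) - 1)
    stop("need exactly ", length(components) - 1, " edge signs")
  if (!all(signs %in% c(-1L, 1L)))
    stop("edge signs must be +1 (activation) or -1 (inhibition)")
  structure(list(name = name, components = components, signs = signs,
                 terminal_label = terminal_label),
            class = "cascade_spec")
}

#' @export
print.cascade_spec <- function(x, ...) {
  edges <- c(ifelse(x$signs == 1, " -> ", " -| "), "")
  cat(x$name, ": ", paste0(x$components, edges, collapse = ""),
      if (!is.null(x$terminal_label)) paste0(" => ", x$terminal_label), "\n",
      sep = "")
  invisible(x)
}

#' Parse a cascade definition file
#'
#' One cascade per line in the grammar
#' `name: A -> B -| C [=> terminal label]`, where `->` is an activating edge
#' and `-|` an inhibitory one. Blank lines and lines starting with `#` are
#' skipped.
#'
#' @param path cascade file.
#' @return list of [cascade_spec()] objects.
#' @export
parse_cascades <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(seq_along(lines), function(i) parse_cascade_line(lines[i], i))
}

parse_cascade_line <- function(line, lineno = NA) {
  loc <- if (is.na(lineno)) "" else paste0(" (line ", lineno, ")")
  parts <- strsplit(line, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2)
    stop("parse error: cascade line missing 'name:' prefix", loc)
  name <- trimws(parts[1])
  rest <- trimws(paste(parts[-1], collapse = ":"))
  terminal <- NULL
  if (grepl("=>", rest, fixed = TRUE)) {
    tp <- strsplit(rest, "=>", fixed = TRUE)[[1]]
    rest <- trimws(tp[1])
    terminal <- trimws(paste(tp[-1], collapse = "=>"))
  }
  toks <- strsplit(rest, "\\s+")[[1]]
  if (length(toks) %% 2 != 1 || length(toks) < 3) {
    if (length(toks) == 1)
      stop("parse error: cascade '", name, "' has a single component", loc)
    stop("parse error: malformed cascade '", name, "'", loc)
  }
  comps <- toks[seq(1, length(toks), by = 2)]
  edges <- toks[seq(2, length(toks), by = 2)]
  bad <- !edges %in% c("->", "-|")
  if (any(bad))
    stop("parse error: unknown edge token '", edges[bad][1], "' in cascade '",
         name, "'", loc)
  signs <- ifelse(edges == "->", 1L, -1L)
  cascade_spec(name, comps, signs, terminal_label = terminal)
}

#' Read TF ChIP peaks from a BED file
#'
#' BED3+ with 0-based half-open intervals; an optional 4th column names the
#' TF. `start < end` is enforced.
#'
#' @param path BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `tf`.
#' @export
read_bed_peaks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), tf = character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(f)
  if (any(n < 3))
    stop("parse error: BED line ", which(n < 3)[1], " has fewer than 3 fields")
  start <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(f, `[`, "", 3)))
  if (anyNA(start) || anyNA(end))
    stop("parse error: non-numeric coordinate at BED line ",
         which(is.na(start) | is.na(end))[1])
  bad <- start >= end
  if (any(bad))
    stop("parse error: start >= end at BED line ", which(bad)[1])
  data.frame(chrom = vapply(f, `[`, "", 1),
             start = as.integer(start), end = as.integer(end),
             tf = ifelse(n >= 4, vapply(f, function(x) x[4], ""), NA_character_))
}

#' Write peaks as BED
#' @param peaks data.frame with `chrom`, `start`, `end` and optional `tf`.
#' @param path output path.
#' @export
write_bed_peaks <- function(peaks, path) {
  cols <- c("chrom", "start", "end")
  if ("tf" %in% names(peaks) && !all(is.na(peaks$tf))) cols <- c(cols, "tf")
  utils::write.table(peaks[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-model table
#'
#' TSV with columns `gene`, `chrom`, `strand`, `tss`, `end`. On disk `tss`
#' and `end` are 1-based positions; they are converted to the package's
#' internal 0-based convention so they compose directly with BED peaks.
#' For minus-strand genes `tss` is the genomic right end of the transcript.
#'
#' @param path TSV path.
#' @return data.frame with 0-based `tss` and `end`.
#' @export
read_gene_models <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "chrom", "strand", "tss", "end")
  if (!all(req %in% names(d)))
    stop("gene-model table must have columns ", paste(req, collapse = ", "))
  if (any(!d$strand %in% c("+", "-")))
    stop("gene model missing strand (must be '+' or '-'): ",
         d$gene[!d$strand %in% c("+", "-")][1])
  d$tss <- as.integer(d$tss) - 1L
  d$end <- as.integer(d$end) - 1L
  d
}

#' Write a gene-model table (1-based on disk)
#' @param models data.frame with 0-based `tss`, `end` (internal convention).
#' @param path output path.
#' @export
write_gene_models <- function(models, path) {
  out <- models
  out$tss <- out$tss + 1L
  out$end <- out$end + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Central defaults for the whole chain: the baseline condition, the FDR
#' accepted for rank-product calls, the minimum absolute beta change for
#' differential methylation, the probe-consistency threshold, EASE enrichment
#' gates, permutation count, clustering K and the consistency exclusion list
#' (the GNAS complex locus by default).
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    baseline = "baseline",
    fdr = 0.05,
    min_beta_change = 0.25,
    probe_consistency_delta = 0.15,
    enrichment = list(min_fold = 1.2, max_p = 0.05),
    n_perm = 100,
    seed = 1,
    k = 3,
    exclude_genes = c("GNAS"),
    detection_p = 0.05,
    detection_mode = "any",
    collapse_rule = "mean",
    tol = 0
  )
}

#' Read a run configuration file
#'
#' YAML key-value file; missing keys fall back to [default_config()].
#'
#' @param path YAML config.
#' @return nested named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  merge_config(default_config(), cfg)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}
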