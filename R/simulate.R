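#' Ground-truth configuration for the synthetic study
#'
#' Describes a seeded three-condition (baseline / mid / high) replicated
#' expression + methylation experiment with planted monotone regulation
#' classes, anti-correlated methylation for a subset of trend genes, planted
#' over-represented annotation and TF-target sets, and qPCR induction
#' time-courses whose maximal induction correlates with a planted outcome
#' proportion. Every artifact drawn from the same truth (including the seed)
#' is byte-identical across runs.
#'
#' @param seed integer master seed; each artifact derives its own stream from
#'   `seed` plus a fixed per-artifact offset.
#' @param n_genes number of genes.
#' @param n_conditions number of ordered conditions (3: baseline, mid, high).
#' @param n_replicates replicates per condition (>= 2).
#' @param deg_fraction_increasing,deg_fraction_decreasing proportions of
#'   genes with planted monotone up / down expression trends (sum <= 1).
#' @param effect_size planted log2FC of the high condition vs baseline.
#' @param mid_fraction fraction of the effect realized in the mid condition.
#' @param noise_sd i.i.d. Gaussian noise sd on the log2 scale (>= 0; 0 is the
#'   exact zero-noise limit).
#' @param meth_coupled_fraction fraction of trend genes whose methylation
#'   moves opposite to expression.
#' @param meth_effect planted |delta beta| (high vs baseline) for coupled
#'   genes (>= 0.25 by default so coupled genes clear the DMG gate).
#' @param beta_noise_sd Gaussian noise sd on the beta scale (clipped to
#'   \[0, 1\]).
#' @param planted_set_sizes sizes of annotation sets planted with
#'   over-representation in the increasing class.
#' @param planted_set_enrichment_fold target fold enrichment (>= 1).
#' @param n_null_sets number of additional unenriched annotation sets.
#' @param tf_target_size size of the planted TF's target set.
#' @param cascade_specs optional list of [cascade_spec()] with planted
#'   log2FCs (attribute `fc`), passed through to the study bundle.
#' @param qpcr list: `genes`, `times` (hours), `n_units`, `r_true` in (-1,1\],
#'   `ct_noise_sd`, `n_ct_replicates`, `log2_max_mean`, `log2_max_sd`.
#' @return object of class `simulation_truth`.
#' @export
simulation_truth <- function(seed = 1,
                             n_genes = 2000,
                             n_conditions = 3,
                             n_replicates = 3,
                             deg_fraction_increasing = 0.05,
                             deg_fraction_decreasing = 0.05,
                             effect_size = 2,
                             mid_fraction = 0.5,
                             noise_sd = 0.5,
                             meth_coupled_fraction = 0.5,
                             meth_effect = 0.3,
                             beta_noise_sd = 0.05,
                             planted_set_sizes = c(30, 30),
                             planted_set_enrichment_fold = 20,
                             n_null_sets = 5,
                             tf_target_size = 40,
                             cascade_specs = NULL,
                             qpcr = list()) {
  frac <- c(deg_fraction_increasing, deg_fraction_decreasing, mid_fraction,
            meth_coupled_fraction)
  if (any(frac < 0 | frac > 1))
    stop("configuration error: fractions must lie in [0, 1]")
  if (deg_fraction_increasing + deg_fraction_decreasing > 1)
    stop("configuration error: DEG fractions sum above 1")
  if (n_replicates < 2)
    stop("configuration error: n_replicates must be >= 2")
  if (noise_sd < 0 || beta_noise_sd < 0)
    stop("configuration error: noise sd must be non-negative")
  if (n_conditions != 3)
    stop("configuration error: the study design has 3 ordered conditions")
  if (planted_set_enrichment_fold < 1)
    stop("configuration error: enrichment fold must be >= 1")
  qp <- utils::modifyList(
    list(genes = c("FOXC1", "FOXD1", "FOXQ1"),
         times = c(0, 24, 48, 72), n_units = 4, r_true = 0.95,
         ct_noise_sd = 0, n_ct_replicates = 2,
         log2_max_mean = 2, log2_max_sd = 0.5),
    qpcr)
  if (qp$r_true <= -1 || qp$r_true > 1)
    stop("configuration error: r_true must lie in (-1, 1]")
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 n_conditions = n_conditions, n_replicates = n_replicates,
                 deg_fraction_increasing = deg_fraction_increasing,
                 deg_fraction_decreasing = deg_fraction_decreasing,
                 effect_size = effect_size, mid_fraction = mid_fraction,
                 noise_sd = noise_sd,
                 meth_coupled_fraction = meth_coupled_fraction,
                 meth_effect = meth_effect, beta_noise_sd = beta_noise_sd,
                 planted_set_sizes = planted_set_sizes,
                 planted_set_enrichment_fold = planted_set_enrichment_fold,
                 n_null_sets = n_null_sets, tf_target_size = tf_target_size,
                 cascade_specs = cascade_specs, qpcr = qp),
            class = "simulation_truth")
}

# run expr with a seeded, self-contained RNG stream; offsets keep artifacts
# independently reproducible
with_stream <- function(truth, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(list = ".Random.seed",
                                   envir = globalenv())))
  set.seed((truth$seed + offset) %% .Machine$integer.max)
  force(expr)
}

condition_names <- function(truth) c("baseline", "mid", "high")

study_design <- function(truth) {
  conds <- condition_names(truth)
  data.frame(
    sample = paste(rep(conds, each = truth$n_replicates),
                   seq_len(truth$n_replicates), sep = "_"),
    condition = rep(conds, each = truth$n_replicates),
    replicate = rep(seq_len(truth$n_replicates), times = length(conds)),
    stringsAsFactors = FALSE)
}

#' Simulate the expression matrix with planted regulation classes
#'
#' Trend genes have condition means baseline + (0, mid_fraction x effect,
#' effect), signed per class, plus i.i.d. Gaussian noise; null genes are
#' flat. Per-gene baselines are uniform on log2 intensities 6-12.
#'
#' @param truth a [simulation_truth()].
#' @return list: `expr` (raw `expr_matrix`), `labels` (data.frame `gene`,
#'   `class` in increasing / decreasing / null).
#' @export
simulate_expression <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  with_stream(truth, 101L, {
    G <- truth$n_genes
    n_inc <- round(truth$deg_fraction_increasing * G)
    n_dec <- round(truth$deg_fraction_decreasing * G)
    genes <- sprintf("g%05d", seq_len(G))
    class <- rep("null", G)
    class[seq_len(n_inc)] <- "increasing"
    if (n_dec > 0) class[n_inc + seq_len(n_dec)] <- "decreasing"
    design <- study_design(truth)
    base <- stats::runif(G, 6, 12)
    step <- c(baseline = 0, mid = truth$mid_fraction * truth$effect_size,
              high = truth$effect_size)
    sgn <- c(increasing = 1, decreasing = -1, null = 0)[class]
    mu <- outer(sgn, step[design$condition]) + base
    vals <- mu + stats::rnorm(length(mu), 0, truth$noise_sd)
    dimnames(vals) <- list(genes, design$sample)
    list(expr = expression_matrix(vals, design, stage = "raw"),
         labels = data.frame(gene = genes, class = class,
                             stringsAsFactors = FALSE))
  })
}

#' Simulate methylation beta values coupled to expression dynamics
#'
#' Each gene carries 1-3 probes. For the coupled fraction of trend genes the
#' beta condition means move opposite to expression with planted magnitude
#' `meth_effect` (high vs baseline) and `mid_fraction x meth_effect` (mid);
#' betas get Gaussian noise and are clipped to \[0, 1\].
#'
#' @param truth a [simulation_truth()].
#' @param gene_labels label frame from [simulate_expression()].
#' @return list: `beta` (a [beta_table()]), `labels` (data.frame `gene`,
#'   `coupled`).
#' @export
simulate_methylation <- function(truth, gene_labels) {
  stopifnot(inherits(truth, "simulation_truth"))
  with_stream(truth, 202L, {
    G <- nrow(gene_labels)
    design <- study_design(truth)
    n_probes <- sample(1:3, G, replace = TRUE)
    probe_gene <- rep(gene_labels$gene, n_probes)
    probes <- paste0("cg", sprintf("%06d", seq_along(probe_gene)))
    trend <- gene_labels$class != "null"
    coupled <- rep(FALSE, G)
    idx <- which(trend)
    n_coupled <- round(truth$meth_coupled_fraction * length(idx))
    if (n_coupled > 0) coupled[sample(idx, n_coupled)] <- TRUE
    expr_sgn <- c(increasing = 1, decreasing = -1, null = 0)[gene_labels$class]
    meth_sgn <- ifelse(coupled, -expr_sgn, 0)     # opposite to expression
    # coupled baselines leave headroom for the full planted step, so clipping
    # to [0, 1] cannot erode the promised |delta beta|
    lo <- ifelse(meth_sgn < 0, truth$meth_effect + 0.05, 0.05)
    hi <- ifelse(meth_sgn > 0, 0.95 - truth$meth_effect, 0.95)
    lo[meth_sgn == 0] <- 0.2
    hi[meth_sgn == 0] <- 0.8
    base_beta <- lo + stats::runif(G) * (hi - lo)
    step <- c(baseline = 0, mid = truth$mid_fraction * truth$meth_effect,
              high = truth$meth_effect)
    mu_gene <- outer(meth_sgn, step[design$condition]) + base_beta
    mu <- mu_gene[rep(seq_len(G), n_probes), , drop = FALSE]
    vals <- mu + stats::rnorm(length(mu), 0, truth$beta_noise_sd)
    vals <- pmin(pmax(vals, 0), 1)
    dimnames(vals) <- list(probes, design$sample)
    list(beta = beta_table(vals,
                           data.frame(probe = probes, gene = probe_gene,
                                      stringsAsFactors = FALSE),
                           design),
         labels = data.frame(gene = gene_labels$gene, coupled = coupled,
                             stringsAsFactors = FALSE))
  })
}

# draw a set of size m whose overlap with `inside` targets the configured
# fold enrichment over a background of size N
draw_enriched_set <- function(m, inside, universe, fold) {
  N <- length(universe)
  k <- min(m, length(inside), round(fold * m * length(inside) / N))
  members_in <- sample(inside, k)
  members_out <- sample(setdiff(universe, inside), m - k)
  sample(c(members_in, members_out))
}

#' Simulate annotation sets, TF peaks and gene models
#'
#' Annotation sets are drawn with planted over-representation of the
#' increasing-expression class at the configured fold (null sets are drawn
#' uniformly). A synthetic TF's ChIP peaks are placed 5 kb upstream of the
#' TSS of each intended target so that the 10 kb / 3 kb window rule recovers
#' exactly the planted target list; genes alternate strands along the
#' chromosome and decoy peaks fall outside every window.
#'
#' @param truth a [simulation_truth()].
#' @param gene_labels label frame from [simulate_expression()].
#' @return list: `gene_sets` (named list, planted sets named `planted_set_i`),
#'   `peaks` (BED-style frame), `gene_models` (0-based), `tf_targets`
#'   (character vector of the planted TF's true targets).
#' @export
simulate_annotations <- function(truth, gene_labels) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (truth$planted_set_enrichment_fold < 1)
    stop("configuration error: enrichment fold must be >= 1")
  with_stream(truth, 303L, {
    genes <- gene_labels$gene
    inc <- genes[gene_labels$class == "increasing"]
    fold <- truth$planted_set_enrichment_fold
    sets <- list()
    for (i in seq_along(truth$planted_set_sizes))
      sets[[paste0("planted_set_", i)]] <-
        draw_enriched_set(truth$planted_set_sizes[i], inc, genes, fold)
    for (i in seq_len(truth$n_null_sets))
      sets[[paste0("null_set_", i)]] <-
        sample(genes, truth$planted_set_sizes[1])
    G <- length(genes)
    strand <- rep(c("+", "-"), length.out = G)
    anchor <- seq_len(G) * 100000L             # 100 kb spacing, 20 kb bodies
    tss <- ifelse(strand == "+", anchor, anchor + 20000L)
    gend <- ifelse(strand == "+", anchor + 20000L, anchor)
    gene_models <- data.frame(gene = genes, chrom = "chr1", strand = strand,
                              tss = tss, end = gend,
                              stringsAsFactors = FALSE)
    targets <- sort(draw_enriched_set(truth$tf_target_size, inc, genes, fold))
    ti <- match(targets, genes)
    peak_start <- ifelse(strand[ti] == "+", tss[ti] - 5000L, tss[ti] + 4800L)
    peaks <- data.frame(chrom = "chr1", start = peak_start,
                        end = peak_start + 200L, tf = "TF_planted",
                        stringsAsFactors = FALSE)
    decoys <- data.frame(chrom = "chr1",
                         start = (G + 10L + seq_len(20)) * 100000L,
                         end = (G + 10L + seq_len(20)) * 100000L + 200L,
                         tf = "TF_planted", stringsAsFactors = FALSE)
    list(gene_sets = sets, peaks = rbind(peaks, decoys),
         gene_models = gene_models, tf_targets = targets)
  })
}

#' Simulate qPCR Ct tables, induction time-courses and outcomes
#'
#' For each gene and experimental unit (cell line x protocol) a log2
#' induction time-course is planted with its peak inside the 72 h window; Ct
#' values are built backwards from the reference gene so that delta-delta-Ct
#' reconstruction returns the planted fold changes (exactly so at zero Ct
#' noise). Outcome proportions are an affine function of the standardized
#' maximal induction plus independent noise, giving population correlation
#' `r_true`.
#'
#' @param truth a [simulation_truth()].
#' @return list: `ct` (matrix genes + reference x samples), `design` (sample,
#'   condition, replicate, unit, time), `series` (planted fold-change
#'   time-courses: gene, unit, time, fold), `outcomes` (gene x unit matrix of
#'   outcome proportions), `truth_max` (gene x unit matrix of planted maximal
#'   inductions), `reference` gene name.
#' @export
simulate_qpcr <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  qp <- truth$qpcr
  with_stream(truth, 404L, {
    genes <- qp$genes
    units <- paste0("unit", seq_len(qp$n_units))
    times <- qp$times
    shape <- {                                  # peak at the 3rd time point
      w <- rep(0.7, length(times))
      w[1] <- 0; w[min(2, length(times))] <- 0.4
      w[min(3, length(times))] <- 1
      w
    }
    L <- matrix(stats::rnorm(length(genes) * length(units), qp$log2_max_mean,
                             qp$log2_max_sd),
                length(genes), length(units),
                dimnames = list(genes, units))
    series <- do.call(rbind, lapply(genes, function(g)
      do.call(rbind, lapply(seq_along(units), function(u)
        data.frame(gene = g, unit = units[u], time = times,
                   fold = 2^(L[g, u] * shape), stringsAsFactors = FALSE)))))
    reps <- seq_len(qp$n_ct_replicates)
    design <- expand.grid(replicate = reps, time = times, unit = units,
                          stringsAsFactors = FALSE)
    design <- data.frame(
      sample = paste(design$unit, design$time, design$replicate, sep = "_"),
      condition = paste(design$unit, design$time, sep = "_"),
      replicate = design$replicate, unit = design$unit, time = design$time,
      stringsAsFactors = FALSE)
    dct0 <- stats::runif(length(genes), -6, -2)  # expression vs reference at t0
    names(dct0) <- genes
    ref_ct <- 20
    ct <- matrix(NA_real_, length(genes) + 1, nrow(design),
                 dimnames = list(c(qp$genes, "GAPDH"), design$sample))
    ct["GAPDH", ] <- ref_ct + stats::rnorm(nrow(design), 0, qp$ct_noise_sd)
    for (g in genes) {
      lfc <- vapply(seq_len(nrow(design)), function(j) {
        u <- design$unit[j]; tt <- design$time[j]
        L[g, u] * shape[match(tt, times)]
      }, numeric(1))
      ct[g, ] <- ref_ct - (dct0[g] + lfc) +
        stats::rnorm(nrow(design), 0, qp$ct_noise_sd)
    }
    m <- 2^L                                    # planted maximal induction
    r <- qp$r_true
    outcomes <- matrix(NA_real_, length(genes), length(units),
                       dimnames = list(genes, units))
    for (g in genes) {
      ms <- as.numeric(scale(m[g, ]))
      z <- stats::rnorm(length(units))
      outcomes[g, ] <- pmin(pmax(0.5 + 0.08 * (r * ms + sqrt(1 - r^2) * z),
                                 0.01), 0.99)
    }
    list(ct = ct, design = design, series = series, outcomes = outcomes,
         truth_max = m, reference = "GAPDH")
  })
}

#' Generate the full synthetic study bundle
#'
#' Runs every generator from one truth configuration and (optionally) writes
#' all artifacts as plain-text files: expression and beta TSVs, design,
#' probe map, truth labels, GMT gene sets, BED peaks, gene models and the
#' qPCR tables.
#'
#' @param truth a [simulation_truth()].
#' @param outdir optional output directory (created if missing).
#' @return list with elements `expr`, `labels`, `meth`, `annotations`,
#'   `qpcr`, `design`, `truth`.
#' @export
simulate_study <- function(truth, outdir = NULL) {
  ex <- simulate_expression(truth)
  me <- simulate_methylation(truth, ex$labels)
  an <- simulate_annotations(truth, ex$labels)
  qp <- simulate_qpcr(truth)
  out <- list(expr = ex$expr, labels = ex$labels, meth = me,
              annotations = an, qpcr = qp, design = ex$expr$design,
              truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_expression_table(ex$expr, p("expression.tsv"))
    write_design(ex$expr$design, p("design.tsv"))
    utils::write.table(ex$labels, p("truth_labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_expression_table(me$beta$betas, p("beta.tsv"))
    utils::write.table(me$beta$probe_to_gene, p("probe_map.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(me$labels, p("meth_labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_gene_sets(an$gene_sets, p("gene_sets.gmt"))
    write_bed_peaks(an$peaks, p("peaks.bed"))
    write_gene_models(an$gene_models, p("gene_models.tsv"))
    write_expression_table(qp$ct, p("qpcr_ct.tsv"))
    utils::write.table(qp$design, p("qpcr_design.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene = rownames(qp$outcomes), qp$outcomes,
                 check.names = FALSE),
      p("qpcr_outcomes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
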