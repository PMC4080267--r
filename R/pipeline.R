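#' Pipeline configuration
#'
#' Collects the tunable parameters of [run_pipeline()].  Defaults follow
#' the screening procedure the package implements: top-N outlier
#' selection with N = 300, survivors reported at the rank thresholds
#' 50..300, Benjamini-Hochberg adjustment at alpha 0.05, increasing
#' expected class ordering, and a 1000-iteration resampling null.
#'
#' `pc_combinations` controls which PC is used per modality: `"auto"`
#' picks the top F-ranked discriminating PC for each modality; otherwise
#' supply a list of `c(genotype_pc, methylation_pc)` pairs (several pairs
#' run the whole selection once per combination, the way swapped PC
#' choices are explored when two adjacent PCs separate the classes
#' equally well).
#'
#' @param N Selection size per modality.
#' @param thresholds Ascending rank thresholds (each `<= N`) at which
#'   surviving probes are tabulated.
#' @param alpha Significance level for the adjusted t-test P-values.
#' @param adjust `"BH"` or `"bonferroni"`.
#' @param direction Expected class-mean ordering, `"increasing"` or
#'   `"decreasing"`.
#' @param pc_combinations `"auto"` or a list of integer pairs.
#' @param n_iter Resampling-null iterations (0 skips the resampling
#'   stage).
#' @param compare Run the comparison selectors (Table-4-style report).
#' @param center Center probes before PCA.
#' @param seed Integer seed for the resampling stage.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(N = 300,
                            thresholds = c(50, 100, 150, 200, 250, 300),
                            alpha = 0.05,
                            adjust = c("BH", "bonferroni"),
                            direction = c("increasing", "decreasing"),
                            pc_combinations = "auto",
                            n_iter = 1000,
                            compare = TRUE,
                            center = FALSE,
                            seed = 1L) {
  adjust <- match.arg(adjust)
  direction <- match.arg(direction)
  thresholds <- sort(as.integer(thresholds))
  if (any(thresholds > N))
    stop("thresholds must not exceed N", call. = FALSE)
  if (!identical(pc_combinations, "auto")) {
    if (!is.list(pc_combinations) ||
        !all(vapply(pc_combinations, length, 0L) == 2))
      stop("pc_combinations must be \"auto\" or a list of (genotype, methylation) PC index pairs",
           call. = FALSE)
  }
  structure(list(N = as.integer(N), thresholds = thresholds,
                 alpha = alpha, adjust = adjust, direction = direction,
                 pc_combinations = pc_combinations,
                 n_iter = as.integer(n_iter), compare = isTRUE(compare),
                 center = isTRUE(center), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full gene-screening pipeline
#'
#' End-to-end orchestration of the screen: zero-substitute missing
#' values, align the two modalities to their common probe universe,
#' decompose each by PCA, rank PCs by tissue-class separation, select
#' top-N outlier probes per modality along the chosen PC(s), intersect
#' across modalities and score the overlap with the hypergeometric tail
#' test, filter the intersection by the three pairwise one-sided t-tests
#' (required to pass in both modalities), tabulate survivors at each rank
#' threshold, test the genotype-vs-methylation intensity bias on the
#' intersection, run the resampling null, and (optionally) benchmark the
#' comparison selectors.  Identical inputs, configuration and seed give
#' identical output.
#'
#' @param cfg A [pipeline_config()].
#' @param genotype,methylation [omics_matrix()] objects; alternatively
#'   supply `params` to simulate them.
#' @param design A [sample_design()] (ignored when `params` is given).
#' @param params Optional [simulation_params()]; when supplied the input
#'   dataset is generated by [generate_paired_dataset()] and the ground
#'   truth is carried into the result.
#' @return Object of class `pipeline_result`: list with `pca`
#'   (per-modality [fit_pca()] results), `pc_ranking`, `combinations` (one
#'   entry per PC combination, each holding `selection` per modality,
#'   `intersection`, `overlap_pvalue`, `overlap_log_pvalue`, `ttest` per
#'   modality, `surviving_probe_ids`, `threshold_table`, `bias_table`,
#'   `resampling`), `comparison`, `universe_size`, `truth` (when
#'   simulated), `config`, and `log` (per-stage parameter messages).
#' @export
run_pipeline <- function(cfg = pipeline_config(), genotype = NULL,
                         methylation = NULL, design = NULL,
                         params = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  truth <- NULL
  if (!is.null(params)) {
    d <- generate_paired_dataset(params)
    genotype <- d$genotype; methylation <- d$methylation
    design <- d$design; truth <- d$truth
    note("simulated dataset: %d probes, %d planted, seed %d",
         params$n_probes, params$n_signal, params$seed)
  }
  if (is.null(genotype) || is.null(methylation) || is.null(design))
    stop("supply genotype, methylation and design, or simulation params",
         call. = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  al <- stage("align", align_modalities(genotype, methylation))
  g <- al$a; m <- al$b
  M <- length(probe_ids(g))
  note("aligned universe: %d probes, %d samples", M, length(sample_ids(g)))

  # zero substitution applies to the decomposition (and the complete-data
  # comparison selectors); the t-test stages drop missing cells instead
  g0 <- substitute_missing_with_zero(g)
  m0 <- substitute_missing_with_zero(m)
  pca_g <- stage("pca", fit_pca(g0, center = cfg$center))
  pca_m <- stage("pca", fit_pca(m0, center = cfg$center))
  rank_g <- stage("rank_pcs", rank_discriminating_pcs(pca_g, design))
  rank_m <- stage("rank_pcs", rank_discriminating_pcs(pca_m, design))

  combos <- if (identical(cfg$pc_combinations, "auto")) {
    note("auto PC choice: genotype PC%d (F=%.1f), methylation PC%d (F=%.1f)",
         rank_g$pc[1], rank_g$f_statistic[1],
         rank_m$pc[1], rank_m$f_statistic[1])
    list(c(rank_g$pc[1], rank_m$pc[1]))
  } else cfg$pc_combinations

  run_combo <- function(pcs) {
    sel_g <- stage("select", select_outliers(pca_g, pcs[1], cfg$N))
    sel_m <- stage("select", select_outliers(pca_m, pcs[2], cfg$N))
    common <- intersect_selections(sel_g, sel_m)
    lp <- overlap_pvalue(M, cfg$N, cfg$N, length(common), log = TRUE)
    note("PC(g)=%d PC(m)=%d: overlap %d of %d (log10 P = %.1f)",
         pcs[1], pcs[2], length(common), cfg$N, lp / log(10))

    tt_g <- tt_m <- NULL
    surv <- character(0)
    if (length(common)) {
      tt_g <- stage("ttest", pairwise_class_ttests(
        g, design, common, direction = cfg$direction,
        adjust = cfg$adjust, alpha = cfg$alpha))
      tt_m <- stage("ttest", pairwise_class_ttests(
        m, design, common, direction = cfg$direction,
        adjust = cfg$adjust, alpha = cfg$alpha))
      surv <- intersect(tt_g$surviving_probe_ids,
                        tt_m$surviving_probe_ids)
    }

    thr_tab <- do.call(rbind, lapply(cfg$thresholds, function(th) {
      cth <- intersect_selections(
        sel_g$probe_ids[seq_len(min(th, length(sel_g$probe_ids)))],
        sel_m$probe_ids[seq_len(min(th, length(sel_m$probe_ids)))])
      sth <- character(0)
      if (length(cth) >= 1) {
        a <- pairwise_class_ttests(g, design, cth,
                                   direction = cfg$direction,
                                   adjust = cfg$adjust, alpha = cfg$alpha)
        b <- pairwise_class_ttests(m, design, cth,
                                   direction = cfg$direction,
                                   adjust = cfg$adjust, alpha = cfg$alpha)
        sth <- intersect(a$surviving_probe_ids, b$surviving_probe_ids)
      }
      data.frame(threshold = th, n_common = length(cth),
                 n_surviving = length(sth),
                 surviving = paste(sort(sth), collapse = ","))
    }))

    bias <- if (length(common) >= 2)
      stage("bias", modality_bias_test(g, m, common, design)) else NULL
    resamp <- if (cfg$n_iter > 0 && length(common) >= 2)
      stage("resampling", resampling_null(g, m, length(common),
                                          cfg$n_iter, design,
                                          seed = cfg$seed,
                                          alpha = cfg$alpha)) else NULL
    list(pc_genotype = pcs[1], pc_methylation = pcs[2],
         selection = list(genotype = sel_g, methylation = sel_m),
         intersection = common,
         overlap_pvalue = exp(lp), overlap_log_pvalue = lp,
         ttest = list(genotype = tt_g, methylation = tt_m),
         surviving_probe_ids = sort(surv),
         threshold_table = thr_tab, bias_table = bias,
         resampling = resamp)
  }
  combinations <- lapply(combos, run_combo)
  names(combinations) <- vapply(combos, function(p)
    sprintf("g%d_m%d", p[1], p[2]), character(1))

  comparison <- NULL
  if (cfg$compare) {
    comparison <- stage("compare", compare_methods(
      g0, m0, design, N = cfg$N,
      pc_genotype = combinations[[1]]$pc_genotype,
      pc_methylation = combinations[[1]]$pc_methylation))
    note("comparison overlaps: %s",
         paste(sprintf("%s=%s", comparison$method,
                       ifelse(is.na(comparison$overlap), "--",
                              comparison$overlap)), collapse = " "))
  }

  structure(list(pca = list(genotype = pca_g, methylation = pca_m),
                 pc_ranking = list(genotype = rank_g, methylation = rank_m),
                 combinations = combinations,
                 comparison = comparison,
                 universe_size = M,
                 truth = truth,
                 config = cfg,
                 log = log),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", x$universe_size, "probes in universe\n")
  for (nm in names(x$combinations)) {
    cb <- x$combinations[[nm]]
    cat(sprintf("  [%s] overlap %d (log10 P = %.1f), surviving %d\n", nm,
                length(cb$intersection), cb$overlap_log_pvalue / log(10),
                length(cb$surviving_probe_ids)))
  }
  invisible(x)
}

#' Score a pipeline result against simulation ground truth
#'
#' Recall and precision of a probe set against the planted signal probes
#' of a simulated dataset.
#'
#' @param probe_set Character vector (e.g. `surviving_probe_ids` or an
#'   intersection) to score.
#' @param truth The `truth` element of [generate_paired_dataset()] /
#'   [run_pipeline()].
#' @return Named numeric vector with `recall`, `precision`.
#' @export
score_recovery <- function(probe_set, truth) {
  planted <- truth$signal_probe_ids
  hit <- length(intersect(probe_set, planted))
  c(recall = if (length(planted)) hit / length(planted) else NA_real_,
    precision = if (length(probe_set)) hit / length(probe_set) else
      NA_real_)
}

#' Write a pipeline report bundle
#'
#' Emits the tabular outputs of [run_pipeline()] as TSV files plus a JSON
#' run manifest (configuration, seed, package version, per-stage log)
#' into a directory: per combination the ranked selections, the
#' intersection, the threshold table, the modality-bias table and the
#' resampling table; plus the PCA summary (contribution and F per PC)
#' and the comparison report.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tab, name)
    utils::write.table(tab, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  for (mod in c("genotype", "methylation")) {
    rk <- result$pc_ranking[[mod]]
    pca_sum <- data.frame(pc = paste0("PC", rk$pc),
                          contribution =
                            result$pca[[mod]]$contribution[rk$pc],
                          f_statistic = rk$f_statistic)
    w(pca_sum[order(rk$pc), ], paste0("pca_summary_", mod, ".tsv"))
  }
  for (nm in names(result$combinations)) {
    cb <- result$combinations[[nm]]
    write_selection(cb$selection$genotype,
                    file.path(dir, paste0(nm, "_selection_genotype.tsv")))
    write_selection(cb$selection$methylation,
                    file.path(dir, paste0(nm, "_selection_methylation.tsv")))
    w(data.frame(probe_id = cb$intersection,
                 surviving = cb$intersection %in% cb$surviving_probe_ids),
      paste0(nm, "_intersection.tsv"))
    w(cb$threshold_table, paste0(nm, "_threshold_table.tsv"))
    if (!is.null(cb$bias_table))
      w(cb$bias_table, paste0(nm, "_bias_table.tsv"))
    if (!is.null(cb$resampling))
      w(cb$resampling$table, paste0(nm, "_resampling_table.tsv"))
  }
  if (!is.null(result$comparison))
    write_comparison(result$comparison, file.path(dir, "comparison.tsv"))
  manifest <- list(
    package = "gsmscreen",
    version = as.character(utils::packageVersion("gsmscreen")),
    config = unclass(result$config),
    universe_size = result$universe_size,
    overlap = lapply(result$combinations, function(cb)
      list(pc_genotype = cb$pc_genotype,
           pc_methylation = cb$pc_methylation,
           n_common = length(cb$intersection),
           log10_pvalue = cb$overlap_log_pvalue / log(10),
           n_surviving = length(cb$surviving_probe_ids))),
    log = result$log)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
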