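#' Intersect two probe selections
#'
#' Exact set intersection of the probes in two selection sets, returned
#' in deterministic lexicographic order.
#'
#' @param a,b `selection_set` objects (or plain character vectors of
#'   probe identifiers) drawn from the same aligned probe universe.
#' @return Sorted character vector of common probe identifiers.
#' @export
intersect_selections <- function(a, b) {
  ids <- function(s) if (inherits(s, "selection_set")) s$probe_ids else
    as.character(s)
  sort(intersect(ids(a), ids(b)))
}

#' Hypergeometric overlap significance of two probe sets
#'
#' Probability of observing at least `observed` probes in common between
#' two independently drawn subsets of sizes `k1` and `k2` from a universe
#' of `M` probes: the upper tail `P(X >= observed)` with
#' `X ~ Hypergeometric(M, k1, k2)`.  The tail is computed in log space,
#' so probabilities far below the double underflow threshold remain
#' available as log-probabilities via `log = TRUE`.
#'
#' @param M Universe size.
#' @param k1,k2 Sizes of the two drawn sets.
#' @param observed Observed overlap; must satisfy
#'   `observed <= min(k1, k2) <= M`.
#' @param log Return the natural-log probability instead (default
#'   `FALSE`; the plain probability may underflow to 0 for extreme
#'   overlaps).
#' @return Tail probability (or its natural log).
#' @examples
#' overlap_pvalue(250000, 300, 300, 68)          # << 1e-16
#' overlap_pvalue(250000, 300, 300, 0)           # 1
#' @export
overlap_pvalue <- function(M, k1, k2, observed, log = FALSE) {
  if (any(c(M, k1, k2, observed) < 0) || k1 > M || k2 > M ||
      observed > min(k1, k2))
    stop("inconsistent counts: need observed <= min(k1, k2) <= M",
         call. = FALSE)
  lp <- if (observed == 0) 0 else
    stats::phyper(observed - 1, k1, M - k1, k2,
                  lower.tail = FALSE, log.p = TRUE)
  if (log) lp else exp(lp)
}

#' Three pairwise one-sided class t-tests per probe
#'
#' For each probe, Welch two-sample one-sided t-tests for the three class
#' pairs normal-vs-tumor, blood-vs-tumor and blood-vs-normal.  With
#' `direction = "increasing"` (blood < normal < tumor) the alternatives
#' are tumor > normal, tumor > blood and normal > blood; `"decreasing"`
#' reverses them.  P-values are adjusted across all probes and all three
#' comparisons jointly (the default) or within each comparison, and a
#' probe passes when all three adjusted P-values fall below `alpha`.
#' Probes for which a comparison is untestable (a class constant or with
#' fewer than two finite values) are flagged and never pass.
#'
#' @param x An [omics_matrix()].
#' @param design A [sample_design()] covering the samples of `x`.
#' @param probes Probe identifiers to test (default: all).
#' @param direction `"increasing"` or `"decreasing"` expected ordering of
#'   class means over (blood, normal, tumor).
#' @param adjust `"BH"` (Benjamini-Hochberg, default) or `"bonferroni"`.
#' @param alpha Significance level for the adjusted P-values.
#' @param joint Adjust across probes x comparisons jointly (default) or
#'   per comparison.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Object of class `class_ttest_result`: a list with `table`
#'   (data.frame: probe_id, raw and adjusted P per comparison, `pass`,
#'   `untestable`), `surviving_probe_ids`, and the call parameters.
#' @export
pairwise_class_ttests <- function(x, design, probes = probe_ids(x),
                                  direction = c("increasing", "decreasing"),
                                  adjust = c("BH", "bonferroni"),
                                  alpha = 0.05, joint = TRUE,
                                  var_equal = FALSE) {
  stopifnot(inherits(x, "omics_matrix"))
  direction <- match.arg(direction)
  adjust <- match.arg(adjust)
  missing_probes <- setdiff(probes, probe_ids(x))
  if (length(missing_probes))
    stop("probes absent from matrix: ",
         paste(utils::head(missing_probes, 3), collapse = ", "),
         call. = FALSE)
  cls <- tissue_of(design, sample_ids(x))
  # comparison c(low, high); one-sided alternative: high > low when
  # increasing, high < low when decreasing
  pairs <- list(normal_vs_tumor = c("normal", "tumor"),
                blood_vs_tumor = c("blood", "tumor"),
                blood_vs_normal = c("blood", "normal"))
  alt <- if (direction == "increasing") "greater" else "less"
  raw <- matrix(NA_real_, length(probes), 3,
                dimnames = list(probes, names(pairs)))
  for (pr in probes) {
    v <- x$values[pr, ]
    for (cmp in names(pairs)) {
      lo <- v[cls == pairs[[cmp]][1]]
      hi <- v[cls == pairs[[cmp]][2]]
      lo <- lo[is.finite(lo)]                     # missing cells dropped
      hi <- hi[is.finite(hi)]
      p <- if (length(lo) < 2 || length(hi) < 2) NA_real_ else
        tryCatch(stats::t.test(hi, lo, alternative = alt,
                               var.equal = var_equal)$p.value,
                 error = function(e) NA_real_)
      raw[pr, cmp] <- p
    }
  }
  untestable <- apply(raw, 1, anyNA)
  if (any(untestable))
    message(sum(untestable),
            " probe(s) untestable (constant or insufficient data); excluded")
  adj <- raw
  if (joint) {
    adj[] <- stats::p.adjust(as.vector(raw), method = adjust)
  } else {
    for (j in 1:3) adj[, j] <- stats::p.adjust(raw[, j], method = adjust)
  }
  pass <- !untestable & apply(adj < alpha, 1, all)
  pass[is.na(pass)] <- FALSE
  tab <- data.frame(probe_id = probes,
                    p_normal_vs_tumor = raw[, 1],
                    p_blood_vs_tumor = raw[, 2],
                    p_blood_vs_normal = raw[, 3],
                    adj_normal_vs_tumor = adj[, 1],
                    adj_blood_vs_tumor = adj[, 2],
                    adj_blood_vs_normal = adj[, 3],
                    pass = pass, untestable = untestable,
                    row.names = NULL)
  structure(list(table = tab,
                 surviving_probe_ids = probes[pass],
                 direction = direction, adjust = adjust, alpha = alpha,
                 joint = joint, modality = x$modality),
            class = "class_ttest_result")
}

#' Genotype-versus-methylation intensity bias test
#'
#' For each tissue class, tests whether the genotype measurement exceeds
#' the DNA-methylation measurement over all (probe, sample) cells of that
#' class: a one-sided t-test of genotype - methylation > 0, paired over
#' cells by default (the two modalities measure the same probe in the
#' same sample), or unpaired via `paired = FALSE`.  Class means of each
#' modality are reported alongside the P-value.
#'
#' @param g,m [omics_matrix()] objects (genotype, methylation) over
#'   identical samples and a shared probe universe.
#' @param probes Non-empty set of probe identifiers present in both.
#' @param design A [sample_design()].
#' @param paired Pair cells across modalities (default `TRUE`).
#' @return `data.frame` with one row per tissue class: `class`,
#'   `genotype_mean`, `methylation_mean`, `p_value`.
#' @export
modality_bias_test <- function(g, m, probes, design, paired = TRUE) {
  stopifnot(inherits(g, "omics_matrix"), inherits(m, "omics_matrix"))
  if (length(probes) == 0)
    stop("empty probe set", call. = FALSE)
  if (!all(probes %in% probe_ids(g)) || !all(probes %in% probe_ids(m)))
    stop("probes must be present in both matrices", call. = FALSE)
  if (!identical(sample_ids(g), sample_ids(m)))
    stop("matrices must cover identical samples in identical order",
         call. = FALSE)
  cls <- tissue_of(design, sample_ids(g))
  out <- lapply(tissue_levels(), function(tl) {
    gv <- as.vector(g$values[probes, cls == tl, drop = FALSE])
    mv <- as.vector(m$values[probes, cls == tl, drop = FALSE])
    if (paired) {
      keep <- !is.na(gv) & !is.na(mv)
      gv <- gv[keep]; mv <- mv[keep]
    } else {
      gv <- gv[!is.na(gv)]; mv <- mv[!is.na(mv)]
    }
    p <- tryCatch(stats::t.test(gv, mv, paired = paired,
                                alternative = "greater")$p.value,
                  error = function(e)
                    stop("class '", tl, "' untestable: ",
                         conditionMessage(e), call. = FALSE))
    if (!is.finite(p))
      stop("class '", tl, "' untestable: zero variance of the ",
           if (paired) "paired differences" else "measurements",
           call. = FALSE)
    data.frame(class = tl, genotype_mean = mean(gv),
               methylation_mean = mean(mv), p_value = p)
  })
  do.call(rbind, out)
}

#' Resampling null for the modality bias test
#'
#' Draws `n_iter` random probe subsets of size `n_snps` from the shared
#' probe universe, applies [modality_bias_test()] to each, and adjusts
#' the resulting P-values per tissue class across iterations by the
#' Benjamini-Hochberg criterion.  On unbiased data the count of
#' significant iterations per class stays near zero; a systematic
#' normalization bias between the modalities would surface here.
#'
#' @inheritParams modality_bias_test
#' @param n_snps Subset size (at most the shared probe count).
#' @param n_iter Number of random subsets (>= 1).
#' @param seed Integer seed; output is reproducible.
#' @param alpha Significance level applied to the adjusted P-values.
#' @return Object of class `resampling_null`: list with `table`
#'   (data.frame: class, adjusted-P lower and upper bound, count of
#'   significant iterations), the per-iteration adjusted P matrix
#'   `adjusted`, and the call parameters.
#' @export
resampling_null <- function(g, m, n_snps, n_iter, design, seed = 1L,
                            alpha = 0.05) {
  shared <- intersect(probe_ids(g), probe_ids(m))
  if (n_snps > length(shared))
    stop("n_snps exceeds the shared probe count", call. = FALSE)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  raw <- withr::with_seed(seed, {
    t(vapply(seq_len(n_iter), function(i) {
      probes <- sample(shared, n_snps)
      modality_bias_test(g, m, probes, design)$p_value
    }, numeric(3)))
  })
  colnames(raw) <- tissue_levels()
  adj <- apply(raw, 2, stats::p.adjust, method = "BH")
  if (n_iter == 1) adj <- matrix(adj, 1, 3,
                                 dimnames = list(NULL, tissue_levels()))
  tab <- data.frame(class = tissue_levels(),
                    lower_bound = apply(adj, 2, min),
                    upper_bound = apply(adj, 2, max),
                    n_significant = colSums(adj < alpha),
                    row.names = NULL)
  structure(list(table = tab, adjusted = adj, n_snps = n_snps,
                 n_iter = n_iter, alpha = alpha, seed = seed),
            class = "resampling_null")
}

#' @export
print.resampling_null <- function(x, ...) {
  cat(sprintf("resampling_null: %d subsets of %d probes (BH across iterations)\n",
              x$n_iter, x$n_snps))
  print(x$table, row.names = FALSE)
  invisible(x)
}
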