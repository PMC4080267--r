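#' Correlation-based top-N probe selection
#'
#' Computes, for every probe, the Pearson or Spearman correlation between
#' its measurements and the ordinal tissue code y (1 = blood, 2 = normal,
#' 3 = tumor), then selects the N probes with the largest correlation
#' coefficients.  "Largest" is read as largest signed value by default,
#' which targets positively class-ordered probes; set `absolute = TRUE`
#' to rank by magnitude.  Probes with undefined correlation (constant
#' measurements) are ranked last.  Ties break lexicographically by probe
#' identifier.
#'
#' @param x An [omics_matrix()] without missing values.
#' @param design A [sample_design()].
#' @param method `"pearson"` or `"spearman"`.
#' @param N Number of probes to select.
#' @param absolute Rank by `|r|` instead of signed r.
#' @return A `selection_set` (method recorded as `method`).
#' @export
correlation_select <- function(x, design,
                               method = c("pearson", "spearman"),
                               N, absolute = FALSE) {
  stopifnot(inherits(x, "omics_matrix"))
  method <- match.arg(method)
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  if (anyNA(x$values))
    stop("matrix has missing values; apply substitute_missing_with_zero()",
         call. = FALSE)
  y <- tissue_code(design, sample_ids(x))
  r <- suppressWarnings(
    as.numeric(stats::cor(t(x$values), y, method = method)))
  names(r) <- probe_ids(x)
  if (anyNA(r))
    message(sum(is.na(r)),
            " probe(s) with undefined correlation ranked last")
  key <- if (absolute) abs(r) else r
  ord <- order(-key, names(r), na.last = TRUE)
  N <- min(N, length(r))
  sel <- ord[seq_len(N)]
  selection_set(modality = x$modality, method = method,
                probe_ids = names(r)[sel], scores = unname(r[sel]), N = N)
}

#' PLS-based top-N probe selection (multiclass-direct strategy)
#'
#' Fits a single-response partial least squares regression of the ordinal
#' tissue code y on the probe matrix (probes as predictors, NIPALS
#' algorithm on column-centered data), applying PLS directly to the
#' multiclass samples.  Probes are ranked by an aggregate weight: the sum
#' over the first `n_components` components of the absolute loading
#' weight multiplied by the component's score variance, a VIP-like
#' summary of how much each probe contributes to the y-predictive
#' subspace.  With the default single component the ranking reduces to
#' the absolute covariance of each (centered) probe with y.
#'
#' @inheritParams correlation_select
#' @param n_components Number of PLS components (>= 1 and at most the
#'   sample rank, `n_samples - 1`).
#' @return A `selection_set` (method `"pls"`; `scores` are aggregate
#'   weights).
#' @export
pls_select <- function(x, design, N, n_components = 1) {
  stopifnot(inherits(x, "omics_matrix"))
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  if (anyNA(x$values))
    stop("matrix has missing values; apply substitute_missing_with_zero()",
         call. = FALSE)
  n <- ncol(x$values)
  if (n_components < 1 || n_components > n - 1)
    stop("n_components must lie in [1, n_samples - 1]", call. = FALSE)
  y <- as.numeric(tissue_code(design, sample_ids(x)))
  X <- t(x$values)                      # samples x probes
  X <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  agg <- numeric(ncol(X))
  for (comp in seq_len(n_components)) {
    w <- drop(crossprod(X, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop("y has no remaining covariance with the predictors at component ",
           comp, call. = FALSE)
    w <- w / nw
    tt <- drop(X %*% w)
    ss <- sum(tt^2)
    agg <- agg + abs(w) * ss / (n - 1)
    p_load <- drop(crossprod(X, tt)) / ss
    q <- sum(yc * tt) / ss
    X <- X - tcrossprod(tt, p_load)
    yc <- yc - q * tt
  }
  names(agg) <- probe_ids(x)
  N <- min(N, length(agg))
  ord <- order(-agg, names(agg))[seq_len(N)]
  selection_set(modality = x$modality, method = "pls",
                probe_ids = names(agg)[ord], scores = unname(agg[ord]),
                N = N)
}

#' Cross-modality overlap benchmark of feature selectors
#'
#' For each requested method, selects the top-N probes independently in
#' the genotype and methylation matrices and counts how many probes the
#' two selections share.  The PCA pipeline (`"pca"`) picks, per modality,
#' the top class-discriminating PC by [rank_discriminating_pcs()] unless
#' explicit PC indices are supplied.  Stepwise-LDA and lasso selectors
#' are reported as `NA` ("--" in the TSV report): at full SNP-array scale
#' they are not executable, and they are deliberately not implemented
#' here.
#'
#' @param g,m Aligned [omics_matrix()] objects without missing values.
#' @param design A [sample_design()].
#' @param N Selection size per modality.
#' @param methods Methods to benchmark.
#' @param pc_genotype,pc_methylation Optional explicit PC index per
#'   modality for the `"pca"` method (default: auto via F ranking).
#' @param n_components Components for the PLS selector.
#' @return Object of class `comparison_report`: data.frame with columns
#'   `method`, `overlap` (plus `NA` rows for stepwise and lasso).
#' @export
compare_methods <- function(g, m, design, N = 300,
                            methods = c("pca", "pearson", "spearman",
                                        "pls"),
                            pc_genotype = NULL, pc_methylation = NULL,
                            n_components = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!identical(probe_ids(g), probe_ids(m)))
    stop("matrices are not aligned; run align_modalities() first",
         call. = FALSE)
  one <- function(method) {
    if (method == "pca") {
      pg <- fit_pca(g); pm <- fit_pca(m)
      ig <- if (is.null(pc_genotype))
        rank_discriminating_pcs(pg, design)$pc[1] else pc_genotype
      im <- if (is.null(pc_methylation))
        rank_discriminating_pcs(pm, design)$pc[1] else pc_methylation
      sg <- select_outliers(pg, ig, N)
      sm <- select_outliers(pm, im, N)
    } else if (method == "pls") {
      sg <- pls_select(g, design, N, n_components)
      sm <- pls_select(m, design, N, n_components)
    } else {
      sg <- correlation_select(g, design, method, N)
      sm <- correlation_select(m, design, method, N)
    }
    length(intersect_selections(sg, sm))
  }
  overlaps <- vapply(methods, one, numeric(1))
  tab <- data.frame(method = c(methods, "stepwise", "lasso"),
                    overlap = c(overlaps, NA_real_, NA_real_),
                    row.names = NULL)
  structure(tab, class = c("comparison_report", "data.frame"), N = N)
}

#' Write a comparison report as TSV (Table-4 layout)
#'
#' Methods without a result (stepwise, lasso) are written as `--`.
#'
#' @param x A `comparison_report`.
#' @param path Output path.
#' @export
write_comparison <- function(x, path) {
  stopifnot(inherits(x, "comparison_report"))
  out <- data.frame(method = x$method,
                    overlap = ifelse(is.na(x$overlap), "--",
                                     as.character(x$overlap)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
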