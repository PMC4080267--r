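#' Principal component analysis of a probe-by-sample matrix
#'
#' Decomposes the (complete) matrix by economy-size singular value
#' decomposition, embedding probes as PC scores and samples as PC
#' loadings.  By default the matrix is not centered: on positive array
#' intensities the first, dominant component then captures the overall
#' baseline level and does not separate tissue classes, while
#' class-discriminating structure appears on later components.  Centered
#' analysis (probe-wise means removed) is available via `center`.
#'
#' With `X` the probe-by-sample matrix and `X = U D V'` its SVD, probe
#' scores are `U D` (probes x PCs), sample loadings are `V'` (PCs x
#' samples) and the contribution of PC i is `d_i^2 / sum(d^2)`, the
#' fraction of total (uncentered) variance it explains.  Each PC's sign
#' is fixed so that the sum of its sample loadings is nonnegative, making
#' reports reproducible across platforms.
#'
#' @param x An [omics_matrix()] with no missing entries (apply
#'   [substitute_missing_with_zero()] first) and at least 2 probes and 2
#'   samples.
#' @param center Logical; subtract probe-wise means before decomposition.
#' @return Object of class `pca_result`: list with `probe_scores`
#'   (probes x PCs), `sample_loadings` (PCs x samples), `contribution`
#'   (per-PC fraction summing to 1), `modality`, `center`.
#' @export
fit_pca <- function(x, center = FALSE) {
  stopifnot(inherits(x, "omics_matrix"))
  v <- x$values
  if (anyNA(v))
    stop("matrix has missing values; apply substitute_missing_with_zero()",
         call. = FALSE)
  if (nrow(v) < 2 || ncol(v) < 2)
    stop("need at least 2 probes and 2 samples", call. = FALSE)
  if (center) v <- v - rowMeans(v)
  s <- svd(v)
  k <- length(s$d)
  # fix per-PC sign: sum of sample loadings nonnegative; fall back to the
  # largest-magnitude loading when the sum is numerically zero
  for (j in seq_len(k)) {
    sgn <- sum(s$v[, j])
    if (abs(sgn) < 1e-12) sgn <- s$v[which.max(abs(s$v[, j])), j]
    if (sgn < 0) {
      s$u[, j] <- -s$u[, j]
      s$v[, j] <- -s$v[, j]
    }
  }
  pcs <- paste0("PC", seq_len(k))
  scores <- s$u %*% diag(s$d, k, k)
  dimnames(scores) <- list(rownames(v), pcs)
  loadings <- t(s$v)
  dimnames(loadings) <- list(pcs, colnames(v))
  structure(list(probe_scores = scores,
                 sample_loadings = loadings,
                 contribution = stats::setNames(s$d^2 / sum(s$d^2), pcs),
                 modality = x$modality,
                 center = center),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result [%s%s]: %d probes, %d samples, %d PCs\n",
              x$modality, if (x$center) ", centered" else "",
              nrow(x$probe_scores), ncol(x$sample_loadings),
              length(x$contribution)))
  cat("top contributions:",
      paste(sprintf("%s=%.3f", names(x$contribution)[1:min(4,
            length(x$contribution))],
            x$contribution[1:min(4, length(x$contribution))]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Rank principal components by tissue-class separation
#'
#' The study's PC choice was made by inspecting sample-loading plots; this
#' operation makes the choice reproducible by scoring every PC with a
#' classical one-way three-class F statistic on its sample loadings
#' grouped by tissue, and ordering PCs by decreasing F.  A PC whose
#' loadings are constant has an undefined F and is ranked last (F
#' reported as 0).  The ranking is advisory: any downstream step accepts
#' an explicit PC index.
#'
#' @param p A [fit_pca()] result.
#' @param design A [sample_design()] covering all samples of `p`.
#' @param n_candidates Number of leading PCs to score (default: all).
#' @return `data.frame` with columns `pc` (index), `f_statistic`,
#'   `p_value`, ordered by decreasing F (ties by PC index).
#' @export
rank_discriminating_pcs <- function(p, design,
                                    n_candidates = nrow(p$sample_loadings)) {
  stopifnot(inherits(p, "pca_result"))
  samples <- colnames(p$sample_loadings)
  cls <- tissue_of(design, samples)
  if (any(table(cls) < 2))
    stop("degenerate design: every tissue class needs >= 2 samples",
         call. = FALSE)
  n_candidates <- min(n_candidates, nrow(p$sample_loadings))
  stat <- vapply(seq_len(n_candidates), function(j) {
    ft <- tryCatch(stats::oneway.test(p$sample_loadings[j, ] ~ cls,
                                      var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(ft) || !is.finite(ft$statistic))
      c(0, 1)
    else c(ft$statistic, ft$p.value)
  }, numeric(2))
  out <- data.frame(pc = seq_len(n_candidates),
                    f_statistic = stat[1, ],
                    p_value = stat[2, ])
  out[order(-out$f_statistic, out$pc), , drop = FALSE]
}

#' Select top outlier probes along a principal component
#'
#' An outlier probe is one with extreme absolute score along the chosen
#' axis; selection is two-sided, matching embeddings in which
#' discriminating probes appear on both flanks of the cloud.  Ties are
#' broken lexicographically by probe identifier so the selection is
#' deterministic, and flipping the PC's sign leaves the selection
#' unchanged.
#'
#' @param p A [fit_pca()] result.
#' @param pc_index 1-based index of the PC to use.
#' @param N Number of probes to select; clamped (with a warning) to the
#'   number of probes available.
#' @return Object of class `selection_set`: list with `modality`,
#'   `method` (`"pca"`), `pc_index`, `N`, `probe_ids` (ranked), `scores`
#'   (the signed PC scores, ordered by decreasing magnitude).
#' @export
select_outliers <- function(p, pc_index, N) {
  stopifnot(inherits(p, "pca_result"))
  if (pc_index < 1 || pc_index > ncol(p$probe_scores))
    stop("pc_index out of range", call. = FALSE)
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  sc <- p$probe_scores[, pc_index]
  if (N > length(sc)) {
    warning("N exceeds the number of probes; clamped to ", length(sc))
    N <- length(sc)
  }
  ord <- order(-abs(sc), names(sc))[seq_len(N)]
  selection_set(modality = p$modality, method = "pca",
                probe_ids = names(sc)[ord], scores = unname(sc[ord]),
                pc_index = pc_index, N = N)
}

selection_set <- function(modality, method, probe_ids, scores,
                          pc_index = NA_integer_, N = length(probe_ids)) {
  structure(list(modality = modality, method = method,
                 pc_index = pc_index, N = N,
                 probe_ids = probe_ids, scores = scores),
            class = "selection_set")
}

#' @export
print.selection_set <- function(x, ...) {
  cat(sprintf("selection_set [%s, %s%s]: %d probes\n", x$modality,
              x$method,
              if (!is.na(x$pc_index)) paste0(", PC", x$pc_index) else "",
              length(x$probe_ids)))
  invisible(x)
}

#' Write a selection set as TSV (rank, probe_id, score)
#'
#' @param x A `selection_set`.
#' @param path Output path.
#' @export
write_selection <- function(x, path) {
  stopifnot(inherits(x, "selection_set"))
  utils::write.table(data.frame(rank = seq_along(x$probe_ids),
                                probe_id = x$probe_ids,
                                score = x$scores),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
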