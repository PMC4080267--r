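#' Binary fingerprint collection
#'
#' Holds fixed-length binary molecular fingerprints for a compound
#' library, one row per compound.  Fingerprints are abstract bit vectors;
#' producing them from chemical structures is outside the package's
#' scope.
#'
#' @param bits Integer/logical matrix of 0/1 values with compound
#'   identifiers as row names (0-row matrices are allowed for empty
#'   collections).
#' @return Object of class `fingerprint_set`: list with `bits`.
#' @export
fingerprint_set <- function(bits) {
  if (!is.matrix(bits))
    stop("'bits' must be a matrix", call. = FALSE)
  if (nrow(bits) > 0 && is.null(rownames(bits)))
    stop("'bits' must have compound identifiers as row names",
         call. = FALSE)
  storage.mode(bits) <- "integer"
  if (nrow(bits) > 0 && !all(bits %in% c(0L, 1L)))
    stop("fingerprints must be binary", call. = FALSE)
  structure(list(bits = bits), class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat(sprintf("fingerprint_set: %d compounds x %d bits\n",
              nrow(x$bits), ncol(x$bits)))
  invisible(x)
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `|a AND b| / |a OR b|`, in \[0, 1\]; defined as 0 when both
#' fingerprints are all-zero (reported via a message).
#'
#' @param a,b Binary vectors of equal length (0/1 or logical).
#' @return Tanimoto index.
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
#' @export
tanimoto <- function(a, b) {
  a <- as.integer(as.logical(a)); b <- as.integer(as.logical(b))
  if (length(a) != length(b))
    stop("fingerprints have different lengths", call. = FALSE)
  un <- sum(a | b)
  if (un == 0) {
    message("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  sum(a & b) / un
}

#' Filter a compound library by Tanimoto similarity to references
#'
#' Keeps every library compound whose best Tanimoto index over the
#' reference ligand fingerprints is strictly larger than `threshold`
#' (thresholds around 0.20--0.25 are typical for ligand-based
#' prescreening).  Output order is deterministic (by compound
#' identifier), and the best-matching reference is reported per
#' compound.
#'
#' @param library,references `fingerprint_set` objects with equal bit
#'   lengths; `references` must be non-empty.
#' @param threshold Similarity threshold in \[0, 1\] (strict inequality).
#' @return `data.frame` with columns `compound_id`, `best_reference`,
#'   `tanimoto` for the passing compounds.
#' @export
filter_by_tanimoto <- function(library, references, threshold) {
  stopifnot(inherits(library, "fingerprint_set"),
            inherits(references, "fingerprint_set"))
  if (nrow(references$bits) == 0)
    stop("empty reference collection", call. = FALSE)
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  if (nrow(library$bits) == 0)
    return(data.frame(compound_id = character(0),
                      best_reference = character(0),
                      tanimoto = numeric(0)))
  if (ncol(library$bits) != ncol(references$bits))
    stop("bit lengths differ between library and references",
         call. = FALSE)
  L <- library$bits
  R <- references$bits
  inter <- tcrossprod(L, R)                       # |a AND b|
  uni <- outer(rowSums(L), rowSums(R), `+`) - inter
  tan <- ifelse(uni == 0, 0, inter / uni)
  best <- apply(tan, 1, which.max)
  best_val <- tan[cbind(seq_len(nrow(tan)), best)]
  keep <- best_val > threshold
  out <- data.frame(compound_id = rownames(L)[keep],
                    best_reference = rownames(R)[best[keep]],
                    tanimoto = best_val[keep],
                    row.names = NULL)
  out[order(out$compound_id), , drop = FALSE]
}

#' Ranked score trials over a compound library
#'
#' Container for repeated scoring runs (e.g. repeated docking-score
#' computations) over one compound library: a trial-by-compound score
#' matrix.  Descending ranks per trial (1 = best score) are derived on
#' construction; ties break by compound identifier so each trial's ranks
#' are a permutation of `1..N_c`.
#'
#' @param scores Numeric trial-by-compound matrix with compound
#'   identifiers as column names.
#' @return Object of class `rank_trial_set`: list with `scores`, `ranks`
#'   (same shape; descending rank of the score within each trial).
#' @export
rank_trial_set <- function(scores) {
  if (!is.matrix(scores) || !is.numeric(scores))
    stop("'scores' must be a numeric matrix (trials x compounds)",
         call. = FALSE)
  if (is.null(colnames(scores)))
    stop("'scores' must have compound identifiers as column names",
         call. = FALSE)
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("trial", seq_len(nrow(scores)))
  ranks <- t(apply(scores, 1, function(s) {
    r <- integer(length(s))
    r[order(-s, colnames(scores))] <- seq_along(s)
    r
  }))
  dimnames(ranks) <- dimnames(scores)
  structure(list(scores = scores, ranks = ranks),
            class = "rank_trial_set")
}

#' @export
print.rank_trial_set <- function(x, ...) {
  cat(sprintf("rank_trial_set: %d trials x %d compounds\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Expected number of unique compounds among random top-k lists
#'
#' Closed-form expected size of the union of the top-k sets from
#' `n_trials` mutually independent random rankings of `Nc` compounds:
#' `n0(k) = Nc * (1 - (1 - k/Nc)^n_trials)`.  For three trials this
#' equals the classical form `k * (1 + (1 - k/Nc) * (2 - k/Nc))`.
#' Observed union sizes far below `n0(k)` (close to `k`) indicate high
#' concordance between the trials.
#'
#' @param k Depth of the ranked lists, `0 <= k <= Nc` (vectorized).
#' @param Nc Total number of compounds (>= 1).
#' @param n_trials Number of independent rankings (default 3).
#' @return Expected union size, same length as `k`.
#' @export
expected_common <- function(k, Nc, n_trials = 3) {
  if (Nc < 1) stop("Nc must be >= 1", call. = FALSE)
  if (any(k < 0) || any(k > Nc))
    stop("k must lie in [0, Nc]", call. = FALSE)
  Nc * (1 - (1 - k / Nc)^n_trials)
}

#' Observed vs expected common-selection curve
#'
#' For each requested depth k, counts the compounds selected in common by
#' the trials' top-k lists and sets the count against the
#' independent-rankings expectation [expected_common()] and the
#' complete-match reference k.  "In common" is, by default, the number of
#' unique compounds in the union of the top-k sets (the quantity whose
#' expectation `n0(k)` describes); `mode = "intersection"` counts
#' compounds ranked in the top k by every trial instead.
#'
#' @param x A [rank_trial_set()] with >= 2 trials.
#' @param k_values Depths to evaluate; all must be `<= N_c`.
#' @param mode `"union"` (default) or `"intersection"`.
#' @return `data.frame` with columns `k`, `observed`, `expected_null`
#'   (n0(k) at the set's trial count), `complete_match` (= k).
#' @export
observed_common_curve <- function(x, k_values,
                                  mode = c("union", "intersection")) {
  stopifnot(inherits(x, "rank_trial_set"))
  mode <- match.arg(mode)
  if (nrow(x$ranks) < 2)
    stop("need at least two trials", call. = FALSE)
  Nc <- ncol(x$ranks)
  if (any(k_values > Nc))
    stop("k exceeds the number of compounds", call. = FALSE)
  obs <- vapply(k_values, function(k) {
    inside <- x$ranks <= k                        # trials x compounds
    if (mode == "union") sum(colSums(inside) > 0)
    else sum(colSums(inside) == nrow(inside))
  }, numeric(1))
  data.frame(k = k_values, observed = obs,
             expected_null = expected_common(k_values, Nc, nrow(x$ranks)),
             complete_match = k_values)
}

#' Pairwise Pearson correlations between scoring trials
#'
#' @param x A [rank_trial_set()] with >= 2 trials and >= 3 compounds.
#' @return Symmetric trial-by-trial correlation matrix with unit
#'   diagonal; entries involving a constant score vector are `NA` (with a
#'   warning).
#' @export
trial_score_correlations <- function(x) {
  stopifnot(inherits(x, "rank_trial_set"))
  if (nrow(x$scores) < 2 || ncol(x$scores) < 3)
    stop("need >= 2 trials and >= 3 compounds", call. = FALSE)
  const <- apply(x$scores, 1, function(s) stats::sd(s) == 0)
  if (any(const))
    warning("constant score vector in trial(s) ",
            paste(rownames(x$scores)[const], collapse = ", "),
            "; correlations undefined")
  suppressWarnings(stats::cor(t(x$scores)))
}

#' Aggregate compound ranking over trials
#'
#' Ranks compounds by their best (`mode = "best"`) or mean
#' (`mode = "mean"`) score over the trials, in descending order with ties
#' broken by compound identifier.
#'
#' @param x A [rank_trial_set()].
#' @param mode `"best"` or `"mean"`.
#' @return Character vector of compound identifiers, best first.
#' @export
rank_compounds <- function(x, mode = c("best", "mean")) {
  stopifnot(inherits(x, "rank_trial_set"))
  mode <- match.arg(mode)
  agg <- if (mode == "best") apply(x$scores, 2, max) else
    colMeans(x$scores)
  colnames(x$scores)[order(-agg, colnames(x$scores))]
}
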