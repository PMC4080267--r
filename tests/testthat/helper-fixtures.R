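# Shared fixtures and independent oracles used across test files.

# tiny probe x sample matrix with explicit dimnames
tiny_matrix <- function(values, probes, samples,
                        modality = "genotype") {
  omics_matrix(matrix(values, length(probes), length(samples),
                      dimnames = list(probes, samples)), modality)
}

# balanced design: n subjects x three tissues, tissue-major sample order
balanced_design <- function(n = 5) {
  subj <- sprintf("s%02d", seq_len(n))
  tis <- rep(c("blood", "normal", "tumor"), each = n)
  sample_design(paste0(rep(subj, 3), "_", tis), rep(subj, 3), tis)
}

# matrix with rows drawn around per-class means for a balanced design
class_matrix <- function(probes, means_by_class, n = 5, sd = 0.1,
                         modality = "genotype", seed = 1) {
  d <- balanced_design(n)
  withr::with_seed(seed, {
    vals <- t(vapply(seq_along(probes), function(i) {
      mu <- means_by_class[[i]][as.integer(d$tissue)]
      stats::rnorm(3 * n, mu, sd)
    }, numeric(3 * n)))
    dimnames(vals) <- list(probes, d$sample_id)
    list(m = omics_matrix(vals, modality), design = d)
  })
}

# brute-force Benjamini-Hochberg step-up (independent of p.adjust)
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# exhaustive hypergeometric upper tail by enumerating all k2-subsets of M
enum_overlap_tail <- function(M, k1, k2, observed) {
  a <- seq_len(k1)
  subsets <- utils::combn(M, k2)
  hits <- apply(subsets, 2, function(b) sum(b %in% a))
  mean(hits >= observed)
}
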