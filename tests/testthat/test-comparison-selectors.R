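test_that("correlation selectors honor their defining invariances", {
  d <- balanced_design(10)
  y <- tissue_code(d, d$sample_id)
  withr::local_seed(3)
  # "curved" is an exact monotone transform of y: its midranks equal
  # y's midranks, so Spearman rho is exactly 1 while Pearson r is not
  vals <- rbind(exact = as.numeric(y),
                curved = exp(as.numeric(y)),
                noise1 = rnorm(30), noise2 = rnorm(30),
                noise3 = rnorm(30))
  colnames(vals) <- d$sample_id
  m <- omics_matrix(vals, "genotype")

  pear <- correlation_select(m, d, "pearson", 5)
  expect_identical(pear$probe_ids[1], "exact")
  expect_gt(pear$scores[1], 0.999)

  spear <- correlation_select(m, d, "spearman", 5)
  r_curved_s <- spear$scores[spear$probe_ids == "curved"]
  r_curved_p <- pear$scores[pear$probe_ids == "curved"]
  expect_equal(r_curved_s, 1, tolerance = 1e-12)
  expect_lt(r_curved_p, 0.99)          # pearson penalizes curvature

  # positive affine rescaling of a probe leaves pearson selection intact
  m2 <- m
  m2$values["curved", ] <- 3 * m2$values["curved", ] + 10
  expect_identical(correlation_select(m2, d, "pearson", 5)$probe_ids,
                   pear$probe_ids)
})

test_that("correlation selection equals a brute-force per-probe oracle", {
  d <- balanced_design(8)
  withr::local_seed(19)
  vals <- matrix(rnorm(500 * 24), 500, 24,
                 dimnames = list(sprintf("p%03d", 1:500), d$sample_id))
  m <- omics_matrix(vals, "genotype")
  y <- as.numeric(tissue_code(d, d$sample_id))
  for (meth in c("pearson", "spearman")) {
    sel <- correlation_select(m, d, meth, 50)
    r <- vapply(rownames(vals),
                function(p) cor(vals[p, ], y, method = meth), numeric(1))
    oracle <- names(sort(r, decreasing = TRUE))[1:50]
    # same membership and same ranking
    expect_identical(sel$probe_ids,
                     names(r)[order(-r, names(r))][1:50])
    expect_setequal(sel$probe_ids, oracle)
  }
})

test_that("constant probes rank last in correlation selection", {
  d <- balanced_design(4)
  vals <- rbind(good = as.numeric(tissue_code(d, d$sample_id)),
                flat = rep(2, 12))
  colnames(vals) <- d$sample_id
  m <- omics_matrix(vals, "genotype")
  expect_message(sel <- correlation_select(m, d, "pearson", 2),
                 "undefined")
  expect_identical(sel$probe_ids, c("good", "flat"))
})

test_that("PLS ranks a dominant predictor first and matches mixOmics weights", {
  d <- balanced_design(10)
  y <- as.numeric(tissue_code(d, d$sample_id))
  withr::local_seed(29)
  vals <- rbind(signal = y + rnorm(30, 0, 0.05),
                matrix(rnorm(40 * 30), 40, 30,
                       dimnames = list(sprintf("n%02d", 1:40), NULL)))
  colnames(vals) <- d$sample_id
  m <- omics_matrix(vals, "genotype")
  sel <- pls_select(m, d, N = 5, n_components = 1)
  expect_identical(sel$probe_ids[1], "signal")

  # two-probe toy: the probe equal to y has the maximal weight
  toy_vals <- rbind(isy = y, other = rep(c(1, 2, 1), 10))
  colnames(toy_vals) <- d$sample_id
  toy <- omics_matrix(toy_vals, "genotype")
  expect_identical(pls_select(toy, d, 2, 1)$probe_ids[1], "isy")

  # independent oracle: first-component loading weights from mixOmics
  skip_if_not_installed("mixOmics")
  w_ref <- mixOmics::pls(t(vals), y, ncomp = 1, scale = FALSE,
                         mode = "regression")$loadings$X[, 1]
  full <- pls_select(m, d, N = nrow(vals), n_components = 1)
  w_ours <- full$scores[match(names(w_ref), full$probe_ids)]
  # same direction up to global sign and scale
  expect_equal(abs(unname(w_ref)) / max(abs(w_ref)),
               w_ours / max(w_ours), tolerance = 1e-6)

  expect_error(pls_select(m, d, 5, n_components = 30), "n_components")
})

test_that("permuting labels collapses PLS recovery of the planted probes", {
  d <- generate_paired_dataset(simulation_params(n_probes = 500,
                                                 n_signal = 25,
                                                 missing_rate = 0,
                                                 seed = 33))
  g <- d$genotype
  # with true labels the planted probes dominate the ranking
  real <- length(intersect(
    pls_select(g, d$design, N = 25, n_components = 1)$probe_ids,
    d$truth$signal_probe_ids))
  expect_gte(real, 23)
  # permuted labels: the class information is gone on average.  The
  # planted probes share one signal direction, so single permutations
  # whose shuffled y happens to tilt toward it still recover many of
  # them (and the inflated planted variance feeds a covariance
  # ranking); the permutation distribution is therefore wide, but its
  # center collapses far below the true-label recovery.
  hits <- withr::with_seed(13, vapply(1:100, function(i) {
    dp <- d$design
    dp$tissue <- dp$tissue[sample(nrow(dp))]
    sel <- pls_select(g, dp, N = 25, n_components = 1)
    length(intersect(sel$probe_ids, d$truth$signal_probe_ids))
  }, numeric(1)))
  expect_lt(mean(hits), 0.6 * real)
  expect_lt(median(hits), 0.5 * real)
})

test_that("compare_methods counts cross-modality overlaps per method", {
  d <- generate_paired_dataset(simulation_params(n_probes = 800,
                                                 n_signal = 40,
                                                 missing_rate = 0,
                                                 seed = 44))
  # identical views: every method's overlap equals N
  g <- d$genotype
  twin <- omics_matrix(g$values, "methylation")
  rep_same <- compare_methods(g, twin, d$design, N = 60)
  done <- rep_same$method %in% c("pca", "pearson", "spearman", "pls")
  expect_true(all(rep_same$overlap[done] == 60))
  expect_true(all(is.na(rep_same$overlap[!done])))  # stepwise/lasso "--"

  # independent noise: overlaps near the hypergeometric mean N^2/M
  null <- generate_paired_dataset(simulation_params(n_probes = 2000,
                                                    n_signal = 0,
                                                    missing_rate = 0,
                                                    seed = 45))
  rep_null <- compare_methods(null$genotype, null$methylation,
                              null$design, N = 100)
  expect_true(all(rep_null$overlap[done] < 30))   # mean 5, far from 100

  path <- withr::local_tempfile(fileext = ".tsv")
  write_comparison(rep_same, path)
  tab <- read.delim(path)
  expect_identical(tab$overlap[tab$method == "lasso"], "--")
})

test_that("planted-signal data put every selector near full recovery, PCA included", {
  d <- generate_paired_dataset(simulation_params(n_probes = 2000,
                                                 n_signal = 50,
                                                 seed = 46))
  g0 <- substitute_missing_with_zero(d$genotype)
  m0 <- substitute_missing_with_zero(d$methylation)
  rep_sig <- compare_methods(g0, m0, d$design, N = 100)
  ov <- setNames(rep_sig$overlap, rep_sig$method)
  expect_gte(ov[["pca"]], 45)
  expect_gte(ov[["pearson"]], 45)
})
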