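test_that("selection intersection is exact and lexicographically ordered", {
  a <- selection <- c("p3", "p1", "p2")
  expect_identical(intersect_selections(a, a), c("p1", "p2", "p3"))
  expect_identical(intersect_selections(c("p1", "p2"), c("p3", "p4")),
                   character(0))
  expect_identical(intersect_selections(c("z", "b", "a"), c("a", "z")),
                   c("a", "z"))
})

test_that("overlap tail probability matches exhaustive enumeration for small M", {
  for (obs in 0:3) {
    expect_equal(overlap_pvalue(10, 3, 3, obs),
                 enum_overlap_tail(10, 3, 3, obs), tolerance = 1e-12)
  }
  expect_equal(overlap_pvalue(12, 4, 5, 2), enum_overlap_tail(12, 4, 5, 2),
               tolerance = 1e-12)
})

test_that("overlap tail is 1 at zero, monotone in observed, valid in log space", {
  expect_identical(overlap_pvalue(1000, 50, 60, 0), 1)
  p <- vapply(0:50, function(o) overlap_pvalue(1000, 50, 60, o),
              numeric(1))
  expect_true(all(diff(p) <= 0))
  # log-space survives far past double underflow of the density product
  lp <- overlap_pvalue(250000, 300, 300, 300, log = TRUE)
  expect_true(is.finite(lp) && lp < -2000)
  expect_error(overlap_pvalue(10, 3, 3, 4), "inconsistent")
  expect_error(overlap_pvalue(10, 12, 3, 1), "inconsistent")
})

test_that("pairwise class t-tests match a manual Welch oracle", {
  probes <- c("flat", "up")
  fx <- class_matrix(probes, list(c(2, 2, 2), c(1, 2, 3)), n = 10,
                     sd = 0.3, seed = 31)
  res <- pairwise_class_ttests(fx$m, fx$design, probes)
  tab <- res$table

  # oracle: Welch one-sided p from first principles for one comparison
  cls <- tissue_of(fx$design, sample_ids(fx$m))
  hi <- fx$m$values["up", cls == "tumor"]
  lo <- fx$m$values["up", cls == "normal"]
  se <- sqrt(var(hi) / 10 + var(lo) / 10)
  df <- se^4 / ((var(hi) / 10)^2 / 9 + (var(lo) / 10)^2 / 9)
  p_manual <- pt((mean(hi) - mean(lo)) / se, df, lower.tail = FALSE)
  expect_equal(tab$p_normal_vs_tumor[tab$probe_id == "up"], p_manual,
               tolerance = 1e-12)

  # flat probe: raw one-sided p near 0.5 per comparison, fails
  flat_p <- unlist(tab[tab$probe_id == "flat",
                       c("p_normal_vs_tumor", "p_blood_vs_tumor",
                         "p_blood_vs_normal")])
  expect_true(all(flat_p > 0.05))
  expect_false(tab$pass[tab$probe_id == "flat"])
  expect_true(tab$pass[tab$probe_id == "up"])
  expect_identical(res$surviving_probe_ids, "up")
})

test_that("strong planted ordering passes; the reverse direction fails it", {
  fx <- class_matrix(c("inc"), list(c(1, 2, 3)), n = 30, sd = 0.1,
                     seed = 17)
  up <- pairwise_class_ttests(fx$m, fx$design, "inc",
                              direction = "increasing")
  expect_true(up$table$pass)
  down <- pairwise_class_ttests(fx$m, fx$design, "inc",
                                direction = "decreasing")
  expect_false(down$table$pass)
  expect_true(all(unlist(down$table[, 2:4]) > 0.95))
})

test_that("adjustment is joint, order-preserving and equals brute-force BH", {
  withr::local_seed(23)
  probes <- sprintf("p%02d", 1:20)
  fx <- class_matrix(probes,
                     replicate(20, cumsum(runif(3, 0, 0.5)),
                               simplify = FALSE),
                     n = 6, sd = 0.4, seed = 23)
  res <- pairwise_class_ttests(fx$m, fx$design, probes)
  raw <- as.matrix(res$table[, 2:4])
  adj <- as.matrix(res$table[, 5:7])
  expect_true(all(adj >= raw - 1e-15))
  expect_equal(as.vector(adj), bh_stepup(as.vector(raw)),
               tolerance = 1e-12)
  # order preservation
  o <- order(as.vector(raw))
  expect_true(all(diff(as.vector(adj)[o]) >= -1e-15))

  bonf <- pairwise_class_ttests(fx$m, fx$design, probes,
                                adjust = "bonferroni")
  expect_equal(as.vector(as.matrix(bonf$table[, 5:7])),
               pmin(as.vector(raw) * 60, 1), tolerance = 1e-12)
})

test_that("zero-variance probes are flagged untestable and never pass", {
  fx <- class_matrix(c("ok"), list(c(1, 2, 3)), n = 5, sd = 0.1,
                     seed = 2)
  vals <- rbind(fx$m$values, const = rep(1, 15))
  m <- omics_matrix(vals, "genotype")
  expect_message(res <- pairwise_class_ttests(m, fx$design,
                                              c("ok", "const")),
                 "untestable")
  expect_true(res$table$untestable[res$table$probe_id == "const"])
  expect_false(res$table$pass[res$table$probe_id == "const"])
})

test_that("modality bias test recovers a planted offset and is null at equality", {
  d <- balanced_design(10)
  withr::local_seed(41)
  probes <- sprintf("p%03d", 1:50)
  g <- matrix(rnorm(50 * 30, 2, 0.2), 50, 30,
              dimnames = list(probes, d$sample_id))
  gm <- omics_matrix(g, "genotype")

  # methylation identical to genotype: no bias, p = 0.5 (unpaired; the
  # paired difference vector is identically zero, hence untestable)
  same <- omics_matrix(g, "methylation")
  eq <- modality_bias_test(gm, same, probes, d, paired = FALSE)
  expect_equal(eq$p_value, rep(0.5, 3), tolerance = 1e-9)
  expect_error(modality_bias_test(gm, same, probes, d), "untestable")

  off <- omics_matrix(g - 0.4 + rnorm(length(g), 0, 0.05), "methylation")
  res <- modality_bias_test(gm, off, probes, d)
  expect_identical(res$class, c("blood", "normal", "tumor"))
  expect_true(all(res$genotype_mean > res$methylation_mean))
  expect_true(all(res$p_value < 1e-10))

  expect_error(modality_bias_test(gm, off, character(0), d), "empty")
})

test_that("a single cell is untestable for the bias test", {
  d <- sample_design(c("s1", "s2", "s3"), c("u1", "u1", "u1"),
                     c("blood", "normal", "tumor"))
  g <- tiny_matrix(c(1, 2, 3), "p1", c("s1", "s2", "s3"), "genotype")
  m <- tiny_matrix(c(0, 1, 2), "p1", c("s1", "s2", "s3"), "methylation")
  expect_error(modality_bias_test(g, m, "p1", d), "untestable")
})

test_that("resampling null is seeded, bounded and collapses at one iteration", {
  d <- generate_paired_dataset(simulation_params(n_probes = 300,
                                                 n_signal = 0,
                                                 seed = 6))
  r1 <- resampling_null(d$genotype, d$methylation, 20, 25, d$design,
                        seed = 9)
  r2 <- resampling_null(d$genotype, d$methylation, 20, 25, d$design,
                        seed = 9)
  expect_identical(r1$table, r2$table)
  expect_true(all(r1$table$lower_bound <= r1$table$upper_bound))
  expect_true(all(r1$table$n_significant <= 25))

  one <- resampling_null(d$genotype, d$methylation, 20, 1, d$design,
                         seed = 2)
  expect_equal(one$table$lower_bound, one$table$upper_bound)

  expect_error(resampling_null(d$genotype, d$methylation, 400, 5,
                               d$design), "n_snps")
  expect_error(resampling_null(d$genotype, d$methylation, 20, 0,
                               d$design), "n_iter")
})
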