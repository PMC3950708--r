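test_that("multinomial log-likelihood matches the direct sum", {
  x <- pattern_counts(c(595, 210, 195))
  expect_equal(multinomial_loglik(x, 0.3, 1),
               595 * log(0.595) + 210 * log(0.21) + 195 * log(0.195),
               tolerance = 1e-10)
  # class with positive count but zero probability
  expect_warning(ll <- multinomial_loglik(pattern_counts(c(10, 5, 1)), 0, 1),
                 "zero model probability")
  expect_identical(ll, -Inf)
})

test_that("the published estimates sit near the optimum of the surface", {
  counts <- stomach_pattern_counts("normal")
  at_paper <- multinomial_loglik(counts, 0.0028, 0.7134)
  expect_gt(at_paper, multinomial_loglik(counts, 0.01, 0.7134))
  expect_gt(at_paper, multinomial_loglik(counts, 0.0028, 3))
})

test_that("ML fit reproduces the stomach-cancer estimates", {
  fn <- fit_ml(stomach_pattern_counts("normal"))
  ft <- fit_ml(stomach_pattern_counts("tumor"))
  expect_true(fn$converged)
  expect_true(ft$converged)
  # point estimates: published values to the printed rounding for m, and
  # within the flat likelihood ridge (<< 1 SE) for theta
  expect_lt(abs(fn$m_hat - 0.0028), 1e-4)
  expect_equal(fn$theta_hat, 0.7134, tolerance = 0.02)
  expect_lt(abs(ft$m_hat - 0.0037), 1e-4)
  expect_equal(ft$theta_hat, 1.4750, tolerance = 0.02)
  # standard errors to one significant figure of the published ones
  expect_equal(signif(fn$se_m, 1), 0.0002)
  expect_equal(signif(fn$se_theta, 1), 0.1)
  expect_equal(signif(ft$se_m, 1), 0.0003)
  expect_equal(signif(ft$se_theta, 1), 0.2)
})

test_that("ML fit recovers simulated truth within sampling error", {
  set.seed(31)
  sim <- simulate_dataset(sim_config(0.3, 0.1, n_genes = 10000, seed = 31))
  fit <- fit_ml(sim$counts)
  expect_lt(abs(fit$m_hat - 0.3), 3 * fit$se_m)
  expect_lt(abs(fit$theta_hat - 0.1), 3 * fit$se_theta)
})

test_that("degenerate all-zero counts hit the boundary with a warning", {
  expect_warning(fit <- fit_ml(pattern_counts(c(1000, 0, 0, 0, 0, 0))),
                 "boundary")
  expect_lte(fit$m_hat, 1e-5)
  expect_false(fit$converged)
})

test_that("expected duplication/deletion probabilities follow the formulas", {
  expect_equal(round(expected_duplication_probability(0.0028, 0.7134), 4),
               0.0012)
  expect_equal(expected_duplication_probability(0.5, 1e-9), 0,
               tolerance = 1e-8)
  expect_equal(expected_duplication_probability(0.37, 1e9), 0.37,
               tolerance = 1e-6)
  expect_equal(expected_deletion_probability(0.0028, 0.7134),
               (1 - 0.0028) * 0.7134 / 1.7134, tolerance = 1e-12)
  expect_equal(expected_deletion_probability(1, 2), 0)
  expect_equal(expected_deletion_probability(0, 1), 0.5)
  # m <-> 1 - m symmetry
  expect_equal(expected_deletion_probability(0.2, 0.7),
               expected_duplication_probability(0.8, 0.7))
})

test_that("expected changes per gene equal the pairwise discordance", {
  ch <- expected_changes_per_gene(0.3, 1)
  expect_equal(unname(ch["directional"]), 0.105)
  expect_equal(unname(ch["total"]), pairwise_pattern_probs(0.3, 1)[2])
  expect_equal(unname(expected_changes_per_gene(0, 5)), c(0, 0))
  expect_equal(unname(expected_changes_per_gene(1, 5)), c(0, 0))
  expect_equal(round(expected_changes_per_gene(0.0028, 0.7134)[["directional"]],
                     4), 0.0012)
})

test_that("goodness-of-fit test behaves as Pearson chi-square with df = n", {
  x <- pattern_counts(c(500, 300, 200))
  g <- gof_test(x, c(500, 300, 200))
  expect_equal(g$statistic, 0)
  expect_equal(g$p.value, 1)
  expect_equal(g$df, 2)
  # agrees with stats::chisq.test given the same expected probabilities
  ref <- suppressWarnings(stats::chisq.test(x$x, p = c(0.5, 0.3, 0.2)))
  g2 <- gof_test(x, x$N * c(0.5, 0.3, 0.2))
  expect_equal(g2$statistic, unname(ref$statistic))
  expect_equal(g2$p.value, ref$p.value)
  expect_error(gof_test(x, c(500, 300, 0)), "pool")
  expect_error(gof_test(x, c(1, 2)), "same 0..n")
})

test_that("gof on the printed rounded expected counts matches the published p", {
  # using the published rounded expected counts directly
  g_normal <- gof_test(stomach_pattern_counts("normal"),
                       c(20880, 44.6, 24.1, 17.8, 15.6, 17.6))
  expect_lt(abs(g_normal$p.value - 0.8283), 0.01)
  g_tumor <- gof_test(stomach_pattern_counts("tumor"),
                      c(20798, 103.2, 46.4, 26.9, 16.4, 8.9))
  expect_lt(abs(log10(g_tumor$p.value) - log10(7.3e-07)), 1)
})

test_that("counts round-trip through the two-column TSV format", {
  x <- stomach_pattern_counts("tumor")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pattern_counts(x, path)
  expect_equal(read_pattern_counts(path), x)
})
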