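test_that("paired pattern counting enumerates (normal, tumor) cells", {
  pc <- count_paired_patterns(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(unlist(pc[c("n00", "n01", "n10", "n11")]),
               c(n00 = 1, n01 = 1, n10 = 1, n11 = 1))
  pc0 <- count_paired_patterns(rep(0, 21000), rep(0, 21000))
  expect_equal(pc0$n00, 21000)
  expect_equal(pc0$n01 + pc0$n10 + pc0$n11, 0)
  expect_error(count_paired_patterns(c(0, 1), c(0, 1, 0)), "same length")
  expect_error(count_paired_patterns(c(0, 2), c(0, 1)), "0/1")
})

test_that("patient S1 of the study fixture carries 64 tumor duplications", {
  dm <- stomach_duplication_matrix()
  pc <- count_paired_patterns(dm$data[, "S1_normal"], dm$data[, "S1_tumor"])
  expect_equal(pc$n01 + pc$n11, 64)
})

test_that("branch estimation inverts the transition probabilities exactly", {
  # forward-computed from (m_e = 0.01, T_e = 0.25), then inverted
  P <- transition_matrix(0.01, 0.25)
  n0 <- 1e7
  n1 <- 1e7
  pc <- structure(list(n00 = round(n0 * P[1, 1]), n01 = round(n0 * P[1, 2]),
                       n10 = round(n1 * P[2, 1]), n11 = round(n1 * P[2, 2]),
                       n0 = n0, n1 = n1), class = "paired_counts")
  est <- estimate_branch(pc)
  expect_true(est$valid)
  expect_equal(est$m_e, 0.01, tolerance = 1e-4)
  expect_equal(est$T_e, 0.25, tolerance = 1e-4)
  # roundtrip identity on (p01, p10) in the valid region
  set.seed(41)
  for (i in 1:20) {
    p01 <- runif(1, 0, 0.5)
    p10 <- runif(1, 0, 0.99 - p01)
    pc <- structure(list(n00 = 0, n01 = 0, n10 = 0, n11 = 0,
                         n0 = 1, n1 = 1), class = "paired_counts")
    pc$n01 <- p01; pc$n0 <- 1
    pc$n10 <- p10; pc$n1 <- 1
    est <- estimate_branch(pc)
    if (!est$valid) next
    Pf <- transition_matrix(est$m_e, est$T_e)
    expect_equal(Pf[1, 2], p01, tolerance = 1e-12)
    expect_equal(Pf[2, 1], p10, tolerance = 1e-12)
  }
})

test_that("empirical frequencies and their binomial SEs follow definitions", {
  pc <- count_paired_patterns(
    c(rep(0, 20980), rep(1, 20)),
    c(rep(0, 20936), rep(1, 44), rep(0, 5), rep(1, 15)))
  expect_equal(pc$n00, 20936)
  expect_equal(pc$n01, 44)
  expect_equal(pc$n10, 5)
  expect_equal(pc$n11, 15)
  est <- estimate_branch(pc)
  expect_equal(est$p01_hat, 44 / 20980)
  expect_equal(est$p10_hat, 5 / 20)
  se <- binomial_se(pc)
  p <- 44 / 20980
  expect_equal(unname(se["se_p01"]), sqrt(p * (1 - p) / 20980))
  expect_equal(unname(se["se_p10"]), sqrt(0.25 * 0.75 / 20))
})

test_that("degenerate paired data yields flagged, not failing, estimates", {
  no_change <- count_paired_patterns(c(0, 0, 1), c(0, 0, 1))
  est <- estimate_branch(no_change)
  expect_false(est$valid)
  expect_equal(est$T_e, 0)
  all0 <- count_paired_patterns(c(0, 0, 0), c(0, 1, 0))
  est2 <- estimate_branch(all0)   # n1 = 0
  expect_false(est2$valid)
  expect_equal(est2$p01_hat, 1 / 3)
  expect_true(is.na(binomial_se(all0)["se_p10"]))
})

test_that("simulated extended branches are re-estimated within 3 SE", {
  set.seed(42)
  m_e <- 0.02
  T_e <- 0.6
  ext <- data.frame(m_e = rep(m_e, 2), T_e = rep(T_e, 2))
  sim <- simulate_dataset(sim_config(0.05, 0.5, n_genes = 2e5,
                                     n_individuals = 2, seed = 42,
                                     extended = ext))
  est <- estimate_branches(sim$matrix)
  P <- transition_matrix(m_e, T_e)
  for (i in 1:2) {
    expect_lt(abs(est$p01_hat[i] - P[1, 2]), 3 * est$se_p01[i])
    expect_lt(abs(est$p10_hat[i] - P[2, 1]), 3 * est$se_p10[i])
  }
})

test_that("deletion-dominant branches show p10 >> p01 (study pattern)", {
  est <- estimate_branches(stomach_duplication_matrix())
  expect_true(all(est$valid))
  expect_true(all(est$p10_hat > 10 * est$p01_hat))
})
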