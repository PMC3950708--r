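test_that("branch probability is the matching transition-matrix entry", {
  expect_equal(branch_probability(0, 0, 0.3, 0), 1)
  expect_equal(branch_probability(0, 1, 0.3, 1), 0.3 * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(branch_probability(1, 0, 0.42, 0.7),
               (1 - 0.42) * (1 - exp(-0.7)), tolerance = 1e-12)
  expect_error(branch_probability(2, 0, 0.3, 1), "0/1")
})

test_that("joint probability with internals given multiplies branch factors", {
  phy <- ape::read.tree(text = "(N1:1000,N2:1000);")
  tr <- dup_tree(phy, m = 0.3)
  # long branches: stationary root times two independent stationary tips
  lik <- gene_likelihood_given_internals(tr, c(N1 = 0, N2 = 0),
                                         internal_states = 0)
  expect_equal(lik, 0.7^3, tolerance = 1e-9)
  # zero-length branch joining unequal states is impossible
  phy0 <- ape::read.tree(text = "(N1:0,N2:0.5);")
  expect_equal(gene_likelihood_given_internals(dup_tree(phy0, 0.3),
                                               c(N1 = 1, N2 = 0),
                                               internal_states = 0), 0)
})

test_that("pruning equals brute-force enumeration over internal states", {
  set.seed(51)
  for (rep in 1:12) {
    ntip <- sample(3:5, 1)
    with_ext <- rep %% 2 == 0
    tr <- random_dup_tree(ntip, m = runif(1, 0.05, 0.95),
                          extended = with_ext)
    tips <- stats::setNames(rbinom(ntip, 1, 0.5), tr$phy$tip.label)
    tumors <- if (with_ext) {
      stats::setNames(rbinom(ntip, 1, 0.5), tr$phy$tip.label)
    } else NULL
    expect_equal(gene_likelihood(tr, tips, tumors),
                 brute_force_gene_likelihood(tr, tips, tumors),
                 tolerance = 1e-12)
  }
})

test_that("pattern probabilities sum to one over all observables", {
  set.seed(52)
  # normal tips only
  tr <- random_dup_tree(4, m = 0.27)
  total <- sum(vapply(all_patterns(tr$phy$tip.label),
                      function(p) gene_likelihood(tr, p), numeric(1)))
  expect_equal(total, 1, tolerance = 1e-12)
  # paired normal/tumor observations
  tr2 <- random_dup_tree(3, m = 0.6, extended = TRUE)
  combos <- expand.grid(n = seq_along(all_patterns(tr2$phy$tip.label)),
                        t = seq_along(all_patterns(tr2$phy$tip.label)))
  norm_pats <- all_patterns(tr2$phy$tip.label)
  total2 <- sum(vapply(seq_len(nrow(combos)), function(i) {
    gene_likelihood(tr2, norm_pats[[combos$n[i]]], norm_pats[[combos$t[i]]])
  }, numeric(1)))
  expect_equal(total2, 1, tolerance = 1e-12)
})

test_that("likelihood is invariant to the root position (reversibility)", {
  # same unrooted 3-tip metric tree, rooted on two different edges
  t1 <- dup_tree(ape::read.tree(text = "((N1:0.3,N2:0.5):0.2,N3:0.6);"),
                 m = 0.35)
  t2 <- dup_tree(ape::read.tree(text = "((N2:0.5,N3:0.8):0.15,N1:0.15);"),
                 m = 0.35)
  for (p in all_patterns(c("N1", "N2", "N3"))) {
    expect_equal(gene_likelihood(t1, p), gene_likelihood(t2, p),
                 tolerance = 1e-12)
  }
})

test_that("pairwise tree likelihood integrates to the coalescent closed form", {
  # two tips at distance 2t from each other, t ~ Exp(2/theta): averaging the
  # discordant-pair likelihood over t recovers p_1 / 2 = theta m(1-m)/(theta+1)
  m <- 0.3
  theta <- 1.3
  f <- function(t) {
    vapply(t, function(ti) {
      phy <- ape::read.tree(text = sprintf("(N1:%.10f,N2:%.10f);", ti, ti))
      gene_likelihood(dup_tree(phy, m), c(N1 = 0, N2 = 1)) *
        (2 / theta) * exp(-2 * ti / theta)
    }, numeric(1))
  }
  got <- stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value
  expect_equal(got, theta * m * (1 - m) / (theta + 1), tolerance = 1e-8)
})

test_that("dataset log-likelihood sums per-gene logs and flags zeros", {
  tr <- random_dup_tree(3, m = 0.4)
  empty <- dataset_loglik(tr, matrix(0L, 0, 3))
  expect_equal(empty$loglik, 0)
  tips <- matrix(c(0L, 1L, 0L), 1, dimnames = list(NULL, tr$phy$tip.label))
  one <- dataset_loglik(tr, tips)
  expect_equal(one$loglik,
               log(gene_likelihood(tr, tips[1, ])), tolerance = 1e-12)
  # impossible gene under a zero-length cherry
  phy0 <- ape::read.tree(text = "((N1:0,N2:0):1,N3:1);")
  tr0 <- dup_tree(phy0, 0.3)
  bad <- matrix(c(1L, 0L, 0L), 1, dimnames = list(NULL, c("N1", "N2", "N3")))
  expect_warning(res <- dataset_loglik(tr0, bad), "zero pattern")
  expect_identical(res$loglik, -Inf)
  expect_equal(res$zero_genes, 1L)
})

test_that("the generating tree outscores a perturbed tree on simulated data", {
  set.seed(53)
  true_tree <- dup_tree(
    ape::read.tree(text = "((N1:0.4,N2:0.4):0.3,(N3:0.5,N4:0.5):0.2);"),
    m = 0.4)
  wrong_tree <- dup_tree(
    ape::read.tree(text = "((N1:0.4,N3:0.4):0.3,(N2:0.5,N4:0.5):0.2);"),
    m = 0.4)
  # simulate tip states on the fixed true tree by state propagation
  n_genes <- 400
  sim_gene <- function() {
    phy <- true_tree$phy
    po <- ape::reorder.phylo(phy, "postorder")
    states <- integer(4 + phy$Nnode)
    states[5] <- rbinom(1, 1, 0.4)  # root
    for (e in rev(seq_len(nrow(po$edge)))) {
      P <- transition_matrix(0.4, po$edge.length[e])
      states[po$edge[e, 2]] <- rbinom(1, 1, P[states[po$edge[e, 1]] + 1, 2])
    }
    states[1:4]
  }
  tips <- t(replicate(n_genes, sim_gene()))
  colnames(tips) <- true_tree$phy$tip.label
  expect_gt(dataset_loglik(true_tree, tips)$loglik,
            dataset_loglik(wrong_tree, tips)$loglik)
})
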