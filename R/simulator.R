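#' Simulation configuration
#'
#' Bundles the parameters of a coalescent duplication/deletion simulation.
#' Defaults mirror the stomach-cancer study design: five sampled genomes.
#'
#' @param m,theta model parameters (duplication fraction, population size
#'   parameter).
#' @param n_genes number of independent genes to simulate.
#' @param n_individuals number of sampled genomes (default 5, the study's
#'   design).
#' @param seed optional RNG seed, recorded in the output.
#' @param extended optional data.frame with columns `m_e`, `T_e` (one row
#'   per individual): tumor genomes are generated from each normal tip
#'   through an extended branch with those parameters.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(m, theta, n_genes, n_individuals = 5L, seed = NULL,
                       extended = NULL) {
  check_m(m)
  check_theta(theta)
  stopifnot(n_genes >= 1, n_individuals >= 2)
  if (!is.null(extended)) {
    stopifnot(all(c("m_e", "T_e") %in% names(extended)),
              nrow(extended) == n_individuals)
  }
  structure(list(m = m, theta = theta, n_genes = as.integer(n_genes),
                 n_individuals = as.integer(n_individuals), seed = seed,
                 extended = extended), class = "sim_config")
}

#' Simulate one coalescent gene tree
#'
#' Epoch representation of a ranked coalescent genealogy, forward in
#' time: while `k` lineages exist the epoch duration is
#' `Exponential(k (k - 1) / theta)` (pairwise coalescence rate
#' `2 / theta`, so `E(t_2) = theta / 2`), and at each split a uniformly
#' chosen lineage is duplicated (a uniformly random ranked topology).
#'
#' @param n number of sampled genomes, `>= 2`.
#' @param theta population size parameter.
#' @return an object of class `gene_tree`: list with `n`, `durations`
#'   (epoch lengths for `k = 2..n`) and `splits` (for `k = 2..n-1`, the
#'   index of the lineage copied at the end of the `k`-lineage epoch).
#' @export
simulate_gene_tree <- function(n, theta) {
  stopifnot(n >= 2)
  check_theta(theta)
  k <- 2:n
  structure(list(n = as.integer(n),
                 durations = stats::rexp(n - 1L, rate = k * (k - 1) / theta),
                 splits = if (n > 2L)
                   vapply(2:(n - 1L), function(k) sample.int(k, 1L),
                          integer(1L)) else integer()),
            class = "gene_tree")
}

#' Evolve one gene along a simulated gene tree
#'
#' The root state is drawn from the stationary distribution `(1 - m, m)`
#' and shared by the first two lineages; each lineage then flips
#' `0 -> 1` at rate `m` and `1 -> 0` at rate `1 - m` (scaled time,
#' `a + b = 1`).  Branch endpoints are sampled from the exact two-state
#' transition probabilities, so tip states have exactly the model's law.
#'
#' @param tree a [simulate_gene_tree()] result.
#' @param m duplication fraction.
#' @return integer vector of 0/1 states for the `n` sampled genomes.
#' @export
evolve_gene <- function(tree, m) {
  stopifnot(inherits(tree, "gene_tree"))
  check_m(m)
  states <- rep(stats::rbinom(1L, 1L, m), 2L)
  for (k in 2:tree$n) {
    f <- -expm1(-tree$durations[k - 1L])
    p1 <- ifelse(states == 1L, 1 - (1 - m) * f, m * f)
    states <- as.integer(stats::runif(k) < p1)
    if (k < tree$n) states <- c(states, states[tree$splits[k - 1L]])
  }
  states
}

# Vectorized tip-state simulation across genes: one genealogy per gene,
# identical in law to simulate_gene_tree + evolve_gene, but drawing all
# genes' epoch durations and transitions at once.
simulate_tip_states <- function(m, theta, n, n_genes) {
  st <- matrix(0L, n_genes, n)
  root <- stats::rbinom(n_genes, 1L, m)
  st[, 1L] <- root
  st[, 2L] <- root
  k <- 2L
  repeat {
    f <- -expm1(-stats::rexp(n_genes, rate = k * (k - 1) / theta))
    for (l in seq_len(k)) {
      p1 <- ifelse(st[, l] == 1L, 1 - (1 - m) * f, m * f)
      st[, l] <- as.integer(stats::runif(n_genes) < p1)
    }
    if (k == n) break
    st[, k + 1L] <- st[cbind(seq_len(n_genes),
                             sample.int(k, n_genes, replace = TRUE))]
    k <- k + 1L
  }
  st
}

#' Simulate a duplication dataset
#'
#' Simulates `n_genes` independent genes, each on its own coalescent
#' genealogy (gene trees vary across loci), under the two-state
#' duplication/deletion chain.  When `extended` branch parameters are
#' supplied, a tumor genome is generated from each normal tip through its
#' extended branch, yielding a paired matrix.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (a [duplication_matrix()]; tumor columns
#'   present iff `extended` was given), `counts` (normal-genome
#'   [pattern_counts()]) and `config`.
#' @examples
#' sim <- simulate_dataset(sim_config(0.01, 0.1, n_genes = 1000, seed = 1))
#' sim$counts
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_individuals
  normal <- simulate_tip_states(config$m, config$theta, n, config$n_genes)
  pats <- sprintf("P%d", seq_len(n))
  if (is.null(config$extended)) {
    data <- normal
    colnames(data) <- paste0(pats, "_normal")
    dm <- duplication_matrix(data, patient = pats,
                             role = rep("normal", n))
  } else {
    data <- matrix(0L, config$n_genes, 2L * n)
    for (i in seq_len(n)) {
      P <- transition_matrix(config$extended$m_e[i], config$extended$T_e[i])
      p1 <- P[normal[, i] + 1L, 2L]
      data[, 2L * i - 1L] <- normal[, i]
      data[, 2L * i] <- as.integer(stats::runif(config$n_genes) < p1)
    }
    dm <- duplication_matrix(data, patient = rep(pats, each = 2L),
                             role = rep(c("normal", "tumor"), n))
  }
  list(matrix = dm,
       counts = pattern_counts(tabulate(rowSums(normal) + 1L, n + 1L)),
       config = config)
}

#' Parameter-recovery experiment
#'
#' For each `(m, theta)` setting and each gene count, simulates
#' `replicates` independent datasets, fits each by [fit_ml()], and
#' reports the root-mean-square error
#' `RMSE = sqrt(mean((estimate - truth)^2))` per parameter.  Replicate
#' seeds are derived deterministically from `seed`.
#'
#' @param settings list of `c(m, theta)` pairs; defaults to the four
#'   benchmark settings `(0.01, 0.01)`, `(0.01, 0.1)`, `(0.3, 0.01)`,
#'   `(0.3, 0.1)`.
#' @param n_genes vector of dataset sizes; default `c(1000, 5000, 10000)`.
#' @param replicates simulations per cell (default 10).
#' @param n_individuals sampled genomes per dataset (default 5).
#' @param seed root RNG seed.
#' @return data.frame with columns `m`, `theta`, `n_genes`, `rmse_m`,
#'   `rmse_theta`, `n_fit` (replicates that converged; failures are
#'   excluded with a warning).
#' @examples
#' \donttest{
#' recovery_experiment(n_genes = 1000, replicates = 3, seed = 1)
#' }
#' @export
recovery_experiment <- function(settings = list(c(0.01, 0.01), c(0.01, 0.1),
                                                c(0.3, 0.01), c(0.3, 0.1)),
                                n_genes = c(1000, 5000, 10000),
                                replicates = 10, n_individuals = 5,
                                seed = 1) {
  out <- list()
  cell <- 0L
  for (s in settings) for (G in n_genes) {
    cell <- cell + 1L
    est <- matrix(NA_real_, replicates, 2L)
    for (r in seq_len(replicates)) {
      set.seed((seed + 7919L * cell + r) %% .Machine$integer.max)
      x <- pattern_counts(tabulate(
        rowSums(simulate_tip_states(s[1L], s[2L], n_individuals, G)) + 1L,
        n_individuals + 1L))
      fit <- tryCatch(suppressWarnings(fit_ml(x)), error = function(e) NULL)
      if (!is.null(fit)) est[r, ] <- c(fit$m_hat, fit$theta_hat)
    }
    ok <- stats::complete.cases(est)
    if (!all(ok)) {
      warning(sum(!ok), " replicate fit(s) failed at (m=", s[1L],
              ", theta=", s[2L], ", genes=", G, ")", call. = FALSE)
    }
    out[[cell]] <- data.frame(
      m = s[1L], theta = s[2L], n_genes = G,
      rmse_m = sqrt(mean((est[ok, 1L] - s[1L])^2)),
      rmse_theta = sqrt(mean((est[ok, 2L] - s[2L])^2)),
      n_fit = sum(ok))
  }
  do.call(rbind, out)
}
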