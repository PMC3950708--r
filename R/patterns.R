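#' Frequency-class probabilities under the coalescent duplication model
#'
#' For a gene evolving under the two-state duplication/deletion chain along
#' a random coalescent genealogy of `n` sampled genomes, `pattern_probs()`
#' returns the probabilities `p_0, ..., p_n` that exactly `i` of the `n`
#' genomes carry the duplication.  The genealogy is never sampled: both the
#' random topology and the exponential epoch durations are marginalized
#' exactly.
#'
#' The computation is a forward-in-time dynamic program over coalescent
#' epochs.  The root state is drawn from the stationary distribution
#' `(1 - m, m)` and is shared by the first two lineages.  While `k`
#' lineages exist, the number of lineages in the duplicated state performs
#' a birth-death walk (rates `(k - j) m` up, `j (1 - m)` down) for an
#' `Exponential(k (k - 1) / theta)` epoch; the distribution of the walk at
#' the end of the epoch is obtained in closed form through the resolvent
#' identity `E[exp(Q t)] = lambda (lambda I - Q)^{-1}` for
#' `t ~ Exp(lambda)`.  At each split a uniformly chosen lineage is copied,
#' which by exchangeability marginalizes the topology.
#'
#' Time is scaled so that the total flip rate per lineage is one
#' (`a + b = 1`), matching `theta = 4 u N_e` with `u` the per-gene change
#' rate; the pairwise coalescence rate is then `2 / theta`.
#'
#' @param m stationary duplication fraction, in `[0, 1]`.
#' @param theta population size parameter `4 u N_e`, positive.
#' @param n number of sampled genomes, an integer `>= 2`.
#' @return numeric vector `p` of length `n + 1`, `p[i + 1] = p_i`,
#'   non-negative and summing to one.
#' @examples
#' pattern_probs(0.3, 1, 2)   # equals pairwise_pattern_probs(0.3, 1)
#' pattern_probs(0.0028, 0.7134, 5)
#' @seealso [pairwise_pattern_probs()] for the closed-form two-genome case,
#'   [epoch_resolvent()] for the inner step.
#' @export
pattern_probs <- function(m, theta, n) {
  check_m(m)
  check_theta(theta)
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 2) {
    stop("'n' must be a single integer >= 2", call. = FALSE)
  }
  n <- as.integer(n)
  v <- numeric(3L)
  v[1L] <- 1 - m
  v[3L] <- m
  for (k in 2:n) {
    v <- epoch_resolvent(v, k, m, theta)
    if (k < n) v <- split_lineage_distribution(v, k)
  }
  v
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta <= 0) {
    stop("'theta' must be a single positive value", call. = FALSE)
  }
  theta
}

#' Closed-form frequency-class probabilities for two genomes
#'
#' For `n = 2` the coalescent marginalization has the closed form
#' \deqn{p_0 = (1-m)^2 + m(1-m)/(\theta+1),\quad
#'       p_1 = 2\theta m(1-m)/(\theta+1),\quad
#'       p_2 = m^2 + m(1-m)/(\theta+1).}
#' These are used as an independent check of [pattern_probs()].
#'
#' @inheritParams pattern_probs
#' @return numeric vector `c(p_0, p_1, p_2)`.
#' @examples
#' pairwise_pattern_probs(0.3, 1)  # (0.595, 0.210, 0.195)
#' @export
pairwise_pattern_probs <- function(m, theta) {
  check_m(m)
  check_theta(theta)
  shared <- m * (1 - m) / (theta + 1)
  c((1 - m)^2 + shared,
    2 * theta * m * (1 - m) / (theta + 1),
    m^2 + shared)
}

#' Evolve a one-count distribution through one coalescent epoch
#'
#' Given the distribution of the number `j` of lineages (out of `k`) in the
#' duplicated state at the start of an epoch, returns its distribution at
#' the end of the epoch, with the exponential epoch duration
#' `t_k ~ Exp(k (k - 1) / theta)` integrated out exactly via the resolvent
#' `lambda (lambda I - Q_k)^{-1}`.  `Q_k` is the tridiagonal generator of
#' the flip process: `j -> j + 1` at rate `(k - j) m`, `j -> j - 1` at rate
#' `j (1 - m)`.
#'
#' @param v probability vector over `j = 0..k` (length `k + 1`).
#' @param k number of extant lineages, an integer `>= 2`.
#' @inheritParams pattern_probs
#' @return probability vector of length `k + 1`.
#' @export
epoch_resolvent <- function(v, k, m, theta) {
  if (!is.numeric(v) || length(v) != k + 1L || any(v < -1e-12)) {
    stop("'v' must be a probability vector over 0..k", call. = FALSE)
  }
  lambda <- k * (k - 1) / theta
  j <- 0:k
  up <- (k - j) * m
  dn <- j * (1 - m)
  A <- diag(lambda + up + dn, k + 1L)          # lambda I - Q
  A[cbind(j[-(k + 1L)] + 1L, j[-(k + 1L)] + 2L)] <- -up[-(k + 1L)]
  A[cbind(j[-1L] + 1L, j[-1L])] <- -dn[-1L]
  w <- tryCatch(solve(t(A), lambda * v),
                error = function(e) stop("singular resolvent system (k = ", k,
                                         ", theta = ", theta, "): ",
                                         conditionMessage(e), call. = FALSE))
  pmax(as.numeric(w), 0)
}

# Split one uniformly chosen lineage of k into two copies: the one-count j
# maps to j + 1 with probability j / k, else stays.  Exchangeability makes
# the uniform choice exact topology marginalization.
split_lineage_distribution <- function(v, k) {
  j <- 0:k
  w <- numeric(k + 2L)
  w[j + 2L] <- v * (j / k)
  w[j + 1L] <- w[j + 1L] + v * (1 - j / k)
  w
}
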