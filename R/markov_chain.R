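#' Two-state duplication/deletion Markov chain
#'
#' A gene is either single-copy (state `0`) or duplicated (state `1`).
#' Duplication occurs at rate `a` and deletion at rate `b`.  Only the
#' relative rates are identifiable from presence/absence data, so the
#' package works throughout in the reparameterized coordinates
#' `m = a / (a + b)` (the stationary duplication fraction) and the scaled
#' elapsed time `T = (a + b) t`.
#'
#' @param a duplication rate per gene per unit time (>= 0).
#' @param b deletion rate per gene per unit time (>= 0); `a + b` must be
#'   positive.
#' @param t elapsed time (>= 0); may be a vector.
#'
#' @return `dupdel_rates()` returns a list with components `a`, `b`,
#'   `m = a/(a+b)` and a function `T(t) = (a+b) t` converting raw times to
#'   scaled branch lengths.
#' @examples
#' r <- dupdel_rates(a = 0.3, b = 0.7)
#' r$m          # 0.3
#' r$T(2)       # scaled length 2
#' @export
dupdel_rates <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (a < 0 || b < 0 || a + b <= 0) {
    stop("rates must satisfy a >= 0, b >= 0 and a + b > 0", call. = FALSE)
  }
  list(a = a, b = b, m = a / (a + b), T = function(t) {
    if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
    (a + b) * t
  })
}

check_m <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0 || m > 1) {
    stop("'m' must be a single value in [0, 1]", call. = FALSE)
  }
  m
}

check_T <- function(T) {
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T < 0) {
    stop("'T' must be a single non-negative value", call. = FALSE)
  }
  T
}

#' Transition probabilities of the duplication/deletion chain
#'
#' Computes the 2x2 matrix of transition probabilities over a scaled branch
#' of length `T = (a + b) t` under the two-state chain with stationary
#' duplication fraction `m`:
#' \deqn{P_{01}(T) = m (1 - e^{-T}), \quad P_{10}(T) = (1 - m)(1 - e^{-T}),}
#' with `P_00` and `P_11` the complements.  Rows index the parent state,
#' columns the child state, in the order (0, 1).  As `T` grows both rows
#' converge to the stationary distribution `(1 - m, m)`.
#'
#' @param m stationary duplication fraction, in `[0, 1]`.
#' @param T scaled branch length, `>= 0`.
#' @return a 2x2 row-stochastic matrix with dimnames `c("0", "1")`.
#' @examples
#' transition_matrix(0.3, 0)    # identity
#' transition_matrix(0.3, 1e3)  # both rows ~ (0.7, 0.3)
#' @seealso [stationary_distribution()], [reversibility_residual()]
#' @export
transition_matrix <- function(m, T) {
  check_m(m)
  check_T(T)
  f <- -expm1(-T)  # 1 - exp(-T), accurate for small T
  P <- matrix(c(1 - m * f, (1 - m) * f,
                m * f,     1 - (1 - m) * f),
              nrow = 2L, dimnames = list(c("0", "1"), c("0", "1")))
  P
}

#' Stationary distribution of the duplication/deletion chain
#'
#' @inheritParams transition_matrix
#' @return named numeric vector `c("0" = 1 - m, "1" = m)`.
#' @examples
#' stationary_distribution(0.0028)
#' @export
stationary_distribution <- function(m) {
  check_m(m)
  c("0" = 1 - m, "1" = m)
}

#' Detailed-balance residual of the chain
#'
#' The chain is time reversible: the flux identity
#' `(1 - m) P_01(T) = m P_10(T)` holds for every branch length.  This
#' helper returns the (floating-point) residual of that identity, useful
#' as a numerical self-check.
#'
#' @inheritParams transition_matrix
#' @return the residual `(1 - m) P_01(T) - m P_10(T)`, zero up to
#'   floating-point error.
#' @export
reversibility_residual <- function(m, T) {
  P <- transition_matrix(m, T)
  (1 - m) * P["0", "1"] - m * P["1", "0"]
}
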