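#' Paired normal/tumor pattern counts for one patient
#'
#' Tallies genes by their (normal, tumor) duplication status: `n00`,
#' `n01`, `n10`, `n11`, where the first digit is the normal genome and the
#' second the tumor genome of the same patient.
#'
#' @param normal,tumor equal-length binary (0/1) vectors over genes.
#' @return an object of class `paired_counts` with the four cell counts
#'   plus the margins `n0 = n00 + n01` and `n1 = n10 + n11`.
#' @examples
#' count_paired_patterns(c(0, 0, 1, 1), c(0, 1, 0, 1))
#' @export
count_paired_patterns <- function(normal, tumor) {
  if (length(normal) != length(tumor)) {
    stop("'normal' and 'tumor' must have the same length", call. = FALSE)
  }
  if (!all(normal %in% c(0, 1)) || !all(tumor %in% c(0, 1))) {
    stop("states must be 0/1", call. = FALSE)
  }
  n01 <- sum(normal == 0 & tumor == 1)
  n10 <- sum(normal == 1 & tumor == 0)
  n11 <- sum(normal == 1 & tumor == 1)
  n00 <- length(normal) - n01 - n10 - n11
  structure(list(n00 = n00, n01 = n01, n10 = n10, n11 = n11,
                 n0 = n00 + n01, n1 = n10 + n11),
            class = "paired_counts")
}

#' @export
print.paired_counts <- function(x, ...) {
  cat(sprintf("Paired (normal,tumor) counts: 00=%d 01=%d 10=%d 11=%d\n",
              x$n00, x$n01, x$n10, x$n11))
  invisible(x)
}

#' Estimate tumor-branch parameters from paired counts
#'
#' Conditional on the normal state, transitions along the extended branch
#' leading to the tumor genome are binomial with probabilities
#' `p01 = m_e (1 - exp(-T_e))` and `p10 = (1 - m_e)(1 - exp(-T_e))`.
#' The empirical frequencies `p01_hat = n01 / n0` and `p10_hat = n10 / n1`
#' invert in closed form:
#' `T_e = -log(1 - p01_hat - p10_hat)`, `m_e = p01_hat / (p01_hat + p10_hat)`.
#'
#' @param counts a [count_paired_patterns()] object.
#' @return an object of class `branch_estimate` with `p01_hat`, `p10_hat`,
#'   `m_e`, `T_e`, `valid` and `reason`.  When the inversion is undefined
#'   (`n1 = 0`, no observed change, or `p01_hat + p10_hat >= 1`) the
#'   empirical frequencies are still reported with `valid = FALSE`.
#' @export
estimate_branch <- function(counts) {
  stopifnot(inherits(counts, "paired_counts"))
  p01 <- if (counts$n0 > 0) counts$n01 / counts$n0 else NA_real_
  p10 <- if (counts$n1 > 0) counts$n10 / counts$n1 else NA_real_
  out <- list(p01_hat = p01, p10_hat = p10, m_e = NA_real_, T_e = NA_real_,
              valid = FALSE, reason = "")
  if (counts$n0 == 0 || counts$n1 == 0) {
    out$reason <- "empty margin: m_e and T_e not identifiable"
  } else if (counts$n01 == 0 && counts$n10 == 0) {
    out$T_e <- 0
    out$reason <- "no observed change: T_e = 0, m_e undefined"
  } else if (p01 + p10 >= 1) {
    out$reason <- "p01 + p10 >= 1: branch length undefined"
  } else {
    out$m_e <- p01 / (p01 + p10)
    out$T_e <- -log1p(-(p01 + p10))
    out$valid <- TRUE
  }
  structure(out, class = "branch_estimate")
}

#' @export
print.branch_estimate <- function(x, ...) {
  cat(sprintf("Extended-branch estimate: p01=%.6g p10=%.6g", x$p01_hat,
              x$p10_hat))
  if (x$valid) cat(sprintf("  m_e=%.6g T_e=%.6g\n", x$m_e, x$T_e))
  else cat("  [", x$reason, "]\n", sep = "")
  invisible(x)
}

#' Binomial standard errors of the empirical transition frequencies
#'
#' `sqrt(p_hat (1 - p_hat) / n)` for each of `p01_hat` (denominator `n0`)
#' and `p10_hat` (denominator `n1`); `NA` when a denominator is zero.
#'
#' @param counts a [count_paired_patterns()] object.
#' @return named numeric vector `c(se_p01 = , se_p10 = )`.
#' @export
binomial_se <- function(counts) {
  stopifnot(inherits(counts, "paired_counts"))
  se1 <- if (counts$n0 > 0) {
    p <- counts$n01 / counts$n0
    sqrt(p * (1 - p) / counts$n0)
  } else NA_real_
  se2 <- if (counts$n1 > 0) {
    p <- counts$n10 / counts$n1
    sqrt(p * (1 - p) / counts$n1)
  } else NA_real_
  c(se_p01 = se1, se_p10 = se2)
}

#' Per-patient tumor-branch estimates for a duplication matrix
#'
#' Runs [count_paired_patterns()], [estimate_branch()] and [binomial_se()]
#' for every declared (normal, tumor) pair of a [duplication_matrix()].
#' Degenerate patients yield flagged rows rather than errors, so a batch
#' never aborts on one patient.
#'
#' @param x a [duplication_matrix()].
#' @return a data.frame with one row per patient: `patient`, the four cell
#'   counts, `p01_hat`, `p10_hat`, `se_p01`, `se_p10`, `m_e`, `T_e`,
#'   `valid`.
#' @examples
#' est <- estimate_branches(stomach_duplication_matrix())
#' @export
estimate_branches <- function(x) {
  stopifnot(inherits(x, "duplication_matrix"))
  pats <- patients(x)
  rows <- lapply(pats, function(p) {
    pc <- count_paired_patterns(x$data[, paste0(p, "_normal")],
                                x$data[, paste0(p, "_tumor")])
    be <- estimate_branch(pc)
    se <- binomial_se(pc)
    data.frame(patient = p, n00 = pc$n00, n01 = pc$n01, n10 = pc$n10,
               n11 = pc$n11, p01_hat = be$p01_hat, p10_hat = be$p10_hat,
               se_p01 = se[[1L]], se_p10 = se[[2L]],
               m_e = be$m_e, T_e = be$T_e, valid = be$valid)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
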