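#' Per-gene cancer-related duplication (or deletion) counts
#'
#' A cancer-related duplication for one patient is the pattern
#' (normal = 0, tumor = 1) at a gene: the duplication is present in the
#' tumor genome but absent from the same patient's normal genome.  In
#' deletion mode the pattern of interest is (normal = 1, tumor = 0).
#' `y` is the number of patients showing the pattern at each gene.
#'
#' @param x a [duplication_matrix()] with paired columns.
#' @param mode `"duplication"` or `"deletion"`.
#' @return list with `y` (named integer per gene) and `histogram`
#'   (gene counts over `y = 0..n_patients`).
#' @examples
#' h <- cancer_related_counts(stomach_duplication_matrix())$histogram
#' @export
cancer_related_counts <- function(x, mode = c("duplication", "deletion")) {
  mode <- match.arg(mode)
  nm <- role_matrix(x, "normal")
  tm <- role_matrix(x, "tumor")
  if (ncol(nm) != ncol(tm)) {
    stop("every patient needs both a normal and a tumor column",
         call. = FALSE)
  }
  y <- if (mode == "duplication") rowSums(nm == 0L & tm == 1L)
       else rowSums(nm == 1L & tm == 0L)
  y <- as.integer(y)
  names(y) <- rownames(x$data)
  list(y = y,
       histogram = stats::setNames(tabulate(y + 1L, ncol(nm) + 1L),
                                   0:ncol(nm)))
}

#' Upper-tail binomial probability of a cancer-related count
#'
#' `P(Y >= y)` under `Y ~ Binomial(n_patients, p)`, where `p` is the
#' baseline probability of the pattern in normal genomes (for
#' duplications, [expected_duplication_probability()] at the
#' normal-genome fit).  `P(Y >= 0) = 1`.
#'
#' @param y observed count(s), `0 <= y <= n_patients`; vectorized.
#' @param n_patients number of patients.
#' @param p baseline probability, in `(0, 1)`.
#' @return upper-tail probabilities.
#' @examples
#' binomial_upper_tail(2, 5, 0.0012)  # ~1.4e-05
#' @export
binomial_upper_tail <- function(y, n_patients, p) {
  if (any(y < 0) || any(y > n_patients) || any(y != round(y))) {
    stop("'y' must be integers in 0..n_patients", call. = FALSE)
  }
  if (p <= 0 || p >= 1) stop("'p' must be in (0, 1)", call. = FALSE)
  stats::pbinom(y - 1, n_patients, p, lower.tail = FALSE)
}

#' Bonferroni adjustment of per-level binomial tails
#'
#' Genes sharing a count `y` share a p-value, so adjustment operates on
#' levels.  Method `"global"` (the default for new data) multiplies each
#' level's p-value by the total number of genes tested, i.e. genes showing
#' the pattern at all (`y >= 1`).  Method `"per-level"` multiplies by the
#' number of genes observed at that level; it is the reconstruction that
#' reproduces the published adjusted values of the stomach-cancer table.
#' Adjusted values are truncated at 1.
#'
#' @param histogram gene counts over levels `y = 0..n` (named or not).
#' @param p_raw upper-tail p-values per level, same length.
#' @param method `"global"` or `"per-level"`.
#' @param alpha significance level for the calls.
#' @return data.frame with `y`, `count`, `p_raw`, `p_adj`, `significant`
#'   (level `y = 0` is never called).
#' @export
adjust_and_call <- function(histogram, p_raw,
                            method = c("global", "per-level"),
                            alpha = 0.05) {
  method <- match.arg(method)
  if (length(histogram) != length(p_raw)) {
    stop("'histogram' and 'p_raw' must align over levels 0..n",
         call. = FALSE)
  }
  y <- seq_along(histogram) - 1L
  mult <- if (method == "global") sum(histogram[y >= 1L]) else histogram
  p_adj <- pmin(p_raw * mult, 1)
  data.frame(y = y, count = as.integer(histogram), p_raw = p_raw,
             p_adj = p_adj, significant = y >= 1L & p_adj < alpha)
}

#' Identify genes associated with the tumor genomes
#'
#' Full pipeline: per-gene cancer-related counts, binomial upper-tail
#' p-values against a baseline probability, and Bonferroni adjustment.
#'
#' @param x a [duplication_matrix()].
#' @param baseline_p baseline pattern probability; either a number, or a
#'   `dupcoal_fit` of the normal genomes from which
#'   [expected_duplication_probability()] (or the deletion analogue) is
#'   evaluated and, by default, rounded to 4 decimals as the source
#'   analysis does.
#' @param mode `"duplication"` or `"deletion"`.
#' @param method adjustment method, see [adjust_and_call()].
#' @param alpha significance level.
#' @param round_baseline round a fit-derived baseline to 4 decimals.
#' @return list with `genes` (data.frame gene, y, p_raw, p_adj,
#'   significant for genes with `y >= 1`), `levels` (the
#'   [adjust_and_call()] table), `baseline_p` and `mode`.
#' @examples
#' fit <- fit_ml(stomach_pattern_counts("normal"))
#' assoc <- associate_genes(stomach_duplication_matrix(), fit)
#' sum(assoc$genes$significant)  # 9
#' @export
associate_genes <- function(x, baseline_p,
                            mode = c("duplication", "deletion"),
                            method = c("global", "per-level"),
                            alpha = 0.05, round_baseline = TRUE) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (inherits(baseline_p, "dupcoal_fit")) {
    baseline_p <- if (mode == "duplication") {
      expected_duplication_probability(baseline_p$m_hat, baseline_p$theta_hat)
    } else {
      expected_deletion_probability(baseline_p$m_hat, baseline_p$theta_hat)
    }
    if (round_baseline) baseline_p <- round(baseline_p, 4)
  }
  cr <- cancer_related_counts(x, mode)
  n_pat <- length(cr$histogram) - 1L
  p_raw_levels <- binomial_upper_tail(0:n_pat, n_pat, baseline_p)
  lev <- adjust_and_call(cr$histogram, p_raw_levels, method, alpha)
  keep <- cr$y >= 1L
  genes <- data.frame(gene = names(cr$y)[keep], y = cr$y[keep],
                      p_raw = p_raw_levels[cr$y[keep] + 1L],
                      p_adj = lev$p_adj[cr$y[keep] + 1L],
                      significant = lev$significant[cr$y[keep] + 1L],
                      row.names = NULL)
  genes <- genes[order(-genes$y, genes$gene), ]
  rownames(genes) <- NULL
  list(genes = genes, levels = lev, baseline_p = baseline_p, mode = mode)
}

#' Sensitivity of the association calls to baseline uncertainty
#'
#' Re-runs [associate_genes()] with the baseline probability evaluated at
#' the four corners of the `(m, theta)` 95% confidence box
#' (estimate +/- 2 SE), mirroring the robustness check of the source
#' analysis.
#'
#' @param x a [duplication_matrix()].
#' @param fit a `dupcoal_fit` of the normal genomes.
#' @inheritParams associate_genes
#' @return data.frame with one row per corner: `m`, `theta`,
#'   `baseline_p`, `n_significant`, `genes` (comma-separated).
#' @export
association_sensitivity <- function(x, fit,
                                    mode = c("duplication", "deletion"),
                                    method = c("global", "per-level"),
                                    alpha = 0.05) {
  stopifnot(inherits(fit, "dupcoal_fit"))
  mode <- match.arg(mode)
  method <- match.arg(method)
  corners <- expand.grid(
    m = pmin(pmax(fit$m_hat + c(-2, 2) * fit$se_m, 1e-9), 1 - 1e-9),
    theta = pmax(fit$theta_hat + c(-2, 2) * fit$se_theta, 1e-9))
  rows <- lapply(seq_len(nrow(corners)), function(i) {
    p <- if (mode == "duplication") {
      expected_duplication_probability(corners$m[i], corners$theta[i])
    } else {
      expected_deletion_probability(corners$m[i], corners$theta[i])
    }
    a <- associate_genes(x, p, mode, method, alpha)
    sig <- a$genes$gene[a$genes$significant]
    data.frame(m = corners$m[i], theta = corners$theta[i], baseline_p = p,
               n_significant = length(sig),
               genes = paste(sort(sig), collapse = ","))
  })
  do.call(rbind, rows)
}
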