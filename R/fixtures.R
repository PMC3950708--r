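#' Stomach-cancer study fixtures
#'
#' The raw genomes of the five-patient stomach-cancer study are not
#' publicly deposited; what survives are its printed summary tables.
#' These helpers return those summaries, and
#' [stomach_duplication_matrix()] deterministically expands them into a
#' complete synthetic gene-by-genome matrix that is simultaneously
#' consistent with all of them:
#' per-patient tumor duplication totals (64, 84, 57, 75, 72; 352 events),
#' the tumor and normal frequency-class counts, and the histogram of
#' cancer-related duplications (tumor-only, per gene) with its nine
#' significant genes.  The matrix is a reconstruction with the published
#' marginals, not the original data; per-patient normal totals and the
#' identity of non-significant genes are not recoverable and are assigned
#' deterministically.
#'
#' The normal frequency-class column is typographically damaged in the
#' source; `c(20885, 46, 23, 18, 10, 18)` is the unique reading that sums
#' to the 21 000 genes considered, and the tumor column is cross-validated
#' by the per-patient totals (`sum(i * x_i) = 352`).
#'
#' @param role `"normal"` or `"tumor"`.
#' @return `stomach_pattern_counts()`: a [pattern_counts()];
#'   `stomach_patient_totals()`: named integer vector of tumor
#'   duplication totals per patient; `stomach_assoc_histogram()`: counts
#'   of genes with `y = 1..5` cancer-related duplications;
#'   `stomach_significant_genes()`: the nine gene symbols;
#'   `stomach_duplication_matrix()`: a 21000 x 10 [duplication_matrix()].
#' @examples
#' stomach_pattern_counts("tumor")
#' @name stomach_fixtures
NULL

#' @rdname stomach_fixtures
#' @export
stomach_pattern_counts <- function(role = c("normal", "tumor")) {
  role <- match.arg(role)
  pattern_counts(switch(role,
    normal = c(20885, 46, 23, 18, 10, 18),
    tumor  = c(20803, 129, 26, 16, 7, 19)))
}

#' @rdname stomach_fixtures
#' @export
stomach_patient_totals <- function() {
  c(S1 = 64L, S2 = 84L, S3 = 57L, S4 = 75L, S5 = 72L)
}

#' @rdname stomach_fixtures
#' @export
stomach_assoc_histogram <- function() {
  stats::setNames(c(109L, 7L, 1L, 0L, 1L), 1:5)
}

#' @rdname stomach_fixtures
#' @export
stomach_significant_genes <- function() {
  c("CDH4", "CLPS", "CLSTN2", "EML5", "NPEPL1", "SENP5", "SPTB",
    "VAMP7", "XAGE-4")
}

#' @rdname stomach_fixtures
#' @export
stomach_duplication_matrix <- function() {
  n_genes <- 21000L
  pats <- names(stomach_patient_totals())
  np <- length(pats)

  # Per-gene specification: normal multiplicity i, tumor set composed of
  # r patients retained from the normal set plus y cancer-related ones.
  # The block sizes below are the unique-by-construction solution linking
  # the normal classes (46,23,18,10,18), tumor classes (129,26,16,7,19),
  # the cancer-related histogram (109,7,1,0,1) and 352 tumor events.
  blocks <- rbind(
    # i (normal), r (retained), y (tumor-only), count
    c(0, 0, 1, 86),   # tumor-only duplications
    c(0, 0, 2, 7),
    c(0, 0, 3, 1),
    c(0, 0, 5, 1),
    c(1, 0, 1, 23),   # normal duplication deleted, cancer-related elsewhere
    c(1, 0, 0, 13),   # normal duplication lost in tumor
    c(1, 1, 0, 10),
    c(2, 1, 0, 10),
    c(2, 2, 0, 13),
    c(3, 2, 0, 6),
    c(3, 3, 0, 12),
    c(4, 3, 0, 3),
    c(4, 4, 0, 7),
    c(5, 5, 0, 18))
  colnames(blocks) <- c("i", "r", "y", "count")

  spec <- blocks[rep(seq_len(nrow(blocks)), blocks[, "count"]), 1:3,
                 drop = FALSE]
  tumor_mult <- spec[, "r"] + spec[, "y"]

  normal <- matrix(0L, nrow(spec), np)
  tumor <- matrix(0L, nrow(spec), np)

  # Assign tumor columns greedily (largest remaining patient capacity
  # first) so that column sums hit the per-patient totals exactly.
  capacity <- as.integer(stomach_patient_totals())
  ord <- order(tumor_mult, decreasing = TRUE)
  cursor <- 0L  # deterministic cyclic pointer for unconstrained choices
  for (g in ord) {
    k <- tumor_mult[g]
    if (k == 0L) next
    chosen <- order(capacity, decreasing = TRUE)[seq_len(k)]
    capacity[chosen] <- capacity[chosen] - 1L
    tumor[g, chosen] <- 1L
    # retained duplications sit in both genomes of the same patient
    if (spec[g, "r"] > 0L) normal[g, chosen[seq_len(spec[g, "r"])]] <- 1L
  }
  stopifnot(all(capacity == 0L))

  # Remaining normal duplications (deleted in the tumor): any patients not
  # already carrying this gene's tumor duplication, chosen cyclically.
  for (g in seq_len(nrow(spec))) {
    extra <- spec[g, "i"] - spec[g, "r"]
    if (extra == 0L) next
    free <- which(tumor[g, ] == 0L & normal[g, ] == 0L)
    stopifnot(length(free) >= extra)
    pick <- free[((cursor + seq_len(extra) - 1L) %% length(free)) + 1L]
    cursor <- cursor + extra
    normal[g, pick] <- 1L
  }

  data <- matrix(0L, n_genes, 2L * np)
  data[seq_len(nrow(spec)), seq(1L, 2L * np, by = 2L)] <- normal
  data[seq_len(nrow(spec)), seq(2L, 2L * np, by = 2L)] <- tumor

  genes <- sprintf("gene_%05d", seq_len(n_genes))
  # the nine significant genes are the ones with y >= 2
  genes[which(spec[, "y"] >= 2L)] <- stomach_significant_genes()
  rownames(data) <- genes

  duplication_matrix(data,
                     patient = rep(pats, each = 2L),
                     role = rep(c("normal", "tumor"), np))
}
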