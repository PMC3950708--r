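#' Gene-by-genome duplication matrix
#'
#' A binary matrix with one row per gene and one column per sequenced
#' genome; `1` denotes duplication.  Columns come in (normal, tumor) pairs
#' per patient and are named `<patient>_normal` / `<patient>_tumor`.
#'
#' @param data integer 0/1 matrix, genes in rows (rownames are gene ids),
#'   samples in columns.
#' @param patient character vector, one patient id per column.
#' @param role character vector per column, `"normal"` or `"tumor"`.
#' @return an object of class `duplication_matrix` wrapping the validated
#'   matrix; columns are renamed `<patient>_<role>`.
#' @seealso [read_duplication_matrix()], [matrix_to_pattern_counts()]
#' @export
duplication_matrix <- function(data, patient, role) {
  data <- as.matrix(data)
  if (ncol(data) != length(patient) || ncol(data) != length(role)) {
    stop("'patient' and 'role' must have one entry per column", call. = FALSE)
  }
  if (!all(role %in% c("normal", "tumor"))) {
    stop("roles must be 'normal' or 'tumor'", call. = FALSE)
  }
  bad <- which(!(data %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(data))
    stop(sprintf("non-binary entry '%s' at gene '%s', column '%s'",
                 data[bad[1L]],
                 if (is.null(rownames(data))) rc[1L] else rownames(data)[rc[1L]],
                 paste0(patient[rc[2L]], "_", role[rc[2L]])), call. = FALSE)
  }
  if (is.null(rownames(data))) {
    rownames(data) <- sprintf("gene_%05d", seq_len(nrow(data)))
  }
  if (anyDuplicated(rownames(data))) {
    stop("duplicate gene id: ", rownames(data)[anyDuplicated(rownames(data))],
         call. = FALSE)
  }
  for (p in unique(patient[role == "tumor"])) {
    if (!any(patient == p & role == "normal")) {
      stop("tumor column for patient '", p, "' has no matching normal column",
           call. = FALSE)
    }
  }
  storage.mode(data) <- "integer"
  colnames(data) <- paste0(patient, "_", role)
  structure(list(data = data, patient = patient, role = role),
            class = "duplication_matrix")
}

#' @export
print.duplication_matrix <- function(x, ...) {
  cat("Duplication matrix:", nrow(x$data), "genes x", ncol(x$data),
      "genomes (", length(patients(x)), "patients )\n")
  cat("  duplications:", sum(x$data), "entries in",
      sum(rowSums(x$data) > 0), "genes\n")
  invisible(x)
}

#' @export
dim.duplication_matrix <- function(x) dim(x$data)

#' Patients declared in a duplication matrix
#' @param x a [duplication_matrix()].
#' @return character vector of patient ids (those with a normal column).
#' @export
patients <- function(x) {
  stopifnot(inherits(x, "duplication_matrix"))
  unique(x$patient[x$role == "normal"])
}

#' Submatrix of normal or tumor genomes
#' @param x a [duplication_matrix()].
#' @param role `"normal"` or `"tumor"`.
#' @return plain integer matrix, columns ordered by patient.
#' @export
role_matrix <- function(x, role = c("normal", "tumor")) {
  role <- match.arg(role)
  stopifnot(inherits(x, "duplication_matrix"))
  keep <- x$role == role
  m <- x$data[, keep, drop = FALSE]
  m[, order(x$patient[keep]), drop = FALSE]
}

#' Read and write duplication matrices as TSV
#'
#' The TSV has a `gene` column followed by one column per genome, named
#' `<patient>_<role>` with role `normal` or `tumor`; entries are 0/1.
#' `write_duplication_matrix()` and `read_duplication_matrix()` are exact
#' inverses.
#'
#' @param path file path.
#' @param x a [duplication_matrix()].
#' @return `read_duplication_matrix()` returns a [duplication_matrix()];
#'   the writer returns `path` invisibly.
#' @export
read_duplication_matrix <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         check.names = FALSE, colClasses = "character")
  if (names(d)[1L] != "gene") {
    stop("first column must be 'gene'", call. = FALSE)
  }
  samples <- names(d)[-1L]
  parts <- regmatches(samples, regexec("^(.+)_(normal|tumor)$", samples))
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop("column '", samples[which(bad)[1L]],
         "' is not named <patient>_<normal|tumor>", call. = FALSE)
  }
  data <- suppressWarnings(
    vapply(d[-1L], function(col) as.numeric(col), numeric(nrow(d))))
  if (nrow(d) == 1L) data <- matrix(data, nrow = 1L)
  rownames(data) <- d$gene
  duplication_matrix(data,
                     patient = vapply(parts, `[`, "", 2L),
                     role = vapply(parts, `[`, "", 3L))
}

#' @rdname read_duplication_matrix
#' @export
write_duplication_matrix <- function(x, path) {
  stopifnot(inherits(x, "duplication_matrix"))
  d <- data.frame(gene = rownames(x$data), x$data, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Frequency-class counts from a duplication matrix
#'
#' `x_i` is the number of genes duplicated in exactly `i` of the selected
#' genomes (normal or tumor columns).
#'
#' @param x a [duplication_matrix()].
#' @param role `"normal"` or `"tumor"`.
#' @return a [pattern_counts()] object over classes `0..n_patients`.
#' @examples
#' matrix_to_pattern_counts(stomach_duplication_matrix(), "tumor")
#' @export
matrix_to_pattern_counts <- function(x, role = c("normal", "tumor")) {
  m <- role_matrix(x, role)
  pattern_counts(tabulate(rowSums(m) + 1L, ncol(m) + 1L))
}

#' Filter junction calls into high-confidence duplication events
#'
#' A junction is accepted as a duplication call iff it has at least 10
#' supporting mate pairs, was successfully assembled de novo, maps with
#' both flank lengths at least 70, shows no repeat sequence on either
#' side, and covers at most two genes (junctions spanning more genes break
#' the gene-independence assumption and are excluded).  All bounds are
#' inclusive.
#'
#' @param records data.frame with columns `mate_pairs`, `assembled`
#'   (logical), `left_length`, `right_length`, `repeat_left`,
#'   `repeat_right` (logical), `genes_covered` (count).
#' @param keep_all if `TRUE` return all records with a logical `accepted`
#'   column instead of the accepted subset.
#' @return the accepted subset of `records` (default), or all records with
#'   an `accepted` column when `keep_all = TRUE`.
#' @export
filter_junctions <- function(records, keep_all = FALSE) {
  need <- c("mate_pairs", "assembled", "left_length", "right_length",
            "repeat_left", "repeat_right", "genes_covered")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("junction table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$mate_pairs < 0) || any(records$left_length < 0) ||
      any(records$right_length < 0) || any(records$genes_covered < 0)) {
    stop("counts and lengths must be non-negative", call. = FALSE)
  }
  ok <- records$mate_pairs >= 10 &
    as.logical(records$assembled) &
    records$left_length >= 70 &
    records$right_length >= 70 &
    !as.logical(records$repeat_left) &
    !as.logical(records$repeat_right) &
    records$genes_covered <= 2
  if (keep_all) {
    records$accepted <- ok
    records
  } else {
    records[ok, , drop = FALSE]
  }
}

#' Read a junction table from TSV
#' @param path file path; columns as in [filter_junctions()].
#' @return a data.frame.
#' @export
read_junctions <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t")
  for (col in c("assembled", "repeat_left", "repeat_right")) {
    if (col %in% names(d)) d[[col]] <- as.logical(d[[col]])
  }
  d
}
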