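#' Gene-by-sample expression matrix with a unit tag
#'
#' A thin container pairing a nonnegative numeric gene x sample matrix
#' with the unit of its values (`counts`, `FPKM`, `CPM` or `TPM`), so
#' that unit transforms can refuse mismatched input.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples
#'   in columns (unique colnames), all values `>= 0`.
#' @param unit One of `"counts"`, `"FPKM"`, `"CPM"`, `"TPM"`.
#' @return An object of class `expr_matrix`.
#' @examples
#' m <- matrix(c(5, 5, 2, 8), 2, dimnames = list(c("A", "B"), c("s1", "s2")))
#' expression_matrix(m, "FPKM")
#' @export
expression_matrix <- function(values, unit = c("counts", "FPKM", "CPM", "TPM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (!is.numeric(values)) abort("expression values must be numeric")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    abort("genes (rownames) must be present and unique")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    abort("samples (colnames) must be present and unique")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("expression values must be finite and >= 0")
  }
  if (unit == "counts" && any(abs(values - round(values)) > 1e-8)) {
    abort("unit 'counts' requires integer-valued data")
  }
  structure(list(values = values, unit = unit), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An `expr_matrix`.
#' @export
expr_unit <- function(x) x$unit

#' @rdname expression_matrix
#' @export
expr_genes <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
expr_samples <- function(x) colnames(x$values)

#' Read / write expression matrices as TSV
#'
#' The TSV schema has a first column headed `gene`; remaining columns are
#' sample identifiers holding numeric values.
#'
#' @param path File path.
#' @param unit Unit tag of the stored values.
#' @return `read_expression_tsv` returns an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, unit) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene") abort("first column of %s must be 'gene'", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene
  expression_matrix(m, unit)
}

#' @rdname read_expression_tsv
#' @param x An [expression_matrix()].
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene = rownames(x$values), x$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Shared column-normalization core for FPKM->TPM and counts->CPM: scale
# every sample column to sum 1e6, then add the offset.
column_normalize_1e6 <- function(values, offset, what) {
  csums <- colSums(values)
  bad <- csums <= 0
  if (any(bad)) {
    abort("zero %s column sum in sample(s): %s", what,
          paste(colnames(values)[bad], collapse = ", "))
  }
  sweep(values, 2L, csums, "/") * 1e6 + offset
}

#' Convert FPKM to offset TPM
#'
#' Transcripts per million are obtained by dividing each gene's FPKM by
#' the per-sample FPKM total and multiplying by one million; a small
#' offset (default 0.01) is then added so that zero values remain
#' strictly positive for downstream log/geometric-mean scoring. Because
#' the offset is added after the ratio step, scores computed on the
#' result are exactly invariant to per-sample rescaling of the input.
#'
#' @param matrix An [expression_matrix()] with unit `FPKM`.
#' @param offset Value added after normalization (default 0.01).
#' @return An [expression_matrix()] with unit `TPM`.
#' @examples
#' m <- expression_matrix(
#'   matrix(c(5, 5, 0, 10), 2, dimnames = list(c("A", "B"), c("s1", "s2"))),
#'   "FPKM")
#' fpkm_to_tpm(m)$values
#' @export
fpkm_to_tpm <- function(matrix, offset = 0.01) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$unit != "FPKM") {
    abort("fpkm_to_tpm() requires unit 'FPKM', got '%s'", matrix$unit)
  }
  assert_scalar_number(offset, "offset", 0)
  out <- column_normalize_1e6(matrix$values, offset, "FPKM")
  expression_matrix(out, "TPM")
}

#' Convert raw counts to offset CPM
#'
#' Counts per million per sample, plus a small offset (default 0.01) so
#' that zero counts remain strictly positive for geometric-mean scoring.
#'
#' @param matrix An [expression_matrix()] with unit `counts`.
#' @param offset Value added after normalization (default 0.01).
#' @return An [expression_matrix()] with unit `CPM`.
#' @export
counts_to_cpm <- function(matrix, offset = 0.01) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$unit != "counts") {
    abort("counts_to_cpm() requires unit 'counts', got '%s'", matrix$unit)
  }
  assert_scalar_number(offset, "offset", 0)
  out <- column_normalize_1e6(matrix$values, offset, "library")
  expression_matrix(out, "CPM")
}
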