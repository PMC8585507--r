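#' Named gene signature
#'
#' A named set of gene symbols scored by the geometric mean of their
#' offset TPM/CPM values, optionally with an alias map resolving
#' alternative symbols to one canonical symbol (e.g. CD25 -> IL2RA).
#'
#' @param name Signature name.
#' @param genes Character vector of gene symbols (nonempty, unique after
#'   alias resolution).
#' @param alias_map Named character vector mapping alternative symbols to
#'   canonical ones.
#' @return An object of class `gene_signature`.
#' @examples
#' gene_signature("demo", c("CD25", "CD69"), alias_map = c(CD25 = "IL2RA"))
#' @export
gene_signature <- function(name, genes, alias_map = character()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a nonempty string")
  }
  if (!is.character(genes) || !length(genes)) {
    abort("`genes` must be a nonempty character vector")
  }
  genes <- resolve_aliases(genes, alias_map)
  if (anyDuplicated(genes)) {
    abort("duplicate gene symbols after alias resolution: %s",
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  structure(list(name = name, genes = genes, alias_map = alias_map),
            class = "gene_signature")
}

resolve_aliases <- function(genes, alias_map) {
  if (!length(alias_map)) return(genes)
  hit <- genes %in% names(alias_map)
  genes[hit] <- unname(alias_map[genes[hit]])
  genes
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %s\n", x$name,
              paste(x$genes, collapse = ", ")))
  invisible(x)
}

#' Built-in signatures: TCR.strong and T activation
#'
#' `tcr_strong_signature()` returns the five-gene strong-TCR-signal
#' metric (TNFRSF4, ICOS, IRF8, TNIP3, STAT4): pharmacodynamic
#' correlates of anti-PD1 therapy combined with genes upregulated only in
#' clinical responders that also mark strong TCR signaling.
#' `t_activation_signature()` returns the canonical T-cell activation
#' comparator set (NR4A1, CD69, IL2RA, TNFRSF9); CD25 is accepted as an
#' alias of IL2RA.
#'
#' @return A [gene_signature()].
#' @examples
#' tcr_strong_signature()
#' @export
tcr_strong_signature <- function() {
  gene_signature("TCR.strong",
                 c("TNFRSF4", "ICOS", "IRF8", "TNIP3", "STAT4"))
}

#' @rdname tcr_strong_signature
#' @export
t_activation_signature <- function() {
  gene_signature("T.activation",
                 c("NR4A1", "CD69", "IL2RA", "TNFRSF9"),
                 alias_map = c(CD25 = "IL2RA"))
}

#' Geometric-mean signature score per sample
#'
#' For each sample, the score is the geometric mean of the expression
#' values of the signature genes:
#' \deqn{score_s = \exp\left(\frac{1}{k}\sum_{g} \ln v_{gs}\right)}
#' Values must be strictly positive (guaranteed by the 0.01 offset of
#' [fpkm_to_tpm()] / [counts_to_cpm()]). Signature genes absent from the
#' matrix are a hard error unless `allow_missing = TRUE`, in which case
#' scoring proceeds on the intersection and the dropped genes are
#' reported via a warning.
#'
#' @param matrix An [expression_matrix()] with unit `TPM` or `CPM`.
#' @param signature A [gene_signature()].
#' @param allow_missing Score on the gene intersection instead of
#'   erroring when signature genes are absent (default `FALSE`).
#' @return A tibble with columns `sample_id`, `signature`, `score`.
#' @examples
#' m <- expression_matrix(matrix(c(2, 4, 8, 16, 32), 5, 1,
#'   dimnames = list(c("A", "B", "C", "D", "E"), "s1")), "TPM")
#' signature_score(m, gene_signature("demo", LETTERS[1:5]))$score # 8
#' @export
signature_score <- function(matrix, signature, allow_missing = FALSE) {
  stopifnot(inherits(matrix, "expr_matrix"),
            inherits(signature, "gene_signature"))
  if (!matrix$unit %in% c("TPM", "CPM")) {
    abort("signature_score() expects TPM or CPM values, got '%s'; %s",
          matrix$unit, "apply fpkm_to_tpm() or counts_to_cpm() first")
  }
  vals <- matrix$values
  rownames(vals) <- resolve_aliases(rownames(vals), signature$alias_map)
  if (anyDuplicated(rownames(vals))) {
    abort("alias resolution produced duplicate gene rows: %s",
          paste(unique(rownames(vals)[duplicated(rownames(vals))]),
                collapse = ", "))
  }
  genes <- signature$genes
  missing <- setdiff(genes, rownames(vals))
  if (length(missing)) {
    if (!allow_missing) {
      abort("signature gene(s) not in matrix: %s",
            paste(missing, collapse = ", "))
    }
    warning(sprintf("scoring '%s' without missing gene(s): %s",
                    signature$name, paste(missing, collapse = ", ")),
            call. = FALSE)
    genes <- setdiff(genes, missing)
    if (!length(genes)) abort("no signature genes present in the matrix")
  }
  sub <- vals[genes, , drop = FALSE]
  if (any(sub <= 0)) {
    abort("signature_score() requires strictly positive values; %s",
          "use the offset transforms")
  }
  score <- exp(colMeans(log(sub)))
  tibble::tibble(sample_id = colnames(sub),
                 signature = signature$name,
                 score = unname(score))
}

#' Write signature scores as TSV
#'
#' @param scores Tibble from [signature_score()].
#' @param path Output path.
#' @export
write_score_tsv <- function(scores, path) {
  write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
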