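#' Differential-expression thresholds
#'
#' Inclusion rules for turning a DEG table into a gene set. Both
#' inequalities are strict: up-regulated sets keep genes with
#' `log2fc > lfc_min` and `padj < padj_max` (down-sets mirror the fold
#' change). Presets match the contrasts feeding signature derivation:
#'
#' * `deg_thresholds_human()` — human on-therapy contrasts:
#'   `log2fc > 0.5`, `padj < 0.1`.
#' * `deg_thresholds_mouse_dose()` — mouse high- vs low-dose 4 h
#'   contrast: `log2fc > 1`, `padj < 0.05`.
#' * `deg_thresholds_mouse_pd1()` — mouse anti-PD1 re-challenge
#'   contrast: `padj < 0.05` only (any positive fold change).
#'
#' @param lfc_min Minimum absolute log2 fold change (strict).
#' @param padj_max Maximum adjusted p (strict), in `(0, 1]`.
#' @param direction `"up"` or `"down"`.
#' @return An object of class `deg_thresholds`.
#' @export
deg_thresholds <- function(lfc_min, padj_max, direction = c("up", "down")) {
  direction <- match.arg(direction)
  assert_scalar_number(lfc_min, "lfc_min", 0)
  assert_scalar_number(padj_max, "padj_max", 0, upper = 1, strict_lower = TRUE)
  structure(list(lfc_min = lfc_min, padj_max = padj_max,
                 direction = direction),
            class = "deg_thresholds")
}

#' @rdname deg_thresholds
#' @export
deg_thresholds_human <- function() deg_thresholds(0.5, 0.1)

#' @rdname deg_thresholds
#' @export
deg_thresholds_mouse_dose <- function() deg_thresholds(1, 0.05)

#' @rdname deg_thresholds
#' @export
deg_thresholds_mouse_pd1 <- function() deg_thresholds(0, 0.05)

#' Read a DEG table (TSV: gene, log2fc, padj)
#'
#' @param path File path.
#' @return A tibble with columns `gene`, `log2fc`, `padj`.
#' @export
read_deg_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "padj")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort("DEG table %s missing column(s): %s", path,
          paste(miss, collapse = ", "))
  }
  tibble::as_tibble(df[need])
}

#' Threshold a DEG table into a gene set
#'
#' @param table Data frame with columns `gene`, `log2fc`, `padj`; one row
#'   per gene.
#' @param thresholds A [deg_thresholds()] object.
#' @return Character vector of gene symbols passing both strict
#'   inequalities.
#' @examples
#' tab <- data.frame(gene = c("A", "B"), log2fc = c(0.6, 0.5),
#'                   padj = c(0.05, 0.05))
#' threshold_deg(tab, deg_thresholds_human()) # "A" only: boundary excluded
#' @export
threshold_deg <- function(table, thresholds) {
  stopifnot(inherits(thresholds, "deg_thresholds"))
  if (NROW(table) == 0L) abort("DEG table is empty")
  need <- c("gene", "log2fc", "padj")
  miss <- setdiff(need, names(table))
  if (length(miss)) abort("DEG table missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(table$gene)) {
    abort("duplicate genes in DEG table: %s",
          paste(unique(table$gene[duplicated(table$gene)]), collapse = ", "))
  }
  if (any(table$padj < 0 | table$padj > 1, na.rm = TRUE)) {
    abort("`padj` values must lie in [0, 1]")
  }
  keep <- !is.na(table$log2fc) & !is.na(table$padj) &
    table$padj < thresholds$padj_max &
    (if (thresholds$direction == "up") table$log2fc > thresholds$lfc_min
     else table$log2fc < -thresholds$lfc_min)
  table$gene[keep]
}

#' Built-in mouse-to-human symbol overrides
#'
#' Explicit overrides layered on top of the default case-mapping rule of
#' [map_orthologs()]. The default table is an identity-style map for the
#' signature genes (whose mouse symbols differ from human only by case).
#'
#' @return Named character vector, mouse symbol -> human symbol.
#' @export
ortholog_overrides <- function() {
  c(Tnfrsf4 = "TNFRSF4", Icos = "ICOS", Irf8 = "IRF8", Tnip3 = "TNIP3",
    Stat4 = "STAT4", Il2ra = "IL2RA", Nr4a1 = "NR4A1", Cd69 = "CD69",
    Tnfrsf9 = "TNFRSF9", Cd5 = "CD5", Gpr65 = "GPR65", Gcnt1 = "GCNT1")
}

#' Map mouse gene symbols to human symbols
#'
#' Mapping is a static table plus a case rule, for reproducibility: a
#' symbol maps through the explicit `overrides` first; otherwise, if it
#' is pure-case-mappable (a conventional symbol that becomes its human
#' ortholog by uppercasing), it is uppercased. Murine-specific symbol
#' classes with no human counterpart by that rule — Riken clones
#' (`...Rik`), predicted `Gm` models and digit-led identifiers — are
#' reported as unmapped rather than silently dropped.
#'
#' @param mouse_genes Character vector of mouse symbols.
#' @param overrides Named character vector of explicit mappings.
#' @return Character vector of human symbols (deduplicated), with the
#'   unmapped input symbols in attribute `"unmapped"`.
#' @examples
#' map_orthologs(c("Icos", "Tnfrsf4", "1700012B09Rik"))
#' @export
map_orthologs <- function(mouse_genes, overrides = ortholog_overrides()) {
  if (!is.character(mouse_genes)) abort("`mouse_genes` must be character")
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      abort("`overrides` must be a named character vector")
    }
    if (any(duplicated(names(overrides)))) {
      conf <- tapply(unname(overrides), names(overrides),
                     function(v) length(unique(v)) > 1L)
      if (any(conf)) {
        abort("conflicting duplicate mappings for: %s",
              paste(names(conf)[conf], collapse = ", "))
      }
      overrides <- overrides[!duplicated(names(overrides))]
    }
  }
  mappable <- grepl("^[A-Za-z][A-Za-z0-9.-]*$", mouse_genes) &
    !grepl("Rik$", mouse_genes) & !grepl("^Gm[0-9]", mouse_genes)
  out <- character(length(mouse_genes))
  hit <- mouse_genes %in% names(overrides)
  out[hit] <- unname(overrides[mouse_genes[hit]])
  out[!hit & mappable] <- toupper(mouse_genes[!hit & mappable])
  unmapped <- mouse_genes[!hit & !mappable]
  if (length(unmapped)) {
    message(sprintf("map_orthologs: %d symbol(s) unmapped: %s",
                    length(unmapped),
                    paste(utils::head(unmapped, 10L), collapse = ", ")))
  }
  mapped <- unique(out[nzchar(out)])
  attr(mapped, "unmapped") <- unmapped
  mapped
}

#' Classify genes into the six response/TCR-signal intersection groups
#'
#' Genes upregulated in clinical responders (`res`) are partitioned by
#' their joint membership of three further up-DEG sets: on-therapy
#' regardless of response (`ot`), 4-h strong TCR stimulation in mice
#' (`strong4h`), and anti-PD1 re-challenge in mice (`pd1`):
#'
#' * **I** — in `ot`, `strong4h` and `pd1`: pharmacodynamic correlates of
#'   anti-PD1 that also mark strong TCR signaling (e.g. ICOS, TNIP3).
#' * **II** — in `strong4h` and `pd1` only: responder-specific markers of
#'   strong TCR signaling under anti-PD1 (e.g. TNFRSF4, IRF8, STAT4).
#' * **III** — in `ot` and `strong4h`, not `pd1`.
#' * **IV** — in `strong4h` only.
#' * **V** — in `pd1` only.
#' * **VI** — in `ot` and `pd1`, not `strong4h`.
#'
#' Genes in `res` matching none of these patterns, and genes absent from
#' `res`, are `unassigned`.
#'
#' @param res,ot,strong4h,pd1 Character vectors of (human) gene symbols.
#' @return A tibble with columns `gene`, `group` covering the union of
#'   all four sets.
#' @export
classify_groups <- function(res, ot, strong4h, pd1) {
  genes <- sort(unique(c(res, ot, strong4h, pd1)))
  in_res <- genes %in% res
  in_ot <- genes %in% ot
  in_4h <- genes %in% strong4h
  in_pd1 <- genes %in% pd1
  group <- rep("unassigned", length(genes))
  group[in_res & in_ot & in_4h & in_pd1] <- "I"
  group[in_res & !in_ot & in_4h & in_pd1] <- "II"
  group[in_res & in_ot & in_4h & !in_pd1] <- "III"
  group[in_res & !in_ot & in_4h & !in_pd1] <- "IV"
  group[in_res & !in_ot & !in_4h & in_pd1] <- "V"
  group[in_res & in_ot & !in_4h & in_pd1] <- "VI"
  tibble::tibble(gene = genes, group = group)
}

#' Derive the strong-TCR-signal signature from a group assignment
#'
#' The signature is the union of group I (anti-PD1 pharmacodynamic
#' correlates marking strong TCR signals) and group II (responder-only
#' strong-TCR/anti-PD1 genes), sorted lexicographically. On the
#' contrasts that motivated it this yields the five-gene TCR.strong set.
#'
#' @param assignment Tibble from [classify_groups()].
#' @return A [gene_signature()] named `"TCR.strong-derived"`.
#' @export
derive_signature <- function(assignment) {
  need <- c("gene", "group")
  miss <- setdiff(need, names(assignment))
  if (length(miss)) abort("assignment missing column(s): %s",
                          paste(miss, collapse = ", "))
  genes <- sort(assignment$gene[assignment$group %in% c("I", "II")])
  if (!length(genes)) {
    abort("no genes in groups I/II; review the DEG thresholds feeding %s",
          "the classifier")
  }
  gene_signature("TCR.strong-derived", genes)
}

#' Write a group assignment as TSV (columns gene, group)
#'
#' @param assignment Tibble from [classify_groups()].
#' @param path Output path.
#' @export
write_group_tsv <- function(assignment, path) {
  write.table(as.data.frame(assignment), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
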