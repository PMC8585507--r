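#' Read a pipeline configuration file
#'
#' Pipeline commands are driven by a single structured YAML file with one
#' block per stage (`simulate_timer`, `score`, `derive`, `stratify`) plus
#' a top-level `seed`. Every command writes its outputs next to a JSON
#' manifest recording the seed, package version and input checksums, so
#' runs are reproducible and auditable.
#'
#' @param path Path to a YAML config file.
#' @return A named list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  cfg$seed <- cfg$seed %||% 1
  structure(cfg, class = c("pipeline_config", "list"))
}

write_manifest <- function(dir, command, seed, inputs = character(),
                           outputs = character(), extra = list()) {
  checksum <- function(paths) {
    paths <- paths[file.exists(paths)]
    if (!length(paths)) return(NULL)
    as.list(tools::md5sum(paths))
  }
  manifest <- c(list(
    command = command,
    package = "tcrstrong",
    version = as.character(utils::packageVersion("tcrstrong")),
    seed = seed,
    inputs = checksum(inputs),
    outputs = checksum(outputs)
  ), extra)
  path <- file.path(dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

log_msg <- function(fmt, ...) {
  message(sprintf("[tcrstrong] %s", sprintf(fmt, ...)))
}

cfg_field <- function(block, name, default = NULL, required = FALSE) {
  val <- block[[name]]
  if (is.null(val)) {
    if (required) abort("config field `%s` is required", name)
    return(default)
  }
  val
}

kinetics_from_config <- function(block) {
  block <- block %||% list()
  do.call(timer_kinetics, block)
}

protocol_from_config <- function(block) {
  if (is.null(block) || is.null(block$doses)) {
    abort("config field `protocol.doses` is required")
  }
  doses <- block$doses
  if (is.list(doses)) doses <- do.call(rbind, lapply(doses, as.numeric))
  block$doses <- doses
  do.call(stimulation_protocol, block)
}

#' Simulate a Timer flow experiment from a config
#'
#' Simulates an unstimulated control sample and one stimulated sample per
#' requested observation time, normalizes channels against the control,
#' and writes per-time flow-event CSVs plus a summary JSON with the
#' fraction of cells showing active TCR signaling (Blue+) and the mean
#' Timer angle per time point.
#'
#' @param config A `pipeline_config` (or list) with a `simulate_timer`
#'   block: `out_dir`, `n_cells`, `t_obs_h` (vector), `kinetics` (fields
#'   of [timer_kinetics()]), `protocol` (fields of
#'   [stimulation_protocol()]).
#' @return Invisibly, the summary as a list.
#' @export
run_simulate_timer <- function(config) {
  block <- config$simulate_timer %||% abort("missing `simulate_timer` block")
  out_dir <- cfg_field(block, "out_dir", required = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_cells <- cfg_field(block, "n_cells", 5000)
  t_obs <- as.numeric(cfg_field(block, "t_obs_h", required = TRUE))
  seed <- config$seed %||% 1
  kinetics <- kinetics_from_config(block$kinetics)
  protocol <- protocol_from_config(block$protocol)

  zero_protocol <- stimulation_protocol(
    cbind(0, 0), ec50_ug = protocol$ec50_ug, hill_n = protocol$hill_n,
    signal_duration_h = protocol$signal_duration_h)
  controls <- simulate_flow_sample(n_cells, zero_protocol, kinetics,
                                   t_obs_h = max(t_obs),
                                   seed = derive_seed(seed, 999983))
  outputs <- character()
  summary <- list()
  for (i in seq_along(t_obs)) {
    ev <- simulate_flow_sample(n_cells, protocol, kinetics, t_obs[i],
                               seed = derive_seed(seed, i))
    ev <- normalize_channels(ev, controls)
    path <- file.path(out_dir, sprintf("events_t%03.0fh.csv", t_obs[i]))
    write_flow_csv(ev, path)
    outputs <- c(outputs, path)
    frac_active <- mean(ev$locus %in% c("new", "persistent"))
    ang <- if (any(ev$timer_positive)) mean_timer_angle(ev) else NA_real_
    summary[[i]] <- list(t_obs_h = t_obs[i],
                         fraction_active = frac_active,
                         fraction_timer_positive = mean(ev$timer_positive),
                         mean_timer_angle_deg = ang,
                         rechallenge = rechallenge_summary(ev))
    log_msg("t = %g h: %.1f%% active, mean angle %.1f deg", t_obs[i],
            100 * frac_active, ang)
  }
  summary_path <- file.path(out_dir, "timer_summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  write_manifest(out_dir, "simulate_timer", seed,
                 outputs = c(outputs, summary_path))
  invisible(summary)
}

#' Score an expression matrix with a gene signature, from a config
#'
#' Reads the expression TSV, applies the unit transform implied by the
#' declared input unit (FPKM -> TPM, counts -> CPM; TPM/CPM are scored
#' directly) and writes the score table TSV.
#'
#' @param config A `pipeline_config` with a `score` block: `expression`
#'   (TSV path), `unit`, `signature` (`TCR.strong`, `T.activation`, or a
#'   list with `name` and `genes`), `out`.
#' @return Invisibly, the score tibble.
#' @export
run_score <- function(config) {
  block <- config$score %||% abort("missing `score` block")
  path <- cfg_field(block, "expression", required = TRUE)
  unit <- cfg_field(block, "unit", required = TRUE)
  out <- cfg_field(block, "out", required = TRUE)
  mat <- read_expression_tsv(path, unit)
  mat <- switch(mat$unit,
                FPKM = fpkm_to_tpm(mat),
                counts = counts_to_cpm(mat),
                CPM = mat,
                TPM = mat)
  sig_spec <- cfg_field(block, "signature", "TCR.strong")
  signature <- if (is.character(sig_spec)) {
    switch(sig_spec,
           TCR.strong = tcr_strong_signature(),
           T.activation = t_activation_signature(),
           abort("unknown signature '%s'", sig_spec))
  } else {
    gene_signature(sig_spec$name %||% "custom", unlist(sig_spec$genes))
  }
  scores <- signature_score(mat, signature,
                            allow_missing = isTRUE(block$allow_missing))
  dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
  write_score_tsv(scores, out)
  write_manifest(dirname(out), "score", config$seed %||% 1,
                 inputs = path, outputs = out)
  log_msg("scored %d sample(s) with %s", nrow(scores), signature$name)
  invisible(scores)
}

#' Derive the strong-TCR-signal signature from four DEG tables
#'
#' Applies per-contrast thresholds to the responder (`res`), on-therapy
#' (`ot`), strong-4h (`strong4h`) and anti-PD1 (`pd1`) DEG tables, maps
#' mouse symbols on the murine contrasts to human, classifies all genes
#' into intersection groups I-VI, and derives the group I + II signature.
#'
#' @param config A `pipeline_config` with a `derive` block: `deg` (named
#'   paths for the four contrasts), optional `mouse_contrasts` (default
#'   `c("strong4h", "pd1")`), `out_dir`.
#' @return Invisibly, a list with `assignment` and `signature`.
#' @export
run_derive <- function(config) {
  block <- config$derive %||% abort("missing `derive` block")
  deg_paths <- cfg_field(block, "deg", required = TRUE)
  out_dir <- cfg_field(block, "out_dir", required = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  contrasts <- c("res", "ot", "strong4h", "pd1")
  miss <- setdiff(contrasts, names(deg_paths))
  if (length(miss)) abort("missing DEG table path(s) for: %s",
                          paste(miss, collapse = ", "))
  thresholds <- list(res = deg_thresholds_human(),
                     ot = deg_thresholds_human(),
                     strong4h = deg_thresholds_mouse_dose(),
                     pd1 = deg_thresholds_mouse_pd1())
  mouse_contrasts <- cfg_field(block, "mouse_contrasts", c("strong4h", "pd1"))
  sets <- lapply(contrasts, function(con) {
    p <- deg_paths[[con]]
    if (!file.exists(p)) abort("DEG table for '%s' not found: %s", con, p)
    genes <- threshold_deg(read_deg_tsv(p), thresholds[[con]])
    if (con %in% mouse_contrasts) genes <- map_orthologs(genes)
    genes
  })
  names(sets) <- contrasts
  assignment <- classify_groups(sets$res, sets$ot, sets$strong4h, sets$pd1)
  signature <- derive_signature(assignment)
  write_group_tsv(assignment, file.path(out_dir, "group_assignment.tsv"))
  writeLines(signature$genes, file.path(out_dir, "derived_signature.txt"))
  write_manifest(out_dir, "derive", config$seed %||% 1,
                 inputs = unlist(deg_paths),
                 outputs = file.path(out_dir, c("group_assignment.tsv",
                                                "derived_signature.txt")))
  log_msg("derived signature of %d gene(s): %s", length(signature$genes),
          paste(signature$genes, collapse = ", "))
  invisible(list(assignment = assignment, signature = signature))
}

#' Median-split survival stratification from a config
#'
#' Joins on-therapy scores to patient metadata, excludes patients with
#' non-evaluated or missing outcomes (listing them in the manifest),
#' splits at the median score, and writes Kaplan-Meier CSVs, a log-rank
#' JSON, and the paired pre/on change table.
#'
#' @param config A `pipeline_config` with a `stratify` block: `scores`
#'   (TSV from [run_score()]), `metadata` (patient TSV), `endpoint`
#'   (`PFS`/`OS`), `out_dir`.
#' @return Invisibly, the [stratified_survival()] result.
#' @export
run_stratify <- function(config) {
  block <- config$stratify %||% abort("missing `stratify` block")
  score_path <- cfg_field(block, "scores", required = TRUE)
  meta_path <- cfg_field(block, "metadata", required = TRUE)
  endpoint <- cfg_field(block, "endpoint", "PFS")
  out_dir <- cfg_field(block, "out_dir", required = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  scores_df <- read.delim(score_path, stringsAsFactors = FALSE)
  meta <- read_patient_tsv(meta_path)
  meta$response <- classify_response(meta$bor)
  on <- meta[meta$timepoint == "on", ]
  excluded <- on$patient_id[on$response == "excluded"]
  on <- on[on$response != "excluded", ]
  bad_join <- setdiff(on$patient_id, scores_df$sample_id)
  if (length(bad_join)) {
    abort("no score for patient(s): %s", paste(bad_join, collapse = ", "))
  }
  on$score <- scores_df$score[match(on$patient_id, scores_df$sample_id)]

  strat <- stratified_survival(on, endpoint = endpoint)
  write_km_csv(strat$curves, file.path(out_dir, "km_curves.csv"))
  jsonlite::write_json(
    list(endpoint = endpoint, statistic = strat$test$statistic,
         p = strat$test$p_two_sided, n_a = strat$test$n_a,
         n_b = strat$test$n_b, median_cut = strat$median),
    file.path(out_dir, "logrank.json"), auto_unbox = TRUE, digits = NA)

  # paired pre/on change, when the score table carries both timepoints
  paired_meta <- meta[meta$response != "excluded", ]
  pc <- NULL
  if ("timepoint" %in% names(scores_df)) {
    paired_meta$score <- scores_df$score[
      match(paste(paired_meta$patient_id, paired_meta$timepoint),
            paste(scores_df$sample_id, scores_df$timepoint))]
    keep <- !is.na(paired_meta$score)
    if (any(keep)) {
      pc <- suppressMessages(paired_change(paired_meta[keep, ]))
      write.table(as.data.frame(pc$deltas),
                  file.path(out_dir, "paired_change.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  write_manifest(out_dir, "stratify", config$seed %||% 1,
                 inputs = c(score_path, meta_path),
                 outputs = file.path(out_dir, c("km_curves.csv",
                                                "logrank.json")),
                 extra = list(endpoint = endpoint,
                              excluded_patients = as.list(excluded)))
  log_msg("%s log-rank: chi-sq %.3f, p %.4g (High n=%d, Low n=%d)",
          endpoint, strat$test$statistic, strat$test$p_two_sided,
          strat$test$n_a, strat$test$n_b)
  invisible(strat)
}

#' Generate and write a synthetic cohort from a config
#'
#' Runs the synthetic cohort generator and writes the pre- and on-therapy
#' FPKM matrices, patient metadata (with survival endpoints), on/pre
#' score table and the generating truth, in the same TSV schemas the
#' scoring and stratification commands consume.
#'
#' @param config A `pipeline_config` with a `synth_cohort` block holding
#'   `out_dir` plus any fields of [synth_cohort_config()].
#' @return Invisibly, the generated cohort list.
#' @export
run_synth_cohort <- function(config) {
  block <- config$synth_cohort %||% abort("missing `synth_cohort` block")
  out_dir <- cfg_field(block, "out_dir", required = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fields <- block[setdiff(names(block), "out_dir")]
  if (!is.null(config$seed) && is.null(fields$seed)) {
    fields$seed <- config$seed
  }
  cfg <- do.call(synth_cohort_config, fields)
  coh <- generate_cohort(cfg)
  write_expression_tsv(coh$pre, file.path(out_dir, "expression_pre.tsv"))
  write_expression_tsv(coh$on, file.path(out_dir, "expression_on.tsv"))
  write_patient_tsv(coh$metadata, file.path(out_dir, "metadata.tsv"))
  pre_sc <- signature_score(fpkm_to_tpm(coh$pre), tcr_strong_signature())
  scores <- rbind(cbind(as.data.frame(pre_sc), timepoint = "pre"),
                  cbind(as.data.frame(coh$scores), timepoint = "on"))
  write.table(scores, file.path(out_dir, "scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(coh$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "synth_cohort", cfg$seed,
                 outputs = file.path(out_dir, c("expression_pre.tsv",
                                                "expression_on.tsv",
                                                "metadata.tsv", "scores.tsv")))
  log_msg("synthetic cohort: %d patients x %d genes",
          nrow(coh$truth), length(expr_genes(coh$on)))
  invisible(coh)
}
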