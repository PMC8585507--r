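#' Configuration for the synthetic checkpoint-blockade cohort generator
#'
#' Describes a melanoma-like anti-PD1 cohort with paired pre-/on-therapy
#' biopsies: log-normal background gene expression, a responder-specific
#' on-therapy lift on the TCR.strong signature genes, and survival times
#' whose hazard is linked to the (log) signature score.
#'
#' Default cohort sizes mirror the on-therapy analysis cohort of the
#' nivolumab study that motivated the score (31 responders, 24
#' non-responders, ~40% ipilimumab-naive).
#'
#' @param n_responders,n_nonresponders Patients per response group.
#' @param prop_ipi_naive Proportion of patients labelled `ipi_naive`
#'   (remainder `ipi_progressed`).
#' @param n_background_genes Number of background genes (default 1000).
#' @param baseline_log2_fpkm_mean,baseline_log2_fpkm_sd Mean and SD of
#'   per-gene baseline log2 FPKM.
#' @param signature_effect_log2fc Log2 fold change added to the five
#'   TCR.strong genes in on-therapy responders (default 1).
#' @param t_activation_effect_log2fc Same for the T-activation comparator
#'   genes (default 0, so the score-separates/comparator-does-not
#'   scenario is the default construction).
#' @param noise_sd Per-observation log2 noise SD (default 0.25).
#' @param baseline_median_survival_days Median PFS at score z = 0
#'   (default 180 d); overall survival uses twice this baseline.
#' @param beta Log-hazard change per 1 SD of log score (negative =
#'   higher score is protective; default -0.7).
#' @param censor_days Administrative censoring horizon (default 1095 d,
#'   three years of follow-up).
#' @param seed Master seed.
#' @return An object of class `synth_cohort_config`.
#' @export
synth_cohort_config <- function(n_responders = 31,
                                n_nonresponders = 24,
                                prop_ipi_naive = 0.4,
                                n_background_genes = 1000,
                                baseline_log2_fpkm_mean = 3,
                                baseline_log2_fpkm_sd = 1.5,
                                signature_effect_log2fc = 1,
                                t_activation_effect_log2fc = 0,
                                noise_sd = 0.25,
                                baseline_median_survival_days = 180,
                                beta = -0.7,
                                censor_days = 1095,
                                seed = 1) {
  assert_scalar_number(n_responders, "n_responders", 1)
  assert_scalar_number(n_nonresponders, "n_nonresponders", 1)
  assert_scalar_number(prop_ipi_naive, "prop_ipi_naive", 0, upper = 1)
  assert_scalar_number(n_background_genes, "n_background_genes", 1)
  assert_scalar_number(baseline_log2_fpkm_sd, "baseline_log2_fpkm_sd", 0)
  assert_scalar_number(noise_sd, "noise_sd", 0)
  assert_scalar_number(baseline_median_survival_days,
                       "baseline_median_survival_days", 0,
                       strict_lower = TRUE)
  assert_scalar_number(censor_days, "censor_days", 0, strict_lower = TRUE)
  structure(
    list(n_responders = as.integer(n_responders),
         n_nonresponders = as.integer(n_nonresponders),
         prop_ipi_naive = prop_ipi_naive,
         n_background_genes = as.integer(n_background_genes),
         baseline_log2_fpkm_mean = baseline_log2_fpkm_mean,
         baseline_log2_fpkm_sd = baseline_log2_fpkm_sd,
         signature_effect_log2fc = signature_effect_log2fc,
         t_activation_effect_log2fc = t_activation_effect_log2fc,
         noise_sd = noise_sd,
         baseline_median_survival_days = baseline_median_survival_days,
         beta = beta, censor_days = censor_days, seed = seed),
    class = "synth_cohort_config"
  )
}

#' Generate a synthetic paired pre/on expression cohort
#'
#' Each gene draws a baseline log2 FPKM from
#' `Normal(baseline_log2_fpkm_mean, baseline_log2_fpkm_sd)`; every
#' observation adds `Normal(0, noise_sd)` log2 noise. On-therapy
#' responders additionally receive `signature_effect_log2fc` on the five
#' TCR.strong genes (and `t_activation_effect_log2fc` on the
#' T-activation genes). Best overall response codes are drawn as CR/PR/SD
#' for responders and PD for non-responders.
#'
#' @param config A [synth_cohort_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A list with `pre` and `on` ([expression_matrix()] objects,
#'   unit FPKM), `metadata` (patient tibble, one row per patient per
#'   timepoint), and `truth` (per-patient latent response and realized
#'   signature lift).
#' @export
generate_expression <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_cohort_config"))
  seed <- seed %||% config$seed
  sig_genes <- tcr_strong_signature()$genes
  tact_genes <- t_activation_signature()$genes
  bg_genes <- sprintf("BGENE%04d", seq_len(config$n_background_genes))
  if (length(intersect(bg_genes, c(sig_genes, tact_genes)))) {
    abort("background gene symbols collide with signature genes")
  }
  genes <- c(bg_genes, sig_genes, tact_genes)
  n_pat <- config$n_responders + config$n_nonresponders
  patients <- sprintf("PT%03d", seq_len(n_pat))
  response <- rep(c("responder", "nonresponder"),
                  c(config$n_responders, config$n_nonresponders))
  n_naive <- round(config$prop_ipi_naive * n_pat)

  with_seed(derive_seed(seed, 1), {
    # interleave cohort labels across response groups
    cohort <- rep("ipi_progressed", n_pat)
    cohort[sample.int(n_pat, n_naive)] <- "ipi_naive"
    bor <- ifelse(response == "responder",
                  sample(c("CR", "PR", "SD"), n_pat, replace = TRUE,
                         prob = c(0.15, 0.45, 0.4)),
                  "PD")
    baseline <- rnorm(length(genes), config$baseline_log2_fpkm_mean,
                      config$baseline_log2_fpkm_sd)
    names(baseline) <- genes

    make_matrix <- function(timepoint) {
      eff <- matrix(0, length(genes), n_pat,
                    dimnames = list(genes, patients))
      if (timepoint == "on") {
        resp_cols <- response == "responder"
        eff[sig_genes, resp_cols] <- config$signature_effect_log2fc
        eff[tact_genes, resp_cols] <- config$t_activation_effect_log2fc
      }
      noise <- matrix(rnorm(length(genes) * n_pat, 0, config$noise_sd),
                      length(genes), n_pat)
      log2v <- baseline + eff + noise
      expression_matrix(2^log2v, "FPKM")
    }
    pre <- make_matrix("pre")
    on <- make_matrix("on")
  })

  metadata <- tibble::tibble(
    patient_id = rep(patients, 2L),
    cohort = rep(cohort, 2L),
    timepoint = rep(c("pre", "on"), each = n_pat),
    bor = rep(bor, 2L),
    pfs_days = NA_real_, pfs_event = NA_integer_,
    os_days = NA_real_, os_event = NA_integer_
  )
  truth <- tibble::tibble(
    patient_id = patients, response = response, cohort = cohort,
    signature_lift_log2fc = ifelse(response == "responder",
                                   config$signature_effect_log2fc, 0)
  )
  list(pre = pre, on = on, metadata = metadata, truth = truth)
}

#' Generate survival endpoints linked to signature scores
#'
#' Event times are exponential with per-patient hazard
#' \eqn{h_i = h_0 \exp(\beta z_i)}, where \eqn{z_i} is the standardized
#' log score and \eqn{h_0 = \ln 2 / } median-survival baseline;
#' administrative censoring applies at `censor_days`. PFS uses
#' `baseline_median_survival_days`; OS uses twice that baseline, with
#' independent draws.
#'
#' @param config A [synth_cohort_config()].
#' @param scores Named positive numeric vector of per-patient signature
#'   scores (names = patient ids).
#' @param seed Optional seed overriding `config$seed`.
#' @return A tibble with `patient_id`, `pfs_days`, `pfs_event`,
#'   `os_days`, `os_event`, and the latent `true_log_hazard_pfs`.
#' @export
generate_survival <- function(config, scores, seed = NULL) {
  stopifnot(inherits(config, "synth_cohort_config"))
  if (any(!is.finite(scores)) || any(scores <= 0)) {
    abort("`scores` must be finite and positive")
  }
  seed <- seed %||% config$seed
  z <- as.numeric(scale(log(scores)))
  if (any(!is.finite(z))) z <- rep(0, length(scores)) # zero-variance scores
  draw <- function(median_days, z, u) {
    h0 <- log(2) / median_days
    h <- h0 * exp(config$beta * z)
    t <- -log(u) / h
    event <- as.integer(t <= config$censor_days)
    list(time = pmin(t, config$censor_days), event = event, h = h)
  }
  n <- length(scores)
  with_seed(derive_seed(seed, 2), {
    u_pfs <- runif(n)
    u_os <- runif(n)
  })
  pfs <- draw(config$baseline_median_survival_days, z, u_pfs)
  os <- draw(2 * config$baseline_median_survival_days, z, u_os)
  tibble::tibble(
    patient_id = names(scores) %||% sprintf("PT%03d", seq_len(n)),
    pfs_days = pfs$time, pfs_event = pfs$event,
    os_days = os$time, os_event = os$event,
    true_log_hazard_pfs = log(pfs$h)
  )
}

#' Generate a full synthetic cohort (expression + metadata + survival)
#'
#' Convenience composition of [generate_expression()], TCR.strong scoring
#' of the on-therapy samples, and [generate_survival()]; survival columns
#' are filled into the metadata.
#'
#' @param config A [synth_cohort_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @param signature Signature used for the score-hazard link (default
#'   [tcr_strong_signature()]).
#' @return As [generate_expression()], with survival columns filled and
#'   an extra `scores` element (on-therapy score tibble).
#' @export
generate_cohort <- function(config, seed = NULL,
                            signature = tcr_strong_signature()) {
  seed <- seed %||% config$seed
  cohort <- generate_expression(config, seed = seed)
  scores <- signature_score(fpkm_to_tpm(cohort$on), signature)
  sc <- setNames(scores$score, scores$sample_id)
  surv <- generate_survival(config, sc, seed = seed)
  md <- cohort$metadata
  idx <- match(md$patient_id, surv$patient_id)
  md$pfs_days <- surv$pfs_days[idx]
  md$pfs_event <- surv$pfs_event[idx]
  md$os_days <- surv$os_days[idx]
  md$os_event <- surv$os_event[idx]
  cohort$metadata <- md
  cohort$scores <- scores
  cohort$survival <- surv
  cohort
}

#' Generate DEG tables with prescribed set memberships
#'
#' Emits one DEG table per contrast (`res`, `ot`, `strong4h`, `pd1`) such
#' that thresholding each table with its contrast's thresholds recovers
#' the prescribed memberships exactly: member genes receive a log2 fold
#' change and adjusted p strictly inside the inclusion region, non-member
#' genes strictly outside, with at least `margin` clearance on whichever
#' threshold excludes them.
#'
#' @param memberships Named list: gene symbol -> character subset of
#'   `c("res", "ot", "strong4h", "pd1")` (possibly empty).
#' @param thresholds Named list of [deg_thresholds()] per contrast;
#'   defaults to the presets (human for `res`/`ot`, mouse dose for
#'   `strong4h`, mouse anti-PD1 for `pd1`).
#' @param margin Minimum clearance from each threshold (default 0.05). On
#'   the member side of a tight padj cutoff the clearance is capped at
#'   half the threshold, since adjusted p values cannot go below zero.
#' @param seed Seed for the jittered placements.
#' @return Named list of four DEG tibbles (`gene`, `log2fc`, `padj`).
#' @examples
#' tabs <- generate_deg_tables(list(ICOS = c("res", "ot", "strong4h", "pd1")))
#' threshold_deg(tabs$res, deg_thresholds_human())
#' @export
generate_deg_tables <- function(memberships,
                                thresholds = list(
                                  res = deg_thresholds_human(),
                                  ot = deg_thresholds_human(),
                                  strong4h = deg_thresholds_mouse_dose(),
                                  pd1 = deg_thresholds_mouse_pd1()),
                                margin = 0.05,
                                seed = 1) {
  if (!length(memberships)) {
    empty <- tibble::tibble(gene = character(), log2fc = numeric(),
                            padj = numeric())
    return(list(res = empty, ot = empty, strong4h = empty, pd1 = empty))
  }
  if (is.null(names(memberships)) || any(!nzchar(names(memberships)))) {
    abort("`memberships` must be a named list (gene -> contrasts)")
  }
  contrasts <- c("res", "ot", "strong4h", "pd1")
  bad <- setdiff(unlist(memberships), contrasts)
  if (length(bad)) abort("unknown contrast name(s): %s",
                         paste(unique(bad), collapse = ", "))
  genes <- names(memberships)
  out <- list()
  for (ci in seq_along(contrasts)) {
    con <- contrasts[ci]
    th <- thresholds[[con]]
    if (is.null(th)) abort("no thresholds supplied for contrast '%s'", con)
    if (margin <= 0 || th$padj_max <= 0) {
      abort("margin %g infeasible for padj threshold %g", margin, th$padj_max)
    }
    # the member-side padj margin cannot exceed the room below the
    # threshold; cap it at half the threshold for tight cutoffs
    padj_margin <- min(margin, th$padj_max / 2)
    member <- vapply(memberships, function(m) con %in% m, logical(1))
    n <- length(genes)
    with_seed(derive_seed(seed, 100 + ci), {
      lfc <- numeric(n); padj <- numeric(n)
      # members: strictly inside both strict inequalities, with margin
      lfc[member] <- th$lfc_min + margin + runif(sum(member), 0, 1.5)
      padj[member] <- runif(sum(member), 0, th$padj_max - padj_margin)
      # non-members: fail the fold-change or the p threshold (or both)
      if (any(!member)) {
        fail_lfc <- runif(sum(!member)) < 0.5
        lfc_nm <- ifelse(fail_lfc,
                         th$lfc_min - margin - runif(sum(!member), 0, 1),
                         th$lfc_min + margin + runif(sum(!member), 0, 1.5))
        padj_hi <- th$padj_max + margin +
          runif(sum(!member), 0, max(1 - th$padj_max - margin, 0.01))
        padj_nm <- ifelse(fail_lfc,
                          runif(sum(!member), 0, 1),
                          pmin(1, padj_hi))
        lfc[!member] <- lfc_nm
        padj[!member] <- padj_nm
      }
    })
    out[[con]] <- tibble::tibble(gene = genes, log2fc = lfc, padj = padj)
  }
  out
}

#' Membership pattern reproducing the published signature derivation
#'
#' The four-set memberships of the annotated genes from the intersection
#' analysis that motivated the TCR.strong signature: ICOS and TNIP3 in
#' all four sets (group I); TNFRSF4, IRF8 and STAT4 in the responder,
#' strong-4h and anti-PD1 sets (group II); plus exemplar genes of groups
#' III-VI.
#'
#' @return Named list suitable for [generate_deg_tables()].
#' @export
published_memberships <- function() {
  list(
    ICOS = c("res", "ot", "strong4h", "pd1"),
    TNIP3 = c("res", "ot", "strong4h", "pd1"),
    TNFRSF4 = c("res", "strong4h", "pd1"),
    IRF8 = c("res", "strong4h", "pd1"),
    STAT4 = c("res", "strong4h", "pd1"),
    IFNG = c("res", "ot", "strong4h"),
    GZMB = c("res", "ot", "strong4h"),
    CTLA4 = c("res", "ot", "strong4h"),
    IL2RA = c("res", "strong4h"),
    CD5 = c("res", "pd1"),
    GPR65 = c("res", "pd1"),
    GCNT1 = c("res", "pd1"),
    TNFRSF9 = c("res", "ot", "pd1")
  )
}
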