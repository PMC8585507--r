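small_config <- function(...) {
  synth_cohort_config(n_responders = 10, n_nonresponders = 10,
                      n_background_genes = 40, seed = 123, ...)
}

test_that("generator output is deterministic given config and seed", {
  cfg <- small_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$pre$values, b$pre$values)
  expect_identical(a$on$values, b$on$values)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$scores, b$scores)
  c2 <- generate_cohort(cfg, seed = 124)
  expect_false(identical(a$on$values, c2$on$values))
})

test_that("null construction: zero effect gives ~zero mean score delta in both groups", {
  cfg <- small_config(signature_effect_log2fc = 0)
  coh <- generate_expression(cfg)
  sig <- tcr_strong_signature()
  pre <- signature_score(fpkm_to_tpm(coh$pre), sig)
  on <- signature_score(fpkm_to_tpm(coh$on), sig)
  delta <- log2(on$score) - log2(pre$score)
  resp <- coh$truth$response[match(on$sample_id, coh$truth$patient_id)]
  # noise_sd 0.25 per observation; mean delta SE ~ 0.25*sqrt(2/5)/sqrt(10)
  for (grp in c("responder", "nonresponder")) {
    expect_lt(abs(mean(delta[resp == grp])), 0.2)
  }
})

test_that("a 1 log2-unit noiseless effect exactly doubles the responder score", {
  cfg <- synth_cohort_config(n_responders = 10, n_nonresponders = 10,
                             n_background_genes = 1000, seed = 123,
                             signature_effect_log2fc = 1, noise_sd = 0)
  coh <- generate_expression(cfg)
  sig <- tcr_strong_signature()
  resp <- coh$truth$response == "responder"
  # on the FPKM scale the shift is a uniform x2 on the signature genes,
  # so their geometric mean doubles exactly
  gm <- function(m) exp(colMeans(log(m$values[sig$genes, , drop = FALSE])))
  ratio_fpkm <- gm(coh$on) / gm(coh$pre)
  expect_equal(unname(ratio_fpkm[resp]), rep(2, sum(resp)), tolerance = 1e-12)
  expect_equal(unname(ratio_fpkm[!resp]), rep(1, sum(!resp)), tolerance = 1e-12)
  # after TPM normalization the library-size denominator shifts only by
  # the signature genes' share of 1005 genes, so the score ratio stays
  # within a few percent of 2
  pre <- signature_score(fpkm_to_tpm(coh$pre), sig)
  on <- signature_score(fpkm_to_tpm(coh$on), sig)
  ratio <- on$score / pre$score
  expect_equal(ratio[resp], rep(2, sum(resp)), tolerance = 0.05)
  expect_equal(ratio[!resp], rep(1, sum(!resp)), tolerance = 0.05)
})

test_that("on-therapy scores separate responders from non-responders across seeds", {
  hits <- 0L
  nseed <- 50
  for (s in seq_len(nseed)) {
    cfg <- synth_cohort_config(n_responders = 50, n_nonresponders = 50,
                               n_background_genes = 30,
                               signature_effect_log2fc = 1, noise_sd = 0.25,
                               seed = 1000 + s)
    coh <- generate_expression(cfg)
    on <- signature_score(fpkm_to_tpm(coh$on), tcr_strong_signature())
    resp <- coh$truth$response[match(on$sample_id, coh$truth$patient_id)]
    mw <- mannwhitney_u(on$score[resp == "responder"],
                        on$score[resp == "nonresponder"])
    if (mw$p_two_sided < 0.01) hits <- hits + 1L
  }
  expect_gte(hits / nseed, 0.95)
})

test_that("null cohorts give exchangeable responder/non-responder scores", {
  pvals <- vapply(seq_len(200), function(s) {
    cfg <- synth_cohort_config(n_responders = 12, n_nonresponders = 12,
                               n_background_genes = 15,
                               signature_effect_log2fc = 0, seed = 5000 + s)
    coh <- generate_expression(cfg)
    on <- signature_score(fpkm_to_tpm(coh$on), tcr_strong_signature())
    resp <- coh$truth$response[match(on$sample_id, coh$truth$patient_id)]
    mannwhitney_u(on$score[resp == "responder"],
                  on$score[resp == "nonresponder"])$p_two_sided
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("increasing the signature effect increases responder on-therapy scores", {
  mean_log_score <- function(effect) {
    cfg <- small_config(signature_effect_log2fc = effect)
    coh <- generate_expression(cfg)
    on <- signature_score(fpkm_to_tpm(coh$on), tcr_strong_signature())
    resp <- coh$truth$response[match(on$sample_id, coh$truth$patient_id)]
    mean(log(on$score[resp == "responder"]))
  }
  ms <- vapply(c(0, 0.5, 1, 2), mean_log_score, numeric(1))
  expect_true(all(diff(ms) > 0))
})

test_that("T-activation genes carry no effect by default", {
  cfg <- small_config(signature_effect_log2fc = 1.5, noise_sd = 0.1)
  coh <- generate_expression(cfg)
  tact_pre <- signature_score(fpkm_to_tpm(coh$pre), t_activation_signature())
  tact_on <- signature_score(fpkm_to_tpm(coh$on), t_activation_signature())
  resp <- coh$truth$response[match(tact_on$sample_id, coh$truth$patient_id)]
  delta <- log2(tact_on$score) - log2(tact_pre$score)
  expect_lt(abs(mean(delta[resp == "responder"])), 0.25)
})

test_that("survival: beta = 0 equalizes strata; negative beta protects High", {
  cfg0 <- synth_cohort_config(n_responders = 100, n_nonresponders = 100,
                              n_background_genes = 10, beta = 0, seed = 30)
  scores <- setNames(exp(rnorm(200)), sprintf("PT%03d", 1:200))
  s0 <- generate_survival(cfg0, scores)
  labels <- median_split(scores)
  hi <- labels == "High"
  lr0 <- logrank_test(s0$pfs_days[hi], s0$pfs_event[hi],
                      s0$pfs_days[!hi], s0$pfs_event[!hi])
  expect_gt(lr0$p_two_sided, 0.001) # no systematic separation

  cfg1 <- synth_cohort_config(n_responders = 100, n_nonresponders = 100,
                              n_background_genes = 10, beta = -1, seed = 30)
  s1 <- generate_survival(cfg1, scores)
  km_hi <- km_estimate(s1$pfs_days[hi], s1$pfs_event[hi])
  km_lo <- km_estimate(s1$pfs_days[!hi], s1$pfs_event[!hi])
  expect_gt(km_survival_at(km_hi, 180), km_survival_at(km_lo, 180))
  expect_error(generate_survival(cfg1, c(a = -1)), "positive")
})

test_that("beta sign and magnitude are recoverable from a large simulation", {
  cfg <- synth_cohort_config(n_responders = 250, n_nonresponders = 250,
                             n_background_genes = 10, beta = -0.7, seed = 77)
  scores <- setNames(exp(rnorm(500, sd = 1)), sprintf("PT%03d", 1:500))
  sv <- generate_survival(cfg, scores)
  z <- as.numeric(scale(log(scores)))
  fit <- survival::coxph(survival::Surv(sv$pfs_days, sv$pfs_event) ~ z)
  beta_hat <- unname(coef(fit))
  expect_lt(beta_hat, 0)
  expect_lt(abs(beta_hat - (-0.7)), 0.2)
})

test_that("DEG tables round-trip the prescribed memberships exactly", {
  tabs <- generate_deg_tables(published_memberships(), seed = 9)
  ths <- list(res = deg_thresholds_human(), ot = deg_thresholds_human(),
              strong4h = deg_thresholds_mouse_dose(),
              pd1 = deg_thresholds_mouse_pd1())
  sets <- lapply(names(ths), function(con) threshold_deg(tabs[[con]], ths[[con]]))
  names(sets) <- names(ths)
  memb <- published_memberships()
  for (con in names(ths)) {
    expected <- names(memb)[vapply(memb, function(m) con %in% m, logical(1))]
    expect_setequal(sets[[con]], expected)
  }
  # the published memberships derive exactly the five signature genes
  g <- classify_groups(sets$res, sets$ot, sets$strong4h, sets$pd1)
  sig <- derive_signature(g)
  expect_equal(sig$genes, c("ICOS", "IRF8", "STAT4", "TNFRSF4", "TNIP3"))
})

test_that("random membership patterns round-trip across 100 draws", {
  ths <- list(res = deg_thresholds_human(), ot = deg_thresholds_human(),
              strong4h = deg_thresholds_mouse_dose(),
              pd1 = deg_thresholds_mouse_pd1())
  contrasts <- names(ths)
  set.seed(55)
  for (rep in 1:100) {
    n_genes <- sample(3:12, 1)
    memb <- lapply(seq_len(n_genes), function(i) {
      contrasts[runif(4) < 0.5]
    })
    names(memb) <- sprintf("R%02dG%02d", rep, seq_len(n_genes))
    tabs <- generate_deg_tables(memb, seed = rep)
    for (con in contrasts) {
      got <- threshold_deg(tabs[[con]], ths[[con]])
      expected <- names(memb)[vapply(memb, function(m) con %in% m, logical(1))]
      expect_setequal(got, expected)
    }
  }
  # empty memberships produce four empty tables
  empty <- generate_deg_tables(list())
  expect_true(all(vapply(empty, nrow, integer(1)) == 0L))
})
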