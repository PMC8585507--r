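test_that("best-overall-response classification", {
  expect_equal(classify_response(c("CR", "PR", "SD")), rep("responder", 3))
  expect_equal(classify_response("PD"), "nonresponder")
  expect_equal(classify_response(c("NE", "missing", NA)), rep("excluded", 3))
  expect_error(classify_response("CRX"), "unknown")
})

test_that("median split sends strict exceedances High, median ties Low", {
  s1 <- median_split(c(1, 2, 3, 4))
  expect_equal(as.character(s1), c("Low", "Low", "High", "High"))
  expect_equal(attr(s1, "median"), 2.5)
  s2 <- median_split(c(1, 2, 3))
  expect_equal(as.character(s2), c("Low", "Low", "High"))
  # ties exactly at the median go Low
  s3 <- median_split(c(1, 2, 2, 5))
  expect_equal(as.character(s3), c("Low", "Low", "Low", "High"))
  expect_warning(median_split(c(3, 3, 3)), "Low")
  expect_error(median_split(5), ">= 2")

  set.seed(13)
  sc <- rnorm(20)
  labels <- median_split(sc)
  # sort-based oracle: the top half of the order statistics are High
  oracle <- ifelse(rank(sc) > 10, "High", "Low")
  expect_equal(as.character(labels), oracle)

  # external cut (whole-cohort median reused on a subgroup)
  sub <- median_split(c(10, 20), median_value = 15)
  expect_equal(as.character(sub), c("Low", "High"))
})

test_that("Kaplan-Meier product-limit estimate matches hand computation", {
  cv <- km_estimate(c(10, 3, 7, 20), c(1, 0, 0, 0))
  expect_equal(km_survival_at(cv, 10), 1 - 1 / 2) # risk set 2 at t=10
  cv2 <- km_estimate(rep(10, 4), c(1, 0, 0, 0))
  expect_equal(km_survival_at(cv2, 10), 0.75)

  # times {5+, 8, 12, 12, 20+}
  cv3 <- km_estimate(c(5, 8, 12, 12, 20), c(0, 1, 1, 1, 0))
  expect_equal(km_survival_at(cv3, 8), 0.75)
  expect_equal(km_survival_at(cv3, 12), 0.25)
  expect_equal(km_survival_at(cv3, 25), 0.25)

  allc <- km_estimate(c(1, 5, 9), c(0, 0, 0))
  expect_true(all(allc$survival == 1))

  # survival is non-increasing, starts at 1, stays in [0, 1]
  set.seed(2)
  cv4 <- km_estimate(rexp(40), rbinom(40, 1, 0.7))
  expect_true(all(diff(cv4$survival) <= 1e-12))
  expect_true(all(cv4$survival >= 0 & cv4$survival <= 1))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "nonnegative")
})

test_that("KM with no censoring equals 1 - empirical CDF of event times", {
  set.seed(3)
  t <- rexp(60)
  cv <- km_estimate(t, rep(1, 60))
  probe <- quantile(t, c(0.1, 0.5, 0.9))
  expect_equal(km_survival_at(cv, probe), 1 - ecdf(t)(probe),
               ignore_attr = TRUE)
})

test_that("log-rank test matches hand-coded Mantel-Cox arithmetic", {
  # identical groups: chi-square 0, p = 1
  t <- c(2, 5, 9); e <- c(1, 1, 0)
  same <- logrank_test(t, e, t, e)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_two_sided, 1)

  lr <- logrank_test(c(2, 4), c(1, 1), c(6, 8), c(1, 1))
  hand <- mantel_cox_hand(c(2, 4), c(1, 1), c(6, 8), c(1, 1))
  expect_equal(lr$statistic, hand$chisq, tolerance = 1e-10)
  expect_equal(lr$p_two_sided, hand$p, tolerance = 1e-10)

  set.seed(4)
  for (i in 1:5) {
    ta <- rexp(12); tb <- rexp(12, rate = 1.5)
    ea <- rbinom(12, 1, 0.8); eb <- rbinom(12, 1, 0.8)
    if (sum(ea) + sum(eb) == 0) next
    lr <- logrank_test(ta, ea, tb, eb)
    hand <- mantel_cox_hand(ta, ea, tb, eb)
    expect_equal(lr$statistic, hand$chisq, tolerance = 1e-8)
  }
  expect_error(logrank_test(1:3, c(0, 0, 0), 4:6, c(0, 0, 0)), "zero events")
})

test_that("log-rank p is consistent with a permutation reference", {
  set.seed(6)
  ta <- rexp(12, 1); tb <- rexp(12, 2.2)
  ea <- rep(1, 12); eb <- rep(1, 12)
  obs <- logrank_test(ta, ea, tb, eb)
  time <- c(ta, tb); event <- c(ea, eb)
  nperm <- 2000
  stats <- replicate(nperm, {
    idx <- sample(24, 12)
    mantel_cox_hand(time[idx], event[idx], time[-idx], event[-idx])$chisq
  })
  p_perm <- mean(stats >= obs$statistic)
  se <- sqrt(p_perm * (1 - p_perm) / nperm)
  expect_lt(abs(obs$p_two_sided - p_perm), 3 * se + 0.02)
})

test_that("Mann-Whitney exact path equals full enumeration for small samples", {
  mw <- mannwhitney_u(c(7, 8, 9), c(1, 2, 3))
  expect_equal(mw$statistic, 9)
  expect_equal(mw$p_two_sided, 0.1)
  expect_equal(mw$method, "exact")

  set.seed(10)
  for (i in 1:20) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    a <- rnorm(n); b <- rnorm(m, mean = runif(1, -1, 1))
    mw <- mannwhitney_u(a, b)
    oracle <- mw_enum_p(a, b)
    expect_equal(mw$statistic, oracle$u, label = sprintf("U rep %d", i))
    expect_equal(mw$p_two_sided, oracle$p, tolerance = 1e-12,
                 label = sprintf("p rep %d", i))
    # identity: U_a + U_b = n*m
    expect_equal(mw$statistic + mannwhitney_u(b, a)$statistic, n * m)
  }
})

test_that("Mann-Whitney handles ties via the normal approximation", {
  a <- c(1, 2, 3); b <- c(1, 2, 3)
  mw <- mannwhitney_u(a, b)
  expect_equal(mw$method, "normal approximation")
  expect_equal(mw$p_two_sided, 1)
  big_a <- rnorm(30); big_b <- rnorm(40)
  expect_equal(mannwhitney_u(big_a, big_b)$method, "normal approximation")
  expect_error(mannwhitney_u(numeric(0), 1), "nonempty")
})

test_that("paired pre/on change joins timepoints and groups by response", {
  rec <- tibble::tibble(
    patient_id = c("p1", "p1", "p2", "p2", "p3"),
    timepoint = c("pre", "on", "pre", "on", "pre"),
    bor = c("PR", "PR", "PD", "PD", "SD"),
    score = c(2, 6, 3, 3, 9))
  pc <- suppressMessages(paired_change(rec))
  expect_equal(pc$unmatched, "p3")
  expect_equal(pc$deltas$delta[pc$deltas$patient_id == "p1"], 4)
  expect_equal(pc$deltas$delta[pc$deltas$patient_id == "p2"], 0)
  expect_equal(pc$summary$mean_delta[pc$summary$response == "responder"], 4)

  # all pre == on -> all deltas zero
  rec0 <- tibble::tibble(patient_id = rep(c("a", "b"), each = 2),
                         timepoint = rep(c("pre", "on"), 2),
                         bor = "PR", score = c(5, 5, 7, 7))
  expect_true(all(paired_change(rec0)$deltas$delta == 0))

  dup <- rbind(rec[1:2, ], rec[1, ])
  expect_error(paired_change(dup), "duplicate")

  # mixed fixture vs a join-then-subtract oracle
  set.seed(11)
  ids <- sprintf("q%02d", 1:12)
  long <- tibble::tibble(
    patient_id = rep(ids, each = 2),
    timepoint = rep(c("pre", "on"), 12),
    bor = rep(sample(c("CR", "PR", "SD", "PD"), 12, replace = TRUE), each = 2),
    score = runif(24, 1, 50))
  pc2 <- paired_change(long)
  wide_pre <- long$score[long$timepoint == "pre"]
  wide_on <- long$score[long$timepoint == "on"]
  expect_equal(pc2$deltas$delta[match(ids, pc2$deltas$patient_id)],
               wide_on - wide_pre)
})

test_that("stratified survival composes split, KM and log-rank; rank-invariant", {
  set.seed(12)
  n <- 40
  score <- exp(rnorm(n))
  # strong protective score effect
  t <- rexp(n, rate = 0.01 * exp(-1.2 * scale(log(score))[, 1]))
  rec <- tibble::tibble(patient_id = sprintf("r%02d", 1:n),
                        pfs_days = pmin(t, 500),
                        pfs_event = as.integer(t <= 500),
                        score = score)
  strat <- stratified_survival(rec, endpoint = "PFS")
  expect_equal(unname(strat$test$n_a + strat$test$n_b), n)
  med_hi <- km_survival_at(strat$curves$High, 100)
  med_lo <- km_survival_at(strat$curves$Low, 100)
  expect_gt(med_hi, med_lo)

  # manual composition of the three operations gives the same answer
  labels <- median_split(setNames(score, rec$patient_id))
  hi <- labels == "High"
  manual <- logrank_test(rec$pfs_days[hi], rec$pfs_event[hi],
                         rec$pfs_days[!hi], rec$pfs_event[!hi])
  expect_equal(strat$test$statistic, manual$statistic)
  expect_equal(strat$test$p_two_sided, manual$p_two_sided)

  # invariance under strictly monotone transforms of the score
  rec2 <- rec; rec2$score <- log(rec$score) * 3 + 100
  strat2 <- stratified_survival(rec2, endpoint = "PFS")
  expect_equal(as.character(strat2$labels), as.character(strat$labels))
  expect_equal(strat2$test$statistic, strat$test$statistic)
})

test_that("log-rank type-I error is calibrated near the nominal 5%", {
  nsim <- 1000
  alpha <- 0.05
  rejections <- 0L
  set.seed(20)
  for (i in seq_len(nsim)) {
    ta <- rexp(25); tb <- rexp(25)
    ea <- as.integer(ta <= 3); eb <- as.integer(tb <= 3)
    ta <- pmin(ta, 3); tb <- pmin(tb, 3)
    if (sum(ea) + sum(eb) == 0) next
    lr <- logrank_test(ta, ea, tb, eb)
    if (lr$p_two_sided < alpha) rejections <- rejections + 1L
  }
  rate <- rejections / nsim
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
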