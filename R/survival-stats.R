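#' Classify best overall response into responder / non-responder
#'
#' Complete remission (CR), partial remission (PR) and stable disease
#' (SD) count as clinical responders; progressive disease (PD) as
#' non-responders; non-evaluated (NE) or missing outcomes are excluded
#' from analysis.
#'
#' @param bor Character vector of best-overall-response codes (`CR`,
#'   `PR`, `SD`, `PD`, `NE`, `missing` or `NA`).
#' @return Character vector in `{responder, nonresponder, excluded}`.
#' @examples
#' classify_response(c("CR", "SD", "PD", "NE"))
#' @export
classify_response <- function(bor) {
  bor <- as.character(bor)
  bor[is.na(bor)] <- "missing"
  known <- c("CR", "PR", "SD", "PD", "NE", "missing")
  bad <- setdiff(unique(bor), known)
  if (length(bad)) {
    abort("unknown best-overall-response code(s): %s",
          paste(bad, collapse = ", "))
  }
  out <- rep("excluded", length(bor))
  out[bor %in% c("CR", "PR", "SD")] <- "responder"
  out[bor == "PD"] <- "nonresponder"
  out
}

#' Median-split scores into High and Low groups
#'
#' The median is the midpoint of the order statistics (mean of the two
#' middle values for even n). Scores strictly above the median are
#' `High`; scores at or below it are `Low` (ties at the median go Low).
#'
#' @param scores Numeric vector (>= 2 values), optionally named.
#' @param median_value Optional externally supplied cut (e.g. the
#'   whole-cohort median when splitting a subgroup); defaults to the
#'   median of `scores`.
#' @return Factor with levels `High`, `Low`, named like `scores`; the cut
#'   used is in attribute `"median"`.
#' @examples
#' median_split(c(a = 1, b = 2, c = 3, d = 4)) # c, d High
#' @export
median_split <- function(scores, median_value = NULL) {
  if (length(scores) < 2L) abort("median_split() needs >= 2 scores")
  if (any(!is.finite(scores))) abort("scores must be finite")
  cut <- median_value %||% median(scores)
  labels <- factor(ifelse(scores > cut, "High", "Low"),
                   levels = c("High", "Low"))
  if (all(labels == "Low")) {
    warning("all scores at or below the median cut; every sample is Low",
            call. = FALSE)
  }
  names(labels) <- names(scores)
  attr(labels, "median") <- cut
  labels
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps the product-limit estimator: at each distinct event time
#' \eqn{t_j}, survival multiplies by \eqn{1 - d_j/n_j}; censored subjects
#' leave the risk set after their time.
#'
#' @param times Nonnegative follow-up times.
#' @param events Event indicator (1/TRUE = event, 0/FALSE = censored).
#' @return An object of class `km_curve`: a tibble with columns `time`,
#'   `n_risk`, `n_event`, `survival`.
#' @examples
#' km_estimate(c(5, 8, 12, 12, 20), c(0, 1, 1, 1, 0))
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events)) {
    abort("`times` and `events` must have equal length")
  }
  if (any(times < 0)) abort("`times` must be nonnegative")
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, survival = fit$surv)
  class(out) <- c("km_curve", class(out))
  out
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @param t Times at which to read off survival.
#' @return Survival probabilities (1 before the first observed time).
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(tt) {
    idx <- which(curve$time <= tt)
    if (!length(idx)) 1 else curve$survival[max(idx)]
  }, numeric(1))
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' Chi-square statistic \eqn{(\sum_j (O_{Aj} - E_{Aj}))^2 / \sum_j V_j}
#' over distinct event times, with a two-sided p value from the
#' chi-square distribution on 1 degree of freedom.
#'
#' @param times_a,events_a Follow-up times and event flags, group A.
#' @param times_b,events_b Follow-up times and event flags, group B.
#' @return A list with `statistic` (chi-square), `p_two_sided`, `n_a`,
#'   `n_b`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b)) {
    abort("both groups must be nonempty")
  }
  ea <- as.integer(as.logical(events_a))
  eb <- as.integer(as.logical(events_b))
  if (sum(ea) + sum(eb) == 0L) {
    abort("log-rank test undefined with zero events")
  }
  time <- c(times_a, times_b)
  event <- c(ea, eb)
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 0)
  stat <- unname(sd$chisq)
  list(statistic = stat,
       p_two_sided = pchisq(stat, df = 1, lower.tail = FALSE),
       n_a = length(times_a), n_b = length(times_b))
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two samples with 0.5 credit for ties. For small
#' samples (`min(n, m) <= 8`) with no ties the exact two-sided p value is
#' used; otherwise a tie-corrected normal approximation (without
#' continuity correction, so identical samples give p = 1). The reported
#' statistic is U for the first sample; `U_a + U_b = n * m`.
#'
#' @param a,b Numeric score vectors.
#' @return A list with `statistic` (U for `a`), `p_two_sided`, `n_a`,
#'   `n_b`, `method`.
#' @examples
#' mannwhitney_u(c(7, 8, 9), c(1, 2, 3)) # U = 9, exact p = 0.1
#' @export
mannwhitney_u <- function(a, b) {
  if (!length(a) || !length(b)) abort("both samples must be nonempty")
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    abort("scores must be finite")
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- min(length(a), length(b)) <= 8L && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = FALSE)
  )
  list(statistic = unname(wt$statistic),
       p_two_sided = min(1, wt$p.value),
       n_a = length(a), n_b = length(b),
       method = if (exact) "exact" else "normal approximation")
}

#' Paired pre- to on-therapy score change per patient
#'
#' Joins each patient's pre- and on-therapy signature scores and reports
#' the per-patient delta (on - pre), grouped by responder status.
#' Patients lacking either timepoint are reported and excluded.
#'
#' @param records Tibble/data frame with columns `patient_id`,
#'   `timepoint` (`pre`/`on`), `score`, and `bor` (or a precomputed
#'   `response` column).
#' @return A list with `deltas` (tibble: `patient_id`, `response`, `pre`,
#'   `on`, `delta`), `summary` (per response group: n, mean delta,
#'   standard error), and `unmatched` (patient ids excluded).
#' @export
paired_change <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("patient_id", "timepoint", "score")
  miss <- setdiff(need, names(records))
  if (length(miss)) abort("records missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (!"response" %in% names(records)) {
    if (!"bor" %in% names(records)) {
      abort("records need a `response` or `bor` column")
    }
    records$response <- classify_response(records$bor)
  }
  if (anyDuplicated(records[c("patient_id", "timepoint")])) {
    dup <- records$patient_id[duplicated(records[c("patient_id", "timepoint")])]
    abort("duplicate timepoint records for patient(s): %s",
          paste(unique(dup), collapse = ", "))
  }
  ids <- unique(records$patient_id)
  pre <- records[records$timepoint == "pre", ]
  on <- records[records$timepoint == "on", ]
  matched <- intersect(pre$patient_id, on$patient_id)
  unmatched <- setdiff(ids, matched)
  if (length(unmatched)) {
    message(sprintf("paired_change: excluding %d patient(s) without both %s",
                    length(unmatched), "timepoints"))
  }
  if (!length(matched)) {
    return(list(deltas = tibble::tibble(patient_id = character(),
                                        response = character(),
                                        pre = numeric(), on = numeric(),
                                        delta = numeric()),
                summary = tibble::tibble(response = character(),
                                         n = integer(),
                                         mean_delta = numeric(),
                                         se = numeric()),
                unmatched = unmatched))
  }
  pre_score <- setNames(pre$score, pre$patient_id)[matched]
  on_score <- setNames(on$score, on$patient_id)[matched]
  resp <- setNames(on$response, on$patient_id)[matched]
  deltas <- tibble::tibble(patient_id = matched,
                           response = unname(resp),
                           pre = unname(pre_score),
                           on = unname(on_score),
                           delta = unname(on_score - pre_score))
  summ <- do.call(rbind, lapply(split(deltas$delta, deltas$response),
                                function(d) {
    data.frame(n = length(d), mean_delta = mean(d),
               se = if (length(d) > 1L) sd(d) / sqrt(length(d)) else NA_real_)
  }))
  summ <- tibble::tibble(response = rownames(summ),
                         n = summ$n, mean_delta = summ$mean_delta,
                         se = summ$se)
  list(deltas = deltas, summary = summ, unmatched = unmatched)
}

#' Median-split survival stratification
#'
#' Splits patients at the median of their on-therapy signature scores
#' into High and Low strata, estimates a Kaplan-Meier curve per stratum
#' and compares them by the log-rank (Mantel-Cox) test. Only ranks
#' matter: any strictly monotone transform of the scores yields the same
#' stratification.
#'
#' @param records Tibble with one row per patient carrying the endpoint
#'   columns `pfs_days`/`pfs_event` and/or `os_days`/`os_event`, and a
#'   `score` column of on-therapy signature scores (or supply `scores`).
#' @param scores Optional named numeric vector of on-therapy scores
#'   (names = `patient_id`), overriding the `score` column.
#' @param endpoint `"PFS"` or `"OS"`.
#' @param median_value Optional external median cut (e.g. reuse the
#'   whole-cohort cut when stratifying a subgroup).
#' @return A list with `labels` (named High/Low factor), `curves` (list
#'   of `km_curve`s for High and Low), `test` (log-rank result), and
#'   `median` (the cut used).
#' @export
stratified_survival <- function(records, scores = NULL,
                                endpoint = c("PFS", "OS"),
                                median_value = NULL) {
  endpoint <- match.arg(endpoint)
  records <- tibble::as_tibble(records)
  tcol <- if (endpoint == "PFS") "pfs_days" else "os_days"
  ecol <- if (endpoint == "PFS") "pfs_event" else "os_event"
  miss <- setdiff(c("patient_id", tcol, ecol), names(records))
  if (length(miss)) abort("records missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (is.null(scores)) {
    if (!"score" %in% names(records)) {
      abort("supply `scores` or a `score` column in `records`")
    }
    scores <- setNames(records$score, records$patient_id)
  }
  keep <- records$patient_id %in% names(scores) &
    is.finite(records[[tcol]]) & !is.na(records[[ecol]])
  records <- records[keep, ]
  if (nrow(records) < 2L) abort("fewer than two patients with scores and %s",
                                endpoint)
  sc <- scores[records$patient_id]
  labels <- median_split(sc, median_value = median_value)
  hi <- labels == "High"
  if (!any(hi) || all(hi)) {
    abort("median split produced an empty stratum")
  }
  curves <- list(
    High = km_estimate(records[[tcol]][hi], records[[ecol]][hi]),
    Low = km_estimate(records[[tcol]][!hi], records[[ecol]][!hi])
  )
  test <- logrank_test(records[[tcol]][hi], records[[ecol]][hi],
                       records[[tcol]][!hi], records[[ecol]][!hi])
  list(labels = labels, curves = curves, test = test,
       median = attr(labels, "median"))
}

#' Read / write patient metadata tables
#'
#' Patient metadata TSV schema: `patient_id, cohort, timepoint, bor,
#' pfs_days, pfs_event, os_days, os_event` (event flags 0/1).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_patient_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "timepoint", "bor")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort("patient table %s missing column(s): %s", path,
                          paste(miss, collapse = ", "))
  tibble::as_tibble(df)
}

#' @rdname read_patient_tsv
#' @param records Patient tibble.
#' @export
write_patient_tsv <- function(records, path) {
  write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a Kaplan-Meier curve set as CSV (group, time, survival, n_risk)
#'
#' @param curves Named list of `km_curve`s.
#' @param path Output path.
#' @export
write_km_csv <- function(curves, path) {
  rows <- do.call(rbind, lapply(names(curves), function(g) {
    cv <- curves[[g]]
    data.frame(group = g, time = cv$time, survival = cv$survival,
               n_risk = cv$n_risk)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
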