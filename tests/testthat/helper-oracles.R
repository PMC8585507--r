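# Independent reference implementations used to cross-check the package.

# Exact two-sided Mann-Whitney p by full enumeration of all C(n+m, n)
# group assignments (no ties assumed).
mw_enum_p <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(n + m, n)
  u_all <- apply(idx, 2L, function(ii) sum(r[ii]) - n * (n + 1) / 2)
  p <- if (u_obs > n * m / 2) 2 * mean(u_all >= u_obs) else 2 * mean(u_all <= u_obs)
  list(u = u_obs, p = min(1, p))
}

# Hand-coded Mantel-Cox arithmetic: hypergeometric O-E and variance terms
# summed over distinct event times.
mantel_cox_hand <- function(times_a, events_a, times_b, events_b) {
  time <- c(times_a, times_b)
  event <- c(as.integer(events_a), as.integer(events_b))
  ingrp <- rep(c(TRUE, FALSE), c(length(times_a), length(times_b)))
  etimes <- sort(unique(time[event == 1]))
  oe <- 0; v <- 0
  for (tj in etimes) {
    at_risk <- time >= tj
    nj <- sum(at_risk)
    naj <- sum(at_risk & ingrp)
    dj <- sum(event == 1 & time == tj)
    daj <- sum(event == 1 & time == tj & ingrp)
    oe <- oe + (daj - dj * naj / nj)
    if (nj > 1) {
      v <- v + dj * (naj / nj) * (1 - naj / nj) * (nj - dj) / (nj - 1)
    }
  }
  chisq <- oe^2 / v
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Truth-table reference for the four-set intersection classifier.
group_truth_table <- function(in_res, in_ot, in_4h, in_pd1) {
  if (!in_res) return("unassigned")
  if (in_ot && in_4h && in_pd1) return("I")
  if (!in_ot && in_4h && in_pd1) return("II")
  if (in_ot && in_4h && !in_pd1) return("III")
  if (!in_ot && in_4h && !in_pd1) return("IV")
  if (!in_ot && !in_4h && in_pd1) return("V")
  if (in_ot && !in_4h && in_pd1) return("VI")
  "unassigned"
}

# Column-normalization oracle coded independently of the package path.
tpm_oracle <- function(values, offset = 0.01) {
  out <- values
  for (j in seq_len(ncol(values))) {
    out[, j] <- values[, j] / sum(values[, j]) * 1e6 + offset
  }
  out
}

# Small helper: a two-dose prime/re-challenge protocol used across tests.
test_protocol <- function(prime_ug = 80, rechallenge_ug = 8, gap_h = 24, ...) {
  stimulation_protocol(rbind(c(0, prime_ug), c(gap_h, rechallenge_ug)), ...)
}
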