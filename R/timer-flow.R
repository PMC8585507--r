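#' Immunization / re-challenge stimulation protocol
#'
#' Describes a sequence of antigen doses given to a cohort of reporter
#' T cells, together with the dose-response and threshold-recalibration
#' parameters that govern per-cell activation.
#'
#' A priming dose temporarily raises the activation threshold of the
#' population: any dose given within `recalibration_reset_h` of an earlier
#' dose sees an effective EC50 multiplied by
#' `1 + recalibration_kappa * priming_dose / ec50_ug`, where the priming
#' dose is the most recent earlier dose inside that window. The shift is
#' dose-dependent and decays away (resets) after `recalibration_reset_h`.
#' Checkpoint blockade acts on re-challenge doses only: it scales the
#' effective EC50 by `blockade_ec50_mult` (<= 1 lowers the threshold;
#' isotype control = 1) and the transcription rate of re-challenge
#' signaling episodes by `blockade_rate_mult` (>= 1).
#'
#' @param doses Two-column matrix/data frame of `(time_h, dose_ug)` rows,
#'   ordered by time, or a list of length-2 vectors.
#' @param ec50_ug Dose of half-maximal activation probability (default
#'   8 ug, the intermediate dose of the hundred-fold titration range).
#' @param hill_n Hill coefficient of the dose-response.
#' @param signal_duration_h Duration (h) of active reporter transcription
#'   once a cell activates; default 2 h, a transient pulse that
#'   reproduces population arrest of the reporter within 24 h.
#' @param recalibration_kappa Strength of the dose-dependent threshold
#'   shift at re-challenge (0 disables recalibration).
#' @param recalibration_reset_h Window (h) after which the threshold
#'   shift has reset.
#' @param blockade_ec50_mult EC50 multiplier under checkpoint blockade
#'   (applied to re-challenge doses; `<= 1`).
#' @param blockade_rate_mult Transcription-rate multiplier under blockade
#'   (applied to re-challenge signaling episodes; `>= 1`).
#' @return An object of class `stimulation_protocol`.
#' @examples
#' # prime with 80 ug, re-challenge 24 h later with 8 ug
#' stimulation_protocol(rbind(c(0, 80), c(24, 8)))
#' @export
stimulation_protocol <- function(doses,
                                 ec50_ug = 8,
                                 hill_n = 1,
                                 signal_duration_h = 2,
                                 recalibration_kappa = 1,
                                 recalibration_reset_h = 72,
                                 blockade_ec50_mult = 1,
                                 blockade_rate_mult = 1) {
  if (is.list(doses) && !is.data.frame(doses)) {
    doses <- do.call(rbind, lapply(doses, function(d) {
      if (length(d) != 2L) abort("each dose must be (time_h, dose_ug)")
      as.numeric(d)
    }))
  }
  doses <- as.matrix(doses)
  if (ncol(doses) != 2L) abort("`doses` must have columns (time_h, dose_ug)")
  time_h <- as.numeric(doses[, 1L])
  dose_ug <- as.numeric(doses[, 2L])
  if (any(!is.finite(time_h)) || any(time_h < 0)) {
    abort("dose times must be finite and nonnegative")
  }
  if (is.unsorted(time_h, strictly = TRUE)) {
    abort("doses must be strictly ordered by time")
  }
  if (any(dose_ug < 0)) abort("doses must be nonnegative")
  assert_scalar_number(ec50_ug, "ec50_ug", 0, strict_lower = TRUE)
  assert_scalar_number(hill_n, "hill_n", 0, strict_lower = TRUE)
  assert_scalar_number(signal_duration_h, "signal_duration_h", 0,
                       strict_lower = TRUE)
  assert_scalar_number(recalibration_kappa, "recalibration_kappa", 0)
  assert_scalar_number(recalibration_reset_h, "recalibration_reset_h", 0,
                       strict_lower = TRUE)
  assert_scalar_number(blockade_ec50_mult, "blockade_ec50_mult", 0,
                       strict_lower = TRUE)
  assert_scalar_number(blockade_rate_mult, "blockade_rate_mult", 0,
                       strict_lower = TRUE)
  structure(
    list(doses = data.frame(time_h = time_h, dose_ug = dose_ug),
         ec50_ug = ec50_ug, hill_n = hill_n,
         signal_duration_h = signal_duration_h,
         recalibration_kappa = recalibration_kappa,
         recalibration_reset_h = recalibration_reset_h,
         blockade_ec50_mult = blockade_ec50_mult,
         blockade_rate_mult = blockade_rate_mult),
    class = "stimulation_protocol"
  )
}

#' @export
print.stimulation_protocol <- function(x, ...) {
  cat("<stimulation_protocol>\n")
  cat(sprintf("  %d dose(s); EC50 %g ug, Hill n %g, signal %g h\n",
              nrow(x$doses), x$ec50_ug, x$hill_n, x$signal_duration_h))
  for (i in seq_len(nrow(x$doses))) {
    cat(sprintf("    t = %g h: %g ug\n", x$doses$time_h[i], x$doses$dose_ug[i]))
  }
  if (x$blockade_ec50_mult != 1 || x$blockade_rate_mult != 1) {
    cat(sprintf("  blockade: EC50 x%g, rate x%g at re-challenge\n",
                x$blockade_ec50_mult, x$blockade_rate_mult))
  }
  invisible(x)
}

# Per-dose activation probabilities and effective EC50 multipliers for a
# protocol. Dose 1 is priming (no recalibration, no blockade effect);
# later doses are re-challenges.
protocol_activation_probs <- function(protocol) {
  d <- protocol$doses
  n <- nrow(d)
  mult <- rep(1, n)
  if (n > 1L) {
    for (j in 2:n) {
      prev <- which(d$time_h < d$time_h[j] &
                      d$time_h[j] - d$time_h <= protocol$recalibration_reset_h)
      fold <- 1
      if (length(prev)) {
        priming <- d$dose_ug[max(prev)]
        fold <- 1 + protocol$recalibration_kappa * priming / protocol$ec50_ug
      }
      mult[j] <- fold * protocol$blockade_ec50_mult
    }
  }
  p <- vapply(seq_len(n), function(j) {
    activation_probability(d$dose_ug[j], protocol$ec50_ug, protocol$hill_n,
                           ec50_multiplier = mult[j])
  }, numeric(1))
  list(prob = p, ec50_mult = mult)
}

# Transcription schedule for a cell that activated at the doses flagged in
# `activated` (logical per dose). Re-challenge episodes carry the blockade
# rate multiplier.
activation_schedule <- function(protocol, activated) {
  idx <- which(activated)
  if (!length(idx)) return(signal_schedule())
  start <- protocol$doses$time_h[idx]
  end <- start + protocol$signal_duration_h
  rate <- ifelse(idx > 1L, protocol$blockade_rate_mult, 1)
  # merge overlapping episodes, keeping the higher rate
  ord <- order(start)
  start <- start[ord]; end <- end[ord]; rate <- rate[ord]
  ms <- start[1L]; me <- end[1L]; mr <- rate[1L]
  out <- list()
  for (k in seq_along(start)[-1L]) {
    if (start[k] < me) {
      me <- max(me, end[k]); mr <- max(mr, rate[k])
    } else {
      out[[length(out) + 1L]] <- c(ms, me, mr)
      ms <- start[k]; me <- end[k]; mr <- rate[k]
    }
  }
  out[[length(out) + 1L]] <- c(ms, me, mr)
  m <- do.call(rbind, out)
  signal_schedule(m[, 1:2, drop = FALSE], rate_mult = m[, 3L])
}

#' Simulate a flow-cytometry sample of Timer reporter T cells
#'
#' Each cell independently decides, per dose, whether it crosses the
#' activation threshold (Bernoulli with the Hill [activation_probability()],
#' including threshold recalibration and blockade multipliers for
#' re-challenge doses). Every activated cell then follows the same
#' deterministic reporter kinetics — the digital rule — with
#' `signal_duration_h` of transcription per activation. Measured
#' fluorescence adds multiplicative log-normal noise (`noise_cv`) on the
#' kinetic signal plus additive truncated-Gaussian autofluorescence.
#'
#' Randomness is counter-based: cell `i` draws from a stream seeded
#' deterministically from `(seed, i)`, so enlarging `n_cells` never
#' changes earlier cells.
#'
#' @param n_cells Number of cells (>= 1).
#' @param protocol A [stimulation_protocol()].
#' @param kinetics A [timer_kinetics()].
#' @param t_obs_h Observation time (h).
#' @param seed Master integer seed.
#' @return A tibble of cell events with columns `cell_id`, `blue`, `red`
#'   (raw a.u.), `blue_norm`, `red_norm` (NA until [normalize_channels()]),
#'   `timer_positive`, `locus`, `angle_deg`, plus the per-dose activation
#'   flags as a `activated` matrix attribute.
#' @export
simulate_flow_sample <- function(n_cells, protocol, kinetics, t_obs_h, seed) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1) {
    abort("`n_cells` must be >= 1")
  }
  n_cells <- as.integer(n_cells)
  stopifnot(inherits(protocol, "stimulation_protocol"),
            inherits(kinetics, "timer_kinetics"))
  assert_scalar_number(t_obs_h, "t_obs_h", 0)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single integer")
  }

  n_doses <- nrow(protocol$doses)
  pa <- protocol_activation_probs(protocol)
  # doses after the observation time cannot have acted yet
  live <- protocol$doses$time_h <= t_obs_h

  sigma <- sqrt(log(1 + kinetics$noise_cv^2))

  u <- matrix(0, n_cells, max(n_doses, 1L))
  noise <- matrix(0, n_cells, 4L)
  for (i in seq_len(n_cells)) {
    with_seed(derive_seed(seed, i), {
      if (n_doses) u[i, seq_len(n_doses)] <- runif(n_doses)
      noise[i, ] <- rnorm(4L)
    })
  }
  activated <- matrix(FALSE, n_cells, max(n_doses, 1L))
  if (n_doses) {
    activated[, seq_len(n_doses)] <-
      sweep(u[, seq_len(n_doses), drop = FALSE], 2L, pa$prob, "<") &
      rep(live, each = n_cells)
  }

  # deterministic kinetics per distinct activation pattern
  pat_key <- apply(activated, 1L, function(a) paste(as.integer(a), collapse = ""))
  blue_k <- numeric(n_cells); red_k <- numeric(n_cells)
  for (key in unique(pat_key)) {
    rows <- pat_key == key
    a <- as.logical(as.integer(strsplit(key, "")[[1L]]))
    if (any(a)) {
      sched <- activation_schedule(protocol, a)
      st <- solve_timer(kinetics, sched, t_obs_h)
      blue_k[rows] <- st$blue
      red_k[rows] <- st$red
    }
  }

  # measurement model: multiplicative log-normal (mean 1) + truncated
  # Gaussian autofluorescence
  ln_b <- exp(sigma * noise[, 1L] - sigma^2 / 2)
  ln_r <- exp(sigma * noise[, 2L] - sigma^2 / 2)
  bg_b <- pmax(0, kinetics$background_blue + kinetics$background_blue_sd * noise[, 3L])
  bg_r <- pmax(0, kinetics$background_red + kinetics$background_red_sd * noise[, 4L])
  blue <- blue_k * ln_b + bg_b
  red <- red_k * ln_r + bg_r

  blue_gate <- kinetics$background_blue + 3 * kinetics$background_blue_sd
  red_gate <- kinetics$background_red + 3 * kinetics$background_red_sd
  locus <- classify_locus(blue, red, blue_gate, red_gate)

  out <- tibble::tibble(
    cell_id = seq_len(n_cells),
    blue = blue, red = red,
    blue_norm = NA_real_, red_norm = NA_real_,
    timer_positive = locus != "negative",
    locus = locus,
    angle_deg = NA_real_
  )
  attr(out, "activated") <- activated[, seq_len(max(n_doses, 1L)), drop = FALSE]
  attr(out, "gates") <- c(blue = blue_gate, red = red_gate)
  out
}

#' Classify Timer signal locus by quadrant gating
#'
#' Quadrant gating of raw blue/red fluorescence against per-channel
#' positivity gates: Blue+Red- cells carry *new* TCR signals, Blue+Red+
#' *persistent* signals, Blue-Red+ *arrested* signals (transcription
#' initiated, now stopped), and Blue-Red- cells are Timer-negative.
#'
#' @param blue,red Raw fluorescence values (vectorised).
#' @param blue_gate,red_gate Positivity gates (> 0), typically control
#'   mean + 3 SD.
#' @return Character vector in `{negative, new, persistent, arrested}`.
#' @examples
#' classify_locus(c(100, 100, 5, 5), c(5, 100, 100, 5), 19, 19)
#' @export
classify_locus <- function(blue, red, blue_gate, red_gate) {
  assert_scalar_number(blue_gate, "blue_gate", 0, strict_lower = TRUE)
  assert_scalar_number(red_gate, "red_gate", 0, strict_lower = TRUE)
  bp <- blue > blue_gate
  rp <- red > red_gate
  out <- rep("negative", length(blue))
  out[bp & !rp] <- "new"
  out[bp & rp] <- "persistent"
  out[!bp & rp] <- "arrested"
  out
}

#' Normalize Timer fluorescence channels against an unstimulated control
#'
#' Per channel: subtract the control mean, divide by the 99th percentile
#' of (control-subtracted) values among Timer-positive events, multiply by
#' 100 and clip to `[0, 100]`. An event is Timer-positive when its raw
#' value exceeds control mean + `k` SD on either channel. Timer angles are
#' filled for positive events.
#'
#' @param events Cell-event tibble from [simulate_flow_sample()] or read
#'   from a flow-event CSV.
#' @param controls Cell-event tibble of unstimulated control events.
#' @param k Positivity threshold in control SDs (default 3).
#' @return `events` with `blue_norm`, `red_norm`, `timer_positive`,
#'   `locus` and `angle_deg` filled.
#' @export
normalize_channels <- function(events, controls, k = 3) {
  if (NROW(controls) == 0L) abort("`controls` must be nonempty")
  if (NROW(events) == 0L) abort("`events` must be nonempty")
  mu_b <- mean(controls$blue); sd_b <- sd(controls$blue)
  mu_r <- mean(controls$red); sd_r <- sd(controls$red)
  if (!is.finite(sd_b) || !is.finite(sd_r) || sd_b == 0 || sd_r == 0) {
    abort("control channels must have positive variance")
  }
  gate_b <- mu_b + k * sd_b
  gate_r <- mu_r + k * sd_r
  pos <- events$blue > gate_b | events$red > gate_r
  if (!any(pos)) {
    events$blue_norm <- 0
    events$red_norm <- 0
    events$timer_positive <- FALSE
    events$locus <- "negative"
    events$angle_deg <- NA_real_
    return(events)
  }
  scale_b <- as.numeric(quantile(events$blue[pos] - mu_b, 0.99, names = FALSE))
  scale_r <- as.numeric(quantile(events$red[pos] - mu_r, 0.99, names = FALSE))
  scale_b <- max(scale_b, .Machine$double.eps)
  scale_r <- max(scale_r, .Machine$double.eps)
  bn <- pmin(100, pmax(0, (events$blue - mu_b) / scale_b * 100))
  rn <- pmin(100, pmax(0, (events$red - mu_r) / scale_r * 100))
  events$blue_norm <- bn
  events$red_norm <- rn
  events$timer_positive <- pos
  events$locus <- classify_locus(events$blue, events$red, gate_b, gate_r)
  ang <- rep(NA_real_, NROW(events))
  ok <- pos & (bn > 0 | rn > 0)
  ang[ok] <- timer_angle(bn[ok], rn[ok])
  events$angle_deg <- ang
  events
}

#' Timer angle of a cell in blue-red space
#'
#' The angular position of a Timer-positive cell in normalized blue-red
#' space: 0 degrees = pure blue (new TCR signal), 90 degrees = pure red
#' (arrested signal). Computed as `atan2(red_norm, blue_norm)` in degrees.
#'
#' @param blue_norm,red_norm Normalized channel values in `[0, 100]`
#'   (vectorised).
#' @return Angle in degrees, in `[0, 90]`.
#' @examples
#' timer_angle(50, 50) # 45
#' @export
timer_angle <- function(blue_norm, red_norm) {
  if (any(blue_norm < 0) || any(red_norm < 0)) {
    abort("normalized channel values must be >= 0")
  }
  if (any(blue_norm == 0 & red_norm == 0)) {
    abort("Timer angle is undefined when both channels are zero")
  }
  atan2(red_norm, blue_norm) * 180 / pi
}

#' Mean Timer angle of a sample
#'
#' Arithmetic mean of the per-cell Timer angle over Timer-positive events
#' only; summarizes where the responding population sits on its blue-to-red
#' trajectory.
#'
#' @param events Cell-event tibble with `timer_positive` and `angle_deg`
#'   filled (see [normalize_channels()]).
#' @return Mean angle in degrees.
#' @export
mean_timer_angle <- function(events) {
  ang <- events$angle_deg[events$timer_positive]
  ang <- ang[!is.na(ang)]
  if (!length(ang)) abort("no Timer-positive events with a defined angle")
  mean(ang)
}

#' Summarize a re-challenge experiment
#'
#' After priming and re-challenge, Blue+Red+ (persistent) cells responded
#' to both stimulations, while Blue-Red+ (arrested) cells failed to
#' re-activate the reporter. Fractions are taken over Timer-positive
#' events; `active` is the Blue+ fraction of all events.
#'
#' @param events Cell-event tibble with `locus` filled.
#' @return A list with `responders` (persistent / Timer-positive),
#'   `arrested_nonresponders` (arrested / Timer-positive), and `active`
#'   (Blue+ fraction of all events).
#' @export
rechallenge_summary <- function(events) {
  if (NROW(events) == 0L) abort("`events` must be nonempty")
  pos <- events$locus != "negative"
  n_pos <- sum(pos)
  responders <- if (n_pos) sum(events$locus == "persistent") / n_pos else NA_real_
  arrested <- if (n_pos) sum(events$locus == "arrested") / n_pos else NA_real_
  active <- sum(events$locus %in% c("new", "persistent")) / NROW(events)
  list(responders = responders, arrested_nonresponders = arrested,
       active = active)
}

#' Write / read flow-event tables
#'
#' Plain-text CSV with one row per cell: `cell_id, blue, red, blue_norm,
#' red_norm, timer_positive, locus, angle_deg`.
#'
#' @param events Cell-event tibble.
#' @param path Output file path.
#' @return `read_flow_csv` returns a cell-event tibble.
#' @export
write_flow_csv <- function(events, path) {
  cols <- c("cell_id", "blue", "red", "blue_norm", "red_norm",
            "timer_positive", "locus", "angle_deg")
  utils::write.csv(as.data.frame(events)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_flow_csv
#' @export
read_flow_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "blue", "red", "blue_norm", "red_norm",
            "timer_positive", "locus", "angle_deg")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort("flow CSV missing columns: %s",
                          paste(miss, collapse = ", "))
  df$timer_positive <- as.logical(df$timer_positive)
  tibble::as_tibble(df)
}
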