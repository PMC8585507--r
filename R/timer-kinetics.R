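#' Fluorescent Timer reporter kinetics
#'
#' Parameters of the two-state maturation model for a fluorescent Timer
#' protein: newly translated protein fluoresces blue and matures
#' irreversibly into a red form, so the blue:red balance of a cell encodes
#' time since transcription. While NFAT-driven transcription is active,
#' blue protein is produced at `transcription_rate`; all blue loss is
#' maturation into red, so the blue half-life is the maturation half-time.
#'
#' The governing equations are
#' \deqn{dB/dt = s(t) - \lambda_B B, \qquad dR/dt = \lambda_B B - \lambda_R R}
#' with \eqn{\lambda_B = \ln 2 / t_{1/2}^{blue}} and
#' \eqn{\lambda_R = \ln 2 / t_{1/2}^{red}}.
#'
#' @param blue_half_life_h Half-life of the blue (immature) form in hours.
#'   Default 4 h, the measured Nr4a3-Timer blue half-life.
#' @param red_half_life_h Half-life of the red (mature) form in hours.
#'   Default 120 h. `Inf` disables red decay. Must exceed the blue
#'   half-life.
#' @param transcription_rate Fluorescence production rate (a.u./h) while
#'   signaling is active.
#' @param background_blue,background_red Mean autofluorescence (a.u.) per
#'   channel, added to every measured event.
#' @param background_blue_sd,background_red_sd Standard deviation of the
#'   autofluorescence (Gaussian, truncated at zero).
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   measurement noise applied to the kinetic signal.
#' @return An object of class `timer_kinetics`.
#' @examples
#' kin <- timer_kinetics()
#' kin$lambda_blue # ln(2)/4
#' @export
timer_kinetics <- function(blue_half_life_h = 4,
                           red_half_life_h = 120,
                           transcription_rate = 100,
                           background_blue = 10,
                           background_red = 10,
                           background_blue_sd = 3,
                           background_red_sd = 3,
                           noise_cv = 0.25) {
  assert_scalar_number(blue_half_life_h, "blue_half_life_h", 0, strict_lower = TRUE)
  if (!(is.numeric(red_half_life_h) && length(red_half_life_h) == 1L &&
        red_half_life_h > 0)) {
    abort("`red_half_life_h` must be a single positive number (Inf allowed)")
  }
  if (blue_half_life_h >= red_half_life_h) {
    abort("blue half-life (%s h) must be shorter than red half-life (%s h)",
          blue_half_life_h, red_half_life_h)
  }
  assert_scalar_number(transcription_rate, "transcription_rate", 0)
  assert_scalar_number(background_blue, "background_blue", 0)
  assert_scalar_number(background_red, "background_red", 0)
  assert_scalar_number(background_blue_sd, "background_blue_sd", 0)
  assert_scalar_number(background_red_sd, "background_red_sd", 0)
  assert_scalar_number(noise_cv, "noise_cv", 0)
  structure(
    list(
      blue_half_life_h = blue_half_life_h,
      red_half_life_h = red_half_life_h,
      transcription_rate = transcription_rate,
      background_blue = background_blue,
      background_red = background_red,
      background_blue_sd = background_blue_sd,
      background_red_sd = background_red_sd,
      noise_cv = noise_cv,
      lambda_blue = log(2) / blue_half_life_h,
      lambda_red = if (is.finite(red_half_life_h)) log(2) / red_half_life_h else 0
    ),
    class = "timer_kinetics"
  )
}

#' @export
print.timer_kinetics <- function(x, ...) {
  cat("<timer_kinetics>\n")
  cat(sprintf("  blue half-life: %g h   red half-life: %g h\n",
              x$blue_half_life_h, x$red_half_life_h))
  cat(sprintf("  transcription rate: %g a.u./h, noise CV %g\n",
              x$transcription_rate, x$noise_cv))
  cat(sprintf("  background blue %g +/- %g, red %g +/- %g a.u.\n",
              x$background_blue, x$background_blue_sd,
              x$background_red, x$background_red_sd))
  invisible(x)
}

#' Transcription on/off schedule for one cell
#'
#' Ordered, non-overlapping intervals during which reporter transcription
#' is active. Each interval carries a rate multiplier (default 1) applied
#' to the kinetics' `transcription_rate`, so e.g. checkpoint-blockade
#' conditions can raise the production rate of re-challenge episodes.
#'
#' @param intervals A two-column matrix or data frame of
#'   `(t_start_h, t_end_h)` rows, or a list of length-2 vectors. May be
#'   empty (no transcription).
#' @param rate_mult Rate multiplier per interval, recycled to the number
#'   of intervals.
#' @return An object of class `signal_schedule` (a data frame with columns
#'   `start`, `end`, `rate_mult`).
#' @examples
#' signal_schedule(rbind(c(0, 2), c(24, 26)))
#' @export
signal_schedule <- function(intervals = NULL, rate_mult = 1) {
  if (is.null(intervals) || (is.data.frame(intervals) && nrow(intervals) == 0L) ||
      (is.matrix(intervals) && nrow(intervals) == 0L) ||
      (is.list(intervals) && length(intervals) == 0L)) {
    df <- data.frame(start = numeric(0), end = numeric(0),
                     rate_mult = numeric(0))
    return(structure(df, class = c("signal_schedule", "data.frame")))
  }
  if (is.list(intervals) && !is.data.frame(intervals)) {
    intervals <- do.call(rbind, lapply(intervals, function(iv) {
      if (length(iv) != 2L) abort("each interval must be (start, end)")
      as.numeric(iv)
    }))
  }
  intervals <- as.matrix(intervals)
  if (ncol(intervals) != 2L) abort("`intervals` must have two columns")
  start <- as.numeric(intervals[, 1L])
  end <- as.numeric(intervals[, 2L])
  if (any(!is.finite(start)) || any(!is.finite(end))) {
    abort("interval bounds must be finite")
  }
  if (any(end <= start)) abort("each interval needs t_start < t_end")
  rate_mult <- rep_len(as.numeric(rate_mult), length(start))
  if (any(rate_mult < 0)) abort("`rate_mult` must be >= 0")
  ord <- order(start)
  start <- start[ord]; end <- end[ord]; rate_mult <- rate_mult[ord]
  if (length(start) > 1L && any(start[-1L] < end[-length(end)])) {
    abort("intervals must not overlap")
  }
  structure(data.frame(start = start, end = end, rate_mult = rate_mult),
            class = c("signal_schedule", "data.frame"))
}

# Advance (B, R) by tau under constant production rate s, using the exact
# solution of the linear two-compartment system. Vectorised over tau.
propagate_timer <- function(B0, R0, s, lambda_b, lambda_r, tau) {
  C <- B0 - s / lambda_b
  eb <- exp(-lambda_b * tau)
  B <- s / lambda_b + C * eb
  if (lambda_r > 0) {
    er <- exp(-lambda_r * tau)
    R <- R0 * er + s * (1 - er) / lambda_r +
      lambda_b * C * (eb - er) / (lambda_r - lambda_b)
  } else {
    R <- R0 + s * tau + C * (1 - eb)
  }
  list(B = B, R = R)
}

#' Solve the Timer maturation model along a transcription schedule
#'
#' Evaluates the exact piecewise solution of the blue/red maturation
#' system for a cell whose transcription is switched on and off by a
#' [signal_schedule()]. Starting from `B(0) = R(0) = 0`, production is
#' `transcription_rate * rate_mult` inside schedule intervals and zero
#' outside.
#'
#' @param kinetics A [timer_kinetics()] object.
#' @param schedule A [signal_schedule()] object.
#' @param times Non-negative, ascending observation times in hours.
#' @return A tibble with columns `time_h`, `blue`, `red` (noise-free
#'   kinetic values, no background).
#' @examples
#' kin <- timer_kinetics(transcription_rate = 1)
#' solve_timer(kin, signal_schedule(cbind(0, 24)), times = c(4, 24, 28))
#' @export
solve_timer <- function(kinetics, schedule, times) {
  stopifnot(inherits(kinetics, "timer_kinetics"))
  if (!inherits(schedule, "signal_schedule")) {
    schedule <- signal_schedule(schedule)
  }
  if (length(times) == 0L) abort("`times` must be nonempty")
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0)) {
    abort("`times` must be finite and nonnegative")
  }
  if (is.unsorted(times)) abort("`times` must be ascending")

  lb <- kinetics$lambda_blue
  lr <- kinetics$lambda_red
  knots <- sort(unique(c(0, schedule$start, schedule$end)))
  knots <- knots[knots >= 0]

  blue <- numeric(length(times))
  red <- numeric(length(times))
  B <- 0; R <- 0; t_cur <- 0
  seg_rate <- function(t0, t1) {
    mid <- (t0 + t1) / 2
    hit <- which(schedule$start <= mid & mid < schedule$end)
    if (length(hit)) kinetics$transcription_rate * schedule$rate_mult[hit[1L]] else 0
  }
  # walk the union of knots and requested times in order
  grid <- sort(unique(c(knots, times)))
  for (t_next in grid) {
    if (t_next > t_cur) {
      # split [t_cur, t_next] at internal knots (none by construction of grid)
      s <- seg_rate(t_cur, t_next)
      st <- propagate_timer(B, R, s, lb, lr, t_next - t_cur)
      B <- st$B; R <- st$R
      t_cur <- t_next
    }
    at <- which(times == t_next)
    if (length(at)) {
      blue[at] <- B
      red[at] <- R
    }
  }
  tibble::tibble(time_h = times, blue = blue, red = red)
}

#' Probability that a T cell activates at a given antigen dose
#'
#' Hill dose-response for the per-cell probability of crossing the
#' NFAT-Nr4a3 activation threshold. Activation is digital: a cell either
#' crosses the threshold (with this probability) or stays quiescent, and
#' all activated cells then follow the same reporter kinetics, so dose
#' changes the responding fraction, not the trajectory.
#'
#' @param dose_ug Antigen dose (micrograms), `>= 0`. Vectorised.
#' @param ec50_ug Dose of half-maximal activation probability.
#' @param hill_n Hill coefficient (> 0).
#' @param ec50_multiplier Multiplier on the effective EC50 (recalibration
#'   by a priming episode raises it; checkpoint blockade lowers it).
#' @return Probability in `[0, 1]`.
#' @examples
#' activation_probability(80, ec50_ug = 8) # 80/88
#' @export
activation_probability <- function(dose_ug, ec50_ug, hill_n = 1,
                                   ec50_multiplier = 1) {
  if (any(dose_ug < 0)) abort("`dose_ug` must be >= 0")
  assert_scalar_number(hill_n, "hill_n", 0, strict_lower = TRUE)
  ec50_eff <- ec50_ug * ec50_multiplier
  if (!is.numeric(ec50_eff) || any(ec50_eff <= 0)) {
    abort("effective EC50 (ec50_ug * ec50_multiplier) must be > 0")
  }
  dn <- dose_ug^hill_n
  dn / (dn + ec50_eff^hill_n)
}
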