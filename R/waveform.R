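#' Cardiac inflow waveform
#'
#' An idealized aortic-valve flow waveform: a rectified two-term sinusoid
#' over the systolic ejection window (default 40% of the cycle) and zero
#' inflow during diastole, sampled over one period with the first and last
#' samples equal (periodic). The second harmonic skews the ejection shape
#' without changing the cycle mean.
#'
#' @param mean_lmin cycle-mean flow, L/min (default 5, the healthy cardiac
#'   output).
#' @param period cycle period, s (default 0.8).
#' @param systole_fraction fraction of the cycle spent ejecting.
#' @param dt sample spacing, s.
#' @param second_harmonic relative amplitude of the second sinusoid term.
#' @return A `flow_waveform`: list with `time` (s), `q` (m^3/s), `period`.
#' @export
#' @examples
#' w <- cardiac_waveform()
#' cycle_mean_flow(w)  # 5 L/min
cardiac_waveform <- function(mean_lmin = 5, period = 0.8,
                             systole_fraction = 0.4, dt = 1e-3,
                             second_harmonic = 0.15) {
  t <- seq(0, period, by = dt)
  if (abs(t[length(t)] - period) > 1e-12) t <- c(t, period)
  u <- t / (systole_fraction * period)
  q <- ifelse(u <= 1, pmax(0, sin(pi * u) + second_harmonic * sin(2 * pi * u)), 0)
  w <- new_flow_waveform(t, q, period)
  scale_waveform(w, target_lmin = mean_lmin)
}

new_flow_waveform <- function(time, q, period) {
  if (abs(q[1] - q[length(q)]) > 1e-12) {
    abort("waveform must be periodic: first and last samples must agree")
  }
  if (!all(is.finite(q))) abort("waveform contains non-finite samples")
  structure(list(time = time, q = q, period = period), class = "flow_waveform")
}

#' Cycle-mean of a waveform
#'
#' Trapezoidal mean of the flow over one period, in L/min.
#'
#' @param w a `flow_waveform`.
#' @return Scalar, L/min.
#' @export
cycle_mean_flow <- function(w) {
  si_to_lmin(trapz(w$time, w$q) / w$period)
}

#' Rescale a flow waveform
#'
#' Uniform multiplicative scaling to a target cycle-mean flow, or by a
#' fractional reduction of cardiac output (e.g. `reduction = 0.7` models the
#' 70% cardiac-output drop of cardiogenic shock).
#'
#' @param w a `flow_waveform` with positive cycle mean.
#' @param target_lmin target cycle-mean flow, L/min.
#' @param reduction fractional reduction in \[0, 1); used when `target_lmin`
#'   is `NULL`.
#' @return The rescaled `flow_waveform`.
#' @export
#' @examples
#' w <- cardiac_waveform(mean_lmin = 5)
#' cycle_mean_flow(scale_waveform(w, reduction = 0.7))  # 1.5 L/min
scale_waveform <- function(w, target_lmin = NULL, reduction = NULL) {
  current <- cycle_mean_flow(w)
  if (current <= 0) abort("waveform cycle mean must be positive")
  if (is.null(target_lmin)) {
    if (is.null(reduction)) abort("give either target_lmin or reduction")
    if (reduction < 0 || reduction >= 1) abort("reduction must lie in [0, 1)")
    target_lmin <- (1 - reduction) * current
  }
  if (target_lmin <= 0) abort("target cycle-mean flow must be positive")
  w$q <- w$q * (target_lmin / current)
  w
}

# Periodic linear interpolation of the waveform at arbitrary times.
waveform_at <- function(w, t) {
  tt <- t %% w$period
  approx(w$time, w$q, xout = tt, rule = 2)$y
}

#' Cycle-mean flow of a sampled series
#'
#' Trapezoidal time integral of a flow series over the final full cycle,
#' divided by the period, reported in L/min. This is the mean outlet flow
#' used to compare perfusion between cases.
#'
#' @param time sample times, s (uniformly covering >= 1 full cycle).
#' @param q flow samples, m^3/s.
#' @param period cycle period, s.
#' @return Scalar mean flow, L/min.
#' @export
mean_flow <- function(time, q, period) {
  span <- time[length(time)] - time[1]
  if (span < period - 1e-9) abort("flow series covers less than one full cycle")
  t_end <- time[length(time)]
  sel <- time >= t_end - period - 1e-12
  si_to_lmin(trapz(time[sel], q[sel]) / period)
}
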