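#' Three-element Windkessel (RCR) outlet parameters
#'
#' The RCR outlet couples a proximal resistance `Rp` in series with the
#' parallel combination of a distal resistance `Rd` and a compliance `C`.
#' Its time constant `tau = Rd * C` sets the speed of the pressure response:
#' for a constant inflow `Q0` the outlet pressure relaxes to
#' `(Rp + Rd) * Q0`, and with no inflow an initial pressure decays as
#' `exp(-t / tau)`.
#'
#' @param Rp proximal resistance, Pa s/m^3.
#' @param Rd distal resistance, Pa s/m^3.
#' @param C compliance, m^3/Pa.
#' @param P0 reference (venous) pressure, Pa.
#' @return An object of class `windkessel_params` with derived `tau`.
#' @export
windkessel_params <- function(Rp, Rd, C, P0 = 0) {
  for (f in c("Rp", "Rd", "C")) {
    v <- get(f)
    if (!is_scalar_number(v) || v <= 0) abort(sprintf("field '%s' must be > 0", f))
  }
  structure(list(Rp = Rp, Rd = Rd, C = C, tau = Rd * C, P0 = P0),
            class = "windkessel_params")
}

#' Advance a Windkessel outlet by one timestep
#'
#' Integrates the distal-pressure ODE `C dPd/dt = Q - Pd / Rd` over `dt`
#' with an exact exponential step (treating `Q` as the average inflow over
#' the step) and returns the outlet pressure `P = Pd + Rp * Q`. Stepping
#' this ODE is equivalent to evaluating the RCR convolution integral for the
#' same flow history.
#'
#' @param state list with element `Pd` (distal pressure, Pa); use
#'   `list(Pd = <initial>)` to start.
#' @param Q average inflow over the step, m^3/s.
#' @param dt timestep, s (> 0).
#' @param params a [windkessel_params()].
#' @return List with `state` (advanced) and `pressure` (outlet pressure at
#'   the end of the step, Pa).
#' @export
rcr_outlet_step <- function(state, Q, dt, params) {
  if (!is_scalar_number(dt) || dt <= 0) abort("dt must be > 0")
  decay <- exp(-dt / params$tau)
  Pd <- params$P0 + (state$Pd - params$P0) * decay +
    params$Rd * Q * (1 - decay)
  list(state = list(Pd = Pd), pressure = Pd + params$Rp * Q)
}

#' Integrate an RCR outlet over a flow history
#'
#' Convenience wrapper around [rcr_outlet_step()]: steps through a sampled
#' flow series (using the trapezoidal average of consecutive samples as the
#' per-step inflow) and records the outlet pressure.
#'
#' @param params a [windkessel_params()].
#' @param time sample times, s (uniform).
#' @param q inflow samples, m^3/s.
#' @param Pd0 initial distal pressure, Pa.
#' @return Tibble with columns `time`, `q`, `Pd`, `pressure`.
#' @export
wk_simulate <- function(params, time, q, Pd0 = params$P0) {
  n <- length(time)
  Pd <- numeric(n)
  Pd[1] <- Pd0
  state <- list(Pd = Pd0)
  for (i in 2:n) {
    out <- rcr_outlet_step(state, (q[i] + q[i - 1]) / 2, time[i] - time[i - 1],
                           params)
    state <- out$state
    Pd[i] <- state$Pd
  }
  tibble(time = time, q = q, Pd = Pd, pressure = Pd + params$Rp * q)
}
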