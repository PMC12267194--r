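#' Calibration targets for the Windkessel outlets
#'
#' The paper-style calibration goal is qualitative -- a physiological
#' pressure range and flow split -- so the concrete numbers are package
#' conventions: mean aortic pressure 93 mmHg, peak root pressure inside the
#' 120-130 mmHg systolic band, and a resting flow split of 70% descending
#' aorta / 15% BCA / 7.5% LCCA / 7.5% LSA. The proximal resistance is
#' initialized at 10% of each outlet's total resistance and the compliance
#' from a time constant of 1.5 s, both standard Windkessel practice.
#'
#' @param map_mmhg target cycle-mean root pressure, mmHg.
#' @param peak_band_mmhg length-2 systolic band for the peak root pressure.
#' @param splits named fractions (summing to 1) of the cycle-mean flow per
#'   outlet.
#' @param rp_fraction initial `Rp / (Rp + Rd)` per outlet.
#' @param tau_s initial Windkessel time constant, s.
#' @param split_tol relative tolerance on the achieved flow split.
#' @param max_iter fixed-point iteration cap.
#' @return An object of class `calibration_targets`.
#' @export
calibration_targets <- function(map_mmhg = 93,
                                peak_band_mmhg = c(120, 130),
                                splits = c(descending = 0.70, bca = 0.15,
                                           lcca = 0.075, lsa = 0.075),
                                rp_fraction = 0.1,
                                tau_s = 1.5,
                                split_tol = 0.01,
                                max_iter = 20) {
  if (abs(sum(splits) - 1) > 1e-9) abort("flow-split fractions must sum to 1")
  if (length(peak_band_mmhg) != 2 || diff(peak_band_mmhg) <= 0) {
    abort("peak_band_mmhg must be an increasing length-2 band")
  }
  structure(
    list(map_mmhg = map_mmhg, peak_band_mmhg = peak_band_mmhg,
         splits = splits, rp_fraction = rp_fraction, tau_s = tau_s,
         split_tol = split_tol, max_iter = as.integer(max_iter)),
    class = "calibration_targets"
  )
}

#' Calibrate the Windkessel outlet parameters
#'
#' Deterministic fixed-point calibration of the RCR outlets on a healthy
#' network: total peripheral resistance is set from the target mean pressure
#' over the cardiac mean flow and distributed per the target split; `Rp` is
#' a fixed fraction of each outlet's resistance and `C` follows from the
#' target time constant. The network is then simulated and the resistances,
#' their distribution and the compliances are corrected iteratively (at most
#' `max_iter` passes) until every outlet's cycle-mean flow share is within
#' `split_tol` of its target and the peak root pressure lies inside the
#' systolic band. If the compliance correction saturates while the peak
#' stays above the band, the proximal-resistance fraction is reduced
#' stepwise (the peak cannot fall below the `Rp * Qpeak` floor otherwise).
#'
#' @param net a [build_network()] result (healthy mode).
#' @param cardiac the healthy `flow_waveform` used for calibration.
#' @param targets a [calibration_targets()].
#' @param cfg [sim_config()] used for the calibration runs.
#' @return List of class `rcr_calibration`: `network` (with parameters
#'   attached), `params` (tibble per outlet), `iterations` (per-pass
#'   diagnostics), `converged`.
#' @export
calibrate_rcr <- function(net, cardiac, targets = calibration_targets(),
                          cfg = sim_config()) {
  splits <- targets$splits[net$outlets$outlet]
  if (anyNA(splits)) {
    abort(sprintf("calibration targets carry no split for outlet(s): %s",
                  paste(setdiff(net$outlets$outlet, names(targets$splits)),
                        collapse = ", ")))
  }
  q_mean <- lmin_to_si(cycle_mean_flow(cardiac))
  map_pa <- mmhg_to_pa(targets$map_mmhg)
  peak_lo <- targets$peak_band_mmhg[1]
  peak_hi <- targets$peak_band_mmhg[2]
  peak_target <- mean(targets$peak_band_mmhg)

  rp_frac <- targets$rp_fraction
  R_tot <- map_pa / q_mean
  R_o <- R_tot / splits - net$outlets$seg_resistance
  make_params <- function(R_o, rp_frac, C_scale) {
    Rp <- rp_frac * R_o
    Rd <- (1 - rp_frac) * R_o
    tibble(outlet = net$outlets$outlet, Rp = Rp, Rd = Rd,
           C = C_scale * targets$tau_s / Rd, P0 = 0)
  }
  C_scale <- 1
  history <- list()
  converged <- FALSE
  last <- NULL

  for (it in seq_len(targets$max_iter)) {
    params <- make_params(R_o, rp_frac, C_scale)
    net_try <- set_windkessel(net, params)
    sim <- simulate_flow(net_try, cardiac, cfg)
    td <- tidy(sim)
    gl <- glance(sim)
    split_sim <- td$mean_flow_lmin / sum(td$mean_flow_lmin)
    names(split_sim) <- td$outlet
    split_sim <- split_sim[net$outlets$outlet]
    split_err <- max(abs(split_sim / splits - 1))
    peak <- gl$peak_root_mmhg
    history[[it]] <- tibble(iter = it, peak_root_mmhg = peak,
                            mean_root_mmhg = gl$mean_root_mmhg,
                            split_err = split_err, rp_fraction = rp_frac,
                            c_scale = C_scale)
    last <- list(network = net_try, params = params, sim = sim)
    if (split_err <= targets$split_tol && peak >= peak_lo && peak <= peak_hi) {
      converged <- TRUE
      break
    }
    # corrections: total resistance -> mean pressure; per-outlet share ->
    # split; compliance -> pulse pressure (clamped per pass)
    R_o <- R_o * (split_sim / splits) * (targets$map_mmhg / gl$mean_root_mmhg)
    pulse_sim <- peak - gl$mean_root_mmhg
    pulse_target <- peak_target - targets$map_mmhg
    fac <- max(0.25, min(4, pulse_sim / pulse_target))
    C_scale_new <- C_scale * fac
    if (peak > peak_hi && C_scale_new > 50) {
      rp_frac <- rp_frac * 0.85
      C_scale_new <- C_scale
    }
    C_scale <- C_scale_new
  }

  if (!converged) {
    abort(paste0(
      "pressure band / flow split unreachable within the iteration cap; ",
      sprintf("last iterate: peak %.1f mmHg, split error %.2f%%",
              history[[length(history)]]$peak_root_mmhg,
              100 * history[[length(history)]]$split_err)
    ))
  }
  structure(
    list(network = last$network, params = last$params,
         iterations = bind_rows(history), converged = converged),
    class = "rcr_calibration"
  )
}

#' @export
print.rcr_calibration <- function(x, ...) {
  it <- x$iterations[nrow(x$iterations), ]
  cat(sprintf("<rcr_calibration> converged in %d pass(es): peak root %.1f mmHg, split error %.2f%%\n",
              it$iter, it$peak_root_mmhg, 100 * it$split_err))
  invisible(x)
}
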