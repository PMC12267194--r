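#' Simulation configuration
#'
#' @param dt timestep, s; must satisfy `dt <= period / 200`.
#' @param n_cycles number of cardiac cycles to simulate (>= 1, default 3);
#'   only the final cycle is analyzed, the earlier ones shed the transient.
#' @param ef_lmin constant ECMO support flow injected retrograde at the
#'   descending aorta, L/min (0 for no support).
#' @param init `"auto"` to start the Windkessel states at their predicted
#'   cycle-mean operating point, or a numeric vector of initial distal
#'   pressures (Pa) named by outlet.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 1e-3, n_cycles = 3, ef_lmin = 0, init = "auto") {
  if (!is_scalar_number(dt) || dt <= 0) abort("dt must be > 0")
  if (!is_scalar_number(n_cycles) || n_cycles < 1) abort("n_cycles must be >= 1")
  if (!is_scalar_number(ef_lmin) || ef_lmin < 0) abort("ef_lmin must be >= 0")
  structure(list(dt = dt, n_cycles = as.integer(n_cycles),
                 ef_lmin = ef_lmin, init = init),
            class = "sim_config")
}

# Interior segments are the aortic pieces; branch segments are folded into
# their outlet's series resistance.
interior_segments <- function(net) {
  filter(net$segments, !grepl("_outlet$", .data$to))
}

#' Simulate pulsatile flow on the lumped network
#'
#' Advances the resistive network coupled to its Windkessel outlet states
#' with an implicit (backward-Euler) scheme: at every timestep the outlet
#' ODEs are eliminated into the nodal conductance matrix, the node pressures
#' are solved exactly, and the outlet states are updated. The cardiac
#' waveform is imposed at the root; in ECMO mode a constant ECMO flow enters
#' at the descending end while distal perfusion leaves through the abdominal
#' outlet. Instantaneous mass conservation holds to linear-solver precision.
#'
#' @param net a calibrated [build_network()] (see [set_windkessel()] /
#'   [calibrate_rcr()]).
#' @param cardiac a `flow_waveform` for the root inflow.
#' @param cfg a [sim_config()].
#' @return An object of class `flow_sim`: `times` (s), `node_pressure`
#'   (Pa, one column per node), `outlet_flow` (m^3/s, one column per
#'   outlet), `segment_flow`, `cardiac_q`, plus the network and config.
#' @export
simulate_flow <- function(net, cardiac, cfg = sim_config()) {
  if (any(is.na(net$outlets$Rp))) {
    abort("network outlets carry no Windkessel parameters; calibrate first")
  }
  if (cfg$dt > cardiac$period / 200) {
    abort("timestep must be <= period / 200")
  }
  if (cfg$ef_lmin > 0 && net$mode != "ecmo") {
    abort("EF > 0 requires a network built with mode = 'ecmo'")
  }

  segs <- interior_segments(net)
  nodes <- unique(c("root", segs$from, segs$to))
  n_nodes <- length(nodes)
  ni <- setNames(seq_len(n_nodes), nodes)

  dt <- cfg$dt
  ef <- lmin_to_si(cfg$ef_lmin)
  out <- net$outlets
  Rt <- out$seg_resistance + out$Rp
  a <- out$C / dt
  b <- a + 1 / out$Rd + 1 / Rt
  g_eff <- (1 - 1 / (Rt * b)) / Rt
  o_node <- ni[out$node]

  K <- matrix(0, n_nodes, n_nodes)
  for (i in seq_len(nrow(segs))) {
    g <- 1 / segs$resistance[i]
    f <- ni[[segs$from[i]]]; t <- ni[[segs$to[i]]]
    K[f, f] <- K[f, f] + g
    K[t, t] <- K[t, t] + g
    K[f, t] <- K[f, t] - g
    K[t, f] <- K[t, f] - g
  }
  for (k in seq_len(nrow(out))) {
    K[o_node[k], o_node[k]] <- K[o_node[k], o_node[k]] + g_eff[k]
  }
  Kinv <- tryCatch(solve(K), error = function(e) {
    abort("singular network: the vascular graph is disconnected or degenerate")
  })

  # initial Windkessel states
  if (identical(cfg$init, "auto")) {
    q_tot <- lmin_to_si(cycle_mean_flow(cardiac)) + ef
    G <- 1 / (Rt + out$Rd)
    q_o <- q_tot * G / sum(G)
    Pd <- out$P0 + q_o * out$Rd
  } else {
    Pd <- cfg$init[out$outlet]
    if (anyNA(Pd)) abort("init must name an initial distal pressure per outlet")
  }

  n_steps <- as.integer(round(cfg$n_cycles * cardiac$period / dt))
  times <- seq_len(n_steps) * dt
  q_card <- waveform_at(cardiac, times)

  P <- matrix(NA_real_, n_steps, n_nodes, dimnames = list(NULL, nodes))
  Q_out <- matrix(NA_real_, n_steps, nrow(out),
                  dimnames = list(NULL, out$outlet))
  for (s in seq_len(n_steps)) {
    rhs <- numeric(n_nodes)
    rhs[ni[["root"]]] <- q_card[s]
    if (ef > 0) rhs[ni[["desc_end"]]] <- rhs[ni[["desc_end"]]] + ef
    src <- (a * Pd + out$P0 / out$Rd) / (b * Rt)
    for (k in seq_len(nrow(out))) rhs[o_node[k]] <- rhs[o_node[k]] + src[k]
    p <- drop(Kinv %*% rhs)
    Pd_new <- (a * Pd + out$P0 / out$Rd + p[o_node] / Rt) / b
    Q_out[s, ] <- (p[o_node] - Pd_new) / Rt
    Pd <- Pd_new
    P[s, ] <- p
  }

  seg_flow <- matrix(NA_real_, n_steps, nrow(segs),
                     dimnames = list(NULL, segs$segment))
  for (i in seq_len(nrow(segs))) {
    seg_flow[, i] <- (P[, ni[[segs$from[i]]]] - P[, ni[[segs$to[i]]]]) /
      segs$resistance[i]
  }

  structure(
    list(times = times, node_pressure = P, outlet_flow = Q_out,
         segment_flow = seg_flow, cardiac_q = q_card, cardiac = cardiac,
         net = net, cfg = cfg, nodes = nodes),
    class = "flow_sim"
  )
}

# Indices of the final simulated cycle.
final_cycle_idx <- function(sim) {
  t_end <- sim$times[length(sim$times)]
  which(sim$times >= t_end - sim$cardiac$period - 1e-12)
}

#' @export
print.flow_sim <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<flow_sim> %s, %.1f s simulated (EF %.1f L/min)\n",
              x$net$mode, max(x$times), x$cfg$ef_lmin))
  cat(sprintf("  peak root pressure %.1f mmHg, total outflow %.2f L/min\n",
              g$peak_root_mmhg, g$total_outflow_lmin))
  invisible(x)
}

#' @export
tidy.flow_sim <- function(x, ...) {
  idx <- final_cycle_idx(x)
  per <- x$cardiac$period
  map(colnames(x$outlet_flow), function(o) {
    tibble(
      outlet = o,
      mean_flow_lmin = mean_flow(x$times[idx], x$outlet_flow[idx, o], per),
      peak_flow_lmin = si_to_lmin(max(x$outlet_flow[idx, o]))
    )
  }) |> bind_rows()
}

#' @export
glance.flow_sim <- function(x, ...) {
  idx <- final_cycle_idx(x)
  per <- x$cardiac$period
  root_p <- x$node_pressure[idx, "root"]
  inflow <- mean_flow(x$times[idx], x$cardiac_q[idx], per) + x$cfg$ef_lmin
  outflow <- sum(tidy(x)$mean_flow_lmin)
  tibble(
    peak_root_mmhg = pa_to_mmhg(max(root_p)),
    min_root_mmhg = pa_to_mmhg(min(root_p)),
    mean_root_mmhg = pa_to_mmhg(mean(root_p)),
    total_inflow_lmin = inflow,
    total_outflow_lmin = outflow,
    mass_residual = abs(outflow - inflow) / inflow,
    time_span_s = max(x$times)
  )
}

#' @export
autoplot.flow_sim <- function(object, ...) {
  pd <- as_tibble(pa_to_mmhg(object$node_pressure))
  pd$time <- object$times
  pd <- pivot_longer(pd, -"time", names_to = "node", values_to = "pressure_mmhg")
  qd <- as_tibble(si_to_lmin(object$outlet_flow))
  qd$time <- object$times
  qd <- pivot_longer(qd, -"time", names_to = "outlet", values_to = "flow_lmin")
  p1 <- ggplot(pd, aes(.data$time, .data$pressure_mmhg, colour = .data$node)) +
    geom_line() + labs(x = "time [s]", y = "pressure [mmHg]") + theme_minimal()
  p2 <- ggplot(qd, aes(.data$time, .data$flow_lmin, colour = .data$outlet)) +
    geom_line() + labs(x = "time [s]", y = "outlet flow [L/min]") + theme_minimal()
  list(pressure = p1, flow = p2)
}

# Axial net flow profile along the aorta at one timestep: the cardiac inflow
# minus every branch draw proximal of s (positive = antegrade).
axial_flow_profile <- function(sim, s_faces, step) {
  q <- rep(sim$cardiac_q[step], length(s_faces))
  for (b in c("bca", "lcca", "lsa")) {
    if (!b %in% colnames(sim$outlet_flow)) next
    s_b <- sim$net$ostia_s[[b]]
    q <- q - ifelse(s_faces > s_b, sim$outlet_flow[step, b], 0)
  }
  q
}
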