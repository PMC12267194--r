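#' Transport of the ECMO blood fraction along the aorta
#'
#' Advects the ECMO-blood volume fraction `phi` (phase-2; native blood is
#' phase-1 with `phi = 0`) along the aortic axis with a conservative
#' first-order upwind finite-volume scheme. The axial velocity in each cell
#' is the net axial flow divided by the local lumen area; native blood
#' (`phi = 0`) enters at the root and ECMO blood (`phi = 1`) enters
#' retrograde at the descending end; each supra-aortic branch draws the
#' fraction present at its ostium. Sub-stepping is applied automatically
#' whenever the advective CFL condition would be violated at the simulation
#' timestep.
#'
#' @param sim a [simulate_flow()] result.
#' @param n_cells number of finite-volume cells along the aortic axis.
#' @param cfl Courant number used for sub-stepping (< 1).
#' @return An object of class `ecmo_transport`: `s_cells` (cell centers,
#'   mm), `phi` (time x cell matrix in \[0, 1\]), `s_star` (watershed arc
#'   position per timestep, mm; `NA` when flow is antegrade everywhere),
#'   `ostium_phi` (time x branch), and a `balance` list with the phase-2
#'   volume bookkeeping over the final cycle.
#' @export
transport_fraction <- function(sim, n_cells = 240, cfl = 0.9) {
  net <- sim$net
  s_end <- net$s_end / 1000                           # m
  ds <- s_end / n_cells
  s_faces <- seq(0, s_end, length.out = n_cells + 1)  # m
  s_cells <- (head(s_faces, -1) + tail(s_faces, -1)) / 2
  r_cells <- approx(net$axis$s / 1000, net$axis$r / 1000, xout = s_cells,
                    rule = 2)$y
  area <- pi * r_cells^2                              # m^2
  vol <- area * ds                                    # m^3

  branches <- intersect(c("bca", "lcca", "lsa"), colnames(sim$outlet_flow))
  s_b <- net$ostia_s[branches] / 1000
  cell_b <- pmin(n_cells, pmax(1, findInterval(s_b, s_faces,
                                               rightmost.closed = TRUE)))
  names(cell_b) <- branches

  n_steps <- length(sim$times)
  dt <- sim$cfg$dt
  phi <- numeric(n_cells)
  phi_hist <- matrix(NA_real_, n_steps, n_cells)
  s_star <- rep(NA_real_, n_steps)
  ostium_phi <- matrix(NA_real_, n_steps, length(branches),
                       dimnames = list(NULL, branches))

  idx_final <- final_cycle_idx(sim)
  cum_in_ef <- 0; cum_out <- 0
  v2_start <- if (idx_final[1] == 1) 0 else NA_real_
  warned <- FALSE

  s_faces_mm <- s_faces * 1000
  for (step in seq_len(n_steps)) {
    q_card <- sim$cardiac_q[step]
    # face flows: cardiac inflow minus branch draws proximal of the face
    q_faces <- rep(q_card, n_cells + 1)
    for (b in branches) {
      q_faces[s_faces > s_b[[b]] + 1e-12] <-
        q_faces[s_faces > s_b[[b]] + 1e-12] - sim$outlet_flow[step, b]
    }
    q_b <- sim$outlet_flow[step, branches]

    # CFL bound includes the branch draw at ostium cells so the upwind
    # update can never empty a cell within one sub-step
    out_bound <- (max(abs(q_faces)) + max(0, q_b, na.rm = TRUE)) / min(vol)
    n_sub <- max(1L, ceiling(dt * out_bound / cfl))
    if (n_sub > 1 && !warned) {
      inform(sprintf("transport CFL sub-stepping engaged (up to %d sub-steps)",
                     n_sub))
      warned <- TRUE
    }
    dts <- dt / n_sub
    for (sub in seq_len(n_sub)) {
      phi_up <- c(0, phi)              # ghost: native blood at the root
      phi_dn <- c(phi, 1)              # ghost: ECMO blood below the entry
      flux <- ifelse(q_faces >= 0,
                     q_faces * phi_up,
                     q_faces * phi_dn)
      dphi <- (head(flux, -1) - tail(flux, -1)) / vol
      # branch uptake removes phi at the ostium cell together with its volume
      for (b in branches) {
        i <- cell_b[[b]]
        dphi[i] <- dphi[i] - q_b[[b]] * phi[i] / vol[i]
      }
      if (step %in% idx_final) {
        q_bot <- q_faces[n_cells + 1]
        cum_in_ef <- cum_in_ef + dts * max(-q_bot, 0)
        cum_out <- cum_out + dts * (max(q_bot, 0) * phi[n_cells] +
                                      sum(q_b * phi[cell_b]))
      }
      phi <- phi + dts * dphi
      phi <- pmin(1, pmax(0, phi))
    }
    if (step == idx_final[1] - 1) v2_start <- sum(phi * vol)
    phi_hist[step, ] <- phi
    ostium_phi[step, ] <- phi[cell_b]
    s_star[step] <- watershed_from_profile(q_faces, s_faces_mm)
  }

  v2_end <- sum(phi * vol)
  structure(
    list(s_cells = s_cells * 1000, phi = phi_hist, s_star = s_star,
         ostium_phi = ostium_phi, times = sim$times,
         balance = list(v2_start = v2_start, v2_end = v2_end,
                        cum_ef_in = cum_in_ef, cum_phase2_out = cum_out),
         n_cells = n_cells, ds_mm = ds * 1000),
    class = "ecmo_transport"
  )
}

# Most proximal face where the axial net flow turns non-positive; NA when
# flow is antegrade everywhere.
watershed_from_profile <- function(q_faces, s_faces_mm) {
  neg <- which(q_faces <= 0)
  if (length(neg) == 0) return(NA_real_)
  s_faces_mm[neg[1]]
}

#' @export
print.ecmo_transport <- function(x, ...) {
  cat(sprintf("<ecmo_transport> %d cells x %d steps; final-cycle phase-2 balance error %.2f%%\n",
              x$n_cells, nrow(x$phi), 100 * transport_balance_error(x)))
  invisible(x)
}

# Relative error of the phase-2 volume budget over the final cycle.
transport_balance_error <- function(tr) {
  b <- tr$balance
  if (b$cum_ef_in <= 0) return(0)
  abs((b$v2_end - b$v2_start + b$cum_phase2_out) - b$cum_ef_in) / b$cum_ef_in
}

#' @export
autoplot.ecmo_transport <- function(object, ...) {
  d <- as_tibble(object$phi)
  names(d) <- sprintf("c%04d", seq_len(ncol(object$phi)))
  d$time <- object$times
  d <- pivot_longer(d, -"time", names_to = "cell", values_to = "phi")
  d$s_mm <- object$s_cells[as.integer(sub("c", "", d$cell))]
  ggplot(d, aes(.data$time, .data$s_mm, fill = .data$phi)) +
    geom_raster() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = "time [s]", y = "arc length along aorta [mm]",
         fill = expression(phi),
         title = "ECMO blood fraction along the aortic axis") +
    theme_minimal()
}

#' Locate the native/ECMO watershed zone
#'
#' Finds the arc position `s*` where the axial net flow changes sign at the
#' queried phase of the final cycle (systolic peak = time of maximum cardiac
#' inflow; diastolic = time of minimum cardiac inflow) and classifies it
#' against the ostium positions into one of: `ascending`, `bca_lcca`,
#' `lcca_lsa`, `at_lsa`, `descending`, or `none` (flow antegrade
#' everywhere). With several sign changes the most proximal is reported and
#' flagged.
#'
#' @param sim a [simulate_flow()] result.
#' @param phase `"systolic"` or `"diastolic"`.
#' @param n_faces resolution of the axial profile used for localization.
#' @return One-row tibble of class `watershed_report`: `phase`, `zone`,
#'   `s_star_mm`, `multiple_crossings`.
#' @export
watershed_location <- function(sim, phase = c("systolic", "diastolic"),
                               n_faces = 241) {
  phase <- match.arg(phase)
  idx <- final_cycle_idx(sim)
  step <- if (phase == "systolic") {
    idx[which.max(sim$cardiac_q[idx])]
  } else {
    idx[which.min(sim$cardiac_q[idx])]
  }
  s_faces <- seq(0, sim$net$s_end, length.out = n_faces)
  q <- axial_flow_profile(sim, s_faces, step)
  sgn <- sign(q)
  crossings <- sum(diff(sgn[sgn != 0]) != 0)
  s_star <- watershed_from_profile(q, s_faces)
  ds <- s_faces[2] - s_faces[1]
  ost <- sim$net$ostia_s
  zone <- if (is.na(s_star)) {
    "none"
  } else if (abs(s_star - ost[["lsa"]]) <= ds) {
    "at_lsa"
  } else if (s_star < ost[["bca"]]) {
    "ascending"
  } else if (s_star < ost[["lcca"]]) {
    "bca_lcca"
  } else if (s_star < ost[["lsa"]]) {
    "lcca_lsa"
  } else {
    "descending"
  }
  structure(
    tibble(phase = phase, zone = zone, s_star_mm = s_star,
           multiple_crossings = crossings > 1),
    class = c("watershed_report", "tbl_df", "tbl", "data.frame")
  )
}
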