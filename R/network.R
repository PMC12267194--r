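#' Blood properties
#'
#' Constant-density Newtonian blood: density 1060 kg/m^3 and dynamic
#' viscosity 3.5e-3 Pa s by default.
#'
#' @param density kg/m^3.
#' @param viscosity dynamic viscosity, Pa s.
#' @return An object of class `fluid_props`.
#' @export
fluid_props <- function(density = 1060, viscosity = 3.5e-3) {
  stopifnot_positive(density, "density")
  stopifnot_positive(viscosity, "viscosity")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_props")
}

#' Poiseuille resistance of a vessel segment
#'
#' `R = 8 * mu * L / (pi * r^4)` for fully developed laminar flow.
#'
#' @param length_m segment length, m.
#' @param radius_m lumen radius, m.
#' @param viscosity dynamic viscosity, Pa s.
#' @return Resistance, Pa s/m^3.
#' @export
poiseuille_resistance <- function(length_m, radius_m, viscosity = 3.5e-3) {
  if (any(radius_m <= 0)) abort("non-positive radius in resistance computation")
  8 * viscosity * length_m / (pi * radius_m^4)
}

#' Build a lumped vascular network from the seven tracts
#'
#' Reduces the aortic geometry to a resistive network: nodes at the root,
#' the three supra-aortic ostia and the descending end, with segment
#' resistances `8 mu L / (pi r^4)` computed from each tract's length and
#' mean inscribed radius. The aortic axis (arc length and local radius from
#' root to descending end) is retained for the 1D transport of the ECMO
#' blood fraction.
#'
#' In `"healthy"` mode the descending end carries its own Windkessel
#' outlet. In `"ecmo"` mode the descending end is the ECMO return site: a
#' constant ECMO flow enters there and distal (abdominal) perfusion leaves
#' through an appended abdominal segment whose Windkessel outlet reuses the
#' descending parameters.
#'
#' @param tracts a [split_tracts()] result with features computable for all
#'   seven tracts.
#' @param fluid a [fluid_props()].
#' @param mode `"healthy"` or `"ecmo"`.
#' @param abdominal list with `length_mm` and optional `radius_mm` for the
#'   abdominal segment appended in ECMO mode.
#' @return An object of class `vessel_network`: tibbles `segments` and
#'   `outlets`, plus the transport `axis` and ostium arc lengths.
#' @export
build_network <- function(tracts, fluid = fluid_props(),
                          mode = c("healthy", "ecmo"),
                          abdominal = list(length_mm = 60, radius_mm = NULL)) {
  mode <- match.arg(mode)
  ostia_s <- attr(tracts, "ostia_s")
  if (is.null(ostia_s)) abort("tracts must come from split_tracts()")
  main <- filter(tracts, .data$tract == "total")
  if (any(main$r <= 0)) abort("non-positive inscribed radius on the aortic axis")

  seg_between <- function(s0, s1, name, from, to) {
    sel <- main$s >= s0 - 1e-9 & main$s <= s1 + 1e-9
    r_mean <- mean(main$r[sel])
    L <- s1 - s0
    tibble(segment = name, from = from, to = to,
           length_mm = L, radius_mm = r_mean,
           resistance = poiseuille_resistance(L / 1000, r_mean / 1000,
                                              fluid$viscosity))
  }
  branch_seg <- function(bname) {
    b <- filter(tracts, .data$tract == bname)
    L <- max(b$s)
    r_mean <- mean(b$r)
    tibble(segment = bname, from = paste0(bname, "_ostium"), to = paste0(bname, "_outlet"),
           length_mm = L, radius_mm = r_mean,
           resistance = poiseuille_resistance(L / 1000, r_mean / 1000,
                                              fluid$viscosity))
  }
  s_end <- max(main$s)
  segments <- bind_rows(
    seg_between(0, ostia_s[["bca"]], "ascending", "root", "bca_ostium"),
    seg_between(ostia_s[["bca"]], ostia_s[["lcca"]], "arch_a", "bca_ostium", "lcca_ostium"),
    seg_between(ostia_s[["lcca"]], ostia_s[["lsa"]], "arch_b", "lcca_ostium", "lsa_ostium"),
    seg_between(ostia_s[["lsa"]], s_end, "descending", "lsa_ostium", "desc_end"),
    branch_seg("bca"), branch_seg("lcca"), branch_seg("lsa")
  )
  # coincident ostia (bovine arch, or clamped LCCA projections) collapse an
  # arch piece to zero length: drop it and merge its end nodes
  node_map <- c(root = "root", bca_ostium = "bca_ostium",
                lcca_ostium = "lcca_ostium", lsa_ostium = "lsa_ostium",
                desc_end = "desc_end")
  for (nm in c("arch_a", "arch_b")) {
    i <- which(segments$segment == nm & segments$length_mm < 1e-9)
    if (length(i) == 1) {
      keep_node <- node_map[[segments$from[i]]]
      drop_node <- segments$to[i]
      node_map[node_map == drop_node] <- keep_node
      segments <- segments[-i, ]
    }
  }
  remap <- function(x) ifelse(x %in% names(node_map), unname(node_map[x]), x)
  segments$from <- remap(segments$from)
  segments$to <- remap(segments$to)

  outlets <- tibble(
    outlet = c("bca", "lcca", "lsa"),
    node = unname(node_map[paste0(c("bca", "lcca", "lsa"), "_ostium")]),
    seg_resistance = segments$resistance[match(c("bca", "lcca", "lsa"),
                                               segments$segment)],
    Rp = NA_real_, Rd = NA_real_, C = NA_real_, P0 = 0
  )
  if (mode == "healthy") {
    outlets <- bind_rows(outlets, tibble(
      outlet = "descending", node = "desc_end", seg_resistance = 0,
      Rp = NA_real_, Rd = NA_real_, C = NA_real_, P0 = 0
    ))
  } else {
    r_abd <- abdominal$radius_mm %||% main$r[nrow(main)]
    R_abd <- poiseuille_resistance(abdominal$length_mm / 1000, r_abd / 1000,
                                   fluid$viscosity)
    outlets <- bind_rows(outlets, tibble(
      outlet = "abdominal", node = "desc_end", seg_resistance = R_abd,
      Rp = NA_real_, Rd = NA_real_, C = NA_real_, P0 = 0
    ))
  }

  axis <- main[, c("s", "r")]
  structure(
    list(mode = mode, fluid = fluid, segments = segments, outlets = outlets,
         axis = axis, ostia_s = ostia_s, s_end = s_end),
    class = "vessel_network"
  )
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf("<vessel_network> mode '%s': %d segments, outlets: %s\n",
              x$mode, nrow(x$segments), paste(x$outlets$outlet, collapse = ", ")))
  if (all(is.na(x$outlets$Rp))) cat("  Windkessel outlets not yet calibrated\n")
  invisible(x)
}

#' Attach Windkessel parameters to the network outlets
#'
#' @param net a [build_network()] result.
#' @param params tibble with columns `outlet`, `Rp`, `Rd`, `C` (and
#'   optionally `P0`); `outlet = "descending"` parameters are reused for the
#'   `"abdominal"` outlet of an ECMO-mode network.
#' @return The network with outlet parameters set.
#' @export
set_windkessel <- function(net, params) {
  p <- as_tibble(params)
  if ("abdominal" %in% net$outlets$outlet && !"abdominal" %in% p$outlet &&
      "descending" %in% p$outlet) {
    pd <- p[p$outlet == "descending", ]
    pd$outlet <- "abdominal"
    p <- bind_rows(p, pd)
  }
  idx <- match(net$outlets$outlet, p$outlet)
  if (anyNA(idx)) {
    abort(sprintf("missing Windkessel parameters for outlet(s): %s",
                  paste(net$outlets$outlet[is.na(idx)], collapse = ", ")))
  }
  for (f in c("Rp", "Rd", "C")) net$outlets[[f]] <- p[[f]][idx]
  if ("P0" %in% names(p)) net$outlets$P0 <- p$P0[idx]
  bad <- net$outlets$Rp <= 0 | net$outlets$Rd <= 0 | net$outlets$C <= 0
  if (any(bad)) abort("Windkessel parameters must be positive for every outlet")
  net
}
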