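# Discrete Frenet estimators.
#
# Derivatives are taken with central differences against arc length, and the
# polyline is optionally pre-smoothed with a short moving average before the
# curvature/torsion estimates: discrete third differences amplify sampling
# noise, and the window (default 5 points) is recorded in the output.
smooth_polyline <- function(pts, window) {
  if (window <= 1 || nrow(pts) < window) return(pts)
  half <- (window - 1) %/% 2
  n <- nrow(pts)
  out <- pts
  for (i in seq_len(n)) {
    # the window tapers symmetrically near the ends: an asymmetric average
    # would drag boundary points sideways and kink the curve
    h <- min(half, i - 1, n - i)
    if (h > 0) out[i, ] <- colMeans(pts[(i - h):(i + h), , drop = FALSE])
  }
  out
}

# Curvature and signed torsion at interior vertices of a polyline.
discrete_frenet <- function(pts) {
  n <- nrow(pts)
  if (n < 5) abort("curvature/torsion need at least 5 points")
  s <- cumulative_arclength(pts)

  d1 <- matrix(NA_real_, n, 3)
  d2 <- matrix(NA_real_, n, 3)
  for (i in 2:(n - 1)) {
    h1 <- s[i] - s[i - 1]
    h2 <- s[i + 1] - s[i]
    d1[i, ] <- (pts[i + 1, ] - pts[i - 1, ]) / (h1 + h2)
    d2[i, ] <- 2 * ((pts[i + 1, ] - pts[i, ]) / h2 -
                      (pts[i, ] - pts[i - 1, ]) / h1) / (h1 + h2)
  }
  d3 <- matrix(NA_real_, n, 3)
  for (i in 3:(n - 2)) {
    d3[i, ] <- (d2[i + 1, ] - d2[i - 1, ]) / (s[i + 1] - s[i - 1])
  }

  idx <- 3:(n - 2)
  cr <- t(apply(cbind(d1[idx, ], d2[idx, ]), 1, function(v) {
    pracma_cross(v[1:3], v[4:6])
  }))
  num <- row_norms(cr)
  speed <- row_norms(d1[idx, , drop = FALSE])
  kappa <- num / speed^3
  tau <- rep(0, length(idx))
  ok <- kappa > 1e-6  # torsion is undefined at zero curvature
  tau[ok] <- rowSums(cr[ok, , drop = FALSE] * d3[idx, , drop = FALSE][ok, , drop = FALSE]) /
    num[ok]^2
  tibble(index = idx, kappa = kappa, tau = tau)
}

#' Morphometric features of one tract
#'
#' Computes, for a centerline polyline with inscribed radii, the five
#' quantities used to characterize aortic tracts: (i) length, (ii) tortuosity
#' (polyline length over the endpoint chord, so always >= 1), (iii) mean and
#' SD of the maximal-inscribed-sphere radius, (iv) mean and SD of curvature
#' (inverse osculating-circle radius) and (v) mean and SD of signed torsion
#' (rotation rate of the osculating plane). Curvature and torsion use
#' discrete Frenet formulas on a moving-average-smoothed copy of the
#' polyline; torsion is set to 0 where curvature < 1e-6 /mm.
#'
#' @param tract tibble with columns `x`, `y`, `z` and optionally `r` (mm).
#' @param smooth_window moving-average window (points) applied before the
#'   curvature/torsion estimates only; 1 disables smoothing.
#' @return One-row tibble: `length`, `tortuosity`, `radius_mean`,
#'   `radius_sd`, `curvature_mean`, `curvature_sd`, `torsion_mean`,
#'   `torsion_sd`, `smooth_window`.
#' @export
#' @examples
#' th <- seq(0, pi, length.out = 100)
#' semi <- tibble::tibble(x = 25 * cos(th), y = 25 * sin(th), z = 0, r = 5)
#' compute_features(semi)$tortuosity  # pi/2
compute_features <- function(tract, smooth_window = 5) {
  pts <- as.matrix(tract[, c("x", "y", "z")])
  keep <- c(TRUE, row_norms(diff(pts)) > 1e-9)
  if (sum(keep) < nrow(pts)) {
    pts <- pts[keep, , drop = FALSE]
    tract <- tract[keep, ]
  }
  if (nrow(pts) < 4) abort("tract is degenerate: fewer than 4 distinct points")

  len <- sum(row_norms(diff(pts)))
  chord <- vnorm(pts[nrow(pts), ] - pts[1, ])
  if (chord < 1e-9) abort("tract endpoints coincide; tortuosity undefined")

  sm <- smooth_polyline(pts, smooth_window)
  fr <- discrete_frenet(sm)
  # drop estimates whose stencil touches the tapered boundary windows
  trim <- if (smooth_window > 1) (smooth_window - 1) %/% 2 else 0
  if (nrow(fr) > 2 * trim + 4) {
    fr <- fr[fr$index > 2 + trim & fr$index <= nrow(sm) - 2 - trim, ]
  }

  r <- if ("r" %in% names(tract)) tract$r else rep(NA_real_, nrow(tract))
  tibble(
    length = len,
    tortuosity = len / chord,
    radius_mean = mean(r),
    radius_sd = sd(r),
    curvature_mean = mean(fr$kappa),
    curvature_sd = sd(fr$kappa),
    torsion_mean = mean(fr$tau),
    torsion_sd = sd(fr$tau),
    smooth_window = smooth_window
  )
}

#' Split a centerline tree into the seven characteristic tracts
#'
#' Partitions the aortic centerline at the ostium projections into ascending
#' (root to BCA ostium), arch (BCA to LSA ostium) and descending (LSA ostium
#' to outlet), and adds the three branch tracts and the total aorta: seven
#' tracts in all. The three main tracts share their boundary points, so
#' their lengths sum exactly to the total length.
#'
#' @param tree a `centerline_tree`.
#' @param ostia optional named integer vector of main-centerline row indices
#'   for the BCA/LCCA/LSA ostium projections; defaults to the tree's branch
#'   attachment rows.
#' @return An object of class `tract_set`: a tibble with columns `tract`,
#'   `x`, `y`, `z`, `r`, `s`, carrying the ostium arc lengths as attribute
#'   `ostia_s`.
#' @export
split_tracts <- function(tree, ostia = NULL) {
  from_tree <- is.null(ostia)
  ostia <- ostia %||% tree$attach
  i_bca <- ostia[["bca"]]; i_lcca <- ostia[["lcca"]]; i_lsa <- ostia[["lsa"]]
  if (from_tree) {
    # shape-model sweeps of a population mixing bovine and standard arches
    # can project the LCCA ostium marginally outside [BCA, LSA]; clamp it,
    # which reproduces the shared-origin (bovine) semantics at the boundary
    i_lcca <- min(max(i_lcca, i_bca), i_lsa)
  }
  # bovine arches may share the BCA/LCCA ostium; otherwise order is strict
  if (i_lcca < i_bca || i_lsa < i_lcca || i_lsa <= i_bca) {
    abort("ostia out of order along the arch (need BCA <= LCCA < LSA)")
  }
  main <- tree$main
  n <- nrow(main)
  piece <- function(rows, name) mutate(main[rows, ], tract = name)
  tracts <- bind_rows(
    piece(seq_len(n), "total"),
    piece(1:i_bca, "ascending"),
    piece(i_bca:i_lsa, "arch"),
    piece(i_lsa:n, "descending"),
    mutate(tree$branches$bca, tract = "bca"),
    mutate(tree$branches$lcca, tract = "lcca"),
    mutate(tree$branches$lsa, tract = "lsa")
  )
  structure(
    tracts[, c("tract", "x", "y", "z", "r", "s")],
    ostia_s = c(bca = main$s[i_bca], lcca = main$s[i_lcca], lsa = main$s[i_lsa]),
    ostia_rows = c(bca = i_bca, lcca = i_lcca, lsa = i_lsa),
    class = c("tract_set", class(tracts))
  )
}

tract_names <- function() {
  c("total", "ascending", "arch", "descending", "bca", "lcca", "lsa")
}

#' Morphometric feature table for a set of geometries
#'
#' Extracts centerlines, splits the seven tracts and computes the five
#' morphometric quantities for every geometry in a corresponded set.
#'
#' @param geometries list of `aorta_geometry` objects (or a single one).
#' @param smooth_window see [compute_features()].
#' @return Tibble with one row per geometry x tract: `label`, `tract` and the
#'   [compute_features()] columns.
#' @export
feature_table <- function(geometries, smooth_window = 5) {
  if (inherits(geometries, "aorta_geometry")) geometries <- list(geometries)
  rows <- map(geometries, function(g) {
    tracts <- split_tracts(centerlines_from_geometry(g))
    per <- map(tract_names(), function(tn) {
      ft <- compute_features(filter(tracts, .data$tract == tn),
                             smooth_window = smooth_window)
      mutate(ft, tract = tn)
    })
    mutate(bind_rows(per), label = g$label)
  })
  out <- bind_rows(rows)
  out[, c("label", "tract", setdiff(names(out), c("label", "tract")))]
}

feature_quantities <- function() {
  c("length", "tortuosity", "radius_mean", "radius_sd",
    "curvature_mean", "curvature_sd", "torsion_mean", "torsion_sd")
}

#' Compare morphometric features against the template
#'
#' Computes the percent difference of every quantity from the template value,
#' per tract, as `100 * (value - template) / template`. Where the template
#' value is (near) zero the difference is reported as an absolute difference
#' and flagged in the `absolute_difference` column. Population mean and SD
#' per (tract, quantity) are attached as attribute `population_summary`.
#'
#' @param features tibble from [feature_table()].
#' @param template_label label of the template geometry (default
#'   `"template"`).
#' @return Long tibble: `label`, `tract`, `quantity`, `value`,
#'   `template_value`, `pct_diff`, `absolute_difference`.
#' @export
compare_to_template <- function(features, template_label = "template") {
  if (!template_label %in% features$label) {
    abort(sprintf("template geometry '%s' not present in the feature table",
                  template_label))
  }
  long <- pivot_longer(features[, c("label", "tract", feature_quantities())],
                       cols = all_of(feature_quantities()),
                       names_to = "quantity", values_to = "value")
  tmpl <- filter(long, .data$label == template_label)
  tmpl <- rename(tmpl, template_value = "value")
  out <- left_join(long, tmpl[, c("tract", "quantity", "template_value")],
                   by = c("tract", "quantity"))
  # a signed quantity whose template value sits near zero (torsion of a
  # near-planar tract, say) would make percent differences explode; such
  # cells fall back to absolute differences and are flagged
  out <- mutate(
    group_by(out, .data$tract, .data$quantity),
    absolute_difference =
      abs(.data$template_value) < 0.05 * max(abs(.data$value), 1e-12),
    pct_diff = ifelse(.data$absolute_difference,
                      .data$value - .data$template_value,
                      100 * (.data$value - .data$template_value) /
                        .data$template_value)
  )
  out <- ungroup(out)
  summ <- summarise(group_by(out, .data$tract, .data$quantity),
                    mean = mean(.data$value), sd = sd(.data$value),
                    .groups = "drop")
  structure(out, population_summary = summ,
            template_label = template_label,
            class = c("feature_comparison", class(out)))
}

#' Select the morphologically most representative geometries
#'
#' Restricts the comparison table to single-mode shapes generated from modes
#' below `mode_limit`, ranks them by the maximum absolute percent deviation
#' from the template across all (tract, quantity) cells, and returns the top
#' `k` labels plus the template. Ties break by lexicographic label order, so
#' selection is deterministic.
#'
#' @param comparison a [compare_to_template()] table.
#' @param k number of geometries to select.
#' @param mode_limit only shapes from modes `< mode_limit` are eligible.
#' @return Character vector of selected labels (template last).
#' @export
select_representatives <- function(comparison, k = 20, mode_limit = 10) {
  if (nrow(comparison) == 0) abort("empty feature comparison")
  template_label <- attr(comparison, "template_label") %||% "template"
  scores <- summarise(group_by(comparison, .data$label),
                      score = max(abs(.data$pct_diff), na.rm = TRUE),
                      .groups = "drop")
  scores <- filter(scores, .data$label != template_label)
  info <- parse_sd_label(scores$label)
  scores <- scores[!is.na(info$mode) & info$mode < mode_limit &
                     lengths(regmatches(scores$label, gregexpr("_sd", scores$label))) == 1, ]
  scores <- arrange(scores, desc(.data$score), .data$label)
  if (k > nrow(scores)) {
    warn(sprintf("requested k = %d but only %d eligible geometries; returning all",
                 k, nrow(scores)))
    k <- nrow(scores)
  }
  c(scores$label[seq_len(k)], template_label)
}

#' Result planes along the aorta
#'
#' Defines the three cross-sectional result planes used to probe the flow
#' field: pre-arch at 85% of the ascending tract's arc length, post-arch at
#' 10% of the descending tract, and a descending plane at 90% of the
#' descending tract. Each plane is anchored on the centerline with the local
#' Frenet tangent (central difference, normalized) as its unit normal.
#'
#' @param tracts a [split_tracts()] result.
#' @return Tibble with columns `plane`, `tract`, `fraction`, `x`, `y`, `z`,
#'   `nx`, `ny`, `nz`.
#' @export
define_result_planes <- function(tracts) {
  plane_at <- function(tract_name, frac, plane_name) {
    p <- filter(tracts, .data$tract == tract_name)
    if (nrow(p) < 3) abort(sprintf("tract '%s' too short to interpolate a plane", tract_name))
    s <- p$s - p$s[1]
    target <- frac * s[length(s)]
    i <- findInterval(target, s, rightmost.closed = TRUE)
    i <- max(1, min(i, nrow(p) - 1))
    w <- (target - s[i]) / (s[i + 1] - s[i])
    pt <- (1 - w) * c(p$x[i], p$y[i], p$z[i]) + w * c(p$x[i + 1], p$y[i + 1], p$z[i + 1])
    nrm <- unitize(c(p$x[i + 1], p$y[i + 1], p$z[i + 1]) - c(p$x[i], p$y[i], p$z[i]))
    tibble(plane = plane_name, tract = tract_name, fraction = frac,
           x = pt[1], y = pt[2], z = pt[3],
           nx = nrm[1], ny = nrm[2], nz = nrm[3])
  }
  bind_rows(
    plane_at("ascending", 0.85, "pre-arch"),
    plane_at("descending", 0.10, "post-arch"),
    plane_at("descending", 0.90, "descending")
  )
}

#' @export
autoplot.tract_set <- function(object, ...) {
  ggplot(object, aes(x = .data$x, y = .data$z, colour = .data$tract)) +
    geom_path(linewidth = 0.8) +
    coord_equal() +
    labs(x = "x [mm]", y = "z [mm]", colour = "tract",
         title = "Centerline tracts (frontal projection)") +
    theme_minimal()
}
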