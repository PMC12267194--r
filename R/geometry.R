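#' Surface sampling resolution
#'
#' Controls how densely the swept-tube surfaces are sampled. The default
#' (360 main-vessel rings, 54 rings per branch, 48 samples per ring) yields
#' 25,056 surface points per geometry, i.e. a node budget of ~25,000.
#'
#' @param main_rings number of rings along the main vessel (root to
#'   descending end).
#' @param branch_rings number of rings along each supra-aortic branch.
#' @param ring_samples number of circumferential samples per ring.
#' @return An object of class `geometry_resolution`.
#' @export
geometry_resolution <- function(main_rings = 360, branch_rings = 54,
                                ring_samples = 48) {
  if (main_rings < 8 || branch_rings < 4 || ring_samples < 6) {
    abort("resolution too coarse: need >= 8 main rings, >= 4 branch rings, >= 6 ring samples")
  }
  structure(
    list(
      main_rings = as.integer(main_rings),
      branch_rings = as.integer(branch_rings),
      ring_samples = as.integer(ring_samples)
    ),
    class = "geometry_resolution"
  )
}

n_points_for <- function(res) {
  res$main_rings * res$ring_samples + 3L * res$branch_rings * res$ring_samples
}

#' Point layout shared by a corresponded population
#'
#' Maps each surface point index to its parametric location: a component
#' (`"aorta"`, `"bca"`, `"lcca"`, `"lsa"`), a ring index within that
#' component and a circumferential sample index. All geometries built at the
#' same resolution share this layout; it is what makes the population
#' point-corresponded.
#'
#' @param resolution a [geometry_resolution()].
#' @return A tibble with columns `point`, `component`, `ring`, `sample`.
#' @export
layout_from_resolution <- function(resolution) {
  comps <- c("aorta", "bca", "lcca", "lsa")
  rings <- c(resolution$main_rings, rep(resolution$branch_rings, 3))
  m <- resolution$ring_samples
  tab <- purrr::map2(comps, rings, function(comp, nr) {
    tibble(
      component = comp,
      ring = rep(seq_len(nr), each = m),
      sample = rep(seq_len(m), nr)
    )
  })
  out <- bind_rows(tab)
  out$point <- seq_len(nrow(out))
  out[, c("point", "component", "ring", "sample")]
}

# --- centerline construction ------------------------------------------------

# Main-vessel centerline position at arc lengths s (vector), plus radii.
# Ascending runs along +z from the origin; the arch is a circular arc in the
# x-z plane (center at (-R, 0, L_asc)) carrying an out-of-plane sin^2 bump of
# amplitude `torsion_amplitude`; the descending segment continues straight
# along the arch's end tangent.
main_centerline_points <- function(params, s) {
  L_asc <- params$ascending_length
  R <- params$arch_radius
  ang <- params$arch_angle
  L_arch <- R * ang
  L_main <- L_asc + L_arch + params$descending_length
  A <- params$torsion_amplitude

  pts <- matrix(0, nrow = length(s), ncol = 3)
  in_asc <- s <= L_asc
  in_arch <- s > L_asc & s <= L_asc + L_arch
  in_desc <- s > L_asc + L_arch

  pts[in_asc, 3] <- s[in_asc]

  th <- (s[in_arch] - L_asc) / R
  u <- th / ang
  pts[in_arch, 1] <- -R + R * cos(th)
  pts[in_arch, 2] <- A * sin(pi * u)^2
  pts[in_arch, 3] <- L_asc + R * sin(th)

  # arch end point and tangent (the sin^2 bump has zero slope at the ends,
  # so the end tangent is in-plane)
  p_end <- c(-R + R * cos(ang), 0, L_asc + R * sin(ang))
  t_end <- c(-sin(ang), 0, cos(ang))
  if (any(in_desc)) {
    ds <- s[in_desc] - (L_asc + L_arch)
    pts[in_desc, ] <- matrix(p_end, nrow = sum(in_desc), ncol = 3, byrow = TRUE) +
      outer(ds, t_end)
  }

  radii <- params$root_radius * (1 + (params$taper_ratio - 1) * s / L_main)
  list(points = pts, radii = radii, length = L_main,
       arch_span = c(L_asc, L_asc + L_arch))
}

# Spherical linear interpolation between two unit vectors.
slerp <- function(v0, v1, f) {
  d <- max(-1, min(1, sum(v0 * v1)))
  om <- acos(d)
  if (om < 1e-9) return(v0)
  (sin((1 - f) * om) * v0 + sin(f * om) * v1) / sin(om)
}

# Branch centerline: starts just inside the aortic wall at the ostium and
# sweeps outward, its direction blending from the local radial direction d0
# to a more cranial direction d1 over the first 60% of the branch (after an
# optional shared bovine trunk during which the direction is held at d0).
branch_centerline_points <- function(origin, d0, d1, length_mm, n,
                                     trunk = 0) {
  step <- length_mm / (n - 1)
  pts <- matrix(0, nrow = n, ncol = 3)
  pts[1, ] <- origin
  blend_len <- 0.6 * length_mm
  for (k in 2:n) {
    v <- (k - 1.5) * step
    f <- if (v <= trunk) 0 else min(1, (v - trunk) / blend_len)
    d <- unitize(slerp(d0, d1, f))
    pts[k, ] <- pts[k - 1, ] + d * step
  }
  pts
}

# Ostium geometry for one branch: origin point on the wall, initial and
# final sweep directions.
branch_frame <- function(params, u, tilt) {
  L_asc <- params$ascending_length
  R <- params$arch_radius
  ang <- params$arch_angle
  th <- u * ang
  s_ost <- L_asc + u * R * ang
  centre <- main_centerline_points(params, s_ost)
  radial <- c(cos(th), 0, sin(th))
  d0 <- unitize(radial + c(0, tilt, 0))
  d1 <- unitize(0.25 * radial + c(0, tilt, 1))
  wall <- drop(centre$points) + d0 * 0.9 * centre$radii
  list(s = s_ost, origin = wall, d0 = d0, d1 = d1)
}

# Parallel-transport an orthonormal frame along a polyline; returns the
# normal (n) and binormal (b) at every vertex.
transport_frames <- function(pts) {
  n_pt <- nrow(pts)
  tangents <- matrix(0, n_pt, 3)
  tangents[1, ] <- unitize(pts[2, ] - pts[1, ])
  tangents[n_pt, ] <- unitize(pts[n_pt, ] - pts[n_pt - 1, ])
  if (n_pt > 2) {
    for (i in 2:(n_pt - 1)) tangents[i, ] <- unitize(pts[i + 1, ] - pts[i - 1, ])
  }
  nrm <- matrix(0, n_pt, 3)
  bin <- matrix(0, n_pt, 3)
  seed <- if (abs(tangents[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  nrm[1, ] <- unitize(seed - sum(seed * tangents[1, ]) * tangents[1, ])
  bin[1, ] <- pracma_cross(tangents[1, ], nrm[1, ])
  for (i in 2:n_pt) {
    v <- nrm[i - 1, ] - sum(nrm[i - 1, ] * tangents[i, ]) * tangents[i, ]
    if (vnorm(v) < 1e-12) v <- bin[i - 1, ]
    nrm[i, ] <- unitize(v)
    bin[i, ] <- pracma_cross(tangents[i, ], nrm[i, ])
  }
  list(tangent = tangents, normal = nrm, binormal = bin)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Sweep circular rings along a centerline: one ring of `m` samples per
# centerline vertex, radius per vertex.
sweep_tube <- function(centers, radii, m) {
  fr <- transport_frames(centers)
  theta <- 2 * pi * (seq_len(m) - 1) / m
  out <- matrix(0, nrow = nrow(centers) * m, ncol = 3)
  for (i in seq_len(nrow(centers))) {
    ring <- centers[rep(i, m), , drop = FALSE] +
      radii[i] * (outer(cos(theta), fr$normal[i, ]) +
                    outer(sin(theta), fr$binormal[i, ]))
    out[((i - 1) * m + 1):(i * m), ] <- ring
  }
  out
}

# --- geometry assembly ------------------------------------------------------

#' Build one synthetic aortic geometry
#'
#' Constructs a swept-tube surface from anatomical parameters: circular rings
#' are swept along the main centerline (ascending + arch + descending, with a
#' linearly tapering radius) and along each supra-aortic branch. The exact
#' centerline tree and the ostium landmarks used during construction are
#' stored on the result as ground truth, so downstream centerline extraction
#' can be validated.
#'
#' @param params an [aorta_params()] object.
#' @param resolution a [geometry_resolution()].
#' @param label geometry label (string).
#' @return An object of class `aorta_geometry`: a list with elements
#'   `label`, `points` (n x 3 matrix, mm), `layout` (see
#'   [layout_from_resolution()]), `centerline` (ground-truth
#'   `centerline_tree`), `ostia` (named surface point indices for the three
#'   ostium landmarks) and `params`.
#' @export
#' @examples
#' g <- build_geometry(aorta_params(),
#'   resolution = geometry_resolution(main_rings = 40, branch_rings = 8,
#'                                    ring_samples = 12))
#' nrow(g$points)
build_geometry <- function(params, resolution = geometry_resolution(),
                           label = "aorta") {
  validate_aorta_params(params)
  res <- resolution
  m <- res$ring_samples

  # main vessel
  cl <- main_centerline_points(params,
                               s = seq(0, params$ascending_length +
                                         params$arch_radius * params$arch_angle +
                                         params$descending_length,
                                       length.out = res$main_rings))
  s_main <- seq(0, cl$length, length.out = res$main_rings)
  main_pts <- sweep_tube(cl$points, cl$radii, m)

  # branches
  tilts <- c(bca = -0.25, lcca = 0, lsa = 0.25)
  u <- params$branch_origin_u
  if (params$bovine_arch) u[["lcca"]] <- u[["bca"]]
  # distinct ostia require distinct nearest rings (bovine BCA/LCCA excepted)
  ring_of <- function(s_ost) which.min(abs(s_main - s_ost))
  branch_info <- imap(tilts, function(tilt, nm) {
    bf <- branch_frame(params, u[[nm]], tilt)
    trunk <- if (params$bovine_arch && nm == "lcca") params$bovine_trunk_length else 0
    d0 <- if (params$bovine_arch && nm == "lcca") {
      branch_frame(params, u[["bca"]], tilts[["bca"]])$d0
    } else {
      bf$d0
    }
    origin <- if (params$bovine_arch && nm == "lcca") {
      branch_frame(params, u[["bca"]], tilts[["bca"]])$origin
    } else {
      bf$origin
    }
    centers <- branch_centerline_points(origin, d0, bf$d1,
                                        params$branch_lengths[[nm]],
                                        res$branch_rings, trunk = trunk)
    list(name = nm, s_ostium = bf$s, attach_ring = ring_of(bf$s),
         centers = centers, radius = params$branch_radii[[nm]])
  })
  attach_rings <- map_dbl(branch_info, "attach_ring")
  distinct_needed <- if (params$bovine_arch) 2 else 3
  if (length(unique(attach_rings)) < distinct_needed) {
    abort("resolution too coarse to place three distinct ostia on the arch")
  }

  branch_pts <- map(branch_info, function(b) {
    sweep_tube(b$centers, rep(b$radius, nrow(b$centers)), m)
  })

  points <- rbind(main_pts, branch_pts$bca, branch_pts$lcca, branch_pts$lsa)
  layout <- layout_from_resolution(res)

  # ground-truth centerline tree
  tree <- new_centerline_tree(
    main = tibble(
      x = cl$points[, 1], y = cl$points[, 2], z = cl$points[, 3],
      r = cl$radii, s = s_main
    ),
    branches = map(branch_info, function(b) {
      tibble(
        x = b$centers[, 1], y = b$centers[, 2], z = b$centers[, 3],
        r = b$radius,
        s = cumulative_arclength(b$centers)
      )
    }),
    attach = setNames(as.integer(attach_rings), names(branch_info))
  )

  # ostium landmarks: surface point on the main vessel nearest each branch
  # origin
  ostia <- map_dbl(branch_info, function(b) {
    ring <- b$attach_ring
    idx <- which(layout$component == "aorta" & layout$ring == ring)
    ring_pts <- points[idx, , drop = FALSE]
    d <- row_norms(ring_pts - matrix(b$centers[1, ], nrow(ring_pts), 3, byrow = TRUE))
    idx[which.min(d)]
  })

  new_aorta_geometry(
    label = label, points = points, layout = layout,
    centerline = tree, ostia = setNames(as.integer(ostia), names(branch_info)),
    params = params, resolution = res
  )
}

new_aorta_geometry <- function(label, points, layout, centerline, ostia,
                               params = NULL, resolution = NULL) {
  if (!all(is.finite(points))) abort("geometry contains non-finite coordinates")
  structure(
    list(label = label, points = points, layout = layout,
         centerline = centerline, ostia = ostia, params = params,
         resolution = resolution),
    class = "aorta_geometry"
  )
}

#' @export
print.aorta_geometry <- function(x, ...) {
  cat(sprintf("<aorta_geometry '%s'> %d surface points (%d components)\n",
              x$label, nrow(x$points), length(unique(x$layout$component))))
  invisible(x)
}

# Triangulate the swept tubes (quad strips split into triangles), used by the
# mesh writers and the surface-area helper. Vertices are 1-based indices into
# the geometry's point matrix.
geometry_faces <- function(g) {
  lay <- g$layout
  m <- max(lay$sample)
  faces <- list()
  for (comp in unique(lay$component)) {
    idx <- lay$point[lay$component == comp]
    nr <- length(idx) / m
    base <- matrix(idx, nrow = m, ncol = nr)
    for (j in seq_len(nr - 1)) {
      a <- base[, j]
      b <- base[c(2:m, 1), j]
      cpt <- base[c(2:m, 1), j + 1]
      d <- base[, j + 1]
      faces[[length(faces) + 1]] <- cbind(a, b, cpt)
      faces[[length(faces) + 1]] <- cbind(a, cpt, d)
    }
  }
  do.call(rbind, faces)
}

mesh_surface_area <- function(points, faces) {
  v1 <- points[faces[, 2], ] - points[faces[, 1], ]
  v2 <- points[faces[, 3], ] - points[faces[, 1], ]
  cx <- v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2]
  cy <- v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3]
  cz <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}
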