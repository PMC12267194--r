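#' Centerline trees
#'
#' A `centerline_tree` holds the main aortic centerline (root to descending
#' outlet) and one polyline per supra-aortic branch, each with per-point
#' maximal-inscribed-sphere radius `r` and arc length `s` (mm). Branch
#' polylines record the main-centerline row (`attach`) nearest their ostium,
#' so the four root-to-outlet polylines share the root-to-bifurcation prefix
#' point-for-point.
#'
#' @param main tibble with columns `x`, `y`, `z`, `r`, `s`.
#' @param branches named list (`bca`, `lcca`, `lsa`) of tibbles with the same
#'   columns (`s` local to the branch).
#' @param attach named integer vector of main-centerline row indices.
#' @return An object of class `centerline_tree`.
#' @export
new_centerline_tree <- function(main, branches, attach) {
  if (any(diff(main$s) <= 0)) abort("main centerline arc length must be strictly increasing")
  if (any(main$r <= 0)) abort("inscribed radii must be positive")
  structure(
    list(main = as_tibble(main),
         branches = map(branches, as_tibble),
         attach = attach),
    class = "centerline_tree"
  )
}

#' @export
print.centerline_tree <- function(x, ...) {
  cat(sprintf("<centerline_tree> main: %d pts (%.1f mm); branches: %s\n",
              nrow(x$main), max(x$main$s),
              paste(sprintf("%s %d pts", names(x$branches),
                            map_dbl(x$branches, nrow)), collapse = ", ")))
  invisible(x)
}

#' Materialize one root-to-outlet polyline
#'
#' Returns the polyline from the aortic root to the requested outlet as a
#' tibble with cumulative arc length. For a branch outlet this is the shared
#' main-centerline prefix up to the ostium followed by the branch polyline.
#'
#' @param tree a `centerline_tree`.
#' @param outlet one of `"descending"`, `"bca"`, `"lcca"`, `"lsa"`.
#' @return Tibble with columns `x`, `y`, `z`, `r`, `s`.
#' @export
tree_polyline <- function(tree, outlet = c("descending", "bca", "lcca", "lsa")) {
  outlet <- match.arg(outlet)
  if (outlet == "descending") return(tree$main)
  k <- tree$attach[[outlet]]
  pre <- tree$main[seq_len(k), ]
  br <- tree$branches[[outlet]]
  out <- bind_rows(pre[, c("x", "y", "z", "r")], br[, c("x", "y", "z", "r")])
  out$s <- cumulative_arclength(as.matrix(out[, c("x", "y", "z")]))
  out
}

#' Recover the centerline tree from a corresponded surface
#'
#' Rebuilds the centerline of a swept-tube geometry from its surface points
#' using the population ring layout: the centerline point of each ring is the
#' centroid of that ring's surface points, and the local
#' maximal-inscribed-sphere radius is the minimum distance from the centroid
#' to the ring's points. Branch attachment is taken as the main-centerline
#' point nearest each branch's first ring centroid. This is exact for the
#' swept-tube geometry class generated by this package and replaces
#' Voronoi-based centerline extraction.
#'
#' @param g an `aorta_geometry` (must carry its ring layout).
#' @return A `centerline_tree`.
#' @export
#' @examples
#' g <- build_geometry(aorta_params(),
#'   resolution = geometry_resolution(main_rings = 40, branch_rings = 8,
#'                                    ring_samples = 12))
#' tr <- centerlines_from_geometry(g)
#' max(abs(tr$main$r - g$centerline$r)) < 1e-6
centerlines_from_geometry <- function(g) {
  if (is.null(g$layout)) abort("geometry carries no ring layout metadata")
  lay <- g$layout
  pts <- g$points

  comp_tree <- function(comp) {
    idx <- lay$component == comp
    ring <- lay$ring[idx]
    p <- pts[lay$point[idx], , drop = FALSE]
    centers <- cbind(
      rowsum(p[, 1], ring), rowsum(p[, 2], ring), rowsum(p[, 3], ring)
    ) / as.vector(table(ring))
    d <- row_norms(p - centers[ring, , drop = FALSE])
    rmin <- as.vector(tapply(d, ring, min))
    dimnames(centers) <- NULL
    list(centers = centers, r = unname(rmin))
  }

  main <- comp_tree("aorta")
  s_main <- cumulative_arclength(main$centers)
  branches <- list()
  attach <- integer(0)
  for (b in c("bca", "lcca", "lsa")) {
    bt <- comp_tree(b)
    branches[[b]] <- tibble(
      x = bt$centers[, 1], y = bt$centers[, 2], z = bt$centers[, 3],
      r = bt$r, s = cumulative_arclength(bt$centers)
    )
    d0 <- row_norms(main$centers -
                      matrix(bt$centers[1, ], nrow(main$centers), 3, byrow = TRUE))
    attach[[b]] <- which.min(d0)
  }
  new_centerline_tree(
    main = tibble(x = main$centers[, 1], y = main$centers[, 2],
                  z = main$centers[, 3], r = main$r, s = s_main),
    branches = branches,
    attach = attach
  )
}
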