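# Mesh and centerline export. The PLY/STL writers are deliberately minimal
# ASCII writers for the package's own swept-tube meshes; open tube ends are
# closed with triangle fans for export, and the corresponding rings are
# flagged as inlet/outlet boundaries in the population manifest (surface
# formats carry no boundary labels).

#' Export a geometry as ASCII PLY or STL
#'
#' @param g an `aorta_geometry`.
#' @param path output file path.
#' @param close_ends close the open tube ends with triangle fans (adds apex
#'   vertices beyond the corresponded point set).
#' @return `path`, invisibly.
#' @export
write_geometry_ply <- function(g, path, close_ends = TRUE) {
  mesh <- export_mesh(g, close_ends)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("comment aortaflow geometry %s", g$label),
    sprintf("element vertex %d", nrow(mesh$vertices)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(mesh$faces)),
    "property list uchar int vertex_indices",
    "end_header"
  ), con)
  writeLines(sprintf("%.6f %.6f %.6f", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' @rdname write_geometry_ply
#' @export
write_geometry_stl <- function(g, path, close_ends = TRUE) {
  mesh <- export_mesh(g, close_ends)
  v <- mesh$vertices
  f <- mesh$faces
  n1 <- v[f[, 2], ] - v[f[, 1], ]
  n2 <- v[f[, 3], ] - v[f[, 1], ]
  nx <- n1[, 2] * n2[, 3] - n1[, 3] * n2[, 2]
  ny <- n1[, 3] * n2[, 1] - n1[, 1] * n2[, 3]
  nz <- n1[, 1] * n2[, 2] - n1[, 2] * n2[, 1]
  nn <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-30)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", g$label), con)
  body <- sprintf(
    "facet normal %.6e %.6e %.6e\n outer loop\n  vertex %.6e %.6e %.6e\n  vertex %.6e %.6e %.6e\n  vertex %.6e %.6e %.6e\n endloop\nendfacet",
    nx / nn, ny / nn, nz / nn,
    v[f[, 1], 1], v[f[, 1], 2], v[f[, 1], 3],
    v[f[, 2], 1], v[f[, 2], 2], v[f[, 2], 3],
    v[f[, 3], 1], v[f[, 3], 2], v[f[, 3], 3]
  )
  writeLines(body, con)
  writeLines(sprintf("endsolid %s", g$label), con)
  invisible(path)
}

# Vertices + triangular faces for export, optionally closing tube ends.
export_mesh <- function(g, close_ends = TRUE) {
  vertices <- g$points
  faces <- geometry_faces(g)
  if (close_ends) {
    lay <- g$layout
    for (comp in unique(lay$component)) {
      for (end in c(min(lay$ring[lay$component == comp]),
                    max(lay$ring[lay$component == comp]))) {
        idx <- lay$point[lay$component == comp & lay$ring == end]
        apex <- colMeans(g$points[idx, , drop = FALSE])
        vertices <- rbind(vertices, apex)
        a <- nrow(vertices)
        m <- length(idx)
        ring_faces <- cbind(idx, idx[c(2:m, 1)], rep(a, m))
        if (end != 1) ring_faces <- ring_faces[, c(2, 1, 3)]
        faces <- rbind(faces, ring_faces)
      }
    }
  }
  list(vertices = vertices, faces = unname(faces))
}

#' Export the centerline tree as CSV
#'
#' Writes one row per centerline point with columns `branch_id`, `tract_id`,
#' `point_index`, `s_mm`, `x_mm`, `y_mm`, `z_mm`, `r_inscribed_mm`. The
#' tract id is filled from [split_tracts()] for the main vessel (branch
#' points carry their branch name).
#'
#' @param g an `aorta_geometry`.
#' @param path output CSV path.
#' @return The written tibble, invisibly.
#' @export
write_centerline_csv <- function(g, path) {
  tree <- centerlines_from_geometry(g)
  rows <- attr(split_tracts(tree), "ostia_rows")
  main <- tree$main
  tract_id <- cut(seq_len(nrow(main)),
                  breaks = c(0, rows[["bca"]], rows[["lsa"]], nrow(main)),
                  labels = c("ascending", "arch", "descending"))
  out <- bind_rows(
    tibble(branch_id = "aorta", tract_id = as.character(tract_id),
           point_index = seq_len(nrow(main)), s_mm = main$s,
           x_mm = main$x, y_mm = main$y, z_mm = main$z, r_inscribed_mm = main$r),
    bind_rows(imap(tree$branches, function(b, nm) {
      tibble(branch_id = nm, tract_id = nm, point_index = seq_len(nrow(b)),
             s_mm = b$s, x_mm = b$x, y_mm = b$y, z_mm = b$z,
             r_inscribed_mm = b$r)
    }))
  )
  readr::write_csv(out, path)
  invisible(out)
}

#' Export a corresponded population
#'
#' Writes one PLY file per geometry plus a JSON manifest recording labels,
#' the generating seed and spec echo, the point count and the
#' inlet/outlet boundary rings.
#'
#' @param geometries named list of `aorta_geometry` objects.
#' @param dir output directory (created if needed).
#' @param spec optional [population_spec()] echoed into the manifest.
#' @return Manifest list, invisibly.
#' @export
write_population <- function(geometries, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in geometries) {
    write_geometry_ply(g, file.path(dir, paste0(g$label, ".ply")))
  }
  res <- geometries[[1]]$resolution
  manifest <- list(
    labels = map_chr(geometries, "label"),
    n_points = nrow(geometries[[1]]$points),
    seed = if (!is.null(spec)) spec$seed else NULL,
    spec = if (!is.null(spec)) {
      list(n_subjects = spec$n_subjects, cv = spec$cv,
           bovine_arch_probability = spec$bovine_arch_probability)
    } else NULL,
    boundaries = list(
      inlet = "aorta ring 1",
      outlets = c("aorta ring N", "bca ring N", "lcca ring N", "lsa ring N")
    ),
    resolution = unclass(res)
  )
  jsonlite::write_json(manifest, file.path(dir, "population_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a corresponded point set from CSV or ASCII PLY
#'
#' Reads user-supplied corresponded geometries in the package's own formats:
#' a CSV with columns `x`, `y`, `z` (ordered per the population layout) or
#' an ASCII PLY written by [write_geometry_ply()] (end-cap apex vertices are
#' dropped using the layout's point count).
#'
#' @param path file path (`.csv` or `.ply`).
#' @param layout the population layout ([layout_from_resolution()]).
#' @param label geometry label.
#' @return An `aorta_geometry` (centerline recovered by the ring-centroid
#'   rule).
#' @export
read_geometry <- function(path, layout, label = basename(path)) {
  n_expect <- nrow(layout)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- readr::read_csv(path, show_col_types = FALSE)
    pts <- as.matrix(d[, c("x", "y", "z")])
  } else {
    lines <- readLines(path)
    n_vert <- as.integer(sub("element vertex ", "",
                             grep("^element vertex", lines, value = TRUE)[1]))
    start <- which(lines == "end_header")[1] + 1
    vals <- do.call(rbind, strsplit(lines[start:(start + n_vert - 1)], " "))
    pts <- matrix(as.numeric(vals[, 1:3]), ncol = 3)
  }
  if (nrow(pts) < n_expect) {
    abort(sprintf("point set has %d points; layout expects %d", nrow(pts), n_expect))
  }
  pts <- pts[seq_len(n_expect), , drop = FALSE]
  g <- new_aorta_geometry(label = label, points = pts, layout = layout,
                          centerline = NULL, ostia = NULL)
  g$centerline <- centerlines_from_geometry(g)
  g
}
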