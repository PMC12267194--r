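#' Stack corresponded geometries into a shape matrix
#'
#' Flattens each geometry's point coordinates (x1, y1, z1, x2, ...) into one
#' row of a subjects-by-coordinates matrix. All geometries must share the
#' population layout; the layout and resolution are carried along so that
#' shapes synthesized from the model can be folded back into geometries.
#'
#' @param geometries list of corresponded `aorta_geometry` objects.
#' @return A numeric matrix of class `shape_matrix` with one row per subject
#'   (rownames = labels) and attributes `layout` and `resolution`.
#' @export
shape_matrix <- function(geometries) {
  if (length(geometries) < 2) abort("need at least 2 corresponded shapes")
  n_pts <- nrow(geometries[[1]]$points)
  rows <- map(geometries, function(g) {
    if (nrow(g$points) != n_pts) {
      abort(sprintf("geometry '%s' has %d points; expected %d (not corresponded)",
                    g$label, nrow(g$points), n_pts))
    }
    as.vector(t(g$points))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- map_chr(geometries, "label")
  structure(m, layout = geometries[[1]]$layout,
            resolution = geometries[[1]]$resolution,
            class = c("shape_matrix", "matrix", "array"))
}

#' Fit a PCA statistical shape model
#'
#' Principal component analysis of a corresponded shape matrix: the mean
#' shape is the arithmetic mean, and the modes (eigenvectors) and
#' eigenvalues come from the singular value decomposition of the centered
#' matrix with the sample-covariance divisor n - 1. Each mode's sign is
#' fixed so that its largest-magnitude loading is positive, removing the SVD
#' sign ambiguity so that mode/SD labels are reproducible. By default all
#' `n_subjects` components are retained; with centered data the last
#' eigenvalue is numerically zero, so the model has at most n - 1
#' non-trivial modes.
#'
#' @param shapes a [shape_matrix()].
#' @param n_modes number of modes to retain (default: number of subjects).
#' @return An object of class `aorta_pca`: list with `mean` (flattened mean
#'   shape), `eigenvalues` (mm^2, non-increasing), `modes` (columns,
#'   orthonormal), `scores` (training scores), `n_modes`, `labels`,
#'   `layout`, `resolution`.
#' @export
fit_pca <- function(shapes, n_modes = NULL) {
  if (!inherits(shapes, "shape_matrix")) abort("`shapes` must be a shape_matrix")
  n <- nrow(shapes)
  mean_shape <- colMeans(shapes)
  xc <- sweep(unclass(shapes), 2, mean_shape)
  sv <- svd(xc, nu = n, nv = min(n, ncol(xc)))
  k <- n_modes %||% n
  k <- as.integer(k)
  if (k < 1 || k > min(n, ncol(xc))) {
    abort(sprintf("n_modes must lie in [1, %d]", min(n, ncol(xc))))
  }
  eig <- sv$d^2 / (n - 1)
  modes <- sv$v[, seq_len(k), drop = FALSE]
  scores <- xc %*% modes
  for (j in seq_len(k)) {
    i_max <- which.max(abs(modes[, j]))
    if (modes[i_max, j] < 0) {
      modes[, j] <- -modes[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(mean = mean_shape, eigenvalues = eig[seq_len(k)], modes = modes,
         scores = scores, n_modes = k,
         labels = rownames(shapes),
         layout = attr(shapes, "layout"),
         resolution = attr(shapes, "resolution")),
    class = "aorta_pca"
  )
}

#' @export
print.aorta_pca <- function(x, ...) {
  cat(sprintf("<aorta_pca> %d modes from %d shapes (%d coordinates)\n",
              x$n_modes, length(x$labels), length(x$mean)))
  ev <- explained_variance_fractions(x)
  cat(sprintf("  first modes explain: %s\n",
              paste(sprintf("%.1f%%", 100 * head(ev, 3)), collapse = ", ")))
  invisible(x)
}

explained_variance_fractions <- function(model) {
  tot <- sum(model$eigenvalues)
  if (tot == 0) return(rep(0, model$n_modes))
  model$eigenvalues / tot
}

#' Cumulative explained variance
#'
#' Fraction of the total shape variance captured by the first `k` modes.
#'
#' @param model an [fit_pca()] model.
#' @param k number of leading modes (1 <= k <= n_modes).
#' @return Scalar fraction in \[0, 1\], non-decreasing in `k`.
#' @export
explained_variance <- function(model, k) {
  if (!is_scalar_number(k) || k < 1 || k > model$n_modes) {
    abort(sprintf("k must lie in [1, %d]", model$n_modes))
  }
  tot <- sum(model$eigenvalues)
  if (tot == 0) return(1)
  sum(model$eigenvalues[seq_len(k)]) / tot
}

# Fold a flattened coordinate vector back into an aorta_geometry, recovering
# the centerline tree by the ring-centroid rule (SSM shapes inherit the
# template's ring layout).
shape_to_geometry <- function(flat, model, label) {
  pts <- matrix(flat, ncol = 3, byrow = TRUE)
  g <- new_aorta_geometry(
    label = label, points = pts, layout = model$layout,
    centerline = NULL, ostia = NULL, params = NULL,
    resolution = model$resolution
  )
  g$centerline <- centerlines_from_geometry(g)
  lay <- model$layout
  g$ostia <- map_dbl(c(bca = "bca", lcca = "lcca", lsa = "lsa"), function(b) {
    k <- g$centerline$attach[[b]]
    ctr <- as.numeric(g$centerline$main[k, c("x", "y", "z")])
    idx <- lay$point[lay$component == "aorta" & lay$ring == k]
    d <- row_norms(pts[idx, , drop = FALSE] - matrix(ctr, length(idx), 3, byrow = TRUE))
    idx[which.min(d)]
  })
  g$ostia <- setNames(as.integer(g$ostia), c("bca", "lcca", "lsa"))
  g
}

#' Synthesize a shape from the model
#'
#' Generates `mean + sum_i sd[i] * sqrt(lambda_i) * mode_i`, i.e. a shape
#' displaced along each mode by the requested number of population standard
#' deviations.
#'
#' @param model an [fit_pca()] model.
#' @param sd numeric vector of per-mode SD multipliers (length <= n_modes;
#'   shorter vectors are zero-padded).
#' @param label optional label; by default encodes the nonzero entries as
#'   `"m<k>_sd<+/-v>"` (0-based mode index), or `"template"` when all zero.
#' @return An `aorta_geometry`.
#' @export
#' @examples
#' \dontrun{
#' g <- generate_shape(model, sd = c(-2))  # mode 0 at -2 SD
#' }
generate_shape <- function(model, sd, label = NULL) {
  if (length(sd) > model$n_modes) {
    abort(sprintf("sd has %d entries but the model has %d modes",
                  length(sd), model$n_modes))
  }
  sd_full <- rep(0, model$n_modes)
  sd_full[seq_along(sd)] <- sd
  coef <- sd_full * sqrt(model$eigenvalues)
  flat <- model$mean + drop(model$modes %*% coef)
  label <- label %||% sd_label(sd_full)
  shape_to_geometry(flat, model, label)
}

# Canonical label for a per-mode SD vector: "m<k>_sd<+/-v>" per nonzero
# entry (0-based mode index), joined with "__"; all-zero -> "template".
sd_label <- function(sd) {
  nz <- which(abs(sd) > 0)
  if (length(nz) == 0) return("template")
  paste(sprintf("m%d_sd%+g", nz - 1, sd[nz]), collapse = "__")
}

#' Parse mode/SD labels
#'
#' Inverse of the canonical `"m<k>_sd<+/-v>"` labeling for single-mode
#' shapes. Multi-mode labels and `"template"` yield `NA`.
#'
#' @param labels character vector.
#' @return Tibble with columns `label`, `mode` (0-based), `sd`.
#' @export
parse_sd_label <- function(labels) {
  m <- regmatches(labels, regexec("^m([0-9]+)_sd([+-][0-9.]+)$", labels))
  tibble(
    label = labels,
    mode = map_dbl(m, ~ if (length(.x) == 3) as.numeric(.x[[2]]) else NA_real_),
    sd = map_dbl(m, ~ if (length(.x) == 3) as.numeric(.x[[3]]) else NA_real_)
  )
}

#' Default mode/SD augmentation scheme
#'
#' The concrete sweep used to augment the dataset: unit SD steps (-3..+3,
#' excluding 0) for the first five modes, the +-3 SD extremes for modes 5-7,
#' and +3 SD only for every later mode. On a 19-mode model this yields
#' 6*5 + 2*3 + 1*11 = 47 novel shapes, which together with the template
#' gives 48 geometries.
#'
#' @param n_modes number of modes in the model.
#' @return Named list (by 0-based mode index) of SD multiplier vectors, of
#'   class `augment_scheme`.
#' @export
default_augment_scheme <- function(n_modes = 19) {
  scheme <- list()
  for (mode in seq_len(n_modes) - 1) {
    scheme[[as.character(mode)]] <-
      if (mode <= 4) c(-3, -2, -1, 1, 2, 3)
      else if (mode <= 7) c(-3, 3)
      else 3
  }
  validate_augment_scheme(scheme)
}

validate_augment_scheme <- function(scheme) {
  for (mode in names(scheme)) {
    v <- scheme[[mode]]
    if (any(v == 0)) abort(sprintf("scheme mode %s contains a zero SD multiplier", mode))
    if (anyDuplicated(v)) abort(sprintf("scheme mode %s contains duplicate multipliers", mode))
  }
  structure(scheme, class = "augment_scheme")
}

#' Augment the dataset by single-mode SD sweeps
#'
#' Generates one geometry per (mode, SD multiplier) pair of the scheme --
#' single-mode perturbations only -- plus the template (mean shape), for a
#' total of `1 + sum(lengths(scheme))` geometries.
#'
#' @param model an [fit_pca()] model.
#' @param scheme an augmentation scheme (named list, 0-based mode index ->
#'   SD multipliers); default [default_augment_scheme()] over the model's
#'   modes.
#' @return Named list of `aorta_geometry` objects; the first is labeled
#'   `"template"`.
#' @export
augment_dataset <- function(model, scheme = default_augment_scheme(model$n_modes)) {
  if (!inherits(model, "aorta_pca") || model$n_modes < 1) {
    abort("`model` must be a fitted aorta_pca with at least one mode")
  }
  scheme <- validate_augment_scheme(scheme)
  modes <- as.integer(names(scheme))
  if (any(modes < 0) || any(modes >= model$n_modes)) {
    abort("scheme refers to modes outside the model")
  }
  out <- list(template = generate_shape(model, rep(0, model$n_modes)))
  for (mode in names(scheme)) {
    for (mult in scheme[[mode]]) {
      sdv <- rep(0, model$n_modes)
      sdv[as.integer(mode) + 1] <- mult
      g <- generate_shape(model, sdv)
      out[[g$label]] <- g
    }
  }
  out
}

# --- persistence ------------------------------------------------------------

#' Save / load a fitted shape model
#'
#' Persists the model as a directory holding JSON metadata
#' (`model.json`: eigenvalues, labels, resolution, provenance) together with
#' CSV arrays for the mean shape and the mode matrix, and the layout table.
#'
#' @param model an [fit_pca()] model.
#' @param dir directory to create/overwrite.
#' @return `save_pca_model()` returns `dir` invisibly; `load_pca_model()`
#'   returns the restored `aorta_pca`.
#' @export
save_pca_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    n_modes = model$n_modes,
    eigenvalues = model$eigenvalues,
    labels = model$labels,
    resolution = unclass(model$resolution),
    package_version = as.character(packageVersion("aortaflow"))
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(tibble(mean = model$mean), file.path(dir, "mean.csv"))
  modes <- as_tibble(model$modes, .name_repair = ~ sprintf("m%d", seq_along(.x) - 1))
  readr::write_csv(modes, file.path(dir, "modes.csv"))
  readr::write_csv(tibble(scores = as.vector(model$scores)),
                   file.path(dir, "scores.csv"))
  readr::write_csv(model$layout, file.path(dir, "layout.csv"))
  invisible(dir)
}

#' @rdname save_pca_model
#' @export
load_pca_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  modes <- as.matrix(readr::read_csv(file.path(dir, "modes.csv"),
                                     show_col_types = FALSE))
  mean_shape <- readr::read_csv(file.path(dir, "mean.csv"),
                                show_col_types = FALSE)$mean
  scores <- readr::read_csv(file.path(dir, "scores.csv"),
                            show_col_types = FALSE)$scores
  layout <- readr::read_csv(file.path(dir, "layout.csv"), show_col_types = FALSE)
  res <- do.call(geometry_resolution, as.list(meta$resolution))
  structure(
    list(mean = mean_shape, eigenvalues = meta$eigenvalues,
         modes = unname(modes),
         scores = matrix(scores, ncol = meta$n_modes),
         n_modes = meta$n_modes, labels = meta$labels,
         layout = as_tibble(layout), resolution = res),
    class = "aorta_pca"
  )
}

# --- broom-style methods ----------------------------------------------------

#' @export
tidy.aorta_pca <- function(x, ...) {
  ev <- explained_variance_fractions(x)
  tibble(
    mode = seq_len(x$n_modes) - 1,
    eigenvalue = x$eigenvalues,
    prop_variance = ev,
    cum_variance = cumsum(ev)
  )
}

#' @export
glance.aorta_pca <- function(x, ...) {
  tibble(
    n_shapes = length(x$labels),
    n_modes = x$n_modes,
    total_variance = sum(x$eigenvalues),
    variance_first_10 = if (x$n_modes >= 10) explained_variance(x, 10) else NA_real_
  )
}

#' @export
autoplot.aorta_pca <- function(object, ...) {
  td <- tidy(object)
  ggplot(td, aes(x = .data$mode)) +
    geom_col(aes(y = .data$prop_variance), fill = "steelblue") +
    geom_line(aes(y = .data$cum_variance), colour = "firebrick") +
    geom_point(aes(y = .data$cum_variance), colour = "firebrick") +
    labs(x = "mode", y = "variance fraction",
         title = "Individual and cumulative explained variance") +
    theme_minimal()
}
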