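test_that("ring centroids and inscribed radii are exact on analytic rings", {
  th <- 2 * pi * (0:23) / 24
  # circular ring of radius 10 about (3, -2, 7)
  circ <- cbind(3 + 10 * cos(th), -2 + 10 * sin(th), 7)
  # elliptical ring a = 12, b = 8: min distance equals the semi-minor axis
  ell <- cbind(12 * cos(th), 8 * sin(th), 0)
  pts <- rbind(circ, ell)
  lay <- tibble::tibble(point = seq_len(nrow(pts)), component = "aorta",
                        ring = rep(1:2, each = 24), sample = rep(1:24, 2))
  # minimal branch stubs so the tree assembles
  stub <- function(comp, x0) {
    p <- cbind(x0 + rep(c(0, 1, 2, 3), each = 4) * 0.5,
               rep(2 * cos(2 * pi * (0:3) / 4), 4),
               rep(2 * sin(2 * pi * (0:3) / 4), 4) + 20)
    list(p = p, lay = tibble::tibble(component = comp,
                                     ring = rep(1:4, each = 4),
                                     sample = rep(1:4, 4)))
  }
  stubs <- lapply(c("bca", "lcca", "lsa"), stub, x0 = 30)
  pts <- rbind(pts, do.call(rbind, lapply(stubs, `[[`, "p")))
  lay <- dplyr::bind_rows(lay[, -1], dplyr::bind_rows(lapply(stubs, `[[`, "lay")))
  lay$point <- seq_len(nrow(lay))
  g <- aortaflow:::new_aorta_geometry("rings", pts, lay, NULL, NULL)
  tr <- centerlines_from_geometry(g)
  expect_equal(as.numeric(tr$main[1, c("x", "y", "z")]), c(3, -2, 7),
               tolerance = 1e-9)
  expect_equal(tr$main$r[1], 10, tolerance = 1e-6)
  expect_equal(tr$main$r[2], 8, tolerance = 0.01)
})

test_that("recovered centerlines stay within half a local radius of truth", {
  pop <- tiny_population(n = 3, seed = 77)
  for (g in pop) {
    tr <- centerlines_from_geometry(g)
    for (b in c("bca", "lcca", "lsa")) {
      got <- as.matrix(tr$branches[[b]][, c("x", "y", "z")])
      truth <- as.matrix(g$centerline$branches[[b]][, c("x", "y", "z")])
      dev <- sqrt(rowSums((got - truth)^2))
      expect_lt(max(dev / g$centerline$branches[[b]]$r), 0.5)
    }
  }
  g2 <- pop[[1]]; g2$layout <- NULL
  expect_error(centerlines_from_geometry(g2), "layout")
})

test_that("tract splitting partitions the aorta into seven tracts", {
  tracts <- template_tracts()
  expect_setequal(unique(tracts$tract), aortaflow:::tract_names())
  len <- function(tn) {
    p <- as.matrix(tracts[tracts$tract == tn, c("x", "y", "z")])
    sum(sqrt(rowSums(diff(p)^2)))
  }
  expect_equal(len("ascending") + len("arch") + len("descending"),
               len("total"), tolerance = 1e-6)
  tree <- centerlines_from_geometry(build_geometry(aorta_params(), tiny_res()))
  expect_error(split_tracts(tree, ostia = c(bca = 40, lcca = 30, lsa = 50)),
               "out of order")
})

test_that("Frenet estimators match closed forms on line, circle and helix", {
  z <- seq(0, 100, length.out = 50)
  straight <- tibble::tibble(x = 0, y = 0, z = z, r = 5)
  f <- compute_features(straight)
  expect_equal(f$tortuosity, 1)
  expect_lt(abs(f$curvature_mean), 1e-9)
  expect_lt(abs(f$torsion_mean), 1e-9)

  th <- seq(0, pi, length.out = 300)
  circle <- tibble::tibble(x = 25 * cos(th), y = 25 * sin(th), z = 0, r = 1)
  fc <- compute_features(circle)
  expect_equal(fc$curvature_mean, 1 / 25, tolerance = 0.01)
  expect_lt(abs(fc$torsion_mean), 1e-9)

  fh <- compute_features(helix_points(a = 10, b = 5, n = 200))
  expect_equal(fh$curvature_mean, 10 / 125, tolerance = 0.02)
  expect_equal(fh$torsion_mean, 5 / 125, tolerance = 0.02)

  expect_error(compute_features(straight[rep(1, 10), ]), "degenerate")
})

test_that("Frenet estimators converge on the helix as sampling doubles", {
  err <- vapply(c(100, 200, 400), function(n) {
    f <- compute_features(helix_points(n = n))
    abs(f$curvature_mean - 0.08) / 0.08 + abs(f$torsion_mean - 0.04) / 0.04
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3] / err[2], 0.55)  # observed order >= 1
})

test_that("features are invariant to rigid-body motion", {
  tracts <- template_tracts()
  arch <- tracts[tracts$tract == "arch", ]
  f0 <- compute_features(arch)
  ang <- 0.7
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  moved <- arch
  xyz <- as.matrix(arch[, c("x", "y", "z")]) %*% R
  moved$x <- xyz[, 1] + 12; moved$y <- xyz[, 2] - 4; moved$z <- xyz[, 3] + 100
  f1 <- compute_features(moved)
  for (q in c("length", "tortuosity", "curvature_mean", "torsion_mean")) {
    expect_equal(f1[[q]], f0[[q]], tolerance = 1e-6)
  }
})

test_that("tortuosity is >= 1 for every tract of every geometry", {
  pop <- tiny_population(n = 5, seed = 55)
  ft <- feature_table(pop)
  expect_true(all(ft$tortuosity >= 1))
  expect_true(all(ft$length > 0))
  expect_true(all(ft$radius_mean > 0))
})

test_that("template comparison computes percent differences and summaries", {
  pop <- tiny_population(n = 4, seed = 9)
  names(pop)[1] <- "template"; pop[[1]]$label <- "template"
  ft <- feature_table(pop)
  cmp <- compare_to_template(ft)
  tmpl_rows <- cmp[cmp$label == "template" & !cmp$absolute_difference, ]
  expect_true(all(abs(tmpl_rows$pct_diff) < 1e-9))
  summ <- attr(cmp, "population_summary")
  expect_true(all(c("tract", "quantity", "mean", "sd") %in% names(summ)))
  # constructed arithmetic: 1.2 vs template 1.0 -> +20%
  toy <- tibble::tibble(
    label = c("template", "x"), tract = "total",
    length = c(1, 1.2), tortuosity = 1, radius_mean = 1, radius_sd = 0,
    curvature_mean = 1, curvature_sd = 0, torsion_mean = 1, torsion_sd = 0
  )
  tc <- compare_to_template(toy)
  expect_equal(tc$pct_diff[tc$label == "x" & tc$quantity == "length"], 20)
  expect_error(compare_to_template(dplyr::filter(ft, label != "template")),
               "template")
})

test_that("symmetric +/-SD pairs have near-cancelling length deviations", {
  pop <- tiny_population(n = 8, seed = 61)
  model <- fit_pca(shape_matrix(pop))
  aug <- augment_dataset(model, validate_augment_scheme(list(`0` = c(-2, 2))))
  cmp <- compare_to_template(feature_table(aug))
  lens <- cmp[cmp$quantity == "length" & cmp$tract == "total" &
                cmp$label != "template", ]
  # length responds almost linearly to a mode sweep, so the +/- pair mean
  # cancels to within a few percentage points
  expect_lt(abs(mean(lens$pct_diff)), 5)
  expect_lt(abs(mean(lens$pct_diff)), max(abs(lens$pct_diff)))
})

test_that("representative selection ranks by maximum deviation", {
  pop <- tiny_population(n = 8, seed = 25)
  model <- fit_pca(shape_matrix(pop))
  aug <- augment_dataset(model, default_augment_scheme(model$n_modes))
  cmp <- compare_to_template(feature_table(aug))
  sel <- select_representatives(cmp, k = 4, mode_limit = 3)
  expect_length(sel, 5)
  expect_identical(sel[5], "template")
  info <- parse_sd_label(sel[1:4])
  expect_true(all(info$mode < 3))
  # k larger than the eligible pool returns everything, with a warning
  expect_warning(all_sel <- select_representatives(cmp, k = 1000, mode_limit = 3),
                 "only")
  eligible <- parse_sd_label(setdiff(names(aug), "template"))
  expect_length(all_sel, sum(eligible$mode < 3, na.rm = TRUE) + 1)
  # an injected dominant deviation ranks first
  big <- cmp
  big$pct_diff[big$label == "m1_sd+1"] <- 1e6
  expect_identical(select_representatives(big, k = 1, mode_limit = 3)[1],
                   "m1_sd+1")
})

test_that("result planes sit on the centerline with unit Frenet normals", {
  tracts <- template_tracts()
  planes <- define_result_planes(tracts)
  expect_identical(planes$plane, c("pre-arch", "post-arch", "descending"))
  expect_equal(sqrt(planes$nx^2 + planes$ny^2 + planes$nz^2), rep(1, 3),
               tolerance = 1e-9)
  for (i in seq_len(3)) {
    tr <- tracts[tracts$tract == planes$tract[i], ]
    p <- as.matrix(tr[, c("x", "y", "z")])
    o <- c(planes$x[i], planes$y[i], planes$z[i])
    # distance from the origin to the polyline
    dmin <- min(vapply(seq_len(nrow(p) - 1), function(j) {
      a <- p[j, ]; b <- p[j + 1, ]
      t <- max(0, min(1, sum((o - a) * (b - a)) / sum((b - a)^2)))
      sqrt(sum((o - (a + t * (b - a)))^2))
    }, numeric(1)))
    expect_lt(dmin, 1e-6)
  }
  # straight descending tract: post-arch at s0 + 10% L, descending at 90% L
  desc <- tracts[tracts$tract == "descending", ]
  L <- max(desc$s) - min(desc$s)
  s_planes <- c(0.10, 0.90) * L
  got <- planes[planes$tract == "descending", c("x", "y", "z")]
  for (j in 1:2) {
    target <- approx(desc$s - min(desc$s), desc$z, xout = s_planes[j])$y
    expect_equal(got$z[j], target, tolerance = 1e-6)
  }
})

test_that("bovine-arch tracts share the ascending/arch boundary at the ostium", {
  g <- build_geometry(aorta_params(bovine_arch = TRUE), tiny_res())
  tracts <- split_tracts(centerlines_from_geometry(g))
  ost <- attr(tracts, "ostia_s")
  expect_equal(ost[["bca"]], ost[["lcca"]])
  asc <- tracts[tracts$tract == "ascending", ]
  expect_equal(max(asc$s), ost[["bca"]])
})
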