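test_that("invalid anatomical parameters fail naming the offending field", {
  expect_error(aorta_params(root_radius = -1), "root_radius")
  expect_error(aorta_params(arch_angle = pi / 4), "arch_angle")
  expect_error(aorta_params(branch_origin_u = c(0.5, 0.3, 0.7)),
               "branch_origin_u")
  expect_error(aorta_params(branch_radii = c(20, 3, 5)), "branch_radii")
  expect_error(population_spec(n_subjects = 1), "n_subjects")
  expect_error(population_spec(cv = list(root_radius = -0.1)), "cv\\$root_radius")
})

test_that("a sampled population is corresponded with the requested size", {
  pop <- tiny_population(n = 5, seed = 7)
  expect_length(pop, 5)
  shapes <- lapply(pop, function(g) dim(g$points))
  expect_true(all(vapply(shapes, identical, logical(1), shapes[[1]])))
  layouts <- lapply(pop, function(g) g$layout)
  expect_true(all(vapply(layouts, identical, logical(1), layouts[[1]])))
})

test_that("zero CV reproduces the mean-parameter template exactly", {
  cv0 <- lapply(aortaflow:::default_param_cv(), function(x) 0)
  pop <- sample_population(
    population_spec(n_subjects = 2, cv = cv0, bovine_arch_probability = 0),
    resolution = tiny_res()
  )
  tmpl <- build_geometry(aorta_params(), tiny_res())
  expect_equal(pop[[1]]$points, tmpl$points)
  expect_equal(pop[[2]]$points, tmpl$points)
})

test_that("sampling is deterministic given the seed", {
  a <- tiny_population(n = 4, seed = 123)
  b <- tiny_population(n = 4, seed = 123)
  expect_identical(lapply(a, function(g) g$points),
                   lapply(b, function(g) g$points))
  c <- tiny_population(n = 4, seed = 124)
  expect_false(identical(a[[1]]$points, c[[1]]$points))
})

test_that("every sampled parameter set satisfies its invariants", {
  spec <- population_spec(n_subjects = 2, seed = 99)
  ok <- aortaflow:::with_local_seed(99, {
    sum(vapply(seq_len(10000), function(i) {
      p <- aortaflow:::sample_aorta_params(spec)
      inherits(tryCatch(validate_aorta_params(p), error = function(e) NULL),
               "aorta_params")
    }, logical(1)))
  })
  expect_identical(ok, 10000L)
})

test_that("default resolution hits the ~25,000-node budget", {
  res <- geometry_resolution()
  n <- aortaflow:::n_points_for(res)
  expect_gte(n, 24000)
  expect_lte(n, 26000)
  g <- build_geometry(aorta_params(), res)
  expect_identical(nrow(g$points), n)
})

test_that("a planar semicircular arch has tortuosity pi/2", {
  p <- aorta_params(torsion_amplitude = 0, arch_angle = pi)
  span <- p$ascending_length + c(0, pi * p$arch_radius)
  cl <- aortaflow:::main_centerline_points(p, seq(span[1], span[2],
                                                  length.out = 400))
  arc <- tibble::tibble(x = cl$points[, 1], y = cl$points[, 2],
                        z = cl$points[, 3], r = cl$radii)
  expect_equal(compute_features(arc)$tortuosity, pi / 2, tolerance = 1e-4)
  # the arch stays planar when the torsional perturbation is off
  expect_lt(diff(range(cl$points[, 2])), 1e-12)
})

test_that("a straight swept tube has the area of a cylinder", {
  ctr <- cbind(0, 0, seq(0, 100, length.out = 120))
  pts <- aortaflow:::sweep_tube(ctr, rep(10, 120), 48)
  lay <- tibble::tibble(point = seq_len(nrow(pts)), component = "aorta",
                        ring = rep(seq_len(120), each = 48),
                        sample = rep(seq_len(48), 120))
  g <- aortaflow:::new_aorta_geometry("cyl", pts, lay, NULL, NULL)
  area <- aortaflow:::mesh_surface_area(pts, aortaflow:::geometry_faces(g))
  expect_equal(area, 2 * pi * 10 * 100, tolerance = 0.01)
})

test_that("the bovine variant shares the BCA/LCCA origin", {
  p <- aorta_params(bovine_arch = TRUE)
  g <- build_geometry(p, tiny_res())
  expect_identical(g$centerline$attach[["bca"]], g$centerline$attach[["lcca"]])
  tracts <- split_tracts(centerlines_from_geometry(g))
  ost <- attr(tracts, "ostia_s")
  expect_equal(ost[["bca"]], ost[["lcca"]])
})

test_that("ground-truth centerline is recovered by ring centroids", {
  pop <- tiny_population(n = 4, seed = 5)
  for (g in pop) {
    tr <- centerlines_from_geometry(g)
    dev <- sqrt(rowSums((as.matrix(tr$main[, c("x", "y", "z")]) -
                           as.matrix(g$centerline$main[, c("x", "y", "z")]))^2))
    expect_lt(max(dev / g$centerline$main$r), 0.5)
    expect_equal(tr$main$r, g$centerline$main$r, tolerance = 1e-8)
  }
})

test_that("mesh and centerline exports round-trip", {
  g <- build_geometry(aorta_params(), tiny_res(), label = "t")
  d <- withr::local_tempdir()
  write_geometry_ply(g, file.path(d, "t.ply"))
  write_geometry_stl(g, file.path(d, "t.stl"))
  cl <- write_centerline_csv(g, file.path(d, "cl.csv"))
  expect_true(all(c("branch_id", "tract_id", "point_index", "s_mm",
                    "r_inscribed_mm") %in% names(cl)))
  g2 <- read_geometry(file.path(d, "t.ply"), g$layout, "t2")
  expect_equal(g2$points, g$points, tolerance = 1e-5)
  man <- write_population(list(t = g), d, spec = population_spec(seed = 3))
  expect_identical(man$n_points, nrow(g$points))
  expect_true(file.exists(file.path(d, "population_manifest.json")))
})
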