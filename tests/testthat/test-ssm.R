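test_that("degenerate populations give the expected spectra", {
  pop <- tiny_population(n = 3, seed = 1)
  # all-identical population: zero eigenvalues, mean equals the shape
  clones <- lapply(seq_len(3), function(i) {
    g <- pop[[1]]; g$label <- sprintf("c%d", i); g
  })
  m0 <- fit_pca(shape_matrix(clones))
  expect_lt(max(m0$eigenvalues), 1e-18)
  expect_equal(m0$mean, as.vector(t(pop[[1]]$points)))

  # two subjects: exactly one nonzero eigenvalue, mode 0 explains 100%
  m2 <- fit_pca(shape_matrix(pop[1:2]))
  expect_gt(m2$eigenvalues[1], 0)
  expect_lt(m2$eigenvalues[2] / m2$eigenvalues[1], 1e-12)
  expect_equal(explained_variance(m2, 1), 1, tolerance = 1e-12)
})

test_that("explained variance fractions are normalized and monotone", {
  pop <- tiny_population(n = 10, seed = 8)
  model <- fit_pca(shape_matrix(pop))
  fr <- tidy(model)$prop_variance
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  ev <- vapply(seq_len(model$n_modes), explained_variance, numeric(1),
               model = model)
  expect_true(all(diff(ev) >= -1e-12))
  expect_equal(ev[model$n_modes], 1)
  expect_true(all(diff(model$eigenvalues) <= 1e-9))
  expect_error(explained_variance(model, 0), "k must lie")
  expect_error(explained_variance(model, model$n_modes + 1), "k must lie")
})

test_that("a constructed spectrum gives the hand-computed fraction", {
  model <- structure(list(eigenvalues = c(8, 1, 1), n_modes = 3),
                     class = "aorta_pca")
  expect_equal(explained_variance(model, 1), 0.8)
})

test_that("modes are orthonormal and training scores are centered", {
  pop <- tiny_population(n = 8, seed = 21)
  model <- fit_pca(shape_matrix(pop))
  gram <- crossprod(model$modes)
  expect_lt(max(abs(gram - diag(model$n_modes))), 1e-8)
  expect_lt(max(abs(colMeans(model$scores))), 1e-8)
})

test_that("training shapes are reconstructed exactly from their scores", {
  pop <- tiny_population(n = 7, seed = 13)
  model <- fit_pca(shape_matrix(pop))
  for (i in c(1, 4, 7)) {
    sdv <- ifelse(model$eigenvalues > 1e-12,
                  model$scores[i, ] / sqrt(model$eigenvalues), 0)
    g <- generate_shape(model, sdv, label = "recon")
    rel <- max(abs(g$points - pop[[i]]$points)) / max(abs(pop[[i]]$points))
    expect_lt(rel, 1e-6)
  }
})

test_that("shape generation is linear in the SD coefficients", {
  pop <- tiny_population(n = 6, seed = 3)
  model <- fit_pca(shape_matrix(pop))
  mean_pts <- generate_shape(model, rep(0, model$n_modes))$points
  expect_equal(as.vector(t(mean_pts)), model$mean)
  cvec <- c(1.5, -0.5, 2)
  g1 <- generate_shape(model, cvec)$points
  g2 <- generate_shape(model, 2 * cvec)$points
  expect_equal(g2 - mean_pts, 2 * (g1 - mean_pts), tolerance = 1e-9)
  expect_error(generate_shape(model, rep(1, model$n_modes + 1)), "modes")
})

test_that("augmentation yields the documented counts and parsable labels", {
  pop <- tiny_population(n = 6, seed = 30)
  model <- fit_pca(shape_matrix(pop))
  scheme <- default_augment_scheme(model$n_modes)
  aug <- augment_dataset(model, scheme)
  expect_length(aug, 1 + sum(lengths(scheme)))
  expect_identical(names(aug)[1], "template")
  expect_false(anyDuplicated(names(aug)) > 0)
  info <- parse_sd_label(setdiff(names(aug), "template"))
  expect_false(anyNA(info$mode))
  # labels round-trip to their (mode, SD) pair
  for (i in seq_len(nrow(info))) {
    sdv <- rep(0, model$n_modes)
    sdv[info$mode[i] + 1] <- info$sd[i]
    expect_identical(aortaflow:::sd_label(sdv), info$label[i])
  }
  expect_length(augment_dataset(model, validate_augment_scheme(list())), 1)
})

test_that("the default scheme on a 19-mode model has 47 novel entries", {
  scheme <- default_augment_scheme(19)
  expect_identical(sum(lengths(scheme)), 47L)
  expect_error(validate_augment_scheme(list(`0` = c(1, 0))), "zero")
  expect_error(validate_augment_scheme(list(`0` = c(2, 2))), "duplicate")
})

test_that("augmented shapes at |SD| <= 3 keep positive edge lengths", {
  pop <- tiny_population(n = 6, seed = 17)
  model <- fit_pca(shape_matrix(pop))
  aug <- augment_dataset(model, validate_augment_scheme(
    list(`0` = c(-3, 3), `1` = c(-3, 3))))
  for (g in aug) {
    faces <- aortaflow:::geometry_faces(g)
    e1 <- sqrt(rowSums((g$points[faces[, 1], ] - g$points[faces[, 2], ])^2))
    expect_gt(min(e1), 0)
  }
})

test_that("inconsistent shape rows fail naming the subject", {
  pop <- tiny_population(n = 3, seed = 2)
  pop[[2]]$points <- pop[[2]]$points[-1, ]
  expect_error(shape_matrix(pop), "subj02")
})

test_that("model persistence round-trips", {
  pop <- tiny_population(n = 5, seed = 44)
  model <- fit_pca(shape_matrix(pop))
  d <- withr::local_tempdir()
  save_pca_model(model, file.path(d, "model"))
  m2 <- load_pca_model(file.path(d, "model"))
  expect_equal(m2$mean, model$mean, tolerance = 1e-12)
  expect_equal(m2$eigenvalues, model$eigenvalues, tolerance = 1e-12)
  expect_equal(m2$modes, model$modes, tolerance = 1e-12)
  g <- generate_shape(m2, c(1, -1))
  expect_s3_class(g, "aorta_geometry")
})
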