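#' End-to-end pipeline configuration
#'
#' Bundles every stage's parameters: the synthetic population, the
#' augmentation scheme, morphometric selection (k geometries from the first
#' `mode_limit` modes, plus the size of the ECMO subset), fluid properties,
#' the cardiac waveform, Windkessel calibration targets, the ECMO support
#' levels and the cardiogenic-shock reduction.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed global seed; fanned out to per-stage seeds by a counter.
#' @param population a [population_spec()] (its seed is replaced by the
#'   stage seed derived from `seed`).
#' @param resolution a [geometry_resolution()].
#' @param scheme augmentation scheme or `NULL` for
#'   [default_augment_scheme()].
#' @param k_healthy geometries selected for healthy simulations (the
#'   template is simulated in addition).
#' @param mode_limit modes eligible for selection.
#' @param k_ecmo geometries re-simulated under ECMO support.
#' @param ef_levels ECMO flow levels, L/min.
#' @param shock_reduction fractional cardiac-output reduction of the shock
#'   waveform.
#' @param healthy_lmin healthy cardiac output, L/min.
#' @param fluid a [fluid_props()].
#' @param calibration a [calibration_targets()].
#' @param sim a [sim_config()] (EF is overridden per run).
#' @param n_cells transport grid cells.
#' @param write_meshes also export PLY meshes of the augmented set.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            population = population_spec(),
                            resolution = geometry_resolution(),
                            scheme = NULL,
                            k_healthy = 20,
                            mode_limit = 10,
                            k_ecmo = 4,
                            ef_levels = c(0, 4, 6),
                            shock_reduction = 0.70,
                            healthy_lmin = 5,
                            fluid = fluid_props(),
                            calibration = calibration_targets(),
                            sim = sim_config(),
                            n_cells = 240,
                            write_meshes = FALSE) {
  if (any(ef_levels < 0)) abort("EF levels must be non-negative")
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), population = population,
         resolution = resolution, scheme = scheme, k_healthy = k_healthy,
         mode_limit = mode_limit, k_ecmo = k_ecmo, ef_levels = ef_levels,
         shock_reduction = shock_reduction, healthy_lmin = healthy_lmin,
         fluid = fluid, calibration = calibration, sim = sim,
         n_cells = n_cells, write_meshes = write_meshes),
    class = "pipeline_config"
  )
}

stage_seed <- function(config, k) (config$seed %% 100000L) * 20L + k

write_stage_csv <- function(x, out_dir, rel) {
  path <- file.path(out_dir, rel)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(x, path)
  rel
}

#' Run the complete study pipeline
#'
#' Executes, in order: population generation, shape-model fit, mode/SD
#' augmentation, morphometric analysis, representative selection, calibrated
#' healthy simulations (template + selected geometries, sharing the
#' template-calibrated Windkessel outlets), ECMO-subset selection (the
#' `k_ecmo` geometries with the largest absolute LCCA cycle-mean-flow
#' deviation from the template in the healthy runs) and shock/ECMO
#' simulations with fraction transport and watershed localization across the
#' configured EF levels. Every table is written under `out_dir` and hashed
#' into a run manifest; the run is deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `run_manifest`: `files` (tibble of relative
#'   paths and md5 hashes), `config`, `seed`, `stages`, `timestamp`.
#' @export
run_all <- function(config) {
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stages <- character(0)
  t0 <- Sys.time()

  run_stage <- function(name, code) {
    stages[[length(stages) + 1]] <<- name
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # 1. synthetic population ---------------------------------------------
  pop <- run_stage("generate", {
    spec <- config$population
    spec$seed <- stage_seed(config, 1L)
    sample_population(spec, resolution = config$resolution)
  })
  pop_tbl <- bind_rows(map(pop, function(g) {
    tibble(label = g$label, n_points = nrow(g$points),
           bovine_arch = g$params$bovine_arch,
           root_radius = g$params$root_radius)
  }))
  files <- c(files, write_stage_csv(pop_tbl, out_dir, "population/subjects.csv"))

  # 2. shape model -------------------------------------------------------
  model <- run_stage("ssm", fit_pca(shape_matrix(pop)))
  files <- c(files, write_stage_csv(tidy(model), out_dir, "ssm/eigenvalues.csv"))

  # 3. augmentation ------------------------------------------------------
  augmented <- run_stage("augment", {
    scheme <- config$scheme %||% default_augment_scheme(model$n_modes)
    augment_dataset(model, scheme)
  })
  files <- c(files, write_stage_csv(
    tibble(label = names(augmented)), out_dir, "ssm/augmented_labels.csv"))
  if (config$write_meshes) {
    run_stage("meshes", write_population(augmented, file.path(out_dir, "meshes")))
  }

  # 4. morphometry -------------------------------------------------------
  features <- run_stage("morpho", feature_table(augmented))
  comparison <- compare_to_template(features)
  files <- c(files,
             write_stage_csv(features, out_dir, "morpho/features.csv"),
             write_stage_csv(as_tibble(comparison), out_dir, "morpho/comparison.csv"),
             write_stage_csv(attr(comparison, "population_summary"), out_dir,
                             "morpho/population_summary.csv"))

  # 5. selection ---------------------------------------------------------
  selected <- run_stage("select", {
    select_representatives(comparison, k = config$k_healthy,
                           mode_limit = config$mode_limit)
  })
  files <- c(files, write_stage_csv(tibble(label = selected), out_dir,
                                    "selection/healthy_labels.csv"))

  # 6. healthy simulations ----------------------------------------------
  healthy <- run_stage("healthy", {
    waveform <- cardiac_waveform(mean_lmin = config$healthy_lmin,
                                 dt = config$sim$dt)
    tmpl_tracts <- split_tracts(centerlines_from_geometry(augmented$template))
    tmpl_net <- build_network(tmpl_tracts, config$fluid, mode = "healthy")
    cal <- calibrate_rcr(tmpl_net, waveform, config$calibration, config$sim)
    sims <- map(selected, function(lab) {
      tracts <- split_tracts(centerlines_from_geometry(augmented[[lab]]))
      net <- set_windkessel(build_network(tracts, config$fluid, "healthy"),
                            cal$params)
      simulate_flow(net, waveform, config$sim)
    })
    names(sims) <- selected
    list(cal = cal, sims = sims, waveform = waveform)
  })
  flows <- bind_rows(imap(healthy$sims, function(s, lab) {
    mutate(tidy(s), label = lab)
  }))
  tmpl_flows <- filter(flows, .data$label == "template")
  flows <- left_join(flows,
                     rename(tmpl_flows[, c("outlet", "mean_flow_lmin")],
                            template_flow_lmin = "mean_flow_lmin"),
                     by = "outlet")
  flows <- mutate(flows, pct_dev = 100 * (.data$mean_flow_lmin - .data$template_flow_lmin) /
                    .data$template_flow_lmin)
  pressures <- bind_rows(imap(healthy$sims, function(s, lab) {
    mutate(glance(s), label = lab)
  }))
  files <- c(files,
             write_stage_csv(flows, out_dir, "healthy/flows.csv"),
             write_stage_csv(pressures, out_dir, "healthy/pressures.csv"),
             write_stage_csv(healthy$cal$params, out_dir, "healthy/windkessel.csv"))

  # 7. ECMO subset -------------------------------------------------------
  ecmo_labels <- run_stage("ecmo_select", {
    lcca <- filter(flows, .data$outlet == "lcca", .data$label != "template")
    lcca <- arrange(lcca, desc(abs(.data$pct_dev)), .data$label)
    head(lcca$label, config$k_ecmo)
  })
  files <- c(files, write_stage_csv(tibble(label = ecmo_labels), out_dir,
                                    "ecmo/selection.csv"))

  # 8. ECMO simulations --------------------------------------------------
  ecmo <- run_stage("ecmo", {
    shock <- scale_waveform(healthy$waveform, reduction = config$shock_reduction)
    rows <- list()
    for (lab in ecmo_labels) {
      tracts <- split_tracts(centerlines_from_geometry(augmented[[lab]]))
      net <- set_windkessel(build_network(tracts, config$fluid, "ecmo"),
                            healthy$cal$params)
      for (ef in config$ef_levels) {
        cfg <- config$sim
        cfg$ef_lmin <- ef
        sim <- simulate_flow(net, shock, cfg)
        tr <- transport_fraction(sim, n_cells = config$n_cells)
        ws_s <- watershed_location(sim, "systolic")
        ws_d <- watershed_location(sim, "diastolic")
        idx <- final_cycle_idx(sim)
        td <- tidy(sim); gl <- glance(sim)
        phi_mean <- colMeans(tr$ostium_phi[idx, , drop = FALSE])
        rows[[length(rows) + 1]] <- bind_cols(
          tibble(label = lab, ef_lmin = ef),
          pivot_wider(td[, c("outlet", "mean_flow_lmin")],
                      names_from = "outlet", values_from = "mean_flow_lmin",
                      names_prefix = "qbar_"),
          tibble(peak_root_mmhg = gl$peak_root_mmhg,
                 min_root_mmhg = gl$min_root_mmhg,
                 zone_systolic = ws_s$zone, s_star_systolic = ws_s$s_star_mm,
                 zone_diastolic = ws_d$zone, s_star_diastolic = ws_d$s_star_mm,
                 phi_bca = phi_mean[["bca"]], phi_lcca = phi_mean[["lcca"]],
                 phi_lsa = phi_mean[["lsa"]],
                 phase2_balance_err = transport_balance_error(tr))
        )
        ts <- tibble(time = sim$times,
                     as_tibble(pa_to_mmhg(sim$node_pressure)),
                     as_tibble(si_to_lmin(sim$outlet_flow)),
                     s_star_mm = tr$s_star)
        files <<- c(files, write_stage_csv(
          ts, out_dir, sprintf("ecmo/timeseries_%s_ef%g.csv", lab, ef)))
      }
    }
    bind_rows(rows)
  })
  files <- c(files, write_stage_csv(ecmo, out_dir, "ecmo/results.csv"))

  manifest <- new_run_manifest(out_dir, files, config, stages, t0)
  report_files <- report(manifest)
  manifest <- new_run_manifest(out_dir, c(files, report_files), config, c(stages, "report"), t0)
  jsonlite::write_json(
    list(seed = config$seed, stages = manifest$stages,
         files = manifest$files,
         package_version = as.character(packageVersion("aortaflow")),
         timestamp = format(manifest$timestamp, "%Y-%m-%dT%H:%M:%S")),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns", pretty = TRUE
  )
  manifest
}

new_run_manifest <- function(out_dir, files, config, stages, t0) {
  hashes <- unname(tools::md5sum(file.path(out_dir, files)))
  structure(
    list(files = tibble(path = files, md5 = hashes),
         out_dir = out_dir, seed = config$seed, config = config,
         stages = stages, timestamp = t0),
    class = "run_manifest"
  )
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> seed %d, %d stages, %d files under %s\n",
              x$seed, length(x$stages), nrow(x$files), x$out_dir))
  invisible(x)
}

#' Summarize a completed run
#'
#' Recomputes the study's summary tables from the stage outputs on disk:
#' per-outlet healthy mean-flow deviations from the template, mean flow as a
#' function of ECMO level with a per-outlet linear fit (slope and R^2), and
#' the watershed zone per (geometry, EF, phase).
#'
#' @param manifest a [run_all()] manifest, or an output directory.
#' @return Invisibly, the character vector of report files written (relative
#'   to the output directory). The tables themselves are attached as
#'   attribute `"tables"`.
#' @export
report <- function(manifest) {
  out_dir <- if (inherits(manifest, "run_manifest")) manifest$out_dir else manifest
  need <- c("healthy/flows.csv", "ecmo/results.csv")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing) > 0) {
    abort(sprintf("missing stage outputs: %s (run the '%s' stage first)",
                  paste(missing, collapse = ", "),
                  if (grepl("healthy", missing[1])) "healthy" else "ecmo"))
  }
  flows <- readr::read_csv(file.path(out_dir, "healthy/flows.csv"),
                           show_col_types = FALSE)
  ecmo <- readr::read_csv(file.path(out_dir, "ecmo/results.csv"),
                          show_col_types = FALSE)

  pct_tbl <- pivot_wider(flows[, c("label", "outlet", "pct_dev")],
                         names_from = "outlet", values_from = "pct_dev",
                         names_prefix = "pct_dev_")

  long <- pivot_longer(ecmo, cols = dplyr::starts_with("qbar_"),
                       names_to = "outlet", values_to = "qbar_lmin",
                       names_prefix = "qbar_")
  # an essentially perfect linear fit is the expected outcome here, so the
  # corresponding summary.lm() warning is suppressed
  fits <- suppressWarnings(summarise(
    group_by(long, .data$label, .data$outlet),
    slope = coef(lm(qbar_lmin ~ ef_lmin))[2],
    intercept = coef(lm(qbar_lmin ~ ef_lmin))[1],
    r_squared = summary(lm(qbar_lmin ~ ef_lmin))$r.squared,
    .groups = "drop"
  ))
  watershed <- bind_rows(
    mutate(ecmo[, c("label", "ef_lmin", "zone_systolic", "s_star_systolic")],
           phase = "systolic",
           zone = .data$zone_systolic, s_star_mm = .data$s_star_systolic),
    mutate(ecmo[, c("label", "ef_lmin", "zone_diastolic", "s_star_diastolic")],
           phase = "diastolic",
           zone = .data$zone_diastolic, s_star_mm = .data$s_star_diastolic)
  )[, c("label", "ef_lmin", "phase", "zone", "s_star_mm")]

  rel <- c(
    write_stage_csv(pct_tbl, out_dir, "report/mean_flow_pct.csv"),
    write_stage_csv(fits, out_dir, "report/ef_linearity.csv"),
    write_stage_csv(watershed, out_dir, "report/watershed.csv")
  )
  out <- structure(rel, tables = list(mean_flow_pct = pct_tbl,
                                      ef_linearity = fits,
                                      watershed = watershed))
  invisible(out)
}
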