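# Shared fixtures. Tests run at a reduced surface resolution: all geometric
# relations checked here (ring centroids, tract partitions, resistances) are
# resolution-independent, so the coarse sampling only speeds things up.

tiny_res <- function() {
  geometry_resolution(main_rings = 60, branch_rings = 10, ring_samples = 12)
}

tiny_population <- function(n = 6, seed = 42, ...) {
  sample_population(population_spec(n_subjects = n, seed = seed, ...),
                    resolution = tiny_res())
}

template_tracts <- function(res = tiny_res(), params = aorta_params()) {
  g <- build_geometry(params, res, label = "template")
  split_tracts(centerlines_from_geometry(g))
}

# Calibrated healthy template network + waveform, computed once per session.
calibrated_template <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tracts <- template_tracts(geometry_resolution(main_rings = 120,
                                                    branch_rings = 20,
                                                    ring_samples = 16))
      w <- cardiac_waveform(mean_lmin = 5)
      cal <- calibrate_rcr(build_network(tracts, mode = "healthy"), w)
      cache <<- list(tracts = tracts, waveform = w, cal = cal)
    }
    cache
  }
})

# Shock ECMO simulation at a given EF on the calibrated template network.
shock_ecmo_sim <- function(ef, n_cycles = 3) {
  ct <- calibrated_template()
  net <- set_windkessel(build_network(ct$tracts, mode = "ecmo"), ct$cal$params)
  shock <- scale_waveform(ct$waveform, reduction = 0.7)
  simulate_flow(net, shock, sim_config(ef_lmin = ef, n_cycles = n_cycles))
}

# Analytic helix fixture: radius a, pitch parameter b, closed-form
# curvature a/(a^2+b^2) and torsion b/(a^2+b^2).
helix_points <- function(a = 10, b = 5, n = 200, turns = 2) {
  th <- seq(0, turns * 2 * pi, length.out = n)
  tibble::tibble(x = a * cos(th), y = a * sin(th), z = b * th, r = 1)
}
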