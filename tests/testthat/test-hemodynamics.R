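test_that("segment resistances follow the Poiseuille closed form", {
  mu <- 3.5e-3
  expect_equal(poiseuille_resistance(0.1, 0.01, mu),
               8 * mu * 0.1 / (pi * 0.01^4), tolerance = 1e-12)
  # the r^4 law: doubling the radius divides the resistance by 16
  expect_equal(poiseuille_resistance(0.1, 0.02, mu),
               poiseuille_resistance(0.1, 0.01, mu) / 16, tolerance = 1e-12)
  f <- fluid_props()
  expect_identical(f$density, 1060)
  expect_identical(f$viscosity, 3.5e-3)
  expect_error(poiseuille_resistance(0.1, -0.01), "radius")
})

test_that("network construction wires the seven tracts", {
  tracts <- template_tracts()
  net <- build_network(tracts, mode = "healthy")
  expect_setequal(net$segments$segment,
                  c("ascending", "arch_a", "arch_b", "descending",
                    "bca", "lcca", "lsa"))
  expect_setequal(net$outlets$outlet, c("bca", "lcca", "lsa", "descending"))
  net_e <- build_network(tracts, mode = "ecmo")
  expect_setequal(net_e$outlets$outlet, c("bca", "lcca", "lsa", "abdominal"))
  expect_error(simulate_flow(net, cardiac_waveform()), "calibrate")
})

test_that("a dead network decays to zero flow", {
  ct <- calibrated_template()
  net <- ct$cal$network
  still <- cardiac_waveform(mean_lmin = 1)
  still$q <- rep(0, length(still$q))
  sim <- simulate_flow(net, still,
                       sim_config(init = setNames(rep(0, 4), net$outlets$outlet)))
  idx <- aortaflow:::final_cycle_idx(sim)
  expect_lt(max(abs(sim$outlet_flow[idx, ])), 1e-9)
})

test_that("three cycles of 0.8 s span 2.4 s and conserve mass to 1e-6", {
  ct <- calibrated_template()
  sim <- simulate_flow(ct$cal$network, ct$waveform)
  expect_equal(max(sim$times), 2.4, tolerance = 1e-9)
  expect_lt(glance(sim)$mass_residual, 1e-6)
  # instantaneous conservation at every timestep
  tot_out <- rowSums(sim$outlet_flow)
  expect_lt(max(abs(tot_out - sim$cardiac_q)) / max(sim$cardiac_q), 1e-9)
})

test_that("mass is conserved in ECMO runs including the EF source", {
  for (ef in c(0, 4)) {
    sim <- shock_ecmo_sim(ef)
    gl <- glance(sim)
    expect_lt(gl$mass_residual, 1e-6)
    expect_equal(gl$total_inflow_lmin, 1.5 + ef, tolerance = 1e-6)
  }
})

test_that("healthy pressure decreases from root to descending outlet at systole", {
  ct <- calibrated_template()
  sim <- simulate_flow(ct$cal$network, ct$waveform)
  idx <- aortaflow:::final_cycle_idx(sim)
  peak <- idx[which.max(sim$cardiac_q[idx])]
  p <- sim$node_pressure[peak, c("root", "bca_ostium", "lcca_ostium",
                                 "lsa_ostium", "desc_end")]
  expect_true(all(diff(p) < 0))
})

test_that("calibration meets the split and pressure targets deterministically", {
  ct <- calibrated_template()
  sim <- simulate_flow(ct$cal$network, ct$waveform)
  td <- tidy(sim)
  splits <- td$mean_flow_lmin / sum(td$mean_flow_lmin)
  names(splits) <- td$outlet
  targets <- calibration_targets()$splits
  expect_equal(splits[names(targets)], targets, tolerance = 0.01)
  peak <- glance(sim)$peak_root_mmhg
  expect_gte(peak, 120)
  expect_lte(peak, 130)
  # raising the target mean pressure by 10% raises total resistance ~10%
  t2 <- calibration_targets(map_mmhg = 93 * 1.1)
  cal2 <- calibrate_rcr(build_network(ct$tracts, mode = "healthy"),
                        ct$waveform, t2)
  r1 <- sum(1 / (ct$cal$params$Rp + ct$cal$params$Rd))
  r2 <- sum(1 / (cal2$params$Rp + cal2$params$Rd))
  expect_equal((1 / r2) / (1 / r1), 1.1, tolerance = 0.02)
  # determinism
  cal3 <- calibrate_rcr(build_network(ct$tracts, mode = "healthy"),
                        ct$waveform)
  expect_identical(cal3$params, ct$cal$params)
})

test_that("supra-aortic mean flows rise linearly with EF and recover healthy levels", {
  ct <- calibrated_template()
  healthy <- tidy(simulate_flow(ct$cal$network, ct$waveform))
  efs <- c(0, 4, 6)
  flows <- lapply(efs, function(ef) tidy(shock_ecmo_sim(ef)))
  for (b in c("bca", "lcca", "lsa")) {
    q <- vapply(flows, function(f) f$mean_flow_lmin[f$outlet == b], numeric(1))
    fit <- summary(suppressWarnings(lm(q ~ efs)))
    expect_gt(fit$r.squared, 0.99)
    expect_true(all(diff(q) > 0))
    q_healthy <- healthy$mean_flow_lmin[healthy$outlet == b]
    expect_gte(q[3], q[1])
    expect_gte(q[3], 0.95 * q_healthy)
  }
})
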