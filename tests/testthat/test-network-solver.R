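test_that("segment resistance formula and scalings", {
  expect_equal(poiseuille_resistance(1e-3, 0.1, 0.0035),
               8 * 0.0035 * 0.1 / (pi * 1e-12))   # ~ 8.913e8
  expect_equal(poiseuille_resistance(0.5e-3, 0.1, 0.0035),
               16 * poiseuille_resistance(1e-3, 0.1, 0.0035))
  expect_equal(poiseuille_resistance(1e-3, 0.1, 0.007),
               2 * poiseuille_resistance(1e-3, 0.1, 0.0035))
})

test_that("single pipe at g = 0: dP = R(mu*) Q", {
  net <- pipe_network(radius = 2e-3, length = 0.2, r_out = 5e8)
  q <- 1e-5
  sol <- solve_instant(net, q, 0, default_params)
  mu_star <- sol$mu[1]
  r_pipe <- poiseuille_resistance(2e-3, 0.2, mu_star)
  dp <- sol$pressures["in"] - sol$pressures["out"]
  expect_equal(unname(dp), r_pipe * q, tolerance = 1e-9)
  expect_equal(unname(sol$flows["pipe"]), q, tolerance = 1e-12)
  # converged viscosity is consistent with the wall shear rate
  shear <- 4 * q / (pi * (2e-3)^3)
  expect_equal(unname(mu_star),
               blended_viscosity(4e-3, shear, default_params),
               tolerance = 1e-5)
})

test_that("hydrostatic statics: zero inflow gives rho g h pressure
           difference and zero flow", {
  h <- 0.3
  net <- pipe_network(radius = 2e-3, length = 0.4, dz = h, r_out = 1e9)
  sol <- solve_instant(net, 0, 9.81, default_params)
  expect_equal(unname(abs(sol$flows["pipe"])), 0, tolerance = 1e-15)
  dp <- unname(sol$pressures["in"] - sol$pressures["out"])
  expect_equal(dp, 1050 * 9.81 * h, tolerance = 1e-9)
})

test_that("symmetric Y splits flow exactly evenly", {
  net <- y_network()
  sol <- solve_instant(net, 2e-5, 0, default_params)
  expect_equal(unname(sol$flows["br_a"]), unname(sol$flows["br_b"]))
  expect_equal(unname(sol$flows["br_a"]), 1e-5, tolerance = 1e-12)
})

test_that("fixed point independent of the initial viscosity guess", {
  net <- y_network(r_out = 2e9)
  ns <- nrow(net$segments)
  s1 <- solve_instant(net, 3e-5, 9.81, default_params,
                      mu_init = rep(0.0035, ns))
  s2 <- solve_instant(net, 3e-5, 9.81, default_params,
                      mu_init = rep(0.15, ns))
  expect_equal(s1$flows, s2$flows, tolerance = 1e-8)
})

test_that("piezometric equivalence: g = 0 solution ignores elevations", {
  net_flat <- pipe_network(radius = 2e-3, length = 0.4, dz = 0)
  net_up <- pipe_network(radius = 2e-3, length = 0.4, dz = 0.3)
  a <- solve_instant(net_flat, 1e-5, 0, default_params)
  b <- solve_instant(net_up, 1e-5, 0, default_params)
  expect_equal(a$flows, b$flows, tolerance = 1e-12)
})

test_that("run_case: conservation, cycle identity, outlet volume", {
  net <- y_network(r_out = 1e9)
  wave <- generate_inflow(waveform_spec(heart_rate = 60), dt = 0.01)
  cc <- case_config(g = 9.81, dt = 0.01, n_cycles = 3)
  res <- run_case(net, wave, cc, default_params, recompute_cycles = TRUE)
  # genuine multi-cycle march converges with zero change (memoryless)
  expect_true(res$convergence$converged)
  expect_lt(res$convergence$max_change, 1e-12)
  # nodal mass balance at every node and instant
  expect_lt(max(abs(mass_balance_residuals(res))), 1e-9)
  # outlet volume per cycle equals the inlet stroke volume
  vol_out <- sum(res$outlet_flows) * wave$dt
  expect_equal(vol_out, stroke_volume(wave), tolerance = 1e-9)
})

test_that("microgravity transform scales exactly what it should", {
  inp <- build_study_inputs(dt = 0.01, wspec = waveform_spec())
  mg <- apply_microgravity(inp$wave, inp$net$outlets,
                           gravity_case(dt = 0.01))
  expect_equal(stroke_volume(mg$wave) / stroke_volume(inp$wave), 1.2,
               tolerance = 1e-12)
  ratio <- mg$outlets$resistance_Pa_s_per_m3 /
    inp$net$outlets$resistance_Pa_s_per_m3
  ei <- inp$net$outlets$region == "external_iliac"
  expect_equal(ratio[ei], rep(1.93, sum(ei)))
  expect_true(all(ratio[!ei] == 1))
  expect_equal(mg$cc$g, 0)
  # transformed outlets still satisfy the extrusion round trip
  expect_equal(poiseuille_resistance(mg$outlets$radius_m,
                                     mg$outlets$extrusion_length_m,
                                     mg$outlets$mu_eff_Pa_s),
               mg$outlets$resistance_Pa_s_per_m3, tolerance = 1e-12)
  # missing region -> warning, no-op
  expect_warning(
    mg2 <- apply_microgravity(inp$wave, inp$net$outlets,
                              gravity_case(dt = 0.01),
                              iliac_region = "no_such_region"),
    "no outlets")
  expect_equal(mg2$outlets$resistance_Pa_s_per_m3,
               inp$net$outlets$resistance_Pa_s_per_m3)
})

test_that("degenerate networks are rejected", {
  nodes <- data.frame(node = c("in", "out", "orphan"), z = 0)
  segs <- data.frame(segment_id = "pipe", from = "in", to = "out",
                     radius_m = 1e-3, length_m = 0.1, delta_z_m = 0,
                     region = "t", stringsAsFactors = FALSE)
  outs <- make_outlet_spec("o1", "t", 1e-3, 1e9); outs$node <- "out"
  expect_error(vessel_network(nodes, segs, "in", outs), "not connected")
  expect_error(pipe_network(dz = 0.5, length = 0.1), NA)  # length clamped
})
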