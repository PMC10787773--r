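test_that("default network has the study's outlet census", {
  net <- generate_network(geometry_spec())
  expect_equal(nrow(net$outlets), 72L)   # 1+32+26+2+2+2+2+1+2+2
  counts <- table(net$outlets$region)
  spec <- geometry_spec()
  expect_equal(unname(c(counts[names(spec$outlet_counts)])),
               unname(as.integer(spec$outlet_counts)))
  # CRA outlets: fractal bc, half the 163 um calibre, at eye elevation
  cra <- net$outlets[net$outlets$bc_type == "fractal", ]
  expect_equal(nrow(cra), 2L)
  expect_equal(cra$radius_m, rep(163e-6 / 2, 2))
  z <- net$nodes$z[match(cra$node, net$nodes$node)]
  expect_equal(z, rep(0.35, 2))
  # upright anchors: eye above the inlet, external iliac below
  ei <- net$outlets[net$outlets$region == "external_iliac", ]
  expect_true(all(net$nodes$z[match(ei$node, net$nodes$node)] < 0))
})

test_that("zero jitter gives exact bilateral symmetry; fixed seed
           reproduces", {
  net <- generate_network(geometry_spec(jitter_fraction = 0))
  segs <- net$segments
  rL <- segs$radius_m[segs$segment_id == "ica_L"]
  rR <- segs$radius_m[segs$segment_id == "ica_R"]
  expect_identical(rL, rR)
  n1 <- generate_network(geometry_spec(jitter_fraction = 0.05, seed = 9L))
  n2 <- generate_network(geometry_spec(jitter_fraction = 0.05, seed = 9L))
  expect_identical(n1, n2)
  n3 <- generate_network(geometry_spec(jitter_fraction = 0.05, seed = 10L))
  expect_false(identical(n1$segments$radius_m, n3$segments$radius_m))
})

test_that("inflow generator meets its analytic constraints", {
  spec <- waveform_spec(heart_rate = 60, stroke_vol = 70e-6,
                        systolic_fraction = 0.35, peak_to_mean = 3)
  wave <- generate_inflow(spec, dt = 0.001)
  expect_equal(stroke_volume(wave), 70e-6, tolerance = 1e-9)
  expect_true(all(wave$q >= 0))
  # peak sample equals the analytic raised-cosine peak
  q_mean <- 70e-6 / 1
  q_peak <- 3 * q_mean
  expect_equal(max(wave$q), q_peak, tolerance = 1e-12)
  # doubling stroke volume doubles every sample
  w2 <- generate_inflow(waveform_spec(stroke_vol = 140e-6), dt = 0.001)
  expect_equal(w2$q, 2 * wave$q, tolerance = 1e-12)
  # infeasible peak/mean combination errors
  expect_error(generate_inflow(waveform_spec(peak_to_mean = 8,
                                             systolic_fraction = 0.5)),
               "infeasible")
  expect_error(generate_inflow(spec, dt = 0.0007), "divide")
})

test_that("perturb_geometry: identity at 0, reproducible, bounded", {
  net <- generate_network(geometry_spec())
  expect_identical(perturb_geometry(net, 0), net)
  p1 <- perturb_geometry(net, 0.1, seed = 3L)
  p2 <- perturb_geometry(net, 0.1, seed = 3L)
  expect_identical(p1, p2)
  ratio <- p1$segments$radius_m / net$segments$radius_m
  expect_true(all(abs(ratio - 1) <= 0.1))
  expect_true(all(abs(p1$segments$delta_z_m) <=
                    p1$segments$length_m * (1 + 1e-12)))
  expect_error(perturb_geometry(net, 0.5), "magnitude")
})

test_that("design_outlets wires fractal and Murray resistances", {
  inp <- build_study_inputs(dt = 0.01)
  out <- inp$net$outlets
  # extrusion round trip for every outlet
  expect_equal(poiseuille_resistance(out$radius_m, out$extrusion_length_m,
                                     out$mu_eff_Pa_s),
               out$resistance_Pa_s_per_m3, tolerance = 1e-12)
  # fractal outlets match a direct tree computation
  frac <- out[out$bc_type == "fractal", ]
  direct <- retinal_outlet_resistances(frac$radius_m, inp$bp, inp$params)
  expect_equal(frac$resistance_Pa_s_per_m3, direct)
  # Murray regions: implied region flows at p_sys hit the split table
  mur <- out[out$bc_type == "murray", ]
  q <- inp$ref$p_sys / mur$resistance_Pa_s_per_m3
  frac_tab <- tapply(q, mur$region, sum) / inp$ref$q_sys
  sp <- inp$splits[match(names(frac_tab), inp$splits$region), ]
  expect_equal(unname(c(frac_tab)), sp$co_fraction, tolerance = 1e-12)
})

test_that("network CSV round trip preserves the model", {
  dir <- withr::local_tempdir()
  inp <- build_study_inputs(dt = 0.01)
  write_network(inp$net, dir)
  write_waveform(inp$wave, file.path(dir, "waveform.csv"))
  net2 <- read_network(file.path(dir, "nodes.csv"),
                       file.path(dir, "segments.csv"),
                       file.path(dir, "outlets.csv"), "root")
  expect_equal(net2$segments$radius_m, inp$net$segments$radius_m)
  expect_equal(net2$outlets$resistance_Pa_s_per_m3,
               inp$net$outlets$resistance_Pa_s_per_m3)
  w2 <- read_waveform(file.path(dir, "waveform.csv"))
  expect_equal(w2$q, inp$wave$q)
  expect_equal(w2$period, inp$wave$period)
})
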