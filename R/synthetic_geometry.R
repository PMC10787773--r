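#' Synthetic heart-to-eye geometry specification
#'
#' Parameters of the stand-in arterial network: region outlet counts
#' (defaults are the study's split table: 72 outlets in total), trunk
#' radii, elevation anchors for the upright posture (aortic root datum
#' z = 0, eye above, iliac outlets below) and an optional seeded radius
#' jitter.
#'
#' @param outlet_counts named integer vector of outlets per region.
#' @param cra_diameter central retinal artery diameter, m (default
#'   163 um).
#' @param eye_z,brain_z,iliac_z elevation anchors, m relative to the
#'   aortic root.
#' @param jitter_fraction relative radius jitter (uniform, +-); default
#'   0 (exactly bilaterally symmetric network).
#' @param seed RNG seed for the jitter.
#' @return object of class `geometry_spec`.
#' @export
geometry_spec <- function(
    outlet_counts = c(celiac = 1L, cerebral = 32L, coronary = 26L,
                      external_carotid = 2L, internal_iliac = 2L,
                      external_iliac = 2L, ophthalmic = 2L,
                      mesenteric = 1L, renal = 2L, subclavian = 2L),
    cra_diameter = 163e-6,
    eye_z = 0.35, brain_z = 0.40, iliac_z = -0.55,
    jitter_fraction = 0, seed = 1L) {
  stopifnot(all(outlet_counts >= 1L), cra_diameter > 0,
            jitter_fraction >= 0, jitter_fraction < 0.5,
            eye_z > 0, brain_z > 0, iliac_z < 0)
  structure(list(outlet_counts = outlet_counts,
                 cra_diameter = cra_diameter, eye_z = eye_z,
                 brain_z = brain_z, iliac_z = iliac_z,
                 jitter_fraction = jitter_fraction,
                 seed = as.integer(seed)),
            class = "geometry_spec")
}

#' Generate the synthetic heart-to-eye network
#'
#' Builds a connected tree: aortic root -> arch (coronaries,
#' brachiocephalic -> right carotid / right subclavian, left carotid,
#' left subclavian) -> descending aorta (celiac, mesenteric, renals) ->
#' iliac bifurcation (internal / external iliacs); each carotid
#' bifurcation feeds the external carotid outlet and the internal
#' carotid, which joins the vertebral-fed circle-of-Willis side node
#' supplying the cerebral outlets and the ophthalmic artery ending in
#' the central retinal artery (CRA) outlet at eye elevation.  Outlet
#' resistances are NOT assigned here (placeholder 1); use
#' [design_outlets] or [build_study_inputs].
#'
#' The outlet manifest carries `bc_type`: "fractal" for the two CRA
#' (ophthalmic-region) retinal outlets, "murray" for every other
#' region.
#'
#' @param spec a [geometry_spec].
#' @return a [vessel_network] (outlet resistances all placeholder 1).
#' @export
generate_network <- function(spec = geometry_spec()) {
  jf <- spec$jitter_fraction
  jit <- function(r) {
    if (jf == 0) return(r)
    r * (1 + stats::runif(length(r), -jf, jf))
  }
  if (jf > 0) set.seed(spec$seed)

  nodes <- list(); segs <- list(); outs <- list()
  add_node <- function(node, z) nodes[[length(nodes) + 1]] <<-
    data.frame(node = node, z = z)
  add_seg <- function(id, from, to, r, len, dz, region)
    segs[[length(segs) + 1]] <<- data.frame(
      segment_id = id, from = from, to = to, radius_m = r,
      length_m = len, delta_z_m = dz, region = region,
      stringsAsFactors = FALSE)
  add_out <- function(id, region, node, r, bc)
    outs[[length(outs) + 1]] <<- data.frame(
      outlet_id = id, region = region, node = node, radius_m = r,
      bc_type = bc, stringsAsFactors = FALSE)

  # a terminal branch: one leaf segment + one outlet at its end
  leaf <- function(id, from, z_from, z_to, r_seg, len, region,
                   bc = "murray", r_out = r_seg) {
    node <- paste0(id, "_n")
    add_node(node, z_to)
    add_seg(id, from, node, r_seg, len, z_to - z_from, region)
    add_out(id, region, node, r_out, bc)
  }

  add_node("root", 0)
  add_node("arch", 0.05)
  add_seg("asc_aorta", "root", "arch", jit(0.0115), 0.06, 0.05, "aorta")

  # coronaries: two mains off the root, 13 outlets each
  for (side in c("L", "R")) {
    main <- paste0("cor_main_", side)
    add_node(main, 0)
    add_seg(main, "root", main, jit(0.002), 0.03, 0, "coronary")
    for (k in 1:13) {
      leaf(sprintf("coronary_%s%02d", side, k), main, 0, 0,
           jit(0.0007), 0.025, "coronary")
    }
  }

  # head and arm vessels
  add_node("bct", 0.08)
  add_seg("bct", "arch", "bct", jit(0.006), 0.04, 0.03, "aorta")
  for (side in c("L", "R")) {
    sub <- paste0("sub_", side)
    add_node(sub, if (side == "R") 0.08 else 0.05 + 0.03)
    origin <- if (side == "R") "bct" else "arch"
    z0 <- if (side == "R") 0.08 else 0.05
    add_seg(paste0("subclavian_a_", side), origin, sub, jit(0.004),
            0.05, 0.08 - z0, "subclavian")
    leaf(paste0("subclavian_", side), sub, 0.08, 0.08, jit(0.004),
         0.08, "subclavian")
    # vertebral artery to the basilar confluence
    carb <- paste0("carb_", side)
    add_node(carb, 0.15)
    add_seg(paste0("common_carotid_", side), origin, carb, jit(0.0035),
            0.12, 0.15 - z0, "carotid")
    leaf(paste0("external_carotid_", side), carb, 0.15, 0.19,
         jit(0.0025), 0.05, "external_carotid")
  }
  add_node("bas", 0.35)
  add_seg("vertebral_L", "sub_L", "bas", jit(0.0015), 0.32, 0.27,
          "vertebral")
  add_seg("vertebral_R", "sub_R", "bas", jit(0.0015), 0.32, 0.27,
          "vertebral")
  add_node("cow_mid", 0.40)
  add_seg("basilar", "bas", "cow_mid", jit(0.002), 0.06, 0.05,
          "cerebral")
  for (side in c("L", "R")) {
    cow <- paste0("cow_", side)
    add_node(cow, 0.40)
    add_seg(paste0("ica_", side), paste0("carb_", side), cow,
            jit(0.002), 0.26, 0.25, "cerebral")
    add_seg(paste0("pcom_", side), "cow_mid", cow, jit(0.001), 0.02, 0,
            "cerebral")
    for (k in 1:16) {
      leaf(sprintf("cerebral_%s%02d", side, k), cow, 0.40, 0.40,
           jit(0.0008), 0.03, "cerebral")
    }
    # ophthalmic artery down to the eye, ending in the CRA outlet
    eye <- paste0("eye_", side)
    add_node(eye, spec$eye_z)
    add_seg(paste0("ophthalmic_", side), cow, eye, jit(0.0006), 0.06,
            spec$eye_z - 0.40, "ophthalmic")
    leaf(paste0("cra_", side), eye, spec$eye_z, spec$eye_z,
         jit(spec$cra_diameter / 2), 0.01, "ophthalmic", bc = "fractal")
  }

  # descending aorta and abdomen
  add_node("d1", -0.10)
  add_seg("desc_aorta_1", "arch", "d1", jit(0.009), 0.18, -0.15, "aorta")
  leaf("celiac", "d1", -0.10, -0.10, jit(0.0035), 0.04, "celiac")
  add_node("d2", -0.12)
  add_seg("desc_aorta_2", "d1", "d2", jit(0.0085), 0.03, -0.02, "aorta")
  leaf("mesenteric", "d2", -0.12, -0.12, jit(0.004), 0.05, "mesenteric")
  add_node("d3", -0.15)
  add_seg("desc_aorta_3", "d2", "d3", jit(0.008), 0.04, -0.03, "aorta")
  leaf("renal_L", "d3", -0.15, -0.15, jit(0.0025), 0.05, "renal")
  leaf("renal_R", "d3", -0.15, -0.15, jit(0.0025), 0.05, "renal")
  add_node("ilbif", -0.20)
  add_seg("abdominal_aorta", "d3", "ilbif", jit(0.007), 0.06, -0.05,
          "aorta")
  for (side in c("L", "R")) {
    ci <- paste0("ci_", side)
    add_node(ci, -0.26)
    add_seg(paste0("common_iliac_", side), "ilbif", ci, jit(0.005),
            0.08, -0.06, "iliac")
    leaf(paste0("internal_iliac_", side), ci, -0.26, -0.45,
         jit(0.003), 0.21, "internal_iliac")
    leaf(paste0("external_iliac_", side), ci, -0.26, spec$iliac_z,
         jit(0.004), abs(spec$iliac_z + 0.26) + 0.03, "external_iliac")
  }

  nodes <- do.call(rbind, nodes)
  segs <- do.call(rbind, segs)
  outs <- do.call(rbind, outs)
  # radii jitter breaks delta_z consistency never (z untouched); lengths fixed
  outs <- cbind(outs,
                resistance_Pa_s_per_m3 = 1,
                mu_eff_Pa_s = 1,
                extrusion_length_m = 4 * outs$radius_m)
  net <- vessel_network(nodes, segs, "root", outs)
  # sanity: counts match the spec
  tab <- table(net$outlets$region)
  want <- spec$outlet_counts
  if (!all(names(want) %in% names(tab)) ||
      !all(tab[names(want)] == want)) {
    stop("generated outlet counts disagree with geometry_spec")
  }
  net
}

#' Assign designed resistances to a generated network's outlets
#'
#' Fractal-tree resistances (via [retinal_outlet_resistances]) for
#' outlets with `bc_type == "fractal"`, Murray's-law resistances per
#' region (via [murray_outlet_resistances]) for the rest, all converted
#' to effective-viscosity extruded outlets ([make_outlet_spec]).
#' Regions covered only by fractal outlets keep their split-table entry
#' for bookkeeping but receive no Murray resistance.
#'
#' @param net a [vessel_network] from [generate_network].
#' @param splits a completed region-split table.
#' @param ref a [systolic_reference].
#' @param bp a [branching_params].
#' @param params a [rheology_params].
#' @return the network with designed outlet resistances and effective
#'   viscosities.
#' @export
design_outlets <- function(net, splits = complete_split_table(),
                           ref = systolic_reference(),
                           bp = branching_params(),
                           params = rheology_params()) {
  out <- net$outlets
  frac <- out$bc_type == "fractal"
  if (any(frac)) {
    out$resistance_Pa_s_per_m3[frac] <-
      retinal_outlet_resistances(out$radius_m[frac], bp, params)
  }
  for (reg in unique(out$region[!frac])) {
    sel <- !frac & out$region == reg
    cf <- splits$co_fraction[match(reg, splits$region)]
    if (is.na(cf)) stop(sprintf("region '%s' missing from split table", reg))
    out$resistance_Pa_s_per_m3[sel] <-
      murray_outlet_resistances(cf, out$radius_m[sel], ref)
  }
  out$extrusion_length_m <- 4 * out$radius_m
  out$mu_eff_Pa_s <- resistance_to_effective_viscosity(
    out$resistance_Pa_s_per_m3, out$radius_m, out$extrusion_length_m)
  net$outlets <- out
  net
}

#' Synthetic inflow waveform specification and generator
#'
#' Single-peaked pulsatile inflow: a raised-cosine systolic bump over
#' `systolic_fraction` of the period on top of a constant diastolic
#' plateau.  The peak is `peak_to_mean` times the cycle-mean flow and
#' the plateau is chosen analytically so the sampled stroke volume is
#' exact (sampling at t = 0, dt, ..., T - dt makes the rectangle rule
#' exact for the cosine term when the systolic interval is a whole
#' number of steps).
#'
#' @param heart_rate beats per minute.
#' @param stroke_vol stroke volume, m^3 (default 70 ml).
#' @param systolic_fraction fraction of the cycle in systole.
#' @param peak_to_mean peak flow over cycle-mean flow.
#' @param rho blood density, kg m^-3.
#' @return object of class `waveform_spec`.
#' @export
waveform_spec <- function(heart_rate = 60, stroke_vol = 70e-6,
                          systolic_fraction = 0.35, peak_to_mean = 3,
                          rho = 1050) {
  stopifnot(heart_rate > 0, stroke_vol > 0,
            systolic_fraction > 0, systolic_fraction < 1,
            peak_to_mean >= 1, rho > 0)
  structure(list(heart_rate = heart_rate, stroke_vol = stroke_vol,
                 systolic_fraction = systolic_fraction,
                 peak_to_mean = peak_to_mean, rho = rho),
            class = "waveform_spec")
}

#' @rdname waveform_spec
#' @param spec a `waveform_spec`.
#' @param dt sampling interval, s; must divide the period.
#' @return a [waveform].
#' @export
generate_inflow <- function(spec = waveform_spec(), dt = 0.001) {
  period <- 60 / spec$heart_rate
  n <- round(period / dt)
  if (abs(n * dt - period) > 1e-9) stop("dt must divide the period")
  m <- round(spec$systolic_fraction * n)  # systolic samples
  if (m < 2 || m >= n) stop("infeasible systolic fraction at this dt")
  ts <- m * dt
  q_mean <- spec$stroke_vol / period
  q_peak <- spec$peak_to_mean * q_mean
  # integral: q_dia*T + (q_peak - q_dia)*ts/2 = SV
  q_dia <- (spec$stroke_vol - q_peak * ts / 2) / (period - ts / 2)
  if (q_dia < 0) {
    stop("infeasible peak_to_mean / systolic_fraction combination")
  }
  t <- (seq_len(n) - 1) * dt
  q <- rep(q_dia, n)
  sys <- seq_len(m)
  q[sys] <- q_dia + (q_peak - q_dia) * 0.5 * (1 - cos(2 * pi * t[sys] / ts))
  waveform(t, q * spec$rho, period, spec$rho)
}

#' Jitter a network's radii and lengths
#'
#' Robustness harness: multiplies every segment and outlet radius and
#' every segment length by independent uniform factors in
#' `[1 - magnitude, 1 + magnitude]`, then re-derives outlet extrusions.
#' Elevations (hence gravity heads) are untouched, keeping `|dz| <= L`
#' safe for `magnitude <= 0.2` with the default geometry.  Outlet
#' resistances are left as-is; re-run [design_outlets] afterwards.
#'
#' @param net a [vessel_network].
#' @param magnitude relative jitter in `[0, 0.2]`.
#' @param seed RNG seed.
#' @return the perturbed network.
#' @export
perturb_geometry <- function(net, magnitude, seed = 1L) {
  stopifnot(magnitude >= 0, magnitude <= 0.2)
  if (magnitude == 0) return(net)
  set.seed(seed)
  ns <- nrow(net$segments)
  no <- nrow(net$outlets)
  net$segments$radius_m <- net$segments$radius_m *
    (1 + stats::runif(ns, -magnitude, magnitude))
  slack <- abs(net$segments$delta_z_m) / net$segments$length_m
  lj <- stats::runif(ns, -magnitude, magnitude)
  # never shrink a length below its elevation change
  len_new <- net$segments$length_m * (1 + lj)
  net$segments$length_m <- pmax(len_new, abs(net$segments$delta_z_m))
  net$outlets$radius_m <- net$outlets$radius_m *
    (1 + stats::runif(no, -magnitude, magnitude))
  net$outlets$extrusion_length_m <- 4 * net$outlets$radius_m
  net
}

#' Assemble the default study inputs
#'
#' Convenience wrapper producing everything one run needs: the synthetic
#' network with designed outlets, the inflow waveform, the completed
#' split table and the systolic reference (taken from the waveform's
#' systolic peak unless supplied).
#'
#' @param gspec a [geometry_spec].
#' @param wspec a [waveform_spec].
#' @param dt sampling interval, s.
#' @param p_sys systolic pressure for the Murray design point, Pa.
#' @param bp a [branching_params].
#' @param params a [rheology_params].
#' @return list `net`, `wave`, `splits`, `ref`, `params`, `bp`.
#' @export
build_study_inputs <- function(gspec = geometry_spec(),
                               wspec = waveform_spec(), dt = 0.001,
                               p_sys = mmHg_to_Pa(120),
                               bp = branching_params(),
                               params = rheology_params()) {
  wave <- generate_inflow(wspec, dt)
  ref <- systolic_reference(p_sys = p_sys, q_sys = max(wave$q))
  splits <- complete_split_table()
  net <- generate_network(gspec)
  net <- design_outlets(net, splits, ref, bp, params)
  list(net = net, wave = wave, splits = splits, ref = ref,
       params = params, bp = bp)
}
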