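#' Gravity-case configuration
#'
#' Settings for one quasi-static pulsatile solve.  The two study cases
#' are provided by [gravity_case] (upright, g = 9.81) and
#' [microgravity_case] (g = 0, stroke volume x1.2, external-iliac outlet
#' resistance x1.93).
#'
#' @param g gravitational acceleration magnitude, m s^-2 (acts downward,
#'   i.e. toward negative z).
#' @param sv_scale stroke-volume multiplier applied to the inflow.
#' @param region_resistance_multipliers named numeric vector mapping
#'   region -> outlet-resistance factor (unlisted regions get 1).
#' @param n_cycles cycles to march (default 4).
#' @param dt time step, s (default 0.001).
#' @param cycle_tolerance relative change in cycle-averaged outlet flows
#'   below which the march is converged (default 0.03).
#' @param label case label for reports.
#' @return an object of class `case_config`.
#' @export
case_config <- function(g = 9.81, sv_scale = 1,
                        region_resistance_multipliers = numeric(0),
                        n_cycles = 4L, dt = 0.001,
                        cycle_tolerance = 0.03,
                        label = "case") {
  stopifnot(g >= 0, sv_scale > 0, n_cycles >= 2, dt > 0,
            cycle_tolerance > 0)
  structure(list(g = g, sv_scale = sv_scale,
                 region_resistance_multipliers =
                   region_resistance_multipliers,
                 n_cycles = as.integer(n_cycles), dt = dt,
                 cycle_tolerance = cycle_tolerance, label = label),
            class = "case_config")
}

#' @rdname case_config
#' @export
gravity_case <- function(dt = 0.001) {
  case_config(g = 9.81, sv_scale = 1, dt = dt, label = "gravity")
}

#' @rdname case_config
#' @export
microgravity_case <- function(dt = 0.001) {
  case_config(g = 0, sv_scale = 1.2,
              region_resistance_multipliers = c(external_iliac = 1.93),
              dt = dt, label = "microgravity")
}

# Precompute index structures for repeated nodal assembly.
.network_index <- function(net) {
  nodes <- net$nodes$node
  list(n = length(nodes),
       i = match(net$segments$from, nodes),
       j = match(net$segments$to, nodes),
       z = net$nodes$z,
       inlet = match(net$inlet_node, nodes),
       out_node = match(net$outlets$node, nodes),
       r = net$segments$radius_m,
       len = net$segments$length_m,
       d = 2 * net$segments$radius_m,
       r_out = net$outlets$resistance_Pa_s_per_m3)
}

#' Solve one quasi-static instant
#'
#' Linear nodal solve of the resistive network at inflow `q_in` under
#' gravitational acceleration `g`.  Segment flow obeys
#' Q = (P_from - P_to - rho g dz) / R_seg, outlets drain to a physical
#' pressure of 0 at their own elevation, and the inlet injects `q_in`.
#' Segment viscosities come from [blended_viscosity] at the Poiseuille
#' wall shear rate 4|Q|/(pi r^3) and are iterated to a fixed point by
#' under-relaxed Picard iteration.
#'
#' @param net a [vessel_network].
#' @param q_in inlet volumetric flow, m^3 s^-1.
#' @param g gravitational acceleration, m s^-2.
#' @param params a [rheology_params].
#' @param mu_init optional initial segment-viscosity vector, Pa s.
#' @param shear_floor minimum shear rate fed to the viscosity law, s^-1.
#' @param tol relative viscosity-change convergence tolerance.
#' @param max_iter Picard iteration cap.
#' @param relax under-relaxation factor in (0, 1].
#' @return list with `pressures` (named, Pa, physical), `flows` (named
#'   by segment), `outlet_flows` (named by outlet id), `mu` (converged
#'   segment viscosities), `iterations`.
#' @export
solve_instant <- function(net, q_in, g, params = rheology_params(),
                          mu_init = NULL, shear_floor = 1e-6,
                          tol = 1e-6, max_iter = 200L, relax = 0.5) {
  idx <- if (!is.null(attr(net, "index"))) attr(net, "index")
         else .network_index(net)
  .solve_instant_idx(net, idx, q_in, g, params, mu_init, shear_floor,
                     tol, max_iter, relax)
}

.solve_instant_idx <- function(net, idx, q_in, g, params, mu_init,
                               shear_floor, tol, max_iter, relax) {
  n <- idx$n
  rho <- params$rho
  mu <- if (is.null(mu_init)) {
    blended_viscosity(idx$d, rep(100, length(idx$d)), params)
  } else {
    stopifnot(length(mu_init) == length(idx$d), all(mu_init > 0))
    mu_init
  }
  dz <- net$segments$delta_z_m
  head_term <- rho * g * dz
  q <- NULL
  for (it in seq_len(max_iter)) {
    r_seg <- 8 * mu * idx$len / (pi * idx$r^4)
    cond <- 1 / r_seg
    G <- matrix(0, n, n)
    b <- numeric(n)
    # vectorised stamping (duplicate indices must accumulate -> loop-free
    # via tapply-style sums on linear indices)
    add <- function(ii, jj, vv) {
      lin <- (jj - 1L) * n + ii
      acc <- rowsum(vv, lin)
      G[as.integer(rownames(acc))] <<- G[as.integer(rownames(acc))] + acc[, 1]
    }
    add(idx$i, idx$i, cond)
    add(idx$j, idx$j, cond)
    add(idx$i, idx$j, -cond)
    add(idx$j, idx$i, -cond)
    bacc <- rowsum(c(head_term * cond, -head_term * cond),
                   c(idx$i, idx$j))
    b[as.integer(rownames(bacc))] <- b[as.integer(rownames(bacc))] + bacc[, 1]
    # NOTE: b holds +rho g dz/R at 'from' and -... at 'to': flow out of
    # 'from' is (P_f - P_t - rho g dz)/R, so the head term moves to RHS.
    oacc <- rowsum(1 / idx$r_out, idx$out_node)
    G[cbind(as.integer(rownames(oacc)), as.integer(rownames(oacc)))] <-
      G[cbind(as.integer(rownames(oacc)), as.integer(rownames(oacc)))] +
      oacc[, 1]
    b[idx$inlet] <- b[idx$inlet] + q_in
    p <- tryCatch(solve(G, b), error = function(e) {
      stop("singular nodal system (disconnected or degenerate network): ",
           conditionMessage(e))
    })
    q <- (p[idx$i] - p[idx$j] - head_term) * cond
    shear <- pmax(4 * abs(q) / (pi * idx$r^3), shear_floor)
    mu_new <- blended_viscosity(idx$d, shear, params)
    delta <- if (length(mu)) max(abs(mu_new - mu) / mu) else 0
    # on convergence return the viscosity that produced this solution,
    # keeping pressures/flows/mu mutually consistent
    if (delta >= tol) mu <- relax * mu_new + (1 - relax) * mu
    if (delta < tol) {
      names(p) <- net$nodes$node
      names(q) <- net$segments$segment_id
      q_out <- p[idx$out_node] / idx$r_out
      names(q_out) <- net$outlets$outlet_id
      return(list(pressures = p, flows = q, outlet_flows = q_out,
                  mu = mu, iterations = it))
    }
  }
  stop(sprintf(
    "viscosity fixed point not converged in %d iterations (residual %.3g)",
    max_iter, delta))
}

#' Run one pulsatile case
#'
#' Marches [solve_instant] over the inflow waveform for `cc$n_cycles`
#' cardiac cycles and retains the final cycle.  The network is
#' memoryless (no compliance or inertance), so successive cycles are
#' identical; by default one cycle is solved and reused, with the
#' cycle-convergence check reported on the cycle-averaged outlet flows.
#' Set `recompute_cycles = TRUE` to force a genuine multi-cycle march.
#'
#' Outlet-resistance multipliers and the stroke-volume scale in `cc` are
#' NOT applied here; use [apply_microgravity] to derive transformed
#' inputs.  `run_case` consumes the waveform and outlets as given.
#'
#' @param net a [vessel_network].
#' @param wave a [waveform]; its sampling must match `cc$dt`.
#' @param cc a [case_config].
#' @param params a [rheology_params].
#' @param recompute_cycles logical; re-solve every cycle from scratch.
#' @return object of class `case_result`: matrices `flows`
#'   (segments x time), `pressures` (nodes x time), `outlet_flows`
#'   (outlets x time), `mu` (segments x time), `tau_w` (segments x time,
#'   Pa), `t` (final-cycle sample times), `convergence` report, the
#'   `net`, `wave`, `cc` used.
#' @export
run_case <- function(net, wave, cc = gravity_case(),
                     params = rheology_params(),
                     recompute_cycles = FALSE) {
  if (abs(wave$dt - cc$dt) > 1e-12) {
    stop("waveform sampling interval does not match case dt")
  }
  idx <- .network_index(net)
  nt <- length(wave$t)
  ns <- nrow(net$segments)
  solve_cycle <- function(mu_warm) {
    flows <- matrix(0, ns, nt, dimnames = list(net$segments$segment_id))
    press <- matrix(0, idx$n, nt, dimnames = list(net$nodes$node))
    qout <- matrix(0, nrow(net$outlets), nt,
                   dimnames = list(net$outlets$outlet_id))
    mus <- matrix(0, ns, nt, dimnames = list(net$segments$segment_id))
    mu_prev <- mu_warm
    for (k in seq_len(nt)) {
      sol <- .solve_instant_idx(net, idx, wave$q[k], cc$g, params,
                                mu_prev, 1e-6, 1e-6, 200L, 0.5)
      flows[, k] <- sol$flows
      press[, k] <- sol$pressures
      qout[, k] <- sol$outlet_flows
      mus[, k] <- sol$mu
      mu_prev <- sol$mu
    }
    list(flows = flows, pressures = press, outlet_flows = qout, mu = mus)
  }
  cyc <- solve_cycle(NULL)
  cycles <- vector("list", cc$n_cycles)
  cycles[[1]] <- cyc
  for (c_i in 2:cc$n_cycles) {
    cycles[[c_i]] <- if (recompute_cycles) {
      solve_cycle(cycles[[c_i - 1]]$mu[, nt])
    } else {
      cycles[[c_i - 1]]
    }
  }
  avg_last <- rowMeans(cycles[[cc$n_cycles]]$outlet_flows)
  avg_prev <- rowMeans(cycles[[cc$n_cycles - 1]]$outlet_flows)
  max_change <- max(abs(avg_last - avg_prev) / pmax(abs(avg_prev), 1e-300))
  if (max_change >= cc$cycle_tolerance) {
    stop(sprintf(
      "cycle-to-cycle change %.3g exceeds tolerance %.3g after %d cycles",
      max_change, cc$cycle_tolerance, cc$n_cycles))
  }
  final <- cycles[[cc$n_cycles]]
  tau <- 4 * final$mu * final$flows / (pi * idx$r^3)
  structure(list(flows = final$flows, pressures = final$pressures,
                 outlet_flows = final$outlet_flows, mu = final$mu,
                 tau_w = tau, t = wave$t,
                 convergence = list(n_cycles = cc$n_cycles,
                                    max_change = max_change,
                                    converged = TRUE,
                                    recomputed = recompute_cycles),
                 net = net, wave = wave, cc = cc, params = params),
            class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf(
    "case_result '%s': %d segments x %d samples (g=%.3g, sv_scale=%.3g)\n",
    x$cc$label, nrow(x$flows), ncol(x$flows), x$cc$g, x$cc$sv_scale))
  cat(sprintf("  cycle convergence: max change %.3g over %d cycles\n",
              x$convergence$max_change, x$convergence$n_cycles))
  invisible(x)
}

#' Nodal mass-balance residuals of a solved case
#'
#' For every node and instant: inflow minus outflow (segments, outlets,
#' inlet source), normalised by the instantaneous inlet flow.
#'
#' @param res a `case_result`.
#' @return matrix nodes x time of relative residuals.
#' @export
mass_balance_residuals <- function(res) {
  net <- res$net
  idx <- .network_index(net)
  n <- idx$n; nt <- ncol(res$flows)
  resid <- matrix(0, n, nt, dimnames = list(net$nodes$node))
  for (k in seq_len(nt)) {
    bal <- numeric(n)
    q <- res$flows[, k]
    bal <- bal - unname(tapply(q, factor(idx$i, levels = seq_len(n)), sum,
                               default = 0))
    bal <- bal + unname(tapply(q, factor(idx$j, levels = seq_len(n)), sum,
                               default = 0))
    bal[is.na(bal)] <- 0
    qo <- res$outlet_flows[, k]
    oacc <- tapply(qo, factor(idx$out_node, levels = seq_len(n)), sum,
                   default = 0)
    oacc[is.na(oacc)] <- 0
    bal <- bal - unname(oacc)
    bal[idx$inlet] <- bal[idx$inlet] + res$wave$q[k]
    resid[, k] <- bal / max(abs(res$wave$q[k]), max(abs(res$wave$q)))
  }
  resid
}

#' Microgravity case transform
#'
#' Derives the simulated-microgravity inputs from the Earth-gravity
#' inputs: the inflow waveform is vertically scaled so stroke volume
#' rises by exactly 20%, every external-iliac outlet resistance is
#' multiplied by 1.93 (effective viscosity recomputed so the extruded
#' outlet still encodes the new resistance), all other outlets are left
#' untouched, and gravitational acceleration is set to 0.
#'
#' @param wave the gravity-case [waveform].
#' @param outlets the gravity-case outlet table.
#' @param cc_gravity the gravity [case_config].
#' @param sv_scale stroke-volume factor (default 1.2).
#' @param iliac_factor external-iliac resistance factor (default 1.93).
#' @param iliac_region region label carrying the factor.
#' @return list `wave`, `outlets`, `cc` for the microgravity case.
#' @export
apply_microgravity <- function(wave, outlets, cc_gravity = gravity_case(),
                               sv_scale = 1.2, iliac_factor = 1.93,
                               iliac_region = "external_iliac") {
  w2 <- waveform(wave$t, wave$massflow * sv_scale, wave$period, wave$rho)
  out2 <- outlets
  hit <- out2$region == iliac_region
  if (!any(hit)) {
    warning(sprintf("no outlets in region '%s'; resistances unchanged",
                    iliac_region))
  } else {
    out2$resistance_Pa_s_per_m3[hit] <-
      out2$resistance_Pa_s_per_m3[hit] * iliac_factor
    out2$mu_eff_Pa_s[hit] <- resistance_to_effective_viscosity(
      out2$resistance_Pa_s_per_m3[hit], out2$radius_m[hit],
      out2$extrusion_length_m[hit])
  }
  cc <- case_config(g = 0, sv_scale = sv_scale,
                    region_resistance_multipliers =
                      stats::setNames(iliac_factor, iliac_region),
                    n_cycles = cc_gravity$n_cycles, dt = cc_gravity$dt,
                    cycle_tolerance = cc_gravity$cycle_tolerance,
                    label = "microgravity")
  list(wave = w2, outlets = out2, cc = cc)
}
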