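#' Peak and average of a cyclic waveform
#'
#' @param series numeric vector: one full cycle, uniform sampling.
#' @return named numeric `c(peak = max, average = time mean)`.
#' @export
waveform_peak_and_average <- function(series) {
  if (length(series) == 0) stop("empty series")
  c(peak = max(series), average = mean(series))
}

#' Signed percent change between two case values
#'
#' Full precision; round for table display (the comparison report
#' rounds to the nearest integer percent).
#'
#' @param g_value baseline (gravity) value, nonzero.
#' @param ug_value microgravity value.
#' @return 100 * (ug_value - g_value) / g_value.
#' @export
percent_change <- function(g_value, ug_value) {
  if (any(g_value == 0)) stop("zero baseline in percent_change")
  100 * (ug_value - g_value) / g_value
}

#' Combine a bilateral pair of values
#'
#' Arithmetic mean with the sample standard deviation of the pair as the
#' companion spread.
#'
#' @param left,right same-unit values.
#' @return named numeric `c(mean, sd)`.
#' @export
paired_mean <- function(left, right) {
  left <- unname(left); right <- unname(right)
  c(mean = (left + right) / 2, sd = stats::sd(c(left, right)))
}

#' Poiseuille wall shear stress series
#'
#' tau_w(t) = 4 mu(t) Q(t) / (pi r^3): the fully developed laminar-pipe
#' surrogate for the 3D wall shear field.
#'
#' @param flow flow series, m^3 s^-1.
#' @param radius vessel radius, m.
#' @param viscosity viscosity series (or scalar), Pa s.
#' @return wall shear stress series, Pa (signed with the flow).
#' @export
poiseuille_wss <- function(flow, radius, viscosity) {
  stopifnot(radius > 0, all(viscosity > 0))
  4 * viscosity * flow / (pi * radius^3)
}

#' Time-averaged wall shear stress
#'
#' (1/T) integral of |tau| over one cycle (rectangle rule on the uniform
#' cyclic samples).
#'
#' @param tau wall shear series over one full cycle, Pa.
#' @return TAWSS, Pa.
#' @export
tawss <- function(tau) {
  if (length(tau) == 0) stop("empty series")
  mean(abs(tau))
}

#' Oscillatory shear index
#'
#' 0.5 * (1 - |integral tau| / integral |tau|), in [0, 0.5]; 0 for
#' unidirectional shear.  An all-zero series is defined as 0.  The
#' quasi-static solver's flows are predominantly unidirectional, so OSI
#' is near-identically zero in this reduction; the operator exists for
#' completeness and for externally supplied series.
#'
#' @param tau wall shear series over one full cycle, Pa.
#' @return OSI, dimensionless.
#' @export
osi <- function(tau) {
  if (length(tau) == 0) stop("empty series")
  denom <- sum(abs(tau))
  if (denom == 0) return(0)
  0.5 * (1 - abs(sum(tau)) / denom)
}

#' Mean and Poiseuille centreline velocity from flow
#'
#' The 0D surrogate has no velocity profile; `v_mean = Q / (pi r^2)` and
#' the parabolic-profile centreline value `2 v_mean` are reported,
#' explicitly labelled (a 3D maximal-velocity probe is not claimed).
#'
#' @param flow flow series, m^3 s^-1.
#' @param radius vessel radius, m.
#' @return list `v_mean`, `v_centreline` (m s^-1 series).
#' @export
velocity_from_flow <- function(flow, radius) {
  stopifnot(radius > 0)
  vm <- flow / (pi * radius^2)
  list(v_mean = vm, v_centreline = 2 * vm)
}

# sites reported in the comparison table: segment id -> label stem
.report_sites <- function(net) {
  want <- c(ica_L = "ICA_L", ica_R = "ICA_R",
            vertebral_L = "VA_L", vertebral_R = "VA_R")
  want[names(want) %in% net$segments$segment_id]
}

#' Gravity vs microgravity comparison report
#'
#' Builds the study-style comparison table from two solved cases on the
#' same network: internal carotid (ICA) and vertebral (VA) mass flow
#' rates (peak and cycle average, kg/s), central retinal artery (CRA)
#' volumetric flows (peak and average, ul/min, per side and combined
#' across eyes), CRA mean velocity, and per-region TAWSS summaries.
#' Percent changes are exact internally and rounded to the nearest
#' integer in the `pct_change` column.
#'
#' @param gravity,micro `case_result` objects from [run_case] on the
#'   same network.
#' @return list of class `comparison_report`: `table` (MetricRow
#'   data.frame: quantity, units, gravity, microgravity, pct_change,
#'   pct_change_exact), `region_tawss` (per-region TAWSS data.frame),
#'   `retinal` (combined-eye CRA summaries).
#' @export
build_comparison_report <- function(gravity, micro) {
  ng <- gravity$net; nu <- micro$net
  if (!identical(ng$segments$segment_id, nu$segments$segment_id) ||
      max(abs(ng$segments$radius_m - nu$segments$radius_m)) > 0) {
    stop("cases were not run on the same network")
  }
  rho <- gravity$params$rho
  rows <- list()
  add <- function(quantity, units, g, u) {
    rows[[length(rows) + 1]] <<- data.frame(
      quantity = quantity, units = units, gravity = g, microgravity = u,
      pct_change = round(percent_change(g, u)),
      pct_change_exact = percent_change(g, u),
      stringsAsFactors = FALSE)
  }
  sites <- .report_sites(ng)
  for (i in seq_along(sites)) {
    seg <- names(sites)[i]; lab <- sites[i]
    for (res_metric in c("peak", "average")) {
      g <- waveform_peak_and_average(gravity$flows[seg, ] * rho)[res_metric]
      u <- waveform_peak_and_average(micro$flows[seg, ] * rho)[res_metric]
      add(sprintf("%s MFR_%s", lab, sub("average", "ave", res_metric)),
          "kg/s", unname(g), unname(u))
    }
  }
  cra <- intersect(c("cra_L", "cra_R"), ng$segments$segment_id)
  cra_stats <- list()
  for (seg in cra) {
    lab <- toupper(sub("cra_", "CRA_", seg))
    r <- ng$segments$radius_m[match(seg, ng$segments$segment_id)]
    qg <- m3s_to_ul_min(gravity$flows[seg, ])
    qu <- m3s_to_ul_min(micro$flows[seg, ])
    for (res_metric in c("peak", "average")) {
      g <- waveform_peak_and_average(qg)[res_metric]
      u <- waveform_peak_and_average(qu)[res_metric]
      add(sprintf("%s Q_%s", lab, sub("average", "ave", res_metric)),
          "ul/min", unname(g), unname(u))
      cra_stats[[paste(seg, res_metric)]] <- c(g = unname(g), u = unname(u))
    }
    vg <- velocity_from_flow(gravity$flows[seg, ], r)$v_mean * 100
    vu <- velocity_from_flow(micro$flows[seg, ], r)$v_mean * 100
    add(sprintf("%s V_mean_ave", lab), "cm/s (mean velocity)",
        mean(vg), mean(vu))
  }
  retinal <- NULL
  if (length(cra) == 2) {
    pk_g <- paired_mean(cra_stats[["cra_L peak"]]["g"],
                        cra_stats[["cra_R peak"]]["g"])
    pk_u <- paired_mean(cra_stats[["cra_L peak"]]["u"],
                        cra_stats[["cra_R peak"]]["u"])
    av_g <- paired_mean(cra_stats[["cra_L average"]]["g"],
                        cra_stats[["cra_R average"]]["g"])
    av_u <- paired_mean(cra_stats[["cra_L average"]]["u"],
                        cra_stats[["cra_R average"]]["u"])
    retinal <- data.frame(
      quantity = c("retinal Q_peak (combined)", "retinal Q_ave (combined)"),
      units = "ul/min",
      gravity = c(pk_g["mean"], av_g["mean"]),
      gravity_sd = c(pk_g["sd"], av_g["sd"]),
      microgravity = c(pk_u["mean"], av_u["mean"]),
      microgravity_sd = c(pk_u["sd"], av_u["sd"]),
      stringsAsFactors = FALSE)
    retinal$pct_change <- round(percent_change(retinal$gravity,
                                               retinal$microgravity))
    rownames(retinal) <- NULL
  }
  regs <- sort(unique(ng$segments$region))
  region_tawss <- data.frame(
    region = regs,
    gravity_Pa = vapply(regs, function(r) {
      sel <- ng$segments$region == r
      mean(apply(gravity$tau_w[sel, , drop = FALSE], 1, tawss))
    }, numeric(1)),
    microgravity_Pa = vapply(regs, function(r) {
      sel <- ng$segments$region == r
      mean(apply(micro$tau_w[sel, , drop = FALSE], 1, tawss))
    }, numeric(1)),
    stringsAsFactors = FALSE)
  region_tawss$pct_change <- round(percent_change(
    region_tawss$gravity_Pa, region_tawss$microgravity_Pa))
  rownames(region_tawss) <- NULL
  structure(list(table = do.call(rbind, rows), region_tawss = region_tawss,
                 retinal = retinal),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 4, ...) {
  cat("Gravity vs simulated-microgravity comparison\n\n")
  tab <- x$table
  tab$gravity <- signif(tab$gravity, digits)
  tab$microgravity <- signif(tab$microgravity, digits)
  tab$pct_change_exact <- NULL
  print(tab, row.names = FALSE)
  if (!is.null(x$retinal)) {
    cat("\nCombined (left+right) retinal flow:\n")
    r <- x$retinal
    for (i in seq_len(nrow(r))) {
      cat(sprintf("  %s: %.1f +- %.1f vs %.1f +- %.1f %s (%+d%%)\n",
                  r$quantity[i], r$microgravity[i], r$microgravity_sd[i],
                  r$gravity[i], r$gravity_sd[i], r$units[i],
                  r$pct_change[i]))
    }
  }
  cat("\nRegion TAWSS (Pa):\n")
  rt <- x$region_tawss
  rt$gravity_Pa <- signif(rt$gravity_Pa, digits)
  rt$microgravity_Pa <- signif(rt$microgravity_Pa, digits)
  print(rt, row.names = FALSE)
  invisible(x)
}

#' Write a comparison report to CSV
#'
#' Emits `table2_style.csv` (rounded percent column plus full-precision
#' companion) and `region_tawss.csv` under `dir`.
#'
#' @param report a `comparison_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_comparison_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$table, file.path(dir, "table2_style.csv"),
                   row.names = FALSE)
  utils::write.csv(report$region_tawss, file.path(dir, "region_tawss.csv"),
                   row.names = FALSE)
  if (!is.null(report$retinal)) {
    utils::write.csv(report$retinal, file.path(dir, "retinal_combined.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
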