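#' Construct a vessel network
#'
#' A directed acyclic vessel graph from a single inlet to outlet
#' terminals.  Segments are cylindrical conduits; every leaf node of the
#' segment graph must carry exactly one outlet boundary condition (an
#' extruded-outlet spec row, see [make_outlet_spec]).
#'
#' @param nodes data.frame with columns `node` (label) and `z` (elevation,
#'   m; positive up).
#' @param segments data.frame with columns `segment_id`, `from`, `to`,
#'   `radius_m`, `length_m`, `delta_z_m` (z(to) - z(from)), `region`.
#' @param inlet_node label of the inlet node.
#' @param outlets data.frame of outlet specs with an additional `node`
#'   column naming the attachment node (one per leaf).
#' @return an object of class `vessel_network`.
#' @export
vessel_network <- function(nodes, segments, inlet_node, outlets) {
  stopifnot(all(c("node", "z") %in% names(nodes)),
            all(c("segment_id", "from", "to", "radius_m", "length_m",
                  "delta_z_m", "region") %in% names(segments)),
            all(c("outlet_id", "region", "node", "radius_m",
                  "resistance_Pa_s_per_m3", "mu_eff_Pa_s",
                  "extrusion_length_m") %in% names(outlets)))
  if (anyDuplicated(nodes$node)) stop("duplicate node labels")
  if (anyDuplicated(segments$segment_id)) stop("duplicate segment ids")
  if (!inlet_node %in% nodes$node) stop("inlet node not in node table")
  if (!all(c(segments$from, segments$to) %in% nodes$node)) {
    stop("segment endpoint not in node table")
  }
  if (nrow(segments) > 0) {
    if (any(segments$radius_m <= 0) || any(segments$length_m <= 0)) {
      stop("segment radius and length must be positive")
    }
    if (any(abs(segments$delta_z_m) > segments$length_m * (1 + 1e-9))) {
      stop("|delta_z| exceeds segment length")
    }
    zc <- nodes$z[match(segments$to, nodes$node)] -
      nodes$z[match(segments$from, nodes$node)]
    if (any(abs(zc - segments$delta_z_m) > 1e-9)) {
      stop("segment delta_z inconsistent with node elevations")
    }
  }
  if (!all(outlets$node %in% nodes$node)) {
    stop("outlet attachment node not in node table")
  }
  # every leaf node (never a 'from') carries exactly one outlet; further
  # outlets may attach at interior nodes (lumped side-branch beds), and
  # a single-node network may carry all outlets at the inlet itself
  leaves <- setdiff(segments$to, segments$from)
  n_at_leaf <- table(factor(outlets$node, levels = leaves))
  if (length(leaves) && any(n_at_leaf != 1)) {
    stop("every leaf node must carry exactly one outlet")
  }
  if (nrow(outlets) == 0) stop("network needs at least one outlet")
  # connectivity from the inlet (undirected reachability)
  adj <- rbind(cbind(segments$from, segments$to),
               cbind(segments$to, segments$from))
  reach <- inlet_node
  repeat {
    nxt <- unique(adj[adj[, 1] %in% reach, 2])
    new <- setdiff(nxt, reach)
    if (length(new) == 0) break
    reach <- c(reach, new)
  }
  if (!setequal(reach, nodes$node)) stop("network is not connected")
  structure(list(nodes = nodes, segments = segments,
                 inlet_node = inlet_node, outlets = outlets),
            class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf(
    "vessel_network: %d nodes, %d segments, %d outlets; inlet '%s'\n",
    nrow(x$nodes), nrow(x$segments), nrow(x$outlets), x$inlet_node))
  tab <- table(x$outlets$region)
  cat("  outlets by region:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Inflow waveform
#'
#' Uniformly sampled periodic inflow over one cardiac cycle.  Samples are
#' at t = 0, dt, ..., period - dt (rectangle-rule quadrature of a
#' periodic signal is then exact for the generator's trigonometric
#' shape).
#'
#' @param t time samples, s.
#' @param massflow mass flow rate, kg s^-1.
#' @param period cycle period, s.
#' @param rho density used for volume conversion, kg m^-3.
#' @return object of class `waveform` with `q` (volumetric, m^3 s^-1).
#' @export
waveform <- function(t, massflow, period, rho = 1050) {
  stopifnot(length(t) == length(massflow), length(t) >= 2,
            period > 0, rho > 0)
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-12) stop("waveform must be uniformly sampled")
  if (any(massflow < 0)) stop("default inflow must be non-negative")
  sv <- sum(massflow) * dt[1] / rho
  if (sv <= 0) stop("stroke volume must be positive")
  structure(list(t = t, massflow = massflow, q = massflow / rho,
                 period = period, rho = rho, dt = dt[1]),
            class = "waveform")
}

#' Stroke volume of a waveform
#'
#' Rectangle-rule integral of volumetric flow over one period.
#'
#' @param wave a [waveform].
#' @return stroke volume, m^3.
#' @export
stroke_volume <- function(wave) sum(wave$q) * wave$dt

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "waveform: period %.3g s, dt %.4g s, %d samples\n  stroke volume %.4g ml, peak %.4g / mean %.4g m^3/s\n",
    x$period, x$dt, length(x$t), stroke_volume(x) * 1e6,
    max(x$q), mean(x$q)))
  invisible(x)
}

#' Read / write network, outlet and waveform tables
#'
#' Plain-CSV interchange for the solver inputs.  `read_network` expects
#' a nodes CSV (`node`, `z`), a segments CSV (`segment_id`, `from`, `to`,
#' `radius_m`, `length_m`, `delta_z_m`, `region`) and an outlets CSV
#' (outlet-spec columns plus `node`); `read_waveform` expects columns
#' `t_s` and `massflow_kg_s`.
#'
#' @param nodes_csv,segments_csv,outlets_csv,path,file file paths.
#' @param inlet_node inlet node label.
#' @param net a `vessel_network`.
#' @param wave a `waveform`.
#' @param rho density for mass/volume conversion, kg m^-3.
#' @param dir output directory (created if missing).
#' @name network_io
NULL

#' @rdname network_io
#' @export
read_network <- function(nodes_csv, segments_csv, outlets_csv, inlet_node) {
  vessel_network(utils::read.csv(nodes_csv, stringsAsFactors = FALSE),
                 utils::read.csv(segments_csv, stringsAsFactors = FALSE),
                 inlet_node,
                 utils::read.csv(outlets_csv, stringsAsFactors = FALSE))
}

#' @rdname network_io
#' @export
write_network <- function(net, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(net$nodes, file.path(dir, "nodes.csv"),
                   row.names = FALSE)
  utils::write.csv(net$segments, file.path(dir, "segments.csv"),
                   row.names = FALSE)
  utils::write.csv(net$outlets, file.path(dir, "outlets.csv"),
                   row.names = FALSE)
  writeLines(net$inlet_node, file.path(dir, "inlet.txt"))
  invisible(dir)
}

#' @rdname network_io
#' @export
read_waveform <- function(file, rho = 1050) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("t_s", "massflow_kg_s") %in% names(d)))
  n <- nrow(d)
  dt <- d$t_s[2] - d$t_s[1]
  waveform(d$t_s, d$massflow_kg_s, period = n * dt, rho = rho)
}

#' @rdname network_io
#' @export
write_waveform <- function(wave, file) {
  utils::write.csv(data.frame(t_s = wave$t, massflow_kg_s = wave$massflow),
                   file, row.names = FALSE)
  invisible(file)
}
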