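#' Structured-tree branching parameters
#'
#' Parameters of the deterministic asymmetric fractal tree used to lump
#' the retinal arteriolar bed below each retinal outlet into a single
#' resistance.  A parent of radius r_p spawns daughters obeying the
#' radius-exponent law r_p^k = r_d1^k + r_d2^k with r_d2 =
#' asymmetry_index * r_d1, so asymmetry_index = 1 gives a symmetric
#' bifurcation.  Segment length is `length_ratio_fn(diameter) * radius`.
#' Branching stops when a daughter diameter would fall below
#' `terminal_diameter` (the capillary-bed calibre); leaves drain to
#' `terminal_pressure`.
#'
#' Default exponent, asymmetry and length-ratio map are standard
#' structured-tree (Olufsen-type) choices, exposed here because the
#' literature fits vary; none is sacred.
#'
#' @param radius_exponent k of the radius power law (dimensionless).
#' @param asymmetry_index daughter radius ratio r_d2 / r_d1, in (0, 1].
#' @param length_ratio_fn function mapping vessel diameter (m) to the
#'   length-to-radius ratio; default is piecewise constant: 50 below
#'   60 um, 40 from 60 to 150 um, 30 above.
#' @param terminal_diameter capillary-bed diameter, m (default 4 um).
#' @param terminal_pressure distal datum pressure, Pa (default 0).
#' @return an object of class `branching_params`.
#' @export
branching_params <- function(radius_exponent = 2.76,
                             asymmetry_index = 0.8,
                             length_ratio_fn = default_length_ratio,
                             terminal_diameter = 4e-6,
                             terminal_pressure = 0) {
  stopifnot(radius_exponent > 0,
            asymmetry_index > 0, asymmetry_index <= 1,
            is.function(length_ratio_fn),
            terminal_diameter > 0)
  structure(list(radius_exponent = radius_exponent,
                 asymmetry_index = asymmetry_index,
                 length_ratio_fn = length_ratio_fn,
                 terminal_diameter = terminal_diameter,
                 terminal_pressure = terminal_pressure),
            class = "branching_params")
}

#' @rdname branching_params
#' @param diameter vessel diameter, m.
#' @export
default_length_ratio <- function(diameter) {
  ifelse(diameter < 60e-6, 50, ifelse(diameter < 150e-6, 40, 30))
}

#' Build a structured asymmetric fractal tree
#'
#' Deterministic recursion: each node of radius r gets two daughters
#' r1 = r * (1 + a^k)^(-1/k) and r2 = a * r1 unless either daughter
#' diameter would fall below the terminal diameter, in which case the
#' node is a leaf.
#'
#' @param root_radius radius of the root segment, m.
#' @param bp a [branching_params] object.
#' @param max_depth recursion guard (generations), default 60.
#' @return a `tree_segment`: list with `radius`, `length`, `children`
#'   (list of 0 or 2 `tree_segment`s).
#' @export
build_structured_tree <- function(root_radius, bp = branching_params(),
                                  max_depth = 60L) {
  stopifnot(root_radius > 0, max_depth >= 1)
  k <- bp$radius_exponent
  scale1 <- (1 + bp$asymmetry_index^k)^(-1 / k)
  scale2 <- bp$asymmetry_index * scale1
  rmin <- bp$terminal_diameter / 2
  build <- function(r, depth) {
    if (depth > max_depth) {
      stop(sprintf(
        "max_depth %d exceeded building structured tree (radius %.3g m)",
        max_depth, r))
    }
    len <- bp$length_ratio_fn(2 * r) * r
    r1 <- r * scale1
    r2 <- r * scale2
    children <- if (r1 < rmin || r2 < rmin) {
      list()
    } else {
      list(build(r1, depth + 1L), build(r2, depth + 1L))
    }
    structure(list(radius = r, length = len, children = children),
              class = "tree_segment")
  }
  build(root_radius, 1L)
}

#' Count leaves and depth of a structured tree
#'
#' @param tree a `tree_segment`.
#' @return list with `n_leaves`, `n_segments`, `depth`.
#' @export
tree_summary <- function(tree) {
  if (length(tree$children) == 0) {
    return(list(n_leaves = 1L, n_segments = 1L, depth = 1L))
  }
  s1 <- tree_summary(tree$children[[1]])
  s2 <- tree_summary(tree$children[[2]])
  list(n_leaves = s1$n_leaves + s2$n_leaves,
       n_segments = 1L + s1$n_segments + s2$n_segments,
       depth = 1L + max(s1$depth, s2$depth))
}

#' Equivalent resistance of a structured tree
#'
#' Each segment contributes a Hagen-Poiseuille resistance
#' 8 mu L / (pi r^4) with mu from the Fahraeus-Lindqvist law at the
#' segment's own diameter (every tree vessel is below the FL-only
#' threshold; this is asserted).  Children combine in parallel; leaves
#' drain to the terminal-pressure datum, which carries no resistance.
#'
#' @param tree a `tree_segment` from [build_structured_tree].
#' @param params a [rheology_params] object.
#' @return total resistance, Pa s m^-3.
#' @export
tree_resistance <- function(tree, params = rheology_params()) {
  rec <- function(node) {
    d <- 2 * node$radius
    if (d > params$d_fl_max) {
      stop(sprintf(
        "tree segment diameter %.3g m exceeds the FL-only threshold %.3g m",
        d, params$d_fl_max))
    }
    mu <- fl_effective_viscosity(d, params)
    r_own <- 8 * mu * node$length / (pi * node$radius^4)
    if (length(node$children) == 0) return(r_own)
    r1 <- rec(node$children[[1]])
    r2 <- rec(node$children[[2]])
    r_own + 1 / (1 / r1 + 1 / r2)
  }
  rec(tree)
}

#' Fractal-tree resistances for a set of retinal outlets
#'
#' Element-wise [build_structured_tree] + [tree_resistance]; order
#' preserved.
#'
#' @param outlet_radii vector of outlet root radii, m.
#' @param bp a [branching_params] object.
#' @param params a [rheology_params] object.
#' @param max_depth recursion guard passed through.
#' @return numeric vector of resistances, Pa s m^-3 (same order).
#' @export
retinal_outlet_resistances <- function(outlet_radii,
                                       bp = branching_params(),
                                       params = rheology_params(),
                                       max_depth = 60L) {
  if (length(outlet_radii) == 0) return(numeric(0))
  stopifnot(all(outlet_radii > 0))
  vapply(outlet_radii, function(r) {
    tree_resistance(build_structured_tree(r, bp, max_depth), params)
  }, numeric(1))
}
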