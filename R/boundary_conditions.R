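#' Cardiac-output split table
#'
#' Assumed distribution of cardiac output over arterial regions, as a
#' fraction of total cardiac output per region (not per outlet).  One
#' region is flagged `residual`: its fraction is computed, never listed,
#' so the table always sums to exactly 1 (see [complete_split_table]).
#'
#' The default table is the study's literature-derived distribution:
#' celiac 14%, cerebral 12.78%, coronary 5%, external carotid 9.45%,
#' internal iliac 4%, external iliac 9%, ophthalmic 0.68%, mesenteric
#' 16%, renal 23%, subclavian = residual (6.09%).
#'
#' @param regions character vector of region names.
#' @param n_outlets integer vector, outlets per region.
#' @param co_fraction numeric vector, fraction of cardiac output (NA for
#'   the residual region).
#' @param paired logical vector, bilateral region flag.
#' @param residual_region name of the region whose fraction is the
#'   residual of cardiac output.
#' @return data.frame of class `region_split` with attribute
#'   `residual_region`; fractions not yet completed (residual is NA).
#' @export
region_split_table <- function(
    regions = c("celiac", "cerebral", "coronary", "external_carotid",
                "internal_iliac", "external_iliac", "ophthalmic",
                "mesenteric", "renal", "subclavian"),
    n_outlets = c(1L, 32L, 26L, 2L, 2L, 2L, 2L, 1L, 2L, 2L),
    co_fraction = c(0.14, 0.1278, 0.05, 0.0945, 0.04, 0.09, 0.0068,
                    0.16, 0.23, NA_real_),
    paired = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
               TRUE),
    residual_region = "subclavian") {
  stopifnot(length(regions) == length(n_outlets),
            length(regions) == length(co_fraction),
            length(regions) == length(paired),
            residual_region %in% regions,
            !anyDuplicated(regions))
  out <- data.frame(region = regions, n_outlets = as.integer(n_outlets),
                    co_fraction = co_fraction, paired = paired,
                    stringsAsFactors = FALSE)
  attr(out, "residual_region") <- residual_region
  class(out) <- c("region_split", class(out))
  out
}

#' Complete a split table by assigning the residual region
#'
#' The residual region receives 1 minus the sum of all listed fractions.
#'
#' @param splits a `region_split` data.frame ([region_split_table]).
#' @param residual_region region receiving the residual; defaults to the
#'   table's own `residual_region` attribute.
#' @return the table with every `co_fraction` set; sums to 1 exactly.
#' @export
complete_split_table <- function(splits = region_split_table(),
                                 residual_region =
                                   attr(splits, "residual_region")) {
  stopifnot(residual_region %in% splits$region)
  i <- match(residual_region, splits$region)
  listed <- splits$co_fraction[-i]
  if (anyNA(listed)) {
    stop("only the residual region may have an unset co_fraction")
  }
  s <- sum(listed)
  if (s >= 1) {
    stop(sprintf("listed cardiac-output fractions sum to %.6f >= 1", s))
  }
  splits$co_fraction[i] <- 1 - s
  splits
}

#' Systolic reference operating point
#'
#' Systolic pressure and flow defining the Murray's-law outlet design
#' point: each region's outlets, taken together at pressure drop `p_sys`
#' to a zero distal datum, pass `q_sys * co_fraction`.
#'
#' @param p_sys systolic pressure, Pa.
#' @param q_sys systolic volumetric flow, m^3 s^-1.
#' @return an object of class `systolic_reference`.
#' @export
systolic_reference <- function(p_sys = mmHg_to_Pa(120),
                               q_sys = 2.1e-4) {
  stopifnot(p_sys > 0, q_sys > 0)
  structure(list(p_sys = p_sys, q_sys = q_sys),
            class = "systolic_reference")
}

#' Murray's-law outlet resistances for one region
#'
#' Distributes the region's share of systolic flow over its outlets by
#' cube-of-radius weighting and converts the implied per-outlet flow to
#' a resistance at the systolic design point:
#' R_i = p_sys / (q_sys * co_fraction * r_i^3 / sum_j r_j^3).
#'
#' @param co_fraction the region's fraction of cardiac output.
#' @param outlet_radii vector of outlet radii, m.
#' @param ref a [systolic_reference].
#' @return numeric vector of resistances, Pa s m^-3 (order preserved).
#' @export
murray_outlet_resistances <- function(co_fraction, outlet_radii,
                                      ref = systolic_reference()) {
  if (length(outlet_radii) == 0) {
    if (co_fraction > 0) {
      stop("region with nonzero cardiac-output split has no outlets")
    }
    return(numeric(0))
  }
  stopifnot(all(outlet_radii > 0), co_fraction > 0, co_fraction <= 1)
  w <- outlet_radii^3 / sum(outlet_radii^3)
  ref$p_sys / (ref$q_sys * co_fraction * w)
}

#' Effective viscosity encoding a resistance in an extruded outlet
#'
#' Inverts Hagen-Poiseuille: mu = R pi r^4 / (8 L), so a straight
#' extrusion of radius `radius` and length `length` filled with this
#' fictitious viscosity presents exactly resistance `R` to Poiseuille
#' flow.
#'
#' @param R target resistance, Pa s m^-3.
#' @param radius extrusion radius, m.
#' @param length extrusion length, m.
#' @return effective viscosity, Pa s.
#' @export
resistance_to_effective_viscosity <- function(R, radius, length) {
  if (any(R <= 0) || any(radius <= 0) || any(length <= 0)) {
    stop("R, radius and length must all be positive")
  }
  R * pi * radius^4 / (8 * length)
}

#' Hagen-Poiseuille resistance of a cylindrical segment
#'
#' R = 8 mu L / (pi r^4).
#'
#' @param radius segment radius, m.
#' @param length segment length, m.
#' @param mu dynamic viscosity, Pa s.
#' @return resistance, Pa s m^-3.
#' @export
poiseuille_resistance <- function(radius, length, mu) {
  stopifnot(all(radius > 0), all(length > 0), all(mu > 0))
  8 * mu * length / (pi * radius^4)
}

#' Build an extruded-outlet specification
#'
#' Converts a designed outlet resistance into the extruded-outlet
#' representation: extrusion length twice the outlet diameter (4 r) and
#' the effective viscosity that reproduces `R` over that extrusion, with
#' a zero-pressure distal face.
#'
#' @param outlet_id outlet label.
#' @param region region label.
#' @param radius outlet radius, m.
#' @param R designed resistance, Pa s m^-3.
#' @return one-row data.frame with columns `outlet_id`, `region`,
#'   `radius_m`, `resistance_Pa_s_per_m3`, `mu_eff_Pa_s`,
#'   `extrusion_length_m`.
#' @export
make_outlet_spec <- function(outlet_id, region, radius, R) {
  stopifnot(all(radius > 0), all(R > 0))
  len <- 4 * radius
  data.frame(outlet_id = as.character(outlet_id),
             region = as.character(region),
             radius_m = radius,
             resistance_Pa_s_per_m3 = R,
             mu_eff_Pa_s = resistance_to_effective_viscosity(R, radius, len),
             extrusion_length_m = len,
             stringsAsFactors = FALSE)
}
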