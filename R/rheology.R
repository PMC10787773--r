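#' Blood rheology parameters
#'
#' Container for every constant of the blended viscosity model: the
#' Carreau-Yasuda (CY) shear-thinning law used in vessels wider than
#' `d_cy_min`, the Fahraeus-Lindqvist (FL) diameter-dependent law used in
#' vessels narrower than `d_fl_max`, and the linear blend in between.
#'
#' The FL branch is `mu_plasma * mu_rel(D, Hct)` where `mu_rel` is a
#' relative-viscosity law; the default is the Pries et al. in-vitro fit
#' (see [pries_relative_viscosity]) and an alternative fit can be plugged
#' in via `relative_viscosity_fn`.
#'
#' @param eta_inf infinite-shear CY viscosity, Pa s.
#' @param eta_0 zero-shear CY viscosity, Pa s.
#' @param lambda_cy CY relaxation time, s.
#' @param a_cy CY Yasuda exponent (dimensionless).
#' @param n_cy CY power-law index (dimensionless).
#' @param haematocrit discharge haematocrit, volume fraction in (0, 1).
#' @param mu_plasma plasma viscosity, Pa s.
#' @param rho blood density, kg m^-3.
#' @param d_fl_max largest diameter (m) at which the FL law applies alone.
#' @param d_cy_min smallest diameter (m) at which the CY law applies alone.
#' @param relative_viscosity_fn function `(diameter_um, haematocrit) ->
#'   relative viscosity`; defaults to [pries_relative_viscosity].
#' @return an object of class `rheology_params`.
#' @export
rheology_params <- function(eta_inf = 0.0035,
                            eta_0 = 0.16,
                            lambda_cy = 8.2,
                            a_cy = 0.64,
                            n_cy = 0.2128,
                            haematocrit = 0.45,
                            mu_plasma = 0.0012,
                            rho = 1050,
                            d_fl_max = 0.6e-3,
                            d_cy_min = 1.2e-3,
                            relative_viscosity_fn = pries_relative_viscosity) {
  stopifnot(eta_inf > 0, eta_0 > 0, eta_inf < eta_0,
            lambda_cy > 0, a_cy > 0,
            haematocrit > 0, haematocrit < 1,
            mu_plasma > 0, rho > 0,
            d_fl_max > 0, d_cy_min > d_fl_max,
            is.function(relative_viscosity_fn))
  structure(list(eta_inf = eta_inf, eta_0 = eta_0, lambda_cy = lambda_cy,
                 a_cy = a_cy, n_cy = n_cy, haematocrit = haematocrit,
                 mu_plasma = mu_plasma, rho = rho,
                 d_fl_max = d_fl_max, d_cy_min = d_cy_min,
                 relative_viscosity_fn = relative_viscosity_fn),
            class = "rheology_params")
}

#' @export
print.rheology_params <- function(x, ...) {
  cat("Blended blood rheology parameters\n")
  cat(sprintf("  Carreau-Yasuda: eta_inf=%g eta_0=%g Pa s, lambda=%g s, a=%g, n=%g\n",
              x$eta_inf, x$eta_0, x$lambda_cy, x$a_cy, x$n_cy))
  cat(sprintf("  FL branch: Hct=%g, mu_plasma=%g Pa s\n",
              x$haematocrit, x$mu_plasma))
  cat(sprintf("  Blend window: %g-%g mm diameter; rho=%g kg/m^3\n",
              x$d_fl_max * 1e3, x$d_cy_min * 1e3, x$rho))
  invisible(x)
}

#' Pries in-vitro relative blood viscosity
#'
#' Relative apparent viscosity of blood flowing in a glass tube of diameter
#' `d_um` (micrometres) at discharge haematocrit `hct`, after Pries,
#' Neuhaus and Gaehtgens' in-vitro fit.  Captures the Fahraeus-Lindqvist
#' minimum near 7 um and the rise toward the bulk value in wide tubes.
#'
#' @param d_um tube diameter in micrometres (vectorised).
#' @param hct discharge haematocrit, fraction.
#' @return relative viscosity (dimensionless, 1 = plasma).
#' @export
pries_relative_viscosity <- function(d_um, hct) {
  stopifnot(all(d_um > 0), hct >= 0, hct < 1)
  mu45 <- 220 * exp(-1.3 * d_um) + 3.2 - 2.44 * exp(-0.06 * d_um^0.645)
  # shape exponent C of the haematocrit dependence
  s <- 1 / (1 + 1e-11 * d_um^12)
  cc <- (0.8 + exp(-0.075 * d_um)) * (-1 + s) + (1 - s)
  if (hct == 0) return(rep(1, length(d_um)))
  1 + (mu45 - 1) * ((1 - hct)^cc - 1) / ((1 - 0.45)^cc - 1)
}

#' Carreau-Yasuda viscosity
#'
#' eta(g) = eta_inf + (eta_0 - eta_inf) * (1 + (lambda g)^a)^((n-1)/a),
#' strictly decreasing in the shear rate g, bounded in (eta_inf, eta_0].
#'
#' @param shear_rate shear rate, s^-1 (vectorised, >= 0).
#' @param params a [rheology_params] object.
#' @return viscosity, Pa s.
#' @export
carreau_yasuda_viscosity <- function(shear_rate, params = rheology_params()) {
  if (any(shear_rate < 0)) stop("shear_rate must be non-negative")
  with(params,
       eta_inf + (eta_0 - eta_inf) *
         (1 + (lambda_cy * shear_rate)^a_cy)^((n_cy - 1) / a_cy))
}

#' Fahraeus-Lindqvist effective viscosity
#'
#' Diameter-driven apparent viscosity `mu_plasma * mu_rel(D, Hct)`;
#' shear-rate independent.
#'
#' @param diameter vessel diameter, m (vectorised, > 0).
#' @param params a [rheology_params] object.
#' @return viscosity, Pa s.
#' @export
fl_effective_viscosity <- function(diameter, params = rheology_params()) {
  if (any(diameter <= 0)) stop("diameter must be positive")
  params$mu_plasma *
    params$relative_viscosity_fn(diameter * 1e6, params$haematocrit)
}

#' Blended diameter/shear viscosity
#'
#' FL below `d_fl_max` (default 0.6 mm), Carreau-Yasuda above `d_cy_min`
#' (default 1.2 mm), linear interpolation in diameter between the two.
#' Continuous at both thresholds.
#'
#' @param diameter vessel diameter, m (vectorised, > 0).
#' @param shear_rate shear rate, s^-1 (vectorised or scalar, >= 0).
#' @param params a [rheology_params] object.
#' @return viscosity, Pa s.
#' @export
blended_viscosity <- function(diameter, shear_rate,
                              params = rheology_params()) {
  if (any(diameter <= 0)) stop("diameter must be positive")
  if (any(shear_rate < 0)) stop("shear_rate must be non-negative")
  n <- max(length(diameter), length(shear_rate))
  d <- rep_len(diameter, n)
  g <- rep_len(shear_rate, n)
  w <- pmin(1, pmax(0, (d - params$d_fl_max) /
                         (params$d_cy_min - params$d_fl_max)))
  mu <- numeric(n)
  lo <- w < 1   # FL contributes
  hi <- w > 0   # CY contributes
  fl <- numeric(n); cy <- numeric(n)
  if (any(lo)) fl[lo] <- fl_effective_viscosity(d[lo], params)
  if (any(hi)) cy[hi] <- carreau_yasuda_viscosity(g[hi], params)
  mu <- (1 - w) * fl + w * cy
  mu
}
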