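# Air-sea gas exchange: Schmidt number, O2 solubility, piston velocity and
# the wind-history weighted transfer velocity used for mixed-layer budgets.

#' Hydrographic state of a station
#'
#' Bundles the temperature, salinity and mixed-layer depth that the gas
#' exchange and productivity calculations require.
#'
#' @param temperature In-situ temperature, degrees C. Must lie in -2..40,
#'   the validity range of the Schmidt and solubility fits.
#' @param salinity Practical salinity, PSU, in 0..42.
#' @param mld Mixed-layer depth, m, strictly positive.
#'
#' @return An object of class `hydro_state`.
#' @examples
#' hydro_state(25, 34.5, 30)
#' @export
hydro_state <- function(temperature, salinity, mld) {
  stopifnot(is.numeric(temperature), is.numeric(salinity), is.numeric(mld))
  if (temperature < -2 || temperature > 40)
    stop("temperature outside fit validity range (-2..40 degC): ", temperature)
  if (salinity < 0 || salinity > 42)
    stop("salinity outside fit validity range (0..42 PSU): ", salinity)
  if (mld <= 0) stop("mixed-layer depth must be positive")
  structure(list(temperature = temperature, salinity = salinity, mld = mld),
            class = "hydro_state")
}

#' Gas exchange parameterization
#'
#' Holds the coefficients of the wind-speed gas-transfer parameterization.
#' Defaults are the modern quadratic form, k = a * u10^2 * (Sc/660)^-1/2
#' with a = 0.251 cm h-1 (m s-1)-2, together with the seawater Schmidt
#' number polynomial for O2 (4th order in temperature). All coefficients
#' live here, not in the formulas, so alternative parameterizations can be
#' swapped in by configuration.
#'
#' @param coef Quadratic coefficient a, cm h-1 per (m s-1)^2.
#' @param sc_ref Reference Schmidt number (dimensionless), default 660
#'   (CO2 in seawater at 20 degC), the conventional normalization.
#' @param sc_coefs Numeric vector of polynomial coefficients for the O2
#'   Schmidt number in seawater, lowest order first (Sc = c0 + c1*T + ...).
#' @param window Length in days of the wind-history window used by
#'   [weighted_piston_velocity()], default 60.
#'
#' @return An object of class `gas_exchange_params`.
#' @export
gas_exchange_params <- function(coef = 0.251,
                                sc_ref = 660,
                                sc_coefs = c(1920.4, -135.6, 5.2122,
                                             -0.10939, 0.00093777),
                                window = 60) {
  if (coef <= 0) stop("quadratic coefficient must be positive")
  if (window < 1) stop("weighting window must be at least 1 day")
  structure(list(coef = coef, sc_ref = sc_ref, sc_coefs = sc_coefs,
                 window = window),
            class = "gas_exchange_params")
}

#' Schmidt number for O2 in seawater
#'
#' Evaluates the configured Schmidt-number polynomial at the station
#' temperature. The default coefficients are the published 4th-order fit
#' for O2 in seawater (salinity 35), valid for -2..40 degC.
#'
#' @param hydro A [hydro_state()].
#' @param params A [gas_exchange_params()].
#'
#' @return Dimensionless Schmidt number (> 0, decreasing in temperature).
#' @examples
#' schmidt_number(hydro_state(20, 35, 30))
#' @export
schmidt_number <- function(hydro, params = gas_exchange_params()) {
  t <- hydro$temperature
  if (t < -2 || t > 40)
    stop("temperature outside Schmidt polynomial validity (-2..40 degC)")
  sc <- sum(params$sc_coefs * t^(seq_along(params$sc_coefs) - 1))
  if (sc <= 0) stop("Schmidt polynomial evaluated non-positive; check coefficients")
  sc
}

#' Equilibrium O2 concentration in seawater
#'
#' Oxygen solubility at one atmosphere of water-saturated air, from the
#' Garcia and Gordon (1992) fit to the Benson and Krause data, evaluated in
#' mL L-1 and converted to mmol m-3 (1 mL L-1 = 44.6596 mmol m-3, ideal
#' molar volume of O2 at STP).
#'
#' @param hydro A [hydro_state()].
#'
#' @return Equilibrium O2 concentration, mmol m-3.
#' @examples
#' o2_saturation(hydro_state(20, 35, 30))
#' @export
o2_saturation <- function(hydro) {
  t <- hydro$temperature
  s <- hydro$salinity
  if (t < -2 || t > 40) stop("temperature outside solubility fit validity")
  if (s < 0 || s > 42) stop("salinity outside solubility fit validity")
  # scaled temperature of the Garcia-Gordon formulation
  ts <- log((298.15 - t) / (273.15 + t))
  a <- c(2.00907, 3.22014, 4.05010, 4.94457, -0.256847, 3.88767)
  b <- c(-0.00624523, -0.00737614, -0.0103410, -0.00817083)
  c0 <- -4.88682e-7
  lnc <- sum(a * ts^(0:5)) + s * sum(b * ts^(0:3)) + c0 * s^2
  exp(lnc) * 44.6596
}

#' Instantaneous piston velocity from wind speed
#'
#' Gas-transfer (piston) velocity k = a * u10^2 * (Sc/Sc_ref)^-1/2, computed
#' in cm h-1 and returned in m d-1 (x 24/100).
#'
#' @param u10 Wind speed at 10 m, m s-1, non-negative.
#' @param hydro A [hydro_state()].
#' @param params A [gas_exchange_params()].
#'
#' @return Piston velocity, m d-1.
#' @examples
#' piston_velocity(7, hydro_state(20, 35, 30))
#' @export
piston_velocity <- function(u10, hydro, params = gas_exchange_params()) {
  if (any(u10 < 0)) stop("wind speed must be non-negative")
  sc <- schmidt_number(hydro, params)
  k_cmh <- params$coef * u10^2 * (sc / params$sc_ref)^(-0.5)
  k_cmh * 24 / 100
}

#' Wind-history weighted piston velocity
#'
#' Mixed-layer gas signatures integrate over the days preceding sampling, so
#' a single day's wind is not representative. Daily piston velocities over a
#' trailing window are combined with weights that discount each earlier day
#' by the fraction of the mixed layer already ventilated since then: with
#' f_i = min(1, k_i * dt / z_ml) and days counted backwards from the
#' sampling day (i = 1 most recent), omega_i = f_i * prod_{j<i} (1 - f_j),
#' renormalized to sum to one.
#'
#' @param history Data frame with columns `date` and `u10` (m s-1), daily
#'   records ending at the sampling date. Rows are sorted by date
#'   internally.
#' @param hydro A [hydro_state()]; the mixed-layer depth sets the
#'   ventilation fraction.
#' @param params A [gas_exchange_params()]; `params$window` days are used
#'   (fewer if the history is shorter).
#'
#' @return A list with `k_w` (m d-1), and diagnostic vectors `weights` and
#'   `k_daily` ordered most-recent-first.
#' @export
weighted_piston_velocity <- function(history, hydro,
                                     params = gas_exchange_params()) {
  if (!is.data.frame(history) || nrow(history) < 1)
    stop("wind history must contain at least one daily record")
  if (hydro$mld <= 0) stop("mixed-layer depth must be positive")
  history <- history[order(history$date), , drop = FALSE]
  n <- min(nrow(history), params$window)
  u <- rev(utils::tail(history$u10, n))   # index 1 = sampling day
  k <- piston_velocity(u, hydro, params)
  f <- pmin(1, k * 1 / hydro$mld)
  omega <- f * cumprod(c(1, 1 - f[-n]))
  if (sum(omega) == 0) {
    omega <- rep(1 / n, n)                # calm window: unweighted mean
  } else {
    omega <- omega / sum(omega)
  }
  list(k_w = sum(omega * k), weights = omega, k_daily = k)
}
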