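# Electron-balance denitrification/anammox stoichiometry and the
# trap-flux-driven ODZ nitrogen-loss budget.

#' Organic-matter elemental formula
#'
#' Composition C_a H_b O_c N_d P_e of the organic matter being oxidized.
#' The default is the N-rich marine plankton composition C106 H175 O42 N16 P.
#'
#' @param carbon,hydrogen,oxygen,nitrogen,phosphorus Stoichiometric counts
#'   (non-negative reals; carbon strictly positive).
#'
#' @return An object of class `om_formula`.
#' @examples
#' om_formula()             # C106 H175 O42 N16 P
#' om_formula(1, 2, 1, 0, 0) # CH2O
#' @export
om_formula <- function(carbon = 106, hydrogen = 175, oxygen = 42,
                       nitrogen = 16, phosphorus = 1) {
  v <- c(carbon, hydrogen, oxygen, nitrogen, phosphorus)
  if (any(!is.finite(v)) || any(v < 0))
    stop("element counts must be non-negative finite numbers")
  if (carbon <= 0) stop("formula must contain carbon")
  structure(list(carbon = carbon, hydrogen = hydrogen, oxygen = oxygen,
                 nitrogen = nitrogen, phosphorus = phosphorus),
            class = "om_formula")
}

#' Denitrification stoichiometry by electron balance
#'
#' Balances complete heterotrophic oxidation of organic matter by nitrate,
#' with products CO2, NH3, H3PO4, H2O and N2:
#'
#'   C_a H_b O_c N_d P_e + (E/5) HNO3 ->
#'     a CO2 + d NH3 + e H3PO4 + n H2O + (E/10) N2
#'
#' where E = 4a + b - 2c - 3d + 5e is the number of electrons released by
#' oxidizing the organic matter to those reference products, and each
#' nitrate accepts 5 electrons on reduction to N2. Water balances hydrogen.
#' For C106 H175 O42 N16 P this yields the canonical coefficients
#' 94.4 HNO3 and 47.2 N2.
#'
#' @param om An [om_formula()].
#'
#' @return An object of class `denit_stoich` with components `hno3_demand`,
#'   `n2_denit`, `nh3_released`, `co2`, `h3po4`, `h2o`, plus the electron
#'   count `electrons` and the source formula.
#' @examples
#' st <- derive_stoichiometry(om_formula())
#' st$hno3_demand  # 94.4
#' st$n2_denit     # 47.2
#' @export
derive_stoichiometry <- function(om) {
  stopifnot(inherits(om, "om_formula"))
  e <- 4 * om$carbon + om$hydrogen - 2 * om$oxygen -
    3 * om$nitrogen + 5 * om$phosphorus
  if (e <= 0)
    stop("organic matter is already fully oxidized (available electrons <= 0)")
  hno3 <- e / 5
  st <- structure(list(
    hno3_demand  = hno3,
    n2_denit     = e / 10,
    nh3_released = om$nitrogen,
    co2          = om$carbon,
    h3po4        = om$phosphorus,
    h2o          = (om$hydrogen + hno3 - 3 * om$nitrogen -
                      3 * om$phosphorus) / 2,
    electrons    = e,
    formula      = om),
    class = "denit_stoich")
  resid <- balance_check(st, om)
  if (any(abs(resid) > 1e-9))
    stop("internal error: derived equation does not balance")
  st
}

#' Elemental balance residuals of a denitrification equation
#'
#' Left-minus-right atom counts for C, H, O, N and P of the reaction
#' OM + hno3_demand HNO3 -> co2 CO2 + nh3 NH3 + h3po4 H3PO4 + h2o H2O +
#' n2 N2. A correctly derived stoichiometry has all residuals below 1e-9.
#'
#' @param st A `denit_stoich` (see [derive_stoichiometry()]), possibly
#'   perturbed.
#' @param om The [om_formula()] on the left-hand side.
#'
#' @return Named numeric vector of residuals for C, H, O, N, P.
#' @export
balance_check <- function(st, om) {
  c(C = om$carbon - st$co2,
    H = om$hydrogen + st$hno3_demand -
      (3 * st$nh3_released + 3 * st$h3po4 + 2 * st$h2o),
    O = om$oxygen + 3 * st$hno3_demand - (2 * st$co2 + 4 * st$h3po4 + st$h2o),
    N = om$nitrogen + st$hno3_demand - (st$nh3_released + 2 * st$n2_denit),
    P = om$phosphorus - st$h3po4)
}

#' Nitrogen-loss yield per organic carbon
#'
#' Moles of N lost as N2 per mole of organic C respired. Denitrification
#' contributes 2 * n2_denit N per formula unit. With anammox pairing the
#' released NH3 is oxidized 1:1 with nitrite drawn from the oxidized-N pool,
#' so each mole of NH3 adds a further 2 N (one from ammonium, one from
#' nitrite) to the loss.
#'
#' @param st A `denit_stoich` from [derive_stoichiometry()].
#' @param pairing Logical; include the anammox contribution (default TRUE).
#'
#' @return mol N2-N per mol organic C.
#' @examples
#' n_loss_yield(derive_stoichiometry(om_formula()))        # 1.1925
#' n_loss_yield(derive_stoichiometry(om_formula()), FALSE) # 0.8906
#' @export
n_loss_yield <- function(st, pairing = TRUE) {
  n_denit <- 2 * st$n2_denit
  n_anammox <- if (pairing) 2 * st$nh3_released else 0
  (n_denit + n_anammox) / st$co2
}

#' Budget configuration
#'
#' Parameters of the ODZ nitrogen-loss budget.
#'
#' @param export_scale Multiplier converting sediment-trap organic C to
#'   total organic C consumed (traps miss dissolved organics and active
#'   transport; total fluxes run 2-3x trap fluxes). Default 2.
#' @param layer_thickness Thickness of the upper-ODZ layer over which the
#'   consumption is spread, m. Default 200 (the top ~30% of the ODZ, where
#'   most N2 production occurs).
#' @param residence_time Residence time of ODZ water, years, over which
#'   biogenic N2 accumulates. Default 3.9.
#' @param residence_time_sd Its 1-sigma uncertainty, years. Default 0.8.
#' @param days_per_year Default 365.25.
#' @param anammox_pairing Pair released NH3 1:1 with nitrite (default TRUE).
#' @param consumed_fraction Fraction of the scaled consumed flux respired
#'   within the layer; default 1.
#'
#' @return An object of class `budget_config`.
#' @export
budget_config <- function(export_scale = 2, layer_thickness = 200,
                          residence_time = 3.9, residence_time_sd = 0.8,
                          days_per_year = 365.25, anammox_pairing = TRUE,
                          consumed_fraction = 1) {
  if (export_scale < 1) stop("export_scale must be at least 1")
  if (layer_thickness <= 0) stop("layer thickness must be positive")
  if (residence_time <= 0) stop("residence time must be positive")
  if (consumed_fraction <= 0 || consumed_fraction > 1)
    stop("consumed_fraction must lie in (0, 1]")
  structure(list(export_scale = export_scale,
                 layer_thickness = layer_thickness,
                 residence_time = residence_time,
                 residence_time_sd = residence_time_sd,
                 days_per_year = days_per_year,
                 anammox_pairing = anammox_pairing,
                 consumed_fraction = consumed_fraction),
            class = "budget_config")
}

.flux_at <- function(traps, depth) {
  i <- which(abs(traps$depth_m - depth) < 1e-6)
  if (length(i) != 1)
    stop("no trap flux at depth ", depth, " m")
  traps$c_flux_mmol_m2_d[i]
}

#' Organic carbon consumed between two trap depths
#'
#' Difference between the sinking C flux entering the layer at `top_depth`
#' and leaving at `bottom_depth`. A negative difference (flux increasing
#' with depth) signals in-situ production inside the layer; it is returned
#' with attribute `in_situ_signal = TRUE` rather than clipped.
#'
#' @param traps Data frame with columns `depth_m` and `c_flux_mmol_m2_d`.
#' @param top_depth,bottom_depth Depths, m, that must both be present in
#'   `traps`.
#'
#' @return Consumed flux, mmol C m-2 d-1.
#' @export
consumed_flux <- function(traps, top_depth, bottom_depth) {
  d <- .flux_at(traps, top_depth) - .flux_at(traps, bottom_depth)
  attr(d, "in_situ_signal") <- d < 0
  d
}

#' In-situ production contribution to a flux depth
#'
#' Fraction of the particle flux at `lower` attributable to production
#' between `upper` and `lower`, max(0, flux(lower) - flux(upper)) /
#' flux(lower).
#'
#' @param traps Data frame as in [consumed_flux()].
#' @param upper,lower Depths, m; `flux(lower)` must be positive.
#'
#' @return Fraction in \[0, 1\].
#' @export
in_situ_contribution <- function(traps, upper, lower) {
  fl <- .flux_at(traps, lower)
  if (fl <= 0) stop("flux at the lower depth must be positive")
  max(0, fl - .flux_at(traps, upper)) / fl
}

#' Volumetric N2 production rate from consumed carbon flux
#'
#' Spreads the scaled consumed flux uniformly over the layer and converts C
#' respired to N lost via the stoichiometric yield:
#' rate = consumed * export_scale * consumed_fraction * yield /
#' layer_thickness, converted from mmol N m-3 d-1 to nM N d-1 (x 1000).
#'
#' @param consumed Consumed organic C flux, mmol C m-2 d-1, non-negative.
#' @param cfg A [budget_config()].
#' @param yield N-loss yield, mol N per mol C (see [n_loss_yield()]).
#'
#' @return N2 production rate in N units, nM N d-1.
#' @export
n2_production_rate <- function(consumed, cfg = budget_config(),
                               yield) {
  if (consumed < 0) stop("consumed flux must be non-negative")
  if (cfg$layer_thickness <= 0) stop("layer thickness must be positive")
  consumed * cfg$export_scale * cfg$consumed_fraction * yield /
    cfg$layer_thickness * 1000
}

#' Accumulated biogenic N2 over the water residence time
#'
#' @param rate N2 production rate, nM N d-1, non-negative.
#' @param cfg A [budget_config()]; uses `residence_time` and
#'   `days_per_year`.
#'
#' @return Accumulated biogenic N2, uM N.
#' @export
n2_accumulation <- function(rate, cfg = budget_config()) {
  if (rate < 0) stop("rate must be non-negative")
  rate * cfg$residence_time * cfg$days_per_year / 1000
}
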