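# Mixed-layer productivity from triple oxygen isotopes and O2/Ar, Monte
# Carlo uncertainty, O2->C conversions, 13C incubation rates, depth
# integration and export efficiency.

#' Triple-oxygen-isotope constants
#'
#' End-member parameters of the triple-oxygen-isotope (17O-excess) system.
#' Atmospheric O2 carries a mass-independent 17O depletion from
#' stratospheric photochemistry, while photosynthetic O2 does not; the
#' excess 17Delta in mixed-layer dissolved O2 therefore records gross
#' photosynthesis independently of respiration. The defaults are standard
#' literature values: mass-dependent slope lambda = 0.518, photosynthetic
#' end-member 249 per meg, air-equilibrated-water value 8 per meg.
#'
#' @param lambda Mass-dependent fractionation slope, dimensionless, in (0,1).
#' @param d17_photo 17Delta of photosynthetic O2, per meg.
#' @param d17_eq 17Delta of O2 in air-equilibrated seawater, per meg.
#'   Must be below `d17_photo`.
#'
#' @return An object of class `isotope_constants`.
#' @export
isotope_constants <- function(lambda = 0.518, d17_photo = 249, d17_eq = 8) {
  if (lambda <= 0 || lambda >= 1) stop("lambda must lie in (0, 1)")
  if (d17_photo <= d17_eq)
    stop("photosynthetic end-member must exceed the equilibrium value")
  structure(list(lambda = lambda, d17_photo = d17_photo, d17_eq = d17_eq),
            class = "isotope_constants")
}

#' O2-to-carbon conversion ratios
#'
#' @param gross_o2_to_net_c Mol gross O2 per mol net C fixed; converts
#'   TOI-based GPP to incubation-equivalent NPP. Default 2.7.
#' @param ncp_o2_to_c Mol O2 per mol C for net community production with a
#'   recycled nitrogen source. Default 1.1.
#'
#' @return An object of class `conversion_constants`.
#' @export
conversion_constants <- function(gross_o2_to_net_c = 2.7, ncp_o2_to_c = 1.1) {
  if (gross_o2_to_net_c <= 0 || ncp_o2_to_c <= 0)
    stop("conversion ratios must be positive")
  structure(list(gross_o2_to_net_c = gross_o2_to_net_c,
                 ncp_o2_to_c = ncp_o2_to_c),
            class = "conversion_constants")
}

#' One station's dissolved-gas state
#'
#' @param station Station identifier.
#' @param date Sampling date.
#' @param delta17 delta17-O of dissolved O2, per mil vs atmospheric O2.
#' @param delta18 delta18-O of dissolved O2, per mil vs atmospheric O2.
#' @param o2ar_supersat Biological O2/Ar supersaturation,
#'   measured/(equilibrium) - 1, dimensionless. Negative values indicate
#'   net heterotrophy and are legal.
#' @param sd_delta17,sd_delta18,sd_o2ar Measurement standard deviations
#'   (same units as the measurements); default 0.
#'
#' @return An object of class `toi_sample`.
#' @export
toi_sample <- function(station, date, delta17, delta18, o2ar_supersat,
                       sd_delta17 = 0, sd_delta18 = 0, sd_o2ar = 0) {
  if (delta17 <= -1000 || delta18 <= -1000)
    stop("delta values at or below -1000 per mil are unphysical")
  if (o2ar_supersat <= -1) stop("O2/Ar supersaturation must exceed -1")
  if (any(c(sd_delta17, sd_delta18, sd_o2ar) < 0))
    stop("measurement uncertainties must be non-negative")
  structure(list(station = station, date = date,
                 delta17 = delta17, delta18 = delta18,
                 o2ar_supersat = o2ar_supersat,
                 sd_delta17 = sd_delta17, sd_delta18 = sd_delta18,
                 sd_o2ar = sd_o2ar),
            class = "toi_sample")
}

#' 17O excess of dissolved oxygen
#'
#' 17Delta = \[ln(1 + d17/1000) - lambda * ln(1 + d18/1000)\] * 1e6, in per
#' meg. Insensitive to mass-dependent fractionation by construction, so
#' respiration drops out and photosynthetic O2 addition remains.
#'
#' @param delta17,delta18 per-mil delta values (> -1000).
#' @param consts An [isotope_constants()].
#'
#' @return 17Delta in per meg.
#' @examples
#' delta17_excess(1.0, 1.93)
#' @export
delta17_excess <- function(delta17, delta18, consts = isotope_constants()) {
  if (any(delta17 <= -1000) || any(delta18 <= -1000))
    stop("delta values at or below -1000 per mil are unphysical")
  (log1p(delta17 / 1000) - consts$lambda * log1p(delta18 / 1000)) * 1e6
}

#' Gross primary production from triple oxygen isotopes
#'
#' Steady-state single-box mixed-layer balance: the air-sea O2 flux carrying
#' the equilibrium 17Delta is balanced by photosynthetic O2 input carrying
#' the photosynthetic end-member, so
#' GPP = k * \[O2\]eq * (17D_diss - 17D_eq) / (17D_photo - 17D_diss).
#' Mixing and advection are neglected.
#'
#' @param sample A [toi_sample()].
#' @param k Piston velocity, m d-1, positive.
#' @param o2eq Equilibrium O2 concentration, mmol m-3 (see
#'   [o2_saturation()]).
#' @param consts An [isotope_constants()].
#'
#' @return GPP in mmol O2 m-2 d-1. A warning flags 17Delta below the
#'   equilibrium end-member (extrapolation, negative GPP); 17Delta at or
#'   above the photosynthetic end-member is an error.
#' @export
gpp_from_toi <- function(sample, k, o2eq, consts = isotope_constants()) {
  if (k <= 0) stop("piston velocity must be positive")
  d17x <- delta17_excess(sample$delta17, sample$delta18, consts)
  if (d17x >= consts$d17_photo)
    stop("dissolved 17Delta (", round(d17x, 1),
         " per meg) at or above the photosynthetic end-member; ",
         "steady-state balance undefined")
  if (d17x < consts$d17_eq)
    warning("dissolved 17Delta below the equilibrium end-member; ",
            "extrapolating to negative GPP")
  k * o2eq * (d17x - consts$d17_eq) / (consts$d17_photo - d17x)
}

#' Net community production from O2/Ar supersaturation
#'
#' Under steady state the biological O2 supersaturation (O2/Ar referenced to
#' equilibrium, argon cancelling the physical component) is exported through
#' the surface: NCP = k * \[O2\]eq * D(O2/Ar).
#'
#' @inheritParams gpp_from_toi
#'
#' @return NCP in mmol O2 m-2 d-1; negative when the mixed layer is net
#'   heterotrophic (not clipped).
#' @export
ncp_from_o2ar <- function(sample, k, o2eq) {
  if (k <= 0) stop("piston velocity must be positive")
  if (sample$o2ar_supersat <= -1)
    stop("O2/Ar supersaturation must exceed -1")
  k * o2eq * sample$o2ar_supersat
}

#' Monte Carlo uncertainty propagation
#'
#' Perturbs each uncertain input with independent Gaussian noise of its
#' stated standard deviation, re-evaluates `fn`, and summarizes the draws.
#'
#' @param fn Function taking a named list of inputs and returning a single
#'   numeric value.
#' @param inputs Named list of central input values (numeric scalars).
#' @param sigmas Named numeric vector/list of standard deviations; names
#'   must be a subset of `names(inputs)`; inputs without a sigma are held
#'   fixed. All sigmas must be non-negative.
#' @param n_draws Number of draws, at least 100. Default 1000.
#' @param seed RNG seed (mandatory, for reproducibility).
#'
#' @return List with `mean`, `sd`, `draws` (the evaluated values),
#'   `n_draws`, `seed`.
#' @export
monte_carlo_uncertainty <- function(fn, inputs, sigmas, n_draws = 1000, seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  if (n_draws < 100) stop("n_draws must be at least 100")
  sigmas <- unlist(sigmas)
  if (any(sigmas < 0)) stop("standard deviations must be non-negative")
  if (!all(names(sigmas) %in% names(inputs)))
    stop("sigma names must match input names: ",
         paste(setdiff(names(sigmas), names(inputs)), collapse = ", "))
  set.seed(seed)
  draws <- vapply(seq_len(n_draws), function(i) {
    x <- inputs
    for (nm in names(sigmas))
      x[[nm]] <- x[[nm]] + stats::rnorm(1, 0, sigmas[[nm]])
    fn(x)
  }, numeric(1))
  list(mean = mean(draws), sd = stats::sd(draws), draws = draws,
       n_draws = n_draws, seed = seed)
}

#' Convert gross O2 production to net carbon units
#'
#' Divides TOI-based GPP (gross O2) by the gross O2 : net C ratio to give a
#' rate comparable to incubation-based NPP.
#'
#' @param gpp_o2 GPP, mmol O2 m-2 d-1.
#' @param consts A [conversion_constants()].
#' @return NPP-equivalent rate, mmol C m-2 d-1.
#' @examples
#' convert_gpp_to_npp(41)   # ~15 mmol C m-2 d-1
#' @export
convert_gpp_to_npp <- function(gpp_o2, consts = conversion_constants()) {
  gpp_o2 / consts$gross_o2_to_net_c
}

#' Convert NCP from O2 to carbon units
#'
#' @param ncp_o2 NCP, mmol O2 m-2 d-1.
#' @param consts A [conversion_constants()].
#' @return NCP in mmol C m-2 d-1.
#' @export
convert_ncp_to_c <- function(ncp_o2, consts = conversion_constants()) {
  ncp_o2 / consts$ncp_o2_to_c
}

#' Volumetric carbon fixation rate from 13C incubations
#'
#' Per bottle, the fraction of the particulate pool turned over is the rise
#' in particulate 13C atom percent relative to the enrichment of the
#' dissolved inorganic pool:
#' rate = (atomPC_final - atomPC_natural) / (atomDIC - atomPC_natural) *
#' \[PC\] / dt. Dark-bottle rates are subtracted from light-bottle rates.
#'
#' @param samples Data frame of replicate bottles with columns `light`
#'   (logical), `pc_um` (particulate C, uM), `atom_pc_t0` (natural-abundance
#'   particulate atom percent 13C), `atom_pc_final`, `atom_dic` (dissolved
#'   pool atom percent after spike), `duration_h`.
#' @param floor_at_zero Clip a negative light-minus-dark difference to 0;
#'   default FALSE (sign is informative).
#'
#' @return Net volumetric rate, uM C d-1.
#' @export
npp_13c_rate <- function(samples, floor_at_zero = FALSE) {
  req <- c("light", "pc_um", "atom_pc_t0", "atom_pc_final", "atom_dic",
           "duration_h")
  if (!all(req %in% names(samples)))
    stop("missing columns: ", paste(setdiff(req, names(samples)), collapse = ", "))
  if (!any(samples$light) || !any(!samples$light))
    stop("need at least one light and one dark replicate")
  if (any(samples$atom_dic <= samples$atom_pc_t0))
    stop("dissolved pool enrichment must exceed natural particulate abundance")
  if (any(samples$duration_h <= 0)) stop("incubation duration must be positive")
  rate <- with(samples,
    (atom_pc_final - atom_pc_t0) / (atom_dic - atom_pc_t0) *
      pc_um / (duration_h / 24))
  net <- mean(rate[samples$light]) - mean(rate[!samples$light])
  if (floor_at_zero) max(0, net) else net
}

#' Depth-integrate a volumetric rate profile
#'
#' Trapezoidal integration of a volumetric rate (uM C d-1) over
#' `[z_top, z_bottom]`, with linear interpolation at the bounds and no
#' extrapolation beyond the sampled depths. uM * m = mmol m-2.
#'
#' @param depths Strictly increasing sample depths, m.
#' @param rates Volumetric rates at `depths`, uM C d-1.
#' @param z_top,z_bottom Integration bounds, m, inside the sampled range.
#'
#' @return Integrated rate, mmol C m-2 d-1.
#' @examples
#' integrate_profile(c(0, 75), c(1.0, 0.3), 0, 75)  # 48.75
#' @export
integrate_profile <- function(depths, rates, z_top, z_bottom) {
  if (length(depths) < 2 || length(depths) != length(rates))
    stop("need at least two (depth, rate) pairs")
  if (any(diff(depths) <= 0)) stop("depths must be strictly increasing")
  if (z_top >= z_bottom) stop("z_top must be above z_bottom")
  if (z_top < min(depths) || z_bottom > max(depths))
    stop("integration bounds outside sampled depth range; no extrapolation")
  z <- sort(unique(c(z_top, z_bottom, depths[depths > z_top & depths < z_bottom])))
  r <- stats::approx(depths, rates, xout = z)$y
  sum(diff(z) * (utils::head(r, -1) + utils::tail(r, -1)) / 2)
}

#' Export efficiency
#'
#' Fraction of net primary production exported from the mixed layer,
#' NCP / NPP, reported in percent.
#'
#' @param ncp_c NCP, mmol C m-2 d-1.
#' @param npp_c NPP, mmol C m-2 d-1, strictly positive.
#' @return Export efficiency in percent.
#' @export
export_efficiency <- function(ncp_c, npp_c) {
  if (npp_c <= 0) stop("NPP must be positive")
  100 * ncp_c / npp_c
}
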