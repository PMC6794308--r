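# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with known ground truth, so all downstream stages are
# testable without any external download. Forward models invert the exact
# closed forms used by the analysis functions, so noise-free scenarios
# round-trip to machine precision.

#' Scenario configuration for the synthetic-data generators
#'
#' Defaults describe an offshore eastern tropical North Pacific station:
#' oligotrophic mixed-layer rates, trade-wind wind speeds, a warm shallow
#' mixed layer, sediment traps at 105/150/750 m with in-situ production
#' injected inside the upper ODZ, a Prochlorococcus-dominated clade mix,
#' and a free-living cyanophage:host ratio around 35.
#'
#' @param seed RNG seed.
#' @param n_days Days of wind history.
#' @param wind_mean Mean daily 10 m wind speed, m s-1.
#' @param wind_sdlog Log-scale standard deviation of the lognormal daily
#'   wind distribution (0 gives constant wind).
#' @param true_gpp True gross primary production, mmol O2 m-2 d-1.
#' @param true_ncp True net community production, mmol O2 m-2 d-1.
#' @param mld Mixed-layer depth, m.
#' @param temperature,salinity Mixed-layer hydrography (degC, PSU).
#' @param trap_depths Sediment-trap depths, m, strictly increasing.
#' @param trap_background Background sinking C flux at the shallowest trap,
#'   mmol C m-2 d-1.
#' @param trap_attenuation Power-law attenuation exponent of the background
#'   flux with depth (0 = no attenuation).
#' @param in_situ_production Extra C flux, mmol C m-2 d-1, injected at trap
#'   depths inside `injection_depths` (production within the layer).
#' @param injection_depths Length-2 vector (top, bottom), m.
#' @param cn_ratio Molar C:N of sinking matter, used to derive N fluxes.
#' @param community Named numeric vector of true clade relative abundances
#'   for the genotyping marker; must sum to 1.
#' @param marker_gene,marker_length,marker_length_unit Genotyping marker
#'   and its reference length (ITS, nucleotide space, by default).
#' @param two_copy_clades Clades carrying two copies of the marker.
#' @param host_gene,host_length Host normalizer marker (single-copy core
#'   gene) and its reference length (aa).
#' @param virus_gene,virus_length Viral marker and reference length (aa).
#' @param virus_host_ratio Target length-normalized virus:host ratio.
#' @param library_sizes Named integer vector: total sequences per
#'   metagenome.
#' @param marker_reads Placed genotyping-marker reads per sample.
#' @param host_reads Expected host-marker reads per sample.
#' @param contamination_fraction Fraction of marker reads given a pendant
#'   branch length of 3.0 (spurious placements, to exercise the filter).
#' @param short_fraction Fraction of marker reads given length 50 nt
#'   (below the length filter).
#' @param read_length Nominal read length, nt.
#' @param peptide_sizes Named integer vector of peptide-set sizes.
#' @param peptide_overlaps Data frame `(a, b, fraction)` of pairwise
#'   overlap fractions (of the smaller set) realized exactly.
#' @param noise Named list of noise magnitudes: `delta17`, `delta18`
#'   (per mil, additive Gaussian), `o2ar` (dimensionless, additive
#'   Gaussian), `flux` (log-scale SD of multiplicative lognormal noise on
#'   trap fluxes). Defaults are typical measurement precisions: 0.005 and
#'   0.01 per mil on the isotope deltas (a few per meg on the 17O excess),
#'   0.002 on O2/Ar, and 10 percent lognormal on trap fluxes. Set all to 0
#'   for exactly invertible scenarios.
#'
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1,
                            n_days = 60,
                            wind_mean = 7,
                            wind_sdlog = 0.3,
                            true_gpp = 60,
                            true_ncp = 6,
                            mld = 30,
                            temperature = 25,
                            salinity = 34.5,
                            trap_depths = c(105, 150, 750),
                            trap_background = 0.39,
                            trap_attenuation = 0,
                            in_situ_production = 0.27,
                            injection_depths = c(105, 150),
                            cn_ratio = 106 / 16,
                            community = c(Pro_LLI = 0.35, Pro_LLII = 0.1,
                                          Pro_LLIV_V = 0.4, NC1 = 0.05,
                                          Syn = 0.1),
                            marker_gene = "ITS",
                            marker_length = 600,
                            marker_length_unit = "nt",
                            two_copy_clades = c("Syn", "Pro_LLIV_V", "NC1"),
                            host_gene = "rpoB",
                            host_length = 1200,
                            virus_gene = "viral_polA",
                            virus_length = 700,
                            virus_host_ratio = 35,
                            library_sizes = c(stn_100m = 1e6),
                            marker_reads = 1e4,
                            host_reads = 2000,
                            contamination_fraction = 0,
                            short_fraction = 0,
                            read_length = 125,
                            peptide_sizes = c(trap_105m = 100,
                                              wc_100m = 100,
                                              wc_50m = 100),
                            peptide_overlaps = data.frame(
                              a = c("trap_105m", "trap_105m"),
                              b = c("wc_100m", "wc_50m"),
                              fraction = c(0.67, 0.15)),
                            noise = list(delta17 = 0.005, delta18 = 0.01,
                                         o2ar = 0.002, flux = 0.1)) {
  if (n_days < 1) stop("n_days must be at least 1")
  if (true_gpp < 0) stop("true_gpp must be non-negative")
  if (abs(sum(community) - 1) > 1e-9)
    stop("community abundances must sum to 1")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (any(diff(trap_depths) <= 0)) stop("trap depths must be strictly increasing")
  if (any(unlist(noise) < 0)) stop("noise magnitudes must be non-negative")
  if (any(peptide_overlaps$fraction < 0 | peptide_overlaps$fraction > 1))
    stop("overlap fractions must lie in [0, 1]")
  structure(as.list(environment()), class = "scenario_config")
}

#' Simulate a daily wind-speed history
#'
#' Daily 10 m wind speeds drawn from a lognormal distribution with the
#' configured arithmetic mean — positive and right-skewed like trade-wind
#' records, and trivially invertible for tests. A zero `wind_sdlog` (or a
#' zero mean) gives a constant series.
#'
#' @param cfg A [scenario_config()].
#'
#' @return Data frame with columns `date` and `u10` (m s-1), ending at the
#'   nominal sampling date.
#' @export
make_wind_series <- function(cfg) {
  if (cfg$n_days < 1) stop("n_days must be at least 1")
  set.seed(cfg$seed)
  if (cfg$wind_sdlog == 0 || cfg$wind_mean == 0) {
    u <- rep(cfg$wind_mean, cfg$n_days)
  } else {
    meanlog <- log(cfg$wind_mean) - cfg$wind_sdlog^2 / 2
    u <- stats::rlnorm(cfg$n_days, meanlog, cfg$wind_sdlog)
  }
  data.frame(date = as.Date("2012-04-10") - rev(seq_len(cfg$n_days) - 1),
             u10 = u)
}

#' Forward-model a triple-oxygen-isotope / O2-Ar sample
#'
#' Inverts the steady-state mixed-layer balances so that, at zero noise,
#' [gpp_from_toi()] and [ncp_from_o2ar()] recover the configured true rates
#' exactly: the dissolved 17Delta is placed where the GPP balance demands,
#' 17D_diss = (GPP * 17D_photo + k * O2eq * 17D_eq) / (GPP + k * O2eq),
#' a nominal delta18 is chosen and delta17 back-computed, and the O2/Ar
#' supersaturation is set to NCP / (k * O2eq). Gaussian noise of the
#' configured magnitude is then added to each observable.
#'
#' @param cfg A [scenario_config()].
#' @param k Gas transfer velocity, m d-1, positive.
#' @param consts An [isotope_constants()].
#'
#' @return A [toi_sample()] whose `sd_*` fields carry the configured noise
#'   magnitudes.
#' @export
make_toi_sample <- function(cfg, k, consts = isotope_constants()) {
  if (k <= 0) stop("gas transfer velocity must be positive")
  if (cfg$true_gpp < 0) stop("true_gpp must be non-negative")
  hydro <- hydro_state(cfg$temperature, cfg$salinity, cfg$mld)
  o2eq <- o2_saturation(hydro)
  g <- cfg$true_gpp
  d17x <- (g * consts$d17_photo + k * o2eq * consts$d17_eq) / (g + k * o2eq)
  delta18 <- 0.5                       # nominal; 17Delta is slope-corrected
  delta17 <- (exp(d17x / 1e6 + consts$lambda * log1p(delta18 / 1000)) - 1) * 1000
  supersat <- cfg$true_ncp / (k * o2eq)
  set.seed(cfg$seed + 1L)
  toi_sample(station = "synthetic", date = as.Date("2012-04-10"),
             delta17 = delta17 + stats::rnorm(1, 0, cfg$noise$delta17),
             delta18 = delta18 + stats::rnorm(1, 0, cfg$noise$delta18),
             o2ar_supersat = supersat + stats::rnorm(1, 0, cfg$noise$o2ar),
             sd_delta17 = cfg$noise$delta17,
             sd_delta18 = cfg$noise$delta18,
             sd_o2ar = cfg$noise$o2ar)
}

#' Simulate a sediment-trap flux profile
#'
#' Background flux follows a power-law attenuation from the shallowest trap
#' depth; the configured in-situ production is added to traps lying inside
#' the injection interval (exclusive of its top). N fluxes derive from the
#' C fluxes via the configured C:N ratio. Multiplicative lognormal noise of
#' magnitude `noise$flux` is applied last.
#'
#' @param cfg A [scenario_config()]; needs at least 2 trap depths.
#'
#' @return Data frame with columns `depth_m`, `c_flux_mmol_m2_d`,
#'   `n_flux_umol_m2_d`, plus attribute `truth` (list with the background
#'   and injected components and the injected contribution fraction at the
#'   bottom of the injection interval).
#' @export
make_trap_profile <- function(cfg) {
  z <- cfg$trap_depths
  if (length(z) < 2) stop("need at least 2 trap depths")
  background <- cfg$trap_background * (z / z[1])^(-cfg$trap_attenuation)
  inj <- ifelse(z > cfg$injection_depths[1] & z <= cfg$injection_depths[2],
                cfg$in_situ_production, 0)
  cflux <- background + inj
  set.seed(cfg$seed + 2L)
  if (cfg$noise$flux > 0)
    cflux <- cflux * stats::rlnorm(length(z), -cfg$noise$flux^2 / 2,
                                   cfg$noise$flux)
  i_bot <- which(z > cfg$injection_depths[1] & z <= cfg$injection_depths[2])
  truth_frac <- if (length(i_bot))
    cfg$in_situ_production /
      (background[max(i_bot)] + cfg$in_situ_production) else 0
  out <- data.frame(depth_m = z,
                    c_flux_mmol_m2_d = cflux,
                    n_flux_umol_m2_d = cflux / cfg$cn_ratio * 1000)
  attr(out, "truth") <- list(background = background, injected = inj,
                             contribution_fraction = truth_frac)
  out
}

#' Simulate a phylogenetic-placement read table
#'
#' Genotyping-marker reads are a multinomial draw over clades with
#' probability proportional to abundance x gene length x copy number (more
#' template and longer genes recruit more reads). Optional contaminant
#' reads carry pendant branch length 3.0, and optional short reads fall
#' below the length filter, so the filtering stage can be exercised with a
#' known removable fraction. Host- and virus-marker reads are Poisson draws
#' whose expectations realize the configured length-normalized virus:host
#' ratio.
#'
#' @param cfg A [scenario_config()].
#'
#' @return List with `reads` (flat placement table: `read_id`, `gene`,
#'   `clade`, `branch_length`, `read_len_nt`, `sample_id`), `samples`
#'   (sample metadata with `library_size`), `genes`, `copy_numbers`, and
#'   `truth` (configured community, contaminant/short fractions and target
#'   virus:host ratio).
#' @export
make_placement_table <- function(cfg) {
  if (length(cfg$community) == 0) stop("community must be non-empty")
  if (abs(sum(cfg$community) - 1) > 1e-9)
    stop("community abundances must sum to 1")
  set.seed(cfg$seed + 3L)
  copy <- ifelse(names(cfg$community) %in% cfg$two_copy_clades, 2, 1)
  all_reads <- lapply(names(cfg$library_sizes), function(sid) {
    p <- cfg$community * cfg$marker_length * copy
    counts <- as.vector(stats::rmultinom(1, cfg$marker_reads, p / sum(p)))
    marker <- data.frame(
      clade = rep(names(cfg$community), counts),
      gene = cfg$marker_gene,
      stringsAsFactors = FALSE)
    # host and virus markers: ratio defined on length-normalized abundance,
    # so E[v] = ratio * E[h] * L_v / L_h
    h <- stats::rpois(1, cfg$host_reads)
    v <- stats::rpois(1, cfg$virus_host_ratio * cfg$host_reads *
                        cfg$virus_length / cfg$host_length)
    extra <- data.frame(
      clade = c(rep("host_cyano", h), rep("cyanophage", v)),
      gene = c(rep(cfg$host_gene, h), rep(cfg$virus_gene, v)),
      stringsAsFactors = FALSE)
    reads <- rbind(marker, extra)
    n <- nrow(reads)
    reads$read_id <- sprintf("%s_r%06d", sid, seq_len(n))
    reads$sample_id <- sid
    reads$branch_length <- stats::runif(n, 0, 1.5)
    reads$read_len_nt <- cfg$read_length
    # flagged-removable reads: long pendant branches and short reads,
    # spread over clades so filtering does not bias the composition
    n_marker <- nrow(marker)
    n_contam <- round(cfg$contamination_fraction * n_marker)
    n_short <- round(cfg$short_fraction * n_marker)
    idx <- sample(n_marker, n_contam + n_short)
    if (n_contam > 0) reads$branch_length[idx[seq_len(n_contam)]] <- 3.0
    if (n_short > 0) reads$read_len_nt[idx[n_contam + seq_len(n_short)]] <- 50
    reads
  })
  reads <- do.call(rbind, all_reads)
  rownames(reads) <- NULL
  samples <- data.frame(sample_id = names(cfg$library_sizes),
                        library_size = as.numeric(cfg$library_sizes),
                        row.names = NULL)
  genes <- data.frame(
    gene = c(cfg$marker_gene, cfg$host_gene, cfg$virus_gene),
    ref_length = c(cfg$marker_length, cfg$host_length, cfg$virus_length),
    length_unit = c(cfg$marker_length_unit, "aa", "aa"))
  copy_numbers <- if (length(cfg$two_copy_clades)) {
    data.frame(gene = cfg$marker_gene, clade = cfg$two_copy_clades,
               copy_number = 2)
  } else {
    data.frame(gene = character(0), clade = character(0),
               copy_number = numeric(0))
  }
  list(reads = reads[c("read_id", "gene", "clade", "branch_length",
                       "read_len_nt", "sample_id")],
       samples = samples, genes = genes, copy_numbers = copy_numbers,
       truth = list(community = cfg$community,
                    contamination_fraction = cfg$contamination_fraction,
                    short_fraction = cfg$short_fraction,
                    virus_host_ratio = cfg$virus_host_ratio))
}

#' Construct peptide tables with exact overlap structure
#'
#' Builds per-sample peptide sets realizing the configured pairwise
#' intersections exactly: each configured pair (a, b) shares
#' round(fraction * min(|a|, |b|)) peptides unique to that pair, and the
#' remainder of each set is sample-specific. Requested intersections that
#' exceed a set's size are rejected.
#'
#' @param cfg A [scenario_config()]; uses `peptide_sizes` and
#'   `peptide_overlaps`.
#'
#' @return Data frame with columns `sample_id`, `peptide`, `taxon` (all
#'   "cyanobacteria").
#' @export
make_peptide_tables <- function(cfg) {
  sizes <- cfg$peptide_sizes
  ov <- cfg$peptide_overlaps
  if (any(ov$fraction < 0 | ov$fraction > 1))
    stop("overlap fractions must lie in [0, 1]")
  counter <- 0L
  new_peps <- function(n) {
    p <- sprintf("PEP%06d", counter + seq_len(n))
    counter <<- counter + n
    p
  }
  sets <- stats::setNames(vector("list", length(sizes)), names(sizes))
  for (s in names(sizes)) sets[[s]] <- character(0)
  if (nrow(ov)) for (i in seq_len(nrow(ov))) {
    a <- ov$a[i]; b <- ov$b[i]
    n_shared <- round(ov$fraction[i] * min(sizes[[a]], sizes[[b]]))
    if (length(sets[[a]]) + n_shared > sizes[[a]] ||
        length(sets[[b]]) + n_shared > sizes[[b]])
      stop("inconsistent overlap specification: requested intersection ",
           "exceeds the size of '", a, "' or '", b, "'")
    shared <- new_peps(n_shared)
    sets[[a]] <- c(sets[[a]], shared)
    sets[[b]] <- c(sets[[b]], shared)
  }
  for (s in names(sizes))
    sets[[s]] <- c(sets[[s]], new_peps(sizes[[s]] - length(sets[[s]])))
  do.call(rbind, lapply(names(sets), function(s)
    data.frame(sample_id = s, peptide = sets[[s]],
               taxon = "cyanobacteria", row.names = NULL)))
}
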