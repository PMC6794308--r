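---
title: "From mixed-layer productivity to oxygen-deficient-zone nitrogen loss: models and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From mixed-layer productivity to oxygen-deficient-zone nitrogen loss: models and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odzn2)
```

This package connects four quantitative strands that together constrain
nitrogen loss in an oceanic oxygen-deficient zone (ODZ): mixed-layer
productivity from dissolved-gas tracers, sinking organic-matter fluxes from
sediment traps, marker-gene quantification of the microbial and viral
community from phylogenetic-placement output, and a stoichiometric budget
that converts respired organic carbon into N~2~ production. This vignette
explains each model, its assumptions, the tunable parameters and their
defaults, the synthetic-data generator used for testing, and the numerical
choices made where the design was genuinely open.

## Air–sea gas exchange

The productivity tracers live in the surface mixed layer and exchange with
the atmosphere, so every rate is proportional to the gas-transfer (piston)
velocity $k$. We use the standard quadratic wind-speed parameterization

$$k = a\,u_{10}^2\,\left(\frac{Sc}{660}\right)^{-1/2},$$

with $a = 0.251$ cm h^-1^ (m s^-1^)^-2^, the 4th-order seawater Schmidt
number polynomial for O~2~, and the Garcia–Gordon (Benson–Krause) O~2~
solubility fit. All coefficients are configuration, not code: swap in
another parameterization by changing `gas_exchange_params()` or the
`gas_exchange:` section of the YAML config. Outputs are strictly in
m d^-1^ and mmol m^-3^.

Because a single day's wind is not representative of the window over which
the mixed layer acquired its gas signature, `weighted_piston_velocity()`
weights the trailing daily piston velocities by how much of the mixed layer
each day ventilated before more recent days overwrote it: with
$f_i = \min(1, k_i \Delta t / z_{ml})$ and $i$ counted backwards from the
sampling day, $\omega_i = f_i \prod_{j<i}(1-f_j)$, renormalized to sum to
one. The cap at 1 prevents negative weight products under strong winds over
a shallow mixed layer; a fully calm window falls back to an unweighted
mean. The window length (default 60 days) is exposed as configuration
because no single value is canonical; 60 days comfortably exceeds the
mixed-layer residence time of O~2~ for typical trade-wind speeds.

## Mixed-layer productivity

**Gross primary production (GPP)** comes from the triple-oxygen-isotope
(TOI) excess

$$^{17}\Delta = \left[\ln(1+\delta^{17}O/1000) -
\lambda \ln(1+\delta^{18}O/1000)\right]\times 10^6 \quad \text{(per meg)},$$

which is insensitive to mass-dependent fractionation (respiration) and so
isolates the balance between atmospheric O~2~ invasion (low $^{17}\Delta$)
and photosynthetic O~2~ (high $^{17}\Delta$). At steady state with mixing
and advection neglected,

$$\mathrm{GPP} = k\,[O_2]_{eq}\,
\frac{^{17}\Delta_{diss} - {}^{17}\Delta_{eq}}
     {^{17}\Delta_{photo} - {}^{17}\Delta_{diss}}.$$

The end-members are not universal constants; we default to standard
literature values ($\lambda = 0.518$, $^{17}\Delta_{photo} = 249$ per meg,
$^{17}\Delta_{eq} = 8$ per meg) and expose all three in
`isotope_constants()`. A dissolved excess below the equilibrium end-member
triggers an extrapolation warning (negative GPP); at or above the
photosynthetic end-member the balance diverges and the function refuses.

**Net community production (NCP)** uses the biological O~2~ supersaturation
from O~2~/Ar (argon cancels the physically induced part):
$\mathrm{NCP} = k\,[O_2]_{eq}\,\Delta(O_2/Ar)$. Negative values (net
heterotrophy) are reported, never clipped, because the sign is the result.

**Unit conversions.** TOI-based GPP in O~2~ units converts to
incubation-equivalent net primary production (NPP) with a gross O~2~ : net
C ratio of 2.7; NCP converts to carbon export units with O~2~ : C = 1.1,
appropriate for production on recycled nitrogen. Both are plain ratios in
`conversion_constants()`.

**^13^C incubations** give volumetric NPP:
$\mathrm{rate} = \frac{A_{PC}^{final}-A_{PC}^{nat}}{A_{DIC}-A_{PC}^{nat}}
\cdot \frac{[PC]}{\Delta t}$, with dark-bottle rates subtracted from light
rates. Natural-abundance atom% defaults to 1.1 and is a column of the
input, not a constant. Negative light-minus-dark differences are kept
unless `floor_at_zero = TRUE`. Depth integration is trapezoidal with
interpolation at the bounds and a hard error instead of extrapolation.

**Uncertainty** is propagated by Monte Carlo: each uncertain input is
perturbed with independent Gaussian noise of its stated standard deviation
and the estimator re-evaluated (default 1000 draws; a seed is mandatory).
Independence between $\delta^{17}O$ and $\delta^{18}O$ errors is a
simplification — real mass-spectrometric errors are partly correlated,
which would shrink the $^{17}\Delta$ error — so the propagated GPP
uncertainty is mildly conservative.

## The stoichiometric nitrogen-loss budget

Organic matter of composition $C_aH_bO_cN_dP_e$ oxidized completely by
nitrate to CO~2~, NH~3~, H~3~PO~4~ and H~2~O releases

$$E = 4a + b - 2c - 3d + 5e$$

electrons; each NO~3~^-^ reduced to N~2~ accepts five, so the nitrate
demand is $E/5$ and denitrification produces $E/10$ N~2~ per formula unit.
Water closes the hydrogen balance. For the default composition
C~106~H~175~O~42~N~16~P this gives the canonical coefficients 94.4 HNO~3~
and 47.2 N~2~, and `balance_check()` verifies every derived equation
element by element (a property tested over random formulas).

Anammox consumes the released ammonia 1:1 with nitrite. We debit that
nitrite from the oxidized-N pool, so each mole of NH~3~ adds two N to the
loss (one from NH~4~^+^, one from NO~2~^-^), giving a yield of
$(2 \cdot 47.2 + 2 \cdot 16)/106 = 1.19$ mol N per mol C with pairing and
$0.89$ without; the toggle exists for sensitivity analysis.

The budget chain is then: consumed organic C = trap flux entering the ODZ
layer (150 m) minus flux leaving at its bottom (750 m); doubled
(`export_scale = 2`) because traps miss dissolved organic carbon export and
zooplankton active transport, which make total fluxes 2–3 times trap
fluxes; multiplied by the yield; spread uniformly over the upper 200 m of
the ODZ (where most N~2~ production occurs); and accumulated over the
3.9 ± 0.8 yr residence time of ODZ water. With the default measured fluxes
(0.39, 0.66, 0.34 mmol C m^-2^ d^-1^ at 105, 150, 750 m) this yields
0.32 and 0.64 mmol C m^-2^ d^-1^, about 4 nM N d^-1^, and roughly
6 µM N as N~2~ — most of the ~10 µM biogenic N~2~ observed. The flux
*increase* from 105 to 150 m is interpreted as in-situ production inside
the ODZ contributing ~40% of the 150 m particle flux; flux inversions are
therefore flagged, never silently clipped. Differences are reported
unrounded; integer rounding happens only at report time, and the reported
accumulation follows the integer-rounded rate as in the worked example.
The `consumed_fraction` parameter (default 1) exists because "most
consumption in the top 30%" can be read as spanning settings between the
4 and 6 nM d^-1^ endpoints; we default to the lower-end interpretation
rather than guess a single intent.

```{r budget}
run_reproduction_report()
```

## Placement-based quantification

The metagenomic input is the *output* of a phylogenetic-placement pipeline
(short reads recruited by homology search, aligned, and placed on fixed
reference trees), either as a flat table or as jplace JSON plus an
edge-to-clade map. The package then:

1. **Filters**: reads attached by a pendant branch length > 2.0
   substitutions/site are spurious (typically a different gene); reads
   shorter than 100 nt / 33 aa are dropped. Paired reads placed as one are
   counted once (collapsed by read id). The e-value cutoff (< 10^-5^)
   belongs to the upstream search and is recorded as provenance only.
2. **Normalizes**: count / (library size × reference gene length) × 100,
   then divided by the clade's marker copy number — e.g. the rRNA ITS is
   present in two copies in *Synechococcus*, *Prochlorococcus* LLIV/V and
   NC1, exactly that list. Whether ×100 precedes or follows copy-number
   division is mathematically irrelevant; we do ×100 first. Gene lengths
   carry an explicit unit (aa for protein markers, nt for ITS) to keep
   unit mixing greppable.
3. **Ratios and comparisons**: the cyanophage:host ratio divides
   length-normalized viral DNA-polymerase abundance by cyanobacterial
   *rpoB* abundance (length normalization, not raw counts, because the two
   markers differ in reference length). Zero host abundance yields an
   explicit undefined flag, not infinity. Composition fractions,
   two-sample proportion comparisons against the 1:1 line, and Venn-style
   peptide-overlap partitions round out the module.

For reads with multiple placements (jplace), the best placement by
like-weight ratio wins; ties break toward the lower edge number (the more
basal edge) with a warning, since no canonical rule exists.

## The synthetic-data generator

Every pipeline input can be generated with known ground truth, written in
the same on-disk formats the analysis reads (`write_scenario_data()`), with
the truth in a YAML sidecar so tests never re-derive it.

* **Wind**: lognormal daily speeds around a configured mean — positive and
  right-skewed like trade-wind records, trivially invertible.
* **TOI/O~2~/Ar samples**: the forward model algebraically inverts the
  steady-state GPP and NCP relations, so noise-free scenarios round-trip
  to machine precision; this is the basis of the parameter-recovery tests.
* **Trap profiles**: power-law-attenuating background plus a production
  term injected between two depths, with the injected contribution
  fraction recorded.
* **Placement tables**: multinomial reads over clades with probability
  proportional to abundance × gene length × copy number; a configurable
  fraction of contaminant (branch length 3.0) and short reads to exercise
  the filters; host and viral marker counts drawn (Poisson) to realize a
  target length-normalized virus:host ratio.
* **Peptide tables**: sets realizing configured pairwise intersections
  exactly; inconsistent requests (intersection larger than a set) are
  rejected.

Default observation noise reflects typical measurement precision: 0.005
and 0.01 per mil (Gaussian) on $\delta^{17}O$ and $\delta^{18}O$ — a few
per meg on $^{17}\Delta$ — 0.002 on O~2~/Ar supersaturation, and 10%
multiplicative lognormal on trap fluxes. Noise on $\delta$ values is
additive (how such errors are quoted) and on fluxes multiplicative
(errors scale with the flux).

What the generator does **not** emulate: raw sequencing reads and their
error profiles, alignment and placement uncertainty (placements are taken
as given), ocean circulation, time-varying mixed layers, or correlated
measurement errors. Passing tests therefore demonstrate correctness of the
quantification and budget arithmetic under the stated models, not
robustness to upstream bioinformatic error.

## Problem sizes and numerical choices

The test suite works at desk scale: placement tables of 10^4^–10^5^ reads,
200 regenerated stations for the Monte Carlo comparison, 1000 random
formulas for the stoichiometry property, 1000 Monte Carlo draws. These
sizes put sampling error well below the asserted tolerances (multinomial
standard errors shrink as $n^{-1/2}$) while keeping the whole suite fast.
All generators are bit-reproducible given (seed, config); statistical
assertions use three-standard-error bounds, with means over independent
replicates where a single draw would make the check needlessly
seed-sensitive.

## Known limitations

* The steady-state single-box mixed-layer model ignores entrainment,
  vertical mixing and advection; it is a fair approximation for the
  oligotrophic ETNP in spring but not generally.
* Isotope end-members and the solubility/Schmidt fits are literature
  defaults, not fitted to any particular cruise; change them in config
  when working with a different calibration.
* The budget treats the ODZ layer as a single box with uniform respiration
  of a fixed organic-matter composition; real attenuation profiles and
  variable stoichiometry are out of scope.
* Real abundance depth-profiles require the original metagenomes;
  the property-based synthetic checks validate the arithmetic, not the
  field observations.
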