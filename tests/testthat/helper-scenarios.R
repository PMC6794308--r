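# shared fixtures for the test suite

zero_noise <- list(delta17 = 0, delta18 = 0, o2ar = 0, flux = 0)

# a noise-free scenario whose forward models invert exactly
quiet_scenario <- function(...) {
  scenario_config(noise = zero_noise, ...)
}

# station BB2 trap fluxes used by the worked budget
bb2_traps <- data.frame(depth_m = c(105, 150, 750),
                        c_flux_mmol_m2_d = c(0.39, 0.66, 0.34))
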