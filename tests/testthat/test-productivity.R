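test_that("17O excess follows its logarithmic definition", {
  expect_equal(delta17_excess(0, 0), 0)
  # hand logarithm evaluation
  expect_equal(delta17_excess(1.0, 1.930),
               (log(1.001) - 0.518 * log(1.00193)) * 1e6)
  # a purely mass-dependent pair leaves no excess
  d18 <- 12
  d17 <- ((1 + d18 / 1000)^0.518 - 1) * 1000
  expect_equal(delta17_excess(d17, d18), 0, tolerance = 1e-9)
  expect_error(delta17_excess(-1000, 0), "unphysical")
})

test_that("GPP from TOI is zero at equilibrium and errors at the photosynthetic end-member", {
  consts <- isotope_constants()
  o2eq <- 210
  # construct deltas whose 17Delta equals the equilibrium end-member
  d18 <- 0.5
  d17_eq <- (exp(consts$d17_eq / 1e6 + consts$lambda * log1p(d18 / 1000)) - 1) * 1000
  s_eq <- toi_sample("s", Sys.Date(), d17_eq, d18, 0)
  expect_equal(gpp_from_toi(s_eq, 3, o2eq, consts), 0, tolerance = 1e-9)
  d17_hot <- (exp(consts$d17_photo / 1e6 + consts$lambda * log1p(d18 / 1000)) - 1) * 1000
  s_hot <- toi_sample("s", Sys.Date(), d17_hot, d18, 0)
  expect_error(gpp_from_toi(s_hot, 3, o2eq, consts), "end-member")
})

test_that("GPP is monotone in the dissolved excess and linear in k and O2eq", {
  consts <- isotope_constants()
  mk <- function(d17x) {
    d18 <- 0.5
    d17 <- (exp(d17x / 1e6 + consts$lambda * log1p(d18 / 1000)) - 1) * 1000
    toi_sample("s", Sys.Date(), d17, d18, 0)
  }
  g <- vapply(seq(10, 240, by = 10),
              function(x) gpp_from_toi(mk(x), 3, 210, consts), numeric(1))
  expect_true(all(diff(g) > 0))
  s <- mk(60)
  expect_equal(gpp_from_toi(s, 6, 210, consts), 2 * gpp_from_toi(s, 3, 210, consts))
  expect_equal(gpp_from_toi(s, 3, 420, consts), 2 * gpp_from_toi(s, 3, 210, consts))
})

test_that("NCP from O2/Ar is k * O2eq * supersaturation with sign preserved", {
  s <- toi_sample("s", Sys.Date(), 1, 2, 0.01)
  expect_equal(ncp_from_o2ar(s, 3, 210), 6.3)
  s0 <- toi_sample("s", Sys.Date(), 1, 2, 0)
  expect_equal(ncp_from_o2ar(s0, 3, 210), 0)
  sneg <- toi_sample("s", Sys.Date(), 1, 2, -0.02)
  expect_lt(ncp_from_o2ar(sneg, 3, 210), 0)
})

test_that("noise-free synthetic stations round-trip GPP and NCP exactly", {
  for (gpp in c(0, 41, 60, 182)) {
    cfg <- quiet_scenario(true_gpp = gpp, true_ncp = 6)
    k <- 3
    s <- make_toi_sample(cfg, k)
    h <- hydro_state(cfg$temperature, cfg$salinity, cfg$mld)
    o2eq <- o2_saturation(h)
    expect_equal(gpp_from_toi(s, k, o2eq), gpp, tolerance = 1e-9)
    expect_equal(ncp_from_o2ar(s, k, o2eq), 6, tolerance = 1e-9)
  }
  # zero production leaves the air-equilibrium signature
  cfg0 <- quiet_scenario(true_gpp = 0, true_ncp = 0)
  s0 <- make_toi_sample(cfg0, 3)
  expect_equal(delta17_excess(s0$delta17, s0$delta18),
               isotope_constants()$d17_eq, tolerance = 1e-6)
  expect_equal(s0$o2ar_supersat, 0)
})

test_that("Monte Carlo propagation is reproducible and matches Gaussian theory", {
  fn <- function(x) 3 * x$a + 1
  res <- monte_carlo_uncertainty(fn, list(a = 2), c(a = 0.5), 2000, seed = 7)
  expect_equal(res$sd, 3 * 0.5, tolerance = 3 / sqrt(2000) * 3)
  expect_equal(res$mean, 7, tolerance = 0.1)
  res2 <- monte_carlo_uncertainty(fn, list(a = 2), c(a = 0.5), 2000, seed = 7)
  expect_identical(res$draws, res2$draws)
  res0 <- monte_carlo_uncertainty(fn, list(a = 2), c(a = 0), 200, seed = 1)
  expect_equal(res0$sd, 0)
  expect_error(monte_carlo_uncertainty(fn, list(a = 2), c(a = -1), 200, seed = 1),
               "non-negative")
  expect_error(monte_carlo_uncertainty(fn, list(a = 2), c(a = 1), 50, seed = 1),
               "at least 100")
})

test_that("O2-to-carbon conversions use the configured ratios exactly", {
  expect_equal(round(convert_gpp_to_npp(41)), 15)
  expect_equal(convert_gpp_to_npp(182), 182 / 2.7)
  expect_equal(convert_gpp_to_npp(0), 0)
  expect_equal(convert_ncp_to_c(1.1), 1)
  expect_equal(convert_ncp_to_c(3.52), 3.2)
  # exact inverse of multiplying by the ratio
  expect_equal(convert_gpp_to_npp(15 * 2.7), 15)
  expect_equal(convert_ncp_to_c(4.4 * 1.1), 4.4)
})

test_that("13C incubation rates follow the enrichment formula with dark subtraction", {
  mk <- function(light, final) {
    data.frame(light = light, pc_um = 2, atom_pc_t0 = 1.1,
               atom_pc_final = final, atom_dic = 10, duration_h = 24)
  }
  # particulate pool rises halfway to the dissolved enrichment in one day
  halfway <- (1.1 + 10) / 2
  s <- rbind(mk(TRUE, halfway), mk(FALSE, 1.1))
  expect_equal(npp_13c_rate(s), 1.0)
  # no uptake
  s0 <- rbind(mk(TRUE, 1.1), mk(FALSE, 1.1))
  expect_equal(npp_13c_rate(s0), 0)
  # dark equals light
  sd <- rbind(mk(TRUE, 3), mk(FALSE, 3))
  expect_equal(npp_13c_rate(sd), 0)
  expect_error(npp_13c_rate(mk(TRUE, 3)), "light and one dark")
  bad <- rbind(mk(TRUE, 3), mk(FALSE, 1.1))
  bad$atom_dic <- 1.1
  expect_error(npp_13c_rate(bad), "must exceed")
})

test_that("depth integration is an exact trapezoid without extrapolation", {
  expect_equal(integrate_profile(c(0, 50), c(1, 1), 0, 50), 50)
  expect_equal(integrate_profile(c(0, 75), c(1.0, 0.3), 0, 75), 48.75)
  # linear profile: trapezoid is exact; sub-interval too
  z <- c(0, 10, 30, 75)
  r <- 2 - 0.02 * z
  expect_equal(integrate_profile(z, r, 0, 75), 2 * 75 - 0.01 * 75^2)
  expect_equal(integrate_profile(z, r, 5, 40), (2 * 40 - 0.01 * 40^2) -
                 (2 * 5 - 0.01 * 5^2))
  expect_error(integrate_profile(z, r, 0, 100), "extrapolation")
  expect_error(integrate_profile(c(0, 0, 50), c(1, 1, 1), 0, 50), "increasing")
})

test_that("export efficiency is NCP over NPP in percent", {
  expect_equal(export_efficiency(5, 5), 100)
  expect_equal(export_efficiency(3.2, 24.6), 100 * 3.2 / 24.6)
  expect_equal(export_efficiency(0, 10), 0)
  expect_error(export_efficiency(1, 0), "positive")
})
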