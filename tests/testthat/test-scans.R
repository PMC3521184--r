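test_that("light sweeps start at zero, rise monotonically and saturate", {
  grid <- c(0, 100, 250, 500, 1000, 2000, 4000, 8000)
  for (maker in list(make_toy_c3, make_toy_c4)) {
    sw <- light_sweep(maker(), grid, "biomass")
    expect_equal(sw$biomass_flux[1], 0, tolerance = 1e-9)
    expect_true(all(diff(sw$biomass_flux) >= -1e-7))
    # saturation: the last step adds essentially nothing
    expect_lt(diff(utils::tail(sw$biomass_flux, 2)), 1e-6)
  }
})

test_that("the C4 leaf uses light more efficiently below saturation", {
  grid <- c(0, 200, 400)
  s3 <- light_sweep(make_toy_c3(), grid, "biomass")
  s4 <- light_sweep(make_toy_c4(), grid, "biomass")
  slope3 <- diff(s3$biomass_flux) / diff(grid)
  slope4 <- diff(s4$biomass_flux) / diff(grid)
  expect_gte(slope4[1], slope3[1] - 1e-9)
})

test_that("doubling the light bound below saturation doubles the optimum", {
  m <- make_toy_c3()
  v1 <- light_sweep(m, 200, "biomass")$biomass_flux
  v2 <- light_sweep(m, 400, "biomass")$biomass_flux
  expect_equal(v2, 2 * v1, tolerance = 1e-6)
})

test_that("light sweeps demand a photon exchange and an ascending grid", {
  expect_error(light_sweep(chain_model(), c(0, 10)), "photon exchange")
  expect_error(light_sweep(make_toy_c3(), c(10, 0)))
})

test_that("CO2 sweeps recompute r, rise and saturate like an A-Ci curve", {
  grid <- c(100, 380, 550, 800, 1000)
  s3 <- co2_sweep(make_toy_c3(), grid, "c3")
  s4 <- co2_sweep(make_toy_c4(), grid, "c4")
  for (sw in list(s3, s4)) {
    expect_true(all(diff(sw$biomass_flux) >= -1e-7))
    expect_true(all(sw$biomass_flux >= 0))
  }
  # saturating: the relative gain shrinks along the grid
  gain3 <- diff(s3$biomass_flux)
  expect_lt(gain3[length(gain3)], gain3[1])
  # cross-module consistency: the r column is exactly the kinetics output
  expect_equal(s3$r, vapply(grid, function(ca) c3_ratio(ca)$r, numeric(1)))
  expect_equal(s4$r, vapply(grid, function(ca) c4_ratio(ca)$r, numeric(1)))
  # under strict carbon limitation the identical biomass stoichiometries
  # tie exactly
  expect_gte(s4$biomass_flux[1], s3$biomass_flux[1] - 1e-7)
})

test_that("under co-limiting light the C4 curve rises faster at low CO2", {
  # a tight photon budget exposes the photorespiratory burden of the C3
  # leaf at low CO2, where its carboxylation:oxygenation ratio collapses
  grid <- c(100, 200, 380)
  s3 <- co2_sweep(make_toy_c3(fixture_spec("c3", photon_bound = 300)),
                  grid, "c3")
  s4 <- co2_sweep(make_toy_c4(fixture_spec("c4", photon_bound = 300)),
                  grid, "c4")
  expect_gt(s4$biomass_flux[1], s3$biomass_flux[1])
  expect_true(all(s4$biomass_flux >= s3$biomass_flux - 1e-7))
})

test_that("a single-point CO2 grid is a plain FBA at that concentration", {
  sw <- co2_sweep(make_toy_c3(), 380, "c3")
  m <- install_rubisco(make_toy_c3(), c3_ratio(380)$r, "M.chloroplast")
  m <- set_bounds(m, "EX_co2", lower = -0.1 * 380)
  expect_equal(sw$biomass_flux, fba(m)$objective_value, tolerance = 1e-8)
})

test_that("subtype scenarios zero the unselected decarboxylases", {
  m <- make_toy_c4()
  singles <- c("NADP_ME", "NAD_ME", "PCK")
  dec <- c(NADP_ME = "R00216", NAD_ME = "R00214", PCK = "R00341")
  res <- lapply(c(singles, "ALL"), function(s) subtype_scenario(m, s))
  names(res) <- c(singles, "ALL")
  for (s in singles) {
    off <- dec[setdiff(singles, s)]
    for (id in off) {
      expect_equal(res[[s]][[paste0("flux_", id)]], 0, tolerance = 1e-9)
    }
  }
  # relaxation never hurts an LP: ALL is at least every single subtype
  for (s in singles) {
    expect_gte(res$ALL$biomass_flux, res[[s]]$biomass_flux - 1e-7)
  }
  # the PCK route, with its single-ATP decarboxylation, leads the singles
  expect_gte(res$PCK$biomass_flux, res$NADP_ME$biomass_flux - 1e-7)
  expect_gte(res$PCK$biomass_flux, res$NAD_ME$biomass_flux - 1e-7)
  expect_error(subtype_scenario(make_toy_c3(), "PCK"), "decarboxylase")
})

test_that("sweep and subtype outputs are deterministic", {
  g <- c(0, 500, 1000)
  expect_identical(light_sweep(make_toy_c4(), g, "biomass"),
                   light_sweep(make_toy_c4(), g, "biomass"))
  expect_identical(subtype_scenario(make_toy_c4(), "PCK"),
                   subtype_scenario(make_toy_c4(), "PCK"))
})

test_that("autoplot methods return ggplot objects", {
  sw <- light_sweep(make_toy_c3(), c(0, 500, 1000), "biomass")
  expect_s3_class(ggplot2::autoplot(sw), "ggplot")
  rep <- scan_all(chain_model())
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
})
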