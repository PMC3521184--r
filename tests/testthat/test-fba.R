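test_that("a single bottleneck sets the optimum of a chain", {
  sol <- fba(chain_model(cap = 10))
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-8)
})

test_that("the diamond optimum matches the hand-computed LP", {
  # supply 8, two branches capped at 5: export = min(8, 5 + 5) = 8
  sol <- fba(diamond_model(supply = 8, branch_cap = 5))
  expect_equal(sol$objective_value, 8, tolerance = 1e-8)
  expect_equal(sol$objective_value,
               brute_lp(diamond_model(), c(EX_b = 1)), tolerance = 1e-8)
  # branch-limited case
  sol2 <- fba(diamond_model(supply = 20, branch_cap = 5))
  expect_equal(sol2$objective_value, 10, tolerance = 1e-8)
})

test_that("an unproducible biomass precursor yields a zero optimum", {
  m <- chain_model()
  m <- set_bounds(m, "R1", 0, 0)  # sole producer of the precursor
  sol <- fba(m)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
})

test_that("optimize agrees with a vertex-enumeration oracle on random nets", {
  for (seed in 1:20) {
    m <- random_model(seed)
    w <- stats::setNames(m$objective$weight, m$objective$reaction_id)
    for (sense in c("max", "min")) {
      sol <- fba(m, sense = sense)
      ref <- brute_lp(m, w, maximize = sense == "max")
      expect_identical(sol$status, "optimal")
      expect_equal(sol$objective_value, ref, tolerance = 1e-6,
                   label = sprintf("seed %d (%s)", seed, sense))
    }
  }
})

test_that("scaling the objective scales the optimum linearly", {
  m <- diamond_model()
  v1 <- fba(m)$objective_value
  m2 <- set_objective(m, c(EX_b = 3.5))
  expect_equal(fba(m2)$objective_value, 3.5 * v1, tolerance = 1e-8)
})

test_that("reported solutions satisfy mass balance and bounds", {
  for (m in list(chain_model(), diamond_model(), make_toy_c3(),
                 make_toy_c4())) {
    sol <- fba(m)
    S <- stoich_matrix(m)
    expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
    expect_true(all(sol$fluxes >= m$reactions$lower_bound - 1e-6))
    expect_true(all(sol$fluxes <= m$reactions$upper_bound + 1e-6))
  }
})

test_that("infeasibility is reported in the status, never as silent zeros", {
  m <- chain_model()
  m <- set_bounds(m, "EX_bio", lower = 5)   # force export
  m <- set_bounds(m, "R1", 0, 0)            # while blocking production
  expect_identical(fba(m)$status, "infeasible")
})

test_that("flux_ranges brackets forced, blocked and flexible reactions", {
  fr <- flux_ranges(chain_model(cap = 10), fraction_of_optimum = 1)
  forced <- fr[fr$reaction_id == "R1", ]
  expect_equal(c(forced$min_flux, forced$max_flux), c(10, 10),
               tolerance = 1e-7)

  # a reaction cut off from the network is blocked at (0, 0)
  m <- chain_model()
  m <- set_bounds(m, "T_a", 0, 0)
  fr2 <- flux_ranges(m, fraction_of_optimum = 0)
  r1 <- fr2[fr2$reaction_id == "R1", ]
  expect_equal(c(r1$min_flux, r1$max_flux), c(0, 0), tolerance = 1e-9)

  # each diamond branch spans (3, 5) when the optimum (8) is held
  fr3 <- flux_ranges(diamond_model(supply = 8, branch_cap = 5), 1)
  for (id in c("R_up", "R_down")) {
    b <- fr3[fr3$reaction_id == id, ]
    expect_equal(c(b$min_flux, b$max_flux), c(3, 5), tolerance = 1e-7)
  }
  expect_true(all(fr3$min_flux <= fr3$max_flux + 1e-12))
})

test_that("tidy and glance summarize solutions", {
  sol <- fba(chain_model())
  td <- tidy(sol)
  expect_named(td, c("reaction_id", "flux"))
  expect_equal(nrow(td), 5)
  g <- glance(sol)
  expect_equal(g$objective_value, 10)
  expect_identical(g$status, "optimal")
})
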