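test_that("validation rejects broken models and names the offender", {
  met <- tibble::tibble(id = c("a_ext", "b_c"),
                        compartment = c("ext", "M.cytosol"))
  rxn <- tibble::tibble(id = c("EX_a", "R1"),
                        lower_bound = c(-10, 0), upper_bound = c(0, 10))
  sto <- tibble::tibble(reaction_id = c("EX_a", "R1", "R1"),
                        metabolite_id = c("a_ext", "a_ext", "b_c"),
                        coefficient = c(-1, -1, 1))
  expect_s3_class(stoich_model(met, rxn, sto, c(R1 = 1)), "stoich_model")

  bad_sto <- dplyr::mutate(sto, metabolite_id =
                             dplyr::if_else(metabolite_id == "b_c", "X",
                                            metabolite_id))
  expect_error(stoich_model(met, rxn, bad_sto), "R1.*X")
  expect_error(stoich_model(met, dplyr::mutate(rxn, lower_bound = c(5, 0)),
                            sto), "EX_a")
  expect_error(stoich_model(met[c(1, 1), ], rxn, sto), "duplicate")
  expect_error(
    stoich_model(met, rxn, sto[sto$reaction_id != "R1", ], c(R1 = 1)),
    "empty stoichiometry.*R1")
  expect_error(stoich_model(met, rxn, sto, c(nope = 1)), "nope")
})

test_that("a model without an exchange reaction is rejected", {
  met <- tibble::tibble(id = c("a_c", "b_c"),
                        compartment = rep("M.cytosol", 2))
  rxn <- tibble::tibble(id = "R1", lower_bound = 0, upper_bound = 10)
  sto <- tibble::tibble(reaction_id = "R1", metabolite_id = c("a_c", "b_c"),
                        coefficient = c(-1, 1))
  expect_error(stoich_model(met, rxn, sto), "exchange")
})

test_that("apply_overrides changes only the named bounds and is idempotent", {
  m <- make_toy_c3()
  ov <- constraint_override(c("R_aco", "T_co2"), new_lower = c(-50, NA),
                            new_upper = c(50, 80))
  m2 <- apply_overrides(m, ov)
  i <- match("R_aco", m2$reactions$id)
  expect_equal(unlist(m2$reactions[i, c("lower_bound", "upper_bound")]),
               c(lower_bound = -50, upper_bound = 50))
  j <- match("T_co2", m2$reactions$id)
  expect_equal(m2$reactions$upper_bound[j], 80)
  expect_equal(m2$reactions$lower_bound[j], m$reactions$lower_bound[j])
  untouched <- setdiff(m$reactions$id, ov$reaction_id)
  expect_equal(m2$reactions[match(untouched, m2$reactions$id), ],
               m$reactions[match(untouched, m$reactions$id), ])
  expect_identical(apply_overrides(m2, ov), m2)

  expect_identical(apply_overrides(m, ov[0, ]), m)
  expect_error(apply_overrides(m, constraint_override("ghost", 0, 1)), "ghost")
  expect_error(apply_overrides(m, constraint_override("R_aco", 10, -10)),
               "invert")
  expect_error(constraint_override("R_aco"), "at least one")
})

test_that("opening the CO2 leak bound makes leak flux feasible", {
  m <- make_toy_c4(fixture_spec("c4", leak_upper = 0))
  fr <- flux_ranges(m, fraction_of_optimum = 0)
  leg <- fr[fr$reaction_id == "T_co2_leak", ]
  expect_equal(c(leg$min_flux, leg$max_flux), c(0, 0))
  m2 <- apply_overrides(m, constraint_override("T_co2_leak", new_upper = 1000))
  sol <- fba(set_objective(m2, stats::setNames(1, "T_co2_leak")))
  expect_gt(sol$objective_value, 1)
})

test_that("both bundled fixtures are elementally balanced", {
  for (m in list(make_toy_c3(), make_toy_c4())) {
    audit <- audit_atom_balance(m)
    expect_lt(max(abs(audit$imbalance)), 1e-8)
  }
})
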