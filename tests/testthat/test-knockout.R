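test_that("single-route and redundant deletions classify correctly", {
  m <- chain_model()
  sc <- delete_and_score(m, "R1", "reaction")
  expect_equal(sc$ratio, 0)
  expect_identical(sc$class, "zero")

  mp <- parallel_model(n_paths = 2, supply = 6)   # spare path capacity
  sc2 <- delete_and_score(mp, "R1", "reaction")
  expect_equal(sc2$ratio, 1, tolerance = 1e-9)
  expect_identical(sc2$class, "unchanged")

  expect_error(delete_and_score(m, "ghost", "reaction"), "ghost")
  m0 <- set_bounds(m, "EX_a", 0, 0)
  expect_error(delete_and_score(m0, "R1", "reaction"), "wild-type")
})

test_that("enzyme knockout removes every reaction carrying the EC number", {
  m4 <- make_toy_c4()
  # PEPC is the sole entry point for carbon into the bundle sheath
  expect_equal(delete_and_score(m4, "4.1.1.31", "enzyme")$ratio, 0)
  # in the C3 leaf the same EC is only anaplerotic and fully substitutable
  expect_equal(delete_and_score(make_toy_c3(), "4.1.1.31", "enzyme")$ratio, 1,
               tolerance = 1e-9)
  # Rubisco is lethal in both models under both objectives
  for (m in list(make_toy_c3(), m4)) {
    for (obj in c("biomass", "co2_fixation")) {
      expect_equal(
        delete_and_score(set_objective(m, obj), "4.1.1.39", "enzyme")$ratio, 0)
    }
  }
})

test_that("scan_all equals an independent per-deletion re-optimization", {
  m <- make_toy_c3()
  rep <- scan_all(m, objective_name = "biomass")
  wt <- fba(m)$objective_value
  # oracle: a literal loop of bound-zeroing plus a fresh solve
  for (i in seq_len(nrow(rep$entries))) {
    id <- rep$entries$deleted_id[i]
    ko <- fba(set_bounds(m, id, 0, 0))
    ref <- if (ko$status == "optimal") max(0, ko$objective_value / wt) else 0
    expect_equal(rep$entries$ratio[i], ref, tolerance = 1e-6, label = id)
  }
  expect_equal(sum(rep$tally$count), nrow(rep$entries))
  expect_equal(sum(rep$tally$percentage), 100, tolerance = 0.1)
})

test_that("degenerate architectures give all-or-nothing tallies", {
  rep_par <- scan_all(parallel_model(n_paths = 3, supply = 3),
                      exclude_exchanges = TRUE)
  path_rows <- rep_par$entries[grepl("^R[0-9]$", rep_par$entries$deleted_id), ]
  expect_true(all(path_rows$class == "unchanged"))

  rep_chain <- scan_all(chain_model(), exclude_exchanges = TRUE)
  expect_true(all(rep_chain$entries$class == "zero"))
})

test_that("deleting a superset of reactions never raises the ratio", {
  m <- make_toy_c4()
  wt <- fba(m)$objective_value
  # EC 2.2.1.1 tags two transketolase steps; each alone vs both together
  both <- delete_and_score(m, "2.2.1.1", "enzyme")$ratio
  for (id in c("R_tkt1_bs", "R_tkt2_bs")) {
    single <- delete_and_score(m, id, "reaction", wild_type = wt)$ratio
    expect_lte(both, single + 1e-9)
  }
})

test_that("class boundaries honor the zero/unchanged tolerance contract", {
  m <- make_toy_c4()
  rep <- scan_all(m, objective_name = "biomass")
  z <- rep$entries[rep$entries$class == "zero", ]
  expect_true(all(z$ratio <= 1e-6))
  u <- rep$entries[rep$entries$class == "unchanged", ]
  expect_true(all(abs(u$ratio - 1) <= 1e-6))
  r_lo <- rep$entries[rep$entries$class == "reduced_below_090", ]
  if (nrow(r_lo)) expect_true(all(r_lo$ratio > 1e-6 & r_lo$ratio < 0.90))
  r_hi <- rep$entries[rep$entries$class == "reduced_above_090", ]
  if (nrow(r_hi)) expect_true(all(r_hi$ratio >= 0.90 & r_hi$ratio < 1 - 1e-6))
})

test_that("essential overlap respects the ortholog map contract", {
  ra <- scan_all(make_toy_c3(), objective_name = "biomass")
  rb <- scan_all(make_toy_c4(), objective_name = "biomass")
  ov <- essential_overlap(ra, rb, ortholog_map())
  # every mapped C3-essential reaction is also C4-essential, so the A-only
  # set can contain unmapped ids at most
  expect_true(all(!ov$a_only %in% names(ortholog_map())))
  expect_true(length(ov$shared) > 0)
  # C4 keeps extra essentials of its own (the C4 cycle)
  expect_true("R_pepc" %in% ov$b_only)

  # identical reports leave nothing unshared
  id_map <- stats::setNames(ra$entries$deleted_id, ra$entries$deleted_id)
  self <- essential_overlap(ra, ra, id_map)
  expect_length(self$a_only, 0)
  expect_length(self$b_only, 0)

  # disjoint essential sets share nothing
  fake <- ra
  fake$entries$class[fake$entries$class == "zero"] <- "unchanged"
  expect_length(essential_overlap(fake, rb, ortholog_map())$shared, 0)
})
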