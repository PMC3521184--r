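# Published reference ratios at the five standard ambient CO2 levels
ref_table2 <- tibble::tibble(
  ca = c(100, 380, 550, 800, 1000),
  r_c3 = c(1.139, 4.33, 6.26, 9.11, 11.39),
  r_c4 = c(22.2282, 70.7281, 85.9654, 87.1062, 88.0189))

test_that("C3 and C4 ratios reproduce the published table within 0.5%", {
  for (i in seq_len(nrow(ref_table2))) {
    r3 <- c3_ratio(ref_table2$ca[i])
    r4 <- c4_ratio(ref_table2$ca[i])
    expect_lt(abs(r3$r - ref_table2$r_c3[i]) / ref_table2$r_c3[i], 0.005)
    expect_lt(abs(r4$r - ref_table2$r_c4[i]) / ref_table2$r_c4[i], 0.005)
  }
})

test_that("the C4 limitation branch switches between 100 and 380 ubar", {
  expect_identical(c4_ratio(100)$branch, "pep_limited_equality")
  for (ca in c(380, 550, 800, 1000)) {
    expect_identical(c4_ratio(ca)$branch, "rubisco_limited")
  }
})

test_that("ratio curves increase with CO2 within each limitation regime", {
  grid <- seq(50, 1500, by = 10)
  r3 <- vapply(grid, function(ca) c3_ratio(ca)$r, numeric(1))
  expect_true(all(diff(r3) > 0))
  # the C4 equations change limitation regime near 215 ubar (the PEP arm
  # stops binding); r rises strictly within each regime and across the
  # reference concentrations, but not through the switch itself
  res4 <- lapply(grid, c4_ratio)
  r4 <- vapply(res4, `[[`, numeric(1), "r")
  br <- vapply(res4, `[[`, character(1), "branch")
  for (b in unique(br)) {
    expect_true(all(diff(r4[br == b]) > 0), label = b)
  }
  ref_ca <- c(100, 380, 550, 800, 1000)
  r4_ref <- vapply(ref_ca, function(ca) c4_ratio(ca)$r, numeric(1))
  expect_true(all(diff(r4_ref) > 0))
  # the CO2-concentrating mechanism keeps the C4 ratio above the C3 ratio
  # at the reference concentrations
  r3_ref <- vapply(ref_ca, function(ca) c3_ratio(ca)$r, numeric(1))
  expect_true(all(r4_ref > r3_ref))
})

test_that("oxygenation vanishes as O2 goes to zero", {
  k <- c3_kinetics(O2 = 0.001)
  expect_gt(c3_ratio(380, k)$r, 1e4)
})

test_that("invalid inputs raise domain errors", {
  expect_error(c3_ratio(0), "positive")
  expect_error(c3_ratio(-5), "positive")
  expect_error(c4_ratio(0), "positive")
  expect_error(c3_kinetics(ci_fraction = 1.5))
  expect_error(c4_kinetics(alpha = 2))
})

test_that("the combined reaction has the prescribed stoichiometry", {
  ids <- c(RuBP = "rubp_x", CO2 = "co2_x", H2O = "h2o_x", O2 = "o2_x",
           PGA = "pga_x", PGCA = "pgca_x")
  for (r in c(1, 4.33, 70.7281)) {
    rxn <- build_combined_rubisco(r, ids)
    sto <- rxn$stoichiometry[[1]]
    coef <- stats::setNames(sto$coefficient, sto$metabolite_id)
    expect_equal(unname(coef[ids]),
                 c(-(r + 1), -r, -r, -1, 2 * r + 1, 1))
    expect_equal(rxn$lower_bound, 0)  # irreversible
  }
  expect_error(build_combined_rubisco(4.33, ids[-1]), "RuBP")
  expect_error(build_combined_rubisco(-1, ids))
})

test_that("the combined reaction conserves carbon on a grid of r", {
  # RuBP C5, CO2 C1, PGA C3, PGCA C2
  for (r in c(0.1, 0.5, 1, 2, 4.33, 10, 50, 100)) {
    c_in <- 5 * (r + 1) + r
    c_out <- 3 * (2 * r + 1) + 2
    expect_equal(c_in, c_out)
  }
})

test_that("install_rubisco replaces split reactions and is idempotent", {
  m_split <- make_toy_c3(fixture_spec("c3", include_split_rubisco = TRUE))
  n0 <- nrow(m_split$reactions)
  expect_true(all(c("R_rubisco_c", "R_rubisco_o") %in% m_split$reactions$id))
  m1 <- install_rubisco(m_split, 4.33, "M.chloroplast")
  expect_equal(nrow(m1$reactions), n0 - 1)  # two removed, one added
  expect_false(any(c("R_rubisco_c", "R_rubisco_o") %in% m1$reactions$id))
  # applying again with another r replaces, never duplicates
  m2 <- install_rubisco(m1, 6.26, "M.chloroplast")
  expect_equal(nrow(m2$reactions), nrow(m1$reactions))
  co2_coef <- function(m) {
    sto <- m$stoichiometry
    sto$coefficient[sto$reaction_id == "R_rubisco" &
                      startsWith(sto$metabolite_id, "co2")]
  }
  expect_equal(co2_coef(m2), -6.26)
  # C4 installation lands in the bundle-sheath chloroplast
  m4 <- install_rubisco(make_toy_c4(), 70.7281, "BS.chloroplast")
  sto <- m4$stoichiometry[m4$stoichiometry$reaction_id == "R_rubisco", ]
  expect_true(all(endsWith(sto$metabolite_id, "_BSchl")))
  expect_error(install_rubisco(make_toy_c3(), 4.33, "BS.chloroplast"), "rubp")
})

test_that("ratio_table matches the scalar functions", {
  rt <- ratio_table(c(100, 550))
  expect_equal(rt$r_c3, c(c3_ratio(100)$r, c3_ratio(550)$r))
  expect_equal(rt$r_c4, c(c4_ratio(100)$r, c4_ratio(550)$r))
})
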