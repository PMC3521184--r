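test_that("a zero-volume flux space is reported and replicated", {
  m <- chain_model(cap = 10)
  m <- set_bounds(m, "EX_a", -10, -10)   # pin the whole chain at 10
  expect_warning(ens <- achr_sample(m, n_warmup = 50, n_points = 20, seed = 1),
                 "single point")
  expect_true(ens$degenerate)
  expect_equal(max(abs(sweep(ens$points, 2, ens$points[1, ]))), 0)
  expect_equal(unname(ens$points[1, "R1"]), 10, tolerance = 1e-7)
})

test_that("the sampled marginal on a 1-D segment is close to uniform", {
  ens <- achr_sample(segment_model(cap = 10), n_warmup = 200, n_points = 2000,
                     seed = 11)
  x <- ens$points[, "R1"]
  expect_true(all(x >= -1e-6 & x <= 10 + 1e-6))
  ks <- suppressWarnings(stats::ks.test(x, "punif", 0, 10))
  expect_gt(ks$p.value, 0.01)
  # both coordinates of the coupled pair move identically
  expect_lt(max(abs(ens$points[, "R1"] - ens$points[, "R_bio"])), 1e-6)
})

test_that("identical seeds give identical ensembles and differ otherwise", {
  m <- make_toy_c3()
  a <- achr_sample(m, n_warmup = 100, n_points = 50, seed = 99)
  b <- achr_sample(m, n_warmup = 100, n_points = 50, seed = 99)
  expect_identical(a$points, b$points)
  c <- achr_sample(m, n_warmup = 100, n_points = 50, seed = 100)
  expect_false(identical(a$points, c$points))
})

test_that("every sampled point is a feasible steady-state flux", {
  m <- make_toy_c3()
  ens <- achr_sample(m, n_warmup = 200, n_points = 100, seed = 3)
  S <- stoich_matrix(m)
  expect_lt(max(abs(S %*% t(ens$points))), 1e-6)
  lb <- m$reactions$lower_bound
  ub <- m$reactions$upper_bound
  expect_true(all(t(ens$points) >= lb - 1e-6))
  expect_true(all(t(ens$points) <= ub + 1e-6))
})

test_that("stoichiometrically coupled chains collapse into one set", {
  ens <- achr_sample(chain_model(cap = 10), n_warmup = 100, n_points = 200,
                     seed = 5)
  cs <- correlated_sets(ens)
  # all five reactions carry the same flux; one set holds them all
  expect_equal(max(cs$sets$set_id), 1)
  expect_setequal(cs$sets$reaction_id,
                  c("EX_a", "T_a", "R1", "R_bio", "EX_bio"))
  # and coupling agrees with the flux-range oracle: the interior reactions
  # share one range while the uptake exchange mirrors it with opposite sign
  m <- chain_model(cap = 10)
  fr <- flux_ranges(m, 0)
  inner <- fr[fr$reaction_id != "EX_a", ]
  expect_true(all(abs(inner$min_flux - 0) < 1e-6))
  expect_true(all(abs(inner$max_flux - 10) < 1e-6))
  ex <- fr[fr$reaction_id == "EX_a", ]
  expect_equal(c(ex$min_flux, ex$max_flux), c(-10, 0), tolerance = 1e-6)
})

test_that("free parallel branches split while anticorrelated pairs merge", {
  # free input: the two branch fluxes vary independently -> different sets
  free <- achr_sample(diamond_model(supply = 20, branch_cap = 5),
                      n_warmup = 200, n_points = 400, seed = 7)
  cs_free <- correlated_sets(free)
  sets <- cs_free$sets
  up <- sets$set_id[sets$reaction_id == "R_up"]
  down <- sets$set_id[sets$reaction_id == "R_down"]
  expect_true(length(up) == 0 || length(down) == 0 || up != down)

  # pinned total: v_up + v_down = 8, so the branches are anticorrelated
  # with |rho| = 1 and merge into one set
  m <- diamond_model(supply = 8, branch_cap = 5)
  m <- set_bounds(m, "EX_a", -8, -8)
  pinned <- achr_sample(m, n_warmup = 200, n_points = 400, seed = 7)
  cs_pin <- correlated_sets(pinned)
  s2 <- cs_pin$sets
  expect_equal(s2$set_id[s2$reaction_id == "R_up"],
               s2$set_id[s2$reaction_id == "R_down"])
})

test_that("invariant reactions are excluded into the reported pool", {
  m <- diamond_model(supply = 8, branch_cap = 5)
  m <- set_bounds(m, "EX_a", -8, -8)
  ens <- achr_sample(m, n_warmup = 200, n_points = 100, seed = 2)
  cs <- correlated_sets(ens)
  expect_true(all(c("EX_a", "T_a") %in% cs$invariant))
  expect_error(correlated_sets(structure(list(points = ens$points[1, ,
    drop = FALSE], model_label = "x"), class = "sample_ensemble")),
    "at least 2")
})

test_that("the C4 leaf partitions into more correlated sets than the C3 leaf", {
  cs3 <- correlated_sets(achr_sample(make_toy_c3(), n_warmup = 400,
                                     n_points = 300, seed = 21))
  cs4 <- correlated_sets(achr_sample(make_toy_c4(), n_warmup = 400,
                                     n_points = 300, seed = 21))
  expect_gte(max(cs4$sets$set_id), max(cs3$sets$set_id))
  # the bundle-sheath Calvin cycle forms one coupled module
  calvin <- c("R_prk_bs", "R_tkt1_bs", "R_tkt2_bs", "R_tal_bs")
  sets4 <- cs4$sets[cs4$sets$reaction_id %in% calvin, ]
  expect_equal(length(unique(sets4$set_id)), 1)
})
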