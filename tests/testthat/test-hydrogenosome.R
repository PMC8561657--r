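test_that("formate to acetate+ethanol ratio is exactly 1 without PFO flux", {
  m <- set_bounds(base_model(), "PFO", lower = 0, upper = 0)
  p <- pfba(m)
  expect_equal(formate_ratio(p), 1, tolerance = 1e-6)
  # and in other feasible solutions too (different representative points)
  tr <- hydrogem:::solve_tracking(m, c(EX_lac_e = 0.3, EX_etoh_e = 0.4))
  expect_equal(formate_ratio(tr), 1, tolerance = 1e-6)
})

test_that("forcing PFO flux f makes the ratio F/(F+f) < 1", {
  f <- 0.2
  m <- set_bounds(base_model(), "PFO", lower = f, upper = f)
  p <- pfba(m)
  v <- stats::setNames(p$fluxes$flux, p$fluxes$reaction)
  total_pfl <- unname(v["PFL"] + v["PFLH"])
  expect_equal(formate_ratio(p), total_pfl / (total_pfl + f),
               tolerance = 1e-6)
  expect_lt(formate_ratio(p), 1)
})

test_that("no H2 can be made when PFO is blocked in the base scenario", {
  m <- set_bounds(base_model(), "PFO", lower = 0, upper = 0)
  s <- fba(m, objective = "EX_h2_e")
  expect_equal(s$objective_value, 0, tolerance = 1e-9)
})

test_that("gross production counts only producing terms, per direction", {
  m <- toy_model(list(
    list(id = "in", stoich = c(A_x = 1), kind = "exchange", lb = -10),
    list(id = "r", stoich = c(A_x = -1, B_x = 1), lb = -10),
    list(id = "out", stoich = c(B_x = -1), kind = "exchange", lb = -10)),
    objective = "out")
  m$metabolites$compartment <- "c"
  m$metabolites$id <- c("A_c", "B_c")
  m$stoichiometry$metabolite <- sub("_x$", "_c", m$stoichiometry$metabolite)
  s <- fba(m)
  expect_equal(compartment_production(s, m, "B", "c"), 10)
  expect_equal(compartment_production(s, m, "A", "c"), 10)
  # run the interconversion backward: production flips to the other side
  m2 <- set_bounds(m, "out", lower = -10, upper = -2) # force B uptake
  s2 <- fba(m2, objective = "in")
  v2 <- stats::setNames(s2$fluxes$flux, s2$fluxes$reaction)
  expect_lt(v2[["r"]], 0)
  # the reversed interconversion now produces A; B is produced only by the
  # reversed exchange inflow
  expect_equal(compartment_production(s2, m2, "A", "c"), -v2[["r"]])
  expect_equal(compartment_production(s2, m2, "B", "c"), -v2[["out"]])
})

test_that("the bifurcating scenario grows at least as fast as the base", {
  mu_b <- fba(base_model())$objective_value
  mu_f <- fba(bif_model())$objective_value
  expect_gte(mu_f, mu_b - 1e-9)
  # alongside-mode is a capability superset of both
  mu_k <- fba(nlan_core_model(scenario_config("bifurcating",
                                              keep_ferredoxin = TRUE)))
  expect_gte(mu_k$objective_value, mu_f - 1e-9)
})

test_that("proton module off means zero synthase flux; on allows it", {
  p0 <- pfba(base_model())
  v0 <- stats::setNames(p0$fluxes$flux, p0$fluxes$reaction)
  expect_identical(unname(v0["ATPS"]), 0)
  s1 <- fba(proton_model(), objective = "ATPS")
  expect_gt(s1$objective_value, 0)
})

test_that("Table-style flux constraints concentrate the formate ratio", {
  m <- base_model()
  meas <- nlan_flux_measurements()
  mc <- apply_measured_bounds(m, meas)
  sm_free <- cached("sample300", sample_fluxes(m, n = 300, seed = 9))
  sm_con <- cached("sample300_con", sample_fluxes(mc, n = 300, seed = 9))
  r_free <- formate_ratio(sm_free)$ratio
  r_con <- formate_ratio(sm_con)$ratio
  # constrained ratios live inside the experimentally implied envelope
  lo <- meas$lower_bound[meas$id == "for"] /
    (meas$upper_bound[meas$id == "ac"] + meas$upper_bound[meas$id == "etoh"])
  hi <- meas$upper_bound[meas$id == "for"] /
    (meas$lower_bound[meas$id == "ac"] + meas$lower_bound[meas$id == "etoh"])
  expect_true(all(r_con >= lo - 1e-6 & r_con <= hi + 1e-6))
  expect_lt(diff(range(r_con)), diff(range(r_free)))
})
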