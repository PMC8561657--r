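test_that("pFBA silences a futile two-cycle that plain FBA may carry", {
  m <- toy_model(list(
    list(id = "in", stoich = c(A = 1), kind = "exchange"),
    list(id = "r1", stoich = c(A = -1, B = 1)),
    list(id = "cyc_f", stoich = c(B = -1, C2 = 1)),
    list(id = "cyc_b", stoich = c(C2 = -1, B = 1)),
    list(id = "out", stoich = c(B = -1), kind = "exchange")),
    objective = "out")
  s <- pfba(m)
  expect_equal(s$objective_value, 10, tolerance = 1e-8)
  v <- stats::setNames(s$fluxes$flux, s$fluxes$reaction)
  expect_equal(unname(v["cyc_f"]), 0, tolerance = 1e-8)
  expect_equal(unname(v["cyc_b"]), 0, tolerance = 1e-8)
})

test_that("pFBA attains the FBA optimum at fraction 1 with minimal |v|", {
  m <- base_model()
  f <- fba(m)
  p <- pfba(m)
  expect_equal(p$objective_value, f$objective_value, tolerance = 1e-7)
  # total flux is minimal among sampled feasible points at the same growth
  sm <- cached("pfba_sample",
               sample_fluxes(set_bounds(m, m$objective,
                                        lower = f$objective_value - 1e-9),
                             n = 100, objective_fraction = 1, seed = 5))
  sums <- rowSums(abs(as.matrix(sm$samples)))
  expect_true(all(attr(p, "total_flux") <= sums + 1e-6))
})

test_that("FVA brackets: blocked reactions, biomass at fraction 0.9", {
  m <- base_model()
  f <- fba(m)
  r <- fva(m, objective_fraction = 0.9,
           reactions = c("BIFH", "BIOMASS", "EX_h2_e"))
  expect_equal(r$min_flux[r$reaction == "BIFH"], 0, tolerance = 1e-9)
  expect_equal(r$max_flux[r$reaction == "BIFH"], 0, tolerance = 1e-9)
  expect_equal(r$min_flux[r$reaction == "BIOMASS"],
               0.9 * f$objective_value, tolerance = 1e-6)
  expect_equal(r$max_flux[r$reaction == "BIOMASS"], f$objective_value,
               tolerance = 1e-6)
  expect_true(all(r$min_flux <= r$max_flux + 1e-9))
})

test_that("each diamond branch spans [0, total] at fraction 1", {
  m <- diamond_model()
  r <- fva(m, objective_fraction = 1,
           reactions = c("left", "right"))
  expect_equal(r$min_flux, c(0, 0), tolerance = 1e-8)
  expect_equal(r$max_flux, c(10, 10), tolerance = 1e-8)
})

test_that("pFBA fluxes lie inside every FVA interval at the same fraction", {
  m <- base_model()
  p <- pfba(m, objective_fraction = 0.9)
  some <- c("PFLH", "PFO", "LDH", "EX_for_e", "EX_ac_e", "GAPD", "HEX1")
  r <- fva(m, objective_fraction = 0.9, reactions = some)
  v <- stats::setNames(p$fluxes$flux, p$fluxes$reaction)
  expect_true(all(v[some] >= r$min_flux - 1e-6))
  expect_true(all(v[some] <= r$max_flux + 1e-6))
})

test_that("measured-flux bounds are applied and tighten monotonically", {
  m <- base_model()
  meas <- nlan_flux_measurements()
  mc <- apply_measured_bounds(m, meas)
  rx <- mc$reactions
  expect_equal(rx$lower_bound[rx$id == "EX_h2_e"], 0.05)
  expect_equal(rx$upper_bound[rx$id == "EX_h2_e"], 0.19)
  expect_identical(apply_measured_bounds(m, meas[0, ]), m)
  f0 <- fba(m)$objective_value
  f1 <- fba(mc)$objective_value
  expect_lte(f1, f0 + 1e-9) # constraint tightening never helps
  # widening back restores the unconstrained optimum
  mw <- set_bounds(mc, paste0("EX_", meas$id, "_e"), lower = 0, upper = 1000)
  expect_equal(fba(mw)$objective_value, f0, tolerance = 1e-7)
})

test_that("all carbon uptakes closed leaves maintenance unsatisfiable", {
  m <- base_model()
  elems <- parse_formula(m$metabolites$formula)
  cmet <- m$metabolites$id[elems$C > 0 & m$metabolites$compartment == "e"]
  ex <- m$stoichiometry$reaction[m$stoichiometry$metabolite %in% cmet]
  ex <- intersect(unique(ex), m$reactions$id[m$reactions$kind == "exchange"])
  mc <- set_bounds(m, ex, lower = 0)
  s <- fba(mc)
  expect_true(s$status == "infeasible" ||
                (s$status == "optimal" && s$objective_value < 1e-9))
})

test_that("carbon closure holds in parsimonious solutions", {
  m <- base_model()
  p <- pfba(m)
  v <- stats::setNames(p$fluxes$flux, p$fluxes$reaction)
  elems <- parse_formula(m$metabolites$formula)
  carbon <- stats::setNames(elems$C, m$metabolites$id)
  ex <- m$reactions$id[m$reactions$kind == "exchange"]
  st <- m$stoichiometry[m$stoichiometry$reaction %in% ex, ]
  # exchange coefficient is -1, uptake flux negative: sum(C * coef * v)
  # is carbon inflow minus outflow, which biomass must drain
  net_c <- sum(carbon[st$metabolite] * st$coefficient * v[st$reaction])
  biomass_c <- attr(attr(m, "biomass"), "carbon_drained") * v["BIOMASS"]
  expect_equal(unname(net_c), unname(biomass_c), tolerance = 1e-6)
})
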