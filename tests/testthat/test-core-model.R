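test_that("base scenario wires the hydrogenosome as curated", {
  m <- base_model()
  rx <- m$reactions
  core <- c("PFLH", "PFO", "FDXH2", "H2DH", "ASCT", "SUCOAS", "ME")
  expect_true(all(core %in% rx$id))
  expect_gt(rx$upper_bound[rx$id == "FDXH2"], 0)
  # hydrogen dehydrogenase forward-only: lower bound exactly 0
  expect_identical(rx$lower_bound[rx$id == "H2DH"], 0)
  # speculative reactions are present but bounded to zero
  for (spec_rxn in c("BIFH", "CPLX12", "ATPS")) {
    expect_true(rx$speculative[rx$id == spec_rxn])
    expect_identical(rx$lower_bound[rx$id == spec_rxn], 0)
    expect_identical(rx$upper_bound[rx$id == spec_rxn], 0)
  }
})

test_that("scenario toggles move the intended bounds", {
  mb <- bif_model()
  rx <- mb$reactions
  expect_identical(rx$upper_bound[rx$id == "FDXH2"], 0) # replaced
  expect_gt(rx$upper_bound[rx$id == "BIFH"], 0)
  mk <- nlan_core_model(scenario_config("bifurcating",
                                        keep_ferredoxin = TRUE))
  expect_gt(mk$reactions$upper_bound[mk$reactions$id == "FDXH2"], 0)
  mr <- nlan_core_model(scenario_config(h2_dehydrogenase_reversible = TRUE))
  expect_lt(mr$reactions$lower_bound[mr$reactions$id == "H2DH"], 0)
  expect_error(scenario_config(bifurcating_stoich = c(nadh = 1, fd = 1,
                                                      h2 = 3)),
               "electron balance")
})

test_that("the base model grows at the measured glucose uptake", {
  s <- fba(base_model())
  expect_equal(s$status, "optimal")
  expect_gt(s$objective_value, 1e-3)
})

test_that("deleting zero-bounded speculative reactions leaves optima alone", {
  m <- base_model()
  f0 <- fba(m)$objective_value
  spec_ids <- m$reactions$id[m$reactions$speculative]
  m2 <- m
  m2$reactions <- m2$reactions[!m2$reactions$id %in% spec_ids, ]
  m2$stoichiometry <-
    m2$stoichiometry[!m2$stoichiometry$reaction %in% spec_ids, ]
  expect_equal(fba(m2)$objective_value, f0, tolerance = 1e-9)
})

test_that("ATP yield per glucose is 3 with the ferredoxin hydrogenase and 4
           with the bifurcating hydrogenase", {
  # energy-only audit: biomass closed, maintenance freed, maximize ATP
  # hydrolysis at glucose uptake 1
  energy_cap <- function(m) {
    m <- set_bounds(m, "BIOMASS", lower = 0, upper = 0)
    m <- set_bounds(m, "ATPM", lower = 0, upper = 1000)
    m <- set_bounds(m, "EX_glc_e", lower = -1)
    fba(m, objective = "ATPM")$objective_value
  }
  expect_equal(energy_cap(base_model()), 3, tolerance = 1e-6)
  expect_equal(energy_cap(bif_model()), 4, tolerance = 1e-6)
})

test_that("speculative toggles are logged at INFO when verbose", {
  withr::local_options(hydrogem.verbose = TRUE)
  expect_message(nlan_core_model(scenario_config("bifurcating")),
                 "bifurcating hydrogenase enabled")
})
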