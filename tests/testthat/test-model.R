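test_that("the curated core model passes the balance audit", {
  m <- base_model()
  expect_equal(nrow(check_balance(m)), 0)
})

test_that("a reaction corrupted by removing one water is flagged", {
  m <- base_model()
  # ENO: pg2 -> pep + h2o ; drop the water
  st <- m$stoichiometry
  m$stoichiometry <- st[!(st$reaction == "ENO" & st$metabolite == "h2o_c"), ]
  v <- check_balance(m)
  v <- v[v$reaction == "ENO", ]
  expect_setequal(v$element, c("H", "O"))
  expect_equal(v$imbalance[v$element == "O"], -1)
  expect_equal(v$imbalance[v$element == "H"], -2)
})

test_that("exchange, biomass and maintenance reactions are exempt", {
  m <- base_model()
  v <- check_balance(m)
  expect_false(any(grepl("^EX_", v$reaction)))
  exch <- m$stoichiometry[m$stoichiometry$reaction == "EX_glc_e", ]
  expect_equal(nrow(exch), 1) # touches exactly one extracellular metabolite
  expect_equal(exch$metabolite, "glc_e")
})

test_that("model JSON write/read round trip is exact", {
  m <- base_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m$reactions$lower_bound, m2$reactions$lower_bound)
  expect_identical(m$reactions$upper_bound, m2$reactions$upper_bound)
  o1 <- m$stoichiometry[order(m$stoichiometry$reaction,
                              m$stoichiometry$metabolite), ]
  o2 <- m2$stoichiometry[order(m2$stoichiometry$reaction,
                               m2$stoichiometry$metabolite), ]
  expect_identical(o1$coefficient, o2$coefficient)
  expect_identical(sort(m$metabolites$id), sort(m2$metabolites$id))
  expect_identical(m$objective, m2$objective)
  # and a solved quantity survives the trip
  expect_equal(fba(m2)$objective_value, fba(m)$objective_value,
               tolerance = 1e-9)
})

test_that("malformed model files give pointer-style parse errors", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(id = "x", metabolites = list()), path,
                       auto_unbox = TRUE)
  expect_error(read_model(path), "/reactions")
})

test_that("sole-carbon-source setup scales uptake to glucose equivalents", {
  m <- base_model()
  mg <- set_sole_carbon_source(m, "glc", 1.5)
  rx <- mg$reactions
  expect_equal(rx$lower_bound[rx$id == "EX_glc_e"], -1.5)
  other_sugars <- paste0("EX_", c("fru", "gal", "man", "srb", "xyl",
                                  "cellb", "malt", "sucr", "raff"), "_e")
  expect_true(all(rx$lower_bound[rx$id %in% other_sugars] == 0))
  # cellobiose carries twice the carbon of glucose
  mc <- set_sole_carbon_source(m, "cellb", 1.5)
  expect_equal(mc$reactions$lower_bound[
    mc$reactions$id == "EX_cellb_e"], -0.75)
  # vitamin exchanges are untouched
  expect_equal(mg$reactions$lower_bound[mg$reactions$id == "EX_btn_e"], -1)
  expect_error(set_sole_carbon_source(m, "unknownose", 1),
               "unknown substrate")
})

test_that("constructor enforces the model invariants", {
  mets <- tibble::tibble(id = c("a_c", "a_c"), name = "a", formula = "",
                         charge = 0, compartment = "c")
  rx <- tibble::tibble(id = "r", name = "r", lower_bound = 0,
                       upper_bound = 1, kind = "internal", subsystem = "",
                       speculative = FALSE, confidence = 0L,
                       gene_association = NA_character_)
  st <- tibble::tibble(reaction = "r", metabolite = "a_c", coefficient = 1)
  expect_error(metabolic_model(mets, rx, st, "r"), "duplicate metabolite")
  mets2 <- mets[1, ]
  expect_error(metabolic_model(mets2, rx, st, "missing"), "objective")
  mets3 <- mets2; mets3$compartment <- "m"
  expect_error(metabolic_model(mets3, rx, st, "r"), "compartment")
  rx2 <- rx; rx2$lower_bound <- 2
  expect_error(metabolic_model(mets2, rx2, st, "r"), "lower_bound")
})
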