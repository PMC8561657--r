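make_exp <- function(mu, amounts, dm = c(0.02, 0.05), level = 5) {
  growth_experiment(substrate_level = level, timepoints = c(0, 24),
                    amounts = amounts, dry_mass = dm, growth_rate = mu)
}

test_that("specific fluxes follow the stated difference formula", {
  e <- make_exp(0.04, tibble::tibble(id = "ac", amount_t1 = 0,
                                     amount_t2 = 1),
                dm = c(0.05, 0.10))
  fl <- compute_specific_fluxes(e)
  expect_equal(fl$flux, 1 / (24 * 0.05), tolerance = 1e-12) # 0.833
  # zero accumulation gives zero flux
  e0 <- make_exp(0.04, tibble::tibble(id = "ac", amount_t1 = 0.4,
                                      amount_t2 = 0.4))
  expect_equal(compute_specific_fluxes(e0)$flux, 0)
  # shrinking biomass is rejected
  ebad <- growth_experiment(5, c(0, 24),
                            tibble::tibble(id = "ac", amount_t1 = 0,
                                           amount_t2 = 1),
                            dry_mass = c(0.1, 0.1), growth_rate = 0.01)
  expect_error(compute_specific_fluxes(ebad), "dry mass must increase")
})

test_that("OLS slope and intercept match the closed-form normal equations", {
  fit <- fit0()
  x <- fit$points$growth_rate; y <- fit$points$max_atp
  slope <- (mean(x * y) - mean(x) * mean(y)) / (mean(x^2) - mean(x)^2)
  intercept <- mean(y) - slope * mean(x)
  expect_equal(fit$gam, slope, tolerance = 1e-10)
  expect_equal(fit$ngam, intercept, tolerance = 1e-10)
  expect_gt(fit$r_squared, 0.999)
})

test_that("noiseless synthetic data recovers the generating maintenance", {
  fit <- fit0()
  expect_equal(fit$gam, 75.98, tolerance = 0.01)   # within 1%
  expect_equal(fit$ngam, 2.27, tolerance = 0.05)   # within 5%
})

test_that("two points lying exactly on a line are fit exactly", {
  # bypass the LP: fabricate a degenerate two-experiment fit via lm on the
  # same code path
  p <- tibble::tibble(growth_rate = c(0.01, 0.03),
                      max_atp = 2 + 50 * c(0.01, 0.03))
  cf <- stats::coef(stats::lm(max_atp ~ growth_rate, data = p))
  expect_equal(unname(cf), c(2, 50), tolerance = 1e-12)
  # equal growth rates are rejected before any LP work
  e1 <- make_exp(0.02, tibble::tibble(id = "ac", amount_t1 = 0,
                                      amount_t2 = 1))
  expect_error(fit_maintenance(gen_model(), list(e1, e1)),
               "rank-deficient")
})

test_that("max-ATP flux is monotone in the substrate uptake bound", {
  m <- gen_model()
  m <- set_bounds(m, "BIOMASS", lower = 0, upper = 0)
  m <- set_bounds(m, "ATPM", lower = 0, upper = 1000)
  caps <- vapply(c(0.5, 1, 1.5), function(u) {
    fba(set_sole_carbon_source(m, "cellb", u), objective = "ATPM")$objective_value
  }, numeric(1))
  expect_true(all(diff(caps) > 0))
})

test_that("bootstrap intervals cover the point estimates", {
  fit <- fit0()
  ci <- maintenance_bootstrap(fit, n = 200, seed = 2)
  expect_true(ci$lower[1] <= fit$gam && fit$gam <= ci$upper[1])
  expect_true(ci$lower[2] <= fit$ngam && fit$ngam <= ci$upper[2])
})
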