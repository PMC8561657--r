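test_that("identical generator specifications give identical datasets", {
  des <- cached("design", growth_experiment_design(
    generator_spec(seed = 1, noise_cv = 0)))
  s <- generator_spec(seed = 42, noise_cv = 0.05)
  e1 <- generate_growth_experiments(s, design = des)
  e2 <- generate_growth_experiments(s, design = des)
  expect_identical(serialize(e1, NULL), serialize(e2, NULL))
  e3 <- generate_growth_experiments(generator_spec(seed = 43,
                                                   noise_cv = 0.05),
                                    design = des)
  expect_false(identical(e1[[1]]$amounts, e3[[1]]$amounts))
})

test_that("generated experiments are valid inputs for the fitting stage", {
  des <- cached("design", growth_experiment_design(
    generator_spec(seed = 1, noise_cv = 0)))
  exps <- generate_growth_experiments(generator_spec(seed = 3), design = des)
  expect_length(exps, 5)
  for (e in exps) {
    expect_s3_class(e, "growth_experiment")
    expect_true(all(e$amounts$amount_t1 >= 0))
    expect_gt(diff(e$dry_mass), 0)
    expect_gt(e$growth_rate, 0)
  }
  mus <- vapply(exps, `[[`, numeric(1), "growth_rate")
  expect_true(all(diff(mus) > 0)) # growth rises with substrate level
})

test_that("flux-table generation mirrors observed-range bound semantics", {
  means <- c(ac = 0.56, h2 = 0.10)
  # sd = 0 collapses the interval onto the mean
  t0 <- generate_flux_measurements(means, c(ac = 0, h2 = 0),
                                   generator_spec(seed = 5))
  expect_equal(t0$lower_bound, t0$mean)
  expect_equal(t0$upper_bound, t0$mean)
  # negative draws are truncated at zero
  tneg <- generate_flux_measurements(c(x = 0.01), c(x = 1),
                                     generator_spec(seed = 6,
                                                    n_replicates = 20))
  expect_gte(tneg$lower_bound, 0)
})

test_that("generated intervals overlap the measured table for most seeds", {
  ref <- nlan_flux_measurements()
  means <- stats::setNames(ref$mean, ref$id)
  sds <- stats::setNames(ref$sd, ref$id)
  hits <- 0L; total <- 0L
  for (seed in 1:40) {
    g <- generate_flux_measurements(means, sds,
                                    generator_spec(seed = seed))
    for (i in seq_len(nrow(ref))) {
      total <- total + 1L
      gi <- g[g$id == ref$id[i], ]
      if (gi$lower_bound <= ref$upper_bound[i] &&
          gi$upper_bound >= ref$lower_bound[i]) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("generated MIDs are reproducible and collapse to truth at zero
           noise", {
  net_def <- mfa_network_core()
  net <- emu_net()
  theta <- c(pfo = 0.1, pepck = 0.1, me = 0.05, ldh = 0.5, etoh = 0.4,
             fumx = 0.1)
  fl <- net_def$flux_fn(theta)
  tr <- tracer_spec()
  m0 <- generate_mids(net, fl$fluxes, tr,
                      generator_spec(seed = 2, noise_cv = 0,
                                     n_replicates = 1))
  sim <- simulate_mids(net, fl$fluxes, tr)
  for (id in unique(m0$emu)) {
    expect_equal(m0$fraction[m0$emu == id], unname(sim[[id]]),
                 tolerance = 1e-12)
  }
  m1 <- generate_mids(net, fl$fluxes, tr, generator_spec(seed = 2))
  m2 <- generate_mids(net, fl$fluxes, tr, generator_spec(seed = 2))
  expect_identical(m1, m2)
  # noisy fractions stay simplex-valid
  expect_true(all(m1$fraction >= 0))
  sums <- tapply(m1$fraction, paste(m1$emu, m1$replicate), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
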