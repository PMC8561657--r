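# Synthetic-data generators: growth experiments for maintenance fitting,
# measured-flux tables, and labeled MID datasets.

#' Generator specification
#'
#' @param seed Integer seed; identical specifications generate identical
#'   datasets.
#' @param noise_cv Coefficient of variation of measurement noise
#'   (multiplicative lognormal on amounts, default 0.05).
#' @param n_replicates Replicates per condition (used by the flux-table and
#'   MID generators).
#' @param substrate_levels Initial cellobiose concentrations, g/L.
#' @param gam,ngam Ground-truth maintenance parameters embedded in the
#'   generating model (mmol ATP/gDW and mmol ATP/gDW/h).
#' @param uptake_max,uptake_k Monod-type map from substrate level to
#'   glucose-equivalent uptake, `u = uptake_max * level / (uptake_k + level)`
#'   mmol/gDW/h. Defaults reproduce the measured 1.5 mmol/gDW/h glucose
#'   equivalent at the 5 g/L reference condition while keeping growth
#'   positive at 1 g/L; only monotonicity matters to the fit.
#' @param volume Culture liquid volume, L.
#' @param initial_dry_mass Dry mass at the first sampling point, g.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(seed = 1L, noise_cv = 0.05, n_replicates = 3L,
                           substrate_levels = c(1, 2, 3, 4, 5),
                           gam = 75.98, ngam = 2.27,
                           uptake_max = 1.8, uptake_k = 1,
                           volume = 0.04, initial_dry_mass = 0.02) {
  stopifnot(noise_cv >= 0, all(substrate_levels > 0),
            !anyDuplicated(substrate_levels))
  structure(list(seed = as.integer(seed), noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates),
                 substrate_levels = substrate_levels,
                 gam = gam, ngam = ngam, uptake_max = uptake_max,
                 uptake_k = uptake_k, volume = volume,
                 initial_dry_mass = initial_dry_mass),
            class = "generator_spec")
}

#' Noise-free design of the cellobiose-gradient experiment
#'
#' For each substrate level, converts the level to a glucose-equivalent
#' uptake bound (Monod map), solves FBA for the growth rate, and picks a
#' representative near-optimal flux distribution whose fermentation-product
#' profile tracks the measured-flux table scaled to the uptake. This is the
#' deterministic part of the growth-experiment generator and can be reused
#' across noise replicates.
#'
#' @param spec A [generator_spec()].
#' @param model Optional generating model; by default the base core model is
#'   built with the spec's ground-truth GAM/NGAM.
#' @return A tibble with one row per level: `level`, `uptake`, `growth_rate`
#'   and a list-column `fluxes` (named exchange fluxes, mmol/gDW/h).
#' @export
growth_experiment_design <- function(spec = generator_spec(), model = NULL) {
  if (is.null(model)) {
    model <- nlan_core_model(
      composition = biomass_composition(gam = spec$gam, ngam = spec$ngam))
  }
  ref <- nlan_flux_measurements()
  purrr::map_dfr(spec$substrate_levels, function(level) {
    u <- spec$uptake_max * level / (spec$uptake_k + level)
    m <- set_sole_carbon_source(model, "cellb", u)
    s <- fba(m)
    if (s$status != "optimal" || s$objective_value <= 0) {
      stop("generating model does not grow at level ", level, " g/L",
           call. = FALSE)
    }
    mu <- s$objective_value
    targets <- stats::setNames(ref$mean * u / 1.5,
                               paste0("EX_", ref$id, "_e"))
    tr <- solve_tracking(m, targets,
                         fix = stats::setNames(list(mu), model$objective))
    fl <- stats::setNames(tr$fluxes$flux, tr$fluxes$reaction)
    keep <- c(paste0("EX_", ref$id, "_e"), "EX_cellb_e")
    tibble::tibble(level = level, uptake = u, growth_rate = mu,
                   fluxes = list(fl[keep]))
  })
}

#' Generate synthetic cellobiose-gradient growth experiments
#'
#' Emits two-timepoint (24 h apart) growth experiments consistent with the
#' generating model at the spec's ground-truth GAM/NGAM: product amounts are
#' constructed so that the difference estimator of [compute_specific_fluxes()]
#' recovers the generating fluxes exactly at zero noise, then multiplicative
#' lognormal noise at `noise_cv` is applied to every measured amount. Dry
#' masses and the pressure-derived growth rate are taken as given
#' (noise-free), matching how they are obtained in practice.
#'
#' @param spec A [generator_spec()].
#' @param model Optional generating model (see [growth_experiment_design()]).
#' @param design Optional precomputed design, to amortize the LP solves over
#'   many noise replicates.
#' @return A list of [growth_experiment()] objects; the attribute
#'   `ground_truth` records the generating GAM/NGAM.
#' @export
generate_growth_experiments <- function(spec = generator_spec(),
                                        model = NULL, design = NULL) {
  if (is.null(design)) design <- growth_experiment_design(spec, model)
  set.seed(spec$seed)
  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  mw_cellb <- formula_weight("C12H22O11")
  exps <- lapply(seq_len(nrow(design)), function(i) {
    mu <- design$growth_rate[i]
    fl <- design$fluxes[[i]]
    m1 <- spec$initial_dry_mass
    m2 <- m1 * exp(mu * 24)
    dm <- m2 - m1
    ids <- sub("^EX_(.*)_e$", "\\1", names(fl))
    delta <- unname(fl) * 24 * dm
    a1 <- ifelse(delta >= 0, 0.5 * delta,
                 design$level[i] * spec$volume * 1000 / mw_cellb)
    a2 <- a1 + delta
    if (any(a2 < 0)) stop("substrate depleted below zero in design",
                          call. = FALSE)
    if (spec$noise_cv > 0) {
      a1 <- a1 * exp(stats::rnorm(length(a1), 0, sdlog))
      a2 <- a2 * exp(stats::rnorm(length(a2), 0, sdlog))
    }
    growth_experiment(
      substrate_level = design$level[i],
      timepoints = c(0, 24),
      amounts = tibble::tibble(id = ids, amount_t1 = a1, amount_t2 = a2),
      dry_mass = c(m1, m2),
      growth_rate = mu)
  })
  attr(exps, "ground_truth") <- c(gam = spec$gam, ngam = spec$ngam)
  exps
}

#' Generate a measured-flux table from means and SDs
#'
#' Draws `n_replicates` rates per product from a normal distribution
#' truncated at zero; the reported bounds are the min/max of the replicate
#' draws (mirroring how observed ranges bound measured fluxes).
#'
#' @param means,sds Named numeric vectors (names are base metabolite ids).
#' @param spec A [generator_spec()] (supplies `seed` and `n_replicates`).
#' @return A tibble with columns `id`, `mean`, `sd`, `lower_bound`,
#'   `upper_bound`.
#' @export
generate_flux_measurements <- function(means, sds, spec = generator_spec()) {
  stopifnot(length(means) == length(sds), !is.null(names(means)))
  set.seed(spec$seed)
  purrr::map_dfr(names(means), function(id) {
    draws <- pmax(stats::rnorm(spec$n_replicates, means[[id]], sds[[id]]), 0)
    tibble::tibble(id = id, mean = mean(draws), sd = stats::sd(draws),
                   lower_bound = min(draws), upper_bound = max(draws))
  })
}

#' Generate noisy mass-isotopomer measurements
#'
#' Simulates steady-state MIDs with [simulate_mids()], then adds additive
#' Gaussian noise to the fractions, truncates at zero and renormalizes each
#' distribution; the reported SE is the noise SD (floored for weighting).
#'
#' @param network An EMU network from [emu_decompose()].
#' @param fluxes Named flux vector for the network's reactions.
#' @param tracer A [tracer_spec()].
#' @param spec A [generator_spec()]; `noise_cv` is used as the additive SD
#'   on mole fractions.
#' @return A tibble with columns `emu`, `mass`, `fraction`, `se`,
#'   `replicate`.
#' @export
generate_mids <- function(network, fluxes, tracer, spec = generator_spec()) {
  mids <- simulate_mids(network, fluxes, tracer)
  set.seed(spec$seed)
  sd <- spec$noise_cv
  purrr::map_dfr(seq_len(spec$n_replicates), function(rep) {
    purrr::map_dfr(names(mids), function(id) {
      x <- mids[[id]]
      if (sd > 0) {
        x <- pmax(x + stats::rnorm(length(x), 0, sd), 0)
        x <- x / sum(x)
      }
      tibble::tibble(emu = id, mass = seq_along(x) - 1L, fraction = x,
                     se = max(sd, 1e-3), replicate = rep)
    })
  })
}
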