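# Scenario analyses of hydrogenosomal energy metabolism.

#' Gross production of a metabolite in a compartment
#'
#' Sums, per flux vector, the positive stoichiometric contributions to the
#' metabolite in the given compartment (production only; consumption is not
#' netted against it, and a reversible reaction running backward counts
#' toward production of the opposite side). For a `flux_sample` the mean
#' over samples is returned.
#'
#' @param x A `flux_sample` or `flux_solution`.
#' @param model The model the fluxes belong to.
#' @param metabolite Base metabolite id (e.g. `"nad"`, `"atp"`).
#' @param compartment `"c"` or `"h"` (or `"e"`).
#' @return Mean gross production flux (mmol/gDW/h).
#' @export
compartment_production <- function(x, model, metabolite, compartment) {
  met <- paste0(metabolite, "_", compartment)
  st <- model$stoichiometry[model$stoichiometry$metabolite == met, ]
  if (!nrow(st)) return(0)
  if (inherits(x, "flux_solution")) {
    v <- stats::setNames(x$fluxes$flux, x$fluxes$reaction)
    return(sum(pmax(st$coefficient * v[st$reaction], 0)))
  }
  stopifnot(inherits(x, "flux_sample"))
  V <- as.matrix(x$samples[, st$reaction, drop = FALSE])
  contrib <- sweep(V, 2, st$coefficient, `*`)
  mean(rowSums(pmax(contrib, 0)))
}

#' Compare hydrogenosome scenarios
#'
#' Rebuilds the core model for each scenario configuration, solves FBA for
#' the growth rate, samples fluxes at `objective_fraction` of the optimum,
#' and summarizes compartment-wise gross NAD+ and ATP production and the
#' sampled H2 secretion range.
#'
#' @param configs Named list of [scenario_config()] objects.
#' @param composition,distribution Biomass inputs shared by all scenarios.
#' @param n Samples per scenario.
#' @param objective_fraction Optimality fraction for sampling (default 0.9).
#' @param seed Integer seed.
#' @param sample If `FALSE`, skip sampling (growth rates only).
#' @return A `scenario_comparison`: tibble with one row per scenario and
#'   columns `scenario`, `growth_rate`, `h2_min`, `h2_max` and per-compartment
#'   production columns.
#' @export
compare_scenarios <- function(configs = list(base = scenario_config(),
                                             bifurcating =
                                               scenario_config("bifurcating")),
                              composition = biomass_composition(),
                              distribution = monomer_distribution(),
                              n = 2000, objective_fraction = 0.9, seed = 1L,
                              sample = TRUE) {
  stopifnot(is.list(configs), length(names(configs)) == length(configs))
  res <- purrr::map_dfr(names(configs), function(nm) {
    model <- nlan_core_model(configs[[nm]], composition, distribution)
    s <- fba(model)
    row <- tibble::tibble(scenario = nm, growth_rate = s$objective_value)
    if (sample) {
      sm <- sample_fluxes(model, n = n,
                          objective_fraction = objective_fraction,
                          seed = seed)
      h2 <- sm$samples[["EX_h2_e"]]
      row$h2_min <- min(h2); row$h2_max <- max(h2)
      for (met in c("nad", "atp")) {
        for (comp in c("c", "h")) {
          row[[paste0(met, "_", comp, "_production")]] <-
            compartment_production(sm, model, met, comp)
        }
      }
      row$atps_flux <- if ("ATPS" %in% names(sm$samples)) {
        mean(sm$samples[["ATPS"]])
      } else 0
    }
    row
  })
  structure(res, class = c("scenario_comparison", class(res)))
}

#' Formate to (acetate + ethanol) molar ratio
#'
#' The stoichiometric signature of pyruvate formate lyase dominance: every
#' acetyl-CoA made by PFL co-produces one formate, and acetate and ethanol
#' are the only acetyl-CoA sinks, so the secreted molar ratio
#' formate/(acetate + ethanol) equals exactly 1 when PFO carries no flux and
#' falls below 1 as PFO (which releases CO2 instead of formate) takes over.
#'
#' @param x A `flux_solution` or `flux_sample`.
#' @return For a solution, a single ratio; for a sample, a tibble of
#'   per-sample ratios plus `summary` attribute (min/median/max).
#' @export
formate_ratio <- function(x) {
  if (inherits(x, "flux_solution")) {
    v <- stats::setNames(x$fluxes$flux, x$fluxes$reaction)
    return(unname(v["EX_for_e"] / (v["EX_ac_e"] + v["EX_etoh_e"])))
  }
  stopifnot(inherits(x, "flux_sample"))
  r <- x$samples[["EX_for_e"]] /
    (x$samples[["EX_ac_e"]] + x$samples[["EX_etoh_e"]])
  out <- tibble::tibble(sample = seq_along(r), ratio = r)
  attr(out, "summary") <- c(min = min(r), median = stats::median(r),
                            max = max(r))
  out
}

#' Sensitivity of prediction error to single measured-flux constraints
#'
#' For each measured product, constrains only that product's exchange to its
#' measured interval, samples fluxes at near-optimal growth, and reports the
#' absolute relative error of the sample-mean predicted flux of every
#' product against its measured mean.
#'
#' @param model A solvable core model.
#' @param measurements Measured-flux table (see [nlan_flux_measurements()]);
#'   the `products` subset is analysed.
#' @param products Base ids of the products to constrain/score (default the
#'   five fermentation products).
#' @param n Samples per constraint condition.
#' @param objective_fraction Optimality fraction (default 0.9).
#' @param seed Integer seed.
#' @param aggregate `"mean"` (default) or `"median"` sample aggregator.
#' @return A tibble with columns `constraint`, `product`, `predicted`,
#'   `measured`, `rel_error`, plus rows `constraint = "none"` for the
#'   unconstrained model; class `constraint_sensitivity`.
#' @export
constraint_sensitivity <- function(model,
                                   measurements = nlan_flux_measurements(),
                                   products = c("ac", "etoh", "for", "h2",
                                                "lac"),
                                   n = 2000, objective_fraction = 0.9,
                                   seed = 1L,
                                   aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else stats::median
  meas <- measurements[measurements$id %in% products, ]
  score_one <- function(constraint, m) {
    sm <- sample_fluxes(m, n = n, objective_fraction = objective_fraction,
                        seed = seed)
    purrr::map_dfr(seq_len(nrow(meas)), function(i) {
      pred <- agg(sm$samples[[paste0("EX_", meas$id[i], "_e")]])
      tibble::tibble(constraint = constraint, product = meas$id[i],
                     predicted = pred, measured = meas$mean[i],
                     rel_error = abs(pred - meas$mean[i]) / meas$mean[i])
    })
  }
  out <- score_one("none", model)
  for (i in seq_len(nrow(meas))) {
    mc <- apply_measured_bounds(model, meas[i, ])
    out <- dplyr::bind_rows(out, score_one(meas$id[i], mc))
  }
  structure(out, class = c("constraint_sensitivity", class(out)))
}
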