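# Maintenance-energy (GAM/NGAM) estimation from growth experiments.

#' A single growth experiment on a cellobiose gradient
#'
#' @param substrate_level Initial cellobiose concentration, g/L.
#' @param timepoints Two sampling times in hours (default 0 and 24; the
#'   second sample is taken 24 h after the first, both in exponential phase).
#' @param amounts Tibble with columns `id`, `amount_t1`, `amount_t2`:
#'   culture-wide amounts (mmol) of each measured compound at the two
#'   timepoints (fermentation products positive accumulation; the substrate
#'   row records depletion so its accumulation is negative; headspace H2 is
#'   included as `h2`).
#' @param dry_mass Dry cell mass (g) at the two timepoints.
#' @param growth_rate Pressure-derived specific growth rate, 1/h (taken as
#'   given; the pressure-to-growth transformation is out of scope).
#' @return A `growth_experiment` object.
#' @export
growth_experiment <- function(substrate_level, timepoints = c(0, 24),
                              amounts, dry_mass, growth_rate) {
  stopifnot(length(timepoints) == 2, length(dry_mass) == 2)
  if (diff(timepoints) <= 0) stop("timepoints must be increasing",
                                  call. = FALSE)
  if (growth_rate <= 0) stop("growth_rate must be > 0", call. = FALSE)
  structure(list(substrate_level = substrate_level,
                 timepoints = timepoints,
                 amounts = tibble::as_tibble(amounts),
                 dry_mass = dry_mass,
                 growth_rate = growth_rate),
            class = "growth_experiment")
}

#' Specific fluxes from a two-timepoint growth experiment
#'
#' The specific flux of each compound is its molar accumulation divided by
#' the time between measurements and the difference in cell dry masses
#' (mmol/gDW/h). The dry-mass difference is used because lysed mature cells
#' no longer contribute to metabolism.
#'
#' @param experiment A [growth_experiment()].
#' @return A tibble with columns `id`, `flux` (negative = consumption).
#' @export
compute_specific_fluxes <- function(experiment) {
  stopifnot(inherits(experiment, "growth_experiment"))
  dt <- diff(experiment$timepoints)
  dm <- diff(experiment$dry_mass)
  if (dm <= 0) {
    stop("dry mass must increase between timepoints (lysed biomass no ",
         "longer contributes to metabolism)", call. = FALSE)
  }
  a <- experiment$amounts
  tibble::tibble(id = a$id,
                 flux = (a$amount_t2 - a$amount_t1) / (dt * dm))
}

#' Estimate GAM and NGAM by maximum-ATP-yield regression
#'
#' For each experiment the measured product fluxes are applied as secretion
#' caps (and the substrate flux as an uptake cap), biomass flux is fixed to
#' zero so the ATP cost of growth is not double-counted, and the cytosolic
#' ATP-hydrolysis demand (`ATPM`) is maximized. Ordinary least squares of
#' the maximum ATP yield against the pressure-derived growth rate gives the
#' growth-associated maintenance as the slope and the non-growth-associated
#' maintenance as the intercept.
#'
#' @param model A core model (the maintenance parameters embedded in it do
#'   not influence the fit: the ATP-demand bound is released and biomass is
#'   closed during the solves).
#' @param experiments A list of [growth_experiment()] objects with at least
#'   two distinct growth rates.
#' @param substrate Base id of the growth substrate (default cellobiose).
#' @return A `maintenance_fit` object with elements `gam`, `ngam`,
#'   `r_squared`, `points` (tibble of growth rate vs maximum ATP yield) and
#'   the underlying `lm` fit. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
fit_maintenance <- function(model, experiments, substrate = "cellb") {
  stopifnot(length(experiments) >= 2)
  mu <- vapply(experiments, function(e) e$growth_rate, numeric(1))
  if (length(unique(round(mu, 12))) < 2) {
    stop("rank-deficient regression: all growth rates are equal",
         call. = FALSE)
  }
  base <- set_bounds(model, model$objective, lower = 0, upper = 0)
  base <- set_bounds(base, "ATPM", lower = 0, upper = BIG)
  atp <- vapply(experiments, function(e) {
    fl <- compute_specific_fluxes(e)
    m <- base
    for (i in seq_len(nrow(fl))) {
      ex <- paste0("EX_", fl$id[i], "_e")
      if (!ex %in% m$reactions$id) {
        stop("no exchange reaction for measured compound: ", fl$id[i],
             call. = FALSE)
      }
      if (fl$flux[i] >= 0) {
        m <- set_bounds(m, ex, lower = 0, upper = fl$flux[i])
      } else {
        m <- set_bounds(m, ex, lower = fl$flux[i], upper = 0)
      }
    }
    s <- fba(m, objective = "ATPM")
    if (s$status != "optimal") {
      stop("max-ATP solve not optimal (", s$status, ") for experiment at ",
           e$substrate_level, " g/L", call. = FALSE)
    }
    s$objective_value
  }, numeric(1))
  points <- tibble::tibble(growth_rate = mu, max_atp = atp)
  fit <- stats::lm(max_atp ~ growth_rate, data = points)
  cf <- stats::coef(fit)
  structure(list(gam = unname(cf[["growth_rate"]]),
                 ngam = unname(cf[["(Intercept)"]]),
                 r_squared = summary(fit)$r.squared,
                 residuals = stats::residuals(fit),
                 points = points, fit = fit),
            class = "maintenance_fit")
}

#' @export
print.maintenance_fit <- function(x, ...) {
  cat("<maintenance_fit> GAM = ", round(x$gam, 3),
      " mmol ATP/gDW;  NGAM = ", round(x$ngam, 3),
      " mmol ATP/gDW/h;  R^2 = ", round(x$r_squared, 4), "\n", sep = "")
  invisible(x)
}

#' Bootstrap confidence intervals for a maintenance fit
#'
#' Case-resampling bootstrap over experiments (an extension beyond the OLS
#' point estimate; the regression itself reports no interval).
#'
#' @param fit A `maintenance_fit`.
#' @param n Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return A tibble with `term`, `lower`, `upper`.
#' @export
maintenance_bootstrap <- function(fit, n = 1000, level = 0.95, seed = 1L) {
  stopifnot(inherits(fit, "maintenance_fit"))
  set.seed(seed)
  p <- fit$points
  draws <- vapply(seq_len(n), function(i) {
    idx <- sample.int(nrow(p), replace = TRUE)
    if (length(unique(p$growth_rate[idx])) < 2) return(c(NA, NA))
    cf <- stats::coef(stats::lm(max_atp ~ growth_rate, data = p[idx, ]))
    c(cf[["growth_rate"]], cf[["(Intercept)"]])
  }, numeric(2))
  a <- (1 - level) / 2
  tibble::tibble(
    term = c("gam", "ngam"),
    lower = apply(draws, 1, stats::quantile, probs = a, na.rm = TRUE),
    upper = apply(draws, 1, stats::quantile, probs = 1 - a, na.rm = TRUE))
}
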