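# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method generics::tidy
tidy.flux_solution <- function(x, ...) x$fluxes

#' @exportS3Method generics::glance
glance.flux_solution <- function(x, ...) {
  tibble::tibble(status = x$status, objective_value = x$objective_value,
                 kind = x$kind)
}

#' @exportS3Method generics::tidy
tidy.maintenance_fit <- function(x, ...) {
  tibble::tibble(term = c("gam", "ngam"),
                 estimate = c(x$gam, x$ngam),
                 units = c("mmol ATP/gDW", "mmol ATP/gDW/h"))
}

#' @exportS3Method generics::glance
glance.maintenance_fit <- function(x, ...) {
  tibble::tibble(gam = x$gam, ngam = x$ngam, r_squared = x$r_squared,
                 n_experiments = nrow(x$points))
}

#' @exportS3Method generics::tidy
tidy.mfa_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par),
                 identifiable = x$identifiability$identifiable[
                   match(names(x$par), x$identifiability$parameter)])
}

#' @exportS3Method generics::glance
glance.mfa_fit <- function(x, ...) {
  tibble::tibble(ssr = x$ssr, convergence = x$convergence,
                 n_parameters = length(x$par))
}

#' @exportS3Method generics::tidy
tidy.flux_sample <- function(x, ...) {
  tidyr::pivot_longer(x$samples, cols = dplyr::everything(),
                      names_to = "reaction", values_to = "flux")
}

#' @exportS3Method ggplot2::autoplot
autoplot.maintenance_fit <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$growth_rate, y = .data$max_atp)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$gam, intercept = object$ngam,
                         linetype = 2) +
    ggplot2::labs(x = expression(paste("growth rate ", mu, " (1/h)")),
                  y = "maximum ATP yield (mmol/gDW/h)",
                  title = sprintf("GAM = %.2f mmol ATP/gDW, NGAM = %.2f mmol ATP/gDW/h",
                                  object$gam, object$ngam))
}

#' @exportS3Method ggplot2::autoplot
autoplot.flux_sample <- function(object, reactions = NULL, ...) {
  df <- tidy.flux_sample(object)
  if (!is.null(reactions)) df <- df[df$reaction %in% reactions, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$flux)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::facet_wrap(~reaction, scales = "free") +
    ggplot2::labs(x = "flux (mmol/gDW/h)", y = "samples")
}

#' @exportS3Method ggplot2::autoplot
autoplot.scenario_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object, cols = dplyr::ends_with("_production"),
    names_to = "pool", values_to = "production")
  df$pool <- sub("_production$", "", df$pool)
  df <- tidyr::separate(df, "pool", into = c("metabolite", "compartment"),
                        sep = "_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario,
                                   y = .data$production,
                                   fill = .data$compartment)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metabolite, scales = "free_y") +
    ggplot2::labs(y = "mean gross production (mmol/gDW/h)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.constraint_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$constraint,
                                       y = .data$rel_error,
                                       fill = .data$product)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "constrained product", y = "absolute relative error")
}

#' @exportS3Method ggplot2::autoplot
autoplot.flux_ranges <- function(object, reactions = NULL, ...) {
  df <- object
  if (!is.null(reactions)) df <- df[df$reaction %in% reactions, ]
  ggplot2::ggplot(df, ggplot2::aes(y = stats::reorder(.data$reaction,
                                                      .data$max_flux))) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$min_flux,
                                         xmax = .data$max_flux)) +
    ggplot2::labs(x = "flux range (mmol/gDW/h)", y = NULL)
}

#' @importFrom rlang .data
NULL
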