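# Qualitative substrate-utilization / vitamin-essentiality validation.

GROWTH_THRESHOLD <- 1e-4 # h^-1; in-silico growth call threshold

#' Predict growth on a sole carbon source
#'
#' Closes every other carbon uptake, sets the substrate uptake to
#' `uptake_limit` in glucose-carbon equivalents, and runs FBA; the call is
#' `"+"` iff the predicted growth rate exceeds `threshold`.
#'
#' @param model A solvable `metabolic_model` (with maintenance attached).
#' @param substrate Base id of the substrate (e.g. `"xyl"`).
#' @param uptake_limit Glucose-equivalent uptake, mmol/gDW/h.
#' @param threshold Growth-call threshold in 1/h.
#' @return `"+"` or `"-"`.
#' @export
predict_carbon_growth <- function(model, substrate, uptake_limit = 1.5,
                                  threshold = GROWTH_THRESHOLD) {
  m <- set_sole_carbon_source(model, substrate, uptake_limit)
  s <- fba(m)
  if (s$status == "optimal" && s$objective_value > threshold) "+" else "-"
}

#' Predict vitamin essentiality by omission
#'
#' Closes the vitamin's uptake exchange and runs FBA. Returns `"+"` if growth
#' persists without the vitamin (it is dispensable, e.g. synthesized de
#' novo), `"-"` if growth is abolished (the vitamin is essential).
#'
#' @param model A solvable `metabolic_model`.
#' @param vitamin Base id of the vitamin (e.g. `"btn"`, `"pheme"`).
#' @param threshold Growth-call threshold in 1/h.
#' @return `"+"` or `"-"`.
#' @export
predict_vitamin_essentiality <- function(model, vitamin,
                                         threshold = GROWTH_THRESHOLD) {
  ex <- paste0("EX_", vitamin, "_e")
  if (!ex %in% model$reactions$id) {
    stop("unknown vitamin (no exchange reaction): ", vitamin, call. = FALSE)
  }
  s <- fba(set_bounds(model, ex, lower = 0))
  if (s$status == "optimal" && s$objective_value > threshold) "+" else "-"
}

#' Run the full utilization battery through the model
#'
#' Computes the model's growth/essentiality call for every test in the
#' battery (one FBA per carbon source, one per vitamin).
#'
#' @param model A solvable `metabolic_model`.
#' @param tests Test table as from [nlan_utilization_tests()].
#' @param uptake_limit Glucose-equivalent uptake for carbon tests.
#' @param threshold Growth-call threshold in 1/h.
#' @return The test tibble with an added `model_call` column.
#' @export
run_utilization_battery <- function(model, tests = nlan_utilization_tests(),
                                    uptake_limit = 1.5,
                                    threshold = GROWTH_THRESHOLD) {
  tests$model_call <- vapply(seq_len(nrow(tests)), function(i) {
    if (tests$test_type[i] == "carbon") {
      predict_carbon_growth(model, tests$id[i], uptake_limit, threshold)
    } else {
      predict_vitamin_essentiality(model, tests$id[i], threshold)
    }
  }, character(1))
  tests
}

#' Score qualitative predictions against experimental outcomes
#'
#' Treats the experimental column as truth and `"+"` as the positive class.
#' The Matthews correlation coefficient is defined as 0 whenever a marginal
#' of the confusion matrix is zero.
#'
#' @param tests A tibble with columns `experimental` and one of `model_call`
#'   (preferred) or `predicted`, coded `"+"`/`"-"`.
#' @return A list with `accuracy`, `mcc` and `confusion`
#'   (a tibble with `tp`, `fp`, `fn`, `tn`).
#' @export
score_predictions <- function(tests) {
  pred <- tests[["model_call"]] %||% tests[["predicted"]]
  truth <- tests[["experimental"]]
  stopifnot(all(pred %in% c("+", "-")), all(truth %in% c("+", "-")))
  tp <- sum(pred == "+" & truth == "+")
  fp <- sum(pred == "+" & truth == "-")
  fn <- sum(pred == "-" & truth == "+")
  tn <- sum(pred == "-" & truth == "-")
  denom2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 == 0) 0 else (tp * tn - fp * fn) / sqrt(denom2)
  list(accuracy = (tp + tn) / length(pred),
       mcc = mcc,
       confusion = tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn))
}
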