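#' Packaged substrate-utilization and vitamin-essentiality test battery
#'
#' The 46 growth tests: 36 sole carbon sources and 10 vitamin-omission
#' tests, each with the experimentally observed outcome and the curated
#' model's expected call. For carbon tests `+` means growth on the substrate
#' as sole carbon source; for vitamin tests `+` means growth persists when
#' that vitamin is omitted from the medium (i.e. the vitamin is not
#' essential).
#'
#' @return A tibble with columns `substrate`, `id`, `test_type`,
#'   `predicted`, `experimental`.
#' @export
nlan_utilization_tests <- function() {
  path <- system.file("extdata", "table4.tsv", package = "hydrogem",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Measured extracellular fluxes during exponential growth on cellobiose
#'
#' Mean, standard deviation and observed lower/upper bounds of the six
#' measured fermentation-product fluxes (mmol/gDW/h): succinate, lactate,
#' ethanol, formate, acetate and H2.
#'
#' @return A tibble with columns `metabolite`, `id`, `mean`, `sd`,
#'   `lower_bound`, `upper_bound`.
#' @export
nlan_flux_measurements <- function() {
  path <- system.file("extdata", "table5.tsv", package = "hydrogem",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}
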