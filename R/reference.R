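#' Published point-agreement counts from the GB national application
#'
#' Point-match confusion counts from the national-scale evaluation of the
#' boundary-height model against Countryside Survey 2007 field mapping of
#' woody and other linear features: points sampled at 5-m intervals within the
#' intersected 5-m buffers of the two networks, matched by nearest neighbour.
#'
#' @return A [confusion_matrix()] (model class x survey class).
#' @export
gb_validation_counts <- function() {
  confusion_matrix(n_ww = 109854, n_wo = 80623, n_ow = 146737, n_oo = 288115)
}

#' Published national woody-linear-feature totals (thousand km)
#'
#' National length estimates for Great Britain and its component countries:
#' the boundary-height model's totals alongside the Countryside Survey 2007
#' stratified field-survey estimates (with their standard errors).
#'
#' @return Tibble: `country`, `model_thousand_km`, `survey_thousand_km`,
#'   `survey_se_thousand_km`.
#' @export
gb_national_totals <- function() {
  tibble::tibble(
    country = c("Great Britain", "England", "Scotland", "Wales"),
    model_thousand_km = c(420.9, 333.0, 34.0, 53.8),
    survey_thousand_km = c(700, 547, 46, 106),
    survey_se_thousand_km = c(22.3, 20.1, 5.5, 7.9)
  )
}

#' Compare model totals against survey totals
#'
#' @param totals Tibble with `country`, `model_thousand_km`,
#'   `survey_thousand_km` columns; defaults to [gb_national_totals()].
#' @return The input with `ratio_pct` (model as a percentage of the survey
#'   estimate) and `shortfall_pct` (how much lower the model is).
#' @export
national_comparison <- function(totals = gb_national_totals()) {
  totals |>
    dplyr::mutate(
      ratio_pct = 100 * .data$model_thousand_km / .data$survey_thousand_km,
      shortfall_pct = 100 * (1 - .data$model_thousand_km / .data$survey_thousand_km)
    )
}
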