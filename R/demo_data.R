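#' Bundled demonstration datasets
#'
#' Small plain-text tables from a 96-h acute copper toxicity study on the
#' ten-spotted live-bearer (*Cnesterodon decemmaculatus*) in hard,
#' sediment-laden water of a dryland South American river, bundled so the
#' full analysis chain can be exercised without external data:
#'
#' * `demo_lc50_series()` - the study's probit LC50s (mg/L) with 95%
#'   confidence limits at 24, 48, 72, and 96 h of exposure.
#' * `demo_seasonal_summary()` - dry/wet-season descriptive statistics
#'   (n, mean, median, max, min, std) for 16 hydrological and water-quality
#'   variables at the river's monitoring station (2003-2010).
#' * `demo_dm_values()` - the dm statistic values reported for the 15
#'   variables observed in both seasons.
#' * `demo_sampling_chemistry()` - the water chemistry measured on the
#'   bioassay sampling date (May 2009; the day of month in the `date`
#'   column is synthetic, only the month is known).
#'
#' @return A tibble (see each description).
#' @name demo_data
NULL

demo_file <- function(name) {
  system.file("extdata", name, package = "cuptox", mustWork = TRUE)
}

#' @rdname demo_data
#' @export
demo_lc50_series <- function() {
  tibble::as_tibble(utils::read.csv(demo_file("demo_lc50_series.csv")))
}

#' @rdname demo_data
#' @export
demo_seasonal_summary <- function() {
  tibble::as_tibble(utils::read.csv(demo_file("demo_seasonal_summary.csv")))
}

#' @rdname demo_data
#' @export
demo_dm_values <- function() {
  tibble::as_tibble(utils::read.csv(demo_file("demo_dm_values.csv")))
}

#' @rdname demo_data
#' @export
demo_sampling_chemistry <- function() {
  read_monitoring_csv(demo_file("demo_sampling_chemistry.csv"))
}
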