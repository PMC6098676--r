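#' Build the annual covariate table
#'
#' Physical covariates for modelling an annual reproduction index:
#' population density at the beginning of each year (the previous year-end
#' census total divided by the reserve area), total rainfall for the
#' calendar year, and total rainfall for the prior year. Standardized
#' (mean 0, sample SD 1) versions of each are computed over the supplied
#' modelling window. A one-year-lagged density column is included for
#' collinearity diagnostics; in a monotonically growing population it is
#' nearly collinear with density and is not intended as a model term.
#'
#' @param census A `pfc_census` tibble (needs `year` and `total`).
#' @param years Integer vector: the modelling window. Density requires the
#'   census to cover `min(years) - 1` (and the lagged column
#'   `min(years) - 2`).
#' @param rainfall Optional data frame with columns `year`, `rain_mm`
#'   covering `years` and the prior year. When `NULL`, rain columns are
#'   omitted and models are restricted to rain-free terms downstream.
#' @param area_km2 Reserve area in square kilometres.
#'
#' @return A tibble with columns `year`, `density`, `density_lag`,
#'   `density_z`, and (when rainfall is supplied) `rain`, `rain_1`,
#'   `rain_z`, `rain_1_z`.
#' @export
build_covariates <- function(census, years, rainfall = NULL, area_km2 = 220) {
  stopifnot(area_km2 > 0)
  years <- as.integer(years)
  need <- c(years - 1L, years - 2L)
  gap <- setdiff(need, census$year)
  if (length(gap)) {
    stop("census lacks years needed for density: ", paste(sort(gap), collapse = ", "),
      call. = FALSE
    )
  }
  total_at <- stats::setNames(census$total, census$year)
  out <- tibble::tibble(
    year = years,
    density = as.numeric(total_at[as.character(years - 1L)]) / area_km2,
    density_lag = as.numeric(total_at[as.character(years - 2L)]) / area_km2
  )
  out$density_z <- standardize(out$density)
  if (!is.null(rainfall)) {
    if (!all(c("year", "rain_mm") %in% names(rainfall))) {
      stop("rainfall needs columns year, rain_mm", call. = FALSE)
    }
    rain_at <- stats::setNames(rainfall$rain_mm, rainfall$year)
    rain <- as.numeric(rain_at[as.character(years)])
    rain_1 <- as.numeric(rain_at[as.character(years - 1L)])
    if (anyNA(rain) || anyNA(rain_1)) {
      stop("rainfall does not cover the modelling window and the prior year",
        call. = FALSE
      )
    }
    out$rain <- rain
    out$rain_1 <- rain_1
    out$rain_z <- standardize(rain)
    out$rain_1_z <- standardize(rain_1)
  }
  out
}
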