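#' False-signal experiment for covariate inference on PFC series
#'
#' Runs the full analysis pipeline — simulate a population, compute PFC,
#' transform, rank every covariate-subset AR(2) model — on replicate
#' populations in which reproduction is (by default) independent of density
#' and rainfall, and records how often the model-selection machinery
#' nevertheless implicates each covariate: its relative importance and
#' whether the model-averaged 95% confidence interval for its coefficient
#' excludes zero. With zero effect injectors any such implication is a
#' false signal.
#'
#' Each replicate uses its own RNG stream derived from `seed`. Replicates
#' where the simulated population cannot support the analysis (extinction,
#' years without adult females inside the response window, or a response
#' window shorter than needed) are recorded as failed and excluded from the
#' summaries.
#'
#' @param config A [sim_config()].
#' @param replicates Number of replicate populations (at least 1; the
#'   sampling properties quoted in the package's documentation use 500).
#' @param seed Master seed; replicate r uses `seed + r`.
#'
#' @return An object of class `pfc_false_signal`: a list with `results`
#'   (one row per successful replicate: relative importances, averaged
#'   coefficients, CI-excludes-zero flags) and `summary` (per covariate:
#'   median relative importance and the fraction of replicates whose CI
#'   excludes zero).
#' @export
false_signal_experiment <- function(config = sim_config(), replicates = 100,
                                    seed = 1) {
  if (replicates < 1) stop("need at least one replicate", call. = FALSE)
  rows <- purrr::map(seq_len(replicates), function(r) {
    res <- tryCatch(
      analyse_replicate(config, seed + r),
      error = function(e) NULL
    )
    res
  })
  ok <- !purrr::map_lgl(rows, is.null)
  results <- dplyr::bind_rows(rows[ok])
  covars <- intersect(c("density", "rain", "rain_1"), unique(results$term))
  summary_tbl <- results |>
    dplyr::filter(.data$term %in% covars) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      median_importance = stats::median(.data$relative_importance),
      mean_importance = mean(.data$relative_importance),
      frac_ci_excludes_zero = mean(.data$ci_excludes_zero, na.rm = TRUE),
      .groups = "drop"
    )
  structure(
    list(
      results = results, summary = summary_tbl,
      n_replicates = replicates, n_failed = sum(!ok), seed = seed
    ),
    class = "pfc_false_signal"
  )
}

# one replicate: simulate -> PFC -> design -> ranking -> averaged estimates
analyse_replicate <- function(config, seed) {
  sim <- simulate_population(config, seed = seed)
  if (sim$extinct || is.null(sim$pfc)) stop("replicate unusable")
  if (any(diff(sim$pfc$year) != 1)) stop("gap in PFC years")
  cov_years <- sim$pfc$year[-(1:2)]
  covs <- build_covariates(sim$census, cov_years,
    rainfall = sim$rainfall, area_km2 = config$area_km2
  )
  des <- ar_design(sim$pfc, covs)
  rk <- rank_models(des)
  avg <- model_average(rk)
  avg$ci_excludes_zero <- avg$in_confidence_set &
    abs(avg$estimate) - 1.96 * avg$se_unconditional > 0
  avg$seed <- seed
  avg
}

#' @export
print.pfc_false_signal <- function(x, ...) {
  cat(
    "False-signal experiment:", x$n_replicates, "replicates (",
    x$n_failed, "failed )\n"
  )
  print(x$summary)
  invisible(x)
}

#' PFC variance experiment
#'
#' Distribution across replicate simulated populations of the annual PFC
#' (mean and SD) and of the dispersion of its moving averages, quantifying
#' how much year-to-year variation demographic stochasticity and founding
#' effects alone produce, and how moving-average smoothing suppresses it.
#'
#' @param config A [sim_config()].
#' @param replicates Number of replicate populations.
#' @param windows Moving-average windows to summarise.
#' @param seed Master seed; replicate r uses `seed + r`.
#'
#' @return An object of class `pfc_variance_exp`: `results` has one row
#'   per successful replicate with `pfc_mean`, `pfc_sd` and one `ma_sd_<w>`
#'   column per window; `summary` aggregates them.
#' @export
pfc_variance_experiment <- function(config = sim_config(), replicates = 100,
                                    windows = c(3, 11), seed = 1) {
  if (replicates < 1) stop("need at least one replicate", call. = FALSE)
  rows <- purrr::map(seq_len(replicates), function(r) {
    sim <- tryCatch(simulate_population(config, seed = seed + r),
      error = function(e) NULL
    )
    if (is.null(sim) || sim$extinct || is.null(sim$pfc)) return(NULL)
    if (nrow(sim$pfc) < max(windows) || any(diff(sim$pfc$year) != 1)) return(NULL)
    out <- tibble::tibble(
      seed = seed + r,
      pfc_mean = mean(sim$pfc$pfc),
      pfc_sd = sd_pop(sim$pfc$pfc)
    )
    for (w in windows) {
      out[[paste0("ma_sd_", w)]] <- sd_pop(moving_average(sim$pfc$pfc, w))
    }
    out
  })
  results <- dplyr::bind_rows(rows)
  if (!nrow(results)) stop("no usable replicates", call. = FALSE)
  summary_tbl <- dplyr::summarise(
    results,
    dplyr::across(-dplyr::all_of("seed"), mean)
  )
  structure(
    list(
      results = results, summary = summary_tbl,
      n_replicates = replicates, n_failed = replicates - nrow(results),
      windows = windows, seed = seed
    ),
    class = "pfc_variance_exp"
  )
}

#' @export
print.pfc_variance_exp <- function(x, ...) {
  cat(
    "PFC variance experiment:", x$n_replicates, "replicates (",
    x$n_failed, "failed )\n"
  )
  print(x$summary)
  invisible(x)
}
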