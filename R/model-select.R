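#' Assemble the AR(2) regression problem
#'
#' Builds the design data for autoregressive modelling of a transformed
#' annual reproduction index. The response is the count-based modified
#' arcsine transform ([zar_transform()]) of births over adult females; the
#' lag terms are its values one and two years prior. All candidate models
#' share one common response window — the years for which both lags and
#' every covariate exist — so that their information criteria are
#' comparable. Lagged responses enter untransformed in scale; only the
#' physical covariates are standardized (inside [build_covariates()]).
#'
#' @param pfc A `pfc_series` tibble (columns `year`, `births`,
#'   `adult_females`), e.g. from [compute_pfc()] or reconstructed from a
#'   census via [births_from_census()].
#' @param covariates Output of [build_covariates()], or `NULL` for a purely
#'   autoregressive problem.
#'
#' @return A tibble of class `pfc_design` with columns `year`, `y`, `lag1`,
#'   `lag2` and a standardized column per available covariate (`density`,
#'   `rain`, `rain_1`).
#' @export
ar_design <- function(pfc, covariates = NULL) {
  stopifnot(all(c("year", "births", "adult_females") %in% names(pfc)))
  pfc <- dplyr::arrange(pfc, year)
  if (any(diff(pfc$year) != 1)) stop("pfc series has year gaps", call. = FALSE)
  z <- zar_transform(pfc$births, pfc$adult_females)
  d <- tibble::tibble(
    year = pfc$year,
    y = z,
    lag1 = dplyr::lag(z, 1),
    lag2 = dplyr::lag(z, 2)
  )
  if (!is.null(covariates)) {
    keep <- c(
      "year",
      density = "density_z", rain = "rain_z", rain_1 = "rain_1_z"
    )
    keep <- keep[c(TRUE, c("density_z", "rain_z", "rain_1_z") %in% names(covariates))]
    d <- dplyr::inner_join(d, dplyr::select(covariates, dplyr::all_of(keep)),
      by = "year"
    )
  }
  d <- tidyr::drop_na(d)
  if (nrow(d) < 4) stop("insufficient data: fewer than 4 complete responses", call. = FALSE)
  class(d) <- c("pfc_design", class(d))
  d
}

#' Candidate model terms available in a design
#'
#' @param design A `pfc_design` tibble.
#' @return Character vector among `lag1`, `lag2`, `density`, `rain`, `rain_1`.
#' @export
ar_terms <- function(design) {
  intersect(c("lag1", "lag2", "density", "rain", "rain_1"), names(design))
}

#' Fit one candidate model by maximum likelihood
#'
#' Gaussian conditional maximum likelihood for the regression
#' `y = b0 + sum(coef * term) + e`, `e ~ N(0, sigma^2)`: the coefficients
#' solve the least-squares normal equations, the ML variance estimate uses
#' the divisor `n`, and `logLik = -(n/2) (log(2 pi sigma^2) + 1)`.
#' Coefficient standard errors use the unbiased residual-variance divisor
#' `n - p`. The parameter count `k` is the number of regression coefficients
#' (intercept included) plus one for `sigma^2`.
#'
#' @param design A `pfc_design` tibble (or any data frame with a `y`
#'   column and the term columns).
#' @param terms Character vector of term names (possibly empty for the
#'   intercept-only null model).
#'
#' @return An object of class `pfc_fit` with elements `terms`,
#'   `coefficients`, `se`, `sigma2`, `logLik`, `k`, `n`, `AICc`,
#'   `r_squared`, `residuals`, `fitted`.
#' @export
fit_ar_model <- function(design, terms = character()) {
  bad <- setdiff(terms, names(design))
  if (length(bad)) stop("unknown terms: ", paste(bad, collapse = ", "), call. = FALSE)
  y <- design$y
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n))
  for (t in terms) X <- cbind(X, design[[t]])
  colnames(X) <- c("(Intercept)", terms)
  p <- ncol(X)
  if (n <= p) stop("insufficient data: n must exceed the coefficient count", call. = FALSE)
  qr_x <- qr(X)
  if (qr_x$rank < p) stop("rank-deficient (collinear) design", call. = FALSE)
  beta <- qr.coef(qr_x, y)
  fitted <- as.numeric(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  exact <- rss < 1e-12 * max(tss, 1)
  sigma2 <- rss / n
  ll <- if (exact) Inf else -(n / 2) * (log(2 * pi * sigma2) + 1)
  k <- p + 1
  se <- if (exact) {
    rep(0, p)
  } else {
    sqrt(diag(chol2inv(qr.R(qr_x))) * rss / (n - p))
  }
  names(se) <- colnames(X)
  structure(
    list(
      terms = terms,
      coefficients = beta,
      se = se,
      sigma2 = sigma2,
      logLik = ll,
      k = k,
      n = n,
      AICc = if (exact) -Inf else aicc(ll, k, n),
      r_squared = if (tss == 0) stop("zero total sum of squares", call. = FALSE) else 1 - rss / tss,
      residuals = res,
      fitted = fitted
    ),
    class = "pfc_fit"
  )
}

#' @export
print.pfc_fit <- function(x, ...) {
  cat("AR regression fit (conditional ML)\n")
  cat("  terms:", if (length(x$terms)) paste(x$terms, collapse = " + ") else "(null)", "\n")
  cat("  n =", x$n, " k =", x$k, " logLik =", format(x$logLik, digits = 6),
    " AICc =", format(x$AICc, digits = 6), "\n")
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`, defined only for
#' `n > k + 1`.
#'
#' @param logLik Maximised log-likelihood.
#' @param k Number of estimated parameters (including the error variance).
#' @param n Number of observations.
#' @return The AICc value.
#' @export
aicc <- function(logLik, k, n) {
  if (n - k - 1 <= 0) {
    stop("AICc undefined: need n > k + 1", call. = FALSE)
  }
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

all_model_specs <- function(terms) {
  specs <- purrr::map(0:(2^length(terms) - 1), function(m) {
    terms[bitwAnd(m, 2^(seq_along(terms) - 1)) > 0]
  })
  specs[order(lengths(specs), purrr::map_chr(specs, paste, collapse = "+"))]
}

#' Rank all covariate-subset models by AICc
#'
#' Fits every subset of the available terms (all 32 models when both lags
#' and the three physical covariates are present; the 8 rain-free models
#' when no rainfall series is available) on the identical response window,
#' ranks them by AICc, and attaches Akaike weights
#' `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)`, cumulative weights, and
#' membership in the smallest confidence set whose weights reach
#' `confidence_level`. Ties in AICc are broken by fewer parameters, then by
#' the term labels.
#'
#' @param design A `pfc_design` tibble.
#' @param terms Candidate terms; defaults to every term in the design.
#' @param confidence_level Cumulative-weight threshold for the confidence
#'   set.
#'
#' @return An object of class `pfc_ranking`: a tibble with one row per
#'   model (`model`, `terms` list column, `k`, `logLik`, `AICc`, `delta`,
#'   `weight`, `cumweight`, `in_confidence_set`) and the fitted objects in
#'   `attr(, "fits")`.
#' @export
rank_models <- function(design, terms = ar_terms(design), confidence_level = 0.95) {
  specs <- all_model_specs(terms)
  fits <- purrr::map(specs, function(s) fit_ar_model(design, s))
  tab <- tibble::tibble(
    model = purrr::map_chr(specs, function(s) {
      if (length(s)) paste(s, collapse = " + ") else "null"
    }),
    terms = specs,
    k = purrr::map_dbl(fits, "k"),
    logLik = purrr::map_dbl(fits, "logLik"),
    AICc = purrr::map_dbl(fits, "AICc")
  )
  ord <- order(tab$AICc, tab$k, tab$model)
  tab <- tab[ord, ]
  fits <- fits[ord]
  tab$delta <- tab$AICc - tab$AICc[1]
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  tab$cumweight <- cumsum(tab$weight)
  cutoff <- match(TRUE, tab$cumweight >= confidence_level)
  tab$in_confidence_set <- seq_len(nrow(tab)) <= cutoff
  attr(tab, "fits") <- fits
  attr(tab, "confidence_level") <- confidence_level
  attr(tab, "n") <- fits[[1]]$n
  class(tab) <- c("pfc_ranking", class(tab))
  tab
}

#' @export
print.pfc_ranking <- function(x, n = nrow(x), ...) {
  cat(
    "AICc model ranking:", nrow(x), "models on n =", attr(x, "n"),
    "responses;", sum(x$in_confidence_set), "in the",
    attr(x, "confidence_level"), "confidence set\n"
  )
  print(tibble::as_tibble(x[, c("model", "k", "AICc", "delta", "weight", "cumweight")]), n = n)
  invisible(x)
}

#' Model-averaged coefficients, unconditional SEs and relative importance
#'
#' Coefficients are averaged over the confidence-set models that contain
#' each term ("natural" averaging), with the weights renormalised within
#' that subset; the unconditional standard error folds in between-model
#' spread, `sum_i w_i sqrt(var_i + (theta_i - theta_bar)^2)`. Relative
#' importance is the sum of Akaike weights over all ranked models
#' containing the term.
#'
#' @param ranking A [rank_models()] ranking.
#' @return A tibble with columns `term`, `estimate`, `se_unconditional`,
#'   `relative_importance`, `n_models` (confidence-set models containing
#'   the term), `in_confidence_set` (whether any does).
#' @export
model_average <- function(ranking) {
  fits <- attr(ranking, "fits")
  terms <- unique(unlist(ranking$terms))
  cs <- which(ranking$in_confidence_set)
  purrr::map_dfr(terms, function(t) {
    has <- purrr::map_lgl(ranking$terms, function(s) t %in% s)
    ri <- sum(ranking$weight[has])
    in_cs <- intersect(cs, which(has))
    if (!length(in_cs)) {
      return(tibble::tibble(
        term = t, estimate = NA_real_, se_unconditional = NA_real_,
        relative_importance = ri, n_models = 0L, in_confidence_set = FALSE
      ))
    }
    w <- ranking$weight[in_cs]
    w <- w / sum(w)
    est <- purrr::map_dbl(fits[in_cs], function(f) f$coefficients[[t]])
    var_ <- purrr::map_dbl(fits[in_cs], function(f) f$se[[t]]^2)
    theta <- sum(w * est)
    se_u <- sum(w * sqrt(var_ + (est - theta)^2))
    tibble::tibble(
      term = t, estimate = theta, se_unconditional = se_u,
      relative_importance = ri, n_models = length(in_cs),
      in_confidence_set = TRUE
    )
  })
}

#' Proportion of response variance explained by a fit
#'
#' `1 - RSS/TSS` on the fitted window.
#'
#' @param fit A `pfc_fit` object.
#' @return A proportion (at most 1; negative values are possible for models
#'   worse than the mean).
#' @export
variance_explained <- function(fit) fit$r_squared

#' Tidy and summarise fitted objects
#'
#' `tidy()` returns one row per coefficient of a `pfc_fit`, or the ranking
#' table of a `pfc_ranking`; `glance()` returns the one-row fit summary.
#'
#' @param x A `pfc_fit` or `pfc_ranking` object.
#' @param ... Unused.
#' @return A tibble.
#' @name pfc-tidiers
NULL

#' @rdname pfc-tidiers
#' @export
tidy.pfc_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = as.numeric(x$coefficients),
    std.error = as.numeric(x$se),
    statistic = as.numeric(x$coefficients) / ifelse(x$se == 0, NA, x$se)
  )
}

#' @rdname pfc-tidiers
#' @export
glance.pfc_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, sigma2 = x$sigma2, logLik = x$logLik,
    AICc = x$AICc, k = x$k, nobs = x$n
  )
}

#' @rdname pfc-tidiers
#' @export
tidy.pfc_ranking <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$terms <- purrr::map_chr(out$terms, paste, collapse = " + ")
  out
}

#' @rdname pfc-tidiers
#' @export
glance.pfc_ranking <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x), nobs = attr(x, "n"),
    n_confidence_set = sum(x$in_confidence_set),
    best_model = x$model[1], weight_best = x$weight[1]
  )
}
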