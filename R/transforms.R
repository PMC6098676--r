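#' Arcsine-square-root transformation for proportions
#'
#' The customary variance-stabilising transformation for proportion data,
#' `asin(sqrt(p))`, mapping \[0, 1\] onto \[0, pi/2\] radians.
#'
#' @param p Proportion(s) in \[0, 1\].
#' @return Radians in \[0, pi/2\].
#' @export
#' @examples
#' arcsine_sqrt(0.25) # pi/6
arcsine_sqrt <- function(p) {
  if (any(p < 0 | p > 1)) stop("proportions must lie in [0, 1]", call. = FALSE)
  asin(sqrt(p))
}

#' Modified arcsine transformation for binomial counts
#'
#' The count-based modification of the arcsine-square-root transformation
#' that better normalises proportions near zero and one:
#' `(asin(sqrt(x/(n+1))) + asin(sqrt((x+1)/(n+1)))) / 2`.
#' Unlike the plain transform it never reaches the boundary values 0 or
#' pi/2, and it uses the underlying counts rather than the rounded
#' proportion.
#'
#' @param x Successes (births), `0 <= x <= n`.
#' @param n Trials (adult females), `n >= 1`.
#' @return Radians strictly inside (0, pi/2).
#' @export
#' @examples
#' zar_transform(4, 5)
zar_transform <- function(x, n) {
  if (any(n < 1)) stop("n must be at least 1", call. = FALSE)
  if (any(x < 0 | x > n)) stop("x must lie in [0, n]", call. = FALSE)
  0.5 * (asin(sqrt(x / (n + 1))) + asin(sqrt((x + 1) / (n + 1))))
}

#' Centre and scale a series
#'
#' Subtracts the mean and divides by the sample (n - 1 divisor) standard
#' deviation over the supplied window.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Numeric vector with mean 0 and sample SD 1.
#' @export
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize a constant (or degenerate) series", call. = FALSE)
  }
  (x - mean(x)) / s
}

# population (divisor n) standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Moving average of an annual series
#'
#' Full-window means only: a window of `w` over a series of length `m`
#' yields `m - w + 1` values. Windows are trailing, so each value is aligned
#' to the last year of its window; the dispersion of the smoothed series
#' does not depend on this alignment choice.
#'
#' @param x Numeric vector.
#' @param window Integer window length, `1 <= window <= length(x)`.
#' @return Numeric vector of length `length(x) - window + 1`.
#' @export
#' @examples
#' moving_average(1:5, 3)
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window < 1) stop("window must be at least 1", call. = FALSE)
  if (window > length(x)) {
    stop("window (", window, ") exceeds series length (", length(x), ")",
      call. = FALSE
    )
  }
  out <- stats::filter(x, rep(1 / window, window), sides = 1)
  as.numeric(out[window:length(x)])
}

#' Moving-average summary across window sizes
#'
#' Mean and dispersion of the smoothed series for each window size. Odd
#' windows (3, 5, ..., 11 by default) are used, the centred-moving-average
#' convention for annual series. The headline dispersion `sd_n` uses the
#' population (divisor n) standard deviation; the sample (divisor n - 1)
#' version is reported alongside.
#'
#' @param x Numeric vector of annual values.
#' @param windows Integer vector of window sizes.
#' @return A tibble with columns `window`, `n_windows`, `mean`, `sd_n`,
#'   `sd_sample`.
#' @export
moving_average_summary <- function(x, windows = seq(3L, 11L, by = 2L)) {
  purrr::map_dfr(windows, function(w) {
    v <- moving_average(x, w)
    tibble::tibble(
      window = as.integer(w), n_windows = length(v),
      mean = mean(v), sd_n = sd_pop(v), sd_sample = stats::sd(v)
    )
  })
}

#' Sample autocorrelation and partial autocorrelation
#'
#' Standard sample ACF (lag-0 value 1) with the PACF obtained from the
#' autocorrelations by the Durbin-Levinson recursion, and the usual
#' large-sample 95% significance bound `1.96/sqrt(n)`.
#'
#' @param x Numeric series, longer than `max_lag + 1`.
#' @param max_lag Largest lag to report.
#' @return An object of class `pfc_correlogram`: a tibble with columns
#'   `lag`, `acf`, `pacf` (`NA` at lag 0), plus attributes `n` and `bound`.
#' @export
correlogram <- function(x, max_lag = 10) {
  n <- length(x)
  if (n <= max_lag + 1) stop("series too short for max_lag", call. = FALSE)
  if (sd_pop(x) == 0) stop("degenerate (constant) series", call. = FALSE)
  ac <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
    demean = TRUE)$acf)
  pac <- durbin_levinson_pacf(ac[-1])
  out <- tibble::tibble(
    lag = 0:max_lag,
    acf = ac,
    pacf = c(NA_real_, pac)
  )
  attr(out, "n") <- n
  attr(out, "bound") <- 1.96 / sqrt(n)
  class(out) <- c("pfc_correlogram", class(out))
  out
}

# PACF from autocorrelations rho[1..K] via the Durbin-Levinson recursion
durbin_levinson_pacf <- function(rho) {
  K <- length(rho)
  pacf <- numeric(K)
  phi <- numeric(0)
  for (k in seq_len(K)) {
    if (k == 1) {
      a <- rho[1]
    } else {
      num <- rho[k] - sum(phi * rho[(k - 1):1])
      den <- 1 - sum(phi * rho[1:(k - 1)])
      a <- num / den
    }
    pacf[k] <- a
    phi <- if (k == 1) a else c(phi - a * rev(phi), a)
  }
  pacf
}
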