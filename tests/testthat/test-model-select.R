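test_that("ar_design builds the common response window", {
  cen <- rhino_census()
  rep <- reproduce_analysis(cen)
  des <- rep$design
  expect_equal(des$year, 1989:2008)
  expect_equal(nrow(des), 20)
  expect_named(des, c("year", "y", "lag1", "lag2", "density"))
  # lag columns really are the transformed series shifted
  z <- zar_transform(rep$pfc$births, rep$pfc$adult_females)
  expect_equal(des$y, z[-(1:2)])
  expect_equal(des$lag1, z[2:21])
  expect_equal(des$lag2, z[1:20])
})

test_that("fit_ar_model agrees with an independent normal-equations oracle", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(10:50, 1)
    p <- sample(0:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    d <- tibble::as_tibble(as.data.frame(X))
    terms <- names(d)
    d$y <- rnorm(n, sd = runif(1, 0.5, 2))
    f <- fit_ar_model(d, terms)
    # oracle: solve the normal equations directly
    Xd <- cbind(1, X)
    beta <- solve(t(Xd) %*% Xd, t(Xd) %*% d$y)
    expect_equal(unname(f$coefficients), as.numeric(beta), tolerance = 1e-8)
    rss <- sum((d$y - Xd %*% beta)^2)
    expect_equal(f$sigma2, rss / n, tolerance = 1e-8)
    expect_equal(f$logLik, -(n / 2) * (log(2 * pi * rss / n) + 1), tolerance = 1e-8)
  }
})

test_that("fit_ar_model matches lm estimates and standard errors", {
  set.seed(1)
  d <- tibble::tibble(a = rnorm(30), b = rnorm(30))
  d$y <- 1 + 2 * d$a - d$b + rnorm(30, sd = 0.3)
  f <- fit_ar_model(d, c("a", "b"))
  ref <- lm(y ~ a + b, data = d)
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-10)
  expect_equal(f$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
  # ML likelihood (divisor n) matches stats::logLik on the lm fit
  expect_equal(f$logLik, as.numeric(logLik(ref)), tolerance = 1e-10)
})

test_that("noiseless data takes the exact-interpolation guard path", {
  d <- tibble::tibble(x1 = c(1, 2, 3, 4, 5))
  d$y <- 2 * d$x1 + 1
  f <- fit_ar_model(d, "x1")
  expect_equal(unname(f$coefficients), c(1, 2), tolerance = 1e-10)
  expect_equal(f$logLik, Inf)
  expect_equal(f$AICc, -Inf)
})

test_that("degenerate designs raise errors", {
  d <- tibble::tibble(x1 = rnorm(10))
  d$x2 <- 2 * d$x1
  d$y <- rnorm(10)
  expect_error(fit_ar_model(d, c("x1", "x2")), "rank-deficient")
  expect_error(fit_ar_model(d[1:2, ], c("x1", "x2")), "insufficient")
  expect_error(fit_ar_model(d, "nope"), "unknown terms")
})

test_that("aicc applies the small-sample correction", {
  expect_equal(aicc(0, 4, 20), 8 + 40 / 15)
  expect_equal(aicc(-10, 3, 25), 20 + 6 + 24 / 21)
  # converges to AIC as n grows
  expect_lt(abs(aicc(0, 3, 1e6) - 6), 1e-4)
  expect_error(aicc(0, 4, 5), "n > k \\+ 1")
})

test_that("AR(2) parameter recovery from a long simulated series", {
  set.seed(99)
  n <- 5000
  b <- c(0.2, -0.5, -0.2)
  sim <- as.numeric(arima.sim(list(ar = c(b[2], b[3])), n = n, sd = 0.2)) +
    b[1] / (1 - b[2] - b[3])
  d <- tibble::tibble(
    y = sim[3:n], lag1 = sim[2:(n - 1)], lag2 = sim[1:(n - 2)]
  )
  f <- fit_ar_model(d, c("lag1", "lag2"))
  mc_se <- 3 / sqrt(n)
  expect_equal(unname(f$coefficients[["lag1"]]), -0.5, tolerance = mc_se)
  expect_equal(unname(f$coefficients[["lag2"]]), -0.2, tolerance = mc_se)
  expect_equal(sqrt(f$sigma2), 0.2, tolerance = 0.01)
})

test_that("rank_models fits every subset with consistent weights", {
  cen <- rhino_census()
  rep <- reproduce_analysis(cen)
  rk <- rep$ranking
  expect_equal(nrow(rk), 8) # rain-free: subsets of {lag1, lag2, density}
  expect_equal(rk$delta[1], 0)
  expect_equal(sum(rk$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(rk$AICc) >= 0))
  # confidence set is the smallest prefix reaching 0.95
  cs <- sum(rk$in_confidence_set)
  expect_gte(rk$cumweight[cs], 0.95)
  if (cs > 1) expect_lt(rk$cumweight[cs - 1], 0.95)
  # all models share the same response window
  fits <- attr(rk, "fits")
  expect_true(all(purrr::map_dbl(fits, "n") == 20))
})

test_that("Akaike weights follow the exp(-delta/2) formula", {
  # two-model toy: delta = c(0, 2)
  w <- exp(-c(0, 2) / 2)
  w <- w / sum(w)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
})

test_that("ranking is invariant to affine rescaling of a covariate", {
  cen <- rhino_census()
  rep <- reproduce_analysis(cen)
  des <- rep$design
  des2 <- des
  des2$density <- 100 + 3 * des2$density
  rk1 <- rank_models(des)
  rk2 <- rank_models(des2)
  expect_equal(rk1$model, rk2$model)
  expect_equal(rk1$AICc, rk2$AICc, tolerance = 1e-8)
})

test_that("model averaging follows natural averaging with unconditional SEs", {
  # two models, equal weights, coefficients 1 and 3 with zero variance:
  # average 2, unconditional SE 1 (pure between-model spread)
  w <- c(0.5, 0.5)
  est <- c(1, 3)
  theta <- sum(w * est)
  se_u <- sum(w * sqrt(0 + (est - theta)^2))
  expect_equal(theta, 2)
  expect_equal(se_u, 1)

  cen <- rhino_census()
  rk <- reproduce_analysis(cen)$ranking
  avg <- model_average(rk)
  # relative importance of a term is at least the weight of the best model
  # containing it, and at most 1
  for (t in avg$term) {
    has <- purrr::map_lgl(rk$terms, function(s) t %in% s)
    expect_gte(avg$relative_importance[avg$term == t], max(rk$weight[has]))
    expect_lte(avg$relative_importance[avg$term == t], 1)
  }
  # recompute lag1's averaged estimate by hand from the confidence set
  fits <- attr(rk, "fits")
  in_cs <- which(rk$in_confidence_set & purrr::map_lgl(rk$terms, function(s) "lag1" %in% s))
  w2 <- rk$weight[in_cs] / sum(rk$weight[in_cs])
  est2 <- purrr::map_dbl(fits[in_cs], function(f) f$coefficients[["lag1"]])
  expect_equal(avg$estimate[avg$term == "lag1"], sum(w2 * est2), tolerance = 1e-12)
})

test_that("single-model confidence set returns that model's coefficient and SE", {
  set.seed(5)
  d <- tibble::tibble(x = rnorm(200))
  d$y <- 3 * d$x + rnorm(200, sd = 0.1) # x overwhelmingly supported
  rk <- rank_models(d, terms = "x")
  expect_true(rk$in_confidence_set[1] && sum(rk$in_confidence_set) == 1)
  avg <- model_average(rk)
  f_best <- attr(rk, "fits")[[1]]
  expect_equal(avg$estimate, unname(f_best$coefficients[["x"]]))
  expect_equal(avg$se_unconditional, unname(f_best$se[["x"]]))
  expect_equal(avg$relative_importance, sum(rk$weight[purrr::map_lgl(rk$terms, function(s) "x" %in% s)]))
})

test_that("variance_explained has the right limits and recovers simulated R2", {
  d <- tibble::tibble(x = c(1, 2, 3, 4))
  d$y <- 2 * d$x
  expect_equal(variance_explained(fit_ar_model(d, "x")), 1)
  d$y <- c(1, 5, 2, 4)
  expect_equal(variance_explained(fit_ar_model(d, character())), 0)

  set.seed(21)
  n <- 1e4
  x <- rnorm(n)
  y <- x + rnorm(n) # true R2 = 0.5
  f <- fit_ar_model(tibble::tibble(x = x, y = y), "x")
  expect_lt(abs(variance_explained(f) - 0.5), 0.02)
})

test_that("tidy and glance methods return well-formed tibbles", {
  cen <- rhino_census()
  rep <- reproduce_analysis(cen)
  f <- fit_ar_model(rep$design, c("lag1", "lag2"))
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "statistic"))
  expect_equal(nrow(td), 3)
  gl <- glance(f)
  expect_equal(gl$nobs, 20)
  expect_equal(gl$AICc, f$AICc)
  td_r <- tidy(rep$ranking)
  expect_true(is.character(td_r$terms))
  expect_equal(glance(rep$ranking)$n_models, 8)
})
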