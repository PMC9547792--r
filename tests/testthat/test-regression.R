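test_that("standardize matches the z-score oracle and is idempotent", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize(rnorm(20))
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(4, 5)), class = "nichevar_error_validation")
})

test_that("OLS wrapper recovers perfect fits and simulated slopes", {
  d <- tibble::tibble(x = 1:20, y = 3 + 2 * (1:20))
  # a zero-residual fit makes summary.lm warn that its tests are unreliable
  f <- suppressWarnings(ols_fit(d, y ~ x))
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(tidy(f)$estimate[2], 2, tolerance = 1e-10)
  set.seed(50)
  big <- tibble::tibble(x = rnorm(1e4))
  big$y <- 2 * big$x + rnorm(1e4)
  fb <- ols_fit(big, y ~ x)
  sl <- tidy(fb)[tidy(fb)$term == "x", ]
  expect_lt(abs(sl$estimate - 2), 3 * sl$std_error)
  expect_error(ols_fit(tibble::tibble(x = 1:5, x2 = 2 * (1:5), y = rnorm(5)),
                       y ~ x + x2), class = "nichevar_error_data")
})

test_that("BIC-on-PNW and WIC-on-PNW slopes sum to one with equal SEs", {
  s <- quick_summary()
  fb <- ols_fit(s, bic_size ~ pnw_size)
  fw <- ols_fit(s, wic_size ~ pnw_size)
  bb <- tidy(fb)[2, ]; ww <- tidy(fw)[2, ]
  expect_equal(bb$estimate + ww$estimate, 1, tolerance = 1e-10)
  expect_equal(bb$std_error, ww$std_error, tolerance = 1e-10)
  ft <- ols_fit(s, bic_taxa ~ pnw_taxa)
  fu <- ols_fit(s, wic_taxa ~ pnw_taxa)
  expect_equal(tidy(ft)$estimate[2] + tidy(fu)$estimate[2], 1, tolerance = 1e-10)
})

test_that("beta regression reduces to the univariate ML fit when intercept-only", {
  set.seed(8)
  y <- rbeta(300, 4, 6)
  f0 <- beta_regression(tibble::tibble(y = y), y ~ 1)
  nll <- function(par) -sum(dbeta(y, exp(par[1]), exp(par[2]), log = TRUE))
  o <- optim(c(log(2), log(2)), nll, method = "BFGS")
  a <- exp(o$par[1]); b <- exp(o$par[2])
  expect_equal(plogis(tidy(f0)$estimate[1]), a / (a + b), tolerance = 1e-4)
  expect_equal(f0$phi, a + b, tolerance = 1e-3)
})

test_that("beta regression recovers simulated coefficients and precision", {
  set.seed(77)
  x <- rnorm(2000)
  mu <- plogis(0 + 1 * x)
  y <- rbeta(2000, mu * 20, (1 - mu) * 20)
  f <- beta_regression(tibble::tibble(y = y, x = x), y ~ x)
  cf <- tidy(f)
  expect_lt(abs(cf$estimate[1] - 0), 3 * cf$std_error[1])
  expect_lt(abs(cf$estimate[2] - 1), 3 * cf$std_error[2])
  expect_equal(f$phi, 20, tolerance = 0.1)
  expect_equal(f$aic, -2 * f$loglik + 2 * 3, tolerance = 1e-10)
})

test_that("boundary responses are rejected, not squeezed", {
  d <- tibble::tibble(y = c(0, runif(20, 0.2, 0.8)), x = rnorm(21))
  expect_error(beta_regression(d, y ~ x), "strictly inside",
               class = "nichevar_error_validation")
})

test_that("AIC selects the generating link most of the time", {
  hits <- 0
  for (r in 1:20) {
    set.seed(100 + r)
    x <- runif(500, -2, 2)
    mu <- exp(-exp(-(0.5 + 0.7 * x)))
    y <- pmin(pmax(rbeta(500, mu * 15, (1 - mu) * 15), 1e-8), 1 - 1e-8)
    sel <- beta_regression_aic(tibble::tibble(y = y, x = x), y ~ x)
    hits <- hits + (sel$best$link == "loglog")
  }
  expect_gte(hits, 16)
})

test_that("beta log-likelihood is a local optimum", {
  set.seed(51)
  x <- rnorm(200)
  mu <- plogis(0.3 + 0.5 * x)
  y <- rbeta(200, mu * 10, (1 - mu) * 10)
  f <- beta_regression(tibble::tibble(y = y, x = x), y ~ x)
  est <- tidy(f)$estimate
  ll <- function(b) sum(dbeta(y, plogis(b[1] + b[2] * x) * f$phi,
                              (1 - plogis(b[1] + b[2] * x)) * f$phi, log = TRUE))
  for (d in list(c(1e-3, 0), c(-1e-3, 0), c(0, 1e-3), c(0, -1e-3))) {
    expect_lte(ll(est + d), f$loglik + 1e-9)
  }
})

test_that("Pearson test matches the hand computation oracle", {
  d <- tibble::tibble(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3))
  ct <- pearson_test(d, x, y)
  expect_equal(ct$r, 0.6)
  expect_equal(ct$statistic, 0.6 * sqrt(2 / (1 - 0.36)), tolerance = 1e-10)
  perfect <- tibble::tibble(x = 1:10, y = 1:10)
  expect_equal(pearson_test(perfect, x, y)$r, 1)
  expect_error(pearson_test(tibble::tibble(x = rep(1, 5), y = rnorm(5)), x, y),
               class = "nichevar_error_validation")
})

test_that("Pearson p-values are uniform under independence", {
  set.seed(52)
  ps <- vapply(1:200, function(i) {
    d <- tibble::tibble(x = rnorm(15), y = rnorm(15))
    pearson_test(d, x, y)$p_value
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
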