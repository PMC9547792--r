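#' Standardize a numeric vector to mean 0, SD 1
#'
#' `(x - mean(x)) / sd(x)` with the usual n - 1 standard deviation. Errors on
#' constant input rather than silently returning NaN.
#'
#' @param x A numeric vector without NA.
#' @return The standardized vector.
#' @export
standardize <- function(x) {
  if (anyNA(x)) abort_validation("x must not contain NA")
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort_validation("cannot standardize a constant vector")
  (x - mean(x)) / s
}

#' Ordinary least squares via the standard linear model
#'
#' Thin data-first wrapper over [stats::lm()] returning the common
#' `regression_fit` container used by the Table-1 battery: coefficient table
#' with t statistics, overall F against the intercept-only model, R-squared,
#' log-likelihood and AIC.
#'
#' @param data A data frame.
#' @param formula A model formula evaluated in `data`.
#' @return An object of class `regression_fit` (`model = "linear"`,
#'   `link = "identity"`).
#' @export
#' @examples
#' d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + rnorm(10))
#' glance(ols_fit(d, y ~ x))
ols_fit <- function(data, formula) {
  fit <- lm(formula, data = data)
  if (anyNA(coef(fit))) abort_data("rank-deficient design (singular fit)")
  sm <- summary(fit)
  cf <- sm$coefficients
  coefs <- tibble::tibble(
    term = rownames(cf), estimate = unname(cf[, 1]),
    std_error = unname(cf[, 2]), statistic = unname(cf[, 3]),
    p_value = unname(cf[, 4]))
  fstat <- sm$fstatistic
  new_regression_fit(
    model = "linear", link = "identity", coefficients = coefs,
    f_statistic = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    df = if (is.null(fstat)) c(NA_real_, NA_real_) else unname(fstat[2:3]),
    f_p_value = if (is.null(fstat)) NA_real_ else
      unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    r_squared = sm$r.squared,
    loglik = as.numeric(logLik(fit)),
    aic = stats::AIC(fit), phi = NA_real_, n = nrow(stats::model.frame(fit)),
    fit = fit)
}

#' Beta regression by maximum likelihood
#'
#' Fits a beta-distributed response on the open interval (0, 1) with mean
#' linked to the linear predictor, `mu_i = g^{-1}(x_i' beta)`, and a common
#' precision `phi` (density parameterized by shapes `mu * phi` and
#' `(1 - mu) * phi`). Estimation is quasi-Newton (BFGS) on `(beta, log phi)`
#' with the analytic gradient, started from the link-transformed least
#' squares fit; standard errors come from the observed information. The
#' pseudo-R-squared is the squared correlation between the linear predictor
#' and the link-transformed response.
#'
#' Boundary responses (0 or 1) are a hard error: squeezing them inside the
#' interval silently changes the estimand, so the caller must decide.
#'
#' @inheritParams ols_fit
#' @param link Mean link: `"logit"`, `"probit"`, `"cloglog"`, or `"loglog"`
#'   (`g(mu) = -log(-log(mu))`).
#' @return A `regression_fit` (`model = "beta"`) with z statistics and the
#'   precision estimate `phi`.
#' @export
beta_regression <- function(data, formula, link = c("logit", "probit", "cloglog", "loglog")) {
  link <- match.arg(link)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (any(y <= 0 | y >= 1)) {
    abort_validation(paste(
      "beta regression requires responses strictly inside (0, 1);",
      "boundary values must be handled explicitly by the caller"))
  }
  if (nrow(X) <= ncol(X) + 1) abort_data("too few observations for beta regression")
  lk <- beta_link(link)
  # start from OLS on the link scale; moment estimate of phi
  beta0 <- stats::lm.fit(X, lk$linkfun(y))$coefficients
  mu0 <- lk$linkinv(drop(X %*% beta0))
  v0 <- max(var(y - mu0), 1e-6)
  phi0 <- max(mean(mu0 * (1 - mu0)) / v0 - 1, 1)
  negll <- function(par) {
    eta <- drop(X %*% par[-length(par)])
    mu <- lk$linkinv(eta)
    phi <- exp(par[length(par)])
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  grad <- function(par) {
    eta <- drop(X %*% par[-length(par)])
    mu <- lk$linkinv(eta)
    phi <- exp(par[length(par)])
    ystar <- log(y) - log1p(-y)
    mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
    dmu <- phi * (ystar - mustar) * lk$mu.eta(eta)
    dphi <- sum(digamma(phi) - mu * digamma(mu * phi) -
                  (1 - mu) * digamma((1 - mu) * phi) +
                  mu * log(y) + (1 - mu) * log1p(-y))
    -c(drop(crossprod(X, dmu)), dphi * phi)
  }
  opt <- optim(c(beta0, log(phi0)), negll, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12), hessian = TRUE)
  if (opt$convergence != 0) {
    rlang::abort(paste0("beta regression failed to converge (optim code ",
                        opt$convergence, "): ", opt$message %||% ""),
                 class = "nichevar_error_optim")
  }
  p <- ncol(X)
  # delta method back from log(phi); observed information for beta
  Vfull <- tryCatch(solve(opt$hessian), error = function(e) {
    rlang::abort("singular observed information in beta regression",
                 class = "nichevar_error_optim")
  })
  se_beta <- unname(sqrt(diag(Vfull)[seq_len(p)]))
  est <- unname(opt$par[seq_len(p)])
  z <- est / se_beta
  phi_hat <- unname(exp(opt$par[p + 1]))
  eta_hat <- drop(X %*% est)
  coefs <- tibble::tibble(
    term = colnames(X), estimate = est, std_error = se_beta,
    statistic = z, p_value = 2 * pnorm(-abs(z)))
  ll <- -opt$value
  new_regression_fit(
    model = "beta", link = link, coefficients = coefs,
    f_statistic = NA_real_, df = c(NA_real_, NA_real_), f_p_value = NA_real_,
    r_squared = if (sd(eta_hat) > 0) cor(eta_hat, lk$linkfun(y))^2 else NA_real_,
    loglik = ll, aic = -2 * ll + 2 * (p + 1), phi = phi_hat,
    n = length(y), fit = opt)
}

#' Fit a beta regression under several links and rank by AIC
#'
#' @inheritParams beta_regression
#' @param links Character vector of links to try.
#' @return A list with `fits` (named list of `regression_fit`), `aic`
#'   (named vector), and `best` (the fit with minimal AIC).
#' @export
beta_regression_aic <- function(data, formula,
                                links = c("logit", "probit", "cloglog", "loglog")) {
  fits <- lapply(links, function(l) beta_regression(data, formula, link = l))
  names(fits) <- links
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  list(fits = fits, aic = aic, best = fits[[which.min(aic)]])
}

beta_link <- function(link) {
  # linkfun is used only for starting values and the pseudo-R-squared;
  # clamp to dodge log(0)/qnorm(0) overflow at near-boundary responses
  clamp <- function(mu) pmin(pmax(mu, 1e-10), 1 - 1e-10)
  if (link == "loglog") {
    list(linkfun = function(mu) -log(-log(clamp(mu))),
         linkinv = function(eta) {
           pmin(pmax(exp(-exp(-eta)), .Machine$double.eps), 1 - 1e-15)
         },
         mu.eta = function(eta) exp(-exp(-eta) - eta))
  } else {
    lk <- stats::make.link(link)
    list(linkfun = function(mu) lk$linkfun(clamp(mu)),
         linkinv = function(eta) {
           pmin(pmax(lk$linkinv(eta), .Machine$double.eps), 1 - 1e-15)
         },
         mu.eta = lk$mu.eta)
  }
}

#' Pearson product-moment correlation test
#'
#' Data-first wrapper over [stats::cor.test()]: `r`, the t statistic
#' `r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, and the
#' two-sided p-value.
#'
#' @param data A data frame.
#' @param x,y Column names (unquoted) of the two variables.
#' @return A one-row tibble: `r`, `statistic`, `df`, `p_value`, `n`.
#' @export
#' @examples
#' d <- tibble::tibble(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3))
#' pearson_test(d, a, b) # r = 0.6
pearson_test <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  if (length(xv) < 3) abort_data("need at least 3 observations")
  if (sd(xv) == 0 || sd(yv) == 0) abort_validation("zero variance in x or y")
  ct <- cor.test(xv, yv, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 n = length(xv))
}

new_regression_fit <- function(model, link, coefficients, f_statistic, df,
                               f_p_value, r_squared, loglik, aic, phi, n, fit) {
  structure(list(model = model, link = link, coefficients = coefficients,
                 f_statistic = f_statistic, df = df, f_p_value = f_p_value,
                 r_squared = r_squared, loglik = loglik, aic = aic,
                 phi = phi, n = n, fit = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> %s (%s link), n = %d, %s = %.3f, AIC = %.2f\n",
              x$model, x$link, x$n,
              if (x$model == "beta") "pseudo-R2" else "R2", x$r_squared, x$aic))
  print(x$coefficients)
  invisible(x)
}

#' @rdname ols_fit
#' @param x A `regression_fit`.
#' @param ... Unused.
#' @export
tidy.regression_fit <- function(x, ...) x$coefficients

#' @rdname ols_fit
#' @export
glance.regression_fit <- function(x, ...) {
  tibble::tibble(model = x$model, link = x$link, r_squared = x$r_squared,
                 f_statistic = x$f_statistic, df1 = x$df[1], df2 = x$df[2],
                 f_p_value = x$f_p_value, loglik = x$loglik, aic = x$aic,
                 phi = x$phi, n = x$n)
}
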