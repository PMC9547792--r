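test_that("Bray-Curtis matches hand oracles and is scale-free", {
  expect_equal(as.numeric(bray_curtis(matrix(c(2, 0, 0, 2), 2, byrow = TRUE))), 1)
  expect_equal(as.numeric(bray_curtis(matrix(c(3, 1, 3, 1), 2, byrow = TRUE))), 0)
  expect_equal(as.numeric(bray_curtis(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))), 0.5)
  set.seed(40)
  m <- random_count_matrix(7, 5)
  expect_equal(as.numeric(bray_curtis(m * 11)), as.numeric(bray_curtis(m)),
               tolerance = 1e-12)
  m0 <- m; m0[2, ] <- 0
  expect_error(bray_curtis(m0), class = "nichevar_error_data")
})

test_that("NMDS recovers an exact low-dimensional configuration", {
  set.seed(41)
  X <- matrix(rnorm(60), 30, 2)
  d <- dist(X)
  fit <- suppressWarnings(nmds(d, k = 2, n_starts = 10, seed = 1))
  expect_lte(fit$stress, 0.01)
  pr <- vegan::procrustes(X, fit$points, symmetric = TRUE)
  expect_lte(pr$ss, 0.01)
  # three points embed any triangle exactly in two dimensions
  tri <- dist(rbind(c(0, 0), c(3, 0), c(1, 4)))
  expect_lte(suppressWarnings(nmds(tri, k = 2, n_starts = 5, seed = 1))$stress, 1e-6)
})

test_that("NMDS is deterministic per seed and stable across seeds", {
  set.seed(42)
  X <- matrix(rnorm(80), 40, 2)
  d <- dist(X)
  f1 <- suppressWarnings(nmds(d, k = 2, n_starts = 8, seed = 3))
  f2 <- suppressWarnings(nmds(d, k = 2, n_starts = 8, seed = 3))
  expect_identical(f1$points, f2$points)
  f3 <- suppressWarnings(nmds(d, k = 2, n_starts = 8, seed = 99))
  expect_lt(abs(f1$stress - f3$stress), 1e-6)
})

test_that("NMDS stress is invariant to label permutation and axes are variance-ordered", {
  set.seed(43)
  m <- random_count_matrix(25, 6)
  rownames(m) <- sprintf("f%02d", 1:25)
  d <- bray_curtis(m)
  f <- nmds(d, k = 3, n_starts = 20, seed = 5)
  perm <- sample(25)
  dperm <- stats::as.dist(as.matrix(d)[perm, perm])
  fperm <- nmds(dperm, k = 3, n_starts = 20, seed = 5)
  # permuting labels changes the random starts, so the best local optimum
  # can wobble at the fourth decimal of stress
  expect_lt(abs(f$stress - fperm$stress), 1e-3)
  v <- apply(f$points, 2, var)
  expect_true(all(diff(v) <= 1e-12))
})

test_that("NMDS1 sign follows the orienting covariate", {
  set.seed(44)
  m <- random_count_matrix(20, 6)
  rownames(m) <- sprintf("f%02d", 1:20)
  d <- bray_curtis(m)
  tot <- rowSums(m)
  f <- nmds(d, k = 2, n_starts = 8, seed = 2, orient_by = tot)
  expect_gte(cor(f$points[, 1], tot), 0)
})

test_that("univariate Euclidean PERMANOVA equals classical OLS F", {
  set.seed(45)
  for (r in 1:10) {
    n <- sample(10:40, 1)
    y <- rnorm(n)
    x <- rnorm(n)
    pf <- permanova(dist(y), data.frame(x = x), n_perm = 99, seed = r)
    f_ols <- anova(lm(y ~ x))$`F value`[1]
    expect_equal(tidy(pf)$f[1], f_ols, tolerance = 1e-8)
  }
})

test_that("PERMANOVA sums of squares decompose exactly; p absent when n_perm = 0", {
  set.seed(46)
  m <- random_count_matrix(20, 6)
  d <- bray_curtis(m)
  pred <- data.frame(d13C = rnorm(20), d15N = rnorm(20))
  res <- tidy(permanova(d, pred, n_perm = 199, seed = 1))
  total <- res$ss[res$term == "Total"]
  expect_equal(sum(res$ss[res$term != "Total"]), total, tolerance = 1e-8)
  expect_true(all(res$p_value[!is.na(res$p_value)] > 0))
  r0 <- tidy(permanova(d, pred, n_perm = 0, seed = 1))
  expect_true(all(is.na(r0$p_value)))
  expect_equal(r0$f[1:2], res$f[1:2], tolerance = 1e-12)
})

test_that("PERMANOVA p-values are calibrated under independence", {
  set.seed(47)
  ps <- vapply(1:60, function(r) {
    y <- matrix(rpois(15 * 4, 3) + 1, 15, 4)
    d <- bray_curtis(y)
    tidy(permanova(d, data.frame(x = rnorm(15)), n_perm = 99, seed = r))$p_value[1]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("degenerate PERMANOVA inputs error clearly", {
  set.seed(48)
  m <- random_count_matrix(10, 4)
  d <- bray_curtis(m)
  expect_error(permanova(d, data.frame(x = rep(1, 10))),
               class = "nichevar_error_data")
  expect_error(permanova(d, data.frame(x = rnorm(9))),
               class = "nichevar_error_schema")
  expect_error(permanova(d, data.frame(x = c(NA, rnorm(9)))),
               class = "nichevar_error_validation")
})
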