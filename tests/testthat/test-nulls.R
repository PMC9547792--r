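test_that("disjoint extreme prey sizes are detected as specialization", {
  s <- tibble::tibble(fish_id = rep(c("a", "b"), each = 10),
                      size = c(rnorm(10, 2, 0.05), rnorm(10, 40, 0.05)))
  set.seed(1)
  r <- null_continuous(s, R = 999, seed = 5)
  expect_lte(r$p_value, 0.01)
  expect_lt(r$observed, r$null_mean)
})

test_that("degenerate null inputs give p = 1 with a warning", {
  flat <- tibble::tibble(fish_id = c("a", "a", "b"), size = c(3, 3, 3))
  expect_warning(r <- null_continuous(flat, R = 99, seed = 1), "identical")
  expect_equal(r$p_value, 1)
  onecat <- matrix(c(4, 7), 2, 1)
  expect_warning(rc <- null_categorical(onecat, R = 99, seed = 1), "single")
  expect_equal(rc$p_value, 1)
})

test_that("null model guards: R and seed are required", {
  s <- tibble::tibble(fish_id = c("a", "b"), size = c(1, 2))
  expect_error(null_continuous(s, R = 10, seed = 1), class = "nichevar_error_config")
  expect_error(null_continuous(s, R = 999), class = "nichevar_error_config")
})

test_that("strong Dirichlet specialization is flagged by the categorical test", {
  hits <- 0
  for (r in 1:20) {
    lk <- simulate_lake(lake_config(n_fish = 30, n_categories = 8, alpha = 0.05,
                                    lambda = 20), seed = 600 + r)
    m <- build_diet_matrix(lk$diet)
    p <- null_categorical(m, R = 199, seed = r)$p_value
    hits <- hits + (p <= 0.01)
  }
  expect_gte(hits, 19)
})

test_that("E matches hand oracles and its boundary identities", {
  expect_equal(e_index(matrix(c(5, 0, 5, 0), 2, byrow = TRUE)), 0)
  expect_equal(e_index(diag(c(3, 7))), 1)
  expect_equal(e_index(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)), 0.5)
})

test_that("E is invariant to row/column order and count duplication", {
  set.seed(21)
  m <- random_count_matrix(8, 5)
  e0 <- e_index(m)
  expect_equal(e_index(m[sample(8), sample(5)]), e0)
  expect_equal(e_index(m * 7L), e0)
})

test_that("E_adj boundary identity and null behaviour", {
  mono <- diag(c(6, 6, 6))
  r <- e_adjusted(mono, R = 199, seed = 3)
  expect_equal(r$e, 1)
  expect_equal(r$e_adj, 1)
  # generalist population: E_adj collapses toward 0 and is never negative
  eadj <- vapply(1:10, function(i) {
    lk <- simulate_lake(lake_config(n_fish = 30, lambda = 50, alpha = 1e6),
                        seed = 3000 + i)
    e_adjusted(build_diet_matrix(lk$diet), R = 199, seed = i)$e_adj
  }, numeric(1))
  expect_lte(median(eadj), 0.02)
  expect_true(all(eadj >= 0))
})

test_that("E_adj increases along a specialization gradient", {
  alphas <- exp(seq(log(1000), log(0.05), length.out = 13))
  eadj <- vapply(seq_along(alphas), function(i) {
    lk <- simulate_lake(lake_config(n_fish = 30, lambda = 50, alpha = alphas[i]),
                        seed = 400 + i)
    e_adjusted(build_diet_matrix(lk$diet), R = 199, seed = i)$e_adj
  }, numeric(1))
  # near the generalist end E_adj is clipped at ~0, so adjacent lakes can tie
  # or swap within noise; the trend across the gradient must be strongly
  # monotone and strict over the specialized half
  expect_gte(cor(eadj, -log(alphas), method = "spearman"), 0.9)
  expect_gt(eadj[13], eadj[7])
  expect_gt(eadj[7], eadj[1])
})

test_that("Monte Carlo p-values use the add-one convention and null mean is the draw mean", {
  set.seed(12)
  m <- random_count_matrix(6, 4)
  r <- null_categorical(m, R = 99, seed = 8)
  expect_equal(r$p_value,
               (1 + sum(r$null_draws <= r$observed)) / (r$R + 1))
  expect_equal(r$null_mean, mean(r$null_draws))
  expect_equal(r$null_bic_mean, mean(r$null_bic))
})
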