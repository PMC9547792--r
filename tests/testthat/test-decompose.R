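test_that("continuous decomposition matches the law-of-total-variance oracle", {
  s <- tibble::tibble(fish_id = c("a", "a", "b", "b"), size = c(1, 3, 5, 7))
  d <- decompose_continuous(s)
  expect_equal(d$tnw, 5)
  expect_equal(d$wic, 1)
  expect_equal(d$bic, 4)
  # pooled ML variance equals TNW exactly under item weighting
  expect_equal(d$tnw, mean(s$size^2) - mean(s$size)^2)
})

test_that("degenerate continuous inputs behave as the theory says", {
  same <- tibble::tibble(fish_id = c("a", "a", "b"), size = c(2, 2, 2))
  d <- decompose_continuous(same)
  expect_equal(c(d$tnw, d$wic, d$bic), c(0, 0, 0))
  singles <- tibble::tibble(fish_id = c("a", "b", "c"), size = c(1, 5, 9))
  d1 <- decompose_continuous(singles)
  expect_equal(d1$wic, 0)
  expect_equal(d1$bic, d1$tnw)
  one <- tibble::tibble(fish_id = "a", size = c(1, 2))
  expect_error(decompose_continuous(one), class = "nichevar_error_data")
})

test_that("Shannon decomposition matches the hand entropy oracle", {
  m <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  d <- decompose_shannon(m)
  expect_equal(d$tnw, 0.69315, tolerance = 1e-4)
  expect_equal(d$wic, 0.56233, tolerance = 1e-4)
  expect_equal(d$bic, 0.13082, tolerance = 1e-4)
})

test_that("Shannon edge cases: proportional rows, disjoint monophagy, one individual", {
  prop <- matrix(c(2, 4, 1, 2, 4, 8), 3, byrow = TRUE)
  expect_equal(decompose_shannon(prop)$bic, 0, tolerance = 1e-12)
  mono <- diag(c(5, 5))
  d <- decompose_shannon(mono)
  expect_equal(d$wic, 0)
  expect_equal(d$bic, log(2))
  expect_error(decompose_shannon(matrix(1:3, 1)), class = "nichevar_error_data")
})

test_that("conservation WIC + BIC = PNW holds on random inputs, both weightings", {
  set.seed(101)
  for (r in 1:50) {
    m <- random_count_matrix(sample(3:20, 1), sample(2:10, 1))
    for (w in c("items", "equal")) {
      d <- decompose_shannon(m, weighting = w)
      expect_lt(abs(d$wic + d$bic - d$tnw), 1e-10 * max(d$tnw, 1))
      expect_gte(d$bic, 0)
    }
    s <- random_size_samples(sample(3:15, 1))
    for (w in c("items", "equal")) {
      ds <- decompose_continuous(s, weighting = w)
      expect_lt(abs(ds$wic + ds$bic - ds$tnw), 1e-10 * max(ds$tnw, 1))
    }
  }
})

test_that("TNW is invariant to how pooled items are partitioned among individuals", {
  set.seed(7)
  x <- rnorm(60, 10, 3)
  for (r in 1:10) {
    n_fish <- sample(2:10, 1)
    id <- sample(seq_len(n_fish), 60, replace = TRUE)
    # ensure every individual owns at least one item
    id[seq_len(n_fish)] <- seq_len(n_fish)
    d <- decompose_continuous(tibble::tibble(fish_id = as.character(id), size = x))
    expect_equal(d$tnw, mean(x^2) - mean(x)^2, tolerance = 1e-12)
  }
})

test_that("tidy and glance summarize a decomposition", {
  d <- decompose_shannon(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  td <- tidy(d)
  expect_equal(td$component, c("tnw", "wic", "bic"))
  expect_equal(sum(td$proportion[2:3]), 1, tolerance = 1e-10)
  g <- glance(d)
  expect_equal(g$axis, "taxa")
  expect_equal(g$n_items, 8)
})
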