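test_that("identical config and seed give byte-identical output", {
  cfg <- lake_config(n_fish = 6, lambda = 10)
  a <- simulate_lake(cfg, seed = 11)
  b <- simulate_lake(cfg, seed = 11)
  expect_identical(a$diet, b$diet)
  expect_identical(a$fish, b$fish)
  expect_identical(a$truth, b$truth)
  c <- simulate_lake(cfg, seed = 12)
  expect_false(identical(a$diet, c$diet))
})

test_that("ground truth satisfies the conservation identity by construction", {
  for (s in 1:20) {
    cfg <- lake_config(sigma_within = runif(1, 0, 1), sigma_between = runif(1, 0, 1))
    tr <- simulate_lake(cfg, seed = s)$truth
    expect_identical(tr$true_tnw_size, tr$true_wic_size + tr$true_bic_size)
    expect_gte(tr$expected_sample_bic_size, tr$true_bic_size)
  }
})

test_that("huge Dirichlet concentration gives generalists, zero sigmas degenerate sizes", {
  cfg <- lake_config(n_fish = 40, lambda = 30, alpha = 1e9)
  set.seed(3)
  p <- nichevar:::rdirichlet(100, cfg$alpha * cfg$q)
  tv <- 0.5 * rowSums(abs(sweep(p, 2, cfg$q)))
  expect_lt(max(tv), 1e-4)
  flat <- simulate_lake(lake_config(sigma_within = 0, sigma_between = 0), seed = 4)
  expect_equal(unique(flat$diet$length_mm), exp(log(7)))
})

test_that("invalid configurations are rejected", {
  expect_error(lake_config(alpha = 0), class = "nichevar_error_config")
  expect_error(lake_config(lambda = -1), class = "nichevar_error_config")
  expect_error(lake_config(q = c(0.5, 0.6), n_categories = 2),
               class = "nichevar_error_config")
  expect_error(lake_config(n_fish = 1), class = "nichevar_error_config")
  expect_error(simulate_lake(lake_config()), class = "nichevar_error_config")
})

test_that("zero-truncated item counts never produce empty stomachs", {
  cfg <- lake_config(n_fish = 60, lambda = 1.2)
  lk <- simulate_lake(cfg, seed = 9)
  counts <- table(lk$diet$fish_id)
  expect_equal(length(counts), 60)
  expect_true(all(counts >= 1))
})

test_that("null elevation gradient shares truth; negative effects are monotone", {
  g0 <- simulate_gradient(n_lakes = 5, elevation_effect = c(sigma_within = 0, sigma_between = 0),
                          base_config = lake_config(n_fish = 4, lambda = 5), seed = 2)
  expect_equal(length(unique(g0$truths$true_tnw_size)), 1)
  g1 <- simulate_gradient(n_lakes = 5,
                          elevation_effect = c(sigma_within = -4e-4, sigma_between = -4e-4),
                          base_config = lake_config(n_fish = 4, lambda = 5), seed = 2)
  expect_true(all(diff(g1$truths$true_tnw_size) < 0))
})

test_that("per-lake seeds are stable: adding lakes never changes earlier lakes", {
  base <- lake_config(n_fish = 4, lambda = 5)
  g5 <- simulate_gradient(n_lakes = 5, base_config = base, seed = 31,
                          elevation_range = c(2508, 3337))
  g5b <- simulate_gradient(n_lakes = 5, base_config = base, seed = 31,
                           elevation_range = c(2508, 3337))
  expect_identical(g5$diet, g5b$diet)
})

test_that("estimated size-niche gradient recovers a negative elevation slope", {
  rej <- 0
  for (r in 1:30) {
    g <- simulate_gradient(base_config = lake_config(lambda = 50), seed = 7000 + r)
    est <- vapply(unique(g$diet$lake_id), function(l) {
      decompose_continuous(build_size_samples(g$diet, l, log_transform = TRUE))$tnw
    }, numeric(1))
    sm <- summary(lm(est ~ standardize(g$truths$elevation_m)))
    rej <- rej + (sm$coefficients[2, 1] < 0 && sm$coefficients[2, 4] < 0.05)
  }
  expect_gte(rej, 26)
})

test_that("synthetic CSVs round-trip through the readers", {
  g <- simulate_gradient(n_lakes = 3, base_config = lake_config(n_fish = 5, lambda = 6),
                         seed = 15)
  dir <- tempfile()
  paths <- write_synthetic_csv(g, dir)
  diet <- read_diet_csv(paths["diet"])
  expect_equal(nrow(diet), nrow(g$diet))
  expect_equal(diet$length_mm, g$diet$length_mm, tolerance = 1e-12)
  fish <- read_fish_csv(paths["fish"])
  expect_equal(nrow(fish), nrow(g$fish))
  lakes <- read_lake_csv(paths["lakes"])
  expect_equal(lakes$lake_id, g$lakes$lake_id)
})
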