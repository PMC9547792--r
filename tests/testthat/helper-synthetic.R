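# Shared fixtures and a cached calibration run (used by both the null-model
# calibration test and the p-value uniformity property test, so the 1000
# simulated populations are generated once per test run).

.cache <- new.env(parent = emptyenv())

# 1000 generalist populations (alpha = 1e6, no between-individual size
# variation), both Monte Carlo specialization tests at R = 199.
calibration_pvalues <- function() {
  if (!is.null(.cache$calib)) return(.cache$calib)
  n_pop <- 1000
  p_cont <- numeric(n_pop)
  p_cat <- numeric(n_pop)
  cfg <- lake_config(n_fish = 30, lambda = 20, alpha = 1e6, sigma_between = 0)
  for (i in seq_len(n_pop)) {
    lk <- simulate_lake(cfg, seed = 50000 + i)
    ss <- build_size_samples(lk$diet, log_transform = TRUE)
    mat <- build_diet_matrix(lk$diet)
    p_cont[i] <- null_continuous(ss, R = 199, seed = i)$p_value
    p_cat[i] <- null_categorical(mat, R = 199, seed = i)$p_value
  }
  .cache$calib <- list(continuous = p_cont, categorical = p_cat, R = 199)
  .cache$calib
}

withr_tempfile <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# small deterministic diet table: two fish, two orders
tiny_diet <- function() {
  tibble::tibble(
    lake_id = "L1",
    fish_id = c("a", "a", "a", "b", "b"),
    prey_order = c("Diptera", "Diptera", "Ephemeroptera", "Diptera", "Odonata"),
    life_stage = c("adult", "adult", "juvenile", "juvenile", "juvenile"),
    habitat = c("aquatic", "aquatic", "aquatic", "aquatic", "aquatic"),
    length_mm = c(2, 3, 8, NA, 12))
}

random_count_matrix <- function(n, k) {
  m <- matrix(rpois(n * k, 2), n, k)
  empty <- rowSums(m) == 0
  m[cbind(which(empty), sample.int(k, sum(empty), replace = TRUE))] <- 1L
  m
}

random_size_samples <- function(n_fish) {
  n_i <- sample(1:6, n_fish, replace = TRUE)
  tibble::tibble(fish_id = rep(sprintf("f%02d", seq_len(n_fish)), n_i),
                 size = exp(rnorm(sum(n_i), 2, 0.5)))
}

# per-lake summary from a quick synthetic gradient (cached; several tests
# only need some plausible lake-level table)
quick_summary <- function() {
  if (!is.null(.cache$summary)) return(.cache$summary)
  g <- simulate_gradient(n_lakes = 8,
                         base_config = lake_config(n_fish = 12, lambda = 15),
                         seed = 77)
  b <- build_lake_summary(g$diet, fish = g$fish, lakes = g$lakes,
                          R = 99, n_draws_bayes = 1000, nmds_starts = 5,
                          seed = 99)
  .cache$summary <- b$summary
  .cache$summary
}
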