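#' Configuration for one synthetic lake population
#'
#' Describes the generative model behind [simulate_lake()]. Individual diet
#' proportions are `p_i ~ Dirichlet(alpha * q)` around the shared pool `q`:
#' small `alpha` gives strongly individual-specific diets, `alpha -> Inf`
#' perfect generalists. Stomach counts are zero-truncated Poisson (empty
#' stomachs are excluded upstream in the real protocol, so they are never
#' generated). Item log-lengths are normal around an individual mean which is
#' itself normal around the lake grand mean, so the within- and
#' between-individual variance components are known exactly. Isotopes are
#' bivariate normal.
#'
#' Defaults describe a mid-elevation Sierra Nevada lake: ~18 fish per
#' population, 8 invertebrate prey categories with geometrically decaying
#' pooled proportions, ~20 identifiable items per stomach, prey around
#' 7 mm with log-scale SDs 0.5 within and 0.3 between individuals, and
#' freshwater salmonid muscle isotope values near (-25, 8) per-mil.
#'
#' @param n_fish Number of fish (>= 2).
#' @param n_categories Number of resource categories K (>= 1).
#' @param q Pooled diet proportions (simplex of length K); default geometric
#'   decay.
#' @param alpha Dirichlet concentration (> 0) controlling specialization.
#' @param lambda Mean of the zero-truncated Poisson for items per stomach.
#' @param size_mean Grand mean of log prey length (log-mm).
#' @param sigma_between SD of individual mean log-lengths (>= 0).
#' @param sigma_within SD of item log-lengths around the individual mean
#'   (>= 0).
#' @param isotope_mean Length-2 mean of (d13C, d15N), per-mil.
#' @param isotope_cov 2x2 positive-definite isotope covariance.
#' @param elevation_m,area_ha Lake covariates.
#' @param lake_id Lake label.
#' @return A validated list of class `lake_config`.
#' @export
lake_config <- function(n_fish = 18, n_categories = 8,
                        q = NULL, alpha = 2, lambda = 20,
                        size_mean = log(7), sigma_between = 0.3,
                        sigma_within = 0.5,
                        isotope_mean = c(-25, 8),
                        isotope_cov = matrix(c(1, 0.3, 0.3, 0.8), 2),
                        elevation_m = 2900, area_ha = 10,
                        lake_id = "synthetic") {
  if (n_fish < 2) abort_config("n_fish must be >= 2")
  if (n_categories < 1) abort_config("n_categories must be >= 1")
  if (is.null(q)) {
    q <- 0.6^seq_len(n_categories)
    q <- q / sum(q)
  }
  if (length(q) != n_categories) abort_config("q must have length n_categories")
  if (abs(sum(q) - 1) > 1e-12 || any(q < 0)) abort_config("q must be a simplex summing to 1")
  if (alpha <= 0) abort_config("alpha must be positive")
  if (lambda <= 0) abort_config("lambda must be positive")
  if (sigma_between < 0 || sigma_within < 0) abort_config("sigmas must be non-negative")
  check_pd(isotope_cov, "isotope_cov")
  structure(list(
    n_fish = as.integer(n_fish), n_categories = as.integer(n_categories),
    q = q, alpha = alpha, lambda = lambda, size_mean = size_mean,
    sigma_between = sigma_between, sigma_within = sigma_within,
    isotope_mean = isotope_mean, isotope_cov = isotope_cov,
    elevation_m = elevation_m, area_ha = area_ha,
    lake_id = as.character(lake_id)),
    class = "lake_config")
}

# Invertebrate category labels: order, life stage, habitat. Recycled when
# K > 10.
synthetic_categories <- function(K) {
  base <- data.frame(
    order = c("Diptera", "Ephemeroptera", "Trichoptera", "Coleoptera",
              "Odonata", "Hymenoptera", "Hemiptera", "Annelida",
              "Plecoptera", "Araneae"),
    stage = c("juvenile", "juvenile", "juvenile", "adult", "juvenile",
              "adult", "adult", "adult", "juvenile", "adult"),
    habitat = c("aquatic", "aquatic", "aquatic", "aquatic", "aquatic",
                "terrestrial", "terrestrial", "aquatic", "aquatic",
                "terrestrial"))
  idx <- ((seq_len(K) - 1) %% nrow(base)) + 1
  out <- base[idx, ]
  dup <- duplicated(idx) | duplicated(idx, fromLast = TRUE)
  out$order <- ifelse(dup, paste0(out$order, "_", seq_len(K)), out$order)
  out
}

#' Simulate one lake with known niche-component ground truth
#'
#' Draws a full lake dataset (diet records, fish records, lake record) from
#' the model described in [lake_config()], together with the exact truth the
#' estimators should recover: `true_wic_size = sigma_within^2`,
#' `true_bic_size = sigma_between^2`, their sum, the finite-sampling
#' expectation of the estimated BIC
#' (`sigma_between^2 + sigma_within^2 * sum(w_i / n_i)`, from the law of
#' total variance with `w_i = n_i / N`), and the true 95% isotope ellipse
#' area `pi * chi2_2(0.95) * sqrt(det(isotope_cov))`.
#'
#' @param config A [lake_config()].
#' @param seed Integer seed; identical (config, seed) gives identical output.
#' @return A list of class `synthetic_lake`: tibbles `diet`, `fish`, `lake`,
#'   and a list `truth`.
#' @export
simulate_lake <- function(config, seed) {
  stopifnot(inherits(config, "lake_config"))
  if (missing(seed) || is.null(seed)) abort_config("an integer `seed` is required")
  withr_seed(seed)
  K <- config$n_categories
  nf <- config$n_fish
  cats <- synthetic_categories(K)
  n_i <- rztpois(nf, config$lambda)
  p <- rdirichlet(nf, config$alpha * config$q)
  mu_i <- rnorm(nf, config$size_mean, config$sigma_between)
  fish_ids <- sprintf("%s_f%02d", config$lake_id, seq_len(nf))
  diet <- lapply(seq_len(nf), function(i) {
    k <- sample.int(K, n_i[i], replace = TRUE, prob = p[i, ])
    tibble::tibble(
      lake_id = config$lake_id,
      fish_id = fish_ids[i],
      prey_order = cats$order[k],
      life_stage = cats$stage[k],
      habitat = cats$habitat[k],
      length_mm = exp(rnorm(n_i[i], mu_i[i], config$sigma_within)))
  })
  diet <- dplyr::bind_rows(diet)
  iso <- rmvnorm2(nf, config$isotope_mean, config$isotope_cov)
  sl <- rnorm(nf, 150, 15)
  fish <- tibble::tibble(
    fish_id = fish_ids, lake_id = config$lake_id,
    standard_length_mm = sl,
    wet_mass_g = 1.1e-5 * sl^3 * exp(rnorm(nf, 0, 0.1)),
    d13C = iso[, 1], d15N = iso[, 2],
    has_stomach_contents = TRUE)
  lake <- tibble::tibble(lake_id = config$lake_id,
                         elevation_m = config$elevation_m,
                         area_ha = config$area_ha)
  w <- n_i / sum(n_i)
  truth <- list(
    true_wic_size = config$sigma_within^2,
    true_bic_size = config$sigma_between^2,
    true_tnw_size = config$sigma_within^2 + config$sigma_between^2,
    expected_sample_bic_size =
      config$sigma_between^2 + config$sigma_within^2 * sum(w / n_i),
    true_tnw_taxa = shannon_entropy(config$q),
    generalist = config$alpha >= 1e4,
    true_iso_area = pi * qchisq(0.95, 2) * sqrt(det(config$isotope_cov)),
    n_i = n_i, seed = seed)
  structure(list(diet = diet, fish = fish, lake = lake, truth = truth,
                 config = config),
            class = "synthetic_lake")
}

#' Simulate a gradient of lakes along elevation
#'
#' Generates `n_lakes` lakes with elevations evenly spaced over
#' `elevation_range` whose size-axis variance components follow a log-linear
#' elevation law:
#' `sigma(e) = sigma_base * exp(slope * (e - min(elevation_range)))` with
#' separate per-metre slopes for the within- and between-individual SDs.
#' Negative slopes on both reproduce the field pattern of population niche
#' width on the prey-size axis shrinking with elevation. Lake areas are drawn
#' log-uniform over `area_range`. Per-lake seeds derive deterministically
#' from `seed` by a counter-based mix, so inserting a lake never perturbs the
#' others.
#'
#' @param n_lakes Number of lakes (>= 2).
#' @param elevation_effect Named numeric vector with per-metre slopes
#'   `c(sigma_within = ..., sigma_between = ...)` on the log SDs.
#' @param base_config A [lake_config()] giving everything else.
#' @param elevation_range Length-2 range in metres (default the 2508-3337 m
#'   span of the study system).
#' @param area_range Length-2 range of lake areas in hectares (default
#'   2-21 ha).
#' @param seed Integer master seed.
#' @return A list of class `synthetic_gradient`: combined tibbles `diet`,
#'   `fish`, `lakes`, a per-lake `truths` tibble, and `configs`.
#' @export
simulate_gradient <- function(n_lakes = 13,
                              elevation_effect = c(sigma_within = -4e-4,
                                                   sigma_between = -4e-4),
                              base_config = lake_config(),
                              elevation_range = c(2508, 3337),
                              area_range = c(2, 21),
                              seed) {
  if (n_lakes < 2) abort_config("n_lakes must be >= 2")
  if (missing(seed) || is.null(seed)) abort_config("an integer `seed` is required")
  stopifnot(inherits(base_config, "lake_config"))
  elev <- seq(elevation_range[1], elevation_range[2], length.out = n_lakes)
  withr_seed(derive_seed(seed, "simulate", 0))
  areas <- exp(runif(n_lakes, log(area_range[1]), log(area_range[2])))
  sw_slope <- elevation_effect[["sigma_within"]]
  sb_slope <- elevation_effect[["sigma_between"]]
  lakes <- vector("list", n_lakes)
  for (i in seq_len(n_lakes)) {
    de <- elev[i] - elevation_range[1]
    cfg <- base_config
    cfg$sigma_within <- base_config$sigma_within * exp(sw_slope * de)
    cfg$sigma_between <- base_config$sigma_between * exp(sb_slope * de)
    cfg$elevation_m <- elev[i]
    cfg$area_ha <- areas[i]
    cfg$lake_id <- sprintf("L%02d", i)
    lakes[[i]] <- simulate_lake(cfg, seed = derive_seed(seed, "simulate", i))
  }
  truths <- dplyr::bind_rows(lapply(lakes, function(l) {
    tibble::tibble(lake_id = l$lake$lake_id,
                   elevation_m = l$lake$elevation_m,
                   area_ha = l$lake$area_ha,
                   true_wic_size = l$truth$true_wic_size,
                   true_bic_size = l$truth$true_bic_size,
                   true_tnw_size = l$truth$true_tnw_size,
                   expected_sample_bic_size = l$truth$expected_sample_bic_size,
                   true_tnw_taxa = l$truth$true_tnw_taxa,
                   true_iso_area = l$truth$true_iso_area)
  }))
  structure(list(
    diet = dplyr::bind_rows(lapply(lakes, `[[`, "diet")),
    fish = dplyr::bind_rows(lapply(lakes, `[[`, "fish")),
    lakes = dplyr::bind_rows(lapply(lakes, `[[`, "lake")),
    truths = truths,
    configs = lapply(lakes, `[[`, "config"),
    seed = seed),
    class = "synthetic_gradient")
}

#' Write a synthetic dataset to the CSV schema the readers accept
#'
#' Emits `diet.csv`, `fish.csv`, `lakes.csv` and `truth.json` into a
#' directory, in exactly the format [read_diet_csv()] and friends accept.
#'
#' @param x A `synthetic_lake` or `synthetic_gradient`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_csv <- function(x, dir) {
  stopifnot(inherits(x, c("synthetic_lake", "synthetic_gradient")))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lakes <- if (inherits(x, "synthetic_lake")) x$lake else x$lakes
  truth <- if (inherits(x, "synthetic_lake")) x$truth[
    setdiff(names(x$truth), "n_i")] else x$truths
  paths <- c(diet = file.path(dir, "diet.csv"),
             fish = file.path(dir, "fish.csv"),
             lakes = file.path(dir, "lakes.csv"),
             truth = file.path(dir, "truth.json"))
  readr::write_csv(x$diet, paths["diet"])
  readr::write_csv(x$fish[, c("fish_id", "lake_id", "standard_length_mm",
                              "wet_mass_g", "d13C", "d15N")], paths["fish"])
  readr::write_csv(lakes, paths["lakes"])
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# Zero-truncated Poisson by rejection (exact; cheap for lambda >= 1).
rztpois <- function(n, lambda) {
  out <- rpois(n, lambda)
  while (any(out == 0)) {
    z <- out == 0
    out[z] <- rpois(sum(z), lambda)
  }
  out
}

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  # at very small concentrations gamma draws can all underflow to zero; the
  # Dirichlet limit is then a point mass on one category drawn by weight
  zero <- rowSums(g) == 0
  if (any(zero)) {
    for (i in which(zero)) {
      g[i, sample.int(length(alpha), 1, prob = alpha)] <- 1
    }
  }
  sweep(g, 1, rowSums(g), "/")
}

rmvnorm2 <- function(n, mean, cov) {
  L <- chol(cov)
  z <- matrix(rnorm(n * 2), n, 2)
  sweep(z %*% L, 2, mean, "+")
}
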