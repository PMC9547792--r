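#' Per-lake niche metrics on both diet axes
#'
#' Computes, for one lake, the full set of diet-based niche statistics: the
#' prey-size decomposition (PNW/WIC/BIC with its Monte Carlo specialization
#' test and null BIC mean), the taxonomic Shannon decomposition with its
#' test, and Araujo's E with the null adjustment. Returned as a single tidy
#' row so per-lake rows stack straight into the regression battery.
#'
#' @inheritParams build_diet_matrix
#' @inheritParams null_continuous
#' @param log_sizes Analyze log-transformed prey lengths (default `FALSE`,
#'   raw mm).
#' @param weighting Individual weighting for the decompositions.
#' @return A one-row tibble: `lake_id`, `n_fish`, `n_items`, `pnw_size`,
#'   `wic_size`, `bic_size`, `bic_over_pnw_size`, `p_size`, `null_bic_size`,
#'   `pnw_taxa`, `wic_taxa`, `bic_taxa`, `bic_over_pnw_taxa`, `e`, `e_null`,
#'   `e_adj`, `p_taxa`, `median_prey_length`, `r_null`, `seed`.
#' @export
lake_metrics <- function(diet, lake = NULL,
                         scheme = c("order_stage_habitat", "order_stage", "order"),
                         log_sizes = FALSE, weighting = c("items", "equal"),
                         R = 999, seed) {
  scheme <- match.arg(scheme)
  weighting <- match.arg(weighting)
  if (missing(seed) || is.null(seed)) abort_config("an integer `seed` is required")
  mat <- build_diet_matrix(diet, lake, scheme)
  dtaxa <- decompose_shannon(mat, weighting)
  ntaxa <- null_categorical(mat, R = R, seed = derive_seed(seed, "metrics", 1))
  eadj <- e_adjusted(mat, R = R, seed = derive_seed(seed, "metrics", 2))
  size_row <- tryCatch({
    ss <- build_size_samples(diet, lake, log_transform = log_sizes)
    dsize <- decompose_continuous(ss, weighting)
    nsize <- null_continuous(ss, R = R, seed = derive_seed(seed, "metrics", 3),
                             weighting = weighting)
    list(pnw_size = dsize$tnw, wic_size = dsize$wic, bic_size = dsize$bic,
         bic_over_pnw_size = dsize$bic_over_tnw, p_size = nsize$p_value,
         null_bic_size = nsize$null_bic_mean,
         median_prey_length = median(ss$size))
  }, nichevar_error_data = function(e) {
    list(pnw_size = NA_real_, wic_size = NA_real_, bic_size = NA_real_,
         bic_over_pnw_size = NA_real_, p_size = NA_real_,
         null_bic_size = NA_real_, median_prey_length = NA_real_)
  })
  tibble::tibble(
    lake_id = attr(mat, "lake_id"),
    n_fish = nrow(mat), n_items = sum(mat),
    pnw_size = size_row$pnw_size, wic_size = size_row$wic_size,
    bic_size = size_row$bic_size,
    bic_over_pnw_size = size_row$bic_over_pnw_size,
    p_size = size_row$p_size, null_bic_size = size_row$null_bic_size,
    pnw_taxa = dtaxa$tnw, wic_taxa = dtaxa$wic, bic_taxa = dtaxa$bic,
    bic_over_pnw_taxa = dtaxa$bic_over_tnw,
    null_bic_taxa = ntaxa$null_bic_mean,
    e = eadj$e, e_null = eadj$e_null, e_adj = eadj$e_adj,
    p_taxa = eadj$p_value, p_taxa_wic = ntaxa$p_value,
    median_prey_length = size_row$median_prey_length,
    r_null = R, seed = seed)
}

#' Build the per-lake summary feeding the regression battery
#'
#' Runs [lake_metrics()] for every lake, adds the Bayesian isotopic niche
#' width (95% ellipse area with credible interval) from the fish table, the
#' lake covariates, and the mean position of each lake's fish along NMDS1
#' from a single ordination of all individuals across lakes (Bray-Curtis,
#' k dimensions, principal-axis rotation, NMDS1 sign anchored to total prey
#' count).
#'
#' @param diet Diet tibble covering all lakes ([read_diet_csv()] schema).
#' @param fish Fish tibble with isotope columns, or `NULL` to skip isotopes.
#' @param lakes Lake tibble (`lake_id`, `elevation_m`, `area_ha`), or `NULL`.
#' @inheritParams lake_metrics
#' @param n_draws_bayes Posterior draws for the isotope ellipse.
#' @param nmds_k,nmds_starts,nmds_transform Ordination options.
#' @param seed Master seed; stage seeds are derived deterministically.
#' @return A list of class `lake_summary_build`: `summary` (one row per
#'   lake), `nmds` (the `nmds_result`), `nmds_coords` (per-individual
#'   tibble), `ellipses` (per-lake `ellipse_posterior` list).
#' @export
build_lake_summary <- function(diet, fish = NULL, lakes = NULL,
                               scheme = "order_stage_habitat",
                               log_sizes = FALSE, weighting = "items",
                               R = 999, n_draws_bayes = 4000,
                               nmds_k = 3, nmds_starts = 20,
                               nmds_transform = "none", seed) {
  if (missing(seed) || is.null(seed)) abort_config("an integer `seed` is required")
  lake_ids <- unique(diet$lake_id)
  metrics <- dplyr::bind_rows(lapply(seq_along(lake_ids), function(i) {
    lake_metrics(diet, lake = lake_ids[i], scheme = scheme,
                 log_sizes = log_sizes, weighting = weighting, R = R,
                 seed = derive_seed(seed, "metrics", 100 + i))
  }))

  # one ordination across all lakes; fish ids namespaced by lake
  global <- diet
  global$fish_id <- paste(global$lake_id, global$fish_id, sep = "|")
  global$lake_id <- "all"
  gmat <- build_diet_matrix(global, lake = "all", scheme = scheme)
  d <- bray_curtis(gmat, transform = nmds_transform)
  ord <- nmds(d, k = nmds_k, n_starts = nmds_starts,
              seed = derive_seed(seed, "ordinate", 1),
              orient_by = rowSums(gmat))
  coords <- tidy(ord) %>%
    tidyr::separate(.data$id, into = c("lake_id", "fish_id"), sep = "\\|",
                    extra = "merge")
  mean_nmds1 <- coords %>%
    group_by(.data$lake_id) %>%
    summarise(mean_nmds1 = mean(.data$NMDS1), .groups = "drop")
  out <- left_join(metrics, mean_nmds1, by = "lake_id")

  ellipses <- NULL
  if (!is.null(fish) && all(c("d13C", "d15N") %in% names(fish))) {
    ellipses <- lapply(seq_along(lake_ids), function(i) {
      pts <- fish[fish$lake_id == lake_ids[i] & !is.na(fish$d13C), c("d13C", "d15N")]
      if (nrow(pts) < 3) return(NULL)
      ellipse_area_bayes(pts, n_draws = n_draws_bayes,
                         seed = derive_seed(seed, "isotope", i))
    })
    names(ellipses) <- lake_ids
    iso <- dplyr::bind_rows(lapply(lake_ids, function(l) {
      e <- ellipses[[l]]
      tibble::tibble(
        lake_id = l,
        pnw_iso = if (is.null(e)) NA_real_ else e$point_estimate,
        pnw_iso_lo = if (is.null(e)) NA_real_ else e$credible_interval[1],
        pnw_iso_hi = if (is.null(e)) NA_real_ else e$credible_interval[2],
        pnw_iso_ml = if (is.null(e)) NA_real_ else e$ml_area)
    }))
    out <- left_join(out, iso, by = "lake_id")
  }
  if (!is.null(lakes)) {
    out <- left_join(out, lakes[, c("lake_id", "elevation_m", "area_ha")],
                     by = "lake_id")
  }
  structure(list(summary = out, nmds = ord, nmds_coords = coords,
                 ellipses = ellipses, seed = seed),
            class = "lake_summary_build")
}

#' Fit the full regression battery over a lake summary
#'
#' Reproduces the study's inference table from a per-lake summary: population
#' niche widths against standardized elevation and lake area (linear); the
#' between- and within-individual components against their niche width per
#' axis (linear; the two slopes sum to 1 by construction); the proportional
#' contribution BIC/PNW and the adjusted specialization index against niche
#' width (beta regression, log-log link for the size axis and logit for the
#' taxonomic axis, following AIC selection on the field data); median prey
#' length and mean NMDS1 against niche width (linear); and the WIC-BIC
#' Pearson correlations per axis.
#'
#' @param summary A per-lake tibble as built by [build_lake_summary()];
#'   columns among `pnw_size`, `wic_size`, `bic_size`, `bic_over_pnw_size`,
#'   `pnw_taxa`, `wic_taxa`, `bic_taxa`, `bic_over_pnw_taxa`, `e_adj`,
#'   `pnw_iso`, `median_prey_length`, `mean_nmds1`, `elevation_m`, `area_ha`.
#'   Rows with missing modeled values are an error.
#' @param standardize_beta Standardize the PNW predictors of the beta
#'   regressions (default `FALSE`: raw predictors).
#' @param link_selection `"fixed"` (the links above) or `"aic"` (pick the
#'   best of logit/probit/cloglog/loglog per model).
#' @return A tibble of class `table1` with one row per slope or correlation:
#'   `figure`, `response`, `model`, `link`, `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, `f_statistic`, `df1`, `df2`, `r_squared`. The
#'   fitted objects are in `attr(, "fits")`.
#' @export
run_table1 <- function(summary, standardize_beta = FALSE,
                       link_selection = c("fixed", "aic")) {
  link_selection <- match.arg(link_selection)
  need <- c("pnw_size", "wic_size", "bic_size", "bic_over_pnw_size",
            "pnw_taxa", "wic_taxa", "bic_taxa", "bic_over_pnw_taxa",
            "e_adj", "median_prey_length", "mean_nmds1",
            "elevation_m", "area_ha")
  miss <- setdiff(need, names(summary))
  if (length(miss) > 0) {
    abort_schema(paste0("lake summary lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyNA(summary[, need])) abort_validation("modeled columns contain NA")
  d <- summary
  d$elev_z <- standardize(d$elevation_m)
  d$area_z <- standardize(d$area_ha)
  if (standardize_beta) {
    d$pnw_size_b <- standardize(d$pnw_size)
    d$pnw_taxa_b <- standardize(d$pnw_taxa)
  } else {
    d$pnw_size_b <- d$pnw_size
    d$pnw_taxa_b <- d$pnw_taxa
  }

  fits <- list()
  rows <- list()
  add_linear <- function(figure, response, formula) {
    f <- ols_fit(d, formula)
    fits[[paste(figure, response)]] <<- f
    g <- glance(f)
    cf <- tidy(f) %>% filter(.data$term != "(Intercept)")
    rows[[length(rows) + 1]] <<- mutate(cf,
      figure = figure, response = response, model = "linear", link = "identity",
      f_statistic = g$f_statistic, df1 = g$df1, df2 = g$df2,
      r_squared = g$r_squared)
  }
  add_beta <- function(figure, response, formula, link) {
    f <- if (link_selection == "aic") {
      beta_regression_aic(d, formula)$best
    } else {
      beta_regression(d, formula, link = link)
    }
    fits[[paste(figure, response)]] <<- f
    cf <- tidy(f) %>% filter(.data$term != "(Intercept)")
    rows[[length(rows) + 1]] <<- mutate(cf,
      figure = figure, response = response, model = "beta", link = f$link,
      f_statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
      r_squared = f$r_squared)
  }
  add_pearson <- function(figure, response, x, y) {
    ct <- pearson_test(d, {{ x }}, {{ y }})
    rows[[length(rows) + 1]] <<- tibble::tibble(
      term = "correlation", estimate = ct$r, std_error = NA_real_,
      statistic = ct$statistic, p_value = ct$p_value,
      figure = figure, response = response, model = "pearson",
      link = NA_character_, f_statistic = NA_real_, df1 = ct$df,
      df2 = NA_real_, r_squared = NA_real_)
  }

  add_linear("Fig1A", "pnw_size", pnw_size ~ elev_z + area_z)
  add_linear("Fig1B", "pnw_taxa", pnw_taxa ~ elev_z + area_z)
  if ("pnw_iso" %in% names(summary) && !anyNA(summary$pnw_iso)) {
    add_linear("Fig1C", "pnw_iso", pnw_iso ~ elev_z + area_z)
  }
  add_linear("Fig2A", "bic_size", bic_size ~ pnw_size)
  add_linear("Fig2A", "wic_size", wic_size ~ pnw_size)
  add_linear("Fig2D", "bic_taxa", bic_taxa ~ pnw_taxa)
  add_linear("Fig2D", "wic_taxa", wic_taxa ~ pnw_taxa)
  add_beta("Fig2B", "bic_over_pnw_size", bic_over_pnw_size ~ pnw_size_b, "loglog")
  add_beta("Fig2E", "bic_over_pnw_taxa", bic_over_pnw_taxa ~ pnw_taxa_b, "logit")
  add_beta("EadjModel", "e_adj", e_adj ~ pnw_taxa_b, "logit")
  add_linear("Fig3C", "median_prey_length", median_prey_length ~ pnw_size)
  add_linear("Fig3D", "mean_nmds1", mean_nmds1 ~ pnw_taxa)
  add_pearson("Fig2C", "wic_size-bic_size", wic_size, bic_size)
  add_pearson("Fig2F", "wic_taxa-bic_taxa", wic_taxa, bic_taxa)

  out <- dplyr::bind_rows(rows) %>%
    select(all_of(c("figure", "response", "model", "link", "term", "estimate",
                    "std_error", "statistic", "p_value", "f_statistic",
                    "df1", "df2", "r_squared")))
  attr(out, "fits") <- fits
  class(out) <- c("table1", class(out))
  out
}
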