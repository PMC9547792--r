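#' Pipeline run configuration
#'
#' Collects every knob of an end-to-end run: either paths to the three input
#' CSVs (`diet`, `fish`, `lakes`) or a synthetic-gradient description, plus
#' the analysis options of each stage. Validates eagerly so a bad run fails
#' before any work. All stage seeds derive deterministically from the master
#' seed.
#'
#' @param input Named list of CSV paths (`diet`, `fish`, `lakes`) or `NULL`
#'   to simulate.
#' @param synthetic Named list of arguments for [simulate_gradient()]
#'   (ignored when `input` is given); `NULL` means the defaults.
#' @param category_scheme Resource-category granularity (see
#'   [build_diet_matrix()]).
#' @param log_transform_sizes Analyze log prey lengths.
#' @param r_null Monte Carlo replicates for the specialization nulls
#'   (>= 99).
#' @param n_draws_bayes Posterior draws for the isotope ellipse (>= 1000).
#' @param nmds_k,nmds_starts,nmds_transform Ordination options.
#' @param n_perm PERMANOVA permutations.
#' @param seed Master seed (integer).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            category_scheme = "order_stage_habitat",
                            log_transform_sizes = FALSE,
                            r_null = 999, n_draws_bayes = 4000,
                            nmds_k = 3, nmds_starts = 20,
                            nmds_transform = "none",
                            n_perm = 999, seed = 1) {
  if (!is.null(input)) {
    if (!all(c("diet", "fish", "lakes") %in% names(input))) {
      abort_config("input must name diet, fish and lakes CSV paths")
    }
  }
  if (r_null < 99) abort_config("r_null must be at least 99")
  if (n_draws_bayes < 1000) abort_config("n_draws_bayes must be at least 1000")
  if (!category_scheme %in% c("order_stage_habitat", "order_stage", "order")) {
    abort_config("unknown category_scheme")
  }
  if (!nmds_transform %in% c("none", "sqrt", "wisconsin")) {
    abort_config("unknown nmds_transform")
  }
  structure(list(input = input, synthetic = synthetic,
                 category_scheme = category_scheme,
                 log_transform_sizes = isTRUE(log_transform_sizes),
                 r_null = as.integer(r_null),
                 n_draws_bayes = as.integer(n_draws_bayes),
                 nmds_k = as.integer(nmds_k),
                 nmds_starts = as.integer(nmds_starts),
                 nmds_transform = nmds_transform,
                 n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; unknown keys
#' are an error.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort_config(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/read -> per-lake niche metrics -> global ordination
#' and PERMANOVA -> isotope ellipses -> regression battery, and writes
#' `lake_summary.csv`, `table1.csv`, `nmds_coords.csv`, `permanova.csv` and
#' a `provenance.json` (config echo, derived seeds, package version,
#' exclusion counts) into `out_dir`. Identical (config, seed) runs produce
#' byte-identical CSVs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, created if needed; `NULL` writes nothing.
#' @return A list of class `niche_pipeline`: `lake_summary`, `table1`,
#'   `nmds_coords`, `permanova`, `build` (the [build_lake_summary()] result),
#'   `truths` (synthetic runs only), `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  truths <- NULL
  exclusions <- list()
  if (!is.null(config$input)) {
    diet <- read_diet_csv(config$input$diet)
    fish <- read_fish_csv(config$input$fish)
    lakes <- read_lake_csv(config$input$lakes)
  } else {
    args <- config$synthetic %||% list()
    args$seed <- args$seed %||% derive_seed(config$seed, "simulate", 0)
    sim <- do.call(simulate_gradient, args)
    diet <- sim$diet
    fish <- sim$fish
    lakes <- sim$lakes
    truths <- sim$truths
  }
  # exclusion rule: fish without any diet record never enter the matrices
  with_diet <- unique(paste(diet$lake_id, diet$fish_id))
  all_fish <- unique(paste(fish$lake_id, fish$fish_id))
  exclusions$fish_without_diet_records <- length(setdiff(all_fish, with_diet))
  exclusions$unmeasured_prey_items <- sum(is.na(diet$length_mm))

  build <- build_lake_summary(
    diet, fish = fish, lakes = lakes,
    scheme = config$category_scheme,
    log_sizes = config$log_transform_sizes,
    R = config$r_null, n_draws_bayes = config$n_draws_bayes,
    nmds_k = config$nmds_k, nmds_starts = config$nmds_starts,
    nmds_transform = config$nmds_transform,
    seed = config$seed)

  # PERMANOVA: diet composition of every fish with isotopes, across lakes
  perm <- NULL
  if (all(c("d13C", "d15N") %in% names(fish))) {
    global <- diet
    global$fish_id <- paste(global$lake_id, global$fish_id, sep = "|")
    global$lake_id <- "all"
    gmat <- build_diet_matrix(global, lake = "all", scheme = config$category_scheme)
    key <- paste(fish$lake_id, fish$fish_id, sep = "|")
    pred <- fish[match(rownames(gmat), key), c("d13C", "d15N")]
    keep <- stats::complete.cases(pred)
    exclusions$fish_without_isotopes <- sum(!keep)
    if (sum(keep) >= 5) {
      dsub <- stats::as.dist(as.matrix(bray_curtis(
        gmat[keep, colSums(gmat[keep, , drop = FALSE]) > 0, drop = FALSE],
        transform = config$nmds_transform)))
      perm <- permanova(dsub, pred[keep, ], n_perm = config$n_perm,
                        seed = derive_seed(config$seed, "ordinate", 2))
    }
  }

  tab1 <- run_table1(build$summary)
  provenance <- list(
    package_version = as.character(utils::packageVersion("nichevar")),
    config = config[setdiff(names(config), c("input", "synthetic"))],
    input = config$input,
    synthetic = !is.null(truths),
    master_seed = config$seed,
    exclusions = exclusions,
    n_lakes = nrow(build$summary),
    n_fish = length(all_fish))

  out <- structure(list(
    lake_summary = build$summary, table1 = tibble::as_tibble(tab1),
    nmds_coords = build$nmds_coords,
    permanova = if (is.null(perm)) NULL else tidy(perm),
    build = build, truths = truths, provenance = provenance),
    class = "niche_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(out$lake_summary, file.path(out_dir, "lake_summary.csv"))
    readr::write_csv(out$table1, file.path(out_dir, "table1.csv"))
    readr::write_csv(out$nmds_coords, file.path(out_dir, "nmds_coords.csv"))
    if (!is.null(out$permanova)) {
      readr::write_csv(out$permanova, file.path(out_dir, "permanova.csv"))
    }
    if (!is.null(truths)) {
      readr::write_csv(truths, file.path(out_dir, "truths.csv"))
    }
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

#' @export
print.niche_pipeline <- function(x, ...) {
  cat("<niche_pipeline>", nrow(x$lake_summary), "lakes,",
      x$provenance$n_fish, "fish; master seed", x$provenance$master_seed, "\n")
  cat("  lake_summary:", paste(dim(x$lake_summary), collapse = " x "),
      "| table1 rows:", nrow(x$table1), "\n")
  invisible(x)
}
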