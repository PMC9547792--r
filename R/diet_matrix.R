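#' Build an individuals-by-resource-category count matrix
#'
#' Cross-tabulates prey items into a count matrix with one row per fish and
#' one column per resource category. The category can be the taxonomic order
#' alone, order crossed with life stage, or the full order x life stage x
#' habitat triple (the default, the richest partition the records support).
#'
#' Fish with no prey records for the lake are absent from the matrix: empty
#' stomachs are an upstream exclusion, so every row sum is at least 1.
#'
#' @param diet A diet tibble as returned by [read_diet_csv()] or
#'   [simulate_lake()].
#' @param lake Optional lake id; if `NULL`, `diet` must contain one lake.
#' @param scheme Category granularity: `"order_stage_habitat"` (default),
#'   `"order_stage"`, or `"order"`.
#' @return An integer matrix of class `diet_matrix` (rows = fish, columns =
#'   categories sorted lexicographically), with attributes `lake_id` and
#'   `scheme`.
#' @export
#' @examples
#' diet <- tibble::tibble(
#'   lake_id = "L1", fish_id = c("a", "a", "a", "b"),
#'   prey_order = c("Diptera", "Diptera", "Ephemeroptera", "Diptera"),
#'   life_stage = "adult", habitat = "aquatic", length_mm = c(3, 4, 6, 3))
#' build_diet_matrix(diet, scheme = "order")
build_diet_matrix <- function(diet, lake = NULL,
                              scheme = c("order_stage_habitat", "order_stage", "order")) {
  scheme <- match.arg(scheme)
  diet <- subset_lake(diet, lake)
  if (nrow(diet) == 0) {
    abort_data("no diet records for this lake (empty population)")
  }
  cat_label <- switch(scheme,
    order = diet$prey_order,
    order_stage = paste(diet$prey_order, diet$life_stage, sep = ":"),
    order_stage_habitat = paste(diet$prey_order, diet$life_stage, diet$habitat, sep = ":"))
  fish <- factor(diet$fish_id, levels = unique(diet$fish_id))
  cats <- factor(cat_label, levels = sort(unique(cat_label)))
  counts <- table(fish, cats)
  m <- matrix(as.integer(counts), nrow = nlevels(fish),
              dimnames = list(levels(fish), levels(cats)))
  structure(m, class = c("diet_matrix", class(m)),
            lake_id = unique(diet$lake_id), scheme = scheme)
}

#' Extract per-individual prey-size samples
#'
#' Collects measurable prey lengths per fish, dropping unmeasured items and
#' omitting fish with no measurable items. Optionally natural-log transforms
#' lengths; the flag is recorded on the result so provenance survives.
#'
#' @inheritParams build_diet_matrix
#' @param log_transform Apply `log()` to lengths (default `FALSE`).
#' @return A tibble of class `size_samples` with columns `fish_id` and `size`,
#'   and attributes `lake_id` and `log_transform`.
#' @export
build_size_samples <- function(diet, lake = NULL, log_transform = FALSE) {
  diet <- subset_lake(diet, lake)
  diet <- diet[!is.na(diet$length_mm), , drop = FALSE]
  if (nrow(diet) == 0) {
    abort_data("no measurable prey lengths for this lake")
  }
  size <- if (log_transform) log(diet$length_mm) else diet$length_mm
  out <- tibble::tibble(fish_id = diet$fish_id, size = size)
  structure(out, class = c("size_samples", class(out)),
            lake_id = unique(diet$lake_id), log_transform = log_transform)
}

#' Convert a diet matrix back to long format
#'
#' Inverse of [build_diet_matrix()] up to row/column order and prey lengths
#' (which the count matrix does not retain). Category labels are split back
#' into their components when the scheme encodes them.
#'
#' @param mat A `diet_matrix`.
#' @return A tibble with one row per prey item.
#' @export
diet_matrix_to_long <- function(mat) {
  stopifnot(inherits(mat, "diet_matrix"))
  scheme <- attr(mat, "scheme")
  idx <- which(mat > 0, arr.ind = TRUE)
  rows <- rep(idx[, 1], mat[idx])
  cols <- rep(idx[, 2], mat[idx])
  lab <- colnames(mat)[cols]
  parts <- switch(scheme,
    order = list(order = lab, stage = "unknown", habitat = "unknown"),
    order_stage = {
      sp <- strsplit(lab, ":", fixed = TRUE)
      list(order = vapply(sp, `[`, "", 1), stage = vapply(sp, `[`, "", 2),
           habitat = "unknown")
    },
    order_stage_habitat = {
      sp <- strsplit(lab, ":", fixed = TRUE)
      list(order = vapply(sp, `[`, "", 1), stage = vapply(sp, `[`, "", 2),
           habitat = vapply(sp, `[`, "", 3))
    })
  tibble::tibble(
    lake_id = attr(mat, "lake_id"),
    fish_id = rownames(mat)[rows],
    prey_order = parts$order,
    life_stage = parts$stage,
    habitat = parts$habitat,
    length_mm = NA_real_
  ) %>% arrange(.data$fish_id, .data$prey_order)
}

#' @export
print.diet_matrix <- function(x, ...) {
  cat("<diet_matrix> lake ", attr(x, "lake_id"), ": ",
      nrow(x), " fish x ", ncol(x), " categories (scheme ",
      attr(x, "scheme"), "), ", sum(x), " prey items\n", sep = "")
  print(unclass(x))
  invisible(x)
}

# Row-proportion matrix p_ik.
diet_proportions <- function(mat) {
  sweep(unclass(mat), 1, rowSums(mat), "/")
}

subset_lake <- function(diet, lake) {
  stopifnot(is.data.frame(diet))
  need <- c("lake_id", "fish_id", "prey_order", "life_stage", "habitat", "length_mm")
  miss <- setdiff(need, names(diet))
  if (length(miss) > 0) {
    abort_schema(paste0("diet table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (!is.null(lake)) {
    diet <- diet[diet$lake_id == lake, , drop = FALSE]
  } else if (length(unique(diet$lake_id)) > 1) {
    abort_data("diet table contains multiple lakes; pass `lake`")
  }
  diet
}
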