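#' Decompose the prey-size niche into within- and between-individual parts
#'
#' Partitions the total population niche width on a continuous axis (here the
#' variance of prey size) into the within-individual component (WIC, the
#' weighted mean of individual diet variances) and the between-individual
#' component (BIC, the weighted variance of individual mean sizes), with
#' WIC + BIC = PNW exactly. Variances use the maximum-likelihood (divide by
#' n) form so the identity is exact: with item weights `w_i = n_i / N`, PNW
#' equals the ML variance of all pooled items.
#'
#' @param samples A `size_samples` tibble from [build_size_samples()], or any
#'   data frame with columns `fish_id` and `size`.
#' @param weighting `"items"` (default; individuals weighted by number of prey
#'   items, `w_i = n_i/N`) or `"equal"` (`w_i = 1/n_fish`; PNW is then defined
#'   through the same law-of-total-variance identity rather than the pooled
#'   item variance).
#' @return An object of class `niche_decomposition` with elements `axis`
#'   (`"size"`), `tnw`, `wic`, `bic`, `wic_over_tnw`, `bic_over_tnw`,
#'   `weighting`, `n_individuals`, `n_items` and a per-individual tibble
#'   `individuals` (`fish_id`, `n`, `w`, `mean`, `var`).
#' @export
#' @examples
#' s <- tibble::tibble(fish_id = c("a", "a", "b", "b"), size = c(1, 3, 5, 7))
#' decompose_continuous(s) # PNW 5, WIC 1, BIC 4
decompose_continuous <- function(samples, weighting = c("items", "equal")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(samples), all(c("fish_id", "size") %in% names(samples)))
  x <- samples$size
  id <- factor(samples$fish_id, levels = unique(samples$fish_id))
  if (nlevels(id) < 2) {
    abort_data("need at least 2 individuals to decompose the niche")
  }
  n_i <- as.numeric(tabulate(id))
  m_i <- as.numeric(tapply(x, id, mean))
  # ML within-individual variance: E[x^2] - E[x]^2 per individual
  s2_i <- as.numeric(tapply(x, id, function(v) mean(v^2) - mean(v)^2))
  w <- if (weighting == "items") n_i / sum(n_i) else rep(1 / length(n_i), length(n_i))
  wic <- sum(w * s2_i)
  mbar <- sum(w * m_i)
  bic <- sum(w * (m_i - mbar)^2)
  new_decomposition(
    axis = "size", tnw = wic + bic, wic = wic, bic = bic,
    weighting = weighting,
    individuals = tibble::tibble(fish_id = levels(id), n = as.integer(n_i),
                                 w = w, mean = m_i, var = s2_i),
    n_items = length(x))
}

#' Decompose the taxonomic (Shannon) niche into WIC and BIC
#'
#' Population niche width on the taxonomic axis is the Shannon-Weaver
#' diversity of the pooled diet, `PNW = -sum(q_k log q_k)` with pooled
#' proportions `q_k = sum_i w_i p_ik`. WIC is the weighted mean of individual
#' diet diversities and BIC = PNW - WIC, non-negative by concavity of the
#' entropy, zero exactly when every individual's proportions equal the pooled
#' proportions.
#'
#' @param mat A `diet_matrix` from [build_diet_matrix()], or any non-negative
#'   count matrix with one row per individual.
#' @inheritParams decompose_continuous
#' @param base Logarithm base for the entropy (default natural log, nats).
#' @return A `niche_decomposition` (axis `"taxa"`); see
#'   [decompose_continuous()].
#' @export
#' @examples
#' m <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
#' decompose_shannon(m) # PNW 0.693, WIC 0.562, BIC 0.131
decompose_shannon <- function(mat, weighting = c("items", "equal"), base = exp(1)) {
  weighting <- match.arg(weighting)
  mat <- as_count_matrix(mat)
  if (nrow(mat) < 2) abort_data("need at least 2 individuals to decompose the niche")
  n_i <- rowSums(mat)
  p <- sweep(mat, 1, n_i, "/")
  w <- if (weighting == "items") n_i / sum(n_i) else rep(1 / nrow(mat), nrow(mat))
  q <- colSums(p * w)
  tnw <- shannon_entropy(q, base)
  h_i <- apply(p, 1, shannon_entropy, base = base)
  wic <- sum(w * h_i)
  new_decomposition(
    axis = "taxa", tnw = tnw, wic = wic, bic = tnw - wic,
    weighting = weighting,
    individuals = tibble::tibble(fish_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
                                 n = as.integer(n_i), w = w, mean = NA_real_,
                                 var = h_i),
    n_items = sum(mat))
}

new_decomposition <- function(axis, tnw, wic, bic, weighting, individuals, n_items) {
  bic <- max(bic, 0) # guard tiny negative rounding on the taxa axis
  structure(list(
    axis = axis, tnw = tnw, wic = wic, bic = bic,
    wic_over_tnw = if (tnw > 0) wic / tnw else NA_real_,
    bic_over_tnw = if (tnw > 0) bic / tnw else NA_real_,
    weighting = weighting, individuals = individuals,
    n_individuals = nrow(individuals), n_items = n_items),
    class = "niche_decomposition")
}

#' @export
print.niche_decomposition <- function(x, ...) {
  cat("<niche_decomposition> axis:", x$axis,
      sprintf("(%d individuals, %d items, %s weighting)\n",
              x$n_individuals, x$n_items, x$weighting))
  cat(sprintf("  PNW = %.5g, WIC = %.5g, BIC = %.5g (BIC/PNW = %.3f)\n",
              x$tnw, x$wic, x$bic, x$bic_over_tnw))
  invisible(x)
}

#' @rdname decompose_continuous
#' @param x A `niche_decomposition`.
#' @param ... Unused.
#' @export
tidy.niche_decomposition <- function(x, ...) {
  tibble::tibble(
    component = c("tnw", "wic", "bic"),
    value = c(x$tnw, x$wic, x$bic),
    proportion = c(1, x$wic_over_tnw, x$bic_over_tnw))
}

#' @rdname decompose_continuous
#' @export
glance.niche_decomposition <- function(x, ...) {
  tibble::tibble(
    axis = x$axis, tnw = x$tnw, wic = x$wic, bic = x$bic,
    wic_over_tnw = x$wic_over_tnw, bic_over_tnw = x$bic_over_tnw,
    n_individuals = x$n_individuals, n_items = x$n_items,
    weighting = x$weighting)
}

as_count_matrix <- function(mat) {
  if (inherits(mat, "diet_matrix")) {
    m <- unclass(mat)
    attr(m, "lake_id") <- NULL
    attr(m, "scheme") <- NULL
  } else if (is.matrix(mat) && is.numeric(mat)) {
    m <- mat
  } else {
    abort_schema("expected a diet_matrix or a numeric count matrix")
  }
  if (any(m < 0)) abort_validation("counts must be non-negative")
  if (any(rowSums(m) == 0)) abort_data("all-zero rows (empty stomachs) are not allowed")
  m
}
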