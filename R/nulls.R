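#' Monte Carlo specialization test for the prey-size axis
#'
#' Tests the null hypothesis of no individual specialization: generalist
#' consumers sampling prey randomly from a shared distribution. Each replicate
#' redraws, for every individual, its `n_i` items with replacement from the
#' pooled empirical item multiset and recomputes WIC/PNW. The p-value is the
#' add-one Monte Carlo tail probability of a null WIC/PNW as small or smaller
#' than observed (specialized populations have low WIC/PNW). The mean of the
#' null BIC draws is retained for plotting against observed BIC, so sampling
#' effects can be judged by eye.
#'
#' @inheritParams decompose_continuous
#' @param R Number of Monte Carlo replicates (at least 99).
#' @param seed Integer seed; required for reproducibility.
#' @return An object of class `null_model` with elements `statistic_name`,
#'   `observed` (WIC/PNW), `null_draws`, `null_mean`, `null_bic`,
#'   `null_bic_mean`, `p_value`, `R`, `seed`.
#' @export
null_continuous <- function(samples, R = 999, seed, weighting = c("items", "equal")) {
  weighting <- match.arg(weighting)
  check_null_args(R, seed)
  stopifnot(is.data.frame(samples), all(c("fish_id", "size") %in% names(samples)))
  obs <- decompose_continuous(samples, weighting)
  x <- samples$size
  id <- factor(samples$fish_id, levels = unique(samples$fish_id))
  n_i <- as.numeric(tabulate(id))
  N <- length(x)
  w <- if (weighting == "items") n_i / N else rep(1 / nlevels(id), nlevels(id))
  if (var(x) == 0) {
    rlang::warn("all pooled items identical; specialization test is degenerate (p = 1)")
    return(new_null_model("wic_over_tnw_size", NA_real_, rep(NA_real_, R),
                          rep(NA_real_, R), 1, R, seed))
  }
  withr_seed(seed)
  g <- rep(seq_len(nlevels(id)), times = n_i)
  draws <- matrix(sample(x, N * R, replace = TRUE), nrow = N, ncol = R)
  s1 <- rowsum(draws, g, reorder = TRUE)
  s2 <- rowsum(draws^2, g, reorder = TRUE)
  m_i <- s1 / n_i
  v_i <- s2 / n_i - m_i^2
  wic_r <- colSums(w * v_i)
  mbar_r <- colSums(w * m_i)
  bic_r <- colSums(w * m_i^2) - mbar_r^2
  ratio_r <- wic_r / (wic_r + bic_r)
  obs_ratio <- obs$wic_over_tnw
  p <- (1 + sum(ratio_r <= obs_ratio)) / (R + 1)
  new_null_model("wic_over_tnw_size", obs_ratio, ratio_r, bic_r, p, R, seed)
}

#' Monte Carlo specialization test for the taxonomic axis
#'
#' Categorical analogue of [null_continuous()]: each replicate draws every
#' individual's diet as Multinomial(`n_i`, `q`) with `q` the pooled diet
#' proportions, then recomputes the Shannon WIC/PNW.
#'
#' @inheritParams null_continuous
#' @inheritParams decompose_shannon
#' @return A `null_model`; see [null_continuous()].
#' @export
null_categorical <- function(mat, R = 999, seed, weighting = c("items", "equal"),
                             base = exp(1)) {
  weighting <- match.arg(weighting)
  check_null_args(R, seed)
  m <- as_count_matrix(mat)
  obs <- decompose_shannon(m, weighting, base)
  if (ncol(m) < 2) {
    rlang::warn("single resource category; specialization test is degenerate (p = 1)")
    return(new_null_model("wic_over_tnw_taxa", 1, rep(1, R), rep(0, R), 1, R, seed))
  }
  n_i <- rowSums(m)
  N <- sum(n_i)
  q <- colSums(m) / N
  w <- if (weighting == "items") n_i / N else rep(1 / nrow(m), nrow(m))
  withr_seed(seed)
  wic_r <- numeric(R)
  pooled <- matrix(0, nrow = ncol(m), ncol = R)
  for (i in seq_len(nrow(m))) {
    cnt <- rmultinom(R, n_i[i], q) # K x R
    p_i <- cnt / n_i[i]
    h_i <- -colSums(ifelse(p_i > 0, p_i * log(p_i), 0)) / log(base)
    wic_r <- wic_r + w[i] * h_i
    pooled <- pooled + if (weighting == "items") cnt else p_i / nrow(m)
  }
  qs <- sweep(pooled, 2, colSums(pooled), "/")
  tnw_r <- -colSums(ifelse(qs > 0, qs * log(qs), 0)) / log(base)
  ratio_r <- ifelse(tnw_r > 0, wic_r / tnw_r, 1)
  bic_r <- tnw_r - wic_r
  obs_ratio <- obs$wic_over_tnw
  p <- (1 + sum(ratio_r <= obs_ratio)) / (R + 1)
  new_null_model("wic_over_tnw_taxa", obs_ratio, ratio_r, bic_r, p, R, seed)
}

#' Araujo's E: mean pairwise diet dissimilarity
#'
#' `E` is the mean over unordered pairs of individuals of one minus the
#' proportional similarity `PS_ij = sum_k min(p_ik, p_jk)` of their diet
#' proportion vectors. `E = 0` means identical diets for every individual;
#' `E = 1` means no overlap at all (complete specialization).
#'
#' @inheritParams decompose_shannon
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' e_index(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)) # 0.5
e_index <- function(mat) {
  m <- as_count_matrix(mat)
  if (nrow(m) < 2) abort_data("need at least 2 individuals for E")
  p <- sweep(m, 1, rowSums(m), "/")
  mean_pairwise_dissimilarity(p)
}

mean_pairwise_dissimilarity <- function(p) {
  n <- nrow(p)
  tot <- 0
  for (i in seq_len(n - 1)) {
    rest <- p[(i + 1):n, , drop = FALSE]
    ps <- rowSums(pmin(rest, rep(p[i, ], each = nrow(rest))))
    tot <- tot + sum(1 - ps)
  }
  tot / (n * (n - 1) / 2)
}

#' Null-adjusted Araujo's E
#'
#' Raw `E` is positive even for perfect generalists because finite stomachs
#' sample the shared prey distribution with noise. `E_adj` rescales `E`
#' against the Monte Carlo null mean `E_null` (individuals drawing their
#' `n_i` items as Multinomial(`n_i`, `q`)):
#' `E_adj = max(0, (E - E_null) / (1 - E_null))`, ranging from 0 when
#' `E = E_null` to 1 when individual diets have no overlap. The adjustment
#' makes lakes comparable when `E_null` varies with sample sizes.
#'
#' @inheritParams null_categorical
#' @return An object of class `e_adjusted` with elements `e`, `e_null`,
#'   `e_adj`, `p_value` (add-one tail probability of a null `E` at least as
#'   large as observed), `null_draws`, `R`, `seed`.
#' @export
e_adjusted <- function(mat, R = 999, seed) {
  check_null_args(R, seed)
  m <- as_count_matrix(mat)
  e_obs <- e_index(m)
  n <- nrow(m)
  K <- ncol(m)
  n_i <- rowSums(m)
  q <- colSums(m) / sum(m)
  withr_seed(seed)
  # one K x R block of multinomial draws per individual, then E per replicate
  blocks <- lapply(seq_len(n), function(i) rmultinom(R, n_i[i], q) / n_i[i])
  e_null_draws <- vapply(seq_len(R), function(r) {
    p <- matrix(vapply(blocks, function(b) b[, r], numeric(K)),
                nrow = n, ncol = K, byrow = TRUE)
    mean_pairwise_dissimilarity(p)
  }, numeric(1))
  e_null <- mean(e_null_draws)
  if (e_null >= 1) rlang::abort("E_null = 1 is impossible with finite counts", # nocov
                                class = "nichevar_error_internal")             # nocov
  p <- (1 + sum(e_null_draws >= e_obs)) / (R + 1)
  structure(list(e = e_obs, e_null = e_null,
                 e_adj = max(0, (e_obs - e_null) / (1 - e_null)),
                 p_value = p, null_draws = e_null_draws, R = R, seed = seed),
            class = "e_adjusted")
}

new_null_model <- function(name, observed, draws, bic_draws, p, R, seed) {
  structure(list(
    statistic_name = name, observed = observed, null_draws = draws,
    null_mean = mean(draws), null_bic = bic_draws,
    null_bic_mean = mean(bic_draws), p_value = p, R = R, seed = seed),
    class = "null_model")
}

check_null_args <- function(R, seed) {
  if (missing(seed) || is.null(seed)) abort_config("an integer `seed` is required")
  if (!is.numeric(R) || R < 99) abort_config("R must be at least 99")
}

withr_seed <- function(seed) set.seed(as.integer(seed))

#' @export
print.null_model <- function(x, ...) {
  cat("<null_model>", x$statistic_name,
      sprintf(": observed %.4f vs null mean %.4f (R = %d), p = %.4g\n",
              x$observed, x$null_mean, x$R, x$p_value))
  invisible(x)
}

#' @export
print.e_adjusted <- function(x, ...) {
  cat(sprintf("<e_adjusted> E = %.4f, E_null = %.4f, E_adj = %.4f, p = %.4g (R = %d)\n",
              x$e, x$e_null, x$e_adj, x$p_value, x$R))
  invisible(x)
}

#' @rdname null_continuous
#' @param x A `null_model`.
#' @param ... Unused.
#' @export
glance.null_model <- function(x, ...) {
  tibble::tibble(statistic = x$statistic_name, observed = x$observed,
                 null_mean = x$null_mean, null_bic_mean = x$null_bic_mean,
                 p_value = x$p_value, R = x$R, seed = x$seed)
}

#' @rdname e_adjusted
#' @param x An `e_adjusted`.
#' @param ... Unused.
#' @export
glance.e_adjusted <- function(x, ...) {
  tibble::tibble(e = x$e, e_null = x$e_null, e_adj = x$e_adj,
                 p_value = x$p_value, R = x$R, seed = x$seed)
}
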