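#' Bray-Curtis dissimilarities between individual diets
#'
#' Computes the Bray-Curtis dissimilarity
#' `d_ij = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk)` between the rows of a
#' diet count matrix, optionally after a square-root or Wisconsin double
#' standardization. The computation is delegated to [vegan::vegdist()].
#'
#' @inheritParams decompose_shannon
#' @param transform `"none"` (default), `"sqrt"`, or `"wisconsin"` (species
#'   maximum then site total standardization).
#' @return A `dist` object with labels, values in `[0, 1]`.
#' @export
bray_curtis <- function(mat, transform = c("none", "sqrt", "wisconsin")) {
  transform <- match.arg(transform)
  m <- as_count_matrix(mat)
  m <- switch(transform,
    none = m,
    sqrt = sqrt(m),
    wisconsin = vegan::wisconsin(m))
  vegan::vegdist(m, method = "bray")
}

#' Non-metric multidimensional scaling of diet dissimilarities
#'
#' Wraps [vegan::metaMDS()] (Kruskal stress-1, monotone regression by pooled
#' adjacent violators, multiple random starts plus a metric-scaling start)
#' and post-processes the best configuration: centered, rotated to principal
#' axes so axis 1 carries the maximum variance, and given a deterministic
#' sign. When `orient_by` is supplied, NMDS1 is flipped so its correlation
#' with that covariate is non-negative; otherwise each axis is flipped so its
#' largest-magnitude coordinate is positive.
#'
#' @param d A `dist` of dissimilarities, e.g. from [bray_curtis()].
#' @param k Number of dimensions (default 3).
#' @param n_starts Number of random starts (default 20).
#' @param max_iter Maximum iterations per start.
#' @param seed Integer seed for the random starts.
#' @param orient_by Optional numeric vector (one value per point, e.g. total
#'   prey count) fixing the sign of NMDS1.
#' @return An object of class `nmds_result`: `points` (n x k matrix, columns
#'   `NMDS1..NMDSk`), `stress` (Kruskal stress-1 in [0, 1]), `k`,
#'   `converged`, `n_starts`.
#' @export
nmds <- function(d, k = 3, n_starts = 20, max_iter = 500, seed = 1,
                 orient_by = NULL) {
  stopifnot(inherits(d, "dist"), k >= 1)
  withr_seed(seed)
  fit <- vegan::metaMDS(d, k = k, try = n_starts, trymax = n_starts,
                        maxit = max_iter, autotransform = FALSE,
                        wascores = FALSE, trace = 0)
  pts <- scale(fit$points, center = TRUE, scale = FALSE)
  # principal-axis rotation: variance maximized along NMDS1, then NMDS2, ...
  pc <- svd(pts)
  pts <- pts %*% pc$v
  for (j in seq_len(ncol(pts))) {
    flip <- if (j == 1 && !is.null(orient_by)) {
      stopifnot(length(orient_by) == nrow(pts))
      cor(pts[, 1], orient_by) < 0
    } else {
      pts[which.max(abs(pts[, j])), j] < 0
    }
    if (isTRUE(flip)) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("NMDS", seq_len(ncol(pts)))
  rownames(pts) <- labels(d)
  structure(list(points = pts, stress = fit$stress, k = k,
                 converged = isTRUE(fit$converged) || (is.numeric(fit$converged) && fit$converged > 0),
                 n_starts = n_starts, seed = seed),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("<nmds_result> k = %d, stress = %.4f, converged: %s (%d starts)\n",
              x$k, x$stress, x$converged, x$n_starts))
  invisible(x)
}

#' @rdname nmds
#' @param x An `nmds_result`.
#' @param ... Unused.
#' @export
tidy.nmds_result <- function(x, ...) {
  tibble::as_tibble(x$points, rownames = "id")
}

#' @rdname nmds
#' @export
glance.nmds_result <- function(x, ...) {
  tibble::tibble(k = x$k, stress = x$stress, converged = x$converged,
                 n_starts = x$n_starts, seed = x$seed)
}

#' PERMANOVA of diet composition on isotope predictors
#'
#' Distance-based permutational multivariate analysis of variance: the
#' dissimilarity matrix is Gower-centered and sequential (Type I) sums of
#' squares with pseudo-F statistics are computed per predictor, with p-values
#' from raw-row permutations (add-one tail probability). Delegates to
#' [vegan::adonis2()] with `by = "terms"`. With a univariate Euclidean
#' distance this reduces exactly to classical ANOVA F.
#'
#' @param d A `dist` of dissimilarities among individuals.
#' @param predictors A data frame of per-individual covariates (e.g. columns
#'   `d13C`, `d15N`), rows aligned with `d`.
#' @param n_perm Number of permutations; `0` returns statistics only
#'   (p absent).
#' @param seed Integer seed for the permutations.
#' @return An object of class `permanova_result`; its `table` element (also
#'   returned by `tidy()`) has columns `term`, `df`, `ss`, `r2`, `f`,
#'   `p_value`.
#' @export
permanova <- function(d, predictors, n_perm = 999, seed = 1) {
  stopifnot(inherits(d, "dist"), is.data.frame(predictors))
  n <- attr(d, "Size")
  if (nrow(predictors) != n) {
    abort_schema("predictors must have one row per individual in d")
  }
  if (anyNA(predictors)) abort_validation("predictors must be complete (no NA)")
  degenerate <- vapply(predictors, function(x) length(unique(x)) < 2, TRUE)
  if (any(degenerate)) {
    abort_data(paste0("constant predictor(s): ",
                      paste(names(predictors)[degenerate], collapse = ", ")))
  }
  withr_seed(seed)
  fml <- stats::as.formula(paste("d ~", paste(names(predictors), collapse = " + ")))
  fit <- vegan::adonis2(fml, data = predictors, permutations = max(n_perm, 0),
                        by = "terms")
  tab <- tibble::tibble(
    term = rownames(fit),
    df = fit$Df,
    ss = fit$SumOfSqs,
    r2 = fit$R2,
    f = fit$F,
    p_value = if (n_perm > 0) fit$`Pr(>F)` else NA_real_)
  structure(list(table = tab, n_perm = n_perm, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova_result> %d permutations\n", x$n_perm))
  print(x$table)
  invisible(x)
}

#' @rdname permanova
#' @param x A `permanova_result`.
#' @param ... Unused.
#' @export
tidy.permanova_result <- function(x, ...) x$table
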