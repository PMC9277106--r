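# Essential dynamics: covariance PCA of pocket features.
#
# Features are mean-centered but never variance-scaled (all columns share
# Angstrom units); eigenvalues use the unbiased F-1 denominator. The
# number of retained components is the smallest k whose cumulative
# variance fraction reaches `variance_threshold`, capped at `max_pcs`
# (defaults 0.90 and 15).

#' Fit a principal-component model of pocket motion
#'
#' @param features F x 3m feature matrix (see [extract_features()]).
#' @param variance_threshold Cumulative variance fraction to retain.
#' @param max_pcs Hard cap on retained components (`Inf` to disable).
#' @return An `eded_pca`: `mean`, `components` (rows, orthonormal),
#'   `eigenvalues` (Angstrom^2, non-increasing), `variance_fraction`,
#'   `cumulative_fraction`, `n_retained`, plus the two tuning knobs.
#' @export
fit_pca <- function(features, variance_threshold = 0.90, max_pcs = 15) {
  x <- unclass(features)
  if (nrow(x) < 2L) abort_eded("PCA needs at least 2 frames", "too_few_frames")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  total <- sum(ev)
  if (total <= .Machine$double.eps)
    abort_eded("all frames identical: zero total variance, PCA undefined",
               "zero_variance")
  rot <- p$rotation
  # deterministic sign: the largest-magnitude entry of each component is positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  frac <- ev / total
  cum <- cumsum(frac)
  n_ret <- min(which(cum >= variance_threshold - 1e-12)[1], max_pcs,
               length(ev))
  structure(list(mean = p$center, components = t(rot), eigenvalues = ev,
                 variance_fraction = frac, cumulative_fraction = cum,
                 n_retained = as.integer(n_ret),
                 variance_threshold = variance_threshold, max_pcs = max_pcs),
            class = "eded_pca")
}

#' @export
print.eded_pca <- function(x, ...) {
  cat(sprintf("<eded_pca> %d features, %d PCs retained (%.1f%% variance at threshold %.0f%%, cap %s)\n",
              length(x$mean), x$n_retained,
              100 * x$cumulative_fraction[x$n_retained],
              100 * x$variance_threshold, format(x$max_pcs)))
  invisible(x)
}

#' Project features onto the retained principal components
#'
#' @param features F x 3m matrix with the model's feature dimensionality.
#' @param model An `eded_pca`.
#' @param n_pcs Number of components to keep; defaults to the model's
#'   `n_retained`, `"all"` keeps every component.
#' @return F x n_pcs score matrix (class `eded_projection`).
#' @export
project <- function(features, model, n_pcs = NULL) {
  x <- unclass(features)
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$mean))
    abort_eded(sprintf("feature dimensionality %d does not match model (%d)",
                       ncol(x), length(model$mean)), "dimension_mismatch")
  if (identical(n_pcs, "all")) n_pcs <- nrow(model$components)
  n_pcs <- n_pcs %||% model$n_retained
  scores <- sweep(x, 2, model$mean) %*% t(model$components[seq_len(n_pcs), , drop = FALSE])
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  structure(scores, class = c("eded_projection", "matrix", "array"))
}

#' Back-project PC coordinates to approximate Cartesian features
#'
#' Reconstructs `mean + sum_k score_k * component_k` — the approximate
#' Cartesian image of a point in PC space (for example a cluster center).
#'
#' @param scores Vector or matrix of PC coordinates (k columns, k at most
#'   the number of model components).
#' @param model An `eded_pca`.
#' @return Feature vector(s) in the original 3m-dimensional space.
#' @export
reconstruct <- function(scores, model) {
  if (is.vector(scores)) scores <- matrix(scores, nrow = 1)
  scores <- unclass(scores)
  k <- ncol(scores)
  if (k > nrow(model$components))
    abort_eded(sprintf("%d score columns exceed the model's %d components",
                       k, nrow(model$components)), "dimension_mismatch")
  out <- scores %*% model$components[seq_len(k), , drop = FALSE]
  sweep(out, 2, model$mean, "+")
}
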