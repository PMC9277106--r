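# Conformational state selection: K-means in PC space, occupancy free
# energies, and one representative trajectory frame per state.
#
# Clusters are relabelled by descending population, so cluster 0 is the
# most populated state (S0) and also the free-energy reference. Relative
# free energies come from cluster occupancies, dG_conf(1,i) =
# -ln(N_i / N_1) in kT; a user-supplied vector can replace them at the
# scoring stage.

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (j in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1L, prob = probs), ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers
}

#' Cluster the projected trajectory into conformational states
#'
#' Standard squared-Euclidean K-means in retained-PC space with
#' k-means++-style seeding, run `restarts` times; the run with the lowest
#' total within-cluster sum of squares wins. Labels are renumbered by
#' descending population (cluster 0 = most populated).
#'
#' @param proj F x d PC score matrix (see [project()]).
#' @param k Number of clusters (default 4).
#' @param seed Integer RNG seed; the caller's RNG state is left untouched.
#' @param restarts Independent seeded runs (default 10).
#' @return An `eded_clusters`: `k`, `assignments` (0-based label per
#'   frame), `centers` (k x d), `populations`, `dg_conf` (kT),
#'   `inertia`, `seed`. Representatives are attached separately by
#'   [select_representatives()].
#' @export
kmeans_cluster <- function(proj, k = 4, seed = 1L, restarts = 10L) {
  x <- unclass(proj)
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (k < 1L) abort_eded("k must be >= 1", "bad_k")
  if (k > n) abort_eded(sprintf("k = %d exceeds the %d available frames", k, n), "bad_k")

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = kmeanspp_init(x, k),
                                       iter.max = 200L, algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(fit) || any(fit$size == 0L)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best))
    abort_eded(sprintf("K-means produced an empty cluster in all %d restarts", restarts),
               "empty_cluster")

  ord <- order(-best$size, seq_len(k))      # descending population, stable
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  assignments <- relabel[best$cluster] - 1L # 0-based, 0 = most populated
  centers <- best$centers[ord, , drop = FALSE]
  rownames(centers) <- paste0("S", seq_len(k) - 1L)
  populations <- as.vector(best$size[ord]) / n
  structure(list(k = as.integer(k), assignments = assignments,
                 centers = centers, populations = populations,
                 dg_conf = conf_free_energies(populations),
                 inertia = best$tot.withinss, seed = seed,
                 representative_frames = NULL),
            class = "eded_clusters")
}

#' @export
print.eded_clusters <- function(x, ...) {
  cat(sprintf("<eded_clusters> k = %d, populations: %s\n", x$k,
              paste(sprintf("%.3f", x$populations), collapse = " ")))
  invisible(x)
}

#' Relative conformational free energies from cluster populations
#'
#' In `"populations"` mode, dG_conf(1,i) = -ln(P_i / P_1) in kT, with the
#' most-populated cluster as reference (dG = 0). In `"equal"` mode every
#' conformation is treated as equally likely and all dG_conf are 0, the
#' limit in which the ensemble score reduces to equal weighting.
#'
#' @param populations Positive cluster population fractions, summing to 1.
#' @param mode `"populations"` (default) or `"equal"`.
#' @return Numeric vector of dG_conf in kT, one per cluster.
#' @export
conf_free_energies <- function(populations, mode = c("populations", "equal")) {
  mode <- match.arg(mode)
  if (any(populations <= 0))
    abort_eded("cluster populations must be strictly positive", "zero_population")
  if (abs(sum(populations) - 1) > 1e-6)
    abort_eded("cluster populations must sum to 1", "bad_populations")
  if (mode == "equal") return(rep(0, length(populations)))
  -log(populations / max(populations))
}

#' Pick the representative trajectory frame of each cluster
#'
#' For each cluster, the member frame closest to the cluster center is
#' selected; ties break to the lowest frame index. The default metric is
#' Euclidean distance in retained-PC space; `metric = "cartesian"`
#' measures instead against the back-projected center in feature space
#' (requires `model` and `features`).
#'
#' @param proj PC score matrix used for clustering.
#' @param ensemble An `eded_clusters`.
#' @param metric `"pc"` (default) or `"cartesian"`.
#' @param model,features Required for `metric = "cartesian"`: the
#'   `eded_pca` model and the original feature matrix.
#' @return Integer vector of frame indices (1-based), one per cluster in
#'   label order; also attached to a copy of `ensemble` if assigned back.
#' @export
select_representatives <- function(proj, ensemble, metric = c("pc", "cartesian"),
                                   model = NULL, features = NULL) {
  metric <- match.arg(metric)
  x <- unclass(proj)
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (metric == "cartesian" && (is.null(model) || is.null(features)))
    abort_eded("metric = 'cartesian' needs both `model` and `features`",
               "missing_argument")
  reps <- integer(ensemble$k)
  for (i in seq_len(ensemble$k)) {
    members <- which(ensemble$assignments == i - 1L)
    if (length(members) == 0L)
      abort_eded(sprintf("cluster %d has no member frames", i - 1L), "empty_cluster")
    if (metric == "pc") {
      pts <- x[members, , drop = FALSE]
      ctr <- ensemble$centers[i, ]
    } else {
      pts <- unclass(features)[members, , drop = FALSE]
      ctr <- as.vector(reconstruct(ensemble$centers[i, ], model))
    }
    d2 <- rowSums(sweep(pts, 2, ctr)^2)
    reps[i] <- members[which.min(d2)]   # which.min is first minimum: lowest index
  }
  reps
}
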