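# Plain-text persistence of pipeline intermediates (CSV + YAML sidecars),
# so every stage can be rerun standalone — in particular the seam between
# representative export and docking-score import, where docking happens
# outside this package.

#' Write / read the pocket definition (YAML)
#'
#' @param pocket An `eded_pocket`.
#' @param path YAML path.
#' @return The path (write) or an `eded_pocket` (read).
#' @export
write_pocket <- function(pocket, path) {
  write_yaml_full(list(cutoff = pocket$cutoff, source = pocket$source,
                        residues = lapply(seq_len(nrow(pocket$residues)), function(i)
                          as.list(pocket$residues[i, ]))), path)
  invisible(path)
}

#' @rdname write_pocket
#' @export
read_pocket <- function(path) {
  y <- yaml::read_yaml(path)
  residues <- do.call(rbind, lapply(y$residues, as.data.frame))
  residues$resno <- as.integer(residues$resno)
  structure(list(residues = residues, cutoff = y$cutoff, source = y$source),
            class = "eded_pocket")
}

#' Write / read a feature matrix (CSV plus YAML sidecar)
#'
#' Columns are `<chain>:<resno>:<resname>:<x|y|z>`; the sidecar records
#' residue order, alignment range and center-of-mass mode.
#'
#' @param features An `eded_features` matrix.
#' @param path CSV path (the sidecar is `<path>.yaml`).
#' @return The path (write) or an `eded_features` (read).
#' @export
write_features <- function(features, path) {
  utils::write.csv(as.data.frame(unclass(features)), path, row.names = FALSE)
  write_yaml_full(list(residue_order = attr(features, "residue_order"),
                        align_range = attr(features, "align_range"),
                        com_mode = attr(features, "com_mode")),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  meta <- if (file.exists(paste0(path, ".yaml"))) yaml::read_yaml(paste0(path, ".yaml"))
          else list()
  structure(m, class = c("eded_features", "matrix", "array"),
            residue_order = unlist(meta$residue_order),
            align_range = unlist(meta$align_range),
            com_mode = meta$com_mode %||% "residue")
}

#' Write / read a fitted PC model (flat CSV files plus YAML metadata)
#'
#' @param model An `eded_pca`.
#' @param dir Directory for `mean.csv`, `components.csv`,
#'   `eigenvalues.csv`, `meta.yaml`.
#' @return The directory (write) or an `eded_pca` (read).
#' @export
write_pca <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(mean = model$mean), file.path(dir, "mean.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(model$components),
                   file.path(dir, "components.csv"), row.names = FALSE)
  utils::write.csv(data.frame(eigenvalue = model$eigenvalues,
                              variance_fraction = model$variance_fraction,
                              cumulative_fraction = model$cumulative_fraction),
                   file.path(dir, "eigenvalues.csv"), row.names = FALSE)
  write_yaml_full(list(n_retained = model$n_retained,
                        variance_threshold = model$variance_threshold,
                        max_pcs = if (is.finite(model$max_pcs)) model$max_pcs else "Inf"),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_pca
#' @export
read_pca <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  ev <- utils::read.csv(file.path(dir, "eigenvalues.csv"))
  structure(list(
    mean = utils::read.csv(file.path(dir, "mean.csv"))$mean,
    components = as.matrix(utils::read.csv(file.path(dir, "components.csv"))),
    eigenvalues = ev$eigenvalue, variance_fraction = ev$variance_fraction,
    cumulative_fraction = ev$cumulative_fraction,
    n_retained = as.integer(meta$n_retained),
    variance_threshold = meta$variance_threshold,
    max_pcs = if (identical(meta$max_pcs, "Inf")) Inf else meta$max_pcs),
    class = "eded_pca")
}

#' Write / read PC scores (CSV)
#'
#' @param proj Score matrix from [project()].
#' @param path CSV path.
#' @return The path (write) or an `eded_projection` (read).
#' @export
write_scores <- function(proj, path) {
  utils::write.csv(as.data.frame(unclass(proj)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  structure(as.matrix(utils::read.csv(path, check.names = FALSE)),
            class = c("eded_projection", "matrix", "array"))
}

#' Write / read the cluster ensemble (assignments CSV + summary YAML)
#'
#' @param ensemble An `eded_clusters`.
#' @param csv_path Per-frame assignment CSV (`frame`, `cluster`).
#' @param yaml_path Ensemble summary YAML (k, seed, populations, dG_conf,
#'   centers, representative frames).
#' @return `yaml_path` (write) or an `eded_clusters` (read).
#' @export
write_clusters <- function(ensemble, csv_path, yaml_path) {
  utils::write.csv(data.frame(frame = seq_along(ensemble$assignments),
                              cluster = ensemble$assignments),
                   csv_path, row.names = FALSE)
  write_yaml_full(list(k = ensemble$k, seed = ensemble$seed,
                        populations = as.numeric(ensemble$populations),
                        dg_conf = as.numeric(ensemble$dg_conf),
                        inertia = ensemble$inertia,
                        centers = apply(ensemble$centers, 1, as.numeric,
                                        simplify = FALSE),
                        representative_frames =
                          as.list(ensemble$representative_frames)),
                   yaml_path)
  invisible(yaml_path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(csv_path, yaml_path) {
  df <- utils::read.csv(csv_path)
  y <- yaml::read_yaml(yaml_path)
  centers <- do.call(rbind, lapply(y$centers, unlist))
  rownames(centers) <- paste0("S", seq_len(y$k) - 1L)
  reps <- unlist(y$representative_frames)
  structure(list(k = as.integer(y$k), assignments = as.integer(df$cluster),
                 centers = centers, populations = unlist(y$populations),
                 dg_conf = unlist(y$dg_conf), inertia = y$inertia,
                 seed = y$seed,
                 representative_frames = if (length(reps)) as.integer(reps) else NULL),
            class = "eded_clusters")
}

#' Read experimental activity labels from CSV
#'
#' Expected columns: `compound_id`, `class` (e.g. strong / medium /
#' weak).
#'
#' @param path CSV path.
#' @return Data frame with `compound_id` and `class`.
#' @export
read_activity_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "class") %in% names(df)))
    abort_eded("labels CSV needs columns 'compound_id' and 'class'", "bad_labels")
  df
}
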