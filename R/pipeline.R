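# End-to-end pipeline: pocket -> features -> PCA -> clustering ->
# representatives -> (optional) ensemble scoring -> (optional)
# evaluation, with a YAML-configurable front end and a run manifest.
# Docking itself happens outside the package, between representative
# export and score import; both sides of that seam are persisted as
# plain text so the pipeline is resumable.

default_config <- function() {
  list(reference = NULL, trajectory = NULL, topology = NULL,
       scores = NULL, labels = NULL, out_dir = "ededock_run",
       ligand = "LIG", pocket_cutoff = 3.0, align_range = NULL,
       variance_threshold = 0.90, max_pcs = 15, k = 4, seed = 1L,
       restarts = 10L, temperature = 300, triage_cutoff = -9,
       com_mode = "residue", rep_metric = "pc",
       dg_conf_mode = "populations", dg_conf = NULL,
       active_classes = c("strong", "medium"), elbow_max_k = 8L)
}

#' Load and validate a pipeline configuration
#'
#' @param config A YAML file path or a named list; missing entries take
#'   the documented defaults (3 Angstrom pocket cutoff, 90% variance,
#'   15-PC cap, k = 4, 300 K, -9 kcal/mol triage cutoff).
#' @return A complete, validated config list.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (cfg$pocket_cutoff <= 0) abort_eded("pocket_cutoff must be positive", "bad_config")
  if (cfg$variance_threshold <= 0 || cfg$variance_threshold > 1)
    abort_eded("variance_threshold must lie in (0, 1]", "bad_config")
  if (cfg$k < 1) abort_eded("k must be >= 1", "bad_config")
  if (cfg$temperature <= 0) abort_eded("temperature must be positive", "bad_config")
  if (!cfg$com_mode %in% c("residue", "sidechain"))
    abort_eded("com_mode must be 'residue' or 'sidechain'", "bad_config")
  if (!cfg$rep_metric %in% c("pc", "cartesian"))
    abort_eded("rep_metric must be 'pc' or 'cartesian'", "bad_config")
  cfg
}

stage_error <- function(stage, e) {
  abort_eded(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             "stage_failure")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, ededock_error = function(e) stage_error(stage, e),
           error = function(e) stage_error(stage, e))
}

checksum <- function(paths) {
  paths <- paths[vapply(paths, function(p) is.character(p) && file.exists(p),
                        TRUE)]
  if (length(paths) == 0L) return(list())
  md5 <- tools::md5sum(unlist(paths))
  as.list(md5)
}

# paths relative to the run directory, so manifests (and their checksums)
# do not depend on where the run directory lives
rel_to <- function(paths, root) {
  root <- normalizePath(root, winslash = "/")
  vapply(paths, function(p) {
    p <- normalizePath(p, winslash = "/", mustWork = FALSE)
    sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1", root), "/?"), "", p)
  }, "", USE.NAMES = FALSE)
}

#' Run the full essential-dynamics ensemble docking pipeline
#'
#' Executes pocket selection, featurization, PCA, K-means clustering and
#' representative export; if a docking-score table is configured, scores
#' the compounds against the ensemble and triages them; if activity
#' labels are configured as well, evaluates the screen. All intermediates
#' land in `out_dir` as CSV/YAML/PDB, and a `manifest.yaml` records the
#' configuration, seed, package version, input checksums and every
#' per-stage output. Reruns with the same config and seed are
#' byte-identical.
#'
#' `reference` and `trajectory` may be file paths (PDB; trajectory also
#' multi-model PDB or DCD with a `topology` PDB) or in-memory
#' `eded_structure` / `eded_trajectory` objects.
#'
#' @param config YAML path or named list, see [load_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- load_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()

  ref <- run_stage("reference", {
    if (inherits(cfg$reference, "eded_structure")) cfg$reference
    else if (is.character(cfg$reference)) read_structure(cfg$reference, cfg$ligand)
    else abort_eded("config needs 'reference' (PDB path or structure)", "bad_config")
  })

  pocket <- run_stage("pocket", select_pocket(ref, cfg$pocket_cutoff))
  outputs$pocket <- write_pocket(pocket, file.path(out, "pocket.yaml"))

  traj <- run_stage("trajectory", {
    if (inherits(cfg$trajectory, "eded_trajectory")) cfg$trajectory
    else if (is.character(cfg$trajectory))
      read_trajectory(cfg$topology %||% cfg$trajectory, cfg$trajectory)
    else abort_eded("config needs 'trajectory' (path or trajectory object)", "bad_config")
  })

  features <- run_stage("features",
    extract_features(traj, pocket, ref, cfg$align_range, cfg$com_mode))
  outputs$features <- write_features(features, file.path(out, "features.csv"))

  model <- run_stage("reduce", fit_pca(features, cfg$variance_threshold, cfg$max_pcs))
  write_pca(model, file.path(out, "pca"))
  outputs$pca <- file.path(out, "pca",
                           c("mean.csv", "components.csv", "eigenvalues.csv",
                             "meta.yaml"))
  proj <- project(features, model)
  outputs$scores_pc <- write_scores(proj, file.path(out, "pc_scores.csv"))

  ensemble <- run_stage("cluster",
    kmeans_cluster(proj, cfg$k, cfg$seed, cfg$restarts))
  elbow <- run_stage("cluster", {
    ks <- seq_len(min(cfg$elbow_max_k, nrow(proj)))
    data.frame(k = ks, inertia = vapply(ks, function(kk)
      kmeans_cluster(proj, kk, cfg$seed, max(3L, cfg$restarts %/% 3L))$inertia, 0))
  })
  utils::write.csv(elbow, file.path(out, "elbow.csv"), row.names = FALSE)
  outputs$elbow <- file.path(out, "elbow.csv")

  ensemble$representative_frames <- run_stage("select",
    select_representatives(proj, ensemble, cfg$rep_metric,
                           model = model, features = features))
  outputs$clusters <- write_clusters(ensemble, file.path(out, "clusters.csv"),
                                     file.path(out, "ensemble.yaml"))
  outputs$representatives <- run_stage("select",
    write_representatives(traj, ensemble$representative_frames,
                          file.path(out, "representatives")))

  ranked <- eval_json <- NULL
  if (!is.null(cfg$scores)) {
    ctx <- thermal_context(cfg$temperature)
    tab <- run_stage("score", {
      if (inherits(cfg$scores, "eded_scores")) cfg$scores
      else if (is.character(cfg$scores) && file.exists(cfg$scores))
        read_score_table(cfg$scores)
      else abort_eded(sprintf("scores file not found: %s", cfg$scores), "missing_input")
    })
    dg_conf <- run_stage("score", {
      if (!is.null(cfg$dg_conf)) cfg$dg_conf
      else if (length(ensemble$populations) == length(tab$conformation_ids))
        conf_free_energies(ensemble$populations, cfg$dg_conf_mode)
      else abort_eded(sprintf(
        "score table has %d conformations but the ensemble has %d clusters",
        length(tab$conformation_ids), ensemble$k), "dimension_mismatch")
    })
    res <- run_stage("score",
      score_ensemble(tab, dg_conf, ctx, cfg$triage_cutoff))
    ranked <- res[order(res$ensemble_dg_bind), , drop = FALSE]
    rownames(ranked) <- NULL
    utils::write.csv(ranked, file.path(out, "ranked.csv"), row.names = FALSE)
    outputs$ranked <- file.path(out, "ranked.csv")

    if (!is.null(cfg$labels)) {
      labels <- run_stage("evaluate", {
        if (is.data.frame(cfg$labels)) cfg$labels
        else if (is.character(cfg$labels) && file.exists(cfg$labels))
          read_activity_labels(cfg$labels)
        else abort_eded(sprintf("labels file not found: %s", cfg$labels),
                        "missing_input")
      })
      ev <- run_stage("evaluate",
        evaluate_screen(res, labels, cfg$triage_cutoff, cfg$active_classes))
      jsonlite::write_json(ev, file.path(out, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null")
      outputs$evaluation <- file.path(out, "evaluation.json")
      dist <- merge(ranked[, c("compound_id", "ensemble_dg_bind")], labels,
                    by = "compound_id", all.x = TRUE, sort = TRUE)
      utils::write.csv(dist, file.path(out, "score_distribution.csv"),
                       row.names = FALSE)
      outputs$distribution <- file.path(out, "score_distribution.csv")
    }
  }

  cfg_serial <- cfg
  cfg_serial$out_dir <- "."      # the manifest lives inside the run directory
  cfg_serial$reference <- if (is.character(cfg$reference)) cfg$reference else "<in-memory>"
  cfg_serial$trajectory <- if (is.character(cfg$trajectory)) cfg$trajectory else "<in-memory>"
  cfg_serial$scores <- if (is.character(cfg$scores)) cfg$scores
                       else if (is.null(cfg$scores)) NULL else "<in-memory>"
  cfg_serial$labels <- if (is.character(cfg$labels)) cfg$labels
                       else if (is.null(cfg$labels)) NULL else "<in-memory>"
  out_files <- unlist(outputs)
  out_rel <- rel_to(out_files, out)
  out_md5 <- checksum(as.list(out_files))
  names(out_md5) <- out_rel
  outputs_rel <- utils::relist(out_rel, outputs)
  manifest <- list(
    package = "ededock",
    version = as.character(utils::packageVersion("ededock")),
    seed = cfg$seed,
    config = cfg_serial[order(names(cfg_serial))],
    input_checksums = checksum(list(cfg$reference, cfg$trajectory,
                                    cfg$scores, cfg$labels)),
    outputs = outputs_rel,
    output_checksums = out_md5)
  write_yaml_full(manifest, file.path(out, "manifest.yaml"))
  manifest$out_dir <- out
  invisible(manifest)
}

#' Write synthetic pipeline inputs with ground truth to disk
#'
#' Generates the four-state preset system ([make_multistate_system()]),
#' writes the reference complex, a multi-model PDB trajectory, a
#' docking-score table, activity labels derived from the true ensemble
#' scores, and a YAML manifest of the generative ground truth.
#'
#' @param out_dir Output directory.
#' @param seed Integer RNG seed.
#' @param n_frames Trajectory length (default 2000).
#' @param n_compounds Compounds in the score table (default 200).
#' @param noise_sigma Docking-score noise, kcal/mol.
#' @param missing_rate Missing-pose fraction.
#' @param rigid_jitter Apply per-frame rigid jitter to the trajectory.
#' @return List of written paths, invisibly.
#' @export
simulate_inputs <- function(out_dir, seed = 1L, n_frames = 2000L,
                            n_compounds = 200L, noise_sigma = 0.25,
                            missing_rate = 0, rigid_jitter = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sys <- make_multistate_system()
  ref_path <- file.path(out_dir, "reference.pdb")
  make_reference_complex(sys$geometry, file = ref_path)
  sim <- make_state_trajectory(sys$states, n_frames, seed = seed,
                               rigid_jitter = rigid_jitter,
                               geometry = sys$geometry)
  traj_path <- file.path(out_dir, "trajectory.pdb")
  write_trajectory(sim$trajectory, traj_path)
  sc <- make_score_table(sys$states, n_compounds, noise_sigma = noise_sigma,
                         missing_rate = missing_rate, seed = seed + 1L)
  scores_path <- file.path(out_dir, "scores.csv")
  write_score_table(sc$table, scores_path)
  # activity classes from the true ensemble scores: strong / medium / weak
  q <- stats::quantile(sc$true_ensemble, c(1 / 3, 2 / 3))
  cls <- cut(sc$true_ensemble, c(-Inf, q[1], q[2], Inf),
             labels = c("strong", "medium", "weak"))
  labels_path <- file.path(out_dir, "labels.csv")
  utils::write.csv(data.frame(compound_id = names(sc$true_ensemble),
                              class = as.character(cls)),
                   labels_path, row.names = FALSE)
  truth_path <- file.path(out_dir, "ground_truth.yaml")
  write_yaml_full(list(seed = seed,
                        populations = sim$populations,
                        dg_conf_true = as.numeric(sys$dg_conf_true),
                        state_labels = as.integer(sim$labels),
                        true_ensemble = as.list(sc$true_ensemble)),
                   truth_path)
  invisible(list(reference = ref_path, trajectory = traj_path,
                 scores = scores_path, labels = labels_path,
                 ground_truth = truth_path))
}
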