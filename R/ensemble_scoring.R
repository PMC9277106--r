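# Thermodynamically weighted aggregation of per-conformation docking
# scores, virtual-screening triage, and evaluation against activity
# classes.
#
# For a compound with docking scores dG_bind(i) (kcal/mol) against n
# receptor conformations with relative conformational free energies
# dG_conf(1,i) (kT, reference state 0), the ensemble binding score is
#
#   Ensemble dG_bind = kT * ln( sum_i e^{-dG_conf,i}
#                             / sum_i e^{-dG_conf,i - dG_bind,i/kT} )
#
# i.e. kT * ln(P_unbound / P_bound): the numerator sums the apo
# (unbound-receptor) Boltzmann weights of all n conformations, the
# denominator the Boltzmann weights of the corresponding complexes. Both
# partitions are evaluated on a max-shifted log-sum-exp path, so scores in
# [-50, 50] kcal/mol and dG_conf up to hundreds of kT are safe. High-energy
# receptor states contribute negligibly to either sum, which is the point:
# a favourable docking score against an irrelevant rare conformation
# cannot dominate the ensemble score as it would in a plain average.

#' Thermal context (temperature and kT)
#'
#' @param temperature Absolute temperature in K (default 300).
#' @return List with `temperature` (K) and `kT` (kcal/mol; 0.59616 at
#'   300 K, using R = 0.0019872041 kcal/(mol K)).
#' @export
thermal_context <- function(temperature = 300) {
  if (!is.finite(temperature) || temperature <= 0)
    abort_eded("temperature must be a positive number of kelvin", "bad_temperature")
  list(temperature = temperature, kT = .R_KCAL * temperature)
}

check_reference <- function(dg_conf) {
  if (any(dg_conf < -1e-9))
    abort_eded("dG_conf must be non-negative (reference state = 0)", "bad_reference")
  if (min(dg_conf) > 1e-9)
    abort_eded("no reference conformation: some dG_conf must be 0", "bad_reference")
}

#' Boltzmann-weighted ensemble binding score of one compound
#'
#' @param dg_bind Docking scores per conformation, kcal/mol (`NA` = no
#'   pose for that conformation; its term is omitted from the bound
#'   partition but the conformation still counts in the unbound one).
#' @param dg_conf Relative conformational free energies, kT, reference 0
#'   (see [conf_free_energies()]).
#' @param ctx A [thermal_context()].
#' @return List: `score` (kcal/mol), `contributions` (fraction of the
#'   bound partition per conformation; `NA` where the pose is missing),
#'   `n_used`, and `missing` (was any pose absent).
#' @export
ensemble_score <- function(dg_bind, dg_conf, ctx = thermal_context()) {
  if (length(dg_bind) != length(dg_conf))
    abort_eded(sprintf("%d scores vs %d conformations", length(dg_bind),
                       length(dg_conf)), "dimension_mismatch")
  check_reference(dg_conf)
  ok <- !is.na(dg_bind)
  if (!any(ok))
    abort_eded("all docking scores missing for this compound", "all_missing")
  kT <- ctx$kT
  log_unbound <- logsumexp(-dg_conf)
  terms <- rep(NA_real_, length(dg_bind))
  terms[ok] <- -dg_conf[ok] - dg_bind[ok] / kT
  log_bound <- logsumexp(terms[ok])
  contributions <- exp(terms - log_bound)
  list(score = kT * (log_unbound - log_bound),
       contributions = contributions,
       n_used = sum(ok), missing = any(!ok))
}

#' Equal-weighting ensemble score (all conformations equally likely)
#'
#' The limit of [ensemble_score()] with every dG_conf set to 0:
#' `kT * ln( n / sum_i e^{-dG_bind,i/kT} )`, with n the ensemble size
#' (missing poses still count toward n but not the sum).
#'
#' @inheritParams ensemble_score
#' @return The equal-weighting score, kcal/mol.
#' @export
equal_weight_score <- function(dg_bind, ctx = thermal_context()) {
  ok <- !is.na(dg_bind)
  if (!any(ok)) abort_eded("all docking scores missing", "all_missing")
  kT <- ctx$kT
  kT * (log(length(dg_bind)) - logsumexp(-dg_bind[ok] / kT))
}

#' Read a compound-by-conformation docking score table from CSV
#'
#' Expected layout: first column `compound_id`, one numeric column per
#' conformation; an empty cell is a missing pose.
#'
#' @param path CSV path.
#' @return An `eded_scores`: list with `compound_ids`,
#'   `conformation_ids`, and `dg_bind` (compound x conformation matrix,
#'   kcal/mol, `NA` = missing).
#' @export
read_score_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "compound_id")
    abort_eded("score CSV must have a leading 'compound_id' column plus one column per conformation",
               "bad_score_table")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$compound_id
  score_table(df$compound_id, colnames(m), m)
}

#' Construct a docking score table
#'
#' @param compound_ids Character vector.
#' @param conformation_ids Character vector, length n.
#' @param dg_bind Compound x conformation matrix, kcal/mol (`NA` allowed).
#' @return An `eded_scores` object.
#' @export
score_table <- function(compound_ids, conformation_ids, dg_bind) {
  dg_bind <- as.matrix(dg_bind)
  if (nrow(dg_bind) != length(compound_ids) ||
      ncol(dg_bind) != length(conformation_ids))
    abort_eded("score matrix dimensions do not match id vectors", "bad_score_table")
  none <- rowSums(!is.na(dg_bind)) == 0L
  if (any(none))
    abort_eded(sprintf("compound(s) with no docking score at all: %s",
                       paste(compound_ids[none], collapse = ",")), "all_missing")
  dimnames(dg_bind) <- list(compound_ids, conformation_ids)
  structure(list(compound_ids = as.character(compound_ids),
                 conformation_ids = as.character(conformation_ids),
                 dg_bind = dg_bind),
            class = "eded_scores")
}

#' Score every compound of a table against the conformational ensemble
#'
#' @param scores An `eded_scores` table (see [read_score_table()]).
#' @param dg_conf dG_conf per conformation, kT (length = number of
#'   conformation columns).
#' @param ctx A [thermal_context()].
#' @param cutoff Triage cutoff, kcal/mol (default -9): compounds scoring
#'   at or below it are predicted active.
#' @return Data frame with one row per compound: `compound_id`,
#'   `ensemble_dg_bind`, `n_conformations_used`, `missing_pose`,
#'   `predicted_active`, and one `contrib_<conformation>` column per
#'   conformation.
#' @export
score_ensemble <- function(scores, dg_conf, ctx = thermal_context(), cutoff = -9) {
  res <- lapply(seq_along(scores$compound_ids), function(i)
    ensemble_score(scores$dg_bind[i, ], dg_conf, ctx))
  contrib <- do.call(rbind, lapply(res, `[[`, "contributions"))
  colnames(contrib) <- paste0("contrib_", scores$conformation_ids)
  out <- data.frame(compound_id = scores$compound_ids,
                    ensemble_dg_bind = vapply(res, `[[`, 0, "score"),
                    n_conformations_used = vapply(res, `[[`, 0L, "n_used"),
                    missing_pose = vapply(res, `[[`, FALSE, "missing"),
                    stringsAsFactors = FALSE)
  out$predicted_active <- out$ensemble_dg_bind <= cutoff
  cbind(out, as.data.frame(contrib))
}

#' Partition scored compounds at a triage cutoff
#'
#' Predicted active iff `ensemble_dg_bind <= cutoff` (a score exactly at
#' the cutoff passes). Each partition is ordered by ascending score, best
#' first; ties keep input order.
#'
#' @param results Data frame from [score_ensemble()] (needs
#'   `ensemble_dg_bind`).
#' @param cutoff Triage cutoff, kcal/mol (default -9).
#' @return List with data frames `active` and `inactive`.
#' @export
triage <- function(results, cutoff = -9) {
  if (!is.finite(cutoff)) abort_eded("cutoff must be finite", "bad_cutoff")
  ord <- order(results$ensemble_dg_bind)
  sorted <- results[ord, , drop = FALSE]
  list(active = sorted[sorted$ensemble_dg_bind <= cutoff, , drop = FALSE],
       inactive = sorted[sorted$ensemble_dg_bind > cutoff, , drop = FALSE])
}

#' Evaluate triage predictions against experimental activity classes
#'
#' Compounds labelled with a class in `active_classes` count as truly
#' active; predictions come from the triage cutoff. Rates with an empty
#' denominator are reported as `NA` (undefined), never as 0.
#'
#' @param results Data frame from [score_ensemble()].
#' @param labels Data frame with columns `compound_id` and `class`
#'   (e.g. strong / medium / weak).
#' @param cutoff Triage cutoff, kcal/mol.
#' @param active_classes Classes counting as experimentally active.
#' @return List with confusion counts `tp`, `fp`, `tn`, `fn`, and
#'   `accuracy`, `fnr`, `fpr`.
#' @export
evaluate_screen <- function(results, labels, cutoff = -9,
                            active_classes = c("strong", "medium")) {
  idx <- match(results$compound_id, labels$compound_id)
  if (anyNA(idx))
    abort_eded(sprintf("unlabeled compound(s): %s",
                       paste(results$compound_id[is.na(idx)], collapse = ",")),
               "unlabeled_compound")
  truth <- labels$class[idx] %in% active_classes
  pred <- results$ensemble_dg_bind <= cutoff
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  rate <- function(num, den) if (den == 0L) NA_real_ else num / den
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = rate(tp + tn, tp + fp + tn + fn),
       fnr = rate(fn, fn + tp), fpr = rate(fp, fp + tn))
}

#' Summarise the top-scoring fraction of a screen
#'
#' Selects the best `ceiling(top_fraction * N)` compounds by ascending
#' ensemble score and reports summary statistics of their scores, the
#' screening-wide analogue of "mean score of the top 2.5%".
#'
#' @param results Data frame from [score_ensemble()].
#' @param top_fraction Fraction in (0, 1] (default 0.025).
#' @return List: `n_top`, `mean`, `median`, `sd`, `min`, `max`
#'   (kcal/mol), and `scores` (the selected scores, ascending).
#' @export
screen_summary <- function(results, top_fraction = 0.025) {
  if (nrow(results) == 0L) abort_eded("no scored compounds", "empty_results")
  if (top_fraction <= 0 || top_fraction > 1)
    abort_eded("top_fraction must lie in (0, 1]", "bad_fraction")
  s <- sort(results$ensemble_dg_bind)
  m <- ceiling(top_fraction * length(s))
  top <- s[seq_len(m)]
  list(n_top = m, mean = mean(top), median = stats::median(top),
       sd = if (m > 1L) stats::sd(top) else 0, min = top[1], max = top[m],
       scores = top)
}
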