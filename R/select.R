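# Importance ranking, elbow cutoff and the iterative selection loop.
#
# Each iteration averages the per-model importances, ranks features in
# decreasing order, and cuts the ranked curve at its elbow: both axes are
# min-max normalized to [0, 1] and the cutoff sits at the point of maximum
# perpendicular distance below the chord joining the first and last points
# (the rotation-equivalent form of the kneebow method, which makes the
# cutoff invariant to positive rescaling of the importances).  Features
# strictly above that point are "Significant".

#' Average and rank per-model feature importances
#'
#' @param importances a list of named numeric vectors (one per model, same
#'   feature set), or a models x features matrix.
#' @return A `ranked_importances` data.frame with columns `feature` and
#'   `importance`, sorted by decreasing importance (stable ties), and the
#'   elbow cutoff as attribute `cutoff_index` (the number of significant
#'   features).
#' @export
rank_features <- function(importances) {
  if (is.list(importances)) {
    ids <- names(importances[[1]])
    same <- vapply(importances, function(v) identical(names(v), ids),
                   logical(1))
    if (!all(same)) stop("models report mismatched feature sets")
    importances <- do.call(rbind, importances)
  }
  avg <- colMeans(importances)
  ord <- order(-avg)  # stable: ties keep input order
  ranked <- data.frame(feature = names(avg)[ord], importance = avg[ord],
                       row.names = NULL)
  attr(ranked, "cutoff_index") <- find_cutoff(ranked$importance)
  class(ranked) <- c("ranked_importances", "data.frame")
  ranked
}

#' Elbow cutoff on a decreasing importance curve
#'
#' Both axes (rank position, importance) are min-max normalized to `[0, 1]`;
#' the elbow is the point of maximum perpendicular distance below the chord
#' from the first to the last point, and the significant set is everything
#' strictly before it.  Degenerate curves (fewer than 3 points, constant, or
#' nowhere below the chord) retain all features with a warning — the method
#' never silently selects zero features.
#'
#' @param values numeric vector sorted in decreasing order.
#' @return The number of significant features (an integer in `[1,
#'   length(values)]`), with the elbow position as attribute
#'   `"elbow_index"`.
#' @export
find_cutoff <- function(values) {
  n <- length(values)
  if (is.unsorted(rev(values))) stop("values must be sorted decreasing")
  if (n < 3L) {
    warning("fewer than 3 features; retaining all")
    return(structure(n, elbow_index = NA_integer_))
  }
  if (max(values) == min(values)) {
    warning("constant importance curve has no elbow; retaining all features")
    return(structure(n, elbow_index = NA_integer_))
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (values - min(values)) / (max(values) - min(values))
  # chord runs from (0, 1) to (1, 0); signed gap below it is (1 - x) - y
  gap <- (1 - x) - y
  if (max(gap) <= 0) {
    warning("curve is nowhere below its chord (no convex elbow); retaining all features")
    return(structure(n, elbow_index = NA_integer_))
  }
  e <- which.max(gap)
  structure(e - 1L, elbow_index = as.integer(e))
}

#' Significant features of a ranked importance list
#'
#' @param ranked a [rank_features()] result.
#' @return Character vector of the features above the elbow, in decreasing
#'   importance order.
#' @export
significant_features <- function(ranked) {
  ranked$feature[seq_len(attr(ranked, "cutoff_index"))]
}

#' Run the iterative selection loop of one run
#'
#' Iteration 0 trains the ensemble on the full feature set; each subsequent
#' iteration restricts the raw profile to the previous iteration's
#' significant features, re-applies the configured treatment to the subset
#' (term-frequency denominators shrink, so this is not a no-op), and
#' retrains with the run's fixed test and validation sets.  The loop skips
#' vacuous retraining once 2 or fewer features remain.
#'
#' @param x raw (untreated) profile matrix, samples x features.
#' @param y a [label_vector()].
#' @param plan a [make_split_plan()] result.
#' @param n_iterations number of training iterations (default 5).
#' @param importance_metric `"gini"` or `"shap"`.
#' @param grid hyperparameter grid for [train_rf_ensemble()].
#' @param treatment data treatment re-applied at each subset
#'   (`"none"`, `"tf_igm"`, `"scaling"`).
#' @param lambda_ TF-IGM lambda.
#' @return A `run_result`: lists `iterations` (one `iteration_result` per
#'   level) and `selections` (the ranked list and significant set derived
#'   from each level's models).
#' @export
iterate_selection <- function(x, y, plan, n_iterations = 5,
                              importance_metric = c("gini", "shap"),
                              grid = default_rf_grid(),
                              treatment = c("none", "tf_igm", "scaling"),
                              lambda_ = 7) {
  importance_metric <- match.arg(importance_metric)
  treatment <- match.arg(treatment)
  x <- as.matrix(x)
  features <- colnames(x)
  iterations <- list()
  selections <- list()
  for (j in seq_len(n_iterations) - 1L) {
    if (length(features) <= 2L) break
    xj <- apply_treatment(x[, features, drop = FALSE], treatment,
                          lambda_ = lambda_)
    iter <- train_rf_ensemble(xj, y, plan, importance_metric = importance_metric,
                              grid = grid, iteration_index = j)
    ranked <- rank_features(lapply(iter$models, `[[`, "importance"))
    sel <- significant_features(ranked)
    iterations[[j + 1L]] <- iter
    selections[[j + 1L]] <- list(
      run_index = plan$run_index, iteration_index = j,
      ranked = ranked, features = sel,
      median_test_auc = iter$median_test_auc,
      median_validation_auc = iter$median_validation_auc
    )
    if (length(sel) == 0L) break
    features <- sel
  }
  structure(list(run_index = plan$run_index, plan = plan,
                 iterations = iterations, selections = selections,
                 n_requested = n_iterations),
            class = "run_result")
}

#' Check that selection did not degrade classification performance
#'
#' One-sided Wilcoxon signed-rank test (alpha = 0.05) of whether the
#' later iteration's per-forest test AUCs are lower than the earlier
#' iteration's, paired by forest (the validation and test subsets are shared
#' across iterations within a run).  A degradation triggers a warning, never
#' an abort.
#'
#' @param iter0,iter1 two `iteration_result`s from the same run.
#' @return `"ok"` or `"degraded"` (invisibly warns when degraded).
#' @export
check_selection_validity <- function(iter0, iter1) {
  a0 <- vapply(iter0$models, `[[`, 1, "auc_test")
  a1 <- vapply(iter1$models, `[[`, 1, "auc_test")
  if (all(a1 == a0)) return("ok")
  p <- suppressWarnings(
    wilcox.test(a1, a0, paired = TRUE, alternative = "less", exact = FALSE)
  )$p.value
  if (!is.na(p) && p < 0.05) {
    warning(sprintf(
      "classification performance dropped after selection (p = %.3g)", p
    ))
    "degraded"
  } else {
    "ok"
  }
}

#' Export a ranked importance list with its significance labels
#'
#' @param ranked a [rank_features()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ranked_importances <- function(ranked, path) {
  cut <- attr(ranked, "cutoff_index")
  out <- data.frame(ranked,
                    status = ifelse(seq_len(nrow(ranked)) <= cut,
                                    "Significant", "Non Significant"))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
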