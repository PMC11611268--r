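# Seeded ensemble training.
#
# One "run" fixes a held-out test subset (20% of the samples, stratified by
# class).  Within a run, each of the n_forests models gets its own validation
# subset (20% of the non-test samples, stratified) and is tuned by a
# grid search with 5-fold cross-validation on its training split.  Every
# random choice is a pure function of (base_seed, run_index, forest_index):
#   seed(run, forest) = base_seed + 1000 * run + forest
# with forest 0 reserved for the test-set draw.

#' Area under the ROC curve (rank-based, midrank ties)
#'
#' Equals the Mann-Whitney U statistic divided by n1 * n0.
#'
#' @param scores numeric prediction scores (higher = more likely class 1).
#' @param truth binary truth vector (0/1, or a [label_vector()]).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, truth) {
  truth <- as.integer(unclass(truth))
  if (length(unique(truth)) != 2L) stop("both classes must be present in truth")
  r <- rank(scores)  # midranks for ties
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

seed_for <- function(base_seed, run_index, forest_index) {
  as.integer(base_seed + 1000L * run_index + forest_index)
}

# Stratified draw of round(fraction * n_class) ids per class.
stratified_draw <- function(ids, y, fraction) {
  unlist(lapply(split(ids, y[ids]), function(class_ids) {
    sample(class_ids, round(fraction * length(class_ids)))
  }), use.names = FALSE)
}

#' Build the split plan of one run
#'
#' Draws the run's test subset (fixed for every iteration of the run and
#' shared by taxonomic and functional profiles) and one validation subset
#' per forest from the remaining samples.  Splits are stratified by class by
#' default; a user-supplied pre-conceived test set is honored as-is.
#'
#' @param labels a [label_vector()].
#' @param run_index run number (1-based).
#' @param base_seed integer base seed.
#' @param test_fraction fraction of all samples set aside as the test set
#'   (default 0.2).
#' @param validation_fraction fraction of the non-test samples used as each
#'   forest's validation set (default 0.2).
#' @param n_forests number of models per iteration (default 20).
#' @param stratify stratify the draws by class (default `TRUE`).
#' @param test_ids optional character vector of pre-conceived test sample
#'   ids (overrides the random draw).
#' @return A `split_plan` object.
#' @export
make_split_plan <- function(labels, run_index, base_seed,
                            test_fraction = 0.2, validation_fraction = 0.2,
                            n_forests = 20, stratify = TRUE, test_ids = NULL) {
  y <- labels
  ids <- names(y)
  if (min(table(unclass(y))) < 2L) stop("need at least 2 samples per class")
  if (is.null(test_ids)) {
    set.seed(seed_for(base_seed, run_index, 0L))
    test_ids <- if (stratify) {
      stratified_draw(ids, y, test_fraction)
    } else {
      sample(ids, round(test_fraction * length(ids)))
    }
  } else {
    stopifnot(all(test_ids %in% ids))
  }
  pool <- setdiff(ids, test_ids)
  if (length(unique(unclass(y)[pool])) < 2L) {
    stop("a class is absent from the training pool")
  }
  validation <- lapply(seq_len(n_forests), function(k) {
    set.seed(seed_for(base_seed, run_index, k))
    for (attempt in 1:25) {
      v <- if (stratify) {
        stratified_draw(pool, y, validation_fraction)
      } else {
        sample(pool, round(validation_fraction * length(pool)))
      }
      train <- setdiff(pool, v)
      if (length(unique(unclass(y)[train])) == 2L &&
          length(unique(unclass(y)[v])) == 2L) {
        return(v)
      }
    }
    stop("could not draw a validation split leaving both classes in training")
  })
  structure(list(run_index = run_index, base_seed = base_seed,
                 test_ids = sort(test_ids), train_pool = pool,
                 validation_ids = validation, n_forests = n_forests),
            class = "split_plan")
}

#' Default random-forest hyperparameter grid
#'
#' Three tuned axes: the number of trees per forest, the depth cap standing
#' for the number of leaves per tree (0 = unlimited), and the share of
#' features each split may consult.
#'
#' @param num_trees,max_depth,mtry_mode candidate values for each axis;
#'   `mtry_mode` entries are `"sqrt"`, `"log2"` or a numeric fraction of the
#'   feature count.
#' @return A data.frame with one row per candidate configuration.
#' @export
default_rf_grid <- function(num_trees = c(50, 100, 200),
                            max_depth = c(0, 6, 7),
                            mtry_mode = list("sqrt", "log2", 0.5)) {
  grid <- expand.grid(num_trees = num_trees, max_depth = max_depth,
                      mtry_i = seq_along(mtry_mode))
  grid$mtry_mode <- unlist(mtry_mode)[grid$mtry_i]
  grid$mtry_i <- NULL
  grid
}

#' A single-configuration grid for quick, desk-scale experiments
#' @return A one-row grid (100 trees, unlimited depth, sqrt mtry).
#' @export
small_rf_grid <- function() {
  default_rf_grid(num_trees = 100, max_depth = 0, mtry_mode = list("sqrt"))
}

resolve_mtry <- function(mode, p) {
  m <- if (identical(mode, "sqrt")) {
    sqrt(p)
  } else if (identical(mode, "log2")) {
    log2(p)
  } else {
    as.numeric(mode) * p
  }
  max(1L, min(p, floor(m)))
}

balanced_weights <- function(y_factor) {
  tab <- table(y_factor)
  w <- length(y_factor) / (length(tab) * tab)
  as.numeric(w)  # ordered by factor levels
}

fit_ranger <- function(x, y01, cfg, seed) {
  df <- data.frame(..y = factor(y01, levels = c(0, 1)), x,
                   check.names = FALSE)
  ranger::ranger(
    dependent.variable.name = "..y", data = df,
    num.trees = cfg$num_trees,
    max.depth = cfg$max_depth,
    mtry = resolve_mtry(cfg$mtry_mode, ncol(x)),
    probability = TRUE, importance = "impurity",
    class.weights = balanced_weights(factor(y01, levels = c(0, 1))),
    seed = seed, num.threads = 1
  )
}

predict_prob <- function(fit, x) {
  if (inherits(fit, "ranger")) {
    p <- predict(fit, data.frame(x, check.names = FALSE),
                 num.threads = 1)$predictions
    p[, "1"]
  } else {  # e1071 svm
    attr(predict(fit, x, probability = TRUE), "probabilities")[, "1"]
  }
}

cv_folds <- function(y01, k = 5) {
  # stratified fold assignment; relies on the caller having seeded the RNG
  fold <- integer(length(y01))
  for (cls in unique(y01)) {
    idx <- sample(which(y01 == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

grid_search_cv <- function(x, y01, grid, seed, fit_fun, k = 5) {
  if (nrow(grid) == 1L) return(1L)
  set.seed(seed)
  fold <- cv_folds(y01, k)
  cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
    scores <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      te <- fold == f
      if (length(unique(y01[te])) < 2L || length(unique(y01[tr])) < 2L) {
        return(NA_real_)
      }
      fit <- fit_fun(x[tr, , drop = FALSE], y01[tr], grid[g, , drop = FALSE],
                     seed + g)
      auc(predict_prob(fit, x[te, , drop = FALSE]), y01[te])
    }, numeric(1))
    mean(scores, na.rm = TRUE)
  }, numeric(1))
  which.max(cv_auc)  # ties -> first configuration
}

youden_threshold <- function(scores, truth) {
  truth <- as.integer(unclass(truth))
  cand <- sort(unique(scores))
  j <- vapply(cand, function(th) {
    tpr <- mean(scores[truth == 1L] >= th)
    fpr <- mean(scores[truth == 0L] >= th)
    tpr - fpr
  }, numeric(1))
  cand[which.max(j)]
}

#' Train one iteration's ensemble of random forests
#'
#' Trains `plan$n_forests` grid-searched random forests (balanced class
#' weights, Gini split criterion, 5-fold cross-validated grid search on each
#' forest's training split), records train/validation/test AUCs, the chosen
#' hyperparameters, a Youden-optimal probability threshold, and per-feature
#' importances (normalized Gini mean impurity decrease, or mean |SHAP| over
#' the validation samples under the path-dependent tree algorithm).
#'
#' @param x treated profile matrix (samples x features).
#' @param y a [label_vector()].
#' @param plan a [make_split_plan()] result.
#' @param importance_metric `"gini"` or `"shap"`.
#' @param grid hyperparameter grid, see [default_rf_grid()].
#' @param iteration_index 0-based iteration number (recorded).
#' @return An `iteration_result`: per-model records, median validation and
#'   test AUCs, and the importance vector averaged over the ensemble.
#' @export
train_rf_ensemble <- function(x, y, plan, importance_metric = c("gini", "shap"),
                              grid = default_rf_grid(), iteration_index = 0L) {
  importance_metric <- match.arg(importance_metric)
  train_ensemble(x, y, plan, kind = "rf", grid = grid,
                 importance_metric = importance_metric,
                 iteration_index = iteration_index)
}

#' Default SVM hyperparameter grid
#'
#' Tunes the regularization parameter C, the kernel (linear or RBF) and,
#' for the RBF kernel, gamma; `gamma = NA` means the `1/p` heuristic.
#'
#' @param cost,gamma candidate values.
#' @return A data.frame with one row per configuration.
#' @export
default_svm_grid <- function(cost = c(0.1, 1, 10), gamma = c(NA, 0.01, 0.1)) {
  rbind(
    data.frame(kernel = "linear", cost = cost, gamma = NA_real_),
    expand.grid(kernel = "radial", cost = cost, gamma = gamma,
                stringsAsFactors = FALSE)
  )
}

fit_svm <- function(x, y01, cfg, seed) {
  set.seed(seed)
  yf <- factor(y01, levels = c(0, 1))
  w <- balanced_weights(yf)
  g <- if (is.na(cfg$gamma)) 1 / ncol(x) else cfg$gamma
  e1071::svm(x, yf, kernel = cfg$kernel, cost = cfg$cost, gamma = g,
             probability = TRUE, class.weights = c("0" = w[1], "1" = w[2]))
}

#' Train one iteration's ensemble of SVM classifiers
#'
#' Same protocol as [train_rf_ensemble()] (grid-searched, balanced weights,
#' per-forest validation subsets) but with support-vector classifiers.  SVMs
#' emit no importance vector and therefore support single-iteration
#' performance runs only.
#'
#' @inheritParams train_rf_ensemble
#' @param grid see [default_svm_grid()].
#' @return An `iteration_result` without importances.
#' @export
train_svm_ensemble <- function(x, y, plan, grid = default_svm_grid(),
                               iteration_index = 0L) {
  if (iteration_index > 0L) {
    stop("SVM supports single-iteration performance runs only")
  }
  train_ensemble(x, y, plan, kind = "svm", grid = grid,
                 importance_metric = "none", iteration_index = 0L)
}

train_ensemble <- function(x, y, plan, kind, grid, importance_metric,
                           iteration_index) {
  if (ncol(x) < 1L) stop("at least one feature is required")
  x <- as.matrix(x)
  y01 <- setNames(as.integer(unclass(y)), names(y))
  fit_fun <- if (kind == "rf") fit_ranger else fit_svm
  models <- lapply(seq_len(plan$n_forests), function(k) {
    seed <- seed_for(plan$base_seed, plan$run_index, k)
    val_ids <- plan$validation_ids[[k]]
    train_ids <- setdiff(plan$train_pool, val_ids)
    xtr <- x[train_ids, , drop = FALSE]
    ytr <- y01[train_ids]
    best <- grid_search_cv(xtr, ytr, grid, seed, fit_fun)
    cfg <- grid[best, , drop = FALSE]
    fit <- fit_fun(xtr, ytr, cfg, seed)
    p_tr <- predict_prob(fit, xtr)
    p_val <- predict_prob(fit, x[val_ids, , drop = FALSE])
    p_te <- predict_prob(fit, x[plan$test_ids, , drop = FALSE])
    imp <- switch(importance_metric,
      gini = {
        v <- fit$variable.importance[colnames(x)]
        if (sum(v) > 0) v / sum(v) else v  # normalize to sum 1 per model
      },
      shap = {
        phi <- forest_shap(fit, xtr, x[val_ids, , drop = FALSE])
        colMeans(abs(phi))
      },
      none = NULL
    )
    list(
      model_kind = kind,
      chosen_hyperparameters = as.list(cfg),
      auc_train = auc(p_tr, ytr),
      auc_validation = auc(p_val, y01[val_ids]),
      auc_test = auc(p_te, y01[plan$test_ids]),
      probability_threshold = youden_threshold(p_val, y01[val_ids]),
      importance = imp
    )
  })
  avg_imp <- if (importance_metric == "none") NULL else {
    rowMeans(vapply(models, `[[`, numeric(ncol(x)), "importance"))
  }
  structure(list(
    run_index = plan$run_index,
    iteration_index = iteration_index,
    feature_ids = colnames(x),
    models = models,
    median_validation_auc = median(vapply(models, `[[`, 1, "auc_validation")),
    median_test_auc = median(vapply(models, `[[`, 1, "auc_test")),
    averaged_importance = avg_imp
  ), class = "iteration_result")
}

#' Export an ensemble's per-model records as a table
#'
#' One row per trained model: chosen hyperparameters, probability threshold
#' and train/validation/test AUCs.
#'
#' @param iter an `iteration_result`.
#' @return A data.frame.
#' @export
model_records <- function(iter) {
  rows <- lapply(seq_along(iter$models), function(k) {
    m <- iter$models[[k]]
    hp <- paste(names(m$chosen_hyperparameters),
                unlist(m$chosen_hyperparameters),
                sep = "=", collapse = "; ")
    data.frame(model = k, kind = m$model_kind, hyperparameters = hp,
               probability_threshold = m$probability_threshold,
               auc_train = m$auc_train, auc_validation = m$auc_validation,
               auc_test = m$auc_test)
  })
  do.call(rbind, rows)
}
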