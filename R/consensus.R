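# Multi-run orchestration and consensus compilation.
#
# The pipeline repeats the whole select-train-cut loop over n_runs runs,
# each with its own test subset (shared between the taxonomic and functional
# profiles of a run).  Per iteration level, the runs' significant lists are
# combined into nested categories:
#   Robust     selected by every run,
#   Confident  selected by >= 75% of runs (ceil(0.75 * n_runs)),
#   Candidate  selected by at least one run.

#' Combine per-run selections into Robust/Confident/Candidate sets
#'
#' @param selection_lists list (one element per run) of character vectors of
#'   significant features at a fixed iteration level.
#' @param n_runs total number of runs (denominator of the thresholds).
#' @return A list with `robust`, `confident`, `candidate` (character
#'   vectors, decreasing selection count) and `counts` (named integer
#'   vector of per-feature selection counts).
#' @export
categorize_features <- function(selection_lists, n_runs = length(selection_lists)) {
  feats <- unlist(lapply(selection_lists, unique))
  counts <- sort(table(feats), decreasing = TRUE)
  counts <- setNames(as.integer(counts), names(counts))
  conf_thr <- ceiling(0.75 * n_runs)
  list(
    robust = names(counts)[counts == n_runs],
    confident = names(counts)[counts >= conf_thr],
    candidate = names(counts),
    counts = counts,
    confident_threshold = conf_thr
  )
}

#' Pick the optimal iteration level
#'
#' The retained level is the one whose run-median AUCs have the highest
#' median (or mean) across runs; ties go to the smallest level.
#'
#' @param auc_matrix numeric matrix of run-median test AUCs, one row per
#'   iteration level (level 0 first), one column per run.
#' @param stat `"median"` (default) or `"mean"`.
#' @return 0-based index of the optimal iteration level.
#' @export
pick_optimal_iteration <- function(auc_matrix, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  f <- if (stat == "median") median else mean
  summary <- apply(as.matrix(auc_matrix), 1, f)
  which.max(summary) - 1L  # which.max takes the first maximum
}

#' Warn when the best median AUC makes the selection unreliable
#'
#' @param best_median_auc the best per-level summary AUC.
#' @param threshold reliability threshold (default 0.6; the flag is raised
#'   on strictly lower values).
#' @return `TRUE` (with a warning) when unreliable, else `FALSE`.
#' @export
reliability_warning <- function(best_median_auc, threshold = 0.6) {
  if (best_median_auc < threshold) {
    warning(sprintf(
      "best median AUC %.3f is below %.2f: the variable selection may be unreliable",
      best_median_auc, threshold
    ))
    TRUE
  } else {
    FALSE
  }
}

#' Compare taxonomic and functional run-median AUCs
#'
#' Two-sided Mann-Whitney U test between the two profiles' run-median AUCs
#' at their own optimal levels.  Exact U distribution when there are no
#' ties; normal approximation without continuity correction otherwise (so
#' identical samples give p = 1 exactly).
#'
#' @param auc_a,auc_b numeric vectors of run-median AUCs (>= 3 each).
#' @param alpha significance level for the flag (default 0.05).
#' @return List with `statistic` (U), `p_value` and `significant`.
#' @export
compare_profiles <- function(auc_a, auc_b, alpha = 0.05) {
  if (length(auc_a) < 3L || length(auc_b) < 3L) {
    stop("need at least 3 run-median AUCs per profile")
  }
  ht <- suppressWarnings(wilcox.test(auc_a, auc_b, correct = FALSE))
  p <- ht$p.value
  if (is.nan(p)) p <- 1  # fully tied samples: zero-variance normal approx
  list(statistic = unname(ht$statistic), p_value = p,
       significant = is.finite(p) && p < alpha)
}

#' Run the full consensus pipeline
#'
#' Orchestrates `n_runs` independent runs of the iterative
#' selection loop on a functional profile and, optionally, the matching
#' taxonomic profile (both profiles of a run share the run's test set), then
#' compiles per-level Robust/Confident/Candidate consensus sets, picks the
#' optimal iteration level, raises the reliability flag, and compares the
#' two profiles' AUC distributions when both are present.
#'
#' Runs that stop early (2 or fewer features left) carry their last
#' selection and AUC forward to the remaining levels, keeping every level
#' comparable across runs.
#'
#' @param x_func functional profile: a [sofa_table()] or raw matrix,
#'   samples x annotations.
#' @param y a [label_vector()].
#' @param x_taxa optional taxonomic profile ([abundance_table()]); converted
#'   to relative abundances before training.
#' @param n_runs,n_iterations,n_forests protocol sizes (defaults 10, 5, 20).
#' @param base_seed integer seed from which every run/forest seed derives.
#' @param importance_metric `"gini"` or `"shap"`.
#' @param grid hyperparameter grid ([default_rf_grid()]).
#' @param treatment data treatment (`"none"`, `"tf_igm"`, `"scaling"`),
#'   re-applied after each selection.
#' @param lambda_ TF-IGM lambda.
#' @param optimal_stat summary used to pick the optimal level (`"median"`
#'   or `"mean"` of the run medians).
#' @param test_sets optional list of pre-conceived test id vectors, one per
#'   run.
#' @param stratify stratify splits by class (default `TRUE`).
#' @return A `consensus_report`: per profile, the run results, the
#'   per-level AUC matrix, consensus sets, optimal level and reliability
#'   flag; plus the profile comparison when both profiles were given.
#' @export
run_pipeline <- function(x_func, y, x_taxa = NULL,
                         n_runs = 10, n_iterations = 5, n_forests = 20,
                         base_seed = 42,
                         importance_metric = c("gini", "shap"),
                         grid = default_rf_grid(),
                         treatment = c("none", "tf_igm", "scaling"),
                         lambda_ = 7,
                         optimal_stat = c("median", "mean"),
                         test_sets = NULL, stratify = TRUE) {
  importance_metric <- match.arg(importance_metric)
  treatment <- match.arg(treatment)
  optimal_stat <- match.arg(optimal_stat)
  profiles <- list(functional = as.matrix(x_func))
  if (!is.null(x_taxa)) {
    profiles$taxonomic <- unclass(to_relative_abundance(x_taxa))
  }
  for (p in names(profiles)) {
    stopifnot(identical(sort(rownames(profiles[[p]])), sort(names(y))))
    profiles[[p]] <- profiles[[p]][names(y), , drop = FALSE]
  }
  plans <- lapply(seq_len(n_runs), function(r) {
    make_split_plan(y, r, base_seed, n_forests = n_forests,
                    stratify = stratify,
                    test_ids = if (!is.null(test_sets)) test_sets[[r]])
  })
  report <- list(
    n_runs = n_runs, n_iterations = n_iterations, n_forests = n_forests,
    base_seed = base_seed, importance_metric = importance_metric,
    treatment = treatment, optimal_stat = optimal_stat,
    profiles = list()
  )
  for (p in names(profiles)) {
    runs <- lapply(plans, function(plan) {
      iterate_selection(profiles[[p]], y, plan,
                        n_iterations = n_iterations,
                        importance_metric = importance_metric,
                        grid = grid, treatment = treatment, lambda_ = lambda_)
    })
    report$profiles[[p]] <- summarize_profile(runs, n_runs, n_iterations,
                                              optimal_stat)
  }
  if (length(profiles) == 2L && n_runs >= 3L) {
    opt_f <- report$profiles$functional$optimal_iteration + 1L
    opt_t <- report$profiles$taxonomic$optimal_iteration + 1L
    report$comparison <- compare_profiles(
      report$profiles$taxonomic$auc_matrix[opt_t, ],
      report$profiles$functional$auc_matrix[opt_f, ]
    )
  }
  structure(report, class = "consensus_report")
}

# Per-level compilation with carry-forward for early-stopped runs.
summarize_profile <- function(runs, n_runs, n_iterations, optimal_stat) {
  level_selection <- function(run, level) {
    j <- min(level + 1L, length(run$selections))
    run$selections[[j]]
  }
  auc_matrix <- sapply(seq_len(n_runs), function(r) {
    vapply(seq_len(n_iterations) - 1L, function(j) {
      level_selection(runs[[r]], j)$median_test_auc
    }, numeric(1))
  })
  auc_matrix <- matrix(auc_matrix, nrow = n_iterations,
                       dimnames = list(paste0("iteration_", seq_len(n_iterations) - 1L),
                                       paste0("run_", seq_len(n_runs))))
  consensus <- lapply(seq_len(n_iterations) - 1L, function(j) {
    categorize_features(
      lapply(runs, function(run) level_selection(run, j)$features),
      n_runs = n_runs
    )
  })
  names(consensus) <- rownames(auc_matrix)
  optimal <- pick_optimal_iteration(auc_matrix, optimal_stat)
  f <- if (optimal_stat == "median") median else mean
  best <- f(auc_matrix[optimal + 1L, ])
  list(
    runs = runs,
    auc_matrix = auc_matrix,
    consensus = consensus,
    optimal_iteration = optimal,
    best_summary_auc = best,
    reliability_flag = reliability_warning(best)
  )
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("<consensus_report> %d runs x %d iterations x %d models (%s importance, %s treatment)\n",
              x$n_runs, x$n_iterations, x$n_forests, x$importance_metric,
              x$treatment))
  for (p in names(x$profiles)) {
    pr <- x$profiles[[p]]
    opt <- pr$optimal_iteration
    cons <- pr$consensus[[opt + 1L]]
    cat(sprintf(
      "  %-10s optimal level %d (%s AUC %.3f%s): %d robust / %d confident / %d candidate features\n",
      p, opt, x$optimal_stat, pr$best_summary_auc,
      if (pr$reliability_flag) ", UNRELIABLE" else "",
      length(cons$robust), length(cons$confident), length(cons$candidate)
    ))
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("  taxonomic vs functional AUCs: U = %g, p = %.3g%s\n",
                x$comparison$statistic, x$comparison$p_value,
                if (x$comparison$significant) " (*)" else ""))
  }
  invisible(x)
}

#' Consensus sets of a profile at a given iteration level
#'
#' @param report a [run_pipeline()] result.
#' @param profile `"functional"` or `"taxonomic"`.
#' @param level 0-based iteration level; default the profile's optimal.
#' @return The [categorize_features()] output at that level.
#' @export
consensus_at <- function(report, profile = "functional", level = NULL) {
  pr <- report$profiles[[profile]]
  if (is.null(pr)) stop(sprintf("no '%s' profile in this report", profile))
  if (is.null(level)) level <- pr$optimal_iteration
  pr$consensus[[level + 1L]]
}

#' Write the pipeline's headline outputs to a directory
#'
#' Emits, per profile: the per-run/per-iteration model records (TSV), the
#' per-level AUC matrix, and one CSV of Robust/Confident/Candidate features
#' (with selection counts) per iteration level.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in names(report$profiles)) {
    pr <- report$profiles[[p]]
    data.table::fwrite(
      data.table::data.table(level = rownames(pr$auc_matrix), pr$auc_matrix),
      file.path(dir, sprintf("%s_auc_matrix.tsv", p)), sep = "\t"
    )
    for (r in seq_along(pr$runs)) {
      for (it in pr$runs[[r]]$iterations) {
        rec <- model_records(it)
        data.table::fwrite(
          rec,
          file.path(dir, sprintf("%s_run%d_iteration%d_models.tsv",
                                 p, r, it$iteration_index)),
          sep = "\t"
        )
      }
    }
    for (lvl in names(pr$consensus)) {
      cons <- pr$consensus[[lvl]]
      status <- ifelse(cons$candidate %in% cons$robust, "Robust",
                       ifelse(cons$candidate %in% cons$confident,
                              "Confident", "Candidate"))
      data.table::fwrite(
        data.frame(feature = cons$candidate,
                   selection_count = cons$counts[cons$candidate],
                   category = status),
        file.path(dir, sprintf("%s_%s_selection.csv", p, lvl))
      )
    }
  }
  invisible(dir)
}
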