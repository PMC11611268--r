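# Taxon <-> annotation linkage analytics: link strengths, profile
# assignment, functional-redundancy screening and annotation categories.

#' Strength of each taxon's contribution to an annotation's score
#'
#' For annotation F, each linked taxon M (association count x > 0)
#' contributes
#'   strength(M) = nbar(M) * x(F, M) / sum over linked taxa of the same,
#' with nbar the taxon's mean abundance across all samples of the dataset
#' (the formula carries no group index).  Strengths sum to 1 over the
#' annotation's linked taxa.
#'
#' @param assoc an [association_matrix()].
#' @param abund an [abundance_table()] (same taxa).
#' @param annotation annotation identifier (a column of `assoc`).
#' @param sample_ids optional subset of samples over which the mean
#'   abundance is taken (per-group variant); default all samples.
#' @return Named numeric vector of strengths over the linked taxa.
#' @export
link_strength <- function(assoc, abund, annotation, sample_ids = NULL) {
  if (!annotation %in% colnames(assoc)) {
    stop(sprintf("annotation '%s' is not in the association matrix", annotation))
  }
  a <- unclass(abund)
  if (!is.null(sample_ids)) a <- a[sample_ids, , drop = FALSE]
  x <- unclass(assoc)[, annotation]
  linked <- names(x)[x > 0]
  linked <- intersect(linked, colnames(a))
  if (length(linked) == 0L) {
    stop(sprintf("annotation '%s' has no linked taxon in the abundance table",
                 annotation))
  }
  nbar <- colMeans(a[, linked, drop = FALSE])
  raw <- nbar * x[linked]
  if (sum(raw) == 0) {
    stop(sprintf("all taxa linked to '%s' have zero mean abundance", annotation))
  }
  raw / sum(raw)
}

#' Assign a feature to the control or unhealthy profile
#'
#' The feature's values are averaged within each class; it is assigned to
#' the class where it is most prevalent on average.  The reported ratio is
#' mean(control) / mean(unhealthy) when control-dominant and
#' -mean(unhealthy) / mean(control) otherwise, so its magnitude is always
#' >= 1 and its sign encodes the profile.  Equal means assign control with
#' ratio +1.  A zero mean in the minority direction yields a signed
#' infinity with a warning.
#'
#' @param values numeric vector of per-sample scores, named by sample id.
#' @param labels a [label_vector()].
#' @return List with `profile` (`"control"` or `"unhealthy"`) and
#'   `ponderated_ratio`.
#' @export
assign_profile <- function(values, labels) {
  y <- unclass(labels)[names(values)]
  if (length(unique(y)) != 2L) stop("both classes must be present")
  m_ctrl <- mean(values[y == 0L])
  m_unh <- mean(values[y == 1L])
  if (m_ctrl >= m_unh) {
    if (m_unh == 0 && m_ctrl > 0) {
      warning("unhealthy mean is zero; ratio reported as +Inf")
      return(list(profile = "control", ponderated_ratio = Inf))
    }
    ratio <- if (m_ctrl == 0 && m_unh == 0) 1 else m_ctrl / m_unh
    list(profile = "control", ponderated_ratio = ratio)
  } else {
    if (m_ctrl == 0) {
      warning("control mean is zero; ratio reported as -Inf")
      return(list(profile = "unhealthy", ponderated_ratio = -Inf))
    }
    list(profile = "unhealthy", ponderated_ratio = -m_unh / m_ctrl)
  }
}

#' Functional-redundancy screen by Jaccard proximity
#'
#' Taxa are compared through the binary support of their annotation sets
#' (association count > 0).  Pairs with Jaccard proximity at or above the
#' threshold count as close neighbors ("functionally identical"); the
#' summary is the fraction of taxa with no close neighbor.  Taxa with an
#' empty annotation set are excluded with a warning.
#'
#' @param assoc an [association_matrix()].
#' @param proximity_threshold similarity cutoff (default 0.95).
#' @return List with `proximity` (taxa x taxa Jaccard matrix),
#'   `neighbor_counts` (close neighbors per taxon, self excluded) and
#'   `fraction_without_neighbor`.
#' @export
jaccard_redundancy <- function(assoc, proximity_threshold = 0.95) {
  b <- unclass(assoc) > 0
  empty <- rowSums(b) == 0
  if (any(empty)) {
    warning(sprintf("excluding %d taxa with empty annotation sets: %s",
                    sum(empty),
                    paste(head(rownames(b)[empty], 5), collapse = ", ")))
    b <- b[!empty, , drop = FALSE]
  }
  if (nrow(b) < 2L) stop("need at least 2 taxa with annotations")
  storage.mode(b) <- "double"
  inter <- b %*% t(b)
  sizes <- rowSums(b)
  union <- outer(sizes, sizes, "+") - inter
  prox <- inter / union
  close <- prox >= proximity_threshold
  diag(close) <- FALSE
  counts <- rowSums(close)
  list(proximity = prox, neighbor_counts = counts,
       fraction_without_neighbor = mean(counts == 0))
}

#' Categorize robust annotations by their taxon linkage
#'
#' Annotations linked to no robust taxon are `"Cumulative"` (their signal
#' emerges from summed weak contributions), regardless of their total
#' linkage.  The remaining annotations are split by their total number of
#' linked taxa: the top decile is `"Ubiquitous"`, the bottom decile
#' `"Specific"`, everything else `"In-between"`.  Deciles are taken over
#' the value scale (min-max range) by default, or over the empirical
#' distribution with `decile_mode = "quantile"`.
#'
#' @param robust_annotations character vector of robust annotation ids.
#' @param robust_taxa character vector of robust taxon ids.
#' @param assoc an [association_matrix()].
#' @param decile_mode `"range"` or `"quantile"`.
#' @return Named character vector of categories, one per robust annotation.
#' @export
categorize_annotations <- function(robust_annotations, robust_taxa, assoc,
                                   decile_mode = c("range", "quantile")) {
  decile_mode <- match.arg(decile_mode)
  if (length(robust_annotations) == 0L) stop("robust annotation set is empty")
  x <- unclass(assoc)[, robust_annotations, drop = FALSE]
  total <- colSums(x > 0)
  robust_linked <- colSums(x[intersect(robust_taxa, rownames(x)), ,
                             drop = FALSE] > 0)
  category <- setNames(rep("In-between", length(robust_annotations)),
                       robust_annotations)
  cumulative <- robust_linked == 0
  category[cumulative] <- "Cumulative"
  rest <- total[!cumulative]
  if (length(rest) > 0) {
    if (decile_mode == "range") {
      lo <- min(rest) + 0.1 * (max(rest) - min(rest))
      hi <- max(rest) - 0.1 * (max(rest) - min(rest))
    } else {
      lo <- quantile(rest, 0.1, names = FALSE)
      hi <- quantile(rest, 0.9, names = FALSE)
    }
    category[names(rest)[rest <= lo]] <- "Specific"
    category[names(rest)[rest >= hi]] <- "Ubiquitous"
    if (max(rest) == min(rest)) category[names(rest)] <- "In-between"
  }
  category
}

#' Annotated shortlist reports for robust features
#'
#' Builds the per-feature summary tables for the robust sets at a report's
#' optimal iteration level: averaged importance over all runs' models at
#' that level, the profile assignment with its signed ratio, and the total
#' and robust linked counterparts (taxa linked to each robust annotation,
#' annotations linked to each robust taxon).  Rows are ordered by
#' decreasing averaged importance.
#'
#' @param report a [run_pipeline()] result with both profiles.
#' @param assoc the [association_matrix()] behind the functional profile.
#' @param abund the [abundance_table()] (relative abundances are computed
#'   internally for the taxon table).
#' @param sofa the functional [sofa_table()] scored from `abund` and
#'   `assoc`.
#' @param labels the [label_vector()].
#' @return List of two data.frames, `annotations` and `taxa`.
#' @export
annotate_shortlists <- function(report, assoc, abund, sofa, labels) {
  stopifnot(!is.null(report$profiles$functional),
            !is.null(report$profiles$taxonomic))
  rel <- to_relative_abundance(abund)
  robust_annot <- consensus_at(report, "functional")$robust
  robust_taxa <- consensus_at(report, "taxonomic")$robust
  x <- unclass(assoc)

  annot_tab <- shortlist_table(
    report$profiles$functional, robust_annot,
    values = unclass(sofa), labels = labels,
    total_linked = colSums(x[, robust_annot, drop = FALSE] > 0),
    robust_linked = colSums(x[intersect(robust_taxa, rownames(x)),
                              robust_annot, drop = FALSE] > 0)
  )
  taxa_tab <- shortlist_table(
    report$profiles$taxonomic, robust_taxa,
    values = unclass(rel), labels = labels,
    total_linked = rowSums(x[robust_taxa, , drop = FALSE] > 0),
    robust_linked = rowSums(x[robust_taxa, intersect(robust_annot, colnames(x)),
                              drop = FALSE] > 0)
  )
  list(annotations = annot_tab, taxa = taxa_tab)
}

shortlist_table <- function(profile_summary, robust_ids, values, labels,
                            total_linked, robust_linked) {
  if (length(robust_ids) == 0L) {
    return(data.frame(id = character(0), average_importance = numeric(0),
                      profile = character(0), ponderated_ratio = numeric(0),
                      linked_total = integer(0), linked_robust = integer(0)))
  }
  level <- profile_summary$optimal_iteration
  # average importance over every model of every run at the optimal level
  imp_rows <- lapply(profile_summary$runs, function(run) {
    j <- min(level + 1L, length(run$iterations))
    avg <- run$iterations[[j]]$averaged_importance
    avg[robust_ids]
  })
  avg_imp <- rowMeans(do.call(cbind, imp_rows), na.rm = TRUE)
  prof <- lapply(robust_ids, function(id) {
    assign_profile(values[, id], labels)
  })
  out <- data.frame(
    id = robust_ids,
    average_importance = avg_imp,
    profile = vapply(prof, `[[`, character(1), "profile"),
    ponderated_ratio = vapply(prof, `[[`, numeric(1), "ponderated_ratio"),
    linked_total = as.integer(total_linked[robust_ids]),
    linked_robust = as.integer(robust_linked[robust_ids]),
    row.names = NULL
  )
  out[order(-out$average_importance), , drop = FALSE]
}

#' Edge list of robust annotation-taxon links
#'
#' One row per (robust annotation, linked taxon) pair with the link
#' strength and the taxon's profile assignment — the raw material for
#' bipartite linkage graphics.
#'
#' @inheritParams annotate_shortlists
#' @return A data.frame with columns `annotation`, `taxon`, `strength`,
#'   `taxon_robust`, `taxon_profile`.
#' @export
linkage_edges <- function(report, assoc, abund, labels) {
  rel <- to_relative_abundance(abund)
  robust_annot <- consensus_at(report, "functional")$robust
  robust_taxa <- consensus_at(report, "taxonomic")$robust
  rows <- lapply(robust_annot, function(f) {
    s <- link_strength(assoc, rel, f)
    data.frame(annotation = f, taxon = names(s), strength = unname(s),
               taxon_robust = names(s) %in% robust_taxa)
  })
  edges <- do.call(rbind, rows)
  if (is.null(edges)) return(edges)
  edges$taxon_profile <- vapply(edges$taxon, function(t) {
    assign_profile(unclass(rel)[, t], labels)$profile
  }, character(1))
  edges
}
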