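# Functional score profiles and their normalizations.
#
# The score of a functional annotation F in sample i is the abundance-weighted
# count of the protein clusters carrying F across the sample's taxa:
#   score(F, i) = sum_t  n(t, i) * x(F, t)
# where n is the (relative) abundance of taxon t in sample i and x the number
# of protein clusters of taxon t annotated with F.  The optional TF-IGM
# weighting boosts annotations concentrated in few samples.

#' Convert an abundance table to relative abundances (percent)
#'
#' Each value is recomputed as a percentage of its sample's total, so every
#' row sums to 100.  Zeros are preserved; an all-zero sample is an error.
#'
#' @param tbl an [abundance_table()].
#' @return An [abundance_table()] with rows summing to 100.
#' @export
to_relative_abundance <- function(tbl) {
  totals <- rowSums(tbl)
  if (any(totals == 0)) {
    stop(sprintf("sample '%s' has no positive abundance",
                 rownames(tbl)[which(totals == 0)[1]]))
  }
  abundance_table(sweep(unclass(tbl), 1, totals, "/") * 100)
}

#' Compute functional annotation scores from abundances and associations
#'
#' Matrix form of the per-annotation weighted sum: `scores = A %*% X` with
#' `A` the samples x taxa abundance table and `X` the taxa x annotations
#' association matrix.  Annotations scoring zero in every sample are dropped
#' (they carry no information and their term frequency would be undefined).
#' Taxa present in the abundance table but missing from the association
#' matrix count as annotation-free (all-zero row, with a warning).
#'
#' @param abund an [abundance_table()].
#' @param assoc an [association_matrix()].
#' @return A raw [sofa_table()] (samples x annotations).
#' @export
compute_sofa <- function(abund, assoc) {
  assoc <- align_taxa(abund, assoc)
  scores <- unclass(abund) %*% unclass(assoc)
  keep <- colSums(scores) > 0
  sofa_table(scores[, keep, drop = FALSE], normalization = "raw")
}

#' Term frequency of annotations within each sample
#'
#' Divides each sample's scores by the sample's total score, so rows sum
#' to 1.
#'
#' @param sofa a [sofa_table()] of non-negative scores.
#' @return A [sofa_table()] with `normalization = "tf"`.
#' @export
term_frequency <- function(sofa) {
  totals <- rowSums(sofa)
  if (any(totals == 0)) {
    stop(sprintf("sample '%s' has zero total score; cannot normalize",
                 rownames(sofa)[which(totals == 0)[1]]))
  }
  sofa_table(sweep(unclass(sofa), 1, totals, "/"), normalization = "tf")
}

#' Inverse gravity moment of each annotation
#'
#' For each annotation, the term-frequency values are sorted in decreasing
#' order across the n samples (stable sort; ties take consecutive ranks) and
#'   igm = T1 / sum_r (Tr * r).
#' An annotation positive in exactly one sample has igm = 1; a perfectly
#' uniform annotation has igm = 2 / (n (n + 1)).  An all-zero annotation is
#' assigned igm = 0 (no discriminative weight; avoids 0/0).
#'
#' @param tf a [sofa_table()] of term frequencies.
#' @return Named numeric vector of igm values in `[0, 1]`.
#' @export
inverse_gravity_moment <- function(tf) {
  n <- nrow(tf)
  r <- seq_len(n)
  apply(unclass(tf), 2, function(col) {
    s <- sort(col, decreasing = TRUE, method = "radix")
    denom <- sum(s * r)
    if (denom == 0) 0 else s[1] / denom
  })
}

#' TF-IGM weighting of a functional score table
#'
#' Computes term frequencies, then weights each annotation f as
#'   tf_igm(f, i) = tf(f, i) * (1 + lambda * igm(f)).
#' The gravity-moment weight is fitted on all provided samples, matching the
#' reference protocol (see the methods vignette for the leakage discussion).
#'
#' @param sofa a raw or relative [sofa_table()].
#' @param lambda_ weighting strength, a value in `[5, 9]`; default 7.
#' @return A [sofa_table()] with `normalization = "tf_igm"` and the lambda
#'   recorded in its attributes.
#' @export
tf_igm_transform <- function(sofa, lambda_ = 7) {
  if (!is.numeric(lambda_) || length(lambda_) != 1L ||
      lambda_ < 5 || lambda_ > 9) {
    stop("lambda_ must be a single value in [5, 9]")
  }
  tf <- term_frequency(sofa)
  igm <- inverse_gravity_moment(tf)
  out <- sweep(unclass(tf), 2, 1 + lambda_ * igm, "*")
  sofa_table(out, normalization = "tf_igm", lambda_ = lambda_)
}

#' Standard scaling (zero mean, unit variance per feature)
#'
#' Centers and scales each column using the population (divide-by-n)
#' standard deviation, so results are bit-reproducible against the common
#' Python convention.  Zero-variance features map to 0.  Fitted statistics
#' can be reused to transform held-out samples.
#'
#' @param tbl a matrix-like table, samples in rows (at least 2 to fit).
#' @param fit_stats optional statistics from a previous call (a list with
#'   `mean` and `sd`); when given, `tbl` is transformed with them.
#' @return The scaled matrix with the fitted statistics attached as
#'   attribute `"fit_stats"`.
#' @export
standard_scale <- function(tbl, fit_stats = NULL) {
  m <- as.matrix(tbl)
  if (is.null(fit_stats)) {
    if (nrow(m) < 2L) stop("standard scaling needs at least 2 samples")
    mu <- colMeans(m)
    sigma <- sqrt(colMeans(sweep(m, 2, mu, "-")^2))  # population sd
    fit_stats <- list(mean = mu, sd = sigma)
  }
  sigma <- fit_stats$sd
  out <- sweep(m, 2, fit_stats$mean[colnames(m)], "-")
  nz <- sigma[colnames(m)] > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, sigma[colnames(m)][nz], "/")
  out[, !nz] <- 0
  attr(out, "fit_stats") <- fit_stats
  out
}

#' Apply a data treatment to a (possibly column-subset) profile table
#'
#' The treatment configured for a pipeline run is re-applied from the raw
#' scores every time the feature set shrinks, because term-frequency
#' denominators (and scaling statistics) change with the column subset —
#' re-normalization after selection is deliberately not a no-op.
#'
#' @param x raw profile matrix (samples x features).
#' @param treatment `"none"`, `"tf_igm"` or `"scaling"`.
#' @param lambda_ TF-IGM lambda (used when `treatment == "tf_igm"`).
#' @param fit_ids optional sample ids on which scaling statistics are
#'   fitted (strict-leakage mode); default fits on all samples, matching
#'   the reference protocol.
#' @return A numeric matrix of treated values.
#' @export
apply_treatment <- function(x, treatment = c("none", "tf_igm", "scaling"),
                            lambda_ = 7, fit_ids = NULL) {
  treatment <- match.arg(treatment)
  m <- as.matrix(x)
  if (treatment == "none") return(m)
  if (treatment == "tf_igm") {
    return(unclass(tf_igm_transform(sofa_table(m), lambda_ = lambda_)))
  }
  if (is.null(fit_ids)) {
    unclass(standard_scale(m))
  } else {
    stats <- attr(standard_scale(m[fit_ids, , drop = FALSE]), "fit_stats")
    unclass(standard_scale(m, fit_stats = stats))
  }
}
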