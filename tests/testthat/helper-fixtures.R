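# Shared fixtures and independent oracles for the test suite.

# Strip class and provenance attributes, keeping only the bare matrix.
bare <- function(m) {
  m <- unclass(m)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

named_matrix <- function(values, nrow, prefix_row = "s", prefix_col = "f") {
  m <- matrix(values, nrow = nrow)
  dimnames(m) <- list(paste0(prefix_row, seq_len(nrow(m))),
                      paste0(prefix_col, seq_len(ncol(m))))
  m
}

random_abundance <- function(n_samples, n_taxa, seed) {
  set.seed(seed)
  abundance_table(named_matrix(rlnorm(n_samples * n_taxa), n_samples,
                               "s", "t"))
}

random_association <- function(n_taxa, n_annot, seed, density = 0.4) {
  set.seed(seed)
  counts <- matrix(rbinom(n_taxa * n_annot, 1, density) *
                     (1 + rpois(n_taxa * n_annot, 2)), nrow = n_taxa)
  dimnames(counts) <- list(paste0("t", seq_len(n_taxa)),
                           paste0("a", seq_len(n_annot)))
  association_matrix(counts)
}

toy_labels <- function(n, seed = 1, prefix = "s") {
  set.seed(seed)
  label_vector(sample(rep(0:1, length.out = n)),
               sample_ids = paste0(prefix, seq_len(n)))
}

# A small two-class dataset where a few features carry a clean mean shift.
separable_data <- function(n_per_class = 30, n_features = 10,
                           n_signal = 2, shift = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(0:1, each = n_per_class)
  x <- matrix(rnorm(n * n_features), nrow = n)
  x[, seq_len(n_signal)] <- x[, seq_len(n_signal)] + shift * y
  dimnames(x) <- list(paste0("s", seq_len(n)), paste0("f", seq_len(n_features)))
  list(x = x, y = label_vector(y, sample_ids = rownames(x)))
}

# ---- Independent oracles ----------------------------------------------------

# Triple-loop evaluation of the annotation score sum.
sofa_oracle <- function(abund, assoc) {
  a <- unclass(abund); x <- unclass(assoc)
  out <- matrix(0, nrow(a), ncol(x), dimnames = list(rownames(a), colnames(x)))
  for (i in seq_len(nrow(a))) {
    for (f in seq_len(ncol(x))) {
      s <- 0
      for (t in colnames(a)) s <- s + a[i, t] * x[t, f]
      out[i, f] <- s
    }
  }
  out
}

# Brute-force inverse gravity moment of one annotation column.
igm_oracle <- function(tf_col) {
  s <- sort(tf_col, decreasing = TRUE)
  if (sum(s) == 0) return(0)
  s[1] / sum(s * seq_along(s))
}

# Elbow oracle: min-max normalize both axes, then take the point of maximum
# perpendicular distance to the chord, among points below it, via the
# two-point line distance formula (independent of the implementation's
# signed-gap form).
elbow_oracle <- function(values) {
  n <- length(values)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (values - min(values)) / (max(values) - min(values))
  x1 <- x[1]; y1 <- y[1]; x2 <- x[n]; y2 <- y[n]
  num <- (y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1
  below <- num > 0  # points under the descending chord
  if (!any(below)) return(NA_integer_)
  d <- abs(num) / sqrt((y2 - y1)^2 + (x2 - x1)^2)
  d[!below] <- -Inf
  which.max(d)
}

# Exact Shapley values for one tree under path-dependent expectations
# (enumeration over all feature subsets; usable for <= ~6 features).
shapley_oracle_tree <- function(tree, cover, x, n_features) {
  expvalue <- function(node, subset) {
    if (tree$terminal[node]) return(tree$value[node])
    f <- tree$feat[node]
    if (f %in% subset) {
      child <- if (x[f] <= tree$thresh[node]) tree$left[node] else tree$right[node]
      expvalue(child, subset)
    } else {
      (cover[tree$left[node]] * expvalue(tree$left[node], subset) +
         cover[tree$right[node]] * expvalue(tree$right[node], subset)) /
        cover[node]
    }
  }
  phi <- numeric(n_features)
  all_f <- seq_len(n_features)
  for (i in all_f) {
    others <- setdiff(all_f, i)
    for (k in 0:length(others)) {
      combos <- if (k == 0) list(integer(0)) else
        asplit(utils::combn(others, k), 2)
      w <- factorial(k) * factorial(n_features - k - 1) / factorial(n_features)
      for (s in combos) {
        phi[i] <- phi[i] + w * (expvalue(1L, c(s, i)) - expvalue(1L, s))
      }
    }
  }
  phi
}

expect_setequal_chr <- function(a, b) {
  expect_setequal(as.character(a), as.character(b))
}
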