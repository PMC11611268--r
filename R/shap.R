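# Path-dependent SHAP values for ranger probability forests.
#
# Implements the polynomial-time tree algorithm that propagates subset
# weights down each tree, with conditional expectations taken along the
# tree's own paths (children weighted by their training cover).  Covers are
# reconstructed by routing the training data through each tree, since ranger
# does not expose per-node sample counts.  Verified in the test suite
# against a brute-force Shapley enumeration on small trees and against the
# local-accuracy identity sum(phi) = f(x) - E[f].

# Flatten one ranger tree into parallel vectors (1-based node ids).
extract_tree <- function(fit, tree_index, positive_level = "1") {
  ti <- ranger::treeInfo(fit, tree_index)
  pred_col <- paste0("pred.", positive_level)
  list(
    left = ti$leftChild + 1L,   # NA for leaves
    right = ti$rightChild + 1L,
    feat = ti$splitvarID + 1L,
    thresh = ti$splitval,
    value = ti[[pred_col]],
    terminal = ti$terminal
  )
}

# Training-sample count through every node of one tree.
node_covers <- function(tree, train_x) {
  n_nodes <- length(tree$terminal)
  cover <- numeric(n_nodes)
  for (i in seq_len(nrow(train_x))) {
    node <- 1L
    repeat {
      cover[node] <- cover[node] + 1
      if (tree$terminal[node]) break
      node <- if (train_x[i, tree$feat[node]] <= tree$thresh[node]) {
        tree$left[node]
      } else {
        tree$right[node]
      }
    }
  }
  cover
}

path_extend <- function(m, pz, po, pi) {
  l <- length(m$w)
  m$d <- c(m$d, pi)
  m$z <- c(m$z, pz)
  m$o <- c(m$o, po)
  m$w <- c(m$w, if (l == 0L) 1 else 0)
  if (l > 0L) {
    for (i in l:1) {
      m$w[i + 1] <- m$w[i + 1] + po * m$w[i] * i / (l + 1)
      m$w[i] <- pz * m$w[i] * (l - i + 1) / (l + 1)
    }
  }
  m
}

path_unwind <- function(m, j) {
  L <- length(m$w)
  n <- m$w[L]
  z <- m$z[j]
  o <- m$o[j]
  if (L > 1L) {
    for (i in (L - 1):1) {
      if (o != 0) {
        tmp <- m$w[i]
        m$w[i] <- n * L / (i * o)
        n <- tmp - m$w[i] * z * (L - i) / L
      } else {
        m$w[i] <- m$w[i] * L / (z * (L - i))
      }
    }
  }
  keep <- seq_len(L)[-j]
  list(d = m$d[keep], z = m$z[keep], o = m$o[keep], w = m$w[seq_len(L - 1L)])
}

path_unwound_sum <- function(m, j) {
  L <- length(m$w)
  n <- m$w[L]
  z <- m$z[j]
  o <- m$o[j]
  total <- 0
  for (i in (L - 1):1) {
    if (o != 0) {
      tmp <- n * L / (i * o)
      total <- total + tmp
      n <- m$w[i] - tmp * z * (L - i) / L
    } else {
      total <- total + m$w[i] * L / (z * (L - i))
    }
  }
  total
}

# SHAP values of one tree for one explicand x (numeric vector).
tree_shap_one <- function(tree, cover, x, n_features) {
  phi <- numeric(n_features)
  recurse <- function(node, m, pz, po, pi) {
    m <- path_extend(m, pz, po, pi)
    if (tree$terminal[node]) {
      L <- length(m$w)
      if (L > 1L) {
        for (j in 2:L) {
          total <- path_unwound_sum(m, j)
          phi[m$d[j]] <<- phi[m$d[j]] +
            total * (m$o[j] - m$z[j]) * tree$value[node]
        }
      }
      return(invisible(NULL))
    }
    f <- tree$feat[node]
    goes_left <- x[f] <= tree$thresh[node]
    hot <- if (goes_left) tree$left[node] else tree$right[node]
    cold <- if (goes_left) tree$right[node] else tree$left[node]
    iz <- 1
    io <- 1
    k <- match(f, m$d)
    if (!is.na(k)) {
      iz <- m$z[k]
      io <- m$o[k]
      m <- path_unwind(m, k)
    }
    recurse(hot, m, iz * cover[hot] / cover[node], io, f)
    recurse(cold, m, iz * cover[cold] / cover[node], 0, f)
  }
  recurse(1L, list(d = numeric(0), z = numeric(0), o = numeric(0),
                   w = numeric(0)), 1, 1, 0)
  phi
}

#' SHAP values of a ranger probability forest
#'
#' Per-sample additive attributions of the predicted probability of the
#' positive class, averaged over trees.  Path-dependent: conditional
#' expectations follow the trees' own split covers, reconstructed from the
#' training data.
#'
#' @param fit a `ranger` probability forest.
#' @param train_x the matrix the forest was trained on (for covers).
#' @param x matrix of samples to explain.
#' @return Matrix (samples x features) of SHAP values, with the
#'   forest-average baseline as attribute `"expected_value"`.
#' @export
forest_shap <- function(fit, train_x, x) {
  train_x <- as.matrix(train_x)
  x <- as.matrix(x)
  p <- ncol(train_x)
  phi <- matrix(0, nrow = nrow(x), ncol = p,
                dimnames = list(rownames(x), colnames(train_x)))
  expected <- 0
  for (t in seq_len(fit$num.trees)) {
    tree <- extract_tree(fit, t)
    cover <- node_covers(tree, train_x)
    leaves <- which(tree$terminal)
    expected <- expected + sum(tree$value[leaves] * cover[leaves]) / cover[1L]
    for (i in seq_len(nrow(x))) {
      phi[i, ] <- phi[i, ] + tree_shap_one(tree, cover, x[i, ], p)
    }
  }
  phi <- phi / fit$num.trees
  attr(phi, "expected_value") <- expected / fit$num.trees
  phi
}
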