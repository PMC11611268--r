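# Functional scores and their normalizations.

test_that("relative abundance scales rows to 100 and is idempotent", {
  tbl <- abundance_table(named_matrix(c(2, 30, 2, 70), 2, "s", "t"))
  rel <- to_relative_abundance(tbl)
  expect_equal(unname(unclass(rel)[1, ]), c(50, 50))
  expect_equal(unclass(to_relative_abundance(rel)), unclass(rel))
  for (seed in 1:5) {
    r <- to_relative_abundance(random_abundance(6, 4, seed))
    expect_equal(unname(rowSums(r)), rep(100, 6), tolerance = 1e-9)
  }
  zero <- abundance_table(named_matrix(c(1, 0, 1, 0), 2, "s", "t"))
  expect_error(to_relative_abundance(zero), "s2")
})

test_that("annotation scores equal the abundance-weighted cluster counts", {
  abund <- abundance_table(named_matrix(c(2, 1), 1, "s", "t"))
  assoc <- association_matrix(named_matrix(c(3, 1), 2, "t", "a"))
  expect_equal(unname(unclass(compute_sofa(abund, assoc))[1, 1]), 7)

  zeroab <- abundance_table(named_matrix(rep(0, 4), 2, "s", "t"))
  assoc2 <- random_association(2, 3, 1)
  rownames(assoc2) <- c("t1", "t2")
  expect_equal(ncol(compute_sofa(zeroab, assoc2)), 0)  # all-zero columns drop

  disjoint <- association_matrix(named_matrix(1:4, 2, "x", "a"))
  expect_error(compute_sofa(random_abundance(2, 2, 1), disjoint),
               "no shared taxa")
})

test_that("matrix-product scores match a triple-loop oracle and are linear", {
  for (seed in 1:10) {
    abund <- random_abundance(5, 4, seed)
    assoc <- random_association(4, 6, seed + 100)
    got <- compute_sofa(abund, assoc)
    want <- sofa_oracle(abund, assoc)
    want <- want[, colSums(want) > 0, drop = FALSE]
    expect_equal(bare(got), want, tolerance = 1e-12)
  }
  a <- random_abundance(3, 4, 1)
  b <- random_abundance(3, 4, 2)
  assoc <- association_matrix(named_matrix(rep(1L, 24), 4, "t", "a"))
  combo <- abundance_table(2 * unclass(a) + 3 * unclass(b))
  expect_equal(unclass(compute_sofa(combo, assoc)),
               2 * unclass(compute_sofa(a, assoc)) +
                 3 * unclass(compute_sofa(b, assoc)),
               tolerance = 1e-12)
})

test_that("taxa missing from the association matrix contribute zero, with warning", {
  abund <- random_abundance(3, 3, 1)  # taxa t1..t3
  assoc <- random_association(2, 4, 2)  # taxa t1..t2 only
  expect_warning(got <- compute_sofa(abund, assoc), "contribute no annotation")
  manual <- unclass(abund)[, 1:2] %*% unclass(assoc)
  manual <- manual[, colSums(manual) > 0, drop = FALSE]
  expect_equal(bare(got), manual, tolerance = 1e-12)
})

test_that("term frequencies sum to one per sample", {
  s <- sofa_table(named_matrix(c(1, 1, 2), 1, "s", "a"))
  expect_equal(unname(unclass(term_frequency(s))[1, ]), c(0.25, 0.25, 0.5))
  one <- sofa_table(named_matrix(c(3, 5), 2, "s", "a"))
  expect_equal(unname(bare(term_frequency(one))), matrix(1, 2, 1))
  for (seed in 1:5) {
    tf <- term_frequency(sofa_table(unclass(random_abundance(5, 7, seed))))
    expect_equal(unname(rowSums(tf)), rep(1, 5), tolerance = 1e-12)
  }
  z <- sofa_table(named_matrix(c(0, 1, 0, 2), 2, "s", "a"))
  expect_error(term_frequency(z), "s1")
})

test_that("inverse gravity moment matches its closed forms and oracle", {
  # positive in exactly one of n samples -> igm = 1
  tf <- sofa_table(named_matrix(c(0.4, 0, 0, 0.6, 1, 0.4), 3, "s", "a"))
  igm <- inverse_gravity_moment(tf)
  expect_equal(unname(igm["a1"]), 1)
  # uniform across n samples -> 2 / (n (n + 1)); here n = 3 -> 1/6
  uni <- sofa_table(named_matrix(rep(0.2, 3), 3, "s", "a"))
  expect_equal(unname(inverse_gravity_moment(uni)), 1 / 6)
  # all-zero column -> 0 by convention
  zero <- sofa_table(named_matrix(c(0, 0, 1, 1), 2, "s", "a"))
  expect_equal(unname(inverse_gravity_moment(zero)["a1"]), 0)
  # brute-force sort-and-sum oracle on random columns
  set.seed(42)
  for (rep in 1:20) {
    col <- runif(7)
    tf <- sofa_table(named_matrix(col, 7, "s", "a"))
    expect_equal(unname(inverse_gravity_moment(tf)), igm_oracle(col),
                 tolerance = 1e-12)
  }
})

test_that("igm stays in [0, 1] and grows when mass concentrates on top", {
  set.seed(7)
  for (rep in 1:20) {
    col <- runif(6)
    igm1 <- igm_oracle(col)
    expect_gte(igm1, 0)
    expect_lte(igm1, 1)
    # move mass from the smallest to the largest value
    s <- sort(col, decreasing = TRUE)
    moved <- c(s[1] + s[6] / 2, s[2:5], s[6] / 2)
    expect_gte(igm_oracle(moved), igm1 - 1e-12)
  }
})

test_that("tf-igm weighting follows the direct formula with lambda = 7", {
  # one annotation concentrated in one sample: tf 0.5, igm 1 -> 0.5 * 8 = 4
  s <- sofa_table(named_matrix(c(1, 0, 1, 3), 2, "s", "a"))
  out <- tf_igm_transform(s, lambda_ = 7)
  expect_equal(unname(unclass(out)["s1", "a1"]), 4)
  expect_equal(attr(out, "normalization"), "tf_igm")
  expect_equal(attr(out, "lambda_"), 7)
  # elementwise oracle on random tables
  for (seed in 1:5) {
    raw <- sofa_table(unclass(random_abundance(6, 5, seed)))
    tf <- bare(term_frequency(raw))
    igm <- vapply(seq_len(ncol(tf)), function(j) igm_oracle(tf[, j]),
                  numeric(1))
    want <- tf * rep(1 + 7 * igm, each = nrow(tf))
    expect_equal(unname(bare(tf_igm_transform(raw, 7))), unname(want),
                 tolerance = 1e-12)
  }
  expect_error(tf_igm_transform(s, lambda_ = 4.9), "\\[5, 9\\]")
  expect_error(tf_igm_transform(s, lambda_ = 9.1), "\\[5, 9\\]")
})

test_that("tf-igm preserves within-sample ranking at equal igm", {
  # two annotations with identical igm keep their within-sample order
  m <- named_matrix(c(4, 1, 2, 0.5, 1, 1), 2, "s", "a")  # a3 uniform-ish
  raw <- sofa_table(m)
  tf <- unclass(term_frequency(raw))
  igm <- inverse_gravity_moment(term_frequency(raw))
  out <- unclass(tf_igm_transform(raw, 7))
  same_igm <- which(abs(igm - igm[1]) < 1e-12)
  if (length(same_igm) >= 2) {
    for (i in 1:2) {
      expect_equal(order(tf[i, same_igm]), order(out[i, same_igm]))
    }
  }
})

test_that("re-applying tf-igm to a column subset is not a no-op", {
  raw <- sofa_table(unclass(random_abundance(8, 6, 3)))
  full <- unclass(tf_igm_transform(raw, 7))
  sub_cols <- colnames(raw)[1:3]
  sub <- unclass(tf_igm_transform(sofa_table(unclass(raw)[, sub_cols]), 7))
  expect_false(isTRUE(all.equal(full[, sub_cols], sub)))
})

test_that("standard scaling centers with population sd and handles held-out data", {
  m <- named_matrix(c(1, 3, 5, 5), 2, "s", "f")
  sc <- standard_scale(m)
  expect_equal(unname(sc[, "f1"]), c(-1, 1))  # population sd of (1,3) is 1
  expect_equal(unname(sc[, "f2"]), c(0, 0))   # constant feature -> zeros
  set.seed(9)
  big <- named_matrix(rnorm(200), 20)
  sc2 <- standard_scale(big)
  expect_equal(unname(colMeans(sc2)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(sc2, 2, function(v) sqrt(mean(v^2)))),
               rep(1, 10), tolerance = 1e-12)
  # reuse of fitted stats on new samples
  new <- named_matrix(rnorm(30), 3)
  colnames(new) <- colnames(big)
  tr <- standard_scale(new, fit_stats = attr(sc2, "fit_stats"))
  expect_equal(unname(tr[1, 1]),
               (new[1, 1] - mean(big[, 1])) / sqrt(mean((big[, 1] - mean(big[, 1]))^2)),
               tolerance = 1e-12)
  expect_error(standard_scale(big[1, , drop = FALSE]), "at least 2")
})
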