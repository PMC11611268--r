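# Taxon-annotation linkage analytics.

test_that("link strengths normalize the mean-abundance-weighted counts", {
  abund <- abundance_table(named_matrix(c(2, 4, 1, 1, 3, 3), 2, "s", "t"))
  assoc <- association_matrix(
    named_matrix(c(3L, 0L, 1L, 2L, 0L, 0L), 3, "t", "a")
  )
  # single linked taxon
  s1 <- link_strength(assoc, abund, "a2")
  expect_equal(unname(s1), 1)
  expect_equal(names(s1), "t1")
  # two taxa, equal mean abundance, equal counts -> 0.5 each
  eq_ab <- abundance_table(named_matrix(c(1, 3, 1, 3), 2, "s", "t"))
  eq_as <- association_matrix(named_matrix(c(2L, 2L), 2, "t", "a"))
  expect_equal(unname(link_strength(eq_as, eq_ab, "a1")), c(0.5, 0.5))
  # random cases: sums to 1 and matches the direct formula
  for (seed in 1:10) {
    ab <- random_abundance(6, 5, seed)
    as_ <- random_association(5, 4, seed + 50)
    for (f in colnames(as_)) {
      x <- unclass(as_)[, f]
      if (sum(x) == 0) next
      s <- link_strength(as_, ab, f)
      expect_equal(sum(s), 1, tolerance = 1e-12)
      linked <- names(x)[x > 0]
      raw <- colMeans(unclass(ab))[linked] * x[linked]
      expect_equal(s, raw / sum(raw), tolerance = 1e-12)
    }
  }
  zero_ab <- abundance_table(named_matrix(c(0, 0, 1, 1), 2, "s", "t"))
  one_as <- association_matrix(named_matrix(c(1L, 0L), 2, "t", "a"))
  expect_error(link_strength(one_as, zero_ab, "a1"), "zero mean abundance")
})

test_that("profile assignment encodes dominance in the ratio's sign", {
  y <- label_vector(c(s1 = 0, s2 = 0, s3 = 1, s4 = 1))
  ctrl_dom <- c(s1 = 4, s2 = 4, s3 = 2, s4 = 2)
  res <- assign_profile(ctrl_dom, y)
  expect_equal(res$profile, "control")
  expect_equal(res$ponderated_ratio, 2)
  unh_dom <- c(s1 = 2, s2 = 2, s3 = 4, s4 = 4)
  res2 <- assign_profile(unh_dom, y)
  expect_equal(res2$profile, "unhealthy")
  expect_equal(res2$ponderated_ratio, -2)
  # tie -> control with +1
  tie <- c(s1 = 3, s2 = 3, s3 = 3, s4 = 3)
  expect_equal(assign_profile(tie, y),
               list(profile = "control", ponderated_ratio = 1))
  # swapping the labels flips the sign, keeps the magnitude
  y_sw <- label_vector(c(s1 = 1, s2 = 1, s3 = 0, s4 = 0))
  res3 <- assign_profile(ctrl_dom, y_sw)
  expect_equal(res3$ponderated_ratio, -res$ponderated_ratio)
  # zero minority mean -> signed infinity with warning
  expect_warning(inf <- assign_profile(c(s1 = 1, s2 = 1, s3 = 0, s4 = 0), y),
                 "Inf")
  expect_equal(inf$ponderated_ratio, Inf)
})

test_that("jaccard proximity flags functionally identical taxa", {
  counts <- rbind(
    tA = c(1L, 1L, 1L, 0L),
    tB = c(2L, 5L, 1L, 0L),  # same support as tA -> proximity 1
    tC = c(0L, 0L, 0L, 3L)   # disjoint support
  )
  colnames(counts) <- paste0("a", 1:4)
  red <- jaccard_redundancy(association_matrix(counts))
  expect_equal(red$proximity["tA", "tB"], 1)
  expect_equal(red$proximity["tA", "tC"], 0)
  expect_equal(red$proximity["tB", "tA"], red$proximity["tA", "tB"])
  expect_equal(unname(red$neighbor_counts), c(1, 1, 0))
  expect_equal(red$fraction_without_neighbor, 1 / 3)
})

test_that("proximity just above the threshold counts as a close neighbor", {
  # 24 shared of 25 union -> proximity 0.96 >= 0.95
  base <- c(rep(1L, 24), 0L, 0L)
  other <- c(rep(1L, 24), 1L, 0L)
  third <- c(rep(0L, 24), 0L, 1L)
  counts <- rbind(tA = base, tB = other, tC = third)
  colnames(counts) <- paste0("a", seq_along(base))
  red <- jaccard_redundancy(association_matrix(counts),
                            proximity_threshold = 0.95)
  expect_equal(red$proximity["tA", "tB"], 0.96)
  expect_equal(unname(red$neighbor_counts[c("tA", "tB")]), c(1, 1))
  # empty-support taxa are excluded with a warning
  counts2 <- rbind(counts, tD = rep(0L, length(base)))
  expect_warning(red2 <- jaccard_redundancy(association_matrix(counts2)),
                 "empty annotation sets")
  expect_false("tD" %in% rownames(red2$proximity))
})

test_that("annotation categories partition the robust set", {
  # five annotations with total linkage 1, 5, 10, 50, 100; a5 additionally
  # has no robust-taxon link at all -> Cumulative regardless of totals
  n_taxa <- 120
  counts <- matrix(0L, n_taxa, 6,
                   dimnames = list(sprintf("t%03d", 1:n_taxa),
                                   paste0("a", 1:6)))
  counts[1, "a1"] <- 1L
  counts[1:5, "a2"] <- 1L
  counts[1:10, "a3"] <- 1L
  counts[1:50, "a4"] <- 1L
  counts[1:100, "a5"] <- 1L
  counts[30:43, "a6"] <- 1L  # 14 taxa, none robust
  assoc <- association_matrix(counts)
  robust_taxa <- c("t001", "t002")
  robust_annot <- paste0("a", 1:6)
  # range deciles of the non-cumulative totals {1,5,10,50,100}: scale
  # [1,100], bottom <= 10.9, top >= 90.1
  cat_range <- categorize_annotations(robust_annot, robust_taxa, assoc,
                                      decile_mode = "range")
  expect_equal(unname(cat_range["a6"]), "Cumulative")
  expect_equal(unname(cat_range["a5"]), "Ubiquitous")  # max of the scale
  expect_equal(unname(cat_range[c("a1", "a2", "a3")]),
               rep("Specific", 3))
  expect_equal(unname(cat_range["a4"]), "In-between")
  # quantile deciles of {1,5,10,50,100}: 10th pct 2.6, 90th pct 80
  cat_q <- categorize_annotations(robust_annot, robust_taxa, assoc,
                                  decile_mode = "quantile")
  expect_equal(unname(cat_q["a1"]), "Specific")
  expect_equal(unname(cat_q["a5"]), "Ubiquitous")
  expect_equal(unname(cat_q[c("a2", "a3", "a4")]), rep("In-between", 3))
  expect_equal(unname(cat_q["a6"]), "Cumulative")
  # exactly one category per robust annotation
  expect_true(all(cat_range %in%
                    c("Ubiquitous", "Specific", "In-between", "Cumulative")))
  expect_error(categorize_annotations(character(0), robust_taxa, assoc),
               "empty")
})

test_that("shortlist reports join importances, profiles and link counts", {
  dat <- generate_dataset(synthetic_config(
    n_samples_per_class = 25, n_taxa = 20, n_annotations = 30,
    cumulative_n_taxa = 13, seed = 9
  ))
  sofa <- compute_sofa(dat$abundance, dat$association)
  report <- suppressWarnings(
    run_pipeline(unclass(sofa), dat$labels, x_taxa = dat$abundance,
                 n_runs = 2, n_iterations = 1, n_forests = 3,
                 base_seed = 70, grid = small_rf_grid())
  )
  tabs <- annotate_shortlists(report, dat$association, dat$abundance,
                              sofa, dat$labels)
  expect_named(tabs, c("annotations", "taxa"))
  at <- tabs$annotations
  if (nrow(at) > 0) {
    expect_true(all(diff(at$average_importance) <= 0))  # ordered rows
    expect_true(all(abs(at$ponderated_ratio) >= 1))
    expect_true(all(at$linked_robust <= at$linked_total))
    # link counts equal the generator's bipartite degrees
    x <- unclass(dat$association)
    expect_equal(at$linked_total,
                 unname(colSums(x[, at$id, drop = FALSE] > 0)))
  }
  edges <- linkage_edges(report, dat$association, dat$abundance, dat$labels)
  if (!is.null(edges)) {
    sums <- tapply(edges$strength, edges$annotation, sum)
    expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
  }
})
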