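# Synthetic microbiome datasets with planted group effects.
#
# Emulates the statistical structure the pipeline assumes: per-taxon
# log-normal abundances with a class-dependent shift on planted signal taxa,
# closed to per-sample relative abundances (compositional, MetaPhlAn-style);
# a sparse zero-inflated-Poisson bipartite taxon-annotation association
# matrix; and an optional "cumulative" construct — one or more annotations
# linked exclusively to a group of individually weak, same-direction taxa,
# so that their signal is invisible per taxon but strong once summed on the
# functional side.

#' Configuration of the synthetic-data generator
#'
#' Defaults are the generator's study conditions: 100 samples per class,
#' 50 taxa, 200 annotations, 10% association density with mean protein
#' multiplicity 3, 3 signal taxa shifted by 2 log-sd between classes, and
#' one cumulative annotation spread over 15 taxa shifted by 0.6 log-sd
#' each (individually sub-threshold next to the 2-log-sd signal taxa, yet
#' collectively a strong functional effect once summed over 15 taxa).
#'
#' @param n_samples_per_class samples per class.
#' @param n_taxa,n_annotations numbers of taxa and annotations.
#' @param association_density probability that a (taxon, annotation) pair is
#'   linked.
#' @param association_mean_count mean protein-cluster count of a linked
#'   pair (zero-truncated Poisson).
#' @param n_signal_taxa taxa carrying the strong planted effect.
#' @param effect_size class shift of signal taxa, in units of the log-sd.
#' @param abundance_sdlog log-sd of the per-taxon abundance model.
#' @param n_cumulative_annotations annotations planted as cumulative.
#' @param cumulative_n_taxa weak taxa sharing each cumulative annotation
#'   (at least 13 for the effect the construct emulates).
#' @param cumulative_effect per-taxon class shift of the weak taxa, in
#'   log-sd units (individually sub-threshold).
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples_per_class = 100,
                             n_taxa = 50,
                             n_annotations = 200,
                             association_density = 0.1,
                             association_mean_count = 3,
                             n_signal_taxa = 3,
                             effect_size = 2,
                             abundance_sdlog = 1,
                             n_cumulative_annotations = 1,
                             cumulative_n_taxa = 15,
                             cumulative_effect = 0.6,
                             seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_signal_taxa > cfg$n_taxa) {
    stop("more signal taxa than taxa")
  }
  if (cfg$n_cumulative_annotations > 0 &&
      cfg$n_signal_taxa + cfg$cumulative_n_taxa > cfg$n_taxa) {
    stop("signal and cumulative taxa exceed the number of taxa")
  }
  if (cfg$effect_size < 0 || cfg$cumulative_effect < 0) {
    stop("effect sizes must be non-negative")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic dataset with planted effects
#'
#' @param cfg a [synthetic_config()].
#' @return List with `abundance` (relative [abundance_table()], rows sum to
#'   100), `labels` (a [label_vector()], 0 = control, 1 = unhealthy),
#'   `association` (an [association_matrix()]) and `ground_truth` (planted
#'   signal taxa, cumulative taxa and cumulative annotations).
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  set.seed(cfg$seed)
  n <- 2L * cfg$n_samples_per_class
  taxa <- sprintf("taxon_%03d", seq_len(cfg$n_taxa))
  annots <- sprintf("GO:%07d", seq_len(cfg$n_annotations))
  samples <- sprintf("sample_%03d", seq_len(n))
  y <- rep(c(0L, 1L), each = cfg$n_samples_per_class)

  signal_taxa <- taxa[seq_len(cfg$n_signal_taxa)]
  cumulative_taxa <- character(0)
  cumulative_annots <- character(0)
  if (cfg$n_cumulative_annotations > 0) {
    cumulative_taxa <- taxa[cfg$n_signal_taxa + seq_len(cfg$cumulative_n_taxa)]
    cumulative_annots <- annots[seq_len(cfg$n_cumulative_annotations)]
  }

  # per-taxon baseline log-mean; class shift on planted taxa.  Planted taxa
  # are given a low baseline (disease-associated taxa are typically rare) so
  # that the per-sample closure to relative abundances does not let their
  # shift distort the unplanted taxa's profiles.
  baseline <- rnorm(cfg$n_taxa, mean = 0, sd = 1)
  names(baseline) <- taxa
  baseline[c(signal_taxa, cumulative_taxa)] <- -2
  shift <- setNames(rep(0, cfg$n_taxa), taxa)
  shift[signal_taxa] <- cfg$effect_size * cfg$abundance_sdlog
  shift[cumulative_taxa] <- cfg$cumulative_effect * cfg$abundance_sdlog

  values <- matrix(0, nrow = n, ncol = cfg$n_taxa,
                   dimnames = list(samples, taxa))
  for (t in seq_len(cfg$n_taxa)) {
    meanlog <- baseline[t] + shift[t] * y
    values[, t] <- rlnorm(n, meanlog = meanlog, sdlog = cfg$abundance_sdlog)
  }
  abund <- to_relative_abundance(abundance_table(values))

  # sparse association counts: Bernoulli(density) x (1 + Poisson(mean - 1))
  linked <- matrix(rbinom(cfg$n_taxa * cfg$n_annotations, 1,
                          cfg$association_density),
                   nrow = cfg$n_taxa)
  counts <- linked * (1 + matrix(rpois(cfg$n_taxa * cfg$n_annotations,
                                       max(cfg$association_mean_count - 1, 0)),
                                 nrow = cfg$n_taxa))
  dimnames(counts) <- list(taxa, annots)
  # cumulative annotations link exactly their weak taxa, nothing else
  if (length(cumulative_annots) > 0) {
    counts[, cumulative_annots] <- 0
    counts[cumulative_taxa, cumulative_annots] <- 1 +
      matrix(rpois(length(cumulative_taxa) * length(cumulative_annots),
                   max(cfg$association_mean_count - 1, 0)),
             nrow = length(cumulative_taxa))
  }
  # every taxon must carry at least one annotation so SoFA columns exist
  bare <- rowSums(counts) == 0
  if (any(bare)) {
    pick <- sample(setdiff(annots, cumulative_annots), sum(bare),
                   replace = TRUE)
    counts[cbind(which(bare), match(pick, annots))] <- 1
  }

  list(
    abundance = abund,
    labels = label_vector(y, sample_ids = samples),
    association = association_matrix(counts),
    ground_truth = list(
      signal_taxa = signal_taxa,
      cumulative_taxa = cumulative_taxa,
      cumulative_annotations = cumulative_annots
    ),
    config = cfg
  )
}

#' Write an association matrix as per-taxon annotation tables
#'
#' Emits the directory layout accepted by [read_esmecata_annotations()]:
#' one TSV per taxon with columns `cluster`, `GO`, `EC`; a pair with count
#' k yields k cluster rows listing the annotation (GO tokens in the GO
#' column, EC tokens in the EC column).  A taxon without annotations gets a
#' header-only file.  Round-trips to the input matrix.
#'
#' @param assoc an [association_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_esmecata_like <- function(assoc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- unclass(assoc)
  for (t in rownames(m)) {
    x <- setNames(m[t, ], colnames(m))  # survives 1-column matrices
    rows <- data.frame(cluster = character(0), GO = character(0),
                       EC = character(0))
    cluster_i <- 0L
    for (f in colnames(m)[x > 0]) {
      is_go <- startsWith(f, "GO:")
      for (k in seq_len(x[f])) {
        cluster_i <- cluster_i + 1L
        rows <- rbind(rows, data.frame(
          cluster = sprintf("%s_cluster_%04d", t, cluster_i),
          GO = if (is_go) f else "",
          EC = if (is_go) "" else f
        ))
      }
    }
    data.table::fwrite(rows, file.path(dir, paste0(t, ".tsv")), sep = "\t")
  }
  invisible(dir)
}

#' Bundled benchmark-cohort dimensions
#'
#' Sample and feature counts of six published gut-microbiome case-control
#' cohorts (cirrhosis, colorectal cancer, IBD, obesity and two type-2
#' diabetes cohorts) widely used to benchmark microbiome classifiers:
#' cohort sizes, initial taxon counts, and the number of functional
#' annotations their taxa map to.
#'
#' @return A data.frame with one row per cohort.
#' @export
benchmark_cohorts <- function() {
  path <- system.file("extdata", "benchmark_cohorts.tsv", package = "funtaxa")
  data.table::fread(path, data.table = FALSE)
}
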