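#' @import data.table
#' @importFrom stats median quantile rbinom rlnorm rnorm rpois runif sd setNames wilcox.test
#' @importFrom utils head
NULL

# ---- Domain types -----------------------------------------------------------
#
# All four core containers are thin S3 wrappers around a base matrix with
# dimnames, so that downstream linear algebra stays idiomatic.  Samples are
# always rows for sample-indexed tables; taxa are rows of the association
# matrix.

#' Construct an abundance table (samples x taxa)
#'
#' Non-negative abundance values, one row per sample, one column per taxon.
#' Absence is encoded as 0; missing values are not allowed.
#'
#' @param values numeric matrix with unique row (sample) and column (taxon)
#'   names.
#' @return An `abundance_table` object.
#' @export
abundance_table <- function(values) {
  values <- as.matrix(values)
  check_id_matrix(values, "abundance table")
  if (anyNA(values)) stop("abundance table contains missing values")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf(
      "negative abundance at sample '%s', taxon '%s'",
      rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]
    ))
  }
  structure(values, class = c("abundance_table", "matrix", "array"))
}

#' Construct a binary label vector
#'
#' @param labels vector of two distinct classes, named by sample id (or
#'   `sample_ids` given separately). Internally coded 0 = control,
#'   1 = unhealthy.
#' @param sample_ids optional character vector of sample identifiers.
#' @param control optional value of `labels` to treat as the control class;
#'   defaults to the first of the sorted unique labels (stable across runs).
#' @return A named integer vector of class `label_vector` with attribute
#'   `classes = c(control, unhealthy)` recording the original coding.
#' @export
label_vector <- function(labels, sample_ids = NULL, control = NULL) {
  if (!is.null(sample_ids)) names(labels) <- sample_ids
  if (is.null(names(labels))) stop("labels must carry sample ids")
  if (anyDuplicated(names(labels))) stop("duplicate sample ids in labels")
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2L) {
    stop(sprintf("binary labels required (found %d classes)", length(lev)))
  }
  if (!is.null(control)) {
    control <- as.character(control)
    if (!control %in% lev) stop("'control' is not one of the label values")
    lev <- c(control, setdiff(lev, control))
  }
  y <- setNames(as.integer(as.character(labels) == lev[2L]), names(labels))
  structure(y, classes = lev, class = "label_vector")
}

#' Construct a taxon-annotation association matrix
#'
#' Counts of protein clusters of each taxon (rows) carrying each functional
#' annotation (columns; GO terms and/or EC numbers).
#'
#' @param counts non-negative integer matrix, taxa x annotations.
#' @return An `association_matrix` object.
#' @export
association_matrix <- function(counts) {
  counts <- as.matrix(counts)
  check_id_matrix(counts, "association matrix")
  if (anyNA(counts)) stop("association matrix contains missing values")
  if (any(counts < 0)) stop("association counts must be non-negative")
  if (any(counts != round(counts))) stop("association counts must be integers")
  storage.mode(counts) <- "double"
  structure(counts, class = c("association_matrix", "matrix", "array"))
}

#' Construct a functional score table (samples x annotations)
#'
#' @param scores numeric matrix, samples x annotations.
#' @param normalization one of `"raw"`, `"relative"`, `"tf"`, `"tf_igm"`,
#'   `"standard_scaled"`.
#' @param lambda_ the TF-IGM lambda actually applied (recorded for
#'   provenance; `NA` unless `normalization == "tf_igm"`).
#' @return A `sofa_table` object.
#' @export
sofa_table <- function(scores,
                       normalization = c("raw", "relative", "tf", "tf_igm",
                                         "standard_scaled"),
                       lambda_ = NA_real_) {
  normalization <- match.arg(normalization)
  scores <- as.matrix(scores)
  check_id_matrix(scores, "functional score table")
  if (anyNA(scores)) stop("functional score table contains missing values")
  if (normalization %in% c("raw", "relative", "tf", "tf_igm") &&
      any(scores < 0)) {
    stop("raw functional scores must be non-negative")
  }
  structure(scores,
            normalization = normalization, lambda_ = lambda_,
            class = c("sofa_table", "matrix", "array"))
}

check_id_matrix <- function(m, what) {
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m)))) {
    stop(sprintf("%s must carry row and column identifiers", what))
  }
  if (anyDuplicated(rownames(m))) {
    stop(sprintf("duplicate row identifiers in %s", what))
  }
  if (anyDuplicated(colnames(m))) {
    stop(sprintf("duplicate column identifiers in %s", what))
  }
  invisible(m)
}

# ---- Readers ----------------------------------------------------------------

read_id_table <- function(path) {
  # fread sniffs TSV vs CSV; first column holds identifiers
  dt <- data.table::fread(path, header = TRUE, sep = "auto",
                          data.table = FALSE, check.names = FALSE)
  if (ncol(dt) < 2L) stop(sprintf("'%s' has no data columns", path))
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop(sprintf("non-numeric entries in '%s'", path))
  colnames(m) <- names(dt)[-1L]  # as.matrix silently deduplicates names
  rownames(m) <- ids
  m
}

#' Read a taxonomic abundance table from TSV/CSV
#'
#' The file must have one header row and one identifier column.  Orientation
#' (samples in rows versus taxa in rows) is either declared or, in `"auto"`
#' mode, resolved by matching identifiers against a label vector: the side
#' sharing at least 50% of its identifiers with the labels is taken to be
#' the sample side.  Silent transposition being the most dangerous failure
#' mode, ambiguity is an error, never a guess.
#'
#' @param path file path (TSV or CSV, sniffed).
#' @param orientation one of `"auto"`, `"samples_in_rows"`, `"taxa_in_rows"`.
#' @param labels optional [label_vector()] used to resolve `"auto"`.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path,
                                 orientation = c("auto", "samples_in_rows",
                                                 "taxa_in_rows"),
                                 labels = NULL) {
  orientation <- match.arg(orientation)
  m <- read_id_table(path)
  if (orientation == "auto") {
    if (is.null(labels)) {
      stop("orientation 'auto' needs a label vector to match sample ids ",
           "against; pass 'labels' or declare the orientation")
    }
    ids <- names(labels)
    row_hit <- mean(rownames(m) %in% ids)
    col_hit <- mean(colnames(m) %in% ids)
    if (row_hit >= 0.5 && col_hit < 0.5) {
      orientation <- "samples_in_rows"
    } else if (col_hit >= 0.5 && row_hit < 0.5) {
      orientation <- "taxa_in_rows"
    } else {
      stop(sprintf(
        "cannot resolve orientation of '%s': %.0f%% of rows and %.0f%% of columns match the label ids",
        path, 100 * row_hit, 100 * col_hit
      ))
    }
  }
  if (orientation == "taxa_in_rows") m <- t(m)
  abundance_table(m)
}

#' Read a binary label file
#'
#' One row per sample: an identifier column and a label column (TSV or CSV).
#'
#' @param path file path.
#' @param control optional label value to use as the control class.
#' @return A [label_vector()].
#' @export
read_labels <- function(path, control = NULL) {
  dt <- data.table::fread(path, header = TRUE, sep = "auto",
                          data.table = FALSE, check.names = FALSE)
  if (ncol(dt) < 2L) stop(sprintf("'%s' must have id and label columns", path))
  label_vector(dt[[2L]], sample_ids = as.character(dt[[1L]]),
               control = control)
}

#' Read a precomputed taxon-annotation association matrix from TSV/CSV
#'
#' Taxa in rows, annotations in columns, integer counts.
#'
#' @param path file path.
#' @return An [association_matrix()].
#' @export
read_association_matrix <- function(path) {
  association_matrix(read_id_table(path))
}

go_ec_pattern <- "^(GO:[0-9]{7}|[0-9]+(\\.([0-9]+|-)){3})$"

#' Read per-taxon annotation tables into an association matrix
#'
#' Parses the output layout of the EsMeCaTa annotation step: one TSV per
#' taxon, each row one protein cluster with comma-separated GO-term and
#' EC-number lists.  The count for (taxon, annotation) is the number of
#' cluster rows listing the annotation; a cluster row contributes at most 1
#' per annotation even if a token repeats on the row (clusters are counted,
#' not tokens).  Annotation tokens that look like neither a GO term nor an
#' EC number are skipped with a message.  Extra columns are ignored, so
#' minor layout revisions of the upstream tool still parse.
#'
#' @param path a directory of per-taxon TSV files (taxon id = file name
#'   without extension), or a single such file.
#' @return An [association_matrix()]; annotations appearing in no taxon are
#'   absent, taxa with no parseable annotation get an all-zero row (with a
#'   warning).
#' @export
read_esmecata_annotations <- function(path) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.(tsv|csv)$", full.names = TRUE)
  } else {
    path
  }
  if (length(files) == 0L) stop(sprintf("no annotation tables under '%s'", path))
  per_taxon <- lapply(files, read_one_taxon_annotation)
  names(per_taxon) <- vapply(files, function(f) {
    sub("\\.(tsv|csv)$", "", basename(f))
  }, character(1))
  all_annots <- sort(unique(unlist(lapply(per_taxon, names))))
  counts <- matrix(0, nrow = length(per_taxon), ncol = length(all_annots),
                   dimnames = list(names(per_taxon), all_annots))
  for (t in names(per_taxon)) {
    hits <- per_taxon[[t]]
    if (length(hits) == 0L) {
      warning(sprintf("taxon '%s' has an empty annotation table", t))
      next
    }
    counts[t, names(hits)] <- hits
  }
  association_matrix(counts)
}

read_one_taxon_annotation <- function(file) {
  dt <- data.table::fread(file, header = TRUE, sep = "\t",
                          data.table = FALSE, check.names = FALSE,
                          colClasses = "character", fill = TRUE)
  if (nrow(dt) == 0L) return(integer(0))
  # column 1: cluster id; annotation tokens live in the GO / EC columns
  annot_cols <- intersect(c("GO", "EC", "GOs", "ECs", "go", "ec"), names(dt))
  if (length(annot_cols) == 0L && ncol(dt) >= 3L) annot_cols <- names(dt)[2:3]
  tally <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(dt))) {
    tokens <- unlist(strsplit(unlist(dt[i, annot_cols, drop = TRUE]), ","))
    tokens <- trimws(tokens)
    tokens <- tokens[nzchar(tokens)]
    bad <- tokens[!grepl(go_ec_pattern, tokens)]
    if (length(bad) > 0) {
      message(sprintf("skipping unparseable annotation token(s) in %s: %s",
                      basename(file), paste(unique(bad), collapse = ", ")))
      tokens <- tokens[grepl(go_ec_pattern, tokens)]
    }
    for (tok in unique(tokens)) {  # per-cluster set semantics
      tally[[tok]] <- (if (is.null(tally[[tok]])) 0L else tally[[tok]]) + 1L
    }
  }
  unlist(as.list(tally))
}

# ---- Writers ----------------------------------------------------------------

#' Write a core table to TSV
#'
#' Writes any of the matrix-backed containers (abundance, association,
#' functional score tables) with identifiers as the first column, or a
#' label vector as a two-column (sample, label) table.  Files written this
#' way round-trip through the corresponding reader.
#'
#' @param x the object to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  UseMethod("write_table")
}

#' @export
write_table.default <- function(x, path) {
  m <- as.matrix(x)
  dt <- data.table::data.table(id = rownames(m))
  for (j in colnames(m)) dt[[j]] <- m[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @export
write_table.label_vector <- function(x, path) {
  lev <- attr(x, "classes")
  data.table::fwrite(
    data.table::data.table(sample = names(x), label = lev[unclass(x) + 1L]),
    path, sep = "\t"
  )
  invisible(path)
}

#' @export
print.label_vector <- function(x, ...) {
  lev <- attr(x, "classes")
  cat(sprintf("<label_vector> %d samples (%s = control: %d, %s = unhealthy: %d)\n",
              length(x), lev[1], sum(x == 0L), lev[2], sum(x == 1L)))
  invisible(x)
}

# Align an abundance table with an association matrix: every taxon of the
# abundance table must appear in the association matrix; missing taxa get an
# all-zero row with a warning (they contribute no function).
align_taxa <- function(abund, assoc) {
  taxa <- colnames(abund)
  missing <- setdiff(taxa, rownames(assoc))
  if (length(missing) == length(taxa)) {
    stop("no shared taxa between abundance table and association matrix")
  }
  if (length(missing) > 0) {
    warning(sprintf(
      "%d taxa absent from the association matrix contribute no annotation: %s",
      length(missing), paste(head(missing, 5), collapse = ", ")
    ))
    pad <- matrix(0, nrow = length(missing), ncol = ncol(assoc),
                  dimnames = list(missing, colnames(assoc)))
    assoc <- rbind(assoc, pad)
  }
  assoc_sub <- assoc[taxa, , drop = FALSE]
  structure(assoc_sub, class = c("association_matrix", "matrix", "array"))
}
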