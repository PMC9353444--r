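#' Read a labeled expression matrix
#'
#' Ingests a normalized (e.g. log-normalized) genes-by-cells expression
#' matrix together with a cell-to-cluster label table. Two matrix formats
#' are supported: a dense TSV with gene symbols in the first column and
#' barcodes in the header, or a MatrixMarket triplet file with companion
#' one-column feature and barcode lists (a second feature column, as in
#' 10x-style `features.tsv`, is used as the symbol column when present).
#'
#' Normalization itself happens upstream; this reader only checks that the
#' matrix looks like normalized expression: negative entries (as produced
#' by z-scoring) are rejected. Cells without a cluster label are dropped
#' with a message reporting the count; a label table sharing no barcode
#' with the matrix is a fatal error.
#'
#' @param matrix_path dense TSV or `.mtx` file.
#' @param features_path,barcodes_path companion lists, required for `.mtx`
#'   input and ignored for dense input.
#' @param labels_path 2-column TSV mapping barcode to cluster name.
#' @param species symbol-normalization convention for the gene index.
#' @param dedup policy for duplicate gene symbols after normalization:
#'   `"error"` (default) or `"first"` (keep the first occurrence).
#' @return an object of class `labeled_expression` with elements `matrix`
#'   (genes x cells), `genes`, `cells`, `labels` (character, aligned with
#'   `cells`).
#' @export
read_expression <- function(matrix_path, features_path = NULL,
                            barcodes_path = NULL, labels_path,
                            species = c("human", "mouse"),
                            dedup = c("error", "first")) {
  species <- match.arg(species)
  dedup <- match.arg(dedup)
  if (grepl("\\.mtx(\\.gz)?$", matrix_path)) {
    if (is.null(features_path) || is.null(barcodes_path)) {
      validation_error("MatrixMarket input requires features and barcodes files")
    }
    m <- as.matrix(Matrix::readMM(matrix_path))
    feats <- read_tsv_plain(features_path)
    genes <- if (ncol(feats) >= 2L) feats[[2L]] else feats[[1L]]
    cells <- read_tsv_plain(barcodes_path)[[1L]]
  } else {
    tab <- utils::read.delim(matrix_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    cells <- colnames(m)
  }
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    validation_error("matrix dimensions do not match feature/barcode lists")
  }
  storage.mode(m) <- "double"
  if (any(m < 0)) {
    validation_error("expression matrix contains negative values; ",
                     "expected non-negative normalized expression ",
                     "(z-scored input is not supported)")
  }
  genes <- normalize_symbols(genes, species)
  if (anyDuplicated(genes)) {
    if (dedup == "error") {
      validation_error("duplicate gene symbols after normalization: ",
                       paste(unique(genes[duplicated(genes)]), collapse = ", "),
                       " (set dedup = 'first' to keep first occurrences)")
    }
    keep <- !duplicated(genes)
    m <- m[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  if (anyDuplicated(cells)) validation_error("duplicate cell barcodes")
  dimnames(m) <- list(genes, cells)

  lab_tab <- read_labels(labels_path)
  lab <- lab_tab$cluster[match(cells, lab_tab$barcode)]
  if (all(is.na(lab))) {
    validation_error("no barcode in the labels file matches the matrix")
  }
  dropped <- sum(is.na(lab))
  if (dropped > 0L) {
    message("read_expression: dropped ", dropped, " unlabeled cell(s)")
    m <- m[, !is.na(lab), drop = FALSE]
    cells <- cells[!is.na(lab)]
    lab <- lab[!is.na(lab)]
  }
  new_labeled_expression(m, lab)
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
}

read_labels <- function(path) {
  tab <- read_tsv(path)
  if (!all(c("barcode", "cluster") %in% names(tab))) {
    # tolerate headerless 2-column files
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) schema_error("labels file needs columns barcode, cluster")
    names(tab)[1:2] <- c("barcode", "cluster")
  }
  tab$barcode <- as.character(tab$barcode)
  tab$cluster <- as.character(tab$cluster)
  if (anyDuplicated(tab$barcode)) {
    validation_error("a barcode appears more than once in the labels file")
  }
  tab
}

#' Construct a labeled expression object from in-memory data
#'
#' @param matrix non-negative genes x cells matrix with dimnames.
#' @param labels character vector of cluster names, one per column.
#' @return a `labeled_expression`.
#' @export
labeled_expression <- function(matrix, labels) {
  new_labeled_expression(matrix, labels)
}

new_labeled_expression <- function(m, labels) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    validation_error("expression matrix must carry gene and cell dimnames")
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(m)) {
    validation_error("need exactly one cluster label per cell")
  }
  if (any(is.na(labels) | !nzchar(labels))) {
    validation_error("every cell must have a non-empty cluster label")
  }
  if (any(m < 0)) validation_error("expression values must be non-negative")
  structure(list(matrix = m, genes = rownames(m), cells = colnames(m),
                 labels = labels),
            class = "labeled_expression")
}

#' @export
print.labeled_expression <- function(x, ...) {
  cat("<labeled_expression> ", length(x$genes), " genes x ", length(x$cells),
      " cells in ", length(unique(x$labels)), " clusters\n", sep = "")
  invisible(x)
}

#' Per-cluster expression profiles
#'
#' Summarizes a labeled expression matrix into one profile per cluster:
#' the arithmetic mean of normalized expression over the cluster's cells
#' (the `Exprs` quantity entering the interaction-power product) and the
#' cell count. All cells of a cluster contribute, whether or not a gene
#' passes any DEG filter.
#'
#' @param x a `labeled_expression`.
#' @return an object of class `cluster_profiles`: list with `mean_expr`
#'   (genes x clusters matrix) and `n_cells` (named integer).
#' @export
cluster_profiles <- function(x) {
  stopifnot(inherits(x, "labeled_expression"))
  clusters <- sort(unique(x$labels))
  mm <- vapply(clusters, function(cl) {
    rowMeans(x$matrix[, x$labels == cl, drop = FALSE])
  }, numeric(length(x$genes)))
  mm <- matrix(mm, nrow = length(x$genes),
               dimnames = list(x$genes, clusters))
  n <- vapply(clusters, function(cl) sum(x$labels == cl), integer(1L))
  structure(list(mean_expr = mm, n_cells = n), class = "cluster_profiles")
}

validate_degs <- function(degs) {
  check_columns(degs, c("gene", "cluster", "log2fc", "adj_p"), "DEG table")
  if (any(degs$adj_p < 0 | degs$adj_p > 1, na.rm = TRUE)) {
    validation_error("adjusted p values must lie in [0,1]")
  }
  invisible(TRUE)
}

#' Select differentially regulated genes of a cluster
#'
#' Filters a DEG table (columns `gene`, `cluster`, `log2fc`, `adj_p`) to
#' the genes of one cluster whose fold change is sign-consistent with the
#' requested direction, exceeds `min_abs_log2fc` in magnitude (strictly),
#' and whose adjusted p-value is at most `max_adj_p`. The defaults —
#' log2 fold change > 0.25, adjusted p <= 0.05 — are the conventional
#' cutoffs for calling a gene regulated in cluster-vs-rest comparisons.
#'
#' @param degs DEG table (data.frame).
#' @param cluster cluster name; must occur in the table.
#' @param direction `"up"`, `"down"` or `"both"` (`both` is the union of
#'   the two one-sided selections).
#' @param min_abs_log2fc non-negative fold-change cutoff.
#' @param max_adj_p significance cutoff in \[0,1\].
#' @return sorted character vector of gene symbols.
#' @export
select_regulated <- function(degs, cluster,
                             direction = c("up", "down", "both"),
                             min_abs_log2fc = 0.25, max_adj_p = 0.05) {
  direction <- match.arg(direction)
  validate_degs(degs)
  if (min_abs_log2fc < 0) validation_error("min_abs_log2fc must be >= 0")
  if (max_adj_p < 0 || max_adj_p > 1) {
    validation_error("max_adj_p must lie in [0,1]")
  }
  if (!cluster %in% degs$cluster) {
    validation_error("unknown cluster '", cluster, "' in DEG table")
  }
  d <- degs[degs$cluster == cluster, , drop = FALSE]
  sign_ok <- switch(direction,
                    up = d$log2fc > 0,
                    down = d$log2fc < 0,
                    both = d$log2fc != 0)
  keep <- sign_ok & abs(d$log2fc) > min_abs_log2fc & d$adj_p <= max_adj_p
  sort(unique(d$gene[keep]))
}
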