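#' Canonical unordered gene-pair set
#'
#' Pair sets are the common currency of database comparison: each pair is
#' stored unordered (members sorted lexicographically) and deduplicated,
#' so two databases publishing the same interaction in opposite orders
#' still intersect.
#'
#' @param gene_a,gene_b character vectors of pair members (recycled
#'   together), or `gene_a` may be a 2-column data.frame.
#' @param name label for the set.
#' @return an object of class `pair_set`: list with `name` and `pairs`
#'   (character vector of canonical `"A|B"` keys, sorted, unique).
#' @export
pair_set <- function(gene_a, gene_b = NULL, name = "pairs") {
  if (is.data.frame(gene_a)) {
    stopifnot(ncol(gene_a) >= 2L)
    gene_b <- as.character(gene_a[[2L]])
    gene_a <- as.character(gene_a[[1L]])
  }
  stopifnot(length(gene_a) == length(gene_b))
  keys <- paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b), sep = "|")
  structure(list(name = name, pairs = sort(unique(keys))),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat("<pair_set> '", x$name, "': ", length(x$pairs), " unordered pairs\n",
      sep = "")
  invisible(x)
}

#' Read / write a pair set as 2-column TSV
#'
#' @param path TSV with columns `gene_a`, `gene_b` (header required).
#' @param name label for the set; defaults to the file name.
#' @return a `pair_set`.
#' @export
read_pair_set <- function(path, name = basename(path)) {
  tab <- read_tsv(path)
  check_columns(tab, c("gene_a", "gene_b"), "pair-set table")
  pair_set(tab$gene_a, tab$gene_b, name = name)
}

#' @rdname read_pair_set
#' @param x a `pair_set`.
#' @export
write_pair_set <- function(x, path) {
  stopifnot(inherits(x, "pair_set"))
  parts <- strsplit(x$pairs, "|", fixed = TRUE)
  write_tsv(data.frame(gene_a = vapply(parts, `[`, "", 1L),
                       gene_b = vapply(parts, `[`, "", 2L),
                       stringsAsFactors = FALSE), path)
}

#' Coverage ratio of one pair database by a reference database
#'
#' The fraction of another database's pairs that the reference database
#' also contains: `|reference ∩ other| / |other|`. Equals 1 whenever the
#' other set is a subset of the reference, 0 when they are disjoint.
#'
#' @param reference,other `pair_set` objects; `other` must be nonempty.
#' @return ratio in \[0,1\].
#' @export
coverage_ratio <- function(reference, other) {
  stopifnot(inherits(reference, "pair_set"), inherits(other, "pair_set"))
  if (length(other$pairs) == 0L) {
    validation_error("coverage ratio is undefined for an empty comparison set")
  }
  length(intersect(reference$pairs, other$pairs)) / length(other$pairs)
}

check_result_map <- function(results) {
  stopifnot(is.list(results))
  ok <- vapply(results, inherits, logical(1L), what = "pair_set")
  if (length(results) && !all(ok)) {
    validation_error("per-cluster-pair results must be pair_set objects")
  }
  invisible(TRUE)
}

#' Average fetched-pair count of a method over all cluster pairs
#'
#' Mean number of gene pairs a method reports per ordered cluster pair,
#' averaged over all `n_clusters^2` ordered pairs (cluster pairs absent
#' from the result map count as empty).
#'
#' @param per_clusterpair_results named list mapping `"i->j"` keys to
#'   `pair_set` objects.
#' @param n_clusters total number of clusters `N`; the denominator is
#'   `N * N`.
#' @return mean pair count.
#' @export
average_pair_count <- function(per_clusterpair_results, n_clusters) {
  if (n_clusters < 1) validation_error("n_clusters must be >= 1")
  check_result_map(per_clusterpair_results)
  total <- sum(vapply(per_clusterpair_results,
                      function(ps) length(ps$pairs), integer(1L)))
  total / (n_clusters * n_clusters)
}

#' Average overlapped-pair count of a focal method against the others
#'
#' A fetched pair of the focal method counts as overlapped in a cluster
#' pair if at least one other method also fetched it there. The statistic
#' is the mean over all `N^2` ordered cluster pairs of the count of the
#' focal method's pairs validated by the union of the other methods; it
#' is therefore bounded above by [average_pair_count()] of the focal
#' method.
#'
#' @param results_by_method named list: method -> (named list:
#'   `"i->j"` -> `pair_set`).
#' @param focal_method name of the method being evaluated.
#' @param n_clusters total number of clusters `N`.
#' @return mean overlapped count.
#' @export
average_overlap_count <- function(results_by_method, focal_method,
                                  n_clusters) {
  if (n_clusters < 1) validation_error("n_clusters must be >= 1")
  if (length(results_by_method) < 2L) {
    validation_error("overlap needs at least two methods")
  }
  if (!focal_method %in% names(results_by_method)) {
    validation_error("focal method '", focal_method, "' not in results")
  }
  lapply(results_by_method, check_result_map)
  focal <- results_by_method[[focal_method]]
  others <- results_by_method[names(results_by_method) != focal_method]
  keys <- unique(unlist(lapply(results_by_method, names), use.names = FALSE))
  total <- 0
  for (key in keys) {
    fp <- focal[[key]]
    if (is.null(fp) || !length(fp$pairs)) next
    union_other <- unique(unlist(lapply(others, function(m) {
      if (is.null(m[[key]])) character(0) else m[[key]]$pairs
    }), use.names = FALSE))
    total <- total + length(intersect(fp$pairs, union_other))
  }
  total / (n_clusters * n_clusters)
}
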