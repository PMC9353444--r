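#' Interaction power of a gene pair
#'
#' The strength score of a candidate interaction is the product of the two
#' partners' cluster-mean normalized expression:
#' `Power = Exprs(A) * Exprs(B)`. Inputs must be non-negative, so the
#' power is non-negative and zero whenever either partner is silent.
#'
#' @param exprs_a,exprs_b mean normalized expression values (vectorized).
#' @return numeric vector of powers.
#' @examples
#' compute_power(2, 3)   # 6
#' compute_power(0, 7.5) # 0
#' @export
compute_power <- function(exprs_a, exprs_b) {
  if (any(exprs_a < 0) || any(exprs_b < 0)) {
    validation_error("expression means must be non-negative")
  }
  exprs_a * exprs_b
}

# permutation index matrix: one column per permutation of the cells.
# Depends only on (n_cells, n_perm, seed), so every scoring entry point
# sees the same permutations for the same seed regardless of which genes
# or clusters it scores.
perm_index_matrix <- function(n_cells, n_perm, seed) {
  with_seed(seed, {
    matrix(unlist(lapply(seq_len(n_perm), function(i) sample.int(n_cells)),
                  use.names = FALSE),
           nrow = n_cells, ncol = n_perm)
  })
}

# permuted cluster means for a set of genes: array genes x clusters x n_perm
permuted_cluster_means <- function(x, genes, clusters, perms) {
  G <- x$matrix[genes, , drop = FALSE]
  n_perm <- ncol(perms)
  out <- array(NA_real_, dim = c(length(genes), length(clusters), n_perm),
               dimnames = list(genes, clusters, NULL))
  for (p in seq_len(n_perm)) {
    labs <- x$labels[perms[, p]]
    for (ci in seq_along(clusters)) {
      out[, ci, p] <- rowMeans(G[, labs == clusters[ci], drop = FALSE])
    }
  }
  out
}

finish_pvalue <- function(exceed_count, n_perm, conservative) {
  p <- if (conservative) (1 + exceed_count) / (1 + n_perm)
       else exceed_count / n_perm
  pmin(pmax(p, 0), 1)
}

#' Cell-label permutation p-value for one gene pair
#'
#' Assesses whether the observed interaction power between a sender
#' cluster (expressing `gene_a`) and a receiver cluster (expressing
#' `gene_b`) exceeds what random cluster assignments produce. The full
#' label vector over all cells is shuffled `n_perm` times (cluster sizes
#' are preserved), the power is recomputed under each shuffle, and the
#' p-value is the fraction of permutations whose power reaches the
#' observed one (upper tail by default).
#'
#' @param x a `labeled_expression`.
#' @param sender_cluster,receiver_cluster cluster names.
#' @param gene_a,gene_b gene symbols present in the matrix.
#' @param n_perm number of permutations; defaults to 100.
#' @param seed RNG seed; the caller's RNG state is untouched.
#' @param tail `"upper"` counts permutations with permuted power >=
#'   observed (large powers significant); `"lower"` counts <=.
#' @param conservative_p if `TRUE`, use the (1 + count) / (1 + N)
#'   estimator, which can never return exactly zero.
#' @return p-value in \[0,1\].
#' @export
permutation_pvalue <- function(x, sender_cluster, receiver_cluster,
                               gene_a, gene_b, n_perm = 100, seed = 1L,
                               tail = c("upper", "lower"),
                               conservative_p = FALSE) {
  tail <- match.arg(tail)
  stopifnot(inherits(x, "labeled_expression"))
  if (n_perm < 1) validation_error("n_perm must be >= 1")
  for (g in c(gene_a, gene_b)) {
    if (!g %in% x$genes) validation_error("gene '", g, "' not in matrix")
  }
  for (cl in c(sender_cluster, receiver_cluster)) {
    if (!any(x$labels == cl)) {
      validation_error("cluster '", cl, "' has no cells")
    }
  }
  va <- as.numeric(x$matrix[gene_a, ])
  vb <- as.numeric(x$matrix[gene_b, ])
  obs <- compute_power(mean(va[x$labels == sender_cluster]),
                       mean(vb[x$labels == receiver_cluster]))
  perms <- perm_index_matrix(length(x$labels), n_perm, seed)
  pp <- vapply(seq_len(n_perm), function(p) {
    labs <- x$labels[perms[, p]]
    mean(va[labs == sender_cluster]) * mean(vb[labs == receiver_cluster])
  }, numeric(1L))
  cnt <- if (tail == "upper") sum(pp >= obs) else sum(pp <= obs)
  finish_pvalue(cnt, n_perm, conservative_p)
}

#' Combined gene-selection specification for one side of an interaction
#'
#' Bundles the DEG-based expression filter with the annotation-based
#' [gene_filter()] applied to one cluster's genes when enumerating
#' candidate pairs. The canonical sender spec selects up-regulated,
#' confidently extracellular cytokines; the canonical receiver spec
#' selects up-regulated, confidently membrane-bound receptors.
#'
#' @inheritParams gene_filter
#' @inheritParams select_regulated
#' @return an object of class `selection_spec`.
#' @export
selection_spec <- function(categories = NULL, min_confidence = 4L,
                           groups = NULL, classes = NULL, go_terms = NULL,
                           direction = c("up", "down", "both"),
                           min_abs_log2fc = 0.25, max_adj_p = 0.05) {
  direction <- match.arg(direction)
  structure(list(filter = gene_filter(categories, min_confidence, groups,
                                      classes, go_terms),
                 direction = direction,
                 min_abs_log2fc = min_abs_log2fc,
                 max_adj_p = max_adj_p),
            class = "selection_spec")
}

# genes of one cluster passing both the DEG filter and the annotation filter,
# restricted to genes present in the expression matrix
selected_cluster_genes <- function(x, degs, gdb, cluster, spec) {
  # clusters without any DEG entry simply select nothing (scans iterate
  # over every cluster, including ones the upstream DEG caller skipped)
  if (!cluster %in% degs$cluster) return(character(0))
  regulated <- select_regulated(degs, cluster, spec$direction,
                                spec$min_abs_log2fc, spec$max_adj_p)
  annotated <- select_genes(gdb, spec$filter)
  genes <- intersect(regulated, annotated)
  missing <- setdiff(genes, x$genes)
  if (length(missing)) {
    message("dropping ", length(missing),
            " selected gene(s) absent from the expression matrix")
  }
  sort(intersect(genes, x$genes))
}

empty_candidate_pairs <- function() {
  structure(
    data.frame(sender_cluster = character(), receiver_cluster = character(),
               sender_gene = character(), receiver_gene = character(),
               power = numeric(), power_fc = numeric(), p_value = numeric(),
               credibility = integer(), confidence_level = character(),
               modes = character(), effects = character(),
               stringsAsFactors = FALSE),
    class = c("candidate_pairs", "data.frame"))
}

deg_log2fc <- function(degs, gene, cluster) {
  hit <- which(degs$gene == gene & degs$cluster == cluster)
  if (length(hit)) degs$log2fc[hit[1L]] else NA_real_
}

# score an enumerated table of (sender_cluster, receiver_cluster,
# sender_gene, receiver_gene) rows: observed power + permutation p
score_enumerated <- function(x, tab, n_perm, seed, tail, conservative_p) {
  prof <- cluster_profiles(x)
  obs <- vapply(seq_len(nrow(tab)), function(k) {
    compute_power(prof$mean_expr[tab$sender_gene[k], tab$sender_cluster[k]],
                  prof$mean_expr[tab$receiver_gene[k], tab$receiver_cluster[k]])
  }, numeric(1L))
  genes <- sort(unique(c(tab$sender_gene, tab$receiver_gene)))
  clusters <- sort(unique(c(tab$sender_cluster, tab$receiver_cluster)))
  perms <- perm_index_matrix(length(x$labels), n_perm, seed)
  pm <- permuted_cluster_means(x, genes, clusters, perms)
  pv <- vapply(seq_len(nrow(tab)), function(k) {
    pp <- pm[tab$sender_gene[k], tab$sender_cluster[k], ] *
      pm[tab$receiver_gene[k], tab$receiver_cluster[k], ]
    cnt <- if (tail == "upper") sum(pp >= obs[k]) else sum(pp <= obs[k])
    finish_pvalue(cnt, n_perm, conservative_p)
  }, numeric(1L))
  tab$power <- obs
  tab$p_value <- pv
  tab
}

# attach DB annotation columns and deterministic ordering; filter by alpha
finalize_candidates <- function(tab, degs, idb_f, alpha) {
  if (nrow(tab) == 0L) return(empty_candidate_pairs())
  ints <- idb_f$interactions
  key <- paste(pmin(tab$sender_gene, tab$receiver_gene),
               pmax(tab$sender_gene, tab$receiver_gene), sep = "|")
  idx <- match(key, ints$pair_id)
  tab$power_fc <- vapply(seq_len(nrow(tab)), function(k) {
    deg_log2fc(degs, tab$sender_gene[k], tab$sender_cluster[k]) +
      deg_log2fc(degs, tab$receiver_gene[k], tab$receiver_cluster[k])
  }, numeric(1L))
  tab$credibility <- ints$credibility[idx]
  tab$confidence_level <- ints$confidence_level[idx]
  act_of <- function(pid, col) {
    a <- idb_f$actions[idb_f$actions$pair_id == pid, col]
    paste(unique(a), collapse = ";")
  }
  tab$modes <- vapply(key, act_of, character(1L), col = "mode")
  tab$effects <- vapply(key, act_of, character(1L), col = "effect")
  # alpha >= 1 disables the significance filter entirely
  if (alpha < 1) tab <- tab[tab$p_value < alpha, , drop = FALSE]
  ord <- order(-tab$power, tab$p_value, tab$sender_gene, tab$receiver_gene,
               tab$sender_cluster, tab$receiver_cluster)
  tab <- tab[ord, c("sender_cluster", "receiver_cluster", "sender_gene",
                    "receiver_gene", "power", "power_fc", "p_value",
                    "credibility", "confidence_level", "modes", "effects")]
  rownames(tab) <- NULL
  class(tab) <- c("candidate_pairs", "data.frame")
  tab
}

#' Infer significant sender-to-receiver gene pairs between two clusters
#'
#' The core inference step: (1) select the sender cluster's genes passing
#' its DEG and annotation filters and the receiver cluster's likewise;
#' (2) enumerate the sender x receiver cross product; (3) keep the pairs
#' present in the interaction database after applying the interaction
#' filter; (4) score each surviving pair with the expression-product power,
#' the log2-fold-change-sum variant, and the cell-label permutation
#' p-value; (5) keep pairs with `p_value < alpha`. The output is sorted by
#' power (descending), then p-value, then gene symbols, so identical
#' inputs and seed give bit-identical tables.
#'
#' @param x a `labeled_expression`.
#' @param degs DEG table (`gene`, `cluster`, `log2fc`, `adj_p`).
#' @param gdb a `gene_db`.
#' @param idb an `interaction_db`.
#' @param sender_cluster,receiver_cluster ordered cluster pair; the sender
#'   contributes the first partner, the receiver the second.
#' @param sender_spec,receiver_spec [selection_spec()] objects.
#' @param ifilter an [interaction_filter()].
#' @param n_perm,seed,tail,conservative_p see [permutation_pvalue()].
#' @param alpha significance cutoff (default 0.05; no multiple-testing
#'   correction is applied, matching the permutation-test convention; use
#'   `p.adjust` on the returned p-values if desired). Any `alpha >= 1`
#'   disables the filter and reports every database-matched pair.
#' @return a `candidate_pairs` data.frame. An empty sender or receiver
#'   selection yields an empty table with a message, not an error.
#' @export
infer_pairs <- function(x, degs, gdb, idb, sender_cluster, receiver_cluster,
                        sender_spec = selection_spec(),
                        receiver_spec = selection_spec(),
                        ifilter = interaction_filter(),
                        n_perm = 100, seed = 1L, alpha = 0.05,
                        tail = c("upper", "lower"), conservative_p = FALSE) {
  tail <- match.arg(tail)
  stopifnot(inherits(x, "labeled_expression"))
  validate_degs(degs)
  for (cl in c(sender_cluster, receiver_cluster)) {
    if (!any(x$labels == cl)) validation_error("cluster '", cl, "' has no cells")
  }
  s_genes <- selected_cluster_genes(x, degs, gdb, sender_cluster, sender_spec)
  r_genes <- selected_cluster_genes(x, degs, gdb, receiver_cluster,
                                    receiver_spec)
  if (!length(s_genes) || !length(r_genes)) {
    message("infer_pairs: empty ",
            if (!length(s_genes)) "sender" else "receiver",
            " gene selection; returning no pairs")
    return(empty_candidate_pairs())
  }
  idb_f <- subset_interactions(idb, ifilter)
  tab <- expand.grid(sender_gene = s_genes, receiver_gene = r_genes,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  key <- paste(pmin(tab$sender_gene, tab$receiver_gene),
               pmax(tab$sender_gene, tab$receiver_gene), sep = "|")
  tab <- tab[key %in% idb_f$interactions$pair_id, , drop = FALSE]
  if (nrow(tab) == 0L) return(empty_candidate_pairs())
  tab$sender_cluster <- sender_cluster
  tab$receiver_cluster <- receiver_cluster
  tab <- score_enumerated(x, tab, n_perm, seed, tail, conservative_p)
  finalize_candidates(tab, degs, idb_f, alpha)
}

#' Aggregate candidate pairs into cluster-pair network summaries
#'
#' For each ordered (sender, receiver) cluster pair, reports the count `M`
#' of retained gene pairs and the aggregated power `W`, the sum of their
#' interaction powers. `W` over all cluster pairs conserves the total
#' power of the input pairs by construction.
#'
#' @param pairs a `candidate_pairs` table (possibly spanning several
#'   cluster pairs).
#' @param all_pairs optional data.frame (`sender_cluster`,
#'   `receiver_cluster`) of cluster pairs to report even when empty
#'   (with `pair_count = 0`, `aggregated_power = 0`).
#' @return data.frame with columns `sender_cluster`, `receiver_cluster`,
#'   `pair_count`, `aggregated_power`, sorted by cluster names.
#' @export
network_summary <- function(pairs, all_pairs = NULL) {
  base <- unique(data.frame(sender_cluster = pairs$sender_cluster,
                            receiver_cluster = pairs$receiver_cluster,
                            stringsAsFactors = FALSE))
  if (!is.null(all_pairs)) {
    base <- unique(rbind(base, all_pairs[, c("sender_cluster",
                                             "receiver_cluster")]))
  }
  if (nrow(base) == 0L) {
    return(data.frame(sender_cluster = character(),
                      receiver_cluster = character(),
                      pair_count = integer(), aggregated_power = numeric(),
                      stringsAsFactors = FALSE))
  }
  base <- base[order(base$sender_cluster, base$receiver_cluster), ,
               drop = FALSE]
  base$pair_count <- vapply(seq_len(nrow(base)), function(k) {
    sum(pairs$sender_cluster == base$sender_cluster[k] &
          pairs$receiver_cluster == base$receiver_cluster[k])
  }, integer(1L))
  base$aggregated_power <- vapply(seq_len(nrow(base)), function(k) {
    sum(pairs$power[pairs$sender_cluster == base$sender_cluster[k] &
                      pairs$receiver_cluster == base$receiver_cluster[k]])
  }, numeric(1L))
  rownames(base) <- NULL
  base
}

#' Scan one gene pair across all ordered cluster pairs
#'
#' Evaluates where in the cluster-pair landscape a named gene pair is
#' active: for every ordered (sender, receiver) cluster pair in which
#' `gene_a` passes the sender selection and `gene_b` the receiver
#' selection, the pair's power and permutation p-value are reported. Used
#' to judge whether a candidate interaction is specific to one cluster
#' pair or shared across many.
#'
#' @inheritParams infer_pairs
#' @param gene_a,gene_b the gene pair (sender-side gene first).
#' @param clusters clusters to scan; defaults to all clusters in `x`.
#' @param exclude_self drop (i, i) self pairs if `TRUE`.
#' @param alpha p-value cutoff; any value >= 1 (the default) disables the
#'   filter and reports all surviving rows.
#' @return data.frame (`sender_cluster`, `receiver_cluster`,
#'   `sender_gene`, `receiver_gene`, `power`, `p_value`).
#' @export
scan_pair_across_clusters <- function(x, degs, gdb, gene_a, gene_b,
                                      clusters = NULL,
                                      sender_spec = selection_spec(),
                                      receiver_spec = selection_spec(),
                                      n_perm = 100, seed = 1L, alpha = 1,
                                      exclude_self = FALSE,
                                      tail = c("upper", "lower"),
                                      conservative_p = FALSE) {
  tail <- match.arg(tail)
  stopifnot(inherits(x, "labeled_expression"))
  validate_degs(degs)
  for (g in c(gene_a, gene_b)) {
    if (!g %in% x$genes) validation_error("gene '", g, "' not in matrix")
  }
  clusters <- clusters %||% sort(unique(x$labels))
  send_ok <- vapply(clusters, function(cl) {
    gene_a %in% selected_cluster_genes(x, degs, gdb, cl, sender_spec)
  }, logical(1L))
  recv_ok <- vapply(clusters, function(cl) {
    gene_b %in% selected_cluster_genes(x, degs, gdb, cl, receiver_spec)
  }, logical(1L))
  tab <- expand.grid(sender_cluster = clusters[send_ok],
                     receiver_cluster = clusters[recv_ok],
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  if (exclude_self) {
    tab <- tab[tab$sender_cluster != tab$receiver_cluster, , drop = FALSE]
  }
  if (nrow(tab) == 0L) {
    return(data.frame(sender_cluster = character(),
                      receiver_cluster = character(),
                      sender_gene = character(), receiver_gene = character(),
                      power = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  tab$sender_gene <- gene_a
  tab$receiver_gene <- gene_b
  tab <- score_enumerated(x, tab, n_perm, seed, tail, conservative_p)
  if (alpha < 1) tab <- tab[tab$p_value < alpha, , drop = FALSE]
  ord <- order(-tab$power, tab$p_value, tab$sender_cluster,
               tab$receiver_cluster)
  tab <- tab[ord, c("sender_cluster", "receiver_cluster", "sender_gene",
                    "receiver_gene", "power", "p_value")]
  rownames(tab) <- NULL
  tab
}

#' Off-target scan: all partners of one gene across all cluster pairs
#'
#' Enumerates every candidate pair in which a named gene participates —
#' across all interaction-database partners of the gene and all ordered
#' cluster pairs — to expose unintended signalling routes a perturbation
#' of that gene would touch. With `role = "sender"` the gene is
#' constrained to the sender side, `"receiver"` to the receiver side, and
#' `"any"` takes the union of both orientations.
#'
#' @inheritParams infer_pairs
#' @param gene the focal gene symbol.
#' @param role which side(s) the focal gene may occupy.
#' @param gene_spec,partner_spec selection specs for the focal gene's side
#'   and the partner's side respectively.
#' @param exclude_self drop (i, i) cluster self pairs if `TRUE`.
#' @return a `candidate_pairs` data.frame over all ordered cluster pairs.
#' @export
scan_gene_partners <- function(x, degs, gdb, idb, gene,
                               role = c("any", "sender", "receiver"),
                               gene_spec = selection_spec(),
                               partner_spec = selection_spec(),
                               ifilter = interaction_filter(),
                               n_perm = 100, seed = 1L, alpha = 0.05,
                               exclude_self = FALSE,
                               tail = c("upper", "lower"),
                               conservative_p = FALSE) {
  role <- match.arg(role)
  tail <- match.arg(tail)
  stopifnot(inherits(x, "labeled_expression"))
  validate_degs(degs)
  if (!gene %in% x$genes) validation_error("gene '", gene, "' not in matrix")
  idb_f <- subset_interactions(idb, ifilter)
  ints <- idb_f$interactions
  partners <- unique(c(ints$gene_b[ints$gene_a == gene],
                       ints$gene_a[ints$gene_b == gene]))
  if (!length(partners)) return(empty_candidate_pairs())
  clusters <- sort(unique(x$labels))

  sel <- function(cl, spec) selected_cluster_genes(x, degs, gdb, cl, spec)
  rows <- list()
  for (sc in clusters) {
    for (rc in clusters) {
      if (exclude_self && sc == rc) next
      if (role %in% c("any", "sender")) {
        if (gene %in% sel(sc, gene_spec)) {
          rg <- intersect(partners, sel(rc, partner_spec))
          if (length(rg)) {
            rows[[length(rows) + 1L]] <- data.frame(
              sender_cluster = sc, receiver_cluster = rc,
              sender_gene = gene, receiver_gene = rg,
              stringsAsFactors = FALSE)
          }
        }
      }
      if (role %in% c("any", "receiver")) {
        if (gene %in% sel(rc, gene_spec)) {
          sg <- intersect(partners, sel(sc, partner_spec))
          if (length(sg)) {
            rows[[length(rows) + 1L]] <- data.frame(
              sender_cluster = sc, receiver_cluster = rc,
              sender_gene = sg, receiver_gene = gene,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows)) return(empty_candidate_pairs())
  tab <- unique(do.call(rbind, rows))
  tab <- score_enumerated(x, tab, n_perm, seed, tail, conservative_p)
  finalize_candidates(tab, degs, idb_f, alpha)
}
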