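#' Plot-ready table for the cluster-pair network dot plot
#'
#' One row per ordered cluster pair with at least one retained gene pair;
#' `dot_size` is the pair count and `dot_color` the aggregated power, the
#' two quantities the network dot display encodes. Row order is
#' deterministic (sorted by cluster names).
#'
#' @param summaries output of [network_summary()].
#' @return data.frame (`sender_cluster`, `receiver_cluster`, `dot_size`,
#'   `dot_color`).
#' @export
network_dot_table <- function(summaries) {
  s <- summaries[summaries$pair_count > 0L, , drop = FALSE]
  out <- data.frame(sender_cluster = s$sender_cluster,
                    receiver_cluster = s$receiver_cluster,
                    dot_size = s$pair_count,
                    dot_color = s$aggregated_power,
                    stringsAsFactors = FALSE)
  out <- out[order(out$sender_cluster, out$receiver_cluster), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Composition of action modes among candidate pairs
#'
#' Tallies the matched action records of a candidate-pair table by mode
#' (the data behind the action-mode pie display). Fractions sum to 1
#' whenever any action is present.
#'
#' @param pairs a `candidate_pairs` table (its `modes` column holds
#'   semicolon-joined matched modes per pair).
#' @return data.frame (`mode`, `count`, `fraction`), sorted by count
#'   descending then mode.
#' @export
action_mode_composition <- function(pairs) {
  modes <- unlist(strsplit(pairs$modes[nzchar(pairs$modes)], ";",
                           fixed = TRUE), use.names = FALSE)
  if (!length(modes)) {
    return(data.frame(mode = character(), count = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  tt <- table(modes)
  out <- data.frame(mode = names(tt), count = as.integer(tt),
                    stringsAsFactors = FALSE)
  out$fraction <- out$count / sum(out$count)
  out <- out[order(-out$count, out$mode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot-ready table for the candidate-pair dot plot
#'
#' One row per candidate pair; `dot_size` is a p-value-derived confidence
#' (`1 - p`) and `dot_color` the active power. Two power readouts exist:
#' the expression product (`expr_product`) and the sum of the two
#' partners' log2 fold changes (`log2fc_sum`); `power_mode` selects which
#' one drives the color scale and the row order, but both columns are
#' always present.
#'
#' @param pairs a `candidate_pairs` table.
#' @param power_mode `"expr_product"` or `"log2fc_sum"`.
#' @return data.frame sorted by the active power (descending), then
#'   p-value, then gene symbols.
#' @export
pair_dot_table <- function(pairs, power_mode = c("expr_product",
                                                 "log2fc_sum")) {
  power_mode <- match.arg(power_mode)
  active <- if (power_mode == "expr_product") pairs$power else pairs$power_fc
  out <- data.frame(
    pair = paste(pairs$sender_gene, pairs$receiver_gene, sep = "->"),
    cluster_pair = paste(pairs$sender_cluster, pairs$receiver_cluster,
                         sep = "->"),
    dot_size = 1 - pairs$p_value,
    dot_color = active,
    expr_product = pairs$power,
    log2fc_sum = pairs$power_fc,
    p_value = pairs$p_value,
    stringsAsFactors = FALSE)
  ord <- order(-out$dot_color, out$p_value, out$pair, out$cluster_pair)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# fixed collapse of the 13 localization categories onto the 4 diagram zones
zone_of_category <- function(category) {
  zones <- rep("cytoplasm", length(category))
  zones[category == "extracellular region"] <- "extracellular space"
  zones[category == "plasma membrane"] <- "cytomembrane"
  zones[category == "nucleus"] <- "cell nucleus"
  zones
}

#' Declarative layout for the two-cell spatial interaction diagram
#'
#' Produces the layout record behind the spatial-pattern display: two cell
#' areas (sender, receiver), each divided into the four canonical zones —
#' extracellular space, cytomembrane, cytoplasm, cell nucleus. Each
#' participating gene becomes a node placed in the zone of its
#' best-supported localization (highest confidence; the 13 annotation
#' categories collapse onto the 4 zones by a fixed mapping: extracellular
#' region to extracellular space, plasma membrane to cytomembrane, nucleus
#' to cell nucleus, everything else to cytoplasm). Node size is the
#' magnitude of the gene's log2 fold change, node color encodes up- (red)
#' versus down-regulation (green); one edge per pair carries its action
#' modes (line color) and effects (arrow). Genes lacking any localization
#' annotation fall back to the cytoplasm zone with a warning. Rendering
#' is cosmetic and out of scope; correctness lives in this record.
#'
#' @param pairs a `candidate_pairs` table for one ordered cluster pair.
#' @param gdb a `gene_db` supplying localizations.
#' @param degs optional DEG table for node sizes; when absent, sizes fall
#'   back to `power_fc`-independent 1.
#' @return list of class `spatial_layout` with elements `zones` (the four
#'   zone names), `nodes` (data.frame: `gene`, `cell` = sender/receiver,
#'   `zone`, `size`, `color`) and `edges` (data.frame: `sender_gene`,
#'   `receiver_gene`, `modes`, `effects`).
#' @export
spatial_pattern_layout <- function(pairs, gdb, degs = NULL) {
  stopifnot(inherits(gdb, "gene_db"))
  zones <- c("extracellular space", "cytomembrane", "cytoplasm",
             "cell nucleus")
  place <- function(gene) {
    loc <- gdb$localizations[gdb$localizations$symbol == gene, , drop = FALSE]
    if (nrow(loc) == 0L) {
      warning("gene '", gene, "' has no localization annotation; ",
              "placed in cytoplasm", call. = FALSE)
      return("cytoplasm")
    }
    best <- loc[which.max(loc$confidence), ]
    zone_of_category(best$category)
  }
  node_row <- function(gene, cell, cluster) {
    l2fc <- if (is.null(degs)) NA_real_ else deg_log2fc(degs, gene, cluster)
    data.frame(gene = gene, cell = cell, zone = place(gene),
               size = if (is.na(l2fc)) 1 else abs(l2fc),
               color = if (!is.na(l2fc) && l2fc < 0) "green" else "red",
               stringsAsFactors = FALSE)
  }
  s_genes <- unique(pairs$sender_gene)
  r_genes <- unique(pairs$receiver_gene)
  nodes <- rbind(
    do.call(rbind, lapply(s_genes, node_row, cell = "sender",
                          cluster = pairs$sender_cluster[1L])),
    do.call(rbind, lapply(r_genes, node_row, cell = "receiver",
                          cluster = pairs$receiver_cluster[1L])))
  if (is.null(nodes)) {
    nodes <- data.frame(gene = character(), cell = character(),
                        zone = character(), size = numeric(),
                        color = character(), stringsAsFactors = FALSE)
  }
  edges <- data.frame(sender_gene = pairs$sender_gene,
                      receiver_gene = pairs$receiver_gene,
                      modes = pairs$modes, effects = pairs$effects,
                      stringsAsFactors = FALSE)
  structure(list(zones = zones, nodes = nodes, edges = edges),
            class = "spatial_layout")
}

#' Serialize a spatial layout to JSON
#'
#' @param layout a `spatial_layout`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spatial_layout <- function(layout, path) {
  stopifnot(inherits(layout, "spatial_layout"))
  jsonlite::write_json(unclass(layout), path, auto_unbox = TRUE,
                       dataframe = "rows", digits = NA)
  invisible(path)
}
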