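#' Default planted sender-to-receiver signals
#'
#' Two ligand-receptor pairs planted across three clusters: a ligand
#' up-shifted in its sender cluster and its receptor up-shifted in the
#' receiver cluster, with the interaction present in the generated
#' database as a highest-confidence binding record.
#'
#' @param effect_size additive expression shift of each planted gene in
#'   its designated cluster (on the normalized-expression scale whose
#'   baseline mean is about 1).
#' @return data.frame with columns `sender_cluster`, `receiver_cluster`,
#'   `ligand`, `receptor`, `effect_size`.
#' @export
default_planted <- function(effect_size = 2.0) {
  data.frame(
    sender_cluster = c("C1", "C2"),
    receiver_cluster = c("C2", "C3"),
    ligand = c("LGA", "LGB"),
    receptor = c("RCA", "RCB"),
    effect_size = effect_size,
    stringsAsFactors = FALSE)
}

#' Generate an internally consistent synthetic test fixture
#'
#' Builds a complete toy dataset for the whole inference workflow: a gene
#' annotation database, an interaction database, a labeled expression
#' matrix with planted sender-to-receiver signal, a DEG table computed
#' from that matrix, and a machine-readable ground-truth table listing
#' exactly the planted pairs.
#'
#' The construction guarantees that the canonical analysis recovers the
#' planted signal end-to-end: planted ligands are annotated (extracellular
#' region, confidence 5; class Cytokine), planted receptors (plasma
#' membrane, confidence 5; class Receptor), and each planted pair exists
#' in the interaction database as an experiment-validated binding record
#' with credibility >= 900. Decoys exercise every filter: annotated
#' ligand/receptor decoys with no database record, database records
#' between unannotated background genes (including one high-credibility
#' binding pair), and low-credibility non-binding records.
#'
#' Expression is baseline noise `exp(N(0, noise_sd))` — non-negative and
#' right-skewed, mimicking log-normalized single-cell cluster structure —
#' plus `effect_size` added to each planted gene in its designated
#' cluster. The DEG table is computed from the generated matrix
#' (cluster-vs-rest log2 mean ratio; Wilcoxon rank-sum p, BH-adjusted
#' within cluster), so fixture DEGs have the same provenance as those an
#' upstream single-cell pipeline would feed the real analysis.
#'
#' @param n_clusters number of clusters (named `C1`, `C2`, ...).
#' @param cells_per_cluster cells per cluster.
#' @param n_genes total genes including planted and decoy genes.
#' @param planted data.frame as in [default_planted()]; effect sizes must
#'   be positive.
#' @param noise_sd standard deviation of the log-scale baseline noise.
#' @param seed RNG seed; identical seeds give identical fixtures.
#' @param dir optional directory; when given, all five tables are also
#'   written there as TSV files (see [write_fixture()]).
#' @return object of class `xtalk_fixture`: list with `gene_db`,
#'   `interaction_db`, `expression`, `degs`, `truth` (and `paths` when
#'   `dir` was given).
#' @export
make_fixture <- function(n_clusters = 3, cells_per_cluster = 20,
                         n_genes = 30, planted = default_planted(),
                         noise_sd = 0.5, seed = 1L, dir = NULL) {
  stopifnot(n_clusters >= 2, cells_per_cluster >= 2, n_genes >= 12)
  if (any(planted$effect_size <= 0)) {
    validation_error("planted effect sizes must be > 0")
  }
  clusters <- paste0("C", seq_len(n_clusters))
  bad_cl <- setdiff(c(planted$sender_cluster, planted$receiver_cluster),
                    clusters)
  if (length(bad_cl)) {
    validation_error("planted cluster(s) not in fixture: ",
                     paste(bad_cl, collapse = ", "))
  }
  planted_genes <- unique(c(planted$ligand, planted$receptor))
  decoy_lig <- paste0("DCL", 1:3)
  decoy_rec <- paste0("DCR", 1:3)
  named <- c(planted_genes, decoy_lig, decoy_rec)
  if (anyDuplicated(named)) {
    validation_error("planted gene names collide with decoy names")
  }
  n_generic <- n_genes - length(named)
  if (n_generic < 4L) {
    validation_error("n_genes too small for ", length(named),
                     " named genes plus background decoys")
  }
  generic <- sprintf("G%03d", seq_len(n_generic))
  if (length(intersect(generic, named))) {
    validation_error("planted gene names collide with decoy names")
  }
  genes <- c(planted_genes, decoy_lig, decoy_rec, generic)

  # --- gene annotation table -------------------------------------------
  ann_row <- function(sym, cat, conf, cls, go) {
    data.frame(symbol = sym, species = "human", loc_category = cat,
               loc_confidence = conf, function_class = cls, go_terms = go,
               stringsAsFactors = FALSE)
  }
  ligs <- unique(c(planted$ligand, decoy_lig))
  recs <- unique(c(planted$receptor, decoy_rec))
  gene_tab <- rbind(
    do.call(rbind, lapply(ligs, ann_row, cat = "extracellular region",
                          conf = 5L, cls = "Cytokine", go = "GO:0006955")),
    do.call(rbind, lapply(recs, ann_row, cat = "plasma membrane",
                          conf = 5L, cls = "Receptor", go = "GO:0006955")),
    do.call(rbind, lapply(generic, ann_row, cat = "cytosol", conf = 5L,
                          cls = "Oxidoreductase", go = "GO:0008152")))

  # --- interaction table -----------------------------------------------
  int_row <- function(a, b, experiments, database, textmining, cred, acts) {
    data.frame(gene_a = a, gene_b = b, experiments = experiments,
               database = database, textmining = textmining,
               credibility = cred, actions = acts, stringsAsFactors = FALSE)
  }
  int_tab <- do.call(rbind, lapply(seq_len(nrow(planted)), function(k) {
    int_row(planted$ligand[k], planted$receptor[k], 800L, 0L, 0L, 950L,
            "binding|undirected|f|unknown;activation|positive|t|a")
  }))
  # background decoy interactions: a high-credibility binding pair between
  # unannotated genes, plus low-credibility / non-binding records
  int_tab <- rbind(
    int_tab,
    int_row(generic[1L], generic[2L], 600L, 0L, 0L, 920L,
            "binding|undirected|f|unknown"),
    int_row(generic[2L], generic[3L], 0L, 300L, 0L, 450L,
            "reaction|unspecified|f|unknown"),
    int_row(generic[3L], generic[4L], 0L, 0L, 350L, 350L,
            "expression|positive|t|a"),
    int_row(generic[1L], generic[4L], 0L, 0L, 200L, 200L,
            "inhibition|negative|t|b"))

  cells <- sprintf("CELL%04d", seq_len(n_clusters * cells_per_cluster))
  labels <- rep(clusters, each = cells_per_cluster)

  fixture <- with_seed(seed, {
    m <- matrix(exp(stats::rnorm(length(genes) * length(cells), 0,
                                 noise_sd)),
                nrow = length(genes), dimnames = list(genes, cells))
    for (k in seq_len(nrow(planted))) {
      m[planted$ligand[k], labels == planted$sender_cluster[k]] <-
        m[planted$ligand[k], labels == planted$sender_cluster[k]] +
        planted$effect_size[k]
      m[planted$receptor[k], labels == planted$receiver_cluster[k]] <-
        m[planted$receptor[k], labels == planted$receiver_cluster[k]] +
        planted$effect_size[k]
    }
    x <- labeled_expression(m, labels)
    degs <- compute_fixture_degs(x)
    list(expression = x, degs = degs)
  })

  truth <- data.frame(sender_cluster = planted$sender_cluster,
                      receiver_cluster = planted$receiver_cluster,
                      sender_gene = planted$ligand,
                      receiver_gene = planted$receptor,
                      effect_size = planted$effect_size,
                      stringsAsFactors = FALSE)

  # route the generated tables through the real loaders so every fixture
  # is loader-valid by construction
  tmp <- tempfile("xtalk_fixture_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  write_tsv(gene_tab, file.path(tmp, "gene_db.tsv"))
  write_tsv(int_tab, file.path(tmp, "interactions.tsv"))
  gdb <- load_gene_db(file.path(tmp, "gene_db.tsv"), "human")
  idb <- load_interaction_db(file.path(tmp, "interactions.tsv"), "human")

  out <- structure(list(gene_db = gdb, interaction_db = idb,
                        expression = fixture$expression,
                        degs = fixture$degs, truth = truth,
                        gene_table = gene_tab, interaction_table = int_tab),
                   class = "xtalk_fixture")
  if (!is.null(dir)) out$paths <- write_fixture(out, dir)
  out
}

# cluster-vs-rest DEG statistics from a labeled expression matrix
compute_fixture_degs <- function(x) {
  clusters <- sort(unique(x$labels))
  rows <- lapply(clusters, function(cl) {
    inside <- x$labels == cl
    mi <- rowMeans(x$matrix[, inside, drop = FALSE])
    mo <- rowMeans(x$matrix[, !inside, drop = FALSE])
    l2fc <- log2((mi + 1e-9) / (mo + 1e-9))
    p <- vapply(seq_len(nrow(x$matrix)), function(g) {
      stats::wilcox.test(x$matrix[g, inside], x$matrix[g, !inside],
                         exact = FALSE)$p.value
    }, numeric(1L))
    data.frame(gene = x$genes, cluster = cl, log2fc = l2fc,
               adj_p = stats::p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.xtalk_fixture <- function(x, ...) {
  cat("<xtalk_fixture> ", length(x$expression$genes), " genes x ",
      length(x$expression$cells), " cells; ", nrow(x$truth),
      " planted pair(s)\n", sep = "")
  invisible(x)
}

#' Write a fixture to disk as plain-text tables
#'
#' Emits the five tables of a fixture (gene annotations, interactions,
#' dense expression TSV, labels, DEGs) plus the ground truth, in the
#' formats the corresponding loaders accept. Identical fixtures write
#' byte-identical files.
#'
#' @param fixture an `xtalk_fixture`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "xtalk_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    gene_db = file.path(dir, "gene_db.tsv"),
    interactions = file.path(dir, "interactions.tsv"),
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    degs = file.path(dir, "degs.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_tsv(fixture$gene_table, paths[["gene_db"]])
  write_tsv(fixture$interaction_table, paths[["interactions"]])
  x <- fixture$expression
  expr_tab <- data.frame(gene = x$genes, as.data.frame(x$matrix),
                         check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(expr_tab, paths[["expression"]])
  write_tsv(data.frame(barcode = x$cells, cluster = x$labels,
                       stringsAsFactors = FALSE), paths[["labels"]])
  write_tsv(fixture$degs, paths[["degs"]])
  write_tsv(fixture$truth, paths[["truth"]])
  invisible(paths)
}

#' The canonical sender / receiver selection specs of the fixture design
#'
#' The planted signal is built to pass exactly these specs: up-regulated,
#' confidently secreted cytokines on the sender side and up-regulated,
#' confidently membrane-bound receptors on the receiver side, joined by
#' highest-confidence binding interactions.
#'
#' @return list with elements `sender`, `receiver`
#'   ([selection_spec()] objects) and `interaction`
#'   ([interaction_filter()]).
#' @export
canonical_specs <- function() {
  list(
    sender = selection_spec(categories = "extracellular region",
                            min_confidence = 4L, groups = "cytokine",
                            direction = "up"),
    receiver = selection_spec(categories = "plasma membrane",
                              min_confidence = 4L, groups = "receptor",
                              direction = "up"),
    interaction = interaction_filter(modes = "binding",
                                     min_level = "highest"))
}
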