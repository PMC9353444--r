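# Shared in-code fixtures and independent oracles for the test suite.

# write a gene annotation table and return its path
write_gene_table <- function(rows, path = tempfile(fileext = ".tsv")) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

gene_row <- function(symbol, category, confidence, class = "Cytokine",
                     go = "GO:0006955", species = "human") {
  data.frame(symbol = symbol, species = species, loc_category = category,
             loc_confidence = confidence, function_class = class,
             go_terms = go, stringsAsFactors = FALSE)
}

# a 10-gene annotation fixture: 3 secreted cytokines at high confidence,
# plus decoys failing either the localization, confidence, or group rule
ten_gene_db <- function() {
  rows <- rbind(
    gene_row("CYT1", "extracellular region", 5, "Cytokine"),
    gene_row("CYT2", "extracellular region", 4, "Chemokine"),
    gene_row("CYT3", "extracellular region", 5, "Interleukin"),
    gene_row("LOWC", "extracellular region", 3, "Cytokine"),
    gene_row("MEMB", "plasma membrane", 5, "Receptor"),
    gene_row("RCP2", "plasma membrane", 4, "Cytokine receptor"),
    gene_row("ENZ1", "cytosol", 5, "Oxidoreductase", go = "GO:0008152"),
    gene_row("ENZ2", "mitochondrion", 5, "Dehydrogenase", go = "GO:0008152"),
    gene_row("NUC1", "nucleus", 5, "Transcription regulator",
             go = "GO:0006355"),
    gene_row("SECE", "extracellular region", 5, "Protease",
             go = "GO:0008152"))
  load_gene_db(write_gene_table(rows), "human")
}

interaction_row <- function(a, b, experiments = 0, database = 0,
                            textmining = 0, credibility = 500,
                            actions = "binding|undirected|f|unknown") {
  data.frame(gene_a = a, gene_b = b, experiments = experiments,
             database = database, textmining = textmining,
             credibility = credibility, actions = actions,
             stringsAsFactors = FALSE)
}

write_interaction_table <- function(rows, path = tempfile(fileext = ".tsv")) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# 5-record interaction fixture: 2 binding records, 3 without binding
five_interaction_db <- function() {
  rows <- rbind(
    interaction_row("CYT1", "MEMB", experiments = 150, credibility = 920,
                    actions = "binding|undirected|f|unknown"),
    interaction_row("CYT2", "RCP2", experiments = 0, database = 400,
                    credibility = 700,
                    actions = "binding|undirected|f|unknown;activation|positive|t|a"),
    interaction_row("ENZ1", "ENZ2", textmining = 300, credibility = 400,
                    actions = "reaction|unspecified|f|unknown"),
    interaction_row("CYT3", "NUC1", experiments = 50, credibility = 300,
                    actions = "expression|positive|t|a"),
    interaction_row("ENZ1", "NUC1", textmining = 150, credibility = 150,
                    actions = "inhibition|negative|t|b"))
  load_interaction_db(write_interaction_table(rows), "human")
}

# a tiny two-cluster labeled expression object built in code
tiny_expression <- function(values = NULL) {
  m <- values %||% rbind(
    LIG = c(1, 1, 1, 0, 0, 0),
    REC = c(0, 0, 0, 1, 1, 1),
    HKG = c(2, 2, 2, 2, 2, 2),
    LOW = c(0.1, 0.2, 0.1, 0.2, 0.1, 0.2))
  colnames(m) <- paste0("cell", seq_len(ncol(m)))
  labeled_expression(m, rep(c("S", "R"), each = ncol(m) / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracle: exact permutation p-value for a two-cluster labeled
# expression by exhaustive enumeration of all distinct label splits.
# Counts, among all C(n, n_s) assignments of the sender label, the
# fraction whose power reaches the observed one.
exact_pair_pvalue <- function(x, sender, receiver, gene_a, gene_b) {
  va <- as.numeric(x$matrix[gene_a, ])
  vb <- as.numeric(x$matrix[gene_b, ])
  n <- length(x$labels)
  n_s <- sum(x$labels == sender)
  stopifnot(length(unique(x$labels)) == 2L)
  obs <- mean(va[x$labels == sender]) * mean(vb[x$labels == receiver])
  splits <- utils::combn(n, n_s)
  powers <- apply(splits, 2L, function(s_idx) {
    mean(va[s_idx]) * mean(vb[-s_idx])
  })
  mean(powers >= obs)
}
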