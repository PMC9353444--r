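test_that("loading a valid annotation table yields indexed gene records", {
  rows <- rbind(gene_row("A1", "extracellular region", 5),
                gene_row("B1", "plasma membrane", 4, "Receptor"),
                gene_row("C1", "cytosol", 2, "Kinase", go = "GO:0016301"))
  db <- load_gene_db(write_gene_table(rows), "human")
  expect_s3_class(db, "gene_db")
  expect_setequal(db$symbols, c("A1", "B1", "C1"))
  expect_equal(nrow(db$localizations), 3L)
  expect_equal(db$functions$group[db$functions$symbol == "C1"], "transferase")
  expect_equal(db$go$go_term[db$go$symbol == "C1"], "GO:0016301")
})

test_that("rows outside the closed vocabularies are rejected", {
  bad_cat <- gene_row("A1", "membrane_raft", 5)
  expect_error(load_gene_db(write_gene_table(bad_cat), "human"),
               class = "cellxtalk_validation_error")
  bad_conf <- gene_row("A1", "cytosol", 7)
  expect_error(load_gene_db(write_gene_table(bad_conf), "human"),
               "confidence")
  bad_class <- gene_row("A1", "cytosol", 3, "Phosphorylation")
  expect_error(load_gene_db(write_gene_table(bad_class), "human"),
               "unknown functional class")
  no_col <- data.frame(symbol = "A1", species = "human")
  expect_error(load_gene_db(write_gene_table(no_col), "human"),
               class = "cellxtalk_schema_error")
})

test_that("duplicate (symbol, category) localizations collapse to the max", {
  rows <- rbind(gene_row("A1", "extracellular region", 5),
                gene_row("A1", "extracellular region", 5),
                gene_row("A1", "extracellular region", 3))
  db <- load_gene_db(write_gene_table(rows), "human")
  loc <- db$localizations[db$localizations$symbol == "A1", ]
  expect_equal(nrow(loc), 1L)
  expect_equal(loc$confidence, 5L)
})

test_that("symbols are case-normalized per species", {
  rows <- gene_row("il6", "extracellular region", 5)
  expect_equal(load_gene_db(write_gene_table(rows), "human")$symbols, "IL6")
  rows$species <- "mouse"
  expect_equal(load_gene_db(write_gene_table(rows), "mouse")$symbols, "Il6")
})

test_that("selection applies localization confidence cutoffs", {
  db <- ten_gene_db()
  spec <- gene_filter(categories = "plasma membrane", min_confidence = 4)
  expect_true("MEMB" %in% select_genes(db, spec))
  # confidence 3 fails the recommended cutoff of 4
  spec_ex <- gene_filter(categories = "extracellular region",
                         min_confidence = 4)
  sel <- select_genes(db, spec_ex)
  expect_false("LOWC" %in% sel)
  expect_true(all(c("CYT1", "CYT2", "CYT3", "SECE") %in% sel))
})

test_that("conjunctive multi-axis selection finds the planted cytokines", {
  db <- ten_gene_db()
  sel <- select_genes(db, gene_filter(categories = "extracellular region",
                                      min_confidence = 4,
                                      groups = "cytokine"))
  expect_equal(sel, c("CYT1", "CYT2", "CYT3"))
  # GO constraint intersects further
  sel_go <- select_genes(db, gene_filter(categories = "extracellular region",
                                         min_confidence = 4,
                                         go_terms = "GO:0008152"))
  expect_equal(sel_go, "SECE")
})

test_that("unknown filter names error rather than silently selecting nothing", {
  db <- ten_gene_db()
  expect_error(gene_filter(categories = "membrane_raft"),
               class = "cellxtalk_validation_error")
  expect_error(gene_filter(groups = "kinases"),
               class = "cellxtalk_validation_error")
  expect_error(select_genes(db, gene_filter(classes = "Not a class")),
               class = "cellxtalk_validation_error")
})

test_that("selection is monotone in confidence and categories, and the empty
          filter selects everything", {
  db <- ten_gene_db()
  expect_setequal(select_genes(db), db$symbols)
  for (conf in 5:1) {
    tighter <- select_genes(db, gene_filter(categories = "extracellular region",
                                            min_confidence = conf))
    if (conf < 5) expect_true(all(prev %in% tighter))
    prev <- tighter
  }
  one_cat <- select_genes(db, gene_filter(categories = "cytosol",
                                          min_confidence = 1))
  two_cat <- select_genes(db, gene_filter(categories = c("cytosol", "nucleus"),
                                          min_confidence = 1))
  expect_true(all(one_cat %in% two_cat))
})

test_that("load -> write -> load round-trips to an identical database", {
  db <- ten_gene_db()
  path <- tempfile(fileext = ".tsv")
  write_gene_db(db, path)
  db2 <- load_gene_db(path, "human")
  expect_equal(db2, db)
})

test_that("the bundled taxonomy is a total 132-class map onto 16 groups", {
  tax <- function_taxonomy()
  expect_equal(nrow(tax), 132L)
  expect_equal(anyDuplicated(tax$class), 0L)
  expect_setequal(unique(tax$group), function_groups())
  expect_length(function_groups(), 16L)
})
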