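test_that("loading derives evidence flags and confidence levels", {
  rows <- interaction_row("A1", "B1", experiments = 150, credibility = 920)
  db <- load_interaction_db(write_interaction_table(rows), "human")
  rec <- db$interactions
  expect_true(rec$experiment_validated)
  expect_false(rec$pathway_curated)
  expect_false(rec$predicted)
  expect_equal(rec$confidence_level, "highest")
  # boundary score 400 is medium
  rows2 <- interaction_row("A1", "B1", credibility = 400)
  expect_equal(load_interaction_db(write_interaction_table(rows2),
                                   "human")$interactions$confidence_level,
               "medium")
})

test_that("invalid credibility, modes and effects are rejected", {
  expect_error(load_interaction_db(write_interaction_table(
    interaction_row("A1", "B1", credibility = 1200)), "human"),
    "credibility")
  expect_error(load_interaction_db(write_interaction_table(
    interaction_row("A1", "B1",
                    actions = "phosphorylation|positive|t|a")), "human"),
    "unknown action mode")
  expect_error(load_interaction_db(write_interaction_table(
    interaction_row("A1", "B1", actions = "binding|sideways|f|unknown")),
    "human"), "unknown action effect")
  # an undirected effect cannot claim directionality
  expect_error(load_interaction_db(write_interaction_table(
    interaction_row("A1", "B1", actions = "binding|undirected|t|a")),
    "human"), "undirected")
})

test_that("credibility binning partitions the full score range", {
  scores <- c(1, 399, 400, 699, 700, 899, 900, 1000)
  levels <- credibility_level(scores)
  expect_equal(levels, c("low", "low", "medium", "medium", "high", "high",
                         "highest", "highest"))
  # every score maps to exactly one level
  all_scores <- seq_len(1000)
  expect_true(all(credibility_level(all_scores) %in% confidence_levels()))
  expect_error(credibility_level(0), "1, 1000")
})

test_that("mode filtering keeps matching records stripped to matching actions", {
  db <- five_interaction_db()
  sub <- subset_interactions(db, interaction_filter(modes = "binding"))
  expect_equal(nrow(sub$interactions), 2L)
  expect_setequal(sub$interactions$pair_id, c("CYT1|MEMB", "CYT2|RCP2"))
  expect_true(all(sub$actions$mode == "binding"))
  # the activation action of CYT2|RCP2 is stripped
  expect_equal(nrow(sub$actions[sub$actions$pair_id == "CYT2|RCP2", ]), 1L)
})

test_that("the empty filter is the identity and filters compose monotonically", {
  db <- five_interaction_db()
  expect_equal(subset_interactions(db, interaction_filter()), db)
  f <- interaction_filter(evidence = "experiment_validated",
                          min_level = "highest")
  sub <- subset_interactions(db, f)
  expect_equal(sub$interactions$pair_id, "CYT1|MEMB")
  # idempotent
  expect_equal(subset_interactions(sub, f), sub)
  # tighter credibility yields subsets
  loose <- subset_interactions(db, interaction_filter(min_credibility = 300))
  tight <- subset_interactions(db, interaction_filter(min_credibility = 700))
  expect_true(all(tight$interactions$pair_id %in% loose$interactions$pair_id))
  # a record with experiments = 0 never passes the experiment-validated class
  f2 <- interaction_filter(evidence = "experiment_validated",
                           min_credibility = 900)
  expect_false("ENZ1|ENZ2" %in%
                 subset_interactions(db, f2)$interactions$pair_id)
})

test_that("contradictory filters error", {
  expect_error(interaction_filter(modes = character(0)),
               class = "cellxtalk_validation_error")
  expect_error(interaction_filter(min_level = "certain"),
               class = "cellxtalk_validation_error")
})

test_that("single-class evidence filters union to all evidenced records", {
  db <- five_interaction_db()
  got <- unique(unlist(lapply(evidence_classes(), function(cls) {
    subset_interactions(db,
                        interaction_filter(evidence = cls))$interactions$pair_id
  })))
  flags <- db$interactions[, evidence_classes()]
  expect_setequal(got, db$interactions$pair_id[rowSums(flags) > 0])
})

test_that("pair lookup is unordered, handles self-pairs and absent pairs", {
  rows <- rbind(interaction_row("B1", "A1", credibility = 500),
                interaction_row("S1", "S1", credibility = 600))
  db <- load_interaction_db(write_interaction_table(rows), "human")
  hit <- match_pair(db, "A1", "B1")
  expect_equal(nrow(hit$interactions), 1L)
  expect_equal(hit$sender_gene, "A1")
  self <- match_pair(db, "S1", "S1")
  expect_equal(nrow(self$interactions), 1L)
  expect_equal(nrow(match_pair(db, "A1", "ZZ9")$interactions), 0L)
})

test_that("interaction databases round-trip through their table format", {
  db <- five_interaction_db()
  path <- tempfile(fileext = ".tsv")
  write_interaction_db(db, path)
  db2 <- load_interaction_db(path, "human")
  expect_equal(db2$interactions, db$interactions)
  expect_equal(db2$actions, db$actions)
})

test_that("the action-mode vocabulary has eight entries", {
  expect_length(action_modes(), 8L)
  expect_length(action_effects(), 4L)
})
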