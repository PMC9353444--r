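test_that("interaction power is the product of cluster-mean expressions", {
  expect_equal(compute_power(2.0, 3.0), 6.0)
  expect_equal(compute_power(0.0, 7.5), 0.0)
  expect_error(compute_power(-1, 2), class = "cellxtalk_validation_error")
  # recompute the fixture's planted pair power from first principles
  fx <- make_fixture(seed = 7)
  prof <- cluster_profiles(fx$expression)
  hand <- mean(fx$expression$matrix["LGA", fx$expression$labels == "C1"]) *
    mean(fx$expression$matrix["RCA", fx$expression$labels == "C2"])
  expect_equal(compute_power(prof$mean_expr["LGA", "C1"],
                             prof$mean_expr["RCA", "C2"]), hand)
})

test_that("constant genes give p = 1 under any shuffle", {
  x <- tiny_expression()
  p <- permutation_pvalue(x, "S", "R", "HKG", "HKG", n_perm = 50, seed = 11)
  expect_equal(p, 1.0)
})

test_that("Monte-Carlo p-value matches exhaustive enumeration on 6 cells", {
  x <- tiny_expression()  # LIG only in S cells, REC only in R cells
  exact <- exact_pair_pvalue(x, "S", "R", "LIG", "REC")
  expect_equal(exact, 1 / 20)  # only the identity split reaches the observed
  n_perm <- 10000
  mc <- permutation_pvalue(x, "S", "R", "LIG", "REC", n_perm = n_perm,
                           seed = 5)
  se <- sqrt(exact * (1 - exact) / n_perm)
  expect_lt(abs(mc - exact), 3 * se)
  # a noisier configuration with a non-extreme exact p
  x2 <- tiny_expression(rbind(GA = c(2.0, 1.1, 0.4, 0.8, 0.3, 0.2),
                              GB = c(0.5, 0.1, 0.9, 1.4, 1.9, 0.7)))
  exact2 <- exact_pair_pvalue(x2, "S", "R", "GA", "GB")
  mc2 <- permutation_pvalue(x2, "S", "R", "GA", "GB", n_perm = n_perm,
                            seed = 5)
  expect_lt(abs(mc2 - exact2),
            3 * sqrt(exact2 * (1 - exact2) / n_perm) + 1e-12)
})

test_that("permutation test defaults and input validation", {
  expect_equal(formals(permutation_pvalue)$n_perm, 100)
  x <- tiny_expression()
  expect_error(permutation_pvalue(x, "S", "R", "NOPE", "REC"),
               "not in matrix")
  expect_error(permutation_pvalue(x, "S", "Z", "LIG", "REC"), "no cells")
  # conservative estimator never returns 0
  p <- permutation_pvalue(x, "S", "R", "LIG", "REC", n_perm = 100, seed = 1,
                          conservative_p = TRUE)
  expect_gt(p, 0)
})

test_that("inference recovers exactly the planted pairs on the fixture", {
  fx <- make_fixture(seed = 7)
  cs <- canonical_specs()
  got <- list()
  for (k in seq_len(nrow(fx$truth))) {
    got[[k]] <- infer_pairs(fx$expression, fx$degs, fx$gene_db,
                            fx$interaction_db,
                            fx$truth$sender_cluster[k],
                            fx$truth$receiver_cluster[k],
                            cs$sender, cs$receiver, cs$interaction,
                            n_perm = 100, seed = 7)
  }
  got <- do.call(rbind, got)
  expect_equal(nrow(got), nrow(fx$truth))
  expect_equal(got[, c("sender_cluster", "receiver_cluster", "sender_gene",
                       "receiver_gene")],
               fx$truth[, c("sender_cluster", "receiver_cluster",
                            "sender_gene", "receiver_gene")],
               ignore_attr = TRUE)
  expect_true(all(got$p_value < 0.05))
  expect_true(all(got$confidence_level == "highest"))
  expect_true(all(got$modes == "binding"))
})

test_that("with alpha = 1 and no filter the result equals a brute-force join", {
  fx <- make_fixture(seed = 3)
  loose <- selection_spec(min_confidence = 1, direction = "both",
                          min_abs_log2fc = 0, max_adj_p = 1)
  got <- infer_pairs(fx$expression, fx$degs, fx$gene_db, fx$interaction_db,
                     "C1", "C2", loose, loose, interaction_filter(),
                     n_perm = 10, seed = 1, alpha = 1.01)
  # oracle: cross join of all genes, kept if the unordered pair is in the DB
  genes <- fx$gene_db$symbols
  grid <- expand.grid(s = genes, r = genes, stringsAsFactors = FALSE)
  key <- paste(pmin(grid$s, grid$r), pmax(grid$s, grid$r), sep = "|")
  expected_n <- sum(key %in% fx$interaction_db$interactions$pair_id)
  expect_equal(nrow(got), expected_n)
})

test_that("a mode filter excluding all matched actions empties the result", {
  fx <- make_fixture(seed = 7)
  cs <- canonical_specs()
  got <- infer_pairs(fx$expression, fx$degs, fx$gene_db, fx$interaction_db,
                     "C1", "C2", cs$sender, cs$receiver,
                     interaction_filter(modes = "catalysis"),
                     n_perm = 50, seed = 1)
  expect_equal(nrow(got), 0L)
  # empty gene selection is a message + empty table, not an error
  none <- selection_spec(min_abs_log2fc = 50)
  expect_message(
    empty <- infer_pairs(fx$expression, fx$degs, fx$gene_db,
                         fx$interaction_db, "C1", "C2", none, none),
    "empty sender")
  expect_equal(nrow(empty), 0L)
})

test_that("identical seeds reproduce tables bit-identically; seeds move only p", {
  fx <- make_fixture(seed = 9)
  loose <- selection_spec(min_confidence = 1, direction = "both",
                          min_abs_log2fc = 0, max_adj_p = 1)
  run <- function(seed) {
    infer_pairs(fx$expression, fx$degs, fx$gene_db, fx$interaction_db,
                "C1", "C2", loose, loose, n_perm = 50, seed = seed,
                alpha = 1.01)
  }
  a <- run(4); b <- run(4); c <- run(5)
  expect_identical(a, b)
  expect_identical(a[, setdiff(names(a), "p_value")],
                   c[, setdiff(names(c), "p_value")])
})

test_that("scaling the matrix scales powers by c^2 and preserves p-values", {
  fx <- make_fixture(seed = 13)
  loose <- selection_spec(min_confidence = 1, direction = "both",
                          min_abs_log2fc = 0, max_adj_p = 1)
  run <- function(x) {
    infer_pairs(x, fx$degs, fx$gene_db, fx$interaction_db, "C1", "C2",
                loose, loose, n_perm = 50, seed = 2, alpha = 1.01)
  }
  base <- run(fx$expression)
  for (c_scale in c(2, 0.5)) {
    scaled <- labeled_expression(fx$expression$matrix * c_scale,
                                 fx$expression$labels)
    got <- run(scaled)
    expect_equal(got$power, base$power * c_scale^2)
    expect_equal(got$p_value, base$p_value)
  }
})

test_that("inference is invariant to gene-row ordering of the matrix", {
  fx <- make_fixture(seed = 21)
  perm <- rev(seq_along(fx$expression$genes))
  shuffled <- labeled_expression(fx$expression$matrix[perm, , drop = FALSE],
                                 fx$expression$labels)
  cs <- canonical_specs()
  run <- function(x) {
    infer_pairs(x, fx$degs, fx$gene_db, fx$interaction_db, "C1", "C2",
                cs$sender, cs$receiver, cs$interaction, n_perm = 100,
                seed = 3)
  }
  expect_identical(run(fx$expression), run(shuffled))
})

test_that("network summaries count and sum retained pairs", {
  empty <- network_summary(empty_pairs <- data.frame(
    sender_cluster = character(), receiver_cluster = character(),
    power = numeric()))
  expect_equal(nrow(empty), 0L)
  forced <- network_summary(empty_pairs,
                            all_pairs = data.frame(sender_cluster = "A",
                                                   receiver_cluster = "B"))
  expect_equal(forced$pair_count, 0L)
  expect_equal(forced$aggregated_power, 0)
  pairs <- data.frame(
    sender_cluster = c("A", "A", "A", "B"),
    receiver_cluster = c("B", "B", "B", "A"),
    power = c(1.5, 2.0, 0.5, 6.0))
  summ <- network_summary(pairs)
  ab <- summ[summ$sender_cluster == "A", ]
  expect_equal(ab$pair_count, 3L)
  expect_equal(ab$aggregated_power, 4.0)
  # conservation: total W equals total power
  expect_equal(sum(summ$aggregated_power), sum(pairs$power))
})

test_that("scanning one pair across clusters respects selection and symmetry", {
  fx <- make_fixture(seed = 7)
  cs <- canonical_specs()
  tab <- scan_pair_across_clusters(fx$expression, fx$degs, fx$gene_db,
                                   "LGA", "RCA",
                                   sender_spec = cs$sender,
                                   receiver_spec = cs$receiver,
                                   n_perm = 50, seed = 1)
  # LGA is up only in C1, RCA up only in C2 -> exactly the (C1, C2) row
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$sender_cluster, "C1")
  expect_equal(tab$receiver_cluster, "C2")
  # a symmetric self-gene scan has mirror-image powers
  loose <- selection_spec(min_confidence = 1, direction = "both",
                          min_abs_log2fc = 0, max_adj_p = 1)
  tab2 <- scan_pair_across_clusters(fx$expression, fx$degs, fx$gene_db,
                                    "G001", "G001", sender_spec = loose,
                                    receiver_spec = loose, n_perm = 5,
                                    seed = 1)
  expect_equal(nrow(tab2), 9L)  # 3 clusters -> <= 9 ordered rows
  key <- paste(tab2$sender_cluster, tab2$receiver_cluster)
  rkey <- paste(tab2$receiver_cluster, tab2$sender_cluster)
  expect_equal(tab2$power[match(rkey, key)], tab2$power)
})

test_that("the off-target scan enumerates partners in the requested role", {
  fx <- make_fixture(seed = 7)
  cs <- canonical_specs()
  any_role <- scan_gene_partners(fx$expression, fx$degs, fx$gene_db,
                                 fx$interaction_db, "LGA", role = "any",
                                 gene_spec = cs$sender,
                                 partner_spec = cs$receiver,
                                 ifilter = cs$interaction,
                                 n_perm = 100, seed = 2)
  # both orientations pass: the cytokine spec admits LGA in C1 on either
  # side, so role = "any" reports the pair once per orientation
  expect_equal(nrow(any_role), 2L)
  expect_setequal(any_role$receiver_gene, c("RCA", "LGA"))
  expect_true(all(any_role$sender_gene %in% c("LGA", "RCA")))
  sender_role <- scan_gene_partners(fx$expression, fx$degs, fx$gene_db,
                                    fx$interaction_db, "LGA", role = "sender",
                                    gene_spec = cs$sender,
                                    partner_spec = cs$receiver,
                                    ifilter = cs$interaction,
                                    n_perm = 100, seed = 2)
  # sender-role results are a subset of role = any
  expect_true(all(do.call(paste, sender_role[, 1:4]) %in%
                    do.call(paste, any_role[, 1:4])))
  # a gene without database partners yields an empty result
  no_partner <- scan_gene_partners(fx$expression, fx$degs, fx$gene_db,
                                   fx$interaction_db, "DCL1",
                                   n_perm = 10, seed = 1)
  expect_equal(nrow(no_partner), 0L)
})
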