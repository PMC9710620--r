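# hand-built target space: x's two nearest are n1, n2; n3 is farther
toy_dsd <- function() {
  nodes <- c("n1", "n2", "n3", "x")
  d <- matrix(5, 4, 4, dimnames = list(nodes, nodes))
  diag(d) <- 0
  d["x", "n1"] <- d["n1", "x"] <- 1
  d["x", "n2"] <- d["n2", "x"] <- 2
  d["x", "n3"] <- d["n3", "x"] <- 3
  class(d) <- c("dsd_matrix", class(d))
  d
}

toy_ce <- function(target_nodes = c("n1", "n2", "n3", "x"),
                   model_nodes = c("m1", "m2"),
                   sims = NULL) {
  d12 <- matrix(0, length(model_nodes), length(target_nodes),
                dimnames = list(model_nodes, target_nodes))
  if (!is.null(sims)) d12[, "x"] <- sims
  structure(list(d12 = d12, p_mat = NULL, landmarks = NULL,
                 model_nodes = model_nodes, target_nodes = target_nodes),
            class = "coembedding")
}

test_that("the weighted two-source vote matches hand accumulation", {
  dsd <- toy_dsd()
  ce <- toy_ce(sims = c(3, 1)) # m1 is x's nearest cross neighbour
  lab_t <- ann_tbl(c("n1", "n2", "n2"), c("g1", "g1", "g2"))
  lab_m <- ann_tbl("m1", "g2")
  p <- predict_dual("x", dsd, ce, lab_t, lab_m,
                    vote_config(d = 2, c = 1, alpha = 1.5))
  # weights: g1 = 1.5 + 1.5 = 3.0, g2 = 1.5 + 1.0 = 2.5
  expect_equal(p$go_id, c("g1", "g2"))
  expect_equal(p$confidence, c(3 / 5.5, 2.5 / 5.5))
})

test_that("label ties break lexicographically by term id", {
  dsd <- toy_dsd()
  lab_t <- ann_tbl(c("n1", "n2"), c("gB", "gA"))
  p <- predict_dual("x", dsd, NULL, lab_t, NULL,
                    vote_config(d = 2, c = 0))
  expect_equal(p$go_id, c("gA", "gB")) # equal weight, gA first
})

test_that("degenerate source counts reduce to the single-source methods", {
  spec <- synth_spec(n_model = 60, n_target = 60, n_orthologs = 30,
                     n_landmarks = 12, seed = 77)
  sim <- simulate_species_pair(spec)
  lm <- select_rbh_landmarks(sim$hits$fwd, sim$hits$rev)
  ds_t <- converged_state(sim$target)
  ds_m <- converged_state(sim$model)
  dsd_t <- dsd_matrix(ds_t)
  ce <- coembed_target(model_embedding(ds_m), ds_t, lm)
  ann_t <- sim$go$BP$ann_target
  ann_m <- sim$go$BP$ann_model
  nodes <- sim$target$nodes

  dual_c0 <- predict_labels(nodes, "dual", dsd_t, ce, ann_t, ann_m,
                            cfg = vote_config(d = 10, c = 0))
  dsd_only <- predict_labels(nodes, "dsd", dsd_t, NULL, ann_t, NULL,
                             cfg = vote_config(d = 10, c = 0))
  expect_equal(as.data.frame(dual_c0), as.data.frame(dsd_only))

  dual_d0 <- predict_labels(nodes, "dual", dsd_t, ce, ann_t, ann_m,
                            cfg = vote_config(d = 0, c = 8))
  munk_only <- predict_labels(nodes, "munk", dsd_t, ce, ann_t, ann_m,
                              cfg = vote_config(d = 5, c = 8))
  expect_equal(as.data.frame(dual_d0), as.data.frame(munk_only))
})

test_that("alpha does not matter when only one source votes", {
  dsd <- toy_dsd()
  lab_t <- ann_tbl(c("n1", "n2", "n2"), c("g1", "g1", "g2"))
  p1 <- predict_dual("x", dsd, NULL, lab_t, NULL,
                     vote_config(d = 2, c = 0, alpha = 0.5))
  p2 <- predict_dual("x", dsd, NULL, lab_t, NULL,
                     vote_config(d = 2, c = 0, alpha = 3))
  expect_equal(p1, p2)
})

test_that("an extra vote for the leading label never demotes it", {
  dsd <- toy_dsd()
  lab1 <- ann_tbl(c("n1", "n2", "n2"), c("g1", "g1", "g2"))
  base <- predict_dual("x", dsd, NULL, lab1, NULL,
                       vote_config(d = 3, c = 0))
  top <- base$go_id[1]
  lab2 <- ann_tbl(c("n1", "n2", "n2", "n3"), c("g1", "g1", "g2", top))
  more <- predict_dual("x", dsd, NULL, lab2, NULL,
                       vote_config(d = 3, c = 0))
  expect_equal(more$go_id[1], top)
})

test_that("a node with no labeled voter abstains", {
  dsd <- toy_dsd()
  lab_t <- ann_tbl("n3", "g1") # outside the d = 1 strict window
  p <- predict_dual("x", dsd, NULL, lab_t, NULL, vote_config(d = 1, c = 0))
  expect_equal(nrow(p), 0L)
  expect_equal(attr(p, "abstain"), "x")
})

# model side for the homology baselines: a 5-node path m1 - ... - m5
model_side <- function() {
  net <- ppi_network(data.frame(from = sprintf("m%d", 1:4),
                                to = sprintf("m%d", 2:5)))
  converged_dsd(net, lazy = TRUE)
}

test_that("top_hit with an unlabeled hit equals the target-only vote", {
  dsd <- toy_dsd()
  hits <- hit_table(tibble::tibble(query = "x", subject = "m9",
                                   pident = 95, qcovs = 95, bitscore = 100))
  lab_t <- ann_tbl(c("n1", "n2"), c("g1", "g2"))
  lab_m <- ann_tbl("m1", "g3") # the hit m9 itself is unlabeled
  p <- predict_homology("top_hit", "x", dsd, NULL, hits, lab_t, lab_m,
                        vote_config(d = 2, c = 0))
  q <- predict_dual("x", dsd, NULL, lab_t, NULL, vote_config(d = 2, c = 0))
  expect_equal(p, q)
})

test_that("all_hits lets every available hit vote when below the cap", {
  dsd <- toy_dsd()
  subjects <- sprintf("h%d", 1:7)
  hits <- hit_table(tibble::tibble(query = "x", subject = subjects,
                                   pident = 50, qcovs = 50,
                                   bitscore = 100 + 1:7))
  lab_m <- ann_tbl(subjects, paste0("t", 1:7))
  p <- predict_homology("all_hits", "x", dsd, NULL, hits,
                        ann_tbl("n1", "g1"), lab_m,
                        vote_config(d = 0, c = 1, top_r = 10))
  # all 7 hits vote with weight 1 each
  expect_setequal(p$go_id, paste0("t", 1:7))
  expect_equal(unique(p$confidence), 1 / 7)
})

test_that("thresholded hits filter on identity and coverage jointly", {
  dsd <- toy_dsd()
  hits <- hit_table(tibble::tibble(
    query = "x", subject = c("hA", "hB", "hC"),
    pident = c(80, 86, 90), qcovs = c(95, 95, 85),
    bitscore = c(100, 90, 80)))
  lab_m <- ann_tbl(c("hA", "hB", "hC"), c("gA", "gB", "gC"))
  p <- predict_homology("thresh_hits", "x", dsd, NULL, hits,
                        ann_tbl("n1", "g1"), lab_m,
                        vote_config(d = 0, c = 1, top_r = 5),
                        thresholds = c(p = 85, q = 90))
  expect_equal(p$go_id, "gB") # only the (86, 95) hit passes both
})

test_that("neighbourhood variants add the hit's model-DSD neighbours", {
  dsd <- toy_dsd()
  dsd_m <- model_side()
  hits <- hit_table(tibble::tibble(query = "x", subject = "m1",
                                   pident = 95, qcovs = 95, bitscore = 100))
  lab_m <- ann_tbl(c("m1", "m2", "m3"), c("gHit", "gN1", "gN2"))
  p <- predict_homology("top_hit_nbhd", "x", dsd, dsd_m, hits,
                        ann_tbl("n1", "g1"), lab_m,
                        vote_config(d = 0, c = 2, top_r = 5))
  # voters: m1 (the hit) plus its 2 nearest model neighbours m2, m3
  expect_setequal(p$go_id, c("gHit", "gN1", "gN2"))
  expect_equal(unique(p$confidence), 1 / 3)
})

test_that("queries with no hits fall back to the target-only vote", {
  dsd <- toy_dsd()
  hits <- hit_table(tibble::tibble(query = "other", subject = "m1",
                                   pident = 95, qcovs = 95, bitscore = 50))
  lab_t <- ann_tbl(c("n1", "n2"), c("g1", "g2"))
  expect_message(
    p <- predict_homology("top_hit", "x", dsd, NULL, hits, lab_t,
                          ann_tbl("m1", "g3"), vote_config(d = 2, c = 0)),
    "no usable hits")
  q <- predict_dual("x", dsd, NULL, lab_t, NULL, vote_config(d = 2, c = 0))
  expect_equal(p, q)
})

test_that("batch prediction is deterministic and equals per-node calls", {
  dsd <- toy_dsd()
  lab_t <- ann_tbl(c("n1", "n2", "n2"), c("g1", "g1", "g2"))
  expect_equal(nrow(predict_labels(character(), "dsd", dsd,
                                   labels_target = lab_t)), 0L)
  nodes <- c("x", "n3", "n1")
  cfg <- vote_config(d = 2, c = 0)
  b1 <- predict_labels(nodes, "dsd", dsd, labels_target = lab_t, cfg = cfg)
  b2 <- predict_labels(nodes, "dsd", dsd, labels_target = lab_t, cfg = cfg)
  expect_identical(b1, b2)
  single <- dplyr::bind_rows(lapply(nodes, function(v) {
    predict_dual(v, dsd, NULL, lab_t, NULL, cfg)
  }))
  expect_equal(as.data.frame(b1), as.data.frame(single),
               ignore_attr = TRUE)
})
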