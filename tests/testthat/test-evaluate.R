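pred_tbl <- function(protein, go_id, confidence) {
  tibble::tibble(protein = protein,
                 rank = stats::ave(confidence, protein,
                                   FUN = function(x) rank(-x)),
                 go_id = go_id, confidence = confidence)
}

test_that("term specificity filtering keeps the intermediate band", {
  ann <- annotation_map(tibble::tibble(
    protein = c(sprintf("p%03d", 1:60), sprintf("q%03d", 1:10),
                sprintf("r%03d", 1:600)),
    go_id = c(rep("g1", 60), rep("g2", 10), rep("g3", 600))))
  out <- filter_terms(ann, 50, 500)
  expect_equal(unique(out$go_id), "g1")
  expect_equal(nrow(out), 60L)
  # unbounded filter is the identity
  expect_equal(nrow(filter_terms(ann, 0, Inf)), nrow(ann))
  expect_error(filter_terms(ann, 1000, 2000), "no terms")
})

test_that("filtering matches a brute-force counting oracle", {
  sim <- simulate_species_pair(synth_spec(n_model = 80, n_target = 80,
                                          n_orthologs = 40, seed = 12))
  ann <- sim$go$BP$ann_target
  got <- filter_terms(ann, 5, 30)
  counts <- table(ann$go_id)
  keep <- names(counts)[counts >= 5 & counts <= 30]
  expect_setequal(unique(got$go_id), keep)
})

test_that("percent accuracy counts rank-1 membership, abstentions wrong", {
  truth <- list(p1 = "g1", p2 = c("g2", "g3"), p3 = "g1", p4 = "g9")
  preds <- pred_tbl(c("p1", "p2", "p3"), c("g1", "g3", "g2"), c(1, 1, 1))
  # p1, p2 correct; p3 wrong; p4 abstained
  expect_equal(percent_accuracy(preds, truth), 50)
  all_right <- pred_tbl(names(truth), c("g1", "g2", "g1", "g9"),
                        rep(1, 4))
  expect_equal(percent_accuracy(all_right, truth), 100)
  expect_equal(percent_accuracy(all_right[1:3, ], truth), 75)
  expect_error(percent_accuracy(preds, list()), "no evaluated")
})

test_that("accuracy matches a hand loop on synthetic predictions", {
  set.seed(31)
  prots <- sprintf("p%02d", 1:50)
  truth <- lapply(stats::setNames(prots, prots),
                  function(p) sample(paste0("g", 1:8), 2))
  preds <- pred_tbl(prots, sample(paste0("g", 1:8), 50, replace = TRUE),
                    rep(1, 50))
  top1 <- stats::setNames(preds$go_id, preds$protein)
  oracle <- mean(vapply(prots, function(p) top1[[p]] %in% truth[[p]], NA))
  expect_equal(percent_accuracy(preds, truth), 100 * oracle)
})

test_that("F1-max reproduces the direct substitution on the one-protein toy", {
  truth <- list(p1 = c("g1", "g2"))
  preds <- pred_tbl("p1", "g1", 0.9)
  out <- f1_max(preds, truth, tau_grid = 0.5)
  expect_equal(out$f1_max, 2 / 3) # prec 1, recall 1/2
  # perfect predictions at confidence 1 give F1* = 1
  truth2 <- list(p1 = c("g1", "g2"), p2 = "g3")
  preds2 <- pred_tbl(c("p1", "p1", "p2"), c("g1", "g2", "g3"), rep(1, 3))
  expect_equal(f1_max(preds2, truth2)$f1_max, 1)
})

test_that("F1-max equals an exhaustive double-loop oracle", {
  set.seed(8)
  prots <- sprintf("p%02d", 1:30)
  terms <- paste0("g", 1:10)
  truth <- lapply(stats::setNames(prots, prots),
                  function(p) sample(terms, sample(1:3, 1)))
  rows <- lapply(prots, function(p) {
    k <- sample(0:3, 1)
    if (k == 0) return(NULL)
    tibble::tibble(protein = p, go_id = sample(terms, k),
                   confidence = round(stats::runif(k, 0.05, 1), 2))
  })
  preds <- dplyr::bind_rows(rows)
  preds$rank <- 1L
  grid <- seq(0, 1, length.out = 21)
  got <- f1_max(preds, truth, tau_grid = grid)
  oracle_best <- 0
  for (tau in grid) {
    precs <- c()
    recs <- c()
    for (p in prots) {
      sel <- preds$go_id[preds$protein == p & preds$confidence >= tau]
      if (length(sel) > 0) {
        precs <- c(precs, length(intersect(sel, truth[[p]])) / length(sel))
      }
      recs <- c(recs, length(intersect(sel, truth[[p]])) / length(truth[[p]]))
    }
    pr <- if (length(precs)) mean(precs) else 0
    rc <- mean(recs)
    f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    oracle_best <- max(oracle_best, f1)
  }
  expect_equal(got$f1_max, oracle_best)
  # precision averaging set alpha_tau can only shrink as tau rises
  sizes <- vapply(grid, function(tau) {
    length(unique(preds$protein[preds$confidence >= tau]))
  }, 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("information content follows the chain rule on the toy chain", {
  ic <- information_content(chain_dag(), base = 2)
  expect_equal(unname(ic$i[c("root", "a", "b")]), c(0, 1, 2))
  flat <- go_dag(c("r", "x"), list(r = character(), x = "r"),
                 conditional_prob = c(r = 1, x = 1))
  expect_equal(unname(information_content(flat)$i), c(0, 0))
})

test_that("information content equals the ancestor path-product oracle", {
  set.seed(21)
  dag <- toy_dag5()
  ic <- information_content(dag)
  for (tm in dag$terms) {
    pr <- prod(dag$conditional_prob[dag$ancestors[[tm]]])
    expect_equal(unname(ic$i[tm]), -log(pr))
  }
})

test_that("Resnik set similarity has its closed-form special cases", {
  dag <- toy_dag5()
  ic <- information_content(dag)
  X <- c("c", "d")
  expect_equal(resnik_set_similarity(X, X, ic), mean(ic$i[X]))
  # sets sharing only the root have zero similarity
  expect_equal(resnik_set_similarity("a", "b", ic), 0)
})

test_that("Resnik scores equal a brute-force lca enumeration", {
  dag <- toy_dag5()
  ic <- information_content(dag)
  sets <- list(c("c", "a"), c("d"), c("b", "c"), c("a", "d"))
  for (X in sets) {
    for (Y in sets) {
      expect_equal(resnik_set_similarity(X, Y, ic),
                   oracle_res_ss(X, Y, dag, ic))
      expect_equal(resnik_set_similarity(X, Y, ic),
                   resnik_set_similarity(Y, X, ic)) # symmetry
    }
  }
})

test_that("disjoint DAG components score zero through the virtual root", {
  dag <- go_dag(c("r1", "r2", "a", "b"),
                list(r1 = character(), r2 = character(), a = "r1", b = "r2"),
                conditional_prob = c(r1 = 1, r2 = 1, a = 0.5, b = 0.5))
  ic <- information_content(dag)
  expect_equal(resnik_set_similarity("a", "b", ic), 0)
})

test_that("the threshold-maximized Resnik score matches its curve", {
  dag <- toy_dag5()
  ic <- information_content(dag)
  truth <- list(p1 = c("c"), p2 = c("d", "a"))
  preds <- dplyr::bind_rows(
    pred_tbl("p1", c("c", "b"), c(0.8, 0.3)),
    pred_tbl("p2", "d", 0.6))
  out <- resnik_scores(preds, truth, ic)
  expect_equal(out$res, max(out$curve$res))
  # at tau = 0.8 only p1's {c} survives: mean of res(c, {c}) and res({d,a}, {})
  s1 <- resnik_set_similarity("c", "c", ic)
  expect_equal(out$curve$res[out$curve$tau == 0.8], mean(c(s1, 0)))
})

test_that("conditional probability estimation recovers planted frequencies", {
  dag <- chain_dag()
  # 8 proteins: all have root, 4 have a, 2 of those have b (after closure)
  ann <- annotation_map(tibble::tibble(
    protein = c(sprintf("p%d", 1:4), sprintf("p%d", 1:2),
                sprintf("p%d", 5:8)),
    go_id = c(rep("a", 4), rep("b", 2), rep("root", 4))))
  est <- estimate_conditional_prob(dag, ann)
  expect_equal(unname(est$conditional_prob["a"]), 4 / 8)
  expect_equal(unname(est$conditional_prob["b"]), 2 / 4)
  expect_equal(unname(est$conditional_prob["root"]), 1)
})
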