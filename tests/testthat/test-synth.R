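test_that("every generator is fully deterministic under its seed", {
  spec <- synth_spec(n_model = 50, n_target = 50, n_orthologs = 25,
                     n_landmarks = 10, seed = 42)
  s1 <- simulate_species_pair(spec)
  s2 <- simulate_species_pair(spec)
  expect_identical(s1$model$edges, s2$model$edges)
  expect_identical(s1$target$edges, s2$target$edges)
  expect_identical(as.data.frame(s1$hits$fwd), as.data.frame(s2$hits$fwd))
  expect_identical(as.data.frame(s1$go$BP$ann_target),
                   as.data.frame(s2$go$BP$ann_target))
  expect_identical(s1$go$MF$dag$conditional_prob,
                   s2$go$MF$dag$conditional_prob)
})

test_that("zero rewiring with full ortholog coverage gives isomorphic nets", {
  spec <- synth_spec(n_model = 40, n_target = 40, n_orthologs = 40,
                     rewire_prob = 0, seed = 5)
  pair <- generate_pair(spec)
  map <- stats::setNames(pair$orthologs$target, pair$orthologs$model)
  mapped <- tibble::tibble(from = unname(map[pair$model$edges$from]),
                           to = unname(map[pair$model$edges$to]))
  mapped <- tibble::tibble(from = pmin(mapped$from, mapped$to),
                           to = pmax(mapped$from, mapped$to))
  mapped <- dplyr::arrange(mapped, .data$from, .data$to)
  expect_equal(as.data.frame(mapped), as.data.frame(pair$target$edges))
})

test_that("rewired ortholog subgraphs keep the expected edge overlap", {
  # each copied edge survives rewiring with prob 1 - q, replacements are
  # essentially disjoint from the original set, so the expected Jaccard
  # overlap is about (1 - q) / (1 + q)
  q <- 0.1
  jac <- vapply(1:8, function(s) {
    spec <- synth_spec(n_model = 120, n_target = 120, n_orthologs = 120,
                       rewire_prob = q, seed = 200 + s)
    pair <- generate_pair(spec)
    map <- stats::setNames(pair$orthologs$target, pair$orthologs$model)
    sub_m <- subset_network(pair$model, pair$orthologs$model)
    a <- paste(pmin(unname(map[sub_m$edges$from]),
                    unname(map[sub_m$edges$to])),
               pmax(unname(map[sub_m$edges$from]),
                    unname(map[sub_m$edges$to])))
    sub_t <- subset_network(pair$target, pair$orthologs$target)
    b <- paste(sub_t$edges$from, sub_t$edges$to)
    length(intersect(a, b)) / length(union(a, b))
  }, 0)
  expected <- (1 - q) / (1 + q)
  expect_lt(abs(mean(jac) - expected), 0.1)
})

test_that("hit generation respects the landmark split and decoy guarantees", {
  spec0 <- synth_spec(n_model = 50, n_target = 50, n_orthologs = 30,
                      decoy_hit_rate = 0, seed = 3)
  pair <- generate_pair(spec0)
  hits <- generate_hits(pair$orthologs, spec0)
  lm <- select_rbh_landmarks(hits$fwd, hits$rev)
  expect_setequal(paste(lm$model, lm$target),
                  paste(pair$orthologs$model, pair$orthologs$target))

  # all mutual hits below the stringent preset -> the zero-landmark error
  spec_weak <- synth_spec(n_model = 50, n_target = 50, n_orthologs = 30,
                          n_landmarks = 0, seed = 3)
  weak <- generate_hits(pair$orthologs, spec_weak)
  expect_error(select_rbh_landmarks(weak$fwd, weak$rev, 90, 85), "relaxing")
  # but the relaxed distant-species preset keeps them
  relaxed <- select_rbh_landmarks(weak$fwd, weak$rev, 75, 50)
  expect_equal(nrow(relaxed), nrow(pair$orthologs))
})

test_that("decoys never displace planted pairs across seeds", {
  for (s in 1:5) {
    spec <- synth_spec(n_model = 60, n_target = 60, n_orthologs = 30,
                       decoy_hit_rate = 0.5, seed = 300 + s)
    pair <- generate_pair(spec)
    hits <- generate_hits(pair$orthologs, spec,
                          model_nodes = pair$model$nodes,
                          target_nodes = pair$target$nodes)
    lm <- select_rbh_landmarks(hits$fwd, hits$rev, 90, 85)
    planted <- paste(pair$orthologs$model, pair$orthologs$target)
    got <- paste(lm$model, lm$target)
    expect_equal(mean(got %in% planted), 1)   # precision
    expect_equal(mean(planted %in% got), 1)   # recall
  }
})

test_that("a depth-1 DAG is flat with equal information accretion", {
  spec <- synth_spec(n_model = 40, n_target = 40, n_orthologs = 20,
                     dag_depth = 1, n_terms = 6, seed = 4)
  pair <- generate_pair(spec)
  go <- generate_go(spec, pair, "BP")
  depths <- vapply(go$dag$terms, function(t) length(go$dag$ancestors[[t]]),
                   1L)
  expect_lte(max(depths), 2L) # root plus one level
  ia <- information_content(go$dag)$ia
  non_root <- ia[ia > 0]
  expect_lt(max(non_root) - min(non_root), 1e-12)
})

test_that("label density scales the annotated-protein count", {
  base <- synth_spec(n_model = 80, n_target = 80, n_orthologs = 40,
                     label_density = 1, seed = 6)
  dense <- generate_go(base, generate_pair(base), "BP")
  sparse_spec <- synth_spec(n_model = 80, n_target = 80, n_orthologs = 40,
                            label_density = 0.1, seed = 6)
  sparse <- generate_go(sparse_spec, generate_pair(sparse_spec), "BP")
  n_dense <- length(unique(dense$ann_target$protein))
  n_sparse <- length(unique(sparse$ann_target$protein))
  expect_equal(n_sparse, round(0.1 * n_dense))
})

test_that("labels co-vary with network proximity more than chance", {
  wins <- vapply(1:5, function(s) {
    spec <- synth_spec(n_model = 80, n_target = 80, n_orthologs = 40,
                       seed = 400 + s)
    pair <- generate_pair(spec)
    go <- generate_go(spec, pair, "BP")
    sets <- annotation_sets(go$ann_target)
    share <- function(sets) {
      ed <- pair$target$edges
      both <- ed$from %in% names(sets) & ed$to %in% names(sets)
      mean(vapply(which(both), function(i) {
        length(intersect(sets[[ed$from[i]]], sets[[ed$to[i]]])) > 0
      }, NA))
    }
    obs <- share(sets)
    set.seed(s)
    shuf <- stats::setNames(sets[sample(length(sets))], names(sets))
    obs > share(shuf)
  }, NA)
  expect_true(all(wins))
})

test_that("the planted signal is learnable well above a shuffled baseline", {
  ratio <- vapply(1:5, function(s) {
    spec <- synth_spec(n_model = 100, n_target = 100, n_orthologs = 50,
                       label_density = 1, seed = 500 + s)
    sim <- simulate_species_pair(spec)
    dsd_t <- dsd_matrix(converged_state(sim$target))
    ann <- sim$go$BP$ann_target
    cfg <- vote_config(d = 5, c = 0)
    run_cv <- function(a) {
      pred <- function(test, train) {
        predict_labels(test, "dsd", dsd_t, labels_target = train, cfg = cfg)
      }
      glance(inverted_kfold(a, pred, k = 2, n_runs = 1,
                            seed = 1))$accuracy_mean
    }
    set.seed(s)
    shuffled <- ann
    shuffled$protein <- sample(unique(ann$protein))[
      match(ann$protein, unique(ann$protein))]
    shuffled <- annotation_map(shuffled)
    run_cv(ann) / max(run_cv(shuffled), 1e-9)
  }, 0)
  expect_gte(mean(ratio), 3)
})

test_that("synthetic inputs write out in the package's own formats", {
  sim <- simulate_species_pair(synth_spec(n_model = 40, n_target = 40,
                                          n_orthologs = 20, seed = 8))
  dir <- withr::local_tempdir()
  write_synth_inputs(sim, dir)
  net <- read_network(file.path(dir, "target_network.tsv"))
  expect_identical(net$edges, sim$target$edges)
  hits <- read_hits(file.path(dir, "hits_fwd.tsv"))
  expect_equal(nrow(hits), nrow(sim$hits$fwd))
  dag <- read_go_dag(file.path(dir, "go_BP.tsv"))
  expect_setequal(dag$terms, sim$go$BP$dag$terms)
  ann <- read_annotations(file.path(dir, "ann_target_BP.tsv"), dag, "BP")
  expect_equal(nrow(ann), nrow(sim$go$BP$ann_target))
})
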