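#' Specification for a synthetic paired-species benchmark
#'
#' Describes two correlated "species": a model network, a target network
#' sharing `n_orthologs` planted ortholog pairs (copied subgraph with
#' edge rewiring), a cross-species sequence hit table in which planted
#' orthologs are mutual best hits and decoys never are, and a layered GO
#' DAG whose labels follow network communities (so that graph proximity
#' predicts shared function) and are conserved across ortholog pairs (so
#' that cross-species transfer carries signal).
#'
#' @param n_model,n_target node counts of the two networks.
#' @param n_orthologs number of planted ortholog pairs
#'   (`<= min(n_model, n_target)`).
#' @param n_landmarks how many ortholog pairs receive hits above the
#'   stringent (q, p) = (90, 85) landmark preset; the remaining pairs get
#'   weaker mutual hits that only pass the relaxed (75, 50) preset. This
#'   emulates real proteome pairs, where only a minority of orthologs are
#'   stringent reciprocal best hits. Default: all of them.
#' @param rewire_prob probability that each copied ortholog-subgraph edge
#'   is rewired in the target network.
#' @param n_terms number of (non-root) GO terms per namespace.
#' @param dag_depth number of DAG levels below the root.
#' @param label_density fraction of target proteins whose annotations are
#'   retained.
#' @param decoy_hit_rate expected number of spurious hit rows per protein
#'   and direction.
#' @param label_signal probability that a community member carries each of
#'   its community's terms.
#' @param conservation probability that an ortholog partner inherits each
#'   of its partner's labels.
#' @param seed integer seed; every generator below is fully deterministic
#'   given the spec.
#' @return a list of class `synth_spec`.
#' @export
synth_spec <- function(n_model = 200, n_target = 200, n_orthologs = 100,
                       n_landmarks = NULL, rewire_prob = 0.3, n_terms = 20,
                       dag_depth = 3, label_density = 0.9,
                       decoy_hit_rate = 0.3, label_signal = 0.8,
                       conservation = 0.7, seed = 1) {
  if (n_orthologs > min(n_model, n_target)) {
    stop("n_orthologs must not exceed min(n_model, n_target)", call. = FALSE)
  }
  if (is.null(n_landmarks)) n_landmarks <- n_orthologs
  stopifnot(rewire_prob >= 0, rewire_prob <= 1,
            label_density >= 0, label_density <= 1,
            label_signal >= 0, label_signal <= 1,
            conservation >= 0, conservation <= 1,
            n_landmarks <= n_orthologs)
  structure(list(n_model = n_model, n_target = n_target,
                 n_orthologs = n_orthologs, n_landmarks = n_landmarks,
                 rewire_prob = rewire_prob, n_terms = n_terms,
                 dag_depth = dag_depth, label_density = label_density,
                 decoy_hit_rate = decoy_hit_rate,
                 label_signal = label_signal, conservation = conservation,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# duplication-divergence growth: each new node copies a random anchor's
# edges (retention 0.5), links to the anchor with prob 0.1, and always
# keeps at least one edge, so the graph stays connected
dd_edges <- function(n, names, retain = 0.5, anchor_link = 0.1) {
  stopifnot(n >= 2)
  from <- c(names[1])
  to <- c(names[2])
  if (n < 3) return(tibble::tibble(from = from, to = to))
  for (i in 3:n) {
    anchor <- sample(i - 1L, 1L)
    nb <- unique(c(from[to == names[anchor]], to[from == names[anchor]]))
    nb <- setdiff(nb, names[i])
    keep <- nb[stats::runif(length(nb)) < retain]
    if (stats::runif(1) < anchor_link) keep <- c(keep, names[anchor])
    if (length(keep) == 0L) keep <- names[anchor]
    from <- c(from, rep(names[i], length(keep)))
    to <- c(to, keep)
  }
  tibble::tibble(from = from, to = to)
}

#' Generate a correlated network pair with planted orthologs
#'
#' The model network grows by duplication-divergence (hub-dominated,
#' biologically shaped degree distribution). The target network copies a
#' connected `n_orthologs`-node subgraph of the model (each copied edge
#' rewired with `rewire_prob`) and grows fresh nodes around it by the
#' same process. Both networks are reduced to their largest connected
#' component; the ortholog map is restricted to surviving pairs.
#'
#' @param spec a [synth_spec()].
#' @return list with `model`, `target` ([ppi_network()]s) and `orthologs`
#'   (tibble with columns `model`, `target`).
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  m_names <- sprintf("M%04d", seq_len(spec$n_model))
  model <- ppi_network(dd_edges(spec$n_model, m_names))
  model <- largest_connected_component(model)

  # connected ortholog subgraph by breadth-first collection
  start <- sample(model$nodes, 1L)
  orth_m <- bfs_collect(model, start, spec$n_orthologs)
  t_names <- sprintf("T%04d", seq_along(orth_m))
  map <- stats::setNames(t_names, orth_m)

  sub <- subset_network(model, orth_m)
  ed <- tibble::tibble(from = unname(map[sub$edges$from]),
                       to = unname(map[sub$edges$to]))
  # rewire copied edges
  if (spec$rewire_prob > 0 && nrow(ed) > 0L) {
    rewire <- stats::runif(nrow(ed)) < spec$rewire_prob
    keep_ed <- ed[!rewire, , drop = FALSE]
    existing <- paste(pmin(keep_ed$from, keep_ed$to),
                      pmax(keep_ed$from, keep_ed$to))
    for (i in which(rewire)) {
      for (try in 1:50) {
        pair <- sample(t_names, 2L)
        key <- paste(min(pair), max(pair))
        if (!key %in% existing) {
          keep_ed <- dplyr::bind_rows(keep_ed,
                                      tibble::tibble(from = pair[1],
                                                     to = pair[2]))
          existing <- c(existing, key)
          break
        }
      }
    }
    ed <- keep_ed
  }
  # grow fresh target nodes
  n_fresh <- spec$n_target - length(orth_m)
  if (n_fresh > 0L) {
    fresh <- sprintf("T%04d", length(orth_m) + seq_len(n_fresh))
    from <- ed$from
    to <- ed$to
    current <- t_names
    for (f in fresh) {
      anchor <- sample(current, 1L)
      nb <- unique(c(from[to == anchor], to[from == anchor]))
      keep <- nb[stats::runif(length(nb)) < 0.5]
      if (length(keep) == 0L) keep <- anchor
      from <- c(from, rep(f, length(keep)))
      to <- c(to, keep)
      current <- c(current, f)
    }
    ed <- tibble::tibble(from = from, to = to)
  }
  target <- largest_connected_component(ppi_network(ed, nodes = t_names))
  if (n_nodes(target) < 10L || n_nodes(model) < 10L) {
    stop("synthetic spec yields a connected remnant below 10 nodes",
         call. = FALSE)
  }
  orth <- tibble::tibble(model = orth_m, target = unname(map[orth_m]))
  orth <- orth[orth$model %in% model$nodes & orth$target %in% target$nodes, ]
  list(model = model, target = target,
       orthologs = dplyr::arrange(orth, .data$model))
}

bfs_collect <- function(net, start, k) {
  g <- as_igraph(net)
  ord <- igraph::bfs(g, root = start, order = TRUE)$order
  nms <- igraph::V(g)$name[as.integer(ord)]
  nms[seq_len(min(k, length(nms)))]
}

#' Generate forward and reverse hit tables for a planted ortholog map
#'
#' Each ortholog pair receives mutual hit rows; `n_landmarks` of them draw
#' identity/coverage above the stringent (90, 85) preset and the rest
#' between the relaxed (75, 50) and stringent presets. Identities come
#' from separated Beta distributions for orthologs versus decoys, and
#' bitscores increase with identity, with decoy bitscores strictly below
#' ortholog bitscores, so planted pairs are always mutual best hits and
#' decoys never are (decoy pairs are additionally never sampled in both
#' directions).
#'
#' @param orthologs tibble with columns `model`, `target` (from
#'   [generate_pair()]).
#' @param spec a [synth_spec()].
#' @param model_nodes,target_nodes optional full node sets from which
#'   decoy partners are drawn (defaults: the ortholog columns).
#' @return list with `fwd` (model proteins as query) and `rev` (target as
#'   query), both [hit_table()]s.
#' @export
generate_hits <- function(orthologs, spec, model_nodes = NULL,
                          target_nodes = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  if (nrow(orthologs) == 0L) stop("empty ortholog map", call. = FALSE)
  set.seed(spec$seed + 1L)
  model_nodes <- model_nodes %||% orthologs$model
  target_nodes <- target_nodes %||% orthologs$target
  n <- nrow(orthologs)
  n_strong <- min(spec$n_landmarks, n)
  strong <- sort(sample.int(n, n_strong))
  ident <- numeric(n)
  covg <- numeric(n)
  ident[strong] <- 85 + 14 * stats::rbeta(n_strong, 2, 1)
  covg[strong] <- 90 + 10 * stats::rbeta(n_strong, 2, 1)
  weak <- setdiff(seq_len(n), strong)
  ident[weak] <- 50 + 30 * stats::rbeta(length(weak), 2, 2)
  covg[weak] <- 75 + 15 * stats::rbeta(length(weak), 2, 2)
  bits <- 2 * ident + stats::runif(n, 0, 5) # always > decoy bitscores
  orth_fwd <- tibble::tibble(query = orthologs$model,
                             subject = orthologs$target,
                             pident = ident, qcovs = covg, bitscore = bits)
  orth_rev <- tibble::tibble(query = orthologs$target,
                             subject = orthologs$model,
                             pident = ident, qcovs = covg, bitscore = bits)

  decoys <- function(queries, subjects, exclude) {
    n_decoy <- stats::rpois(1, spec$decoy_hit_rate * length(queries))
    if (n_decoy == 0L) return(NULL)
    q <- sample(queries, n_decoy, replace = TRUE)
    s <- sample(subjects, n_decoy, replace = TRUE)
    keys <- paste(q, s)
    ok <- !duplicated(keys) & !keys %in% exclude
    q <- q[ok]
    s <- s[ok]
    if (length(q) == 0L) return(NULL)
    tibble::tibble(query = q, subject = s,
                   pident = 100 * stats::rbeta(length(q), 1.5, 6),
                   qcovs = stats::runif(length(q), 10, 90),
                   bitscore = stats::runif(length(q), 20, 90))
  }
  pair_keys_fwd <- paste(orth_fwd$query, orth_fwd$subject)
  dec_fwd <- decoys(model_nodes, target_nodes, pair_keys_fwd)
  pair_keys_rev <- paste(orth_rev$query, orth_rev$subject)
  # never mirror a forward decoy pair in reverse
  mirrored <- if (is.null(dec_fwd)) character() else
    paste(dec_fwd$subject, dec_fwd$query)
  dec_rev <- decoys(target_nodes, model_nodes,
                    c(pair_keys_rev, mirrored))
  list(fwd = hit_table(dplyr::bind_rows(orth_fwd, dec_fwd)),
       rev = hit_table(dplyr::bind_rows(orth_rev, dec_rev)))
}

#' Generate a toy GO DAG with community-driven annotations
#'
#' Builds a layered DAG (`dag_depth` levels under a single root; each term
#' has one parent in the level above, plus occasionally a second). The
#' conditional probability of a term given its parents is constant per
#' level, decreasing with depth. Model-network communities (Louvain) each
#' receive a handful of terms; community members carry each community term
#' with probability `label_signal` plus occasional random noise terms.
#' Target annotations combine ortholog inheritance (each partner label
#' kept with probability `conservation`) with community profiles for
#' fresh nodes, then are subsampled to `label_density`.
#'
#' @param spec a [synth_spec()].
#' @param pair output of [generate_pair()].
#' @param namespace `"BP"` or `"MF"` (distinct term ids and RNG stream per
#'   namespace).
#' @return list with `dag` ([go_dag()]), `ann_model` and `ann_target`
#'   ([annotation_map()]s).
#' @export
generate_go <- function(spec, pair, namespace = c("BP", "MF")) {
  stopifnot(inherits(spec, "synth_spec"))
  namespace <- match.arg(namespace)
  set.seed(spec$seed + 2L + 101L * (namespace == "MF"))
  base_id <- if (namespace == "BP") 1000000L else 2000000L
  root <- sprintf("GO:%07d", base_id)
  terms <- sprintf("GO:%07d", base_id + seq_len(spec$n_terms))
  # distribute terms over levels, deeper levels wider
  lv_weights <- seq_len(spec$dag_depth)
  lv_sizes <- pmax(round(spec$n_terms * lv_weights / sum(lv_weights)), 1L)
  while (sum(lv_sizes) > spec$n_terms) {
    lv_sizes[which.max(lv_sizes)] <- max(lv_sizes) - 1L
  }
  while (sum(lv_sizes) < spec$n_terms) {
    lv_sizes[which.max(lv_sizes)] <- max(lv_sizes) + 1L
  }
  level_of <- rep(seq_len(spec$dag_depth), times = lv_sizes)
  parents <- list()
  parents[[root]] <- character()
  for (idx in seq_along(terms)) {
    lv <- level_of[idx]
    pool <- if (lv == 1L) root else terms[level_of == lv - 1L]
    par <- sample(pool, 1L)
    if (lv > 1L && length(pool) > 1L && stats::runif(1) < 0.3) {
      par <- unique(c(par, sample(setdiff(pool, par), 1L)))
    }
    parents[[terms[idx]]] <- par
  }
  # level-constant conditional probabilities, decreasing with depth
  cp <- stats::setNames(c(1, 0.5 * 0.9^(level_of - 1L)), c(root, terms))
  dag <- go_dag(c(root, terms), parents, conditional_prob = cp,
                namespace = stats::setNames(
                  rep(namespace, spec$n_terms + 1L), c(root, terms)))

  # each term is a "functional module": a graph neighbourhood ball around a
  # seed node, of intermediate coverage, instantiated consistently in both
  # networks (the target seed is the ortholog copy of the model seed when
  # one exists), so that graph proximity predicts shared labels within each
  # network and ortholog pairs share labels across them
  map <- stats::setNames(pair$orthologs$target, pair$orthologs$model)
  seeds_m <- sample(pair$model$nodes, spec$n_terms,
                    replace = spec$n_terms > length(pair$model$nodes))
  frac <- stats::runif(spec$n_terms, 0.05, 0.15)
  ball <- function(net, seed, size) {
    bfs_collect(net, seed, size)
  }
  model_rows <- list()
  target_rows <- list()
  for (ti in seq_len(spec$n_terms)) {
    bm <- ball(pair$model, seeds_m[ti],
               round(frac[ti] * n_nodes(pair$model)))
    take_m <- bm[stats::runif(length(bm)) < spec$label_signal]
    if (length(take_m) > 0L) {
      model_rows[[ti]] <- tibble::tibble(protein = take_m, go_id = terms[ti])
    }
    seed_t <- if (seeds_m[ti] %in% names(map)) unname(map[seeds_m[ti]])
              else sample(pair$target$nodes, 1L)
    bt <- ball(pair$target, seed_t, round(frac[ti] * n_nodes(pair$target)))
    take_t <- bt[stats::runif(length(bt)) < spec$label_signal]
    if (length(take_t) > 0L) {
      target_rows[[ti]] <- tibble::tibble(protein = take_t,
                                          go_id = terms[ti])
    }
  }
  noise <- function(nodes) {
    n_noise <- round(0.05 * length(nodes))
    if (n_noise == 0L) return(NULL)
    tibble::tibble(protein = sample(nodes, n_noise),
                   go_id = sample(terms, n_noise, replace = TRUE))
  }
  ann_model <- dplyr::distinct(dplyr::bind_rows(
    model_rows, noise(pair$model$nodes)))
  # ortholog partners inherit each model label with prob `conservation`
  inh <- ann_model[ann_model$protein %in% names(map), , drop = FALSE]
  keep <- stats::runif(nrow(inh)) < spec$conservation
  ann_target <- dplyr::distinct(dplyr::bind_rows(
    target_rows,
    tibble::tibble(protein = unname(map[inh$protein[keep]]),
                   go_id = inh$go_id[keep]),
    noise(pair$target$nodes)))
  # subsample annotated proteins to label_density
  prots <- sort(unique(ann_target$protein))
  keep_p <- sort(sample(prots, round(spec$label_density * length(prots))))
  ann_target <- ann_target[ann_target$protein %in% keep_p, , drop = FALSE]
  list(dag = dag,
       ann_model = annotation_map(ann_model, namespace),
       ann_target = annotation_map(ann_target, namespace))
}

#' Generate the full synthetic benchmark
#'
#' Convenience wrapper running [generate_pair()], [generate_hits()] and
#' [generate_go()] (both namespaces) from one spec.
#'
#' @param spec a [synth_spec()].
#' @return list with `model`, `target`, `orthologs`, `hits`
#'   (list `fwd`/`rev`), `go` (list with elements `BP` and `MF`, each as
#'   [generate_go()]).
#' @export
simulate_species_pair <- function(spec) {
  pair <- generate_pair(spec)
  hits <- generate_hits(pair$orthologs, spec,
                        model_nodes = pair$model$nodes,
                        target_nodes = pair$target$nodes)
  go <- list(BP = generate_go(spec, pair, "BP"),
             MF = generate_go(spec, pair, "MF"))
  c(pair, list(hits = hits, go = go))
}

#' Write all synthetic inputs in their on-disk formats
#'
#' Emits the two edge lists, the forward/reverse hit tables, the GO DAG
#' TSVs and the annotation TSVs of a simulated species pair into a
#' directory, using the same formats the readers in this package consume.
#'
#' @param sim output of [simulate_species_pair()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synth_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_network(sim$model, file.path(dir, "model_network.tsv"))
  write_network(sim$target, file.path(dir, "target_network.tsv"))
  write_hits(sim$hits$fwd, file.path(dir, "hits_fwd.tsv"))
  write_hits(sim$hits$rev, file.path(dir, "hits_rev.tsv"))
  for (ns in c("BP", "MF")) {
    write_go_dag(sim$go[[ns]]$dag, file.path(dir, paste0("go_", ns, ".tsv")))
    write_annotations(sim$go[[ns]]$ann_model,
                      file.path(dir, paste0("ann_model_", ns, ".tsv")))
    write_annotations(sim$go[[ns]]$ann_target,
                      file.path(dir, paste0("ann_target_", ns, ".tsv")))
  }
  readr::write_tsv(sim$orthologs, file.path(dir, "orthologs.tsv"))
  invisible(dir)
}
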