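# shared fixture builders; everything is generated in code at test time

net_path <- function() {
  ppi_network(data.frame(from = c("a", "b"), to = c("b", "c")))
}

net_k4 <- function() {
  pairs <- t(utils::combn(letters[1:4], 2))
  ppi_network(data.frame(from = pairs[, 1], to = pairs[, 2]))
}

# triangle with a tail: smallest non-bipartite test graph
net_triangle_tail <- function() {
  ppi_network(data.frame(from = c("a", "a", "b", "c"),
                         to = c("b", "c", "c", "d")))
}

# seeded Erdos-Renyi graph, resampled until connected
rand_net <- function(n, p = 0.2, seed = 1, prefix = "n") {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  ed <- igraph::as_edgelist(g)
  nm <- sprintf("%s%03d", prefix, seq_len(n))
  ppi_network(data.frame(from = nm[ed[, 1]], to = nm[ed[, 2]]),
              nodes = nm)
}

# root -> a -> b chain with Pr = 0.5 at each specialization
chain_dag <- function() {
  go_dag(c("root", "a", "b"),
         list(root = character(), a = "root", b = "a"),
         conditional_prob = c(root = 1, a = 0.5, b = 0.5))
}

# small DAG with two branches for Resnik brute-force checks
toy_dag5 <- function() {
  go_dag(c("r", "a", "b", "c", "d"),
         list(r = character(), a = "r", b = "r", c = c("a", "b"), d = "a"),
         conditional_prob = c(r = 1, a = 0.4, b = 0.25, c = 0.5, d = 0.2))
}

ann_tbl <- function(proteins, terms, namespace = "BP") {
  annotation_map(tibble::tibble(protein = proteins, go_id = terms), namespace)
}

# independent Resnik oracle: exhaustive max over explicit common ancestors
oracle_res_tt <- function(x, y, dag, ic) {
  common <- intersect(dag$ancestors[[x]], dag$ancestors[[y]])
  if (length(common) == 0L) return(0)
  max(ic$i[common])
}

oracle_res_ss <- function(X, Y, dag, ic) {
  st <- function(S, y) max(vapply(S, oracle_res_tt, 0, y = y, dag = dag,
                                  ic = ic))
  (sum(vapply(X, function(x) st(Y, x), 0)) +
     sum(vapply(Y, function(y) st(X, y), 0))) / (length(X) + length(Y))
}

# brute-force connected components by hand BFS over an edge tibble
oracle_components <- function(edges, nodes) {
  adj <- lapply(stats::setNames(nodes, nodes), function(x) character())
  for (i in seq_len(nrow(edges))) {
    adj[[edges$from[i]]] <- c(adj[[edges$from[i]]], edges$to[i])
    adj[[edges$to[i]]] <- c(adj[[edges$to[i]]], edges$from[i])
  }
  seen <- character()
  comps <- list()
  for (s in nodes) {
    if (s %in% seen) next
    queue <- s
    comp <- character()
    while (length(queue) > 0L) {
      v <- queue[1]
      queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}
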