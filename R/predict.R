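#' Voting configuration
#'
#' Parameters of the weighted two-source k-nearest-neighbour vote:
#' `d` target-network DSD neighbours (each vote weighted `alpha`), `c`
#' cross-source neighbours (weight 1), and `top_r` ranked labels emitted
#' per protein. The defaults d = 20, c = 10, alpha = 1.5 are the
#' recommended settings from the grid search on the human/mouse pair and
#' transfer unchanged to the other species pairs.
#'
#' @param d nonnegative count of target-network DSD neighbours.
#' @param c nonnegative count of cross-source neighbours (`d + c >= 1`).
#' @param alpha positive multiplicative weight on target-neighbour votes.
#' @param top_r number of ranked labels to emit (default 3).
#' @param neighbor_mode `"strict"` (default): the neighbourhood is the d
#'   nearest nodes, and the labeled ones among them vote — neighbourhoods
#'   stay genuinely local, and a node whose whole window is unlabeled
#'   contributes nothing from that source. `"labeled"`: skip unlabeled
#'   nodes until d labeled voters are found, which maximizes voter count
#'   but lets the window grow arbitrarily wide when labels are sparse
#'   (at small training sets it degenerates into a global majority vote).
#' @return a list of class `vote_config`.
#' @export
vote_config <- function(d = 20, c = 10, alpha = 1.5, top_r = 3,
                        neighbor_mode = c("strict", "labeled")) {
  neighbor_mode <- match.arg(neighbor_mode)
  stopifnot(d >= 0, c >= 0, alpha > 0, top_r >= 1)
  if (d + c < 1) stop("d + c must be at least 1", call. = FALSE)
  structure(list(d = as.integer(d), c = as.integer(c), alpha = alpha,
                 top_r = as.integer(top_r), neighbor_mode = neighbor_mode),
            class = "vote_config")
}

#' @export
print.vote_config <- function(x, ...) {
  cat(sprintf("<vote_config> d = %d, c = %d, alpha = %g, top_r = %d (%s)\n",
              x$d, x$c, x$alpha, x$top_r, x$neighbor_mode))
  invisible(x)
}

# nearest labeled candidates from an already-ordered candidate vector
take_labeled <- function(ordered, labeled, k, mode) {
  if (k <= 0) return(character())
  if (mode == "strict") ordered <- ordered[seq_len(min(k, length(ordered)))]
  hit <- ordered[ordered %in% labeled]
  hit[seq_len(min(k, length(hit)))]
}

# ordered target-network neighbours of `node` (ascending DSD, lexicographic
# ties), node itself excluded
dsd_neighbor_order <- function(dsd, node) {
  vals <- dsd[, node]
  nms <- rownames(dsd)
  ord <- order(vals, nms)
  out <- nms[ord]
  out[out != node]
}

# ordered model-network neighbours of target `node` by d12 similarity
# (descending, lexicographic ties)
d12_neighbor_order <- function(d12, node) {
  vals <- d12[, node]
  nms <- rownames(d12)
  nms[order(-vals, nms)]
}

#' Dual-source weighted k-NN label prediction
#'
#' Predicts GO labels for one target-network protein by a weighted
#' majority vote over two neighbourhoods: its `d` nearest labeled
#' target-network nodes under DSD (each contributing weight `alpha` to
#' every one of its GO terms) and its `c` nearest labeled model-network
#' nodes under the co-embedding similarity (weight 1 each). Confidences
#' are normalized vote mass; label ties break lexicographically by term
#' id. Setting `c = 0` reduces exactly to the single-network DSD k-NN
#' method; `d = 0` reduces to the co-embedding-only k-NN method.
#'
#' @param node target protein identifier.
#' @param dsd target-network `dsd_matrix`.
#' @param ce a [coembedding()][coembed_target()] (may be `NULL` when
#'   `cfg$c == 0`).
#' @param labels_target,labels_model [annotation_map()]s (or any
#'   protein/go_id data frames) for the two species.
#' @param cfg a [vote_config()].
#' @return a tibble with columns `protein`, `rank`, `go_id`, `confidence`;
#'   zero rows with attribute `abstain = TRUE` when no labeled neighbour
#'   was found in either source.
#' @export
predict_dual <- function(node, dsd, ce, labels_target, labels_model,
                         cfg = vote_config()) {
  sets_t <- annotation_sets(labels_target)
  sets_m <- if (is.null(labels_model)) list() else annotation_sets(labels_model)
  predict_dual_impl(node, dsd, ce, sets_t, sets_m, cfg)
}

predict_dual_impl <- function(node, dsd, ce, sets_t, sets_m, cfg) {
  if (!node %in% rownames(dsd)) {
    stop("unknown target node '", node, "'", call. = FALSE)
  }
  voters <- character()
  weights <- numeric()
  if (cfg$d > 0) {
    vt <- take_labeled(dsd_neighbor_order(dsd, node), names(sets_t),
                       cfg$d, cfg$neighbor_mode)
    voters <- c(voters, vt)
    weights <- c(weights, rep(cfg$alpha, length(vt)))
  }
  if (cfg$c > 0) {
    if (is.null(ce)) stop("`ce` required when c > 0", call. = FALSE)
    vm <- take_labeled(d12_neighbor_order(ce$d12, node), names(sets_m),
                       cfg$c, cfg$neighbor_mode)
    voters <- c(voters, vm)
    weights <- c(weights, rep(1, length(vm)))
  }
  conf <- tally_votes_two(voters, weights, sets_t, sets_m)
  finalize_prediction(node, conf, cfg$top_r)
}

# voters may come from either species; try target sets first, then model
tally_votes_two <- function(voters, weights, sets_t, sets_m) {
  w <- new.env(parent = emptyenv())
  for (i in seq_along(voters)) {
    terms <- sets_t[[voters[i]]]
    if (is.null(terms)) terms <- sets_m[[voters[i]]]
    if (is.null(terms) || length(terms) == 0L) next
    for (tm in terms) {
      prev <- if (is.null(w[[tm]])) 0 else w[[tm]]
      assign(tm, prev + weights[i], envir = w)
    }
  }
  terms <- ls(w)
  if (length(terms) == 0L) return(NULL)
  vals <- vapply(terms, function(tm) w[[tm]], 0)
  vals / sum(vals)
}

finalize_prediction <- function(node, conf, top_r) {
  if (is.null(conf)) {
    out <- tibble::tibble(protein = character(), rank = integer(),
                          go_id = character(), confidence = numeric())
    attr(out, "abstain") <- node
    return(out)
  }
  ord <- order(-conf, names(conf))
  keep <- ord[seq_len(min(top_r, length(ord)))]
  tibble::tibble(protein = node, rank = seq_along(keep),
                 go_id = names(conf)[keep], confidence = unname(conf[keep]))
}

#' Simple homology-transfer baseline prediction
#'
#' Six baselines that combine the target-network `d`-nearest-neighbour
#' vote (weight `alpha` each) with model-species voters selected directly
#' from a sequence hit table (weight 1 each):
#' \describe{
#'   \item{top_hit}{the query's best hit}
#'   \item{top_hit_nbhd}{the best hit plus its `c` nearest model-DSD
#'     neighbours}
#'   \item{all_hits}{the first `min(100, available)` hits by bitscore}
#'   \item{all_hits_nbhd}{those hits plus each hit's `c` nearest
#'     model-DSD neighbours}
#'   \item{thresh_hits}{all hits meeting the identity/coverage thresholds}
#'   \item{thresh_hits_nbhd}{those plus each hit's `c` nearest model-DSD
#'     neighbours}
#' }
#' Model-side voters are deduplicated and all carry weight 1. A query with
#' zero usable hits falls back to the target-only vote (with a message).
#'
#' @param method one of the six baseline names above.
#' @param node target protein identifier.
#' @param dsd_target target-network `dsd_matrix`.
#' @param dsd_model model-network `dsd_matrix` (needed for the `_nbhd`
#'   variants only).
#' @param hits a [hit_table()] with target proteins as queries and model
#'   proteins as subjects.
#' @param labels_target,labels_model annotations for the two species.
#' @param cfg a [vote_config()].
#' @param thresholds named vector `c(p = , q = )`: percent identity and
#'   query coverage cutoffs for the `thresh_*` variants.
#' @return as [predict_dual()].
#' @export
predict_homology <- function(method = c("top_hit", "top_hit_nbhd",
                                        "all_hits", "all_hits_nbhd",
                                        "thresh_hits", "thresh_hits_nbhd"),
                             node, dsd_target, dsd_model = NULL, hits,
                             labels_target, labels_model,
                             cfg = vote_config(),
                             thresholds = c(p = 85, q = 90)) {
  method <- match.arg(method)
  sets_t <- annotation_sets(labels_target)
  sets_m <- annotation_sets(labels_model)
  predict_homology_impl(method, node, dsd_target, dsd_model, hits,
                        sets_t, sets_m, cfg, thresholds, quiet = FALSE)
}

predict_homology_impl <- function(method, node, dsd_target, dsd_model, hits,
                                  sets_t, sets_m, cfg, thresholds,
                                  quiet = TRUE) {
  if (!node %in% rownames(dsd_target)) {
    stop("unknown target node '", node, "'", call. = FALSE)
  }
  h <- hits[hits$query == node, , drop = FALSE]
  h <- h[order(-h$bitscore, -h$pident, h$subject), , drop = FALSE]
  base_hits <- switch(
    method,
    top_hit = ,
    top_hit_nbhd = utils::head(h$subject, 1L),
    all_hits = ,
    all_hits_nbhd = utils::head(h$subject, 100L),
    thresh_hits = ,
    thresh_hits_nbhd = h$subject[h$pident >= thresholds[["p"]] &
                                   h$qcovs >= thresholds[["q"]]]
  )
  if (length(base_hits) == 0L && !quiet) {
    message("node '", node, "' has no usable hits; target-only vote")
  }
  model_voters <- base_hits
  if (grepl("_nbhd$", method) && length(base_hits) > 0L) {
    if (is.null(dsd_model)) {
      stop("dsd_model required for the '_nbhd' baselines", call. = FALSE)
    }
    for (hv in base_hits) {
      if (!hv %in% rownames(dsd_model)) next
      nb <- take_labeled(dsd_neighbor_order(dsd_model, hv), names(sets_m),
                         cfg$c, cfg$neighbor_mode)
      model_voters <- c(model_voters, nb)
    }
  }
  model_voters <- unique(model_voters)
  target_voters <- take_labeled(dsd_neighbor_order(dsd_target, node),
                                names(sets_t), cfg$d, cfg$neighbor_mode)
  voters <- c(target_voters, model_voters)
  weights <- c(rep(cfg$alpha, length(target_voters)),
               rep(1, length(model_voters)))
  conf <- tally_votes_two(voters, weights, sets_t, sets_m)
  finalize_prediction(node, conf, cfg$top_r)
}

#' Batch label prediction
#'
#' Runs one prediction method over a set of target proteins and binds the
#' per-protein ranked labels into one tidy table. Output order follows the
#' input node order; results are deterministic under fixed inputs.
#'
#' @param nodes character vector of target protein identifiers.
#' @param method `"dual"` (the two-source weighted vote), `"dsd"`
#'   (single-network k-NN, i.e. dual with c = 0), `"munk"`
#'   (co-embedding-only k-NN, dual with d = 0), or one of the six
#'   homology baseline names (see [predict_homology()]).
#' @param dsd_target target-network `dsd_matrix`.
#' @param ce a [coembedding()][coembed_target()] (for `"dual"`/`"munk"`).
#' @param labels_target,labels_model annotations for the two species.
#' @param cfg a [vote_config()].
#' @param dsd_model,hits,thresholds passed to the homology baselines.
#' @return tibble with columns `protein`, `rank`, `go_id`, `confidence`;
#'   attribute `"abstained"` lists proteins with no labeled voter.
#' @export
predict_labels <- function(nodes, method = "dual", dsd_target, ce = NULL,
                           labels_target, labels_model = NULL,
                           cfg = vote_config(), dsd_model = NULL,
                           hits = NULL, thresholds = c(p = 85, q = 90)) {
  sets_t <- annotation_sets(labels_target)
  sets_m <- if (is.null(labels_model)) list() else annotation_sets(labels_model)
  cfg_use <- cfg
  if (method == "dsd") cfg_use <- modify_cfg(cfg, c = 0L)
  if (method == "munk") cfg_use <- modify_cfg(cfg, d = 0L)
  simple <- c("top_hit", "top_hit_nbhd", "all_hits", "all_hits_nbhd",
              "thresh_hits", "thresh_hits_nbhd")
  out <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    out[[i]] <- if (method %in% c("dual", "dsd", "munk")) {
      predict_dual_impl(nodes[i], dsd_target, ce, sets_t, sets_m, cfg_use)
    } else if (method %in% simple) {
      predict_homology_impl(method, nodes[i], dsd_target, dsd_model, hits,
                            sets_t, sets_m, cfg_use, thresholds)
    } else {
      stop("unknown method '", method, "'", call. = FALSE)
    }
  }
  abstained <- unlist(lapply(out, attr, "abstain"))
  res <- dplyr::bind_rows(out)
  attr(res, "abstained") <- abstained %||% character()
  attr(res, "nodes") <- nodes
  res
}

modify_cfg <- function(cfg, d = cfg$d, c = cfg$c) {
  # preserve validity even at the degenerate source counts
  structure(list(d = as.integer(d), c = as.integer(c), alpha = cfg$alpha,
                 top_r = cfg$top_r, neighbor_mode = cfg$neighbor_mode),
            class = "vote_config")
}
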