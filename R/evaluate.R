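#' Filter GO terms to an intermediate specificity band
#'
#' Retains only terms that annotate between `min_count` and `max_count`
#' proteins of the annotation set (counts taken on the target network's
#' annotated nodes), dropping over-general and over-specific labels;
#' proteins left with zero terms are removed. The band (50, 500) is the
#' reference choice for networks of several thousand annotated proteins
#' (human/mouse scale); (50, 300) for the smaller yeast networks — scale
#' the band with the network.
#'
#' @param ann an [annotation_map()] (or protein/go_id data frame).
#' @param min_count,max_count inclusive bounds on the per-term annotated
#'   protein count.
#' @return the filtered [annotation_map()].
#' @export
filter_terms <- function(ann, min_count = 50, max_count = 500) {
  counts <- table(ann$go_id[!duplicated(paste(ann$protein, ann$go_id))])
  keep <- names(counts)[counts >= min_count & counts <= max_count]
  out <- dplyr::filter(tibble::as_tibble(ann), .data$go_id %in% keep)
  if (nrow(out) == 0L) {
    stop("no terms survive the specificity filter [", min_count, ", ",
         max_count, "]", call. = FALSE)
  }
  ns <- attr(ann, "namespace")
  annotation_map(out, if (is.null(ns)) "BP" else ns)
}

#' Top-1 percent accuracy
#'
#' The percentage of evaluated proteins whose rank-1 predicted label is
#' among their true labels. Proteins present in the truth set for which
#' the method abstained (no prediction rows) count as wrong.
#'
#' @param preds prediction tibble (`protein`, `rank`, `go_id`,
#'   `confidence`) as returned by [predict_labels()].
#' @param truth named list of true GO term sets (see
#'   [annotation_sets()]), defining the evaluated proteins.
#' @return percent in \[0, 100\].
#' @export
percent_accuracy <- function(preds, truth) {
  prots <- names(truth)
  if (length(prots) == 0L) stop("no evaluated proteins", call. = FALSE)
  top1 <- preds[preds$rank == 1L, , drop = FALSE]
  top1 <- stats::setNames(top1$go_id, top1$protein)
  correct <- vapply(prots, function(p) {
    g <- top1[p]
    !is.na(g) && g %in% truth[[p]]
  }, NA)
  100 * mean(correct)
}

#' Protein-centric F1-max
#'
#' For each confidence threshold tau, precision is averaged only over
#' proteins with at least one prediction at confidence > tau, while recall
#' is averaged over *all* test proteins; F1(tau) is the harmonic mean of
#' the two averages and F1* its maximum over the threshold grid. The
#' default grid is the sorted set of distinct emitted confidences (F1 is
#' piecewise constant in tau, so this grid attains the exact maximum);
#' thresholds are applied as `confidence >= tau`.
#'
#' @param preds prediction tibble with confidences.
#' @param truth named list of true GO term sets over the test proteins.
#' @param tau_grid optional numeric vector of thresholds.
#' @return list with `f1_max`, `tau` (an argmax), and the per-threshold
#'   `curve` tibble (tau, precision, recall, f1).
#' @export
f1_max <- function(preds, truth, tau_grid = NULL) {
  prots <- names(truth)
  n_test <- length(prots)
  if (is.null(tau_grid)) {
    tau_grid <- sort(unique(preds$confidence))
    if (length(tau_grid) == 0L) tau_grid <- 1
  }
  if (length(tau_grid) == 0L) stop("empty tau grid", call. = FALSE)
  pred_sets <- split(preds[, c("go_id", "confidence")], preds$protein)
  rows <- lapply(tau_grid, function(tau) {
    precs <- numeric()
    recs <- numeric(n_test)
    for (i in seq_len(n_test)) {
      p <- prots[i]
      ps <- pred_sets[[p]]
      sel <- if (is.null(ps)) character() else ps$go_id[ps$confidence >= tau]
      ti <- truth[[p]]
      if (length(sel) > 0L) {
        precs <- c(precs, length(intersect(sel, ti)) / length(sel))
      }
      recs[i] <- length(intersect(sel, ti)) / length(ti)
    }
    prec <- if (length(precs) > 0L) mean(precs) else 0
    rec <- mean(recs)
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(tau = tau, precision = prec, recall = rec, f1 = f1)
  })
  curve <- dplyr::bind_rows(rows)
  best <- which.max(curve$f1)
  list(f1_max = curve$f1[best], tau = curve$tau[best], curve = curve)
}

#' Information content from conditional probabilities
#'
#' The information accretion of a term is
#' `ia(v) = -log Pr(v | parents(v))`; the information content of a term is
#' the accretion summed over the term and all its ancestors, equivalently
#' `-log` of the product of conditional probabilities over the ancestor
#' closure. The logarithm base defaults to e (natural log); the base only
#' rescales every Resnik score uniformly, so it is fixed globally per
#' analysis.
#'
#' @param dag a [go_dag()] carrying `conditional_prob` (see
#'   [estimate_conditional_prob()] to fill it from a corpus).
#' @param base logarithm base.
#' @return object of class `information_content`: list with named numeric
#'   vectors `ia` and `i`, plus the ancestor closure.
#' @export
information_content <- function(dag, base = exp(1)) {
  stopifnot(inherits(dag, "go_dag"))
  cp <- dag$conditional_prob
  if (is.null(cp)) {
    stop("DAG has no conditional probabilities; supply them or estimate ",
         "with estimate_conditional_prob()", call. = FALSE)
  }
  if (any(cp <= 0 | cp > 1)) {
    stop("conditional probabilities must be in (0, 1]", call. = FALSE)
  }
  ia <- -log(cp) / log(base)
  i <- vapply(dag$terms, function(tm) sum(ia[dag$ancestors[[tm]]]), 0)
  structure(list(ia = ia, i = i, ancestors = dag$ancestors),
            class = "information_content")
}

#' Estimate term conditional probabilities from an annotation corpus
#'
#' `Pr(v | parents(v))` is estimated as the number of proteins annotated
#' (after ancestor closure) with `v` divided by the number annotated with
#' all parents of `v`. Root terms get probability 1; terms with zero
#' parent support get probability 1 (information accretion 0).
#'
#' @param dag a [go_dag()].
#' @param ann an [annotation_map()] used as corpus.
#' @return the [go_dag()] with `conditional_prob` filled in.
#' @export
estimate_conditional_prob <- function(dag, ann) {
  sets <- annotation_sets(ann)
  closed <- lapply(sets, function(ts) {
    ts <- intersect(ts, dag$terms)
    unique(unlist(dag$ancestors[ts], use.names = FALSE))
  })
  n_with <- function(terms) {
    if (length(terms) == 0L) return(length(closed))
    sum(vapply(closed, function(cs) all(terms %in% cs), NA))
  }
  cp <- vapply(dag$terms, function(tm) {
    parents <- dag$parents[[tm]]
    denom <- n_with(parents)
    if (denom == 0L) return(1)
    num <- n_with(tm)
    max(min(num / denom, 1), .Machine$double.eps)
  }, 0)
  go_dag(dag$terms, dag$parents, conditional_prob = cp,
         namespace = dag$namespace)
}

# pairwise term-term Resnik: information content of the most informative
# common ancestor; terms with no common ancestor score 0 (virtual root)
resnik_term_matrix <- function(terms, ic) {
  n <- length(terms)
  out <- matrix(0, n, n, dimnames = list(terms, terms))
  for (a in seq_len(n)) {
    for (b in a:n) {
      common <- intersect(ic$ancestors[[terms[a]]], ic$ancestors[[terms[b]]])
      val <- if (length(common) == 0L) 0 else max(ic$i[common])
      out[a, b] <- val
      out[b, a] <- val
    }
  }
  out
}

#' Resnik semantic similarity between two term sets
#'
#' Term-to-term similarity is the information content of the most
#' informative common ancestor (the DAG generalization of the least
#' common ancestor); set-to-term takes the max over the set, and
#' set-to-set averages the two directed max profiles:
#' `res(X, Y) = (sum_x res(Y, x) + sum_y res(X, y)) / (|X| + |Y|)`.
#' Either set empty gives 0.
#'
#' @param x,y character vectors of GO terms.
#' @param ic an [information_content()].
#' @return nonnegative real.
#' @export
resnik_set_similarity <- function(x, y, ic) {
  x <- intersect(unique(x), names(ic$i))
  y <- intersect(unique(y), names(ic$i))
  if (length(x) == 0L || length(y) == 0L) return(0)
  tm <- resnik_term_matrix(union(x, y), ic)
  sx <- vapply(x, function(t) max(tm[y, t]), 0) # res_st(Y, x)
  sy <- vapply(y, function(t) max(tm[x, t]), 0) # res_st(X, y)
  (sum(sx) + sum(sy)) / (length(x) + length(y))
}

#' Resnik evaluation score over a test set
#'
#' For each threshold tau, the set-to-set Resnik similarity between a
#' protein's true terms and its predicted terms at confidence >= tau is
#' averaged over all test proteins; the reported score is the maximum of
#' that average over the threshold grid (default: the distinct emitted
#' confidences).
#'
#' @param preds prediction tibble.
#' @param truth named list of true GO term sets.
#' @param ic an [information_content()].
#' @param tau_grid optional thresholds.
#' @return list with `res` (the score), `tau` (an argmax) and the
#'   per-threshold `curve`.
#' @export
resnik_scores <- function(preds, truth, ic, tau_grid = NULL) {
  prots <- names(truth)
  if (is.null(tau_grid)) {
    tau_grid <- sort(unique(preds$confidence))
    if (length(tau_grid) == 0L) tau_grid <- 1
  }
  pred_sets <- split(preds[, c("go_id", "confidence")], preds$protein)
  # precompute the term-term matrix over all terms in play once
  all_terms <- intersect(unique(c(unlist(truth, use.names = FALSE),
                                  preds$go_id)), names(ic$i))
  tm <- if (length(all_terms) > 0L) resnik_term_matrix(all_terms, ic) else
    matrix(0, 0, 0)
  set_sim <- function(x, y) {
    x <- intersect(unique(x), all_terms)
    y <- intersect(unique(y), all_terms)
    if (length(x) == 0L || length(y) == 0L) return(0)
    sx <- apply(tm[y, x, drop = FALSE], 2, max)
    sy <- apply(tm[x, y, drop = FALSE], 2, max)
    (sum(sx) + sum(sy)) / (length(x) + length(y))
  }
  rows <- lapply(tau_grid, function(tau) {
    vals <- vapply(prots, function(p) {
      ps <- pred_sets[[p]]
      sel <- if (is.null(ps)) character() else ps$go_id[ps$confidence >= tau]
      set_sim(truth[[p]], sel)
    }, 0)
    tibble::tibble(tau = tau, res = mean(vals))
  })
  curve <- dplyr::bind_rows(rows)
  best <- which.max(curve$res)
  list(res = curve$res[best], tau = curve$tau[best], curve = curve)
}

# CAFA-style ancestor propagation: a protein annotated with v is annotated
# with every ancestor of v; predicted ancestors inherit the max confidence
# of their descendants
propagate_truth <- function(truth, dag) {
  lapply(truth, function(ts) {
    ts <- intersect(ts, dag$terms)
    sort(unique(unlist(dag$ancestors[ts], use.names = FALSE)))
  })
}

propagate_preds <- function(preds, dag) {
  if (nrow(preds) == 0L) return(preds)
  out <- preds |>
    dplyr::rowwise() |>
    dplyr::mutate(go_id = list(
      if (.data$go_id %in% dag$terms) dag$ancestors[[.data$go_id]]
      else .data$go_id)) |>
    dplyr::ungroup() |>
    tidyr::unnest("go_id") |>
    dplyr::group_by(.data$protein, .data$go_id) |>
    dplyr::summarise(confidence = max(.data$confidence), .groups = "drop") |>
    dplyr::group_by(.data$protein) |>
    dplyr::arrange(dplyr::desc(.data$confidence), .data$go_id,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  out[, c("protein", "rank", "go_id", "confidence")]
}
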