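#' Inverted k-fold cross-validation
#'
#' Ordinary k-fold CV trains on k-1 folds; the inverted design does the
#' opposite, stressing the sparse-annotation regime: the annotated
#' proteins are shuffled and split into k folds, and each fold in turn is
#' the *training* set while the other k-1 folds have their annotations
#' hidden and are scored. Larger k therefore means *less* training data.
#' Accuracy, F1-max (over the `top_r` ranked labels the predictor emits)
#' and, when an information-content object is supplied, the Resnik score
#' are recorded per (run, fold) and summarized as mean and standard
#' deviation.
#'
#' @param ann an [annotation_map()] of the target species (already
#'   specificity-filtered).
#' @param predictor a function `(test_proteins, train_ann)` returning a
#'   prediction tibble (`protein`, `rank`, `go_id`, `confidence`);
#'   typically a closure over [predict_labels()].
#' @param k number of folds (k >= 2); one fold trains, k-1 test.
#' @param n_runs number of independent shuffles (default 5).
#' @param seed integer seed; run r uses `seed + r - 1`.
#' @param ic optional [information_content()] for the Resnik score.
#' @param propagate if `TRUE`, ancestor-close truth and predictions
#'   (CAFA-style max-confidence propagation) before scoring; requires
#'   `dag`.
#' @param dag the [go_dag()] (only needed when `propagate = TRUE`).
#' @return a tibble of class `cv_report` with one row per (run, fold) and
#'   columns `run`, `fold`, `n_train`, `n_test`, `accuracy`, `f1_max`,
#'   and `resnik` when `ic` is given. Summarize with [glance()].
#' @export
inverted_kfold <- function(ann, predictor, k = 10, n_runs = 5, seed = 1,
                           ic = NULL, propagate = FALSE, dag = NULL) {
  stopifnot(k >= 2)
  proteins <- sort(unique(ann$protein))
  if (length(proteins) < k) {
    stop("fewer annotated proteins (", length(proteins),
         ") than folds (", k, ")", call. = FALSE)
  }
  if (propagate && is.null(dag)) {
    stop("`dag` required when propagate = TRUE", call. = FALSE)
  }
  truth_all <- annotation_sets(ann)
  rows <- list()
  for (run in seq_len(n_runs)) {
    set.seed(seed + run - 1L)
    shuffled <- sample(proteins)
    fold_of <- rep(seq_len(k), length.out = length(shuffled))
    for (fold in seq_len(k)) {
      train_prots <- shuffled[fold_of == fold]
      test_prots <- sort(shuffled[fold_of != fold])
      if (length(train_prots) == 0L) {
        stop("fold with zero labeled training proteins", call. = FALSE)
      }
      train_ann <- ann[ann$protein %in% train_prots, , drop = FALSE]
      preds <- predictor(test_prots, train_ann)
      truth <- truth_all[test_prots]
      if (propagate) {
        truth <- propagate_truth(truth, dag)
        preds <- propagate_preds(preds, dag)
      }
      row <- tibble::tibble(
        run = run, fold = fold,
        n_train = length(train_prots), n_test = length(test_prots),
        accuracy = percent_accuracy(preds, truth),
        f1_max = f1_max(preds, truth)$f1_max
      )
      if (!is.null(ic)) row$resnik <- resnik_scores(preds, truth, ic)$res
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "k") <- k
  attr(out, "n_runs") <- n_runs
  attr(out, "seed") <- seed
  class(out) <- c("cv_report", class(out))
  out
}

#' One-row mean/sd summary of a cross-validation report
#' @param x a `cv_report`
#' @param ... unused
#' @return one-row tibble with `<metric>_mean` and `<metric>_sd` columns
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  metrics <- intersect(c("accuracy", "f1_max", "resnik"), names(x))
  out <- tibble::tibble(k = attr(x, "k"), n_runs = attr(x, "n_runs"))
  for (m in metrics) {
    out[[paste0(m, "_mean")]] <- mean(x[[m]])
    out[[paste0(m, "_sd")]] <- stats::sd(x[[m]])
  }
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> inverted %d-fold, %d run(s)\n",
              attr(x, "k"), attr(x, "n_runs")))
  print(glance(x))
  invisible(x)
}

# standard (non-inverted) k-fold CV accuracy of one configuration
standard_kfold_accuracy <- function(proteins, ann, predictor, k, seed) {
  set.seed(seed)
  shuffled <- sample(proteins)
  fold_of <- rep(seq_len(k), length.out = length(shuffled))
  accs <- vapply(seq_len(k), function(fold) {
    test_prots <- sort(shuffled[fold_of == fold])
    train_prots <- shuffled[fold_of != fold]
    train_ann <- ann[ann$protein %in% train_prots, , drop = FALSE]
    preds <- predictor(test_prots, train_ann)
    truth <- annotation_sets(ann[ann$protein %in% test_prots, , drop = FALSE])
    percent_accuracy(preds, truth)
  }, 0)
  mean(accs)
}

#' Grid search over voting parameters
#'
#' Splits the annotated proteins 50/50 into a tuning half and a held-out
#' validation half, runs standard (non-inverted) 5-fold cross-validation
#' on the tuning half for every configuration in the grid, and ranks the
#' configurations by mean accuracy. The validation half is never touched
#' during the search; its protein ids are returned so the caller can
#' evaluate the chosen configuration on untouched data.
#'
#' @param grid a data frame with columns among `d`, `c`, `alpha` (missing
#'   columns take the [vote_config()] defaults); one row per
#'   configuration.
#' @param ann the annotation map searched over.
#' @param predictor_factory a function `(cfg)` returning a predictor
#'   `(test_proteins, train_ann)` as for [inverted_kfold()].
#' @param seed integer seed controlling the 50/50 split and fold
#'   assignment (all configurations see identical folds).
#' @param k folds for the inner CV (default 5).
#' @return the grid tibble with a `mean_accuracy` column, sorted best
#'   first; attribute `"validation_proteins"` holds the held-out ids.
#' @export
grid_search <- function(grid, ann, predictor_factory, seed = 1, k = 5) {
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0L) stop("empty parameter grid", call. = FALSE)
  proteins <- sort(unique(ann$protein))
  set.seed(seed)
  half <- sample(proteins, floor(length(proteins) / 2))
  tune_prots <- sort(half)
  valid_prots <- sort(setdiff(proteins, half))
  tune_ann <- ann[ann$protein %in% tune_prots, , drop = FALSE]
  defaults <- vote_config()
  grid$mean_accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- vote_config(
      d = if ("d" %in% names(grid)) grid$d[i] else defaults$d,
      c = if ("c" %in% names(grid)) grid$c[i] else defaults$c,
      alpha = if ("alpha" %in% names(grid)) grid$alpha[i] else defaults$alpha,
      top_r = defaults$top_r
    )
    standard_kfold_accuracy(tune_prots, tune_ann, predictor_factory(cfg),
                            k, seed)
  }, 0)
  out <- dplyr::arrange(grid, dplyr::desc(.data$mean_accuracy))
  attr(out, "validation_proteins") <- valid_prots
  out
}
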