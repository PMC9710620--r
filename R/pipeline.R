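#' Pipeline run configuration
#'
#' Bundles the input paths and every tunable parameter of the end-to-end
#' run: embed the two networks, select landmarks, co-embed, predict, and
#' evaluate by inverted cross-validation. Defaults follow the recommended
#' settings: vote parameters d = 20, c = 10, alpha = 1.5; landmark
#' thresholds (q, p) = (90, 85); term-specificity band (50, 500).
#'
#' @param model_network,target_network edge-list paths (see
#'   [read_network()]).
#' @param hits_fwd,hits_rev hit-table paths, model-as-query and
#'   target-as-query.
#' @param go_dag_bp,ann_model_bp,ann_target_bp BP-namespace DAG and
#'   annotation TSV paths.
#' @param go_dag_mf,ann_model_mf,ann_target_mf optional MF-namespace
#'   paths.
#' @param network_format `"edgelist"` or `"biogrid_tsv"`.
#' @param dsd_mode `"converged"` or `"fixed_t"`.
#' @param t walk length when `dsd_mode = "fixed_t"`.
#' @param q,p landmark coverage/identity thresholds (percent).
#' @param d,c,alpha,top_r vote parameters (see [vote_config()]).
#' @param method prediction method (see [predict_labels()]).
#' @param filter_min,filter_max term specificity band.
#' @param cv_k,cv_runs inverted cross-validation folds and runs.
#' @param seed integer seed for every random choice in the run.
#' @param out_dir output directory for predictions and the report.
#' @param cache_dir directory for cached embeddings (the embedding step
#'   only has to be done once per species pair; reruns with identical
#'   inputs and relevant parameters reuse it).
#' @return a list of class `run_config`.
#' @export
run_config <- function(model_network, target_network, hits_fwd, hits_rev,
                       go_dag_bp, ann_model_bp, ann_target_bp,
                       go_dag_mf = NULL, ann_model_mf = NULL,
                       ann_target_mf = NULL,
                       network_format = "edgelist",
                       dsd_mode = c("converged", "fixed_t"), t = 10,
                       q = 90, p = 85,
                       d = 20, c = 10, alpha = 1.5, top_r = 3,
                       method = "dual",
                       filter_min = 50, filter_max = 500,
                       cv_k = 10, cv_runs = 5, seed = 1,
                       out_dir = "crossfun_out",
                       cache_dir = file.path(out_dir, "cache")) {
  dsd_mode <- match.arg(dsd_mode)
  cfg <- list(model_network = model_network,
              target_network = target_network,
              hits_fwd = hits_fwd, hits_rev = hits_rev,
              go_dag_bp = go_dag_bp, ann_model_bp = ann_model_bp,
              ann_target_bp = ann_target_bp, go_dag_mf = go_dag_mf,
              ann_model_mf = ann_model_mf, ann_target_mf = ann_target_mf,
              network_format = network_format, dsd_mode = dsd_mode, t = t,
              q = q, p = p, d = d, c = c, alpha = alpha, top_r = top_r,
              method = method, filter_min = filter_min,
              filter_max = filter_max, cv_k = cv_k, cv_runs = cv_runs,
              seed = as.integer(seed), out_dir = out_dir,
              cache_dir = cache_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @param ... overrides applied after reading.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  vals <- utils::modifyList(vals, list(...))
  do.call(run_config, vals)
}

# content-addressed cache of an expensive stage
cached_stage <- function(cache_dir, name, key, compute) {
  if (is.null(cache_dir)) return(compute())
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(cache_dir, paste0(name, "-", rlang::hash(key), ".rds"))
  if (file.exists(path)) {
    message("[cache] reusing ", name)
    return(readRDS(path))
  }
  value <- compute()
  saveRDS(value, path)
  value
}

file_key <- function(path) {
  unname(tools::md5sum(path))
}

#' Run the end-to-end prediction pipeline
#'
#' Stages, in order: read and LCC-reduce both networks; compute the
#' target (and, if needed, model) DSD; select reciprocal-best-hit
#' landmarks; build the model embedding and co-embed the target network;
#' specificity-filter the target annotations; evaluate the configured
#' method by inverted k-fold cross-validation per namespace; and predict
#' ranked labels for every target protein using all available
#' annotations. Embedding stages are cached by a content hash of their
#' inputs and relevant parameters, so a rerun with an identical
#' configuration skips them and reproduces identical outputs.
#'
#' @param cfg a [run_config()].
#' @param write if `TRUE`, write `predictions_<ns>.tsv` and
#'   `report.json` under `cfg$out_dir`.
#' @return list with `report` (tibble: one row per namespace with CV
#'   summary), `cv` (named list of `cv_report`s), `predictions` (named
#'   list of prediction tibbles), invisibly the file paths written.
#' @export
run_pipeline <- function(cfg, write = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  message("[stage] networks")
  net_m <- largest_connected_component(
    read_network(cfg$model_network, cfg$network_format))
  net_t <- largest_connected_component(
    read_network(cfg$target_network, cfg$network_format))

  message("[stage] hit tables + landmarks (q = ", cfg$q, ", p = ", cfg$p, ")")
  hits_fwd <- read_hits(cfg$hits_fwd)
  hits_rev <- read_hits(cfg$hits_rev)
  lm <- select_rbh_landmarks(hits_fwd, hits_rev, q = cfg$q, p = cfg$p)
  lm <- lm[lm$model %in% net_m$nodes & lm$target %in% net_t$nodes, ]
  if (nrow(lm) == 0L) {
    stop("pipeline stage 'landmarks': no landmark survives the largest ",
         "connected components", call. = FALSE)
  }

  dsd_key <- list(file_key(cfg$model_network), file_key(cfg$target_network),
                  cfg$network_format, cfg$dsd_mode, cfg$t)
  message("[stage] diffusion states + DSD (", cfg$dsd_mode, ")")
  emb <- cached_stage(cfg$cache_dir, "embeddings", dsd_key, function() {
    if (cfg$dsd_mode == "converged") {
      ds_m <- converged_state(net_m)
      ds_t <- converged_state(net_t)
    } else {
      ds_m <- diffusion_state(net_m, cfg$t)
      ds_t <- diffusion_state(net_t, cfg$t)
    }
    list(ds_m = ds_m, ds_t = ds_t,
         dsd_m = dsd_matrix(ds_m), dsd_t = dsd_matrix(ds_t))
  })

  co_key <- c(dsd_key, list(lm$model, lm$target))
  ce <- cached_stage(cfg$cache_dir, "coembedding", co_key, function() {
    message("[stage] co-embedding (", nrow(lm), " landmarks)")
    coembed_target(model_embedding(emb$ds_m), emb$ds_t, lm)
  })

  vcfg <- vote_config(d = cfg$d, c = cfg$c, alpha = cfg$alpha,
                      top_r = cfg$top_r)
  namespaces <- c("BP", if (!is.null(cfg$go_dag_mf)) "MF")
  cv <- list()
  predictions <- list()
  report_rows <- list()
  for (ns in namespaces) {
    message("[stage] evaluate + predict, namespace ", ns)
    dag_path <- if (ns == "BP") cfg$go_dag_bp else cfg$go_dag_mf
    am_path <- if (ns == "BP") cfg$ann_model_bp else cfg$ann_model_mf
    at_path <- if (ns == "BP") cfg$ann_target_bp else cfg$ann_target_mf
    dag <- read_go_dag(dag_path)
    ann_m <- read_annotations(am_path, dag, ns)
    ann_t <- read_annotations(at_path, dag, ns)
    ann_t <- ann_t[ann_t$protein %in% net_t$nodes, , drop = FALSE]
    ann_t <- filter_terms(ann_t, cfg$filter_min, cfg$filter_max)
    ic <- if (!is.null(dag$conditional_prob)) information_content(dag)
          else information_content(estimate_conditional_prob(dag, ann_m))
    predictor <- function(test_prots, train_ann) {
      predict_labels(test_prots, method = cfg$method, dsd_target = emb$dsd_t,
                     ce = ce, labels_target = train_ann,
                     labels_model = ann_m, cfg = vcfg,
                     dsd_model = emb$dsd_m, hits = hits_rev,
                     thresholds = c(p = cfg$p, q = cfg$q))
    }
    cv[[ns]] <- inverted_kfold(ann_t, predictor, k = cfg$cv_k,
                               n_runs = cfg$cv_runs, seed = cfg$seed,
                               ic = ic)
    predictions[[ns]] <- predict_labels(
      net_t$nodes, method = cfg$method, dsd_target = emb$dsd_t, ce = ce,
      labels_target = ann_t, labels_model = ann_m, cfg = vcfg,
      dsd_model = emb$dsd_m, hits = hits_rev,
      thresholds = c(p = cfg$p, q = cfg$q))
    g <- glance(cv[[ns]])
    g$namespace <- ns
    report_rows[[ns]] <- g
  }
  report <- dplyr::bind_rows(report_rows)
  report <- dplyr::relocate(report, "namespace")
  paths <- character()
  if (write) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (ns in namespaces) {
      pp <- file.path(cfg$out_dir, paste0("predictions_", ns, ".tsv"))
      readr::write_tsv(predictions[[ns]], pp)
      paths <- c(paths, pp)
    }
    rp <- file.path(cfg$out_dir, "report.json")
    jsonlite::write_json(list(
      seed = cfg$seed, method = cfg$method,
      parameters = cfg[c("d", "c", "alpha", "top_r", "q", "p",
                         "filter_min", "filter_max", "cv_k", "cv_runs")],
      summary = report,
      folds = lapply(cv, tibble::as_tibble)
    ), rp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, rp)
  }
  out <- list(report = report, cv = cv, predictions = predictions,
              landmarks = lm, paths = paths)
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$report)
  invisible(x)
}
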