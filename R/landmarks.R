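#' Best hit per query
#'
#' For every query in a hit table, the subject with the maximal bitscore.
#' Ties are resolved deterministically: higher percent identity first, then
#' lexicographically smaller subject id.
#'
#' @param hits a [hit_table()].
#' @return a tibble with columns `query`, `subject`, `pident`, `qcovs`,
#'   `bitscore` — one row per query.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0L) stop("empty hit table", call. = FALSE)
  tibble::as_tibble(unclass(hits)) |>
    dplyr::arrange(.data$query, dplyr::desc(.data$bitscore),
                   dplyr::desc(.data$pident), .data$subject) |>
    dplyr::distinct(.data$query, .keep_all = TRUE)
}

#' Select reciprocal-best-hit landmark pairs
#'
#' A pair (model protein `u`, target protein `v`) is a landmark when `v` is
#' `u`'s best hit, `u` is `v`'s best hit, and *both* direction rows meet
#' the percent-query-coverage threshold `q` and the percent-identity
#' threshold `p`. The resulting pair set is a bijection: each protein
#' appears at most once. The stringent default (q, p) = (90, 85) suits
#' closely related species; a relaxed preset (75, 50) is the documented
#' choice for distant pairs such as the two yeasts, where the stringent
#' thresholds leave too few landmarks.
#'
#' @param fwd hit table with the model species as query.
#' @param rev hit table with the target species as query.
#' @param q minimum percent query coverage (applied to both directions).
#' @param p minimum percent sequence identity (applied to both directions).
#' @return a tibble of class `landmark_set` with columns `model`, `target`
#'   ordered lexicographically by model protein; attributes `q`, `p`.
#' @export
select_rbh_landmarks <- function(fwd, rev, q = 90, p = 85) {
  bf <- best_hits(fwd)
  br <- best_hits(rev)
  pairs <- dplyr::inner_join(
    dplyr::select(bf, model = "query", target = "subject",
                  pident_fwd = "pident", qcovs_fwd = "qcovs"),
    dplyr::select(br, target = "query", model = "subject",
                  pident_rev = "pident", qcovs_rev = "qcovs"),
    by = c("model", "target")
  )
  pairs <- dplyr::filter(pairs,
                         .data$qcovs_fwd >= q, .data$qcovs_rev >= q,
                         .data$pident_fwd >= p, .data$pident_rev >= p)
  out <- dplyr::arrange(dplyr::select(pairs, "model", "target"), .data$model)
  if (nrow(out) == 0L) {
    stop("no reciprocal best hits survive thresholds (q = ", q, ", p = ", p,
         "); consider relaxing them, e.g. the distant-species preset ",
         "(q, p) = (75, 50)", call. = FALSE)
  }
  attr(out, "q") <- q
  attr(out, "p") <- p
  class(out) <- c("landmark_set", class(out))
  out
}

#' Read / write landmark pairs as a two-column TSV
#' @param path file path
#' @return a `landmark_set` tibble
#' @export
read_landmarks <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  names(tab)[1:2] <- c("model", "target")
  out <- dplyr::arrange(tab[, c("model", "target")], .data$model)
  class(out) <- c("landmark_set", class(out))
  out
}

#' @rdname read_landmarks
#' @param lm a `landmark_set`
#' @return `path`, invisibly
#' @export
write_landmarks <- function(lm, path) {
  readr::write_tsv(tibble::as_tibble(unclass(lm))[, c("model", "target")],
                   path)
  invisible(path)
}
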