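#' Gene Ontology DAG
#'
#' A rooted directed acyclic graph of GO terms with, optionally, the
#' conditional probability `Pr(v | parents(v))` attached to every term.
#' These probabilities drive the information-accretion content used by the
#' Resnik evaluation; when absent they can be estimated from an annotation
#' corpus with [estimate_conditional_prob()].
#'
#' @param terms character vector of term identifiers.
#' @param parents named list mapping each term to its (possibly empty)
#'   character vector of parent terms.
#' @param conditional_prob optional named numeric vector in (0, 1],
#'   `Pr(v | parents(v))` per term.
#' @param namespace optional named character vector giving each term's
#'   namespace (`"BP"` or `"MF"`).
#' @return an object of class `go_dag`.
#' @export
go_dag <- function(terms, parents, conditional_prob = NULL, namespace = NULL) {
  terms <- unique(as.character(terms))
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) {
    p <- intersect(as.character(p), terms)
    sort(p)
  })
  dag <- structure(list(terms = terms, parents = parents,
                        conditional_prob = conditional_prob,
                        namespace = namespace),
                   class = "go_dag")
  # reject cycles: topological order must exist
  dag$ancestors <- ancestor_closure(dag)
  if (!is.null(conditional_prob)) {
    cp <- conditional_prob[terms]
    if (any(is.na(cp)) || any(cp <= 0) || any(cp > 1)) {
      stop("conditional_prob must be in (0, 1] for every term", call. = FALSE)
    }
    dag$conditional_prob <- stats::setNames(as.numeric(cp), terms)
  }
  dag
}

#' @export
print.go_dag <- function(x, ...) {
  roots <- sum(vapply(x$parents, length, 1L) == 0L)
  cat(sprintf("<go_dag> %d terms (%d root%s)%s\n", length(x$terms), roots,
              if (roots == 1L) "" else "s",
              if (is.null(x$conditional_prob)) "" else ", with Pr(v|P(v))"))
  invisible(x)
}

#' Parent edges of a GO DAG as a tibble
#' @param x a [go_dag()]
#' @param ... unused
#' @return tibble with columns `term`, `parent` (and `conditional_prob`)
#' @method tidy go_dag
#' @export
tidy.go_dag <- function(x, ...) {
  rows <- purrr::imap(x$parents, function(p, term) {
    if (length(p) == 0L) tibble::tibble(term = term, parent = NA_character_)
    else tibble::tibble(term = term, parent = p)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(x$conditional_prob)) {
    out$conditional_prob <- unname(x$conditional_prob[out$term])
  }
  out
}

# ancestor sets (self included) for every term; errors on cycles
ancestor_closure <- function(dag) {
  n <- length(dag$terms)
  anc <- vector("list", n)
  names(anc) <- dag$terms
  state <- stats::setNames(integer(n), dag$terms) # 0 new, 1 visiting, 2 done
  visit <- function(term) {
    if (state[[term]] == 2L) return(anc[[term]])
    if (state[[term]] == 1L) stop("cycle detected in GO DAG at term ", term,
                                  call. = FALSE)
    state[[term]] <<- 1L
    acc <- term
    for (p in dag$parents[[term]]) acc <- c(acc, visit(p))
    acc <- sort(unique(acc))
    anc[[term]] <<- acc
    state[[term]] <<- 2L
    acc
  }
  for (t in dag$terms) visit(t)
  anc
}

#' Read a GO DAG from disk
#'
#' Two formats: a three-column TSV (`term`, `parent`, `conditional_prob`;
#' root terms carry an empty or `"-"` parent field, the probability column
#' may be omitted), or a minimal OBO subset in which only `[Term]` stanzas
#' with their `id:`, `is_a:` and `namespace:` lines are consumed.
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"obo"`.
#' @return a [go_dag()].
#' @export
read_go_dag <- function(path, format = c("tsv", "obo")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = "c"))
    if (ncol(tab) < 2L) stop("GO DAG TSV needs >= 2 columns", call. = FALSE)
    term <- tab[[1]]
    parent <- tab[[2]]
    parent[parent %in% c("-", "")] <- NA_character_
    terms <- unique(c(term, parent[!is.na(parent)]))
    parents <- split(parent, factor(term, levels = terms))
    parents <- lapply(parents, function(p) p[!is.na(p)])
    cp <- NULL
    if (ncol(tab) >= 3L) {
      cpv <- suppressWarnings(as.numeric(tab[[3]]))
      cp <- tapply(cpv, factor(term, levels = terms),
                   function(v) v[!is.na(v)][1])
      cp <- stats::setNames(as.numeric(cp), terms)
      cp[is.na(cp)] <- 1
    }
    go_dag(terms, parents, conditional_prob = cp)
  } else {
    lines <- readLines(path, warn = FALSE)
    in_term <- FALSE
    cur <- NULL
    terms <- character()
    parents <- list()
    ns <- character()
    flush <- function() {
      if (!is.null(cur) && nzchar(cur$id)) {
        terms <<- c(terms, cur$id)
        parents[[cur$id]] <<- cur$is_a
        ns[cur$id] <<- cur$ns
      }
    }
    for (ln in lines) {
      ln <- trimws(ln)
      if (ln == "[Term]") {
        flush()
        in_term <- TRUE
        cur <- list(id = "", is_a = character(), ns = NA_character_)
      } else if (grepl("^\\[", ln)) {
        flush()
        in_term <- FALSE
        cur <- NULL
      } else if (in_term) {
        if (startsWith(ln, "id:")) {
          cur$id <- trimws(sub("^id:", "", ln))
        } else if (startsWith(ln, "is_a:")) {
          tgt <- trimws(sub("^is_a:", "", ln))
          tgt <- trimws(sub("!.*$", "", tgt))
          cur$is_a <- c(cur$is_a, tgt)
        } else if (startsWith(ln, "namespace:")) {
          nsv <- trimws(sub("^namespace:", "", ln))
          cur$ns <- switch(nsv,
                           biological_process = "BP",
                           molecular_function = "MF",
                           nsv)
        }
      }
    }
    flush()
    if (length(terms) == 0L) stop("no [Term] stanzas in ", path, call. = FALSE)
    go_dag(terms, parents, namespace = ns)
  }
}

#' Protein GO annotations
#'
#' A tidy map from protein identifier to GO term, restricted to one GO
#' namespace (BP or MF). The two namespaces are always analysed as
#' independent experiments.
#'
#' @param x a data frame with columns `protein` and `go_id` (extra columns
#'   ignored).
#' @param namespace `"BP"` or `"MF"`.
#' @return a tibble of class `annotation_map` with columns `protein`,
#'   `go_id` and a `namespace` attribute.
#' @export
annotation_map <- function(x, namespace = c("BP", "MF")) {
  namespace <- match.arg(namespace)
  out <- tibble::tibble(protein = as.character(x[["protein"]]),
                        go_id = as.character(x[["go_id"]]))
  out <- dplyr::distinct(dplyr::arrange(out, .data$protein, .data$go_id))
  attr(out, "namespace") <- namespace
  class(out) <- c("annotation_map", class(out))
  out
}

#' Annotation map as a named list of term sets
#' @param ann an [annotation_map()] (or any protein/go_id data frame)
#' @return named list: protein -> character vector of GO terms
#' @export
annotation_sets <- function(ann) {
  split(ann$go_id, ann$protein)
}

#' Read protein annotations
#'
#' The native format is a three-column TSV (`protein_id`, `go_id`,
#' `namespace`). Terms absent from the companion DAG are dropped with a
#' warning giving the dropped-row count (real annotation exports always
#' contain out-of-subset terms); rows from other namespaces are ignored.
#'
#' @param path path to a TSV file.
#' @param dag a [go_dag()] used to resolve terms.
#' @param namespace `"BP"` or `"MF"`.
#' @return an [annotation_map()].
#' @export
read_annotations <- function(path, dag, namespace = c("BP", "MF")) {
  namespace <- match.arg(namespace)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (ncol(tab) < 3L) stop("annotation TSV needs 3 columns", call. = FALSE)
  names(tab)[1:3] <- c("protein", "go_id", "namespace")
  tab <- dplyr::filter(tab, .data$namespace == !!namespace)
  known <- tab$go_id %in% dag$terms
  if (any(!known)) {
    warning(sprintf("dropped %d annotation row(s) with terms absent from the DAG",
                    sum(!known)), call. = FALSE)
  }
  tab <- tab[known, , drop = FALSE]
  if (nrow(tab) == 0L) {
    stop("no annotations retained for namespace ", namespace, call. = FALSE)
  }
  annotation_map(tab, namespace)
}

#' Read a GAF 2.x annotation file
#'
#' Convenience wrapper over the native TSV reader: consumes the DB Object ID
#' (column 2), GO ID (column 5) and Aspect (column 9, `P` -> BP, `F` -> MF)
#' fields of a Gene Association File.
#'
#' @inheritParams read_annotations
#' @return an [annotation_map()].
#' @export
read_gaf <- function(path, dag, namespace = c("BP", "MF")) {
  namespace <- match.arg(namespace)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, length, 1L) >= 9L
  parts <- parts[ok]
  if (length(parts) == 0L) stop("no GAF records in ", path, call. = FALSE)
  tab <- tibble::tibble(
    protein = vapply(parts, `[[`, "", 2L),
    go_id = vapply(parts, `[[`, "", 5L),
    aspect = vapply(parts, `[[`, "", 9L)
  )
  tab$namespace <- dplyr::case_match(tab$aspect, "P" ~ "BP", "F" ~ "MF",
                                     .default = NA_character_)
  tab <- dplyr::filter(tab, !is.na(.data$namespace),
                       .data$namespace == !!namespace)
  known <- tab$go_id %in% dag$terms
  if (any(!known)) {
    warning(sprintf("dropped %d GAF row(s) with terms absent from the DAG",
                    sum(!known)), call. = FALSE)
  }
  tab <- tab[known, , drop = FALSE]
  if (nrow(tab) == 0L) {
    stop("no annotations retained for namespace ", namespace, call. = FALSE)
  }
  annotation_map(tab, namespace)
}

#' Read a sequence-similarity hit table
#'
#' BLAST outfmt-6-like TSV. The default column mapping expects `qseqid`,
#' `sseqid`, `pident`, `qcovs`, `bitscore`; positions can be remapped for
#' other dialects. Percent fields must lie in \[0, 100\] and at most one row
#' per (query, subject) pair is allowed.
#'
#' @param path path to the TSV (no header by default).
#' @param columns integer positions of query id, subject id, percent
#'   identity, percent query coverage and bitscore, in that order.
#' @param header does the file carry a header line?
#' @return a tibble of class `hit_table` with columns `query`, `subject`,
#'   `pident`, `qcovs`, `bitscore`.
#' @export
read_hits <- function(path, columns = c(1L, 2L, 3L, 4L, 5L), header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, col_names = isTRUE(header),
                         show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  hit_table(tibble::tibble(
    query = as.character(tab[[columns[1]]]),
    subject = as.character(tab[[columns[2]]]),
    pident = as.numeric(tab[[columns[3]]]),
    qcovs = as.numeric(tab[[columns[4]]]),
    bitscore = as.numeric(tab[[columns[5]]])
  ))
}

#' Construct / validate a hit table
#' @param x data frame with columns `query`, `subject`, `pident`, `qcovs`,
#'   `bitscore`.
#' @return a tibble of class `hit_table`.
#' @export
hit_table <- function(x) {
  out <- tibble::as_tibble(x[, c("query", "subject", "pident", "qcovs",
                                 "bitscore")])
  if (any(out$pident < 0 | out$pident > 100, na.rm = TRUE) ||
      any(out$qcovs < 0 | out$qcovs > 100, na.rm = TRUE)) {
    stop("percent identity / coverage must lie in [0, 100]", call. = FALSE)
  }
  if (any(out$bitscore < 0, na.rm = TRUE)) {
    stop("bitscore must be nonnegative", call. = FALSE)
  }
  if (anyDuplicated(out[, c("query", "subject")])) {
    stop("hit table has duplicate (query, subject) rows", call. = FALSE)
  }
  class(out) <- c("hit_table", class(out))
  out
}

#' Write a hit table as outfmt-6-like TSV
#' @param hits a [hit_table()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_hits <- function(hits, path) {
  readr::write_tsv(tibble::as_tibble(unclass(hits))[
    , c("query", "subject", "pident", "qcovs", "bitscore")],
    path, col_names = FALSE)
  invisible(path)
}

#' Write annotations as the native three-column TSV
#' @param ann an [annotation_map()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_annotations <- function(ann, path) {
  ns <- attr(ann, "namespace") %||% "BP"
  readr::write_tsv(tibble::tibble(protein = ann$protein, go_id = ann$go_id,
                                  namespace = ns), path)
  invisible(path)
}

#' Write a GO DAG as the three-column TSV format
#' @param dag a [go_dag()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_go_dag <- function(dag, path) {
  td <- tidy(dag)
  td$parent[is.na(td$parent)] <- "-"
  if (is.null(td$conditional_prob)) td$conditional_prob <- 1
  readr::write_tsv(td, path)
  invisible(path)
}
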