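#' Protein-protein interaction network
#'
#' An undirected, unweighted network over string protein identifiers.
#' Self-loops are excluded and the node order is lexicographic so that every
#' matrix derived from the network (adjacency, diffusion states, DSD,
#' embeddings) aligns to a stable, reproducible node order.
#'
#' @param edges a two-column data frame (or tibble) of interacting protein
#'   identifier pairs. Self-loops are dropped; duplicate and reversed
#'   duplicates are collapsed to a single undirected edge.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node identifiers to include.
#'
#' @return An object of class `ppi_network` with components
#'   \describe{
#'     \item{nodes}{character vector of node identifiers, lexicographic order}
#'     \item{edges}{tibble with columns `from`, `to` (`from < to`)}
#'     \item{adjacency}{symmetric 0/1 matrix aligned to `nodes`}
#'   }
#' @export
ppi_network <- function(edges, nodes = character()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) {
    stop("`edges` must have at least two columns", call. = FALSE)
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  keep <- a != b # no self-loops
  a <- a[keep]
  b <- b[keep]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  ed <- tibble::tibble(from = lo, to = hi) |> dplyr::distinct()
  ed <- dplyr::arrange(ed, .data$from, .data$to)
  nodes <- sort(unique(c(ed$from, ed$to, as.character(nodes))))
  if (length(nodes) == 0L) {
    stop("empty network: no nodes after dropping self-loops", call. = FALSE)
  }
  n <- length(nodes)
  adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(ed) > 0L) {
    i <- match(ed$from, nodes)
    j <- match(ed$to, nodes)
    adj[cbind(i, j)] <- 1
    adj[cbind(j, i)] <- 1
  }
  structure(list(nodes = nodes, edges = ed, adjacency = adj),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes / edges of a network
#' @param net a [ppi_network()]
#' @return integer count
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Edge list of a network as a tibble
#' @param x a [ppi_network()]
#' @param ... unused
#' @return tibble with columns `from`, `to`
#' @method tidy ppi_network
#' @export
tidy.ppi_network <- function(x, ...) x$edges

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Read a PPI network from disk
#'
#' Two dialects are supported: a plain two-column tab-separated edge list
#' (lines starting with `#` are comments), and the BioGRID tab3 export, from
#' which only the two official-symbol interactor columns are consumed; all
#' edges are unweighted presence/absence interactions.
#'
#' @param path path to the file.
#' @param format `"edgelist"` or `"biogrid_tsv"`.
#' @param edge_type for BioGRID input, `"all"` (default), `"physical"` or
#'   `"genetic"`: optional filter on the Experimental System Type column.
#' @return a [ppi_network()] with self-loops dropped, duplicate edges
#'   collapsed and nodes in lexicographic order.
#' @export
read_network <- function(path, format = c("edgelist", "biogrid_tsv"),
                         edge_type = c("all", "physical", "genetic")) {
  format <- match.arg(format)
  edge_type <- match.arg(edge_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edgelist") {
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", lines)
    lines <- lines[keep]
    lineno <- which(keep)
    if (length(lines) == 0L) stop("empty network file: ", path, call. = FALSE)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) < 2L)
    if (length(bad) > 0L) {
      stop(sprintf("malformed edge list line %d in %s: expected 2 fields",
                   lineno[bad[1]], path), call. = FALSE)
    }
    ed <- tibble::tibble(
      from = vapply(parts, `[[`, "", 1L),
      to   = vapply(parts, `[[`, "", 2L)
    )
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE,
                           na = c("", "-"), progress = FALSE)
    cols <- names(tab)
    ia <- grep("Official Symbol Interactor A", cols, fixed = TRUE)
    ib <- grep("Official Symbol Interactor B", cols, fixed = TRUE)
    if (length(ia) != 1L || length(ib) != 1L) {
      stop("not a BioGRID tab3 file (official symbol columns missing): ",
           path, call. = FALSE)
    }
    if (edge_type != "all") {
      it <- grep("Experimental System Type", cols, fixed = TRUE)
      if (length(it) == 1L) {
        tab <- tab[!is.na(tab[[it]]) & tab[[it]] == edge_type, , drop = FALSE]
      }
    }
    ed <- tibble::tibble(from = as.character(tab[[ia]]),
                         to = as.character(tab[[ib]]))
    ed <- dplyr::filter(ed, !is.na(.data$from), !is.na(.data$to))
    if (nrow(ed) == 0L) stop("empty network file: ", path, call. = FALSE)
  }
  ppi_network(ed)
}

#' Write a network as a canonical edge list
#'
#' The output is a tab-separated two-column file with edges sorted
#' lexicographically (`from < to` within each row), so that
#' `read_network(write_network(net))` round-trips byte-identically.
#'
#' @param net a [ppi_network()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  writeLines(paste(net$edges$from, net$edges$to, sep = "\t"), path)
  invisible(path)
}

#' Largest connected component
#'
#' Restricts a network to its largest connected component, the standard
#' preprocessing step before diffusion-based embeddings (random walks are
#' only well defined on a connected graph). Ties between equally sized
#' components are broken in favour of the lexicographically smallest node
#' set.
#'
#' @param net a [ppi_network()]
#' @return a connected [ppi_network()]
#' @export
largest_connected_component <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  g <- as_igraph(net)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # smallest lexicographic node set among tied components
    reps <- vapply(best, function(k) {
      min(net$nodes[comp$membership == k])
    }, "")
    best <- best[order(reps)][1L]
  }
  keep <- net$nodes[comp$membership == best]
  subset_network(net, keep)
}

#' Induced subnetwork on a node set
#' @param net a [ppi_network()]
#' @param nodes character vector of node identifiers to keep
#' @return a [ppi_network()]
#' @export
subset_network <- function(net, nodes) {
  nodes <- intersect(net$nodes, nodes)
  ed <- dplyr::filter(net$edges, .data$from %in% nodes, .data$to %in% nodes)
  ppi_network(ed, nodes = nodes)
}
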