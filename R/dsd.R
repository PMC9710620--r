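#' Diffusion state of a network
#'
#' For a connected network, the diffusion state of node `u` at walk length
#' `t` is the vector whose j-th entry is the expected number of visits to
#' node `j` by a simple degree-normalised random walk of `t` steps starting
#' at `u`. The start position counts as one visit (the k = 0 term), so
#' `he = sum_{k=0..t} P^k` with `P` the row-normalised adjacency and every
#' row of `he` sums to `t + 1`. This convention makes the t = 0 state the
#' identity matrix; it cancels in all DSD differences for t > 0 and in the
#' converged limit.
#'
#' @param net a connected [ppi_network()] (apply
#'   [largest_connected_component()] first).
#' @param t nonnegative integer walk length.
#' @param lazy if `TRUE`, use the lazy walk (probability 1/2 of staying
#'   put), which converges on bipartite graphs; off by default.
#' @return an object of class `diffusion_state`: list with `he` (matrix,
#'   dimnames = node ids), `t`, `nodes`.
#' @export
diffusion_state <- function(net, t, lazy = FALSE) {
  stopifnot(inherits(net, "ppi_network"))
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t != floor(t)) {
    stop("`t` must be a single nonnegative integer", call. = FALSE)
  }
  P <- transition_matrix(net, lazy = lazy)
  n <- nrow(P)
  he <- diag(n)
  if (t > 0) {
    walk <- diag(n)
    for (k in seq_len(t)) {
      walk <- walk %*% P
      he <- he + walk
    }
  }
  dimnames(he) <- list(net$nodes, net$nodes)
  structure(list(he = he, t = t, nodes = net$nodes),
            class = "diffusion_state")
}

transition_matrix <- function(net, lazy = FALSE) {
  deg <- rowSums(net$adjacency)
  if (any(deg == 0)) {
    iso <- net$nodes[deg == 0][1]
    stop("node '", iso, "' is isolated; run largest_connected_component() ",
         "before computing diffusion states", call. = FALSE)
  }
  P <- net$adjacency / deg
  if (lazy) P <- 0.5 * diag(nrow(P)) + 0.5 * P
  P
}

#' @export
print.diffusion_state <- function(x, ...) {
  cat(sprintf("<diffusion_state> %d nodes, t = %s\n", length(x$nodes),
              format(x$t)))
  invisible(x)
}

#' Converged diffusion state
#'
#' The raw expected-visit matrix grows without bound as the walk length
#' increases (each row sums to t + 1), but the *centered* visit profile
#' converges: subtracting the stationary visit rate leaves the walk's
#' fundamental matrix `Z = solve(I - P + W)` with `W = 1 %*% t(pi)`. Row
#' differences of `Z` equal the limiting row differences of the finite-t
#' states, so `dsd_matrix(converged_state(net))` is exactly the converged
#' DSD, and `Z` is the natural diffusion-state matrix to feed the
#' co-embedding kernel in converged mode.
#'
#' @inheritParams diffusion_state
#' @return a `diffusion_state` whose `he` is the fundamental matrix and
#'   whose `t` is `Inf` (the converged sentinel).
#' @export
converged_state <- function(net, lazy = FALSE) {
  stopifnot(inherits(net, "ppi_network"))
  P <- transition_matrix(net, lazy = lazy)
  n <- nrow(P)
  deg <- rowSums(net$adjacency)
  pi_st <- deg / sum(deg)
  Z <- solve(diag(n) - P + matrix(pi_st, n, n, byrow = TRUE))
  dimnames(Z) <- list(net$nodes, net$nodes)
  structure(list(he = Z, t = Inf, nodes = net$nodes),
            class = "diffusion_state")
}

#' Diffusion state distance matrix
#'
#' The DSD between two nodes is the L1 distance between their diffusion
#' state vectors. DSD is a metric on the nodes of a connected graph
#' (non-negative, symmetric, zero exactly on the diagonal, triangle
#' inequality), and it dampens the otherwise dominant influence of hub
#' nodes on walk-based proximities.
#'
#' @param ds a [diffusion_state()].
#' @return a symmetric matrix of class `dsd_matrix` with zero diagonal,
#'   dimnames = node ids.
#' @export
dsd_matrix <- function(ds) {
  stopifnot(inherits(ds, "diffusion_state"))
  d <- l1_distance_matrix(ds$he)
  dimnames(d) <- list(ds$nodes, ds$nodes)
  class(d) <- c("dsd_matrix", class(d))
  d
}

# pairwise L1 distances between the rows of a matrix
l1_distance_matrix <- function(m) {
  unclass(as.matrix(stats::dist(m, method = "manhattan")))
}

#' Converged diffusion state distance
#'
#' As the walk length grows, the DSD matrix stabilises; this computes the
#' limit. The default is a closed-form linear solve: with stationary
#' distribution `pi` (degree / 2|E|) and `W = 1 pi^T`, the limiting row
#' difference is `(e_u - e_v)^T (I - P + W)^{-1}`, so converged DSD(u, v)
#' is the L1 norm of the corresponding row difference of
#' `Z = (I - P + W)^{-1}`. The `"iterative"` method instead accumulates
#' `he` step by step until the DSD matrix changes by less than `tol`, and
#' exists as the independent check of the solve.
#'
#' @param net a connected [ppi_network()].
#' @param tol convergence tolerance on the maximum entrywise DSD change
#'   between consecutive walk lengths (iterative method).
#' @param method `"analytic"` (closed form) or `"iterative"`.
#' @param max_steps step cap for the iterative method.
#' @param lazy use the lazy walk (see [diffusion_state()]).
#' @return a `dsd_matrix`.
#' @export
converged_dsd <- function(net, tol = 1e-8,
                          method = c("analytic", "iterative"),
                          max_steps = 1e6, lazy = FALSE) {
  stopifnot(inherits(net, "ppi_network"))
  method <- match.arg(method)
  if (method == "analytic") {
    d <- l1_distance_matrix(converged_state(net, lazy = lazy)$he)
  } else {
    P <- transition_matrix(net, lazy = lazy)
    n <- nrow(P)
    he <- diag(n)
    walk <- diag(n)
    d_prev <- l1_distance_matrix(he)
    step <- 0L
    delta <- Inf
    repeat {
      step <- step + 1L
      if (step > max_steps) {
        stop(sprintf(
          "converged_dsd did not converge within %d steps (last delta %.3g)",
          as.integer(max_steps), delta), call. = FALSE)
      }
      walk <- walk %*% P
      he <- he + walk
      d <- l1_distance_matrix(he)
      delta <- max(abs(d - d_prev))
      if (delta < tol) break
      d_prev <- d
    }
  }
  dimnames(d) <- list(net$nodes, net$nodes)
  class(d) <- c("dsd_matrix", class(d))
  d
}

#' Check the metric axioms of a distance matrix
#'
#' Exhaustively verifies non-negativity, symmetry, zero diagonal and the
#' triangle inequality over all ordered triples, within a numerical
#' tolerance.
#'
#' @param d a square distance matrix.
#' @param tol numerical slack.
#' @return `TRUE` if all axioms hold, otherwise `FALSE` with attribute
#'   `"violation"` describing the first failure.
#' @export
is_metric <- function(d, tol = 1e-9) {
  d <- unclass(d)
  fail <- function(msg) structure(FALSE, violation = msg)
  if (any(d < -tol)) return(fail("negative distance"))
  if (max(abs(d - t(d))) > tol) return(fail("asymmetric"))
  if (any(abs(diag(d)) > tol)) return(fail("nonzero diagonal"))
  n <- nrow(d)
  for (k in seq_len(n)) {
    # d[i,j] <= d[i,k] + d[k,j] for all i,j, vectorized per intermediate k
    slack <- outer(d[, k], d[k, ], `+`) - d
    if (min(slack) < -tol) {
      return(fail(sprintf("triangle inequality violated via node %d (%.3g)",
                          k, min(slack))))
    }
  }
  TRUE
}
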