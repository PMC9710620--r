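#' Model-network embedding
#'
#' Factorizes a similarity kernel of the model network into per-node
#' vectors `N` with `N %*% t(N) = kernel`. The default kernel is the
#' symmetrized diffusion-state matrix `(He + t(He)) / 2` with negative
#' eigenvalues clipped to zero (the raw expected-visit matrix is neither
#' symmetric nor positive semi-definite, and the factorization needs real
#' square roots of eigenvalues); a regularized-Laplacian kernel
#' `solve(I + lambda * L)` is available for fidelity with the original
#' co-embedding formulation.
#'
#' @param model_ds a [diffusion_state()] of the model network (kernel
#'   `"diffusion"`), or a [ppi_network()] when `kernel = "rl"`.
#' @param kernel `"diffusion"` (symmetrized He) or `"rl"` (regularized
#'   Laplacian).
#' @param lambda regularization for the `"rl"` kernel.
#' @return an object of class `model_embedding`: list with `n_mat` (the
#'   node vectors, rows = nodes), `kernel`, `nodes`.
#' @export
model_embedding <- function(model_ds, kernel = c("diffusion", "rl"),
                            lambda = 0.05) {
  kernel <- match.arg(kernel)
  if (kernel == "diffusion") {
    stopifnot(inherits(model_ds, "diffusion_state"))
    K <- (model_ds$he + t(model_ds$he)) / 2
    nodes <- model_ds$nodes
  } else {
    stopifnot(inherits(model_ds, "ppi_network"))
    A <- model_ds$adjacency
    L <- diag(rowSums(A)) - A
    K <- solve(diag(nrow(A)) + lambda * L)
    nodes <- model_ds$nodes
  }
  if (max(abs(K)) == 0) stop("all-zero kernel", call. = FALSE)
  eig <- eigen(K, symmetric = TRUE)
  vals <- pmax(eig$values, 0) # negative spectrum clipped to zero
  N <- eig$vectors %*% diag(sqrt(vals), nrow = length(vals))
  rownames(N) <- nodes
  # the kernel actually factorized is the PSD part of K
  K <- eig$vectors %*% (vals * t(eig$vectors))
  K <- (K + t(K)) / 2
  dimnames(K) <- list(nodes, nodes)
  structure(list(n_mat = N, kernel = K, nodes = nodes),
            class = "model_embedding")
}

#' @export
print.model_embedding <- function(x, ...) {
  cat(sprintf("<model_embedding> %d nodes, %d dims\n",
              nrow(x$n_mat), ncol(x$n_mat)))
  invisible(x)
}

# Moore-Penrose pseudoinverse via SVD, relative cutoff on singular values
pseudoinverse <- function(A, rcond = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rcond * max(sv$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' Co-embed a target network into a model network's space
#'
#' Solves the landmark-anchored underdetermined linear system: writing
#' `N_L` for the landmark rows of the model embedding and `T_L` for the
#' landmark rows of the target kernel, the target vectors satisfy
#' `N_L %*% t(C2) = T_L`, and the minimum-norm solution
#' `t(C2) = pinv(N_L) %*% T_L` is taken. Cross-species similarities are
#' then `d12 = N %*% t(C2)` (model rows x target columns). The target
#' kernel receives the same symmetrize-and-treat as the model kernel so
#' that landmark similarities are comparable across the two networks.
#'
#' Note the two neighbour conventions that coexist downstream: `d12` holds
#' *similarities* (cross-species neighbours are ranked descending), while
#' `p_mat` — the pairwise L1 distance matrix of the target diffusion
#' states, i.e. the target DSD matrix — holds *distances* (within-target
#' neighbours are ranked ascending).
#'
#' @param model_emb a [model_embedding()].
#' @param target_ds a [diffusion_state()] of the target network.
#' @param lm a `landmark_set` (see [select_rbh_landmarks()]); every model
#'   protein must exist in the model network and every target protein in
#'   the target network.
#' @return an object of class `coembedding`: list with `c_mat` (target
#'   vectors, rows = target nodes), `d12` (model x target similarity
#'   matrix), `p_mat` (target DSD matrix), `landmarks`, `model_nodes`,
#'   `target_nodes`.
#' @export
coembed_target <- function(model_emb, target_ds, lm) {
  stopifnot(inherits(model_emb, "model_embedding"),
            inherits(target_ds, "diffusion_state"))
  if (nrow(lm) < 1L) stop("at least one landmark required", call. = FALSE)
  missing_m <- setdiff(lm$model, model_emb$nodes)
  if (length(missing_m) > 0L) {
    stop("landmark protein '", missing_m[1],
         "' absent from the model network", call. = FALSE)
  }
  missing_t <- setdiff(lm$target, target_ds$nodes)
  if (length(missing_t) > 0L) {
    stop("landmark protein '", missing_t[1],
         "' absent from the target network", call. = FALSE)
  }
  Tker <- (target_ds$he + t(target_ds$he)) / 2
  dimnames(Tker) <- list(target_ds$nodes, target_ds$nodes)
  N_L <- model_emb$n_mat[lm$model, , drop = FALSE]
  T_L <- Tker[lm$target, , drop = FALSE]
  C2t <- pseudoinverse(N_L) %*% T_L # dims x |V2|
  c_mat <- t(C2t)
  rownames(c_mat) <- target_ds$nodes
  d12 <- model_emb$n_mat %*% C2t
  dimnames(d12) <- list(model_emb$nodes, target_ds$nodes)
  p_mat <- l1_distance_matrix(target_ds$he)
  dimnames(p_mat) <- list(target_ds$nodes, target_ds$nodes)
  structure(list(c_mat = c_mat, d12 = d12, p_mat = p_mat, landmarks = lm,
                 model_nodes = model_emb$nodes,
                 target_nodes = target_ds$nodes),
            class = "coembedding")
}

#' @export
print.coembedding <- function(x, ...) {
  cat(sprintf("<coembedding> %d model x %d target nodes, %d landmarks\n",
              length(x$model_nodes), length(x$target_nodes),
              nrow(x$landmarks)))
  invisible(x)
}

#' One-row summary of a co-embedding
#' @param x a [coembed_target()] result
#' @param ... unused
#' @return one-row tibble
#' @method glance coembedding
#' @export
glance.coembedding <- function(x, ...) {
  tibble::tibble(
    n_model = length(x$model_nodes),
    n_target = length(x$target_nodes),
    n_landmarks = nrow(x$landmarks),
    embed_dim = ncol(x$c_mat)
  )
}

#' Nearest cross-species neighbours of a target node
#'
#' The `c` model-network nodes with the largest co-embedding similarity to
#' a target node, ranked descending; similarity ties are broken
#' lexicographically by model node id.
#'
#' @param ce a [coembedding()][coembed_target()].
#' @param target_node a target node identifier.
#' @param c how many neighbours (0 gives an empty vector).
#' @return character vector of model node ids, best first.
#' @export
cross_neighbors <- function(ce, target_node, c) {
  stopifnot(inherits(ce, "coembedding"))
  if (c < 0) stop("`c` must be nonnegative", call. = FALSE)
  if (!target_node %in% ce$target_nodes) {
    stop("unknown target node '", target_node, "'", call. = FALSE)
  }
  if (c == 0) return(character())
  sims <- ce$d12[, target_node]
  ord <- order(-sims, ce$model_nodes)
  ce$model_nodes[ord][seq_len(min(c, length(ord)))]
}
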