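#' k-nearest-neighbour graph
#'
#' Exact kNN search (self excluded) on an arbitrary coordinate matrix; the
#' sparsification backbone for all transition kernels.
#'
#' @param X coordinate matrix (cells x dims), e.g. joint-PCA scores or
#'   spatial coordinates.
#' @param k neighbours per cell (1 <= k < N).
#' @param basis label recording what the coordinates are.
#' @return Object of class `stt_graph`: `indices` (N x k), `dist` (N x k),
#'   `X`, `basis`, `edges` (two-column matrix of directed i -> j pairs).
#' @export
knn_graph <- function(X, k = 30, basis = "pca") {
  X <- as_dense(X)
  n <- nrow(X)
  if (k < 1 || k >= n)
    stt_error("need 1 <= k < number of cells", "stt_validation_error")
  nn <- RANN::nn2(X, k = k + 1)
  idx <- nn$nn.idx; d <- nn$nn.dists
  # drop the self column (usually first; with duplicates it can wander)
  out_idx <- matrix(0L, n, k); out_d <- matrix(0, n, k)
  for (i in seq_len(n)) {
    sel <- which(idx[i, ] != i)
    if (length(sel) > k) sel <- sel[seq_len(k)]
    if (length(sel) < k) sel <- c(sel, setdiff(seq_len(k + 1), sel))[seq_len(k)]
    out_idx[i, ] <- idx[i, sel]
    out_d[i, ] <- d[i, sel]
  }
  edges <- cbind(i = rep(seq_len(n), each = k), j = as.vector(t(out_idx)))
  structure(list(indices = out_idx, dist = out_d, X = X, basis = basis,
                 edges = edges, n = n, k = k), class = "stt_graph")
}

# union of directed edge sets from several graphs -> shared sparsity pattern
union_edges <- function(...) {
  gs <- list(...)
  e <- unique(do.call(rbind, lapply(gs, function(g) g$edges)))
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# row-normalize edge weights into a sparse row-stochastic matrix
edges_to_stochastic <- function(edges, w, n) {
  rs <- rowsum(w, edges[, 1])
  ri <- as.integer(rownames(rs))
  if (length(ri) < n || any(rs <= 0))
    stt_error("a cell has no outgoing weight; graph too sparse",
              "stt_graph_error")
  w <- as.vector(w) / rs[match(edges[, 1], ri)]
  sparseMatrix(i = edges[, 1], j = edges[, 2], x = as.vector(w),
               dims = c(n, n))
}

#' Velocity (inner-product) transition kernel
#'
#' Transition propensity from cell k to neighbour l:
#' `w_kl = exp(V_u[k,] . (U[l,] - U[k,]) + V_s[k,] . (S[l,] - S[k,]))`,
#' computed on the graph edges only. Each row's exponents are shifted by the
#' row maximum before exponentiation (softmax shift-invariance), then
#' row-normalized.
#'
#' @param V_u,V_s cells x genes attractor-averaged velocity matrices
#'   (see [averaged_velocity()]).
#' @param U,S count matrices restricted to the same genes.
#' @param graph an `stt_graph` or a two-column edge matrix (shared pattern).
#' @return sparse row-stochastic matrix P^v.
#' @export
velocity_kernel <- function(V_u, V_s, U, S, graph) {
  e <- if (inherits(graph, "stt_graph")) graph$edges else graph
  n <- max(nrow(U), max(e))
  i <- e[, 1]; j <- e[, 2]
  val <- rowSums(V_u[i, , drop = FALSE] *
                   (U[j, , drop = FALSE] - U[i, , drop = FALSE])) +
         rowSums(V_s[i, , drop = FALSE] *
                   (S[j, , drop = FALSE] - S[i, , drop = FALSE]))
  rowmax <- tapply(val, i, max)
  val <- exp(val - rowmax[as.character(i)])
  edges_to_stochastic(e, val, n)
}

# adaptive-bandwidth Gaussian affinities on an edge pattern, symmetrized
gaussian_edge_affinity <- function(edges, X, bandwidth) {
  i <- edges[, 1]; j <- edges[, 2]
  d2 <- rowSums((X[i, , drop = FALSE] - X[j, , drop = FALSE])^2)
  a <- exp(-d2 / (bandwidth[i] * bandwidth[j]))
  n <- nrow(X)
  A <- sparseMatrix(i = i, j = j, x = a, dims = c(n, n))
  A <- (A + Matrix::t(A)) / 2  # symmetrize on the union pattern
  A
}

# per-cell bandwidth: median kNN distance, floored at machine scale
adaptive_bandwidth <- function(graph) {
  bw <- apply(graph$dist, 1, stats::median)
  floor_val <- sqrt(.Machine$double.eps)
  if (any(bw <= floor_val)) {
    stt_warn("zero kNN bandwidth for some cells; floored at machine scale")
    bw <- pmax(bw, floor_val)
  }
  bw
}

#' Expression-similarity transition kernel
#'
#' Diffusion-map style Gaussian kernel on expression distances:
#' affinities `exp(-d_kl^2 / (sigma_k sigma_l))` with adaptive per-cell
#' bandwidths (median kNN distance), symmetrized, then Markov
#' (row) normalized.
#'
#' @param graph an `stt_graph` built on expression principal components.
#' @param edges optional shared edge pattern (defaults to the graph's own).
#' @return sparse row-stochastic matrix P^c.
#' @export
similarity_kernel <- function(graph, edges = NULL) {
  if (is.null(edges)) edges <- graph$edges
  bw <- adaptive_bandwidth(graph)
  A <- gaussian_edge_affinity(edges, graph$X, bw)
  sm <- Matrix::summary(A)
  edges_to_stochastic(cbind(sm$i, sm$j), sm$x, nrow(A))
}

#' Spatial transition kernel
#'
#' The same Gaussian construction on physical coordinates, with a single
#' global bandwidth (the median neighbour distance), so spatially close
#' cells are more likely to exchange transitions.
#'
#' @param spatial cells x 2 (or 3) coordinate matrix.
#' @param graph_spatial an `stt_graph` built on those coordinates.
#' @param edges optional shared edge pattern.
#' @return sparse row-stochastic matrix P^s.
#' @export
spatial_kernel <- function(spatial, graph_spatial, edges = NULL) {
  if (is.null(spatial))
    stt_error("no spatial coordinates; run with spatial weight 0 instead",
              "stt_config_error")
  if (is.null(edges)) edges <- graph_spatial$edges
  bw0 <- stats::median(graph_spatial$dist)
  bw0 <- max(bw0, sqrt(.Machine$double.eps))
  bw <- rep(bw0, nrow(spatial))
  A <- gaussian_edge_affinity(edges, as_dense(spatial), bw)
  sm <- Matrix::summary(A)
  edges_to_stochastic(cbind(sm$i, sm$j), sm$x, nrow(A))
}

#' Mix the transition kernels into one cellular random walk
#'
#' `P = w1 P^v + w2 P^c + (1 - w1 - w2) P^s`. Without spatial data the
#' spatial weight is folded into the similarity term:
#' `P = w1 P^v + (1 - w1) P^c`.
#'
#' @param Pv,Pc,Ps row-stochastic component matrices (`Ps` optional).
#' @param w1,w2 nonnegative mixture weights with `w1 + w2 <= 1`.
#' @return Object of class `stt_walk`: `P`, components, weights.
#' @export
combine_kernels <- function(Pv, Pc, Ps = NULL, w1 = 0.5, w2 = 0.3) {
  if (w1 < 0 || w2 < 0 || w1 + w2 > 1 + 1e-12)
    stt_error("need w1, w2 >= 0 and w1 + w2 <= 1", "stt_config_error")
  if (is.null(Ps)) {
    P <- w1 * Pv + (1 - w1) * Pc
    weights <- c(w1 = w1, w2 = 1 - w1)
  } else {
    P <- w1 * Pv + w2 * Pc + (1 - w1 - w2) * Ps
    weights <- c(w1 = w1, w2 = w2)
  }
  check_row_stochastic(P)
  structure(list(P = P, Pv = Pv, Pc = Pc, Ps = Ps, weights = weights),
            class = "stt_walk")
}

check_row_stochastic <- function(P, tol = 1e-10) {
  if (min(P) < 0) stt_error("negative transition probability",
                            "stt_validation_error")
  if (max(abs(Matrix::rowSums(P) - 1)) > tol)
    stt_error("matrix is not row-stochastic within tolerance",
              "stt_validation_error")
  invisible(TRUE)
}

#' @export
print.stt_walk <- function(x, ...) {
  cat(sprintf("<stt_walk> %d cells, weights (%s)\n", nrow(x$P),
              paste(sprintf("%s=%.2f", names(x$weights), x$weights),
                    collapse = ", ")))
  invisible(x)
}

#' Export a sparse kernel in MatrixMarket coordinate format
#'
#' @param P sparse matrix.
#' @param path output `.mtx` path.
#' @export
write_kernel_mtx <- function(P, path) {
  Matrix::writeMM(methods::as(methods::as(P, "CsparseMatrix"), "generalMatrix"),
                  path)
  invisible(path)
}
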