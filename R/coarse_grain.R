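#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector for the eigenvalue closest to 1, normalized to a
#' probability vector, refined by a few power iterations.
#'
#' @param P row-stochastic matrix (dense or sparse).
#' @return numeric vector summing to 1.
#' @export
stationary_distribution <- function(P) {
  P <- as_dense(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v <- v / sum(v)
  for (it in 1:50) v <- as.vector(v %*% P)  # polish
  v / sum(v)
}

# real invariant-subspace basis for the K leading eigenvalues (by modulus),
# first column constant, orthonormal in the eta-weighted inner product
leading_basis <- function(P, K, eta) {
  n <- nrow(P)
  e <- eigen(P)
  ord <- order(-Mod(e$values))
  lam <- e$values[ord]; vec <- e$vectors[, ord, drop = FALSE]
  # a complex-conjugate pair must not be split at the K boundary
  adjusted <- FALSE
  if (K < n && Im(lam[K]) != 0 &&
      Mod(lam[K] - Conj(lam[K + 1])) < 1e-8 * (1 + Mod(lam[K]))) {
    K <- if (K + 1 <= n) K + 1 else K - 1
    adjusted <- TRUE
    stt_warn(sprintf(
      "complex Schur pair straddles the cut; adjusted K to %d", K))
  }
  X <- matrix(0, n, K)
  col <- 1; idx <- 1
  while (col <= K) {
    if (abs(Im(lam[idx])) < 1e-10) {
      X[, col] <- Re(vec[, idx]); col <- col + 1; idx <- idx + 1
    } else {
      X[, col] <- Re(vec[, idx])
      if (col + 1 <= K) X[, col + 1] <- Im(vec[, idx])
      col <- col + 2; idx <- idx + 2
    }
  }
  X[, 1] <- 1  # eigenvalue 1 of a stochastic matrix: constant vector
  # eta-weighted modified Gram-Schmidt
  wip <- function(a, b) sum(eta * a * b)
  for (j in seq_len(K)) {
    v <- X[, j]
    if (j > 1) for (m in seq_len(j - 1)) v <- v - wip(X[, m], v) * X[, m]
    nv <- sqrt(wip(v, v))
    if (nv < 1e-12)
      stt_error("leading invariant subspace is numerically degenerate",
                "stt_decomposition_error")
    X[, j] <- v / nv
  }
  # keep first column exactly constant (its normalized value)
  X[, 1] <- 1 / sqrt(sum(eta))
  list(X = X, K = K, eigenvalues = lam[seq_len(min(n, K + 2))],
       adjusted = adjusted)
}

# inner-simplex initialization: pick K rows of X spanning a simplex
index_search <- function(X) {
  K <- ncol(X); n <- nrow(X)
  ortho <- X
  idx <- integer(K)
  for (j in seq_len(K)) {
    nrm <- rowSums(ortho^2)
    idx[j] <- which.max(nrm)
    v <- ortho[idx[j], ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-14) break
    v <- v / nv
    ortho <- ortho - outer(as.vector(ortho %*% v), v)
  }
  idx
}

# feasibility fill of the rotation matrix (partition of unity + nonnegativity)
fill_A <- function(A, X) {
  K <- ncol(A)
  if (K > 1) {
    A[2:K, 1] <- -rowSums(A[2:K, 2:K, drop = FALSE])
    for (j in seq_len(K))
      A[1, j] <- -min(X[, 2:K, drop = FALSE] %*% A[2:K, j, drop = FALSE])
  }
  s <- sum(A[1, ])
  if (s <= 0) return(NULL)
  A / s
}

# crispness objective to maximize: trace(diag(1/A[1,]) A^T A)
crispness <- function(A) sum(colSums(A^2) / A[1, ])

#' Fuzzy coarse-graining of a cellular random walk (GPCCA)
#'
#' Generalized Perron cluster cluster analysis of a (possibly nonreversible)
#' row-stochastic matrix: a real basis of the K-dimensional leading invariant
#' subspace (eigenvalues sorted by modulus; complex pairs kept together,
#' adjusting K by one with a warning if a pair straddles the cut) is rotated
#' into the probability simplex. The rotation starts from the inner-simplex
#' construction and is refined by maximizing the crispness criterion over the
#' free block of the rotation matrix (Nelder-Mead); if refinement fails to
#' produce a feasible rotation the initialization is kept with a warning.
#' Memberships are clipped to the unit interval and row-renormalized. The coarse-grained
#' K x K chain is the membership-projected walk
#' `P_cg = (rho^T D rho)^{-1} rho^T D P rho` with `D = diag(pi)`,
#' whose stationary distribution equals the aggregated `rho^T pi`.
#'
#' @param walk an `stt_walk` (or a row-stochastic matrix).
#' @param K number of attractors (2 <= K <= N).
#' @param refine logical; run the crispness optimization (default TRUE).
#' @return list with `membership` (class `stt_membership`: `rho`, `entropy`,
#'   `hard`), `chain` (class `stt_chain`: `P_cg`, `pi`), `eigenvalues`, `K`.
#' @export
gpcca <- function(walk, K, refine = TRUE) {
  P <- if (inherits(walk, "stt_walk")) walk$P else walk
  P <- as_dense(P)
  n <- nrow(P)
  if (K < 2 || K > n) stt_error("need 2 <= K <= N", "stt_validation_error")
  pi_dist <- stationary_distribution(P)
  eta <- pmax(pi_dist, 1e-12); eta <- eta / sum(eta)
  lb <- leading_basis(P, K, eta)
  X <- lb$X; K <- lb$K
  idx <- index_search(X)
  A0 <- tryCatch(solve(X[idx, , drop = FALSE]), error = function(e) NULL)
  if (is.null(A0)) A0 <- diag(K)
  A0 <- fill_A(A0, X)
  if (is.null(A0))
    stt_error("inner-simplex initialization failed", "stt_decomposition_error")
  A <- A0
  if (refine && K > 1) {
    obj <- function(par) {
      Af <- A0
      Af[2:K, 2:K] <- matrix(par, K - 1, K - 1)
      Af <- fill_A(Af, X)
      if (is.null(Af) || any(!is.finite(Af)) || any(Af[1, ] <= 0)) return(1e10)
      -crispness(Af)
    }
    opt <- tryCatch(
      suppressWarnings(optim(as.vector(A0[2:K, 2:K]), obj,
                             method = "Nelder-Mead",
                             control = list(maxit = 2000, reltol = 1e-10))),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) && opt$value < -0) {
      Af <- A0
      Af[2:K, 2:K] <- matrix(opt$par, K - 1, K - 1)
      Af <- fill_A(Af, X)
      if (!is.null(Af) && -crispness(Af) <= -crispness(A0)) A <- Af
    } else {
      stt_warn("crispness refinement did not converge; using inner-simplex rotation")
    }
  }
  rho <- X %*% A
  rho[rho < 0] <- 0; rho[rho > 1] <- 1
  rs <- rowSums(rho)
  bad <- rs <= 0
  if (any(bad)) rho[bad, ] <- 1 / K
  rho <- rho / rowSums(rho)
  D <- diag(eta)
  M <- crossprod(rho, D %*% rho)
  Ncg <- crossprod(rho, D %*% P %*% rho)
  P_cg <- solve(M, Ncg)
  P_cg[P_cg < 0 & P_cg > -1e-10] <- 0
  P_cg <- P_cg / rowSums(P_cg)
  pi_cg <- as.vector(crossprod(rho, eta))
  pi_cg <- pi_cg / sum(pi_cg)
  membership <- new_membership(rho)
  chain <- structure(list(P_cg = P_cg, pi = pi_cg), class = "stt_chain")
  list(membership = membership, chain = chain,
       eigenvalues = lb$eigenvalues, K = K)
}

new_membership <- function(rho) {
  structure(list(rho = rho,
                 entropy = membership_entropy(rho),
                 # ties broken toward the lowest attractor index
                 hard = max.col(rho, ties.method = "first")),
            class = "stt_membership")
}

#' Transitional entropy of attractor memberships
#'
#' Shannon entropy per cell, `-sum_c rho ln rho` with the `0 ln 0 = 0`
#' convention; 0 for one-hot rows, `ln K` for uniform rows. Large values flag
#' cells with a high propensity to transition between attractors.
#'
#' @param rho membership matrix (or an `stt_membership`).
#' @return numeric vector of per-cell entropies.
#' @export
membership_entropy <- function(rho) {
  if (inherits(rho, "stt_membership")) rho <- rho$rho
  lr <- ifelse(rho > 0, log(rho), 0)
  -rowSums(rho * lr)
}

#' @export
print.stt_membership <- function(x, ...) {
  cat(sprintf("<stt_membership> %d cells x %d attractors, mean entropy %.3f\n",
              nrow(x$rho), ncol(x$rho), mean(x$entropy)))
  invisible(x)
}

#' @export
print.stt_chain <- function(x, ...) {
  cat(sprintf("<stt_chain> %d attractors\n", nrow(x$P_cg)))
  print(round(x$P_cg, 4))
  invisible(x)
}

#' Attractor-averaged velocity
#'
#' Collapses the transition tensor over the attractor axis with membership
#' weights: `V[k, g] = sum_c rho[k, c] v[k, layer, c, g]`. The spliced layer
#' is attractor-independent by construction, so `V_s` does not depend on rho.
#'
#' @param tensor an `stt_tensor`.
#' @param membership an `stt_membership` (or a rho matrix).
#' @return list with matrices `V_u`, `V_s`.
#' @export
averaged_velocity <- function(tensor, membership) {
  rho <- if (inherits(membership, "stt_membership")) membership$rho
         else membership
  d <- dim(tensor$v)
  if (ncol(rho) != d[3])
    stt_error("membership K does not match tensor", "stt_validation_error")
  V_u <- matrix(0, d[1], d[4]); V_s <- matrix(0, d[1], d[4])
  for (c in seq_len(d[3])) {
    V_u <- V_u + rho[, c] * tensor$v[, 1, c, ]
    V_s <- V_s + rho[, c] * tensor$v[, 2, c, ]
  }
  colnames(V_u) <- colnames(V_s) <- dimnames(tensor$v)[[4]]
  list(V_u = V_u, V_s = V_s)
}
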