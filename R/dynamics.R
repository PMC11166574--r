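#' Dynamical manifold from memberships and an embedding
#'
#' Places each cell at the membership-weighted combination of attractor
#' centres, `y_k = sum_c rho[k, c] mu_c`, where `mu_c` is the
#' membership-weighted mean of the 2-D embedding over attractor c. A
#' K-component full-covariance Gaussian mixture is then fitted to the y_k by
#' expectation-maximization, initialized with weights equal to the
#' coarse-grained stationary distribution, means at the mu_c and covariances
#' from the membership-weighted scatter (eigenvalues floored at
#' `1e-6 * span^2`). The landscape is `phi(y) = -ln P(y)` on a rectangular
#' grid over the bounding box padded by 10%, with the density floored at
#' 1e-12 before the logarithm.
#'
#' @param membership an `stt_membership`.
#' @param embedding cells x 2 coordinates (PCA by default elsewhere).
#' @param chain an `stt_chain` providing the stationary weights.
#' @param grid_n grid resolution per axis.
#' @param em_iter,em_tol EM stopping rule (max sweeps; log-likelihood change).
#' @return Object of class `stt_manifold`: `y`, `mu`, `gmm` (weights, means,
#'   covariances), `grid` (x, y, `phi` matrix), `loglik`.
#' @export
build_manifold <- function(membership, embedding, chain, grid_n = 200,
                           em_iter = 200, em_tol = 1e-8) {
  rho <- membership$rho
  E <- as_dense(embedding)
  if (ncol(E) != 2)
    stt_error("embedding must be cells x 2", "stt_validation_error")
  K <- ncol(rho)
  cs <- colSums(rho)
  mu <- crossprod(rho, E) / cs                     # K x 2 attractor centres
  y <- rho %*% mu                                   # cell positions
  span2 <- max(apply(y, 2, function(v) diff(range(v))))^2
  floor_ev <- max(1e-6 * span2, 1e-12)
  w <- chain$pi
  covs <- array(0, c(2, 2, K))
  for (c in seq_len(K)) {
    d <- sweep(y, 2, mu[c, ])
    Cv <- crossprod(d * rho[, c], d) / cs[c]
    covs[, , c] <- floor_cov(Cv, floor_ev)
  }
  fit <- gmm_em(y, w, mu, covs, floor_ev, em_iter, em_tol)
  # landscape grid, 10% padding
  pad <- 0.1
  rx <- range(y[, 1]); ry <- range(y[, 2])
  rx <- rx + c(-1, 1) * pad * max(diff(rx), 1e-6)
  ry <- ry + c(-1, 1) * pad * max(diff(ry), 1e-6)
  gx <- seq(rx[1], rx[2], length.out = grid_n)
  gy <- seq(ry[1], ry[2], length.out = grid_n)
  pts <- cbind(rep(gx, times = grid_n), rep(gy, each = grid_n))
  dens <- gmm_density(pts, fit$w, fit$mu, fit$covs)
  phi <- matrix(-log(pmax(dens, 1e-12)), grid_n, grid_n)
  structure(list(y = y, mu = mu, gmm = fit,
                 grid = list(x = gx, y = gy, phi = phi),
                 loglik = fit$loglik), class = "stt_manifold")
}

floor_cov <- function(Cv, floor_ev) {
  Cv <- (Cv + t(Cv)) / 2
  e <- eigen(Cv, symmetric = TRUE)
  vals <- pmax(e$values, floor_ev)
  e$vectors %*% diag(vals) %*% t(e$vectors)
}

# density of a 2-D Gaussian mixture at points (m x 2)
gmm_density <- function(pts, w, mu, covs) {
  dens <- numeric(nrow(pts))
  for (c in seq_along(w)) {
    S <- covs[, , c]
    det_s <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
    inv <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2) / det_s
    d <- sweep(pts, 2, mu[c, ])
    q <- d[, 1]^2 * inv[1, 1] + 2 * d[, 1] * d[, 2] * inv[1, 2] +
      d[, 2]^2 * inv[2, 2]
    dens <- dens + w[c] * exp(-q / 2) / (2 * pi * sqrt(det_s))
  }
  dens
}

# plain EM for a K-component 2-D full-covariance mixture with a fully
# specified initialization (deterministic) and covariance eigenvalue floor
gmm_em <- function(y, w, mu, covs, floor_ev, max_iter, tol) {
  n <- nrow(y); K <- length(w)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    comp <- matrix(0, n, K)
    for (c in seq_len(K)) {
      S <- covs[, , c]
      det_s <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
      inv <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2) / det_s
      d <- sweep(y, 2, mu[c, ])
      q <- d[, 1]^2 * inv[1, 1] + 2 * d[, 1] * d[, 2] * inv[1, 2] +
        d[, 2]^2 * inv[2, 2]
      comp[, c] <- w[c] * exp(-q / 2) / (2 * pi * sqrt(det_s))
    }
    tot <- rowSums(comp)
    tot[tot <= 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    z <- comp / tot
    nk <- colSums(z)
    w <- nk / n
    for (c in seq_len(K)) {
      if (nk[c] < 1e-10) next
      mu[c, ] <- colSums(z[, c] * y) / nk[c]
      d <- sweep(y, 2, mu[c, ])
      covs[, , c] <- floor_cov(crossprod(d * z[, c], d) / nk[c], floor_ev)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(w = w, mu = mu, covs = covs, loglik = ll, iterations = it)
}

#' @export
print.stt_manifold <- function(x, ...) {
  cat(sprintf("<stt_manifold> %d cells, %d mixture components\n",
              nrow(x$y), length(x$gmm$w)))
  invisible(x)
}

#' Transition path theory on the coarse-grained chain
#'
#' Computes forward and backward committors (linear solves on the chain and
#' its time reversal), the reactive flux `f_ij = pi_i q-_i P_ij q+_j`, the
#' net flux `f+ = max(f - f^T, 0)`, the total reactive flux out of the
#' source set, and a ranked pathway decomposition by iterative removal of
#' widest (max-bottleneck) paths.
#'
#' @param chain an `stt_chain` (or a row-stochastic matrix, in which case
#'   the stationary distribution is computed).
#' @param source,target disjoint nonempty index sets of attractors.
#' @param max_paths cap on the number of decomposed paths.
#' @return Object of class `stt_tpt`: `q_plus`, `q_minus`, `flux_matrix`
#'   (net), `gross_flux`, `rate` (total reactive flux), `paths` (list of
#'   index sequences), `path_fluxes`, `path_fractions`, `unreachable` flag.
#' @export
transition_paths <- function(chain, source, target, max_paths = 50) {
  if (inherits(chain, "stt_chain")) {
    P <- chain$P_cg; pi_d <- chain$pi
  } else {
    P <- as_dense(chain); pi_d <- stationary_distribution(P)
  }
  n <- nrow(P)
  source <- sort(unique(as.integer(source)))
  target <- sort(unique(as.integer(target)))
  if (!length(source) || !length(target) || length(intersect(source, target)))
    stt_error("source and target must be disjoint nonempty sets",
              "stt_validation_error")
  inter <- setdiff(seq_len(n), c(source, target))
  # forward committor: (I - P)q = 0 on intermediate, q=0 on A, 1 on B
  q_plus <- numeric(n); q_plus[target] <- 1
  if (length(inter)) {
    M <- diag(length(inter)) - P[inter, inter, drop = FALSE]
    b <- rowSums(P[inter, target, drop = FALSE])
    q_plus[inter] <- solve(M, b)
  }
  # backward committor via the time-reversed chain
  Pb <- t(P * pi_d) / pi_d      # Pb[i,j] = pi_j P[j,i] / pi_i
  q_minus <- numeric(n); q_minus[source] <- 1
  if (length(inter)) {
    M <- diag(length(inter)) - Pb[inter, inter, drop = FALSE]
    b <- rowSums(Pb[inter, source, drop = FALSE])
    q_minus[inter] <- solve(M, b)
  }
  f <- (pi_d * q_minus) * P * matrix(q_plus, n, n, byrow = TRUE)
  diag(f) <- 0
  fnet <- pmax(f - t(f), 0)
  total <- sum(f[source, , drop = FALSE])
  unreachable <- total <= .Machine$double.eps
  paths <- list(); path_fluxes <- numeric(0)
  if (!unreachable) {
    Fw <- fnet
    for (rep_i in seq_len(max_paths)) {
      bp <- widest_path(Fw, source, target)
      if (is.null(bp) || bp$capacity <= 1e-15 * total) break
      paths[[length(paths) + 1]] <- bp$path
      path_fluxes <- c(path_fluxes, bp$capacity)
      for (s in seq_len(length(bp$path) - 1))
        Fw[bp$path[s], bp$path[s + 1]] <-
          Fw[bp$path[s], bp$path[s + 1]] - bp$capacity
    }
  }
  net_total <- sum(fnet[source, , drop = FALSE]) -
    sum(fnet[, source, drop = FALSE])
  structure(list(q_plus = q_plus, q_minus = q_minus, flux_matrix = fnet,
                 gross_flux = f, rate = total, net_rate = net_total,
                 paths = paths, path_fluxes = path_fluxes,
                 path_fractions = if (length(path_fluxes) && net_total > 0)
                   path_fluxes / net_total else numeric(0),
                 source = source, target = target,
                 unreachable = unreachable), class = "stt_tpt")
}

# widest (max-bottleneck) path from any source to any target state
widest_path <- function(Fw, source, target) {
  n <- nrow(Fw)
  width <- rep(-Inf, n); width[source] <- Inf
  prev <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which(!visited)[which.max(width[!visited])]
    if (!length(u) || width[u] == -Inf) break
    visited[u] <- TRUE
    for (v in which(Fw[u, ] > 0)) {
      w2 <- min(width[u], Fw[u, v])
      if (w2 > width[v]) { width[v] <- w2; prev[v] <- u }
    }
  }
  reach <- target[width[target] > 0 & is.finite(width[target])]
  if (!length(reach)) return(NULL)
  t_best <- reach[which.max(width[reach])]
  path <- t_best
  while (!path[1] %in% source) path <- c(prev[path[1]], path)
  list(path = path, capacity = width[t_best])
}

#' @export
print.stt_tpt <- function(x, ...) {
  cat(sprintf("<stt_tpt> %d -> %d, rate %.4g\n",
              x$source[1], x$target[1], x$rate))
  for (i in seq_along(x$paths))
    cat(sprintf("  path %s  fraction %.3f\n",
                paste(x$paths[[i]], collapse = " -> "),
                x$path_fractions[i]))
  invisible(x)
}

#' Tidy transition-path decomposition
#'
#' @param x an `stt_tpt`.
#' @param ... unused.
#' @return tibble with one row per decomposed path.
#' @export
tidy.stt_tpt <- function(x, ...) {
  tibble::tibble(
    path = vapply(x$paths, paste, character(1), collapse = "->"),
    flux = x$path_fluxes,
    fraction = x$path_fractions)
}

#' Project the averaged velocity into a 2-D embedding
#'
#' Linear mode multiplies the joint velocity `(V_u, V_s)` by the same PCA
#' loadings as the embedding. Nonlinear mode follows the cosine-kernel
#' projection used for velocity streamlines: cosine similarities between a
#' cell's joint velocity and the joint displacement towards each graph
#' neighbour are softmax-converted to transition probabilities (scale
#' `exp(scale * cos)`), and the arrow is the expected embedded displacement
#' minus the uniform-baseline displacement over the same neighbours.
#' An attractor-restricted mode keeps only cells with membership above
#' `cutoff` in the chosen attractor.
#'
#' @param V_u,V_s velocity matrices (cells x genes).
#' @param U,S count matrices on the same genes (nonlinear mode).
#' @param embedding cells x 2 coordinates.
#' @param graph an `stt_graph` (nonlinear mode).
#' @param mode `"nonlinear"` (cosine kernel) or `"linear"` (loadings).
#' @param loadings 2N_G x 2 PCA rotation (linear mode; rows ordered
#'   unspliced genes then spliced genes).
#' @param scale softmax inverse temperature for the cosine kernel.
#' @param rho,attractor,cutoff optional attractor restriction: arrows only
#'   for cells with `rho[, attractor] > cutoff` (others zero).
#' @return cells x 2 matrix of arrows.
#' @export
project_streamlines <- function(V_u, V_s, embedding = NULL, graph = NULL,
                                mode = c("nonlinear", "linear"),
                                U = NULL, S = NULL, loadings = NULL,
                                scale = 10, rho = NULL, attractor = NULL,
                                cutoff = 0.2) {
  mode <- match.arg(mode)
  V <- cbind(V_u, V_s)
  n <- nrow(V)
  if (mode == "linear") {
    if (is.null(loadings))
      stt_error("linear mode needs PCA loadings", "stt_validation_error")
    arrows <- V %*% loadings[, 1:2, drop = FALSE]
  } else {
    if (is.null(graph) || is.null(embedding) || is.null(U) || is.null(S))
      stt_error("nonlinear mode needs U, S, embedding and graph",
                "stt_validation_error")
    X <- cbind(U, S)
    arrows <- matrix(0, n, 2)
    for (i in seq_len(n)) {
      nb <- graph$indices[i, ]
      dx <- X[nb, , drop = FALSE] -
        matrix(X[i, ], length(nb), ncol(X), byrow = TRUE)
      vi <- V[i, ]
      nv <- sqrt(sum(vi^2))
      de <- embedding[nb, , drop = FALSE] -
        matrix(embedding[i, ], length(nb), 2, byrow = TRUE)
      dn <- sqrt(rowSums(de^2)); dn[dn == 0] <- 1
      de_unit <- de / dn
      if (nv == 0) next  # zero velocity: probabilities equal the baseline
      dnorm_ <- sqrt(rowSums(dx^2)); dnorm_[dnorm_ == 0] <- 1
      cosim <- as.vector(dx %*% vi) / (dnorm_ * nv)
      p <- exp(scale * (cosim - max(cosim)))
      p <- p / sum(p)
      arrows[i, ] <- colSums(p * de_unit) - colMeans(de_unit)
    }
  }
  if (!is.null(rho) && !is.null(attractor)) {
    mask <- rho[, attractor] > cutoff
    arrows[!mask, ] <- 0
  }
  arrows
}
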