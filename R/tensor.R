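#' Attractor-wise kinetic parameter estimation
#'
#' Fits, independently per gene, the multistable splicing model
#' dU/dt = alpha_c - beta U, dS/dt = beta U - S (degradation rate fixed at 1
#' by scale invariance) by minimizing the membership-weighted loss
#' \deqn{J(\alpha_c, \beta, \rho) = \sum_c \sum_k (\alpha_c - \beta U_k)^2
#'   \rho_{k,c} + \sum_k (\beta U_k - S_k)^2 + \lambda \sum_c \alpha_c^2 +
#'   \lambda \beta^2.}
#' The minimizer is analytic: with
#' \eqn{m_c = \sum_k U_k \rho_{k,c} / (\sum_k \rho_{k,c} + \lambda)},
#' \eqn{\alpha_c^* = m_c \beta^*} and
#' \deqn{\beta^* = \frac{\sum_k U_k S_k}{\sum_k U_k^2 + \sum_c \sum_k (U_k -
#'   m_c)^2 \rho_{k,c} + \lambda (1 + \sum_c m_c^2)},}
#' the exact stationary point of J given the regularized \eqn{m_c}
#' (the \eqn{\lambda \sum_c m_c^2} term vanishes at \eqn{\lambda = 0}).
#' With one-hot memberships and \eqn{\lambda = 0} this reduces to the
#' indicator-function form used at initialization.
#'
#' @param U,S cells x genes matrices.
#' @param rho cells x K membership matrix; rows on the probability simplex.
#' @param lam regularization strength lambda (>= 0).
#' @return Object of class `stt_kinetics`: `alpha` (K x genes), `beta`
#'   (per gene), `m` (K x genes), `lambda`, `degenerate` (per-gene flag for
#'   an all-zero denominator, where alpha = beta = 0 is returned).
#' @export
estimate_params <- function(U, S, rho, lam = 0.01) {
  U <- as_dense(U); S <- as_dense(S); rho <- as_dense(rho)
  if (!identical(dim(U), dim(S)) || nrow(rho) != nrow(U))
    stt_error("shape mismatch between U, S and rho", "stt_validation_error")
  if (lam < 0) stt_error("lam must be >= 0", "stt_validation_error")
  if (max(abs(rowSums(rho) - 1)) > 1e-6)
    stt_error("rho rows must sum to 1", "stt_validation_error")
  K <- ncol(rho); G <- ncol(U)
  rs <- colSums(rho)                       # K
  m <- (crossprod(rho, U)) / (rs + lam)    # K x G
  num <- colSums(U * S)                    # G
  dev <- numeric(G)
  for (c in seq_len(K))
    dev <- dev + colSums((U - matrix(m[c, ], nrow(U), G, byrow = TRUE))^2 *
                           rho[, c])
  denom <- colSums(U^2) + dev + lam * (1 + colSums(m^2))
  degenerate <- denom <= 0
  beta <- ifelse(degenerate, 0, num / pmax(denom, .Machine$double.eps))
  if (any(beta < 0)) {  # impossible for nonnegative counts; guard anyway
    stt_warn(sprintf("%d genes produced negative beta; clipped to 0",
                     sum(beta < 0)))
    beta <- pmax(beta, 0)
  }
  alpha <- m * matrix(beta, K, G, byrow = TRUE)
  alpha[, degenerate] <- 0
  gn <- colnames(U)
  if (!is.null(gn)) { colnames(alpha) <- gn; names(beta) <- gn }
  structure(list(alpha = alpha, beta = beta, m = m, lambda = lam,
                 degenerate = degenerate, K = K),
            class = "stt_kinetics")
}

#' @export
print.stt_kinetics <- function(x, ...) {
  cat(sprintf("<stt_kinetics> %d attractors x %d genes (lambda = %g)\n",
              nrow(x$alpha), ncol(x$alpha), x$lambda))
  invisible(x)
}

#' Tidy kinetic parameters
#'
#' @param x an `stt_kinetics`.
#' @param ... unused.
#' @return tibble with one row per gene: `gene`, `beta`, `alpha_1..alpha_K`.
#' @export
tidy.stt_kinetics <- function(x, ...) {
  G <- ncol(x$alpha)
  out <- tibble::tibble(
    gene = if (!is.null(colnames(x$alpha))) colnames(x$alpha)
           else paste0("g", seq_len(G)),
    beta = unname(x$beta))
  for (c in seq_len(nrow(x$alpha))) out[[paste0("alpha_", c)]] <- x$alpha[c, ]
  out
}

#' Build the 4-D transition tensor
#'
#' Assembles v of shape cells x 2 x attractors x genes with layer axis
#' (unspliced, spliced):
#' `v[k, u, c, g] = alpha[c, g] - beta[g] U[k, g]` and
#' `v[k, s, c, g] = beta[g] U[k, g] - S[k, g]`. The spliced layer carries no
#' attractor dependence, so its slices are identical across `c`.
#'
#' @param U,S cells x genes matrices.
#' @param params an `stt_kinetics` estimated on the same genes.
#' @return Object of class `stt_tensor`: `v` (4-D array), `params`.
#' @export
build_tensor <- function(U, S, params) {
  U <- as_dense(U); S <- as_dense(S)
  K <- nrow(params$alpha); G <- ncol(params$alpha)
  if (ncol(U) != G)
    stt_error("tensor genes do not match parameter genes", "stt_validation_error")
  n <- nrow(U)
  bU <- sweep(U, 2, params$beta, `*`)
  v <- array(0, dim = c(n, 2, K, G),
             dimnames = list(NULL, c("u", "s"), NULL, colnames(U)))
  vs <- bU - S
  for (c in seq_len(K)) {
    v[, 1, c, ] <- matrix(params$alpha[c, ], n, G, byrow = TRUE) - bU
    v[, 2, c, ] <- vs
  }
  structure(list(v = v, params = params), class = "stt_tensor")
}

#' @export
print.stt_tensor <- function(x, ...) {
  d <- dim(x$v)
  cat(sprintf("<stt_tensor> %d cells x 2 layers x %d attractors x %d genes\n",
              d[1], d[3], d[4]))
  invisible(x)
}

#' Per-gene loss of the multistable splicing model
#'
#' Evaluates J (see [estimate_params()]) exactly, per gene.
#'
#' @inheritParams estimate_params
#' @param params an `stt_kinetics` (its `lambda` is used for the penalty).
#' @return numeric vector of per-gene losses.
#' @export
tensor_loss <- function(U, S, params, rho) {
  U <- as_dense(U); S <- as_dense(S); rho <- as_dense(rho)
  K <- nrow(params$alpha); G <- ncol(U)
  bU <- sweep(U, 2, params$beta, `*`)
  J <- colSums((bU - S)^2)
  for (c in seq_len(K)) {
    res <- matrix(params$alpha[c, ], nrow(U), G, byrow = TRUE) - bU
    J <- J + colSums(res^2 * rho[, c])
  }
  J + params$lambda * (colSums(params$alpha^2) + params$beta^2)
}

#' Gene multistability scores
#'
#' Scores each gene's goodness of fit to the multistable model as
#' `1 - J / (N_C (Var U + Var S))` (population variances over the evaluated
#' cells). A score of 1 means a perfect fit with positive variance; genes with
#' zero variance in both layers get `-Inf` and are never selected.
#'
#' @inheritParams tensor_loss
#' @param threshold selection threshold; genes with score strictly above it
#'   are selected.
#' @return Object of class `stt_scores`: `score` (per gene), `threshold`,
#'   `selected` (integer indices).
#' @export
multistability_score <- function(U, S, params, rho, threshold = 0.5) {
  U <- as_dense(U); S <- as_dense(S)
  J <- tensor_loss(U, S, params, rho)
  denom <- nrow(U) * (matrixStats_colVars(U) + matrixStats_colVars(S))
  score <- ifelse(denom > 0, 1 - J / denom, -Inf)
  structure(list(score = score, threshold = threshold,
                 selected = which(score > threshold)),
            class = "stt_scores")
}

#' @export
print.stt_scores <- function(x, ...) {
  cat(sprintf("<stt_scores> %d genes, %d above threshold %g\n",
              length(x$score), length(x$selected), x$threshold))
  invisible(x)
}

#' Export kinetic parameters and scores as a delimited table
#'
#' @param params an `stt_kinetics`.
#' @param scores optional `stt_scores` on the same genes.
#' @param path output TSV path.
#' @export
write_kinetics <- function(params, path, scores = NULL) {
  df <- as.data.frame(tidy.stt_kinetics(params))
  if (!is.null(scores)) df$score <- scores$score
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
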