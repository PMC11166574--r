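#' One-hot membership initialization from cluster labels
#'
#' Encodes existing clustering output (biological annotation, spatial
#' segmentation, or community-detection labels) as a crisp membership matrix
#' rho^0; K is the number of categories.
#'
#' @param labels categorical vector (>= 2 nonempty categories).
#' @return An `stt_membership` with one-hot rows.
#' @export
initialize_membership <- function(labels) {
  f <- as.factor(labels)
  if (nlevels(f) < 2)
    stt_error("need >= 2 initial clusters", "stt_config_error")
  if (any(tabulate(f, nlevels(f)) == 0))
    stt_error("every initial category must be nonempty", "stt_config_error")
  rho <- matrix(0, length(f), nlevels(f),
                dimnames = list(NULL, levels(f)))
  rho[cbind(seq_along(f), as.integer(f))] <- 1
  new_membership(rho)
}

# best column permutation of `new` matching `old` (max total correlation);
# exact search, K is always small
match_columns <- function(new, old) {
  K <- ncol(new)
  co <- suppressWarnings(cor(new, old))
  co[!is.finite(co)] <- 0
  perms <- all_perms(K)
  sc <- vapply(perms, function(p) sum(co[cbind(p, seq_len(K))]), numeric(1))
  perms[[which.max(sc)]]
}

all_perms <- function(K) {
  if (K == 1) return(list(1L))
  out <- list()
  for (p in all_perms(K - 1)) for (pos in seq_len(K)) {
    q <- p
    q[q >= pos] <- q[q >= pos] + 1L
    out[[length(out) + 1]] <- c(pos, q)
  }
  out
}

# stratified train/test split: |train| = round(frac * N) exactly,
# strata (hard assignments) represented proportionally in both folds
train_test_split <- function(strata, frac, seed) {
  n <- length(strata)
  n_train <- round(frac * n)
  set.seed(seed)
  train <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    k <- floor(frac * length(idx))
    train <- c(train, sample(idx, k))
  }
  # top up (or trim) to hit round(frac * n) exactly
  if (length(train) < n_train) {
    pool <- setdiff(seq_len(n), train)
    train <- c(train, sample(pool, n_train - length(train)))
  } else if (length(train) > n_train) {
    train <- sample(train, n_train)
  }
  sort(train)
}

#' Fit the spatial transition tensor model
#'
#' The alternating scheme: (1) estimate attractor-wise kinetics on the
#' training fold under the current memberships; (2) score genes for
#' multistability on the held-out fold and keep genes above the threshold;
#' (3) rebuild the tensor and the velocity kernel from the selected genes,
#' mix with the similarity (and spatial) kernels, and re-decompose the
#' random walk with GPCCA to update memberships; (4) stop when the mean
#' absolute membership change (after column matching) falls below `tol`, or
#' after `max_iter` rounds. With `max_iter = 0` the initialization-based
#' state is returned untouched (pure estimation, no refinement).
#'
#' @param ds an [stt_dataset] with `initial_labels` (or pass `labels`).
#' @param K number of attractors; defaults to the number of label categories.
#' @param labels optional categorical vector overriding
#'   `ds$initial_labels`.
#' @param w1,w2 kernel mixture weights (velocity, similarity); without
#'   spatial data the remaining weight folds into the similarity term.
#' @param lambda kinetic regularization strength.
#' @param threshold multistability-score selection threshold.
#' @param min_genes abort if fewer genes pass the threshold (capped at N_G).
#' @param max_iter,tol stopping rule (rounds; mean absolute membership
#'   change).
#' @param n_neighbors,n_pcs expression kNN graph size and PCA rank.
#' @param spatial_neighbors spatial kNN graph size.
#' @param train_frac training fraction for the monitor split.
#' @param seed seed for the train/test split (the only randomness).
#' @param use_spatial use the spatial kernel when coordinates are present.
#' @param refilter `"every"` re-selects genes each round; `"once"` freezes
#'   the selection after the first round.
#' @param callback optional function called with the round state (monitor
#'   hook); returning `FALSE` stops the iteration early.
#' @return Object of class `stt_fit`.
#' @export
stt_fit <- function(ds, K = NULL, labels = NULL, w1 = 0.5, w2 = 0.3,
                    lambda = 0.01, threshold = 0.5, min_genes = 3,
                    max_iter = 20, tol = 1e-3, n_neighbors = 30, n_pcs = 30,
                    spatial_neighbors = 8, train_frac = 0.8, seed = 42,
                    use_spatial = TRUE, refilter = c("every", "once"),
                    callback = NULL) {
  refilter <- match.arg(refilter)
  if (is.null(labels)) labels <- ds$initial_labels
  if (is.null(labels))
    stt_error("no initial labels: supply `labels` or set ds$initial_labels",
              "stt_config_error")
  membership <- initialize_membership(labels)
  if (is.null(K)) K <- ncol(membership$rho)
  if (K != ncol(membership$rho))
    stt_error("K must match the number of initial label categories",
              "stt_config_error")
  keep <- !degenerate_genes(ds)
  U_all <- ds$U[, keep, drop = FALSE]
  S_all <- ds$S[, keep, drop = FALSE]
  n_c <- nrow(U_all); n_g <- ncol(U_all)
  min_genes <- min(min_genes, n_g)

  # static graphs and kernels (expression similarity, optional spatial)
  pc <- joint_pca(ds, n_pcs)
  g_expr <- knn_graph(pc$scores, k = min(n_neighbors, n_c - 1), basis = "pca")
  spatial_on <- use_spatial && !is.null(ds$spatial)
  if (spatial_on) {
    g_sp <- knn_graph(ds$spatial, k = min(spatial_neighbors, n_c - 1),
                      basis = "spatial")
    edges <- union_edges(g_expr, g_sp)
  } else {
    g_sp <- NULL
    edges <- union_edges(g_expr)
  }
  edges <- rbind(edges, edges[, 2:1])           # symmetric shared pattern
  edges <- unique(edges)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  Pc <- similarity_kernel(g_expr, edges)
  Ps <- if (spatial_on) spatial_kernel(ds$spatial, g_sp, edges) else NULL

  selected <- seq_len(n_g)
  log_rows <- list()
  params <- NULL; scores_train <- NULL; scores_test <- NULL
  walk <- NULL; chain <- NULL
  delta <- Inf; converged <- FALSE; round_i <- 0

  repeat {
    if (round_i >= max_iter) break
    round_i <- round_i + 1
    split_idx <- train_test_split(membership$hard, train_frac,
                                  seed + round_i - 1)
    test_idx <- setdiff(seq_len(n_c), split_idx)
    if (!length(test_idx)) test_idx <- split_idx  # tiny-data fallback
    params_all <- estimate_params(U_all[split_idx, , drop = FALSE],
                                  S_all[split_idx, , drop = FALSE],
                                  membership$rho[split_idx, , drop = FALSE],
                                  lambda)
    scores_train <- multistability_score(
      U_all[split_idx, , drop = FALSE], S_all[split_idx, , drop = FALSE],
      params_all, membership$rho[split_idx, , drop = FALSE], threshold)
    scores_test <- multistability_score(
      U_all[test_idx, , drop = FALSE], S_all[test_idx, , drop = FALSE],
      params_all, membership$rho[test_idx, , drop = FALSE], threshold)
    if (refilter == "every" || round_i == 1) {
      selected <- scores_test$selected
      if (length(selected) < min_genes)
        stt_error(sprintf(
          "only %d genes pass the multistability threshold %g (floor %d); lower the threshold",
          length(selected), threshold, min_genes), "stt_monitor_error")
    }
    params <- params_all
    tensor <- build_tensor(U_all[, selected, drop = FALSE],
                           S_all[, selected, drop = FALSE],
                           subset_kinetics(params_all, selected))
    V <- averaged_velocity(tensor, membership)
    Pv <- velocity_kernel(V$V_u, V$V_s,
                          U_all[, selected, drop = FALSE],
                          S_all[, selected, drop = FALSE], edges)
    walk <- combine_kernels(Pv, Pc, Ps, w1 = w1, w2 = w2)
    dec <- gpcca(walk, K)
    rho_new <- dec$membership$rho
    perm <- match_columns(rho_new, membership$rho)
    rho_new <- rho_new[, perm, drop = FALSE]
    Pcg <- dec$chain$P_cg[perm, perm, drop = FALSE]
    chain <- structure(list(P_cg = Pcg, pi = dec$chain$pi[perm]),
                       class = "stt_chain")
    delta <- mean(abs(rho_new - membership$rho))
    membership <- new_membership(rho_new)
    log_rows[[round_i]] <- tibble::tibble(
      round = round_i, n_selected = length(selected),
      train_score_median = stats::median(scores_train$score[is.finite(scores_train$score)]),
      test_score_median = stats::median(scores_test$score[is.finite(scores_test$score)]),
      n_pass_train = length(scores_train$selected),
      n_pass_test = length(scores_test$selected),
      delta_membership = delta)
    if (!is.null(callback)) {
      go <- callback(list(round = round_i, delta = delta,
                          scores_train = scores_train,
                          scores_test = scores_test,
                          membership = membership))
      if (isFALSE(go)) break
    }
    if (delta < tol) { converged <- TRUE; break }
  }

  if (round_i == 0) {
    # max_iter = 0: pure estimation under the initialization
    params <- estimate_params(U_all, S_all, membership$rho, lambda)
    scores_train <- multistability_score(U_all, S_all, params,
                                         membership$rho, threshold)
    scores_test <- scores_train
    selected <- scores_test$selected
  }
  tensor <- build_tensor(U_all[, selected, drop = FALSE],
                         S_all[, selected, drop = FALSE],
                         subset_kinetics(params, selected))
  structure(list(
    membership = membership, params = params, tensor = tensor,
    tensor_counts = list(U = U_all[, selected, drop = FALSE],
                         S = S_all[, selected, drop = FALSE]),
    walk = walk, chain = chain, scores_train = scores_train,
    scores_test = scores_test, selected_genes = selected,
    gene_names = colnames(U_all), kept_genes = which(keep),
    pca = pc, graph = g_expr, edges = edges,
    log = if (length(log_rows)) do.call(rbind, log_rows) else NULL,
    rounds = round_i, delta = delta, converged = converged,
    config = list(K = K, w1 = w1, w2 = w2, lambda = lambda,
                  threshold = threshold, max_iter = max_iter, tol = tol,
                  n_neighbors = n_neighbors, n_pcs = n_pcs,
                  spatial_neighbors = spatial_neighbors,
                  train_frac = train_frac, seed = seed,
                  use_spatial = spatial_on, refilter = refilter)
  ), class = "stt_fit")
}

subset_kinetics <- function(params, idx) {
  structure(list(alpha = params$alpha[, idx, drop = FALSE],
                 beta = params$beta[idx], m = params$m[, idx, drop = FALSE],
                 lambda = params$lambda,
                 degenerate = params$degenerate[idx], K = params$K),
            class = "stt_kinetics")
}

#' @export
print.stt_fit <- function(x, ...) {
  cat(sprintf(
    "<stt_fit> %d cells, K = %d attractors, %d/%d genes selected\n",
    nrow(x$membership$rho), x$config$K, length(x$selected_genes),
    length(x$gene_names)))
  cat(sprintf("  %d rounds, delta = %.2e, %s\n", x$rounds, x$delta,
              if (x$converged) "converged" else "stopped at max_iter"))
  invisible(x)
}

#' Tidy per-cell results of a fit
#'
#' @param x an `stt_fit`.
#' @param ... unused.
#' @return tibble: one row per cell with memberships, entropy and hard
#'   attractor assignment.
#' @export
tidy.stt_fit <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$membership$rho))
  names(out) <- paste0("rho_", seq_len(ncol(x$membership$rho)))
  out$entropy <- x$membership$entropy
  out$attractor <- x$membership$hard
  out
}

#' One-line fit summary
#'
#' @param x an `stt_fit`.
#' @param ... unused.
#' @return one-row tibble: rounds, convergence, selected gene count,
#'   mean entropy.
#' @export
glance.stt_fit <- function(x, ...) {
  tibble::tibble(rounds = x$rounds, converged = x$converged,
                 delta_membership = x$delta,
                 n_selected_genes = length(x$selected_genes),
                 mean_entropy = mean(x$membership$entropy))
}

#' Monitor report of the iteration
#'
#' Per-round table of multistability-score summaries on training and test
#' folds, gene counts passing the threshold, and a recommendation when the
#' threshold excludes everything.
#'
#' @param fit an `stt_fit`.
#' @return tibble (also printed); attribute `recommendation` carries the
#'   monitor's advice.
#' @export
monitor_report <- function(fit) {
  log <- fit$log
  if (is.null(log)) {
    log <- tibble::tibble(round = 0L,
                          n_selected = length(fit$selected_genes),
                          train_score_median = stats::median(fit$scores_train$score),
                          test_score_median = stats::median(fit$scores_test$score),
                          n_pass_train = length(fit$scores_train$selected),
                          n_pass_test = length(fit$scores_test$selected),
                          delta_membership = NA_real_)
  }
  rec <- if (utils::tail(log$n_pass_test, 1) == 0)
    "no genes pass the threshold on the test fold: abort or lower the threshold"
  else "ok"
  attr(log, "recommendation") <- rec
  log
}

#' Write the monitor log as JSON lines
#'
#' @param fit an `stt_fit`.
#' @param path output path; one JSON object per round.
#' @export
write_monitor_log <- function(fit, path) {
  log <- monitor_report(fit)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log)))
    writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE), con)
  invisible(path)
}
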