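# shared fixtures, computed once per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, expr, envir = .fixture_cache)
  .fixture_cache[[key]]
}

toggle_sim <- function() cached("toggle_sim",
  simulate_toggle_switch(n_cells = 2000, seed = 11))

toggle_fit <- function() cached("toggle_fit",
  stt_fit(toggle_sim()$dataset, seed = 42))

emt_sim <- function() cached("emt_sim",
  simulate_emt_circuit(n_cells = 1200, seed = 3))

small_toggle_sim <- function() cached("small_toggle_sim",
  simulate_toggle_switch(n_cells = 400, seed = 2))

# random row-stochastic matrix
rand_stochastic <- function(n, seed) {
  set.seed(seed)
  P <- matrix(runif(n * n), n)
  P / rowSums(P)
}

# metastable two-block chain with coupling delta
metastable_chain <- function(delta, n1 = 20, n2 = 20, seed = 3) {
  set.seed(seed)
  n <- n1 + n2
  P <- matrix(0, n, n)
  P[1:n1, 1:n1] <- runif(n1 * n1)
  P[(n1 + 1):n, (n1 + 1):n] <- runif(n2 * n2)
  P <- P + delta * matrix(runif(n * n), n)
  P / rowSums(P)
}

# vectorized Monte-Carlo forward committor (absorption at B before A)
mc_committor <- function(P, A, B, start, n_walkers = 1e5, max_steps = 10000,
                         seed = 1) {
  set.seed(seed)
  n <- nrow(P)
  state <- rep(start, n_walkers)
  absorbed_B <- logical(n_walkers)
  active <- rep(TRUE, n_walkers)
  cum <- t(apply(P, 1, cumsum))
  for (s in seq_len(max_steps)) {
    if (!any(active)) break
    u <- runif(sum(active))
    cur <- state[active]
    nxt <- integer(length(cur))
    for (st in unique(cur)) {
      m <- cur == st
      nxt[m] <- findInterval(u[m], cum[st, ]) + 1L
    }
    state[active] <- nxt
    hitB <- active & state %in% B
    hitA <- active & state %in% A
    absorbed_B[hitB] <- TRUE
    active[hitB | hitA] <- FALSE
  }
  mean(absorbed_B)
}

# distance of each cell's joint state to the nearest of a set of fixed points
dist_to_fps <- function(ds, fixed_points) {
  X <- cbind(ds$U, ds$S)
  d <- Inf
  for (r in seq_len(nrow(fixed_points)))
    d <- pmin(d, sqrt(rowSums(
      (X - matrix(fixed_points[r, ], nrow(X), ncol(X), byrow = TRUE))^2)))
  d
}

# best label agreement over attractor permutations
perm_accuracy <- function(hard, truth) {
  K <- max(hard, truth)
  perms <- if (K == 2) list(1:2, 2:1) else {
    # small K only
    do.call(c, lapply(seq_len(K), function(i) {
      rest <- setdiff(seq_len(K), i)
      if (length(rest) == 1) return(list(c(i, rest)))
      lapply(list(rest, rev(rest)), function(r) c(i, r))
    }))
  }
  max(vapply(perms, function(p) mean(p[hard] == truth), numeric(1)))
}
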