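test_that("zero velocity gives the uniform distribution over neighbours", {
  set.seed(1)
  n <- 12
  U <- matrix(runif(n * 3), n); S <- matrix(runif(n * 3), n)
  g <- knn_graph(cbind(U, S), k = 4)
  V0 <- matrix(0, n, 3)
  Pv <- velocity_kernel(V0, V0, U, S, g)
  expect_equal(max(abs(Matrix::rowSums(Pv) - 1)), 0, tolerance = 1e-12)
  nz <- as.matrix(Pv)[1, g$indices[1, ]]
  expect_equal(unname(nz), rep(1 / 4, 4))
})

test_that("a single neighbour receives probability 1 regardless of velocity", {
  U <- matrix(c(0, 1, 5), 3, 1); S <- U
  edges <- cbind(1:3, c(2, 1, 2))  # each cell one neighbour
  V <- matrix(c(100, -50, 3), 3, 1)
  Pv <- velocity_kernel(V, V, U, S, edges)
  expect_equal(as.vector(Pv[cbind(1:3, c(2, 1, 2))]), rep(1, 3))
})

test_that("3-cell velocity kernel matches a hand-computed softmax", {
  U <- rbind(c(1, 0), c(0, 1), c(2, 2))
  S <- rbind(c(0, 1), c(1, 0), c(1, 1))
  Vu <- rbind(c(1, -1), c(0, 2), c(0.5, 0.5))
  Vs <- rbind(c(0, 1), c(-1, 0), c(1, 0))
  edges <- cbind(c(1, 1, 2, 2, 3, 3), c(2, 3, 1, 3, 1, 2))
  w <- function(k, l) {
    exp(sum(Vu[k, ] * (U[l, ] - U[k, ])) + sum(Vs[k, ] * (S[l, ] - S[k, ])))
  }
  Pv <- as.matrix(velocity_kernel(Vu, Vs, U, S, edges))
  for (k in 1:3) {
    others <- setdiff(1:3, k)
    denom <- sum(vapply(others, function(l) w(k, l), numeric(1)))
    for (l in others) expect_equal(Pv[k, l], w(k, l) / denom, tolerance = 1e-12)
  }
})

test_that("row-max stabilization handles exponents that would overflow", {
  U <- matrix(c(0, 1000, 2000), 3, 1); S <- U
  V <- matrix(1, 3, 1)
  edges <- cbind(c(1, 1, 2, 2, 3, 3), c(2, 3, 1, 3, 1, 2))
  Pv <- velocity_kernel(V, V, U, S, edges)
  expect_true(all(is.finite(as.matrix(Pv))))
  expect_equal(max(abs(Matrix::rowSums(Pv) - 1)), 0, tolerance = 1e-12)
  expect_gt(Pv[1, 3], 0.99)  # much larger inner product wins
})

test_that("similarity kernel matches a dense Gaussian oracle on 4 cells", {
  X <- rbind(c(0, 0), c(1, 0), c(0, 1.5), c(2, 2))
  g <- knn_graph(X, k = 3, basis = "pca")  # fully connected
  Pc <- as.matrix(similarity_kernel(g))
  # dense oracle with the same median-kNN bandwidths
  D2 <- as.matrix(dist(X))^2
  bw <- apply(matrix(g$dist, 4), 1, median)
  A <- exp(-D2 / outer(bw, bw)); diag(A) <- 0
  A <- (A + t(A)) / 2
  oracle <- A / rowSums(A)
  expect_equal(Pc, oracle, ignore_attr = TRUE, tolerance = 1e-12)
  # equidistant neighbours get equal probability
  Xe <- rbind(c(0, 0), c(1, 0), c(-1, 0))
  ge <- knn_graph(Xe, k = 2)
  Pe <- as.matrix(similarity_kernel(ge))
  expect_equal(Pe[1, 2], Pe[1, 3])
})

test_that("similarity to a receding neighbour decays monotonically", {
  probs <- vapply(c(2, 4, 8, 16), function(far) {
    X <- rbind(c(0, 0), c(1, 0), c(far, 0))
    g <- knn_graph(X, k = 2)
    as.matrix(similarity_kernel(g))[1, 3]
  }, numeric(1))
  expect_true(all(diff(probs) < 0))
})

test_that("spatial kernel: lattice symmetry, dense oracle and bandwidth limit", {
  sp <- cbind(seq_len(8), 0)  # 1-D lattice
  g <- knn_graph(sp, k = 2, basis = "spatial")
  Ps <- as.matrix(spatial_kernel(sp, g))
  expect_equal(Ps[4, 3], 0.5); expect_equal(Ps[4, 5], 0.5)
  expect_error(spatial_kernel(NULL, g), class = "stt_config_error")
  # dense oracle on random points
  set.seed(4)
  sp2 <- matrix(runif(12), 6, 2)
  g2 <- knn_graph(sp2, k = 5, basis = "spatial")
  Ps2 <- as.matrix(spatial_kernel(sp2, g2))
  bw <- median(g2$dist)
  A <- exp(-as.matrix(dist(sp2))^2 / bw^2); diag(A) <- 0
  expect_equal(Ps2, A / rowSums(A), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("kernel mixture is the stated convex combination", {
  set.seed(6)
  n <- 10
  X <- matrix(rnorm(n * 2), n)
  g <- knn_graph(X, k = 3)
  Pc <- similarity_kernel(g)
  U <- matrix(rexp(n * 2), n); S <- matrix(rexp(n * 2), n)
  V <- matrix(rnorm(n * 2), n)
  Pv <- velocity_kernel(V, V, U, S, g)
  Ps <- spatial_kernel(X, g)
  w <- combine_kernels(Pv, Pc, Ps, w1 = 0.5, w2 = 0.3)
  expect_equal(as.matrix(w$P),
               as.matrix(0.5 * Pv + 0.3 * Pc + 0.2 * Ps), tolerance = 1e-14)
  # degenerate mixtures
  expect_equal(as.matrix(combine_kernels(Pv, Pc, Ps, 1, 0)$P), as.matrix(Pv))
  same <- combine_kernels(Pv, Pv, Pv, 1 / 3, 1 / 3)
  expect_equal(as.matrix(same$P), as.matrix(Pv), tolerance = 1e-12)
  # entrywise convexity bound
  lower <- 0.5 * as.matrix(Pv)
  expect_true(all(as.matrix(w$P) >= lower - 1e-14))
  # invalid weights
  expect_error(combine_kernels(Pv, Pc, Ps, 0.8, 0.4), class = "stt_config_error")
  expect_error(combine_kernels(Pv, Pc, Ps, -0.1, 0.4), class = "stt_config_error")
  # spatial fallback folds weight into similarity
  wn <- combine_kernels(Pv, Pc, NULL, w1 = 0.4, w2 = 0.3)
  expect_equal(as.matrix(wn$P), as.matrix(0.4 * Pv + 0.6 * Pc), tolerance = 1e-14)
})

test_that("every kernel is row-stochastic within 1e-10 on random instances", {
  set.seed(123)
  for (rep_i in 1:5) {
    n <- sample(20:60, 1)
    G <- sample(2:5, 1)
    U <- matrix(rexp(n * G), n); S <- matrix(rexp(n * G), n)
    sp <- matrix(runif(n * 2), n)
    g <- knn_graph(cbind(U, S), k = sample(3:8, 1))
    gs <- knn_graph(sp, k = 4, basis = "spatial")
    V <- matrix(rnorm(n * G, sd = 0.5), n)
    Pv <- velocity_kernel(V, V, U, S, g)
    Pc <- similarity_kernel(g)
    Ps <- spatial_kernel(sp, gs)
    P <- combine_kernels(
      velocity_kernel(V, V, U, S, g), Pc, NULL, 0.6, 0.4)$P
    for (M in list(Pv, Pc, Ps, P)) {
      expect_lt(max(abs(Matrix::rowSums(M) - 1)), 1e-10)
      expect_gte(min(M), 0)
    }
  }
})

test_that("one-step expected displacement under the velocity kernel follows the drift", {
  sim <- toggle_sim()
  fit <- toggle_fit()
  ds <- sim$dataset
  X <- cbind(fit$tensor_counts$U, fit$tensor_counts$S)
  disp <- as.matrix(fit$walk$Pv %*% X) - X
  truth <- cbind(ds$velocity_u_true, ds$velocity_s_true)
  away <- dist_to_fps(ds, sim$fixed_points) > 0.3
  cosv <- rowSums(disp * truth) /
    (sqrt(rowSums(disp^2)) * sqrt(rowSums(truth^2)) + 1e-12)
  expect_gt(sum(away), 30)
  expect_gt(mean(cosv[away]), 0.2)   # statistically positive alignment
  expect_gt(mean(cosv[away] > 0), 0.8)
})
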