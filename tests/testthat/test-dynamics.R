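test_that("committors and rate have their closed forms on tiny chains", {
  # 2-state chain
  P2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  t2 <- transition_paths(P2, 1, 2)
  pi2 <- stationary_distribution(P2)
  expect_equal(t2$q_plus, c(0, 1))
  expect_equal(t2$q_minus, c(1, 0))
  expect_equal(t2$rate, pi2[1] * P2[1, 2], tolerance = 1e-12)
  # 3-state linear chain: all flux passes the middle state
  P3 <- matrix(c(0.8, 0.2, 0, 0.3, 0.4, 0.3, 0, 0.2, 0.8), 3, byrow = TRUE)
  t3 <- transition_paths(P3, 1, 3)
  expect_equal(length(t3$paths), 1)
  expect_equal(t3$paths[[1]], c(1, 2, 3))
  expect_equal(t3$path_fractions, 1, tolerance = 1e-10)
  expect_true(all(vapply(t3$paths, function(p) 2 %in% p, logical(1))))
})

test_that("committors match a Monte-Carlo absorption oracle", {
  set.seed(9)
  P <- matrix(runif(25), 5); P <- P / rowSums(P)
  tp <- transition_paths(P, 1, 5)
  for (s in 2:4) {
    mc <- mc_committor(P, 1, 5, s, n_walkers = 1e5, seed = s)
    se <- max(sqrt(mc * (1 - mc) / 1e5), 1e-4)
    expect_lt(abs(tp$q_plus[s] - mc), 3 * se)
  }
})

test_that("reactive flux is conserved and committor residuals are tiny", {
  set.seed(30)
  for (rep_i in 1:4) {
    P <- matrix(runif(25) + diag(5), 5); P <- P / rowSums(P)
    tp <- transition_paths(P, 1, 5)
    fo <- sum(tp$flux_matrix[1, ]) - sum(tp$flux_matrix[, 1])
    fi <- sum(tp$flux_matrix[, 5]) - sum(tp$flux_matrix[5, ])
    expect_lt(abs(fo - fi), 1e-10)
    # committor linear system residual
    inter <- 2:4
    res <- (diag(3) - P[inter, inter]) %*% tp$q_plus[inter] -
      P[inter, 5, drop = FALSE]
    expect_lt(max(abs(res)), 1e-10)
    expect_true(all(tp$q_plus >= -1e-12 & tp$q_plus <= 1 + 1e-12))
    # decomposed fractions are nonnegative and sum to at most 1
    expect_true(all(tp$path_fractions >= 0))
    expect_lte(sum(tp$path_fractions), 1 + 1e-8)
  }
})

test_that("unreachable targets give a flagged zero-flux result", {
  P <- as.matrix(Matrix::bdiag(matrix(c(.5, .5, .5, .5), 2),
                               matrix(c(.5, .5, .5, .5), 2)))
  tp <- transition_paths(P, 1, 3)
  expect_true(tp$unreachable)
  expect_equal(tp$rate, 0)
  expect_length(tp$paths, 0)
  # invalid sets
  expect_error(transition_paths(P, 1, 1), class = "stt_validation_error")
})

test_that("manifold geometry: convex positions, EM means at separated centres, minima of phi", {
  set.seed(44)
  # two well-separated attractor blobs
  n <- 200
  grp <- rep(1:2, each = n / 2)
  emb <- cbind(rnorm(n, mean = c(-4, 4)[grp], sd = 0.4),
               rnorm(n, sd = 0.4))
  rho <- cbind(grp == 1, grp == 2) * 1
  # a lone transitional cell
  rho[1, ] <- c(0.5, 0.5)
  m <- new_membership(rho)
  chain <- structure(list(P_cg = diag(2), pi = c(0.5, 0.5)),
                     class = "stt_chain")
  man <- build_manifold(m, emb, chain, grid_n = 80)
  # one-hot cells sit exactly at their attractor centre
  expect_equal(unname(man$y[2, ]), unname(man$mu[grp[2], ]))
  # half-half cell sits at the midpoint
  expect_equal(unname(man$y[1, ]), unname(colMeans(man$mu)))
  # EM means converge to the centres for separated clusters
  expect_equal(unname(man$gmm$mu), unname(man$mu), tolerance = 0.05)
  # phi has a local minimum at each mixture mean
  gx <- man$grid$x; gy <- man$grid$y; phi <- man$grid$phi
  for (c in 1:2) {
    ix <- which.min(abs(gx - man$gmm$mu[c, 1]))
    iy <- which.min(abs(gy - man$gmm$mu[c, 2]))
    patch <- phi[pmax(ix - 3, 1):pmin(ix + 3, length(gx)),
                 pmax(iy - 3, 1):pmin(iy + 3, length(gy))]
    expect_lte(phi[ix, iy], min(patch) + 1e-9)
  }
  expect_true(all(is.finite(phi)))
})

test_that("manifold handles degenerate single-point attractors via the floor", {
  emb <- rbind(matrix(0, 10, 2), matrix(5, 10, 2))
  rho <- cbind(rep(c(1, 0), each = 10), rep(c(0, 1), each = 10))
  m <- new_membership(rho)
  chain <- structure(list(P_cg = diag(2), pi = c(0.5, 0.5)),
                     class = "stt_chain")
  expect_no_error(man <- build_manifold(m, emb, chain, grid_n = 40))
  expect_true(all(is.finite(man$grid$phi)))
})

test_that("streamline projection: zero velocity, linear identity, permutation invariance", {
  set.seed(3)
  n <- 30
  U <- matrix(rexp(n * 2), n); S <- matrix(rexp(n * 2), n)
  emb <- S  # identity embedding on spliced space
  g <- knn_graph(cbind(U, S), k = 5)
  V0 <- matrix(0, n, 2)
  arr0 <- project_streamlines(V0, V0, embedding = emb, graph = g,
                              U = U, S = S)
  expect_equal(arr0, matrix(0, n, 2))
  # linear mode with identity loadings on the spliced block
  loadings <- rbind(matrix(0, 2, 2), diag(2))
  Vs <- matrix(rnorm(n * 2), n)
  arr_lin <- project_streamlines(V0, Vs, mode = "linear", loadings = loadings)
  expect_equal(arr_lin, Vs)
  # gene-order permutation invariance (nonlinear mode)
  Vu <- matrix(rnorm(n * 2), n)
  arr_a <- project_streamlines(Vu, Vs, embedding = emb, graph = g,
                               U = U, S = S)
  arr_b <- project_streamlines(Vu[, 2:1], Vs[, 2:1], embedding = emb,
                               graph = g, U = U[, 2:1], S = S[, 2:1])
  expect_equal(arr_a, arr_b, tolerance = 1e-12)
  # attractor restriction zeroes low-membership cells
  rho <- matrix(0.5, n, 2); rho[1:5, 1] <- 0.1; rho[1:5, 2] <- 0.9
  arr_c <- project_streamlines(Vu, Vs, embedding = emb, graph = g,
                               U = U, S = S, rho = rho, attractor = 1,
                               cutoff = 0.2)
  expect_equal(arr_c[1:5, ], matrix(0, 5, 2))
  expect_false(all(arr_c[6:10, ] == 0))
})

test_that("averaged-tensor streamlines flow into both attractors; a single-equilibrium fit does not", {
  sim <- toggle_sim()
  fit <- toggle_fit()
  U <- fit$tensor_counts$U; S <- fit$tensor_counts$S
  emb <- fit$pca$scores[, 1:2]
  V <- averaged_velocity(fit$tensor, fit$membership)
  arr_stt <- project_streamlines(V$V_u, V$V_s, embedding = emb,
                                 graph = fit$graph, U = U, S = S)
  # naive single-attractor (standard RNA velocity) comparator
  p1 <- estimate_params(U, S, matrix(1, nrow(U), 1), lam = 0.01)
  t1 <- build_tensor(U, S, p1)
  arr_naive <- project_streamlines(t1$v[, 1, 1, ], t1$v[, 2, 1, ],
                                   embedding = emb, graph = fit$graph,
                                   U = U, S = S)
  div_near <- function(arr, fp_row) {
    d <- dist_to_fps(sim$dataset, rbind(fp_row))
    idx <- which(d < 0.6)
    a1 <- coef(lm(arr[idx, 1] ~ emb[idx, 1] + emb[idx, 2]))
    a2 <- coef(lm(arr[idx, 2] ~ emb[idx, 1] + emb[idx, 2]))
    unname(a1[2] + a2[3])
  }
  for (a in 1:2) {
    expect_lt(div_near(arr_stt, sim$fixed_points[a, ]), 0)   # inward flow
    expect_gt(div_near(arr_naive, sim$fixed_points[a, ]),
              div_near(arr_stt, sim$fixed_points[a, ]))
  }
  # the naive field fails to be a sink at at least one attractor
  expect_true(any(vapply(1:2, function(a)
    div_near(arr_naive, sim$fixed_points[a, ]) >= 0, logical(1))))
})

test_that("attractor-level transition paths run on a fitted EMT model", {
  sim <- emt_sim()
  fit <- cached("emt_fit", stt_fit(sim$dataset, seed = 42))
  # identify E-like and M-like attractors from mean spliced SNAIL1/ZEB1
  hard <- fit$membership$hard
  snail <- sim$dataset$S[, 1]
  e_att <- which.min(tapply(snail, hard, mean))
  m_att <- which.max(tapply(snail, hard, mean))
  tp <- transition_paths(fit$chain, e_att, m_att)
  expect_false(tp$unreachable)
  expect_gte(length(tp$paths), 1)
  expect_true(all(tp$path_fractions >= 0))
  ics <- setdiff(1:3, c(e_att, m_att))
  # the dominant path routes through the intermediate attractor
  expect_true(ics %in% tp$paths[[1]])
})
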