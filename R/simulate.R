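#' Specify a stochastic gene circuit with splicing
#'
#' A circuit couples, for each gene i, unspliced and spliced mRNA through
#' dU_i/dt = f_i(S, signal) - beta_i U_i + sigma_i dW,
#' dS_i/dt = beta_i U_i - gamma_i S_i + sigma_i dZ,
#' where the production rates f depend on the spliced levels of the other
#' genes (gene regulation) and optionally an external signal.
#'
#' @param n_genes number of genes.
#' @param f production function: `f(S, signal)` takes an m x n_genes matrix of
#'   spliced states and returns an m x n_genes matrix of nonnegative rates.
#' @param beta,gamma,sigma per-gene splicing rates, degradation rates and
#'   additive noise amplitudes (each positive, recycled to length `n_genes`;
#'   `sigma` may be 0 for deterministic integration).
#' @param signal_levels optional numeric vector of external signal values the
#'   circuit is meant to be driven with.
#' @return An object of class `stt_circuit`.
#' @export
circuit_spec <- function(n_genes, f, beta = 1, gamma = 1, sigma = 0,
                         signal_levels = NULL) {
  beta <- rep_len(beta, n_genes)
  gamma <- rep_len(gamma, n_genes)
  sigma <- rep_len(sigma, n_genes)
  if (any(beta <= 0) || any(gamma <= 0) || any(sigma < 0))
    stt_error("beta, gamma must be > 0 and sigma >= 0 componentwise",
              "stt_validation_error")
  structure(list(n_genes = n_genes, f = f, beta = beta, gamma = gamma,
                 sigma = sigma, signal_levels = signal_levels),
            class = "stt_circuit")
}

# drift of the full (U, S) system; X is m x 2*n_genes, columns (U..., S...)
circuit_drift <- function(spec, X, signal = 0) {
  ng <- spec$n_genes
  U <- X[, seq_len(ng), drop = FALSE]
  S <- X[, ng + seq_len(ng), drop = FALSE]
  Fv <- spec$f(S, signal)
  cbind(sweep(Fv - sweep(U, 2, spec$beta, `*`), 2, rep(1, ng), `*`),
        sweep(U, 2, spec$beta, `*`) - sweep(S, 2, spec$gamma, `*`))
}

#' Euler-Maruyama integration of a circuit
#'
#' Explicit first-order integration of the splicing SDE; after every step,
#' negative entries are clamped to zero. With `sigma = 0` this is plain
#' explicit Euler and is used for deterministic fixed-point analysis.
#' Vectorized over trajectories: `x0` may be a matrix of initial states
#' (one row per trajectory).
#'
#' @param spec an [circuit_spec()].
#' @param x0 initial state(s): numeric vector of length `2*n_genes`
#'   (U then S) or a matrix with that many columns.
#' @param dt time step (> 0).
#' @param n_steps number of steps.
#' @param seed integer RNG seed (only consumed when any `sigma > 0`).
#' @param signal external signal value passed to the production function.
#' @param save_every if `NULL`, only final states are returned; otherwise
#'   snapshots every `save_every` steps are stacked (trajectory x state x time).
#' @return matrix of final states, or a list with `snapshots` (list of state
#'   matrices) and `times` when `save_every` is set.
#' @export
euler_maruyama <- function(spec, x0, dt, n_steps, seed = 1, signal = 0,
                           save_every = NULL) {
  if (dt <= 0) stt_error("dt must be > 0", "stt_validation_error")
  X <- if (is.matrix(x0)) x0 else matrix(x0, nrow = 1)
  if (ncol(X) != 2 * spec$n_genes)
    stt_error("x0 must have 2*n_genes entries per state", "stt_validation_error")
  if (min(X) < 0) stt_error("x0 must be nonnegative", "stt_validation_error")
  stochastic <- any(spec$sigma > 0)
  if (stochastic) set.seed(seed)
  sig2 <- rep(spec$sigma, 2)  # same amplitude on U and S layers
  m <- nrow(X); d <- ncol(X)
  snaps <- list(); times <- numeric(0)
  sq <- sqrt(dt)
  for (step in seq_len(n_steps)) {
    drift <- circuit_drift(spec, X, signal)
    if (any(!is.finite(drift)))
      stt_error(sprintf("non-finite drift at step %d", step),
                "stt_integration_error")
    X <- X + dt * drift
    if (stochastic)
      X <- X + sq * matrix(rnorm(m * d), m, d) %*% diag(sig2, d)
    X[X < 0] <- 0  # clamp, not reflect
    if (!is.null(save_every) && step %% save_every == 0) {
      snaps[[length(snaps) + 1]] <- X
      times <- c(times, step * dt)
    }
  }
  if (is.null(save_every)) return(X)
  list(snapshots = snaps, times = times, final = X)
}

#' Deterministic fixed-point census
#'
#' Integrates the noise-free circuit from a set of initial conditions until
#' the drift norm is negligible, then merges converged endpoints within a
#' tolerance. Endpoints reached by relaxation are stable fixed points
#' (saddles are not reached from generic initial conditions).
#'
#' @param spec an [circuit_spec()].
#' @param signal external signal value.
#' @param inits optional matrix of initial states; by default a random
#'   Latin-style grid over `[0, hi]^{2 n_genes}` with `n_init` points.
#' @param n_init,hi size and range of the default initial-condition set.
#' @param dt,n_steps integration schedule.
#' @param tol merge tolerance (max-norm) for distinct fixed points.
#' @param seed seed for the default initial-condition draw.
#' @return matrix of stable fixed points (one row each, columns U then S).
#' @export
find_fixed_points <- function(spec, signal = 0, inits = NULL, n_init = 300,
                              hi = 3, dt = 0.05, n_steps = 4000, tol = 0.05,
                              seed = 0) {
  d <- 2 * spec$n_genes
  if (is.null(inits)) {
    set.seed(seed)
    inits <- matrix(runif(n_init * d, 0, hi), n_init, d)
  }
  det_spec <- spec
  det_spec$sigma <- rep(0, spec$n_genes)
  ends <- euler_maruyama(det_spec, inits, dt, n_steps, signal = signal)
  dr <- circuit_drift(det_spec, ends, signal)
  conv <- apply(abs(dr), 1, max) < 1e-4
  ends <- ends[conv, , drop = FALSE]
  if (!nrow(ends)) return(matrix(numeric(0), 0, d))
  fp <- merge_points(ends, tol)
  # drop saddles (reachable from initial conditions on invariant manifolds):
  # a stable fixed point has all Jacobian eigenvalues in the left half-plane
  stable <- apply(fp, 1, function(x) {
    J <- drift_jacobian(det_spec, x, signal)
    max(Re(eigen(J, only.values = TRUE)$values)) < 1e-4
  })
  fp[stable, , drop = FALSE]
}

# central-difference Jacobian of the deterministic drift at one state
drift_jacobian <- function(spec, x, signal = 0, h = 1e-6) {
  d <- length(x)
  J <- matrix(0, d, d)
  for (j in seq_len(d)) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h
    xm[j] <- max(xm[j] - h, 0)
    step <- xp[j] - xm[j]
    J[, j] <- (circuit_drift(spec, matrix(xp, 1), signal) -
                 circuit_drift(spec, matrix(xm, 1), signal)) / step
  }
  J
}

merge_points <- function(pts, tol) {
  keep <- pts[1, , drop = FALSE]
  if (nrow(pts) > 1) for (i in 2:nrow(pts)) {
    dists <- apply(abs(sweep(keep, 2, pts[i, ], `-`)), 1, max)
    if (min(dists) >= tol) keep <- rbind(keep, pts[i, ])
  }
  keep
}

# basin labels: integrate each state noise-free, assign nearest fixed point
basin_labels <- function(spec, X, fixed_points, signal = 0, dt = 0.05,
                         n_steps = 4000) {
  det_spec <- spec
  det_spec$sigma <- rep(0, spec$n_genes)
  ends <- euler_maruyama(det_spec, X, dt, n_steps, signal = signal)
  apply(ends, 1, function(e) {
    which.min(colSums((Matrix::t(fixed_points) - e)^2))
  })
}

hill_inh <- function(x, K, n = 4) 1 / (1 + (x / K)^n)
hill_act <- function(x, K, n = 4) (x / K)^n / (1 + (x / K)^n)

#' Default toggle-switch circuit
#'
#' Two genes under symmetric mutual Hill inhibition with basal production:
#' `f_i = b + a / (1 + (S_j / K)^n)`, `beta = gamma = 1`. The defaults
#' (a = 2, b = 0.1, K = 1, n = 4) give two stable fixed points (each gene
#' dominant in one) separated by a symmetric saddle; bistability is verified
#' by [find_fixed_points()] on construction of a simulation.
#'
#' @param a,b,K,n Hill parameters (activation strength, basal rate,
#'   half-saturation, coefficient).
#' @param beta,gamma,sigma kinetic rates and noise amplitude.
#' @return An `stt_circuit` with 2 genes.
#' @export
toggle_circuit <- function(a = 2, b = 0.1, K = 1, n = 4,
                           beta = 1, gamma = 1, sigma = 0.15) {
  f <- function(S, signal = 0) {
    cbind(b + a * hill_inh(S[, 2], K, n),
          b + a * hill_inh(S[, 1], K, n))
  }
  circuit_spec(2, f, beta = beta, gamma = gamma, sigma = sigma)
}

#' Default seven-gene EMT circuit
#'
#' A cascade of two coupled mutual-inhibition switches driven by an external
#' signal (a TGFB-like input entering the first switch additively), plus
#' marker genes. Genes: SNAIL1, MIR34, ZEB1, MIR200, CDH1, VIM, TWIST1.
#' The SNAIL1/MIR34 switch flips first as the signal rises; ZEB1 activation
#' requires high SNAIL1, so the ZEB1/MIR200 switch flips second. The
#' resulting deterministic structure over the signal: a single epithelial
#' state at signal 0, an epithelial/intermediate bistable band, three
#' coexisting states (E, ICS, M) for signal in the tristable window
#' (about 0.4 to 0.6 at the defaults), and a single mesenchymal state at
#' high signal (>= 0.8).
#'
#' @param sigma per-gene noise amplitude.
#' @param params optional named list overriding the Hill constants
#'   `a1, a2, K21, a3, K13, a4, K14, b, n`.
#' @return An `stt_circuit` with 7 genes and default
#'   `signal_levels = c(0, 0.2, 0.4, 0.5, 0.6, 0.8, 1)`.
#' @export
emt_circuit <- function(sigma = 0.1, params = list()) {
  p <- modifyList(list(a1 = 1.6, a2 = 2, K21 = 1.2, a3 = 2.2, K13 = 2.0,
                       a4 = 2, K14 = 2.6, b = 0.1, n = 4), params)
  f <- function(S, signal = 0) {
    n <- p$n
    cbind(
      p$b + signal + p$a1 * hill_inh(S[, 2], 1, n),                     # SNAIL1
      p$b + p$a2 * hill_inh(S[, 1], p$K21, n) * hill_inh(S[, 3], 1, n), # MIR34
      p$b + p$a3 * hill_inh(S[, 4], 1, n) *
        (0.1 + 0.9 * hill_act(S[, 1], p$K13, n)),                       # ZEB1
      p$b + p$a4 * hill_inh(S[, 3], 1, n) * hill_inh(S[, 1], p$K14, n), # MIR200
      p$b + 2 * hill_inh(S[, 1], 1, n) * hill_inh(S[, 3], 1, n),        # CDH1
      p$b + 2 * hill_act(S[, 3], 1, n),                                 # VIM
      p$b + 0.5 * signal                                                # TWIST1
    )
  }
  circuit_spec(7, f, beta = 1, gamma = 1, sigma = sigma,
               signal_levels = c(0, 0.2, 0.4, 0.5, 0.6, 0.8, 1))
}

emt_gene_names <- c("SNAIL1", "MIR34", "ZEB1", "MIR200", "CDH1", "VIM", "TWIST1")

# sample snapshot cells from noisy trajectories: several trajectories from
# random initial conditions, snapshots at regular intervals after burn-in
sample_snapshots <- function(spec, n_cells, signal, seed, dt = 0.02,
                             burn_steps = 500, every = 50, hi = 3,
                             n_traj = NULL) {
  d <- 2 * spec$n_genes
  if (is.null(n_traj)) n_traj <- max(20, ceiling(n_cells / 20))
  n_snap <- ceiling(n_cells / n_traj)
  set.seed(seed)
  X0 <- matrix(runif(n_traj * d, 0, hi), n_traj, d)
  X0 <- euler_maruyama(spec, X0, dt, burn_steps, seed = seed + 1,
                       signal = signal)
  out <- euler_maruyama(spec, X0, dt, n_snap * every, seed = seed + 2,
                        signal = signal, save_every = every)
  X <- do.call(rbind, out$snapshots)
  X[sample.int(nrow(X), n_cells), , drop = FALSE]
}

#' Simulate the toggle-switch benchmark
#'
#' Generates `n_cells` snapshot cells from noisy toggle-switch trajectories
#' pooled across random initial conditions, with ground-truth velocities
#' (the drift evaluated at each sampled state) and attractor labels (the
#' basin of the deterministic fixed point each cell relaxes to).
#'
#' @param n_cells number of cells (>= 2).
#' @param seed integer seed.
#' @param params optional named list forwarded to [toggle_circuit()].
#' @param dt,burn_steps,every snapshot schedule (step size, burn-in steps,
#'   steps between snapshots).
#' @return list of class `stt_simulation`: `dataset` (an [stt_dataset] with
#'   ground-truth layers and `initial_labels` set to the true basins),
#'   `fixed_points`, `circuit`.
#' @export
simulate_toggle_switch <- function(n_cells = 2000, seed = 1, params = list(),
                                   dt = 0.02, burn_steps = 500, every = 50) {
  if (n_cells < 2) stt_error("n_cells must be >= 2", "stt_validation_error")
  spec <- do.call(toggle_circuit, params)
  fp <- find_fixed_points(spec, n_init = 400, seed = seed)
  if (nrow(fp) < 2)
    stt_error("circuit not bistable under supplied parameters",
              "stt_config_error")
  X <- sample_snapshots(spec, n_cells, signal = 0, seed = seed, dt = dt,
                        burn_steps = burn_steps, every = every)
  ng <- spec$n_genes
  U <- X[, seq_len(ng), drop = FALSE]
  S <- X[, ng + seq_len(ng), drop = FALSE]
  drift <- circuit_drift(spec, X, 0)
  labels <- basin_labels(spec, X, fp)
  ds <- stt_dataset(U, S, gene_names = c("gene_x", "gene_y"),
                    initial_labels = factor(paste0("attractor_", labels)),
                    velocity_u_true = drift[, seq_len(ng), drop = FALSE],
                    velocity_s_true = drift[, ng + seq_len(ng), drop = FALSE])
  structure(list(dataset = ds, fixed_points = fp, circuit = spec,
                 basin = labels), class = "stt_simulation")
}

#' Simulate the seven-gene EMT benchmark
#'
#' Pools snapshot cells across the supplied external-signal levels. Within
#' the tristable signal window the deterministic circuit has three stable
#' states (epithelial, intermediate, mesenchymal); the per-level fixed-point
#' census is returned. Cells are labelled E/ICS/M from the deterministic
#' basin they relax to (SNAIL1-low = E; SNAIL1-high, ZEB1-low = ICS;
#' both high = M).
#'
#' @param n_cells total number of cells (>= 3), split evenly across levels.
#' @param signal_levels external signal values (default from the circuit).
#' @param seed integer seed.
#' @param params optional overrides forwarded to [emt_circuit()].
#' @param check_tristable signal value that must exhibit 3 stable states
#'   (set `NULL` to skip the check).
#' @return list of class `stt_simulation` with `dataset` (per-cell `obs$signal`
#'   records the level), `fixed_points` (list per level), `circuit`.
#' @export
simulate_emt_circuit <- function(n_cells = 2100, signal_levels = NULL,
                                 seed = 1, params = list(),
                                 check_tristable = 0.5) {
  if (n_cells < 3) stt_error("n_cells must be >= 3", "stt_validation_error")
  spec <- do.call(emt_circuit, list(params = params))
  if (is.null(signal_levels)) signal_levels <- spec$signal_levels
  if (!length(signal_levels))
    stt_error("signal_levels must be nonempty", "stt_validation_error")
  if (!is.null(check_tristable)) {
    fp_w <- find_fixed_points(spec, signal = check_tristable, n_init = 300,
                              seed = seed)
    if (nrow(fp_w) != 3)
      stt_error("circuit not tristable at the checked signal level under supplied parameters",
                "stt_config_error")
  }
  per <- diff(round(seq(0, n_cells, length.out = length(signal_levels) + 1)))
  Xs <- list(); sigs <- numeric(0); labs <- character(0)
  fps <- list()
  for (i in seq_along(signal_levels)) {
    s <- signal_levels[i]
    fps[[i]] <- find_fixed_points(spec, signal = s, n_init = 250,
                                  seed = seed + i)
    if (per[i] == 0) next
    X <- sample_snapshots(spec, per[i], signal = s, seed = seed + 100 * i)
    Xs[[length(Xs) + 1]] <- X
    sigs <- c(sigs, rep(s, per[i]))
    b <- basin_labels(spec, X, fps[[i]], signal = s)
    fp <- fps[[i]]
    state_name <- function(row) {
      snail <- fp[row, 7 + 1]; zeb <- fp[row, 7 + 3]  # spliced SNAIL1, ZEB1
      if (snail < 1) "E" else if (zeb < 1) "ICS" else "M"
    }
    labs <- c(labs, vapply(b, state_name, character(1)))
  }
  names(fps) <- as.character(signal_levels)
  X <- do.call(rbind, Xs)
  ng <- spec$n_genes
  drift <- matrix(0, nrow(X), 2 * ng)
  for (s in unique(sigs)) {
    idx <- sigs == s
    drift[idx, ] <- circuit_drift(spec, X[idx, , drop = FALSE], s)
  }
  ds <- stt_dataset(X[, seq_len(ng), drop = FALSE],
                    X[, ng + seq_len(ng), drop = FALSE],
                    gene_names = emt_gene_names,
                    initial_labels = factor(labs),
                    velocity_u_true = drift[, seq_len(ng), drop = FALSE],
                    velocity_s_true = drift[, ng + seq_len(ng), drop = FALSE],
                    obs = data.frame(signal = sigs))
  structure(list(dataset = ds, fixed_points = fps, circuit = spec,
                 basin = labs), class = "stt_simulation")
}

#' @export
print.stt_simulation <- function(x, ...) {
  cat(sprintf("<stt_simulation> %d cells, %d genes\n",
              nrow(x$dataset$U), ncol(x$dataset$U)))
  invisible(x)
}
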