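#' Default configuration
#'
#' One nested list holding every tunable of the pipeline, schema-validated:
#' unknown keys are rejected so typos surface before any compute. Values can
#' be overridden programmatically or loaded from a YAML file.
#'
#' @param overrides named nested list of overrides.
#' @return validated config list of class `stt_config`.
#' @export
stt_config <- function(overrides = list()) {
  defaults <- list(
    seed = 1,
    simulate = list(
      circuit = "toggle", n_cells = 2000, sigma = NULL,
      signal_levels = NULL, dt = 0.02, burn_steps = 500, every = 50),
    kernels = list(
      w1 = 0.5, w2 = 0.3, n_neighbors = 30, n_pcs = 30,
      spatial_neighbors = 8),
    fit = list(
      K = NULL, lambda = 0.01, threshold = 0.5, min_genes = 3,
      max_iter = 20, tol = 1e-3, train_frac = 0.8, refilter = "every",
      use_spatial = TRUE),
    dynamics = list(grid_n = 200, source = 1, target = 2),
    pathways = list(min_overlap = 3, embed = "pca", gmt = NULL)
  )
  cfg <- merge_config(defaults, overrides, path = "")
  structure(cfg, class = c("stt_config", "list"))
}

merge_config <- function(base, over, path) {
  if (!length(over)) return(base)
  if (is.null(names(over)) || any(!nzchar(names(over))))
    stt_error(sprintf("config block '%s' must be named", path),
              "stt_config_error")
  for (nm in names(over)) {
    if (!nm %in% names(base))
      stt_error(sprintf("unknown config key '%s%s'", path, nm),
                "stt_config_error")
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]],
                                 as.list(over[[nm]]), paste0(path, nm, "/"))
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Load a configuration from YAML
#'
#' @param path YAML file whose keys mirror [stt_config()].
#' @return validated config.
#' @export
read_config <- function(path) {
  stt_config(yaml::read_yaml(path))
}

validate_weights <- function(w1, w2) {
  if (w1 < 0 || w2 < 0 || w1 + w2 > 1)
    stt_error(sprintf("kernel weights must satisfy w1, w2 >= 0 and w1 + w2 <= 1 (got w1=%g, w2=%g)",
                      w1, w2), "stt_usage_error")
}

#' Run a pipeline stage
#'
#' Thin orchestration over the package functions; each stage reads/writes
#' HDF5 containers and delimited tables so runs are scriptable and plotting
#' stays separate from compute.
#'
#' * `simulate`: generate a benchmark circuit dataset and write it.
#' * `fit`: read a dataset, run [stt_fit()], write memberships, kinetics and
#'   the coarse-grained chain next to `out`.
#' * `dynamics`: fit + dynamical manifold + transition paths, written as
#'   delimited tables.
#' * `pathways`: fit + pathway tensor-similarity clustering from a GMT file.
#'
#' @param command one of `"simulate"`, `"fit"`, `"dynamics"`, `"pathways"`.
#' @param config an [stt_config()] (or overrides list).
#' @param input input h5 path (ignored by `simulate`).
#' @param out output path stem.
#' @return invisibly, the main result object of the stage.
#' @export
run_pipeline <- function(command = c("simulate", "fit", "dynamics",
                                     "pathways"),
                         config = stt_config(), input = NULL, out = NULL) {
  command <- match.arg(command)
  if (!inherits(config, "stt_config")) config <- stt_config(config)
  validate_weights(config$kernels$w1, config$kernels$w2)
  seed <- config$seed
  if (command == "simulate") {
    sc <- config$simulate
    sim <- if (identical(sc$circuit, "toggle")) {
      simulate_toggle_switch(n_cells = sc$n_cells, seed = seed,
                             dt = sc$dt, burn_steps = sc$burn_steps,
                             every = sc$every)
    } else if (identical(sc$circuit, "emt")) {
      simulate_emt_circuit(n_cells = sc$n_cells,
                           signal_levels = sc$signal_levels, seed = seed)
    } else stt_error("simulate$circuit must be 'toggle' or 'emt'",
                     "stt_usage_error")
    if (!is.null(out)) write_dataset(sim$dataset, out)
    return(invisible(sim))
  }
  ds <- read_dataset(input)
  fit <- stt_fit(ds, K = config$fit$K,
                 w1 = config$kernels$w1, w2 = config$kernels$w2,
                 lambda = config$fit$lambda, threshold = config$fit$threshold,
                 min_genes = config$fit$min_genes,
                 max_iter = config$fit$max_iter, tol = config$fit$tol,
                 n_neighbors = config$kernels$n_neighbors,
                 n_pcs = config$kernels$n_pcs,
                 spatial_neighbors = config$kernels$spatial_neighbors,
                 train_frac = config$fit$train_frac, seed = seed,
                 use_spatial = config$fit$use_spatial,
                 refilter = config$fit$refilter)
  if (!is.null(out)) {
    write_membership(fit$membership, paste0(out, "_membership.tsv"))
    write_kinetics(fit$params, paste0(out, "_kinetics.tsv"),
                   scores = fit$scores_test)
    write.table(fit$chain$P_cg, paste0(out, "_pcg.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    write_monitor_log(fit, paste0(out, "_monitor.jsonl"))
  }
  if (command == "fit") return(invisible(fit))
  if (command == "dynamics") {
    emb <- fit$pca$scores[, 1:2, drop = FALSE]
    man <- build_manifold(fit$membership, emb, fit$chain,
                          grid_n = config$dynamics$grid_n)
    tpt <- transition_paths(fit$chain, config$dynamics$source,
                            config$dynamics$target)
    if (!is.null(out)) {
      write.table(cbind(man$y, attractor = fit$membership$hard),
                  paste0(out, "_manifold_positions.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(as.data.frame(tidy.stt_tpt(tpt)),
                  paste0(out, "_paths.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    return(invisible(list(fit = fit, manifold = man, tpt = tpt)))
  }
  # pathways
  pc <- config$pathways
  if (is.null(pc$gmt))
    stt_error("pathways stage needs config$pathways$gmt", "stt_usage_error")
  gs <- read_gmt(pc$gmt)
  pw <- pathway_similarity_and_cluster(fit, gs, min_overlap = pc$min_overlap,
                                       embed = pc$embed, seed = seed)
  if (!is.null(out)) {
    write.table(pw$corr, paste0(out, "_pathway_corr.tsv"), sep = "\t",
                quote = FALSE)
    write.table(as.data.frame(tidy.stt_pathways(pw)),
                paste0(out, "_pathway_clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(list(fit = fit, pathways = pw))
}
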