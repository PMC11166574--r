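#' Joint unspliced/spliced expression dataset
#'
#' The universal input container: a cells-by-genes matrix of unspliced (U)
#' counts, a matching matrix of spliced (S) counts, and optional per-cell
#' spatial coordinates, initial cluster labels and (for simulated data)
#' ground-truth velocity layers. Both dense and `Matrix` sparse inputs are
#' accepted; all downstream operations coerce locally as needed.
#'
#' @param U cells x genes matrix of unspliced counts (nonnegative, finite).
#' @param S cells x genes matrix of spliced counts, same shape as `U`.
#' @param gene_names optional character vector of gene identifiers.
#' @param cell_ids optional character vector of cell identifiers.
#' @param spatial optional cells x 2 (or 3) matrix of physical coordinates.
#' @param initial_labels optional per-cell categorical vector used to
#'   initialize attractor memberships (at least 2 distinct values needed
#'   downstream).
#' @param velocity_u_true,velocity_s_true optional ground-truth velocity
#'   layers (simulated data only).
#' @param obs optional data.frame of extra per-cell annotations.
#'
#' @return An object of class `stt_dataset`.
#' @export
stt_dataset <- function(U, S, gene_names = NULL, cell_ids = NULL,
                        spatial = NULL, initial_labels = NULL,
                        velocity_u_true = NULL, velocity_s_true = NULL,
                        obs = NULL) {
  U <- as_dense(U)
  S <- as_dense(S)
  if (!identical(dim(U), dim(S))) {
    stt_error(sprintf(
      "U and S must have identical shape; got %s vs %s",
      paste(dim(U), collapse = "x"), paste(dim(S), collapse = "x")),
      "stt_validation_error")
  }
  if (any(!is.finite(U)) || any(!is.finite(S)))
    stt_error("U and S must be finite", "stt_validation_error")
  if (min(U) < 0 || min(S) < 0)
    stt_error("U and S must be nonnegative", "stt_validation_error")
  n_c <- nrow(U); n_g <- ncol(U)
  if (is.null(gene_names)) gene_names <- colnames(U)
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(n_g))
  if (is.null(cell_ids)) cell_ids <- rownames(U)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n_c))
  if (!is.null(spatial)) {
    spatial <- as.matrix(spatial)
    if (nrow(spatial) != n_c)
      stt_error(sprintf("spatial has %d rows but dataset has %d cells",
                        nrow(spatial), n_c), "stt_validation_error")
  }
  if (!is.null(initial_labels)) {
    if (length(initial_labels) != n_c)
      stt_error("initial_labels length must equal number of cells",
                "stt_validation_error")
    initial_labels <- as.factor(initial_labels)
  }
  for (v in list(velocity_u_true, velocity_s_true)) {
    if (!is.null(v) && !identical(dim(as_dense(v)), dim(U)))
      stt_error("ground-truth velocity layers must match U/S shape",
                "stt_validation_error")
  }
  dimnames(U) <- dimnames(S) <- list(cell_ids, gene_names)
  structure(list(
    U = U, S = S, gene_names = gene_names, cell_ids = cell_ids,
    spatial = spatial, initial_labels = initial_labels,
    velocity_u_true = if (is.null(velocity_u_true)) NULL else as_dense(velocity_u_true),
    velocity_s_true = if (is.null(velocity_s_true)) NULL else as_dense(velocity_s_true),
    obs = obs
  ), class = "stt_dataset")
}

as_dense <- function(x) {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' @export
print.stt_dataset <- function(x, ...) {
  cat(sprintf("<stt_dataset> %d cells x %d genes\n", nrow(x$U), ncol(x$U)))
  if (!is.null(x$spatial))
    cat(sprintf("  spatial: %d-D coordinates\n", ncol(x$spatial)))
  if (!is.null(x$initial_labels))
    cat(sprintf("  initial_labels: %d categories\n", nlevels(x$initial_labels)))
  if (!is.null(x$velocity_u_true)) cat("  ground-truth velocity layers present\n")
  invisible(x)
}

#' @export
dim.stt_dataset <- function(x) dim(x$U)

#' Genes with zero variance in both layers
#'
#' Flags genes whose unspliced and spliced counts are both constant across
#' cells. Such genes have an undefined multistability score and are excluded
#' from kinetic estimation.
#'
#' @param ds an [stt_dataset].
#' @return logical vector, `TRUE` for degenerate genes.
#' @export
degenerate_genes <- function(ds) {
  vu <- matrixStats_colVars(ds$U)
  vs <- matrixStats_colVars(ds$S)
  unname((vu + vs) <= 0)
}

# population column variances without extra deps
matrixStats_colVars <- function(m) {
  mu <- colMeans(m)
  colMeans(m^2) - mu^2
}

#' Write a dataset to an annotated HDF5 container
#'
#' Stores the dataset in an h5ad-style layout: `layers/unspliced`,
#' `layers/spliced` (plus ground-truth velocity layers when present),
#' per-cell annotations under `obs/`, spatial coordinates under
#' `obsm/X_spatial`, and gene identifiers under `var/_index`.
#' [read_dataset()] inverts it exactly.
#'
#' @param ds an [stt_dataset].
#' @param path output file path (overwritten if present).
#' @export
write_dataset <- function(ds, path) {
  if (file.exists(path)) unlink(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (isFALSE(ok)) stt_error(sprintf("cannot write '%s'", path), "stt_io_error")
  rhdf5::h5createGroup(path, "layers")
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5createGroup(path, "obsm")
  rhdf5::h5createGroup(path, "var")
  rhdf5::h5write(ds$U, path, "layers/unspliced")
  rhdf5::h5write(ds$S, path, "layers/spliced")
  if (!is.null(ds$velocity_u_true)) {
    rhdf5::h5write(ds$velocity_u_true, path, "layers/velocity_u_true")
    rhdf5::h5write(ds$velocity_s_true, path, "layers/velocity_s_true")
  }
  rhdf5::h5write(ds$cell_ids, path, "obs/_index")
  rhdf5::h5write(ds$gene_names, path, "var/_index")
  if (!is.null(ds$initial_labels))
    rhdf5::h5write(as.character(ds$initial_labels), path, "obs/initial_label")
  if (!is.null(ds$obs))
    for (cn in colnames(ds$obs))
      rhdf5::h5write(ds$obs[[cn]], path, paste0("obs/", cn))
  if (!is.null(ds$spatial))
    rhdf5::h5write(ds$spatial, path, "obsm/X_spatial")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a dataset from an annotated HDF5 container
#'
#' @param path file written by [write_dataset()] (or any HDF5 file using the
#'   same layer layout).
#' @param layer_names length-2 character vector naming the unspliced and
#'   spliced layers.
#' @param label_key optional name of a per-cell annotation under `obs/` to use
#'   as initial labels.
#' @param spatial_key optional name of a per-cell matrix under `obsm/`.
#' @return An [stt_dataset].
#' @export
read_dataset <- function(path, layer_names = c("unspliced", "spliced"),
                         label_key = "initial_label",
                         spatial_key = "X_spatial") {
  if (!file.exists(path))
    stt_error(sprintf("file '%s' does not exist", path), "stt_io_error")
  contents <- rhdf5::h5ls(path)
  avail <- file.path(contents$group, contents$name)
  avail <- sub("^/", "", sub("^//", "", avail))
  need <- paste0("layers/", layer_names)
  for (nm in need) {
    if (!nm %in% avail)
      stt_error(sprintf("layer '%s' not found in '%s'",
                        sub("layers/", "", nm), path), "stt_format_error")
  }
  U <- rhdf5::h5read(path, need[1])
  S <- rhdf5::h5read(path, need[2])
  if (!identical(dim(U), dim(S)))
    stt_error(sprintf("layer shapes differ: %s vs %s",
                      paste(dim(U), collapse = "x"),
                      paste(dim(S), collapse = "x")), "stt_validation_error")
  get_opt <- function(key) {
    if (!is.null(key) && key %in% avail) rhdf5::h5read(path, key) else NULL
  }
  labels <- get_opt(if (is.null(label_key)) NULL else paste0("obs/", label_key))
  spatial <- get_opt(if (is.null(spatial_key)) NULL else paste0("obsm/", spatial_key))
  vu <- get_opt("layers/velocity_u_true")
  vs <- get_opt("layers/velocity_s_true")
  cell_ids <- get_opt("obs/_index")
  gene_names <- get_opt("var/_index")
  obs_cols <- setdiff(contents$name[contents$group == "/obs"],
                      c("_index", if (!is.null(label_key)) label_key))
  obs <- NULL
  if (length(obs_cols)) {
    obs <- as.data.frame(lapply(obs_cols, function(cn)
      as.vector(rhdf5::h5read(path, paste0("obs/", cn)))))
    names(obs) <- obs_cols
  }
  rhdf5::h5closeAll()
  stt_dataset(U, S,
              gene_names = as.character(gene_names),
              cell_ids = as.character(cell_ids),
              spatial = spatial,
              initial_labels = if (is.null(labels)) NULL else as.factor(labels),
              velocity_u_true = vu, velocity_s_true = vs, obs = obs)
}

#' Principal components of the joint (U, S) state
#'
#' Computes centred principal components of the concatenated
#' `[U, S]` matrix (the joint state in R^{2 N_G}); the basis for kNN graphs,
#' moment smoothing and the default 2-D embedding.
#'
#' @param ds an [stt_dataset].
#' @param n_pcs number of components to keep (capped at the data rank).
#' @return list with `scores` (cells x n_pcs), `rotation` (2 N_G x n_pcs)
#'   and `center`.
#' @export
joint_pca <- function(ds, n_pcs = 30) {
  X <- cbind(ds$U, ds$S)
  n_pcs <- min(n_pcs, ncol(X), nrow(X) - 1)
  p <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pcs)
  list(scores = p$x, rotation = p$rotation, center = p$center)
}

#' kNN moment smoothing of the count layers
#'
#' Optional preprocessing: replaces each cell's U and S rows by the average
#' over its `n_neighbors` nearest neighbours (self included), neighbours
#' found in joint-PCA space. Off by default throughout the package; provided
#' for noisy real data.
#'
#' @param ds an [stt_dataset].
#' @param n_neighbors neighbourhood size including the cell itself
#'   (`n_neighbors = 1` is the identity transform).
#' @param n_pcs PCA dimensionality for the neighbour search.
#' @return A new [stt_dataset] with smoothed `U`, `S`.
#' @export
smooth_moments <- function(ds, n_neighbors = 30, n_pcs = 30) {
  n_c <- nrow(ds$U)
  if (n_neighbors < 1 || n_neighbors >= n_c + 1)
    stt_error("need 1 <= n_neighbors <= N_C", "stt_validation_error")
  if (n_neighbors == 1) return(ds)
  pc <- joint_pca(ds, n_pcs)
  nn <- RANN::nn2(pc$scores, k = n_neighbors)$nn.idx
  Us <- ds$U; Ss <- ds$S
  for (i in seq_len(n_c)) {
    Us[i, ] <- colMeans(ds$U[nn[i, ], , drop = FALSE])
    Ss[i, ] <- colMeans(ds$S[nn[i, ], , drop = FALSE])
  }
  out <- ds
  out$U <- Us; out$S <- Ss
  out
}

#' Export per-cell results as delimited text
#'
#' Writes memberships, entropy and hard assignments to a TSV file.
#'
#' @param membership an `stt_membership` (see [gpcca()]).
#' @param path output path.
#' @export
write_membership <- function(membership, path) {
  k <- ncol(membership$rho)
  df <- data.frame(membership$rho)
  names(df) <- paste0("rho_", seq_len(k))
  df$entropy <- membership$entropy
  df$attractor <- membership$hard
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
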