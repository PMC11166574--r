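#' Read gene sets from a GMT file
#'
#' Standard tab-delimited GMT: one gene set per line, `name<TAB>description`
#' followed by gene symbols.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path))
    stt_error(sprintf("file '%s' does not exist", path), "stt_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    genes <- parts[-(1:2)]
    genes[nzchar(genes)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Cosine-kernel velocity graph restricted to a gene set
#'
#' For each directed graph edge (k, l): the cosine similarity between cell
#' k's joint velocity `(V_u, V_s)` and the joint displacement
#' `(U_l - U_k, S_l - S_k)`, both restricted to the gene set. With the full
#' gene set this is the global cosine velocity graph.
#'
#' @param V_u,V_s averaged-velocity matrices (cells x genes).
#' @param U,S count matrices on the same genes.
#' @param gene_idx integer (or logical) index of genes to keep.
#' @param edges two-column directed edge matrix (shared across pathways).
#' @return numeric vector of per-edge cosines (0 where either factor has
#'   zero norm).
#' @export
pathway_velocity_graph <- function(V_u, V_s, U, S, gene_idx, edges) {
  i <- edges[, 1]; j <- edges[, 2]
  V <- cbind(V_u[, gene_idx, drop = FALSE], V_s[, gene_idx, drop = FALSE])
  Ug <- U[, gene_idx, drop = FALSE]; Sg <- S[, gene_idx, drop = FALSE]
  dU <- Ug[j, , drop = FALSE] - Ug[i, , drop = FALSE]
  dS <- Sg[j, , drop = FALSE] - Sg[i, , drop = FALSE]
  D <- cbind(dU, dS)
  Vi <- V[i, , drop = FALSE]
  num <- rowSums(Vi * D)
  den <- sqrt(rowSums(Vi^2)) * sqrt(rowSums(D^2))
  ifelse(den > 0, num / den, 0)
}

#' Pathway-level tensor similarity and clustering
#'
#' For every gene set with at least `min_overlap` genes among the selected
#' multistability genes, computes the gene-set-restricted cosine velocity
#' graph on one shared edge ordering, then the pathway-by-pathway Pearson
#' correlation of the flattened graphs, a 2-D embedding of the correlation
#' matrix's principal components (UMAP when available and requested, PCA
#' otherwise), and k-means clustering with k chosen by maximal mean
#' silhouette over `k = 2 .. min(10, n_pathways - 1)`.
#'
#' @param fit an `stt_fit`.
#' @param gene_sets named list of gene symbol vectors (see [read_gmt()]).
#' @param min_overlap minimum genes shared with the selected genes.
#' @param embed `"pca"` (deterministic default) or `"umap"`.
#' @param seed seed for the embedding and k-means.
#' @return Object of class `stt_pathways`: `pathway_names`, `gene_overlap`,
#'   `velocity_graphs` (edges x pathways matrix), `corr`, `embedding2d`,
#'   `cluster_labels`, `chosen_k`, `skipped`.
#' @export
pathway_similarity_and_cluster <- function(fit, gene_sets, min_overlap = 3,
                                           embed = c("pca", "umap"),
                                           seed = 0) {
  embed <- match.arg(embed)
  sel_names <- fit$gene_names[fit$selected_genes]
  overlaps <- lapply(gene_sets, function(gs)
    which(sel_names %in% gs))
  pass <- vapply(overlaps, length, integer(1)) >= min_overlap
  skipped <- names(gene_sets)[!pass]
  if (sum(pass) < 3)
    stt_error(sprintf(
      "only %d pathways have >= %d selected genes (need >= 3); overlaps: %s",
      sum(pass), min_overlap,
      paste(sprintf("%s=%d", names(overlaps), lengths(overlaps)),
            collapse = ", ")), "stt_analysis_error")
  keep_names <- names(gene_sets)[pass]
  tensor <- fit$tensor
  V <- averaged_velocity(tensor, fit$membership)
  kept <- fit$kept_genes  # columns of ds used in the fit
  Usel <- NULL
  # selected-gene count matrices are carried by the tensor's provenance
  edges <- fit$edges
  graphs <- vapply(keep_names, function(nm) {
    gi <- overlaps[[nm]]
    pathway_velocity_graph(V$V_u, V$V_s, fit$tensor_counts$U,
                           fit$tensor_counts$S, gi, edges)
  }, numeric(nrow(edges)))
  corr <- suppressWarnings(cor(graphs))
  corr[!is.finite(corr)] <- 0
  diag(corr) <- 1
  pcs <- prcomp(corr, center = TRUE,
                rank. = min(10, ncol(corr) - 1))$x
  if (embed == "umap" && requireNamespace("uwot", quietly = TRUE)) {
    set.seed(seed)
    emb <- uwot::umap(pcs, n_neighbors = max(2, min(5, nrow(pcs) - 1)),
                      n_components = 2)
  } else {
    emb <- pcs[, 1:2, drop = FALSE]
  }
  n_p <- nrow(emb)
  n_distinct <- nrow(unique(round(emb, 10)))
  if (n_distinct < 2) {
    # all pathway graphs coincide: a single trivial cluster
    chosen_k <- 1L
    cl <- rep(1L, n_p)
    sil <- numeric(0); ks <- integer(0)
  } else {
    ks <- 2:max(2, min(10, n_p - 1, n_distinct))
    sil <- vapply(ks, function(k) {
      set.seed(seed + k)
      cl <- kmeans(emb, centers = k, nstart = 10)$cluster
      mean(cluster::silhouette(cl, stats::dist(emb))[, 3])
    }, numeric(1))
    chosen_k <- ks[which.max(sil)]
    set.seed(seed + chosen_k)
    cl <- kmeans(emb, centers = chosen_k, nstart = 10)$cluster
  }
  structure(list(pathway_names = keep_names,
                 gene_overlap = overlaps[pass],
                 velocity_graphs = graphs, corr = corr,
                 embedding2d = emb, cluster_labels = cl,
                 chosen_k = chosen_k, silhouette = setNames(sil, ks),
                 skipped = skipped), class = "stt_pathways")
}

#' @export
print.stt_pathways <- function(x, ...) {
  cat(sprintf("<stt_pathways> %d pathways in %d clusters (k by silhouette)\n",
              length(x$pathway_names), x$chosen_k))
  invisible(x)
}

#' Tidy pathway clustering results
#'
#' @param x an `stt_pathways`.
#' @param ... unused.
#' @return tibble: pathway, overlap size, embedding coordinates, cluster.
#' @export
tidy.stt_pathways <- function(x, ...) {
  tibble::tibble(pathway = x$pathway_names,
                 n_genes = lengths(x$gene_overlap),
                 dim1 = x$embedding2d[, 1], dim2 = x$embedding2d[, 2],
                 cluster = x$cluster_labels)
}
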