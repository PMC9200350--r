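#' Principal components of the normalized residuals
#'
#' Cells-by-PCs scores used for graph construction and 2-D embedding.
#'
#' @param norm a `normalized_matrix`.
#' @param n_pcs number of components (default 30, capped at the data rank).
#' @return Numeric matrix, cells in rows.
#' @export
residual_pca <- function(norm, n_pcs = 30) {
  x <- t(norm$residuals)
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  if (n_pcs < 1) sc_stop("parameter_error", "n_pcs must be >= 1 and <= data rank")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  scores <- pc$x
  rownames(scores) <- norm$barcodes
  scores
}

#' Build a Jaccard-weighted k-nearest-neighbor graph
#'
#' PCA on the residuals, exact Euclidean k-nearest neighbors, then each edge
#' between cells i and j is weighted by the Jaccard overlap of their
#' neighbor sets; zero-weight edges are dropped. This is the shared-neighbor
#' graph used by Phenograph-style clustering.
#'
#' @param norm a `normalized_matrix`, or a cells-by-features numeric matrix
#'   (e.g. precomputed PCA scores).
#' @param k number of neighbors per cell.
#' @param n_pcs PCA dimensionality (ignored when `norm` is already a matrix).
#' @return An undirected weighted [igraph::graph] with one vertex per cell
#'   (vertex names = barcodes).
#' @export
build_knn_graph <- function(norm, k = 30, n_pcs = 30) {
  pcs <- if (is.matrix(norm)) norm else residual_pca(norm, n_pcs)
  n <- nrow(pcs)
  if (k < 1) sc_stop("parameter_error", "k must be >= 1")
  if (k >= n) sc_stop("parameter_error", "k (%d) must be smaller than the number of cells (%d)", k, n)
  nn <- RANN::nn2(pcs, k = k + 1)$nn.idx
  # drop self from each neighbor list (guard against exact-duplicate points)
  neigh <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    row <- nn[i, ]
    row <- row[row != i]
    neigh[i, ] <- row[seq_len(k)]
  }
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.vector(t(neigh)),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)               # |N(i) intersect N(j)|
  M <- (A + Matrix::t(A)) > 0                   # union of directed kNN edges
  idx <- Matrix::which(Matrix::triu(M, k = 1), arr.ind = TRUE)
  inter <- shared[idx]
  w <- inter / (2 * k - inter)                  # Jaccard of two k-sets
  keep <- w > 0
  g <- igraph::graph_from_data_frame(
    data.frame(from = idx[keep, 1], to = idx[keep, 2], weight = w[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  igraph::V(g)$barcode <- rownames(pcs)
  g
}

#' Cluster a weighted graph by Louvain modularity maximization
#'
#' Communities smaller than `min_size` are flagged `unassigned_small` (they
#' are too small for reliable downstream differential expression); the
#' remaining clusters are renumbered 0, 1, 2, ... by decreasing size.
#'
#' @param g weighted undirected graph from [build_knn_graph()].
#' @param min_size minimum cells per named cluster (default 20).
#' @param seed RNG seed for the Louvain heuristic.
#' @return Object of class `cluster_assignment`: data.frame `assignment`
#'   (barcode, cluster_id integer or NA, label), plus `min_size`, `modularity`.
#' @export
cluster_graph <- function(g, min_size = 20, seed = 1L) {
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  memb <- igraph::membership(comm)
  sizes <- table(memb)
  big <- names(sizes)[sizes >= min_size]
  # order surviving communities by decreasing size, ties by community id
  big <- big[order(-sizes[big], as.integer(big))]
  remap <- stats::setNames(seq_along(big) - 1L, big)
  cluster_id <- unname(remap[as.character(memb)])
  label <- ifelse(is.na(cluster_id), "unassigned_small", as.character(cluster_id))
  barcodes <- igraph::V(g)$barcode
  if (is.null(barcodes)) barcodes <- as.character(seq_along(memb))
  structure(list(
    assignment = data.frame(barcode = barcodes,
                            cluster_id = as.integer(cluster_id),
                            label = label, stringsAsFactors = FALSE),
    min_size = min_size,
    modularity = igraph::modularity(g, memb, weights = igraph::E(g)$weight)),
    class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  tab <- table(x$assignment$label)
  cat(sprintf("cluster_assignment: %d named clusters (min size %d), modularity %.3f\n",
              sum(names(tab) != "unassigned_small"), x$min_size, x$modularity))
  print(tab)
  invisible(x)
}

#' 2-D embedding of cells for visualization
#'
#' UMAP on the PCA scores; deterministic for a fixed seed (single-threaded
#' optimization).
#'
#' @param norm a `normalized_matrix` or a cells-by-features matrix.
#' @param seed RNG seed.
#' @param n_pcs PCA dimensionality.
#' @param n_neighbors UMAP neighborhood size.
#' @return data.frame (barcode, x, y), one row per cell.
#' @export
embed_2d <- function(norm, seed = 1L, n_pcs = 30, n_neighbors = 15) {
  pcs <- if (is.matrix(norm)) norm else residual_pca(norm, n_pcs)
  if (nrow(pcs) < 10) sc_stop("parameter_error", "need >= 10 cells to embed")
  set.seed(seed)
  emb <- uwot::umap(pcs, n_neighbors = min(n_neighbors, nrow(pcs) - 1),
                    n_threads = 1, n_sgd_threads = 0)
  data.frame(barcode = rownames(pcs), x = emb[, 1], y = emb[, 2],
             stringsAsFactors = FALSE)
}
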