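new_embedded_cloud <- function(points, method, explained_variance,
                               source_indices, extra = list()) {
  structure(c(list(points = points, method = method,
                   explained_variance = explained_variance,
                   source_indices = source_indices), extra),
            class = "embedded_cloud")
}

#' @export
print.embedded_cloud <- function(x, ...) {
  cat(sprintf("Embedded cloud (%s): %d points in %d dimensions\n",
              x$method, nrow(x$points), ncol(x$points)))
  cat("  explained variance:",
      paste(sprintf("%.3f", x$explained_variance), collapse = " "), "\n")
  invisible(x)
}

#' Spherical PCA
#'
#' A robust, non-linear PCA variant: every data vector is projected onto the
#' unit sphere before standard PCA (mean-centering plus eigendecomposition of
#' the covariance), so that gross outliers lose their leverage on the
#' principal directions. By default rows are mean-centered across the cloud
#' before the projection, which removes the dominant translational offset;
#' set \code{center_rows = FALSE} to normalize raw rows, in which case
#' already-unitary input reduces to standard PCA.
#'
#' @param X numeric M x D matrix, one observation per row.
#' @param d number of components to keep.
#' @param center_rows subtract the column means before projecting to the
#'   sphere (default \code{TRUE}).
#' @return an \code{embedded_cloud} with M x d scores and per-component
#'   explained-variance fractions.
#' @export
spherical_pca <- function(X, d = 3, center_rows = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 observations")
  if (center_rows) X <- sweep(X, 2L, colMeans(X))
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0))
    stop("degenerate zero-norm row(s): ", paste(which(nrm == 0), collapse = ", "))
  Xs <- X / nrm
  pc <- stats::prcomp(Xs, center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  if (d > rank) {
    warning("requested ", d, " components but rank is ", rank, "; truncating")
    d <- rank
  }
  new_embedded_cloud(pc$x[, seq_len(d), drop = FALSE], "sphpca",
                     var_frac[seq_len(d)], seq_len(nrow(X)),
                     list(rotation = pc$rotation[, seq_len(d), drop = FALSE]))
}

knn_graph <- function(D, k) {
  m <- nrow(D)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    nb <- order(D[i, ])[2:(k + 1L)]
    adj[i, nb] <- TRUE
  }
  adj | t(adj)  # union symmetrization
}

#' Minimal K giving a connected K-nearest-neighbour graph
#'
#' Smallest K >= 1 such that the union-symmetrized K-NN graph of the cloud
#' has exactly one connected component; the neighbourhood size Isomap uses.
#'
#' @param X numeric M x D matrix, or a precomputed \code{dist}/matrix of
#'   distances.
#' @return integer K, at most M - 1.
#' @export
minimal_connected_k <- function(X) {
  D <- as.matrix(if (inherits(X, "dist")) X else stats::dist(X))
  m <- nrow(D)
  if (m < 2L) stop("need at least 2 points")
  for (k in seq_len(m - 1L)) {
    g <- igraph::graph_from_adjacency_matrix(knn_graph(D, k), mode = "undirected")
    if (igraph::components(g)$no == 1L) return(k)
  }
  m - 1L
}

#' Isomap embedding
#'
#' Builds the union-symmetrized K-nearest-neighbour graph (K defaults to the
#' minimal value giving one connected component), weights edges by Euclidean
#' distance, computes exact all-pairs shortest-path (geodesic) distances, and
#' applies classical MDS to the geodesic matrix. Explained-variance fractions
#' are computed over the positive MDS eigenvalues.
#'
#' @param X numeric M x D matrix of observations.
#' @param d embedding dimension.
#' @param k neighbourhood size; \code{NULL} (default) uses
#'   \code{\link{minimal_connected_k}}.
#' @return an \code{embedded_cloud}; element \code{k} records the
#'   neighbourhood size and \code{geodesic} the geodesic distance matrix.
#' @export
isomap_embed <- function(X, d = 3, k = NULL) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (m < d + 1L) stop("need at least d + 1 points")
  D <- as.matrix(stats::dist(X))
  if (is.null(k)) k <- minimal_connected_k(D_as_dist(D))
  adj <- knn_graph(D, k)
  w <- D[adj & upper.tri(D)]
  el <- which(adj & upper.tri(D), arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = w)
  G <- igraph::distances(g, algorithm = "dijkstra")
  if (any(!is.finite(G))) stop("K-NN graph is disconnected at k = ", k)
  mds <- stats::cmdscale(G, k = min(d, m - 1L), eig = TRUE)
  eig <- mds$eig
  pos <- eig[eig > 0]
  neg_mass <- sum(abs(eig[eig < 0]))
  if (neg_mass > sum(pos))
    warning("geodesic distances strongly non-Euclidean (negative eigenvalue mass dominates)")
  dd <- ncol(mds$points)
  if (dd < d) warning("embedding truncated to ", dd, " dimensions")
  var_frac <- (eig[seq_len(dd)] / sum(pos))[seq_len(dd)]
  new_embedded_cloud(mds$points[, seq_len(dd), drop = FALSE], "isomap",
                     var_frac, seq_len(m),
                     list(k = k, eig = eig, geodesic = G))
}

D_as_dist <- function(D) stats::as.dist(D)

#' Reduce a sampled trajectory to a low-dimensional cloud
#'
#' Convenience wrapper flattening an \code{mc_trajectory} into its M x 3N
#' conformation matrix and embedding it.
#'
#' @param traj an \code{mc_trajectory}.
#' @param method \code{"isomap"} or \code{"sphpca"}.
#' @param d embedding dimension (default 3).
#' @param ... passed to the embedding function.
#' @return an \code{embedded_cloud}.
#' @export
embed_trajectory <- function(traj, method = c("isomap", "sphpca"), d = 3, ...) {
  method <- match.arg(method)
  X <- trajectory_matrix(traj)
  switch(method,
         isomap = isomap_embed(X, d = d, ...),
         sphpca = spherical_pca(X, d = d, ...))
}

#' Write an embedded cloud as CSV plus JSON sidecar
#'
#' @param cloud an \code{embedded_cloud}.
#' @param csv_path output CSV (columns index, c1..cd).
#' @param json_path optional sidecar recording method, neighbourhood size and
#'   explained variance.
#' @return \code{csv_path}, invisibly.
#' @export
write_cloud <- function(cloud, csv_path, json_path = NULL) {
  df <- data.frame(index = cloud$source_indices, cloud$points)
  names(df) <- c("index", paste0("c", seq_len(ncol(cloud$points))))
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    meta <- list(method = cloud$method,
                 explained_variance = cloud$explained_variance)
    if (!is.null(cloud$k)) meta$k <- cloud$k
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
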