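#' Topological hierarchical clustering of a conformational cloud
#'
#' The package's central fit. Given a reduced-coordinate cloud (usually an
#' Isomap or spherical-PCA embedding of a sampled pathway), it
#' \enumerate{
#'   \item selects a landmark count by the coverage-saturation rule and the
#'     landmarks by the maxmin scheme,
#'   \item computes the lazy witness H0 filtration and its barcode once,
#'   \item chooses the number of clusters k by the bar-gap rule,
#'   \item extracts the landmark partitions at levels 1..k, prunes blocks
#'     smaller than \code{min_size} at level k as outliers, and
#'   \item assembles the nested hierarchy over the retained landmarks.
#' }
#' When the trajectory and the two endpoint structures are supplied, a
#' per-cluster RMSD report is attached.
#'
#' @param cloud an \code{embedded_cloud}, \code{labeled_cloud} or a plain
#'   point matrix.
#' @param traj optional \code{mc_trajectory} the cloud was derived from.
#' @param endpoints optional list of two \code{calpha} structures
#'   (designated endpoint first) for the report.
#' @param seed master seed for landmark selection.
#' @param gap bar-gap threshold in embedding units (default 0.1).
#' @param min_size minimal cluster size before a block counts as outliers
#'   (default 2).
#' @param max_levels deepest barcode level inspected (default 20).
#' @param n_landmarks optional fixed landmark count (skips the automatic
#'   rule).
#' @param nu lazy witness laziness parameter (default 0, the value used for
#'   component detection).
#' @return an object of class \code{topo_clustering}; see Details.
#' @details The returned object carries \code{points}, \code{landmarks}
#'   (a \code{landmark_set}), \code{barcode}, \code{n_clusters},
#'   \code{retained} (cloud indices of retained landmarks), \code{levels}
#'   (restricted \code{cluster_level}s for i = 1..k), \code{hierarchy}
#'   (a \code{cluster_dendrogram}), \code{membership} (labels of retained
#'   landmarks at the finest level) and, when possible, \code{report}.
#' @export
topo_cluster <- function(cloud, traj = NULL, endpoints = NULL, seed = 1L,
                         gap = 0.1, min_size = 2L, max_levels = 20L,
                         n_landmarks = NULL, nu = 0L) {
  pts <- cloud_points(cloud)
  if (is.null(n_landmarks))
    n_landmarks <- determine_landmark_count(pts, seed = seed)
  lms <- maxmin_landmarks(pts, n_landmarks, seed = seed)
  stream <- lazy_witness_stream(pts, lms, nu = nu)
  barcode <- h0_barcode(stream)
  k <- cluster_count_from_barcode(barcode, max_levels = max_levels, gap = gap)
  level_k <- clusters_at_level(pts, lms, k, stream = stream)
  pruned <- prune_outliers(level_k, min_size = min_size)
  keep <- pruned$keep
  levels <- lapply(seq_len(k), function(i) {
    lv <- clusters_at_level(pts, lms, i, stream = stream)
    structure(list(level = lv$level, scale = lv$scale,
                   membership = as.integer(factor(lv$membership[keep])),
                   landmarks = lv$landmarks[keep]),
              class = "cluster_level")
  })
  hier <- build_hierarchy(levels)
  fit <- structure(list(points = pts, cloud = cloud, landmarks = lms,
                        stream = stream, barcode = barcode, n_clusters = k,
                        retained = pruned$landmarks,
                        levels = levels, hierarchy = hier,
                        membership = levels[[k]]$membership,
                        params = list(seed = seed, gap = gap,
                                      min_size = min_size,
                                      max_levels = max_levels,
                                      n_landmarks = n_landmarks, nu = nu)),
                   class = "topo_clustering")
  if (!is.null(traj) && !is.null(endpoints) && inherits(cloud, "embedded_cloud")) {
    fit$report <- cluster_report(levels[[k]], cloud, traj, endpoints)
    fit$traj <- traj
    fit$endpoints <- endpoints
  }
  fit
}

cloud_points <- function(cloud) {
  if (inherits(cloud, c("embedded_cloud", "labeled_cloud"))) return(cloud$points)
  as.matrix(cloud)
}

#' @export
print.topo_clustering <- function(x, ...) {
  cat("Topological hierarchical clustering\n")
  cat(sprintf("  %d points, %d landmarks (coverage R = %.4g), %d retained\n",
              nrow(x$points), length(x$landmarks$indices),
              x$landmarks$coverage_radius, length(x$retained)))
  cat(sprintf("  %d clusters by the bar-gap rule (gap > %.3g); %d after outlier pruning\n",
              x$n_clusters, x$params$gap, length(unique(x$membership))))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' @export
summary.topo_clustering <- function(object, ...) {
  sizes <- table(object$membership)
  out <- list(n_points = nrow(object$points),
              n_landmarks = length(object$landmarks$indices),
              coverage_radius = object$landmarks$coverage_radius,
              n_retained = length(object$retained),
              n_clusters = object$n_clusters,
              cluster_sizes = as.integer(sizes),
              finite_deaths = finite_deaths_desc(object$barcode),
              report = object$report)
  class(out) <- "summary.topo_clustering"
  out
}

#' @export
print.summary.topo_clustering <- function(x, ...) {
  cat(sprintf("%d points; %d landmarks (R = %.4g), %d retained after pruning\n",
              x$n_points, x$n_landmarks, x$coverage_radius, x$n_retained))
  cat(sprintf("%d clusters; sizes: %s\n", x$n_clusters,
              paste(x$cluster_sizes, collapse = ", ")))
  cat("Largest merge scales:",
      paste(sprintf("%.3g", utils::head(x$finite_deaths, 6)), collapse = ", "),
      "\n")
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Plot a topological clustering
#'
#' @param x a \code{topo_clustering}.
#' @param type \code{"barcode"}, \code{"dendrogram"} or \code{"scatter"}
#'   (first two embedding coordinates, landmarks coloured by cluster).
#' @param ... passed on to the underlying plot.
#' @export
plot.topo_clustering <- function(x, type = c("barcode", "dendrogram", "scatter"),
                                 ...) {
  type <- match.arg(type)
  if (type == "barcode") return(plot(x$barcode, main = "H0 barcode", ...))
  if (type == "dendrogram") return(plot(x$hierarchy, ...))
  pts <- x$points
  graphics::plot(pts[, 1], pts[, 2], pch = 16, col = "grey80",
                 xlab = "c1", ylab = "c2", ...)
  graphics::points(pts[x$retained, 1], pts[x$retained, 2],
                   pch = 19, col = x$membership + 1L)
  invisible(x)
}
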