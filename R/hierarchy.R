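#' Automatic landmark count
#'
#' Coverage-saturation heuristic: landmarks are added in steps of
#' \code{step} (10, 20, 30, ...) and the coverage radius R recorded; a
#' repetition stops at the first count where R drops by less than 5 percent
#' relative to the previous step (adding landmarks no longer improves
#' coverage; a previous R of 0 counts as converged). The procedure is
#' repeated \code{reps} times with different initial landmarks and the
#' returned count is \code{ceiling(mean + 2 sd)} over repetitions, capped at
#' the cloud size.
#'
#' @param cloud point matrix or distance matrix.
#' @param seed master seed; repetition r uses sub-seed \code{seed * 1000 + r}.
#' @param step landmark increment (default 10).
#' @param rel_tol relative R-change threshold (default 0.05).
#' @param reps repetitions to average over (default 5).
#' @return integer landmark count.
#' @export
determine_landmark_count <- function(cloud, seed = 1L, step = 10L,
                                     rel_tol = 0.05, reps = 5L) {
  D <- distance_matrix(cloud)
  m <- nrow(D)
  if (m < step) {
    warning("cloud smaller than the first landmark step; using all ", m, " points")
    return(m)
  }
  counts <- vapply(seq_len(reps), function(r) {
    lm_all <- maxmin_landmarks(D_as_dist(D), min(m, 20L * step),
                               seed = seed * 1000L + r)
    # maxmin is sequential, so the n-landmark set is a prefix of a longer run
    radius_at <- function(n) coverage_radius(D_as_dist(D), lm_all$indices[seq_len(n)])
    n_prev <- step
    r_prev <- radius_at(n_prev)
    repeat {
      n_cur <- n_prev + step
      if (n_cur > length(lm_all$indices)) return(as.numeric(n_prev))
      r_cur <- radius_at(n_cur)
      if (r_prev == 0 || (r_prev - r_cur) / r_prev < rel_tol)
        return(as.numeric(n_cur))
      n_prev <- n_cur
      r_prev <- r_cur
    }
  }, numeric(1))
  n <- as.integer(ceiling(mean(counts) + 2 * stats::sd(counts)))
  min(max(n, 1L), m)
}

finite_deaths_desc <- function(barcode) {
  sort(barcode$death[is.finite(barcode$death)], decreasing = TRUE)
}

#' Number of clusters from the degree-0 barcode
#'
#' Persistent components are separated from noise by the bar-gap rule: with
#' the finite H0 death scales sorted in decreasing order, the cluster count
#' is one (the everlasting component) plus the number of death scales above
#' the last gap larger than \code{gap} between consecutive scales, scanning
#' at most the \code{max_levels} largest. When no gap exceeds the threshold
#' the cloud is a single cluster.
#'
#' @param cloud point matrix or distance matrix for the full cloud.
#' @param landmarks \code{landmark_set} or indices; the same set is used for
#'   every internal scale so the filtration is computed once.
#' @param max_levels deepest level inspected (default 20).
#' @param gap bar-gap threshold in embedding units (default 0.1).
#' @param nu laziness parameter (default 0).
#' @return integer cluster count >= 1.
#' @export
determine_cluster_count <- function(cloud, landmarks, max_levels = 20L,
                                    gap = 0.1, nu = 0L) {
  idx <- if (inherits(landmarks, "landmark_set")) landmarks$indices else landmarks
  if (length(idx) < 2L) return(1L)
  fg <- lazy_witness_stream(cloud, idx, nu = nu)
  cluster_count_from_barcode(h0_barcode(fg), max_levels = max_levels, gap = gap)
}

#' Bar-gap cluster count from an H0 barcode
#'
#' @param barcode an H0 \code{barcode}.
#' @param max_levels,gap as in \code{\link{determine_cluster_count}}.
#' @return integer cluster count.
#' @export
cluster_count_from_barcode <- function(barcode, max_levels = 20L, gap = 0.1) {
  d <- finite_deaths_desc(barcode)
  d <- d[seq_len(min(length(d), max_levels))]
  if (length(d) < 1L) return(1L)
  gaps <- -diff(d)
  big <- which(gaps > gap)
  if (length(big) == 0L) return(1L)
  1L + max(big)
}

#' Landmark partition at a target cluster count
#'
#' The H0 filtration of the lazy witness stream has exactly i components on
#' the scale interval between the (L-i)-th and (L-i+1)-th merge; the
#' partition is taken at the midpoint of that plateau (at the last merge
#' scale for i = 1, at 0 for all-singletons). When simultaneous merges make
#' a count unattainable the nearest achievable partition is returned with a
#' warning.
#'
#' @param cloud point matrix or distance matrix.
#' @param landmarks \code{landmark_set} or indices.
#' @param i target number of clusters (1..L).
#' @param stream optional precomputed \code{\link{lazy_witness_stream}}.
#' @param nu laziness parameter (default 0).
#' @return a \code{cluster_level}: list with \code{level}, \code{scale},
#'   \code{membership} (integer labels per landmark) and \code{landmarks}
#'   (cloud indices).
#' @export
clusters_at_level <- function(cloud, landmarks, i, stream = NULL, nu = 0L) {
  idx <- if (inherits(landmarks, "landmark_set")) landmarks$indices else landmarks
  L <- length(idx)
  stopifnot(i >= 1L, i <= L)
  fg <- if (is.null(stream)) lazy_witness_stream(cloud, idx, nu = nu) else stream
  merges <- sort(finite_deaths_desc(h0_barcode(fg)))  # ascending merge scales
  n_m <- length(merges)
  # after j merges there are L - j components; want j = L - i
  j <- L - i
  lo <- if (j == 0L) 0 else merges[j]
  hi <- if (j >= n_m) Inf else merges[j + 1L]
  if (lo >= hi) {
    warning("no scale yields exactly ", i,
            " components (simultaneous merges); using nearest achievable")
    t_use <- lo
  } else {
    t_use <- if (is.infinite(hi)) lo else (lo + hi) / 2
  }
  membership <- components_at_scale(fg, t_use)
  structure(list(level = as.integer(i), scale = t_use,
                 membership = membership, landmarks = idx),
            class = "cluster_level")
}

#' @export
print.cluster_level <- function(x, ...) {
  cat(sprintf("Cluster level %d: %d blocks over %d landmarks at scale %.4g\n",
              x$level, length(unique(x$membership)), length(x$landmarks),
              x$scale))
  invisible(x)
}

#' Drop outlier landmarks
#'
#' Landmarks in blocks smaller than \code{min_size} at the selected level
#' are discarded as outliers.
#'
#' @param level a \code{cluster_level}.
#' @param min_size minimal retained block size (default 2).
#' @return list with \code{keep} (logical per landmark), \code{landmarks}
#'   (retained cloud indices) and \code{level} (the re-emitted partition).
#' @export
prune_outliers <- function(level, min_size = 2L) {
  sizes <- table(level$membership)
  keep <- level$membership %in% as.integer(names(sizes)[sizes >= min_size])
  if (!any(keep)) stop("all landmarks pruned as outliers; lower min_size")
  membership <- as.integer(factor(level$membership[keep]))
  pruned <- structure(list(level = level$level, scale = level$scale,
                           membership = membership,
                           landmarks = level$landmarks[keep]),
                      class = "cluster_level")
  list(keep = keep, landmarks = level$landmarks[keep], level = pruned)
}

#' Nested hierarchy across cluster levels
#'
#' Levels i = 1..k of a single H0 filtration form a laminar family: every
#' block at level i+1 is contained in exactly one block at level i. The
#' block of level i equal to the union of two level-(i+1) blocks becomes
#' their parent; all other blocks carry over unchanged. Heights are ordinal
#' by level.
#'
#' @param levels list of \code{cluster_level}s for i = 1..k over one
#'   landmark set.
#' @return a \code{cluster_dendrogram}: list with \code{levels},
#'   \code{nodes} (data frame: id, level, block index within level, parent
#'   id) and \code{landmarks}.
#' @export
build_hierarchy <- function(levels) {
  k <- length(levels)
  stopifnot(k >= 1L)
  lmset <- levels[[1L]]$landmarks
  for (lv in levels) if (!identical(lv$landmarks, lmset))
    stop("all levels must share the same landmark set")
  nodes <- data.frame(id = integer(0), level = integer(0), block = integer(0),
                      parent = integer(0))
  id_of <- vector("list", k)  # per level: block index -> node id
  next_id <- 1L
  for (li in seq_len(k)) {
    blocks <- sort(unique(levels[[li]]$membership))
    ids <- integer(length(blocks))
    for (b in blocks) {
      parent <- NA_integer_
      if (li > 1L) {
        members <- which(levels[[li]]$membership == b)
        up <- unique(levels[[li - 1L]]$membership[members])
        if (length(up) != 1L)
          stop("nesting violated between levels ", li - 1L, " and ", li)
        parent <- id_of[[li - 1L]][up]
      }
      ids[b] <- next_id
      nodes <- rbind(nodes, data.frame(id = next_id, level = li, block = b,
                                       parent = parent))
      next_id <- next_id + 1L
    }
    id_of[[li]] <- ids
  }
  structure(list(levels = levels, nodes = nodes, landmarks = lmset),
            class = "cluster_dendrogram")
}

#' @export
print.cluster_dendrogram <- function(x, ...) {
  k <- length(x$levels)
  cat(sprintf("Cluster hierarchy: %d levels, %d leaf blocks, %d landmarks\n",
              k, length(unique(x$levels[[k]]$membership)),
              length(x$landmarks)))
  invisible(x)
}

#' Plot a cluster hierarchy
#'
#' Draws the nested level structure as a dendrogram; bar heights are ordinal
#' (one unit per level), leaves are the finest-level blocks.
#'
#' @param x a \code{cluster_dendrogram}.
#' @param labels optional leaf labels (default block numbers at the finest
#'   level).
#' @param ... passed to \code{plot}.
#' @export
plot.cluster_dendrogram <- function(x, labels = NULL, ...) {
  k <- length(x$levels)
  leaves <- sort(unique(x$levels[[k]]$membership))
  if (is.null(labels)) labels <- paste0("C", leaves)
  # leaf x-positions ordered so that siblings are adjacent: order leaves by
  # their membership path from the root
  paths <- vapply(leaves, function(b) {
    m <- which(x$levels[[k]]$membership == b)[1L]
    paste(vapply(seq_len(k), function(li) x$levels[[li]]$membership[m],
                 integer(1)), collapse = ".")
  }, character(1))
  ord <- order(paths)
  xpos <- numeric(max(leaves))
  xpos[leaves[ord]] <- seq_along(leaves)
  graphics::plot(NA, xlim = c(0.5, length(leaves) + 0.5), ylim = c(0, k),
                 xlab = "", ylab = "level (ordinal)", xaxt = "n", ...)
  graphics::axis(1, at = seq_along(leaves), labels = labels[ord], las = 2)
  # recursive x of a block at level li = mean of its leaf positions
  block_x <- function(li, b) {
    m <- which(x$levels[[li]]$membership == b)
    lv <- unique(x$levels[[k]]$membership[m])
    mean(xpos[lv])
  }
  for (li in seq_len(k)) {
    hb <- k - li  # root on top
    for (b in sort(unique(x$levels[[li]]$membership))) {
      bx <- block_x(li, b)
      if (li < k) {
        members <- which(x$levels[[li]]$membership == b)
        children <- sort(unique(x$levels[[li + 1L]]$membership[members]))
        cx <- vapply(children, function(cb) block_x(li + 1L, cb), numeric(1))
        graphics::segments(min(cx), hb, max(cx), hb)
        graphics::segments(cx, hb, cx, hb - 1)
      }
    }
  }
  invisible(x)
}

#' Per-cluster RMSD report against the endpoints
#'
#' For every block of the partition: its size, the mean and population
#' standard deviation of member RMSDs (optimal superposition, Angstrom) to
#' each endpoint, and a representative member (the one nearest the block's
#' geometric center in the reduced space). Clusters are renumbered in
#' increasing order of mean RMSD to the first endpoint.
#'
#' @param level a \code{cluster_level} (landmark indices refer to trajectory
#'   rows via the cloud's source indices).
#' @param cloud the \code{embedded_cloud} the landmarks live in.
#' @param traj the \code{mc_trajectory} the cloud was computed from.
#' @param endpoints list of two \code{calpha} structures (designated
#'   endpoint first).
#' @return a \code{cluster_report} data frame: cluster, size, mean/sd RMSD
#'   to each endpoint, representative (trajectory model index).
#' @export
cluster_report <- function(level, cloud, traj, endpoints) {
  stopifnot(length(endpoints) == 2L)
  pts <- cloud$points[level$landmarks, , drop = FALSE]
  src <- cloud$source_indices[level$landmarks]
  blocks <- sort(unique(level$membership))
  rows <- lapply(blocks, function(b) {
    m <- which(level$membership == b)
    if (length(m) == 0L) return(NULL)
    structs <- lapply(src[m], function(i) trajectory_structure(traj, i))
    r1 <- vapply(structs, kabsch_rmsd, numeric(1), b = endpoints[[1L]])
    r2 <- vapply(structs, kabsch_rmsd, numeric(1), b = endpoints[[2L]])
    ctr <- colMeans(pts[m, , drop = FALSE])
    d_ctr <- sqrt(rowSums(sweep(pts[m, , drop = FALSE], 2L, ctr)^2))
    data.frame(size = length(m),
               mean_rmsd_1 = mean(r1), sd_rmsd_1 = sd_pop(r1),
               mean_rmsd_2 = mean(r2), sd_rmsd_2 = sd_pop(r2),
               representative = src[m[which.min(d_ctr)]])
  })
  rep_df <- do.call(rbind, rows)
  ord <- order(rep_df$mean_rmsd_1)
  rep_df <- rep_df[ord, , drop = FALSE]
  out <- cbind(cluster = seq_len(nrow(rep_df)), rep_df)
  rownames(out) <- NULL
  attr(out, "block_order") <- blocks[ord]  # original block id per new number
  attr(out, "endpoint_ids") <- vapply(endpoints, function(e) e$id, character(1))
  class(out) <- c("cluster_report", "data.frame")
  out
}

sd_pop <- function(x) {
  if (length(x) < 2L) return(0)
  sqrt(mean((x - mean(x))^2))
}

#' @export
print.cluster_report <- function(x, ...) {
  ids <- attr(x, "endpoint_ids")
  cat(sprintf("Cluster report (RMSD in A vs %s / %s):\n", ids[1], ids[2]))
  df <- data.frame(cluster = x$cluster, size = x$size,
                   rmsd_1 = sprintf("%.2f+-%.2f", x$mean_rmsd_1, x$sd_rmsd_1),
                   rmsd_2 = sprintf("%.2f+-%.2f", x$mean_rmsd_2, x$sd_rmsd_2),
                   representative = x$representative)
  names(df)[3:4] <- paste0("rmsd_", ids)
  print(df, row.names = FALSE)
  invisible(x)
}
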