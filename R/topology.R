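# -- union-find --------------------------------------------------------------

uf_new <- function(n) list(parent = seq_len(n), birth_order = seq_len(n))

uf_find <- function(uf, i) {
  while (uf$parent[i] != i) {
    uf$parent[i] <- uf$parent[uf$parent[i]]
    i <- uf$parent[i]
  }
  i
}

# -- landmarks ---------------------------------------------------------------

#' Maxmin landmark selection
#'
#' Sequential mini-max scheme: the first landmark is drawn uniformly at
#' random (or fixed via \code{first}); each subsequent landmark is the cloud
#' point maximizing its Euclidean distance to the already-chosen set. Ties
#' resolve to the lowest index. The scheme covers the cloud far better than
#' random selection.
#'
#' @param cloud numeric M x d matrix, or a precomputed distance matrix
#'   (\code{dist} or square matrix).
#' @param n number of landmarks; capped at M with a warning.
#' @param seed integer seed for the initial draw.
#' @param first optional index of the first landmark (overrides the random
#'   draw; useful for deterministic analyses).
#' @return a \code{landmark_set}: list with \code{indices} (in maxmin
#'   order), \code{coverage_radius} (max distance of any cloud point to its
#'   nearest landmark) and \code{seed}.
#' @export
maxmin_landmarks <- function(cloud, n, seed = 1L, first = NULL) {
  D <- distance_matrix(cloud)
  m <- nrow(D)
  if (n > m) {
    warning("requested ", n, " landmarks from ", m, " points; capping")
    n <- m
  }
  stopifnot(n >= 1L)
  if (is.null(first)) {
    set.seed(seed)
    first <- sample.int(m, 1L)
  }
  idx <- integer(n)
  idx[1L] <- first
  mind <- D[first, ]
  if (n > 1L) for (i in 2:n) {
    idx[i] <- which.max(mind)
    mind <- pmin(mind, D[idx[i], ])
  }
  structure(list(indices = idx, coverage_radius = max(mind),
                 seed = as.integer(seed)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("Landmark set: %d landmarks, coverage radius R = %.4g\n",
              length(x$indices), x$coverage_radius))
  invisible(x)
}

#' Coverage radius of a landmark set
#'
#' The maximum over cloud points of the distance to the nearest landmark.
#'
#' @param cloud point matrix or distance matrix.
#' @param landmarks a \code{landmark_set} or an integer vector of indices.
#' @return numeric R.
#' @export
coverage_radius <- function(cloud, landmarks) {
  idx <- if (inherits(landmarks, "landmark_set")) landmarks$indices else landmarks
  stopifnot(length(idx) >= 1L)
  D <- distance_matrix(cloud)
  max(apply(D[idx, , drop = FALSE], 2L, min))
}

distance_matrix <- function(x) {
  if (inherits(x, "dist")) return(as.matrix(x))
  x <- as.matrix(x)
  if (nrow(x) == ncol(x) && isTRUE(all.equal(x, t(x))) && all(diag(x) == 0))
    return(x)
  as.matrix(stats::dist(x))
}

# -- Rips oracle -------------------------------------------------------------

#' Vietoris-Rips complex at a fixed scale
#'
#' The flag complex on the graph joining points at distance <= r: every set
#' of up to \code{max_dim + 1} pairwise-close points spans a simplex. Meant
#' as a small-scale oracle (clique enumeration via \pkg{igraph}).
#'
#' @param points point matrix or distance matrix.
#' @param r scale (>= 0).
#' @param max_dim maximal simplex dimension.
#' @return list of matrices \code{simplices[[k+1]]}, each row one k-simplex
#'   (vertex indices).
#' @export
rips_complex <- function(points, r, max_dim = 2L) {
  stopifnot(r >= 0)
  D <- distance_matrix(points)
  m <- nrow(D)
  adj <- D <= r & upper.tri(D)
  g <- igraph::graph_from_adjacency_matrix(D <= r & row(D) != col(D),
                                           mode = "undirected")
  out <- list(matrix(seq_len(m), ncol = 1L))
  for (k in seq_len(max_dim)) {
    cl <- igraph::cliques(g, min = k + 1L, max = k + 1L)
    out[[k + 1L]] <- if (length(cl) == 0L) {
      matrix(integer(0), ncol = k + 1L)
    } else {
      t(vapply(cl, function(x) sort(as.integer(x)), integer(k + 1L)))
    }
  }
  names(out) <- paste0("dim", 0:max_dim)
  out
}

# -- lazy witness filtration -------------------------------------------------

#' Lazy witness edge filtration over landmarks
#'
#' For each landmark pair (z0, z1) the appearance scale is
#' \code{min_y max(d(y,z0), d(y,z1)) - d(y)} over all cloud points y
#' (clamped at 0), where d(y) is 0 for \code{nu = 0} and the distance from y
#' to its nu-th closest landmark otherwise. An edge is present at scale t iff
#' t >= its appearance scale, so the whole filtration is computed once.
#'
#' @param cloud point matrix or distance matrix over the full cloud.
#' @param landmarks \code{landmark_set} or integer indices into the cloud.
#' @param nu laziness parameter, 0 or 1 (0 is used for component detection).
#' @return a \code{filtered_graph}: list with \code{vertices} (landmark
#'   indices into the cloud) and \code{edges}, a data frame with local
#'   vertex columns \code{i}, \code{j} and appearance scale \code{t}.
#' @export
lazy_witness_stream <- function(cloud, landmarks, nu = 0L) {
  stopifnot(nu %in% c(0L, 1L))
  idx <- if (inherits(landmarks, "landmark_set")) landmarks$indices else landmarks
  D <- distance_matrix(cloud)
  L <- length(idx)
  DL <- D[idx, , drop = FALSE]  # L x M landmark-to-cloud distances
  dy <- if (nu == 0L) rep(0, ncol(D)) else apply(DL, 2L, function(col) sort(col)[nu])
  pairs <- which(upper.tri(diag(L)), arr.ind = TRUE)
  t_e <- vapply(seq_len(nrow(pairs)), function(p) {
    a <- pairs[p, 1L]; b <- pairs[p, 2L]
    max(0, min(pmax(DL[a, ], DL[b, ]) - dy))
  }, numeric(1))
  structure(list(vertices = idx,
                 edges = data.frame(i = pairs[, 1L], j = pairs[, 2L], t = t_e)),
            class = "filtered_graph")
}

#' @export
print.filtered_graph <- function(x, ...) {
  cat(sprintf("Filtered graph: %d vertices, %d edges, scales [%.4g, %.4g]\n",
              length(x$vertices), nrow(x$edges),
              min(x$edges$t), max(x$edges$t)))
  invisible(x)
}

#' Lazy witness graph at one scale
#'
#' @param cloud,landmarks,nu as in \code{\link{lazy_witness_stream}}.
#' @param t scale.
#' @return a \code{filtered_graph} restricted to edges present at t.
#' @export
lazy_witness_graph <- function(cloud, landmarks, t, nu = 0L) {
  fg <- lazy_witness_stream(cloud, landmarks, nu = nu)
  fg$edges <- fg$edges[fg$edges$t <= t, , drop = FALSE]
  fg
}

#' Flag expansion of a filtered graph
#'
#' Every (k+1)-clique spans a k-simplex appearing at the maximum of its
#' edges' appearance scales (the lazy witness complex is a flag complex,
#' fully determined by its 1-skeleton).
#'
#' @param graph a \code{filtered_graph}.
#' @param max_dim maximal simplex dimension.
#' @return a \code{filtered_complex}: list of data frames per dimension with
#'   vertex columns (local indices) and appearance scale \code{t}.
#' @export
flag_expansion <- function(graph, max_dim = 2L) {
  stopifnot(max_dim >= 1L)
  L <- length(graph$vertices)
  ed <- graph$edges
  tmat <- matrix(Inf, L, L)
  tmat[cbind(ed$i, ed$j)] <- ed$t
  tmat[cbind(ed$j, ed$i)] <- ed$t
  g <- igraph::graph_from_edgelist(as.matrix(ed[, c("i", "j")]), directed = FALSE)
  if (igraph::vcount(g) < L) g <- igraph::add_vertices(g, L - igraph::vcount(g))
  out <- list(data.frame(v1 = seq_len(L), t = 0))
  out[[2L]] <- data.frame(v1 = ed$i, v2 = ed$j, t = ed$t)
  if (max_dim >= 2L) for (k in 2:max_dim) {
    cl <- igraph::cliques(g, min = k + 1L, max = k + 1L)
    if (length(cl) == 0L) {
      df <- as.data.frame(matrix(numeric(0), ncol = k + 2L))
    } else {
      vs <- t(vapply(cl, function(x) sort(as.integer(x)), integer(k + 1L)))
      tt <- apply(vs, 1L, function(v) {
        prs <- utils::combn(v, 2L)
        max(tmat[cbind(prs[1, ], prs[2, ])])
      })
      df <- data.frame(vs, t = tt)
    }
    names(df) <- c(paste0("v", seq_len(k + 1L)), "t")
    out[[k + 1L]] <- df
  }
  names(out) <- paste0("dim", seq_along(out) - 1L)
  structure(out, class = "filtered_complex")
}

# -- barcodes ----------------------------------------------------------------

new_barcode <- function(degree, birth, death) {
  structure(data.frame(degree = degree, birth = birth, death = death),
            class = c("barcode", "data.frame"))
}

#' Degree-0 persistence barcode of a filtered graph
#'
#' Union-find over edges in order of appearance scale. Every vertex is born
#' at scale 0; at each merge the younger component dies (elder rule; ties
#' resolve to the higher vertex index dying). Each connected component of
#' the final graph contributes one infinite bar.
#'
#' @param graph a \code{filtered_graph}.
#' @return a \code{barcode} data frame (degree, birth, death), finite deaths
#'   sorted increasing, infinite bars last.
#' @export
h0_barcode <- function(graph) {
  L <- length(graph$vertices)
  ed <- graph$edges[order(graph$edges$t, graph$edges$i, graph$edges$j), ,
                    drop = FALSE]
  parent <- seq_len(L)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  deaths <- numeric(0)
  for (e in seq_len(nrow(ed))) {
    ra <- find(ed$i[e]); rb <- find(ed$j[e])
    if (ra != rb) {
      # elder rule: all births are 0; the component with the larger
      # representative index (created later in vertex order) dies
      young <- max(ra, rb); old <- min(ra, rb)
      parent[young] <- old
      deaths <- c(deaths, ed$t[e])
    }
  }
  n_inf <- L - length(deaths)
  new_barcode(degree = 0L,
              birth = rep(0, length(deaths) + n_inf),
              death = c(sort(deaths), rep(Inf, n_inf)))
}

#' Degree-1 persistence barcode of a filtered flag complex
#'
#' Standard persistence algorithm: simplices sorted by (appearance scale,
#' dimension), boundary matrix reduced over the two-element field. Intended
#' for oracle-scale complexes; errors above ~2000 simplices.
#'
#' @param complex a \code{filtered_complex} built to dimension >= 2 (see
#'   \code{\link{flag_expansion}}).
#' @return a \code{barcode} data frame for degree 1 (zero-length bars are
#'   dropped).
#' @export
h1_barcode <- function(complex) {
  if (length(complex) < 3L) stop("complex must be built to dimension >= 2")
  edges <- complex[[2L]]
  tris <- complex[[3L]]
  n_simplex <- nrow(complex[[1L]]) + nrow(edges) + nrow(tris)
  if (n_simplex > 2000L)
    stop("complex too large for the dense persistence oracle (",
         n_simplex, " simplices)")
  # order edges and triangles by appearance; vertices all at 0 precede
  eo <- order(edges$t, edges$v1, edges$v2)
  edges <- edges[eo, , drop = FALSE]
  # H0 pairing to find positive (cycle-creating) edges
  L <- nrow(complex[[1L]])
  parent <- seq_len(L)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  positive_edge <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    ra <- find(edges$v1[e]); rb <- find(edges$v2[e])
    if (ra == rb) positive_edge[e] <- TRUE else parent[max(ra, rb)] <- min(ra, rb)
  }
  if (nrow(tris) == 0L) {
    if (!any(positive_edge)) return(new_barcode(integer(0), numeric(0), numeric(0)))
    return(new_barcode(1L, edges$t[positive_edge], Inf))
  }
  to <- order(tris$t, tris$v1, tris$v2, tris$v3)
  tris <- tris[to, , drop = FALSE]
  # edge key -> filtration position among edges
  ekey <- paste(edges$v1, edges$v2)
  epos <- seq_len(nrow(edges))
  names(epos) <- ekey
  # reduce triangle boundaries over GF(2); columns indexed by edge position
  claimed <- vector("list", nrow(edges))  # reduced column with this low, or NULL
  death_of_edge <- rep(Inf, nrow(edges))
  for (ti in seq_len(nrow(tris))) {
    v <- sort(c(tris$v1[ti], tris$v2[ti], tris$v3[ti]))
    col <- sort(unname(epos[c(paste(v[1], v[2]), paste(v[1], v[3]),
                              paste(v[2], v[3]))]))
    while (length(col) > 0L) {
      low <- col[length(col)]
      other <- claimed[[low]]
      if (is.null(other)) {
        claimed[[low]] <- col
        death_of_edge[low] <- tris$t[ti]
        break
      }
      col <- sort(c(setdiff(col, other), setdiff(other, col)))  # symmetric diff
    }
  }
  birth <- edges$t[positive_edge]
  death <- death_of_edge[positive_edge]
  keep <- death > birth
  new_barcode(rep(1L, sum(keep)), birth[keep], death[keep])
}

#' Connected components of a filtered graph at a scale
#'
#' @param graph a \code{filtered_graph}.
#' @param t scale (edges with appearance <= t are present).
#' @return integer vector of component labels (1-based, by order of first
#'   member), one per landmark.
#' @export
components_at_scale <- function(graph, t) {
  stopifnot(t >= 0)
  L <- length(graph$vertices)
  parent <- seq_len(L)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ed <- graph$edges[graph$edges$t <= t, , drop = FALSE]
  for (e in seq_len(nrow(ed))) {
    ra <- find(ed$i[e]); rb <- find(ed$j[e])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(L), find, integer(1))
  as.integer(factor(roots, levels = unique(roots)))
}

#' Rips filtration of a point set as a filtered complex
#'
#' Convenience oracle: edges appear at their pairwise distance, higher
#' simplices by flag expansion.
#'
#' @param points point matrix or distance matrix.
#' @param max_dim maximal simplex dimension.
#' @return a \code{filtered_complex}.
#' @export
rips_filtration <- function(points, max_dim = 2L) {
  D <- distance_matrix(points)
  m <- nrow(D)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  fg <- structure(list(vertices = seq_len(m),
                       edges = data.frame(i = pairs[, 1L], j = pairs[, 2L],
                                          t = D[pairs])),
                  class = "filtered_graph")
  flag_expansion(fg, max_dim = max_dim)
}

#' Write a barcode as CSV
#'
#' @param barcode a \code{barcode} data frame.
#' @param path output CSV; infinite deaths are written as \code{"inf"}.
#' @return \code{path}, invisibly.
#' @export
write_barcode <- function(barcode, path) {
  df <- as.data.frame(barcode)
  df$death <- ifelse(is.infinite(df$death), "inf", as.character(df$death))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot a barcode
#'
#' Horizontal persistence intervals per degree; infinite bars run to the
#' plot margin with an arrowhead.
#'
#' @param x a \code{barcode}.
#' @param ... passed to \code{plot}.
#' @export
plot.barcode <- function(x, ...) {
  df <- as.data.frame(x)
  if (nrow(df) == 0L) {
    graphics::plot.new(); graphics::title("empty barcode"); return(invisible(x))
  }
  fin <- df$death[is.finite(df$death)]
  xmax <- if (length(fin)) max(fin) * 1.1 else max(df$birth, 1) * 1.5
  if (xmax == 0) xmax <- 1
  df <- df[order(df$degree, -ifelse(is.finite(df$death), df$death - df$birth, Inf)), ]
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, nrow(df) + 1),
                 xlab = "scale", ylab = "", yaxt = "n", ...)
  for (i in seq_len(nrow(df))) {
    d <- min(df$death[i], xmax)
    graphics::segments(df$birth[i], i, d, i,
                       col = ifelse(df$degree[i] == 0L, "grey25", "firebrick"),
                       lwd = 2)
    if (is.infinite(df$death[i]))
      graphics::arrows(df$birth[i], i, xmax, i, length = 0.06, lwd = 2,
                       col = "grey25")
  }
  graphics::legend("bottomright", legend = c("H0", "H1"), lwd = 2,
                   col = c("grey25", "firebrick"), bty = "n")
  invisible(x)
}
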