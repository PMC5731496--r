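#' Gaussian blob cloud
#'
#' k isotropic Gaussian components with labelled points; the standard
#' fixture for cluster-recovery checks. Centers are either given explicitly
#' or placed pairwise \code{separation} apart: on a regular simplex when
#' k <= dim + 1, otherwise at rejection-sampled random positions with that
#' minimum separation.
#'
#' @param k number of components.
#' @param n_per points per component.
#' @param separation pairwise center distance (ignored when \code{centers}
#'   given).
#' @param sigma isotropic standard deviation (> 0).
#' @param dim ambient dimension (default 2).
#' @param centers optional k x dim matrix of centers.
#' @param seed integer seed.
#' @return a \code{labeled_cloud}: list with \code{points} (M x dim),
#'   \code{labels} (1..k per point) and \code{seed}.
#' @export
gaussian_blobs <- function(k, n_per, separation = 1, sigma = 0.05, dim = 2L,
                           centers = NULL, seed = 1L) {
  stopifnot(k >= 1L, n_per >= 1L)
  if (sigma <= 0) stop("sigma must be positive")
  set.seed(seed)
  if (is.null(centers)) {
    if (k == 1L) {
      centers <- matrix(0, 1L, dim)
    } else if (k <= dim + 1L) {
      centers <- regular_simplex(k, dim) * separation
    } else {
      centers <- matrix(stats::runif(k * dim, 0, separation * k), k, dim)
      for (tries in seq_len(1000L)) {
        if (min(stats::dist(centers)) >= separation) break
        centers <- matrix(stats::runif(k * dim, 0, separation * k), k, dim)
      }
      if (min(stats::dist(centers)) < separation)
        stop("could not place ", k, " centers at separation ", separation)
    }
  }
  centers <- as.matrix(centers)
  pts <- do.call(rbind, lapply(seq_len(k), function(b) {
    sweep(matrix(stats::rnorm(n_per * dim, sd = sigma), n_per, dim),
          2L, centers[b, ], "+")
  }))
  structure(list(points = pts, labels = rep(seq_len(k), each = n_per),
                 centers = centers, seed = as.integer(seed)),
            class = "labeled_cloud")
}

# k vertices of a regular simplex with unit pairwise distance, in dim >= k-1
regular_simplex <- function(k, dim) {
  v <- diag(1, k)  # unit-scaled later; pairwise distance sqrt(2)
  v <- v / sqrt(2)
  v <- sweep(v, 2L, colMeans(v))
  # rotate into the first k-1 coordinates via QR, then pad to dim
  q <- qr.Q(qr(t(v)))[, seq_len(k - 1L), drop = FALSE]
  w <- v %*% q
  if (dim < k - 1L) stop("dim too small for a regular ", k, "-simplex")
  cbind(w, matrix(0, k, dim - (k - 1L)))
}

#' Noisy circle cloud
#'
#' n points at uniform angles on a circle with radial Gaussian noise; the
#' canonical fixture carrying one 1-cycle.
#'
#' @param n number of points (>= 3).
#' @param radius circle radius.
#' @param noise radial standard deviation (0 for an exact regular n-gon).
#' @param seed integer seed.
#' @return a \code{labeled_cloud} (all labels 1).
#' @export
circle_cloud <- function(n, radius = 1, noise = 0, seed = 1L) {
  stopifnot(n >= 3L)
  set.seed(seed)
  th <- 2 * pi * (seq_len(n) - 1L) / n
  r <- radius + if (noise > 0) stats::rnorm(n, sd = noise) else 0
  structure(list(points = cbind(r * cos(th), r * sin(th)),
                 labels = rep(1L, n), seed = as.integer(seed)),
            class = "labeled_cloud")
}

#' @export
print.labeled_cloud <- function(x, ...) {
  cat(sprintf("Labeled cloud: %d points, %d components, %d dims\n",
              nrow(x$points), length(unique(x$labels)), ncol(x$points)))
  invisible(x)
}

#' Toy start/goal chain pair
#'
#' A desk-scale stand-in for a pair of endpoint structures: the start is a
#' self-avoiding C-alpha chain with exact 3.8 A virtual bonds (no two
#' residues >= 3 apart closer than 4 A); the goal applies
#' \code{n_perturbations} random pseudo-dihedral rotations (uniform within
#' \code{max_rotation} degrees), keeping only clash-free intermediates.
#'
#' Because independent rotations can largely cancel, a pair is only emitted
#' once the endpoints are at least \code{min_rmsd} apart (further clash-free
#' rotations are applied if needed), so the fixture always represents a
#' genuine transition rather than two copies of the same state. With
#' \code{n_perturbations = 0} the endpoints are identical and no separation
#' is enforced.
#'
#' @param n_res chain length (>= 6).
#' @param n_perturbations number of accepted random rotations (>= 0).
#' @param seed integer seed.
#' @param max_rotation per-move rotation bound in degrees (default 90).
#' @param min_rmsd minimum endpoint separation in Angstrom (default 2).
#' @return list with \code{start} and \code{goal} \code{calpha} structures.
#' @export
toy_chain_pair <- function(n_res, n_perturbations = 10L, seed = 1L,
                           max_rotation = 90, min_rmsd = 2) {
  stopifnot(n_res >= 6L)
  set.seed(seed)
  start <- grow_chain(n_res)
  goal <- start
  applied <- 0L
  tries <- 0L
  while (applied < n_perturbations ||
         (n_perturbations > 0L && kabsch_rmsd(start, goal) < min_rmsd)) {
    tries <- tries + 1L
    if (tries > 500L * max(1L, n_perturbations))
      stop("could not generate a clash-free, separated goal")
    bond <- sample.int(n_res - 3L, 1L)
    cand <- apply_dihedral_rotation(goal, bond,
                                    stats::runif(1, -max_rotation, max_rotation))
    if (!has_clash(cand)) {
      goal <- cand
      applied <- applied + 1L
    }
  }
  goal$id <- paste0(start$id, "_goal")
  list(start = start, goal = goal)
}

# sequential growth with rejection until self-avoiding
grow_chain <- function(n_res, bond = 3.8, clash = 4.0) {
  for (attempt in seq_len(500L)) {
    xyz <- matrix(0, n_res, 3L)
    xyz[2L, ] <- c(bond, 0, 0)
    ok <- TRUE
    for (i in 3:n_res) {
      placed <- FALSE
      for (trial in seq_len(50L)) {
        # bend angle in [60, 140] degrees from the previous bond direction
        prev <- xyz[i - 1L, ] - xyz[i - 2L, ]
        prev <- prev / sqrt(sum(prev^2))
        bend <- stats::runif(1, 60, 140) * pi / 180
        # random unit vector orthogonal to prev
        r <- stats::rnorm(3)
        r <- r - sum(r * prev) * prev
        r <- r / sqrt(sum(r^2))
        dirv <- cos(pi - bend) * prev + sin(pi - bend) * r
        cand <- xyz[i - 1L, ] + bond * dirv
        d_prev <- sqrt(colSums((t(xyz[seq_len(i - 1L), , drop = FALSE]) - cand)^2))
        far <- seq_len(i - 1L) <= i - 3L
        if (!any(d_prev[far] < clash)) {
          xyz[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(calpha_structure(xyz, id = sprintf("toy%d", n_res)))
  }
  stop("self-avoiding chain generation failed")
}

#' Write a labelled cloud as CSV
#'
#' @param cloud a \code{labeled_cloud}.
#' @param path output CSV (columns label, c1..cd).
#' @return \code{path}, invisibly.
#' @export
write_labeled_cloud <- function(cloud, path) {
  df <- data.frame(label = cloud$labels, cloud$points)
  names(df) <- c("label", paste0("c", seq_len(ncol(cloud$points))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
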