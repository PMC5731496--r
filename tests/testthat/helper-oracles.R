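# Independent oracles used across the suite. None of these call the code
# paths they are checking.

# rotation matrix from Euler angles (z-y-z convention)
euler_rotation <- function(a, b, c) {
  rz <- function(t) rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0), c(0, 0, 1))
  ry <- function(t) rbind(c(cos(t), 0, sin(t)), c(0, 1, 0), c(-sin(t), 0, cos(t)))
  rz(a) %*% ry(b) %*% rz(c)
}

# minimal RMSD by numerical optimization over rotations (multi-start),
# independent of the closed-form Kabsch solution
optim_rmsd <- function(A, B, starts = 12L, seed = 1L) {
  A <- sweep(A, 2L, colMeans(A))
  B <- sweep(B, 2L, colMeans(B))
  obj <- function(p) {
    R <- euler_rotation(p[1], p[2], p[3])
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  set.seed(seed)
  best <- Inf
  for (s in seq_len(starts)) {
    p0 <- stats::runif(3, 0, 2 * pi)
    r <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, r$value)
  }
  best
}

# static Betti-1 at a scale by GF(2) rank computations on the boundary
# matrices, independent of the persistence pairing algorithm
gf2_rank <- function(M) {
  if (length(M) == 0L || nrow(M) == 0L || ncol(M) == 0L) return(0L)
  M <- M %% 2L
  rank <- 0L
  row <- 1L
  for (col in seq_len(ncol(M))) {
    piv <- which(M[row:nrow(M), col] == 1L)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) M[c(row, piv), ] <- M[c(piv, row), ]
    hits <- which(M[, col] == 1L)
    hits <- setdiff(hits, row)
    if (length(hits)) M[hits, ] <- (M[hits, , drop = FALSE] + rep(M[row, ], each = length(hits))) %% 2L
    rank <- rank + 1L
    row <- row + 1L
    if (row > nrow(M)) break
  }
  rank
}

betti1_at <- function(complex, r) {
  L <- nrow(complex[[1L]])
  ed <- complex[[2L]]
  ed <- ed[ed$t <= r, , drop = FALSE]
  tr <- complex[[3L]]
  tr <- tr[tr$t <= r, , drop = FALSE]
  ne <- nrow(ed)
  if (ne == 0L) return(0L)
  # rank of d1 = L - components
  g <- igraph::graph_from_edgelist(as.matrix(ed[, c("v1", "v2")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < L) g <- igraph::add_vertices(g, L - igraph::vcount(g))
  rank_d1 <- L - igraph::components(g)$no
  rank_d2 <- 0L
  if (nrow(tr) > 0L) {
    ekey <- paste(ed$v1, ed$v2)
    D2 <- matrix(0L, ne, nrow(tr))
    for (ti in seq_len(nrow(tr))) {
      v <- sort(c(tr$v1[ti], tr$v2[ti], tr$v3[ti]))
      faces <- c(paste(v[1], v[2]), paste(v[1], v[3]), paste(v[2], v[3]))
      D2[match(faces, ekey), ti] <- 1L
    }
    rank_d2 <- gf2_rank(D2)
  }
  ne - rank_d1 - rank_d2
}

# bars of a barcode alive at scale r (born at or before, dying after)
bars_alive_at <- function(barcode, r) {
  sum(barcode$birth <= r & barcode$death > r)
}

# random rigid motion applied to an N x 3 coordinate matrix
random_rigid <- function(X, seed = 1L) {
  set.seed(seed)
  R <- euler_rotation(stats::runif(1, 0, 2 * pi), stats::runif(1, 0, pi),
                      stats::runif(1, 0, 2 * pi))
  sweep(X %*% t(R), 2L, stats::rnorm(3, sd = 5), "+")
}
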