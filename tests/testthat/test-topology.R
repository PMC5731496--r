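test_that("maxmin landmarks match brute force on the integer line", {
  line <- matrix(0:10, ncol = 1)
  lm <- maxmin_landmarks(line, 3, first = 1)  # forced to the point 0
  expect_equal(line[lm$indices], c(0, 10, 5))
  lm_all <- maxmin_landmarks(line, 11, first = 1)
  expect_setequal(lm_all$indices, 1:11)
  expect_equal(lm_all$coverage_radius, 0)
  expect_warning(maxmin_landmarks(line, 20, first = 1), "capping")
})

test_that("coverage radius is the exact max-min distance", {
  line <- matrix(0:10, ncol = 1)
  expect_equal(coverage_radius(line, c(1, 11)), 5)
  expect_equal(coverage_radius(line, 1:11), 0)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  expect_equal(coverage_radius(sq, 5L), sqrt(2) / 2)
})

test_that("coverage radius is non-increasing in the landmark count", {
  for (s in 1:3) {
    set.seed(s)
    X <- matrix(rnorm(60), 30, 2)
    rads <- vapply(1:30, function(n) {
      maxmin_landmarks(X, n, seed = s)$coverage_radius
    }, numeric(1))
    expect_true(all(diff(rads) <= 1e-12))
  }
})

test_that("the Rips complex enumerates the right simplices", {
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  rc <- rips_complex(tri, r = 1, max_dim = 2)
  expect_equal(nrow(rc$dim1), 3L)
  expect_equal(nrow(rc$dim2), 1L)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  rc2 <- rips_complex(sq, r = 1, max_dim = 2)
  expect_equal(nrow(rc2$dim1), 4L)  # no diagonals at r = 1
  expect_equal(nrow(rc2$dim2), 0L)
  rc3 <- rips_complex(sq, r = 0.5, max_dim = 2)
  expect_equal(nrow(rc3$dim1), 0L)  # below min pairwise distance
})

test_that("lazy witness appearance scales match hand enumeration", {
  two <- matrix(c(0, 1), 2, 1)
  fg <- lazy_witness_stream(two, 1:2, nu = 0)
  expect_equal(fg$edges$t, 1)
  coll <- matrix(c(0, 1, 2), 3, 1)
  fg2 <- lazy_witness_stream(coll, c(1, 3), nu = 1)
  expect_equal(fg2$edges$t, 0)  # the middle witness has d(y) = 1
  # nu = 0, landmarks = cloud: every Rips edge present at its length
  set.seed(3)
  X <- matrix(rnorm(16), 8, 2)
  fg3 <- lazy_witness_stream(X, 1:8, nu = 0)
  D <- as.matrix(dist(X))
  for (e in seq_len(nrow(fg3$edges)))
    expect_lte(fg3$edges$t[e], D[fg3$edges$i[e], fg3$edges$j[e]] + 1e-12)
})

test_that("the filtration is monotone and scale-consistent", {
  set.seed(8)
  X <- matrix(rnorm(40), 20, 2)
  lm <- maxmin_landmarks(X, 8, seed = 1)
  fg <- lazy_witness_stream(X, lm, nu = 0)
  ts <- sort(unique(fg$edges$t))
  counts <- vapply(ts, function(t) {
    length(unique(components_at_scale(fg, t)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  g1 <- lazy_witness_graph(X, lm, t = ts[2], nu = 0)
  g2 <- lazy_witness_graph(X, lm, t = ts[4], nu = 0)
  expect_true(all(paste(g1$edges$i, g1$edges$j) %in% paste(g2$edges$i, g2$edges$j)))
})

test_that("flag expansion assigns max-edge appearance to cliques", {
  fg <- structure(list(vertices = 1:3,
                       edges = data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                                          t = c(0.2, 0.5, 0.9))),
                  class = "filtered_graph")
  fc <- flag_expansion(fg, max_dim = 2)
  expect_equal(nrow(fc$dim2), 1L)
  expect_equal(fc$dim2$t, 0.9)
  # path graph: no triangles
  fgp <- structure(list(vertices = 1:3,
                        edges = data.frame(i = c(1, 2), j = c(2, 3),
                                           t = c(0.1, 0.2))),
                   class = "filtered_graph")
  expect_equal(nrow(flag_expansion(fgp, 2)$dim2), 0L)
  # K4 contains one tetrahedron
  fg4 <- structure(list(vertices = 1:4,
                        edges = data.frame(i = c(1, 1, 1, 2, 2, 3),
                                           j = c(2, 3, 4, 3, 4, 4),
                                           t = 1:6 / 10)),
                   class = "filtered_graph")
  expect_equal(nrow(flag_expansion(fg4, 3)$dim3), 1L)
})

test_that("H0 barcodes obey the elder rule and component counts", {
  # three mutually equidistant points: two deaths at the common distance
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  fg <- lazy_witness_stream(tri, 1:3, nu = 0)
  b <- h0_barcode(fg)
  expect_equal(sum(is.infinite(b$death)), 1L)
  expect_equal(b$birth, rep(0, 3))
  # single vertex
  one <- structure(list(vertices = 1L,
                        edges = data.frame(i = integer(0), j = integer(0),
                                           t = numeric(0))),
                   class = "filtered_graph")
  b1 <- h0_barcode(one)
  expect_equal(nrow(b1), 1L)
  expect_true(is.infinite(b1$death))
})

test_that("H0 deaths equal single-linkage merge heights on random clouds", {
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(40), 20, 2)
    b <- h0_barcode(lazy_witness_stream(X, 1:20, nu = 0))
    sl <- hclust(dist(X), method = "single")
    expect_equal(sort(b$death[is.finite(b$death)]), sort(sl$height),
                 tolerance = 1e-9)
  }
})

test_that("H1 barcodes match analytic fixtures", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  b <- h1_barcode(rips_filtration(sq, 2))
  expect_equal(nrow(b), 1L)
  expect_equal(b$birth, 1)
  expect_equal(b$death, sqrt(2))
  # filled triangle: no 1-cycle survives
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  bt <- h1_barcode(rips_filtration(tri, 2))
  expect_equal(nrow(bt), 0L)
  # regular octagon: exactly one long bar
  oct <- circle_cloud(8, radius = 1)$points
  bo <- h1_barcode(rips_filtration(oct, 2))
  long <- bo[bo$death - bo$birth > 0.2, ]
  expect_equal(nrow(long), 1L)
})

test_that("H1 interval counts agree with static Betti ranks at every scale", {
  fixtures <- list(circle_cloud(12, radius = 1)$points,
                   circle_cloud(9, radius = 2, noise = 0.1, seed = 4)$points)
  for (s in 1:3) {
    set.seed(s)
    fixtures[[length(fixtures) + 1L]] <- matrix(rnorm(20), 10, 2)
  }
  for (X in fixtures) {
    fc <- rips_filtration(X, 2)
    b <- h1_barcode(fc)
    probes <- sort(unique(c(fc$dim2$t, fc$dim3$t)))
    probes <- probes + 1e-9  # just after each appearance
    for (r in probes) {
      expect_equal(bars_alive_at(b, r), betti1_at(fc, r))
    }
  }
})

test_that("the H1 oracle refuses oversized complexes", {
  set.seed(1)
  X <- matrix(rnorm(80), 40, 2)  # K40 flag complex is way past the guard
  expect_error(h1_barcode(rips_filtration(X, 2)), "too large")
})

test_that("components at extreme scales are singletons or one block", {
  set.seed(12)
  X <- matrix(rnorm(30), 15, 2)
  lm <- maxmin_landmarks(X, 6, seed = 2)
  fg <- lazy_witness_stream(X, lm, nu = 0)
  tmin <- min(fg$edges$t)
  if (tmin > 0) {
    expect_equal(length(unique(components_at_scale(fg, tmin * 0.99))), 6L)
  }
  expect_equal(length(unique(components_at_scale(fg, max(fg$edges$t)))), 1L)
})

test_that("lazy witness edges at scale t contain the landmark Rips edges", {
  set.seed(20)
  X <- matrix(rnorm(24), 12, 2)
  D <- as.matrix(dist(X))
  fg <- lazy_witness_stream(X, 1:12, nu = 0)
  for (t in c(0.5, 1, 2)) {
    rips_edges <- which(D <= t & upper.tri(D), arr.ind = TRUE)
    present <- fg$edges[fg$edges$t <= t, ]
    key <- paste(present$i, present$j)
    if (nrow(rips_edges) > 0)
      expect_true(all(paste(rips_edges[, 1], rips_edges[, 2]) %in% key))
  }
})

test_that("three separated blobs split into three components mid-scale", {
  bl <- gaussian_blobs(3, 30, separation = 10, sigma = 0.3, seed = 6)
  lm <- maxmin_landmarks(bl$points, 15, seed = 3)
  fg <- lazy_witness_stream(bl$points, lm, nu = 0)
  comp <- components_at_scale(fg, 2)
  expect_equal(length(unique(comp)), 3L)
  # component labels match generating blob labels
  blob_of <- bl$labels[lm$indices]
  expect_equal(length(unique(paste(comp, blob_of))), 3L)
})
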