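make_level <- function(membership, landmarks = seq_along(membership),
                       level = length(unique(membership)), scale = 1) {
  structure(list(level = level, scale = scale,
                 membership = as.integer(membership), landmarks = landmarks),
            class = "cluster_level")
}

test_that("the landmark count rule stops when coverage saturates", {
  # 10 zero-width, widely separated micro-clusters: R collapses to 0 once
  # each holds a landmark, so every repetition stops early
  set.seed(2)
  centers <- matrix(runif(30, 0, 100), 10, 3)
  pts <- centers[rep(1:10, each = 12), ]
  n <- determine_landmark_count(pts, seed = 1)
  expect_lte(n, 30L)
  expect_gte(n, 10L)
  # a continuous 3D cloud needs many more landmarks before R saturates
  set.seed(3)
  cont <- matrix(runif(1500), 500, 3)
  expect_gt(determine_landmark_count(cont, seed = 1), 30L)
  # identical points: R = 0 at the first evaluable step -> 20
  same <- matrix(1, 40, 2)
  expect_equal(determine_landmark_count(same, seed = 3), 20L)
  # determinism under a fixed seed
  expect_equal(determine_landmark_count(pts, seed = 7),
               determine_landmark_count(pts, seed = 7))
  # tiny clouds fall back to all points
  expect_warning(n2 <- determine_landmark_count(matrix(rnorm(10), 5, 2)),
                 "smaller")
  expect_equal(n2, 5L)
})

test_that("the bar-gap rule counts persistent components", {
  bc <- function(deaths) structure(
    data.frame(degree = 0L, birth = 0, death = c(deaths, Inf)),
    class = c("barcode", "data.frame"))
  # two dominant merges over a noise floor
  expect_equal(cluster_count_from_barcode(bc(c(5.0, 4.9, 0.3, 0.28, 0.27))), 3L)
  # no gap above the threshold
  expect_equal(cluster_count_from_barcode(bc(c(0.30, 0.28, 0.27, 0.25))), 1L)
  # single landmark degenerates to one cluster
  expect_equal(cluster_count_from_barcode(bc(numeric(0))), 1L)
  # the gap threshold is configurable
  expect_equal(cluster_count_from_barcode(bc(c(0.30, 0.28, 0.25)), gap = 0.01), 3L)
})

test_that("cluster counts recover three well-separated blobs", {
  bl <- gaussian_blobs(3, 50, separation = 1, sigma = 0.02, seed = 10)
  lm <- maxmin_landmarks(bl$points, determine_landmark_count(bl$points, seed = 10),
                         seed = 10)
  expect_equal(determine_cluster_count(bl$points, lm), 3L)
  expect_equal(determine_cluster_count(bl$points, lm$indices[1]), 1L)
})

test_that("level partitions sit on the right filtration plateaus", {
  bl <- gaussian_blobs(3, 40, separation = 1, sigma = 0.02, seed = 4)
  lm <- maxmin_landmarks(bl$points, 21, seed = 5)
  L <- length(lm$indices)
  lv1 <- clusters_at_level(bl$points, lm, 1)
  expect_equal(length(unique(lv1$membership)), 1L)
  lvL <- clusters_at_level(bl$points, lm, L)
  expect_equal(length(unique(lvL$membership)), L)
  lv3 <- clusters_at_level(bl$points, lm, 3)
  expect_equal(length(unique(lv3$membership)), 3L)
  # partition equals blob labels
  expect_equal(length(unique(paste(lv3$membership, bl$labels[lm$indices]))), 3L)
})

test_that("outlier pruning drops small blocks and nothing else", {
  lv <- make_level(c(1, 1, 1, 2, 2, 3))
  pr <- prune_outliers(lv, min_size = 2)
  expect_equal(sum(pr$keep), 5L)
  expect_equal(length(unique(pr$level$membership)), 2L)
  # min_size 1 is the identity
  pr1 <- prune_outliers(lv, min_size = 1)
  expect_true(all(pr1$keep))
  # everything pruned errors
  expect_error(prune_outliers(make_level(1:4), min_size = 2), "pruned")
})

test_that("hierarchies are laminar with parents as block unions", {
  levels <- list(make_level(c(1, 1, 1, 1), level = 1),
                 make_level(c(1, 1, 2, 2), level = 2),
                 make_level(c(1, 3, 2, 2), level = 3))
  h <- build_hierarchy(levels)
  nodes <- h$nodes
  expect_equal(sum(is.na(nodes$parent)), 1L)  # single root
  # level-2 blocks are children of the root
  root <- nodes$id[is.na(nodes$parent)]
  expect_equal(nodes$parent[nodes$level == 2], rep(root, 2))
  # laminar: any two blocks disjoint or nested
  blocks <- list()
  for (li in seq_along(levels)) {
    for (b in unique(levels[[li]]$membership)) {
      blocks[[length(blocks) + 1L]] <- which(levels[[li]]$membership == b)
    }
  }
  for (i in seq_along(blocks)) for (j in seq_along(blocks)) {
    inter <- length(intersect(blocks[[i]], blocks[[j]]))
    expect_true(inter == 0L ||
                  inter == length(blocks[[i]]) || inter == length(blocks[[j]]))
  }
  # violated nesting is caught
  bad <- list(make_level(c(1, 1, 2, 2), level = 1),
              make_level(c(1, 2, 2, 1), level = 2))
  expect_error(build_hierarchy(bad), "nesting")
  # k = 1 gives a single root
  h1 <- build_hierarchy(list(make_level(rep(1, 4), level = 1)))
  expect_equal(nrow(h1$nodes), 1L)
})

test_that("filtration levels agree with the single-linkage tree", {
  set.seed(30)
  X <- matrix(rnorm(30), 15, 2)
  fg <- lazy_witness_stream(X, 1:15, nu = 0)
  for (i in c(2, 3, 5)) {
    lv <- clusters_at_level(X, 1:15, i, stream = fg)
    # oracle: single linkage on the same witness metric = the H0 filtration;
    # with landmarks = cloud and nu = 0 components match Euclidean
    # single-linkage cutree blocks
    sl <- cutree(hclust(dist(X), method = "single"), k = i)
    expect_equal(length(unique(lv$membership)), i)
    expect_equal(length(unique(paste(lv$membership, sl))), i)
  }
})

test_that("cluster reports carry sizes, population sds and representatives", {
  pair <- toy_chain_pair(9, 12, seed = 21)
  traj <- run_search(pair$start, pair$goal,
                     search_params(max_iterations = 400, seed = 9))
  cloud <- embed_trajectory(traj, "sphpca", d = 2)
  M <- length(traj$conformations)
  lv <- make_level(rep(1:2, length.out = M), landmarks = seq_len(M))
  rep_df <- cluster_report(lv, cloud, traj, list(pair$start, pair$goal))
  expect_s3_class(rep_df, "cluster_report")
  expect_equal(sum(rep_df$size), M)
  expect_true(all(diff(rep_df$mean_rmsd_1) >= 0))  # sorted by endpoint 1
  expect_true(all(rep_df$representative %in% seq_len(M)))
  # population sd convention on a hand-computed two-member cluster
  lv2 <- make_level(c(1, 1), landmarks = c(1L, which.min(traj$rmsd_to_goal)))
  r2 <- cluster_report(lv2, cloud, traj, list(pair$start, pair$goal))
  m <- vapply(c(1L, which.min(traj$rmsd_to_goal)), function(i) {
    kabsch_rmsd(trajectory_structure(traj, i), pair$start)
  }, numeric(1))
  expect_equal(r2$mean_rmsd_1, mean(m), tolerance = 1e-9)
  expect_equal(r2$sd_rmsd_1, sqrt(mean((m - mean(m))^2)), tolerance = 1e-9)
  # single-member cluster has sd 0
  lv3 <- make_level(1, landmarks = 2L)
  expect_equal(cluster_report(lv3, cloud, traj,
                              list(pair$start, pair$goal))$sd_rmsd_1, 0)
})

test_that("report numbering is invariant under input relabeling", {
  pair <- toy_chain_pair(8, 10, seed = 22)
  traj <- run_search(pair$start, pair$goal,
                     search_params(max_iterations = 300, seed = 10))
  cloud <- embed_trajectory(traj, "sphpca", d = 2)
  M <- length(traj$conformations)
  memb <- rep(1:3, length.out = M)
  lv_a <- make_level(memb, landmarks = seq_len(M))
  lv_b <- make_level(c(3, 1, 2)[memb], landmarks = seq_len(M))
  ra <- cluster_report(lv_a, cloud, traj, list(pair$start, pair$goal))
  rb <- cluster_report(lv_b, cloud, traj, list(pair$start, pair$goal))
  expect_equal(ra$mean_rmsd_1, rb$mean_rmsd_1, tolerance = 1e-12)
  expect_equal(ra$size, rb$size)
})

test_that("the full fit returns a coherent classed object", {
  bl <- gaussian_blobs(3, 60, separation = 1, sigma = 0.02, seed = 13)
  fit <- topo_cluster(bl$points, seed = 13)
  expect_s3_class(fit, "topo_clustering")
  expect_equal(fit$n_clusters, 3L)
  expect_equal(length(fit$membership), length(fit$retained))
  # levels are nested by construction
  expect_s3_class(fit$hierarchy, "cluster_dendrogram")
  expect_output(print(fit), "clusters")
  s <- summary(fit)
  expect_s3_class(s, "summary.topo_clustering")
  expect_equal(s$n_clusters, 3L)
})
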