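test_that("k-NN graph matches a brute-force all-pairs oracle", {
  cl <- random_cloud(200, seed = 12)
  g <- build_knn_graph(cl, k = 5)
  d <- as.matrix(stats::dist(cl$positions))
  # oracle edge set: symmetrized 5 nearest neighbours
  oracle <- matrix(FALSE, 200, 200)
  for (i in 1:200) {
    nn <- order(d[i, ])[2:6]
    oracle[i, nn] <- TRUE
    oracle[nn, i] <- TRUE
  }
  got <- matrix(FALSE, 200, 200)
  got[g$edges] <- TRUE
  got[g$edges[, 2:1]] <- TRUE
  # bridging may only ADD edges; for k=5 on 200 random points the raw graph
  # is connected, so the sets must agree exactly
  expect_identical(got, oracle)
  # weights are Euclidean distances
  expect_lt(max(abs(g$weights - d[g$edges])), 1e-12)
})

test_that("sparse graphs are bridged to connectivity", {
  pos <- rbind(cbind(seq(0, 1, length.out = 5), 0, 0),
               cbind(seq(100, 101, length.out = 5), 0, 0))
  cl <- point_cloud(pos, matrix(rep(c(0, 0, 1), each = 10), 10, 3))
  g <- build_knn_graph(cl, k = 2)
  expect_equal(igraph::components(g$graph)$no, 1)
  expect_true(all(is.finite(geodesic_distances(g, 1))))
  # three equidistant points, k = 1: symmetrization connects them
  tri <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                     matrix(rep(c(0, 0, 1), each = 3), 3, 3))
  gt <- build_knn_graph(tri, k = 1)
  expect_equal(igraph::components(gt$graph)$no, 1)
})

test_that("geodesics obey path-graph, metric and oracle checks", {
  chain <- point_cloud(cbind(0:9, 0, 0),
                       matrix(rep(c(0, 0, 1), each = 10), 10, 3))
  g <- build_knn_graph(chain, k = 1)
  expect_equal(geodesic_distances(g, 1), as.numeric(0:9))
  for (s in c(1, 13, 77)) {
    cl <- random_cloud(100, seed = s)
    gg <- build_knn_graph(cl, k = 4)
    gd <- geodesic_distances(gg, 1)
    eu <- sqrt(rowSums(sweep(cl$positions, 2, cl$positions[1, ])^2))
    expect_true(all(gd >= eu - 1e-9))
    bf <- bellman_ford_oracle(100, gg$edges, gg$weights, 1)
    expect_lt(max(abs(gd - bf)), 1e-12)
    # triangle inequality through a random pivot
    gd2 <- geodesic_distances(gg, 50)
    expect_true(all(gd <= gd[50] + gd2 + 1e-9))
  }
})

test_that("geodesic balls respect along-surface distance", {
  # chain spaced 1 mm: radius 2.5 mm from the end keeps exactly 3 points
  chain <- point_cloud(cbind(0:9, 0, 0),
                       matrix(rep(c(0, 0, 1), each = 10), 10, 3))
  g <- build_knn_graph(chain, k = 1)
  ball <- geodesic_ball(chain, g, c(0, 0, 0), radius_mm = 2.5,
                        transform = palatemark:::new_transform())
  expect_identical(sort(ball$indices), 1:3)
  # C-shaped curve: tips 3 mm apart straight-line, ~20 mm along the curve;
  # a 6 mm geodesic ball at one tip must exclude the other tip
  th <- seq(0, 2 * pi * 0.93, length.out = 60)
  r <- 20 / (2 * pi * 0.93)
  cpos <- cbind(r * cos(th), r * sin(th), 0)
  tip_gap <- sqrt(sum((cpos[1, ] - cpos[60, ])^2))
  expect_lt(tip_gap, 3.2)
  cc <- point_cloud(cpos, matrix(rep(c(0, 0, 1), each = 60), 60, 3))
  gc <- build_knn_graph(cc, k = 2)
  ballc <- geodesic_ball(cc, gc, cpos[1, ], radius_mm = 6,
                         transform = palatemark:::new_transform())
  expect_false(60 %in% ballc$indices)
  expect_true(1 %in% ballc$indices)
  # verified against the independent shortest-path oracle
  bf <- bellman_ford_oracle(60, gc$edges, gc$weights, ballc$center_index)
  expect_setequal(ballc$indices, which(bf <= 6))
  # monotone in radius
  ball4 <- geodesic_ball(cc, gc, cpos[1, ], radius_mm = 4,
                         transform = palatemark:::new_transform())
  expect_true(all(ball4$indices %in% ballc$indices))
})

test_that("DBSCAN clusters blobs, flags noise, matches the oracle", {
  set.seed(31)
  blob1 <- matrix(rnorm(30, 0, 0.3), 10, 3)
  blob2 <- matrix(rnorm(30, 0, 0.3), 10, 3) + 100
  lab <- dbscan_cluster(rbind(blob1, blob2), eps = 2, min_samples = 3)
  expect_equal(lab$n_clusters, 2)
  expect_true(all(lab$labels > 0))
  expect_equal(lab$centroids[1, ], colMeans(blob1))
  # isolated point with min_samples = 2 is noise
  lone <- dbscan_cluster(rbind(blob1, c(500, 500, 500)), eps = 2,
                         min_samples = 2)
  expect_identical(lone$labels[11], 0L)
  # brute-force density-reachability oracle on random 50-point sets
  for (s in 1:4) {
    set.seed(s)
    pts <- matrix(runif(150, 0, 10), 50, 3)
    got <- dbscan_cluster(pts, eps = 1.5, min_samples = 3)
    orc <- dbscan_oracle(pts, eps = 1.5, min_samples = 3)
    expect_identical(partition_of(got$labels), orc$partition)
    expect_identical(sort(which(got$labels == 0)), orc$noise)
  }
})

test_that("DBSCAN partitions are stable under input permutation", {
  set.seed(41)
  pts <- rbind(matrix(rnorm(36, 0, 0.4), 12, 3),
               matrix(rnorm(36, 5, 0.4), 12, 3),
               matrix(runif(15, -20, 20), 5, 3))
  base <- dbscan_cluster(pts, eps = 1.5, min_samples = 3)
  for (s in 1:3) {
    set.seed(s)
    perm <- sample.int(nrow(pts))
    shuf <- dbscan_cluster(pts[perm, ], eps = 1.5, min_samples = 3)
    back <- integer(nrow(pts))
    back[perm] <- shuf$labels
    expect_identical(partition_of(back), partition_of(base$labels))
  }
})

test_that("resolve_to_12 returns per-cluster means for 12 tight clusters", {
  set.seed(51)
  centers <- matrix(runif(36, -1, 1), 12, 3) * 10
  cand <- do.call(rbind, lapply(1:12, function(k)
    sweep(matrix(rnorm(c(63, 66)[1 + k %% 2], 0, 0.05),
                 ncol = 3), 2, centers[k, ], `+`)))
  lab <- dbscan_cluster(cand, eps = 0.5, min_samples = 3)
  expect_equal(lab$n_clusters, 12)
  cent <- resolve_to_12(lab, cand)
  for (k in 1:12) {
    m <- which(attr(cent, "membership") == k)
    expect_equal(cent[k, ], colMeans(cand[m, , drop = FALSE]),
                 tolerance = 1e-9)
  }
})

test_that("resolve_to_12 splits merged clusters with verified 2-means", {
  set.seed(61)
  centers <- matrix(runif(36, -8, 8), 12, 3)
  centers[2, ] <- centers[1, ] + c(0.8, 0, 0)    # two groups close together
  cand <- do.call(rbind, lapply(1:12, function(k)
    sweep(matrix(rnorm(15, 0, 0.05), 5, 3), 2, centers[k, ], `+`)))
  lab <- dbscan_cluster(cand, eps = 1.0, min_samples = 3)
  expect_lt(lab$n_clusters, 12)
  cent <- resolve_to_12(lab, cand)
  expect_equal(nrow(cent), 12)
  # every true center recovered within the blob scale
  d <- sqrt(palatemark:::cross_dist2_cpp(centers, cent))
  expect_lt(max(apply(d, 1, min)), 0.5)
  # 2-means split agrees with brute-force Lloyd on the merged group
  merged <- cand[1:10, ]
  sub <- palatemark:::kmeans2(merged)
  km <- stats::kmeans(merged, centers = merged[c(1, 6), ], algorithm = "Lloyd")
  expect_equal(length(unique(sub)), 2)
  agree <- mean((sub == sub[1]) == (km$cluster == km$cluster[1]))
  expect_true(agree %in% c(0, 1))   # same partition up to label swap
})

test_that("resolve_to_12 fails informatively below 12 candidates", {
  cand <- matrix(runif(33), 11, 3)
  lab <- dbscan_cluster(cand, eps = 10, min_samples = 1)
  expect_error(resolve_to_12(lab, cand), "detection failure.*11")
})

test_that("FDI labels follow the arch ordering and mirror correctly", {
  # ground-truth landmarks of canonically oriented synthetic casts must
  # receive their own labels back
  for (s in 1:8) {
    cast <- generate_dataset(1, cast_shape_params(target_vertices = 2500),
                             seed = s)[[1]]
    pc <- preprocess_cast(cast$mesh, cast$landmarks, n_points = 256)
    got <- assign_fdi_labels(pc$landmarks$points)
    expect_lt(max(abs(got$points - pc$landmarks$points)), 1e-12,
              label = sprintf("seed %d label assignment", s))
  }
  cast <- small_cast(seed = 3, target_vertices = 2500)
  pc <- preprocess_cast(cast$mesh, cast$landmarks, n_points = 256)
  mirrored <- pc$landmarks$points %*% diag(c(-1, 1, 1))
  got <- assign_fdi_labels(mirrored)
  # mirroring x swaps quadrants: point labelled 16 is now where 26 was
  expect_equal(got$points[got$labels == "26", ],
               pc$landmarks$points[1, ] * c(-1, 1, 1))
  dup <- pc$landmarks$points
  dup[2, ] <- dup[1, ]
  expect_error(assign_fdi_labels(dup), "ambiguous")
})
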