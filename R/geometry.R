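# Point-cloud geodesics and candidate clustering for the refinement stage.
# Geodesics are approximated by shortest paths on a symmetrized k-NN graph
# over the sampled cloud (the mesh connectivity no longer exists after
# farthest-point sampling), which captures the palate's curved anatomy far
# better than straight-line distances.

#' Build a symmetrized k-nearest-neighbour graph over a point cloud
#'
#' Edge weights are Euclidean distances. If the raw graph is disconnected,
#' components are bridged iteratively by the single shortest inter-component
#' edge so that all geodesics are finite.
#'
#' @param cloud a [point_cloud()].
#' @param k neighbours per point (default 8).
#' @return A `neighbor_graph`: `n`, `edges` (E x 2), `weights`, and the
#'   underlying igraph object in `$graph`.
#' @export
build_knn_graph <- function(cloud, k = 8) {
  pos <- cloud$positions
  n <- nrow(pos)
  if (n <= k) stop("need more points than neighbours (N > k)", call. = FALSE)
  kn <- knn_cpp(pos, as.integer(k))
  from <- rep(seq_len(n), k)
  to <- as.vector(kn$idx)
  w <- as.vector(kn$dist)
  # undirected: keep each unordered pair once
  a <- pmin(from, to); b <- pmax(from, to)
  key <- a * (n + 1) + b
  keep <- !duplicated(key)
  edges <- cbind(a[keep], b[keep])
  w <- w[keep]
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- w
  comp <- igraph::components(g)
  while (comp$no > 1) {
    main <- which(comp$membership == which.max(comp$csize))
    rest <- which(comp$membership != which.max(comp$csize))
    d2 <- cross_dist2_cpp(pos[rest, , drop = FALSE],
                          pos[main, , drop = FALSE])
    hit <- arrayInd(which.min(d2), dim(d2))
    i <- rest[hit[1]]; j <- main[hit[2]]
    g <- igraph::add_edges(g, c(i, j),
                           weight = sqrt(d2[hit[1], hit[2]]))
    edges <- rbind(edges, c(min(i, j), max(i, j)))
    w <- c(w, sqrt(d2[hit[1], hit[2]]))
    comp <- igraph::components(g)
  }
  structure(list(n = n, edges = edges, weights = w, graph = g),
            class = "neighbor_graph")
}

#' Single-source geodesic distances on a neighbour graph
#'
#' Dijkstra shortest paths from `source` to every node; the graph is
#' connected by construction so all distances are finite.
#'
#' @param graph a `neighbor_graph` from [build_knn_graph()].
#' @param source 1-based node index.
#' @return Numeric vector of length `graph$n`.
#' @export
geodesic_distances <- function(graph, source) {
  stopifnot(source >= 1, source <= graph$n)
  as.vector(igraph::distances(graph$graph, v = source, algorithm = "dijkstra"))
}

#' Extract a geodesic ball patch around a point
#'
#' The center is snapped to the nearest cloud point; `radius_mm` is converted
#' to normalized units through `transform$scale`, and the patch collects all
#' points whose graph geodesic to the snapped center is within the radius.
#'
#' @param cloud a [point_cloud()] (normalized frame).
#' @param graph `neighbor_graph` over the same cloud.
#' @param center_point 3-vector in the cloud's frame.
#' @param radius_mm patch radius in millimetres (default 6).
#' @param transform the `normalization_transform` of the cloud (mm ->
#'   normalized); its `scale` converts the radius.
#' @return A `local_patch`: `indices` (into the cloud), `positions`,
#'   `normals`, `center` (snapped), `center_index`, `radius_mm`,
#'   `radius_norm`.
#' @export
geodesic_ball <- function(cloud, graph, center_point, radius_mm = 6,
                          transform = new_transform()) {
  stopifnot(radius_mm > 0)
  pos <- cloud$positions
  d2 <- (pos[, 1] - center_point[1])^2 + (pos[, 2] - center_point[2])^2 +
    (pos[, 3] - center_point[3])^2
  ci <- which.min(d2)
  radius_norm <- radius_mm * transform$scale
  gd <- geodesic_distances(graph, ci)
  idx <- which(gd <= radius_norm)
  structure(list(indices = idx,
                 positions = pos[idx, , drop = FALSE],
                 normals = cloud$normals[idx, , drop = FALSE],
                 center = pos[ci, ], center_index = ci,
                 radius_mm = radius_mm, radius_norm = radius_norm,
                 geodesic = gd[idx]),
            class = "local_patch")
}

#' Density-based spatial clustering (DBSCAN)
#'
#' Standard DBSCAN semantics: a core point has at least `min_samples`
#' neighbours within `eps` (itself included); clusters grow by density
#' reachability; border points join the first-reached core's cluster;
#' unreachable points are noise. Deterministic given input order; no
#' randomness.
#'
#' @param points N x 3 matrix.
#' @param eps neighbourhood radius (same units as `points`).
#' @param min_samples core-point threshold (self-inclusive).
#' @return A `cluster_labeling`: `labels` (0 = noise, 1..K), `n_clusters`,
#'   `centroids` (K x 3 means of member points), `sizes`.
#' @export
dbscan_cluster <- function(points, eps, min_samples) {
  stopifnot(eps > 0, min_samples >= 1)
  points <- as_matrix3(points, "points")
  n <- nrow(points)
  d2 <- cross_dist2_cpp(points, points)
  nb <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))
  core <- vapply(nb, length, 1L) >= min_samples
  labels <- integer(n)        # 0 = unassigned/noise
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(queue)) {
      q <- queue[1]
      queue <- queue[-1]
      for (j in nb[[q]]) {
        if (labels[j] == 0L) labels[j] <- cl
        if (core[j] && !visited[j]) {
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  finalize_labeling(labels, points)
}

finalize_labeling <- function(labels, points) {
  k <- max(labels, 0L)
  cent <- if (k > 0)
    t(vapply(seq_len(k),
             function(c) colMeans(points[labels == c, , drop = FALSE]),
             numeric(3)))
  else matrix(numeric(0), 0, 3)
  structure(list(labels = labels, n_clusters = k, centroids = cent,
                 sizes = if (k > 0) tabulate(labels, k) else integer(0)),
            class = "cluster_labeling")
}

# deterministic 2-means: Lloyd from the two farthest-apart members
kmeans2 <- function(pts) {
  n <- nrow(pts)
  d2 <- cross_dist2_cpp(pts, pts)
  hit <- arrayInd(which.max(d2), dim(d2))
  c1 <- pts[min(hit), ]; c2 <- pts[max(hit), ]
  assign <- integer(n)
  for (iter in 1:100) {
    da <- (pts[, 1] - c1[1])^2 + (pts[, 2] - c1[2])^2 + (pts[, 3] - c1[3])^2
    db <- (pts[, 1] - c2[1])^2 + (pts[, 2] - c2[2])^2 + (pts[, 3] - c2[3])^2
    new_assign <- ifelse(da <= db, 1L, 2L)
    if (identical(new_assign, assign)) break
    assign <- new_assign
    if (all(assign == 1L) || all(assign == 2L)) break
    c1 <- colMeans(pts[assign == 1L, , drop = FALSE])
    c2 <- colMeans(pts[assign == 2L, , drop = FALSE])
  }
  assign
}

#' Resolve a clustering of candidate points to exactly 12 centroids
#'
#' Two clusters whose centroids are closer than `merge_dist` are first
#' merged (closest pair repeatedly): duplicate clusters on one tooth always
#' sit closer together than the smallest inter-tooth pitch, so merging
#' frees slots for under-covered teeth. While fewer than 12 clusters exist,
#' the noise point farthest from the existing centroids is promoted to a
#' new cluster — isolated candidates are typically the only coverage of a
#' sparsely detected tooth, so promotion is preferred over splitting; only
#' when no noise remains is the largest non-coincident cluster divided by
#' deterministic 2-means. With more than 12 clusters the 12 largest are
#' kept (ties by compactness, the smaller mean member-to-centroid
#' distance). Remaining noise points are finally recruited to their nearest
#' centroid.
#'
#' @param labeling a `cluster_labeling` from [dbscan_cluster()].
#' @param candidates the clustered points (N x 3).
#' @param merge_dist centroid-merging distance in the units of `candidates`
#'   (0 disables merging; the pipeline passes 2.5 mm converted to
#'   normalized units).
#' @return 12 x 3 matrix of centroids, with per-candidate final cluster ids
#'   in attribute `"membership"` (0 for unrecruited noise).
#' @export
resolve_to_12 <- function(labeling, candidates, merge_dist = 0) {
  candidates <- as_matrix3(candidates, "candidates")
  n <- nrow(candidates)
  if (n < 12)
    stop(sprintf("detection failure: only %d candidate points (need >= 12)", n),
         call. = FALSE)
  labels <- labeling$labels
  cent_of <- function(labels) {
    cls <- sort(unique(labels[labels > 0]))
    list(cls = cls,
         cent = t(vapply(cls, function(c)
           colMeans(candidates[labels == c, , drop = FALSE]), numeric(3))))
  }
  # merge duplicate clusters, closest centroid pair first
  if (merge_dist > 0) {
    repeat {
      co <- cent_of(labels)
      if (length(co$cls) < 2) break
      d2 <- cross_dist2_cpp(co$cent, co$cent)
      diag(d2) <- Inf
      hit <- arrayInd(which.min(d2), dim(d2))
      if (sqrt(d2[hit[1], hit[2]]) >= merge_dist) break
      labels[labels == co$cls[max(hit)]] <- co$cls[min(hit)]
    }
  }
  had_noise <- any(labels == 0L)
  repeat {
    k <- length(unique(labels[labels > 0]))
    if (k >= 12) break
    noise <- which(labels == 0L)
    if (length(noise)) {
      # promote the most isolated noise point to a new cluster
      if (k == 0) {
        pick <- noise[1]
      } else {
        co <- cent_of(labels)
        d2 <- cross_dist2_cpp(candidates[noise, , drop = FALSE], co$cent)
        pick <- noise[which.max(apply(d2, 1, min))]
      }
      labels[pick] <- max(labels) + 1L
      next
    }
    # no noise left: split the largest cluster with >= 2 distinct points
    sizes <- tabulate(labels, max(labels))
    split_done <- FALSE
    for (c in order(sizes, decreasing = TRUE)) {
      if (sizes[c] < 2) next
      members <- which(labels == c)
      pts <- candidates[members, , drop = FALSE]
      if (all(abs(sweep(pts, 2, pts[1, ])) < 1e-12)) next  # coincident
      sub <- kmeans2(pts)
      if (length(unique(sub)) < 2) next
      labels[members[sub == 2L]] <- max(labels) + 1L
      split_done <- TRUE
      break
    }
    if (!split_done)
      stop("detection failure: cannot resolve 12 clusters", call. = FALSE)
  }
  # rank clusters, keep the 12 largest (ties by compactness)
  co <- cent_of(labels)
  sizes <- vapply(co$cls, function(c) sum(labels == c), 1)
  spreads <- vapply(seq_along(co$cls), function(j) {
    m <- which(labels == co$cls[j])
    mean(sqrt(rowSums(sweep(candidates[m, , drop = FALSE], 2,
                            co$cent[j, ])^2)))
  }, 1)
  keep <- co$cls[order(-sizes, spreads)[1:12]]
  new_labels <- integer(n)
  for (r in seq_along(keep)) new_labels[labels == keep[r]] <- r
  # recruit never-clustered noise to its nearest centroid
  if (had_noise) {
    noise <- which(new_labels == 0L & labeling$labels == 0L)
    if (length(noise)) {
      cent <- t(vapply(1:12, function(c)
        colMeans(candidates[new_labels == c, , drop = FALSE]), numeric(3)))
      d2 <- cross_dist2_cpp(candidates[noise, , drop = FALSE], cent)
      new_labels[noise] <- max.col(-d2, ties.method = "first")
    }
  }
  cent <- t(vapply(1:12, function(c)
    colMeans(candidates[new_labels == c, , drop = FALSE]), numeric(3)))
  attr(cent, "membership") <- new_labels
  cent
}

#' Assign FDI tooth labels to 12 cluster centroids
#'
#' Requires the canonical anatomical frame (occlusal +z, anterior -y).
#' Centroids are ordered by their signed angle around the arch center (mean
#' centroid) in the x-y plane, sweeping from the most posterior-right tooth
#' to the most posterior-left, and labeled 16, 15, ..., 26 in that order.
#'
#' @param centroids 12 x 3 matrix in the canonical (normalized) frame.
#' @return A [landmark_set()] in the `normalized` frame.
#' @export
assign_fdi_labels <- function(centroids) {
  centroids <- as_matrix3(centroids, "centroids")
  stopifnot(nrow(centroids) == 12)
  ctr <- colMeans(centroids)
  xr <- centroids[, 1] - ctr[1]
  yr <- centroids[, 2] - ctr[2]
  # monotone from posterior-right (-) through anterior (0) to posterior-left
  ang <- atan2(-xr, -yr)
  if (min(diff(sort(ang))) < 1e-9)
    stop("ambiguous ordering: two centroids at the same arch angle",
         call. = FALSE)
  landmark_set(centroids[order(ang), , drop = FALSE], FDI_LABELS,
               frame = "normalized")
}
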