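# Independent brute-force oracles and small fixtures shared across tests.
# Oracles deliberately re-derive each quantity from its definition and never
# call the implementation path they check.

# greedy max-min farthest point sampling, O(N*m), ties by lowest index
fps_oracle <- function(X, m, start) {
  n <- nrow(X)
  mind <- rep(Inf, n)
  sel <- integer(m)
  cur <- start
  for (j in seq_len(m)) {
    sel[j] <- cur
    d2 <- (X[, 1] - X[cur, 1])^2 + (X[, 2] - X[cur, 2])^2 +
      (X[, 3] - X[cur, 3])^2
    mind <- pmin(mind, d2)
    cur <- which.max(mind)
  }
  sel
}

# Bellman-Ford single-source shortest paths on an undirected edge list
bellman_ford_oracle <- function(n, edges, weights, source) {
  dist <- rep(Inf, n)
  dist[source] <- 0
  for (it in seq_len(n)) {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]; w <- weights[e]
      if (dist[a] + w < dist[b]) { dist[b] <- dist[a] + w; changed <- TRUE }
      if (dist[b] + w < dist[a]) { dist[a] <- dist[b] + w; changed <- TRUE }
    }
    if (!changed) break
  }
  dist
}

# DBSCAN as literal density reachability: core points, transitive closure
# over core-core eps-neighbourhood, then border attachment. Returns a
# partition (list of sorted member index vectors) plus the noise set, which
# is label-invariant for comparison.
dbscan_oracle <- function(points, eps, min_samples) {
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= min_samples
  # connected components of the core-core reachability graph
  lab <- integer(n)
  cl <- 0L
  for (i in which(core)) {
    if (lab[i] > 0) next
    cl <- cl + 1L
    queue <- i
    lab[i] <- cl
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      for (j in intersect(nb[[q]], which(core))) {
        if (lab[j] == 0) { lab[j] <- cl; queue <- c(queue, j) }
      }
    }
  }
  for (i in which(!core)) {
    cores_near <- intersect(nb[[i]], which(core))
    if (length(cores_near)) lab[i] <- lab[cores_near[1]]
  }
  parts <- lapply(seq_len(cl), function(c) sort(which(lab == c)))
  list(partition = parts[order(vapply(parts, min, 1L))],
       noise = sort(which(lab == 0)))
}

partition_of <- function(labels) {
  cls <- sort(unique(labels[labels > 0]))
  parts <- lapply(cls, function(c) sort(which(labels == c)))
  parts[order(vapply(parts, min, 1L))]
}

# direct double-loop chamfer under the symmetric squared-mean convention
chamfer_oracle <- function(A, B) {
  m1 <- mean(apply(A, 1, function(a) min(colSums((t(B) - a)^2))))
  m2 <- mean(apply(B, 1, function(b) min(colSums((t(A) - b)^2))))
  m1 + m2
}

separation_oracle <- function(A, margin) {
  n <- nrow(A)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((A[i, ] - A[j, ])^2))
    tot <- tot + max(0, margin - d)^2
  }
  tot / (n * (n - 1) / 2)
}

huber_oracle <- function(e, delta = 1) {
  vapply(e, function(x)
    if (abs(x) <= delta) x^2 / 2 else delta * (abs(x) - delta / 2), 1)
}

# random unit normals
random_cloud <- function(n, seed = 1, frame = "normalized") {
  set.seed(seed)
  pos <- matrix(runif(n * 3, -1, 1), n, 3)
  nrm <- matrix(rnorm(n * 3), n, 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  point_cloud(pos, nrm, frame = frame)
}

random_landmarks <- function(seed = 1, frame = "normalized") {
  set.seed(seed)
  lm <- landmark_set(matrix(runif(36, -1, 1), 12, 3))
  lm$frame <- frame
  lm
}

# tiny network configs for gradient and contract tests (64-point inputs)
toy_coarse_config <- function() {
  coarse_config("scaled_down",
                radii = c(0.3, 0.6, 1.2), npoints = c(16L, 8L, 4L),
                nsample = c(8L, 8L, 8L),
                mlps = list(c(8, 8), c(8, 8), c(16, 16)),
                fp_mlps = list(c(8, 8), c(8, 8), c(8, 8)),
                head_width = 8L, n_candidates = 16L)
}

toy_refine_config <- function(patch_points = 64L) {
  refine_config("scaled_down",
                patch_points = patch_points,
                radii = c(0.3, 0.6, 1.2), npoints = c(16L, 8L, 4L),
                nsample = c(8L, 8L, 8L),
                mlps = list(c(8, 8), c(8, 8), c(16, 16)),
                fp_mlps = list(c(8, 8), c(8, 8), c(8, 8)),
                head_width = 8L)
}

as_patch <- function(cloud) {
  structure(list(indices = seq_len(nrow(cloud$positions)),
                 positions = cloud$positions, normals = cloud$normals,
                 center = colMeans(cloud$positions), center_index = 1L,
                 radius_mm = 6, radius_norm = 0.5,
                 is_dup = rep(FALSE, nrow(cloud$positions)),
                 n_unique = nrow(cloud$positions)),
            class = "local_patch")
}

# central finite differences over a parameter index subset
fd_gradient <- function(loss_fn, net, idx, h = 1e-4) {
  vapply(idx, function(i) {
    n1 <- net; n1$flat[i] <- n1$flat[i] + h
    n2 <- net; n2$flat[i] <- n2$flat[i] - h
    (loss_fn(n1) - loss_fn(n2)) / (2 * h)
  }, 1)
}

tetra_stl_text <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  lines <- c("solid tetra")
  for (i in 1:4) {
    lines <- c(lines, "  facet normal 0 0 0", "    outer loop",
               sprintf("      vertex %g %g %g",
                       v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
               "    endloop", "  endfacet")
  }
  c(lines, "endsolid tetra")
}

tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  # outward winding
  f <- rbind(c(1, 2, 4), c(2, 3, 4), c(3, 1, 4), c(1, 3, 2))
  dental_cast_mesh(v, f, "tetra")
}

small_cast <- function(seed = 1, target_vertices = 4000, ...) {
  generate_cast(cast_shape_params(seed = seed,
                                  target_vertices = target_vertices, ...))
}
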