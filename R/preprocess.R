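# Canonical orientation, [-1,1] bounding-box normalization, and
# farthest-point downsampling. A normalization_transform maps cast-frame mm
# coordinates q to normalized coordinates via  q' = scale * (R q + t);
# errors are always reported after inverting back to mm.

new_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                          scale = 1) {
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = as.numeric(scale)),
            class = "normalization_transform")
}

#' Apply or invert a normalization transform
#'
#' @param transform a `normalization_transform` (`rotation`, `translation`,
#'   `scale`), mapping mm to normalized coordinates as
#'   `q' = scale * (R q + t)`.
#' @param points N x 3 matrix.
#' @return Transformed N x 3 matrix.
#' @export
apply_transform <- function(transform, points) {
  points <- as_matrix3(points, "points")
  transform$scale *
    (points %*% t(transform$rotation) +
       matrix(transform$translation, nrow(points), 3, byrow = TRUE))
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform, points) {
  points <- as_matrix3(points, "points")
  (points / transform$scale -
     matrix(transform$translation, nrow(points), 3, byrow = TRUE)) %*%
    transform$rotation
}

# t2 after t1
compose_transform <- function(t2, t1) {
  new_transform(rotation = t2$rotation %*% t1$rotation,
                translation = as.vector(t2$rotation %*% t1$translation) +
                  t2$translation / t1$scale,
                scale = t2$scale * t1$scale)
}

#' Rotate a point cloud into the canonical anatomical frame
#'
#' Principal-component orientation with deterministic, annotation-free sign
#' and axis identification: the smallest-variance axis becomes z (sign so the
#' mean vertex normal points up, occlusal +z); of the two in-plane axes, the
#' antero-posterior one is identified by its larger absolute skewness (a
#' dental arch is symmetric transversely but strongly asymmetric
#' antero-posteriorly) and becomes y, signed so the farthest point along it
#' lies at negative y (incisors anterior-negative); x completes a
#' right-handed frame. Normals are rotated with the positions.
#'
#' @param cloud a [point_cloud()].
#' @return List: `cloud` (rotated, centered on the centroid) and `transform`.
#' @export
canonical_orient <- function(cloud) {
  pos <- cloud$positions
  if (nrow(pos) < 3) stop("degenerate geometry: need at least 3 points",
                          call. = FALSE)
  ctr <- colMeans(pos)
  x <- sweep(pos, 2, ctr)
  cv <- crossprod(x) / nrow(x)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] < 1e-12 * max(eg$values[1], 1e-300))
    stop("degenerate geometry: rank-deficient covariance (collinear points)",
         call. = FALSE)
  ax <- eg$vectors    # columns, decreasing variance
  zax <- ax[, 3]
  if (sum(colMeans(cloud$normals) * zax) < 0) zax <- -zax
  p1 <- x %*% ax[, 1]
  p2 <- x %*% ax[, 2]
  skew <- function(v) {
    s <- stats::sd(v)
    if (s == 0) return(0)
    mean((v - mean(v))^3) / s^3
  }
  ap_first <- abs(skew(p1)) >= abs(skew(p2))
  yax <- if (ap_first) ax[, 1] else ax[, 2]
  py <- if (ap_first) p1 else p2
  if (py[which.max(abs(py))] > 0) yax <- -yax
  xax <- c(yax[2] * zax[3] - yax[3] * zax[2],
           yax[3] * zax[1] - yax[1] * zax[3],
           yax[1] * zax[2] - yax[2] * zax[1])
  rot <- rbind(xax, yax, zax)
  dimnames(rot) <- NULL
  tf <- new_transform(rotation = rot, translation = as.vector(-rot %*% ctr),
                      scale = 1)
  out <- point_cloud(apply_transform(tf, pos),
                     cloud$normals %*% t(rot), frame = cloud$frame)
  list(cloud = out, transform = tf)
}

#' Scale a cloud to fit the normalized [-1, 1] bounding box
#'
#' Translates by the axis-aligned bounding-box center and scales
#' isotropically by 2 / (longest-axis extent), so the longest axis spans
#' exactly [-1, 1] and aspect ratios are preserved. Normals are
#' direction-only and unchanged.
#'
#' @param cloud a [point_cloud()].
#' @param prior optional transform already applied to `cloud` (e.g. from
#'   [canonical_orient()]); the returned transform is the composition, so it
#'   maps original cast-frame mm to normalized coordinates.
#' @return List: `cloud` (frame `normalized`) and `transform`.
#' @export
normalize_bbox <- function(cloud, prior = NULL) {
  pos <- cloud$positions
  lo <- apply(pos, 2, min)
  hi <- apply(pos, 2, max)
  ext <- hi - lo
  if (max(ext) <= 0) stop("degenerate geometry: zero extent", call. = FALSE)
  ctr <- (hi + lo) / 2
  tf <- new_transform(translation = -ctr, scale = 2 / max(ext))
  out <- point_cloud(apply_transform(tf, pos), cloud$normals,
                     frame = "normalized")
  full <- if (is.null(prior)) tf else compose_transform(tf, prior)
  list(cloud = out, transform = full)
}

#' Farthest-point sampling of a point cloud
#'
#' Greedy max-min selection: starting from `start`, repeatedly picks the
#' point maximizing its minimum distance to the already-selected set (ties
#' broken by lowest index). The default start is the point farthest from the
#' centroid, making the whole pipeline deterministic; pass `seed` for a
#' randomized start instead.
#'
#' @param cloud a [point_cloud()].
#' @param m number of points to keep.
#' @param start 1-based index of the first selected point, or `NULL`.
#' @param seed if non-NULL and `start` is NULL, the start is drawn uniformly.
#' @return A [point_cloud()] of `m` points, with the selected indices in
#'   attribute `"indices"`.
#' @export
farthest_point_sample <- function(cloud, m, start = NULL, seed = NULL) {
  n <- nrow(cloud$positions)
  if (m < 1 || m > n) stop(sprintf("cannot sample %d points from %d", m, n),
                           call. = FALSE)
  if (is.null(start)) {
    start <- if (!is.null(seed)) with_seed(seed, sample.int(n, 1))
    else default_fps_start(cloud$positions)
  }
  sel <- fps_cpp(cloud$positions, as.integer(m), as.integer(start))
  out <- point_cloud(cloud$positions[sel, , drop = FALSE],
                     cloud$normals[sel, , drop = FALSE], frame = cloud$frame)
  attr(out, "indices") <- sel
  out
}

default_fps_start <- function(pos) {
  ctr <- colMeans(pos)
  d2 <- (pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2 + (pos[, 3] - ctr[3])^2
  which.max(d2)
}

#' Preprocess a cast for the network pipeline
#'
#' Mesh to 6-channel cloud, canonical orientation, bounding-box
#' normalization, then farthest-point downsampling to `n_points`
#' (24,000 in the full profile). Ground-truth landmarks, when given, are
#' carried through the same transform so training targets live in
#' normalized space.
#'
#' @param mesh a [dental_cast_mesh()].
#' @param landmarks optional [landmark_set()] in the cast frame.
#' @param n_points points retained by farthest-point sampling.
#' @return A `preprocessed_cast`: `cloud` (normalized, sampled), `transform`
#'   (mm -> normalized), `landmarks` (normalized frame or NULL), `cast_id`.
#' @export
preprocess_cast <- function(mesh, landmarks = NULL, n_points = 24000) {
  cloud <- mesh_to_pointcloud(mesh)
  o <- canonical_orient(cloud)
  nb <- normalize_bbox(o$cloud, prior = o$transform)
  n_points <- min(n_points, nrow(nb$cloud$positions))
  sampled <- farthest_point_sample(nb$cloud, n_points)
  lm <- NULL
  if (!is.null(landmarks)) {
    stopifnot(inherits(landmarks, "landmark_set"))
    lm <- landmark_set(apply_transform(nb$transform, landmarks$points),
                       landmarks$labels, frame = "normalized")
  }
  structure(list(cloud = sampled, transform = nb$transform, landmarks = lm,
                 cast_id = mesh$cast_id),
            class = "preprocessed_cast")
}
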