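#' @useDynLib palatemark, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var kmeans predict
#' @importFrom utils write.csv head
NULL

#' Canonical FDI order of the 12 palatal gingival-margin landmarks
#'
#' Upper-right first molar to upper-left first molar: 16, 15, 14, 13, 12, 11,
#' 21, 22, 23, 24, 25, 26. All [landmark_set()] objects store points in this
#' order.
#' @export
FDI_LABELS <- c("16", "15", "14", "13", "12", "11",
                "21", "22", "23", "24", "25", "26")

#' Construct a dental cast mesh
#'
#' A triangular surface mesh of a maxillary dental cast in millimetres.
#'
#' @param vertices numeric V x 3 matrix of coordinates (mm).
#' @param faces integer F x 3 matrix of 1-based vertex indices.
#' @param cast_id character identifier.
#' @return An object of class `dental_cast_mesh` with elements `vertices`,
#'   `faces`, `cast_id`.
#' @export
dental_cast_mesh <- function(vertices, faces, cast_id = "cast") {
  vertices <- as_matrix3(vertices, "vertices")
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(vertices) < 4)
    stop("degenerate mesh: fewer than 4 vertices", call. = FALSE)
  if (!all(is.finite(vertices)))
    stop("mesh vertices contain non-finite coordinates", call. = FALSE)
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face index out of range", call. = FALSE)
    degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    if (any(degen))
      stop(sprintf("%d degenerate faces (repeated vertex index)", sum(degen)),
           call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces,
                 cast_id = as.character(cast_id)),
            class = "dental_cast_mesh")
}

#' @export
print.dental_cast_mesh <- function(x, ...) {
  cat(sprintf("<dental_cast_mesh '%s': %d vertices, %d faces>\n",
              x$cast_id, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Construct a 12-point palatal landmark set
#'
#' @param points numeric 12 x 3 matrix of coordinates, rows matching `labels`.
#' @param labels character FDI codes; must be a permutation of
#'   [FDI_LABELS]. Points are reordered into canonical order 16 -> 26.
#' @param frame coordinate frame tag, `"cast_mm"` or `"normalized"`.
#' @return An object of class `landmark_set`: `labels` (canonical order),
#'   `points`, `frame`.
#' @export
landmark_set <- function(points, labels = FDI_LABELS, frame = "cast_mm") {
  points <- as_matrix3(points, "points")
  labels <- as.character(labels)
  if (length(labels) != nrow(points))
    stop("labels and points length mismatch", call. = FALSE)
  unknown <- setdiff(labels, FDI_LABELS)
  if (length(unknown))
    stop(sprintf("unknown landmark labels: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  dup <- unique(labels[duplicated(labels)])
  if (length(dup))
    stop(sprintf("duplicate landmark labels: %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  missing <- setdiff(FDI_LABELS, labels)
  if (length(missing))
    stop(sprintf("missing landmark labels: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  if (!all(is.finite(points)))
    stop("landmark coordinates contain non-finite values", call. = FALSE)
  ord <- match(FDI_LABELS, labels)
  structure(list(labels = FDI_LABELS, points = points[ord, , drop = FALSE],
                 frame = match.arg(frame, c("cast_mm", "normalized"))),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set [%s], 12 points>\n", x$frame))
  m <- cbind(label = x$labels, round(as.data.frame(x$points), 3))
  colnames(m) <- c("label", "x", "y", "z")
  print(m, row.names = FALSE)
  invisible(x)
}

#' Construct a 6-channel point cloud (positions + unit normals)
#'
#' @param positions numeric N x 3 matrix.
#' @param normals numeric N x 3 matrix of unit vectors.
#' @param frame `"cast_mm"` or `"normalized"`.
#' @return Object of class `point_cloud`.
#' @export
point_cloud <- function(positions, normals, frame = "cast_mm") {
  positions <- as_matrix3(positions, "positions")
  normals <- as_matrix3(normals, "normals")
  if (nrow(positions) < 1) stop("empty point cloud", call. = FALSE)
  if (nrow(positions) != nrow(normals))
    stop("positions/normals size mismatch", call. = FALSE)
  if (!all(is.finite(positions)))
    stop("point cloud positions contain non-finite values", call. = FALSE)
  nn <- sqrt(rowSums(normals^2))
  if (any(abs(nn - 1) > 1e-6))
    stop("point cloud normals are not unit length", call. = FALSE)
  structure(list(positions = positions, normals = normals,
                 frame = match.arg(frame, c("cast_mm", "normalized"))),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud [%s]: %d points>\n", x$frame, nrow(x$positions)))
  invisible(x)
}

as_matrix3 <- function(x, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3) stop(sprintf("%s must have 3 columns", what), call. = FALSE)
  dimnames(x) <- NULL
  x
}
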