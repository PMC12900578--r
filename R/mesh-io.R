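#' Read a dental-cast surface mesh (STL or PLY)
#'
#' Reads binary or ASCII STL and ascii / binary_little_endian PLY. STL
#' triangle soup is welded by exact (bit-wise) coordinate equality — lab
#' scanners repeat shared vertices exactly, and tolerance welding could
#' collapse fine gingival detail.
#'
#' @param path file path; format detected from content, not extension.
#' @param cast_id identifier stored on the mesh; defaults to the file stem.
#' @return A [dental_cast_mesh()].
#' @export
read_mesh <- function(path, cast_id = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (is.null(cast_id)) cast_id <- sub("\\.[^.]*$", "", basename(path))
  head <- readBin(path, "raw", n = 16)
  txt <- rawToChar(head[head != as.raw(0)])
  mesh <- if (grepl("^ply", txt)) {
    read_ply(path)
  } else if (grepl("^\\s*solid", txt) && stl_is_ascii(path)) {
    read_stl_ascii(path)
  } else {
    read_stl_binary(path)
  }
  dental_cast_mesh(mesh$vertices, mesh$faces, cast_id)
}

stl_is_ascii <- function(path) {
  # a binary STL can also start with "solid"; require the facet keyword in
  # the first chunk and a size inconsistent with the binary layout
  raw <- readBin(path, "raw", n = 4096)
  if (any(raw == as.raw(0))) return(FALSE)
  grepl("facet", rawToChar(raw), fixed = TRUE)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vlines)) stop("STL parse error: no vertex records", call. = FALSE)
  toks <- strsplit(trimws(vlines), "\\s+")
  bad <- vapply(toks, length, 1L) != 4L
  if (any(bad)) stop("STL parse error: malformed vertex line", call. = FALSE)
  xyz <- suppressWarnings(
    vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (anyNA(xyz)) stop("STL parse error: non-numeric coordinate", call. = FALSE)
  soup <- t(xyz)
  if (nrow(soup) %% 3 != 0)
    stop("STL parse error: vertex count not a multiple of 3", call. = FALSE)
  weld_soup(soup)
}

read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 84) stop("STL parse error: truncated file", call. = FALSE)
  raw <- readBin(path, "raw", n = sz)
  ntri <- readBin(raw[81:84], "integer", size = 4, endian = "little")
  if (ntri <= 0 || sz < 84 + 50 * ntri)
    stop("STL parse error: truncated binary STL", call. = FALSE)
  # per triangle: 12B normal, 36B vertices, 2B attribute
  base <- 84 + 50 * (seq_len(ntri) - 1) + 12   # skip the normal
  byte_idx <- as.vector(outer(1:36, base, `+`))
  soup <- matrix(readBin(raw[byte_idx], "numeric", size = 4, n = 9 * ntri,
                         endian = "little"),
                 ncol = 3, byrow = TRUE)
  if (!all(is.finite(soup)))
    stop("STL parse error: non-finite coordinate", call. = FALSE)
  weld_soup(soup)
}

# exact bit-wise weld of repeated soup vertices (hex-float keys)
weld_soup <- function(soup) {
  key <- paste(sprintf("%a", soup[, 1]), sprintf("%a", soup[, 2]),
               sprintf("%a", soup[, 3]))
  uid <- match(key, key[!duplicated(key)])
  vertices <- soup[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  keep <- !(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
              faces[, 1] == faces[, 3])
  list(vertices = vertices, faces = faces[keep, , drop = FALSE])
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- read_line_bin(con)
    header <- c(header, ln)
    if (identical(trimws(ln), "end_header")) break
    if (length(header) > 500) stop("PLY parse error: unterminated header",
                                   call. = FALSE)
  }
  fmt_ln <- grep("^format ", header, value = TRUE)[1]
  if (is.na(fmt_ln)) stop("PLY parse error: no format line", call. = FALSE)
  fmt <- strsplit(trimws(fmt_ln), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop(sprintf("unsupported PLY format: %s", fmt), call. = FALSE)

  elems <- list(); cur <- NULL
  for (ln in header) {
    t <- strsplit(trimws(ln), "\\s+")[[1]]
    if (t[1] == "element") {
      cur <- t[2]
      elems[[cur]] <- list(n = as.integer(t[3]), props = list())
    } else if (t[1] == "property" && !is.null(cur)) {
      elems[[cur]]$props[[length(elems[[cur]]$props) + 1]] <-
        if (t[2] == "list") list(list = TRUE, ctype = t[3], itype = t[4],
                                 name = t[5])
        else list(list = FALSE, type = t[2], name = t[3])
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face))
    stop("PLY parse error: vertex/face elements required", call. = FALSE)

  if (fmt == "ascii") ply_read_ascii(con, elems) else ply_read_binary(con, elems)
}

read_line_bin <- function(con) {
  out <- raw()
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (!length(b) || b == as.raw(10)) break
    out <- c(out, b)
  }
  sub("\r$", "", rawToChar(out))
}

ply_type_size <- function(t) {
  switch(t, char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
         short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
         int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
         float = 4L, float32 = 4L, double = 8L, float64 = 8L,
         stop(sprintf("unsupported PLY type: %s", t), call. = FALSE))
}

ply_read_scalar <- function(con, t) {
  sz <- ply_type_size(t)
  if (t %in% c("float", "float32", "double", "float64"))
    readBin(con, "numeric", size = sz, n = 1, endian = "little")
  else readBin(con, "integer", size = sz, n = 1, signed = sz < 4,
               endian = "little")
}

ply_read_ascii <- function(con, elems) {
  nv <- elems$vertex$n
  vprops <- vapply(elems$vertex$props, function(p) p$name, "")
  xyz_col <- match(c("x", "y", "z"), vprops)
  if (anyNA(xyz_col)) stop("PLY parse error: x/y/z properties missing",
                           call. = FALSE)
  vertices <- matrix(0, nv, 3)
  for (i in seq_len(nv)) {
    t <- as.numeric(strsplit(trimws(read_line_bin(con)), "\\s+")[[1]])
    if (anyNA(t[xyz_col])) stop("PLY parse error: bad vertex line", call. = FALSE)
    vertices[i, ] <- t[xyz_col]
  }
  nf <- elems$face$n
  faces <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    t <- as.integer(strsplit(trimws(read_line_bin(con)), "\\s+")[[1]])
    if (t[1] != 3L) stop("PLY parse error: non-triangular face", call. = FALSE)
    faces[i, ] <- t[2:4] + 1L
  }
  list(vertices = vertices, faces = faces)
}

ply_read_binary <- function(con, elems) {
  nv <- elems$vertex$n
  vprops <- elems$vertex$props
  vertices <- matrix(0, nv, 3)
  for (i in seq_len(nv)) {
    vals <- c(x = NA_real_, y = NA_real_, z = NA_real_)
    for (p in vprops) {
      v <- ply_read_scalar(con, p$type)
      if (p$name %in% names(vals)) vals[p$name] <- v
    }
    if (anyNA(vals)) stop("PLY parse error: x/y/z missing", call. = FALSE)
    vertices[i, ] <- vals
  }
  nf <- elems$face$n
  fprop <- elems$face$props[[1]]
  if (!isTRUE(fprop$list)) stop("PLY parse error: face list property expected",
                                call. = FALSE)
  faces <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    cnt <- ply_read_scalar(con, fprop$ctype)
    if (cnt != 3) stop("PLY parse error: non-triangular face", call. = FALSE)
    for (j in 1:3) faces[i, j] <- ply_read_scalar(con, fprop$itype) + 1L
  }
  list(vertices = vertices, faces = faces)
}

#' Write a mesh to STL (ascii or binary) or ascii PLY
#'
#' @param mesh a [dental_cast_mesh()].
#' @param path output path; format chosen by `format` or the file extension.
#' @param format `"stl_ascii"`, `"stl_binary"`, or `"ply"`; default by
#'   extension (`.stl` -> binary STL, `.ply` -> ascii PLY).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "dental_cast_mesh"))
  if (is.null(format)) {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext == "ply") "ply" else "stl_binary"
  }
  format <- match.arg(format, c("stl_ascii", "stl_binary", "ply"))
  v <- mesh$vertices; f <- mesh$faces
  if (format == "ply") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
    return(invisible(path))
  }
  fn <- face_normals(v, f)
  if (format == "stl_ascii") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(sprintf("solid %s", mesh$cast_id), con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g",
                           fn$unit[i, 1], fn$unit[i, 2], fn$unit[i, 3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g",
                           v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", mesh$cast_id), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(charToRaw(sprintf("%-79s", paste("palatemark", mesh$cast_id))),
               as.raw(0))[1:80], con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    tri <- matrix(0, nrow(f), 12)
    tri[, 1:3] <- fn$unit
    tri[, 4:6] <- v[f[, 1], ]; tri[, 7:9] <- v[f[, 2], ]
    tri[, 10:12] <- v[f[, 3], ]
    payload <- writeBin(as.vector(t(tri)), raw(), size = 4, endian = "little")
    payload <- matrix(payload, nrow = 48)
    blocks <- rbind(payload, as.raw(0), as.raw(0))
    writeBin(as.vector(blocks), con)
  }
  invisible(path)
}

# per-face cross products: `vec` is the unnormalized normal (2x area x unit)
face_normals <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  vec <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- sqrt(rowSums(vec^2))
  unit <- vec / ifelse(nrm > 0, nrm, 1)
  list(vec = vec, unit = unit, norm = nrm)
}

#' Convert a mesh to a 6-channel point cloud
#'
#' One point per non-isolated vertex; vertex normals are area-weighted
#' averages of incident face normals (accumulated as face cross products,
#' then unit-normalized). Orientation follows face winding.
#'
#' @param mesh a [dental_cast_mesh()].
#' @return A [point_cloud()] in the `cast_mm` frame.
#' @export
mesh_to_pointcloud <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0) stop("degenerate mesh: no faces, all vertices isolated",
                         call. = FALSE)
  fn <- face_normals(v, f)
  idx <- as.vector(f)
  contrib <- fn$vec[rep(seq_len(nrow(f)), 3), , drop = FALSE]
  acc <- rowsum(contrib, group = idx)
  touched <- as.integer(rownames(acc))
  nrm <- sqrt(rowSums(acc^2))
  unit <- acc / ifelse(nrm > 0, nrm, 1)
  if (any(nrm == 0))
    unit[nrm == 0, ] <- matrix(c(0, 0, 1), sum(nrm == 0), 3, byrow = TRUE)
  point_cloud(v[touched, , drop = FALSE], unit, frame = "cast_mm")
}

#' Read a MeshLab PickPoints (.pp) landmark annotation
#'
#' Expects a `PickedPoints` XML root whose `point` elements carry `x`, `y`,
#' `z` and `name` attributes; names must be the 12 FDI codes 16-26. Output
#' order is normalized to 16 -> 26 regardless of file order.
#'
#' @param path .pp file path.
#' @return A [landmark_set()] in the `cast_mm` frame.
#' @export
read_pickpoints <- function(path) {
  doc <- xml2::read_xml(path)
  pts <- xml2::xml_find_all(doc, ".//point")
  if (!length(pts)) stop("annotation error: no point elements", call. = FALSE)
  labels <- xml2::xml_attr(pts, "name")
  xyz <- cbind(as.numeric(xml2::xml_attr(pts, "x")),
               as.numeric(xml2::xml_attr(pts, "y")),
               as.numeric(xml2::xml_attr(pts, "z")))
  if (anyNA(xyz)) stop("parse error: non-numeric coordinate in .pp",
                       call. = FALSE)
  landmark_set(xyz, labels, frame = "cast_mm")
}

#' Write a landmark set as MeshLab PickPoints XML
#'
#' Coordinates are written with 6 decimals; the `active` attribute is written
#' as 1 (and ignored by [read_pickpoints()]), following MeshLab 2022.02.
#'
#' @param landmarks a [landmark_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pickpoints <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  doc <- xml2::xml_new_root("PickedPoints")
  dd <- xml2::xml_add_child(doc, "DocumentData")
  xml2::xml_add_child(dd, "DateTime", date = format(Sys.Date()))
  for (i in 1:12) {
    xml2::xml_add_child(doc, "point",
                        x = sprintf("%.6f", landmarks$points[i, 1]),
                        y = sprintf("%.6f", landmarks$points[i, 2]),
                        z = sprintf("%.6f", landmarks$points[i, 3]),
                        name = landmarks$labels[i], active = "1")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read / write landmarks in the package's plain-JSON interchange format
#'
#' Format: `{"cast_id": ..., "landmarks": [{"label", "x", "y", "z"}, ...]}`.
#'
#' @param path file path.
#' @return [read_landmarks_json()]: a [landmark_set()].
#' @export
read_landmarks_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  landmark_set(cbind(obj$landmarks$x, obj$landmarks$y, obj$landmarks$z),
               obj$landmarks$label, frame = "cast_mm")
}

#' @rdname read_landmarks_json
#' @param landmarks a [landmark_set()].
#' @param cast_id identifier stored in the file.
#' @export
write_landmarks_json <- function(landmarks, path, cast_id = "cast") {
  stopifnot(inherits(landmarks, "landmark_set"))
  obj <- list(cast_id = cast_id,
              landmarks = data.frame(label = landmarks$labels,
                                     x = landmarks$points[, 1],
                                     y = landmarks$points[, 2],
                                     z = landmarks$points[, 3]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
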