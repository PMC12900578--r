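test_that("ASCII STL triangle soup is welded to the minimal closed mesh", {
  f <- withr::local_tempfile(fileext = ".stl")
  writeLines(tetra_stl_text(), f)
  mesh <- read_mesh(f)
  expect_s3_class(mesh, "dental_cast_mesh")
  expect_equal(nrow(mesh$vertices), 4)
  expect_equal(nrow(mesh$faces), 4)
})

test_that("mesh write/read round-trips preserve the vertex set", {
  cast <- small_cast(seed = 2, target_vertices = 600)
  for (fmt in c("stl_ascii", "stl_binary", "ply")) {
    f <- withr::local_tempfile(fileext = ".dat")
    write_mesh(cast$mesh, f, format = fmt)
    back <- read_mesh(f)
    tol <- if (fmt == "ply") 1e-6 else 1e-4   # STL stores 32-bit floats
    a <- cast$mesh$vertices[do.call(order, as.data.frame(cast$mesh$vertices)), ]
    b <- back$vertices[do.call(order, as.data.frame(back$vertices)), ]
    expect_equal(nrow(a), nrow(b), info = fmt)
    expect_lt(max(abs(a - b)), tol)
  }
})

test_that("STL soup welding is idempotent", {
  cast <- small_cast(seed = 3, target_vertices = 600)
  f1 <- withr::local_tempfile(fileext = ".stl")
  f2 <- withr::local_tempfile(fileext = ".stl")
  write_mesh(cast$mesh, f1, format = "stl_binary")
  m1 <- read_mesh(f1)
  write_mesh(m1, f2, format = "stl_binary")
  m2 <- read_mesh(f2)
  expect_equal(nrow(m1$vertices), nrow(m2$vertices))
  expect_equal(nrow(m1$faces), nrow(m2$faces))
})

test_that("unreadable or degenerate mesh files raise format errors", {
  f <- withr::local_tempfile(fileext = ".stl")
  writeBin(as.raw(1:50), f)
  expect_error(read_mesh(f), "truncated|parse")
  f2 <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid x", "  facet normal 0 0 0", "    outer loop",
               "      vertex 0 0 zebra", "    endloop", "  endfacet",
               "endsolid x"), f2)
  expect_error(read_mesh(f2), "parse error")
  expect_error(read_mesh(tempfile()), "no such file")
})

test_that("PickPoints round-trip normalizes order and preserves coordinates", {
  lm <- landmark_set(matrix(rnorm(36, sd = 20), 12, 3))
  f <- withr::local_tempfile(fileext = ".pp")
  write_pickpoints(lm, f)
  back <- read_pickpoints(f)
  expect_identical(back$labels, FDI_LABELS)
  expect_lt(max(abs(back$points - lm$points)), 1e-6)
  # scrambled file order is normalized to canonical order
  doc <- xml2::read_xml(f)
  pts <- xml2::xml_find_all(doc, ".//point")
  shuf <- xml2::xml_new_root("PickedPoints")
  for (i in rev(seq_along(pts))) xml2::xml_add_child(shuf, pts[[i]])
  f2 <- withr::local_tempfile(fileext = ".pp")
  xml2::write_xml(shuf, f2)
  back2 <- read_pickpoints(f2)
  expect_identical(back2$labels, FDI_LABELS)
  expect_equal(back2$points, back$points)
  # second write is semantically identical
  f3 <- withr::local_tempfile(fileext = ".pp")
  write_pickpoints(back, f3)
  expect_equal(read_pickpoints(f3)$points, back$points)
})

test_that("missing, duplicate and malformed landmark annotations are rejected", {
  lm <- landmark_set(matrix(rnorm(36), 12, 3))
  f <- withr::local_tempfile(fileext = ".pp")
  write_pickpoints(lm, f)
  doc <- xml2::read_xml(f)
  pts <- xml2::xml_find_all(doc, ".//point")
  # drop landmark 23
  xml2::xml_remove(pts[[which(FDI_LABELS == "23")]])
  f2 <- withr::local_tempfile(fileext = ".pp")
  xml2::write_xml(doc, f2)
  expect_error(read_pickpoints(f2), "missing.*23")
  expect_error(landmark_set(matrix(0, 12, 3), c(FDI_LABELS[-2], "16")),
               "duplicate")
  expect_error(landmark_set(matrix(0, 12, 3), c(FDI_LABELS[-1], "99")),
               "unknown")
})

test_that("JSON landmark interchange round-trips", {
  lm <- landmark_set(matrix(rnorm(36, sd = 10), 12, 3))
  f <- withr::local_tempfile(fileext = ".json")
  write_landmarks_json(lm, f, cast_id = "t1")
  back <- read_landmarks_json(f)
  expect_equal(back$points, lm$points, tolerance = 1e-12)
})

test_that("vertex normals follow face geometry", {
  # flat square: both triangles in the z=0 plane, consistent winding
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  f <- rbind(c(1, 2, 3), c(1, 3, 4))
  pc <- mesh_to_pointcloud(dental_cast_mesh(v, f))
  expect_equal(pc$normals, matrix(rep(c(0, 0, 1), each = 4), 4, 3),
               tolerance = 1e-12)
  # convex tetrahedron with outward winding: normals point away from center
  tm <- tetra_mesh()
  pc2 <- mesh_to_pointcloud(tm)
  ctr <- colMeans(tm$vertices)
  dots <- rowSums(pc2$normals * sweep(tm$vertices, 2, ctr))
  expect_true(all(dots > 0))
})

test_that("vertex normals equal the brute-force area-weighted accumulation", {
  cast <- small_cast(seed = 4, target_vertices = 520)
  mesh <- cast$mesh
  # keep a face subset over the full vertex set: some vertices stay isolated
  sub <- dental_cast_mesh(mesh$vertices, mesh$faces[1:60, , drop = FALSE])
  pc <- mesh_to_pointcloud(sub)
  # independent accumulation: explicit per-face loop
  acc <- matrix(0, nrow(sub$vertices), 3)
  for (i in seq_len(nrow(sub$faces))) {
    tri <- sub$faces[i, ]
    e1 <- sub$vertices[tri[2], ] - sub$vertices[tri[1], ]
    e2 <- sub$vertices[tri[3], ] - sub$vertices[tri[1], ]
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    for (k in tri) acc[k, ] <- acc[k, ] + cr
  }
  touched <- which(rowSums(abs(acc)) > 0)
  expected <- acc[touched, ] / sqrt(rowSums(acc[touched, , drop = FALSE]^2))
  expect_equal(nrow(pc$positions), length(touched))
  expect_lt(max(abs(pc$normals - expected)), 1e-9)
  # isolated vertices were dropped
  expect_lt(nrow(pc$positions), nrow(sub$vertices))
})

test_that("mesh invariants are enforced", {
  v <- matrix(rnorm(12), 4, 3)
  expect_error(dental_cast_mesh(v[1:3, ], rbind(c(1, 2, 3))), "4 vertices")
  expect_error(dental_cast_mesh(v, rbind(c(1, 2, 5))), "out of range")
  expect_error(dental_cast_mesh(v, rbind(c(1, 2, 2))), "degenerate")
  pc <- point_cloud(v, matrix(rep(c(0, 0, 1), each = 4), 4, 3))
  expect_error(point_cloud(v, v), "unit length")
  expect_s3_class(pc, "point_cloud")
})
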