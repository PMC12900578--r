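test_that("patch standardization resamples, pads, and flags duplicates", {
  cfg <- refine_config("scaled_down")   # 256-point patches
  big <- as_patch(random_cloud(500, seed = 26))
  std <- standardize_patch(big, cfg)
  expect_equal(nrow(std$positions), 256)
  expect_false(any(std$is_dup))
  # farthest-point property: the retained subset spreads at least as well
  # as random subsets
  d_std <- min(stats::dist(std$positions))
  set.seed(27)
  rand <- replicate(50, min(stats::dist(big$positions[sample.int(500, 256), ])))
  expect_true(all(d_std >= rand))
  # exact size: unchanged membership
  exact <- as_patch(random_cloud(256, seed = 28))
  expect_identical(standardize_patch(exact, cfg)$indices, exact$indices)
  # small patch: padded by repetition with flags
  small <- as_patch(random_cloud(100, seed = 29))
  pad <- standardize_patch(small, cfg)
  expect_equal(nrow(pad$positions), 256)
  expect_equal(sum(pad$is_dup), 156)
  expect_equal(pad$n_unique, 100)
})

test_that("refinement forward yields a probability map over the patch", {
  patch <- as_patch(random_cloud(64, seed = 30))
  net <- refine_init(toy_refine_config(), seed = 3)
  out <- refine_forward(patch, net)
  expect_equal(sum(out$prob), 1, tolerance = 1e-6)
  expect_true(all(out$prob >= 0 & out$prob <= 1))
  # permuting patch points permutes probabilities identically
  set.seed(31)
  perm <- sample.int(64)
  pp <- patch
  pp$positions <- patch$positions[perm, ]
  pp$normals <- patch$normals[perm, ]
  pp$indices <- patch$indices[perm]
  outp <- refine_forward(pp, net)
  expect_equal(outp$prob, out$prob[perm], tolerance = 1e-8)
})

test_that("heatmap targets concentrate, stay symmetric, and normalize", {
  # coincident landmark with tiny sigma concentrates the mass
  patch <- as_patch(random_cloud(64, seed = 32))
  tf <- palatemark:::new_transform(scale = 1)
  spacing <- min(stats::dist(patch$positions))
  t1 <- heatmap_target(patch, patch$positions[7, ], sigma = 0.1 * spacing,
                       transform = tf)
  expect_gt(t1[7], 0.99)
  # symmetric grid: symmetric probabilities
  gx <- as.matrix(expand.grid(x = -3:3, y = -3:3))
  gridpos <- cbind(gx, 0)
  gp <- structure(list(indices = seq_len(nrow(gridpos)), positions = gridpos,
                       normals = matrix(rep(c(0, 0, 1), each = nrow(gridpos)),
                                        ncol = 3),
                       center = c(0, 0, 0), center_index = 25L,
                       radius_mm = 6, radius_norm = 6,
                       is_dup = rep(FALSE, nrow(gridpos)), n_unique = 49L),
                  class = "local_patch")
  tg <- heatmap_target(gp, c(0, 0, 0), sigma = 2, transform = tf)
  m <- matrix(tg, 7, 7)
  expect_lt(max(abs(m - m[7:1, ])), 1e-12)
  expect_lt(max(abs(m - t(m))), 1e-12)
  # normalization over random patches
  for (s in 1:10) {
    p <- as_patch(random_cloud(40, seed = 100 + s))
    expect_equal(sum(heatmap_target(p, p$positions[1, ] + 0.05,
                                    sigma = 1,
                                    transform = palatemark:::new_transform(
                                      scale = 0.05))), 1, tolerance = 1e-12)
  }
  # a landmark far outside the patch is a supervision gap
  expect_error(heatmap_target(patch, c(500, 500, 500), sigma = 1,
                              transform = palatemark:::new_transform(
                                scale = 0.05)),
               "supervision gap")
})

test_that("cross-entropy refinement loss has its closed forms", {
  onehot <- c(1, rep(0, 63))
  expect_equal(refine_loss(onehot, onehot), 0, tolerance = 1e-10)
  unif <- rep(1 / 64, 64)
  expect_equal(refine_loss(unif, onehot), log(64), tolerance = 1e-9)
  set.seed(33)
  p <- softmax <- exp(rnorm(20)); p <- p / sum(p)
  t <- exp(rnorm(20)); t <- t / sum(t)
  direct <- -sum(t * log(p + 1e-12))
  expect_equal(refine_loss(p, t), direct, tolerance = 1e-12)
  expect_gte(refine_loss(p, t), -sum(t * log(t)) - 1e-9)   # >= entropy
})

test_that("landmark extraction snaps to the argmax cloud point", {
  cl <- random_cloud(64, seed = 34)
  patch <- as_patch(cl)
  tf <- palatemark:::new_transform(scale = 0.05)
  onehot <- rep(0, 64); onehot[17] <- 1
  got <- extract_landmark(patch, onehot, tf)
  expect_equal(as.vector(got),
               as.vector(invert_transform(tf, cl$positions[17, , drop = FALSE])))
  expect_identical(attr(got, "cloud_index"), 17L)
  # uniform map: documented tie-break to the lowest parent index
  unif <- rep(1 / 64, 64)
  expect_identical(attr(extract_landmark(patch, unif, tf), "cloud_index"), 1L)
  # merging padded duplicates never changes the argmax relative to the
  # unpadded patch: identical copies get identical per-copy probabilities,
  # and mean-merging preserves the ordering of the unique points
  padded <- standardize_patch(as_patch(random_cloud(40, seed = 35)),
                              refine_config("scaled_down", patch_points = 64L))
  net <- refine_init(toy_refine_config(), seed = 5)
  prob_pad <- refine_forward(padded, net)$prob
  copies <- split(prob_pad, padded$indices)
  expect_true(all(vapply(copies, function(v) diff(range(v)) < 1e-12, TRUE)))
  i_merged <- attr(extract_landmark(padded, prob_pad, tf), "cloud_index")
  first_copy <- !duplicated(padded$indices)
  i_unpadded <- padded$indices[first_copy][which.max(prob_pad[first_copy])]
  expect_identical(i_merged, i_unpadded)
})

test_that("oracle probability maps bound the extraction error by sampling", {
  cast <- small_cast(seed = 36, target_vertices = 2500)
  pc <- preprocess_cast(cast$mesh, cast$landmarks, n_points = 1024)
  graph <- build_knn_graph(pc$cloud, k = 8)
  cfg <- refine_config("scaled_down")
  mm_cloud <- invert_transform(pc$transform, pc$cloud$positions)
  for (k in c(1, 6, 12)) {
    ball <- geodesic_ball(pc$cloud, graph, pc$landmarks$points[k, ],
                          radius_mm = 6, transform = pc$transform)
    patch <- standardize_patch(ball, cfg)
    prob <- heatmap_target(patch, pc$landmarks$points[k, ], sigma = 1,
                           transform = pc$transform)
    got <- extract_landmark(patch, prob, pc$transform)
    err <- sqrt(sum((got - cast$landmarks$points[k, ])^2))
    nearest <- min(sqrt(rowSums(sweep(mm_cloud, 2,
                                      cast$landmarks$points[k, ])^2)))
    expect_lte(err, nearest + 1e-9)
  }
})
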