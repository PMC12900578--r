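test_that("coarse targets point every cloud point at its nearest landmark", {
  cl <- random_cloud(1000, seed = 14)
  lm <- random_landmarks(seed = 15)
  tg <- coarse_targets(cl, lm)
  # p + offset lands exactly on a landmark
  landed <- cl$positions + tg$true_offset
  d <- sqrt(palatemark:::cross_dist2_cpp(landed, lm$points))
  expect_lt(max(apply(d, 1, min)), 1e-12)
  # brute-force 12-way scan
  for (i in seq_len(nrow(cl$positions))) {
    di <- sqrt(colSums((t(lm$points) - cl$positions[i, ])^2))
    expect_identical(tg$nearest[i], which.min(di))
    expect_equal(tg$true_distance[i], min(di), tolerance = 1e-12)
  }
  # a point coincident with landmark 11 has zero distance and offset
  cl2 <- cl
  cl2$positions[1, ] <- lm$points[6, ]   # "11" is the 6th canonical label
  tg2 <- coarse_targets(cl2, lm)
  expect_equal(tg2$true_distance[1], 0)
  expect_equal(tg2$true_offset[1, ], c(0, 0, 0))
  # frame mismatch is refused
  lm_mm <- landmark_set(lm$points, lm$labels, frame = "cast_mm")
  expect_error(coarse_targets(cl, lm_mm), "frame")
})

test_that("candidate generation selects smallest predicted distances", {
  cl <- random_cloud(100, seed = 16)
  out <- list(pred_distance = seq_len(100) / 100,
              pred_offset = matrix(0, 100, 3))
  cand <- make_candidates(cl, out, 10)
  expect_identical(attr(cand, "indices"), 1:10)
  # zero offsets: candidates are input positions
  expect_identical(unclass(cand)[, ], cl$positions[1:10, ])
  # oracle predictions put every candidate on a landmark: chamfer = 0
  lm <- random_landmarks(seed = 17)
  tg <- coarse_targets(cl, lm)
  oracle_out <- list(pred_distance = tg$true_distance,
                     pred_offset = tg$true_offset)
  cand2 <- make_candidates(cl, oracle_out, 64)
  expect_lt(chamfer_loss(cand2, lm), 1e-20)
  expect_error(make_candidates(cl, out, 101), "more candidates")
})

test_that("distance loss follows the Huber form", {
  expect_equal(distance_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  e <- 0.3
  expect_equal(distance_loss(rep(e, 5), rep(0, 5)), e^2 / 2)
  expect_equal(distance_loss(rep(2, 5), rep(0, 5)), 1 * (2 - 0.5))
  set.seed(18)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(distance_loss(a, b), mean(huber_oracle(a - b)),
               tolerance = 1e-12)
})

test_that("chamfer loss matches hand arithmetic and the brute-force oracle", {
  # 1-D toy: candidates {0}, landmarks {1, 3} -> 1 + (1+9)/2 = 6
  expect_equal(chamfer_loss(matrix(0, 1, 1), matrix(c(1, 3), 2, 1)), 6)
  lm12 <- matrix(rnorm(36), 12, 3)
  expect_equal(chamfer_loss(lm12, lm12), 0)
  set.seed(19)
  for (i in 1:3) {
    A <- matrix(rnorm(30), 10, 3)
    B <- matrix(rnorm(21), 7, 3)
    expect_equal(chamfer_loss(A, B), chamfer_oracle(A, B), tolerance = 1e-12)
  }
})

test_that("separation loss penalizes only sub-margin pairs", {
  spread <- cbind(seq(0, 10, length.out = 8), 0, 0)
  expect_equal(separation_loss(spread, margin = 0.05), 0)
  # exactly one coincident pair among well-separated candidates
  pts <- rbind(spread, spread[1, ])
  m <- 0.05
  expect_equal(separation_loss(pts, margin = m), m^2 / choose(9, 2))
  set.seed(20)
  A <- matrix(rnorm(24, sd = 0.05), 8, 3)
  expect_equal(separation_loss(A, margin = 0.1),
               separation_oracle(A, 0.1), tolerance = 1e-12)
})

test_that("total loss composes linearly and vanishes for oracle predictions", {
  cast <- small_cast(seed = 21, target_vertices = 2500)
  pc <- preprocess_cast(cast$mesh, cast$landmarks, n_points = 512)
  tg <- coarse_targets(pc$cloud, pc$landmarks)
  oracle_out <- structure(list(pred_distance = tg$true_distance,
                               pred_offset = tg$true_offset),
                          class = "coarse_output")
  cfg <- coarse_config("scaled_down")
  cand <- make_candidates(pc$cloud, oracle_out, 64)
  total <- coarse_total_loss(oracle_out, tg, cand, pc$landmarks, config = cfg)
  comp <- attr(total, "components")
  # distance, offset and chamfer supervision are exactly satisfied; only the
  # separation hinge can be active (candidates sharing a landmark coincide)
  expect_equal(unname(comp["dist"]), 0)
  expect_equal(unname(comp["offset"]), 0)
  expect_equal(unname(comp["chamfer"]), 0)
  expect_lt(comp["separation"], 1e-3)
  expect_equal(as.numeric(total),
               unname(cfg$loss_weights["separation"] * comp["separation"]))
  # doubling one weight doubles that component's contribution
  w2 <- cfg$loss_weights
  w2["chamfer"] <- 2
  set.seed(22)
  noisy <- structure(list(pred_distance = tg$true_distance + 0.1,
                          pred_offset = tg$true_offset + 0.05),
                     class = "coarse_output")
  cand_n <- make_candidates(pc$cloud, noisy, 64)
  t1 <- coarse_total_loss(noisy, tg, cand_n, pc$landmarks,
                          weights = cfg$loss_weights, config = cfg)
  t2 <- coarse_total_loss(noisy, tg, cand_n, pc$landmarks, weights = w2,
                          config = cfg)
  expect_equal(as.numeric(t2 - t1),
               unname(attr(t1, "components")["chamfer"]), tolerance = 1e-12)
})

test_that("coarse forward has the contracted shapes and determinism", {
  cl <- random_cloud(64, seed = 23)
  net <- coarse_init(toy_coarse_config(), seed = 1)
  out1 <- coarse_forward(cl, net)
  expect_length(out1$pred_distance, 64)
  expect_identical(dim(out1$pred_offset), c(64L, 3L))
  expect_true(all(is.finite(out1$pred_distance)))
  expect_true(all(out1$pred_distance >= 0))
  expect_true(all(is.finite(out1$pred_offset)))
  out2 <- coarse_forward(cl, net)
  expect_identical(out1$pred_distance, out2$pred_distance)
  # mm-frame clouds are refused
  cl_mm <- point_cloud(cl$positions, cl$normals, frame = "cast_mm")
  expect_error(coarse_forward(cl_mm, net), "normalized")
})

test_that("coarse outputs are equivariant under input permutation", {
  cl <- random_cloud(64, seed = 24)
  net <- coarse_init(toy_coarse_config(), seed = 2)
  out <- coarse_forward(cl, net)
  set.seed(25)
  perm <- sample.int(64)
  clp <- point_cloud(cl$positions[perm, ], cl$normals[perm, ],
                     frame = "normalized")
  outp <- coarse_forward(clp, net)
  expect_equal(outp$pred_distance, out$pred_distance[perm], tolerance = 1e-8)
  expect_equal(outp$pred_offset, out$pred_offset[perm, ], tolerance = 1e-8)
})
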