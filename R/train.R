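# Two training loops (coarse, then refinement) and the end-to-end
# predictor. All randomness (splits, weight init, batch order) derives from
# one root seed split into fixed substreams, so a run is bit-reproducible on
# a given platform.

#' Pipeline configuration
#'
#' Bundles the per-stage network configs with the sampling, clustering, and
#' optimization settings of the full workflow.
#'
#' @param profile `"full"` (24,000 points, 256 candidates, 1,024-point
#'   patches) or `"scaled_down"` (2,048 / 64 / 256, halved channels) — the
#'   latter trains on a single CPU in minutes and is the default for tests
#'   and examples.
#' @param ... named overrides (`n_points`, `coarse`, `refine`,
#'   `coarse_epochs`, `refine_epochs`, `coarse_lr`, `refine_lr`,
#'   `grad_clip_norm`, `batch_size`, `split_fractions`, `dbscan_eps_mm`,
#'   `dbscan_min_samples`, `cluster_merge_mm`, `dedup_mm`, `knn_k`,
#'   `ball_radius_mm`, `sdr_thresholds`, `oracle_patches`,
#'   `oracle_patch_jitter_mm`).
#' @return A `pm_config` list.
#' @export
pm_config <- function(profile = c("scaled_down", "full"), ...) {
  profile <- match.arg(profile)
  cfg <- list(profile = profile,
              n_points = if (profile == "full") 24000L else 2048L,
              coarse = coarse_config(profile),
              refine = refine_config(profile),
              coarse_epochs = 50L, refine_epochs = 50L,
              coarse_lr = 0.001, refine_lr = 0.002,
              grad_clip_norm = 0.5,
              batch_size = 1L,
              split_fractions = c(train = 251, val = 63, test = 63) / 377,
              dbscan_eps_mm = if (profile == "full") 3 else 1.5,
              dbscan_min_samples = 4L,
              cluster_merge_mm = 2.5, dedup_mm = 2,
              knn_k = 8L, ball_radius_mm = 6,
              sdr_thresholds = c(0.5, 1, 1.5, 2),
              oracle_patches = TRUE, oracle_patch_jitter_mm = 1.5)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "pm_config")
}

#' Split a dataset into train / validation / test
#'
#' Seeded shuffle followed by a contiguous split: `floor(n * f_train)` to
#' training, `floor(n * f_val)` to validation, the remainder to test. The
#' default fractions are 251/377, 63/377, 63/377, which reproduce a
#' 251/63/63 split at n = 377.
#'
#' @param casts a list.
#' @param fractions length-3 numeric summing to 1.
#' @param seed integer seed.
#' @return List with `train`, `val`, `test` (disjoint, exhaustive) and the
#'   shuffled `indices`.
#' @export
split_dataset <- function(casts, fractions = c(251, 63, 63) / 377, seed = 0L) {
  n <- length(casts)
  stopifnot(n >= 1, abs(sum(fractions) - 1) < 1e-9)
  perm <- with_seed(seed + 101L, sample.int(n))
  n_tr <- floor(n * fractions[1] + 1e-9)
  n_va <- floor(n * fractions[2] + 1e-9)
  n_te <- n - n_tr - n_va
  if (n_tr < 1 || n_va < 1 || n_te < 1)
    stop(sprintf("split error: %d casts give empty partition (%d/%d/%d)",
                 n, n_tr, n_va, n_te), call. = FALSE)
  list(train = casts[perm[seq_len(n_tr)]],
       val = casts[perm[n_tr + seq_len(n_va)]],
       test = casts[perm[n_tr + n_va + seq_len(n_te)]],
       indices = list(train = perm[seq_len(n_tr)],
                      val = perm[n_tr + seq_len(n_va)],
                      test = perm[n_tr + n_va + seq_len(n_te)]))
}

# cache everything weight-independent for the coarse loop
prepare_coarse_cast <- function(pc, config) {
  stopifnot(inherits(pc, "preprocessed_cast"), !is.null(pc$landmarks))
  list(cloud = pc$cloud,
       targets = coarse_targets(pc$cloud, pc$landmarks),
       landmarks = pc$landmarks,
       struct = build_net_structure(pc$cloud$positions, config))
}

#' Train the coarse proposal network
#'
#' Adam over the composite coarse loss; per-epoch train/validation history;
#' the best-validation checkpoint is retained. Fully seeded (weight
#' initialization and batch order).
#'
#' @param train,val lists of `preprocessed_cast` objects with landmarks.
#' @param config a [pm_config()].
#' @param seed integer seed.
#' @param verbose print per-epoch losses.
#' @return A trained `pm_net` with `$history` (data.frame epoch/train/val)
#'   and `$best_epoch`.
#' @export
train_coarse <- function(train, val, config = pm_config(), seed = 0L,
                         verbose = FALSE) {
  ccfg <- config$coarse
  net <- coarse_init(ccfg, seed = seed + 11L)
  prep_tr <- lapply(train, prepare_coarse_cast, config = ccfg)
  prep_va <- lapply(val, prepare_coarse_cast, config = ccfg)
  epochs <- config$coarse_epochs
  hist <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  if (epochs == 0) {
    net$history <- hist
    net$best_epoch <- 0L
    return(net)
  }
  st <- adam_init(length(net$flat))
  best <- list(val = Inf, flat = net$flat, epoch = 0L)
  order_seed <- seed + 23L
  for (ep in seq_len(epochs)) {
    ord <- with_seed(order_seed + ep, sample.int(length(prep_tr)))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tr_losses <- numeric(0)
    for (b in batches) {
      g <- numeric(length(net$flat))
      p_cur <- net_params(net)
      for (i in b) {
        pcst <- prep_tr[[i]]
        lg <- coarse_loss_grad(net, pcst$cloud, pcst$targets,
                               pcst$landmarks, struct = pcst$struct,
                               .params = p_cur)
        if (!is.finite(lg$loss))
          stop(sprintf("training error: non-finite coarse loss at epoch %d",
                       ep), call. = FALSE)
        g <- g + lg$grad / length(b)
        tr_losses <- c(tr_losses, lg$loss)
      }
      upd <- adam_step(net$flat, g, st, config$coarse_lr)
      net$flat <- upd$theta
      st <- upd$state
    }
    p_cur <- net_params(net)
    va_loss <- mean(vapply(prep_va, function(pcst) {
      out <- coarse_forward(pcst$cloud, net, struct = pcst$struct,
                            .params = p_cur)
      cand <- make_candidates(pcst$cloud, out,
                              min(ccfg$n_candidates,
                                  nrow(pcst$cloud$positions)))
      as.numeric(coarse_total_loss(out, pcst$targets, cand, pcst$landmarks,
                                   config = ccfg))
    }, 1))
    hist <- rbind(hist, data.frame(epoch = ep, train = mean(tr_losses),
                                   val = va_loss))
    if (va_loss <= best$val)
      best <- list(val = va_loss, flat = net$flat, epoch = ep)
    if (verbose)
      message(sprintf("coarse epoch %3d  train %.5f  val %.5f",
                      ep, mean(tr_losses), va_loss))
  }
  net$flat <- best$flat
  net$history <- hist
  net$best_epoch <- best$epoch
  net
}

# build the refinement training patches for one preprocessed cast:
# oracle mode centers the 6 mm geodesic ball on each true landmark;
# otherwise centers come from the coarse-stage cluster centroids
prepare_refine_cast <- function(pc, config, coarse_net = NULL,
                                jitter_seed = NULL) {
  oracle <- is.null(coarse_net)
  graph <- build_knn_graph(pc$cloud, k = config$knn_k)
  centers <- if (oracle) {
    jit <- config$oracle_patch_jitter_mm
    if (is.null(jit)) jit <- 0
    noise <- if (jit > 0 && !is.null(jitter_seed))
      with_seed(jitter_seed, matrix(rnorm(36, 0, jit), 12, 3)) *
        pc$transform$scale
    else matrix(0, 12, 3)
    pc$landmarks$points + noise
  } else {
    out <- coarse_forward(pc$cloud, coarse_net)
    cand <- make_candidates(pc$cloud, out,
                            min(config$coarse$n_candidates,
                                nrow(pc$cloud$positions)))
    cent <- resolve_to_12(
      dbscan_cluster(cand, eps = config$dbscan_eps_mm * pc$transform$scale,
                     min_samples = config$dbscan_min_samples),
      cand)
    assign_fdi_labels(cent)$points
  }
  patches <- vector("list", 12)
  targets <- vector("list", 12)
  skipped <- 0L
  for (k in 1:12) {
    ball <- geodesic_ball(pc$cloud, graph, centers[k, ],
                          radius_mm = config$ball_radius_mm,
                          transform = pc$transform)
    patch <- standardize_patch(ball, config$refine)
    tgt <- tryCatch(
      heatmap_target(patch, pc$landmarks$points[k, ],
                     sigma = config$refine$heatmap_sigma,
                     transform = pc$transform),
      error = function(e) NULL)
    if (is.null(tgt)) { skipped <- skipped + 1L; next }
    patches[[k]] <- list(patch = patch, target = tgt,
                         struct = build_net_structure(
                           sweep(patch$positions, 2, patch$center),
                           config$refine))
  }
  list(patches = Filter(Negate(is.null), patches), skipped = skipped)
}

#' Train the refinement network
#'
#' Adam with global gradient-norm clipping (threshold 0.5). By default the
#' training patches are centered on the ground-truth landmarks
#' (oracle-patch mode), which stabilizes early training; pass a trained
#' `coarse_net` with `config$oracle_patches = FALSE` to center them on
#' coarse cluster centroids instead. Casts whose landmark falls outside its
#' patch (supervision gap) are skipped with a count.
#'
#' @param train,val lists of `preprocessed_cast` objects.
#' @param config a [pm_config()].
#' @param coarse_net trained coarse `pm_net` (needed when
#'   `oracle_patches = FALSE`).
#' @param seed integer seed.
#' @param verbose print per-epoch losses.
#' @return A trained `pm_net` with `$history`, `$best_epoch`,
#'   `$n_skipped_patches`.
#' @export
train_refine <- function(train, val, config = pm_config(), coarse_net = NULL,
                         seed = 0L, verbose = FALSE) {
  rcfg <- config$refine
  use_oracle <- isTRUE(config$oracle_patches) || is.null(coarse_net)
  net <- refine_init(rcfg, seed = seed + 31L)
  cn <- if (use_oracle) NULL else coarse_net
  prep_tr <- lapply(seq_along(train), function(i)
    prepare_refine_cast(train[[i]], config, coarse_net = cn,
                        jitter_seed = seed + 1000L + i))
  prep_va <- lapply(seq_along(val), function(i)
    prepare_refine_cast(val[[i]], config, coarse_net = cn,
                        jitter_seed = seed + 5000L + i))
  skipped <- sum(vapply(c(prep_tr, prep_va), function(x) x$skipped, 1L))
  tr_patches <- unlist(lapply(prep_tr, function(x) x$patches),
                       recursive = FALSE)
  va_patches <- unlist(lapply(prep_va, function(x) x$patches),
                       recursive = FALSE)
  epochs <- config$refine_epochs
  hist <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  net$n_skipped_patches <- skipped
  net$target_entropy <- if (length(tr_patches))
    mean(vapply(tr_patches, function(pp)
      -sum(pp$target * log(pp$target + 1e-12)), 1))
  else NA_real_
  if (epochs == 0) {
    net$history <- hist
    net$best_epoch <- 0L
    return(net)
  }
  st <- adam_init(length(net$flat))
  best <- list(val = Inf, flat = net$flat, epoch = 0L)
  batch <- 12L   # one cast's worth of patches per step
  for (ep in seq_len(epochs)) {
    ord <- with_seed(seed + 43L + ep, sample.int(length(tr_patches)))
    batches <- split(ord, ceiling(seq_along(ord) / batch))
    tr_losses <- numeric(0)
    for (b in batches) {
      g <- numeric(length(net$flat))
      p_cur <- net_params(net)
      for (i in b) {
        pp <- tr_patches[[i]]
        lg <- refine_loss_grad(net, pp$patch, pp$target, struct = pp$struct,
                               .params = p_cur)
        if (!is.finite(lg$loss))
          stop(sprintf("training error: non-finite refine loss at epoch %d",
                       ep), call. = FALSE)
        g <- g + lg$grad / length(b)
        tr_losses <- c(tr_losses, lg$loss)
      }
      g <- clip_global_norm(g, config$grad_clip_norm)
      upd <- adam_step(net$flat, g, st, config$refine_lr)
      net$flat <- upd$theta
      st <- upd$state
    }
    p_cur <- net_params(net)
    va_loss <- mean(vapply(va_patches, function(pp) {
      out <- refine_forward(pp$patch, net, struct = pp$struct,
                            .params = p_cur)
      refine_loss(out$prob, pp$target)
    }, 1))
    hist <- rbind(hist, data.frame(epoch = ep, train = mean(tr_losses),
                                   val = va_loss))
    if (va_loss <= best$val)
      best <- list(val = va_loss, flat = net$flat, epoch = ep)
    if (verbose)
      message(sprintf("refine epoch %3d  train %.5f  val %.5f",
                      ep, mean(tr_losses), va_loss))
  }
  net$flat <- best$flat
  net$history <- hist
  net$best_epoch <- best$epoch
  net
}

#' Predict the 12 palatal landmarks on a cast
#'
#' Full two-stage pipeline: mesh to cloud, canonical orientation,
#' normalization, farthest-point sampling, coarse forward pass, candidate
#' generation, DBSCAN clustering resolved to 12 centroids, a 6 mm geodesic
#' patch per centroid, and refinement. Because refined points snap onto
#' gingival-margin concavities, tooth identities are assigned *after*
#' refinement: near-duplicate refined points (two patches converging on the
#' same concavity, closer than `dedup_mm`) are merged, each resulting
#' coverage gap is re-aimed by extracting one further patch at the midpoint
#' of the largest angular gap along the arch, and the final 12 distinct
#' points are labelled by their angular order. Deterministic given weights.
#'
#' @param mesh a [dental_cast_mesh()] (or a `preprocessed_cast`).
#' @param coarse_net,refine_net trained `pm_net` objects.
#' @param config a [pm_config()].
#' @param stage `"refine"` for the full pipeline or `"coarse"` to return
#'   the labelled cluster centroids themselves (for ablation).
#' @return A [landmark_set()] in cast-frame mm.
#' @export
predict_landmarks <- function(mesh, coarse_net, refine_net,
                              config = pm_config(),
                              stage = c("refine", "coarse")) {
  stage <- match.arg(stage)
  pc <- if (inherits(mesh, "preprocessed_cast")) mesh
  else preprocess_cast(mesh, n_points = config$n_points)
  s <- pc$transform$scale
  out <- coarse_forward(pc$cloud, coarse_net)
  cand <- make_candidates(pc$cloud, out,
                          min(config$coarse$n_candidates,
                              nrow(pc$cloud$positions)))
  labeling <- dbscan_cluster(cand, eps = config$dbscan_eps_mm * s,
                             min_samples = config$dbscan_min_samples)
  cent <- tryCatch(
    resolve_to_12(labeling, cand, merge_dist = config$cluster_merge_mm * s),
    error = function(e)
      stop(sprintf("%s [cast %s]", conditionMessage(e), pc$cast_id),
           call. = FALSE))
  if (stage == "coarse") {
    labeled <- assign_fdi_labels(cent)
    return(landmark_set(invert_transform(pc$transform, labeled$points),
                        labeled$labels, frame = "cast_mm"))
  }
  graph <- build_knn_graph(pc$cloud, k = config$knn_k)
  refine_at <- function(center) {
    ball <- geodesic_ball(pc$cloud, graph, center,
                          radius_mm = config$ball_radius_mm,
                          transform = pc$transform)
    patch <- standardize_patch(ball, config$refine)
    pm <- refine_forward(patch, refine_net)
    mm <- extract_landmark(patch, pm$prob, pc$transform)
    as.vector(apply_transform(pc$transform, matrix(mm, 1, 3)))
  }
  pts <- t(vapply(seq_len(12), function(k) refine_at(cent[k, ]), numeric(3)))
  # merge near-duplicate refined points (same concavity), keep first
  dd <- sqrt(cross_dist2_cpp(pts, pts)) / s
  keep <- rep(TRUE, 12)
  for (a in 2:12)
    if (any(dd[a, 1:(a - 1)] < config$dedup_mm & keep[1:(a - 1)]))
      keep[a] <- FALSE
  pts_u <- pts[keep, , drop = FALSE]
  # re-aim into the largest angular gap until 12 distinct points exist
  guard <- 0L
  while (nrow(pts_u) < 12 && guard < 15L) {
    guard <- guard + 1L
    if (nrow(pts_u) < 3) { pts_u <- pts; break }
    ctr <- colMeans(pts_u)
    ang <- atan2(-(pts_u[, 1] - ctr[1]), -(pts_u[, 2] - ctr[2]))
    o <- order(ang)
    gaps <- diff(ang[o])
    g <- which.max(gaps)
    mid_ang <- ang[o][g] + gaps[g] / 2
    nb <- pts_u[o[c(g, g + 1)], , drop = FALSE]
    rad <- mean(sqrt(rowSums(sweep(nb[, 1:2, drop = FALSE], 2,
                                   ctr[1:2])^2)))
    guess <- c(ctr[1] - rad * sin(mid_ang), ctr[2] - rad * cos(mid_ang),
               mean(nb[, 3]))
    cand_pt <- refine_at(guess)
    if (any(sqrt(rowSums(sweep(pts_u, 2, cand_pt)^2)) / s < config$dedup_mm)) {
      # re-aimed patch converged onto a known concavity: take the cloud
      # point nearest the gap midpoint that is still distinct
      d2 <- rowSums(sweep(pc$cloud$positions, 2, guess)^2)
      for (j in order(d2)[seq_len(min(200L, length(d2)))]) {
        cand_pt <- pc$cloud$positions[j, ]
        if (all(sqrt(rowSums(sweep(pts_u, 2, cand_pt)^2)) / s >=
                  config$dedup_mm)) break
      }
    }
    pts_u <- rbind(pts_u, cand_pt)
  }
  if (nrow(pts_u) < 12) {
    # last resort: refill with the dropped raw points, farthest first
    drop_pts <- pts[!keep, , drop = FALSE]
    ord <- order(-apply(sqrt(cross_dist2_cpp(drop_pts, pts_u)), 1, min))
    pts_u <- rbind(pts_u, drop_pts[ord, , drop = FALSE])
  }
  labeled <- tryCatch(assign_fdi_labels(pts_u[1:12, , drop = FALSE]),
                      error = function(e)
                        stop(sprintf("%s [cast %s]", conditionMessage(e),
                                     pc$cast_id), call. = FALSE))
  landmark_set(invert_transform(pc$transform, labeled$points),
               labeled$labels, frame = "cast_mm")
}

#' Fit the two-stage landmark localization model
#'
#' Splits the casts, preprocesses them, trains the coarse proposal network
#' and then the patch refinement network, and returns a fitted model object
#' with the usual methods (`print`, `summary`, `predict`, `plot`).
#'
#' @param casts list of `list(mesh, landmarks)` pairs (e.g. from
#'   [generate_dataset()]).
#' @param config a [pm_config()].
#' @param seed root seed; splits, initialization, and batch order derive
#'   from it.
#' @param verbose print per-epoch losses.
#' @return An object of class `palatemark`: trained nets, split indices,
#'   histories, config, seed.
#' @export
fit_palatemark <- function(casts, config = pm_config(), seed = 0L,
                           verbose = FALSE) {
  sp <- split_dataset(casts, config$split_fractions, seed = seed)
  prep <- function(cs) lapply(cs, function(c)
    preprocess_cast(c$mesh, c$landmarks, n_points = config$n_points))
  tr <- prep(sp$train); va <- prep(sp$val)
  coarse_net <- train_coarse(tr, va, config, seed = seed, verbose = verbose)
  refine_net <- train_refine(tr, va, config,
                             coarse_net = coarse_net, seed = seed,
                             verbose = verbose)
  structure(list(coarse_net = coarse_net, refine_net = refine_net,
                 split = sp$indices, config = config, seed = seed,
                 n_casts = length(casts)),
            class = "palatemark")
}

#' @export
print.palatemark <- function(x, ...) {
  cat("Two-stage palatal landmark localization model\n")
  cat(sprintf("  profile: %s (%d points, %d candidates, %d-point patches)\n",
              x$config$profile, x$config$n_points,
              x$config$coarse$n_candidates, x$config$refine$patch_points))
  cat(sprintf("  casts: %d (train %d / val %d / test %d)\n", x$n_casts,
              length(x$split$train), length(x$split$val),
              length(x$split$test)))
  cat(sprintf("  coarse net: %d parameters, best epoch %d\n",
              length(x$coarse_net$flat), x$coarse_net$best_epoch))
  cat(sprintf("  refine net: %d parameters, best epoch %d\n",
              length(x$refine_net$flat), x$refine_net$best_epoch))
  invisible(x)
}

#' @export
summary.palatemark <- function(object, ...) {
  h1 <- object$coarse_net$history
  h2 <- object$refine_net$history
  cat("Training history (loss):\n")
  if (nrow(h1)) cat(sprintf(
    "  coarse: epoch 1 train %.4f -> epoch %d train %.4f (best val %.4f @ %d)\n",
    h1$train[1], nrow(h1), h1$train[nrow(h1)],
    min(h1$val), object$coarse_net$best_epoch))
  if (nrow(h2)) cat(sprintf(
    "  refine: epoch 1 train %.4f -> epoch %d train %.4f (best val %.4f @ %d)\n",
    h2$train[1], nrow(h2), h2$train[nrow(h2)],
    min(h2$val), object$refine_net$best_epoch))
  print(object)
  invisible(object)
}

#' @export
predict.palatemark <- function(object, newdata, stage = "refine", ...) {
  predict_landmarks(newdata, object$coarse_net, object$refine_net,
                    object$config, stage = stage)
}

#' @export
plot.palatemark <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (nm in c("coarse", "refine")) {
    h <- if (nm == "coarse") x$coarse_net$history else x$refine_net$history
    if (!nrow(h)) next
    graphics::matplot(h$epoch, cbind(h$train, h$val), type = "l", lty = 1,
                      col = c("black", "red3"), xlab = "epoch",
                      ylab = "loss", main = paste(nm, "stage"))
    graphics::legend("topright", c("train", "val"), lty = 1,
                     col = c("black", "red3"), bty = "n")
  }
  invisible(x)
}
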