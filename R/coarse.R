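# Coarse landmark-proposal stage: hierarchical encoder over the full
# normalized cloud with two parallel per-point heads (1D convolutions with
# kernel size 1, i.e. shared linear layers) predicting the distance to the
# nearest landmark and the offset vector pointing at it. The n points with
# the smallest predicted distance, displaced by their predicted offsets,
# form the candidate set. Training uses a composite loss: Huber distance
# supervision (with the offset residual folded in), symmetric squared
# chamfer between candidates and landmarks, and a hinge separation penalty
# against candidate collapse.

#' Configuration of the coarse proposal network
#'
#' Defaults follow the full-scale pipeline: query radii 0.025 / 0.1 / 0.2
#' (normalized units) over 4096 / 1024 / 256 set-abstraction centers and 256
#' candidates from a 24,000-point cloud. The `scaled_down` profile (2,048
#' points, 64 candidates, halved channels) keeps the first set-abstraction
#' level at full cloud resolution — coarser level-1 spacing blurs the
#' gingival-dimple geometry the offset head needs — and trains on one CPU
#' in minutes; it is the test default.
#'
#' @param profile `"full"` or `"scaled_down"`.
#' @param ... named overrides of any config field.
#' @return A `coarse_config` list.
#' @export
coarse_config <- function(profile = c("scaled_down", "full"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "full") {
    list(in_channels = 6L,
         radii = c(0.025, 0.1, 0.2),
         npoints = c(4096L, 1024L, 256L),
         nsample = c(32L, 32L, 32L),
         mlps = list(c(64, 64, 128), c(128, 128, 256), c(256, 256, 512)),
         fp_mlps = list(c(256, 256), c(256, 128), c(128, 128)),
         head_width = 256L,
         n_candidates = 256L,
         sep_margin = 0.05,
         huber_delta = 1,
         loss_weights = c(dist = 1, offset = 1, chamfer = 1, separation = 0.1))
  } else {
    list(in_channels = 6L,
         radii = c(0.05, 0.12, 0.3),
         npoints = c(2048L, 512L, 128L),
         nsample = c(16L, 16L, 16L),
         mlps = list(c(32, 32, 64), c(64, 64, 128), c(128, 128, 256)),
         fp_mlps = list(c(128, 128), c(128, 64), c(64, 64)),
         head_width = 128L,
         n_candidates = 64L,
         sep_margin = 0.05,
         huber_delta = 1,
         loss_weights = c(dist = 1, offset = 1, chamfer = 1, separation = 0.1))
  }
  cfg$heads <- list(distance = 1L, offset = 3L)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "coarse_config", profile = profile)
}

#' Initialize coarse network weights
#'
#' @param config a [coarse_config()].
#' @param seed integer seed for He-normal initialization.
#' @return A `pm_net` object: flat parameter vector, nested template, config.
#' @export
coarse_init <- function(config = coarse_config(), seed = 0L) {
  template <- net_init_params(config, seed)
  structure(list(flat = flatten_params(template), template = template,
                 config = config, type = "coarse"),
            class = "pm_net")
}

#' @export
print.pm_net <- function(x, ...) {
  cat(sprintf("<pm_net %s: %d parameters>\n", x$type, length(x$flat)))
  invisible(x)
}

net_params <- function(net) unflatten_params(net$flat, net$template)

#' Coarse network forward pass
#'
#' @param cloud a [point_cloud()] in the normalized frame.
#' @param net a `pm_net` from [coarse_init()] (possibly trained).
#' @param struct optional cached grouping structure from a previous call on
#'   the same cloud.
#' @param keep_cache keep intermediate activations for backprop.
#' @return A `coarse_output`: `pred_distance` (N, non-negative via softplus),
#'   `pred_offset` (N x 3), plus `struct` (and `cache` if requested).
#' @export
coarse_forward <- function(cloud, net, struct = NULL, keep_cache = FALSE,
                           .params = NULL) {
  stopifnot(inherits(net, "pm_net"), net$type == "coarse")
  if (cloud$frame != "normalized")
    stop("coarse_forward expects a normalized-frame cloud", call. = FALSE)
  config <- net$config
  X0 <- cbind(cloud$positions, cloud$normals)
  if (ncol(X0) != config$in_channels)
    stop("config error: input channel mismatch", call. = FALSE)
  if (is.null(struct)) struct <- build_net_structure(cloud$positions, config)
  p <- if (is.null(.params)) net_params(net) else .params
  bb <- backbone_forward(X0, struct, p)
  hd <- mlp_forward(bb$out, p$heads$distance, final_linear = TRUE)
  ho <- mlp_forward(bb$out, p$heads$offset, final_linear = TRUE)
  out <- list(pred_distance = softplus(as.vector(hd$out)),
              pred_offset = ho$out,
              struct = struct)
  if (keep_cache)
    out$cache <- list(bb = bb, hd = hd, ho = ho, X0 = X0,
                      raw_dist = as.vector(hd$out))
  structure(out, class = "coarse_output")
}

#' Per-point supervision targets for the coarse stage
#'
#' Each point is assigned its nearest landmark: the true distance is the
#' Euclidean distance to it and the true offset the vector reaching it, so
#' `position + true_offset` lands exactly on a landmark.
#'
#' @param cloud a [point_cloud()] in the normalized frame.
#' @param landmarks a [landmark_set()] in the same frame.
#' @return List: `true_distance` (N), `true_offset` (N x 3), `nearest` (N,
#'   index of the assigned landmark 1..12).
#' @export
coarse_targets <- function(cloud, landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (!identical(cloud$frame, landmarks$frame))
    stop("frame error: cloud and landmarks are in different frames",
         call. = FALSE)
  d2 <- cross_dist2_cpp(cloud$positions, landmarks$points)
  nn <- max.col(-d2, ties.method = "first")
  list(true_distance = sqrt(d2[cbind(seq_len(nrow(d2)), nn)]),
       true_offset = landmarks$points[nn, , drop = FALSE] - cloud$positions,
       nearest = nn)
}

#' Combine head outputs into candidate landmark points
#'
#' The `n` points with the smallest predicted distance (ties by lowest
#' index) are displaced by their predicted offsets.
#'
#' @param cloud a [point_cloud()].
#' @param out a `coarse_output`.
#' @param n number of candidates (default from the pipeline config: 256
#'   full-scale).
#' @return `n` x 3 matrix of candidate positions, selected point indices in
#'   attribute `"indices"`.
#' @export
make_candidates <- function(cloud, out, n = 256) {
  np <- nrow(cloud$positions)
  if (n > np) stop("more candidates requested than points", call. = FALSE)
  sel <- order(out$pred_distance)[seq_len(n)]
  cand <- cloud$positions[sel, , drop = FALSE] +
    out$pred_offset[sel, , drop = FALSE]
  attr(cand, "indices") <- sel
  cand
}

# ---- losses ---------------------------------------------------------------

huber_val <- function(e, delta) {
  a <- abs(e)
  ifelse(a <= delta, 0.5 * e^2, delta * (a - 0.5 * delta))
}
huber_grad <- function(e, delta) {
  ifelse(abs(e) <= delta, e, delta * sign(e))
}

#' Huber (smooth-L1) distance loss
#'
#' Mean over points of the Huber penalty on the prediction error, with
#' quadratic zone `delta` (default 1 normalized unit). Zero iff exact.
#'
#' @param pred_distance,true_distance equal-length numeric vectors.
#' @param delta Huber threshold.
#' @return Scalar loss.
#' @export
distance_loss <- function(pred_distance, true_distance, delta = 1) {
  stopifnot(length(pred_distance) == length(true_distance))
  mean(huber_val(pred_distance - true_distance, delta))
}

offset_loss <- function(pred_offset, true_offset, delta = 1) {
  sum(huber_val(pred_offset - true_offset, delta)) / nrow(pred_offset)
}

#' Symmetric squared chamfer loss between candidates and landmarks
#'
#' Mean over candidates of the squared distance to the nearest landmark plus
#' mean over landmarks of the squared distance to the nearest candidate.
#'
#' @param candidates n x 3 matrix.
#' @param landmarks a [landmark_set()] or 12 x 3 matrix in the same frame.
#' @return Scalar loss (>= 0, zero iff the candidate set covers all
#'   landmarks exactly and contains no stray point).
#' @export
chamfer_loss <- function(candidates, landmarks) {
  lm <- if (inherits(landmarks, "landmark_set")) landmarks$points else
    as.matrix(landmarks)
  d2 <- cross_dist2_cpp(pad3(candidates), pad3(lm))
  mean(apply(d2, 1, min)) + mean(apply(d2, 2, min))
}

# allow 1-D / 2-D toy inputs in the loss oracles
pad3 <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 3) cbind(x, matrix(0, nrow(x), 3 - ncol(x))) else x
}

chamfer_grad_candidates <- function(candidates, lm) {
  d2 <- cross_dist2_cpp(candidates, lm)
  nc <- nrow(candidates); nl <- nrow(lm)
  j1 <- max.col(-d2, ties.method = "first")
  g <- 2 / nc * (candidates - lm[j1, , drop = FALSE])
  i2 <- apply(d2, 2, which.min)
  for (j in seq_len(nl)) {
    g[i2[j], ] <- g[i2[j], ] + 2 / nl * (candidates[i2[j], ] - lm[j, ])
  }
  g
}

#' Separation loss penalizing candidate collapse
#'
#' Mean over unordered candidate pairs of the squared hinge
#' `max(0, margin - distance)^2`; zero iff all pairs are at least `margin`
#' apart.
#'
#' @param candidates n x 3 matrix.
#' @param margin minimum pairwise distance (default 0.05 normalized units).
#' @return Scalar loss.
#' @export
separation_loss <- function(candidates, margin = 0.05) {
  stopifnot(margin > 0)
  candidates <- pad3(candidates)
  n <- nrow(candidates)
  if (n < 2) return(0)
  d2 <- cross_dist2_cpp(candidates, candidates)
  d <- sqrt(d2[upper.tri(d2)])
  mean(pmax(0, margin - d)^2)
}

separation_grad <- function(candidates, margin) {
  n <- nrow(candidates)
  if (n < 2) return(matrix(0, n, 3))
  d2 <- cross_dist2_cpp(candidates, candidates)
  d <- sqrt(d2)
  act <- d < margin & upper.tri(d2)
  g <- matrix(0, n, 3)
  P <- n * (n - 1) / 2
  hits <- which(act, arr.ind = TRUE)
  for (r in seq_len(nrow(hits))) {
    i <- hits[r, 1]; j <- hits[r, 2]
    if (d[i, j] < 1e-12) next   # coincident pair: no descent direction
    u <- (candidates[i, ] - candidates[j, ]) / d[i, j]
    coef <- -2 * (margin - d[i, j]) / P
    g[i, ] <- g[i, ] + coef * u
    g[j, ] <- g[j, ] - coef * u
  }
  g
}

#' Total coarse-stage loss with per-component breakdown
#'
#' Weighted sum of Huber distance supervision, Huber offset supervision
#' (folded into distance supervision by default weights), symmetric squared
#' chamfer between candidates and landmarks, and the separation hinge.
#'
#' @param out a `coarse_output`.
#' @param targets from [coarse_targets()].
#' @param candidates from [make_candidates()].
#' @param landmarks a [landmark_set()] (normalized frame).
#' @param weights named vector `dist`, `offset`, `chamfer`, `separation`.
#' @param config a [coarse_config()] (for `sep_margin`, `huber_delta`).
#' @return Scalar loss with attribute `"components"`.
#' @export
coarse_total_loss <- function(out, targets, candidates, landmarks,
                              weights = NULL, config = coarse_config()) {
  if (is.null(weights)) weights <- config$loss_weights
  stopifnot(all(weights >= 0))
  comp <- c(dist = distance_loss(out$pred_distance, targets$true_distance,
                                 config$huber_delta),
            offset = offset_loss(out$pred_offset, targets$true_offset,
                                 config$huber_delta),
            chamfer = chamfer_loss(candidates, landmarks),
            separation = separation_loss(candidates, config$sep_margin))
  total <- sum(weights[names(comp)] * comp)
  attr(total, "components") <- comp
  total
}

# loss + flat gradient for one cast; candidate selection (top-n by predicted
# distance) and grouping structure are treated as fixed during backprop
coarse_loss_grad <- function(net, cloud, targets, landmarks, struct = NULL,
                             .params = NULL) {
  config <- net$config
  if (is.null(.params)) .params <- net_params(net)
  out <- coarse_forward(cloud, net, struct = struct, keep_cache = TRUE,
                        .params = .params)
  n_cand <- min(config$n_candidates, nrow(cloud$positions))
  cand <- make_candidates(cloud, out, n_cand)
  sel <- attr(cand, "indices")
  w <- config$loss_weights
  loss <- coarse_total_loss(out, targets, cand, landmarks,
                            weights = w, config = config)

  n <- length(out$pred_distance)
  d_pd <- w[["dist"]] *
    huber_grad(out$pred_distance - targets$true_distance,
               config$huber_delta) / n
  d_off <- w[["offset"]] *
    huber_grad(out$pred_offset - targets$true_offset, config$huber_delta) / n
  d_cand <- w[["chamfer"]] *
    chamfer_grad_candidates(cand, landmarks$points) +
    w[["separation"]] * separation_grad(cand, config$sep_margin)
  d_off[sel, ] <- d_off[sel, , drop = FALSE] + d_cand

  p <- .params
  d_raw <- d_pd * sigmoid(out$cache$raw_dist)
  hb_d <- mlp_backward(matrix(d_raw, ncol = 1), p$heads$distance,
                       out$cache$hd, final_linear = TRUE)
  hb_o <- mlp_backward(d_off, p$heads$offset, out$cache$ho,
                       final_linear = TRUE)
  dF0 <- hb_d$dX + hb_o$dX
  bbg <- backbone_backward(dF0, out$cache$bb, p)
  grads <- list(sa = bbg$sa, fp = bbg$fp,
                heads = list(distance = hb_d$grads, offset = hb_o$grads))
  list(loss = as.numeric(loss),
       components = attr(loss, "components"),
       grad = flatten_params(grads))
}
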