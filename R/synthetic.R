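# Parametric maxillary-cast generator. The surface is a height field over
# scaled elliptical coordinates (rho, theta): the dental arch ridge sits at
# rho = 1 carrying one sinusoidal-Gaussian bump per tooth, the palatal dome
# is a smooth depression toward rho = 0, and each tooth has an explicit
# gingival-margin dimple on its palatal side at (theta_k, rho_gm). Landmarks
# are the analytically known dimple centers, so no annotation step exists.

#' Shape parameters for the synthetic cast generator
#'
#' @param arch_width transverse width of the dental arch (mm).
#' @param arch_depth antero-posterior depth of the arch (mm).
#' @param palate_depth depth of the palatal dome below the gingival plane (mm).
#' @param tooth_bump_height height of the tooth bumps above the gum ridge (mm).
#' @param surface_noise_sd Gaussian surface roughness added to vertex heights
#'   (mm); emulates scanner noise.
#' @param target_vertices approximate vertex count of the triangulated
#'   surface (within 10 percent). 12,000 is dense enough for testing; 80,000
#'   emulates scanner-resolution casts (60,000-120,000 vertices).
#' @param rigid_pose list with `angles` (xyz rotation, radians) and
#'   `translation` (mm); default is the canonical unposed frame.
#' @param seed integer seed controlling grid jitter and surface noise.
#' @return A `cast_shape_params` list.
#' @export
cast_shape_params <- function(arch_width = 36, arch_depth = 42,
                              palate_depth = 14, tooth_bump_height = 5,
                              surface_noise_sd = 0.05,
                              target_vertices = 12000,
                              rigid_pose = list(angles = c(0, 0, 0),
                                                translation = c(0, 0, 0)),
                              seed = 1L) {
  p <- list(arch_width = arch_width, arch_depth = arch_depth,
            palate_depth = palate_depth,
            tooth_bump_height = tooth_bump_height,
            n_teeth_per_side = 6L,
            surface_noise_sd = surface_noise_sd,
            target_vertices = as.integer(target_vertices),
            rigid_pose = rigid_pose, seed = as.integer(seed))
  lens <- c(p$arch_width, p$arch_depth, p$palate_depth, p$tooth_bump_height)
  if (any(lens <= 0)) stop("length parameters must be positive", call. = FALSE)
  if (p$surface_noise_sd < 0) stop("surface_noise_sd must be >= 0", call. = FALSE)
  if (p$target_vertices < 500)
    stop("target_vertices < 500 cannot resolve 12 tooth bumps", call. = FALSE)
  structure(p, class = "cast_shape_params")
}

# tooth angular centers (theta over [0, pi], posterior-right to
# posterior-left) and mesiodistal width factors (molars 1.6x incisors)
tooth_theta <- function() pi * (seq_len(12) - 0.5) / 12
tooth_width_factor <- function() {
  # 16 15 14 13 12 11 21 22 23 24 25 26
  c(1.6, 1.3, 1.15, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.15, 1.3, 1.6)
}

RHO_GM <- 0.88          # palatal-side radial position of the gingival margin
RHO_RANGE <- c(0.05, 1.22)

# analytic height field z(rho, theta) in mm (noise-free)
cast_height <- function(rho, theta, p) {
  th_k <- tooth_theta()
  fac <- tooth_width_factor()
  ridge <- 2.5 * exp(-(rho - 1)^2 / (2 * 0.06^2))
  dome <- -p$palate_depth * exp(-rho^2 / (2 * 0.38^2))
  z <- ridge + dome
  for (k in 1:12) {
    sig_t <- 0.055 * fac[k]
    z <- z + p$tooth_bump_height *
      exp(-(rho - 1)^2 / (2 * 0.05^2)) * exp(-(theta - th_k[k])^2 / (2 * sig_t^2))
    z <- z - 1.2 *
      exp(-(rho - RHO_GM)^2 / (2 * 0.035^2)) *
      exp(-(theta - th_k[k])^2 / (2 * (0.5 * sig_t)^2))
  }
  z
}

cast_xy <- function(rho, theta, p) {
  a <- p$arch_width / 2
  b <- p$arch_depth
  cbind(rho * a * cos(theta), -rho * b * sin(theta))
}

rotation_xyz <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic maxillary cast with ground-truth landmarks
#'
#' Triangulates the parametric palate/arch surface on a jittered grid and
#' returns the mesh together with the 12 analytically placed palatal
#' gingival-margin landmarks. Deterministic: the same parameters (including
#' `seed`) give bit-identical output.
#'
#' @param params a [cast_shape_params()].
#' @param cast_id identifier stored on the mesh.
#' @return List with elements `mesh` ([dental_cast_mesh()]) and `landmarks`
#'   ([landmark_set()], `cast_mm` frame).
#' @export
generate_cast <- function(params = cast_shape_params(), cast_id = "synthetic") {
  p <- params
  # grid resolution: arc direction carries ~2.8x the physical length of the
  # radial direction for default proportions
  nt <- max(24L, as.integer(round(sqrt(2.8 * p$target_vertices))))
  nr <- max(10L, as.integer(round(p$target_vertices / nt)))
  theta <- seq(0, pi, length.out = nt)
  rho <- seq(RHO_RANGE[1], RHO_RANGE[2], length.out = nr)
  tg <- matrix(rep(theta, times = nr), nt, nr)
  rg <- matrix(rep(rho, each = nt), nt, nr)
  dt <- theta[2] - theta[1]
  dr <- rho[2] - rho[1]
  noise <- with_seed(p$seed, {
    jt <- matrix(runif(nt * nr, -0.3, 0.3) * dt, nt, nr)
    jr <- matrix(runif(nt * nr, -0.3, 0.3) * dr, nt, nr)
    nz <- rnorm(nt * nr, 0, p$surface_noise_sd)
    list(jt = jt, jr = jr, nz = nz)
  })
  # keep boundary nodes on the boundary so the patch stays rectangular
  noise$jt[c(1, nt), ] <- 0
  noise$jr[, c(1, nr)] <- 0
  tj <- tg + noise$jt
  rj <- rg + noise$jr
  xy <- cast_xy(as.vector(rj), as.vector(tj), p)
  z <- cast_height(as.vector(rj), as.vector(tj), p) + noise$nz
  v <- cbind(xy, z)

  # grid triangulation, counter-clockwise in (theta, rho) => normals +z
  i <- rep(seq_len(nt - 1), times = nr - 1)
  j <- rep(seq_len(nr - 1), each = nt - 1)
  v00 <- (j - 1) * nt + i
  v10 <- v00 + 1L
  v01 <- v00 + nt
  v11 <- v01 + 1L
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))

  lm_pts <- cbind(cast_xy(rep(RHO_GM, 12), tooth_theta(), p),
                  cast_height(rep(RHO_GM, 12), tooth_theta(), p))
  rot <- rotation_xyz(p$rigid_pose$angles)
  tr <- p$rigid_pose$translation
  v <- t(rot %*% t(v)) + matrix(tr, nrow(v), 3, byrow = TRUE)
  lm_pts <- t(rot %*% t(lm_pts)) + matrix(tr, 12, 3, byrow = TRUE)
  list(mesh = dental_cast_mesh(v, faces, cast_id),
       landmarks = landmark_set(lm_pts, FDI_LABELS, frame = "cast_mm"))
}

#' Generate a dataset of synthetic casts
#'
#' Each cast gets independently jittered shape parameters (length parameters
#' multiplied by Uniform(0.9, 1.1) draws) and a random rigid pose (rotations
#' uniform within +/- 20 degrees per axis, translations within +/- 10 mm).
#' Reproducible from `seed`.
#'
#' @param n number of casts.
#' @param base_params a [cast_shape_params()] to jitter.
#' @param seed integer seed.
#' @return List of `n` elements, each with `mesh` and `landmarks`.
#' @export
generate_dataset <- function(n, base_params = cast_shape_params(), seed = 1L) {
  stopifnot(n >= 1)
  draws <- with_seed(seed, {
    lapply(seq_len(n), function(i)
      list(jit = runif(4, 0.9, 1.1),
           ang = runif(3, -20, 20) * pi / 180,
           tra = runif(3, -10, 10),
           sub_seed = sample.int(2^30, 1)))
  })
  lapply(seq_len(n), function(i) {
    d <- draws[[i]]
    p <- base_params
    p$arch_width <- p$arch_width * d$jit[1]
    p$arch_depth <- p$arch_depth * d$jit[2]
    p$palate_depth <- p$palate_depth * d$jit[3]
    p$tooth_bump_height <- p$tooth_bump_height * d$jit[4]
    p$rigid_pose <- list(angles = d$ang, translation = d$tra)
    p$seed <- d$sub_seed
    generate_cast(p, cast_id = sprintf("synth%04d", i))
  })
}

#' Add isotropic Gaussian noise to a landmark set
#'
#' Emulates repeat manual annotation sessions for reliability analysis. The
#' default `sd` (0.1507 mm) is calibrated so the mean distance between two
#' independently perturbed sessions is about 0.34 mm, a typical
#' intraexaminer landmarking error.
#'
#' @param landmarks a [landmark_set()].
#' @param sd noise standard deviation per coordinate (mm).
#' @param seed integer seed.
#' @return A [landmark_set()] with the same labels.
#' @export
perturb_landmarks <- function(landmarks, sd = 0.1507, seed = 1L) {
  stopifnot(inherits(landmarks, "landmark_set"), sd >= 0)
  noise <- with_seed(seed, matrix(rnorm(36, 0, sd), 12, 3))
  landmark_set(landmarks$points + noise, landmarks$labels,
               frame = landmarks$frame)
}
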