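#' Canonical class order for moving objects
#'
#' Rubber, hair and floating debris are foreign matter; bubbles are the
#' benign class (a bottle whose only moving objects are bubbles is
#' qualified).
#'
#' @return Character vector of the four class names in canonical order.
#' @export
fm_classes <- function() c("rubber", "hair", "debris", "bubble")

#' Canonical names of the fifteen blob descriptors
#'
#' Order is fixed: six gray-histogram statistics (mean, variance, relative
#' smoothness, third moment, uniformity, entropy), area, bounding-rectangle
#' side ratio, then the seven Hu moment invariants.
#'
#' @return Character vector of length 15.
#' @export
feature_names <- function() {
  c("f01_mean", "f02_var", "f03_smooth", "f04_m3", "f05_unif", "f06_entropy",
    "f07_area", "f08_wl_ratio", "f09_hu1", "f10_hu2", "f11_hu3", "f12_hu4",
    "f13_hu5", "f14_hu6", "f15_hu7")
}

#' Specify one injected moving particle
#'
#' Describes a single moving object to composite into a synthetic scene:
#' its class, gray-level model, size, shape model, per-frame deformation
#' and trajectory. Opaque foreign matter (rubber, hair, debris) blocks
#' transmitted light and images dark; transparent bubbles image bright,
#' with a bright rim and mid-gray interior.
#'
#' @param klass One of `"rubber"`, `"hair"`, `"debris"`, `"bubble"`.
#' @param intensity_mean Mean gray level of the particle's pixels (class
#'   default: rubber 50, hair 60, debris 80, bubble rim 225 / interior 170).
#' @param intensity_sigma Per-pixel gray-level noise of the particle.
#' @param base_area Nominal pixel area (>= 4).
#' @param shape_model One of `"compact_ellipse"`, `"thin_curve"`,
#'   `"ragged_patch"`, `"disk"`; defaults to the class's natural shape.
#' @param deformation_rate Fraction of shape perturbation per frame; 0 for
#'   rubber (shape stable in solution), > 0 for soft matter and bubbles.
#' @param trajectory Either a waypoint matrix (rows `(row, col)`,
#'   traversed piecewise-linearly over the sequence) or one of
#'   `"sinking"`, `"circulating"`, `"rising"` for a class-typical path.
#' @return An object of class `particle_spec`.
#' @export
particle_spec <- function(klass,
                          intensity_mean = NULL,
                          intensity_sigma = 5,
                          base_area = 25,
                          shape_model = NULL,
                          deformation_rate = NULL,
                          trajectory = NULL) {
  klass <- match.arg(klass, fm_classes())
  defaults <- list(
    rubber = list(mean = 50,  shape = "compact_ellipse", deform = 0,    traj = "sinking"),
    hair   = list(mean = 60,  shape = "thin_curve",      deform = 0.15, traj = "circulating"),
    debris = list(mean = 80,  shape = "ragged_patch",    deform = 0.20, traj = "circulating"),
    bubble = list(mean = 225, shape = "disk",            deform = 0.05, traj = "rising"))
  d <- defaults[[klass]]
  intensity_mean <- intensity_mean %||% d$mean
  shape_model <- match.arg(shape_model %||% d$shape,
                           c("compact_ellipse", "thin_curve", "ragged_patch", "disk"))
  deformation_rate <- deformation_rate %||% d$deform
  trajectory <- trajectory %||% d$traj
  stopifnot(base_area >= 4, intensity_sigma >= 0,
            deformation_rate >= 0, deformation_rate <= 1)
  structure(list(klass = klass, intensity_mean = intensity_mean,
                 intensity_sigma = intensity_sigma, base_area = base_area,
                 shape_model = shape_model, deformation_rate = deformation_rate,
                 trajectory = trajectory),
            class = "particle_spec")
}

#' Configure a synthetic spin-stop scene
#'
#' A scene is a static textured background (emulating embossing, labels and
#' scratches on the bottle surface) plus a coherent per-frame illumination
#' flicker, independent per-pixel sensor noise, and a set of injected
#' moving particles. Composition per frame is
#' `clamp(background_mean + texture + flicker + noise)` with particles
#' composited last by replacement.
#'
#' @param frame_height,frame_width Frame dimensions in pixels (>= 16).
#' @param n_frames Number of frames in the sequence.
#' @param background_mean Mean background gray level in `[0, 255]`.
#' @param texture_amplitude Half-range of the static per-pixel offsets.
#' @param flicker_sigma SD of the scalar per-frame illumination flicker.
#' @param pixel_noise_sigma SD of independent per-pixel noise.
#' @param particles List of [particle_spec()] objects (may be empty).
#' @param seed Integer seed; the whole composition is deterministic in it.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(frame_height = 64, frame_width = 64, n_frames = 50,
                         background_mean = 150, texture_amplitude = 8,
                         flicker_sigma = 2, pixel_noise_sigma = 2,
                         particles = list(), seed = 1L) {
  stopifnot(frame_height >= 16, frame_width >= 16, n_frames >= 1,
            background_mean >= 0, background_mean <= 255,
            texture_amplitude >= 0, flicker_sigma >= 0, pixel_noise_sigma >= 0)
  if (inherits(particles, "particle_spec")) particles <- list(particles)
  stopifnot(all(vapply(particles, inherits, logical(1), "particle_spec")))
  structure(list(frame_height = frame_height, frame_width = frame_width,
                 n_frames = n_frames, background_mean = background_mean,
                 texture_amplitude = texture_amplitude,
                 flicker_sigma = flicker_sigma,
                 pixel_noise_sigma = pixel_noise_sigma,
                 particles = particles, seed = as.integer(seed)),
            class = "scene_config")
}

# --- particle rasterization ------------------------------------------------
# Each rasterizer returns a list with integer offset matrix `offsets`
# (columns dr, dc, relative to the particle center) and a numeric
# `intensity` vector (mean gray per offset pixel, before per-pixel noise).

raster_ellipse <- function(area, mean_gray, aspect = 1.5, angle = 0) {
  b <- sqrt(area / (pi * aspect)); a <- aspect * b
  r <- ceiling(a)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  ca <- cos(angle); sa <- sin(angle)
  u <- g$dc * ca + g$dr * sa
  v <- -g$dc * sa + g$dr * ca
  keep <- (u / a)^2 + (v / b)^2 <= 1
  list(offsets = cbind(dr = g$dr[keep], dc = g$dc[keep]),
       intensity = rep(mean_gray, sum(keep)))
}

raster_disk <- function(area, rim_gray, interior_gray) {
  r <- sqrt(area / pi)
  ri <- ceiling(r)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  d <- sqrt(g$dr^2 + g$dc^2)
  keep <- d <= r
  # bright rim (outer ~35% of the radius), mid-gray interior
  rim <- d[keep] > 0.65 * r
  list(offsets = cbind(dr = g$dr[keep], dc = g$dc[keep]),
       intensity = ifelse(rim, rim_gray, interior_gray))
}

raster_curve <- function(area, mean_gray, bend, width = 2L) {
  # thin open curve of total length ~ area / width, rasterized from a
  # quadratic bezier whose control point is displaced by `bend`
  len <- max(4, round(area / width))
  t <- seq(0, 1, length.out = 4L * len)
  p0 <- c(-len / 2, 0); p2 <- c(len / 2, 0)
  p1 <- c(0, bend * len)
  rr <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  cc <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  pts <- unique(cbind(dr = round(rr), dc = round(cc)))
  if (width >= 2L) pts <- unique(rbind(pts, cbind(dr = pts[, 1], dc = pts[, 2] + 1)))
  list(offsets = pts, intensity = rep(mean_gray, nrow(pts)))
}

raster_ragged <- function(area, mean_gray, roughness, n_spokes = 12L) {
  r0 <- sqrt(area / pi)
  theta <- seq(0, 2 * pi, length.out = n_spokes + 1L)[-(n_spokes + 1L)]
  rad <- r0 * (1 + roughness * stats::runif(n_spokes, -1, 1))
  ri <- ceiling(max(rad))
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  ang <- atan2(g$dr, g$dc) %% (2 * pi)
  # linear interpolation of the spoke radii around the circle
  bound <- stats::approx(x = c(theta, 2 * pi), y = c(rad, rad[1]),
                         xout = ang, rule = 2)$y
  keep <- sqrt(g$dr^2 + g$dc^2) <= bound
  list(offsets = cbind(dr = g$dr[keep], dc = g$dc[keep]),
       intensity = rep(mean_gray, sum(keep)))
}

# Rasterize a particle for frame t; consumes RNG draws for deformation.
raster_particle <- function(spec, t) {
  switch(spec$shape_model,
    compact_ellipse = raster_ellipse(spec$base_area, spec$intensity_mean),
    disk = {
      jitter <- 1 + spec$deformation_rate * stats::runif(1, -1, 1)
      raster_disk(spec$base_area * jitter, spec$intensity_mean,
                  interior_gray = 0.75 * spec$intensity_mean)
    },
    thin_curve = {
      bend <- 0.3 + spec$deformation_rate * stats::runif(1, -1, 1)
      raster_curve(spec$base_area, spec$intensity_mean, bend)
    },
    ragged_patch = raster_ragged(spec$base_area, spec$intensity_mean,
                                 roughness = 0.25 + spec$deformation_rate))
}

# Piecewise-linear position (row, col) at frame t of n, 1-based frame index.
particle_position <- function(spec, t, n, H, W) {
  wp <- spec$trajectory
  if (is.character(wp)) {
    m <- c(H, W) / 2
    wp <- switch(wp,
      sinking     = rbind(c(0.25 * H, 0.30 * W), c(0.80 * H, 0.70 * W)),
      rising      = rbind(c(0.80 * H, 0.65 * W), c(0.20 * H, 0.35 * W)),
      circulating = {
        ang <- seq(0, 1.5 * pi, length.out = 9)
        cbind(m[1] + 0.28 * H * sin(ang), m[2] + 0.28 * W * cos(ang))
      })
  }
  wp <- as.matrix(wp)
  if (nrow(wp) == 1L) return(round(wp[1L, ]))
  s <- if (n == 1L) 0 else (t - 1) / (n - 1)
  seg <- s * (nrow(wp) - 1L)
  i <- pmin(floor(seg), nrow(wp) - 2L)
  f <- seg - i
  round((1 - f) * wp[i + 1L, ] + f * wp[i + 2L, ])
}

#' Generate a synthetic frame sequence with ground truth
#'
#' Composes `n_frames` 8-bit grayscale frames: static texture, coherent
#' illumination flicker, per-pixel noise, then each particle in list order
#' (replacement compositing; overlapping particles union their masks).
#' Gray values are clamped to `[0, 255]` and rounded to integers. The RNG
#' draw order is fixed (texture, then per frame: flicker, noise, then per
#' particle: deformation, intensity), so output is bit-identical for a
#' fixed seed.
#'
#' @param config A [scene_config()].
#' @return A list with `frames` (H x W x n integer array), and `truth`:
#'   `masks` (H x W x n logical array of injected pixels), `objects`
#'   (data frame: frame, blob_id, klass, centroid_r, centroid_c, area,
#'   1-based centroids), and `pixels` (per frame, per particle 1-based
#'   coordinate matrices).
#' @export
generate_sequence <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  H <- config$frame_height; W <- config$frame_width; n <- config$n_frames
  with_seed(config$seed, {
    texture <- matrix(stats::runif(H * W, -config$texture_amplitude,
                                   config$texture_amplitude), H, W)
    frames <- array(0L, dim = c(H, W, n))
    masks <- array(FALSE, dim = c(H, W, n))
    objects <- vector("list", n)
    pixels <- vector("list", n)
    for (t in seq_len(n)) {
      flicker <- stats::rnorm(1, 0, config$flicker_sigma)
      noise <- matrix(stats::rnorm(H * W, 0, config$pixel_noise_sigma), H, W)
      fr <- config$background_mean + texture + flicker + noise
      m <- matrix(FALSE, H, W)
      obj_rows <- list(); pix_list <- list()
      for (pi in seq_along(config$particles)) {
        spec <- config$particles[[pi]]
        ras <- raster_particle(spec, t)
        if (nrow(ras$offsets) > max(H, W)^2 ||
            diff(range(ras$offsets[, 1])) >= H ||
            diff(range(ras$offsets[, 2])) >= W)
          stop("particle ", pi, " is larger than the frame")
        pos <- particle_position(spec, t, n, H, W)
        rr <- ras$offsets[, 1] + pos[1]
        cc <- ras$offsets[, 2] + pos[2]
        gray <- ras$intensity +
          stats::rnorm(length(rr), 0, spec$intensity_sigma)
        inside <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
        idx <- cbind(rr[inside], cc[inside])
        fr[idx] <- gray[inside]
        m[idx] <- TRUE
        obj_rows[[pi]] <- data.frame(
          frame = t, blob_id = pi, klass = spec$klass,
          centroid_r = mean(rr[inside]), centroid_c = mean(cc[inside]),
          area = sum(inside))
        pix_list[[pi]] <- idx
      }
      frames[, , t] <- as.integer(round(clamp_gray(fr)))
      masks[, , t] <- m
      objects[[t]] <- if (length(obj_rows)) do.call(rbind, obj_rows) else NULL
      pixels[[t]] <- pix_list
    }
    list(frames = frames,
         truth = list(masks = masks,
                      objects = do.call(rbind, objects),
                      pixels = pixels))
  })
}

#' Default per-class feature distributions for synthetic datasets
#'
#' Class-conditional Gaussian parameters over the fifteen descriptors.
#' The classes are well separated in the gray variance, entropy and the
#' first three Hu moments, and overlap in the remaining features — the
#' structure the feature-weighting stage is expected to uncover.
#'
#' @return Named list (one entry per class) of lists with `mean` and `sd`
#'   numeric vectors of length 15.
#' @export
default_class_params <- function() {
  nm <- feature_names()
  base_mean <- c(100, 0, 0.99, 0, 0.15, 0, 55, 1.8, 0, 0, 0,
                 5e-4, 0, 0, 0)
  base_sd <- c(40, 60, 0.004, 500, 0.05, 0.25, 25, 0.8, 0.03, 0.015,
               0.004, 5e-4, 1e-6, 1e-4, 1e-6)
  sep <- list( # informative features: f02 (variance), f06 (entropy), f09-f11 (Hu 1-3)
    rubber = c(f02_var = 120,  f06_entropy = 2.0, f09_hu1 = 0.17, f10_hu2 = 0.005, f11_hu3 = 0.001),
    hair   = c(f02_var = 400,  f06_entropy = 3.2, f09_hu1 = 0.65, f10_hu2 = 0.300, f11_hu3 = 0.080),
    debris = c(f02_var = 800,  f06_entropy = 4.4, f09_hu1 = 0.33, f10_hu2 = 0.060, f11_hu3 = 0.020),
    bubble = c(f02_var = 1500, f06_entropy = 5.6, f09_hu1 = 0.48, f10_hu2 = 0.150, f11_hu3 = 0.045))
  out <- lapply(fm_classes(), function(k) {
    m <- stats::setNames(base_mean, nm)
    m[names(sep[[k]])] <- sep[[k]]
    list(mean = m, sd = stats::setNames(base_sd, nm))
  })
  stats::setNames(out, fm_classes())
}

#' Generate a labeled synthetic feature dataset
#'
#' Draws `n_per_class` samples per class from class-conditional Gaussians
#' over the fifteen descriptors, in canonical feature order, and clamps
#' features to their valid ranges (variance, area, uniformity, entropy
#' non-negative; smoothness in `[0, 1)`; uniformity at most 1).
#'
#' @param n_per_class Samples per class (>= 1).
#' @param class_params Per-class distributions, as [default_class_params()].
#' @param seed Integer seed.
#' @return Data frame with `4 * n_per_class` rows: 15 feature columns plus
#'   a `label` factor with levels [fm_classes()].
#' @export
generate_feature_dataset <- function(n_per_class = 50,
                                     class_params = default_class_params(),
                                     seed = 1L) {
  stopifnot(n_per_class >= 1, all(fm_classes() %in% names(class_params)))
  nm <- feature_names()
  with_seed(seed, {
    rows <- lapply(fm_classes(), function(k) {
      p <- class_params[[k]]
      x <- vapply(nm, function(f)
        stats::rnorm(n_per_class, p$mean[[f]], p$sd[[f]]), numeric(n_per_class))
      x <- matrix(x, nrow = n_per_class, dimnames = list(NULL, nm))
      x[, "f02_var"] <- pmax(x[, "f02_var"], 0)
      x[, "f03_smooth"] <- pmin(pmax(x[, "f03_smooth"], 0), 1 - 1e-9)
      x[, "f05_unif"] <- pmin(pmax(x[, "f05_unif"], 1e-6), 1)
      x[, "f06_entropy"] <- pmax(x[, "f06_entropy"], 0)
      x[, "f07_area"] <- pmax(round(x[, "f07_area"]), 1)
      x[, "f08_wl_ratio"] <- pmax(x[, "f08_wl_ratio"], 0.05)
      cbind(as.data.frame(x), label = k)
    })
    out <- do.call(rbind, rows)
    out$label <- factor(out$label, levels = fm_classes())
    rownames(out) <- NULL
    out
  })
}
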