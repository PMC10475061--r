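# Synthetic fundus phantom generator.
#
# Emulates the statistical structure of disc-centered fundus data: a bright
# elliptical optic disc on a textured background, dark vessels rendered as
# anti-aliased curves, additive Gaussian pixel noise clipped to [0,1], and -
# for videos - a straight vein segment crossing the disc whose width
# oscillates sinusoidally at a cardiac-like frequency when a pulsation is
# present. Coordinates are 0-based (row, col); everything is a pure function
# of (spec, seed).

#' Phantom generation parameters
#'
#' Describes the geometry and signal statistics of a synthetic disc-centered
#' fundus frame or video. Defaults give a 128x128 frame with an interior
#' bright ellipse, a 5 px vein, a 30% diameter pulsation at 1.2 Hz (a typical
#' resting cardiac frequency), and 3 s of video at 30 fps - the minimum
#' recording contract of the classifier.
#'
#' @param image_height,image_width frame size in pixels
#' @param disc_center numeric (row, col), 0-based pixel coordinates
#' @param disc_radii numeric (vertical, horizontal) radii in pixels
#' @param disc_intensity,background_intensity,vessel_intensity intensities in \[0,1\]
#' @param vessel_base_width vein width in pixels
#' @param pulsation_amplitude fractional diameter modulation `a`, in \[0,1)
#' @param pulsation_frequency pulsation frequency in Hz
#' @param frame_rate video frame rate in Hz
#' @param duration video duration in seconds
#' @param noise_sd additive Gaussian noise standard deviation (intensity units)
#' @param seed integer RNG seed
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(image_height = 128, image_width = 128,
                         disc_center = c(64, 64), disc_radii = c(18, 22),
                         disc_intensity = 0.85, background_intensity = 0.45,
                         vessel_base_width = 5, vessel_intensity = 0.2,
                         pulsation_amplitude = 0.3, pulsation_frequency = 1.2,
                         frame_rate = 30, duration = 3, noise_sd = 0.02,
                         seed = 1L) {
  spec <- structure(list(
    image_height = as.integer(image_height), image_width = as.integer(image_width),
    disc_center = as.numeric(disc_center), disc_radii = as.numeric(disc_radii),
    disc_intensity = disc_intensity, background_intensity = background_intensity,
    vessel_base_width = vessel_base_width, vessel_intensity = vessel_intensity,
    pulsation_amplitude = pulsation_amplitude,
    pulsation_frequency = pulsation_frequency,
    frame_rate = frame_rate, duration = duration, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec, require_interior = TRUE) {
  with(spec, {
    if (pulsation_amplitude < 0 || pulsation_amplitude >= 1)
      stop_data("pulsation amplitude must lie in [0,1), got %g", pulsation_amplitude)
    ints <- c(disc_intensity, background_intensity, vessel_intensity)
    if (any(ints < 0 | ints > 1)) stop_data("intensities must lie in [0,1]")
    if (noise_sd < 0) stop_data("noise_sd must be non-negative")
    if (any(disc_radii <= 0)) stop_data("disc radii must be positive")
    if (require_interior) {
      ok <- disc_center[1] - disc_radii[1] >= 0 &&
        disc_center[1] + disc_radii[1] <= image_height - 1 &&
        disc_center[2] - disc_radii[2] >= 0 &&
        disc_center[2] + disc_radii[2] <= image_width - 1
      if (!ok) stop_data("disc is not interior to the %dx%d frame",
                         image_height, image_width)
    }
  })
  invisible(spec)
}

#' Video clip container
#'
#' @param frames numeric array (frame, row, col) with values in \[0,1\]
#' @param frame_rate frames per second
#' @return an `svp_video`
#' @export
svp_video <- function(frames, frame_rate = 30) {
  nd <- length(dim(frames))
  if (!(nd == 3 || (nd == 4 && dim(frames)[4] %in% c(1, 3))))
    stop_contract("frames must be (frame, row, col) or (frame, row, col, 1|3)")
  structure(list(frames = frames, frame_rate = frame_rate), class = "svp_video")
}

#' @export
print.svp_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<svp_video> %d frames of %dx%d @ %g fps\n", d[1], d[2], d[3],
              x$frame_rate))
  invisible(x)
}

# 0-based pixel coordinate grids
pixel_grid <- function(H, W) {
  list(row = matrix(0:(H - 1), H, W), col = matrix(0:(W - 1), H, W, byrow = TRUE))
}

# analytic ellipse membership on the 0-based pixel grid
disc_mask <- function(spec) {
  g <- pixel_grid(spec$image_height, spec$image_width)
  m <- (g$row - spec$disc_center[1])^2 / spec$disc_radii[1]^2 +
    (g$col - spec$disc_center[2])^2 / spec$disc_radii[2]^2 <= 1
  m + 0
}

# smooth low-frequency background texture (amplitude ~0.03), from current RNG
background_texture <- function(H, W) {
  g <- pixel_grid(H, W)
  tex <- matrix(0, H, W)
  for (k in 1:2) {
    th <- stats::runif(1, 0, pi)
    per <- stats::runif(1, 40, 90)
    ph <- stats::runif(1, 0, 2 * pi)
    tex <- tex + cos(2 * pi * (cos(th) * g$row + sin(th) * g$col) / per + ph)
  }
  0.015 * tex
}

# squared distance field to a sampled curve; pts is n x 2 (row, col)
curve_dist2 <- function(H, W, pts) {
  g <- pixel_grid(H, W)
  d2 <- matrix(Inf, H, W)
  for (k in seq_len(nrow(pts)))
    d2 <- pmin(d2, (g$row - pts[k, 1])^2 + (g$col - pts[k, 2])^2)
  d2
}

# anti-aliased coverage of a curve of width w given squared distances
coverage_alpha <- function(d2, w) clamp01(w / 2 + 0.5 - sqrt(d2))

# a gently bent vessel curve through `through` at angle `theta`
vessel_curve <- function(H, W, through, theta, bend) {
  L <- sqrt(H^2 + W^2)
  s <- seq(0, 1, length.out = ceiling(2 * L))
  u <- c(cos(theta), sin(theta))
  v <- c(-sin(theta), cos(theta))
  cbind(through[1] + (s - 0.5) * L * u[1] + bend * sin(pi * s) * v[1],
        through[2] + (s - 0.5) * L * u[2] + bend * sin(pi * s) * v[2])
}

#' Generate a synthetic fundus image with its ground-truth disc mask
#'
#' Renders a textured background, overwrites the analytic disc ellipse with a
#' flat bright intensity, darkens 2-4 anti-aliased vessel curves crossing the
#' disc by the background-vessel contrast, then adds clipped Gaussian noise.
#' The mask is exactly the ellipse membership set; vessels are not annotated.
#'
#' @param spec a [phantom_spec()]
#' @return a `labeled_image`: list with `frame` (matrix in \[0,1\]) and
#'   binary `mask` of the same size
#' @export
make_disc_image <- function(spec) {
  validate_phantom_spec(spec)
  H <- spec$image_height; W <- spec$image_width
  mask <- disc_mask(spec)
  frame <- with_seed(spec$seed, {
    base <- clamp01(spec$background_intensity + background_texture(H, W))
    base[mask == 1] <- spec$disc_intensity
    nv <- sample(2:4, 1)
    alpha <- matrix(0, H, W)
    for (k in seq_len(nv)) {
      th <- stats::runif(1, 0, pi)
      off <- stats::runif(2, -0.4, 0.4) * spec$disc_radii
      bend <- stats::runif(1, -0.15, 0.15) * sqrt(H^2 + W^2)
      wdt <- spec$vessel_base_width * stats::runif(1, 0.7, 1.3)
      pts <- vessel_curve(H, W, spec$disc_center + off, th, bend)
      alpha <- pmax(alpha, coverage_alpha(curve_dist2(H, W, pts), wdt))
    }
    f <- base - (spec$background_intensity - spec$vessel_intensity) * alpha
    if (spec$noise_sd > 0) f <- f + stats::rnorm(H * W, 0, spec$noise_sd)
    clamp01(f)
  })
  structure(list(frame = frame, mask = mask, spec = spec),
            class = "labeled_image")
}

#' Generate a synthetic fundus video with a known SVP label
#'
#' The static scene (background, disc, two horizontal static vessels offset
#' from the disc center) is shared by all frames. One vertical vein crossing
#' the disc center has per-frame width
#' `w(t) = vessel_base_width * (1 + a*sin(2*pi*f*t/frame_rate))` where `t` is
#' the 0-based frame index, `a = pulsation_amplitude` when `label` is
#' `"present"` and 0 otherwise. Per-frame noise is independent.
#'
#' @param spec a [phantom_spec()]
#' @param label `"present"` or `"absent"`
#' @return a `labeled_clip`: list with `clip` (an `svp_video`), `label`, and
#'   the effective `spec` (amplitude forced to 0 for absent clips)
#' @export
make_svp_clip <- function(spec, label = c("present", "absent")) {
  label <- match.arg(label)
  validate_phantom_spec(spec)
  if (label == "absent") spec$pulsation_amplitude <- 0
  n_frames <- round(spec$frame_rate * spec$duration)
  if (n_frames < 30)
    stop_contract("clip would have %d frames; the classifier requires >= 30", n_frames)
  H <- spec$image_height; W <- spec$image_width
  a <- spec$pulsation_amplitude
  delta <- spec$background_intensity - spec$vessel_intensity
  mask <- disc_mask(spec)
  frames <- with_seed(spec$seed, {
    base <- clamp01(spec$background_intensity + background_texture(H, W))
    base[mask == 1] <- spec$disc_intensity
    # static vessels: near-horizontal curves clear of the measurement row
    off <- max(0.5 * spec$disc_radii[1], spec$vessel_base_width + 4)
    alpha_static <- matrix(0, H, W)
    for (s in c(-1, 1)) {
      th <- pi / 2 + stats::runif(1, -0.04, 0.04)
      bend <- stats::runif(1, -0.02, 0.02) * sqrt(H^2 + W^2)
      pts <- vessel_curve(H, W, spec$disc_center + c(s * off, 0), th, bend)
      alpha_static <- pmax(alpha_static,
                           coverage_alpha(curve_dist2(H, W, pts),
                                          spec$vessel_base_width))
    }
    # vertical pulsating vein through the disc center: distance field is
    # |col - c1|, so per-frame coverage is cheap to recompute
    dcol2 <- (pixel_grid(H, W)$col - spec$disc_center[2])^2
    out <- array(0, dim = c(n_frames, H, W))
    for (t in seq_len(n_frames)) {
      wt <- spec$vessel_base_width *
        (1 + a * sin(2 * pi * spec$pulsation_frequency * (t - 1) / spec$frame_rate))
      alpha <- pmax(alpha_static, coverage_alpha(dcol2, wt))
      f <- base - delta * alpha
      if (spec$noise_sd > 0) f <- f + stats::rnorm(H * W, 0, spec$noise_sd)
      out[t, , ] <- clamp01(f)
    }
    out
  })
  structure(list(clip = svp_video(frames, spec$frame_rate), label = label,
                 spec = spec),
            class = "labeled_clip")
}

#' Generate a label-balanced phantom dataset
#'
#' Per-sample specs are jittered (disc center, radii, pulsation amplitude,
#' vein width) from a seeded RNG; each sample gets its own disjoint seed so
#' the dataset is a pure function of `(base_spec, seed)`.
#'
#' @param n_images number of labeled still images
#' @param n_clips number of labeled clips (must be even; half get each label)
#' @param base_spec the [phantom_spec()] to jitter around
#' @param seed integer seed
#' @return list with `images` (list of `labeled_image`) and `clips`
#'   (list of `labeled_clip`)
#' @export
make_dataset <- function(n_images, n_clips, base_spec = phantom_spec(),
                         seed = 1L) {
  if (n_clips %% 2 != 0) stop_data("n_clips must be even for label balance")
  n <- n_images + n_clips
  jit <- with_seed(seed, list(
    seeds = if (n > 0) sample.int(.Machine$integer.max - 1L, n) else integer(0),
    dcent = matrix(stats::runif(2 * n, -1, 1), ncol = 2),
    drad = matrix(stats::runif(2 * n, 0.85, 1.15), ncol = 2),
    damp = stats::runif(n, 0.7, 1.3),
    dwid = stats::runif(n, 0.85, 1.15)))
  jitter_spec <- function(i) {
    sp <- base_spec
    sp$seed <- jit$seeds[i]
    sp$disc_center <- sp$disc_center + jit$dcent[i, ] * 0.08 *
      c(sp$image_height, sp$image_width)
    sp$disc_radii <- sp$disc_radii * jit$drad[i, ]
    sp$pulsation_amplitude <- min(sp$pulsation_amplitude * jit$damp[i], 0.95)
    sp$vessel_base_width <- sp$vessel_base_width * jit$dwid[i]
    # keep the disc interior after jitter
    sp$disc_center <- pmin(pmax(sp$disc_center, sp$disc_radii + 1),
                           c(sp$image_height, sp$image_width) - 1 - sp$disc_radii)
    sp
  }
  images <- lapply(seq_len(n_images), function(i) make_disc_image(jitter_spec(i)))
  labels <- rep(c("present", "absent"), length.out = max(n_clips, 0))
  clips <- lapply(seq_len(n_clips), function(i)
    make_svp_clip(jitter_spec(n_images + i), labels[i]))
  list(images = images, clips = clips)
}
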