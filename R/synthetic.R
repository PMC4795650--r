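# Synthetic test sequences with analytic ground truth: the two-disk vortex
# benchmark, translation/occlusion pairs for the registration model, and 3D
# sphere phantoms.

#' Divergence-free vortex velocity field on the unit square
#'
#' `u = -sin^2(pi x) sin(2 pi y)`, `v = sin^2(pi y) sin(2 pi x)`. The normal
#' component vanishes on the boundary of `[0, 1]^2` and the field is exactly
#' divergence free.
#'
#' @param x,y coordinates in `[0, 1]` (vectorised).
#' @return a two-column matrix with components `u`, `v`.
#' @export
vortex_velocity <- function(x, y) {
  cbind(u = -sin(pi * x)^2 * sin(2 * pi * y),
        v = sin(pi * y)^2 * sin(2 * pi * x))
}

#' Specification of the two-disk vortex sequence
#'
#' Defaults reproduce the benchmark geometry: a disk of radius 0.15 centred
#' at (0.5, 0.75) and a disk of radius 0.1 centred at (0.2, 0.2) on the unit
#' square, interior intensities drawn in `[200, 255]` (ramping to 200 within
#' a 2-pixel band of the contour), exterior in `[50, 155]` (ramping to 50
#' near the contour), deformed by the vortex field.
#'
#' @param n_frames number of frames.
#' @param size pixels per side.
#' @param dt flow time elapsing between consecutive frames.
#' @param radii,centers disk radii and a 2-column matrix of centres, in unit
#'   coordinates.
#' @param interior_range,exterior_range intensity ranges.
#' @param seed RNG seed fixing the texture.
#' @return a `vortex_spec` list.
#' @export
vortex_spec <- function(n_frames = 50L, size = 100L, dt = 0.002,
                        radii = c(0.15, 0.1),
                        centers = rbind(c(0.5, 0.75), c(0.2, 0.2)),
                        interior_range = c(200, 255),
                        exterior_range = c(50, 155),
                        seed = 0L) {
  if (any(radii <= 0)) stop("radii must be positive")
  if (any(centers <= 0 | centers >= 1)) stop("centers must lie in (0,1)^2")
  if (interior_range[1] <= exterior_range[2])
    stop("interior intensity range must lie above the exterior range")
  structure(list(n_frames = as.integer(n_frames), size = as.integer(size),
                 dt = dt, radii = radii, centers = centers,
                 interior_range = interior_range,
                 exterior_range = exterior_range, seed = as.integer(seed)),
            class = "vortex_spec")
}

# signed distance to the union of the spec's disks (positive inside)
disks_sdf <- function(spec, pts) {
  d <- rep(-Inf, nrow(pts))
  for (k in seq_along(spec$radii)) {
    dk <- spec$radii[k] -
      sqrt((pts[, 1] - spec$centers[k, 1])^2 +
             (pts[, 2] - spec$centers[k, 2])^2)
    d <- pmax(d, dk)
  }
  d
}

# backward characteristic tracing through the (static) vortex field with RK4
# at 4x substep resolution; pts in unit coordinates
trace_back <- function(pts, time, substeps_per_frame = 4L, dt_frame = 0.002) {
  if (time == 0) return(pts)
  nstep <- max(1L, ceiling(abs(time) / dt_frame) * substeps_per_frame)
  hstep <- -time / nstep
  p <- pts
  vel <- function(q) vortex_velocity(q[, 1], q[, 2])
  for (i in seq_len(nstep)) {
    k1 <- vel(p)
    k2 <- vel(p + hstep / 2 * k1)
    k3 <- vel(p + hstep / 2 * k2)
    k4 <- vel(p + hstep * k3)
    p <- p + hstep / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    p <- pmin(pmax(p, 0), 1)
  }
  p
}

#' Generate the two-disk vortex sequence with analytic ground truth
#'
#' Frame 0 draws the textured disks; each later frame is obtained by tracing
#' the vortex characteristics backward with RK4 (4x substeps) and resampling
#' frame 0, so intensities and true masks are advected without cumulative
#' resampling error. Ground-truth masks follow the same characteristics.
#'
#' @param spec a [vortex_spec()].
#' @return list with `frames` (list of [image_frame()]), `masks` (list of
#'   binary matrices) and the `spec`.
#' @export
make_vortex_sequence <- function(spec) {
  if (!inherits(spec, "vortex_spec")) stop("invalid spec")
  n <- spec$size
  px <- 1 / n
  ctr <- (seq_len(n) - 0.5) * px
  pts <- as.matrix(expand.grid(x = ctr, y = ctr))
  sdf0 <- disks_sdf(spec, pts)

  oldseed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed,
                                        envir = globalenv()))
  set.seed(spec$seed)
  tex_in <- matrix(stats::runif(n * n, spec$interior_range[1],
                                spec$interior_range[2]), n, n)
  tex_out <- matrix(stats::runif(n * n, spec$exterior_range[1],
                                 spec$exterior_range[2]), n, n)

  band <- 2 * px
  base_at <- function(p) {
    # nearest-pixel texture + linear ramp to the boundary value in a 2-pixel
    # band on each side of the contour
    sd <- disks_sdf(spec, p)
    i <- pmin(pmax(ceiling(p[, 1] / px), 1), n)
    j <- pmin(pmax(ceiling(p[, 2] / px), 1), n)
    tin <- tex_in[cbind(i, j)]
    tout <- tex_out[cbind(i, j)]
    win <- pmin(sd / band, 1)          # 0 at contour -> 1 past the band
    wout <- pmin(-sd / band, 1)
    ifelse(sd >= 0,
           spec$interior_range[1] + win * (tin - spec$interior_range[1]),
           spec$exterior_range[1] + wout * (tout - spec$exterior_range[1]))
  }

  frames <- vector("list", spec$n_frames)
  masks <- vector("list", spec$n_frames)
  for (k in seq_len(spec$n_frames)) {
    tt <- (k - 1) * spec$dt
    back <- trace_back(pts, tt, dt_frame = max(spec$dt, 1e-9))
    vals <- base_at(back)
    sd <- disks_sdf(spec, back)
    frames[[k]] <- image_frame(matrix(vals, n, n), spacing = 1)
    masks[[k]] <- matrix(as.numeric(sd > 0), n, n)
  }
  list(frames = frames, masks = masks, spec = spec)
}

#' Smooth translated image pair with optional occlusion
#'
#' A smooth random blob image and a copy translated by a (possibly
#' fractional) pixel shift; optionally a constant-intensity rectangle is
#' pasted into the second frame, with its support recorded, to exercise the
#' sparse-error term.
#'
#' @param shift numeric length-2 pixel shift applied to the scene between
#'   frame 1 and frame 2.
#' @param size image side in pixels.
#' @param occlusion optional list with `x0`, `y0`, `x1`, `y1` (1-based pixel
#'   bounds, inclusive) and `value`.
#' @param seed RNG seed.
#' @return list with `frame1`, `frame2` ([image_frame()]), `shift` and
#'   `occlusion_mask` (binary matrix, support of the pasted patch).
#' @export
make_translation_pair <- function(shift, size = 64L, occlusion = NULL,
                                  seed = 0L) {
  if (any(abs(shift) >= size / 4)) stop("shift too large for the frame")
  oldseed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed,
                                        envir = globalenv()))
  set.seed(seed)
  n <- as.integer(size)
  # smooth scene: sum of random Gaussian bumps, analytic so fractional
  # shifts are exact
  nb <- 12L
  cx <- stats::runif(nb, 0.15 * n, 0.85 * n)
  cy <- stats::runif(nb, 0.15 * n, 0.85 * n)
  amp <- stats::runif(nb, 40, 110) * sample(c(-1, 1), nb, TRUE)
  sg <- stats::runif(nb, 0.06 * n, 0.16 * n)
  scene <- function(x, y) {
    v <- rep(120, length(x))
    for (b in seq_len(nb))
      v <- v + amp[b] * exp(-((x - cx[b])^2 + (y - cy[b])^2) / (2 * sg[b]^2))
    v
  }
  ctr <- seq_len(n) - 0.5
  g <- expand.grid(x = ctr, y = ctr)
  f1 <- matrix(scene(g$x, g$y), n, n)
  f2 <- matrix(scene(g$x - shift[1], g$y - shift[2]), n, n)
  occ <- matrix(0, n, n)
  if (!is.null(occlusion)) {
    xs <- occlusion$x0:occlusion$x1
    ys <- occlusion$y0:occlusion$y1
    f2[xs, ys] <- occlusion$value
    occ[xs, ys] <- 1
  }
  list(frame1 = image_frame(f1), frame2 = image_frame(f2),
       shift = shift, occlusion_mask = occ)
}

#' 3D sphere phantom sequence
#'
#' A sphere with the two-level noisy intensity model of the vortex benchmark
#' (interior `[200, 255]` ramping to 200 at the surface, exterior `[50, 155]`
#' ramping to 50), either static, rigidly translated, or radius-oscillated
#' per frame. Analytic masks are returned.
#'
#' @param size voxels per side.
#' @param radius sphere radius in voxels.
#' @param motion list: `list(type = "static")`,
#'   `list(type = "translate", step = c(dx, dy, dz))` (voxels per frame) or
#'   `list(type = "oscillate", amplitude = 0.2, period = 10)` giving
#'   `r(t) = radius * (1 + amplitude * sin(2 pi t / period))`.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return list with `frames` (list of [image_frame()] 3D), `masks`,
#'   `centers`, `radii`.
#' @export
make_sphere_sequence <- function(size = 32L, radius = 10, motion = list(type = "static"),
                                 n_frames = 3L, seed = 0L) {
  n <- as.integer(size)
  if (radius >= n / 2) stop("radius does not fit in the volume")
  oldseed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed,
                                        envir = globalenv()))
  set.seed(seed)
  tex_in <- array(stats::runif(n^3, 200, 255), c(n, n, n))
  tex_out <- array(stats::runif(n^3, 50, 155), c(n, n, n))
  ctr <- seq_len(n) - 0.5
  g <- as.matrix(expand.grid(x = ctr, y = ctr, z = ctr))
  frames <- vector("list", n_frames)
  masks <- vector("list", n_frames)
  centers <- matrix(n / 2, n_frames, 3)
  radii <- rep(radius, n_frames)
  for (k in seq_len(n_frames)) {
    t0 <- k - 1
    if (identical(motion$type, "translate"))
      centers[k, ] <- n / 2 + t0 * motion$step
    if (identical(motion$type, "oscillate"))
      radii[k] <- radius * (1 + motion$amplitude *
                              sin(2 * pi * t0 / motion$period))
    sd <- radii[k] - sqrt((g[, 1] - centers[k, 1])^2 +
                            (g[, 2] - centers[k, 2])^2 +
                            (g[, 3] - centers[k, 3])^2)
    win <- pmin(sd / 2, 1)
    wout <- pmin(-sd / 2, 1)
    vals <- ifelse(sd >= 0, 200 + win * (as.vector(tex_in) - 200),
                   50 + wout * (as.vector(tex_out) - 50))
    frames[[k]] <- image_frame(array(vals, c(n, n, n)))
    masks[[k]] <- array(as.numeric(sd > 0), c(n, n, n))
  }
  list(frames = frames, masks = masks, centers = centers, radii = radii)
}
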