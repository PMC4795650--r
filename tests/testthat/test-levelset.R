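circle_phi <- function(p) 0.25 - sqrt((p[, 1] - 0.5)^2 + (p[, 2] - 0.5)^2)

test_that("multilinear interpolation reproduces vertices, affine fields and the per-leaf oracle", {
  dom <- at_domain(c(64, 64), spacing = 1 / 64)
  tr <- build_tree(dom, circle_phi, max_level = 6)
  X <- adaptivetrack:::vertex_coords(tr)
  af <- node_field(tr, 3 * X[, 1] - 2 * X[, 2] + 0.5)
  # at a vertex
  expect_equal(interpolate(af, X[57, ]), af$values[57])
  # affine anywhere
  set.seed(9)
  P <- cbind(runif(100), runif(100))
  expect_lt(max(abs(interpolate(af, P) - (3 * P[, 1] - 2 * P[, 2] + 0.5))),
            1e-12)
  # random field vs brute-force per-leaf evaluation
  set.seed(10)
  rf <- node_field(tr, rnorm(nrow(X)))
  for (k in 1:20) {
    p <- c(runif(1), runif(1))
    expect_equal(interpolate(rf, p), brute_force_interp(rf, p),
                 tolerance = 1e-12)
  }
  # outside the domain: clamped, equal to the boundary value
  expect_equal(interpolate(af, c(-0.5, 0.5)),
               interpolate(af, c(0, 0.5)))
})

test_that("semi-Lagrangian advection is exact for affine fields under uniform flow", {
  dom <- at_domain(c(64, 64), spacing = 1 / 64)
  tr <- build_tree(dom, circle_phi, max_level = 6)
  X <- adaptivetrack:::vertex_coords(tr)
  phi <- node_field(tr, X[, 1])
  # zero velocity: unchanged
  vz <- list(node_field(tr, 0), node_field(tr, 0))
  expect_equal(advect(phi, vz, 0.1)$values, phi$values, tolerance = 1e-12)
  # uniform velocity (c, 0) on phi = x: x - c dt away from the inflow side
  cvel <- 0.3
  vu <- list(node_field(tr, cvel), node_field(tr, 0))
  adv <- advect(phi, vu, 0.05)
  interior <- X[, 1] > 0.05
  expect_lt(max(abs(adv$values[interior] - (X[interior, 1] - cvel * 0.05))),
            1e-10)
  expect_error(advect(phi, function(p) cbind(rep(NaN, nrow(p)),
                                             rep(0, nrow(p))), 0.1),
               "finite")
})

test_that("a translated disk's contour centroid follows the flow", {
  dom <- at_domain(c(128, 128), spacing = 1 / 128)
  tr <- build_tree(dom, function(p) 0.15 - sqrt((p[, 1] - 0.35)^2 +
                                                  (p[, 2] - 0.5)^2),
                   max_level = 7)
  X <- adaptivetrack:::vertex_coords(tr)
  phi <- node_field(tr, 0.15 - sqrt((X[, 1] - 0.35)^2 + (X[, 2] - 0.5)^2))
  vel <- function(p) cbind(rep(0.5, nrow(p)), rep(0, nrow(p)))
  dt <- 0.005
  for (k in 1:10) phi <- advect(phi, vel, dt)
  pts <- adaptivetrack:::crossing_points(phi, 0)
  centroid <- colMeans(pts)
  expect_lt(abs(centroid[1] - (0.35 + 0.5 * 10 * dt)), 1 / 128)
  expect_lt(abs(centroid[2] - 0.5), 1 / 128)
})

test_that("reinitialization restores the signed-distance property without moving the front", {
  dom <- at_domain(c(128, 128), spacing = 1 / 128)
  tr <- build_tree(dom, circle_phi, max_level = 7)
  X <- adaptivetrack:::vertex_coords(tr)
  h <- tr$h
  # an exact SDF is (near the band) a fixed point
  sdf <- node_field(tr, circle_phi(X))
  re <- reinitialize(sdf, 10)
  band <- abs(sdf$values) <= 3 * h
  expect_lt(max(abs(re$values - sdf$values)[band]), 1e-5)
  expect_true(re$is_sdf)
  # scaled input: gradient magnitude returns to the [0.9, 1.1] band
  re2 <- reinitialize(node_field(tr, 5 * circle_phi(X)), 40)
  gn <- adaptivetrack:::grad_norm(tr, re2$values)
  expect_true(all(gn[band] > 0.9 & gn[band] < 1.1))
  th <- seq(0, 2 * pi, length.out = 180)
  ring <- cbind(0.5 + 0.25 * cos(th), 0.5 + 0.25 * sin(th))
  expect_lt(max(abs(interpolate(re2, ring))), h)
  # vertices exactly on the interface do not move
  idx0 <- which(abs(sdf$values) < 1e-14)
  if (length(idx0))
    expect_equal(re$values[idx0], sdf$values[idx0], tolerance = 1e-12)
  expect_error(reinitialize(sdf, 0), "n_iter")
})

test_that("smoothed Heaviside and Dirac have the mollified properties", {
  eps <- 0.03
  expect_equal(smoothed_heaviside(0, eps), 0.5)
  expect_equal(smoothed_heaviside(2 * eps, eps), 1)
  expect_equal(smoothed_heaviside(-2 * eps, eps), 0)
  expect_equal(smoothed_dirac(2 * eps, eps), 0)
  expect_equal(smoothed_dirac(-2 * eps, eps), 0)
  # dirac integrates to one along a transect
  x <- seq(-5 * eps, 5 * eps, length.out = 4001)
  expect_equal(sum(smoothed_dirac(x, eps)) * diff(x)[1], 1, tolerance = 1e-4)
  # dirac is the derivative of the Heaviside
  hh <- 1e-6
  mid <- seq(-eps, eps, length.out = 11)
  expect_equal(smoothed_dirac(mid, eps),
               (smoothed_heaviside(mid + hh, eps) -
                  smoothed_heaviside(mid - hh, eps)) / (2 * hh),
               tolerance = 1e-5)
  expect_error(smoothed_heaviside(0, -1), "positive")
})

test_that("mask to signed distance and back preserves a disk", {
  n <- 64
  msk <- disk_mask(n, 32, 32, 14)
  dom <- at_domain(c(n, n))
  cfg <- run_config()
  st <- init_tracking_state(image_frame(matrix(100, n, n) + 50 * msk), msk,
                            cfg)
  # phi at the centre is close to the radius
  expect_lt(abs(interpolate(st$shape, c(32, 32)) - 14), 2 * st$tree$h)
  # sign convention: positive inside
  expect_gt(interpolate(st$shape, c(32, 32)), 0)
  expect_lt(interpolate(st$shape, c(2, 2)), 0)
  back <- sdf_to_mask(st$shape)
  expect_gte(dice_coefficient(back, msk), 0.99)
  expect_error(mask_to_sdf(matrix(0, 4, 4),
                           build_tree(at_domain(c(4, 4)),
                                      function(p) rep(0, nrow(p)))),
               "empty")
})

test_that("full-domain mask yields positive phi away from the boundary", {
  n <- 32
  dom <- at_domain(c(n, n))
  tr <- build_tree(dom, function(p) rep(1, nrow(p)), max_level = 5)
  phi <- mask_to_sdf(matrix(1, n, n), tr, n_reinit = 0)
  X <- adaptivetrack:::vertex_coords(tr)
  inner <- X[, 1] > 4 & X[, 1] < 28 & X[, 2] > 4 & X[, 2] < 28
  expect_true(all(phi$values[inner] > 0))
})

test_that("vortex advection forward then backward restores the disk contour", {
  n <- 100
  dom <- at_domain(c(n, n), spacing = 1 / n)
  # uniform level-7 tree so the deforming contour never leaves resolution
  tr <- build_tree(dom, function(p) rep(0, nrow(p)), max_level = 7)
  X <- adaptivetrack:::vertex_coords(tr)
  phi0 <- 0.15 - sqrt((X[, 1] - 0.5)^2 + (X[, 2] - 0.75)^2)
  phi <- node_field(tr, phi0)
  vel_f <- function(p) vortex_velocity(p[, 1], p[, 2])
  vel_b <- function(p) -vortex_velocity(p[, 1], p[, 2])
  dt <- 0.004
  nstep <- 25
  for (k in seq_len(nstep)) phi <- advect(phi, vel_f, dt)
  for (k in seq_len(nstep)) phi <- advect(phi, vel_b, dt)
  m0 <- sdf_to_mask(node_field(tr, phi0))
  m1 <- sdf_to_mask(phi)
  expect_gte(dice_coefficient(m0, m1), 0.95)
})
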