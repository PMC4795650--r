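test_that("central differences are exact on quadratics over random spacings", {
  set.seed(42)
  n <- 1e4
  s1 <- runif(n, 0.05, 3); s2 <- runif(n, 0.05, 3)
  a <- runif(n, -2, 2); b <- runif(n, -2, 2); c0 <- runif(n, -2, 2)
  # u(x) = a x^2 + b x + c sampled at -s1, 0, s2
  st <- list(u0 = c0, u1 = a * s1^2 - b * s1 + c0, u2 = a * s2^2 + b * s2 + c0,
             s1 = s1, s2 = s2)
  expect_lt(max(abs(d_central(st) - b) / pmax(abs(b), 1)), 1e-12)
  expect_lt(max(abs(d_second(st) - 2 * a) / pmax(abs(2 * a), 1)), 1e-12)
})

test_that("one-sided differences and limiter behave as specified", {
  expect_equal(minmod(0, 5), 0)
  expect_equal(minmod(3, 3), 3)
  expect_equal(minmod(2, -1), -1)
  expect_equal(minmod(c(1, -4), c(-2, 3)), c(1, 3))
  # affine slope recovered at order 1 on both sides
  st <- list(u0 = 1, u1 = 1 - 3 * 0.7, u2 = 1 + 3 * 1.3, s1 = 0.7, s2 = 1.3)
  expect_equal(d_one_sided(st, "+", 1), 3)
  expect_equal(d_one_sided(st, "-", 1), 3)
  # u = x^2, uniform h: the limited order-2 forward difference is exact at 0
  h <- 0.5
  st2 <- list(u0 = 0, u1 = h^2, u2 = h^2, s1 = h, s2 = h)
  expect_equal(d_one_sided(st2, "+", 2, dxx0 = 2, dxx_nbr = 2), 0)
  expect_equal(d_one_sided(st2, "-", 2, dxx0 = 2, dxx_nbr = 2), 0)
  # zero second derivatives: order 2 equals order 1
  expect_equal(d_one_sided(st, "+", 2, dxx0 = 0, dxx_nbr = 0),
               d_one_sided(st, "+", 1))
  expect_error(d_one_sided(st, "?", 1), "side")
  expect_error(d_one_sided(st, "+", 3), "order")
  expect_error(d_central(list(u0 = 0, u1 = 0, u2 = 0, s1 = 0, s2 = 1)),
               "positive")
})

test_that("uniform spacing reduces every stencil to the textbook formula", {
  set.seed(1)
  for (k in 1:20) {
    h <- runif(1, 0.1, 2)
    u <- rnorm(3)
    st <- list(u0 = u[2], u1 = u[1], u2 = u[3], s1 = h, s2 = h)
    expect_equal(d_central(st), (u[3] - u[1]) / (2 * h), tolerance = 1e-13)
    expect_equal(d_second(st), (u[3] - 2 * u[2] + u[1]) / h^2,
                 tolerance = 1e-13)
  }
})

test_that("2D ghost interpolation is exact on affine and quadratic fields", {
  set.seed(2)
  for (k in 1:200) {
    s1 <- runif(1, 0.1, 2); s2 <- runif(1, 0.1, 2)
    s3 <- runif(1, 0.1, 2); s4 <- runif(1, 0.1, 2)
    sx <- runif(1, 0.1, 2)              # ghost offset in x (unused by formula)
    co <- rnorm(6)                       # quadratic a x^2+b y^2+c x+d y+e+f xy
    f <- function(x, y) co[1] * x^2 + co[2] * y^2 + co[3] * x + co[4] * y +
      co[5] + co[6] * x * y
    # node at origin; ghost at (sx, 0); transverse samples on the line x = sx
    tj <- list(u0 = f(0, 0), u1 = f(0, -s1), u2 = f(0, s2),
               u3 = f(sx, -s3), u4 = f(sx, s4),
               s1 = s1, s2 = s2, s3 = s3, s4 = s4)
    expect_equal(ghost_value_2d(tj), f(sx, 0), tolerance = 1e-12)
  }
  tjc <- list(u0 = 7, u1 = 7, u2 = 7, u3 = 7, u4 = 7,
              s1 = 1, s2 = 1, s3 = 2, s4 = 2)
  expect_equal(ghost_value_2d(tjc), 7)
  expect_error(ghost_value_2d(modifyList(tjc, list(s3 = 0))), "positive")
})

test_that("3D ghost interpolation is exact on affine and quadratic fields", {
  # geometry: node v0 at origin; x-neighbours at -s1, +s2;
  # first ghost g6 on the +z axis at s4, bracketed along x by u7, u8;
  # second ghost g4 on the +y axis at sy, with four bracketing samples in
  # the x-z plane through g4; u5 is the -z neighbour at s5.
  set.seed(3)
  for (k in 1:200) {
    s <- runif(12, 0.1, 2)
    sy <- runif(1, 0.1, 2)
    co <- rnorm(4)
    f <- function(x, y, z) co[1] * (x^2 + y^2 + z^2) + co[2] * x +
      co[3] * y + co[4] * z
    g6 <- c(0, 0, s[4])
    g4 <- c(0, sy, 0)
    tj <- list(u0 = f(0, 0, 0),
               u1 = f(-s[1], 0, 0), u2 = f(s[2], 0, 0),
               s1 = s[1], s2 = s[2], s4 = s[4],
               u5 = f(0, 0, -s[5]), s5 = s[5],
               u7 = f(-s[7], 0, s[4]), u8 = f(s[8], 0, s[4]),
               s7 = s[7], s8 = s[8],
               u11 = f(-s[10], sy, -s[9]), u12 = f(-s[10], sy, s[12]),
               u9 = f(s[11], sy, -s[9]), u10 = f(s[11], sy, s[12]),
               s9 = s[9], s10 = s[10], s11 = s[11], s12 = s[12])
    out <- ghost_values_3d(tj)
    expect_equal(out$u6G, f(0, 0, s[4]), tolerance = 1e-11)
    expect_equal(out$u4G, f(0, sy, 0), tolerance = 1e-11)
  }
  # constant field
  cc <- as.list(rep(5, 10))
  names(cc) <- c("u0", "u1", "u2", "u5", "u7", "u8", "u9", "u10", "u11", "u12")
  cc <- c(cc, list(s1 = 1, s2 = 1, s4 = 1, s5 = 1, s7 = 1, s8 = 1,
                   s9 = 1, s10 = 1, s11 = 1, s12 = 1))
  out <- ghost_values_3d(cc)
  expect_equal(out$u6G, 5)
  expect_equal(out$u4G, 5)
})

test_that("central differences converge at second order on sin(x)", {
  errs <- c()
  hs <- 0.2 / 2^(0:4)
  x0 <- 0.7
  set.seed(4)
  for (h in hs) {
    r <- runif(1, 0.6, 1.6)              # bounded spacing ratio
    s1 <- h; s2 <- r * h
    st <- list(u0 = sin(x0), u1 = sin(x0 - s1), u2 = sin(x0 + s2),
               s1 = s1, s2 = s2)
    errs <- c(errs, abs(d_central(st) - cos(x0)))
  }
  rate <- log2(errs[-length(errs)] / errs[-1])
  expect_gt(mean(rate), 1.7)
})

test_that("tree-level T-junction ghosts reproduce quadratics in 2D and 3D", {
  for (d in 2:3) {
    dom <- at_domain(rep(32, d))
    phi <- function(p) 8 - sqrt(rowSums(sweep(p, 2, rep(16, d))^2))
    tr <- build_tree(dom, phi, max_level = if (d == 2) 5 else 4, lip = 1.2)
    st <- adaptivetrack:::tree_stencil(tr)
    X <- adaptivetrack:::vertex_coords(tr)
    co <- c(0.3, -0.2, 0.15)
    f <- rowSums(sweep(X, 2, 0, `*`)) # placeholder
    f <- X[, 1]^2 - 0.5 * X[, 2]^2 + 2 * X[, 1] +
      if (d == 3) 0.25 * X[, 3]^2 - X[, 3] else 0
    interior <- rowSums(sapply(seq_len(2 * d),
                               function(k) st$is_bnd[, k])) == 0
    for (axis in seq_len(d)) {
      dd <- adaptivetrack:::d_axis_second(tr, f, axis)
      target <- c(2, -1, 0.5)[axis]
      expect_lt(max(abs(dd[interior] - target)), 1e-9)
    }
  }
})
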