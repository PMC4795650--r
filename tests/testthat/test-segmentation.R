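seg_dom <- at_domain(c(64, 64))
seg_truth <- outer(seq_len(64) - 0.5, seq_len(64) - 0.5,
                   function(x, y) as.numeric(x < 32))
seg_img <- local({
  set.seed(3)
  img <- matrix(0, 64, 64)
  img[1:32, ] <- matrix(runif(32 * 64, 200, 255), 32, 64)
  img[33:64, ] <- matrix(runif(32 * 64, 50, 155), 32, 64)
  image_frame(img)
})
seg_tree <- build_tree(seg_dom, function(p) 32 - p[, 1], max_level = 6)

test_that("the intensity model and log-likelihood ratio behave as a region term", {
  # identical histograms: eta vanishes
  m0 <- intensity_model(seg_img, matrix(rep(c(1, 0), 2048), 64, 64))
  same <- intensity_model(list(seg_img, seg_img),
                          list(seg_truth, seg_truth))
  expect_true(all(same$p_fg > 0) && all(same$p_bg > 0))
  expect_equal(sum(same$p_fg), 1)
  expect_equal(sum(same$p_bg), 1)
  mod_eq <- same; mod_eq$p_bg <- mod_eq$p_fg
  If <- image_to_nodes(seg_tree, seg_img)
  expect_equal(eta(If, mod_eq)$values, rep(0, length(If$values)))
  # two-delta histograms: sign identifies the regions
  fr2 <- image_frame(matrix(c(200, 50), 2, 2))
  msk2 <- matrix(c(1, 0), 2, 2)
  m2 <- intensity_model(fr2, msk2)
  tr2 <- build_tree(at_domain(c(2, 2)), function(p) rep(0, nrow(p)))
  e200 <- eta(node_field(tr2, 200), m2)$values[1]
  e50 <- eta(node_field(tr2, 50), m2)$values[1]
  expect_lt(e200, 0)
  expect_gt(e50, 0)
  # matches an independent per-vertex computation on a random field
  mod <- intensity_model(seg_img, seg_truth)
  ev <- eta(If, mod)$values
  for (i in sample(length(ev), 20)) {
    b <- findInterval(If$values[i], mod$breaks, rightmost.closed = TRUE)
    b <- min(max(b, 1), mod$nbins)
    expect_equal(ev[i], log(mod$p_bg[b]) - log(mod$p_fg[b]))
  }
})

test_that("the box penalty has the printed case split", {
  expect_equal(zeta(0.5), 0)
  expect_equal(zeta(-1), 2)
  expect_equal(zeta(1.5), 1)
  expect_equal(zeta(c(0, 1)), c(0, 0))
})

test_that("the edge function is the inverse smoothed gradient magnitude", {
  tr <- seg_tree
  gconst <- edge_function(image_frame(matrix(7, 64, 64)), tr)
  expect_equal(gconst$values, rep(1, length(gconst$values)))
  # closed form: |grad|^2 = 1/gamma gives 1/2
  expect_equal(1 / (1 + 600 * (1 / 600)), 0.5)
  # strictly decreasing in the squared gradient
  g2 <- sort(runif(50, 0, 0.1))
  gv <- 1 / (1 + 600 * g2)
  expect_true(all(diff(gv) < 0))
  # edges of the bimodal image get small g
  ge <- edge_function(seg_img, tr)
  X <- adaptivetrack:::vertex_coords(tr)
  at_edge <- abs(X[, 1] - 32) <= 1
  far <- abs(X[, 1] - 32) > 8 & X[, 1] > 2 & X[, 1] < 62
  expect_lt(mean(ge$values[at_edge]), 0.2)
  expect_gt(mean(ge$values[far]), mean(ge$values[at_edge]))
})

test_that("shape weights are the squared shape magnitude", {
  X <- adaptivetrack:::vertex_coords(seg_tree)
  z <- node_field(seg_tree, 0)
  expect_equal(prior_weight(z)$values, rep(0, nrow(X)))
  s3 <- node_field(seg_tree, 3)
  expect_equal(prior_weight(s3)$values, rep(9, nrow(X)))
  # vanishes on the zero level set, grows quadratically for an SDF
  sdf <- node_field(seg_tree, 16 - sqrt((X[, 1] - 32)^2 + (X[, 2] - 32)^2))
  w <- combo_weight(sdf)$values
  on_c <- abs(sdf$values) < 1e-9
  expect_true(all(w[on_c] == 0))
  expect_equal(w, sdf$values^2)
})

test_that("a strongly bimodal image is segmented to high Dice with energy descent", {
  mod <- intensity_model(seg_img, seg_truth)
  If <- image_to_nodes(seg_tree, seg_img)
  ev <- eta(If, mod)
  g <- edge_function(seg_img, seg_tree)
  par <- segmentation_params(alpha_s1 = 0.035)
  seg <- solve_segmentation(ev, g, par, n_outer = 40)
  expect_true(all(seg$phi0$values >= 0 & seg$phi0$values <= 1))
  msk <- sdf_to_mask(node_field(seg_tree, seg$phi0$values - 0.5))
  expect_gte(dice_coefficient(msk, seg_truth), 0.99)
  scale <- max(1, abs(seg$energy[1]))
  expect_true(all(diff(seg$energy) <= 1e-8 * scale))
  # the admissibility bound is enforced
  bad <- segmentation_params(alpha_s1 = 0.035, alpha_hat = 1e-9)
  expect_error(solve_segmentation(ev, g, bad), "alpha_hat")
  expect_error(solve_segmentation(ev, node_field(seg_tree, -1), par),
               "non-negative")
})

test_that("a stationary constant indicator stays put when eta vanishes", {
  ev0 <- node_field(seg_tree, 0)
  wgt <- node_field(seg_tree, 1)
  par <- segmentation_params(alpha_s1 = 0.03, alpha_hat = 1)
  for (cst in c(0.2, 0.8)) {
    seg <- solve_segmentation(ev0, wgt, par, init = cst, n_outer = 5)
    expect_equal(seg$phi0$values, rep(cst, length(ev0$values)),
                 tolerance = 1e-10)
  }
})

test_that("the contour locks onto a vanishing-weight locus", {
  # TV weight from a circle SDF prior (vanishing at radius 16); a weak
  # region term prefers radius 19, but crossing the positive-weight annulus
  # costs more than the data gain, so the contour stays at the prior circle
  n <- 64
  dom <- at_domain(c(n, n))
  tr <- build_tree(dom, function(p)
    16 - sqrt((p[, 1] - 32)^2 + (p[, 2] - 32)^2), max_level = 6)
  X <- adaptivetrack:::vertex_coords(tr)
  r <- sqrt((X[, 1] - 32)^2 + (X[, 2] - 32)^2)
  sdfp <- node_field(tr, 16 - r)
  wgt <- node_field(tr, prior_weight(sdfp)$values)   # unit-scale weight
  evv <- node_field(tr, ifelse(r < 19, -0.2, 0.2))
  par <- segmentation_params(alpha_s1 = 0.05)
  init <- node_field(tr, smoothed_heaviside(16 - r, 2))
  seg <- solve_segmentation(evv, wgt, par, init = init, n_outer = 30)
  msk <- sdf_to_mask(node_field(tr, seg$phi0$values - 0.5))
  expect_gte(dice_coefficient(msk, disk_mask(n, 32, 32, 16)), 0.95)
  expect_lte(hausdorff_distance(msk, disk_mask(n, 32, 32, 16)), 2)
})

test_that("segmentation defaults match the reference parameter table", {
  p <- segmentation_params()
  expect_true(p$alpha_s1 >= 0.02 && p$alpha_s1 <= 0.05)
  # the draw is reproducible under the same seed
  expect_identical(p$alpha_s1, segmentation_params()$alpha_s1)
  expect_false(identical(p$alpha_s1,
                         segmentation_params(seed = 99)$alpha_s1))
  expect_identical(p$prior_w, 2e-5)
  expect_identical(p$combo_w, 2e-5)
  expect_identical(p$gamma, 600)
  expect_identical(p$beta, 0.1)
  expect_error(segmentation_params(beta = 0), "positive")
})
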