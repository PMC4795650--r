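test_that("maximum level matches the pixel size", {
  expect_identical(max_level_for_image(c(1024, 1024)), 10L)
  expect_identical(max_level_for_image(c(1, 1)), 0L)
  expect_identical(max_level_for_image(c(202, 201)), 8L)
  expect_error(max_level_for_image(c(0, 4)), "positive")
})

test_that("uniform grid bookkeeping", {
  expect_equal(uniform_cell_count(c(201, 201)), 40401)
  expect_error(uniform_cell_count(c(0, 3)))
})

test_that("far-from-interface field keeps the root cell", {
  dom <- at_domain(c(64, 64), spacing = 1 / 64)
  tr <- build_tree(dom, function(p) rep(10, nrow(p)), max_level = 6, lip = 1)
  expect_identical(nrow(tr$leaves), 1L)
  expect_identical(tr$leaves[1, 1], 0L)
})

test_that("Whitney refinement puts sign-change leaves at the finest level and matches the recursive oracle", {
  dom <- at_domain(c(64, 64), spacing = 1 / 64)
  phi <- circle_sdf_fun(0.5, 0.5, 0.25)
  tr <- build_tree(dom, phi, max_level = 6, lip = 1.2, grade = FALSE)
  f <- phi(adaptivetrack:::vertex_coords(tr))
  cv <- matrix(f[tr$corner_idx], nrow(tr$leaves))
  sc <- apply(cv > 0, 1, function(r) any(r) && !all(r))
  expect_true(all(tr$leaves[sc, 1] == 6L))
  # leaf set identical to the independent recursive splitter
  oracle <- brute_force_split(dom, phi, 6, 1.2)
  k1 <- sort(adaptivetrack:::lkey(tr$leaves[, 1],
                                  tr$leaves[, -1, drop = FALSE], tr$N))
  k2 <- sort(adaptivetrack:::lkey(oracle[, 1],
                                  oracle[, -1, drop = FALSE], tr$N))
  expect_identical(k1, k2)
})

test_that("cell averages agree with direct pixel summation", {
  img <- image_frame(matrix(37, 8, 8))
  expect_equal(cell_average(img, list(level = 0, index = c(0, 0))), 37)
  img2 <- image_frame(matrix(c(0, 0, 100, 100), 2, 2))
  expect_equal(cell_average(img2, list(level = 0, index = c(0, 0))), 50)
  set.seed(7)
  data <- matrix(runif(256, 0, 255), 16, 16)
  img3 <- image_frame(data)
  for (lev in c(1, 2, 4)) {
    idx <- c(sample(0:(2^lev - 1), 1), sample(0:(2^lev - 1), 1))
    w <- 2^(4 - lev)
    direct <- mean(data[idx[1] * w + seq_len(w), idx[2] * w + seq_len(w)])
    expect_equal(cell_average(img3, list(level = lev, index = idx)), direct)
  }
  expect_error(cell_average(img3, list(level = 4, index = c(20, 0))),
               "invalid|outside")
})

test_that("grading is idempotent, forced where levels jump by two, and holds on random trees", {
  dom <- at_domain(c(8, 8))
  # manual ungraded tree: a level-1 leaf adjacent to level-3 leaves
  leaves <- rbind(
    c(1L, 1L, 0L), c(1L, 0L, 1L), c(1L, 1L, 1L),
    c(2L, 0L, 0L), c(2L, 1L, 0L), c(2L, 0L, 1L),
    c(3L, 2L, 2L), c(3L, 3L, 2L), c(3L, 2L, 3L), c(3L, 3L, 3L))
  tr0 <- adaptivetrack:::finalize_tree(dom, leaves, 3L)
  expect_false(adaptivetrack:::is_graded(tr0))
  tr1 <- enforce_grading(tr0)
  expect_true(adaptivetrack:::is_graded(tr1))
  # refinement only: every original leaf is present or subdivided
  expect_gte(nrow(tr1$leaves), nrow(tr0$leaves))
  expect_true(all(tr1$leaves[, 1] <= 3L))
  # idempotence
  tr2 <- enforce_grading(tr1)
  expect_identical(sort(tr2$lkeys), sort(tr1$lkeys))
  # random trees in 2D and 3D
  for (d in 2:3) {
    domd <- at_domain(rep(16, d))
    for (seed in 1:3) {
      tr <- random_graded_tree(domd, 4, p_split = 0.55, seed = seed)
      expect_true(adaptivetrack:::is_graded(tr))
    }
  }
})

test_that("leaves partition the domain for random refinement patterns", {
  for (d in 2:3) {
    dom <- at_domain(rep(16, d), spacing = 1 / 16)
    tr <- random_graded_tree(dom, 4, p_split = 0.6, seed = 11)
    vol <- sum((tr$leaf_w * tr$h)^d)
    expect_equal(vol, 1, tolerance = 1e-12)
  }
})

test_that("raising max_level only refines", {
  dom <- at_domain(c(64, 64), spacing = 1 / 64)
  phi <- circle_sdf_fun(0.5, 0.5, 0.25)
  t5 <- build_tree(dom, phi, max_level = 5, lip = 1.2, grade = FALSE)
  t6 <- build_tree(dom, phi, max_level = 6, lip = 1.2, grade = FALSE)
  # every leaf of the deeper tree lies inside some leaf of the shallower one
  centers_phys <- sweep((t6$leaf_pos + t6$leaf_w / 2) * t6$h, 2,
                        t6$domain$lower, `+`)
  in_t5 <- sweep(centers_phys, 2, t5$domain$lower, `-`) / t5$h
  loc <- adaptivetrack:::locate_leaf(t5, in_t5)
  expect_true(all(t5$leaves[loc, 1] <= t6$leaves[, 1]))
})

test_that("Whitney band compresses the circle to well under 10% of uniform", {
  dom <- at_domain(c(256, 256), spacing = 1 / 256)
  tr <- build_tree(dom, circle_sdf_fun(0.5, 0.5, 0.25), max_level = 8,
                   lip = 1.2)
  expect_lt(nrow(tr$leaves), 0.10 * 2^16)
  # leaf diagonal bounded by distance to the interface (contrapositive of
  # the split rule, plus the finest diagonal)
  centers <- sweep((tr$leaf_pos + tr$leaf_w / 2) * tr$h, 2,
                   dom$lower, `+`)
  phi_c <- abs(circle_sdf_fun(0.5, 0.5, 0.25)(centers))
  diag_len <- sqrt(2) * tr$leaf_w * tr$h
  finest <- sqrt(2) * tr$h
  expect_true(all(diag_len <= 2 * phi_c / 1.2 + 2 * finest + diag_len / 2))
})

test_that("vertex neighbourhoods match the exhaustive scan", {
  dom <- at_domain(c(16, 16))
  # uniform tree: all interior vertices have 2d regular neighbours at h
  tru <- build_tree(dom, function(p) rep(0, nrow(p)), max_level = 3)
  vi <- which(apply(tru$verts, 1, function(v) all(v > 0 & v < tru$N)))[1]
  nb <- vertex_neighborhood(tru, vi)
  expect_length(nb, 4)
  expect_true(all(vapply(nb, `[[`, "", "type") == "neighbor"))
  expect_true(all(vapply(nb, `[[`, 1, "distance") == 2))  # level 3 on 16px
  # random graded tree: classification equals the brute-force oracle
  tr <- random_graded_tree(dom, 4, p_split = 0.5, seed = 3)
  set.seed(5)
  for (vi in sample(nrow(tr$verts), 40)) {
    rec <- vertex_neighborhood(tr, vi)
    k <- 0
    for (axis in 1:2) for (sgn in c(1, -1)) {
      k <- k + 1
      bf <- brute_force_neighbor(tr, vi, axis, sgn)
      expect_identical(rec[[k]]$type, bf$type)
      if (bf$type == "neighbor") {
        expect_identical(rec[[k]]$index, bf$index)
        expect_equal(rec[[k]]$distance, bf$distance)
      }
      if (bf$type == "tjunction")
        expect_equal(rec[[k]]$distance, bf$distance)
    }
  }
})

test_that("a hanging node is reported with its transverse ghost data", {
  # one coarse cell right of two fine cells: the fine cells' shared corner
  # hangs on the coarse cell's left edge
  dom <- at_domain(c(4, 4))
  leaves <- rbind(c(1L, 1L, 0L), c(1L, 1L, 1L),
                  c(2L, 0L, 0L), c(2L, 1L, 0L), c(2L, 0L, 1L),
                  c(2L, 1L, 1L), c(2L, 0L, 2L), c(2L, 1L, 2L),
                  c(2L, 0L, 3L), c(2L, 1L, 3L))
  tr <- adaptivetrack:::finalize_tree(dom, leaves, 2L)
  expect_true(adaptivetrack:::is_graded(tr))
  hang <- which(tr$verts[, 1] == 2 & tr$verts[, 2] == 1)
  nb <- vertex_neighborhood(tr, hang)
  expect_identical(nb[["+x"]]$type, "tjunction")
  expect_equal(nb[["+x"]]$distance, 2)
  expect_equal(nb[["+x"]]$s3, 1)
  expect_equal(nb[["+x"]]$s4, 1)
  expect_identical(nb[["-x"]]$type, "neighbor")
  expect_identical(nb[["+y"]]$type, "neighbor")
})

test_that("tree dump and restore round-trips bit-exactly", {
  dom <- at_domain(c(64, 64), spacing = 1 / 64, lower = c(0.125, -0.25))
  tr <- build_tree(dom, circle_sdf_fun(0.6, 0.3, 0.2), max_level = 6)
  path <- tempfile(fileext = ".tree")
  write_tree(tr, path)
  tr2 <- read_tree(path)
  expect_identical(tr2$leaves, tr$leaves)
  expect_identical(tr2$max_level, tr$max_level)
  expect_identical(tr2$domain$lower, tr$domain$lower)
  expect_identical(tr2$domain$spacing, tr$domain$spacing)
  expect_identical(tr2$vkeys, tr$vkeys)
})
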