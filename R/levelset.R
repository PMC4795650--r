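# Level-set machinery on the tree: interpolation of node fields,
# semi-Lagrangian advection, reinitialization to signed distance, smoothed
# Heaviside/Dirac, and conversions between binary masks and level sets.
# Sign convention throughout: interior {phi > 0}, exterior {phi < 0}.

#' Multilinear interpolation of a node field
#'
#' Evaluates the field at arbitrary physical points by bilinear (trilinear)
#' interpolation within the leaf containing each point, using the leaf's
#' corner values. Points outside the domain are clamped to the boundary.
#'
#' @param field a [node_field()].
#' @param points `n x d` matrix of physical coordinates (or a length-`d`
#'   vector for a single point).
#' @return numeric vector of interpolated values.
#' @export
interpolate <- function(field, points) {
  tree <- field$tree
  if (is.null(dim(points))) points <- matrix(points, 1)
  pf <- sweep(points, 2, tree$domain$lower, `-`) / tree$h
  pf <- pmin(pmax(pf, 0), tree$N)
  li <- locate_leaf(tree, pf)
  loc <- (pf - tree$leaf_pos[li, , drop = FALSE]) / tree$leaf_w[li]
  bits <- corner_bits(tree$dim)
  out <- numeric(nrow(points))
  for (b in seq_len(nrow(bits))) {
    wgt <- rep(1, nrow(points))
    for (a in seq_len(tree$dim))
      wgt <- wgt * if (bits[b, a] == 1) loc[, a] else 1 - loc[, a]
    out <- out + wgt * field$values[tree$corner_idx[li, b]]
  }
  out
}

#' Semi-Lagrangian advection of a level-set field
#'
#' One unconditionally stable semi-Lagrangian step of `phi_t + u . grad phi
#' = 0`: each vertex takes the interpolated value at the backtraced point,
#' with a second-order midpoint trace of the characteristic.
#'
#' @param phi a [node_field()] (the level-set function).
#' @param velocity list of `d` node fields (velocity components) on the same
#'   tree, or a function mapping an `n x d` point matrix to an `n x d`
#'   velocity matrix.
#' @param dt time step; for accuracy keep `dt * max|u|` below about half the
#'   finest spacing.
#' @return advected `node_field`.
#' @export
advect <- function(phi, velocity, dt) {
  tree <- phi$tree
  X <- vertex_coords(tree)
  vel_at <- function(pts) {
    if (is.function(velocity)) {
      v <- velocity(pts)
    } else {
      v <- vapply(velocity, function(comp) interpolate(comp, pts),
                  numeric(nrow(pts)))
    }
    if (any(!is.finite(v))) stop("velocity must be finite")
    v
  }
  v0 <- vel_at(X)
  Xm <- X - (dt / 2) * v0
  vm <- vel_at(Xm)
  Xb <- X - dt * vm
  node_field(tree, interpolate(phi, Xb), is_sdf = FALSE)
}

#' Reinitialize a level-set field to a signed distance function
#'
#' Pseudo-time integration of `phi_tau + S(phi_init)(|grad phi| - 1) = 0`
#' with a Godunov-upwinded gradient built from minmod-limited second-order
#' one-sided differences, and the smoothed signum
#' `S = phi / sqrt(phi^2 + h^2)` frozen at the initial field, so vertices on
#' the interface do not move.
#'
#' @param phi a [node_field()].
#' @param n_iter number of pseudo-time steps (default 10; each step advances
#'   the signed-distance property by about a third of the finest spacing).
#' @return a `node_field` flagged as signed distance.
#' @export
reinitialize <- function(phi, n_iter = 10L) {
  if (n_iter < 1) stop("n_iter must be at least 1")
  tree <- phi$tree
  d <- tree$dim
  h <- finest_spacing(tree)
  f <- phi$values
  # gradient-normalized smoothed signum: robust for initially steep or flat
  # fields, keeps vertices on the interface fixed
  g0 <- pmax(grad_norm(tree, f), 1e-12)
  S <- f / sqrt(f^2 + (g0 * h)^2)
  dtau <- 0.6 * h / d
  for (it in seq_len(n_iter)) {
    g2 <- numeric(length(f))
    for (a in seq_len(d)) {
      dxx <- d_axis_second(tree, f, a)
      Dm <- d_axis_one_sided(tree, f, a, -1, order = 2L, dxx = dxx)
      Dp <- d_axis_one_sided(tree, f, a, +1, order = 2L, dxx = dxx)
      g2 <- g2 + ifelse(S > 0,
                        pmax(pmax(Dm, 0)^2, pmin(Dp, 0)^2),
                        pmax(pmin(Dm, 0)^2, pmax(Dp, 0)^2))
    }
    f <- f - dtau * S * (sqrt(g2) - 1)
  }
  node_field(tree, f, is_sdf = TRUE)
}

#' Smoothed Heaviside and Dirac functions
#'
#' Standard sine-mollified Heaviside supported on `[-eps_h, eps_h]` and its
#' derivative. `eps_h` defaults to 1.5 times the finest spacing when used on
#' tree fields.
#'
#' @param phi_value numeric values of the level-set function.
#' @param eps_h positive half-width of the mollification band.
#' @return numeric vector.
#' @export
smoothed_heaviside <- function(phi_value, eps_h) {
  if (eps_h <= 0) stop("eps_h must be positive")
  x <- phi_value / eps_h
  ifelse(x < -1, 0,
         ifelse(x > 1, 1, 0.5 * (1 + x + sin(pi * x) / pi)))
}

#' @rdname smoothed_heaviside
#' @export
smoothed_dirac <- function(phi_value, eps_h) {
  if (eps_h <= 0) stop("eps_h must be positive")
  x <- phi_value / eps_h
  ifelse(abs(x) > 1, 0, (1 + cos(pi * x)) / (2 * eps_h))
}

# ---- contour point clouds --------------------------------------------------

# zero crossings (against `level`) of a node field along the tree's leaf
# edges; returns physical coordinates (k x d)
crossing_points <- function(field, level = 0) {
  tree <- field$tree
  d <- tree$dim
  f <- field$values - level
  bits <- corner_bits(d)
  pts <- list()
  vx <- tree$verts
  for (axis in seq_len(d)) {
    lowbits <- which(bits[, axis] == 0)
    for (b in lowbits) {
      b2 <- which(apply(bits, 1, function(r) {
        all(r[-axis] == bits[b, -axis]) && r[axis] == 1
      }))
      i0 <- tree$corner_idx[, b]
      i1 <- tree$corner_idx[, b2]
      f0 <- f[i0]; f1 <- f[i1]
      cross <- (f0 > 0) != (f1 > 0)
      if (!any(cross)) next
      t0 <- f0[cross] / (f0[cross] - f1[cross])
      p <- vx[i0[cross], , drop = FALSE]
      p[, axis] <- p[, axis] + t0 * (vx[i1[cross], axis] - p[, axis])
      pts[[length(pts) + 1]] <- p
    }
  }
  if (!length(pts)) return(matrix(numeric(0), 0, d))
  p <- unique(do.call(rbind, pts))
  sweep(p * tree$h, 2, tree$domain$lower, `+`)
}

# minimum distance from each row of `pts` to the point cloud, chunked to
# bound memory
min_dist_to_cloud <- function(pts, cloud, chunk = 2000L) {
  n <- nrow(pts)
  out <- numeric(n)
  if (nrow(cloud) == 0) return(rep(Inf, n))
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    block <- pts[s:e, , drop = FALSE]
    d2 <- matrix(0, e - s + 1, nrow(cloud))
    for (a in seq_len(ncol(pts)))
      d2 <- d2 + outer(block[, a], cloud[, a], `-`)^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

# signed distance field from an indicator-like node field thresholded at
# `level`: exact distance to the interpolated contour, sign from the side
indicator_to_sdf <- function(field, level = 0.5, n_reinit = 5L,
                             max_cloud = 6000L) {
  tree <- field$tree
  cloud <- crossing_points(field, level)
  if (nrow(cloud) == 0) stop("field has no crossings at the given level")
  if (nrow(cloud) > max_cloud)
    cloud <- cloud[seq(1, nrow(cloud), length.out = max_cloud), , drop = FALSE]
  dist <- min_dist_to_cloud(vertex_coords(tree), cloud)
  sgn <- ifelse(field$values > level, 1, -1)
  out <- node_field(tree, sgn * dist, is_sdf = TRUE)
  if (n_reinit > 0) out <- reinitialize(out, n_reinit)
  out
}

#' Convert a binary mask to a signed-distance field on a tree
#'
#' Seeds the field with the exact distance to the pixel-boundary point cloud
#' of the mask (positive inside, negative outside) and then reinitializes.
#'
#' @param mask binary matrix (2D) or array (3D), nonzero = interior.
#' @param tree an `adaptive_tree` whose domain embeds the mask raster.
#' @param n_reinit reinitialization iterations applied to the seed.
#' @return a `node_field` flagged as signed distance.
#' @export
mask_to_sdf <- function(mask, tree, n_reinit = 5L) {
  if (!any(mask != 0)) stop("mask is empty")
  d <- tree$dim
  sp <- tree$domain$spacing
  cloud <- mask_boundary_points(mask, sp, tree$domain$lower)
  verts_phys <- vertex_coords(tree)
  if (nrow(cloud) > 6000)
    cloud <- cloud[seq(1, nrow(cloud), length.out = 6000), , drop = FALSE]
  dist <- min_dist_to_cloud(verts_phys, cloud)
  # sign from the nearest pixel
  pix <- sweep(verts_phys, 2, tree$domain$lower, `-`) / sp
  idx <- matrix(0L, nrow(pix), d)
  for (a in seq_len(d))
    idx[, a] <- pmin(pmax(ceiling(pix[, a]), 1L), dim(mask)[a])
  inside <- mask[idx] != 0
  if (nrow(cloud) == 0) {            # full-domain mask: no boundary at all
    dist <- rep(max(dim(mask)) * sp, nrow(pix))
  }
  out <- node_field(tree, ifelse(inside, dist, -dist), is_sdf = TRUE)
  if (n_reinit > 0 && nrow(cloud) > 0) out <- reinitialize(out, n_reinit)
  out
}

# midpoints of pixel faces separating inside from outside (physical coords)
mask_boundary_points <- function(mask, h, lower) {
  d <- length(dim(mask))
  dm <- dim(mask)
  pts <- list()
  for (a in seq_len(d)) {
    n_a <- dm[a]
    if (n_a < 2) next
    idx_lo <- lapply(seq_len(d), function(k)
      if (k == a) seq_len(n_a - 1) else seq_len(dm[k]))
    idx_hi <- lapply(seq_len(d), function(k)
      if (k == a) 2:n_a else seq_len(dm[k]))
    m_lo <- do.call(`[`, c(list(mask), idx_lo, list(drop = FALSE)))
    m_hi <- do.call(`[`, c(list(mask), idx_hi, list(drop = FALSE)))
    flip <- which((m_lo != 0) != (m_hi != 0), arr.ind = TRUE)
    if (!nrow(flip)) next
    p <- matrix(0, nrow(flip), d)
    for (k in seq_len(d))
      p[, k] <- (flip[, k] - 0.5) * h + lower[k]
    p[, a] <- p[, a] + 0.5 * h       # face between pixel i and i+1
    pts[[length(pts) + 1]] <- p
  }
  if (!length(pts)) return(matrix(numeric(0), 0, d))
  unique(do.call(rbind, pts))
}

#' Rasterize a signed-distance field to a binary mask
#'
#' Thresholds the interpolated field at zero on the pixel centres (interior
#' positive).
#'
#' @param phi a [node_field()].
#' @param pixel_counts raster size per axis (defaults to the tree domain's).
#' @return binary (0/1) matrix or array.
#' @export
sdf_to_mask <- function(phi, pixel_counts = NULL) {
  tree <- phi$tree
  if (is.null(pixel_counts)) pixel_counts <- tree$domain$pixel_counts
  d <- tree$dim
  grids <- lapply(seq_len(d), function(a)
    tree$domain$lower[a] + (seq_len(pixel_counts[a]) - 0.5) *
      tree$domain$spacing)
  pts <- as.matrix(expand.grid(grids))
  vals <- interpolate(phi, pts)
  array(as.numeric(vals > 0), dim = pixel_counts)
}
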