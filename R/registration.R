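# Dense correspondence between consecutive frames with joint sparse-error
# reconstruction. The energy couples a Charbonnier-penalized brightness
# residual |I(T(x),t) - I(x,t-1) - G|, a flow smoothness term (alpha_u), and
# sparsity/smoothness terms on the corruption field G (alpha_g1, alpha_g2).
# Minimization follows the standard coarse-to-fine fixed-point scheme: the
# smoothing terms are taken fully implicit, the data terms semi-implicit
# (lagged nonlinearity), and each linearized system is relaxed with damped
# Jacobi sweeps on the tree.

#' Robust penalizer and its derivative
#'
#' `rho(x^2) = sqrt(x^2 + eps^2)`, the convex Charbonnier penalizer;
#' `rho_prime` is its derivative with respect to the squared argument,
#' `1 / (2 sqrt(x^2 + eps^2))`, which appears as the lagged weight in the
#' Euler-Lagrange equations.
#'
#' @param x_sq squared argument (non-negative).
#' @param epsilon small positive constant (default 1e-3).
#' @export
rho <- function(x_sq, epsilon = 1e-3) {
  if (any(x_sq < 0)) stop("x_sq must be non-negative")
  sqrt(x_sq + epsilon^2)
}

#' @rdname rho
#' @export
rho_prime <- function(x_sq, epsilon = 1e-3) {
  if (any(x_sq < 0)) stop("x_sq must be non-negative")
  1 / (2 * sqrt(x_sq + epsilon^2))
}

#' Registration parameters
#'
#' Defaults follow the reference setting: `alpha_u = 8e-4` (flow
#' smoothness), `alpha_g1 = 9e-5` (sparsity of G), `alpha_g2 = 3e-3`
#' (smoothness of G), `epsilon = 1e-3`. Intensities are normalized to
#' `[0, 1]` internally, flow components are in pixels.
#'
#' @param alpha_u,alpha_g1,alpha_g2 non-negative model weights.
#' @param epsilon Charbonnier constant.
#' @param inner_iters lagged-nonlinearity (warping) iterations per pyramid
#'   level.
#' @param sweeps,sweep_tol relaxation-sweep cap and infinity-norm stopping
#'   tolerance (pixels) for each linear solve.
#' @param g_iters lagged-nonlinearity iterations of the sparse-error update
#'   performed after the flow iterations of each pyramid level.
#' @param min_coarse_px coarsest pyramid level keeps at least this many
#'   pixels per side.
#' @return a `registration_params` list.
#' @export
registration_params <- function(alpha_u = 8e-4, alpha_g1 = 9e-5,
                                alpha_g2 = 3e-3, epsilon = 1e-3,
                                inner_iters = 5L, sweeps = 200L,
                                sweep_tol = 1e-4, min_coarse_px = 32L, g_iters = 2L) {
  if (epsilon <= 0) stop("epsilon must be positive")
  if (any(c(alpha_u, alpha_g1, alpha_g2) < 0)) stop("weights must be >= 0")
  structure(list(alpha_u = alpha_u, alpha_g1 = alpha_g1, alpha_g2 = alpha_g2,
                 epsilon = epsilon, inner_iters = as.integer(inner_iters),
                 sweeps = as.integer(sweeps), sweep_tol = sweep_tol,
                 min_coarse_px = as.integer(min_coarse_px),
                 g_iters = as.integer(g_iters)),
            class = "registration_params")
}

#' Warp a node field through a flow
#'
#' Value at each vertex `x` is the field interpolated at `x + u(x)`
#' (multilinear interpolation); points carried outside the domain clamp to
#' the boundary.
#'
#' @param image_field a [node_field()].
#' @param flow list of `d` node fields (displacement components, physical
#'   units) on the same tree.
#' @return warped `node_field`.
#' @export
warp <- function(image_field, flow) {
  tree <- image_field$tree
  U <- vapply(flow, function(f) f$values, numeric(nrow(tree$verts)))
  if (any(!is.finite(U))) stop("flow must be finite")
  X <- vertex_coords(tree) + U
  node_field(tree, interpolate(image_field, X))
}

#' Brightness residual and warped-image derivatives
#'
#' `I_d = I(T(x), t) - I(x, t-1) - G` together with the spatial derivatives
#' of the warped image, evaluated with the tree's central differences.
#'
#' @param I_prev,I_curr node fields on a common tree.
#' @param flow list of displacement node fields.
#' @param G sparse-error node field (or NULL for zero).
#' @return list with `Id`, `Iw` (warped image) and `deriv` (matrix, one
#'   column per axis).
#' @export
residual <- function(I_prev, I_curr, flow, G = NULL) {
  tree <- I_prev$tree
  if (!identical(tree$lkeys, I_curr$tree$lkeys))
    stop("fields must live on the same tree")
  Iw <- warp(I_curr, flow)
  g <- if (is.null(G)) 0 else G$values
  Id <- Iw$values - I_prev$values - g
  deriv <- vapply(seq_len(tree$dim),
                  function(a) d_axis_central(tree, Iw$values, a),
                  numeric(length(Id)))
  list(Id = Id, Iw = Iw, deriv = deriv)
}

# transfer a node field onto another tree over the same domain
transfer_field <- function(field, new_tree) {
  node_field(new_tree, interpolate(field, vertex_coords(new_tree)),
             is_sdf = field$is_sdf)
}

zero_flow <- function(tree) {
  lapply(seq_len(tree$dim), function(a) node_field(tree, 0))
}

# discrete registration energy by leaf-volume quadrature at the vertices
flow_energy <- function(tree, Ip, Ic, flow, G, params, eps) {
  wq <- vertex_weights(tree)
  res <- residual(Ip, Ic, flow, G)
  gsq <- 0
  for (f in flow) gsq <- gsq + rowSums(tree_gradient(tree, f$values)^2)
  gG <- rowSums(tree_gradient(tree, G$values)^2)
  sum(wq * (rho(res$Id^2, eps) + params$alpha_u * rho(gsq, eps) +
              params$alpha_g1 * rho(G$values^2, eps) +
              params$alpha_g2 * rho(gG, eps)))
}

#' Estimate flow and sparse error between two frames
#'
#' Coarse-to-fine fixed-point minimization of the registration energy on
#' trees: pyramid levels are the input tree capped at decreasing depth; at
#' each level, lagged-nonlinearity iterations alternate a coupled linear
#' solve for the flow increment (smoothing term fully implicit, data term
#' semi-implicit) with an update of `G` from its Euler-Lagrange equation
#' (`alpha_g2` term implicit, data and `alpha_g1` terms semi-implicit). When
#' a `coupling` is supplied, its shape-registration contribution is added to
#' the flow equations.
#'
#' @param frame_prev,frame_curr [image_frame()] objects (the same raster).
#' @param tree the (finest) `adaptive_tree` carrying the solution.
#' @param params a [registration_params()].
#' @param init_flow,init_G optional initial fields on `tree`.
#' @param coupling optional list with `shape` (node field, the previous
#'   frame's signed-distance shape), `band` (node field, the smoothed
#'   interface measure `|grad H(phi)|` of the current shape estimate) and
#'   `weight` (scalar).
#' @return list with `flow` (list of node fields, pixels), `G` (node field,
#'   normalized intensity units), `energy` (trace over the finest-level
#'   iterations) and `converged`.
#' @export
solve_flow_and_G <- function(frame_prev, frame_curr, tree, params =
                               registration_params(), init_flow = NULL,
                             init_G = NULL, coupling = NULL) {
  d <- tree$dim
  eps <- params$epsilon
  mn <- min(min(frame_prev$data), min(frame_curr$data))
  mx <- max(max(frame_prev$data), max(frame_curr$data))
  sc <- max(mx - mn, 1e-12)
  fp <- frame_prev; fp$data <- (frame_prev$data - mn) / sc
  fc <- frame_curr; fc$data <- (frame_curr$data - mn) / sc

  npix <- min(tree$domain$pixel_counts)
  kmax <- max(0, floor(log2(npix / params$min_coarse_px)))
  levels <- seq(max(tree$max_level - kmax, 1L), tree$max_level)

  flow <- NULL; G <- NULL
  energy <- numeric(0)
  for (li in seq_along(levels)) {
    lv <- levels[li]
    tr <- if (lv == tree$max_level) tree else cap_tree(tree, lv)
    Ip <- image_to_nodes(tr, fp)
    Ic <- image_to_nodes(tr, fc)
    if (is.null(flow)) {
      flow <- if (is.null(init_flow)) zero_flow(tr) else
        lapply(init_flow, transfer_field, new_tree = tr)
      G <- if (is.null(init_G)) node_field(tr, 0) else
        transfer_field(init_G, tr)
    } else {
      flow <- lapply(flow, transfer_field, new_tree = tr)
      G <- transfer_field(G, tr)
    }
    cpl <- NULL
    if (!is.null(coupling)) {
      cpl <- list(shape = transfer_field(coupling$shape, tr),
                  band = transfer_field(coupling$band, tr),
                  weight = coupling$weight)
    }
    finest <- lv == tree$max_level

    for (it in seq_len(params$inner_iters)) {
      res <- residual(Ip, Ic, flow, G)
      rhoD <- rho_prime(res$Id^2, eps)
      gsq <- 0
      for (f in flow) gsq <- gsq + rowSums(tree_gradient(tr, f$values)^2)
      a_s <- rho_prime(gsq, eps)
      cc <- diffusion_coeffs(tr, a_s)
      # fold the Laplacian residual of the current flow into the rhs
      couple <- list(w = 0, deriv = matrix(0, length(res$Id), d), phiw = 0)
      if (!is.null(cpl)) {
        phiw <- warp(cpl$shape, flow)
        couple <- list(w = cpl$weight * pmax(cpl$band$values, 0),
                       deriv = vapply(seq_len(d), function(a)
                         d_axis_central(tr, phiw$values, a),
                         numeric(length(res$Id))),
                       phiw = phiw$values)
      }
      du <- solve_flow_increment_with_lag(tr, rhoD, res$deriv, res$Id, cc,
                                          params$alpha_u, couple, params,
                                          flow)
      for (a in seq_len(d))
        flow[[a]] <- node_field(tr, flow[[a]]$values + du[, a])
      if (finest)
        energy <- c(energy, flow_energy(tr, Ip, Ic, flow, G, params, eps))
    }

    for (git in seq_len(params$g_iters)) {
      # ---- G update: once the flow has settled at this level -------------
      resG <- residual(Ip, Ic, flow, NULL)
      Id_noG <- resG$Id
      rhoD2 <- rho_prime((Id_noG - G$values)^2, eps)
      rhoG1 <- rho_prime(G$values^2, eps)
      aG <- rho_prime(rowSums(tree_gradient(tr, G$values)^2), eps)
      cg <- diffusion_coeffs(tr, aG) * params$alpha_g2
      g <- G$values
      st <- tree_stencil(tr)
      cgs <- rowSums(cg)
      denom <- rhoD2 + params$alpha_g1 * rhoG1 + cgs + 1e-12
      for (sweep in seq_len(params$sweeps)) {
        acc <- rhoD2 * Id_noG
        for (dir in seq_len(2 * d))
          acc <- acc + cg[, dir] * as.numeric(st$mats[[dir]] %*% g)
        gnew <- acc / denom
        delta <- max(abs(gnew - g))
        g <- gnew
        if (delta < params$sweep_tol) break
      }
      G <- node_field(tr, g)
    }
    if (finest)
      energy <- c(energy, flow_energy(tr, Ip, Ic, flow, G, params, eps))
  }
  list(flow = flow, G = G, energy = energy,
       converged = length(energy) < 2 ||
         energy[length(energy)] <= energy[1] + 1e-8)
}

# wrapper adding the alpha_u * L(u^k) residual to the rhs before relaxing
solve_flow_increment_with_lag <- function(tree, rhoD, deriv, Id0, cc,
                                          alpha_u, couple, params, flow) {
  st <- tree_stencil(tree)
  d <- tree$dim
  n <- st$n
  lap <- matrix(0, n, d)
  for (a in seq_len(d)) {
    u <- flow[[a]]$values
    acc <- numeric(n)
    for (dir in seq_len(2 * d))
      acc <- acc + cc[, dir] * (as.numeric(st$mats[[dir]] %*% u) - u)
    lap[, a] <- acc
  }
  csum <- rowSums(cc)
  A <- array(0, c(n, d, d))
  b <- matrix(0, n, d)
  for (i in seq_len(d)) {
    for (j in seq_len(d))
      A[, i, j] <- rhoD * deriv[, i] * deriv[, j] +
        couple$w * couple$deriv[, i] * couple$deriv[, j]
    A[, i, i] <- A[, i, i] + alpha_u * csum + 1e-12
    b[, i] <- -(rhoD * Id0 * deriv[, i] +
                  couple$w * couple$phiw * couple$deriv[, i]) +
      alpha_u * lap[, i]
  }
  du <- matrix(0, n, d)
  for (sweep in seq_len(params$sweeps)) {
    rhs <- b
    for (dir in seq_len(2 * d)) {
      nbm <- st$mats[[dir]] %*% du
      rhs <- rhs + alpha_u * cc[, dir] * as.matrix(nbm)
    }
    if (d == 2L) {
      det <- A[, 1, 1] * A[, 2, 2] - A[, 1, 2]^2
      du_new <- cbind((A[, 2, 2] * rhs[, 1] - A[, 1, 2] * rhs[, 2]) / det,
                      (A[, 1, 1] * rhs[, 2] - A[, 1, 2] * rhs[, 1]) / det)
    } else {
      a11 <- A[, 1, 1]; a12 <- A[, 1, 2]; a13 <- A[, 1, 3]
      a22 <- A[, 2, 2]; a23 <- A[, 2, 3]; a33 <- A[, 3, 3]
      det <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
        a13 * (a12 * a23 - a22 * a13)
      i11 <- (a22 * a33 - a23^2) / det
      i12 <- (a13 * a23 - a12 * a33) / det
      i13 <- (a12 * a23 - a13 * a22) / det
      i22 <- (a11 * a33 - a13^2) / det
      i23 <- (a13 * a12 - a11 * a23) / det
      i33 <- (a11 * a22 - a12^2) / det
      du_new <- cbind(i11 * rhs[, 1] + i12 * rhs[, 2] + i13 * rhs[, 3],
                      i12 * rhs[, 1] + i22 * rhs[, 2] + i23 * rhs[, 3],
                      i13 * rhs[, 1] + i23 * rhs[, 2] + i33 * rhs[, 3])
    }
    delta <- max(abs(du_new - du))
    du <- du_new
    if (delta < params$sweep_tol) break
  }
  du
}
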