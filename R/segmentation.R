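# Convex-relaxed segmentation on the tree. The relaxed indicator phi0 in
# [0, 1] minimizes a weighted total-variation term (weight = edge function
# g + dynamic shape prior dp^2 + combination term dc^2) plus the region
# log-likelihood term alpha_s1 * eta * phi0. The box constraint is replaced
# by the exact penalty alpha_hat * zeta(phi0) and the problem is split with
# a quadratic coupling 1/(2 beta) ||phi0 - aux||^2: the aux update is a
# pointwise closed form, the phi0 update is a weighted ROF proximal step
# solved by projected dual iterations with the tree's exact
# gradient/divergence adjoint pair.

#' Foreground/background intensity model
#'
#' Gray-level histograms of the foreground (theta1) and background (theta2),
#' built from one or more frames and matching masks, smoothed with a
#' pseudocount and normalized.
#'
#' @param frames an [image_frame()] or list of them.
#' @param masks matching binary mask(s), nonzero = foreground.
#' @param nbins number of gray-level bins (default 256).
#' @param pseudocount smoothing count added to every bin.
#' @return an `intensity_model` with `p_fg`, `p_bg`, `breaks`.
#' @export
intensity_model <- function(frames, masks, nbins = 256L, pseudocount = 1e-6) {
  if (inherits(frames, "image_frame")) frames <- list(frames)
  if (!is.list(masks)) masks <- list(masks)
  fg <- unlist(lapply(seq_along(frames), function(i)
    frames[[i]]$data[masks[[i]] != 0]))
  bg <- unlist(lapply(seq_along(frames), function(i)
    frames[[i]]$data[masks[[i]] == 0]))
  if (!length(fg) || !length(bg))
    stop("need both foreground and background pixels")
  rng <- range(c(fg, bg))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  cnt <- function(x) {
    b <- findInterval(x, breaks, rightmost.closed = TRUE)
    b <- pmin(pmax(b, 1L), nbins)
    tabulate(b, nbins)
  }
  norm <- function(n) {
    p <- n + pseudocount
    p / sum(p)
  }
  structure(list(p_fg = norm(cnt(fg)), p_bg = norm(cnt(bg)),
                 breaks = breaks, nbins = as.integer(nbins)),
            class = "intensity_model")
}

#' Region log-likelihood ratio
#'
#' `eta(x) = ln p(I | theta2) - ln p(I | theta1)` per vertex: negative where
#' the foreground model is more likely. Intensities outside the histogram
#' range clamp to the end bins.
#'
#' @param image_field node field of intensities.
#' @param model an [intensity_model()].
#' @return a `node_field`.
#' @export
eta <- function(image_field, model) {
  b <- findInterval(image_field$values, model$breaks, rightmost.closed = TRUE)
  b <- pmin(pmax(b, 1L), model$nbins)
  node_field(image_field$tree, log(model$p_bg[b]) - log(model$p_fg[b]))
}

#' @rdname eta
#' @details `eta_on_tree` evaluates the log-ratio per pixel and averages it
#'   onto the tree nodes. At contour vertices, whose node-sampled intensity
#'   mixes foreground and background pixels, this is the unbiased
#'   discretization of the region integral; [eta()] applied to node-sampled
#'   intensities would classify such mixed values by whichever histogram
#'   covers them.
#' @param frame an [image_frame()].
#' @param tree tree on which to sample the result.
#' @export
eta_on_tree <- function(frame, model, tree) {
  b <- findInterval(frame$data, model$breaks, rightmost.closed = TRUE)
  b <- pmin(pmax(b, 1L), model$nbins)
  emap <- array(log(model$p_bg[b]) - log(model$p_fg[b]), dim(frame$data))
  image_to_nodes(tree, image_frame(emap, spacing = frame$spacing,
                                   lower = frame$lower))
}

#' Exact box-constraint penalty
#'
#' `zeta(y) = -2y` for `y < 0`, `2(y - 1)` for `y > 1`, 0 otherwise; with a
#' penalty weight above `alpha_s1/2 * max|eta|` its minimizers satisfy the
#' `[0, 1]` constraint exactly.
#'
#' @param y numeric.
#' @export
zeta <- function(y) ifelse(y < 0, -2 * y, ifelse(y > 1, 2 * (y - 1), 0))

# separable Gaussian blur with edge clamping, 2D or 3D
gaussian_blur <- function(data, sigma) {
  if (sigma <= 0) return(data)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- length(dim(data))
  out <- data
  for (a in seq_len(d)) {
    acc <- array(0, dim(out))
    n_a <- dim(out)[a]
    for (off in -r:r) {
      idx <- pmin(pmax(seq_len(n_a) + off, 1L), n_a)
      sl <- lapply(seq_len(d), function(x) if (x == a) idx else
        seq_len(dim(out)[x]))
      acc <- acc + k[off + r + 1] * do.call(`[`, c(list(out), sl))
    }
    out <- acc
  }
  out
}

#' Edge-stopping function
#'
#' `g = 1 / (1 + gamma |grad I_sigma|^2)` with `I_sigma` the
#' Gaussian-smoothed image, intensities normalized to `[0, 1]`, gradients in
#' 1/pixel. Values in `(0, 1]`, small across strong edges.
#'
#' @param frame an [image_frame()].
#' @param tree tree on which to sample the result.
#' @param gamma edge sensitivity (default 600).
#' @param sigma Gaussian smoothing width in pixels (default 2, which
#'   suppresses the gradient response of pixel-scale texture noise while
#'   leaving step edges orders of magnitude below g = 1).
#' @return a `node_field`.
#' @export
edge_function <- function(frame, tree, gamma = 600, sigma = 2) {
  if (gamma < 0 || sigma < 0) stop("gamma and sigma must be non-negative")
  rng <- range(frame$data)
  sc <- max(diff(rng), 1e-12)
  sm <- gaussian_blur((frame$data - rng[1]) / sc, sigma)
  d <- length(dim(sm))
  g2 <- array(0, dim(sm))
  for (a in seq_len(d)) {
    n_a <- dim(sm)[a]
    ip <- pmin(seq_len(n_a) + 1L, n_a)
    im <- pmax(seq_len(n_a) - 1L, 1L)
    slp <- lapply(seq_len(d), function(x) if (x == a) ip else
      seq_len(dim(sm)[x]))
    slm <- lapply(seq_len(d), function(x) if (x == a) im else
      seq_len(dim(sm)[x]))
    gr <- (do.call(`[`, c(list(sm), slp)) -
             do.call(`[`, c(list(sm), slm))) / 2
    g2 <- g2 + gr^2
  }
  gmap <- 1 / (1 + gamma * g2)
  gframe <- image_frame(gmap, spacing = frame$spacing, lower = frame$lower)
  image_to_nodes(tree, gframe)
}

#' Dynamic shape-prior and combination weights
#'
#' Pointwise squared magnitude of a shape field (the robust estimator is the
#' identity on the squared argument): `dp^2 = |shape|^2`. The weight
#' vanishes exactly on the shape's zero level set and grows quadratically
#' with distance for a signed-distance prior. `combo_weight` first warps the
#' previous frame's shape through the current flow.
#'
#' @param prior_shape a [node_field()] (signed-distance shape prior).
#' @return a `node_field` of non-negative weights.
#' @export
prior_weight <- function(prior_shape) {
  node_field(prior_shape$tree, prior_shape$values^2)
}

#' @rdname prior_weight
#' @param warped_prev_shape previous frame's shape already warped through
#'   the flow, or the raw shape if `flow` is given.
#' @param flow optional flow (list of node fields); when supplied the shape
#'   is warped through it first.
#' @export
combo_weight <- function(warped_prev_shape, flow = NULL) {
  s <- if (is.null(flow)) warped_prev_shape else warp(warped_prev_shape, flow)
  node_field(s$tree, s$values^2)
}

#' Segmentation parameters
#'
#' `alpha_s1` is drawn once per configuration from `alpha_s1_range`
#' (default `[0.02, 0.05]`) with a fixed seed for reproducibility;
#' `alpha_hat` defaults to just above its admissibility bound
#' `alpha_s1/2 * max|eta|`; `beta` is the splitting constant; `prior_w` and
#' `combo_w` scale dp^2 and dc^2 in the TV weight; `gamma` and `sigma`
#' parameterize the edge function.
#'
#' @param alpha_s1 region-term weight; `NULL` draws from `alpha_s1_range`.
#' @param alpha_s1_range,seed range and seed for the draw.
#' @param alpha_hat penalty weight (`NULL`: set from the bound at solve
#'   time).
#' @param beta quadratic-splitting constant.
#' @param prior_w,combo_w weights on the shape prior and combination terms.
#' @param gamma,sigma edge-function parameters.
#' @param dual_iters projected dual iterations per proximal step.
#' @param dual_step dual step size (`NULL`: `0.95 / ||grad||^2` with the
#'   tree gradient's operator norm estimated by power iteration).
#' @param outer_iters alternating-minimization iterations.
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(alpha_s1 = NULL, alpha_s1_range = c(0.02, 0.05),
                                seed = 0L, alpha_hat = NULL, beta = 0.1,
                                prior_w = 2e-5, combo_w = 2e-5, gamma = 600,
                                sigma = 2, dual_iters = 30L, dual_step = NULL,
                                outer_iters = 15L) {
  if (is.null(alpha_s1)) {
    oldseed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed,
                                          envir = globalenv()))
    set.seed(seed)
    alpha_s1 <- stats::runif(1, alpha_s1_range[1], alpha_s1_range[2])
  }
  if (beta <= 0) stop("beta must be positive")
  structure(list(alpha_s1 = alpha_s1, alpha_hat = alpha_hat, beta = beta,
                 prior_w = prior_w, combo_w = combo_w, gamma = gamma,
                 sigma = sigma, dual_iters = as.integer(dual_iters),
                 dual_step = dual_step, outer_iters = as.integer(outer_iters)),
            class = "segmentation_params")
}

# solver's discrete energy: forward-difference weighted TV + splitting +
# pointwise terms (unweighted vertex sum, matching the dual inner product)
seg_energy <- function(tree, w, phi0, aux, eta_v, alpha_s1, alpha_hat, beta) {
  ops <- tv_operators(tree)
  gn2 <- 0
  for (a in seq_len(tree$dim))
    gn2 <- gn2 + as.numeric(ops$G[[a]] %*% phi0)^2
  sum(w * sqrt(gn2)) + sum((phi0 - aux)^2) / (2 * beta) +
    sum(alpha_s1 * eta_v * aux + alpha_hat * zeta(aux))
}

#' Solve the convex-relaxed weighted-TV segmentation
#'
#' Alternating minimization of the split energy: (a) a weighted-TV proximal
#' step for the relaxed indicator with the `1/(2 beta)` coupling, solved by
#' projected dual iterations on the tree (the dual variable is constrained
#' pointwise by the weight); (b) the closed-form pointwise update
#' `aux = clip(phi0 - beta alpha_s1 eta, 0, 1)`, the exact minimizer of the
#' pointwise terms once the penalty weight exceeds its admissibility bound.
#' The returned indicator lies in `[0, 1]` after every outer iteration.
#'
#' @param eta_field region log-likelihood ratio ([eta()]).
#' @param total_weight non-negative TV weight field (edge function plus
#'   shape-prior and combination weights).
#' @param params a [segmentation_params()].
#' @param init optional initial indicator (node field or numeric).
#' @param n_outer override for the number of outer iterations.
#' @return list with `phi0` (node field), `aux` (node field), `energy`
#'   (trace over outer iterations).
#' @export
solve_segmentation <- function(eta_field, total_weight, params =
                                 segmentation_params(), init = NULL,
                               n_outer = NULL) {
  tree <- eta_field$tree
  d <- tree$dim
  w <- total_weight$values
  if (any(w < 0)) stop("TV weight must be non-negative")
  eta_v <- eta_field$values
  alpha_s1 <- params$alpha_s1
  bound <- alpha_s1 / 2 * max(abs(eta_v))
  alpha_hat <- if (is.null(params$alpha_hat)) 1.05 * bound + 1e-12 else
    params$alpha_hat
  if (alpha_hat <= bound)
    stop("alpha_hat must exceed alpha_s1/2 * max|eta| (configuration error)")
  beta <- params$beta
  if (is.null(n_outer)) n_outer <- params$outer_iters
  ops <- tv_operators(tree)
  tau <- if (is.null(params$dual_step)) 0.95 / ops$grad_norm2 else
    params$dual_step

  n <- length(eta_v)
  phi0 <- if (is.null(init)) rep(0.5, n) else
    if (inherits(init, "node_field")) init$values else rep(init, length.out = n)
  phi0 <- pmin(pmax(phi0, 0), 1)
  p <- matrix(0, n, d)
  energy <- numeric(n_outer)
  divp <- numeric(n)
  for (outer in seq_len(n_outer)) {
    aux <- pmin(pmax(phi0 - beta * alpha_s1 * eta_v, 0), 1)
    for (k in seq_len(params$dual_iters)) {
      divp <- numeric(n)
      for (a in seq_len(d))
        divp <- divp - as.numeric(ops$Gt[[a]] %*% p[, a])
      q <- divp - aux / beta
      nrm2 <- numeric(n)
      for (a in seq_len(d)) {
        p[, a] <- p[, a] + tau * as.numeric(ops$G[[a]] %*% q)
        nrm2 <- nrm2 + p[, a]^2
      }
      nrm <- sqrt(nrm2)
      over <- nrm > w
      scl <- ifelse(over, w / pmax(nrm, 1e-300), 1)
      for (a in seq_len(d)) p[, a] <- p[, a] * scl
    }
    divp <- numeric(n)
    for (a in seq_len(d))
      divp <- divp - as.numeric(ops$Gt[[a]] %*% p[, a])
    phi0 <- pmin(pmax(aux - beta * divp, 0), 1)
    energy[outer] <- seg_energy(tree, w, phi0, aux, eta_v, alpha_s1,
                                alpha_hat, beta)
  }
  list(phi0 = node_field(tree, phi0),
       aux = node_field(tree, aux),
       energy = energy, alpha_hat = alpha_hat)
}
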