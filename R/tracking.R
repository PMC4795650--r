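# Per-frame orchestration: rebuild the tree around the incoming shape,
# estimate flow and sparse error with the shape-registration coupling, solve
# the weighted-TV segmentation with the dynamic prior and combination
# weights, threshold, and reinitialize to a signed distance for the next
# frame. Flow, indicator and sparse error are updated twice per frame.

#' Tracking state
#'
#' Per-frame bundle: the adaptive tree, the signed-distance shape, the
#' relaxed indicator, the flow, the sparse error, the frame itself and the
#' foreground/background intensity model. All fields share one tree.
#'
#' @param frame_index integer.
#' @param frame the [image_frame()] this state describes.
#' @param tree the frame's `adaptive_tree`.
#' @param shape signed-distance [node_field()].
#' @param indicator relaxed indicator [node_field()] in `[0, 1]`.
#' @param flow list of displacement node fields (possibly NULL before the
#'   first update).
#' @param sparse_error node field `G` (possibly NULL).
#' @param model an [intensity_model()].
#' @param diagnostics named list (leaf count, energies, ...).
#' @return a `tracking_state`.
#' @export
tracking_state <- function(frame_index, frame, tree, shape, indicator,
                           flow = NULL, sparse_error = NULL, model = NULL,
                           diagnostics = list()) {
  stopifnot(inherits(tree, "adaptive_tree"), inherits(shape, "node_field"))
  structure(list(frame_index = frame_index, frame = frame, tree = tree,
                 shape = shape, indicator = indicator, flow = flow,
                 sparse_error = sparse_error, model = model,
                 diagnostics = diagnostics),
            class = "tracking_state")
}

#' @exportS3Method base::print
print.tracking_state <- function(x, ...) {
  cat(sprintf("<tracking_state frame %d: %d leaves>\n", x$frame_index,
              nrow(x$tree$leaves)))
  invisible(x)
}

# build a tree refined around an existing shape field (clamped interpolation
# supplies phi outside the old tree's hull)
tree_from_shape <- function(domain, shape, config) {
  build_tree(domain, function(p) interpolate(shape, p),
             max_level = config$tree$max_level, lip = config$tree$lip,
             grade = config$tree$grade)
}

#' Initialize tracking from the first frame and its mask
#'
#' Builds the tree around the mask boundary, converts the mask to a signed
#' distance, and extracts the intensity model from this frame.
#'
#' @param frame first [image_frame()].
#' @param mask binary mask of the tracked object in that frame.
#' @param config a [run_config()].
#' @return a `tracking_state`.
#' @export
init_tracking_state <- function(frame, mask, config = run_config()) {
  if (!any(mask != 0)) stop("initial mask is empty")
  domain <- frame_domain(frame)
  cloud <- mask_boundary_points(mask, frame$spacing, frame$lower)
  dmi <- dim(mask)
  phi_seed <- function(pts) {
    dist <- min_dist_to_cloud(pts, cloud)
    pf <- sweep(pts, 2, frame$lower, `-`) / frame$spacing
    idx <- matrix(0L, nrow(pf), length(dmi))
    for (a in seq_along(dmi))
      idx[, a] <- pmin(pmax(ceiling(pf[, a]), 1L), dmi[a])
    ifelse(mask[idx] != 0, dist, -dist)
  }
  tree <- build_tree(domain, phi_seed, max_level = config$tree$max_level,
                     lip = config$tree$lip, grade = config$tree$grade)
  shape <- mask_to_sdf(mask, tree, n_reinit = config$pipeline$reinit_iters)
  eps <- config$pipeline$heaviside_band * finest_spacing(tree)
  ind <- node_field(tree, smoothed_heaviside(shape$values, eps))
  model <- intensity_model(frame, mask)
  tracking_state(1L, frame, tree, shape, ind, model = model,
                 diagnostics = list(leaf_count = nrow(tree$leaves)))
}

#' Track one frame
#'
#' Given the previous frame's state and the new frame: (1) rebuild the tree
#' from the previous shape (Whitney refinement plus 2:1 grading) and sample
#' both frames on it; (2) twice: estimate flow and sparse error with the
#' shape-registration coupling built from the current shape estimate, then
#' assemble the TV weight (edge function + dynamic prior dp^2 + combination
#' dc^2), solve the relaxed segmentation, threshold at 1/2 and rebuild the
#' signed distance.
#'
#' @param state_prev previous `tracking_state`.
#' @param frame new [image_frame()].
#' @param config a [run_config()].
#' @return the new `tracking_state`.
#' @export
track_frame <- function(state_prev, frame, config = run_config()) {
  if (!identical(dim(frame$data), dim(state_prev$frame$data)))
    stop("frame does not match the tracked sequence raster")
  domain <- frame_domain(frame)
  sp <- config$segmentation
  tree <- tree_from_shape(domain, state_prev$shape, config)
  eps <- config$pipeline$heaviside_band * finest_spacing(tree)

  shape_prev <- transfer_field(state_prev$shape, tree)
  shape_cur <- shape_prev
  ind <- node_field(tree, smoothed_heaviside(shape_cur$values, eps))
  flow <- NULL; G <- NULL
  reg_energy <- seg_energy_last <- NA_real_
  ev <- eta_on_tree(frame, state_prev$model, tree)
  g <- edge_function(frame, tree, gamma = sp$gamma, sigma = sp$sigma)

  for (rep in seq_len(config$pipeline$updates_per_frame)) {
    band <- node_field(tree, smoothed_dirac(shape_cur$values, eps) *
                         grad_norm(tree, shape_cur$values))
    reg <- solve_flow_and_G(state_prev$frame, frame, tree,
                            config$registration, init_flow = flow,
                            init_G = G,
                            coupling = list(shape = shape_prev, band = band,
                                            weight = sp$combo_w))
    flow <- reg$flow; G <- reg$G
    reg_energy <- utils::tail(reg$energy, 1)

    phi_w <- warp(shape_prev, flow)
    prior_shape <- if (identical(config$pipeline$prior_variant, "unwarped"))
      shape_prev else phi_w
    wtot <- node_field(tree, g$values +
                         sp$prior_w * prior_weight(prior_shape)$values +
                         sp$combo_w * combo_weight(phi_w)$values)
    seg <- solve_segmentation(ev, wtot, sp, init = ind)
    ind <- seg$phi0
    seg_energy_last <- utils::tail(seg$energy, 1)
    if (all(ind$values <= 0.5))
      stop(sprintf("empty segmentation at frame %d (all background)",
                   state_prev$frame_index + 1L))
    shape_cur <- indicator_to_sdf(ind, 0.5,
                                  n_reinit = config$pipeline$reinit_iters)
  }
  tracking_state(state_prev$frame_index + 1L, frame, tree, shape_cur, ind,
                 flow = flow, sparse_error = G, model = state_prev$model,
                 diagnostics = list(leaf_count = nrow(tree$leaves),
                                    registration_energy = reg_energy,
                                    segmentation_energy = seg_energy_last))
}

#' Track a whole sequence
#'
#' Folds [track_frame()] over the frames, starting from a known initial
#' mask, and collects per-frame masks, 2D contours and diagnostics.
#'
#' @param frames list of [image_frame()] (at least 2).
#' @param initial_mask binary mask for the first frame.
#' @param config a [run_config()].
#' @param truth optional list of ground-truth masks for Dice diagnostics.
#' @return list with `masks`, `contours` (2D only), `diagnostics`
#'   (data.frame: frame, leaf_count, registration and segmentation energy,
#'   dice) and `final_state`.
#' @export
track_sequence <- function(frames, initial_mask, config = run_config(),
                           truth = NULL) {
  if (length(frames) < 2) stop("need at least two frames")
  state <- init_tracking_state(frames[[1]], initial_mask, config)
  n <- length(frames)
  masks <- vector("list", n)
  contours <- vector("list", n)
  masks[[1]] <- array(as.numeric(initial_mask != 0), dim(initial_mask))
  contours[[1]] <- if (state$tree$dim == 2L)
    contour_polylines(state$shape, 0) else NULL
  diag_rows <- vector("list", n)
  diag_rows[[1]] <- data.frame(frame = 1L,
                               leaf_count = nrow(state$tree$leaves),
                               registration_energy = NA_real_,
                               segmentation_energy = NA_real_,
                               dice = if (is.null(truth)) NA_real_ else
                                 dice_coefficient(masks[[1]], truth[[1]]))
  for (t in 2:n) {
    state <- tryCatch(track_frame(state, frames[[t]], config),
                      error = function(e)
                        stop(sprintf("frame %d: %s", t, conditionMessage(e))))
    masks[[t]] <- sdf_to_mask(state$shape)
    contours[[t]] <- if (state$tree$dim == 2L)
      contour_polylines(state$shape, 0) else NULL
    diag_rows[[t]] <- data.frame(frame = t,
                                 leaf_count = state$diagnostics$leaf_count,
                                 registration_energy =
                                   state$diagnostics$registration_energy,
                                 segmentation_energy =
                                   state$diagnostics$segmentation_energy,
                                 dice = if (is.null(truth)) NA_real_ else
                                   dice_coefficient(masks[[t]], truth[[t]]))
  }
  list(masks = masks, contours = contours,
       diagnostics = do.call(rbind, diag_rows), final_state = state)
}

# single-slice 2D segmentation refinement used by the 3D initialization
refine_slice_mask <- function(slice_frame, seed_mask, model, config) {
  if (!any(seed_mask != 0)) return(NULL)
  domain <- frame_domain(slice_frame)
  cfg2 <- config
  tree <- tryCatch({
    st0 <- init_tracking_state(slice_frame, seed_mask, cfg2)
    st0
  }, error = function(e) NULL)
  if (is.null(tree)) return(NULL)
  st0 <- tree
  ev <- eta_on_tree(slice_frame, model, st0$tree)
  sp <- config$segmentation
  g <- edge_function(slice_frame, st0$tree, gamma = sp$gamma,
                     sigma = sp$sigma)
  wtot <- node_field(st0$tree, g$values +
                       sp$prior_w * prior_weight(st0$shape)$values)
  seg <- solve_segmentation(ev, wtot, sp, init = st0$indicator)
  if (all(seg$phi0$values <= 0.5)) return(NULL)
  sdf_to_mask(indicator_to_sdf(seg$phi0, 0.5,
                               n_reinit = config$pipeline$reinit_iters))
}

#' Initialize a 3D segmentation from a single 2D cross-section
#'
#' Runs the 2D segmentation on the chosen slice (seeded by its mask), then
#' either extrudes the refined mask along the third axis (`"extrude"` mode)
#' or propagates it slice by slice outward, each slice seeded by its
#' neighbour's result (`"propagate"` mode, the default), and finally
#' reinitializes in 3D.
#'
#' @param volume_frame a 3D [image_frame()].
#' @param slice_index index of the seeding z-slice.
#' @param initial_mask_2d binary mask of the object in that slice.
#' @param config a [run_config()]; `config$pipeline$init3d_mode` selects the
#'   mode.
#' @return a 3D `tracking_state`.
#' @export
init_3d_from_2d <- function(volume_frame, slice_index, initial_mask_2d,
                            config = run_config()) {
  dm <- dim(volume_frame$data)
  if (length(dm) != 3) stop("volume_frame must be 3D")
  if (!any(initial_mask_2d != 0))
    stop("empty segmentation on the seeding slice")
  nz <- dm[3]
  slice_frame <- function(z) image_frame(volume_frame$data[, , z],
                                         spacing = volume_frame$spacing)
  model <- intensity_model(slice_frame(slice_index), initial_mask_2d)
  m0 <- refine_slice_mask(slice_frame(slice_index), initial_mask_2d, model,
                          config)
  if (is.null(m0)) stop("empty segmentation on the seeding slice")
  vol_mask <- array(0, dm)
  if (identical(config$pipeline$init3d_mode, "extrude")) {
    for (z in seq_len(nz)) vol_mask[, , z] <- m0
  } else {
    vol_mask[, , slice_index] <- m0
    for (dir in c(1L, -1L)) {
      prev <- m0
      z <- slice_index + dir
      while (z >= 1 && z <= nz) {
        mz <- refine_slice_mask(slice_frame(z), prev, model, config)
        if (is.null(mz)) break
        vol_mask[, , z] <- mz
        prev <- mz
        z <- z + dir
      }
    }
  }
  domain <- frame_domain(volume_frame)
  cl <- mask_boundary_points(vol_mask, volume_frame$spacing,
                             volume_frame$lower)
  if (nrow(cl) > 4000)
    cl <- cl[seq(1, nrow(cl), length.out = 4000), , drop = FALSE]
  cloud_fun <- function(pts) {
    dist <- min_dist_to_cloud(pts, cl)
    pf <- sweep(pts, 2, volume_frame$lower, `-`) / volume_frame$spacing
    idx <- matrix(0L, nrow(pf), 3)
    for (a in 1:3) idx[, a] <- pmin(pmax(ceiling(pf[, a]), 1L), dm[a])
    ifelse(vol_mask[idx] != 0, dist, -dist)
  }
  tree <- build_tree(domain, cloud_fun, max_level = config$tree$max_level,
                     lip = config$tree$lip, grade = config$tree$grade)
  shape <- mask_to_sdf(vol_mask, tree,
                       n_reinit = config$pipeline$reinit_iters)
  eps <- config$pipeline$heaviside_band * finest_spacing(tree)
  ind <- node_field(tree, smoothed_heaviside(shape$values, eps))
  tracking_state(1L, volume_frame, tree, shape, ind, model = model,
                 diagnostics = list(leaf_count = nrow(tree$leaves)))
}
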