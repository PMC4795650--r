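#' Image domain description
#'
#' A domain couples a physical box with a pixel (voxel) raster. The tree
#' machinery embeds the raster in the smallest dyadic square/cube, so the
#' physical box spans `pixel_counts * spacing` per axis starting at `lower`;
#' by default one pixel is one length unit, which keeps flow components and
#' distances in pixel units.
#'
#' @param pixel_counts integer vector of length 2 or 3, pixels per axis.
#' @param lower physical coordinates of the lower corner.
#' @param spacing physical edge length of one pixel (isotropic).
#' @return An object of class `at_domain` with fields `dim`, `pixel_counts`,
#'   `lower`, `upper`, `spacing`.
#' @export
at_domain <- function(pixel_counts, lower = rep(0, length(pixel_counts)),
                      spacing = 1) {
  pixel_counts <- as.integer(pixel_counts)
  d <- length(pixel_counts)
  if (!d %in% c(2L, 3L)) stop("domain must be 2- or 3-dimensional")
  if (any(pixel_counts < 1L)) stop("pixel counts must be positive")
  if (length(spacing) != 1L || !is.finite(spacing) || spacing <= 0)
    stop("spacing must be a positive scalar")
  if (length(lower) != d) stop("lower corner must have one entry per axis")
  structure(list(dim = d, pixel_counts = pixel_counts,
                 lower = as.numeric(lower),
                 upper = as.numeric(lower) + pixel_counts * spacing,
                 spacing = spacing),
            class = "at_domain")
}

#' @exportS3Method base::print
print.at_domain <- function(x, ...) {
  cat(sprintf("<at_domain %dD: %s pixels, spacing %g>\n", x$dim,
              paste(x$pixel_counts, collapse = "x"), x$spacing))
  invisible(x)
}

#' Single-channel image frame
#'
#' @param data numeric matrix (2D, `nx` by `ny`) or array (3D). Element
#'   `[i, j]` is the pixel centred at `lower + (i - 1/2, j - 1/2) * spacing`.
#' @param spacing physical pixel size.
#' @param lower physical lower corner.
#' @return An `image_frame` object.
#' @export
image_frame <- function(data, spacing = 1, lower = NULL) {
  if (is.matrix(data)) d <- 2L
  else if (is.array(data) && length(dim(data)) == 3L) d <- 3L
  else stop("frame data must be a matrix or a 3D array")
  if (!all(is.finite(data))) stop("frame contains non-finite values")
  if (is.null(lower)) lower <- rep(0, d)
  structure(list(data = data, dim = d, pixel_counts = dim(data),
                 spacing = spacing, lower = as.numeric(lower)),
            class = "image_frame")
}

#' @exportS3Method base::print
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame %s, range [%g, %g]>\n",
              paste(dim(x$data), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

frame_domain <- function(frame) {
  at_domain(dim(frame$data), lower = frame$lower, spacing = frame$spacing)
}

#' Scalar field sampled at the tree vertices
#'
#' One value per tree vertex, in the order of `tree$verts`.
#'
#' @param tree an `adaptive_tree`.
#' @param values numeric vector, one finite value per vertex.
#' @param is_sdf flag marking the field as a signed distance function
#'   (positive inside the tracked region, negative outside).
#' @return A `node_field` object.
#' @export
node_field <- function(tree, values, is_sdf = FALSE) {
  values <- as.numeric(values)
  if (length(values) == 1L) values <- rep(values, nrow(tree$verts))
  if (length(values) != nrow(tree$verts))
    stop("need exactly one value per tree vertex")
  if (!all(is.finite(values))) stop("node field values must be finite")
  structure(list(tree = tree, values = values, is_sdf = isTRUE(is_sdf)),
            class = "node_field")
}

#' @exportS3Method base::print
print.node_field <- function(x, ...) {
  cat(sprintf("<node_field on %d vertices, range [%.4g, %.4g]%s>\n",
              length(x$values), min(x$values), max(x$values),
              if (x$is_sdf) ", signed distance" else ""))
  invisible(x)
}

# physical coordinates of the tree vertices (n x d)
vertex_coords <- function(tree) {
  sweep(tree$verts * tree$h, 2, tree$domain$lower, `+`)
}
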