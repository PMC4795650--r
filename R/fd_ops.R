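# Pointwise finite-difference primitives on nonuniform one-dimensional
# stencils and at T-junctions. These are the scalar building blocks; the
# field-level operators in stencil.R apply the same formulas over whole trees
# through sparse matrices.

check_stencil <- function(st) {
  if (any(c(st$s1, st$s2) <= 0)) stop("stencil distances must be positive")
}

#' Nonuniform central difference for the first derivative
#'
#' `(u2 - u0)/s2 * s1/(s1 + s2) + (u0 - u1)/s1 * s2/(s1 + s2)`; exact for
#' quadratics on any spacing pair.
#'
#' @param st list with samples `u0` (centre), `u1` (left), `u2` (right) and
#'   positive distances `s1` (left), `s2` (right).
#' @return derivative estimate at the centre.
#' @export
d_central <- function(st) {
  check_stencil(st)
  (st$u2 - st$u0) / st$s2 * st$s1 / (st$s1 + st$s2) +
    (st$u0 - st$u1) / st$s1 * st$s2 / (st$s1 + st$s2)
}

#' Nonuniform central difference for the second derivative
#'
#' `((u2 - u0)/s2 - (u0 - u1)/s1) * 2/(s1 + s2)`; exact for quadratics.
#'
#' @inheritParams d_central
#' @export
d_second <- function(st) {
  check_stencil(st)
  ((st$u2 - st$u0) / st$s2 - (st$u0 - st$u1) / st$s1) * 2 / (st$s1 + st$s2)
}

#' Minmod slope limiter
#'
#' Returns the argument of smaller magnitude (ties return `x`), selecting the
#' gentler of two slope candidates so that one-sided differences never reach
#' across a kink.
#'
#' @param x,y numeric vectors.
#' @return elementwise minmod.
#' @export
minmod <- function(x, y) ifelse(abs(y) < abs(x), y, x)

#' One-sided first derivative, first or second order
#'
#' Order 1 returns the plain forward/backward difference. Order 2 subtracts
#' (adds) `s/2 * minmod(dxx0, dxx_nbr)`, the limited second-derivative
#' correction, giving second-order accuracy away from kinks.
#'
#' @inheritParams d_central
#' @param side `"+"` (forward) or `"-"` (backward).
#' @param order 1 or 2.
#' @param dxx0,dxx_nbr second-derivative values at the centre and at the
#'   neighbour node (required for order 2).
#' @export
d_one_sided <- function(st, side, order = 1L, dxx0 = NULL, dxx_nbr = NULL) {
  check_stencil(st)
  if (!side %in% c("+", "-")) stop("side must be '+' or '-'")
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  base <- if (side == "+") (st$u2 - st$u0) / st$s2 else (st$u0 - st$u1) / st$s1
  if (order == 1L) return(base)
  if (is.null(dxx0) || is.null(dxx_nbr))
    stop("order 2 needs dxx0 and dxx_nbr")
  corr <- minmod(dxx0, dxx_nbr)
  if (side == "+") base - st$s2 / 2 * corr else base + st$s1 / 2 * corr
}

#' Ghost value at a 2D T-junction
#'
#' Third-order interpolation for the missing neighbour: linear interpolation
#' between the transverse samples `u3`, `u4` (at distances `s3`, `s4`) minus
#' `s3 s4/(s1 + s2) * ((u1 - u0)/s1 + (u2 - u0)/s2)`, the transverse
#' second-derivative correction built from the hanging node's own neighbours.
#' Exact on quadratics.
#'
#' @param tj list with fields `u0`, `u1`, `u2`, `s1`, `s2` (hanging node and
#'   its transverse neighbours) and `u3`, `u4`, `s3`, `s4` (coarse-edge
#'   samples bracketing the ghost position).
#' @return scalar ghost value.
#' @export
ghost_value_2d <- function(tj) {
  if (any(c(tj$s1, tj$s2, tj$s3, tj$s4) <= 0))
    stop("T-junction distances must be positive")
  (tj$u3 * tj$s4 + tj$u4 * tj$s3) / (tj$s3 + tj$s4) -
    tj$s3 * tj$s4 / (tj$s1 + tj$s2) *
    ((tj$u1 - tj$u0) / tj$s1 + (tj$u2 - tj$u0) / tj$s2)
}

#' Ghost values at a 3D T-junction
#'
#' Two ghost values are produced. `u6G` interpolates along one transverse
#' direction (samples `u7`, `u8` at `s7`, `s8`) with the second-derivative
#' correction from `u1`, `u2` at `s1`, `s2`. `u4G` combines the four samples
#' `u9`..`u12` (distances `s9`..`s12`) bilinearly and subtracts two
#' corrections, the second of which reuses `u6G` as one of the bracketing
#' values, exactly in that substitution order.
#'
#' @param tj list with fields `u0`, `u1`, `u2`, `s1`, `s2` (first-axis
#'   neighbours of the node), `s4` (distance from the node to the `u6G` ghost
#'   position), `u7`, `u8`, `s7`, `s8`, `u9`..`u12`, `s9`..`s12`, and
#'   optionally `u5`, `s5` (the node's neighbour opposite the `u6G` ghost
#'   along that axis; when absent, `u1`, `s1` stand in, which is only
#'   consistent for fields symmetric in the two axes).
#' @return list with `u6G` and `u4G`.
#' @export
ghost_values_3d <- function(tj) {
  ss <- unlist(tj[grepl("^s", names(tj))])
  if (any(ss <= 0)) stop("T-junction distances must be positive")
  u5 <- if (!is.null(tj$u5)) tj$u5 else tj$u1
  s5 <- if (!is.null(tj$s5)) tj$s5 else tj$s1
  u6G <- (tj$s8 * tj$u7 + tj$s7 * tj$u8) / (tj$s8 + tj$s7) -
    tj$s8 * tj$s7 / (tj$s2 + tj$s1) *
    ((tj$u2 - tj$u0) / tj$s2 + (tj$u1 - tj$u0) / tj$s1)
  u4G <- (tj$s11 * tj$s12 * tj$u11 + tj$s11 * tj$s9 * tj$u12 +
            tj$s10 * tj$s12 * tj$u9 + tj$s10 * tj$s9 * tj$u10) /
    ((tj$s10 + tj$s11) * (tj$s9 + tj$s12)) -
    tj$s10 * tj$s11 / (tj$s2 + tj$s1) *
    ((tj$u2 - tj$u0) / tj$s2 + (tj$u1 - tj$u0) / tj$s1) -
    tj$s9 * tj$s12 / (s5 + tj$s4) *
    ((u5 - tj$u0) / s5 + (u6G - tj$u0) / tj$s4)
  list(u6G = u6G, u4G = u4G)
}
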