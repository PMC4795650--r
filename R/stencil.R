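# Directional neighbour operators on the tree.
#
# For every vertex and every Cartesian direction we either find an existing
# neighbour vertex, detect the domain boundary, or build a third-order ghost
# value at the T-junction (hanging node). Each direction becomes a sparse
# matrix N such that (N %*% f)[i] is the (possibly ghost-interpolated) field
# value at vertex i's neighbour, plus a distance vector s (Inf at the domain
# boundary, where the row reduces to the identity so central differences
# degrade gracefully to one-sided ones).

dir_index <- function(axis, sgn) 2L * (axis - 1L) + if (sgn > 0) 1L else 2L

tree_stencil <- function(tree) {
  cached <- tree$cache$stencil
  if (!is.null(cached)) return(cached)
  d <- tree$dim
  N <- tree$N
  h <- tree$h
  verts <- tree$verts
  n <- nrow(verts)
  ndir <- 2L * d
  delta <- 0.25

  nbr_idx <- matrix(NA_integer_, n, ndir)
  nbr_s <- matrix(Inf, n, ndir)        # physical distances
  is_bnd <- matrix(FALSE, n, ndir)
  is_tj <- matrix(FALSE, n, ndir)
  tj_leaf <- matrix(NA_integer_, n, ndir)

  tcomb <- corner_bits(d - 1L)         # transverse probe sign combinations
  tcomb <- 2 * tcomb - 1

  for (axis in seq_len(d)) for (sgn in c(1, -1)) {
    dir <- dir_index(axis, sgn)
    xa <- verts[, axis]
    bnd <- if (sgn > 0) xa == N else xa == 0
    is_bnd[, dir] <- bnd
    smin <- rep(Inf, n)
    leaf_min <- rep(NA_integer_, n)
    rest <- setdiff(seq_len(d), axis)
    for (ci in seq_len(nrow(tcomb))) {
      P <- verts + 0
      P[, axis] <- xa + sgn * delta
      for (k in seq_along(rest))
        P[, rest[k]] <- verts[, rest[k]] + tcomb[ci, k] * delta
      valid <- !bnd
      for (a in seq_len(d)) valid <- valid & P[, a] >= 0 & P[, a] <= N
      if (!any(valid)) next
      li <- locate_leaf(tree, P[valid, , drop = FALSE])
      w <- tree$leaf_w[li]
      vi <- which(valid)
      upd <- w < smin[vi]
      smin[vi[upd]] <- w[upd]
      leaf_min[vi[upd]] <- li[upd]
    }
    tj_leaf[, dir] <- leaf_min
    cand <- which(!bnd)
    npos <- verts[cand, , drop = FALSE]
    npos[, axis] <- npos[, axis] + sgn * smin[cand]
    m <- match(vkey(npos, N), tree$vkeys)
    reg <- !is.na(m)
    nbr_idx[cand[reg], dir] <- m[reg]
    nbr_s[cand[reg], dir] <- smin[cand[reg]] * h
    is_tj[cand[!reg], dir] <- TRUE
  }

  # ---- assemble sparse rows -------------------------------------------------
  mats <- vector("list", ndir)
  svec <- vector("list", ndir)
  tj_detail <- vector("list", ndir)

  # helper: distances to v's own transverse neighbours (must be regular)
  trans_nbrs <- function(vids, taxis) {
    dm <- dir_index(taxis, -1)
    dp <- dir_index(taxis, +1)
    if (any(is_tj[vids, dm]) || any(is_tj[vids, dp]))
      stop("hanging node with hanging transverse neighbour: tree not graded")
    list(i1 = ifelse(is_bnd[vids, dm], vids, nbr_idx[vids, dm]),
         s1 = nbr_s[vids, dm],
         i2 = ifelse(is_bnd[vids, dp], vids, nbr_idx[vids, dp]),
         s2 = nbr_s[vids, dp])
  }

  for (axis in seq_len(d)) for (sgn in c(1, -1)) {
    dir <- dir_index(axis, sgn)
    ti <- numeric(0); tjc <- numeric(0); tx <- numeric(0)
    svals <- rep(Inf, n)

    bset <- which(is_bnd[, dir])
    rset <- which(!is_bnd[, dir] & !is_tj[, dir])
    jset <- which(is_tj[, dir])
    ti <- c(ti, bset, rset)
    tjc <- c(tjc, bset, nbr_idx[rset, dir])
    tx <- c(tx, rep(1, length(bset) + length(rset)))
    svals[rset] <- nbr_s[rset, dir]

    det <- NULL
    if (length(jset)) {
      C <- tj_leaf[jset, dir]
      w <- tree$leaf_w[C]
      pos <- tree$leaf_pos[C, , drop = FALSE]
      off <- verts[jset, , drop = FALSE] - pos   # offsets within C
      ga <- verts[jset, axis] + sgn * w          # ghost fine coordinate
      rest <- setdiff(seq_len(d), axis)
      svals[jset] <- w * h

      add <- function(rows, cols, coefs) {
        ti <<- c(ti, rows); tjc <<- c(tjc, cols); tx <<- c(tx, coefs)
      }
      inv0 <- function(s) ifelse(is.finite(s), 1 / s, 0)

      if (d == 2L) {
        t1 <- rest[1]
        if (any(off[, t1] * 2 != w))
          stop("unexpected T-junction geometry: tree not graded")
        p3 <- verts[jset, , drop = FALSE]; p3[, axis] <- ga; p3[, t1] <- pos[, t1]
        p4 <- p3; p4[, t1] <- pos[, t1] + w
        i3 <- match(vkey(p3, N), tree$vkeys)
        i4 <- match(vkey(p4, N), tree$vkeys)
        if (anyNA(i3) || anyNA(i4)) stop("missing coarse corner at T-junction")
        s3 <- (verts[jset, t1] - pos[, t1]) * h
        s4 <- (pos[, t1] + w - verts[jset, t1]) * h
        tn <- trans_nbrs(jset, t1)
        cc <- s3 * s4 / (tn$s1 + tn$s2)
        cc[!is.finite(cc)] <- 0
        add(jset, i3, s4 / (s3 + s4))
        add(jset, i4, s3 / (s3 + s4))
        add(jset, jset, cc * (inv0(tn$s1) + inv0(tn$s2)))
        add(jset, tn$i1, -cc * inv0(tn$s1))
        add(jset, tn$i2, -cc * inv0(tn$s2))
        det <- list(v = jset, type = rep("edge", length(jset)),
                    i3 = i3, i4 = i4, s3 = s3, s4 = s4,
                    i1 = tn$i1, i2 = tn$i2, s1 = tn$s1, s2 = tn$s2)
      } else {
        t1 <- rest[1]; t2 <- rest[2]
        half1 <- off[, t1] * 2 == w
        half2 <- off[, t2] * 2 == w
        if (any(!half1 & !half2))
          stop("unexpected 3D T-junction geometry: tree not graded")
        typeA <- half1 & half2
        det <- list(v = jset,
                    type = ifelse(typeA, "face", "edge"),
                    taxes = ifelse(typeA, NA_integer_,
                                   ifelse(half1, t1, t2)))
        corr <- function(rows, taxis_vec, s34_prod_over) {
          # adds the -s3*s4/(s1+s2)*((u1-u0)/s1+(u2-u0)/s2) correction rows
          for (tax in unique(taxis_vec)) {
            sel <- rows[taxis_vec == tax]
            tn <- trans_nbrs(sel, tax)
            cc <- s34_prod_over[match(sel, rows)] / (tn$s1 + tn$s2)
            cc[!is.finite(cc)] <- 0
            add(sel, sel, cc * (inv0(tn$s1) + inv0(tn$s2)))
            add(sel, tn$i1, -cc * inv0(tn$s1))
            add(sel, tn$i2, -cc * inv0(tn$s2))
          }
        }
        if (any(!typeA)) {
          eb <- jset[!typeA]
          wB <- w[!typeA]
          taxB <- det$taxes[!typeA]
          posB <- pos[!typeA, , drop = FALSE]
          gaB <- ga[!typeA]
          p7 <- verts[eb, , drop = FALSE]; p7[, axis] <- gaB
          p8 <- p7
          for (tax in unique(taxB)) {
            s <- taxB == tax
            p7[s, tax] <- posB[s, tax]
            p8[s, tax] <- posB[s, tax] + wB[s]
          }
          i7 <- match(vkey(p7, N), tree$vkeys)
          i8 <- match(vkey(p8, N), tree$vkeys)
          if (anyNA(i7) || anyNA(i8)) stop("missing coarse corner at T-junction")
          s7 <- s8 <- (wB / 2) * h
          add(eb, i7, s8 / (s7 + s8))
          add(eb, i8, s7 / (s7 + s8))
          corr(eb, taxB, s7 * s8)
          det$edge <- list(v = eb, i7 = i7, i8 = i8, s7 = s7, s8 = s8)
        }
        if (any(typeA)) {
          fb <- jset[typeA]
          wA <- w[typeA]
          gaA <- ga[typeA]
          base <- verts[fb, , drop = FALSE]; base[, axis] <- gaA
          ii <- matrix(NA_integer_, length(fb), 4)
          k <- 0
          for (d1 in c(-1, 1)) for (d2 in c(-1, 1)) {
            k <- k + 1
            p <- base
            p[, t1] <- p[, t1] + d1 * wA / 2
            p[, t2] <- p[, t2] + d2 * wA / 2
            ii[, k] <- match(vkey(p, N), tree$vkeys)
          }
          if (anyNA(ii)) stop("missing coarse face corner at T-junction")
          for (k in 1:4) add(fb, ii[, k], rep(0.25, length(fb)))
          corr(fb, rep(t1, length(fb)), (wA / 2 * h)^2)
          corr(fb, rep(t2, length(fb)), (wA / 2 * h)^2)
          det$face <- list(v = fb, corners = ii, sq = wA / 2 * h)
        }
      }
    }
    mats[[dir]] <- Matrix::sparseMatrix(i = ti, j = tjc, x = tx,
                                        dims = c(n, n))
    svec[[dir]] <- svals
    tj_detail[[dir]] <- det
  }

  st <- list(dim = d, n = n, mats = mats, s = svec,
             is_bnd = is_bnd, is_tj = is_tj, nbr_idx = nbr_idx,
             tj_detail = tj_detail)
  tree$cache$stencil <- st
  st
}

nb_vals <- function(st, dir, f) as.numeric(st$mats[[dir]] %*% f)

# ---- field-level derivative operators --------------------------------------

# central first derivative along an axis, exact on quadratics; at boundary
# vertices it reduces to the one-sided first-order difference
d_axis_central <- function(tree, f, axis) {
  st <- tree_stencil(tree)
  dp <- dir_index(axis, +1); dm <- dir_index(axis, -1)
  u2 <- nb_vals(st, dp, f); u1 <- nb_vals(st, dm, f)
  s2 <- st$s[[dp]]; s1 <- st$s[[dm]]
  r1 <- ifelse(!is.finite(s1), 1, ifelse(!is.finite(s2), 0, s1 / (s1 + s2)))
  fwd <- ifelse(is.finite(s2), (u2 - f) / s2, 0)
  bwd <- ifelse(is.finite(s1), (f - u1) / s1, 0)
  # r1 weights the forward part; 1 - r1 the backward part
  out <- fwd * r1 + bwd * (1 - r1)
  # boundary on the minus side: pure forward (r1 = 1 handled above when s1 Inf)
  ifelse(is.finite(s1) | is.finite(s2), out, 0)
}

# second derivative along an axis (zero at boundary vertices)
d_axis_second <- function(tree, f, axis) {
  st <- tree_stencil(tree)
  dp <- dir_index(axis, +1); dm <- dir_index(axis, -1)
  u2 <- nb_vals(st, dp, f); u1 <- nb_vals(st, dm, f)
  s2 <- st$s[[dp]]; s1 <- st$s[[dm]]
  fwd <- ifelse(is.finite(s2), (u2 - f) / s2, 0)
  bwd <- ifelse(is.finite(s1), (f - u1) / s1, 0)
  out <- ifelse(is.finite(s1) & is.finite(s2),
                2 * (fwd - bwd) / (s1 + s2), 0)
  out
}

# one-sided first derivatives; order 2 applies the minmod-limited second
# derivative correction
d_axis_one_sided <- function(tree, f, axis, sgn, order = 2L, dxx = NULL) {
  st <- tree_stencil(tree)
  dir <- dir_index(axis, sgn)
  u <- nb_vals(st, dir, f)
  s <- st$s[[dir]]
  base <- ifelse(is.finite(s), if (sgn > 0) (u - f) / s else (f - u) / s, 0)
  if (order == 1L) return(base)
  if (is.null(dxx)) dxx <- d_axis_second(tree, f, axis)
  dxx_nb <- nb_vals(st, dir, dxx)
  corr <- ifelse(is.finite(s), (s / 2) * minmod(dxx, dxx_nb), 0)
  if (sgn > 0) base - corr else base + corr
}

tree_gradient <- function(tree, f) {
  vapply(seq_len(tree$dim), function(a) d_axis_central(tree, f, a),
         numeric(length(f)))
}

grad_norm <- function(tree, f) sqrt(rowSums(tree_gradient(tree, f)^2))

# divergence-form diffusion coefficients: div(a grad u) at vertex i is
# sum over directions of c[, dir] * (u_nbr - u_i), with a sampled midway
diffusion_coeffs <- function(tree, a_field) {
  st <- tree_stencil(tree)
  d <- tree$dim
  cc <- matrix(0, st$n, 2 * d)
  for (axis in seq_len(d)) {
    dp <- dir_index(axis, +1); dm <- dir_index(axis, -1)
    s2 <- st$s[[dp]]; s1 <- st$s[[dm]]
    # at the domain boundary, mirror the finite distance (zero-flux side)
    sf1 <- ifelse(is.finite(s1), s1, s2)
    sf2 <- ifelse(is.finite(s2), s2, s1)
    fac <- ifelse(is.finite(sf1 + sf2), 2 / (sf1 + sf2), 0)
    amid_p <- 0.5 * (a_field + nb_vals(st, dp, a_field))
    amid_m <- 0.5 * (a_field + nb_vals(st, dm, a_field))
    cc[, dp] <- ifelse(is.finite(s2), fac * amid_p / s2, 0)
    cc[, dm] <- ifelse(is.finite(s1), fac * amid_m / s1, 0)
  }
  cc
}

# forward-difference gradient operators and their exact transposes, used by
# the dual total-variation projection (the pair (G, -t(G)) is an exact
# gradient/divergence adjoint pair in the unweighted vertex inner product)
tv_operators <- function(tree) {
  cached <- tree$cache$tv_ops
  if (!is.null(cached)) return(cached)
  st <- tree_stencil(tree)
  d <- tree$dim
  G <- vector("list", d); Gt <- vector("list", d)
  n <- st$n
  for (axis in seq_len(d)) {
    dp <- dir_index(axis, +1)
    s <- st$s[[dp]]
    inv <- ifelse(is.finite(s), 1 / s, 0)
    D <- Matrix::Diagonal(x = inv)
    G[[axis]] <- D %*% (st$mats[[dp]] - Matrix::Diagonal(n))
    Gt[[axis]] <- Matrix::t(G[[axis]])
  }
  # largest eigenvalue of div o grad (= ||grad||^2) by power iteration;
  # governs the stable dual step size on the nonuniform tree
  K <- Gt[[1]] %*% G[[1]]
  for (a in seq_len(d)[-1]) K <- K + Gt[[a]] %*% G[[a]]
  v <- rep(1, n) + seq_len(n) / n
  lam <- 1
  for (it in 1:50) {
    v2 <- as.numeric(K %*% v)
    lam <- sqrt(sum(v2^2)) / sqrt(sum(v^2))
    v <- v2 / max(sqrt(sum(v2^2)), 1e-300)
  }
  ops <- list(G = G, Gt = Gt, grad_norm2 = lam,
              h_min = min(vapply(seq_len(2 * d), function(k)
                min(st$s[[k]][is.finite(st$s[[k]])]), numeric(1))))
  tree$cache$tv_ops <- ops
  ops
}

finest_spacing <- function(tree) tree$h

#' Describe the neighbourhood of a tree vertex
#'
#' For each Cartesian direction, reports either an existing neighbour vertex
#' with its distance, a domain boundary, or a T-junction record with the
#' transverse vertices and distances entering the ghost-node interpolation.
#'
#' @param tree an `adaptive_tree` (2:1 graded).
#' @param vertex either a vertex index or a physical coordinate vector.
#' @return A list with one entry per direction (`+x`, `-x`, `+y`, ...), each a
#'   list with `type` (`"neighbor"`, `"tjunction"` or `"boundary"`) and the
#'   relevant indices/distances.
#' @export
vertex_neighborhood <- function(tree, vertex) {
  if (length(vertex) == tree$dim && !is.integer(vertex) &&
      (length(vertex) > 1)) {
    fine <- round((vertex - tree$domain$lower) / tree$h)
    vi <- match(vkey(matrix(fine, 1), tree$N), tree$vkeys)
  } else vi <- as.integer(vertex)
  if (is.na(vi) || vi < 1 || vi > nrow(tree$verts))
    stop("vertex not in tree")
  st <- tree_stencil(tree)
  axes <- c("x", "y", "z")[seq_len(tree$dim)]
  out <- list()
  for (axis in seq_len(tree$dim)) for (sgn in c(1, -1)) {
    dir <- dir_index(axis, sgn)
    nm <- paste0(if (sgn > 0) "+" else "-", axes[axis])
    if (st$is_bnd[vi, dir]) {
      out[[nm]] <- list(type = "boundary")
    } else if (!st$is_tj[vi, dir]) {
      out[[nm]] <- list(type = "neighbor", index = st$nbr_idx[vi, dir],
                        distance = st$s[[dir]][vi])
    } else {
      det <- st$tj_detail[[dir]]
      rec <- list(type = "tjunction", distance = st$s[[dir]][vi])
      if (tree$dim == 2L) {
        k <- match(vi, det$v)
        rec <- c(rec, list(i3 = det$i3[k], i4 = det$i4[k],
                           s3 = det$s3[k], s4 = det$s4[k],
                           i1 = det$i1[k], i2 = det$i2[k],
                           s1 = det$s1[k], s2 = det$s2[k]))
      } else {
        k <- match(vi, det$v)
        rec$kind <- det$type[k]
        if (det$type[k] == "edge") {
          ke <- match(vi, det$edge$v)
          rec <- c(rec, list(i7 = det$edge$i7[ke], i8 = det$edge$i8[ke],
                             s7 = det$edge$s7[ke], s8 = det$edge$s8[ke],
                             trans_axis = det$taxes[k]))
        } else {
          kf <- match(vi, det$face$v)
          rec <- c(rec, list(corners = det$face$corners[kf, ],
                             sq = det$face$sq[kf]))
        }
      }
      out[[nm]] <- rec
    }
  }
  out
}
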