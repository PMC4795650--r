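#' Quadtree/Octree depth matching the pixel size
#'
#' The finest tree cells coincide with pixels, so the maximum level is the
#' smallest `L` with `2^L >= max(pixel_counts)`; a 1024 x 1024 image maps to a
#' quadtree of maximum level 10.
#'
#' @param pixel_counts positive integer vector.
#' @return integer level.
#' @export
max_level_for_image <- function(pixel_counts) {
  if (any(!is.finite(pixel_counts)) || any(pixel_counts < 1))
    stop("pixel counts must be positive")
  as.integer(ceiling(log2(max(pixel_counts))))
}

#' Uniform-grid cell count
#'
#' Degrees of freedom of the equivalent uniform (non-adaptive) grid,
#' `prod(cell_counts)`; used for bookkeeping and compression ratios.
#'
#' @param cell_counts integer vector of cells per axis.
#' @return integer count.
#' @export
uniform_cell_count <- function(cell_counts) {
  if (any(cell_counts < 1)) stop("cell counts must be positive")
  prod(as.numeric(cell_counts))
}

# ---- key encodings (exact in doubles for all supported depths) -------------

vkey <- function(verts, N) {
  d <- ncol(verts)
  k <- verts[, 1]
  for (a in seq_len(d)[-1]) k <- k * (N + 1) + verts[, a]
  k
}

lkey <- function(level, idx, N) {
  k <- level
  for (a in seq_len(ncol(idx))) k <- k * N + idx[, a]
  k
}

# ---- finalisation: vertices, corner incidence ------------------------------

corner_bits <- function(d) {
  # 2^d x d matrix of 0/1 corner offsets, binary order
  bits <- as.matrix(expand.grid(rep(list(0:1), d)))[, d:1, drop = FALSE]
  dimnames(bits) <- NULL
  bits
}

finalize_tree <- function(domain, leaves, max_level) {
  d <- domain$dim
  storage.mode(leaves) <- "integer"
  N <- 2L^max_level
  base_level <- max_level_for_image(domain$pixel_counts)
  lev <- leaves[, 1]
  idx <- leaves[, -1, drop = FALSE]
  w <- 2^(max_level - lev)
  pos <- idx * w                       # fine-lattice lower corner
  bits <- corner_bits(d)
  nb <- nrow(bits)
  n_leaf <- nrow(leaves)
  ckeys <- matrix(0, n_leaf, nb)
  corner_pos <- vector("list", nb)
  for (b in seq_len(nb)) {
    cp <- pos + matrix(w, n_leaf, d) * matrix(bits[b, ], n_leaf, d, byrow = TRUE)
    corner_pos[[b]] <- cp
    ckeys[, b] <- vkey(cp, N)
  }
  allkeys <- as.vector(ckeys)
  u <- !duplicated(allkeys)
  vkeys <- allkeys[u]
  allpos <- do.call(rbind, corner_pos)
  verts <- allpos[u, , drop = FALSE]
  ord <- order(vkeys)
  vkeys <- vkeys[ord]
  verts <- verts[ord, , drop = FALSE]
  corner_idx <- matrix(match(as.vector(ckeys), vkeys), n_leaf, nb)
  # the root always spans the image's dyadic square (2^base_level pixels);
  # max_level only sets the finest subdivision, so h is the finest cell size
  tree <- list(domain = domain, dim = d, max_level = as.integer(max_level),
               N = N, h = domain$spacing * 2^(base_level - max_level),
               leaves = leaves, leaf_pos = pos, leaf_w = w,
               lkeys = lkey(lev, idx, N),
               verts = verts, vkeys = vkeys, corner_idx = corner_idx,
               cache = new.env(parent = emptyenv()))
  class(tree) <- "adaptive_tree"
  tree
}

#' @exportS3Method base::print
print.adaptive_tree <- function(x, ...) {
  cat(sprintf("<adaptive_tree %dD: max level %d, %d leaves, %d vertices>\n",
              x$dim, x$max_level, nrow(x$leaves), nrow(x$verts)))
  invisible(x)
}

split_leaves <- function(leaves, which_split, d) {
  if (!any(which_split)) return(leaves)
  keep <- leaves[!which_split, , drop = FALSE]
  sp <- leaves[which_split, , drop = FALSE]
  bits <- corner_bits(d)
  kids <- vector("list", nrow(bits))
  for (b in seq_len(nrow(bits))) {
    child <- sp
    child[, 1] <- sp[, 1] + 1
    child[, -1] <- 2 * sp[, -1, drop = FALSE] +
      matrix(bits[b, ], nrow(sp), d, byrow = TRUE)
    kids[[b]] <- child
  }
  rbind(keep, do.call(rbind, kids))
}

# ---- Whitney construction --------------------------------------------------

#' Build an adaptive tree refined around a level-set function
#'
#' Starting from the root cell, a cell `C` is split whenever
#' `min(|phi|)` over its corner nodes is at most `0.5 * lip * diag(C)` and its
#' level is below `max_level` (Whitney-type refinement), so the finest cells
#' straddle the zero level set: any cell intersecting the interface has a
#' corner within half a diagonal of it and is therefore split whenever
#' `lip >= 1`. Images whose side is not a power of two are
#' embedded in the smallest dyadic square/cube; cells entirely outside the
#' image raster are never split.
#'
#' @param domain an [at_domain()].
#' @param phi_at_point vectorised function taking an `n x d` matrix of
#'   physical points and returning `n` finite values.
#' @param max_level maximum tree depth; default [max_level_for_image()].
#' @param lip Lipschitz bound used by the split rule; 1.2 is a safe default
#'   for signed-distance inputs.
#' @param grade if `TRUE` (default), [enforce_grading()] is applied so that
#'   edge-adjacent leaves differ by at most one level.
#' @return An `adaptive_tree`.
#' @export
build_tree <- function(domain, phi_at_point, max_level = NULL, lip = 1.2,
                       grade = TRUE) {
  if (!inherits(domain, "at_domain")) stop("domain must be an at_domain")
  if (lip <= 0) stop("lip must be positive")
  d <- domain$dim
  if (is.null(max_level)) max_level <- max_level_for_image(domain$pixel_counts)
  max_level <- as.integer(max_level)
  N <- 2L^max_level
  base_level <- max_level_for_image(domain$pixel_counts)
  h <- domain$spacing * 2^(base_level - max_level)  # finest cell size
  px_per_fine <- 2^(base_level - max_level)
  bits <- corner_bits(d)

  phi_cache_keys <- numeric(0)
  phi_cache_vals <- numeric(0)
  eval_phi <- function(pos) {
    # pos: fine-lattice coords, rows unique-ified against cache
    keys <- vkey(pos, N)
    m <- match(keys, phi_cache_keys)
    need <- is.na(m)
    if (any(need)) {
      uk <- keys[need]
      dup <- duplicated(uk)
      newk <- uk[!dup]
      newpos <- pos[need, , drop = FALSE][!dup, , drop = FALSE]
      pts <- sweep(newpos * h, 2, domain$lower, `+`)
      vals <- phi_at_point(pts)
      if (length(vals) != nrow(pts) || any(!is.finite(vals)))
        stop("phi_at_point returned non-finite or wrongly sized values")
      phi_cache_keys <<- c(phi_cache_keys, newk)
      phi_cache_vals <<- c(phi_cache_vals, vals)
      m <- match(keys, phi_cache_keys)
    }
    phi_cache_vals[m]
  }

  leaves <- matrix(0L, 1, 1 + d)
  repeat {
    lev <- leaves[, 1]
    cand <- lev < max_level
    if (!any(cand)) break
    sub <- leaves[cand, , drop = FALSE]
    w <- 2^(max_level - sub[, 1])
    pos <- sub[, -1, drop = FALSE] * w
    # never split cells fully outside the image raster
    inside <- rep(TRUE, nrow(sub))
    for (a in seq_len(d))
      inside <- inside & (pos[, a] * px_per_fine < domain$pixel_counts[a])
    mn <- rep(Inf, nrow(sub))
    for (b in seq_len(nrow(bits))) {
      cp <- pos + matrix(w, nrow(sub), d) *
        matrix(bits[b, ], nrow(sub), d, byrow = TRUE)
      mn <- pmin(mn, abs(eval_phi(cp)))
    }
    diag_size <- sqrt(d) * w * h
    split <- inside & (mn <= 0.5 * lip * diag_size)
    if (!any(split)) break
    flag <- logical(nrow(leaves))
    flag[which(cand)[split]] <- TRUE
    leaves <- split_leaves(leaves, flag, d)
  }
  tree <- finalize_tree(domain, leaves, max_level)
  if (grade) tree <- enforce_grading(tree) else tree
}

# ---- 2:1 grading -----------------------------------------------------------

#' Enforce 2:1 level grading
#'
#' Splits coarse leaves until any two edge-adjacent leaves (face- and
#' edge-adjacent in 3D) differ by at most one level. Only refinement occurs,
#' so Whitney-refined cells are preserved. Idempotent.
#'
#' @param tree an `adaptive_tree`.
#' @return A graded `adaptive_tree`.
#' @export
enforce_grading <- function(tree) {
  d <- tree$dim
  N <- tree$N
  domain <- tree$domain
  leaves <- tree$leaves
  max_level <- tree$max_level
  repeat {
    tr <- finalize_tree(domain, leaves, max_level)
    viol <- grading_violations(tr)
    if (!any(viol)) return(tr)
    leaves <- split_leaves(tr$leaves, viol, d)
  }
}

# leaves that have an edge-adjacent neighbour two or more levels deeper:
# detected by the presence of a vertex at an odd quarter position on one of
# the leaf's faces (2D) or faces/edges (3D).
grading_violations <- function(tree) {
  d <- tree$dim
  N <- tree$N
  w <- tree$leaf_w
  pos <- tree$leaf_pos
  big <- w >= 4                       # only these can violate 2:1
  n <- nrow(pos)
  viol <- logical(n)
  if (!any(big)) return(viol)
  q <- w / 4
  has_vertex <- function(p) {
    ok <- rep(TRUE, nrow(p))
    for (a in seq_len(d)) ok <- ok & p[, a] >= 0 & p[, a] <= N
    out <- logical(nrow(p))
    out[ok] <- !is.na(match(vkey(p[ok, , drop = FALSE], N), tree$vkeys))
    out
  }
  check <- function(offsets) {
    # offsets: list of per-axis multiples of w/4 (vectors length n)
    p <- pos
    for (a in seq_len(d)) p[, a] <- pos[, a] + offsets[[a]]
    viol <<- viol | (big & has_vertex(p))
  }
  qm <- list(`0` = 0 * q, `1` = q, `2` = 2 * q, `3` = 3 * q, `4` = 4 * q)
  if (d == 2L) {
    for (fx in c("0", "4")) for (oy in c("1", "3"))
      check(list(qm[[fx]], qm[[oy]]))
    for (fy in c("0", "4")) for (ox in c("1", "3"))
      check(list(qm[[ox]], qm[[fy]]))
  } else {
    odd <- c("1", "3"); all5 <- c("0", "1", "2", "3", "4")
    # faces perpendicular to each axis: interior quarter points with at least
    # one odd quarter coordinate
    for (a in 1:3) {
      rest <- setdiff(1:3, a)
      for (f in c("0", "4")) {
        for (o1 in c("1", "2", "3")) for (o2 in c("1", "2", "3")) {
          if (o1 == "2" && o2 == "2") next
          off <- vector("list", 3)
          off[[a]] <- qm[[f]]; off[[rest[1]]] <- qm[[o1]]
          off[[rest[2]]] <- qm[[o2]]
          check(off)
        }
      }
    }
    # edges along each axis: odd quarter points
    for (a in 1:3) {
      rest <- setdiff(1:3, a)
      for (e1 in c("0", "4")) for (e2 in c("0", "4")) for (o in odd) {
        off <- vector("list", 3)
        off[[a]] <- qm[[o]]; off[[rest[1]]] <- qm[[e1]]
        off[[rest[2]]] <- qm[[e2]]
        check(off)
      }
    }
  }
  viol
}

is_graded <- function(tree) !any(grading_violations(tree))

# ---- coarsened copies (flow pyramid) ---------------------------------------

cap_tree <- function(tree, lmax) {
  lmax <- as.integer(lmax)
  if (lmax >= tree$max_level) return(tree)
  lev <- pmin(tree$leaves[, 1], lmax)
  shift <- tree$leaves[, 1] - lev
  idx <- tree$leaves[, -1, drop = FALSE] %/% (2^shift)
  keys <- lkey(lev, idx, tree$N %/% 1L)  # same base works: level in key
  keep <- !duplicated(keys)
  leaves <- cbind(lev, idx)[keep, , drop = FALSE]
  finalize_tree(tree$domain, leaves, tree$max_level)
}

# ---- point location --------------------------------------------------------

# pts_fine: n x d fine-lattice (possibly fractional) coordinates in [0, N]
locate_leaf <- function(tree, pts_fine) {
  n <- nrow(pts_fine)
  out <- rep(NA_integer_, n)
  for (l in sort(unique(tree$leaves[, 1]))) {
    todo <- is.na(out)
    if (!any(todo)) break
    w <- 2^(tree$max_level - l)
    idx <- floor(pts_fine[todo, , drop = FALSE] / w)
    idx[idx < 0] <- 0
    idx[idx > 2^l - 1] <- 2^l - 1
    m <- match(lkey(rep(l, sum(todo)), idx, tree$N), tree$lkeys)
    out[which(todo)[!is.na(m)]] <- m[!is.na(m)]
  }
  if (anyNA(out)) stop("point location failed (point outside domain?)")
  out
}

# ---- image-to-tree sampling ------------------------------------------------

sat_table <- function(data) {
  d <- length(dim(data))
  if (d == 2L) {
    s <- matrix(0, nrow(data) + 1, ncol(data) + 1)
    s[-1, -1] <- t(apply(apply(data, 2, cumsum), 1, cumsum))
    s
  } else {
    dm <- dim(data)
    s <- array(0, dm + 1)
    cs <- apply(data, c(2, 3), cumsum)              # along dim 1
    cs <- aperm(apply(cs, c(1, 3), cumsum), c(2, 1, 3))  # along dim 2
    cs <- aperm(apply(cs, c(1, 2), cumsum), c(2, 3, 1))  # along dim 3
    s[-1, -1, -1] <- cs
    s
  }
}

sat_sum2 <- function(s, x0, x1, y0, y1) {
  s[cbind(x1 + 1, y1 + 1)] - s[cbind(x0, y1 + 1)] -
    s[cbind(x1 + 1, y0)] + s[cbind(x0, y0)]
}

sat_sum3 <- function(s, x0, x1, y0, y1, z0, z1) {
  g <- function(i, j, k) s[cbind(i, j, k)]
  g(x1 + 1, y1 + 1, z1 + 1) - g(x0, y1 + 1, z1 + 1) - g(x1 + 1, y0, z1 + 1) -
    g(x1 + 1, y1 + 1, z0) + g(x0, y0, z1 + 1) + g(x0, y1 + 1, z0) +
    g(x1 + 1, y0, z0) - g(x0, y0, z0)
}

# mean pixel value over every leaf; cells outside the raster carry the
# nearest pixel's value
leaf_averages <- function(tree, frame) {
  d <- tree$dim
  np <- dim(frame$data)
  s <- sat_table(frame$data)
  scale <- tree$h / tree$domain$spacing    # pixels per fine-lattice unit
  lo <- tree$leaf_pos * scale              # in pixel units
  hi <- (tree$leaf_pos + tree$leaf_w) * scale
  lo1 <- ceiling(lo - 0.5)                 # first pixel centre inside
  hi1 <- ceiling(hi - 0.5)                 # one past the last
  for (a in seq_len(d)) {
    lo1[, a] <- pmin(pmax(lo1[, a], 0), np[a] - 1)
    hi1[, a] <- pmin(pmax(hi1[, a], 1), np[a])
    hi1[, a] <- pmax(hi1[, a], lo1[, a] + 1)  # nearest pixel when outside
  }
  if (d == 2L) {
    tot <- sat_sum2(s, lo1[, 1] + 1, hi1[, 1], lo1[, 2] + 1, hi1[, 2])
    cnt <- (hi1[, 1] - lo1[, 1]) * (hi1[, 2] - lo1[, 2])
  } else {
    tot <- sat_sum3(s, lo1[, 1] + 1, hi1[, 1], lo1[, 2] + 1, hi1[, 2],
                    lo1[, 3] + 1, hi1[, 3])
    cnt <- (hi1[, 1] - lo1[, 1]) * (hi1[, 2] - lo1[, 2]) *
      (hi1[, 3] - lo1[, 3])
  }
  tot / cnt
}

#' Average image value over one tree cell
#'
#' Arithmetic mean of the pixels whose centres fall in the cell's
#' closed-left/open-right extent; a cell outside the raster carries the
#' nearest pixel's value.
#'
#' @param frame an [image_frame()].
#' @param cell list with `level` and `index` (0-based per-axis index at that
#'   level).
#' @param max_level tree depth defining the dyadic embedding; default
#'   [max_level_for_image()] of the frame.
#' @return scalar mean.
#' @export
cell_average <- function(frame, cell, max_level = NULL) {
  if (is.null(max_level)) max_level <- max_level_for_image(dim(frame$data))
  d <- frame$dim
  if (cell$level < 0 || any(cell$index < 0) ||
      any(cell$index > 2^cell$level - 1))
    stop("invalid cell")
  base <- max_level_for_image(dim(frame$data))
  lo_px <- cell$index * 2^(base - cell$level)
  if (any(lo_px >= dim(frame$data))) stop("cell outside image")
  dummy <- finalize_tree(frame_domain(frame),
                         matrix(as.integer(c(cell$level, cell$index)), 1),
                         max_level)
  leaf_averages(dummy, frame)[1]
}

# node value = mean of the cell averages of the leaves incident to the vertex
image_to_nodes <- function(tree, frame) {
  la <- leaf_averages(tree, frame)
  nb <- ncol(tree$corner_idx)
  idx <- as.vector(tree$corner_idx)
  vals <- rep(la, nb)
  sums <- rowsum(vals, idx)
  cnts <- rowsum(rep(1, length(idx)), idx)
  node_field(tree, as.numeric(sums / cnts))
}

# vertex quadrature weights: each leaf spreads its volume over its corners
vertex_weights <- function(tree) {
  if (!is.null(tree$cache$wq)) return(tree$cache$wq)
  vol <- (tree$leaf_w * tree$h)^tree$dim
  nb <- ncol(tree$corner_idx)
  wq <- rowsum(rep(vol / nb, nb), as.vector(tree$corner_idx))
  wq <- as.numeric(wq)
  tree$cache$wq <- wq
  wq
}

# ---- plain-text dump/restore ----------------------------------------------

#' Write a tree to a plain-text file
#'
#' Header records dimension, maximum level, pixel counts, lower corner and
#' spacing, followed by one `level ix iy [iz]` record per leaf. The
#' round-trip through [read_tree()] is bit-exact.
#'
#' @param tree an `adaptive_tree`.
#' @param path output file.
#' @export
write_tree <- function(tree, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("adaptivetrack-tree %d %d", tree$dim, tree$max_level), con)
  writeLines(paste(tree$domain$pixel_counts, collapse = " "), con)
  writeLines(paste(sprintf("%.17g", tree$domain$lower), collapse = " "), con)
  writeLines(sprintf("%.17g", tree$domain$spacing), con)
  writeLines(apply(tree$leaves, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Restore a tree written by [write_tree()]
#' @param path file path.
#' @return An `adaptive_tree`.
#' @export
read_tree <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ")[[1]]
  if (hdr[1] != "adaptivetrack-tree") stop("not a tree dump")
  d <- as.integer(hdr[2]); L <- as.integer(hdr[3])
  counts <- as.integer(strsplit(lines[2], " ")[[1]])
  lower <- as.numeric(strsplit(lines[3], " ")[[1]])
  spacing <- as.numeric(lines[4])
  rec <- do.call(rbind, lapply(strsplit(lines[-(1:4)], " "), as.integer))
  finalize_tree(at_domain(counts, lower, spacing), rec, L)
}
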