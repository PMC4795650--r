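# Mask comparison metrics and connected components.

#' Dice coefficient of two binary masks
#'
#' `2 |A  and  B| / (|A| + |B|)`.
#'
#' @param a,b binary arrays of identical shape.
#' @return scalar in `[0, 1]` (1 when both masks are empty).
#' @export
dice_coefficient <- function(a, b) {
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Symmetric Hausdorff distance between mask boundaries
#'
#' Maximum over both directions of the largest distance from a boundary
#' point of one mask to the nearest boundary point of the other, in pixel
#' units.
#'
#' @param a,b binary arrays of identical shape.
#' @return distance in pixels (`Inf` if one boundary is empty).
#' @export
hausdorff_distance <- function(a, b) {
  pa <- mask_boundary_points(a != 0, 1, rep(0, length(dim(a))))
  pb <- mask_boundary_points(b != 0, 1, rep(0, length(dim(b))))
  if (!nrow(pa) || !nrow(pb)) return(Inf)
  max(max(min_dist_to_cloud(pa, pb)), max(min_dist_to_cloud(pb, pa)))
}

#' Label connected components of a binary mask
#'
#' Face-connected (4- in 2D, 6- in 3D) component labelling by iterated
#' minimum-label propagation.
#'
#' @param mask binary matrix or 3D array.
#' @return integer array of labels (0 = background).
#' @export
label_components <- function(mask) {
  dm <- dim(mask)
  d <- length(dm)
  lab <- array(0, dm)
  lab[mask != 0] <- seq_len(sum(mask != 0))
  shift_min <- function(l, a, off) {
    n_a <- dm[a]
    idx <- pmin(pmax(seq_len(n_a) + off, 1L), n_a)
    sl <- lapply(seq_len(d), function(x) if (x == a) idx else seq_len(dm[x]))
    do.call(`[`, c(list(l), sl))
  }
  repeat {
    new <- lab
    for (a in seq_len(d)) for (off in c(-1L, 1L)) {
      s <- shift_min(new, a, off)
      upd <- mask != 0 & s != 0 & s < new
      new[upd] <- s[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  # compact labels
  u <- sort(unique(lab[lab > 0]))
  lab[lab > 0] <- match(lab[lab > 0], u)
  storage.mode(lab) <- "integer"
  lab
}

# ---- 2D contour polylines --------------------------------------------------

# marching-squares style contour of a node field at `level`, chained into
# polylines; returns a list of m x 2 matrices in physical coordinates
contour_polylines <- function(field, level = 0) {
  tree <- field$tree
  if (tree$dim != 2L) stop("polyline extraction is 2D only")
  f <- field$values - level
  segs <- list()
  # per leaf: corner order (0,0),(1,0),(0,1),(1,1) -> edges of the square
  ci <- tree$corner_idx
  corner_edges <- rbind(c(1, 2), c(2, 4), c(4, 3), c(3, 1))
  for (li in seq_len(nrow(ci))) {
    vals <- f[ci[li, ]]
    if (all(vals > 0) || all(vals <= 0)) next
    crossings <- list()
    for (e in seq_len(4)) {
      i0 <- ci[li, corner_edges[e, 1]]; i1 <- ci[li, corner_edges[e, 2]]
      f0 <- f[i0]; f1 <- f[i1]
      if ((f0 > 0) == (f1 > 0)) next
      t0 <- f0 / (f0 - f1)
      p <- tree$verts[i0, ] + t0 * (tree$verts[i1, ] - tree$verts[i0, ])
      crossings[[length(crossings) + 1]] <- p
    }
    if (length(crossings) >= 2) {
      # pair crossings sequentially (ambiguous saddle cells are rare at the
      # finest level and split arbitrarily)
      for (k in seq(1, length(crossings) - 1, by = 2))
        segs[[length(segs) + 1]] <- rbind(crossings[[k]], crossings[[k + 1]])
    }
  }
  if (!length(segs)) return(list())
  # chain segments into polylines by matching endpoints
  key <- function(p) paste(round(p[1], 9), round(p[2], 9))
  ends <- new.env(parent = emptyenv())
  for (i in seq_along(segs)) {
    for (p in list(segs[[i]][1, ], segs[[i]][2, ])) {
      k <- key(p)
      ends[[k]] <- c(get0(k, envir = ends), i)
    }
  }
  used <- logical(length(segs))
  lines <- list()
  for (i in seq_along(segs)) {
    if (used[i]) next
    used[i] <- TRUE
    path <- list(segs[[i]][1, ], segs[[i]][2, ])
    repeat {
      tailp <- path[[length(path)]]
      cand <- setdiff(get0(key(tailp), envir = ends), which(used))
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      j <- cand[1]
      used[j] <- TRUE
      nxt <- if (identical(key(segs[[j]][1, ]), key(tailp)))
        segs[[j]][2, ] else segs[[j]][1, ]
      path[[length(path) + 1]] <- nxt
    }
    pl <- do.call(rbind, path)
    lines[[length(lines) + 1]] <-
      sweep(pl * tree$h, 2, tree$domain$lower, `+`)
  }
  lines
}
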