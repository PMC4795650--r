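# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately share no code with the package
# internals beyond the public constructors.

# plain recursive Whitney splitter: returns a matrix (level, ix, iy[, iz])
brute_force_split <- function(domain, phi, max_level, lip) {
  d <- domain$dim
  h <- domain$spacing
  N <- 2^max_level
  out <- list()
  rec <- function(level, idx) {
    w <- 2^(max_level - level)
    pos <- idx * w
    corners <- as.matrix(expand.grid(rep(list(0:1), d)))
    pts <- t(t(corners) * w) + matrix(pos, nrow(corners), d, byrow = TRUE)
    vals <- phi(sweep(pts * h, 2, domain$lower, `+`))
    inside <- all(pos < domain$pixel_counts)
    split <- inside && level < max_level &&
      min(abs(vals)) <= 0.5 * lip * sqrt(d) * w * h
    if (!split) {
      out[[length(out) + 1]] <<- c(level, idx)
      return(invisible())
    }
    for (k in seq_len(nrow(corners))) rec(level + 1, 2 * idx + corners[k, ])
  }
  rec(0, rep(0, d))
  do.call(rbind, out)
}

# slow per-point multilinear evaluation: scan all leaves for containment
brute_force_interp <- function(field, pt) {
  tree <- field$tree
  pf <- (pt - tree$domain$lower) / tree$h
  pf <- pmin(pmax(pf, 0), tree$N)
  d <- tree$dim
  for (li in seq_len(nrow(tree$leaves))) {
    lo <- tree$leaf_pos[li, ]
    w <- tree$leaf_w[li]
    hi <- lo + w
    inside <- all(pf >= lo) &&
      all(pf < hi | (hi == tree$N & pf <= hi))
    if (!inside) next
    tloc <- (pf - lo) / w
    vals <- field$values[tree$corner_idx[li, ]]
    # corner order follows corner_bits: axis offsets in binary order
    bits <- as.matrix(expand.grid(rep(list(0:1), d)))[, d:1, drop = FALSE]
    wgt <- apply(bits, 1, function(b)
      prod(ifelse(b == 1, tloc, 1 - tloc)))
    return(sum(wgt * vals))
  }
  stop("point not located")
}

# exhaustive directional neighbour classification at one vertex
brute_force_neighbor <- function(tree, vi, axis, sgn) {
  v <- tree$verts[vi, ]
  d <- tree$dim
  N <- tree$N
  if ((sgn > 0 && v[axis] == N) || (sgn < 0 && v[axis] == 0))
    return(list(type = "boundary"))
  # leaves adjacent to v whose extent continues in the requested direction:
  # v lies on the leaf's closure and the leaf covers points just beyond v
  sizes <- c()
  for (li in seq_len(nrow(tree$leaves))) {
    lo <- tree$leaf_pos[li, ]
    w <- tree$leaf_w[li]
    hi <- lo + w
    if (!all(v >= lo & v <= hi)) next
    along <- if (sgn > 0) v[axis] >= lo[axis] && v[axis] < hi[axis] else
      v[axis] > lo[axis] && v[axis] <= hi[axis]
    if (along) sizes <- c(sizes, w)
  }
  s <- min(sizes)
  tgt <- v
  tgt[axis] <- tgt[axis] + sgn * s
  idx <- which(apply(tree$verts, 1, function(r) all(r == tgt)))
  if (length(idx) == 1)
    list(type = "neighbor", index = idx, distance = s * tree$h)
  else list(type = "tjunction", distance = s * tree$h)
}

# random graded tree over a given domain by random refinement
random_graded_tree <- function(domain, max_level, p_split = 0.5, seed = 1) {
  set.seed(seed)
  d <- domain$dim
  leaves <- matrix(0L, 1, 1 + d)
  repeat {
    cand <- leaves[, 1] < max_level
    if (!any(cand)) break
    split <- cand & (stats::runif(nrow(leaves)) < p_split)
    if (!any(split)) break
    leaves <- adaptivetrack:::split_leaves(leaves, split, d)
  }
  tr <- adaptivetrack:::finalize_tree(domain, leaves, max_level)
  enforce_grading(tr)
}

# exhaustive integer-lag cross correlation peak
xcorr_peak <- function(a, b, max_lag = 6) {
  best <- c(NA, NA); bestv <- -Inf
  am <- a - mean(a); bm <- b - mean(b)
  n <- nrow(a)
  for (dx in -max_lag:max_lag) for (dy in -max_lag:max_lag) {
    xs <- max(1, 1 + dx):min(n, n + dx)
    ys <- max(1, 1 + dy):min(n, n + dy)
    v <- sum(am[xs - dx, ys - dy] * bm[xs, ys])
    if (v > bestv) { bestv <- v; best <- c(dx, dy) }
  }
  best
}

# disk mask helper
disk_mask <- function(n, cx, cy, r) {
  outer(seq_len(n) - 0.5, seq_len(n) - 0.5,
        function(x, y) as.numeric((x - cx)^2 + (y - cy)^2 < r^2))
}

circle_sdf_fun <- function(cx, cy, r) {
  function(p) r - sqrt((p[, 1] - cx)^2 + (p[, 2] - cy)^2)
}
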