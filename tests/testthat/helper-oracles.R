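# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# squared Euclidean distance to the nearest set voxel, O(N * |set|)
brute_edt_squared <- function(mask) {
  dims <- dim(mask)
  set <- which(mask != 0, arr.ind = TRUE)
  out <- array(Inf, dim = dims)
  idx <- arrayInd(seq_len(prod(dims)), dims)
  for (k in seq_len(nrow(set))) {
    d2 <- (idx[, 1] - set[k, 1])^2 + (idx[, 2] - set[k, 2])^2 +
      (idx[, 3] - set[k, 3])^2
    out <- pmin(out, array(d2, dim = dims))
  }
  out
}

# AUC by exhaustive pair counting, ties worth one half
brute_auc <- function(values, labels) {
  pos <- values[as.logical(labels)]
  neg <- values[!as.logical(labels)]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# two-sided exact signed-rank p-value by enumeration of all sign
# assignments (distinct nonzero differences assumed)
brute_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  ev <- n * (n + 1) / 4
  p <- mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-9)
  min(1, p)
}

# trimmed means by explicit sort-and-slice with a hand-rolled type-7
# quantile (linear interpolation of order statistics)
brute_trimmed_means <- function(v, trim = 0.20) {
  q7 <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  qlo <- q7(v, trim)
  qhi <- q7(v, 1 - trim)
  high <- v[v > qlo]
  low <- v[v < qhi]
  list(mean_high = if (length(high)) mean(high) else mean(v),
       mean_low = if (length(low)) mean(low) else mean(v))
}

# connected component of a mask containing `start` (6-connectivity), by
# repeated masked dilation
flood_component <- function(mask, start) {
  comp <- array(FALSE, dim = dim(mask))
  comp[start[1], start[2], start[3]] <- TRUE
  repeat {
    grown <- comp
    grown[-1, , ] <- grown[-1, , ] | comp[-dim(mask)[1], , ]
    grown[-dim(mask)[1], , ] <- grown[-dim(mask)[1], , ] | comp[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | comp[, -dim(mask)[2], ]
    grown[, -dim(mask)[2], ] <- grown[, -dim(mask)[2], ] | comp[, -1, ]
    grown[, , -1] <- grown[, , -1] | comp[, , -dim(mask)[3]]
    grown[, , -dim(mask)[3]] <- grown[, , -dim(mask)[3]] | comp[, , -1]
    grown <- grown & (mask != 0)
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

# small helpers for fixture construction
mk_mask_grid <- function(arr) voxel_grid(arr * 1, kind = "binary_mask")
mk_map_grid <- function(arr, units = "") {
  voxel_grid(arr, kind = "parametric_map", units = units)
}

# a sphere mask inside an all-ones brain, handy for geometry tests
sphere_mask <- function(n, center, radius) {
  idx <- arrayInd(seq_len(n^3), c(n, n, n))
  d2 <- (idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2 +
    (idx[, 3] - center[3])^2
  array((d2 <= radius^2) * 1, dim = c(n, n, n))
}
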