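#' Construct a DSC time series
#'
#' Holds the raw dynamic susceptibility contrast signal S(x,y,z,t) together
#' with the acquisition parameters needed for the semi-quantitative rCBV
#' reconstruction: echo time TE, temporal spacing, and the pre-bolus window
#' used to estimate the baseline signal S0.
#'
#' @param signal 4D numeric array (x, y, z, t).
#' @param te_s echo time in seconds (default 0.029).
#' @param dt_s temporal spacing in seconds (default 1.8).
#' @param baseline_window integer indices of pre-bolus time points used for
#'   S0 (default the first five).
#' @return An object of class `dsc_series`.
#' @export
dsc_series <- function(signal, te_s = 0.029, dt_s = 1.8,
                       baseline_window = 1:5) {
  if (!is.array(signal) || length(dim(signal)) != 4L)
    stop("'signal' must be a 4D array (x, y, z, t)")
  nt <- dim(signal)[4]
  if (nt < 3L)
    stop("a DSC series needs at least 3 time points")
  if (!is.numeric(te_s) || te_s <= 0) stop("'te_s' must be positive")
  if (!is.numeric(dt_s) || dt_s <= 0) stop("'dt_s' must be positive")
  baseline_window <- as.integer(baseline_window)
  if (any(baseline_window < 1L) || any(baseline_window > nt))
    stop("'baseline_window' indices out of range")
  structure(
    list(signal = signal, te_s = te_s, dt_s = dt_s,
         n_timepoints = nt, baseline_window = baseline_window),
    class = "dsc_series"
  )
}

#' @export
print.dsc_series <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dsc_series> %dx%dx%d, %d time points, dt = %.3g s, TE = %.3g s\n",
              d[1], d[2], d[3], x$n_timepoints, x$dt_s, x$te_s))
  invisible(x)
}

#' Convert DSC signal to contrast-agent concentration
#'
#' Applies the standard spin-echo DSC model `C(t) = -(1/TE) * ln(S(t)/S0)`
#' voxel-wise inside the brain mask, with S0 the mean signal over the
#' pre-bolus baseline window. Concentration units are arbitrary
#' (proportional to delta-R2); only ratios of concentration integrals are
#' used downstream, so the scale cancels.
#'
#' Voxels inside the mask whose signal is not strictly positive at some time
#' point cannot be log-transformed; they are excluded (set to 0) and their
#' count is reported via a warning and the `"excluded_voxels"` attribute.
#'
#' @param series `dsc_series`.
#' @param brain_mask binary `voxel_grid` matching the series' spatial shape.
#' @return 4D concentration array with attribute `excluded_voxels`.
#' @export
signal_to_concentration <- function(series, brain_mask) {
  cm <- conc_matrix(series, brain_mask)
  conc <- cm$conc
  dim(conc) <- dim(series$signal)
  if (cm$excluded_voxels > 0L)
    warning(sprintf("%d in-mask voxels had non-positive signal and were excluded",
                    cm$excluded_voxels))
  attr(conc, "excluded_voxels") <- cm$excluded_voxels
  conc
}

# matrix-form core of the signal->concentration conversion: returns the
# (n_voxels x n_timepoints) concentration matrix, avoiding the 4D reshape
# when the caller works voxel-row-wise anyway
conc_matrix <- function(series, brain_mask) {
  if (!inherits(series, "dsc_series")) stop("'series' must be a dsc_series")
  if (!is_voxel_grid(brain_mask) || brain_mask$kind != "binary_mask")
    stop("'brain_mask' must be a binary_mask voxel_grid")
  d <- dim(series$signal)
  if (!identical(d[1:3], as.integer(brain_mask$shape)))
    stop("brain_mask shape does not match the DSC series")
  nvox <- prod(d[1:3]); nt <- d[4]
  sig <- series$signal
  dim(sig) <- c(nvox, nt)
  idx <- which(as.vector(brain_mask$data) != 0)
  sigm <- sig[idx, , drop = FALSE]

  s0 <- rowMeans(sigm[, series$baseline_window, drop = FALSE])
  if (any(s0 <= 0))
    stop(sprintf("baseline signal S0 is non-positive for %d in-mask voxels",
                 sum(s0 <= 0)))

  bad <- apply_min_over_time(sigm) <= 0
  conc <- matrix(0, nrow = nvox, ncol = nt)
  use <- idx[!bad]
  if (length(use))
    conc[use, ] <- -(1 / series$te_s) *
      log(sigm[!bad, , drop = FALSE] / s0[!bad])
  list(conc = conc, excluded_voxels = sum(bad))
}

# row-wise min over the time dimension, without apply()'s copying overhead
apply_min_over_time <- function(sig) {
  m <- sig[, 1L]
  nt <- ncol(sig)
  if (nt > 1L) for (j in 2:nt) m <- pmin(m, sig[, j])
  m
}

#' Gaussian smoothing of a 1D curve with reflection boundaries
#'
#' @param x numeric vector.
#' @param sigma kernel SD in samples.
#' @param radius kernel half-width (default `ceiling(4 * sigma)`).
#' @return Smoothed vector of the same length.
#' @export
gaussian_smooth1d <- function(x, sigma = 1, radius = ceiling(4 * sigma)) {
  if (sigma <= 0) return(x)
  k <- dnorm(seq(-radius, radius), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  # reflect-pad: scipy-style "reflect" (edge value not repeated twice would be
  # "mirror"; here the edge sample is included, matching ndimage's default)
  left <- x[pmin(n, radius:1)]
  right <- x[pmax(1, n:(n - radius + 1))]
  xp <- c(left, x, right)
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(radius + 1):(radius + n)])
}

#' Estimate the slice-wise arterial input function
#'
#' For one transverse slice of the concentration series, candidate vascular
#' voxels are those whose peak concentration reaches the 98th percentile of
#' in-mask voxel peaks (`P_top`); at least `min_candidates` voxels are
#' enforced by falling back to the voxels with the largest peaks. The AIF is
#' the per-time-point median over candidate curves, Gaussian-smoothed with
#' sigma = 1 time point (reflection boundaries).
#'
#' @param conc_slice 3D array (x, y, t): concentration curves of one slice.
#' @param mask_slice logical/0-1 matrix (x, y) of in-brain voxels.
#' @param min_candidates minimum number of candidate voxels (default 10).
#' @param percentile peak percentile defining `P_top` (default 98).
#' @param sigma_timepoints smoothing SD in time points (default 1).
#' @return An object of class `aif_curve` with fields `concentration`,
#'   `candidate_count`, `p_top_value`, `smoothing_sigma_timepoints`, or
#'   `NULL` when the slice has fewer in-mask voxels than `min_candidates`.
#' @export
estimate_slice_aif <- function(conc_slice, mask_slice, min_candidates = 10,
                               percentile = 98, sigma_timepoints = 1) {
  d <- dim(conc_slice)
  if (length(d) != 3L) stop("'conc_slice' must be a 3D array (x, y, t)")
  inmask <- which(as.vector(mask_slice) != 0)
  if (length(inmask) < min_candidates) return(NULL)
  nt <- d[3]
  curves <- matrix(conc_slice, nrow = d[1] * d[2], ncol = nt)[inmask, ,
                                                              drop = FALSE]
  peaks <- apply_max_over_time(curves)
  p_top <- as.numeric(quantile(peaks, percentile / 100, names = FALSE))
  cand <- which(peaks >= p_top)
  if (length(cand) < min_candidates)
    cand <- order(peaks, decreasing = TRUE)[seq_len(min_candidates)]
  aif <- apply(curves[cand, , drop = FALSE], 2, median)
  aif <- gaussian_smooth1d(aif, sigma = sigma_timepoints)
  structure(
    list(concentration = aif, candidate_count = length(cand),
         p_top_value = p_top, smoothing_sigma_timepoints = sigma_timepoints),
    class = "aif_curve"
  )
}

apply_max_over_time <- function(curves) {
  m <- curves[, 1L]
  nt <- ncol(curves)
  if (nt > 1L) for (j in 2:nt) m <- pmax(m, curves[, j])
  m
}

# trapezoidal quadrature weights for a uniform grid
trapezoid_weights <- function(n, dt) {
  w <- rep(dt, n)
  w[c(1L, n)] <- dt / 2
  w
}

#' Compute the semi-quantitative rCBV map
#'
#' Converts the DSC signal to concentration, estimates a slice-wise AIF, and
#' returns voxel-wise `rCBV = integral(C) / integral(AIF)` with trapezoidal
#' integration over the full acquisition. Slices with too few in-mask voxels
#' for AIF estimation borrow the nearest valid slice's AIF (logged via
#' `message`); slices whose AIF integral is not positive are excluded with a
#' warning (rCBV set to 0). Negative concentrations are kept in the integral
#' unless `clamp_negative = TRUE`.
#'
#' @param series `dsc_series`.
#' @param brain_mask binary `voxel_grid`.
#' @param min_candidates,percentile,sigma_timepoints AIF parameters, see
#'   [estimate_slice_aif()].
#' @param clamp_negative clamp negative concentrations to 0 before
#'   integration (default `FALSE`).
#' @return An object of class `rcbv_map`: list with `grid` (the rCBV
#'   `voxel_grid`), `per_slice_aifs` (list of `aif_curve` or `NULL`), and
#'   `aif_source_slice` (which slice's AIF each slice used).
#' @export
compute_rcbv_map <- function(series, brain_mask, min_candidates = 10,
                             percentile = 98, sigma_timepoints = 1,
                             clamp_negative = FALSE) {
  cm <- conc_matrix(series, brain_mask)
  if (cm$excluded_voxels > 0L)
    warning(sprintf("%d in-mask voxels had non-positive signal and were excluded",
                    cm$excluded_voxels))
  conc_mat <- cm$conc
  d <- dim(series$signal)
  nx <- d[1]; ny <- d[2]; nz <- d[3]; nt <- d[4]
  nxy <- nx * ny
  if (clamp_negative) conc_mat[conc_mat < 0] <- 0

  aifs <- vector("list", nz)
  for (z in seq_len(nz)) {
    sl <- conc_mat[((z - 1) * nxy + 1):(z * nxy), , drop = FALSE]
    dim(sl) <- c(nx, ny, nt)
    # single-bracket assignment: a NULL AIF must keep its slot in the list
    aifs[z] <- list(estimate_slice_aif(sl, brain_mask$data[, , z],
                                       min_candidates = min_candidates,
                                       percentile = percentile,
                                       sigma_timepoints = sigma_timepoints))
  }
  valid <- which(!vapply(aifs, is.null, logical(1)))
  if (length(valid) == 0L)
    stop("no slice has enough in-mask voxels for AIF estimation")
  source_slice <- vapply(seq_len(nz), function(z) {
    if (!is.null(aifs[[z]])) z else valid[which.min(abs(valid - z))]
  }, integer(1))
  n_borrowed <- sum(source_slice != seq_len(nz) & vapply(
    seq_len(nz), function(z) any(brain_mask$data[, , z] != 0), logical(1)))
  if (n_borrowed > 0L)
    message(sprintf("%d slices borrowed the AIF of the nearest valid slice",
                    n_borrowed))

  w <- trapezoid_weights(nt, series$dt_s)
  vox_int <- as.vector(conc_mat %*% w)
  dim(vox_int) <- c(nx, ny, nz)

  rcbv <- array(0, dim = c(nx, ny, nz))
  for (z in seq_len(nz)) {
    aif <- aifs[[source_slice[z]]]
    aif_int <- sum(aif$concentration * w)
    msk <- brain_mask$data[, , z] != 0
    if (!any(msk)) next
    if (aif_int <= 0) {
      warning(sprintf("slice %d excluded: AIF integral is not positive", z))
      next
    }
    sl <- rcbv[, , z]
    sl[msk] <- vox_int[, , z][msk] / aif_int
    rcbv[, , z] <- sl
  }
  structure(
    list(grid = grid_like(rcbv, brain_mask, kind = "parametric_map",
                          units = ""),
         per_slice_aifs = aifs,
         aif_source_slice = source_slice),
    class = "rcbv_map"
  )
}

#' @export
print.rcbv_map <- function(x, ...) {
  nz <- length(x$per_slice_aifs)
  nv <- sum(!vapply(x$per_slice_aifs, is.null, logical(1)))
  cat(sprintf("<rcbv_map> %s; AIF estimated on %d/%d slices\n",
              paste(x$grid$shape, collapse = "x"), nv, nz))
  invisible(x)
}
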