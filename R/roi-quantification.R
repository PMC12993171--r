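#' Cohort-level histogram reference for map normalization
#'
#' For each case, two within-brain percentile values (defaults: 1st and
#' 99th) anchor the case's cumulative intensity histogram; the reference is
#' the across-case mean of those anchors. Normalizing every case's map onto
#' this common range removes global acquisition-scale differences while
#' preserving within-case contrast.
#'
#' @param maps list of `voxel_grid` parametric maps (one per case).
#' @param brain_masks list of binary `voxel_grid` masks, parallel to `maps`.
#' @param percentiles length-2 percentile pair in (0, 100), default
#'   `c(1, 99)`.
#' @return An object of class `cohort_reference` with `low_anchor`,
#'   `high_anchor`, `percentiles`, `n_cases`.
#' @export
compute_cohort_reference <- function(maps, brain_masks,
                                     percentiles = c(1, 99)) {
  if (length(maps) < 1L) stop("need at least one case")
  if (length(maps) != length(brain_masks))
    stop("'maps' and 'brain_masks' must have equal length")
  if (percentiles[2] <= percentiles[1])
    stop("'percentiles' must be increasing")
  anchors <- t(vapply(seq_along(maps), function(i) {
    vals <- maps[[i]]$data[brain_masks[[i]]$data != 0]
    if (length(vals) == 0L) {
      warning(sprintf("case %d skipped: empty brain mask", i))
      return(c(NA_real_, NA_real_))
    }
    quantile(vals, percentiles / 100, names = FALSE)
  }, numeric(2)))
  keep <- stats::complete.cases(anchors)
  if (!any(keep)) stop("no case with a non-empty brain mask")
  ref <- colMeans(anchors[keep, , drop = FALSE])
  if (ref[2] <= ref[1]) stop("degenerate reference: high anchor <= low anchor")
  structure(list(low_anchor = ref[1], high_anchor = ref[2],
                 percentiles = percentiles, n_cases = sum(keep)),
            class = "cohort_reference")
}

# the per-case affine (a, b) mapping the case's percentile values onto the
# reference anchors; shared between map- and statistics-level normalization
normalization_affine <- function(values, ref) {
  q <- quantile(values, ref$percentiles / 100, names = FALSE)
  spread <- q[2] - q[1]
  if (!is.finite(spread) || spread <= 0)
    stop("cannot normalize a map with zero percentile spread")
  a <- (ref$high_anchor - ref$low_anchor) / spread
  b <- ref$low_anchor - a * q[1]
  c(a = a, b = b)
}

#' Normalize a map onto a cohort reference range
#'
#' Applies the increasing affine transform that maps the case's own
#' within-brain percentile values onto the reference anchors. Only in-brain
#' voxels are transformed; background stays 0. Being strictly monotone, the
#' transform preserves within-case value ordering.
#'
#' @param map `voxel_grid` parametric map.
#' @param brain_mask binary `voxel_grid`.
#' @param ref `cohort_reference`.
#' @return Normalized `voxel_grid`.
#' @export
normalize_map <- function(map, brain_mask, ref) {
  if (!inherits(ref, "cohort_reference"))
    stop("'ref' must be a cohort_reference")
  stopifnot_same_grid(map, brain_mask)
  inb <- brain_mask$data != 0
  ab <- normalization_affine(map$data[inb], ref)
  out <- map$data
  out[inb] <- ab["a"] * out[inb] + ab["b"]
  grid_like(out, map)
}

#' Per-ROI statistics with percentile trimming
#'
#' Mean and SD over in-ROI voxels, plus two trimmed means: `mean_high`
#' averages the voxels strictly above the ROI's 20th-percentile value
#' (lowest tail excluded) and `mean_low` those strictly below the
#' 80th-percentile value (highest tail excluded). Percentiles use the
#' linear-interpolation convention; values tied with the cut are excluded
#' together with the trimmed tail. For a constant ROI both trimmed means
#' equal the mean. An empty ROI yields undefined (NA) statistics, flagged
#' via `undefined`, never zeros.
#'
#' @param map `voxel_grid` parametric map.
#' @param roi_mask binary `voxel_grid`.
#' @param trim trimmed tail fraction in (0, 0.5), default 0.20.
#' @return An object of class `roi_stats`: `n_voxels`, `mean`, `sd`,
#'   `mean_low`, `mean_high`, `undefined`.
#' @export
roi_statistics <- function(map, roi_mask, trim = 0.20) {
  stopifnot_same_grid(map, roi_mask)
  if (!is.numeric(trim) || trim <= 0 || trim >= 0.5)
    stop("'trim' must be in (0, 0.5)")
  vals <- map$data[roi_mask$data != 0]
  n <- length(vals)
  if (n == 0L)
    return(structure(list(n_voxels = 0L, mean = NA_real_, sd = NA_real_,
                          mean_low = NA_real_, mean_high = NA_real_,
                          undefined = TRUE), class = "roi_stats"))
  qlo <- quantile(vals, trim, names = FALSE)
  qhi <- quantile(vals, 1 - trim, names = FALSE)
  high <- vals[vals > qlo]
  low <- vals[vals < qhi]
  structure(list(
    n_voxels = n,
    mean = mean(vals),
    sd = if (n > 1L) sd(vals) else 0,
    mean_low = if (length(low)) mean(low) else mean(vals),
    mean_high = if (length(high)) mean(high) else mean(vals),
    undefined = FALSE
  ), class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  if (x$undefined) {
    cat("<roi_stats> empty ROI (undefined)\n")
  } else {
    cat(sprintf("<roi_stats> n=%d mean=%.4g sd=%.4g mean_low=%.4g mean_high=%.4g\n",
                x$n_voxels, x$mean, x$sd, x$mean_low, x$mean_high))
  }
  invisible(x)
}

#' Percent difference of a recurrence-prone value versus a stable value
#'
#' `100 * (value_pos - value_neg) / value_neg`: the relative change of a
#' measure in the recurrence-prone compartment compared with the stable
#' compartment. Conventionally reported to one decimal.
#'
#' @param value_pos,value_neg numeric scalars; `value_neg` must be nonzero.
#' @return Percent difference (unrounded).
#' @export
percent_difference <- function(value_pos, value_neg) {
  if (!is.finite(value_neg) || value_neg == 0)
    stop("'value_neg' must be finite and nonzero")
  100 * (value_pos - value_neg) / value_neg
}
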