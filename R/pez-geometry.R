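#' Squared Euclidean distance to a voxel set
#'
#' Exact separable distance transform in voxel units: for every voxel the
#' squared Euclidean distance to the nearest set voxel of `mask` (0 inside
#' the set). On the 1 mm isotropic working grid voxel units equal mm.
#'
#' @param mask binary `voxel_grid` or 3D 0/1 array.
#' @return 3D array of squared distances.
#' @export
distance_squared_to_mask <- function(mask) {
  data <- if (is_voxel_grid(mask)) mask$data else mask
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'mask' must be a 3D array or voxel_grid")
  if (!any(data != 0)) stop("'mask' is empty")
  .edt_squared_cpp(as.vector(data != 0), as.integer(dim(data)))
}

#' Build the peri-enhancing rim around the tumor core
#'
#' The peri-enhancing zone (PEZ) is the set of brain voxels whose Euclidean
#' distance to the contrast-enhancing core is positive and at most
#' `width_voxels` (default 5): a 5-voxel margin surrounding the 3D core
#' surface, excluding the core itself, clipped to the brain mask and the
#' grid bounds.
#'
#' @param core_mask binary `voxel_grid`, non-empty, inside `brain_mask`.
#' @param brain_mask binary `voxel_grid`.
#' @param width_voxels rim width in voxels (default 5).
#' @return Binary `voxel_grid` of the rim.
#' @export
build_pez <- function(core_mask, brain_mask, width_voxels = 5) {
  if (!is_voxel_grid(core_mask) || core_mask$kind != "binary_mask")
    stop("'core_mask' must be a binary_mask voxel_grid")
  if (!is_voxel_grid(brain_mask) || brain_mask$kind != "binary_mask")
    stop("'brain_mask' must be a binary_mask voxel_grid")
  stopifnot_same_grid(core_mask, brain_mask)
  if (!any(core_mask$data != 0)) stop("'core_mask' is empty")
  if (!is.numeric(width_voxels) || width_voxels < 1)
    stop("'width_voxels' must be >= 1")
  d2 <- distance_squared_to_mask(core_mask)
  rim <- (d2 > 0 & d2 <= width_voxels^2 & brain_mask$data != 0) * 1
  grid_like(rim, core_mask, kind = "binary_mask", units = "")
}

#' Exclude fluid voxels from the rim by ADC threshold
#'
#' Removes rim voxels whose ADC is at or above `threshold` — ventricles and
#' cortical sulci reach ADC values near free water (~3000 x 1e-6 mm^2/s) and
#' would contaminate parenchymal statistics.
#'
#' @param pez_mask binary `voxel_grid`.
#' @param adc ADC map (`voxel_grid`).
#' @param threshold ADC threshold in 1e-6 mm^2/s (> 0).
#' @return List with `cleaned` and `excluded` binary grids
#'   (`cleaned | excluded == pez_mask`).
#' @export
exclude_fluid <- function(pez_mask, adc, threshold) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("'threshold' must be positive")
  stopifnot_same_grid(pez_mask, adc)
  inpez <- pez_mask$data != 0
  fluid <- inpez & adc$data >= threshold
  cleaned <- grid_like((inpez & !fluid) * 1, pez_mask, kind = "binary_mask")
  excluded <- grid_like(fluid * 1, pez_mask, kind = "binary_mask")
  list(cleaned = cleaned, excluded = excluded)
}

#' Suggest a per-case fluid-exclusion ADC threshold
#'
#' Automates the histogram inspection used to pick the fluid cut-off: the
#' smoothed density of in-rim ADC values is scanned for its parenchymal mode
#' (below `fluid_min`) and any fluid mode (at or above `fluid_min`, i.e.
#' CSF-like values); the suggestion is the deepest valley between them. If
#' the histogram is unimodal (no fluid mode), the default of 2000 x 1e-6
#' mm^2/s is returned.
#'
#' @param adc ADC map (`voxel_grid`).
#' @param pez_mask binary `voxel_grid`, non-empty.
#' @param fluid_min lowest ADC considered fluid-like (default 2000).
#' @param default fallback threshold for unimodal histograms (default 2000).
#' @return Suggested threshold in 1e-6 mm^2/s.
#' @export
suggest_fluid_threshold <- function(adc, pez_mask, fluid_min = 2000,
                                    default = 2000) {
  stopifnot_same_grid(adc, pez_mask)
  vals <- adc$data[pez_mask$data != 0]
  if (length(vals) == 0L) stop("'pez_mask' is empty")
  if (length(unique(vals)) < 2L) return(default)
  dens <- density(vals, n = 512)
  y <- dens$y; x <- dens$x
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
               FALSE)
  peaks <- which(is_peak)
  par_peaks <- peaks[x[peaks] < fluid_min]
  fluid_peaks <- peaks[x[peaks] >= fluid_min]
  if (length(par_peaks) == 0L || length(fluid_peaks) == 0L) return(default)
  p1 <- par_peaks[which.max(y[par_peaks])]
  p2 <- fluid_peaks[which.max(y[fluid_peaks])]
  between <- (p1 + 1):(p2 - 1)
  if (length(between) == 0L) return(default)
  x[between[which.min(y[between])]]
}

#' Partition the rim into the four analytical compartments
#'
#' Splits the (fluid-cleaned) peri-enhancing rim by the 2x2 membership
#' (inside/outside the FLAIR-hyperintense region) x (overlapping/not
#' overlapping the follow-up recurrence mapped to baseline): T1+ voxels are
#' recurrence-prone tissue, T1- voxels remain stable. Any overlap with the
#' recurrence mask counts as T1+ (voxel-wise overlap, no minimum fraction).
#'
#' @param pez_mask binary `voxel_grid` (after fluid exclusion).
#' @param flair_mask binary `voxel_grid`.
#' @param recurrence_mask binary `voxel_grid`.
#' @param excluded_fluid optional binary `voxel_grid` carried along for
#'   reporting.
#' @param width_voxels,adc_fluid_threshold metadata recorded on the object.
#' @return An object of class `pez_partition` with the four disjoint
#'   compartment masks `t1pos_flairpos`, `t1neg_flairpos`, `t1pos_flairneg`,
#'   `t1neg_flairneg`, whose union is exactly `pez_mask`.
#' @export
partition_pez <- function(pez_mask, flair_mask, recurrence_mask,
                          excluded_fluid = NULL, width_voxels = NA,
                          adc_fluid_threshold = NA) {
  stopifnot_same_grid(pez_mask, flair_mask, recurrence_mask)
  inpez <- pez_mask$data != 0
  f <- flair_mask$data != 0
  r <- recurrence_mask$data != 0
  mk <- function(sel) grid_like((inpez & sel) * 1, pez_mask,
                                kind = "binary_mask")
  structure(
    list(pez_mask = pez_mask,
         t1pos_flairpos = mk(f & r),
         t1neg_flairpos = mk(f & !r),
         t1pos_flairneg = mk(!f & r),
         t1neg_flairneg = mk(!f & !r),
         excluded_fluid = excluded_fluid,
         width_voxels = width_voxels,
         adc_fluid_threshold = adc_fluid_threshold),
    class = "pez_partition"
  )
}

#' @export
print.pez_partition <- function(x, ...) {
  cat("<pez_partition>\n")
  for (nm in c("t1pos_flairpos", "t1neg_flairpos", "t1pos_flairneg",
               "t1neg_flairneg"))
    cat(sprintf("  %-15s %7.0f mm^3\n", nm, mask_volume_mm3(x[[nm]])))
  if (!is.null(x$excluded_fluid))
    cat(sprintf("  excluded fluid  %7.0f mm^3\n",
                mask_volume_mm3(x$excluded_fluid)))
  invisible(x)
}

# the four compartment labels, in reporting order
pez_compartments <- c("t1pos_flairpos", "t1neg_flairpos",
                      "t1pos_flairneg", "t1neg_flairneg")
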