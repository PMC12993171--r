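#' @useDynLib pezmap, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median quantile rnorm sd density cor.test wilcox.test
#'   pnorm dnorm
#' @importFrom utils write.csv
NULL

#' Construct a 3D voxel grid
#'
#' The common container for all volumetric data in the package: parametric
#' maps (ADC in 1e-6 mm^2/s, unitless rCBV) and binary masks share this
#' representation. Geometry is carried as a per-axis voxel spacing; all
#' internal analysis operates in voxel space on a 1 mm isotropic working
#' grid, so voxel distances and millimetres coincide.
#'
#' @param data 3D numeric array.
#' @param spacing_mm numeric length-3, voxel size per axis in mm (all > 0).
#' @param kind `"parametric_map"` or `"binary_mask"`. Binary masks may only
#'   contain the values 0 and 1.
#' @param units free-text unit string (e.g. `"1e-6 mm^2/s"` for ADC, `""`
#'   for rCBV and masks).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing_mm = c(1, 1, 1),
                       kind = c("parametric_map", "binary_mask"),
                       units = "") {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (length(data) == 0L)
    stop("'data' must be non-empty")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("'spacing_mm' must be three strictly positive values")
  if (kind == "binary_mask") {
    if (is.logical(data)) {
      storage.mode(data) <- "double"
    }
    if (any(data != 0 & data != 1))
      stop("binary_mask grids may only contain values 0 and 1")
  }
  structure(
    list(data = data, spacing_mm = spacing_mm, shape = dim(data),
         kind = kind, units = units),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %s> %s, spacing %s mm%s\n", x$kind,
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              if (nzchar(x$units)) paste0(", units ", x$units) else ""))
  if (x$kind == "binary_mask")
    cat(sprintf("  %d voxels set (%.0f mm^3)\n", sum(x$data),
                sum(x$data) * prod(x$spacing_mm)))
  invisible(x)
}

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

stopifnot_same_grid <- function(...) {
  grids <- list(...)
  ref <- grids[[1L]]
  for (g in grids[-1L]) {
    if (!identical(g$shape, ref$shape))
      stop("grids do not share the same shape")
    if (max(abs(g$spacing_mm - ref$spacing_mm)) > 1e-9)
      stop("grids do not share the same spacing")
  }
  invisible(TRUE)
}

#' Bundle the co-registered volumes of one case
#'
#' @param adc ADC map (`voxel_grid`, parametric_map).
#' @param dsc `dsc_series` or `NULL` when only diffusion is analysed.
#' @param core_mask binary mask of the contrast-enhancing tumor core
#'   including its necrotic interior (the gross total tumor).
#' @param flair_mask binary mask of the FLAIR-hyperintense region.
#' @param recurrence_mask binary mask of follow-up abnormal enhancement
#'   mapped into baseline space (may be empty).
#' @param brain_mask binary brain mask.
#' @param case_id character identifier.
#' @return An object of class `case_volumes`.
#' @export
case_volumes <- function(adc, dsc = NULL, core_mask, flair_mask,
                         recurrence_mask, brain_mask, case_id = "case") {
  for (g in list(adc, core_mask, flair_mask, recurrence_mask, brain_mask))
    if (!is_voxel_grid(g)) stop("all volume members must be voxel_grid objects")
  stopifnot_same_grid(adc, core_mask, flair_mask, recurrence_mask, brain_mask)
  for (nm in c("core_mask", "flair_mask", "recurrence_mask", "brain_mask")) {
    g <- get(nm)
    if (g$kind != "binary_mask")
      stop(sprintf("'%s' must be a binary_mask grid", nm))
  }
  if (any(core_mask$data > brain_mask$data))
    stop("core_mask must lie inside brain_mask")
  if (!is.null(dsc)) {
    if (!inherits(dsc, "dsc_series")) stop("'dsc' must be a dsc_series")
    if (!identical(dim(dsc$signal)[1:3], adc$shape))
      stop("DSC series spatial shape must match the other volumes")
  }
  structure(
    list(adc = adc, dsc = dsc, core_mask = core_mask, flair_mask = flair_mask,
         recurrence_mask = recurrence_mask, brain_mask = brain_mask,
         case_id = as.character(case_id)),
    class = "case_volumes"
  )
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file (.nii or .nii.gz), 3D.
#' @param kind,units passed to [voxel_grid()].
#' @return A `voxel_grid`.
#' @export
read_volume <- function(path, kind = "parametric_map", units = "") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1L, drop = TRUE]
  arr <- array(as.numeric(arr), dim = dim(arr))  # strip image attributes
  sp <- RNifti::pixdim(img)[1:3]
  voxel_grid(arr, spacing_mm = sp, kind = kind, units = units)
}

#' Write a volume to NIfTI
#'
#' @param grid `voxel_grid`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  if (!is_voxel_grid(grid)) stop("'grid' must be a voxel_grid")
  img <- RNifti::asNifti(grid$data, pixdim = grid$spacing_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a case from a manifest file
#'
#' The manifest is a JSON object mapping role names to NIfTI paths
#' (relative paths are resolved against the manifest's directory). Required
#' roles: `adc`, `core_mask`, `flair_mask`, `recurrence_mask`, `brain_mask`;
#' `dsc` is optional. Optional scalar fields `case_id`, `te_s`, `dt_s`,
#' `baseline_window` parameterise the DSC series.
#'
#' @param path manifest JSON file.
#' @return A `case_volumes` object.
#' @export
read_case_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(normalizePath(path))
  need <- c("adc", "core_mask", "flair_mask", "recurrence_mask", "brain_mask")
  for (role in need)
    if (is.null(man[[role]]))
      stop(sprintf("manifest is missing required role '%s'", role))
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)
  adc <- read_volume(resolve(man$adc), kind = "parametric_map",
                     units = "1e-6 mm^2/s")
  rd_mask <- function(role) {
    g <- read_volume(resolve(man[[role]]), kind = "parametric_map")
    g$data <- (g$data != 0) * 1
    g$kind <- "binary_mask"
    g
  }
  dsc <- NULL
  if (!is.null(man$dsc)) {
    img <- RNifti::readNifti(resolve(man$dsc))
    arr <- as.array(img)
    if (length(dim(arr)) != 4L) stop("DSC series must be a 4D NIfTI")
    arr <- array(as.numeric(arr), dim = dim(arr))
    dsc <- dsc_series(arr,
                      te_s = if (is.null(man$te_s)) 0.029 else man$te_s,
                      dt_s = if (is.null(man$dt_s)) 1.8 else man$dt_s,
                      baseline_window = if (is.null(man$baseline_window)) 1:5
                                        else man$baseline_window)
  }
  case_volumes(adc = adc, dsc = dsc,
               core_mask = rd_mask("core_mask"),
               flair_mask = rd_mask("flair_mask"),
               recurrence_mask = rd_mask("recurrence_mask"),
               brain_mask = rd_mask("brain_mask"),
               case_id = if (is.null(man$case_id)) basename(dir) else man$case_id)
}

#' Write a case to disk as NIfTI volumes plus a JSON manifest
#'
#' @param case `case_volumes` (e.g. from [generate_case()]).
#' @param dir output directory (created if needed).
#' @return Path to the manifest file, invisibly.
#' @export
write_case <- function(case, dir) {
  if (!inherits(case, "case_volumes")) stop("'case' must be case_volumes")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  roles <- c("adc", "core_mask", "flair_mask", "recurrence_mask", "brain_mask")
  man <- list(case_id = case$case_id)
  for (role in roles) {
    f <- paste0(role, ".nii.gz")
    write_volume(case[[role]], file.path(dir, f))
    man[[role]] <- f
  }
  if (!is.null(case$dsc)) {
    f <- "dsc.nii.gz"
    img <- RNifti::asNifti(case$dsc$signal,
                           pixdim = c(case$adc$spacing_mm, case$dsc$dt_s))
    RNifti::writeNifti(img, file.path(dir, f))
    man$dsc <- f
    man$te_s <- case$dsc$te_s
    man$dt_s <- case$dsc$dt_s
    man$baseline_window <- case$dsc$baseline_window
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Resample a grid to a target isotropic geometry
#'
#' Parametric maps are interpolated trilinearly; binary masks use
#' nearest-neighbour so values remain in `{0, 1}`. Voxel `i` (0-based) is
#' taken to sit at world position `i * spacing`, with a shared origin at the
#' first voxel centre; positions falling outside the input field of view are
#' filled with 0 (background-neutral for maps and masks alike).
#'
#' @param grid `voxel_grid`.
#' @param target_spacing numeric scalar or length-3, mm (default 1 mm
#'   isotropic).
#' @param target_shape integer length-3; default: input extent in mm rounded
#'   to the nearest voxel.
#' @return A `voxel_grid` with the requested geometry.
#' @export
resample_isotropic <- function(grid, target_spacing = 1,
                               target_shape = NULL) {
  if (!is_voxel_grid(grid)) stop("'grid' must be a voxel_grid")
  target_spacing <- rep_len(as.numeric(target_spacing), 3L)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0))
    stop("'target_spacing' must be strictly positive")
  if (is.null(target_shape))
    target_shape <- pmax(1L, as.integer(round(
      grid$shape * grid$spacing_mm / target_spacing)))
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 1L))
    stop("'target_shape' must be three positive integers")

  if (identical(target_shape, as.integer(grid$shape)) &&
      max(abs(target_spacing - grid$spacing_mm)) < 1e-12)
    return(grid)

  # input-space (0-based, fractional) coordinate of each output voxel centre
  coord <- function(ax) (seq_len(target_shape[ax]) - 1) *
    target_spacing[ax] / grid$spacing_mm[ax]
  cx <- coord(1); cy <- coord(2); cz <- coord(3)
  nin <- grid$shape
  out <- array(0, dim = target_shape)

  if (grid$kind == "binary_mask") {
    ix <- round(cx) + 1L; iy <- round(cy) + 1L; iz <- round(cz) + 1L
    okx <- ix >= 1L & ix <= nin[1]
    oky <- iy >= 1L & iy <= nin[2]
    okz <- iz >= 1L & iz <= nin[3]
    out[okx, oky, okz] <- grid$data[ix[okx], iy[oky], iz[okz]]
  } else {
    # trilinear, separable gather
    lo <- function(c, n) pmin(pmax(floor(c), 0), n - 1)
    fx0 <- lo(cx, nin[1]); fy0 <- lo(cy, nin[2]); fz0 <- lo(cz, nin[3])
    wx <- cx - fx0; wy <- cy - fy0; wz <- cz - fz0
    okx <- cx >= 0 & cx <= nin[1] - 1
    oky <- cy >= 0 & cy <= nin[2] - 1
    okz <- cz >= 0 & cz <= nin[3] - 1
    i0x <- fx0 + 1L; i1x <- pmin(fx0 + 2L, nin[1])
    i0y <- fy0 + 1L; i1y <- pmin(fy0 + 2L, nin[2])
    i0z <- fz0 + 1L; i1z <- pmin(fz0 + 2L, nin[3])
    acc <- array(0, dim = target_shape)
    for (bx in 0:1) for (by in 0:1) for (bz in 0:1) {
      ixs <- if (bx == 0) i0x else i1x
      iys <- if (by == 0) i0y else i1y
      izs <- if (bz == 0) i0z else i1z
      wxs <- if (bx == 0) 1 - wx else wx
      wys <- if (by == 0) 1 - wy else wy
      wzs <- if (bz == 0) 1 - wz else wz
      w <- outer(outer(wxs, wys), wzs)
      acc <- acc + grid$data[ixs, iys, izs, drop = FALSE] * w
    }
    mask_ok <- outer(outer(okx, oky), okz) > 0
    out[mask_ok] <- acc[mask_ok]
  }
  voxel_grid(out, spacing_mm = target_spacing, kind = grid$kind,
             units = grid$units)
}

#' Mask volume by voxel counting
#'
#' Returns the number of set voxels times the voxel volume. On the 1 mm
#' isotropic working grid each voxel is exactly 1 mm^3, so volumes are voxel
#' counts.
#'
#' @param mask binary `voxel_grid`.
#' @return Volume in mm^3.
#' @export
mask_volume_mm3 <- function(mask) {
  if (!is_voxel_grid(mask) || mask$kind != "binary_mask")
    stop("'mask' must be a binary_mask voxel_grid")
  sum(mask$data) * prod(mask$spacing_mm)
}

# internal: new grid sharing geometry with `like`
grid_like <- function(data, like, kind = like$kind, units = like$units) {
  voxel_grid(data, spacing_mm = like$spacing_mm, kind = kind, units = units)
}
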