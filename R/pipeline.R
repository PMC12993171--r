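#' Pipeline configuration
#'
#' Consolidates every tunable analysis parameter so that nothing is hidden:
#' rim width, fluid-threshold policy, normalization anchors, trim fraction,
#' test mode, AIF settings.
#'
#' @param pez_width_voxels rim width (default 5).
#' @param fluid_threshold `"auto"` (per-case histogram suggestion, see
#'   [suggest_fluid_threshold()]) or a fixed numeric value in 1e-6 mm^2/s.
#' @param normalization_percentiles anchors for cohort normalization
#'   (default `c(1, 99)`).
#' @param normalize_adc,normalize_rcbv apply cohort normalization per
#'   modality (both default `TRUE`).
#' @param trim_fraction trimmed tail fraction in (0, 0.5), default 0.20.
#' @param test_mode `"signed_rank"` (paired, default) or `"rank_sum"`.
#' @param roc_region FLAIR region whose per-case compartment means feed the
#'   ROC analysis (default `"flairpos"`).
#' @param min_aif_candidates,aif_percentile,aif_sigma AIF estimation
#'   parameters (defaults 10, 98, 1).
#' @param clamp_negative clamp negative concentrations before integration
#'   (default `FALSE`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(pez_width_voxels = 5,
                            fluid_threshold = "auto",
                            normalization_percentiles = c(1, 99),
                            normalize_adc = TRUE,
                            normalize_rcbv = TRUE,
                            trim_fraction = 0.20,
                            test_mode = c("signed_rank", "rank_sum"),
                            roc_region = c("flairpos", "flairneg"),
                            min_aif_candidates = 10,
                            aif_percentile = 98,
                            aif_sigma = 1,
                            clamp_negative = FALSE) {
  test_mode <- match.arg(test_mode)
  roc_region <- match.arg(roc_region)
  if (!is.numeric(trim_fraction) || trim_fraction <= 0 ||
      trim_fraction >= 0.5)
    stop("'trim_fraction' must be in (0, 0.5)")
  if (!(identical(fluid_threshold, "auto") ||
        (is.numeric(fluid_threshold) && fluid_threshold > 0)))
    stop("'fluid_threshold' must be \"auto\" or a positive number")
  if (pez_width_voxels < 1) stop("'pez_width_voxels' must be >= 1")
  structure(
    list(pez_width_voxels = pez_width_voxels,
         fluid_threshold = fluid_threshold,
         normalization_percentiles = normalization_percentiles,
         normalize_adc = normalize_adc,
         normalize_rcbv = normalize_rcbv,
         trim_fraction = trim_fraction,
         test_mode = test_mode,
         roc_region = roc_region,
         min_aif_candidates = min_aif_candidates,
         aif_percentile = aif_percentile,
         aif_sigma = aif_sigma,
         clamp_negative = clamp_negative),
    class = "pipeline_config"
  )
}

#' Analyze a single case
#'
#' Runs the per-case chain: rCBV reconstruction (when a DSC series is
#' present), rim construction around the core, per-case fluid exclusion by
#' ADC threshold, partition into the four compartments, and trimmed ROI
#' statistics per compartment and modality. Deterministic given inputs and
#' configuration.
#'
#' @param volumes `case_volumes` (or `phantom_case`).
#' @param config `pipeline_config`.
#' @param out_dir optional directory; when given, the compartment masks,
#'   excluded-fluid mask, rCBV map and the statistics CSV are written there.
#' @return List with `stats` (data.frame: one row per compartment x
#'   modality with `n_voxels`, `volume_mm3`, `mean`, `sd`, `mean_low`,
#'   `mean_high`, `undefined`), `partition` (`pez_partition`),
#'   `fluid_threshold`, `rcbv` (`rcbv_map` or `NULL`), and
#'   `brain_percentiles` (per-modality within-brain anchor values, used for
#'   cohort normalization).
#' @export
analyze_case <- function(volumes, config = pipeline_config(),
                         out_dir = NULL) {
  if (inherits(volumes, "phantom_case")) volumes <- volumes$volumes
  if (!inherits(volumes, "case_volumes"))
    stop("'volumes' must be a case_volumes (or phantom_case)")

  maps <- list(adc = volumes$adc)
  rcbv <- NULL
  if (!is.null(volumes$dsc)) {
    rcbv <- compute_rcbv_map(volumes$dsc, volumes$brain_mask,
                             min_candidates = config$min_aif_candidates,
                             percentile = config$aif_percentile,
                             sigma_timepoints = config$aif_sigma,
                             clamp_negative = config$clamp_negative)
    maps$rcbv <- rcbv$grid
  }

  pez_raw <- build_pez(volumes$core_mask, volumes$brain_mask,
                       width_voxels = config$pez_width_voxels)
  threshold <- if (identical(config$fluid_threshold, "auto"))
    suggest_fluid_threshold(volumes$adc, pez_raw)
  else config$fluid_threshold
  fl <- exclude_fluid(pez_raw, volumes$adc, threshold)
  part <- partition_pez(fl$cleaned, volumes$flair_mask,
                        volumes$recurrence_mask,
                        excluded_fluid = fl$excluded,
                        width_voxels = config$pez_width_voxels,
                        adc_fluid_threshold = threshold)

  rows <- list()
  for (modality in names(maps)) {
    for (roi in pez_compartments) {
      st <- roi_statistics(maps[[modality]], part[[roi]],
                           trim = config$trim_fraction)
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = volumes$case_id, roi_label = roi, modality = modality,
        n_voxels = st$n_voxels,
        volume_mm3 = mask_volume_mm3(part[[roi]]),
        mean = st$mean, sd = st$sd,
        mean_low = st$mean_low, mean_high = st$mean_high,
        undefined = st$undefined)
    }
  }
  stats <- do.call(rbind, rows)

  pcts <- config$normalization_percentiles
  inb <- volumes$brain_mask$data != 0
  brain_percentiles <- lapply(maps, function(m)
    quantile(m$data[inb], pcts / 100, names = FALSE))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (roi in pez_compartments)
      write_volume(part[[roi]],
                   file.path(out_dir, paste0(volumes$case_id, "_", roi,
                                             ".nii.gz")))
    write_volume(part$excluded_fluid,
                 file.path(out_dir, paste0(volumes$case_id,
                                           "_excluded_fluid.nii.gz")))
    if (!is.null(rcbv))
      write_volume(rcbv$grid,
                   file.path(out_dir, paste0(volumes$case_id,
                                             "_rcbv.nii.gz")))
    write.csv(stats, file.path(out_dir, paste0(volumes$case_id,
                                               "_stats.csv")),
              row.names = FALSE)
  }

  list(stats = stats, partition = part, fluid_threshold = threshold,
       rcbv = rcbv, brain_percentiles = brain_percentiles)
}

# apply the per-case normalization affine to ROI statistics: increasing
# affine maps commute exactly with means, trimmed means, and scale SD by a
apply_affine_to_stats <- function(stats, ab) {
  for (col in c("mean", "mean_low", "mean_high"))
    stats[[col]] <- ab["a"] * stats[[col]] + ab["b"]
  stats$sd <- ab["a"] * stats$sd
  stats
}

#' Analyze a cohort of cases
#'
#' Runs [analyze_case()] per case, computes the cohort-level normalization
#' reference per modality from the per-case within-brain percentile anchors,
#' normalizes each case's ROI statistics onto the reference (an increasing
#' affine map, which commutes exactly with means, trimmed means and SDs),
#' then performs the group-level inference: per-region paired comparisons of
#' compartment means, ADC-rCBV Pearson correlations, and ROC/Youden analysis
#' of the per-case compartment means.
#'
#' @param cases list whose elements are `case_volumes`, `phantom_case`, or
#'   paths to case manifest JSON files. At least 2 cases.
#' @param config `pipeline_config`.
#' @param keep_case_results keep each case's full [analyze_case()] output
#'   (memory-heavy; default `FALSE`).
#' @return List with `table` (normalized per-case compartment statistics),
#'   `raw_table`, `summary` (see [summarize_cohort()]), `roc` (per-modality
#'   `roc_result` on the configured region, or `NULL` when degenerate),
#'   `correlations` (per-compartment ADC-vs-rCBV `stat_result`),
#'   `reference` (per-modality `cohort_reference`), `fluid_thresholds`.
#' @export
analyze_cohort <- function(cases, config = pipeline_config(),
                           keep_case_results = FALSE) {
  if (length(cases) < 2L) stop("a cohort needs at least 2 cases")
  tabs <- vector("list", length(cases))
  anchors <- vector("list", length(cases))
  thresholds <- numeric(length(cases))
  kept <- if (keep_case_results) vector("list", length(cases)) else NULL
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    if (is.character(cs)) cs <- read_case_manifest(cs)
    res <- analyze_case(cs, config)
    tabs[[i]] <- res$stats
    anchors[[i]] <- res$brain_percentiles
    thresholds[i] <- res$fluid_threshold
    if (keep_case_results) kept[[i]] <- res
    rm(res, cs)
  }
  out <- finalize_cohort(tabs, anchors, thresholds, config)
  out$case_results <- kept
  out
}

#' Generate and analyze a phantom cohort, streaming case by case
#'
#' Equivalent to `analyze_cohort(generate_cohort(n_cases, spec, seed),
#' config)` but generates, analyzes and discards one case at a time, so
#' full-size cohorts with 4D DSC series fit in memory. Ground-truth
#' summaries of each case are collected alongside.
#'
#' @param n_cases,spec,seed as in [generate_cohort()].
#' @param config `pipeline_config`.
#' @return As [analyze_cohort()], plus `truth`: data.frame of per-case
#'   ground-truth quantities (true CBV ratio, rim recurrence share outside
#'   FLAIR, compartment voxel counts).
#' @export
analyze_phantom_cohort <- function(n_cases, spec, seed = 1L,
                                   config = pipeline_config()) {
  plan <- cohort_case_plan(n_cases, spec, seed)
  tabs <- vector("list", length(plan))
  anchors <- vector("list", length(plan))
  thresholds <- numeric(length(plan))
  truths <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    p <- plan[[i]]
    case <- generate_case(p$spec, p$seed, p$case_id)
    res <- analyze_case(case, config)
    tabs[[i]] <- res$stats
    anchors[[i]] <- res$brain_percentiles
    thresholds[i] <- res$fluid_threshold
    tr <- case$truth
    truths[[i]] <- data.frame(
      case_id = p$case_id,
      cbv_ratio_flairpos = tr$cbv_ratio_flairpos,
      fraction_recurrence_outside_flair =
        tr$fraction_recurrence_outside_flair,
      t1pos_flairpos_vox = tr$compartment_voxels[["t1pos_flairpos"]],
      t1neg_flairpos_vox = tr$compartment_voxels[["t1neg_flairpos"]],
      t1pos_flairneg_vox = tr$compartment_voxels[["t1pos_flairneg"]],
      t1neg_flairneg_vox = tr$compartment_voxels[["t1neg_flairneg"]])
    heavy <- !is.null(case$volumes$dsc)
    rm(case, res)
    if (heavy) gc(verbose = FALSE)
  }
  out <- finalize_cohort(tabs, anchors, thresholds, config)
  out$truth <- do.call(rbind, truths)
  out
}

# shared tail of analyze_cohort / analyze_phantom_cohort working from
# per-case stats tables and percentile anchors
finalize_cohort <- function(tabs, anchors, thresholds, config) {
  ids <- vapply(tabs, function(t) t$case_id[1], character(1))
  if (anyDuplicated(ids)) {
    warning("duplicate case ids made unique")
    uid <- make.unique(ids)
    for (i in seq_along(tabs)) tabs[[i]]$case_id <- uid[i]
  }
  raw_table <- do.call(rbind, tabs)
  raw_table <- raw_table[order(raw_table$case_id, raw_table$modality,
                               raw_table$roi_label), ]
  rownames(raw_table) <- NULL
  case_ids <- vapply(tabs, function(t) t$case_id[1], character(1))

  modalities <- unique(raw_table$modality)
  pcts <- config$normalization_percentiles
  refs <- list()
  table <- raw_table
  for (modality in modalities) {
    normalize <- if (modality == "adc") config$normalize_adc
                 else config$normalize_rcbv
    qs <- t(vapply(anchors, function(a) a[[modality]], numeric(2)))
    ref <- structure(list(low_anchor = mean(qs[, 1]),
                          high_anchor = mean(qs[, 2]),
                          percentiles = pcts, n_cases = nrow(qs)),
                     class = "cohort_reference")
    refs[[modality]] <- ref
    if (!normalize) next
    for (i in seq_along(case_ids)) {
      spread <- qs[i, 2] - qs[i, 1]
      if (spread <= 0)
        stop(sprintf("case %s has zero percentile spread for %s",
                     case_ids[i], modality))
      a <- (ref$high_anchor - ref$low_anchor) / spread
      b <- ref$low_anchor - a * qs[i, 1]
      sel <- table$modality == modality & table$case_id == case_ids[i]
      table[sel, ] <- apply_affine_to_stats(table[sel, ], c(a = a, b = b))
    }
  }

  summary <- summarize_cohort(table, mode = config$test_mode)

  rg <- config$roc_region
  roi_pos <- paste0("t1pos_", rg)
  roi_neg <- paste0("t1neg_", rg)
  roc <- list()
  for (modality in modalities) {
    pos <- table$mean[table$modality == modality &
                        table$roi_label == roi_pos]
    neg <- table$mean[table$modality == modality &
                        table$roi_label == roi_neg]
    vals <- c(pos, neg)
    labs <- c(rep(1, length(pos)), rep(0, length(neg)))
    keep <- is.finite(vals)
    roc[[modality]] <- if (sum(labs[keep] == 1) > 0 &&
                           sum(labs[keep] == 0) > 0 &&
                           length(unique(vals[keep])) > 1)
      roc_youden(vals[keep], labs[keep])
    else NULL
  }

  correlations <- list()
  if (all(c("adc", "rcbv") %in% modalities)) {
    for (roi in pez_compartments) {
      a <- table[table$modality == "adc" & table$roi_label == roi, ]
      b <- table[table$modality == "rcbv" & table$roi_label == roi, ]
      ids <- intersect(a$case_id, b$case_id)
      xa <- a$mean[match(ids, a$case_id)]
      xb <- b$mean[match(ids, b$case_id)]
      keep <- is.finite(xa) & is.finite(xb)
      correlations[[roi]] <- if (sum(keep) >= 3 && sd(xa[keep]) > 0 &&
                                 sd(xb[keep]) > 0)
        correlate(xa[keep], xb[keep])
      else NULL
    }
  }

  list(table = table, raw_table = raw_table, summary = summary, roc = roc,
       correlations = correlations, reference = refs,
       fluid_thresholds = thresholds, case_results = NULL)
}
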