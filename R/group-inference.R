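new_stat_result <- function(test_name, statistic, p_value, n_pairs,
                            effect_direction, estimate = NA_real_,
                            degenerate = FALSE, n_dropped = 0L,
                            exact = NA) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, n_pairs = n_pairs,
                 effect_direction = effect_direction, estimate = estimate,
                 degenerate = degenerate, n_dropped = n_dropped,
                 exact = exact),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result %s> n=%d, statistic=%.4g, p=%.4g, direction=%s%s\n",
              x$test_name, x$n_pairs, x$statistic, x$p_value,
              x$effect_direction,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Compare recurrence-prone versus stable compartment values across cases
#'
#' Two-sided Wilcoxon test of per-case values. The default `signed_rank`
#' mode respects the within-patient pairing (each case contributes both
#' compartments): exact p-values for n <= 25 pairs without ties or zero
#' differences, normal approximation with continuity correction otherwise.
#' `rank_sum` treats the two sides as independent samples (Wilcoxon-
#' Mann-Whitney). Cases with a missing value on either side are dropped and
#' counted in `n_dropped`.
#'
#' @param values_t1pos,values_t1neg per-case numeric vectors (equal length
#'   in `signed_rank` mode).
#' @param mode `"signed_rank"` (paired, default) or `"rank_sum"`.
#' @return A `stat_result`. If all paired differences are zero the result is
#'   flagged `degenerate` with `p_value = NA` and direction `"none"`.
#' @export
paired_compare <- function(values_t1pos, values_t1neg,
                           mode = c("signed_rank", "rank_sum")) {
  mode <- match.arg(mode)
  x <- as.numeric(values_t1pos)
  y <- as.numeric(values_t1neg)
  if (mode == "signed_rank") {
    if (length(x) != length(y))
      stop("paired mode requires equal-length vectors")
    ok <- is.finite(x) & is.finite(y)
    n_dropped <- sum(!ok)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n == 0L) stop("no complete pairs")
    d <- x - y
    if (all(d == 0))
      return(new_stat_result("wilcoxon_signed_rank", statistic = 0,
                             p_value = NA_real_, n_pairs = n,
                             effect_direction = "none", degenerate = TRUE,
                             n_dropped = n_dropped))
    use_exact <- n <= 25 && !any(d == 0) && !anyDuplicated(abs(d))
    wt <- suppressWarnings(
      wilcox.test(x, y, paired = TRUE, exact = use_exact,
                  correct = TRUE, alternative = "two.sided"))
    dir <- if (median(d) > 0) "positive" else if (median(d) < 0) "negative"
           else if (mean(d) > 0) "positive" else "negative"
    new_stat_result("wilcoxon_signed_rank",
                    statistic = unname(wt$statistic),
                    p_value = wt$p.value, n_pairs = n,
                    effect_direction = dir, n_dropped = n_dropped,
                    exact = use_exact)
  } else {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) == 0L || length(y) == 0L) stop("empty sample")
    if (length(unique(c(x, y))) == 1L)
      return(new_stat_result("wilcoxon_rank_sum", statistic = NA_real_,
                             p_value = NA_real_,
                             n_pairs = min(length(x), length(y)),
                             effect_direction = "none", degenerate = TRUE))
    use_exact <- max(length(x), length(y)) <= 25 &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
      wilcox.test(x, y, exact = use_exact, correct = TRUE,
                  alternative = "two.sided"))
    dir <- if (median(x) > median(y)) "positive"
           else if (median(x) < median(y)) "negative" else "none"
    new_stat_result("wilcoxon_rank_sum", statistic = unname(wt$statistic),
                    p_value = wt$p.value,
                    n_pairs = min(length(x), length(y)),
                    effect_direction = dir, exact = use_exact)
  }
}

#' Pearson correlation across cases
#'
#' @param x,y per-case numeric vectors (n >= 3, non-constant).
#' @return A `stat_result` with `estimate` = Pearson r and a two-sided
#'   t-distribution p-value.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete cases")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  ct <- cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  new_stat_result("pearson_correlation", statistic = unname(ct$statistic),
                  p_value = ct$p.value, n_pairs = length(x),
                  effect_direction = if (r > 0) "positive"
                                     else if (r < 0) "negative" else "none",
                  estimate = r)
}

#' ROC analysis with Youden-index threshold
#'
#' AUC by the rank (Mann-Whitney) formulation with midrank tie correction
#' (ties count one half). The operating threshold maximizes Youden's
#' J = sensitivity + specificity - 1 over the observed values; ties in J are
#' broken toward higher specificity. The classification direction
#' (`">="`: positives have higher values; `"<="`: lower) defaults to
#' whichever gives AUC >= 0.5.
#'
#' @param values per-observation numbers.
#' @param labels binary labels (1/TRUE = positive class); both classes must
#'   be present.
#' @param direction `"auto"`, `">="`, or `"<="`.
#' @return An object of class `roc_result`: `auc`, `youden_threshold`,
#'   `sensitivity_at_threshold`, `specificity_at_threshold`, `youden_j`,
#'   `direction`.
#' @export
roc_youden <- function(values, labels, direction = c("auto", ">=", "<=")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L)
    stop("both classes must be represented")
  r <- rank(values)
  auc_ge <- (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
  if (direction == "auto")
    direction <- if (auc_ge >= 0.5) ">=" else "<="
  auc <- if (direction == ">=") auc_ge else 1 - auc_ge

  pos <- values[labels]; neg <- values[!labels]
  cand <- sort(unique(values))
  if (direction == ">=") {
    sens <- vapply(cand, function(th) mean(pos >= th), numeric(1))
    spec <- vapply(cand, function(th) mean(neg < th), numeric(1))
  } else {
    sens <- vapply(cand, function(th) mean(pos <= th), numeric(1))
    spec <- vapply(cand, function(th) mean(neg > th), numeric(1))
  }
  j <- sens + spec - 1
  best_j <- max(j)
  at <- which(j >= best_j - 1e-12)
  at <- at[which.max(spec[at])]
  structure(list(auc = auc,
                 youden_threshold = cand[at],
                 sensitivity_at_threshold = sens[at],
                 specificity_at_threshold = spec[at],
                 youden_j = j[at],
                 direction = direction,
                 n_pos = npos, n_neg = nneg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC=%.3f, threshold=%.4g (%s), sens=%.3f, spec=%.3f, J=%.3f\n",
              x$auc, x$youden_threshold, x$direction,
              x$sensitivity_at_threshold, x$specificity_at_threshold,
              x$youden_j))
  invisible(x)
}

#' Summarize a cohort table of compartment statistics
#'
#' Input: one row per (case, compartment, modality) with the ROI statistics
#' columns `mean`, `mean_low`, `mean_high` (the format produced by
#' [analyze_case()]). For each FLAIR region and each measure the summary
#' reports the across-case mean and SD of the recurrence-prone (T1+) and
#' stable (T1-) compartments, the percent difference of the across-case
#' means, and the p-value of the paired comparison. Cases missing either
#' side of a comparison are dropped from that row (complete-case pairing).
#'
#' @param table data.frame with columns `case_id`, `roi_label` (one of the
#'   four compartments), `modality`, `mean`, `mean_low`, `mean_high`.
#' @param mode test mode passed to [paired_compare()].
#' @return data.frame with one row per (region, modality, measure).
#' @export
summarize_cohort <- function(table, mode = "signed_rank") {
  if (nrow(table) == 0L) stop("'table' is empty")
  if (anyDuplicated(table[, c("case_id", "roi_label", "modality")]))
    stop("at most one row per (case_id, roi_label, modality) allowed")
  regions <- list(flairpos = c("t1pos_flairpos", "t1neg_flairpos"),
                  flairneg = c("t1pos_flairneg", "t1neg_flairneg"))
  measures <- c("mean", "mean_low", "mean_high")
  out <- list()
  for (modality in sort(unique(table$modality))) {
    for (rg in names(regions)) {
      pos_rows <- table[table$modality == modality &
                          table$roi_label == regions[[rg]][1], ]
      neg_rows <- table[table$modality == modality &
                          table$roi_label == regions[[rg]][2], ]
      ids <- intersect(pos_rows$case_id, neg_rows$case_id)
      pos_rows <- pos_rows[match(ids, pos_rows$case_id), ]
      neg_rows <- neg_rows[match(ids, neg_rows$case_id), ]
      for (ms in measures) {
        xp <- pos_rows[[ms]]; xn <- neg_rows[[ms]]
        keep <- is.finite(xp) & is.finite(xn)
        xp <- xp[keep]; xn <- xn[keep]
        n <- length(xp)
        if (n == 0L) {
          out[[length(out) + 1L]] <- data.frame(
            region = rg, modality = modality, measure = ms, n_pairs = 0L,
            t1pos_mean = NA_real_, t1pos_sd = NA_real_,
            t1neg_mean = NA_real_, t1neg_sd = NA_real_,
            pct_difference = NA_real_, p_value = NA_real_,
            flag = "no_complete_cases")
          next
        }
        cmp <- paired_compare(xp, xn, mode = mode)
        out[[length(out) + 1L]] <- data.frame(
          region = rg, modality = modality, measure = ms, n_pairs = n,
          t1pos_mean = mean(xp), t1pos_sd = if (n > 1) sd(xp) else 0,
          t1neg_mean = mean(xn), t1neg_sd = if (n > 1) sd(xn) else 0,
          pct_difference = percent_difference(mean(xp), mean(xn)),
          p_value = cmp$p_value,
          # no between-case spread of the differences (e.g. duplicated
          # cases) makes the paired test meaningless
          flag = if (cmp$degenerate || (n > 1L && sd(xp - xn) == 0))
            "degenerate" else "")
      }
    }
  }
  do.call(rbind, out)
}
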