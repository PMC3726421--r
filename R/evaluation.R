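# Evaluation: Dice matching, sensitivity, object-level PPV, median Dice,
# mean nuclear area with linear bias correction.

#' Dice coefficient of two pixel sets
#'
#' `2 |X intersect Y| / (|X| + |Y|)`.
#'
#' @param x,y integer vectors of linear pixel indices (non-empty).
#' @return value in \[0, 1\].
#' @export
dice_coefficient <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stopf("Dice coefficient is undefined for empty regions")
  2 * n_intersect(x, y) / (length(x) + length(y))
}

# pixel sets from a ground-truth label mask
regions_from_labels <- function(lab) {
  k <- max(lab)
  if (k == 0L) return(list())
  idx <- which(lab > 0L)
  unname(split(idx, lab[idx]))
}

#' Match automatic segmentations to ground truth and score
#'
#' For every ground-truth nucleus, the automatic region with maximal Dice is
#' found; the nucleus counts as a true positive when that Dice reaches
#' `cutoff` (default 0.2), otherwise as a false negative. Sensitivity is
#' TP / (TP + FN). The object-level positive predictive value is the
#' fraction of automatic regions whose best Dice against any ground-truth
#' nucleus reaches the cutoff (the synthetic-data surrogate for expert
#' labeling of sampled regions). Median Dice is reported over matched pairs;
#' a variant counting unmatched nuclei as zero is included alongside.
#'
#' @param gt list of ground-truth pixel sets, or an integer label mask.
#' @param pred list of automatic-region pixel sets (e.g. rasterized accepted
#'   ellipses), or a `nucseg_result`.
#' @param cutoff Dice cutoff for a match (default 0.2).
#' @return object of class `nucseg_eval`: list with `tp`, `fn`,
#'   `sensitivity`, `ppv` (`NA` when there are no automatic regions),
#'   `dice_values` (per matched nucleus), `median_dice`,
#'   `median_dice_all` (false negatives scored 0) and `n_pred`.
#' @export
match_and_score <- function(gt, pred, cutoff = 0.2) {
  if (is.matrix(gt)) gt <- regions_from_labels(gt)
  if (inherits(pred, "nucseg_result")) pred <- pred$pixsets
  if (length(gt) == 0L) stopf("ground truth is empty")
  npred <- length(pred)

  best_gt <- rep(0, length(gt))       # best Dice per ground-truth nucleus
  best_pred <- rep(0, npred)          # best Dice per automatic region
  if (npred > 0L) {
    for (i in seq_along(gt)) {
      gi <- gt[[i]]
      for (j in seq_len(npred)) {
        # cheap upper bound: Dice <= 1 only if the index ranges can overlap
        pj <- pred[[j]]
        if (min(gi) > max(pj) || min(pj) > max(gi)) next
        dc <- 2 * n_intersect(gi, pj) / (length(gi) + length(pj))
        if (dc > best_gt[i]) best_gt[i] <- dc
        if (dc > best_pred[j]) best_pred[j] <- dc
      }
    }
  }
  matched <- best_gt >= cutoff
  tp <- sum(matched)
  fn <- sum(!matched)
  dice_values <- best_gt[matched]
  structure(list(
    tp = tp, fn = fn,
    sensitivity = tp / (tp + fn),
    ppv = if (npred > 0L) mean(best_pred >= cutoff) else NA_real_,
    dice_values = dice_values,
    median_dice = if (tp > 0L) median(dice_values) else NA_real_,
    median_dice_all = median(ifelse(matched, best_gt, 0)),
    n_pred = npred
  ), class = "nucseg_eval")
}

#' @export
print.nucseg_eval <- function(x, ...) {
  cat(sprintf(paste0("nucleus segmentation evaluation: TP=%d FN=%d ",
                     "sensitivity=%.3f PPV=%s median Dice=%s (n_pred=%d)\n"),
              x$tp, x$fn, x$sensitivity,
              ifelse(is.na(x$ppv), "NA", sprintf("%.3f", x$ppv)),
              ifelse(is.na(x$median_dice), "NA", sprintf("%.3f", x$median_dice)),
              x$n_pred))
  invisible(x)
}

#' Mean nuclear area of a segmentation
#'
#' Averages the areas (`pi * a * b`) of the accepted ellipses. When a linear
#' correction `(slope, intercept)` is supplied, also reports
#' `slope * mna_raw + intercept`, the calibration used to remove the
#' systematic underestimation caused by segmented junk particles and
#' under-segmented large nuclei.
#'
#' @param result a `nucseg_result`, or a data frame with columns `a`, `b`.
#' @param correction optional numeric `c(slope, intercept)`.
#' @return list with `mna_raw` and `mna_corrected` (equal to `mna_raw` when
#'   no correction is given).
#' @export
mean_nuclear_area <- function(result, correction = NULL) {
  df <- if (inherits(result, "nucseg_result")) result$ellipses else result
  if (is.null(df) || nrow(df) == 0L)
    stopf("no accepted regions: mean nuclear area is undefined")
  mna <- mean(pi * df$a * df$b)
  corrected <- if (is.null(correction)) mna
               else correction[[1]] * mna + correction[[2]]
  list(mna_raw = mna, mna_corrected = corrected)
}

#' Fit the linear mean-nuclear-area correction
#'
#' Least-squares fit of `true ~ automatic` over paired per-image mean
#' nuclear areas, giving the `(slope, intercept)` to pass to
#' [mean_nuclear_area()].
#'
#' @param automatic,truth numeric vectors of per-image MNA values (pixels).
#' @return named numeric vector `c(slope, intercept)`.
#' @export
fit_mna_correction <- function(automatic, truth) {
  if (length(automatic) != length(truth) || length(automatic) < 2L)
    stopf("need >= 2 paired MNA values")
  fit <- lm(truth ~ automatic)
  c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
}
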