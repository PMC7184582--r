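# 2x2 confusion counts and the diagnostic-performance indicator battery.

#' Build 2x2 confusion counts
#'
#' `confusion()` tabulates binary test labels against binary reference
#' labels; `confusion_counts()` constructs the object from the four cells
#' directly.
#'
#' @param reference,test Equal-length binary (0/1 or logical) label vectors;
#'   reference is the gold standard.
#' @return A `confusion_counts` object (fields `tp`, `fp`, `tn`, `fn`).
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion <- function(reference, test) {
  if (length(reference) != length(test)) {
    abort("`reference` and `test` must have equal length.")
  }
  if (length(reference) < 1L) abort("need at least one observation.")
  ref <- as.integer(reference); tst <- as.integer(test)
  if (any(!ref %in% c(0L, 1L)) || any(!tst %in% c(0L, 1L))) {
    abort("labels must be binary (0/1 or logical).")
  }
  confusion_counts(
    tp = sum(ref == 1L & tst == 1L),
    fp = sum(ref == 0L & tst == 1L),
    tn = sum(ref == 0L & tst == 0L),
    fn = sum(ref == 1L & tst == 0L)
  )
}

#' @rdname confusion
#' @param tp,fp,tn,fn Non-negative integer cell counts, total >= 1.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("confusion cells must be non-negative integers.")
  }
  if (sum(cells) < 1) abort("confusion table must contain at least one count.")
  structure(as.list(setNames(as.integer(round(cells)), names(cells))),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(reference = c("1", "0"), test = c("1", "0")))
  print(m)
  invisible(x)
}

#' @export
tidy.confusion_counts <- function(x, ...) {
  tibble(cell = c("tp", "fp", "tn", "fn"),
         count = c(x$tp, x$fp, x$tn, x$fn))
}

# Wilson score interval; x may be a non-integer effective count. Agrees
# with stats::prop.test(correct = FALSE) for integer counts.
wilson_ci <- function(x, n, level = 0.95) {
  if (is.na(n) || n <= 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Diagnostic odds ratio with log-scale confidence interval
#'
#' DOR = (TP/FN)/(FP/TN). The confidence interval is computed on the natural
#' log scale, `log(DOR) +/- z * SE`, with
#' `SE = sqrt(1/TP + 1/TN + 1/FP + 1/FN)`, then exponentiated. When any cell
#' is zero the Haldane-Anscombe correction adds 0.5 to all four cells
#' (flagged by `corrected`). `log10_dor` is the base-10 logarithm of the
#' estimate, the scale on which surveillance tables often print DOR.
#'
#' @param counts A `confusion_counts` object.
#' @param conf_level Confidence level (default 0.95, i.e. z = 1.96).
#' @return One-row tibble: `dor`, `conf.low`, `conf.high`, `log10_dor`,
#'   `corrected`.
#' @examples
#' dor_ci(confusion_counts(tp = 90, fp = 10, tn = 90, fn = 10))
#' @export
dor_ci <- function(counts, conf_level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  z <- qnorm(1 - (1 - conf_level) / 2)
  cells <- c(counts$tp, counts$fn, counts$fp, counts$tn)
  corrected <- any(cells == 0L)
  if (corrected) cells <- cells + 0.5
  tp <- cells[1]; fn <- cells[2]; fp <- cells[3]; tn <- cells[4]
  dor <- (tp / fn) / (fp / tn)
  se <- sqrt(1 / tp + 1 / tn + 1 / fp + 1 / fn)
  tibble(
    dor = dor,
    conf.low = exp(log(dor) - z * se),
    conf.high = exp(log(dor) + z * se),
    log10_dor = log10(dor),
    corrected = corrected
  )
}

#' Hard-label binary ROC AUC
#'
#' For a classifier that emits hard labels the ROC curve has three points,
#' (0,0), (1 - specificity, sensitivity), (1,1); its trapezoidal area equals
#' (sensitivity + specificity) / 2.
#'
#' @param counts A `confusion_counts` object.
#' @return AUC as a proportion, `NA` if sensitivity or specificity is
#'   undefined (empty reference class).
#' @export
binary_auc_from_labels <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  sens <- safe_ratio(counts$tp, counts$tp + counts$fn)
  spec <- safe_ratio(counts$tn, counts$tn + counts$fp)
  if (is.na(sens) || is.na(spec)) return(NA_real_)
  (sens + spec) / 2
}

#' Compute the diagnostic indicator battery from a 2x2 table
#'
#' All indicators are computed literally from the cell counts:
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/N, precision TP/(TP+FP), Youden's index
#' sensitivity+specificity-1, F1 2TP/(2TP+FP+FN), Matthews correlation
#' (TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), hard-label ROC AUC
#' (sensitivity+specificity)/2, and the diagnostic odds ratio of
#' [dor_ci()]. Any indicator whose denominator is zero is `NA`.
#'
#' Confidence intervals: Wilson score intervals for sensitivity,
#' specificity, accuracy and precision; Youden and AUC bounds are combined
#' from the Wilson bounds of sensitivity and specificity; F1 uses a Wilson
#' interval with effective denominator TP + (FP+FN)/2; MCC uses the Fisher
#' z transform. DOR as in [dor_ci()].
#'
#' @param counts A `confusion_counts` object.
#' @param ci_level Confidence level for all intervals.
#' @return An `indicator_set` object; use [tidy()] for the long
#'   indicator/estimate/conf.low/conf.high table and [glance()] for a
#'   one-row wide summary.
#' @examples
#' ind <- indicators(confusion_counts(tp = 50, fp = 10, tn = 90, fn = 50))
#' tidy(ind)
#' @export
indicators <- function(counts, ci_level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn

  sens <- safe_ratio(tp, tp + fn)
  spec <- safe_ratio(tn, tn + fp)
  acc <- safe_ratio(tp + tn, n)
  prec <- safe_ratio(tp, tp + fp)
  youden <- if (is.na(sens) || is.na(spec)) NA_real_ else sens + spec - 1
  f1 <- safe_ratio(2 * tp, 2 * tp + fp + fn)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_
  auc <- binary_auc_from_labels(counts)

  ci_sens <- wilson_ci(tp, tp + fn, ci_level)
  ci_spec <- wilson_ci(tn, tn + fp, ci_level)
  ci_acc <- wilson_ci(tp + tn, n, ci_level)
  ci_prec <- wilson_ci(tp, tp + fp, ci_level)
  ci_youden <- c(ci_sens[1] + ci_spec[1] - 1, ci_sens[2] + ci_spec[2] - 1)
  ci_auc <- (ci_sens + ci_spec) / 2
  ci_f1 <- wilson_ci(tp, tp + (fp + fn) / 2, ci_level)
  ci_mcc <- if (!is.na(mcc) && abs(mcc) < 1 && n > 3) {
    z <- qnorm(1 - (1 - ci_level) / 2)
    tanh(atanh(mcc) + c(-1, 1) * z / sqrt(n - 3))
  } else {
    c(NA_real_, NA_real_)
  }
  dor <- dor_ci(counts, conf_level = ci_level)

  tbl <- tibble(
    indicator = c("sensitivity", "specificity", "accuracy", "precision",
                  "youden", "f1", "mcc", "auc", "dor", "log10_dor"),
    estimate = c(sens, spec, acc, prec, youden, f1, mcc, auc,
                 dor$dor, dor$log10_dor),
    conf.low = c(ci_sens[1], ci_spec[1], ci_acc[1], ci_prec[1], ci_youden[1],
                 ci_f1[1], ci_mcc[1], ci_auc[1], dor$conf.low,
                 log10(dor$conf.low)),
    conf.high = c(ci_sens[2], ci_spec[2], ci_acc[2], ci_prec[2], ci_youden[2],
                  ci_f1[2], ci_mcc[2], ci_auc[2], dor$conf.high,
                  log10(dor$conf.high))
  )
  structure(
    list(counts = counts, ci_level = ci_level,
         dor_corrected = dor$corrected, table = tbl),
    class = "indicator_set"
  )
}

#' @export
print.indicator_set <- function(x, ...) {
  cat(sprintf("<indicator_set: n = %d, %.0f%% CI%s>\n",
              x$counts$tp + x$counts$fp + x$counts$tn + x$counts$fn,
              100 * x$ci_level,
              if (x$dor_corrected) ", DOR Haldane-corrected" else ""))
  print(x$table)
  invisible(x)
}

#' @rdname indicators
#' @param x An `indicator_set`.
#' @param ... Unused.
#' @export
tidy.indicator_set <- function(x, ...) x$table

#' @rdname indicators
#' @export
glance.indicator_set <- function(x, ...) {
  wide <- setNames(as.list(x$table$estimate), x$table$indicator)
  as_tibble(c(wide, list(dor_corrected = x$dor_corrected,
                         n = x$counts$tp + x$counts$fp + x$counts$tn + x$counts$fn)))
}
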