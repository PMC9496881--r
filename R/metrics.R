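#' Pixelwise confusion counts between two binary masks
#'
#' @param segmented,truth 0/1 matrices of identical size (`segmented` is
#'   the predicted mask, `truth` the ground truth).
#' @return An object of class `confusion_counts` with integer fields `TP`,
#'   `FP`, `FN`, `TN` summing to the image area.
#' @export
confusion <- function(segmented, truth) {
  check_binary_mask(segmented, "segmented")
  check_binary_mask(truth, "truth")
  check_same_dim(segmented, truth, "masks")
  s <- as.vector(segmented) != 0
  g <- as.vector(truth) != 0
  confusion_counts(TP = sum(s & g), FP = sum(s & !g),
                   FN = sum(!s & g), TN = sum(!s & !g))
}

#' @rdname confusion
#' @param TP,FP,FN,TN Non-negative counts.
#' @export
confusion_counts <- function(TP, FP, FN, TN = 0L) {
  v <- c(TP, FP, FN, TN)
  if (any(v < 0)) stop("confusion counts must be >= 0")
  v <- as.integer(round(v))
  structure(list(TP = v[1], FP = v[2], FN = v[3], TN = v[4]),
            class = "confusion_counts")
}

#' Dice similarity coefficient
#'
#' `2TP / (2TP + FP + FN)`. When both masks are empty the coefficient is
#' defined as 1 (perfect agreement on emptiness) and a note is emitted.
#'
#' @param counts A `confusion_counts` object (see [confusion()]).
#' @return Fraction in \[0, 1\].
#' @export
dice <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  den <- 2 * counts$TP + counts$FP + counts$FN
  if (den == 0) {
    message("both masks empty: Dice defined as 1")
    return(1)
  }
  2 * counts$TP / den
}

#' Jaccard index
#'
#' `TP / (TP + FP + FN)`; related to Dice by `D = 2J / (1 + J)`. Both-empty
#' masks score 1 with a note, as for [dice()].
#'
#' @inheritParams dice
#' @return Fraction in \[0, 1\].
#' @export
jaccard <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  den <- counts$TP + counts$FP + counts$FN
  if (den == 0) {
    message("both masks empty: Jaccard defined as 1")
    return(1)
  }
  counts$TP / den
}

#' Pearson correlation of two images
#'
#' Mean over all pixels of the product of the standardized images, with
#' means and population (divide-by-MN) standard deviations; equal to the
#' Pearson correlation of the flattened pixel vectors. Constant input has
#' no defined correlation and raises an error.
#'
#' @param Is,Ig Numeric matrices (images or masks) of identical size.
#' @return Value in \[-1, 1\].
#' @export
correlation <- function(Is, Ig) {
  if (!is.matrix(Is) || !is.matrix(Ig)) stop("inputs must be matrices")
  check_same_dim(Is, Ig, "images")
  a <- as.vector(Is) * 1; b <- as.vector(Ig) * 1
  sa <- sqrt(mean((a - mean(a))^2))
  sb <- sqrt(mean((b - mean(b))^2))
  if (sa == 0 || sb == 0) {
    stop("correlation undefined for a constant image (zero variance)")
  }
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

#' Root mean squared pixel error
#'
#' `sqrt(mean((Is - Ig)^2))` on the normalized \[0, 1\] scale.
#'
#' @inheritParams correlation
#' @return Non-negative scalar; 0 exactly when the images are identical.
#' @export
rmse <- function(Is, Ig) {
  if (!is.matrix(Is) || !is.matrix(Ig)) stop("inputs must be matrices")
  check_same_dim(Is, Ig, "images")
  sqrt(mean((as.vector(Is) * 1 - as.vector(Ig) * 1)^2))
}

#' Full segmentation evaluation report
#'
#' Confusion counts plus Dice, Jaccard, correlation and RMSE of a
#' predicted mask against a ground-truth mask. Correlation is reported as
#' `NA` when either mask is constant (all-0 or all-1), where it is
#' undefined.
#'
#' @param segmented,truth 0/1 matrices of identical size.
#' @return An object of class `metrics_report` with fields `dice`,
#'   `jaccard`, `correlation`, `rmse`, `counts`, `M`, `N`.
#' @export
metrics_report <- function(segmented, truth) {
  cts <- confusion(segmented, truth)
  corr <- tryCatch(correlation(as_mask(segmented), as_mask(truth)),
                   error = function(e) NA_real_)
  structure(list(
    dice = suppressMessages(dice(cts)),
    jaccard = suppressMessages(jaccard(cts)),
    correlation = corr,
    rmse = rmse(as_mask(segmented), as_mask(truth)),
    counts = cts,
    M = nrow(segmented), N = ncol(segmented)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Segmentation metrics (%dx%d frame)\n", x$M, x$N))
  cat(sprintf("  Dice        %7.3f%%\n", 100 * x$dice))
  cat(sprintf("  Jaccard     %7.3f%%\n", 100 * x$jaccard))
  cat(sprintf("  correlation %s\n",
              if (is.na(x$correlation)) "undefined (constant mask)"
              else sprintf("%8.6f", x$correlation)))
  cat(sprintf("  RMSE        %8.6f\n", x$rmse))
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n",
              x$counts$TP, x$counts$FP, x$counts$FN, x$counts$TN))
  invisible(x)
}
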