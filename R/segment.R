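#' One-dimensional K-means clustering
#'
#' Lloyd iterations on scalar data with deterministic spread initialization:
#' the K initial centers are placed evenly from the minimum to the maximum
#' value (for K = 2, exactly the minimum and the maximum). Each value is
#' assigned to the nearest center; centers are recomputed as cluster means;
#' iteration stops when no assignment changes or after `max_iter` rounds.
#' An emptied cluster is re-seeded at the point farthest from the remaining
#' centers. Centers are returned sorted ascending with labels relabeled to
#' match.
#'
#' @param values Numeric vector with at least `k` distinct values.
#' @param k Number of clusters.
#' @param seed Unused by the deterministic initialization; retained for API
#'   symmetry with the other seeded stages.
#' @param max_iter Iteration cap.
#' @return A list with `labels` (integer vector in `1..k`), `centers`
#'   (ascending numeric vector of length `k`) and `iterations`.
#' @examples
#' kmeans_1d(c(0, 0, 10, 10), k = 2)
#' @export
kmeans_1d <- function(values, k = 2L, seed = NULL, max_iter = 300L) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite")
  }
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1")
  if (length(unique(values)) < k) {
    stop(sprintf("need at least %d distinct values for %d clusters", k, k))
  }
  centers <- seq(min(values), max(values), length.out = k)
  labels <- integer(length(values))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d <- abs(outer(values, centers, "-"))
    new_labels <- max.col(-d, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(new_labels == j)) {
        # re-seed an empty cluster at the point farthest from the others
        others <- centers[-j]
        far <- which.max(vapply(values,
                                function(v) min(abs(v - others)), numeric(1)))
        new_labels[far] <- j
      }
    }
    centers <- vapply(seq_len(k),
                      function(j) mean(values[new_labels == j]), numeric(1))
    if (identical(new_labels, labels) || iter >= max_iter) {
      labels <- new_labels
      break
    }
    labels <- new_labels
  }
  ord <- order(centers)
  list(labels = match(labels, ord), centers = centers[ord],
       iterations = iter)
}

#' Segment a region of interest by two-cluster K-means
#'
#' Clusters the raw pixel intensities of the block with K = 2 and labels
#' the cluster with the higher center (under the default bright polarity)
#' as tumor; its pixels form the tumor mask inside the block, with zeros
#' everywhere else in the image frame. A constant block carries no lesion
#' evidence and yields an empty mask with a warning.
#'
#' @param diseased Numeric matrix (typically the skull-stripped diseased
#'   image).
#' @param roi A [block()] inside the image.
#' @param seed Passed to [kmeans_1d()] (the initialization is
#'   deterministic; repeated calls give identical masks).
#' @param tumor_polarity `"bright"` (hyperintense lesion, default) or
#'   `"dark"`.
#' @return An object of class `segmentation_result` with fields
#'   `tumor_mask` (full-frame 0/1 matrix), `roi`, `cluster_centers`
#'   (ascending) and `iterations_used`.
#' @export
segment_roi <- function(diseased, roi, seed = NULL,
                        tumor_polarity = c("bright", "dark")) {
  tumor_polarity <- match.arg(tumor_polarity)
  check_gray_image(diseased, "diseased")
  check_block_in_image(roi, diseased)
  px <- extract_block(diseased, roi)
  mask <- matrix(0L, nrow(diseased), ncol(diseased))
  if (length(unique(as.vector(px))) < 2L) {
    warning("constant ROI: no lesion evidence, returning an empty mask")
    return(structure(list(tumor_mask = mask, roi = roi,
                          cluster_centers = c(px[1], px[1]),
                          iterations_used = 0L),
                     class = "segmentation_result"))
  }
  km <- kmeans_1d(as.vector(px), k = 2L, seed = seed)
  tumor_cluster <- if (tumor_polarity == "bright") 2L else 1L
  inroi <- matrix(as.integer(km$labels == tumor_cluster),
                  roi$height, roi$width)
  mask[roi$top:(roi$top + roi$height - 1L),
       roi$left:(roi$left + roi$width - 1L)] <- inroi
  structure(list(tumor_mask = mask, roi = roi,
                 cluster_centers = km$centers,
                 iterations_used = km$iterations),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("K-means (K = 2) ROI segmentation\n  ")
  print(x$roi)
  cat(sprintf("  cluster centers %.4f / %.4f, %d iterations, %d tumor pixels\n",
              x$cluster_centers[1], x$cluster_centers[2],
              x$iterations_used, sum(x$tumor_mask)))
  invisible(x)
}
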