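#' Skull-stripping configuration
#'
#' @param threshold Either the string `"otsu"` (data-driven threshold) or a
#'   numeric intensity in (0, 1) used to binarize the image.
#' @param erosion_radius Radius in pixels of the disk structuring element
#'   used to erode the binary brain mask; 0 disables erosion.
#' @param keep_largest_component Keep only the largest 8-connected
#'   foreground component before masking (removes disconnected bright
#'   artifacts).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(threshold = "otsu", erosion_radius = 5,
                              keep_largest_component = TRUE) {
  if (is.character(threshold)) {
    if (!identical(threshold, "otsu")) {
      stop("`threshold` must be \"otsu\" or a numeric value in (0, 1)")
    }
  } else if (!is_scalar_num(threshold) || threshold <= 0 || threshold >= 1) {
    stop("numeric `threshold` must lie strictly between 0 and 1")
  }
  if (!is_scalar_num(erosion_radius) || erosion_radius < 0) {
    stop("`erosion_radius` must be >= 0")
  }
  structure(list(threshold = threshold,
                 erosion_radius = as.numeric(erosion_radius),
                 keep_largest_component = isTRUE(keep_largest_component)),
            class = "preprocess_config")
}

#' Otsu threshold of a grayscale image
#'
#' Histogram-based threshold maximizing between-class variance, on the
#' normalized \[0, 1\] intensity scale.
#'
#' @param image Numeric matrix with intensities in \[0, 1\].
#' @param levels Number of histogram bins.
#' @return A scalar threshold.
#' @export
otsu_threshold <- function(image, levels = 256L) {
  check_gray_image(image)
  EBImage::otsu(EBImage::Image(image), range = c(0, 1), levels = levels)
}

#' Skull-stripping by threshold, hole filling and erosion
#'
#' Binarizes the image with a fixed or Otsu threshold, fills interior holes
#' of the foreground, erodes with a disk structuring element, optionally
#' keeps only the largest 8-connected component, and masks the original
#' image with the result. The bright skull ring, being the outermost
#' structure, is removed by the erosion step.
#'
#' @param image Numeric matrix, intensities in \[0, 1\].
#' @param config A [preprocess_config()].
#' @return A list with elements `stripped` (the masked image) and
#'   `brain_mask` (0/1 integer matrix).
#' @examples
#' pair <- generate_phantom(phantom_spec(64, 64))
#' st <- skull_strip(pair$diseased)
#' sum(st$stripped[pair$skull_mask == 1])  # skull is gone
#' @export
skull_strip <- function(image, config = preprocess_config()) {
  check_gray_image(image)
  if (!inherits(config, "preprocess_config")) {
    stop("`config` must be a preprocess_config object")
  }
  th <- if (identical(config$threshold, "otsu")) {
    otsu_threshold(image)
  } else {
    config$threshold
  }
  bw <- image > th
  if (!any(bw)) stop("no brain region found (empty foreground at threshold)")

  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bw * 1))) > 0.5

  mask <- filled
  if (config$erosion_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(config$erosion_radius) + 1L,
                                shape = "disc")
    mask <- EBImage::imageData(
      EBImage::erode(EBImage::Image(mask * 1), brush)) > 0.5
  }
  if (config$keep_largest_component && any(mask)) {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
    sizes <- tabulate(lab[lab > 0])
    mask <- lab == which.max(sizes)
  }
  if (!any(mask)) stop("no brain region found (mask empty after erosion)")

  list(stripped = image * mask, brain_mask = as_mask(mask))
}
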