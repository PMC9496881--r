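#' Segment a brain tumor from a co-registered image pair
#'
#' End-to-end three-stage pipeline. Both images are skull-stripped and
#' masked with the intersection of their individual brain masks (so
#' candidate and reference blocks compare tissue to tissue); particle
#' swarm search locates the block maximizing the chosen fitness between
#' the stripped pair; two-cluster K-means of the block's intensities
#' yields the tumor mask; if a ground-truth mask is supplied the result is
#' scored with Dice, Jaccard, correlation and RMSE.
#'
#' @param diseased Numeric matrix in \[0, 1\]: the image carrying the
#'   lesion.
#' @param reference Numeric matrix of the same size: the co-registered
#'   disease-free image (required by the method; the fitness measures
#'   candidate-vs-reference variability).
#' @param truth Optional 0/1 ground-truth tumor mask for evaluation.
#' @param preprocess A [preprocess_config()].
#' @param swarm A [swarm_config()]; its `seed` is overridden by `seed`.
#' @param tumor_polarity `"bright"` or `"dark"` lesion (see
#'   [segment_roi()]).
#' @param seed Integer seed propagated to every stochastic stage.
#' @param output_dir If non-`NULL`, the stripped images, tumor mask, search
#'   trace and a JSON run manifest (configuration, seed, package version)
#'   are written there.
#' @return An object of class `swarmseg`: a list with components
#'   `segmentation` ([segment_roi()] result), `search` ([pso_search()]
#'   result), `metrics` (a [metrics_report()], or `NULL` when `truth` is
#'   missing), `stripped` (list of the two stripped images), `brain_mask`,
#'   `config` and `call`. Methods: `print`, `summary`, `plot`.
#' @examples
#' pair <- generate_phantom(phantom_spec(64, 64))
#' fit <- swarmseg(pair$diseased, pair$reference, truth = pair$tumor_mask,
#'                 swarm = swarm_config(t_max = 20), seed = 7)
#' fit
#' @export
swarmseg <- function(diseased, reference, truth = NULL,
                     preprocess = preprocess_config(),
                     swarm = swarm_config(),
                     tumor_polarity = c("bright", "dark"),
                     seed = 1L, output_dir = NULL) {
  tumor_polarity <- match.arg(tumor_polarity)
  cl <- match.call()
  if (missing(reference) || is.null(reference)) {
    stop("pipeline: the disease-free reference image is required")
  }
  check_gray_image(diseased, "diseased")
  check_gray_image(reference, "reference")
  check_same_dim(diseased, reference, "diseased and reference images")
  if (!is.null(truth)) {
    check_binary_mask(truth, "truth")
    check_same_dim(diseased, truth, "image and truth mask")
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  sd_ <- stage("preprocess", skull_strip(diseased, preprocess))
  sr_ <- stage("preprocess", skull_strip(reference, preprocess))
  shared <- sd_$brain_mask * sr_$brain_mask
  if (!any(shared == 1L)) stop("[preprocess] shared brain mask is empty")
  stripped_d <- diseased * shared
  stripped_r <- reference * shared

  swarm$seed <- as.integer(seed)
  search <- stage("blocksearch", pso_search(stripped_d, stripped_r, swarm))
  segmentation <- stage("segment",
                        segment_roi(stripped_d, search$best_block,
                                    seed = seed,
                                    tumor_polarity = tumor_polarity))
  metrics <- if (!is.null(truth)) {
    stage("metrics", metrics_report(segmentation$tumor_mask, truth))
  }

  fit <- structure(list(
    segmentation = segmentation,
    search = search,
    metrics = metrics,
    stripped = list(diseased = stripped_d, reference = stripped_r),
    brain_mask = shared,
    config = list(preprocess = preprocess, swarm = search_config(search, swarm),
                  tumor_polarity = tumor_polarity, seed = as.integer(seed)),
    call = cl
  ), class = "swarmseg")

  if (!is.null(output_dir)) write_run_artifacts(fit, output_dir)
  fit
}

# The swarm config actually used (image-dependent defaults resolved).
search_config <- function(search, swarm) {
  swarm$block_height <- search$best_block$height
  swarm$block_width <- search$best_block$width
  swarm
}

write_run_artifacts <- function(fit, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  save_image(fit$stripped$diseased, file.path(output_dir, "stripped_diseased.tiff"))
  save_image(fit$stripped$reference, file.path(output_dir, "stripped_reference.tiff"))
  save_mask(fit$segmentation$tumor_mask, file.path(output_dir, "tumor_mask.png"))
  utils::write.csv(
    data.frame(iteration = seq_along(fit$search$fitness_trace) - 1L,
               best_fitness = fit$search$fitness_trace),
    file.path(output_dir, "trace.csv"), row.names = FALSE)
  manifest <- list(
    package = "swarmseg",
    version = as.character(utils::packageVersion("swarmseg")),
    seed = fit$config$seed,
    tumor_polarity = fit$config$tumor_polarity,
    preprocess = unclass(fit$config$preprocess),
    swarm = unclass(fit$config$swarm),
    roi = unclass(fit$segmentation$roi),
    cluster_centers = fit$segmentation$cluster_centers,
    best_fitness = fit$search$best_fitness
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' @export
print.swarmseg <- function(x, ...) {
  cat("Three-stage tumor segmentation (skull-strip / PSO block search /",
      "K-means)\n")
  cat(sprintf("  fitness: %s; seed %d\n",
              x$config$swarm$fitness, x$config$seed))
  cat("  ROI: "); print(x$segmentation$roi)
  cat(sprintf("  best fitness %.6g; tumor pixels %d\n",
              x$search$best_fitness, sum(x$segmentation$tumor_mask)))
  if (!is.null(x$metrics)) {
    cat(sprintf("  Dice %.3f%%, Jaccard %.3f%% vs ground truth\n",
                100 * x$metrics$dice, 100 * x$metrics$jaccard))
  }
  invisible(x)
}

#' @export
summary.swarmseg <- function(object, ...) {
  print(object)
  cat(sprintf("  brain mask: %d px; search: %d unique evaluations, %d cache hits\n",
              sum(object$brain_mask), object$search$evaluations,
              object$search$cache_hits))
  cat(sprintf("  cluster centers: %.4f / %.4f (%d iterations)\n",
              object$segmentation$cluster_centers[1],
              object$segmentation$cluster_centers[2],
              object$segmentation$iterations_used))
  if (!is.null(object$metrics)) print(object$metrics)
  invisible(object)
}

#' @export
plot.swarmseg <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show <- function(m, main) {
    graphics::image(t(m[nrow(m):1, ]), col = grDevices::gray.colors(256, 0, 1),
                    axes = FALSE, main = main, useRaster = TRUE)
  }
  show(x$stripped$diseased, "stripped diseased")
  roi <- x$segmentation$roi
  h <- nrow(x$stripped$diseased); w <- ncol(x$stripped$diseased)
  show(x$stripped$diseased, "ROI")
  graphics::rect((roi$left - 1) / (w - 1), (h - roi$top - roi$height + 1) / (h - 1),
                 (roi$left + roi$width - 2) / (w - 1), (h - roi$top + 1) / (h - 1),
                 border = "red", lwd = 2)
  show(x$segmentation$tumor_mask, "tumor mask")
  invisible(x)
}
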