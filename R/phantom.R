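#' Specification of a synthetic brain phantom
#'
#' Describes a 2-D MRI-like phantom: an elliptical brain of noisy tissue,
#' surrounded by a bright skull ring, on a zero (air) background, with an
#' optional hyperintense circular tumor. A phantom pair consists of a
#' diseased image (with tumor) and a co-registered disease-free reference
#' sharing the same noise realization, so that the only systematic
#' difference between the two images is the lesion itself.
#'
#' Geometric defaults scale with the image size: at the reference size of
#' 128x128 they are brain semi-axes (48, 56), skull thickness 4, tumor
#' radius 10; at 64x64 every length is halved. All intensities are on the
#' normalized \[0, 1\] scale.
#'
#' @param image_height,image_width Image size in pixels.
#' @param brain_center Numeric (row, col) center of the brain ellipse.
#' @param brain_axes Numeric (semi-axis-rows, semi-axis-cols) in pixels.
#' @param skull_thickness Thickness of the elliptical skull annulus, pixels.
#' @param skull_intensity Intensity of the skull ring.
#' @param tissue_mean Mean intensity of brain tissue.
#' @param tissue_noise_sd Standard deviation of additive Gaussian tissue
#'   noise (truncated to \[0, 1\]). The same realization is used in both
#'   images of the pair.
#' @param tumor_center Numeric (row, col) center of the tumor disk.
#' @param tumor_radius Tumor radius in pixels; 0 means no lesion.
#' @param tumor_intensity Intensity of the tumor; must exceed
#'   `tissue_mean + 3 * tissue_noise_sd` (hyperintense lesion, as on
#'   FLAIR/contrast-enhanced T1).
#' @param reference_offset Global intensity offset added to the reference
#'   image inside the skull ellipse (default 0). Models a calibration
#'   difference between the two acquisitions; with a nonzero offset the
#'   pixelwise equality of the pair outside the tumor becomes equality up
#'   to the offset.
#' @param random_seed Integer seed driving the tissue noise.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(image_height = 128L, image_width = 128L,
                         brain_center = NULL, brain_axes = NULL,
                         skull_thickness = NULL, skull_intensity = 0.95,
                         tissue_mean = 0.35, tissue_noise_sd = 0.05,
                         tumor_center = NULL, tumor_radius = NULL,
                         tumor_intensity = 0.85, reference_offset = 0,
                         random_seed = 42L) {
  h <- as.integer(image_height)
  w <- as.integer(image_width)
  if (h < 16L || w < 16L) stop("phantom images must be at least 16x16")
  if (is.null(brain_center)) brain_center <- c((h + 1) / 2, (w + 1) / 2)
  if (is.null(brain_axes)) brain_axes <- round(c(0.375 * h, 0.4375 * w))
  if (is.null(skull_thickness)) {
    skull_thickness <- max(2, round(min(h, w) / 32))
  }
  if (is.null(tumor_radius)) tumor_radius <- max(3, round(min(h, w) * 10 / 128))
  if (is.null(tumor_center)) {
    tumor_center <- brain_center + round(c(-10 * h / 128, 12 * w / 128))
  }
  spec <- structure(list(
    image_height = h, image_width = w,
    brain_center = as.numeric(brain_center),
    brain_axes = as.numeric(brain_axes),
    skull_thickness = as.numeric(skull_thickness),
    skull_intensity = as.numeric(skull_intensity),
    tissue_mean = as.numeric(tissue_mean),
    tissue_noise_sd = as.numeric(tissue_noise_sd),
    tumor_center = as.numeric(tumor_center),
    tumor_radius = as.numeric(tumor_radius),
    tumor_intensity = as.numeric(tumor_intensity),
    reference_offset = as.numeric(reference_offset),
    random_seed = as.integer(random_seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (skull_thickness < 0) stop("skull_thickness must be >= 0")
    if (tissue_noise_sd < 0) stop("tissue_noise_sd must be >= 0")
    if (tumor_radius < 0) stop("tumor_radius must be >= 0")
    for (v in c(skull_intensity, tissue_mean, tumor_intensity)) {
      if (v < 0 || v > 1) stop("intensities must lie in [0, 1]")
    }
    ar <- brain_axes[1] + skull_thickness
    ac <- brain_axes[2] + skull_thickness
    if (brain_center[1] - ar < 1 || brain_center[1] + ar > image_height ||
        brain_center[2] - ac < 1 || brain_center[2] + ac > image_width) {
      stop("brain ellipse plus skull ring must fit inside the image bounds")
    }
    if (tumor_radius > 0) {
      sr <- brain_axes[1] - tumor_radius
      sc <- brain_axes[2] - tumor_radius
      if (sr <= 0 || sc <= 0 ||
          ((tumor_center[1] - brain_center[1]) / sr)^2 +
          ((tumor_center[2] - brain_center[2]) / sc)^2 > 1) {
        stop("tumor disk must lie entirely inside the brain ellipse")
      }
      if (tumor_intensity <= tissue_mean + 3 * tissue_noise_sd) {
        stop("tumor_intensity must exceed tissue_mean + 3*tissue_noise_sd ",
             "(hyperintense lesion)")
      }
    }
  })
  invisible(spec)
}

#' Generate a seeded synthetic phantom pair
#'
#' Renders the diseased image, the disease-free reference, the ground-truth
#' tumor mask, and the skull mask described by a [phantom_spec()]. The
#' tissue noise realization is shared between the two images, so the set of
#' pixels where they differ is exactly the tumor disk (up to a nonzero
#' `reference_offset`). Identical seeds yield bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_pair`: a list with elements
#'   `diseased`, `reference` (numeric matrices in \[0, 1\]), `tumor_mask`,
#'   `skull_mask` (0/1 integer matrices) and `spec`.
#' @examples
#' pair <- generate_phantom(phantom_spec(64, 64))
#' range(pair$diseased)
#' sum(pair$tumor_mask)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    stop("`spec` must be a phantom_spec object")
  }
  validate_phantom_spec(spec)
  h <- spec$image_height; w <- spec$image_width
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  cr <- spec$brain_center[1]; cl <- spec$brain_center[2]
  ar <- spec$brain_axes[1]; ac <- spec$brain_axes[2]
  brain <- ((rr - cr) / ar)^2 + ((cc - cl) / ac)^2 <= 1
  outer_e <- ((rr - cr) / (ar + spec$skull_thickness))^2 +
    ((cc - cl) / (ac + spec$skull_thickness))^2 <= 1
  skull <- outer_e & !brain
  if (spec$tumor_radius > 0) {
    tumor <- (rr - spec$tumor_center[1])^2 + (cc - spec$tumor_center[2])^2 <=
      spec$tumor_radius^2
  } else {
    tumor <- matrix(FALSE, h, w)
  }
  noise <- with_seed(spec$random_seed,
                     matrix(stats::rnorm(h * w, 0, spec$tissue_noise_sd), h, w))

  reference <- matrix(0, h, w)
  reference[skull] <- spec$skull_intensity
  reference[brain] <- clamp01(spec$tissue_mean + spec$reference_offset +
                                noise[brain])
  diseased <- matrix(0, h, w)
  diseased[skull] <- spec$skull_intensity
  diseased[brain] <- clamp01(spec$tissue_mean + noise[brain])
  diseased[tumor] <- clamp01(spec$tumor_intensity + noise[tumor])

  structure(list(
    diseased = diseased,
    reference = reference,
    tumor_mask = as_mask(tumor),
    skull_mask = as_mask(skull),
    spec = spec
  ), class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Synthetic phantom pair: %dx%d\n", s$image_height, s$image_width))
  cat(sprintf("  brain axes (%g, %g), skull thickness %g\n",
              s$brain_axes[1], s$brain_axes[2], s$skull_thickness))
  cat(sprintf("  tissue %.2f +/- %.2f, tumor %.2f (radius %g px, %d px area)\n",
              s$tissue_mean, s$tissue_noise_sd, s$tumor_intensity,
              s$tumor_radius, sum(x$tumor_mask)))
  if (s$reference_offset != 0) {
    cat(sprintf("  reference offset %+.3f\n", s$reference_offset))
  }
  invisible(x)
}

#' Default phantom with a randomized tumor location
#'
#' Samples a tumor center uniformly over the admissible region (the brain
#' ellipse shrunk by the tumor radius) and returns the corresponding
#' default [phantom_spec()]. Used to exercise the pipeline over many
#' lesion placements.
#'
#' @param seed Integer seed driving both the center draw and the phantom's
#'   tissue noise.
#' @param image_height,image_width Image size in pixels.
#' @param ... Further arguments passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
random_phantom_spec <- function(seed, image_height = 128L,
                                image_width = 128L, ...) {
  base <- phantom_spec(image_height, image_width, ...)
  # 1 px margin keeps the rounded center valid
  sr <- base$brain_axes[1] - base$tumor_radius - 1
  sc <- base$brain_axes[2] - base$tumor_radius - 1
  ctr <- with_seed(seed, {
    repeat {
      u <- stats::runif(1, -sr, sr)
      v <- stats::runif(1, -sc, sc)
      if ((u / sr)^2 + (v / sc)^2 <= 1) break
    }
    base$brain_center + round(c(u, v))
  })
  phantom_spec(image_height, image_width, tumor_center = ctr,
               random_seed = seed, ...)
}

#' Read or write a phantom specification
#'
#' A `phantom_spec` round-trips through a plain YAML mapping, so phantom
#' definitions can be versioned alongside analysis configurations.
#'
#' @param spec A [phantom_spec()].
#' @param path File path.
#' @return `write_phantom_spec()` returns `path` invisibly;
#'   `read_phantom_spec()` returns a validated `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(phantom_spec, lst)
}
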