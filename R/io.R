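#' Load a 2-D grayscale image
#'
#' Reads PNG, TIFF or (single-slice) NIfTI input as a numeric matrix and
#' min-max normalizes intensities to \[0, 1\]. A constant image maps to
#' all zeros with a warning. Color input is rejected with an instruction to
#' convert to grayscale; 3-D input requires a `slice` index.
#'
#' @param path Input file.
#' @param format One of `"png"`, `"tiff"`, `"nifti"`; guessed from the
#'   file extension by default. NIfTI support requires the RNifti package.
#' @param slice Slice index for 3-D (NIfTI) volumes.
#' @return Numeric matrix with intensities in \[0, 1\].
#' @export
load_image <- function(path, format = NULL, slice = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     png = "png", tif = "tiff", tiff = "tiff",
                     nii = "nifti", gz = "nifti",
                     stop("cannot guess image format from extension .", ext))
  }
  x <- switch(format,
    png = png::readPNG(path),
    tiff = tiff::readTIFF(path),
    nifti = {
      if (!requireNamespace("RNifti", quietly = TRUE)) {
        stop("NIfTI input requires the RNifti package")
      }
      as.array(RNifti::readNifti(path))
    },
    stop("unsupported format: ", format)
  )
  if (length(dim(x)) == 3L) {
    if (format %in% c("png", "tiff")) {
      if (dim(x)[3] == 2L) {
        x <- x[, , 1L]  # gray + alpha: drop alpha
      } else {
        stop("color (RGB) input is not supported: convert to grayscale first")
      }
    } else {
      if (is.null(slice)) {
        stop("3-D volume: pass `slice` to select a single 2-D frame")
      }
      x <- x[, , as.integer(slice)]
    }
  }
  if (length(dim(x)) != 2L) stop("input must be a single 2-D grayscale frame")
  x <- matrix(as.numeric(x), nrow(x), ncol(x))
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant image: normalized to all zeros")
    return(matrix(0, nrow(x), ncol(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Save an image or a binary mask
#'
#' Images are written as 16-bit grayscale TIFF (preserving intensities to
#' 1/65535); masks as 8-bit PNG with values {0, 255}.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param mask 0/1 matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  check_gray_image(image)
  tiff::writeTIFF(image, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname save_image
#' @export
save_mask <- function(mask, path) {
  check_binary_mask(mask)
  png::writePNG(as_mask(mask) * 1.0, path)
  invisible(path)
}

#' @rdname save_image
#' @export
load_mask <- function(path) {
  m <- load_image(path)
  as_mask(m > 0.5)
}
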