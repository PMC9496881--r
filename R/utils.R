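# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. Used by every seeded operation so that pipelines are reproducible
# while remaining polite library citizens.
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Validate a numeric matrix carrying normalized intensities in [0, 1].
check_gray_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(image) < 1L || ncol(image) < 1L) {
    stop(sprintf("`%s` must be nonempty", arg), call. = FALSE)
  }
  if (anyNA(image) || any(!is.finite(image))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  if (min(image) < 0 || max(image) > 1) {
    stop(sprintf("`%s` intensities must lie in [0, 1]", arg), call. = FALSE)
  }
  invisible(image)
}

check_binary_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) {
    stop(sprintf("`%s` must be a matrix", arg), call. = FALSE)
  }
  v <- as.vector(mask)
  if (is.logical(v)) v <- as.integer(v)
  if (anyNA(v) || !all(v %in% c(0L, 1L))) {
    stop(sprintf("`%s` must contain only 0/1 values", arg), call. = FALSE)
  }
  invisible(mask)
}

check_same_dim <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must have identical dimensions (got %dx%d vs %dx%d)",
                 what, nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  }
  invisible(TRUE)
}

# Coerce logical masks to plain 0/1 integer matrices.
as_mask <- function(x) {
  m <- matrix(as.integer(as.vector(x) != 0), nrow(x), ncol(x))
  m
}
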