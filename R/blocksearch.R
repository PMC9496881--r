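#' Rectangular image block
#'
#' A window into an image, addressed by its top-left pixel (1-based row and
#' column) and its height and width; the block spans rows
#' `top:(top + height - 1)` and columns `left:(left + width - 1)`.
#'
#' @param top,left 1-based row/column of the top-left pixel.
#' @param height,width Block size in pixels, both `>= 2`.
#' @return An object of class `block`.
#' @export
block <- function(top, left, height, width) {
  top <- as.integer(top); left <- as.integer(left)
  height <- as.integer(height); width <- as.integer(width)
  if (height < 2L || width < 2L) stop("block height and width must be >= 2")
  if (top < 1L || left < 1L) stop("block top-left must be >= (1, 1)")
  structure(list(top = top, left = left, height = height, width = width),
            class = "block")
}

check_block_in_image <- function(blk, image) {
  if (!inherits(blk, "block")) stop("`roi` must be a block object")
  if (blk$top + blk$height - 1L > nrow(image) ||
      blk$left + blk$width - 1L > ncol(image)) {
    stop("block exceeds image bounds")
  }
  invisible(blk)
}

#' Extract the pixels of a block
#'
#' @param image Numeric matrix.
#' @param blk A [block()] lying inside the image.
#' @return The `height x width` submatrix.
#' @export
extract_block <- function(image, blk) {
  check_block_in_image(blk, image)
  image[blk$top:(blk$top + blk$height - 1L),
        blk$left:(blk$left + blk$width - 1L), drop = FALSE]
}

#' @export
print.block <- function(x, ...) {
  cat(sprintf("block: rows %d..%d, cols %d..%d (%dx%d)\n",
              x$top, x$top + x$height - 1L, x$left, x$left + x$width - 1L,
              x$height, x$width))
  invisible(x)
}

#' Sum of absolute differences between two blocks
#'
#' The L1 block-dissimilarity used as the comparison fitness in the block
#' search: `sum(|I1 - I2|)`. Zero exactly when the blocks are identical.
#'
#' @param block1,block2 Numeric matrices of identical size.
#' @return Non-negative scalar.
#' @export
sad <- function(block1, block2) {
  if (!is.matrix(block1) || !is.matrix(block2)) {
    stop("blocks must be numeric matrices")
  }
  check_same_dim(block1, block2, "blocks")
  sum(abs(block1 - block2))
}

#' Swarm configuration for the block search
#'
#' Hyperparameters of the particle swarm: each particle carries a
#' continuous (row, col) top-left position and velocity, updated as
#' `V <- omega*V + c1*R1*(P - X) + c2*R2*(G - X)`, `X <- X + V`, with fresh
#' uniform `R1, R2` per particle per iteration, velocity clamped to
#' `[-v_max, v_max]` and position clamped to the valid top-left domain.
#'
#' @param np Number of particles.
#' @param t_max Number of iterations (the only stopping rule).
#' @param omega Inertia weight.
#' @param c1,c2 Cognitive and social acceleration weights.
#' @param v_max Velocity clamp in pixels; default
#'   `max(block_height, block_width)` at search time.
#' @param block_height,block_width Block size in pixels; when `NULL`, both
#'   default at search time to a quarter of the smaller image dimension,
#'   rounded to an even number.
#' @param fitness `"anova"` (two-way ANOVA contrast, [anova_fitness()]) or
#'   `"sad"` (sum of absolute differences, [sad()]).
#' @param seed Integer seed for the swarm's random draws.
#' @return An object of class `swarm_config`.
#' @export
swarm_config <- function(np = 20L, t_max = 50L, omega = 0.72,
                         c1 = 1.49, c2 = 1.49, v_max = NULL,
                         block_height = NULL, block_width = NULL,
                         fitness = c("anova", "sad"), seed = 1L) {
  fitness <- match.arg(fitness)
  if (!is_scalar_num(np) || np < 1) stop("`np` must be >= 1")
  if (!is_scalar_num(t_max) || t_max < 1) stop("`t_max` must be >= 1")
  for (w in list(omega, c1, c2)) {
    if (!is_scalar_num(w) || w < 0) stop("omega, c1, c2 must be >= 0")
  }
  if (!is.null(v_max) && (!is_scalar_num(v_max) || v_max <= 0)) {
    stop("`v_max` must be positive")
  }
  structure(list(np = as.integer(np), t_max = as.integer(t_max),
                 omega = omega, c1 = c1, c2 = c2, v_max = v_max,
                 block_height = block_height, block_width = block_width,
                 fitness = fitness, seed = as.integer(seed)),
            class = "swarm_config")
}

# Fill in image-dependent defaults; validate the block fits.
resolve_swarm_config <- function(config, image) {
  if (is.null(config$block_height) || is.null(config$block_width)) {
    side <- min(nrow(image), ncol(image)) %/% 4L
    side <- max(2L, side - side %% 2L)
    if (is.null(config$block_height)) config$block_height <- side
    if (is.null(config$block_width)) config$block_width <- side
  }
  config$block_height <- as.integer(config$block_height)
  config$block_width <- as.integer(config$block_width)
  if (config$block_height < 2L || config$block_width < 2L) {
    stop("block dimensions must be >= 2")
  }
  if (config$block_height > nrow(image) || config$block_width > ncol(image)) {
    stop("block does not fit inside the image")
  }
  if (is.null(config$v_max)) {
    config$v_max <- max(config$block_height, config$block_width)
  }
  config
}

#' Create an empty fitness cache
#'
#' Fitness values are memoized per integer (row, col) top-left position:
#' re-evaluating an already-visited position is a lookup, not a
#' recomputation. The cache records the number of unique evaluations and
#' cache hits.
#'
#' @return An environment usable as the `cache` argument of
#'   [evaluate_position()].
#' @export
fitness_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$values <- new.env(parent = emptyenv())
  e$evaluations <- 0L
  e$hits <- 0L
  e
}

#' Evaluate (with memoization) the fitness of a block position
#'
#' @param row,col Integer top-left position of the candidate block.
#' @param diseased,reference Numeric matrices of identical size.
#' @param config A resolved [swarm_config()] (block size set).
#' @param cache A [fitness_cache()]; pass `NULL` to disable memoization.
#' @return Scalar fitness of the candidate block against the co-located
#'   reference block.
#' @export
evaluate_position <- function(row, col, diseased, reference, config,
                              cache = NULL) {
  key <- paste0(row, "_", col)
  if (!is.null(cache)) {
    hit <- get0(key, envir = cache$values, inherits = FALSE)
    if (!is.null(hit)) {
      cache$hits <- cache$hits + 1L
      return(hit)
    }
  }
  blk <- block(row, col, config$block_height, config$block_width)
  cand <- extract_block(diseased, blk)
  ref <- extract_block(reference, blk)
  val <- if (config$fitness == "anova") {
    anova_fitness(cand, ref)
  } else {
    sad(cand, ref)
  }
  if (!is.null(cache)) {
    assign(key, val, envir = cache$values)
    cache$evaluations <- cache$evaluations + 1L
  }
  val
}

new_search_result <- function(best_row, best_col, best_fitness, config,
                              trace, evaluations, hits, method) {
  structure(list(
    best_block = block(best_row, best_col,
                       config$block_height, config$block_width),
    best_fitness = best_fitness,
    fitness_trace = trace,
    evaluations = evaluations,
    cache_hits = hits,
    fitness = config$fitness,
    method = method
  ), class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("%s block search (%s fitness)\n", x$method, x$fitness))
  cat("  best "); print(x$best_block)
  cat(sprintf("  best fitness %.6g after %d unique evaluations (%d cache hits)\n",
              x$best_fitness, x$evaluations, x$cache_hits))
  invisible(x)
}

#' Particle swarm search for the maximum-fitness block
#'
#' Runs `t_max` iterations of the velocity/position updates over the
#' integer domain of valid top-left block positions. Positions are kept
#' continuous and rounded to the nearest integer pixel only for fitness
#' evaluation, which is memoized per integer position. Identical seeds and
#' configuration reproduce identical results, including the per-iteration
#' trace of the global best fitness and the cache statistics.
#'
#' @param diseased,reference Numeric matrices of identical size.
#' @param config A [swarm_config()].
#' @param use_cache Set `FALSE` to disable memoization (results are
#'   unchanged; only the evaluation counters differ).
#' @param .r1,.r2 Optional fixed values replacing the uniform draws R1 and
#'   R2 (testing hook for degenerate update-rule cases).
#' @return An object of class `search_result` with fields `best_block`,
#'   `best_fitness`, `fitness_trace` (global best after initialization and
#'   after each iteration, non-decreasing), `evaluations` (unique positions
#'   evaluated) and `cache_hits`.
#' @seealso [exhaustive_search()] for the brute-force oracle.
#' @export
pso_search <- function(diseased, reference, config = swarm_config(),
                       use_cache = TRUE, .r1 = NULL, .r2 = NULL) {
  check_gray_image(diseased, "diseased")
  check_gray_image(reference, "reference")
  check_same_dim(diseased, reference, "diseased and reference images")
  if (!inherits(config, "swarm_config")) {
    stop("`config` must be a swarm_config object")
  }
  config <- resolve_swarm_config(config, diseased)
  rmax <- nrow(diseased) - config$block_height + 1L
  cmax <- ncol(diseased) - config$block_width + 1L
  cache <- if (use_cache) fitness_cache() else NULL
  n_eval <- 0L

  eval_pos <- function(r, c) {
    if (is.null(cache)) n_eval <<- n_eval + 1L
    evaluate_position(r, c, diseased, reference, config, cache)
  }
  clamp_pos <- function(x, upper) pmin(upper, pmax(1, x))

  res <- with_seed(config$seed, {
    np <- config$np
    X <- cbind(stats::runif(np, 1, rmax), stats::runif(np, 1, cmax))
    # zero initial velocity: particles first move under the cognitive and
    # social pulls rather than a random kick into the domain boundary
    V <- matrix(0, np, 2)
    P <- X
    p_fit <- numeric(np)
    for (i in seq_len(np)) {
      p_fit[i] <- eval_pos(round(X[i, 1]), round(X[i, 2]))
    }
    g_idx <- which.max(p_fit)
    G <- P[g_idx, ]
    g_fit <- p_fit[g_idx]
    trace <- numeric(config$t_max + 1L)
    trace[1L] <- g_fit

    for (t in seq_len(config$t_max)) {
      for (i in seq_len(np)) {
        r1 <- if (is.null(.r1)) stats::runif(1) else .r1
        r2 <- if (is.null(.r2)) stats::runif(1) else .r2
        V[i, ] <- config$omega * V[i, ] +
          config$c1 * r1 * (P[i, ] - X[i, ]) +
          config$c2 * r2 * (G - X[i, ])
        V[i, ] <- pmin(config$v_max, pmax(-config$v_max, V[i, ]))
        X[i, 1] <- clamp_pos(X[i, 1] + V[i, 1], rmax)
        X[i, 2] <- clamp_pos(X[i, 2] + V[i, 2], cmax)
        f <- eval_pos(round(X[i, 1]), round(X[i, 2]))
        if (f > p_fit[i]) {
          p_fit[i] <- f
          P[i, ] <- X[i, ]
        }
        if (f > g_fit) {
          g_fit <- f
          G <- X[i, ]
        }
      }
      trace[t + 1L] <- g_fit
    }
    list(G = G, g_fit = g_fit, trace = trace, X = X)
  })

  new_search_result(
    best_row = clamp_pos(round(res$G[1]), rmax),
    best_col = clamp_pos(round(res$G[2]), cmax),
    best_fitness = res$g_fit, config = config, trace = res$trace,
    evaluations = if (use_cache) cache$evaluations else n_eval,
    hits = if (use_cache) cache$hits else 0L,
    method = "particle swarm"
  )
}

#' Exhaustive search over all block positions
#'
#' Brute-force oracle for [pso_search()]: evaluates every valid integer
#' top-left position at stride 1 and returns the true maximum, with ties
#' broken by the smallest (row, col) in lexicographic order.
#'
#' @inheritParams pso_search
#' @return An object of class `search_result`.
#' @export
exhaustive_search <- function(diseased, reference, config = swarm_config()) {
  check_gray_image(diseased, "diseased")
  check_gray_image(reference, "reference")
  check_same_dim(diseased, reference, "diseased and reference images")
  if (!inherits(config, "swarm_config")) {
    stop("`config` must be a swarm_config object")
  }
  config <- resolve_swarm_config(config, diseased)
  rmax <- nrow(diseased) - config$block_height + 1L
  cmax <- ncol(diseased) - config$block_width + 1L

  best_fit <- -Inf
  best <- c(1L, 1L)
  n_eval <- 0L
  trace <- numeric(rmax * cmax)
  for (r in seq_len(rmax)) {
    for (cc in seq_len(cmax)) {
      f <- evaluate_position(r, cc, diseased, reference, config, cache = NULL)
      n_eval <- n_eval + 1L
      if (f > best_fit) {   # strict: first (row, col) in scan order wins ties
        best_fit <- f
        best <- c(r, cc)
      }
      trace[n_eval] <- best_fit
    }
  }
  new_search_result(best[1], best[2], best_fit, config, trace,
                    evaluations = n_eval, hits = 0L, method = "exhaustive")
}
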