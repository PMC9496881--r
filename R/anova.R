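#' Upper-tail p-value of the F distribution
#'
#' Thin validating wrapper around the Fisher-Snedecor upper-tail
#' probability used for every ANOVA table p-value in the package.
#'
#' @param f Observed F statistic, `f >= 0`.
#' @param df1,df2 Numerator and denominator degrees of freedom, `>= 1`.
#' @return `P(F >= f)`.
#' @export
f_pvalue <- function(f, df1, df2) {
  if (!is_scalar_num(f) || f < 0) stop("`f` must be a non-negative scalar")
  if (!is_scalar_num(df1) || df1 < 1 || !is_scalar_num(df2) || df2 < 1) {
    stop("degrees of freedom must be >= 1")
  }
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

#' One-way fixed-effects analysis of variance
#'
#' Decomposes the total sum of squares of grouped observations into a
#' factorial part (between group means) and a residual part (within
#' groups): `SST = SSF + SSE`. The F statistic compares the factor mean
#' square with the residual mean square on (k-1, N-k) degrees of freedom.
#' Groups may have unequal sizes.
#'
#' @param groups A list of numeric vectors, one per group (`k >= 2`, each
#'   nonempty, `N >= k + 1`).
#' @return An object of class `oneway_anova` with fields `k`, `N`, `n_i`,
#'   `group_means`, `grand_mean`, `SSF`, `SSE`, `SST`, `df_factor`,
#'   `df_residual`, `MS_factor`, `MS_residual`, `F`, `p`.
#' @examples
#' oneway_anova(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("`groups` must be a list of at least 2 groups")
  }
  groups <- lapply(groups, as.numeric)
  n_i <- lengths(groups)
  if (any(n_i == 0L)) stop("every group must be nonempty")
  y <- unlist(groups, use.names = FALSE)
  if (anyNA(y) || any(!is.finite(y))) stop("observations must be finite")
  k <- length(groups)
  N <- length(y)
  if (N < k + 1L) stop("need at least k + 1 observations in total")

  grand <- mean(y)
  gm <- vapply(groups, mean, numeric(1))
  SSF <- sum(n_i * (gm - grand)^2)
  SSE <- sum(vapply(seq_len(k),
                    function(i) sum((groups[[i]] - gm[i])^2), numeric(1)))
  SST <- sum((y - grand)^2)
  df1 <- k - 1L
  df2 <- N - k
  MSF <- SSF / df1
  MSE <- SSE / df2
  if (SSE == 0 && SSF == 0) {
    Fv <- 0; p <- 1
  } else if (MSE == 0) {
    Fv <- Inf; p <- 0
  } else {
    Fv <- MSF / MSE
    p <- f_pvalue(Fv, df1, df2)
  }
  structure(list(k = k, N = N, n_i = as.integer(n_i), group_means = gm,
                 grand_mean = grand, SSF = SSF, SSE = SSE, SST = SST,
                 df_factor = df1, df_residual = df2,
                 MS_factor = MSF, MS_residual = MSE, F = Fv, p = p),
            class = "oneway_anova")
}

#' Two-way fixed-effects analysis of variance (balanced)
#'
#' Decomposes the total sum of squares of a balanced a x b factorial design
#' with n replicates per cell into factor A, factor B, interaction and
#' residual parts: `SST = SSA + SSB + SSAB + SSE`. Mean squares are SS/df
#' with residual degrees of freedom `N - a*b`; each F ratio compares a mean
#' square with the residual mean square.
#'
#' @param cells Either a 3-D numeric array `y[a, b, n]`, or a list of `a`
#'   lists each holding `b` numeric vectors of common length `n`.
#'   Requires `a >= 2`, `b >= 2`, `n >= 2`; unbalanced cells are rejected.
#' @return An object of class `twoway_anova` with the cell/marginal/grand
#'   means, sums of squares (`SSA`, `SSB`, `SSAB`, `SSE`, `SST`), degrees
#'   of freedom, mean squares, F ratios and p-values.
#' @examples
#' tw <- twoway_anova(list(list(c(1, 3), c(2, 4)), list(c(5, 7), c(6, 8))))
#' tw$SSA  # 32
#' @export
twoway_anova <- function(cells) {
  y <- as_balanced_array(cells)
  a <- dim(y)[1]; b <- dim(y)[2]; n <- dim(y)[3]
  N <- a * b * n

  grand <- mean(y)
  cell_means <- apply(y, c(1, 2), mean)
  mA <- rowMeans(cell_means)
  mB <- colMeans(cell_means)
  SSA <- b * n * sum((mA - grand)^2)
  SSB <- a * n * sum((mB - grand)^2)
  SSAB <- n * sum((cell_means - grand)^2) - SSA - SSB
  if (SSAB < 0 && SSAB > -1e-12) SSAB <- 0
  SSE <- sum((y - cell_means[slice.index(y, c(1, 2))])^2)
  SST <- sum((y - grand)^2)

  df_A <- a - 1L; df_B <- b - 1L
  df_AB <- df_A * df_B
  df_residual <- N - a * b
  MSA <- SSA / df_A; MSB <- SSB / df_B
  MSAB <- SSAB / df_AB; MSE <- SSE / df_residual

  fp <- function(ss, df) {
    if (SSE == 0 && ss == 0) return(c(0, 1))
    if (MSE == 0) return(c(Inf, 0))
    f <- (ss / df) / MSE
    c(f, f_pvalue(f, df, df_residual))
  }
  ra <- fp(SSA, df_A); rb <- fp(SSB, df_B); rab <- fp(SSAB, df_AB)

  structure(list(a = a, b = b, n = n, N = N,
                 cell_means = cell_means, marginal_means_A = mA,
                 marginal_means_B = mB, grand_mean = grand,
                 marginal_counts_A = rep(b * n, a),
                 marginal_counts_B = rep(a * n, b),
                 SSA = SSA, SSB = SSB, SSAB = SSAB, SSE = SSE, SST = SST,
                 df_A = df_A, df_B = df_B, df_AB = df_AB,
                 df_residual = df_residual,
                 MSA = MSA, MSB = MSB, MSAB = MSAB, MSE = MSE,
                 F_A = ra[1], F_B = rb[1], F_AB = rab[1],
                 p_A = ra[2], p_B = rb[2], p_AB = rab[2]),
            class = "twoway_anova")
}

# Accept list-of-lists or array input; enforce balance, a,b >= 2, n >= 2.
as_balanced_array <- function(cells) {
  if (is.array(cells) && length(dim(cells)) == 3L) {
    y <- cells
  } else if (is.list(cells)) {
    a <- length(cells)
    if (a < 2L) stop("factor A must have at least 2 levels")
    b <- unique(lengths(cells))
    if (length(b) != 1L || b < 2L) {
      stop("factor B must have at least 2 levels, the same in every row")
    }
    ns <- unlist(lapply(cells, lengths), use.names = FALSE)
    n <- unique(ns)
    if (length(n) != 1L) {
      stop("unbalanced design: every cell must hold the same number of ",
           "replicates")
    }
    y <- array(NA_real_, c(a, b, n))
    for (i in seq_len(a)) {
      for (j in seq_len(b)) y[i, j, ] <- as.numeric(cells[[i]][[j]])
    }
  } else {
    stop("`cells` must be an a x b x n array or a list of lists of vectors")
  }
  d <- dim(y)
  if (d[1] < 2L || d[2] < 2L) stop("need a >= 2 and b >= 2 factor levels")
  if (d[3] < 2L) {
    stop("need n >= 2 replicates per cell ",
         "(interaction is inseparable from error when n = 1)")
  }
  if (anyNA(y) || any(!is.finite(y))) stop("observations must be finite")
  storage.mode(y) <- "double"
  y
}

#' Two-way ANOVA block fitness
#'
#' The objective maximized by the block search: a candidate block of the
#' diseased image and the co-located block of the disease-free reference
#' are laid out as a balanced two-way design — factor A is the image source
#' (2 levels), factor B is the column index within the block (or the row
#' index under `layout = "rows"`), and the pixels of each column are the
#' replicates. The fitness is `MSA/MSE + MSB/MSE`: large values indicate
#' strong mean differences between the two images and strong column
#' structure relative to the within-column variability, i.e. lesion
#' evidence in the candidate block.
#'
#' A small guard `eps` is added to MSE so that near-constant blocks cannot
#' produce infinite fitness, and a fully constant pair (zero total sum of
#' squares) scores exactly 0.
#'
#' @param candidate,reference Numeric matrices of identical size
#'   (`h >= 2`, `w >= 2`).
#' @param layout `"cols"` (default): factor B indexes block columns;
#'   `"rows"`: factor B indexes block rows (sensitivity check).
#' @param eps Guard added to MSE in the ratios.
#' @return Scalar fitness, `>= 0`. Symmetric in its two image arguments.
#' @examples
#' pair <- generate_phantom(phantom_spec(64, 64))
#' blk <- block(22, 33, 16, 16)  # covers the tumor
#' anova_fitness(extract_block(pair$diseased, blk),
#'               extract_block(pair$reference, blk))
#' @export
anova_fitness <- function(candidate, reference, layout = c("cols", "rows"),
                          eps = 1e-12) {
  layout <- match.arg(layout)
  if (!is.matrix(candidate) || !is.matrix(reference)) {
    stop("blocks must be numeric matrices")
  }
  check_same_dim(candidate, reference, "candidate and reference blocks")
  if (nrow(candidate) < 2L || ncol(candidate) < 2L) {
    stop("blocks must be at least 2x2")
  }
  if (layout == "rows") {
    candidate <- t(candidate)
    reference <- t(reference)
  }
  h <- nrow(candidate); w <- ncol(candidate)
  N <- 2 * h * w
  grand <- (sum(candidate) + sum(reference)) / N
  sst <- sum((candidate - grand)^2) + sum((reference - grand)^2)
  if (sst == 0) return(0)

  # Balanced layout a = 2 (image), b = w (column), n = h (rows): the sums
  # of squares reduce to closed forms over column means.
  m1 <- mean(candidate); m2 <- mean(reference)
  SSA <- h * w * ((m1 - grand)^2 + (m2 - grand)^2)
  cm1 <- colMeans(candidate); cm2 <- colMeans(reference)
  SSB <- 2 * h * sum(((cm1 + cm2) / 2 - grand)^2)
  SSE <- sum(sweep(candidate, 2, cm1)^2) + sum(sweep(reference, 2, cm2)^2)
  MSA <- SSA
  MSB <- SSB / (w - 1)
  MSE <- SSE / (N - 2 * w)
  MSA / (MSE + eps) + MSB / (MSE + eps)
}

#' @export
print.oneway_anova <- function(x, ...) {
  cat("One-way fixed-effects ANOVA\n")
  df <- as.data.frame(x)
  print(df, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
as.data.frame.oneway_anova <- function(x, ...) {
  data.frame(
    source = c("factor", "residual", "total"),
    SS = c(x$SSF, x$SSE, x$SST),
    df = c(x$df_factor, x$df_residual, x$N - 1L),
    MS = c(x$MS_factor, x$MS_residual, NA),
    F = c(x$F, NA, NA),
    p = c(x$p, NA, NA)
  )
}

#' @export
print.twoway_anova <- function(x, ...) {
  cat(sprintf("Two-way fixed-effects ANOVA (a = %d, b = %d, n = %d)\n",
              x$a, x$b, x$n))
  df <- as.data.frame(x)
  print(df, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
as.data.frame.twoway_anova <- function(x, ...) {
  data.frame(
    source = c("factor A", "factor B", "interaction AB", "residual", "total"),
    SS = c(x$SSA, x$SSB, x$SSAB, x$SSE, x$SST),
    df = c(x$df_A, x$df_B, x$df_AB, x$df_residual, x$N - 1L),
    MS = c(x$MSA, x$MSB, x$MSAB, x$MSE, NA),
    F = c(x$F_A, x$F_B, x$F_AB, NA, NA),
    p = c(x$p_A, x$p_B, x$p_AB, NA, NA)
  )
}

#' Serialize an ANOVA table to JSON
#'
#' @param x A `oneway_anova` or `twoway_anova` object.
#' @param pretty Pretty-print the JSON.
#' @return A JSON string.
#' @export
anova_json <- function(x, pretty = TRUE) {
  if (!inherits(x, c("oneway_anova", "twoway_anova"))) {
    stop("`x` must be an ANOVA table object")
  }
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                   pretty = pretty, matrix = "rowmajor")
}
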