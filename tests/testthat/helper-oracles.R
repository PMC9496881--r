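# Independent brute-force oracles, written as direct transcriptions of the
# defining sums so they share no code with the implementation under test.

oracle_oneway <- function(groups) {
  y <- unlist(groups)
  grand <- sum(y) / length(y)
  ssf <- 0; sse <- 0; sst <- 0
  for (g in groups) {
    gm <- sum(g) / length(g)
    ssf <- ssf + length(g) * (gm - grand)^2
    for (v in g) {
      sse <- sse + (v - gm)^2
      sst <- sst + (v - grand)^2
    }
  }
  list(SSF = ssf, SSE = sse, SST = sst)
}

# Naive triple loop over a balanced a x b x n array.
oracle_twoway <- function(y) {
  a <- dim(y)[1]; b <- dim(y)[2]; n <- dim(y)[3]
  grand <- sum(y) / length(y)
  cellm <- matrix(0, a, b)
  for (i in 1:a) for (j in 1:b) {
    s <- 0
    for (k in 1:n) s <- s + y[i, j, k]
    cellm[i, j] <- s / n
  }
  mA <- numeric(a); for (i in 1:a) mA[i] <- sum(cellm[i, ]) / b
  mB <- numeric(b); for (j in 1:b) mB[j] <- sum(cellm[, j]) / a
  ssa <- 0; for (i in 1:a) ssa <- ssa + b * n * (mA[i] - grand)^2
  ssb <- 0; for (j in 1:b) ssb <- ssb + a * n * (mB[j] - grand)^2
  sscell <- 0
  for (i in 1:a) for (j in 1:b) sscell <- sscell + n * (cellm[i, j] - grand)^2
  ssab <- sscell - ssa - ssb
  sse <- 0; sst <- 0
  for (i in 1:a) for (j in 1:b) for (k in 1:n) {
    sse <- sse + (y[i, j, k] - cellm[i, j])^2
    sst <- sst + (y[i, j, k] - grand)^2
  }
  list(SSA = ssa, SSB = ssb, SSAB = ssab, SSE = sse, SST = sst)
}

random_balanced_design <- function() {
  a <- sample(2:4, 1); b <- sample(2:4, 1); n <- sample(2:5, 1)
  array(rnorm(a * b * n, mean = runif(1, -5, 5), sd = runif(1, 0.1, 3)),
        c(a, b, n))
}

# Build the two-way layout used by anova_fitness explicitly, so the fast
# closed-form path can be checked against the general table.
fitness_via_table <- function(cand, ref, eps = 1e-12) {
  h <- nrow(cand); w <- ncol(cand)
  y <- array(NA_real_, c(2, w, h))
  for (j in 1:w) {
    y[1, j, ] <- cand[, j]
    y[2, j, ] <- ref[, j]
  }
  tw <- twoway_anova(y)
  if (tw$SST == 0) return(0)
  tw$MSA / (tw$MSE + eps) + tw$MSB / (tw$MSE + eps)
}

default_pair_64 <- function() generate_phantom(phantom_spec(64, 64))
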