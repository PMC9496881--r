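test_that("one-way table matches the loop oracle and frozen arithmetic", {
  groups <- list(c(1, 2, 3), c(4, 5, 6))
  ow <- oneway_anova(groups)
  orc <- oracle_oneway(groups)
  expect_equal(ow$SSF, orc$SSF)
  expect_equal(ow$SSE, orc$SSE)
  expect_equal(ow$SSF, 13.5)
  expect_equal(ow$SSE, 4)
  expect_equal(ow$F, 13.5)
  expect_equal(ow$p, stats::pf(13.5, 1, 4, lower.tail = FALSE))

  # unbalanced groups against the oracle
  set.seed(31)
  g <- list(rnorm(3), rnorm(7, 2), rnorm(5, -1))
  ow <- oneway_anova(g)
  orc <- oracle_oneway(g)
  expect_equal(ow$SSF, orc$SSF, tolerance = 1e-12)
  expect_equal(ow$SSE, orc$SSE, tolerance = 1e-12)
  expect_equal(ow$SST, ow$SSF + ow$SSE, tolerance = 1e-9)
  expect_identical(ow$df_factor + ow$df_residual, ow$N - 1L)
})

test_that("degenerate one-way input follows the stated conventions", {
  ow <- oneway_anova(list(c(3, 3), c(3, 3)))
  expect_equal(c(ow$SSF, ow$SSE, ow$SST), c(0, 0, 0))
  expect_equal(ow$F, 0)
  expect_equal(ow$p, 1)
  expect_error(oneway_anova(list(c(1, 2))), "at least 2")
  expect_error(oneway_anova(list(c(1, 2), numeric(0))), "nonempty")
})

test_that("two-way worked example reproduces the hand-checked table", {
  cells <- list(list(c(1, 3), c(2, 4)), list(c(5, 7), c(6, 8)))
  y <- array(NA_real_, c(2, 2, 2))
  y[1, 1, ] <- c(1, 3); y[1, 2, ] <- c(2, 4)
  y[2, 1, ] <- c(5, 7); y[2, 2, ] <- c(6, 8)
  orc <- oracle_twoway(y)   # verify the frozen values independently first
  expect_equal(orc$SSA, 32); expect_equal(orc$SSB, 2)
  expect_equal(orc$SSAB, 0); expect_equal(orc$SSE, 8)

  tw <- twoway_anova(cells)
  expect_equal(tw$SSA, 32)
  expect_equal(tw$SSB, 2)
  expect_equal(tw$SSAB, 0)
  expect_equal(tw$SSE, 8)
  expect_equal(tw$SST, 42)
  expect_equal(tw$MSE, 2)
  expect_equal(tw$F_A, 16)
  expect_equal(tw$F_B, 1)
  expect_identical(tw$df_residual, 4L)  # N - ab, not the printed abn - 1
})

test_that("two-way table agrees with stats::aov on random data", {
  set.seed(77)
  y <- random_balanced_design()
  tw <- twoway_anova(y)
  a <- dim(y)[1]; b <- dim(y)[2]; n <- dim(y)[3]
  df <- expand.grid(k = 1:n, A = factor(1:a), B = factor(1:b))
  df$y <- as.vector(aperm(y, c(3, 1, 2)))
  sm <- summary(stats::aov(y ~ A * B, data = df))[[1]]
  rownames(sm) <- trimws(rownames(sm))
  expect_equal(tw$SSA, sm["A", "Sum Sq"], tolerance = 1e-10)
  expect_equal(tw$SSB, sm["B", "Sum Sq"], tolerance = 1e-10)
  expect_equal(tw$SSAB, sm["A:B", "Sum Sq"], tolerance = 1e-10)
  expect_equal(tw$SSE, sm["Residuals", "Sum Sq"], tolerance = 1e-10)
  expect_equal(tw$p_A, sm["A", "Pr(>F)"], tolerance = 1e-10)
})

test_that("two-way sums of squares are translation- and scale-equivariant", {
  set.seed(12)
  for (rep in 1:10) {
    y <- random_balanced_design()
    tw <- twoway_anova(y)
    sh <- twoway_anova(y + 7.3)
    sc <- twoway_anova(y * 2.5)
    for (f in c("SSA", "SSB", "SSAB", "SSE", "SST")) {
      expect_equal(sh[[f]], tw[[f]], tolerance = 1e-8)
      expect_equal(sc[[f]], 2.5^2 * tw[[f]], tolerance = 1e-8)
    }
    expect_equal(sc$F_A, tw$F_A, tolerance = 1e-8)
    expect_equal(sc$F_B, tw$F_B, tolerance = 1e-8)
  }
})

test_that("constant and unbalanced two-way inputs follow the contracts", {
  yc <- array(4.2, c(2, 2, 3))
  tw <- twoway_anova(yc)
  expect_equal(c(tw$SSA, tw$SSB, tw$SSAB, tw$SSE, tw$SST), rep(0, 5))
  expect_equal(c(tw$F_A, tw$F_B), c(0, 0))
  expect_error(twoway_anova(list(list(c(1, 2), c(1, 2, 3)),
                                 list(c(1, 2), c(1, 2)))), "unbalanced")
  expect_error(twoway_anova(array(1:4, c(2, 2, 1))), "n >= 2")
  expect_error(twoway_anova(list(list(c(1, 2), c(3, 4)))), "at least 2")
})

test_that("F p-values match boundary identities and a quadrature oracle", {
  expect_equal(f_pvalue(0, 3, 9), 1)
  expect_equal(f_pvalue(1, 7, 7), 0.5)  # reciprocal symmetry of F(v, v)
  quad <- integrate(function(x) df(x, 1, 4), lower = 16, upper = Inf,
                    rel.tol = 1e-12)$value
  expect_equal(f_pvalue(16, 1, 4), quad, tolerance = 1e-8)
  expect_error(f_pvalue(2, 0, 4), ">= 1")
  expect_error(f_pvalue(-1, 1, 4), "non-negative")
})

test_that("block fitness follows the two-way table and the SST = 0 guard", {
  expect_equal(anova_fitness(matrix(0.3, 4, 4), matrix(0.3, 4, 4)), 0)

  cells <- matrix(c(1, 3, 2, 4, 5, 7, 6, 8) / 10, 4, 2)
  set.seed(5)
  cand <- matrix(runif(48), 6, 8)
  ref <- matrix(runif(48), 6, 8)
  expect_equal(anova_fitness(cand, ref), fitness_via_table(cand, ref),
               tolerance = 1e-10)
  # worked 2x2x2 example through the fitness path: layout (a=2, b=2, n=2)
  cand2 <- matrix(c(1, 3, 2, 4), 2, 2)
  ref2 <- matrix(c(5, 7, 6, 8), 2, 2)
  expect_equal(anova_fitness(cand2 / 10, ref2 / 10), 17, tolerance = 1e-9)
})

test_that("fitness is symmetric and increased by a mean offset", {
  set.seed(8)
  ref <- matrix(runif(64, 0.2, 0.6), 8, 8)
  cand <- ref + 0.2
  expect_equal(anova_fitness(cand, ref), anova_fitness(ref, cand))
  expect_gt(anova_fitness(cand, ref), anova_fitness(ref, ref))
  expect_error(anova_fitness(matrix(0, 4, 4), matrix(0, 4, 5)),
               "identical dimensions")
})

test_that("fitness separates tumor from tissue blocks on a clean phantom", {
  pair <- generate_phantom(phantom_spec(64, 64, tissue_noise_sd = 0))
  ctr <- pair$spec$tumor_center
  tumor_blk <- block(round(ctr[1]) - 8, round(ctr[2]) - 8, 16, 16)
  tissue_blk <- block(30, 14, 16, 16)   # inside the brain, tumor-free
  f_tumor <- anova_fitness(extract_block(pair$diseased, tumor_blk),
                           extract_block(pair$reference, tumor_blk))
  f_tissue <- anova_fitness(extract_block(pair$diseased, tissue_blk),
                            extract_block(pair$reference, tissue_blk))
  expect_gt(f_tumor, f_tissue)
  expect_equal(f_tissue, 0)  # shared noise: identical tumor-free blocks
})
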