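test_that("sad matches its defining sum", {
  b <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(sad(b, b), 0)
  expect_equal(sad(b, matrix(1, 2, 2)), 6)
  set.seed(4)
  x <- matrix(runif(64), 8, 8); y <- matrix(runif(64), 8, 8)
  loop <- 0
  for (i in 1:8) for (j in 1:8) loop <- loop + abs(x[i, j] - y[i, j])
  expect_equal(sad(x, y), loop)
  expect_error(sad(x, matrix(0, 8, 9)), "identical dimensions")
})

test_that("position evaluation is memoized and bit-stable", {
  pair <- default_pair_64()
  cfg <- swarm_config(block_height = 16, block_width = 16)
  cfg <- swarmseg:::resolve_swarm_config(cfg, pair$diseased)
  cache <- fitness_cache()
  f1 <- evaluate_position(20, 30, pair$diseased, pair$reference, cfg, cache)
  expect_identical(cache$evaluations, 1L)
  expect_identical(cache$hits, 0L)
  f2 <- evaluate_position(20, 30, pair$diseased, pair$reference, cfg, cache)
  expect_identical(cache$evaluations, 1L)
  expect_identical(cache$hits, 1L)
  expect_identical(f1, f2)
})

test_that("sad fitness is zero on tumor-free blocks of a clean phantom", {
  pair <- generate_phantom(phantom_spec(64, 64, tissue_noise_sd = 0))
  cfg <- swarmseg:::resolve_swarm_config(
    swarm_config(block_height = 16, block_width = 16, fitness = "sad"),
    pair$diseased)
  expect_equal(evaluate_position(34, 10, pair$diseased, pair$reference, cfg), 0)
  ctr <- round(pair$spec$tumor_center)
  expect_gt(evaluate_position(ctr[1] - 8, ctr[2] - 8,
                              pair$diseased, pair$reference, cfg), 0)
})

test_that("the update rule collapses onto G in the degenerate case", {
  pair <- default_pair_64()
  cfg <- swarm_config(np = 1, t_max = 1, omega = 0, c1 = 0, c2 = 1,
                      v_max = 100, block_height = 16, block_width = 16,
                      seed = 2)
  # with a single particle G equals its own best: X must land exactly on G
  res <- pso_search(pair$diseased, pair$reference, cfg, .r1 = 1, .r2 = 1)
  expect_s3_class(res, "search_result")
  # velocity = (G - X); X + V = G, so the best block never changes
  res2 <- pso_search(pair$diseased, pair$reference,
                     swarm_config(np = 1, t_max = 10, omega = 0, c1 = 0,
                                  c2 = 1, v_max = 100, block_height = 16,
                                  block_width = 16, seed = 2),
                     .r1 = 1, .r2 = 1)
  expect_equal(res2$best_fitness, res$best_fitness)
  expect_identical(res2$best_block, res$best_block)
  expect_lte(res2$evaluations, 2L)  # initial position, then pinned on G
})

test_that("search is deterministic in the seed, with monotone trace", {
  pair <- default_pair_64()
  cfg <- swarm_config(np = 10, t_max = 15, block_height = 16,
                      block_width = 16, seed = 42)
  a <- pso_search(pair$diseased, pair$reference, cfg)
  b <- pso_search(pair$diseased, pair$reference, cfg)
  expect_identical(a[c("best_block", "best_fitness", "fitness_trace",
                       "evaluations", "cache_hits")],
                   b[c("best_block", "best_fitness", "fitness_trace",
                       "evaluations", "cache_hits")])
  expect_true(all(diff(a$fitness_trace) >= 0))
  expect_lte(a$evaluations, 10 * 16)
})

test_that("memoization is semantically transparent", {
  pair <- default_pair_64()
  cfg <- swarm_config(np = 8, t_max = 10, block_height = 16,
                      block_width = 16, seed = 3)
  with_cache <- pso_search(pair$diseased, pair$reference, cfg)
  without <- pso_search(pair$diseased, pair$reference, cfg, use_cache = FALSE)
  expect_identical(without$best_fitness, with_cache$best_fitness)
  expect_identical(without$fitness_trace, with_cache$fitness_trace)
  expect_identical(without$best_block, with_cache$best_block)
  expect_gt(without$evaluations, with_cache$evaluations)
  expect_identical(without$cache_hits, 0L)
})

test_that("pso never beats the exhaustive oracle", {
  pair <- default_pair_64()
  cfg <- swarm_config(np = 10, t_max = 10, block_height = 16,
                      block_width = 16, seed = 1)
  ex <- exhaustive_search(pair$diseased, pair$reference, cfg)
  for (s in 1:5) {
    cfg$seed <- s
    ps <- pso_search(pair$diseased, pair$reference, cfg)
    expect_lte(ps$best_fitness, ex$best_fitness)
  }
})

test_that("exhaustive search breaks ties at the smallest (row, col)", {
  img <- matrix(0.5, 20, 20)
  cfg <- swarm_config(block_height = 4, block_width = 4)
  ex <- exhaustive_search(img, img, cfg)
  expect_identical(c(ex$best_block$top, ex$best_block$left), c(1L, 1L))
  expect_equal(ex$best_fitness, 0)
  expect_identical(ex$evaluations, 17L * 17L)
})

test_that("the exhaustive optimum overlaps the true tumor on a clean phantom", {
  pair <- generate_phantom(phantom_spec(64, 64, tissue_noise_sd = 0))
  cfg <- swarm_config(block_height = 16, block_width = 16)
  ex <- exhaustive_search(pair$diseased, pair$reference, cfg)
  blk_mask <- matrix(0L, 64, 64)
  blk_mask[ex$best_block$top:(ex$best_block$top + 15),
           ex$best_block$left:(ex$best_block$left + 15)] <- 1L
  expect_gt(sum(blk_mask * pair$tumor_mask), 0)
})

test_that("evaluated positions always stay inside the image", {
  pair <- default_pair_64()
  # violent velocities and many iterations: clamping must keep blocks valid
  cfg <- swarm_config(np = 5, t_max = 30, v_max = 200, block_height = 16,
                      block_width = 16, seed = 99)
  expect_no_error(pso_search(pair$diseased, pair$reference, cfg))
  expect_error(swarm_config(np = 0), ">= 1")
  expect_error(
    pso_search(pair$diseased, pair$reference[1:32, 1:32, drop = FALSE],
               cfg),
    "identical dimensions")
})
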