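ALGS <- c("GWO", "WOA", "BA", "CS", "FA", "MFO", "PSO", "MRFO", "DF")

test_that("binarization follows the threshold and sigmoid transfer rules", {
  expect_equal(binarize(c(0.7, 0.3, 0.5), "threshold"), c(1L, 0L, 0L))
  expect_equal(binarize(c(0, 1), "threshold"), c(0L, 1L))
  # sigmoid at v = 0 sets bits with probability 1/2
  set.seed(1)
  draws <- replicate(4000, binarize(0, "sigmoid"))
  expect_lt(abs(mean(draws) - 0.5), 3 * sqrt(0.25 / 4000))
  # saturated velocities are deterministic
  expect_equal(binarize(rep(50, 10), "sigmoid"), rep(1L, 10))
  expect_equal(binarize(rep(-50, 10), "sigmoid"), rep(0L, 10))
})

test_that("mask repair sets exactly one uniform bit on empty masks only", {
  set.seed(2)
  out <- repair_mask(rep(0L, 5))
  expect_equal(sum(out), 1L)
  m <- c(0L, 1L, 0L)
  expect_identical(repair_mask(m), m)
  # uniformity of the repaired index
  idx <- replicate(10000, which(repair_mask(rep(0L, 5)) == 1L))
  expect_gt(chisq.test(tabulate(idx, 5))$p.value, 0.001)
})

test_that("population initialization is seeded, repaired and half-dense", {
  cfg <- swarm_config("GWO", N = 5, T = 10, seed = 1)
  pop <- init_population(10, cfg)
  expect_equal(dim(pop$positions), c(5, 10))
  expect_true(all(pop$positions >= 0 & pop$positions <= 1))
  expect_true(all(rowSums(pop$masks) >= 1))
  expect_identical(pop, init_population(10, cfg))
  # threshold binarization of Uniform[0,1]: expected density 1/2
  big <- init_population(100, swarm_config("GWO", N = 1000, T = 1, seed = 3))
  frac <- mean(big$masks)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / (1000 * 100)))
})

test_that("swarm_config applies tuned defaults and validates inputs", {
  expect_equal(swarm_config("GWO")$N, 10L)
  expect_equal(swarm_config("MFO")$N, 90L)
  expect_equal(swarm_config("PSO")$params$MinW, 0.1)
  expect_equal(swarm_config("CS")$params$ProbF, 0.3)
  expect_equal(swarm_config("BA")$params$A, 0.2)
  expect_equal(swarm_config("DF")$params$MinW, 0.5)
  expect_equal(swarm_config("WOA")$T, 150L)
  expect_error(swarm_config("GWO", N = 1), class = "zooselect_error_invalid_spec")
  expect_error(swarm_config("GWO", T = 0), class = "zooselect_error_invalid_spec")
})

test_that("every engine is elitist, deterministic and dimension-safe", {
  sim <- toy_dataset(n_pos = 15, n_neg = 15, d = 40, n_informative = 3, seed = 21)
  for (alg in ALGS) {
    cfg <- swarm_config(alg, N = 10, T = 8, seed = 5)
    res <- run_si(sim$dataset, cfg, fitness_config(seed = 5))
    expect_true(all(diff(res$fitness_history) <= 0), info = alg)
    expect_length(res$fitness_history, 8)
    expect_equal(res$fitness_history[8], res$best_fitness$value, info = alg)
    expect_length(res$best_mask, 40)
    expect_gte(sum(res$best_mask), 1)
    res2 <- run_si(sim$dataset, cfg, fitness_config(seed = 5))
    expect_identical(res, res2, info = alg)
  }
})

test_that("a single iteration returns the best of the stepped initial population", {
  sim <- toy_dataset(n_pos = 9, n_neg = 9, d = 20, n_informative = 2, seed = 22)
  for (alg in c("GWO", "PSO", "CS")) {
    res <- run_si(sim$dataset, swarm_config(alg, N = 6, T = 1, seed = 2),
                  fitness_config(seed = 2))
    expect_length(res$fitness_history, 1)
    expect_gte(res$n_evaluations, 6)
  }
})

test_that("evaluation budget stays within N*(T+1) plus engine extras", {
  sim <- toy_dataset(n_pos = 9, n_neg = 9, d = 20, seed = 23)
  N <- 8; T <- 5
  for (alg in ALGS) {
    res <- run_si(sim$dataset, swarm_config(alg, N = N, T = T, seed = 1),
                  fitness_config(seed = 1))
    bound <- if (alg == "CS") N + 2 * N * T else N * (T + 1)
    expect_lte(res$n_evaluations, bound)
  }
})

test_that("engines find a wide-margin separating feature quickly", {
  ds <- separable_dataset(n_pos = 30, n_neg = 30, d = 50, seed = 31)
  for (alg in c("GWO", "PSO", "MRFO")) {
    hits <- 0L
    for (s in 1:5) {
      res <- run_si(ds, swarm_config(alg, N = 10, T = 20, seed = s),
                    fitness_config(seed = s))
      hits <- hits + res$best_mask[1]
    }
    expect_gte(hits, 4L)
  }
})
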