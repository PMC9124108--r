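test_that("the attack coefficient decays linearly from 2 to 0", {
  expect_equal(gwo_coefficient_b(0, 100), 2)
  expect_equal(gwo_coefficient_b(50, 100), 1)
  expect_equal(gwo_coefficient_b(100, 100), 0)
  b <- vapply(0:40, gwo_coefficient_b, 1, m_i = 40)
  expect_true(all(diff(b) <= 0))
  expect_error(gwo_coefficient_b(0, 0), "positive")
})

test_that("stochastic coefficients respect their ranges", {
  set.seed(1)
  for (b in c(0, 0.5, 2)) {
    co <- gwo_coefficients(b, 50)
    expect_true(all(abs(co$A) <= b + 1e-12))
    expect_true(all(co$C >= 0 & co$C <= 2))
  }
  expect_equal(gwo_coefficients(0, 5)$A, rep(0, 5))
})

test_that("the leader update averages the three encircling candidates", {
  zeroA <- function(C = 1) list(A = 0, C = C)
  # fixed point: at the leaders with zero attack terms
  expect_equal(gwo_leader_update(0.4, list(0.4, 0.4, 0.4), b = 1,
                                 coeffs = list(zeroA(), zeroA(), zeroA())),
               0.4)
  # zero attack: mean of the leaders
  expect_equal(gwo_leader_update(0.1, list(0.2, 0.4, 0.9), b = 1,
                                 coeffs = list(zeroA(), zeroA(), zeroA())),
               0.5)
  # hand-traced scalar case
  co <- list(A = 0.5, C = 1)
  expect_equal(gwo_leader_update(0.5, list(0.8, 0.8, 0.8), b = 1,
                                 coeffs = list(co, co, co)), 0.65)
  # results stay inside the unit cube whatever the draws
  set.seed(2)
  for (i in 1:50) {
    x <- runif(8)
    out <- gwo_leader_update(x, list(runif(8), runif(8), runif(8)), b = 2)
    expect_true(all(out >= 0 & out <= 1))
  }
  expect_error(gwo_leader_update(c(0.1, 0.2), list(0.3, 0.3, 0.3), 1),
               "dimension")
})

test_that("binarization thresholds strictly and repairs empty masks", {
  expect_identical(binarize_position(c(0.2, 0.7, 0.5), 0.5),
                   c(FALSE, TRUE, FALSE))
  expect_identical(binarize_position(rep(0.9, 4), 0.5), rep(TRUE, 4))
  expect_identical(binarize_position(c(0.1, 0.3, 0.2), 0.5),
                   c(FALSE, TRUE, FALSE))
})

test_that("subset fitness combines wrapper accuracy and parsimony", {
  # samples carry a unique key in gene 1 so a stub wrapper can be exact
  n <- 10
  values <- cbind(seq_len(n), matrix(rnorm(n * 99), n, 99))
  y <- rep(c(0L, 1L), 5)
  ds <- expression_set(values, y)
  oracle <- function(train_x, train_y, test_x) y[test_x[, 1]]
  eighty <- function(train_x, train_y, test_x) {
    p <- y[test_x[, 1]]
    ifelse(test_x[, 1] <= 2, 1L - p, p)   # always miss samples 1 and 2
  }
  full <- rep(TRUE, 100)
  ten <- c(TRUE, rep(FALSE, 90), rep(TRUE, 9))
  # gamma = 1, |S| = |D|: no parsimony reward
  expect_equal(subset_fitness(full, ds, wrapper = oracle)$fitness, 0.9)
  # gamma = 0.8, |S| = 10, |D| = 100
  fs <- subset_fitness(ten, ds, wrapper = eighty)
  expect_equal(fs$quality, 0.8)
  expect_equal(fs$fitness, 0.81)
  # gamma = 0, |S| = |D|
  wrong <- function(train_x, train_y, test_x) 1L - y[test_x[, 1]]
  expect_equal(subset_fitness(full, ds, wrapper = wrong)$fitness, 0)
  expect_error(subset_fitness(rep(FALSE, 100), ds), "empty")
})

test_that("the hill-climbing bandwidth shrinks from 1 to 0", {
  expect_equal(abhc_bandwidth(0, 4, 100), 1)
  expect_equal(abhc_bandwidth(100, 4, 100), 0)
  expect_equal(abhc_bandwidth(50, 1, 100), 0.5)
  N <- vapply(0:60, abhc_bandwidth, 1, K = 3, maxiter = 60)
  expect_true(all(diff(N) <= 0))
  expect_error(abhc_bandwidth(1, 4, 0), "positive")
  expect_error(abhc_bandwidth(1, 0.5, 10), "K")
})

test_that("hill climbing is greedy and finds a 1-D optimum", {
  f <- function(x) 1 - (x - 0.6)^2
  # zero bandwidth and zero reset rate: position cannot move
  set.seed(4)
  r0 <- abhc_refine(0.1, f, t = 100, maxiter = 100, beta_rate = 0,
                    inner_iters = 20)
  expect_equal(r0$x, 0.1)
  # the refined fitness never decreases
  set.seed(5)
  for (i in 1:10) {
    x0 <- runif(3)
    g <- function(x) sum(sin(5 * x) * x)
    r <- abhc_refine(x0, g, t = 3, maxiter = 10, inner_iters = 15)
    expect_gte(r$fitness, g(x0))
    expect_true(all(r$x >= 0 & r$x <= 1))
  }
  # seeded oracle: converges near 0.6 from a distant start
  set.seed(42)
  r <- abhc_refine(0.1, f, t = 0, maxiter = 200, K = 2, beta_rate = 0,
                   inner_iters = 200)
  expect_lt(abs(r$x - 0.6), 0.05)
})

test_that("feature selection recovers a perfectly separating gene", {
  ds <- zscore_normalize(separable_dataset(n = 30, d = 20, sep_gene = 7))
  fs <- igwo_fs(ds, pack_size = 8, max_iter = 20, inner_iters = 10,
                seed = 2)
  expect_true(fs$subset$mask[7])
  expect_gte(fs$subset$quality, 0.9)
})

test_that("the search contract holds: monotone history, bounds, determinism", {
  ds <- zscore_normalize(separable_dataset(n = 24, d = 15, seed = 8))
  a <- igwo_fs(ds, pack_size = 6, max_iter = 10, inner_iters = 8, seed = 3)
  b <- igwo_fs(ds, pack_size = 6, max_iter = 10, inner_iters = 8, seed = 3)
  expect_identical(a$history, b$history)
  expect_identical(a$subset$mask, b$subset$mask)
  expect_true(all(diff(a$history) >= 0))
  expect_true(all(a$position >= 0 & a$position <= 1))
  expect_length(a$history, 11L)
  # zero iterations: best of the initial pack, history of length one
  z <- igwo_fs(ds, pack_size = 6, max_iter = 0, seed = 3)
  expect_length(z$history, 1L)
  expect_error(igwo_fs(ds, pack_size = 3), "pack_size")
})

test_that("the fitness weight behaves at its extremes", {
  ds <- zscore_normalize(separable_dataset(n = 24, d = 15, seed = 8))
  # alpha = 1: fitness is exactly the wrapper accuracy
  a1 <- igwo_fs(ds, pack_size = 6, max_iter = 5, alpha_weight = 1, seed = 4)
  expect_equal(a1$subset$fitness, a1$subset$quality)
  # alpha = 0: the minimal (singleton) subset maximizes fitness
  a0 <- igwo_fs(ds, pack_size = 6, max_iter = 30, alpha_weight = 0, seed = 4)
  expect_identical(sum(a0$subset$mask), 1L)
})

test_that("selected subsets are written with position ranks", {
  ds <- zscore_normalize(separable_dataset(n = 24, d = 15, seed = 8))
  fs <- igwo_fs(ds, pack_size = 6, max_iter = 5, seed = 3)
  f <- tempfile(fileext = ".tsv")
  write_feature_subset(fs, f)
  tab <- read.delim(f)
  expect_identical(nrow(tab), sum(fs$subset$mask))
  expect_identical(tab$rank, seq_len(nrow(tab)))
  expect_true(all(tab$gene_id %in% fs$selected))
})
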