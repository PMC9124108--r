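test_that("the bell membership matches its closed form", {
  expect_equal(bell_membership(0, 1, 3, 0), 1)
  # half-height at c +/- a for any shape
  for (b in c(0.5, 1, 2, 5)) {
    expect_equal(bell_membership(1.5, a = 0.5, b = b, c = 1), 0.5)
    expect_equal(bell_membership(0.5, a = 0.5, b = b, c = 1), 0.5)
  }
  expect_equal(bell_membership(2, 1, 1, 0), 0.2)
  expect_error(bell_membership(0, -1, 1, 0), "width")
  expect_error(bell_membership(0, 1, 0, 0), "shape")
})

test_that("the bell is symmetric and strictly decreasing in |x - c|", {
  x <- seq(0.05, 4, by = 0.05)
  up <- bell_membership(2 + x, a = 1.3, b = 2, c = 2)
  dn <- bell_membership(2 - x, a = 1.3, b = 2, c = 2)
  expect_equal(up, dn)
  expect_true(all(diff(up) < 0))
  expect_true(all(up > 0 & up < 1))
})

test_that("firing strengths multiply the antecedent memberships", {
  m <- anfis_model(centers = matrix(0, 1, 2), widths = matrix(1, 1, 2),
                   shapes = matrix(1, 1, 2), coefs = matrix(0, 1, 2),
                   bias = 0)
  # memberships 0.5 (at x=1) and 0.2 (at x=2)
  expect_equal(firing_strengths(m, c(1, 2)), 0.1)
  # input at every center: product of ones
  expect_equal(firing_strengths(m, c(0, 0)), 1)
  expect_error(firing_strengths(m, c(1, 2, 3)), "length")
})

test_that("normalized strengths form a probability vector", {
  expect_equal(normalize_strengths(c(1, 1)), c(0.5, 0.5))
  expect_equal(normalize_strengths(5), 1)
  expect_equal(normalize_strengths(c(0.3, 0.1)), c(0.75, 0.25))
  expect_error(normalize_strengths(c(0, 0)), "degenerate")
  set.seed(6)
  for (i in 1:20) expect_equal(sum(normalize_strengths(runif(5))), 1)
})

test_that("the forward pass reproduces the five-layer hand trace", {
  m <- two_rule_model()
  d <- anfis_forward(m, 1, diagnostics = TRUE)
  expect_equal(d$O1[, 1], c(0.5, 0.5))        # bells at 0 and 2, x = 1
  expect_equal(d$O2, c(0.5, 0.5))
  expect_equal(d$O3, c(0.5, 0.5))
  expect_equal(d$f, 1.5)                       # 0.5*1 + 0.5*2
  expect_equal(d$O5, sum(d$O4))
  expect_equal(sum(d$O3), 1)
})

test_that("forward output is a convex combination invariant to rule order", {
  set.seed(7)
  R <- 4; d <- 3
  m <- anfis_model(matrix(rnorm(R * d), R), matrix(runif(R * d, 0.5, 2), R),
                   matrix(runif(R * d, 1, 3), R), matrix(rnorm(R * d), R),
                   rnorm(R))
  X <- matrix(rnorm(20 * d), 20, d)
  f <- anfis_forward(m, X)
  rule_out <- X %*% t(m$coefs) + matrix(m$bias, 20, R, byrow = TRUE)
  expect_true(all(f >= apply(rule_out, 1, min) - 1e-12))
  expect_true(all(f <= apply(rule_out, 1, max) + 1e-12))
  perm <- c(3, 1, 4, 2)
  mp <- anfis_model(m$centers[perm, ], m$widths[perm, ], m$shapes[perm, ],
                    m$coefs[perm, ], m$bias[perm])
  expect_equal(anfis_forward(mp, X), f)
  # constant consequents: output equals the constant
  mc <- anfis_model(m$centers, m$widths, m$shapes,
                    matrix(0, R, d), rep(0.7, R))
  expect_equal(anfis_forward(mc, X), rep(0.7, 20))
})

test_that("scatter-partition initialization places rules on the data", {
  bl <- blob_dataset()
  # one rule: centered at the grand centroid
  m1 <- anfis_init(bl$x, bl$y, n_rules = 1, seed = 2)
  expect_equal(m1$centers[1, ], colMeans(bl$x), ignore_attr = TRUE)
  # determinism
  a <- anfis_init(bl$x, bl$y, n_rules = 3, seed = 2)
  b <- anfis_init(bl$x, bl$y, n_rules = 3, seed = 2)
  expect_identical(a, b)
  # two rules on two blobs: one center inside each blob's bounding box
  m2 <- anfis_init(bl$x, bl$y, n_rules = 2, seed = 2)
  for (cls in 0:1) {
    box <- apply(bl$x[bl$y == cls, ], 2, range)
    inside <- apply(m2$centers, 1, function(ctr)
      all(ctr >= box[1, ] & ctr <= box[2, ]))
    expect_true(any(inside))
  }
  expect_true(all(m2$widths > 0))
  expect_error(anfis_init(bl$x, bl$y, n_rules = 100), "exceeds")
})

test_that("least-squares consequents solve exactly and never hurt", {
  X <- matrix(seq(-1, 1, length.out = 10), ncol = 1)
  m <- anfis_model(matrix(0), matrix(2), matrix(2), matrix(0), 0)
  # exact linear recovery
  fit <- anfis_fit_consequents(m, X, 2 * X[, 1] + 1)
  expect_equal(fit$coefs[1, 1], 2, tolerance = 1e-8)
  expect_equal(fit$bias[1], 1, tolerance = 1e-8)
  # null target: minimum-norm gives all-zero consequents
  fit0 <- anfis_fit_consequents(m, X, rep(0, 10))
  expect_equal(max(abs(c(fit0$coefs, fit0$bias))), 0, tolerance = 1e-10)
  # MSE never increases on a rank-deficient random fixture
  set.seed(8)
  Xr <- matrix(rnorm(12 * 6), 12, 6)
  y <- rbinom(12, 1, 0.5)
  m2 <- anfis_init(Xr, y, n_rules = 3, seed = 1)
  before <- mean((anfis_forward(m2, Xr) - y)^2)
  after <- mean((anfis_forward(anfis_fit_consequents(m2, Xr, y), Xr) - y)^2)
  expect_lte(after, before + 1e-12)
})

test_that("labels come from thresholding the crisp output at one half", {
  expect_identical(predict_label(c(0.9, 0.1, 0.5)), c(1L, 0L, 1L))
  expect_error(predict_label(NaN), "finite")
  m <- two_rule_model()
  expect_identical(predict(m, matrix(c(-3, 1))),
                   predict_label(anfis_forward(m, matrix(c(-3, 1)))))
})

test_that("serialization round-trips a model exactly", {
  set.seed(9)
  m <- anfis_model(matrix(rnorm(6), 2), matrix(runif(6, 0.5, 2), 2),
                   matrix(runif(6, 1, 4), 2), matrix(rnorm(6), 2), rnorm(2),
                   feature_names = c("g1", "g2", "g3"))
  f <- tempfile(fileext = ".json")
  write_anfis(m, f)
  m2 <- read_anfis(f)
  X <- matrix(rnorm(30), 10, 3)
  expect_identical(anfis_forward(m2, X), anfis_forward(m, X))
  expect_identical(m2$feature_names, m$feature_names)
})
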