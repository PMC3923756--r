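test_that("beta moment matching recovers the uniform and a verified shape pair", {
  u <- betaShapesFromMoments(0.5, sqrt(1 / 12))
  expect_equal(u$a, 1, tolerance = 1e-12)
  expect_equal(u$b, 1, tolerance = 1e-12)

  s <- betaShapesFromMoments(0.5, 0.25)
  expect_equal(s$a, 1.5, tolerance = 1e-12)
  expect_equal(s$b, 1.5, tolerance = 1e-12)
  # independent check: numeric moments of Beta(1.5, 1.5)
  m1 <- integrate(function(x) x * dbeta(x, s$a, s$b), 0, 1)$value
  m2 <- integrate(function(x) x^2 * dbeta(x, s$a, s$b), 0, 1)$value
  expect_equal(m1, 0.5, tolerance = 1e-6)
  expect_equal(sqrt(m2 - m1^2), 0.25, tolerance = 1e-6)
})

test_that("beta shapes roundtrip mean and sd to 1e-12", {
  set.seed(5)
  for (rep in 1:25) {
    m <- runif(1, 0.05, 0.95)
    s <- runif(1, 0.01, 0.95) * sqrt(m * (1 - m))
    sh <- betaShapesFromMoments(m, s)
    mean <- sh$a / (sh$a + sh$b)
    sd <- sqrt(sh$a * sh$b / ((sh$a + sh$b)^2 * (sh$a + sh$b + 1)))
    expect_equal(mean, m, tolerance = 1e-12)
    expect_equal(sd, s, tolerance = 1e-12)
  }
})

test_that("infeasible beta variances are rejected with the bound named", {
  expect_error(betaShapesFromMoments(0.5, 0.5), "0.25")
  expect_error(betaShapesFromMoments(0.9, 0.31), "infeasible")
  expect_error(betaShapesFromMoments(1.2, 0.1), "\\(0, 1\\)")
})

test_that("flat Dirichlet has symmetric marginals with Beta(1, n-1) law", {
  p <- dirichletPrior(3)
  draws <- sampleFrom(p, 20000, seed = 1)
  expect_equal(dim(draws), c(20000L, 3L))
  expect_equal(rowSums(draws), rep(1, 20000), tolerance = 1e-12)
  expect_lt(max(abs(colMeans(draws) - 1 / 3)), 0.01)
  # marginal of one component of Dirichlet(1,1,1) is Beta(1, 2)
  ks <- suppressWarnings(stats::ks.test(draws[, 1], stats::pbeta, 1, 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("flat Dirichlet log-density is the simplex-volume constant", {
  p <- dirichletPrior(3)
  expect_equal(logDensity(p, c(0.2, 0.3, 0.5)), log(2), tolerance = 1e-12)
  expect_identical(logDensity(p, c(0.5, 0.5, 0)), -Inf)   # boundary
  expect_identical(logDensity(p, c(0.7, 0.7, -0.4)), -Inf)
})

test_that("an informative marginal elicited from moments is recovered by sampling", {
  sh <- betaShapesFromMoments(0.6, 0.15)
  n <- 3
  hyper <- c(sh$a, rep(sh$b / (n - 1), n - 1))
  draws <- sampleFrom(dirichletPrior(n, hyper), 1e5, seed = 2)
  mcse <- 0.15 / sqrt(1e5)
  expect_lt(abs(mean(draws[, 1]) - 0.6), 4 * mcse)
  expect_lt(abs(sd(draws[, 1]) - 0.15), 0.005)
})

test_that("non-positive hyperparameters are rejected", {
  expect_error(dirichletPrior(3, c(1, 0, 1)))
  expect_error(dirichletPrior(3, c(1, -2, 1)))
  expect_error(dirichletPrior(1, 1))
})
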