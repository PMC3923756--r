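test_that("simulated three-source scenario yields 6.6 per mil at the true diet", {
  sc <- builtinScenario("table1")
  expect_equal(unname(predictConsumerSignal(sc, c(0.7, 0.2, 0.1))), 6.6)
})

test_that("a single-source diet collapses to offset plus routed source signals", {
  sc <- toyRouted()
  for (i in 1:2) {
    alpha <- c(0, 0); alpha[i] <- 1
    pred <- predictConsumerSignal(sc, alpha)
    si <- sc@signalMean[i, , ]
    si[is.na(si)] <- 0  # zero-weight fractions: absent signals never enter
    expected <- sc@offsetMean + colSums(sc@weightMean / 100 * si)
    expect_equal(unname(pred), unname(expected), tolerance = 1e-12)
  }
})

test_that("pig-feed scenario forward values match the hand-computed oracle", {
  # frozen from an independent spreadsheet-style calculation over the
  # printed concentration and signal tables at the true diet
  sc <- builtinScenario("hare_a")
  alpha <- c(0, 0, 0, 0.69, 0.31)
  pred <- predictConsumerSignal(sc, alpha)
  expect_equal(unname(pred["13Ccoll"]), -8.9519665002, tolerance = 1e-9)
  expect_equal(unname(pred["15Ncoll"]), 7.4581658291, tolerance = 1e-9)
  expect_equal(unname(pred["13Cglu"]), -2.7226990050, tolerance = 1e-9)

  beta <- fractionIntake(sc, alpha)
  expect_equal(unname(beta["Protein"]), 0.3300165837, tolerance = 1e-9)
  expect_true(is.na(beta["Bulk"]))  # bulk excluded from the normalization

  pi13 <- proxyContribution(sc, alpha, proxy = "13Ccoll")
  expect_equal(unname(pi13[c("Corn", "Gluten")]),
               c(0.5162009512, 0.4837990488), tolerance = 1e-9)
  expect_equal(unname(pi13[1:3]), c(0, 0, 0))
})

test_that("fraction intake handles trivial and symmetric cases", {
  sc <- toyTwoGroup()
  expect_equal(unname(fractionIntake(sc, c(0.3, 0.7))), 1)
  sym <- dietaryScenario(
    groups = c("A", "B"), fractions = c("F1", "F2"), proxies = "P",
    signalMean = array(1, c(2, 2, 1)),
    concMean = rbind(c(40, 60), c(60, 40)),
    weightMean = matrix(c(50, 50), 2, 1),
    offsetMean = 0, consumerMean = 1, consumerSD = 0.5)
  expect_equal(unname(fractionIntake(sym, c(0.5, 0.5))), c(0.5, 0.5))
})

test_that("equal concentrations make proxy contributions equal intakes", {
  sc <- builtinScenario("table1")
  alpha <- c(0.7, 0.2, 0.1)
  expect_equal(unname(proxyContribution(sc, alpha, proxy = "d15N")), alpha)
  expect_equal(unname(proxyContribution(sc, c(1, 0, 0), proxy = 1)), c(1, 0, 0))
})

test_that("degenerate fraction denominators raise named errors", {
  sc <- toyRouted()
  sc@concMean[, "Protein"] <- 0
  # fraction Protein carries weight for both proxies but no intake mass
  expect_error(predictConsumerSignal(sc, c(0.5, 0.5)), "Protein")
  sc2 <- toyTwoGroup()
  sc2@concMean[] <- 0
  expect_error(fractionIntake(sc2, c(0.5, 0.5)), "zero")
  expect_error(proxyContribution(sc2, c(0.5, 0.5), proxy = 1), "zero total")
})

test_that("relabeling food groups permutes outputs and leaves predictions unchanged", {
  set.seed(42)
  for (rep in 1:5) {
    sc <- randomScenario(nI = 4, nJ = 2, nK = 2)
    alpha <- randomSimplex(4)
    perm <- sample(4)
    scP <- dietaryScenario(
      groups = foodGroups(sc)[perm], fractions = foodFractions(sc),
      proxies = dietaryProxies(sc),
      signalMean = sc@signalMean[perm, , , drop = FALSE],
      concMean = sc@concMean[perm, , drop = FALSE],
      weightMean = sc@weightMean,
      offsetMean = sc@offsetMean,
      consumerMean = sc@consumerMean, consumerSD = sc@consumerSD)
    expect_equal(unname(predictConsumerSignal(scP, alpha[perm])),
                 unname(predictConsumerSignal(sc, alpha)), tolerance = 1e-12)
    expect_equal(unname(proxyContribution(scP, alpha[perm], proxy = 1)),
                 unname(proxyContribution(sc, alpha, proxy = 1)[perm]),
                 tolerance = 1e-12)
  }
})

test_that("predictions are convex in the participating source signals", {
  set.seed(7)
  for (rep in 1:10) {
    sc <- randomScenario()
    alpha <- randomSimplex(3)
    st <- stateAtMeans(sc)
    for (k in 1:2) {
      parts <- numeric(0)
      for (j in 1:2) if (st$wgt[j, k] > 0) parts <- c(parts, st$s[, j, k])
      pred <- predictConsumerSignal(sc, alpha, proxy = k)
      expect_gte(pred, st$delta[k] + min(parts) - 1e-9)
      expect_lte(pred, st$delta[k] + max(parts) + 1e-9)
    }
  }
})

test_that("fraction intakes and proxy contributions are simplexes", {
  set.seed(11)
  for (rep in 1:10) {
    sc <- randomScenario(nI = 4, nJ = 3, nK = 2)
    alpha <- randomSimplex(4)
    beta <- fractionIntake(sc, alpha)
    expect_true(all(beta >= 0))
    expect_equal(sum(beta), 1, tolerance = 1e-12)
    for (k in 1:2) {
      pik <- proxyContribution(sc, alpha, proxy = k)
      expect_true(all(pik >= 0))
      expect_equal(sum(pik), 1, tolerance = 1e-12)
    }
  }
})

test_that("one fraction with uniform concentration is the classical linear mixing model", {
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    S <- round(stats::rnorm(n, 5, 3), 2)
    delta <- round(stats::rnorm(1, 3, 1), 2)
    sc <- dietaryScenario(
      groups = paste0("G", 1:n), fractions = "F", proxies = "P",
      signalMean = array(S, c(n, 1, 1)), concMean = matrix(100, n, 1),
      weightMean = matrix(100, 1, 1), offsetMean = delta,
      consumerMean = 0, consumerSD = 1)
    alpha <- randomSimplex(n)
    expect_equal(unname(predictConsumerSignal(sc, alpha)),
                 delta + sum(alpha * S), tolerance = 1e-12)
  }
})
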