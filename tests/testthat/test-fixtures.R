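test_that("packaged scenarios carry the printed values", {
  t1 <- builtinScenario("table1")
  expect_equal(unname(t1@consumerMean), 6.6)
  expect_equal(unname(t1@consumerSD), 0.2)
  expect_equal(unname(t1@offsetMean), 3)
  expect_equal(unname(t1@offsetSD), 0)   # offset fixed
  expect_equal(unname(t1@signalMean[, 1, 1]), c(2, 6, 10))
  expect_true(all(t1@signalSD == 0))

  h <- builtinScenario("hare_a")
  expect_identical(dim(h@signalMean), c(5L, 3L, 3L))
  expect_equal(h@signalMean["Gluten", "Protein", "13Ccoll"], -15.2)
  expect_equal(h@signalSD["Gluten", "Protein", "13Ccoll"], 0.9)
  expect_equal(h@weightMean["Protein", "13Ccoll"], 74)
  expect_equal(h@weightSD["Protein", "13Ccoll"], 4)
  expect_equal(h@weightMean["Bulk", "13Cglu"], 100)
  expect_equal(unname(h@offsetMean), c(4.8, 3.6, 9.2))
  expect_equal(unname(h@offsetSD), c(0.5, 1.2, 1.8))
  # bulk concentration is the summed macronutrient carbon of each feed
  expect_equal(unname(h@concMean[, "Bulk"]), c(50, 46, 49, 47, 51))
  expect_length(scenarioConstraints(h), 0L)
  expect_error(builtinScenario("table9"))
})

test_that("constraint variants encode the published prior knowledge", {
  b <- scenarioConstraints(builtinScenario("hare_b"))
  expect_length(b, 1L)
  expect_equal(b[[1]]@alphaCoef, c(Corn = 1, Gluten = -1))

  cc <- scenarioConstraints(builtinScenario("hare_c"))
  expect_length(cc, 2L)
  # equivalent to 0.05 < beta_Protein < 0.40
  lo <- cc[[1]]; hi <- cc[[2]]
  expect_equal(lo@betaCoef, c(Protein = 1)); expect_equal(lo@constant, -0.05)
  expect_equal(hi@betaCoef, c(Protein = -1)); expect_equal(hi@constant, 0.40)
})

test_that("carbon bookkeeping reproduces the printed composition table", {
  cc <- macronutrientCarbonContent()
  protWt <- c(Soybean = 62, Barley = 15, Alfalfa = 30, Corn = 12, Gluten = 72)
  expect_equal(unname(carbonWeight(protWt, cc["protein"])),
               c(32, 8, 16, 6, 38))
  expect_equal(energyToCarbonRatio(4, cc[["carbohydrates"]]), 9.0)
  expect_equal(energyToCarbonRatio(4, cc[["protein"]]), 7.6)
  expect_equal(energyToCarbonRatio(9, cc[["lipids"]]), 11.7)
})

test_that("noiseless simulation is the deterministic forward model", {
  t1 <- builtinScenario("table1")
  expect_equal(unname(simulateConsumer(t1, c(0.7, 0.2, 0.1),
                                       noise = character())[1, ]), 6.6)
  # a pure-fish diet: source signal 10 plus the 3 per-mil offset
  expect_equal(unname(simulateConsumer(t1, c(0, 0, 1),
                                       noise = character())[1, ]), 13)
})

test_that("simulator moments match the declared uncertainty inputs", {
  t1 <- builtinScenario("table1")
  sims <- simulateConsumer(t1, c(0.7, 0.2, 0.1), nrep = 10000,
                           noise = "measurement", seed = 8)
  # sd of the mean ~ 0.2/sqrt(n); sd of the sd ~ 0.2/sqrt(2n)
  expect_lt(abs(mean(sims) - 6.6), 3 * 0.2 / sqrt(10000))
  expect_lt(abs(sd(sims) - 0.2), 3 * 0.2 / sqrt(2 * 10000))

  h <- builtinScenario("hare_a")
  hs <- simulateConsumer(h, c(0, 0, 0, 0.69, 0.31), nrep = 400, seed = 9)
  truthPred <- predictConsumerSignal(h, c(0, 0, 0, 0.69, 0.31))
  expect_lt(max(abs(colMeans(hs) - truthPred)), 0.25)
})

test_that("simulated consumers are reproducible under a seed", {
  t1 <- builtinScenario("table1")
  a <- simulateConsumer(t1, c(0.7, 0.2, 0.1), nrep = 5, seed = 10)
  b <- simulateConsumer(t1, c(0.7, 0.2, 0.1), nrep = 5, seed = 10)
  expect_identical(a, b)
})
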