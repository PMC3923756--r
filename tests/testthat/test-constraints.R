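hare <- builtinScenario("hare_a")

test_that("group inequality parses to a difference of intakes", {
  ct <- parseConstraint("Corn > Gluten", hare)
  expect_s4_class(ct, "Constraint")
  expect_identical(ct@relation, "gt")
  expect_equal(ct@alphaCoef, c(Corn = 1, Gluten = -1))
  expect_length(ct@betaCoef, 0L)
  expect_equal(ct@constant, 0)
})

test_that("percent literals become proportions and bound fraction intakes", {
  expect_message(lo <- parseConstraint("Protein > 5", hare), "5%")
  expect_message(hi <- parseConstraint("Protein < 40", hare), "40%")
  expect_equal(lo@betaCoef, c(Protein = 1))
  expect_equal(lo@constant, -0.05)
  expect_equal(hi@betaCoef, c(Protein = -1))
  expect_equal(hi@constant, 0.40)
  # literals <= 1 are already proportions
  eq <- parseConstraint("Corn + Gluten = 0.5", hare)
  expect_identical(eq@relation, "eq")
  expect_equal(eq@constant, -0.5)
})

test_that("canonicalized re-expressions give identical terms", {
  a <- parseConstraint("Corn > Gluten", hare)
  b <- parseConstraint("Gluten < Corn", hare)
  expect_equal(a@alphaCoef[sort(names(a@alphaCoef))],
               b@alphaCoef[sort(names(b@alphaCoef))])
  alpha <- c(Soybean = 0.1, Barley = 0.1, Alfalfa = 0.1, Corn = 0.4, Gluten = 0.3)
  expect_identical(constraintLogTerm(a, alpha), constraintLogTerm(b, alpha))
})

test_that("scaled symbols and malformed syntax behave as specified", {
  ct <- parseConstraint("2*Corn - Gluten > 0.1", hare)
  expect_equal(ct@alphaCoef, c(Corn = 2, Gluten = -1))
  expect_equal(ct@constant, -0.1)
  expect_error(parseConstraint("Corn > Banana", hare), "unknown symbol 'Banana'")
  expect_error(parseConstraint("Corn >", hare), "empty expression")
  expect_error(parseConstraint("Corn + > Gluten", hare), "operator")
  expect_error(parseConstraint("Corn Gluten > 0", hare), "expected '\\+'")
  expect_error(parseConstraint("Corn ? Gluten", hare), "unexpected character")
  expect_error(parseConstraint("Corn > Gluten > 0", hare), "exactly one relation")
})

test_that("inequality terms are the Heaviside indicator with H(0) = 1", {
  ct <- parseConstraint("Corn > Gluten", hare)
  alpha <- c(Soybean = 0, Barley = 0, Alfalfa = 0, Corn = 0.69, Gluten = 0.31)
  expect_identical(constraintLogTerm(ct, alpha), 0)
  alpha2 <- c(Soybean = 0.1, Barley = 0.1, Alfalfa = 0.1, Corn = 0.2, Gluten = 0.5)
  expect_identical(constraintLogTerm(ct, alpha2), -Inf)
  alpha0 <- c(Soybean = 0, Barley = 0, Alfalfa = 0, Corn = 0.5, Gluten = 0.5)
  expect_identical(constraintLogTerm(ct, alpha0), 0)  # boundary kept
})

test_that("equality terms peak at exact satisfaction with the normal pseudo-likelihood", {
  toy <- toyTwoGroup()
  ct <- parseConstraint("A = B", toy, sigma = 0.001)
  expect_identical(constraintLogTerm(ct, c(A = 0.5, B = 0.5)),
                   dnorm(0, 0, 0.001, log = TRUE))
  expect_lt(constraintLogTerm(ct, c(A = 0.6, B = 0.4)),
            constraintLogTerm(ct, c(A = 0.5, B = 0.5)))
})

test_that("overly loose equality sds trigger a warning", {
  toy <- toyTwoGroup()
  expect_warning(parseConstraint("A = B", toy, sigma = 0.5), "much smaller")
  expect_silent(parseConstraint("A = B", toy))
})

test_that("equality constraints converge to the exact conditional as sigma shrinks", {
  # two groups, no data: conditioning on A = B must concentrate at 1/2
  toy <- toyTwoGroup(consumerSD = Inf)
  scenarioConstraints(toy) <- list(parseConstraint("A = B", toy, sigma = 0.002))
  fit <- runMcmc(buildPosteriorLogDensity(toy), quietConfig(seed = 4))
  a <- pooledDraws(fit, "alpha_A")
  expect_lt(abs(mean(a) - 0.5), 0.005)
  expect_lt(sd(a), 0.01)  # spread on the order of sigma, not the prior
})
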