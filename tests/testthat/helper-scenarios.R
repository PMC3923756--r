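# small scenarios built in code for the unit and property tests

# two groups, one fraction, one proxy: exactly determined when consumer = 5
toyTwoGroup <- function(consumerSD = 0.05, consumerMean = 5) {
  dietaryScenario(
    groups = c("A", "B"), fractions = "Protein", proxies = "d15N",
    signalMean = array(c(0, 10), c(2, 1, 1)),
    concMean = matrix(100, 2, 1),
    weightMean = matrix(100, 1, 1),
    offsetMean = 0,
    consumerMean = consumerMean, consumerSD = consumerSD)
}

# routed 2x2x2 scenario with unequal concentrations, all quantities fixed
toyRouted <- function() {
  sm <- array(NA_real_, c(2, 2, 2))
  sm[, 1, 1] <- c(-26, -13)   # protein signals, proxy 1
  sm[, 2, 1] <- c(-23, -11)   # energy signals, proxy 1
  sm[, 1, 2] <- c(2, 8)       # protein signals, proxy 2
  dietaryScenario(
    groups = c("A", "B"), fractions = c("Protein", "Energy"),
    proxies = c("d13C", "d15N"),
    signalMean = sm,
    concMean = rbind(c(30, 60), c(10, 80)),
    weightMean = cbind(c(74, 26), c(100, 0)),
    offsetMean = c(4.8, 3.6),
    consumerMean = c(-9, 6), consumerSD = c(0.5, 0.5))
}

# random fixed-latent scenario for property checks (seeded by caller)
randomScenario <- function(nI = 3, nJ = 2, nK = 2) {
  sm <- array(round(stats::rnorm(nI * nJ * nK, 0, 10), 2), c(nI, nJ, nK))
  conc <- matrix(round(stats::runif(nI * nJ, 5, 95), 1), nI, nJ)
  w <- matrix(stats::runif(nJ * nK), nJ, nK)
  w <- sweep(w, 2, colSums(w), "/") * 100
  dietaryScenario(
    groups = paste0("G", seq_len(nI)),
    fractions = paste0("F", seq_len(nJ)),
    proxies = paste0("P", seq_len(nK)),
    signalMean = sm, concMean = conc, weightMean = w,
    offsetMean = round(stats::rnorm(nK, 3, 1), 2),
    consumerMean = rep(0, nK), consumerSD = rep(0.5, nK))
}

randomSimplex <- function(n) {
  g <- stats::rgamma(n, 1)
  g / sum(g)
}

quietConfig <- function(seed, nChains = 2L, nIterations = 6000L,
                        burnIn = 2000L, thin = 2L) {
  samplerConfig(seed = seed, nChains = nChains, nIterations = nIterations,
                burnIn = burnIn, thin = thin)
}
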