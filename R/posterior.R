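#' Assemble the posterior log-density for a dietary scenario
#'
#' Builds the full hierarchical posterior on an unconstrained
#' parameterization. Intake proportions are mapped to the simplex through a
#' centered stick-breaking (logistic) transform whose log-Jacobian is
#' included, so the flat Dirichlet prior remains flat on the simplex. Every
#' uncertain scenario quantity (source signals, offsets, routing weights,
#' concentrations) becomes a latent parameter with a normal prior at its
#' stated mean/sd; concentrations and routing weights are truncated at zero.
#' The observation likelihood for each proxy is
#' Normal(consumer mean | predicted signal, measurement sd) — source and
#' offset uncertainties propagate through the sampled latents rather than
#' being folded into the observation sd. Constraint pseudo-observations are
#' added on top. Proxies whose consumer sd is non-finite contribute no
#' likelihood (useful for prior-recovery checks).
#'
#' When more than one routing weight for the same proxy is uncertain, the
#' sampled weights are renormalized to sum to 100 within each draw (a notice
#' is emitted at build time); with a single uncertain weight the sampled
#' value is used as-is.
#'
#' @param scenario a valid \linkS4class{DietaryScenario}.
#' @param prior a \linkS4class{DirichletPrior} over group intakes; defaults
#'   to unit hyperparameters (flat on the simplex).
#' @param constraints list of \linkS4class{Constraint}s; defaults to the
#'   constraints stored in the scenario.
#' @return an object of class \code{"mixingPosterior"}: a list with the
#'   log-density \code{logDensity(theta)}, the derived-quantity map
#'   \code{transform(theta)}, \code{nParams}, \code{paramNames} (derived
#'   names), \code{blocks}, \code{baseScales} and \code{init(chain)}, ready
#'   for \code{\link{runMcmc}}.
#' @export
buildPosteriorLogDensity <- function(scenario,
                                     prior = dirichletPrior(length(foodGroups(scenario))),
                                     constraints = scenarioConstraints(scenario)) {
  viol <- validateScenario(scenario)
  if (length(viol))
    stop("invalid scenario:\n  ", paste(viol, collapse = "\n  "))
  stopifnot(is(prior, "DirichletPrior"),
            length(prior@alpha) == length(scenario@groups))

  groups <- scenario@groups; fracs <- scenario@fractions
  proxies <- scenario@proxies
  nI <- length(groups); nJ <- length(fracs); nK <- length(proxies)
  nZ <- nI - 1L

  sMean <- scenario@signalMean; sSD <- scenario@signalSD
  avail <- scenario@signalAvailable
  cMean <- scenario@concMean; cSD <- scenario@concSD
  wMean <- scenario@weightMean; wSD <- scenario@weightSD
  dMean <- scenario@offsetMean; dSD <- scenario@offsetSD
  pMean <- scenario@consumerMean; pSD <- scenario@consumerSD

  # which fractions participate in each proxy (positive or uncertain weight)
  activeJ <- lapply(seq_len(nK), function(k)
    which(wMean[, k] > 0 | wSD[, k] > 0))

  # latent layout: [z | signals | offsets | weights | concentrations]
  sigSub <- which(avail & sSD > 0, arr.ind = TRUE)
  if (nrow(sigSub)) {
    keep <- vapply(seq_len(nrow(sigSub)), function(r)
      sigSub[r, 2L] %in% activeJ[[sigSub[r, 3L]]], logical(1))
    sigSub <- sigSub[keep, , drop = FALSE]
  }
  offIdx <- which(dSD > 0)
  wgtSub <- which(wSD > 0, arr.ind = TRUE)
  conSub <- which(cSD > 0, arr.ind = TRUE)

  nSig <- nrow(sigSub); nOff <- length(offIdx)
  nWgt <- nrow(wgtSub); nCon <- nrow(conSub)
  pos <- nZ
  sigPos <- seq_len(nSig) + pos; pos <- pos + nSig
  offPos <- seq_len(nOff) + pos; pos <- pos + nOff
  wgtPos <- seq_len(nWgt) + pos; pos <- pos + nWgt
  conPos <- seq_len(nCon) + pos; pos <- pos + nCon
  nParams <- pos

  latMean <- c(sMean[sigSub], dMean[offIdx], wMean[wgtSub], cMean[conSub])
  latSD <- c(sSD[sigSub], dSD[offIdx], wSD[wgtSub], cSD[conSub])
  latPos <- c(sigPos, offPos, wgtPos, conPos)
  truncPos <- c(wgtPos, conPos)  # weights and concentrations live on [0, Inf)

  renormProxies <- integer(0)
  if (nWgt) {
    tab <- table(wgtSub[, 2L])
    renormProxies <- as.integer(names(tab)[tab > 1L])
    if (length(renormProxies))
      message("proxies with several uncertain routing weights are renormalized to 100 per draw: ",
              paste(proxies[renormProxies], collapse = ", "))
  }

  obsK <- which(is.finite(pSD) & pSD > 0)
  priorA <- prior@alpha
  priorConst <- lgamma(sum(priorA)) - sum(lgamma(priorA))
  nonBulk <- which(!(fracs %in% scenario@bulkFractions))
  needBeta <- any(vapply(constraints, function(ct) length(ct@betaCoef) > 0, logical(1)))
  sbShift <- log(nI - seq_len(nZ))  # centering: z = 0 gives the barycenter

  sticksToAlpha <- function(z) {
    v <- stats::plogis(z - sbShift)
    alpha <- numeric(nI)
    stick <- 1
    lj <- 0
    for (m in seq_len(nZ)) {
      alpha[m] <- v[m] * stick
      lj <- lj + log(v[m]) + log1p(-v[m]) + log(stick)
      stick <- stick * (1 - v[m])
    }
    alpha[nI] <- stick
    list(alpha = alpha, logJac = lj)
  }

  assembleState <- function(theta) {
    s <- sMean; conc <- cMean; wgt <- wMean; delta <- dMean
    if (nSig) s[sigSub] <- theta[sigPos]
    if (nOff) delta[offIdx] <- theta[offPos]
    if (nWgt) wgt[wgtSub] <- theta[wgtPos]
    if (nCon) conc[conSub] <- theta[conPos]
    for (k in renormProxies) wgt[, k] <- 100 * wgt[, k] / sum(wgt[, k])
    list(s = s, conc = conc, wgt = wgt, delta = delta)
  }

  logDensityFun <- function(theta) {
    sb <- sticksToAlpha(theta[seq_len(nZ)])
    alpha <- sb$alpha
    if (any(alpha <= 0)) return(-Inf)
    lp <- priorConst + sum((priorA - 1) * log(alpha)) + sb$logJac
    if (length(truncPos) && any(theta[truncPos] < 0)) return(-Inf)
    if (length(latPos))
      lp <- lp + sum(stats::dnorm(theta[latPos], latMean, latSD, log = TRUE))

    st <- assembleState(theta)
    for (k in obsK) {
      pred <- st$delta[k]
      for (j in activeJ[[k]]) {
        w <- st$wgt[j, k]
        if (w == 0) next
        ac <- alpha * st$conc[, j]
        denom <- sum(ac)
        if (denom <= 0) return(-Inf)
        pred <- pred + (w / 100) * sum(ac * st$s[, j, k]) / denom
      }
      lp <- lp + stats::dnorm(pMean[[k]], unname(pred), pSD[[k]], log = TRUE)
    }

    if (length(constraints)) {
      names(alpha) <- groups
      beta <- NULL
      if (needBeta) {
        mass <- as.numeric(alpha %*% st$conc)
        tot <- sum(mass[nonBulk])
        if (tot <= 0) return(-Inf)
        beta <- stats::setNames(mass / tot, fracs)
      }
      for (ct in constraints) {
        lp <- lp + constraintLogTerm(ct, alpha, beta)
        if (lp == -Inf) return(-Inf)
      }
    }
    unname(lp)
  }

  derivedNames <- c(
    paste0("alpha_", groups),
    paste0("beta_", fracs[nonBulk]),
    as.vector(outer(groups, proxies, function(g, k) paste0("pi_", g, "_", k))),
    if (nSig) sprintf("s_%s_%s_%s", groups[sigSub[, 1L]], fracs[sigSub[, 2L]],
                      proxies[sigSub[, 3L]]),
    if (nOff) paste0("delta_", proxies[offIdx]),
    if (nWgt) sprintf("w_%s_%s", fracs[wgtSub[, 1L]], proxies[wgtSub[, 2L]]),
    if (nCon) sprintf("c_%s_%s", groups[conSub[, 1L]], fracs[conSub[, 2L]]))

  transformFun <- function(theta) {
    alpha <- sticksToAlpha(theta[seq_len(nZ)])$alpha
    st <- assembleState(theta)
    mass <- as.numeric(alpha %*% st$conc)
    tot <- sum(mass[nonBulk])
    beta <- if (tot > 0) mass / tot else rep(NA_real_, nJ)
    piMat <- matrix(NA_real_, nI, nK)
    for (k in seq_len(nK)) {
      m <- as.numeric(st$conc %*% (st$wgt[, k] / 100)) * alpha
      tm <- sum(m)
      if (tm > 0) piMat[, k] <- m / tm
    }
    out <- c(alpha, beta[nonBulk], as.vector(piMat),
             if (nSig) theta[sigPos], if (nOff) theta[offPos],
             if (nWgt) theta[wgtPos], if (nCon) theta[conPos])
    names(out) <- derivedNames
    out
  }

  # update blocks: sticks singly; latents in small role-based groups
  blocks <- as.list(seq_len(nZ))
  if (nSig) {
    key <- paste(sigSub[, 2L], sigSub[, 3L])  # one block per fraction x proxy
    blocks <- c(blocks, unname(split(sigPos, key)))
  }
  if (nOff) blocks <- c(blocks, as.list(offPos))
  if (nWgt) blocks <- c(blocks, unname(split(wgtPos, wgtSub[, 2L])))
  if (nCon) blocks <- c(blocks, unname(split(conPos, conSub[, 2L])))

  baseScales <- rep(1, nParams)
  if (length(latPos)) baseScales[latPos] <- latSD

  initFun <- function(chain) {
    theta <- numeric(nParams)
    theta[seq_len(nZ)] <- stats::rnorm(nZ, 0, 0.2)
    if (length(latPos)) theta[latPos] <- latMean
    theta
  }

  structure(
    list(logDensity = logDensityFun, transform = transformFun,
         nParams = nParams, paramNames = derivedNames,
         blocks = blocks, baseScales = baseScales, init = initFun,
         scenario = scenario),
    class = "mixingPosterior")
}

#' Wrap a bare log-density for the sampler
#'
#' Convenience wrapper so \code{\link{runMcmc}} can target an arbitrary
#' log-density (e.g. for sampler calibration checks) with the same
#' machinery used for mixing-model posteriors.
#'
#' @param logDensity function of a numeric vector returning a log-density.
#' @param nParams parameter dimension.
#' @param paramNames optional names for the draws.
#' @param init function(chain) returning an initial vector, or a numeric
#'   vector used for every chain.
#' @param blocks list of index vectors updated jointly; defaults to
#'   componentwise updates.
#' @param baseScales per-parameter base proposal scales.
#' @return an object of class \code{"mixingPosterior"}.
#' @export
mcmcModel <- function(logDensity, nParams,
                      paramNames = paste0("p", seq_len(nParams)),
                      init = function(chain) stats::rnorm(nParams),
                      blocks = as.list(seq_len(nParams)),
                      baseScales = rep(1, nParams)) {
  if (is.numeric(init)) {
    initVec <- init
    init <- function(chain) initVec + stats::rnorm(nParams, 0, 0.01)
  }
  structure(
    list(logDensity = logDensity,
         transform = function(theta) stats::setNames(theta, paramNames),
         nParams = nParams, paramNames = paramNames,
         blocks = blocks, baseScales = baseScales, init = init,
         scenario = NULL),
    class = "mixingPosterior")
}
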