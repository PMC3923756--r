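#' Sampler configuration
#'
#' Defaults (4 chains of 30,000 iterations, 10,000 burn-in, thinning 2) are
#' sized so that scenarios with a handful of food groups converge in seconds
#' to a few minutes. Step sizes adapt only during burn-in (Robbins-Monro on
#' the log scale, targeting an acceptance rate of about 0.37), so the
#' post-burn-in chain is a fixed-kernel Metropolis sampler.
#'
#' @param seed integer seed; required, drives every source of randomness.
#' @param nChains number of independent chains (>= 2 for diagnostics).
#' @param nIterations total iterations per chain.
#' @param burnIn iterations discarded (and used for adaptation); must be
#'   smaller than \code{nIterations}.
#' @param thin keep every \code{thin}-th post-burn-in draw.
#' @param targetAcceptance adaptation target for the acceptance rate.
#' @param maxInitRetries reinitialization attempts when the log-density is
#'   non-finite at the start.
#' @return a list of class \code{"samplerConfig"}.
#' @export
samplerConfig <- function(seed, nChains = 4L, nIterations = 30000L,
                          burnIn = 10000L, thin = 2L,
                          targetAcceptance = 0.37, maxInitRetries = 100L) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            nChains >= 1L, thin >= 1L, burnIn >= 0L, burnIn < nIterations,
            targetAcceptance > 0, targetAcceptance < 1)
  structure(
    list(seed = as.integer(seed), nChains = as.integer(nChains),
         nIterations = as.integer(nIterations), burnIn = as.integer(burnIn),
         thin = as.integer(thin), targetAcceptance = targetAcceptance,
         maxInitRetries = as.integer(maxInitRetries)),
    class = "samplerConfig")
}

#' Run the blocked adaptive Metropolis sampler
#'
#' Gradient-free random-walk Metropolis on the model's unconstrained
#' parameterization: stick-breaking coordinates are updated one at a time
#' and latent nuisance parameters in small role-based blocks, with
#' per-block step sizes adapted during burn-in only. Proposals that violate
#' a hard inequality constraint (or any support bound) carry a log-density
#' of \code{-Inf} and are rejected, which preserves detailed balance.
#' Results are bitwise-reproducible for a given (model, config) pair.
#'
#' @param model a \code{"mixingPosterior"} from
#'   \code{\link{buildPosteriorLogDensity}} or \code{\link{mcmcModel}}.
#' @param config a \code{\link{samplerConfig}}.
#' @return a \linkS4class{PosteriorChains} with post-burn-in, thinned draws
#'   of the model's derived quantities.
#' @examples
#' sc <- builtinScenario("table1")
#' post <- buildPosteriorLogDensity(sc)
#' fit <- runMcmc(post, samplerConfig(seed = 1, nIterations = 4000,
#'                                    burnIn = 1000))
#' summarizePosterior(fit, grep("^alpha_", fit@paramNames, value = TRUE))
#' @export
runMcmc <- function(model, config) {
  stopifnot(inherits(model, "mixingPosterior"),
            inherits(config, "samplerConfig"))
  f <- model$logDensity
  blocks <- model$blocks
  nB <- length(blocks)
  scale0 <- model$baseScales
  scale0[scale0 <= 0] <- 1
  nStore <- (config$nIterations - config$burnIn) %/% config$thin
  if (nStore < 1L) stop("no post-burn-in draws to store")

  chains <- vector("list", config$nChains)
  accept <- matrix(NA_real_, config$nChains, nB)
  for (chain in seq_len(config$nChains)) {
    set.seed(chainSeed(config$seed, chain))
    theta <- model$init(chain)
    lp <- f(theta)
    tries <- 0L
    while (!is.finite(lp) && tries < config$maxInitRetries) {
      theta <- model$init(chain)
      lp <- f(theta)
      tries <- tries + 1L
    }
    if (!is.finite(lp))
      stop(sprintf("chain %d: log-density non-finite after %d initializations",
                   chain, tries))

    ls <- rep(log(0.5), nB)          # log step-size multipliers
    accN <- accD <- numeric(nB)
    raw <- matrix(NA_real_, nStore, model$nParams)
    row <- 0L
    for (it in seq_len(config$nIterations)) {
      adapting <- it <= config$burnIn
      for (b in seq_len(nB)) {
        idx <- blocks[[b]]
        prop <- theta
        prop[idx] <- prop[idx] +
          exp(ls[b]) * scale0[idx] * stats::rnorm(length(idx))
        lpP <- f(prop)
        acc <- is.finite(lpP) && (lpP - lp >= 0 || lpP - lp > log(stats::runif(1)))
        if (acc) { theta <- prop; lp <- lpP }
        if (adapting) {
          ls[b] <- ls[b] + (1 + it)^-0.6 *
            ((if (acc) 1 else 0) - config$targetAcceptance)
        } else {
          accD[b] <- accD[b] + 1
          if (acc) accN[b] <- accN[b] + 1
        }
      }
      if (!adapting && (it - config$burnIn) %% config$thin == 0L) {
        row <- row + 1L
        raw[row, ] <- theta
      }
    }
    drawMat <- t(apply(raw[seq_len(row), , drop = FALSE], 1L, model$transform))
    if (length(model$paramNames) == 1L) drawMat <- t(drawMat)
    colnames(drawMat) <- model$paramNames
    chains[[chain]] <- drawMat
    accept[chain, ] <- ifelse(accD > 0, accN / accD, NA_real_)
  }

  new("PosteriorChains",
      draws = chains, paramNames = model$paramNames,
      config = unclass(config), acceptance = accept)
}

chainSeed <- function(seed, chain) {
  ((seed %% 1000000L) * 2000L + chain) %% .Machine$integer.max
}

#' @param x a \linkS4class{PosteriorChains}.
#' @param params optional character vector restricting to some parameters.
#' @return \code{nChains}/\code{nDraws}: integers; \code{pooledDraws}: a
#'   matrix with all chains stacked.
#' @rdname nChains
#' @export
setMethod("nChains", "PosteriorChains", function(x) length(x@draws))

#' @rdname nChains
#' @export
setMethod("nDraws", "PosteriorChains",
          function(x) sum(vapply(x@draws, nrow, integer(1))))

#' @rdname nChains
#' @export
setMethod("pooledDraws", "PosteriorChains", function(x, params = NULL) {
  out <- do.call(rbind, x@draws)
  if (!is.null(params)) {
    miss <- setdiff(params, colnames(out))
    if (length(miss)) stop("unknown parameters: ", paste(miss, collapse = ", "))
    out <- out[, params, drop = FALSE]
  }
  out
})

setMethod("show", "PosteriorChains", function(object) {
  cat("PosteriorChains:", nChains(object), "chains x",
      nrow(object@draws[[1]]), "draws of", length(object@paramNames),
      "parameters\n")
  cat("  seed:", object@config$seed,
      " iterations:", object@config$nIterations,
      " burn-in:", object@config$burnIn,
      " thin:", object@config$thin, "\n")
  ar <- range(object@acceptance, na.rm = TRUE)
  cat(sprintf("  acceptance rates: %.2f-%.2f\n", ar[1], ar[2]))
  invisible(NULL)
})
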