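#' Convergence diagnostics for posterior chains
#'
#' Computes split-\eqn{\hat{R}} (each chain halved, between/within variance
#' ratio) and the effective sample size (via \code{coda::effectiveSize} on
#' the pooled per-chain series) for every parameter, flagging those with
#' \eqn{\hat{R} > 1.05} or ESS < 400. Degenerate (constant) chains yield an
#' \code{NA} \eqn{\hat{R}} and are flagged rather than raising an error.
#'
#' @param chains a \linkS4class{PosteriorChains} with at least 2 chains.
#' @param rhatLimit,essLimit flagging thresholds.
#' @return data.frame with columns \code{parameter}, \code{rhat},
#'   \code{ess}, \code{flagged}.
#' @export
diagnoseChains <- function(chains, rhatLimit = 1.05, essLimit = 400) {
  stopifnot(is(chains, "PosteriorChains"))
  if (nChains(chains) < 2L)
    stop("need at least 2 chains for convergence diagnostics")
  pn <- chains@paramNames
  rhat <- vapply(pn, function(p)
    splitRhat(lapply(chains@draws, function(d) d[, p])), numeric(1))
  ess <- vapply(pn, function(p) {
    sum(vapply(chains@draws, function(d) {
      x <- d[, p]
      if (stats::var(x) == 0 || anyNA(x)) return(NA_real_)
      as.numeric(coda::effectiveSize(coda::mcmc(x)))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  data.frame(
    parameter = pn,
    rhat = rhat,
    ess = ess,
    flagged = is.na(rhat) | rhat > rhatLimit | ess < essLimit,
    row.names = NULL)
}

# split-Rhat (each chain split in half; rank-free version)
splitRhat <- function(chainList) {
  halves <- unlist(lapply(chainList, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[seq_len(n) + n])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior summary table
#'
#' Pools all post-burn-in draws and reports, per parameter, the posterior
#' mean, median, sd and the 2.5/16/50/84/97.5 percentiles — i.e. the bounds
#' of the 68% and 95% credible intervals. Percentiles use the linear
#' interpolation rule (\code{stats::quantile} type 7). Split-\eqn{\hat{R}}
#' and ESS are appended when at least two chains are available.
#'
#' @param chains a \linkS4class{PosteriorChains}.
#' @param params optional character vector of parameters to summarize
#'   (default: all).
#' @return data.frame with one row per parameter and columns
#'   \code{parameter}, \code{mean}, \code{median}, \code{sd}, \code{p2.5},
#'   \code{p16}, \code{p50}, \code{p84}, \code{p97.5}, \code{rhat},
#'   \code{ess}.
#' @export
summarizePosterior <- function(chains, params = NULL) {
  stopifnot(is(chains, "PosteriorChains"))
  pooled <- pooledDraws(chains, params)
  if (nrow(pooled) == 0L) stop("no draws to summarize")
  qs <- c(0.025, 0.16, 0.5, 0.84, 0.975)
  stats <- t(apply(pooled, 2L, function(x) {
    c(mean(x), stats::median(x), stats::sd(x),
      stats::quantile(x, qs, names = FALSE, type = 7))
  }))
  out <- data.frame(
    parameter = colnames(pooled),
    mean = stats[, 1], median = stats[, 2], sd = stats[, 3],
    p2.5 = stats[, 4], p16 = stats[, 5], p50 = stats[, 6],
    p84 = stats[, 7], p97.5 = stats[, 8],
    row.names = NULL)
  if (nChains(chains) >= 2L) {
    d <- diagnoseChains(chains)
    idx <- match(out$parameter, d$parameter)
    out$rhat <- d$rhat[idx]
    out$ess <- d$ess[idx]
  } else {
    out$rhat <- NA_real_
    out$ess <- NA_real_
  }
  out
}
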