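#' Routed, concentration-dependent forward mixing model
#'
#' Computes the consumer signal predicted for a proxy by the routed mixing
#' model. For each food fraction \eqn{j} with positive routing weight, the
#' concentration-weighted source average is
#' \deqn{m_{jk} = \sum_i \alpha_i c_{ij} s_{ijk} / \sum_i \alpha_i c_{ij},}
#' and the prediction is
#' \deqn{P_k = \Delta_k + \sum_j (w_{jk}/100)\, m_{jk}.}
#' The routing weight applies to the per-fraction normalized average: weights
#' describe the physiology of signal formation and are independent of how
#' concentrated the fractions happen to be in a given diet. Zero-weight
#' fractions are skipped entirely, so their signals may be absent.
#'
#' @param scenario a \linkS4class{DietaryScenario}.
#' @param alpha numeric vector of food-group proportions on the simplex
#'   (length = number of groups, non-negative, summing to 1).
#' @param state latent state as returned by \code{\link{stateAtMeans}};
#'   defaults to all quantities at their means.
#' @param proxy proxy name or index; \code{NULL} for all proxies.
#' @return named numeric vector of predicted consumer signals (per mil).
#' @examples
#' sc <- builtinScenario("table1")
#' predictConsumerSignal(sc, c(0.7, 0.2, 0.1))  # 6.6 per mil
#' @export
predictConsumerSignal <- function(scenario, alpha, state = stateAtMeans(scenario),
                                  proxy = NULL) {
  alpha <- checkSimplex(alpha, length(scenario@groups), "alpha")
  ks <- resolveProxy(scenario, proxy)
  out <- numeric(length(ks))
  names(out) <- scenario@proxies[ks]
  for (n in seq_along(ks)) {
    k <- ks[n]
    pred <- state$delta[k]
    for (j in seq_along(scenario@fractions)) {
      w <- state$wgt[j, k]
      if (w == 0) next
      denom <- sum(alpha * state$conc[, j])
      if (denom <= 0)
        stop(sprintf(
          "degenerate mixture: no intake carries fraction '%s' for proxy '%s'",
          scenario@fractions[j], scenario@proxies[k]))
      pred <- pred + (w / 100) * sum(alpha * state$conc[, j] * state$s[, j, k]) / denom
    }
    out[n] <- pred
  }
  out
}

#' Relative intake of each food fraction
#'
#' The diet-wide share of each food fraction, a concentration-weighted
#' average of group intakes:
#' \deqn{\beta_j = \sum_i \alpha_i c_{ij} / \sum_{j'} \sum_i \alpha_i c_{ij'}.}
#' Bulk pseudo-fractions are excluded from the normalization (their
#' concentration is an alias of the macronutrient total, and including them
#' would double-count every gram of the base element); their \eqn{\beta} is
#' reported as \code{NA}.
#'
#' @inheritParams predictConsumerSignal
#' @return named numeric vector over fractions, summing to 1 over non-bulk
#'   fractions.
#' @examples
#' sc <- builtinScenario("hare_a")
#' fractionIntake(sc, c(0, 0, 0, 0.69, 0.31))
#' @export
fractionIntake <- function(scenario, alpha, state = stateAtMeans(scenario)) {
  alpha <- checkSimplex(alpha, length(scenario@groups), "alpha")
  keep <- !(scenario@fractions %in% scenario@bulkFractions)
  mass <- as.numeric(alpha %*% state$conc)  # per fraction
  names(mass) <- scenario@fractions
  tot <- sum(mass[keep])
  if (tot <= 0)
    stop("all fraction concentrations are zero at this intake")
  beta <- mass / tot
  beta[!keep] <- NA_real_
  beta
}

#' Contribution of each food group to a proxy signal
#'
#' The share of the proxy-\eqn{k} signal mass attributable to each food
#' group, aggregating the routing-weighted masses
#' \eqn{\alpha_i (w_{jk}/100) c_{ij}} over fractions and normalizing over
#' groups. Useful e.g. to quantify the aquatic-carbon share of collagen for
#' radiocarbon reservoir corrections.
#'
#' @inheritParams predictConsumerSignal
#' @param proxy proxy name or index (required, single).
#' @return named numeric vector over groups, summing to 1.
#' @export
proxyContribution <- function(scenario, alpha, state = stateAtMeans(scenario),
                              proxy) {
  alpha <- checkSimplex(alpha, length(scenario@groups), "alpha")
  k <- resolveProxy(scenario, proxy)
  if (length(k) != 1L) stop("'proxy' must name a single proxy")
  mass <- as.numeric(state$conc %*% (state$wgt[, k] / 100)) * alpha
  tot <- sum(mass)
  if (tot <= 0)
    stop(sprintf("zero total signal mass for proxy '%s'", scenario@proxies[k]))
  stats::setNames(mass / tot, scenario@groups)
}

checkSimplex <- function(alpha, n, what, tol = 1e-8) {
  alpha <- as.numeric(alpha)
  if (length(alpha) != n)
    stop(sprintf("'%s' must have length %d", what, n))
  if (any(alpha < -tol) || abs(sum(alpha) - 1) > tol)
    stop(sprintf("'%s' must be a simplex vector (>= 0, summing to 1)", what))
  pmax(alpha, 0)
}

resolveProxy <- function(scenario, proxy) {
  if (is.null(proxy)) return(seq_along(scenario@proxies))
  if (is.character(proxy)) {
    k <- match(proxy, scenario@proxies)
    if (anyNA(k)) stop("unknown proxy: ", paste(proxy[is.na(k)], collapse = ", "))
    return(k)
  }
  k <- as.integer(proxy)
  if (any(k < 1L | k > length(scenario@proxies))) stop("proxy index out of range")
  k
}
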