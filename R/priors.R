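#' Beta shape parameters from mean and standard deviation
#'
#' Moment-matches a Beta(a, b) distribution to a requested mean and sd:
#' \deqn{a = m\left(\frac{m(1-m)}{s^2} - 1\right), \qquad
#'       b = (1-m)\left(\frac{m(1-m)}{s^2} - 1\right).}
#' Used to elicit informative marginal priors on individual intake
#' proportions, which can then seed a Dirichlet prior.
#'
#' @param mean target mean, in (0, 1).
#' @param sd target sd; must satisfy \code{sd^2 < mean * (1 - mean)}.
#' @return list with elements \code{a} and \code{b}.
#' @examples
#' betaShapesFromMoments(0.5, sqrt(1 / 12))  # a = b = 1, the uniform
#' @export
betaShapesFromMoments <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), length(mean) == 1L, length(sd) == 1L)
  if (!(mean > 0 && mean < 1)) stop("'mean' must lie strictly in (0, 1)")
  if (sd <= 0) stop("'sd' must be > 0")
  bound <- mean * (1 - mean)
  if (sd^2 >= bound)
    stop(sprintf("infeasible beta variance: need sd^2 < mean*(1-mean) = %g", bound))
  nu <- bound / sd^2 - 1
  list(a = mean * nu, b = (1 - mean) * nu)
}

#' Dirichlet prior over the intake simplex
#'
#' The standard prior over food-group proportions; unit hyperparameters give
#' the flat prior. An informative marginal for one component can be set via
#' \code{\link{betaShapesFromMoments}}: component \code{i} with shapes
#' (a, b) corresponds to hyperparameters \code{alpha[i] = a} and the
#' remaining mass \code{b} spread over the other components.
#'
#' @param nGroups number of food groups (>= 2).
#' @param alpha positive hyperparameter vector of length \code{nGroups};
#'   defaults to all ones.
#' @return a \linkS4class{DirichletPrior}.
#' @examples
#' p <- dirichletPrior(3)
#' draws <- sampleFrom(p, 1000, seed = 1)
#' colMeans(draws)  # ~ 1/3 each
#' @export
dirichletPrior <- function(nGroups, alpha = rep(1, nGroups)) {
  stopifnot(length(alpha) == nGroups)
  new("DirichletPrior", alpha = as.numeric(alpha))
}

#' Log-density and sampling for prior objects
#'
#' @param object a \linkS4class{DirichletPrior}.
#' @param x simplex vector (or matrix of row vectors) at which to evaluate
#'   the log-density.
#' @param n number of draws.
#' @param seed optional integer seed for reproducible sampling.
#' @param ... unused.
#' @return \code{logDensity}: numeric log-density (\code{-Inf} off the open
#'   simplex); \code{sampleFrom}: an \code{n x k} matrix of simplex draws.
#' @rdname logDensity
#' @export
setMethod("logDensity", "DirichletPrior", function(object, x, ...) {
  a <- object@alpha
  dens1 <- function(p) {
    if (length(p) != length(a) || any(p <= 0) || abs(sum(p) - 1) > 1e-8)
      return(-Inf)
    sum((a - 1) * log(p)) + lgamma(sum(a)) - sum(lgamma(a))
  }
  if (is.matrix(x)) apply(x, 1L, dens1) else dens1(as.numeric(x))
})

#' @rdname logDensity
#' @export
setMethod("sampleFrom", "DirichletPrior", function(object, n, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  a <- object@alpha
  g <- matrix(stats::rgamma(n * length(a), shape = rep(a, each = n)),
              nrow = n)
  g / rowSums(g)
})

setMethod("show", "DirichletPrior", function(object) {
  cat("DirichletPrior(", paste(format(object@alpha), collapse = ", "), ")\n",
      sep = "")
  invisible(NULL)
})
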