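#' @import methods
NULL

#' Dietary scenario: the full specification of a mixing problem
#'
#' A \code{DietaryScenario} bundles everything needed to pose a diet
#' reconstruction problem: the axes (food groups \eqn{i}, food fractions
#' \eqn{j}, dietary proxies \eqn{k}) and the mean/sd tables for source
#' signals \eqn{S_{ijk}} (per mil), fraction concentrations \eqn{c_{ij}}
#' (percent of a common base, e.g. carbon dry weight), routing weights
#' \eqn{w_{jk}} (percent, summing to 100 over fractions for each proxy),
#' diet-to-tissue offsets \eqn{\Delta_k} (per mil) and measured consumer
#' signals \eqn{P_k} (per mil).
#'
#' An sd of 0 encodes a fixed (non-stochastic) quantity. Signals can be
#' marked unavailable (\code{signalAvailable}); a signal is only required
#' where the fraction carries positive routing weight for that proxy and the
#' group has positive concentration in that fraction.
#'
#' Fractions listed in \code{bulkFractions} are "scrambled whole-food"
#' pseudo-fractions: they take part in the mixing equation like any other
#' fraction, but are excluded from the fraction-intake normalization (and so
#' cannot be referenced by constraints), since their concentration is an
#' alias of the macronutrient total rather than an additional component.
#'
#' @slot groups,fractions,proxies character vectors naming the axes.
#' @slot signalMean,signalSD numeric arrays, groups x fractions x proxies.
#' @slot signalAvailable logical array of the same shape.
#' @slot concMean,concSD numeric matrices, groups x fractions.
#' @slot weightMean,weightSD numeric matrices, fractions x proxies.
#' @slot offsetMean,offsetSD numeric vectors over proxies.
#' @slot consumerMean,consumerSD numeric vectors over proxies.
#' @slot bulkFractions character, subset of \code{fractions}.
#' @slot constraints list of \linkS4class{Constraint} objects.
#' @seealso \code{\link{dietaryScenario}}, \code{\link{validateScenario}},
#'   \code{\link{builtinScenario}}
#' @export
setClass("DietaryScenario",
  representation(
    groups = "character",
    fractions = "character",
    proxies = "character",
    signalMean = "array",
    signalSD = "array",
    signalAvailable = "array",
    concMean = "matrix",
    concSD = "matrix",
    weightMean = "matrix",
    weightSD = "matrix",
    offsetMean = "numeric",
    offsetSD = "numeric",
    consumerMean = "numeric",
    consumerSD = "numeric",
    bulkFractions = "character",
    constraints = "list"
  )
)

setValidity("DietaryScenario", function(object) {
  v <- validateScenario(object)
  if (length(v) == 0L) TRUE else v
})

#' Algebraic prior constraint on intake proportions
#'
#' A linear relation over food-group intakes (\eqn{\alpha}) and
#' food-fraction intakes (\eqn{\beta}), canonicalized to either
#' \eqn{g = 0} (equality, enforced through a normal pseudo-observation of
#' zero with a small sd \code{sigma}) or \eqn{g > 0} (inequality, enforced
#' through a Bernoulli/Heaviside pseudo-observation of one, i.e. hard
#' truncation of the posterior support; \eqn{H(0) = 1}).
#'
#' @slot label the original constraint text.
#' @slot alphaCoef,betaCoef named numeric coefficient vectors over groups
#'   and (non-bulk) fractions.
#' @slot constant numeric intercept of \eqn{g}, on the proportion scale.
#' @slot relation \code{"eq"} or \code{"gt"}.
#' @slot sigma pseudo-observation sd for equalities (proportion scale).
#' @seealso \code{\link{parseConstraint}}, \code{\link{constraintLogTerm}}
#' @export
setClass("Constraint",
  representation(
    label = "character",
    alphaCoef = "numeric",
    betaCoef = "numeric",
    constant = "numeric",
    relation = "character",
    sigma = "numeric"
  )
)

setValidity("Constraint", function(object) {
  msg <- character()
  if (!object@relation %in% c("eq", "gt"))
    msg <- c(msg, "relation must be 'eq' or 'gt'")
  if (object@relation == "eq" && (length(object@sigma) != 1L || object@sigma <= 0))
    msg <- c(msg, "equality constraints need a single sigma > 0")
  if (length(msg)) msg else TRUE
})

#' Dirichlet prior over intake proportions
#'
#' @slot alpha positive hyperparameter vector, one entry per food group;
#'   all ones is the flat prior on the simplex.
#' @seealso \code{\link{dirichletPrior}}
#' @export
setClass("DirichletPrior", representation(alpha = "numeric"))

setValidity("DirichletPrior", function(object) {
  if (length(object@alpha) < 2L) return("need at least 2 components")
  if (any(!is.finite(object@alpha)) || any(object@alpha <= 0))
    return("hyperparameters must be finite and > 0")
  TRUE
})

#' Posterior draws from the mixing model sampler
#'
#' Holds per-chain matrices of post-burn-in, thinned draws of every derived
#' and latent quantity: intake proportions \code{alpha_<group>}, fraction
#' intakes \code{beta_<fraction>}, proxy contributions
#' \code{pi_<group>_<proxy>}, and sampled latent signals, offsets, weights
#' and concentrations. Also records the sampler configuration, the seed and
#' per-block acceptance rates.
#'
#' @slot draws list of numeric matrices (draws x parameters), one per chain,
#'   with identical column names.
#' @slot paramNames character, the column names.
#' @slot config the \code{\link{samplerConfig}} list used.
#' @slot acceptance numeric matrix of per-chain, per-block acceptance rates.
#' @seealso \code{\link{runMcmc}}, \code{\link{summarizePosterior}},
#'   \code{\link{diagnoseChains}}
#' @export
setClass("PosteriorChains",
  representation(
    draws = "list",
    paramNames = "character",
    config = "list",
    acceptance = "matrix"
  )
)

setValidity("PosteriorChains", function(object) {
  if (length(object@draws) < 1L) return("no chains")
  ok <- vapply(object@draws, function(d)
    is.matrix(d) && identical(colnames(d), object@paramNames), logical(1))
  if (!all(ok)) return("all chains must share the recorded parameter names")
  TRUE
})
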