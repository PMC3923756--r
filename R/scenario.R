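#' Construct a dietary scenario
#'
#' Builds and validates a \linkS4class{DietaryScenario}. Mean/sd pairs are
#' given as separate tables; any sd may be omitted (defaults to 0, i.e. a
#' fixed quantity). Signals that are genuinely unavailable (a fraction that
#' does not contribute to a proxy) are encoded as \code{NA} in
#' \code{signalMean}.
#'
#' @param groups,fractions,proxies character vectors naming the axes; names
#'   must be unique within each axis.
#' @param signalMean numeric array \code{groups x fractions x proxies} of
#'   source signals (per mil); \code{NA} marks an unavailable signal.
#' @param signalSD like \code{signalMean}; \code{NA} or 0 where fixed.
#' @param concMean,concSD numeric matrices \code{groups x fractions},
#'   fraction concentrations in percent of the common base.
#' @param weightMean,weightSD numeric matrices \code{fractions x proxies},
#'   routing weights in percent; each proxy's column must sum to 100.
#' @param offsetMean,offsetSD numeric vectors over proxies, diet-to-tissue
#'   offsets in per mil. The sign convention is
#'   \emph{consumer = mixture + offset}: positive offsets are enrichments of
#'   the consumer tissue relative to diet.
#' @param consumerMean,consumerSD numeric vectors over proxies, the measured
#'   consumer signals and their measurement sds.
#' @param bulkFractions character, names of scrambled whole-food
#'   pseudo-fractions (see \linkS4class{DietaryScenario}).
#' @param constraints list of \linkS4class{Constraint} objects or character
#'   constraint strings (parsed with \code{\link{parseConstraint}}).
#' @return a validated \linkS4class{DietaryScenario}.
#' @examples
#' sc <- dietaryScenario(
#'   groups = c("A", "B"), fractions = "Protein", proxies = "d15N",
#'   signalMean = array(c(0, 10), c(2, 1, 1)),
#'   concMean = matrix(100, 2, 1),
#'   weightMean = matrix(100, 1, 1),
#'   offsetMean = 0, consumerMean = 5, consumerSD = 0.5)
#' foodGroups(sc)
#' @export
dietaryScenario <- function(groups, fractions, proxies,
                            signalMean, signalSD = NULL,
                            concMean, concSD = NULL,
                            weightMean, weightSD = NULL,
                            offsetMean, offsetSD = NULL,
                            consumerMean, consumerSD = NULL,
                            bulkFractions = character(),
                            constraints = list()) {
  nI <- length(groups); nJ <- length(fractions); nK <- length(proxies)
  dimSig <- c(nI, nJ, nK)
  dn3 <- list(groups, fractions, proxies)

  shape3 <- function(x, default = 0) {
    if (is.null(x)) x <- array(default, dimSig)
    x <- array(as.numeric(x), dimSig, dimnames = dn3)
    x
  }
  shape2 <- function(x, default = 0) {
    if (is.null(x)) x <- matrix(default, nI, nJ)
    matrix(as.numeric(x), nI, nJ, dimnames = list(groups, fractions))
  }
  shapeJK <- function(x, default = 0) {
    if (is.null(x)) x <- matrix(default, nJ, nK)
    matrix(as.numeric(x), nJ, nK, dimnames = list(fractions, proxies))
  }
  shapeK <- function(x, default = 0) {
    if (is.null(x)) x <- rep(default, nK)
    stats::setNames(as.numeric(x), proxies)
  }

  sm <- shape3(signalMean)
  ss <- shape3(signalSD)
  ss[is.na(ss)] <- 0
  avail <- !is.na(sm)
  sm[!avail] <- 0

  obj <- new("DietaryScenario",
    groups = as.character(groups),
    fractions = as.character(fractions),
    proxies = as.character(proxies),
    signalMean = sm, signalSD = ss, signalAvailable = avail,
    concMean = shape2(concMean), concSD = shape2(concSD),
    weightMean = shapeJK(weightMean), weightSD = shapeJK(weightSD),
    offsetMean = shapeK(offsetMean), offsetSD = shapeK(offsetSD),
    consumerMean = shapeK(consumerMean), consumerSD = shapeK(consumerSD),
    bulkFractions = as.character(bulkFractions),
    constraints = list()
  )
  # constraints may reference the scenario's own names, so parse after the
  # axes exist but before the final validity check
  obj@constraints <- lapply(constraints, function(ct) {
    if (is.character(ct)) parseConstraint(ct, obj) else ct
  })
  methods::validObject(obj)
  obj
}

#' Axis accessors for dietary scenarios
#'
#' @param x a \linkS4class{DietaryScenario}.
#' @param value for the replacement form, a list of
#'   \linkS4class{Constraint} objects or constraint strings.
#' @return \code{foodGroups}, \code{foodFractions}, \code{dietaryProxies} and
#'   \code{bulkFractions} return character vectors; \code{scenarioConstraints}
#'   returns the list of parsed constraints.
#' @rdname foodGroups
#' @export
setMethod("foodGroups", "DietaryScenario", function(x) x@groups)

#' @rdname foodGroups
#' @export
setMethod("foodFractions", "DietaryScenario", function(x) x@fractions)

#' @rdname foodGroups
#' @export
setMethod("dietaryProxies", "DietaryScenario", function(x) x@proxies)

#' @rdname foodGroups
#' @export
setMethod("bulkFractions", "DietaryScenario", function(x) x@bulkFractions)

#' @rdname foodGroups
#' @export
setMethod("scenarioConstraints", "DietaryScenario", function(x) x@constraints)

#' @rdname foodGroups
#' @export
setReplaceMethod("scenarioConstraints", "DietaryScenario", function(x, value) {
  x@constraints <- lapply(value, function(ct) {
    if (is.character(ct)) parseConstraint(ct, x) else ct
  })
  methods::validObject(x)
  x
})

setMethod("show", "DietaryScenario", function(object) {
  cat("DietaryScenario:",
      length(object@groups), "food groups x",
      length(object@fractions), "fractions x",
      length(object@proxies), "proxies\n")
  cat("  groups:   ", paste(object@groups, collapse = ", "), "\n")
  cat("  fractions:", paste(object@fractions, collapse = ", "))
  if (length(object@bulkFractions))
    cat(" (bulk:", paste(object@bulkFractions, collapse = ", "), ")")
  cat("\n  proxies:  ", paste(object@proxies, collapse = ", "), "\n")
  nUnc <- sum(object@signalSD[object@signalAvailable] > 0) +
    sum(object@concSD > 0) + sum(object@weightSD > 0) + sum(object@offsetSD > 0)
  cat("  uncertain latent quantities:", nUnc, "\n")
  if (length(object@constraints)) {
    cat("  constraints:\n")
    for (ct in object@constraints) cat("    ", ct@label, "\n")
  }
  invisible(NULL)
})

#' Check a dietary scenario's structural invariants
#'
#' Reports (rather than throws) every violated invariant: unique axis names,
#' non-negative sds and concentrations, routing weights summing to 100 per
#' proxy, and availability of every signal that carries positive routing
#' weight and positive concentration.
#'
#' @param scenario a \linkS4class{DietaryScenario} (possibly invalid).
#' @return character vector of human-readable violations; empty if valid.
#' @examples
#' validateScenario(builtinScenario("table1"))
#' @export
validateScenario <- function(scenario) {
  s <- scenario
  v <- character()
  for (axis in c("groups", "fractions", "proxies")) {
    nm <- slot(s, axis)
    if (anyDuplicated(nm))
      v <- c(v, sprintf("duplicate names in %s: %s", axis,
                        paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  if (length(s@groups) < 2L)
    v <- c(v, "need at least 2 food groups")
  if (length(s@fractions) < 1L || length(s@proxies) < 1L)
    v <- c(v, "need at least 1 fraction and 1 proxy")
  if (!all(s@bulkFractions %in% s@fractions))
    v <- c(v, "bulkFractions must name existing fractions")
  if (any(s@signalSD < 0) || any(s@concSD < 0) || any(s@weightSD < 0) ||
      any(s@offsetSD < 0) || any(s@consumerSD < 0, na.rm = TRUE))
    v <- c(v, "all sds must be >= 0")
  if (any(s@concMean < 0))
    v <- c(v, "concentrations must be >= 0")
  wsum <- colSums(s@weightMean)
  bad <- which(abs(wsum - 100) > 1e-9)
  for (k in bad)
    v <- c(v, sprintf("routing weights for proxy '%s' sum to %g, not 100",
                      s@proxies[k], wsum[k]))
  # a signal is needed wherever it would enter the mixture
  for (k in seq_along(s@proxies)) for (j in seq_along(s@fractions)) {
    if (s@weightMean[j, k] <= 0 && s@weightSD[j, k] <= 0) next
    need <- which(s@concMean[, j] > 0)
    miss <- need[!s@signalAvailable[need, j, k]]
    for (i in miss)
      v <- c(v, sprintf(
        "signal missing for group '%s', fraction '%s', proxy '%s' (weight %g, concentration %g)",
        s@groups[i], s@fractions[j], s@proxies[k],
        s@weightMean[j, k], s@concMean[i, j]))
  }
  for (ct in s@constraints) {
    unknown <- c(
      setdiff(names(ct@alphaCoef), s@groups),
      setdiff(names(ct@betaCoef), setdiff(s@fractions, s@bulkFractions)))
    if (length(unknown))
      v <- c(v, sprintf("constraint '%s' references unknown symbols: %s",
                        ct@label, paste(unknown, collapse = ", ")))
  }
  v
}

#' Latent state at the scenario means
#'
#' Returns the deterministic latent state in which every uncertain quantity
#' sits exactly at its stated mean: sampled signals \code{s}, concentrations
#' \code{conc}, routing weights \code{wgt} and offsets \code{delta}. This is
#' the state used for closed-form forward checks.
#'
#' @param scenario a \linkS4class{DietaryScenario}.
#' @return list with elements \code{s} (array), \code{conc}, \code{wgt}
#'   (matrices) and \code{delta} (vector), dimensioned as in the scenario.
#' @export
stateAtMeans <- function(scenario) {
  list(s = scenario@signalMean,
       conc = scenario@concMean,
       wgt = scenario@weightMean,
       delta = scenario@offsetMean)
}
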