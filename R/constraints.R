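#' Parse an algebraic prior constraint
#'
#' Accepts the field notation for expert prior knowledge on intakes, e.g.
#' \code{"Corn > Gluten"}, \code{"Protein > 5"}, \code{"Protein < 40"} or
#' \code{"A + B = 0.5"}. Symbols resolve to food-group intakes
#' (\eqn{\alpha}) or food-fraction intakes (\eqn{\beta}) of the scenario;
#' expressions are linear (sums/differences of optionally scaled symbols and
#' numeric literals). Standalone literals greater than 1 are read as
#' percentages and divided by 100 (with a notice), matching the usual
#' "Protein > 5" shorthand for 5 percent.
#'
#' Relations are canonicalized: \code{x < y} becomes \code{y - x > 0} and
#' \code{x = y} becomes \code{x - y = 0}. Equalities are later enforced as a
#' normal pseudo-observation of zero with sd \code{sigma}; inequalities as a
#' Bernoulli/Heaviside pseudo-observation of one (hard truncation, with
#' \eqn{H(0) = 1}).
#'
#' @param text a single constraint string.
#' @param scenario the \linkS4class{DietaryScenario} whose group/fraction
#'   names the symbols must resolve against (bulk pseudo-fractions cannot be
#'   referenced).
#' @param sigma pseudo-observation sd for equality constraints, on the
#'   proportion scale; should be much smaller than the uncertainties of the
#'   quantities involved (a warning is issued above 0.01).
#' @return a \linkS4class{Constraint}.
#' @examples
#' sc <- builtinScenario("hare_a")
#' parseConstraint("Corn > Gluten", sc)
#' @export
parseConstraint <- function(text, scenario, sigma = 0.001) {
  stopifnot(is.character(text), length(text) == 1L)
  groups <- scenario@groups
  fracs <- setdiff(scenario@fractions, scenario@bulkFractions)

  toks <- tokenizeConstraint(text)
  relIdx <- which(vapply(toks, function(t) t$type == "rel", logical(1)))
  if (length(relIdx) != 1L)
    stop(sprintf("constraint '%s': expected exactly one relation (>, < or =), found %d",
                 text, length(relIdx)))
  rel <- toks[[relIdx]]$value
  lhs <- parseLinear(toks[seq_len(relIdx - 1L)], text)
  rhsToks <- if (relIdx < length(toks)) toks[(relIdx + 1L):length(toks)] else list()
  rhs <- parseLinear(rhsToks, text)

  # canonical form g ? 0 with ? in {">", "="}
  g <- if (rel == "<") subtractLinear(rhs, lhs) else subtractLinear(lhs, rhs)
  relation <- if (rel == "=") "eq" else "gt"

  aCoef <- bCoef <- numeric(0)
  for (sym in names(g$coef)) {
    inA <- sym %in% groups
    inB <- sym %in% fracs
    if (inA && inB)
      stop(sprintf("constraint '%s': symbol '%s' is both a group and a fraction name",
                   text, sym))
    if (!inA && !inB)
      stop(sprintf("constraint '%s': unknown symbol '%s' (position %d)",
                   text, sym, g$pos[[sym]]))
    if (inA) aCoef[sym] <- g$coef[[sym]] else bCoef[sym] <- g$coef[[sym]]
  }
  if (length(aCoef) + length(bCoef) == 0L)
    stop(sprintf("constraint '%s' references no intake symbols", text))
  if (relation == "eq" && sigma > 0.01)
    warning(sprintf(
      "constraint '%s': sigma = %g is large; equality pseudo-observations should use a sd much smaller than the reported uncertainties",
      text, sigma))
  new("Constraint", label = text, alphaCoef = aCoef, betaCoef = bCoef,
      constant = g$const, relation = relation, sigma = sigma)
}

tokenizeConstraint <- function(text) {
  toks <- list()
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    rest <- substr(text, i, n)
    if (ch %in% c(">", "<", "=")) {
      toks[[length(toks) + 1L]] <- list(type = "rel", value = ch, pos = i)
      i <- i + 1L
    } else if (ch %in% c("+", "-", "*")) {
      toks[[length(toks) + 1L]] <- list(type = "op", value = ch, pos = i)
      i <- i + 1L
    } else if (grepl("^[0-9.]", ch)) {
      m <- regmatches(rest, regexpr("^[0-9]*\\.?[0-9]+", rest))
      toks[[length(toks) + 1L]] <-
        list(type = "num", value = as.numeric(m), pos = i)
      i <- i + nchar(m)
    } else if (grepl("^[A-Za-z_]", ch)) {
      m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_.]*", rest))
      toks[[length(toks) + 1L]] <- list(type = "sym", value = m, pos = i)
      i <- i + nchar(m)
    } else {
      stop(sprintf("constraint '%s': unexpected character '%s' at position %d",
                   text, ch, i))
    }
  }
  if (!length(toks)) stop("empty constraint")
  toks
}

# parse a sum of terms; each term is [num '*'] sym | sym | num.
# standalone literals > 1 are percentages.
parseLinear <- function(toks, text) {
  if (!length(toks))
    stop(sprintf("constraint '%s': empty expression side", text))
  coef <- list(); pos <- list(); const <- 0
  sign <- 1; i <- 1L
  expectTerm <- TRUE
  while (i <= length(toks)) {
    t <- toks[[i]]
    if (t$type == "op" && t$value %in% c("+", "-")) {
      if (expectTerm && t$value == "-") { sign <- -sign; i <- i + 1L; next }
      if (expectTerm)
        stop(sprintf("constraint '%s': unexpected '+' at position %d", text, t$pos))
      sign <- if (t$value == "-") -1 else 1
      i <- i + 1L; expectTerm <- TRUE; next
    }
    if (!expectTerm)
      stop(sprintf("constraint '%s': expected '+' or '-' at position %d", text, t$pos))
    if (t$type == "num") {
      # coefficient (num * sym) or standalone literal
      if (i + 1L <= length(toks) && toks[[i + 1L]]$type == "op" &&
          toks[[i + 1L]]$value == "*") {
        if (i + 2L > length(toks) || toks[[i + 2L]]$type != "sym")
          stop(sprintf("constraint '%s': expected symbol after '*' at position %d",
                       text, toks[[i + 1L]]$pos))
        sym <- toks[[i + 2L]]$value
        coef[[sym]] <- (coef[[sym]] %||% 0) + sign * t$value
        pos[[sym]] <- toks[[i + 2L]]$pos
        i <- i + 3L
      } else {
        val <- t$value
        if (val > 1) {
          message(sprintf("constraint literal %g read as %g%% = %g", val, val, val / 100))
          val <- val / 100
        }
        const <- const + sign * val
        i <- i + 1L
      }
    } else if (t$type == "sym") {
      coef[[t$value]] <- (coef[[t$value]] %||% 0) + sign
      pos[[t$value]] <- t$pos
      i <- i + 1L
    } else {
      stop(sprintf("constraint '%s': unexpected token at position %d", text, t$pos))
    }
    sign <- 1; expectTerm <- FALSE
  }
  if (expectTerm)
    stop(sprintf("constraint '%s': expression ends with an operator", text))
  list(coef = unlist(coef) %||% numeric(0), pos = pos, const = const)
}

subtractLinear <- function(a, b) {
  syms <- union(names(a$coef), names(b$coef))
  coef <- stats::setNames(numeric(length(syms)), syms)
  coef[names(a$coef)] <- coef[names(a$coef)] + a$coef
  coef[names(b$coef)] <- coef[names(b$coef)] - b$coef
  coef <- coef[coef != 0]
  list(coef = coef, pos = c(a$pos, b$pos)[names(coef)],
       const = a$const - b$const)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Log-likelihood contribution of a constraint
#'
#' Evaluates the pseudo-observation likelihood of a constraint at given
#' intake proportions: for an equality the log-density of observing zero
#' under Normal(g, sigma); for an inequality 0 when \eqn{g \ge 0} (the
#' Heaviside indicator is satisfied, with \eqn{H(0) = 1}) and \code{-Inf}
#' otherwise.
#'
#' @param constraint a \linkS4class{Constraint}.
#' @param alpha named numeric simplex of group intakes.
#' @param beta named numeric vector of fraction intakes (may be omitted when
#'   the constraint references no fractions).
#' @return a single numeric log-likelihood term.
#' @export
constraintLogTerm <- function(constraint, alpha, beta = NULL) {
  g <- evalConstraint(constraint, alpha, beta)
  if (constraint@relation == "eq")
    stats::dnorm(0, mean = g, sd = constraint@sigma, log = TRUE)
  else if (g >= 0) 0 else -Inf
}

evalConstraint <- function(constraint, alpha, beta = NULL) {
  g <- constraint@constant
  if (length(constraint@alphaCoef)) {
    a <- alpha[names(constraint@alphaCoef)]
    if (anyNA(a)) stop("alpha is missing named entries used by the constraint")
    g <- g + sum(constraint@alphaCoef * a)
  }
  if (length(constraint@betaCoef)) {
    if (is.null(beta)) stop("constraint references fraction intakes but no beta given")
    b <- beta[names(constraint@betaCoef)]
    if (anyNA(b)) stop("beta is missing named entries used by the constraint")
    g <- g + sum(constraint@betaCoef * b)
  }
  unname(g)
}

setMethod("show", "Constraint", function(object) {
  terms <- c(
    sprintf("%+g*alpha[%s]", object@alphaCoef, names(object@alphaCoef)),
    sprintf("%+g*beta[%s]", object@betaCoef, names(object@betaCoef)),
    if (object@constant != 0) sprintf("%+g", object@constant))
  cat("Constraint: ", paste(terms, collapse = " "),
      if (object@relation == "eq") sprintf(" = 0  (sigma = %g)", object@sigma)
      else " > 0", "\n", sep = "")
  cat("  from: ", object@label, "\n", sep = "")
  invisible(NULL)
})
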