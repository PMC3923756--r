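#' Packaged example dietary scenarios
#'
#' Two classic test beds for routed mixing models, built from printed
#' reference tables:
#' \describe{
#'   \item{\code{table1}}{a simulated, non-routed protein scenario: three
#'     food groups (Plant/Animal/Fish) with fixed protein delta-15N of
#'     2/6/10 per mil, one fraction, one proxy, diet-to-tissue offset fixed
#'     at 3 per mil, and a consumer measured at 6.6 +/- 0.2 per mil — the
#'     value implied by a true intake of 70/20/10 percent.}
#'   \item{\code{hare_a}, \code{hare_b}, \code{hare_c}}{a controlled pig
#'     feeding experiment: five feeds (Soybean meal, Barley grain, Alfalfa,
#'     Ground corn, Corn gluten meal; true intake Corn 69 / Gluten 31
#'     percent), three fractions (a Bulk pseudo-fraction plus Protein and
#'     Energy) and three proxies (collagen delta-13C, collagen delta-15N,
#'     collagen-glutamate delta-13C). Collagen delta-13C is routed 74 +/- 4
#'     percent from dietary protein and 26 percent from energy; glutamate
#'     delta-13C tracks the scrambled bulk diet. Variant \code{b} adds the
#'     prior constraint \code{"Corn > Gluten"}; variant \code{c} instead
#'     bounds protein intake to 5-40 percent of total macronutrients.}
#' }
#' Concentrations are carbon dry-weight percentages (wtC) with a
#' conservative absolute sd of 2.5; the Bulk concentration is the summed
#' macronutrient carbon of each feed.
#'
#' @param name one of \code{"table1"}, \code{"hare_a"}, \code{"hare_b"},
#'   \code{"hare_c"}.
#' @return a validated \linkS4class{DietaryScenario}.
#' @examples
#' builtinScenario("hare_b")
#' @export
builtinScenario <- function(name = c("table1", "hare_a", "hare_b", "hare_c")) {
  name <- match.arg(name)
  if (name == "table1") {
    return(dietaryScenario(
      groups = c("Plant", "Animal", "Fish"),
      fractions = "Protein",
      proxies = "d15N",
      signalMean = array(c(2, 6, 10), c(3, 1, 1)),
      concMean = matrix(100, 3, 1),
      weightMean = matrix(100, 1, 1),
      offsetMean = 3,
      consumerMean = 6.6, consumerSD = 0.2))
  }

  groups <- c("Soybean", "Barley", "Alfalfa", "Corn", "Gluten")
  fractions <- c("Bulk", "Protein", "Energy")
  proxies <- c("13Ccoll", "15Ncoll", "13Cglu")
  nI <- 5L; nJ <- 3L; nK <- 3L

  sm <- array(NA_real_, c(nI, nJ, nK),
              dimnames = list(groups, fractions, proxies))
  ss <- array(0, c(nI, nJ, nK), dimnames = dimnames(sm))
  sm[, "Protein", "13Ccoll"] <- c(-26.0, -27.3, -28.0, -13.3, -15.2)
  ss[, "Protein", "13Ccoll"] <- 0.9
  sm[, "Energy", "13Ccoll"] <- c(-23.5, -24.8, -25.5, -10.8, -12.7)
  ss[, "Energy", "13Ccoll"] <- 0.9
  sm[, "Protein", "15Ncoll"] <- c(-0.1, 2.6, 0.7, 6.3, 3.0)
  ss[, "Protein", "15Ncoll"] <- 0.5
  sm[, "Bulk", "13Cglu"] <- c(-24.0, -25.3, -26.0, -11.3, -13.2)
  ss[, "Bulk", "13Cglu"] <- 0.5

  protC <- c(32, 8, 16, 6, 38)
  lipC <- c(1, 2, 4, 4, 2)
  carbC <- c(17, 36, 29, 37, 11)
  energyC <- c(18, 38, 33, 41, 13)
  conc <- cbind(Bulk = protC + lipC + carbC, Protein = protC, Energy = energyC)
  concSD <- matrix(2.5, nI, nJ, dimnames = dimnames(conc))

  wm <- rbind(`13Ccoll` = c(0, 74, 26),
              `15Ncoll` = c(0, 100, 0),
              `13Cglu` = c(100, 0, 0))
  wm <- t(wm); dimnames(wm) <- list(fractions, proxies)
  ws <- matrix(0, nJ, nK, dimnames = dimnames(wm))
  ws["Protein", "13Ccoll"] <- 4

  constraints <- switch(name,
    hare_a = list(),
    hare_b = list("Corn > Gluten"),
    hare_c = list("Protein > 5", "Protein < 40"))

  suppressMessages(dietaryScenario(
    groups = groups, fractions = fractions, proxies = proxies,
    signalMean = sm, signalSD = ss,
    concMean = conc, concSD = concSD,
    weightMean = wm, weightSD = ws,
    offsetMean = c(4.8, 3.6, 9.2), offsetSD = c(0.5, 1.2, 1.8),
    consumerMean = c(-9.2, 5.5, -5.5), consumerSD = c(0.5, 0.5, 0.5),
    bulkFractions = "Bulk",
    constraints = constraints))
}

#' Carbon bookkeeping for macronutrient composition tables
#'
#' \code{macronutrientCarbonContent} returns the reference carbon content
#' (percent by mass) of the macronutrients: protein 52.4, carbohydrates
#' 44.4, lipids 76.8. \code{carbonWeight} converts dry-weight percentages
#' of a fraction into carbon dry-weight percentages (wtC), optionally
#' rounded to integers as composition tables conventionally print them.
#' \code{energyToCarbonRatio} converts a caloric density (kcal/g) and a
#' carbon content into kcal per gram of carbon — the quantity that lets a
#' recommended caloric protein share be re-expressed as a share of
#' macronutrient carbon (approximately 9.0, 7.6 and 11.7 kcal/gC for
#' carbohydrates, protein and lipids, which is similar enough that caloric
#' and carbon shares are interchangeable at a conservative tolerance).
#'
#' @param wtPercent dry-weight percent of the fraction in the food.
#' @param carbonPercent carbon content of the fraction (percent by mass).
#' @param digits rounding for the result; \code{NULL} for full precision.
#' @param kcalPerGram caloric density of the macronutrient.
#' @return numeric vector.
#' @examples
#' carbonWeight(c(62, 15, 30, 12, 72), macronutrientCarbonContent()["protein"])
#' energyToCarbonRatio(4, 44.4)  # carbohydrates: 9.0 kcal/gC
#' @export
macronutrientCarbonContent <- function() {
  c(protein = 52.4, carbohydrates = 44.4, lipids = 76.8)
}

#' @rdname macronutrientCarbonContent
#' @export
carbonWeight <- function(wtPercent, carbonPercent, digits = 0) {
  out <- wtPercent * carbonPercent / 100
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' @rdname macronutrientCarbonContent
#' @export
energyToCarbonRatio <- function(kcalPerGram, carbonPercent, digits = 1) {
  out <- kcalPerGram / (carbonPercent / 100)
  if (!is.null(digits)) out <- round(out, digits)
  out
}
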