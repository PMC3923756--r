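#' Read and write dietary scenarios as plain text tables
#'
#' A scenario lives in a directory of delimiter-separated files, one per
#' role, mirroring how such data are conventionally tabulated:
#' \itemize{
#'   \item \code{scenario.yml} — axes (\code{groups}, \code{fractions},
#'     \code{proxies}), optional \code{bulk_fractions} and a list of
#'     \code{constraints} strings;
#'   \item \code{signals.tsv} — columns \code{group}, \code{fraction}, then
#'     one column per proxy;
#'   \item \code{concentrations.tsv} — column \code{group}, then one column
#'     per fraction;
#'   \item \code{weights.tsv} — column \code{proxy}, then one column per
#'     fraction;
#'   \item \code{offsets.tsv} — columns \code{proxy}, \code{offset};
#'   \item \code{consumer.tsv} — columns \code{proxy}, \code{signal}.
#' }
#' Cells are written \code{"mean(sd)"}; \code{"(-)"} or a bare number means
#' the uncertainty is negligible (sd 0), and a lone dash means the signal is
#' unavailable (no contribution). The scenario is validated on read and a
#' violation aborts with the offending rules listed.
#'
#' @param dir directory containing (or to receive) the scenario files.
#' @param scenario a \linkS4class{DietaryScenario} to write.
#' @return \code{readScenario}: a validated \linkS4class{DietaryScenario};
#'   \code{writeScenario}: \code{dir}, invisibly.
#' @examples
#' d <- file.path(tempdir(), "table1")
#' writeScenario(builtinScenario("table1"), d)
#' readScenario(d)
#' @export
readScenario <- function(dir) {
  need <- c("scenario.yml", "signals.tsv", "concentrations.tsv",
            "weights.tsv", "offsets.tsv", "consumer.tsv")
  paths <- file.path(dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing))
    stop("scenario directory ", dir, " is missing: ",
         paste(missing, collapse = ", "))
  cfg <- yaml::read_yaml(paths[1L])
  for (ax in c("groups", "fractions", "proxies"))
    if (is.null(cfg[[ax]])) stop("scenario.yml lacks '", ax, "'")
  groups <- as.character(cfg$groups)
  fractions <- as.character(cfg$fractions)
  proxies <- as.character(cfg$proxies)

  readTab <- function(p) utils::read.delim(p, check.names = FALSE,
                                           colClasses = "character")
  sig <- readTab(paths[2L])
  conc <- readTab(paths[3L])
  wgt <- readTab(paths[4L])
  off <- readTab(paths[5L])
  cons <- readTab(paths[6L])

  checkCols <- function(d, cols, file) {
    miss <- setdiff(cols, names(d))
    if (length(miss))
      stop(file, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  checkCols(sig, c("group", "fraction", proxies), "signals.tsv")
  checkCols(conc, c("group", fractions), "concentrations.tsv")
  checkCols(wgt, c("proxy", fractions), "weights.tsv")
  checkCols(off, c("proxy", "offset"), "offsets.tsv")
  checkCols(cons, c("proxy", "signal"), "consumer.tsv")

  nI <- length(groups); nJ <- length(fractions); nK <- length(proxies)
  sm <- array(NA_real_, c(nI, nJ, nK))
  ss <- array(0, c(nI, nJ, nK))
  for (r in seq_len(nrow(sig))) {
    i <- match(sig$group[r], groups)
    j <- match(sig$fraction[r], fractions)
    if (is.na(i) || is.na(j))
      stop(sprintf("signals.tsv row %d: unknown group '%s' or fraction '%s'",
                   r, sig$group[r], sig$fraction[r]))
    for (k in seq_len(nK)) {
      cell <- parseCell(sig[[proxies[k]]][r],
                        sprintf("signals.tsv row %d, proxy %s", r, proxies[k]))
      sm[i, j, k] <- cell$mean
      ss[i, j, k] <- cell$sd
    }
  }

  cm <- matrix(0, nI, nJ); cs <- matrix(0, nI, nJ)
  for (r in seq_len(nrow(conc))) {
    i <- match(conc$group[r], groups)
    if (is.na(i)) stop("concentrations.tsv: unknown group '", conc$group[r], "'")
    for (j in seq_len(nJ)) {
      cell <- parseCell(conc[[fractions[j]]][r],
                        sprintf("concentrations.tsv group %s", conc$group[r]),
                        required = TRUE)
      cm[i, j] <- cell$mean; cs[i, j] <- cell$sd
    }
  }

  wm <- matrix(0, nJ, nK); wsd <- matrix(0, nJ, nK)
  for (r in seq_len(nrow(wgt))) {
    k <- match(wgt$proxy[r], proxies)
    if (is.na(k)) stop("weights.tsv: unknown proxy '", wgt$proxy[r], "'")
    for (j in seq_len(nJ)) {
      cell <- parseCell(wgt[[fractions[j]]][r],
                        sprintf("weights.tsv proxy %s", wgt$proxy[r]),
                        required = TRUE)
      wm[j, k] <- cell$mean; wsd[j, k] <- cell$sd
    }
  }

  readK <- function(d, col, file) {
    m <- s <- stats::setNames(numeric(nK), proxies)
    for (r in seq_len(nrow(d))) {
      k <- match(d$proxy[r], proxies)
      if (is.na(k)) stop(file, ": unknown proxy '", d$proxy[r], "'")
      cell <- parseCell(d[[col]][r], sprintf("%s proxy %s", file, d$proxy[r]),
                        required = TRUE)
      m[k] <- cell$mean; s[k] <- cell$sd
    }
    list(mean = m, sd = s)
  }
  offv <- readK(off, "offset", "offsets.tsv")
  consv <- readK(cons, "signal", "consumer.tsv")

  sc <- try(dietaryScenario(
    groups = groups, fractions = fractions, proxies = proxies,
    signalMean = sm, signalSD = ss,
    concMean = cm, concSD = cs,
    weightMean = wm, weightSD = wsd,
    offsetMean = offv$mean, offsetSD = offv$sd,
    consumerMean = consv$mean, consumerSD = consv$sd,
    bulkFractions = as.character(cfg$bulk_fractions %||% character()),
    constraints = as.list(cfg$constraints %||% list())), silent = TRUE)
  if (inherits(sc, "try-error"))
    stop("scenario in ", dir, " is invalid: ", attr(sc, "condition")$message)
  sc
}

# "mean(sd)", "mean(-)", bare number, or a dash for unavailable
parseCell <- function(x, where, required = FALSE) {
  x <- gsub("−", "-", trimws(x))  # tolerate unicode minus
  if (x %in% c("-", "–", "") || is.na(x)) {
    if (required)
      stop(where, ": value required, found '", x, "'")
    return(list(mean = NA_real_, sd = 0))
  }
  m <- regmatches(x, regexec("^(-?[0-9]*\\.?[0-9]+)(?:\\(([-–]|[0-9]*\\.?[0-9]+)\\))?$", x))[[1]]
  if (!length(m)) stop(where, ": cannot parse cell '", x, "'")
  sd <- if (m[3] %in% c("", "-", "–")) 0 else as.numeric(m[3])
  if (is.na(sd) || sd < 0) stop(where, ": negative or unreadable sd in '", x, "'")
  list(mean = as.numeric(m[2]), sd = sd)
}

formatCell <- function(mean, sd, available = TRUE) {
  if (!available || is.na(mean)) return("-")
  if (sd > 0) sprintf("%.10g(%.10g)", mean, sd) else sprintf("%.10g(-)", mean)
}

#' @rdname readScenario
#' @export
writeScenario <- function(scenario, dir) {
  stopifnot(is(scenario, "DietaryScenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- scenario
  groups <- s@groups; fractions <- s@fractions; proxies <- s@proxies

  yaml::write_yaml(
    list(groups = groups, fractions = fractions, proxies = proxies,
         bulk_fractions = as.list(s@bulkFractions),
         constraints = lapply(s@constraints, function(ct) ct@label)),
    file.path(dir, "scenario.yml"))

  writeTab <- function(d, name)
    utils::write.table(d, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  sig <- expand.grid(fraction = fractions, group = groups,
                     stringsAsFactors = FALSE)[, c("group", "fraction")]
  for (k in seq_along(proxies)) {
    sig[[proxies[k]]] <- mapply(function(g, f) {
      i <- match(g, groups); j <- match(f, fractions)
      formatCell(s@signalMean[i, j, k], s@signalSD[i, j, k],
                 s@signalAvailable[i, j, k])
    }, sig$group, sig$fraction)
  }
  writeTab(sig, "signals.tsv")

  conc <- data.frame(group = groups, stringsAsFactors = FALSE)
  for (j in seq_along(fractions))
    conc[[fractions[j]]] <- mapply(formatCell, s@concMean[, j], s@concSD[, j])
  writeTab(conc, "concentrations.tsv")

  wgt <- data.frame(proxy = proxies, stringsAsFactors = FALSE)
  for (j in seq_along(fractions))
    wgt[[fractions[j]]] <- mapply(formatCell, s@weightMean[j, ], s@weightSD[j, ])
  writeTab(wgt, "weights.tsv")

  writeTab(data.frame(proxy = proxies,
                      offset = mapply(formatCell, s@offsetMean, s@offsetSD)),
           "offsets.tsv")
  writeTab(data.frame(proxy = proxies,
                      signal = mapply(formatCell, s@consumerMean, s@consumerSD)),
           "consumer.tsv")
  invisible(dir)
}

#' Write a posterior report to disk
#'
#' Emits three files: \code{summary.tsv} (per-parameter mean, median, sd,
#' percentiles and diagnostics, full precision), \code{draws.tsv} (the raw
#' thinned draws with \code{chain} and \code{iteration} columns) and
#' \code{manifest.json} (seed, sampler configuration, a scenario content
#' hash, and a diagnostics digest), so that a run can be reproduced and
#' audited.
#'
#' @param chains a \linkS4class{PosteriorChains}.
#' @param scenario the \linkS4class{DietaryScenario} that produced it.
#' @param dir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
writeReport <- function(chains, scenario, dir) {
  stopifnot(is(chains, "PosteriorChains"), is(scenario, "DietaryScenario"))
  if (nDraws(chains) == 0L) stop("no draws to report")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  sm <- summarizePosterior(chains)
  utils::write.table(sm, file.path(dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  draws <- do.call(rbind, lapply(seq_along(chains@draws), function(ch)
    cbind(chain = ch, iteration = seq_len(nrow(chains@draws[[ch]])),
          chains@draws[[ch]])))
  utils::write.table(draws, file.path(dir, "draws.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  diag <- diagnoseChains(chains)
  manifest <- list(
    package = as.character(utils::packageVersion("routedmix")),
    seed = chains@config$seed,
    config = chains@config[c("nChains", "nIterations", "burnIn", "thin")],
    scenarioHash = scenarioHash(scenario),
    maxRhat = max(diag$rhat, na.rm = TRUE),
    minEss = min(diag$ess, na.rm = TRUE),
    flaggedParameters = diag$parameter[diag$flagged])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, c("summary.tsv", "draws.tsv", "manifest.json")))
}

#' Content hash of a scenario
#'
#' md5 of the scenario's canonical text serialization; identical scenarios
#' hash identically regardless of how they were constructed.
#'
#' @param scenario a \linkS4class{DietaryScenario}.
#' @return a character md5 digest.
#' @export
scenarioHash <- function(scenario) {
  tmp <- file.path(tempdir(), paste0("scenario-hash-", Sys.getpid()))
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  writeScenario(scenario, tmp)
  files <- sort(list.files(tmp, full.names = TRUE))
  combined <- tempfile()
  on.exit(unlink(combined), add = TRUE)
  writeLines(unlist(lapply(files, readLines)), combined)
  unname(tools::md5sum(combined))
}
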