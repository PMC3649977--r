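## The three type I/II distinguishing properties, cell-line classification,
## and consistency scoring against the observed truth table.

#' Thresholds and horizons of the three apoptosis properties
#'
#' @param alpha PARP-cleavage "alive" threshold: a cell is alive while the
#'   cleaved-PARP fraction is below \code{alpha} (default 0.5).
#' @param beta Apaf-1 MOMP threshold: MOMP has happened once the free-Apaf-1
#'   fraction falls below \code{beta} (default 0.5).
#' @param gamma caspase-activity threshold as a fraction of the total caspase
#'   pool (default 0.01, i.e. 1\%).
#' @param delay caspase-separation delay in hours: activations are sequential
#'   when separated by more than \code{delay} (default 1).
#' @param horizon observation horizon in hours (default 6).
#' @return a validated list of class \code{"PropertySpec"}.
#' @export
propertySpec <- function(alpha = 0.5, beta = 0.5, gamma = 0.01, delay = 1,
                         horizon = 6) {
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1, gamma > 0, gamma < 1,
            delay > 0, horizon > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delay = delay,
                 horizon = horizon), class = "PropertySpec")
}

#' The three type I/II distinguishing properties as STL formulas
#'
#' Property 1 (clonogenic survival): the cell stays alive throughout the
#' horizon, \code{alw[0,horizon](cPARP_frac < alpha)}. Property 2 (sequential
#' caspase activation): at some time caspase-8 is active while caspase-3
#' stays inactive for the following \code{delay} hours,
#' \code{ev(C8act_frac > gamma and alw[0,delay] not (C3act_frac > gamma))}.
#' Property 3 (MOMP-gated death): the cell remains alive until MOMP happens,
#' \code{(Apaf_free_frac < beta) release (cPARP_frac < alpha)}.
#'
#' @param spec a [propertySpec()].
#' @return an [STLFormula-class].
#' @examples
#' formatFormula(makeP1(propertySpec()))
#' @export
makeP1 <- function(spec = propertySpec()) {
  stlAlw(stlPred("cPARP_frac", "<", spec$alpha), c(0, spec$horizon))
}
#' @rdname makeP1
#' @export
makeP2 <- function(spec = propertySpec()) {
  stlEv(stlAnd(stlPred("C8act_frac", ">", spec$gamma),
               stlAlw(stlNot(stlPred("C3act_frac", ">", spec$gamma)),
                      c(0, spec$delay))))
}
#' @rdname makeP1
#' @export
makeP3 <- function(spec = propertySpec()) {
  stlRelease(stlPred("Apaf_free_frac", "<", spec$beta),
             stlPred("cPARP_frac", "<", spec$alpha))
}

#' @rdname makeP1
#' @param id property id, \code{"P1"}, \code{"P2"} or \code{"P3"}.
#' @export
makeProperty <- function(id, spec = propertySpec()) {
  switch(id, P1 = makeP1(spec), P2 = makeP2(spec), P3 = makeP3(spec),
         stop("unknown property id '", id, "'", call. = FALSE))
}

## ---- observation table -----------------------------------------------------

#' The observed property truth table
#'
#' Loads the bundled observed truth values of Properties 1-3 for the twelve
#' cell lines. The HCT116 and SKW6.4 families contribute exactly 16 scoreable
#' (non-NA, non-mixed) entries; the T47D family showed ambiguous, mixed
#' phenotypes and is excluded from consistency scoring. The observed value of
#' Property 2 for parental SKW6.4 is recorded as false (synchronous caspase
#' activation), as reported in the primary description of that experiment;
#' the provenance column documents a conflicting secondary tabulation.
#'
#' @param path CSV file (columns \code{line}, \code{property}, \code{value},
#'   \code{provenance}); defaults to the bundled table.
#' @return data.frame of class \code{"ObservationTable"}.
#' @export
observationTable <- function(path = system.file("extdata",
                                                "observed_properties.csv",
                                                package = "apopSTL")) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = character(0))
  need <- c("line", "property", "value")
  if (!all(need %in% names(obs)))
    stop("observation table needs columns line, property, value",
         call. = FALSE)
  ok <- c("true", "false", "mixed", "NA")
  if (any(!obs$value %in% ok))
    stop("observation values must be one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  class(obs) <- c("ObservationTable", "data.frame")
  obs
}

#' Scoreable entries of an observation table
#'
#' @param obs an [observationTable()].
#' @return the subset with a definite true/false observation (non-NA,
#'   non-mixed), as a data.frame with a logical \code{observed} column.
#' @export
scoreableEntries <- function(obs) {
  keep <- obs$value %in% c("true", "false")
  out <- obs[keep, c("line", "property", "value")]
  out$observed <- out$value == "true"
  rownames(out) <- NULL
  out
}

## ---- classification and scoring -------------------------------------------

#' Simulate cell lines once and cache the traces
#'
#' @param net a [ReactionNetwork-class].
#' @param lines named list of [CellLine-class] objects.
#' @param trailDose ligand dose (ng/ml).
#' @param horizon,gridStep simulation grid (hours).
#' @param paramOverrides optional named parameter overrides.
#' @return named list of [TimedTrace-class] objects.
#' @export
simulateLines <- function(net, lines, trailDose = 50, horizon = 6,
                          gridStep = 1 / 60, paramOverrides = NULL) {
  lapply(lines, function(ln)
    simulateNetwork(net, ln, trailDose = trailDose, horizon = horizon,
                    gridStep = gridStep, paramOverrides = paramOverrides))
}

#' Classify a cell line by the three properties
#'
#' Simulates the nominal cell of a line and evaluates the robustness of
#' Properties 1-3 at time 0.
#'
#' @inheritParams simulateLines
#' @param line a [CellLine-class].
#' @param spec a [propertySpec()].
#' @param ... passed to [simulateNetwork()].
#' @return named numeric vector \code{c(P1=, P2=, P3=)} of robustness values.
#' @export
classifyLine <- function(net, line, spec = propertySpec(), trailDose = 50,
                         ...) {
  tr <- simulateNetwork(net, line, trailDose = trailDose,
                        horizon = spec$horizon, ...)
  vapply(c(P1 = "P1", P2 = "P2", P3 = "P3"), function(id)
    robustnessAt(makeProperty(id, spec), tr, 0), numeric(1))
}

## robustness of P1-P3 on cached traces -> long prediction table
.predictFromTraces <- function(traces, spec) {
  out <- do.call(rbind, lapply(names(traces), function(nm) {
    rho <- vapply(c("P1", "P2", "P3"), function(id)
      robustnessAt(makeProperty(id, spec), traces[[nm]], 0), numeric(1))
    data.frame(line = nm, property = names(rho), robustness = unname(rho),
               stringsAsFactors = FALSE)
  }))
  out$satisfied <- out$robustness > 0
  rownames(out) <- NULL
  out
}

#' Property predictions for a set of cell lines
#'
#' @inheritParams simulateLines
#' @param spec a [propertySpec()].
#' @return data.frame with columns \code{line}, \code{property},
#'   \code{robustness}, \code{satisfied} (one row per line and property).
#' @export
classifyLines <- function(net, lines, spec = propertySpec(), trailDose = 50,
                          gridStep = 1 / 60, paramOverrides = NULL) {
  traces <- simulateLines(net, lines, trailDose = trailDose,
                          horizon = spec$horizon, gridStep = gridStep,
                          paramOverrides = paramOverrides)
  .predictFromTraces(traces, spec)
}

#' Count matches between predictions and observations
#'
#' Scores predicted satisfaction against the scoreable (non-NA, non-mixed)
#' entries of the observation table. Full consistency corresponds to a match
#' on every scoreable entry.
#'
#' @param predictions data.frame with columns \code{line}, \code{property}
#'   and \code{satisfied} (as from [classifyLines()]).
#' @param obs an [observationTable()].
#' @return list with \code{nMatch}, \code{nScoreable} and \code{mismatches}
#'   (data.frame of mismatching \code{line}, \code{property} pairs).
#' @examples
#' \donttest{
#' net <- buildEarm()
#' pred <- classifyLines(net, earmCellLines(net))
#' countMatches(pred, observationTable())$mismatches
#' }
#' @export
countMatches <- function(predictions, obs) {
  sc <- scoreableEntries(obs)
  key <- paste(predictions$line, predictions$property)
  idx <- match(paste(sc$line, sc$property), key)
  if (anyNA(idx))
    stop("missing prediction for observed entries: ",
         paste(paste(sc$line, sc$property)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  hit <- predictions$satisfied[idx] == sc$observed
  list(nMatch = sum(hit), nScoreable = nrow(sc),
       mismatches = sc[!hit, c("line", "property")])
}

#' Match counts over a grid of property thresholds
#'
#' Re-evaluates the consistency score of [countMatches()] for every
#' combination of the PARP (\code{alpha}), Apaf (\code{beta}) and caspase
#' (\code{gamma}) thresholds. Simulations are run once per line and reused
#' across the grid (thresholds only enter the formulas, not the dynamics).
#'
#' @inheritParams simulateLines
#' @param obs an [observationTable()].
#' @param alpha,beta,gamma numeric vectors of thresholds in (0, 1).
#' @param spec base [propertySpec()] supplying delay and horizon.
#' @return data.frame with columns \code{alpha}, \code{beta}, \code{gamma},
#'   \code{nMatch}.
#' @export
thresholdSweep <- function(net, lines, obs, alpha = 0.5, beta = 0.5,
                           gamma = 0.01, spec = propertySpec(),
                           trailDose = 50, gridStep = 1 / 60,
                           paramOverrides = NULL) {
  stopifnot(all(alpha > 0 & alpha < 1), all(beta > 0 & beta < 1),
            all(gamma > 0 & gamma < 1))
  traces <- simulateLines(net, lines, trailDose = trailDose,
                          horizon = spec$horizon, gridStep = gridStep,
                          paramOverrides = paramOverrides)
  grid <- expand.grid(alpha = alpha, beta = beta, gamma = gamma,
                      KEEP.OUT.ATTRS = FALSE)
  grid$nMatch <- vapply(seq_len(nrow(grid)), function(i) {
    sp <- propertySpec(alpha = grid$alpha[i], beta = grid$beta[i],
                       gamma = grid$gamma[i], delay = spec$delay,
                       horizon = spec$horizon)
    countMatches(.predictFromTraces(traces, sp), obs)$nMatch
  }, integer(1))
  grid
}
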